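#' ERP component specification
#'
#' Describes one dipolar ERP component planted by the synthetic-study
#' generator: a Gaussian time course centred at `peak_latency`, radiated from a
#' dipole at the centroid of a source-space compartment, with a per-condition
#' dipole amplitude.
#'
#' Conditions are ordered `intra.match`, `intra.mismatch`, `cross.match`,
#' `cross.mismatch` (factor TASK crossed with factor MATCH).
#'
#' @param name component label, e.g. `"N170"`.
#' @param peak_latency peak time in ms post-stimulus.
#' @param width Gaussian standard deviation of the time course in ms (> 0).
#' @param amplitude numeric length 4: dipole moment in nA.m for each condition
#'   in the order above (a single value is recycled to all four).
#' @param compartment compartment name or integer label of the source-space
#'   atlas hosting the dipole.
#' @param polarity +1 or -1; sign applied to the time course (negative for the
#'   N components).
#' @param orientation `"radial"` (default) or a 3-vector dipole orientation
#'   (normalised internally).
#' @return Object of class `component_spec`.
#' @export
component_spec <- function(name, peak_latency, width, amplitude, compartment,
                           polarity = -1, orientation = "radial") {
  if (length(amplitude) == 1L) amplitude <- rep(amplitude, 4L)
  stopifnot(length(amplitude) == 4L, width > 0, polarity %in% c(-1, 1))
  if (!identical(orientation, "radial")) {
    orientation <- as.numeric(orientation)
    stopifnot(length(orientation) == 3L)
    orientation <- orientation / sqrt(sum(orientation^2))
  }
  structure(list(name = name, peak_latency = peak_latency, width = width,
                 amplitude = stats::setNames(as.numeric(amplitude), .cond_names),
                 compartment = compartment, polarity = polarity,
                 orientation = orientation),
            class = "component_spec")
}

.cond_names <- c("intra.match", "intra.mismatch", "cross.match", "cross.mismatch")

#' Default component set of the simulated 2x2 study
#'
#' Emulates the component structure of a face-learning matching experiment:
#' N170 in both tasks but from distinct compartments, P200 and N250 only in the
#' intra-domain (face) task, and a 330-440 ms N400-like mismatch effect with a
#' task-specific source compartment per task.  Dipole moments are scaled so
#' that scalp peaks fall in the physiological few-microvolt range.
#'
#' @param compartments named integer/character vector assigning a source
#'   compartment to each of `n170_intra`, `n170_cross`, `p200`, `n250`,
#'   `n400_intra`, `n400_cross`.
#' @return list of [component_spec()] objects.
#' @export
default_components <- function(compartments = c(n170_intra = 1, n170_cross = 2,
                                                p200 = 3, n250 = 4,
                                                n400_intra = 5, n400_cross = 6)) {
  stopifnot(length(compartments) == 6L)
  if (is.null(names(compartments)) || !all(nzchar(names(compartments))))
    names(compartments) <- c("n170_intra", "n170_cross", "p200", "n250",
                             "n400_intra", "n400_cross")
  both <- function(intra, cross) c(intra, intra, cross, cross)
  mm <- function(task) {          # mismatch-dominant amplitude pattern
    if (task == "intra") c(2, 5, 0, 0) else c(0, 0, 2, 5)
  }
  list(
    component_spec("N170", 170, 18, both(6, 0), compartments[["n170_intra"]],
                   polarity = -1),
    component_spec("N170", 170, 18, both(0, 6), compartments[["n170_cross"]],
                   polarity = -1),
    component_spec("P200", 200, 20, both(5, 0), compartments[["p200"]],
                   polarity = +1),
    component_spec("N250", 270, 22, both(4, 0), compartments[["n250"]],
                   polarity = -1),
    component_spec("N400", 385, 45, mm("intra"), compartments[["n400_intra"]],
                   polarity = -1),
    component_spec("N400", 385, 45, mm("cross"), compartments[["n400_cross"]],
                   polarity = -1))
}
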