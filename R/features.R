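#' Feature specifications for source reconstruction
#'
#' A *window* feature averages each channel over a fixed latency interval
#' (inclusive bounds), identically for all subjects.  A *peak* feature first
#' locates, per subject, the extremum of the requested polarity of the mean
#' signal over a channel group inside a search window, then samples all
#' channels at that subject-specific latency.
#'
#' @param from,to window bounds in ms (inclusive).
#' @param condition condition label (see `erp_set`) the feature is taken from.
#' @return A `feature_spec` object.
#' @export
feature_window <- function(from, to, condition = "intra.mismatch") {
  stopifnot(from < to)
  structure(list(kind = "window", from = from, to = to, condition = condition),
            class = "feature_spec")
}

#' @rdname feature_window
#' @param name component label (e.g. `"N170"`).
#' @param polarity -1 for a negative peak, +1 for a positive one.
#' @param search search window in ms, length 2.
#' @param channels channel labels whose mean defines the peak; `NULL` uses all.
#' @export
feature_peak <- function(name, polarity, search, channels = NULL,
                         condition = "intra.mismatch") {
  stopifnot(length(search) == 2L, search[1] < search[2], polarity %in% c(-1, 1))
  structure(list(kind = "peak", name = name, polarity = polarity,
                 search = search, channels = channels, condition = condition),
            class = "feature_spec")
}

## posterior channel group used by the default peak specs
.posterior_channels <- function(channels)
  grep("^(P|PO|O|TP)[0-9z]", channels, value = TRUE)

#' Default peak feature specs for the face-sensitive components
#'
#' N170: most negative deflection 130-200 ms; P200: most positive 180-250 ms;
#' N250: most negative 230-310 ms — all defined on the posterior channel
#' group.  These windows are package defaults, configurable per call.
#'
#' @param channels montage channel labels (posterior group is selected from
#'   them).
#' @param condition condition to measure in.
#' @return named list of `feature_spec`s.
#' @export
default_peak_specs <- function(channels, condition = "intra.mismatch") {
  post <- .posterior_channels(channels)
  list(N170 = feature_peak("N170", -1, c(130, 200), post, condition),
       P200 = feature_peak("P200", +1, c(180, 250), post, condition),
       N250 = feature_peak("N250", -1, c(230, 310), post, condition))
}

#' Extract per-subject scalp feature vectors
#'
#' @param erps an `erp_set`.
#' @param spec a `feature_spec` ([feature_window()] or [feature_peak()]).
#' @return A subjects x channels matrix of voltages (microvolts) with
#'   attributes `condition`, `spec` and, for peak features, `peak_latency`
#'   (per-subject, NA where no extremum of the required polarity exists —
#'   those subjects' rows are NA and a warning is issued).
#' @export
extract_feature <- function(erps, spec) {
  stopifnot(inherits(erps, "erp_set"), inherits(spec, "feature_spec"))
  cond <- match(spec$condition, erps$conditions)
  if (is.na(cond)) stop("unknown condition: ", spec$condition)
  ns <- dim(erps$data)[1]
  out <- matrix(NA_real_, ns, length(erps$channels),
                dimnames = list(NULL, erps$channels))
  if (spec$kind == "window") {
    sel <- which(erps$times >= spec$from & erps$times <= spec$to)
    if (!length(sel)) stop("window outside the epoch")
    for (s in seq_len(ns)) {
      block <- erps$data[s, cond, , sel, drop = FALSE]
      dim(block) <- c(length(erps$channels), length(sel))
      out[s, ] <- rowMeans(block)
    }
    attr(out, "condition") <- spec$condition
    attr(out, "spec") <- spec
    return(out)
  }
  ## peak feature
  sel <- which(erps$times >= spec$search[1] & erps$times <= spec$search[2])
  if (!length(sel)) stop("search window outside the epoch")
  chans <- if (is.null(spec$channels)) erps$channels else spec$channels
  ci <- match(chans, erps$channels)
  if (any(is.na(ci))) stop("unknown channel(s) in peak spec")
  lat <- rep(NA_real_, ns)
  for (s in seq_len(ns)) {
    block <- erps$data[s, cond, ci, , drop = FALSE]
    dim(block) <- c(length(ci), length(erps$times))
    y <- colMeans(block)
    yw <- spec$polarity * y[sel]
    k <- which.max(yw)
    ## require a local extremum of the right polarity: interior maximum of
    ## the polarity-flipped trace (window edges rejected), positive deflection
    interior <- k > 1L && k < length(sel)
    if (!interior || yw[k] <= 0) next
    lat[s] <- erps$times[sel[k]]
    out[s, ] <- erps$data[s, cond, , sel[k]]
  }
  if (anyNA(lat))
    warning(sprintf("%s: no %s peak for subject(s) %s; excluded (NA rows)",
                    spec$name, if (spec$polarity < 0) "negative" else "positive",
                    paste(which(is.na(lat)), collapse = ", ")))
  attr(out, "condition") <- spec$condition
  attr(out, "spec") <- spec
  attr(out, "peak_latency") <- lat
  out
}
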