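#' Three concentric sphere head model
#'
#' Constructs a piecewise-homogeneous volume conductor made of three concentric
#' spherical shells: brain (innermost), skull and scalp (outermost).  The scalp
#' potential generated by an intracerebral current dipole is computed from the
#' classical Legendre series solution of Poisson's equation in this geometry,
#' truncated at `n_terms` degrees (see [lead_field()]).
#'
#' The default conductivities follow the triple 0.33 / 0.022 / 0.013 assigned to
#' brain, scalp and skull respectively; the values are interpreted in S/m.  Any
#' other assignment (for example the common convention where scalp conductivity
#' equals brain conductivity and the skull is 40-80 times less conductive) can
#' be requested simply by passing different values.
#'
#' @param radii numeric length 3, shell outer radii in metres, strictly
#'   increasing: brain, skull, scalp.  Defaults are standard adult values.
#' @param conductivities numeric length 3, conductivities in S/m for the brain,
#'   skull and scalp layers (inside-out order), all positive.
#' @param n_terms integer, truncation degree of the Legendre series (>= 1).
#' @return An object of class `head_model`.
#' @examples
#' hm <- head_model()
#' hm
#' @export
head_model <- function(radii = c(0.08, 0.085, 0.092),
                       conductivities = c(brain = 0.33, skull = 0.013, scalp = 0.022),
                       n_terms = 60L) {
  radii <- as.numeric(radii)
  conductivities <- as.numeric(conductivities)
  if (length(radii) != 3L || any(!is.finite(radii)) || any(radii <= 0))
    stop("radii: three finite positive values required (brain, skull, scalp)")
  if (any(diff(radii) <= 0))
    stop("radii: must be strictly increasing (brain < skull < scalp)")
  if (length(conductivities) != 3L || any(!is.finite(conductivities)) ||
      any(conductivities <= 0))
    stop("conductivities: three finite positive values (S/m) required")
  n_terms <- as.integer(n_terms)
  if (is.na(n_terms) || n_terms < 1L) stop("n_terms: must be a positive integer")
  structure(
    list(radii = stats::setNames(radii, c("brain", "skull", "scalp")),
         conductivities = stats::setNames(conductivities,
                                          c("brain", "skull", "scalp")),
         n_terms = n_terms),
    class = "head_model")
}

#' @export
print.head_model <- function(x, ...) {
  cat("Three-sphere head model\n")
  cat(sprintf("  radii (m):          brain %.4f | skull %.4f | scalp %.4f\n",
              x$radii[1], x$radii[2], x$radii[3]))
  cat(sprintf("  conductivity (S/m): brain %.4g | skull %.4g | scalp %.4g\n",
              x$conductivities[1], x$conductivities[2], x$conductivities[3]))
  cat(sprintf("  series truncation:  %d terms\n", x$n_terms))
  invisible(x)
}
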