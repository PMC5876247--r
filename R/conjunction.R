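#' Binarize an inverse-solution map with a local-FDR mixture model
#'
#' Inverse-solution maps mix exact zeros (generators outside the supported
#' compartments) with positive magnitudes whose scale varies strongly across
#' subjects.  Binarization makes second-level analysis scale-free: exact zeros
#' are inactive by definition; the log-magnitudes of the positive generators
#' are fitted with a two-component Gaussian mixture by EM (deterministic
#' quantile-based initialisation, lower-mean component = null), the local
#' false discovery rate `lfdr(z)` is the posterior null probability at each
#' value, and a generator is active when `lfdr(z) < lfdr_threshold`.  Because
#' the whole chain acts on log-magnitudes, multiplying the map by any positive
#' constant shifts every `z` equally and leaves the binary map unchanged.
#'
#' @param magnitudes non-negative per-generator magnitudes (e.g.
#'   `coef(bma_solve(...))`).
#' @param lfdr_threshold posterior null-probability cut-off (default 0.2).
#' @param min_fit minimum number of positive magnitudes needed to fit the
#'   mixture (default 50); fewer gives an all-inactive map with a warning.
#' @return Object of class `binary_map`: logical `active` vector plus the
#'   mixture diagnostics (`null_mean`, `null_sd`, `alt_mean`, `alt_sd`,
#'   `pi_null`, `converged`) and the threshold used.
#' @export
binarize_lfdr <- function(magnitudes, lfdr_threshold = 0.2, min_fit = 50L) {
  if (inherits(magnitudes, "bma_loreta")) magnitudes <- magnitudes$magnitudes
  m <- as.numeric(magnitudes)
  if (any(m < 0)) stop("magnitudes must be non-negative")
  if (length(m) < 50L) stop("at least 50 generators required for the mixture fit")
  active <- rep(FALSE, length(m))
  pos <- which(m > 0)
  diag0 <- list(null_mean = NA_real_, null_sd = NA_real_, alt_mean = NA_real_,
                alt_sd = NA_real_, pi_null = NA_real_, converged = FALSE)
  fail <- function(msg) {
    warning(msg, "; returning all-inactive map")
    structure(c(list(active = active, lfdr = rep(1, length(m)),
                     lfdr_threshold = lfdr_threshold), diag0),
              class = "binary_map")
  }
  if (length(pos) < min_fit)
    return(fail(sprintf("only %d positive magnitudes (< %d)", length(pos), min_fit)))
  z <- log(m[pos])
  if (stats::sd(z) < 1e-12)
    return(fail("degenerate magnitudes (zero spread); no alternative component"))
  fit <- .em_gauss2(z)
  if (!fit$converged)
    return(fail("EM for the two-component mixture did not converge"))
  lfdr <- rep(1, length(m))
  lfdr[pos] <- fit$lfdr
  active[pos] <- fit$lfdr < lfdr_threshold
  structure(list(active = active, lfdr = lfdr, lfdr_threshold = lfdr_threshold,
                 null_mean = fit$mu[1], null_sd = fit$sd[1],
                 alt_mean = fit$mu[2], alt_sd = fit$sd[2],
                 pi_null = fit$pi[1], converged = TRUE),
            class = "binary_map")
}

## two-component Gaussian mixture EM with deterministic quantile init;
## component 1 = null (lower mean enforced on exit)
.em_gauss2 <- function(z, max_iter = 500L, tol = 1e-10) {
  q8 <- stats::quantile(z, 0.8, names = FALSE, type = 7)
  lo <- z[z <= q8]; hi <- z[z > q8]
  if (!length(hi)) hi <- max(z)
  mu <- c(mean(lo), mean(hi))
  sd2 <- c(max(stats::sd(lo), 1e-6), max(stats::sd(hi), 1e-6, na.rm = TRUE))
  if (is.na(sd2[2])) sd2[2] <- sd2[1]
  pi <- c(0.8, 0.2)
  ll_old <- -Inf; converged <- FALSE
  for (it in seq_len(max_iter)) {
    d1 <- pi[1] * stats::dnorm(z, mu[1], sd2[1])
    d2 <- pi[2] * stats::dnorm(z, mu[2], sd2[2])
    tot <- d1 + d2
    tot[tot <= 0] <- .Machine$double.xmin
    r <- d2 / tot                      # responsibility of the alternative
    ll <- sum(log(tot))
    if (is.finite(ll) && abs(ll - ll_old) < tol * (1 + abs(ll))) {
      converged <- TRUE; break
    }
    ll_old <- ll
    n2 <- sum(r); n1 <- length(z) - n2
    if (n2 < 1e-8 || n1 < 1e-8) { converged <- TRUE; break }  # collapsed to one comp.
    mu <- c(sum((1 - r) * z) / n1, sum(r * z) / n2)
    sd2 <- c(sqrt(sum((1 - r) * (z - mu[1])^2) / n1),
             sqrt(sum(r * (z - mu[2])^2) / n2))
    sd2 <- pmax(sd2, 1e-8 * max(stats::sd(z), 1e-12))
    pi <- c(n1, n2) / length(z)
  }
  ## enforce null = lower mean
  if (mu[1] > mu[2]) { mu <- rev(mu); sd2 <- rev(sd2); pi <- rev(pi); r <- 1 - r }
  d1 <- pi[1] * stats::dnorm(z, mu[1], sd2[1])
  d2 <- pi[2] * stats::dnorm(z, mu[2], sd2[2])
  tot <- pmax(d1 + d2, .Machine$double.xmin)
  list(mu = mu, sd = sd2, pi = pi, lfdr = d1 / tot, converged = converged)
}

#' @export
print.binary_map <- function(x, ...) {
  cat(sprintf("Binary map: %d/%d active (lfdr < %g; null N(%.2f, %.2f), pi0 %.2f)\n",
              sum(x$active), length(x$active), x$lfdr_threshold,
              x$null_mean, x$null_sd, x$pi_null))
  invisible(x)
}

## coerce inputs to a subjects x voxels 0/1 matrix
.binary_matrix <- function(maps) {
  if (is.matrix(maps)) return(maps * 1)
  stopifnot(is.list(maps), length(maps) >= 1L)
  act <- lapply(maps, function(m) {
    if (inherits(m, "binary_map")) m$active else as.logical(m)
  })
  len <- lengths(act)
  if (length(unique(len)) != 1L) stop("binary maps differ in length")
  do.call(rbind, lapply(act, as.numeric))
}

#' Conjunction map: proportion of subjects with each voxel active
#'
#' @param maps list of `binary_map`s (or logical vectors), one per subject, or
#'   a subjects x voxels 0/1 matrix.
#' @return Object of class `conjunction_map`: `values` in `{0, 1/n, ..., 1}`
#'   and `n_subjects`.
#' @export
conjunction <- function(maps) {
  B <- .binary_matrix(maps)
  structure(list(values = colMeans(B), n_subjects = nrow(B)),
            class = "conjunction_map")
}

#' @export
print.conjunction_map <- function(x, ...) {
  cat(sprintf("Conjunction map over %d subjects: max %.2f at %d voxel(s)\n",
              x$n_subjects, max(x$values), sum(x$values == max(x$values))))
  invisible(x)
}

#' Signed conjunction of subtraction maps between two conditions
#'
#' Per subject, subtracts the paired binary maps (`a - b`, values -1/0/1 per
#' voxel); the group map is the per-voxel mean of these signed differences —
#' the proportion of subjects in which the voxel is differentially active,
#' signed by the direction of the difference.
#'
#' @param maps_a,maps_b lists of `binary_map`s (or a 0/1 matrix), paired by
#'   subject and of equal length.
#' @return Object of class `diff_conjunction_map` with `values` in `[-1, 1]`,
#'   `n_subjects`, and the subject-level difference matrix `d` (subjects x
#'   voxels).
#' @export
diff_conjunction <- function(maps_a, maps_b) {
  A <- .binary_matrix(maps_a); B <- .binary_matrix(maps_b)
  if (!all(dim(A) == dim(B)))
    stop("conditions have unpaired subjects or differing voxel counts")
  D <- A - B
  structure(list(values = colMeans(D), n_subjects = nrow(D), d = D),
            class = "diff_conjunction_map")
}

#' @export
print.diff_conjunction_map <- function(x, ...) {
  cat(sprintf("Signed difference conjunction over %d subjects: range [%.2f, %.2f]",
              x$n_subjects, min(x$values), max(x$values)))
  if (!is.null(x$mask))
    cat(sprintf("; %d voxels significant at q = %g", sum(x$mask), x$q))
  cat("\n")
  invisible(x)
}

#' Permutation threshold for a signed difference conjunction
#'
#' Tests, per voxel, the null hypothesis of equality of the two conditions by
#' randomly exchanging each subject's condition pair — equivalently flipping
#' the sign of the subject's difference map — independently with probability
#' 1/2 in each iteration.  Two-sided p-values use the add-one estimator
#' `p = (1 + #{|perm| >= |obs|}) / (n_iter + 1)`; the map is then thresholded
#' with BH-FDR across voxels.
#'
#' @param maps_a,maps_b paired binary maps as in [diff_conjunction()].
#' @param n_iter number of permutation iterations (>= 100; default 10000).
#' @param q FDR level across voxels.
#' @param seed integer seed (fixed seed + fixed input reproduce the p-values
#'   bit for bit).
#' @return A `diff_conjunction_map` with `p_values`, logical `mask`, `q` and
#'   `n_iter` added.
#' @export
permutation_threshold <- function(maps_a, maps_b, n_iter = 10000L, q = 0.05,
                                  seed = 1L) {
  n_iter <- as.integer(n_iter)
  if (n_iter < 100L) stop("n_iter must be at least 100")
  dmap <- diff_conjunction(maps_a, maps_b)
  D <- dmap$d
  ns <- nrow(D)
  obs <- abs(colMeans(D))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  S <- matrix(sample(c(-1, 1), n_iter * ns, replace = TRUE), n_iter, ns)
  perm <- abs(S %*% D) / ns                      # n_iter x voxels
  exceed <- colSums(perm >= rep(obs, each = n_iter))
  p <- (1 + exceed) / (n_iter + 1)
  padj <- stats::p.adjust(p, method = "BH")
  dmap$p_values <- p
  dmap$mask <- padj <= q
  dmap$q <- q
  dmap$n_iter <- n_iter
  dmap
}

#' Per-compartment cluster summary of a conjunction map
#'
#' Summarises, per compartment, the voxels whose (absolute) conjunction value
#' reaches `min_value` — or, when the map carries a permutation mask, the
#' masked voxels: cluster size in voxels, mean |value| and SD, sorted by
#' decreasing size.  For signed difference maps the two signs are reported as
#' separate tables (`A > B` and `B > A`).
#'
#' @param map a `conjunction_map` or `diff_conjunction_map`.
#' @param space the matching [source_space()].
#' @param min_value threshold in `[0, 1]` (ignored where a mask is present).
#' @return For plain maps, a data frame `(compartment, cluster_size,
#'   mean_value, sd_value)`; for signed maps, a named list of two such data
#'   frames.
#' @export
cluster_table <- function(map, space, min_value = 0.5) {
  stopifnot(min_value >= 0, min_value <= 1)
  vals <- map$values
  keep <- if (!is.null(map$mask)) map$mask else abs(vals) >= min_value
  one_table <- function(idx) {
    if (!length(idx))
      return(data.frame(compartment = character(), cluster_size = integer(),
                        mean_value = numeric(), sd_value = numeric()))
    comp <- unname(space$atlas[as.character(space$compartment_labels[idx])])
    v <- abs(vals[idx])
    agg <- lapply(split(v, comp), function(g)
      c(n = length(g), m = mean(g), s = if (length(g) > 1) stats::sd(g) else 0))
    out <- data.frame(compartment = names(agg),
                      cluster_size = vapply(agg, `[[`, 0, "n"),
                      mean_value = vapply(agg, `[[`, 0, "m"),
                      sd_value = vapply(agg, `[[`, 0, "s"))
    out <- out[order(-out$cluster_size), ]
    rownames(out) <- NULL
    out
  }
  if (inherits(map, "diff_conjunction_map")) {
    list(`A > B` = one_table(which(keep & vals > 0)),
         `B > A` = one_table(which(keep & vals < 0)))
  } else {
    one_table(which(keep))
  }
}

#' Export conjunction maps and cluster tables as delimited text
#'
#' @param map a `conjunction_map` or `diff_conjunction_map`.
#' @param space the matching `source_space`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_conjunction_map <- function(map, space, path) {
  tab <- data.frame(generator_id = seq_along(map$values),
                    compartment = unname(space$atlas[as.character(space$compartment_labels)]),
                    value = map$values)
  if (!is.null(map$p_values)) {
    tab$p <- map$p_values
    tab$significant <- map$mask
  }
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_conjunction_map
#' @param tabs result of [cluster_table()].
#' @export
write_cluster_table <- function(tabs, path) {
  if (is.data.frame(tabs)) {
    utils::write.csv(tabs, path, row.names = FALSE)
  } else {
    all <- do.call(rbind, lapply(names(tabs), function(nm) {
      t <- tabs[[nm]]
      if (nrow(t)) cbind(direction = nm, t) else NULL
    }))
    if (is.null(all))
      all <- data.frame(direction = character(), compartment = character(),
                        cluster_size = integer(), mean_value = numeric(),
                        sd_value = numeric())
    utils::write.csv(all, path, row.names = FALSE)
  }
  invisible(path)
}
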