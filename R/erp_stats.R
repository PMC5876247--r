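#' Spatio-temporal statistical map
#'
#' Container for electrode x time maps of F, t, p or Z values with optional
#' FDR significance mask.  Created by [rm_anova_2x2()], [posthoc_maps()],
#' [fdr_select()] and [p_to_z()].
#'
#' @param values electrode x time numeric matrix of the statistic.
#' @param p matching matrix of p-values (may be `NULL` for Z maps).
#' @param type one of `"F"`, `"t"`, `"Z"`.
#' @param effect label, e.g. `"TASK"`, `"MATCH"`, `"TASK:MATCH"` or a post hoc
#'   contrast description.
#' @param df degrees-of-freedom pair.
#' @param channels,times dimension labels.
#' @param mask logical matrix of FDR-significant points (optional).
#' @param q,threshold FDR level and realised p threshold (optional).
#' @return Object of class `stat_map`.
#' @export
stat_map <- function(values, p = NULL, type = "F", effect = "", df = c(NA, NA),
                     channels = rownames(values), times = NULL, mask = NULL,
                     q = NULL, threshold = NULL) {
  if (!is.null(p)) {
    stopifnot(all(dim(p) == dim(values)), all(p >= 0 & p <= 1, na.rm = TRUE))
  }
  structure(list(values = values, p = p, type = type, effect = effect, df = df,
                 channels = channels, times = times, mask = mask, q = q,
                 threshold = threshold),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("StatMap [%s] %s: %d x %d points", x$type, x$effect,
              nrow(x$values), ncol(x$values)))
  if (!all(is.na(x$df))) cat(sprintf(", df = (%g, %g)", x$df[1], x$df[2]))
  if (!is.null(x$mask))
    cat(sprintf("; %d significant at q = %g", sum(x$mask), x$q))
  cat("\n")
  invisible(x)
}

#' Mass-univariate 2x2 repeated-measures ANOVA over electrodes and time
#'
#' Fits, at every electrode and time point, the two-way within-subject ANOVA
#' with factors TASK (intra vs cross) and MATCH (match vs mismatch).  For a
#' 2x2 within design each effect reduces to a one-sample test on a subject
#' contrast: with condition means (intra.match, intra.mismatch, cross.match,
#' cross.mismatch), the contrasts are (+,+,-,-)/2 for TASK, (+,-,+,-)/2 for
#' MATCH and (+,-,-,+)/2 for the interaction, and
#' `F = n * mean(contrast)^2 / var(contrast)` with df (1, n-1).  No sphericity
#' correction is involved (none is needed for single-df effects).  Points with
#' zero contrast variance are degenerate and report p = 1 with a warning.
#'
#' @param erps an `erp_set` with exactly 4 conditions and >= 3 subjects.
#' @return Named list of three `stat_map` objects (`task`, `match`,
#'   `interaction`) carrying F values, p-values and df.
#' @export
rm_anova_2x2 <- function(erps) {
  stopifnot(inherits(erps, "erp_set"))
  d <- dim(erps$data)
  if (d[2] != 4L) stop("exactly 4 conditions required (2x2 design)")
  n <- d[1]
  if (n < 3L) stop("at least 3 subjects required")
  contrasts <- list(task = c(1, 1, -1, -1) / 2,
                    match = c(1, -1, 1, -1) / 2,
                    interaction = c(1, -1, -1, 1) / 2)
  effects <- c(task = "TASK", match = "MATCH", interaction = "TASK:MATCH")
  degenerate <- FALSE
  out <- lapply(names(contrasts), function(key) {
    w <- contrasts[[key]]
    ## subject-level contrast array: n x channel x time
    cmat <- w[1] * erps$data[, 1, , ] + w[2] * erps$data[, 2, , ] +
      w[3] * erps$data[, 3, , ] + w[4] * erps$data[, 4, , ]
    dim(cmat) <- c(n, d[3] * d[4])
    m <- colMeans(cmat)
    v <- colSums((cmat - rep(m, each = n))^2) / (n - 1)
    Fv <- ifelse(v > 0, n * m^2 / v, 0)
    p <- stats::pf(Fv, 1, n - 1, lower.tail = FALSE)
    if (any(v == 0)) { degenerate <<- TRUE; p[v == 0] <- 1 }
    Fm <- matrix(Fv, d[3], d[4], dimnames = list(erps$channels, NULL))
    pm <- matrix(p, d[3], d[4], dimnames = list(erps$channels, NULL))
    stat_map(Fm, pm, type = "F", effect = effects[[key]], df = c(1, n - 1),
             channels = erps$channels, times = erps$times)
  })
  if (degenerate)
    warning("zero contrast variance at some points; p set to 1 there")
  stats::setNames(out, names(contrasts))
}

#' Benjamini-Hochberg selection over a statistical map
#'
#' Applies the BH step-up procedure jointly over all electrode x time
#' p-values of the map and records the significance mask and the realised
#' p-value threshold.
#'
#' @param pmap a `stat_map` with p-values.
#' @param q FDR level in (0, 1).
#' @return The map with `mask`, `q` and `threshold` filled in.
#' @export
fdr_select <- function(pmap, q = 0.05) {
  stopifnot(inherits(pmap, "stat_map"))
  if (is.null(pmap$p) || !length(pmap$p)) stop("map carries no p-values")
  if (!(q > 0 && q < 1)) stop("q must be in (0, 1)")
  padj <- stats::p.adjust(as.vector(pmap$p), method = "BH")
  mask <- matrix(padj <= q, nrow(pmap$p), ncol(pmap$p),
                 dimnames = dimnames(pmap$p))
  pmap$mask <- mask
  pmap$q <- q
  pmap$threshold <- if (any(mask)) max(pmap$p[mask]) else 0
  pmap
}

#' Post hoc paired contrast maps within significant ANOVA points
#'
#' Computes paired t maps for the simple effects that decompose each
#' significant main effect: for TASK, intra vs cross within each MATCH level;
#' for MATCH, match vs mismatch within each task.  Tests are run only at the
#' electrode x time points retained in the corresponding main-effect FDR mask,
#' and BH correction is applied jointly across the two within-factor
#' comparisons and all retained points.
#'
#' @param erps the `erp_set` used for the ANOVA.
#' @param anova_maps result of [rm_anova_2x2()] after [fdr_select()] on the
#'   main-effect maps (maps without masks contribute no tests).
#' @param q FDR level for the post hoc correction.
#' @return Named list of `stat_map` t maps (empty masks give empty maps).
#' @export
posthoc_maps <- function(erps, anova_maps, q = 0.05) {
  stopifnot(inherits(erps, "erp_set"))
  pairs <- list(
    task_within_match    = list(effect = "task",  a = 1L, b = 3L),
    task_within_mismatch = list(effect = "task",  a = 2L, b = 4L),
    match_within_intra   = list(effect = "match", a = 1L, b = 2L),
    match_within_cross   = list(effect = "match", a = 3L, b = 4L))
  n <- dim(erps$data)[1]
  tmaps <- list(); pvals <- list()
  for (key in names(pairs)) {
    pr <- pairs[[key]]
    mask <- anova_maps[[pr$effect]]$mask
    if (is.null(mask) || !any(mask)) {
      tmaps[[key]] <- NULL
      next
    }
    diffs <- erps$data[, pr$a, , ] - erps$data[, pr$b, , ]   # n x ch x time
    dim(diffs) <- c(n, length(mask))
    sel <- which(as.vector(mask))
    dsel <- diffs[, sel, drop = FALSE]
    m <- colMeans(dsel)
    sdv <- sqrt(colSums((dsel - rep(m, each = n))^2) / (n - 1))
    tv <- ifelse(sdv > 0, m / (sdv / sqrt(n)), 0)
    p <- 2 * stats::pt(abs(tv), n - 1, lower.tail = FALSE)
    tmat <- matrix(0, nrow(mask), ncol(mask), dimnames = dimnames(mask))
    pmat <- matrix(NA_real_, nrow(mask), ncol(mask), dimnames = dimnames(mask))
    tmat[sel] <- tv; pmat[sel] <- p
    tmaps[[key]] <- stat_map(tmat, pmat, type = "t", effect = key,
                             df = c(1, n - 1), channels = erps$channels,
                             times = erps$times, q = q)
    pvals[[key]] <- p
  }
  if (!length(pvals)) return(tmaps)
  ## joint BH across all retained points of all comparisons
  allp <- unlist(pvals, use.names = FALSE)
  padj <- stats::p.adjust(allp, method = "BH")
  off <- 0L
  for (key in names(tmaps)) {
    np <- length(pvals[[key]])
    adj <- padj[off + seq_len(np)]; off <- off + np
    mask <- matrix(FALSE, nrow(tmaps[[key]]$values), ncol(tmaps[[key]]$values),
                   dimnames = dimnames(tmaps[[key]]$values))
    mask[!is.na(tmaps[[key]]$p)] <- adj <= q
    tmaps[[key]]$mask <- mask
  }
  tmaps
}

#' Transform a p-value map to Z scores
#'
#' Maps p-values to standard-normal quantiles for display.  With
#' `two_sided = TRUE` (the default, appropriate for ANOVA/two-sided p-values)
#' `Z = qnorm(1 - p/2)`, the absolute Z of a two-sided test; with
#' `two_sided = FALSE`, `Z = qnorm(1 - p)`, the one-sided upper-tail mapping.
#' When a signed t map is supplied its sign is copied onto Z.
#'
#' @param pmap a `stat_map` with p-values.
#' @param signed_by optional `stat_map` of t values supplying signs.
#' @param two_sided logical, see above.
#' @return A `stat_map` of type `"Z"` (mask and q carried over).
#' @export
p_to_z <- function(pmap, signed_by = NULL, two_sided = TRUE) {
  stopifnot(inherits(pmap, "stat_map"))
  p <- pmap$p
  if (is.null(p)) stop("map carries no p-values")
  if (any(p == 0, na.rm = TRUE)) {
    warning("p = 0 clipped to the smallest positive double")
    p[p == 0] <- .Machine$double.xmin
  }
  z <- if (two_sided) stats::qnorm(1 - p / 2) else stats::qnorm(1 - p)
  ## p = 1 maps to 0 (two-sided) or -Inf (one-sided); clip to a finite floor
  z[is.infinite(z) & z < 0] <- stats::qnorm(.Machine$double.eps)
  if (!is.null(signed_by)) z <- z * sign(signed_by$values)
  stat_map(z, p = pmap$p, type = "Z", effect = pmap$effect, df = pmap$df,
           channels = pmap$channels, times = pmap$times, mask = pmap$mask,
           q = pmap$q, threshold = pmap$threshold)
}

#' Discrimination sensitivity d'
#'
#' Evaluates `d' = 0.6 * log[(pH (1 - pF)) / (pF (1 - pH))]`, a logistic-type
#' discrimination index computed from hit and false-alarm probabilities.  The
#' logarithm base is configurable (default base 10).
#'
#' @param pH,pF hit and false-alarm probabilities, strictly inside (0, 1);
#'   values of exactly 0 or 1 are an error — apply a correction rule (e.g. the
#'   1/(2N) rule) before calling.
#' @param log_base base of the logarithm (default 10; use `exp(1)` for the
#'   natural log).
#' @return d' value(s).
#' @examples
#' dprime(0.91, 0.11)
#' @export
dprime <- function(pH, pF, log_base = 10) {
  if (any(pH <= 0 | pH >= 1 | pF <= 0 | pF >= 1))
    stop("pH and pF must lie strictly inside (0, 1); apply a correction rule first")
  0.6 * log((pH * (1 - pF)) / (pF * (1 - pH)), base = log_base)
}

#' Export a statistical map as delimited text
#'
#' Writes `electrode, time_ms, value, p, significant` rows plus a JSON sidecar
#' (`<path>.json`) recording effect, type, df, q and threshold.
#'
#' @param map a `stat_map`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_stat_map <- function(map, path) {
  stopifnot(inherits(map, "stat_map"))
  nt <- ncol(map$values)
  tab <- data.frame(
    electrode = rep(map$channels, nt),
    time_ms = rep(if (is.null(map$times)) seq_len(nt) else map$times,
                  each = nrow(map$values)),
    value = as.vector(map$values),
    p = if (is.null(map$p)) NA_real_ else as.vector(map$p),
    significant = if (is.null(map$mask)) NA else as.vector(map$mask))
  utils::write.csv(tab, path, row.names = FALSE)
  meta <- list(effect = map$effect, type = map$type, df = map$df,
               q = map$q, threshold = map$threshold)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}
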