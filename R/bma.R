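#' Bayesian model averaging of LORETA inverse solutions
#'
#' The central fitting function of the package.  Each candidate model
#' restricts the source support to a compartment subset; its Gaussian evidence
#' is maximised over the hyperparameters, posterior model probabilities are
#' formed under a uniform model prior (`weights` proportional to
#' `exp(log_evidence)`), models whose posterior odds against the best model
#' fall below `occam_window` are pruned (the best model is always retained)
#' and the weights renormalised.  The averaged primary current density is the
#' weighted sum of the per-model posterior means, zero-padded outside each
#' model's support; the inverse-solution map holds the per-generator norm of
#' the averaged moment vector.
#'
#' @param feature referenced channel voltages (microvolts), one per lead-field
#'   channel (e.g. a row of [extract_feature()]).
#' @param lf a [lead_field()].
#' @param space the matching [source_space()].
#' @param models list of [compartment_model()]s; defaults to
#'   [enumerate_models()] up to `max_size`.
#' @param max_size maximum compartment-subset size when enumerating.
#' @param occam_window posterior-odds pruning threshold in `[0, Inf]`
#'   (default 1/20); 0 disables pruning, `Inf` keeps only the best model.
#' @param bases optional precomputed model bases (internal use; lets many
#'   feature vectors share the per-model decompositions).
#' @return Object of class `bma_loreta` with elements `magnitudes` (one
#'   non-negative value per generator, nA.m), `pcd` (3 per generator),
#'   `posterior` (data frame: model, log_evidence, weight, retained, alpha,
#'   beta), `models`, `feature`, `fitted`, `residual`, `space_info`, `call`.
#' @examples
#' \donttest{
#' ss <- source_space(120, 4, seed = 1)
#' lf <- lead_field(head_model(n_terms = 30), montage(), ss)
#' v <- predict(lf, replace(numeric(360), 10:12, c(3, 0, 4)))
#' fit <- bma_solve(v, lf, ss, max_size = 1)
#' fit
#' }
#' @export
bma_solve <- function(feature, lf, space, models = NULL, max_size = 2L,
                      occam_window = 1 / 20, bases = NULL) {
  stopifnot(inherits(lf, "lead_field"), inherits(space, "source_space"))
  v <- as.numeric(feature)
  if (length(v) != nrow(lf$matrix))
    stop("feature length does not match the lead-field channel count")
  if (is.null(models)) models <- enumerate_models(space, max_size)
  if (!length(models)) stop("at least one model required")
  if (is.null(bases)) bases <- lapply(models, function(m) .model_basis(lf, space, m))

  nm <- length(models)
  le <- numeric(nm); alpha <- numeric(nm); beta <- numeric(nm)
  for (i in seq_len(nm)) {
    opt <- .optimize_evidence(bases[[i]], v)
    le[i] <- opt$log_evidence; alpha[i] <- opt$alpha; beta[i] <- opt$beta
    models[[i]]$log_evidence <- le[i]
    models[[i]]$alpha <- alpha[i]; models[[i]]$beta <- beta[i]
  }
  ## posterior weights under a uniform model prior; rescale by the maximum
  ## log evidence so that underflow cannot occur
  lw <- le - max(le)
  w <- exp(lw) / sum(exp(lw))
  ## Occam's window: prune by posterior odds against the best model
  odds <- w / max(w)
  retained <- if (is.infinite(occam_window)) seq_along(w) == which.max(w)
              else odds >= occam_window
  retained[which.max(w)] <- TRUE
  wr <- ifelse(retained, w, 0)
  wr <- wr / sum(wr)

  G <- lf$n_generators
  pcd <- numeric(3L * G)
  for (i in which(wr > 0)) {
    ji <- .loreta_from_basis(bases[[i]], v, alpha[i], beta[i])
    pcd[bases[[i]]$cols] <- pcd[bases[[i]]$cols] + wr[i] * ji
  }
  mags <- sqrt(colSums(matrix(pcd, 3L)^2))
  fitted <- drop(lf$matrix %*% pcd)
  post <- data.frame(
    model = vapply(models, function(m) paste(m$names, collapse = "+"), ""),
    log_evidence = le, weight = wr, raw_weight = w, retained = retained,
    alpha = alpha, beta = beta, stringsAsFactors = FALSE)
  structure(list(magnitudes = mags, pcd = pcd, posterior = post,
                 models = models, feature = v, fitted = fitted,
                 residual = v - fitted,
                 space_info = list(compartment_labels = space$compartment_labels,
                                   atlas = space$atlas),
                 occam_window = occam_window, call = match.call()),
            class = "bma_loreta")
}

#' @export
print.bma_loreta <- function(x, ...) {
  nr <- sum(x$posterior$retained)
  cat(sprintf("BMA-LORETA inverse solution: %d generators, %d/%d models retained\n",
              length(x$magnitudes), nr, nrow(x$posterior)))
  top <- x$posterior[order(-x$posterior$weight), ][seq_len(min(3, nr)), ]
  for (i in seq_len(nrow(top)))
    cat(sprintf("  %-14s weight %.3f  logev %.2f\n",
                top$model[i], top$weight[i], top$log_evidence[i]))
  invisible(x)
}

#' @export
summary.bma_loreta <- function(object, ...) {
  lab <- object$space_info$compartment_labels
  by_comp <- tapply(object$magnitudes, lab, sum)
  out <- data.frame(
    compartment = unname(object$space_info$atlas[names(by_comp)]),
    summed_magnitude = as.numeric(by_comp),
    n_generators = as.integer(table(lab)[names(by_comp)]))
  out <- out[order(-out$summed_magnitude), ]
  rownames(out) <- NULL
  res <- list(by_compartment = out, posterior = object$posterior,
              residual_rms = sqrt(mean(object$residual^2)),
              feature_rms = sqrt(mean(object$feature^2)))
  class(res) <- "summary.bma_loreta"
  res
}

#' @export
print.summary.bma_loreta <- function(x, ...) {
  cat("Per-compartment summed |PCD| (nA.m):\n")
  print(utils::head(x$by_compartment, 8), row.names = FALSE)
  cat(sprintf("Residual RMS %.3g uV on feature RMS %.3g uV\n",
              x$residual_rms, x$feature_rms))
  invisible(x)
}

#' @export
coef.bma_loreta <- function(object, ...) object$magnitudes

#' @export
fitted.bma_loreta <- function(object, ...) object$fitted

#' @export
residuals.bma_loreta <- function(object, ...) object$residual

#' @export
plot.bma_loreta <- function(x, ...) {
  lab <- x$space_info$compartment_labels
  by_comp <- tapply(x$magnitudes, lab, sum)
  graphics::barplot(as.numeric(by_comp),
                    names.arg = unname(x$space_info$atlas[names(by_comp)]),
                    las = 2, ylab = "summed |PCD| (nA.m)",
                    main = "BMA source strength by compartment", ...)
  invisible(x)
}

#' Export an inverse-solution map as delimited text
#'
#' Writes `generator_id, compartment, x, y, z, magnitude` rows; the companion
#' [write_model_posterior()] writes `compartments, log_evidence, weight`.
#'
#' @param fit a `bma_loreta`.
#' @param space the matching `source_space`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ismap <- function(fit, space, path) {
  tab <- data.frame(generator_id = seq_along(fit$magnitudes),
                    compartment = unname(space$atlas[as.character(space$compartment_labels)]),
                    x = space$positions[, 1], y = space$positions[, 2],
                    z = space$positions[, 3], magnitude = fit$magnitudes)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ismap
#' @export
write_model_posterior <- function(fit, path) {
  tab <- fit$posterior[, c("model", "log_evidence", "weight")]
  names(tab)[1] <- "compartments"
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
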