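#' Graph Laplacian of a source-space compartment subset
#'
#' Discrete Laplacian `L = D - A` of the neighbour graph restricted to the
#' generators of the given compartments.  `L` is symmetric positive
#' semi-definite with zero row sums; constant fields over a connected subset
#' lie in its null space.  In the LORETA solver the same operator acts on each
#' of the three dipole-moment components (block structure).
#'
#' @param space a [source_space()].
#' @param subset compartment names or integer labels; default all.
#' @return matrix with attribute `generator_index` (the generators spanned).
#' @export
graph_laplacian <- function(space, subset = NULL) {
  stopifnot(inherits(space, "source_space"))
  ids <- if (is.null(subset)) as.integer(names(space$atlas))
         else .resolve_compartments(space, subset)
  gi <- which(space$compartment_labels %in% ids)
  if (!length(gi)) stop("subset contains no generators")
  A <- space$neighbor_graph[gi, gi, drop = FALSE] * 1
  L <- diag(rowSums(A), nrow(A)) - A
  attr(L, "generator_index") <- gi
  L
}

#' Anatomical-constraint model over source compartments
#'
#' A compartment model restricts the LORETA inverse solution to the generators
#' of a compartment subset; competing models are compared by Bayesian evidence
#' and combined by [bma_solve()].
#'
#' @param space a [source_space()].
#' @param compartments nonempty vector of compartment names or labels.
#' @return Object of class `compartment_model` with the compartment ids, the
#'   generator index and slots for the log evidence and the optimised
#'   hyperparameters (prior precision `alpha`, noise precision `beta`).
#' @export
compartment_model <- function(space, compartments) {
  ids <- sort(.resolve_compartments(space, compartments))
  gi <- which(space$compartment_labels %in% ids)
  structure(list(compartments = ids,
                 names = unname(space$atlas[as.character(ids)]),
                 generator_index = gi,
                 log_evidence = NA_real_, alpha = NA_real_, beta = NA_real_),
            class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat(sprintf("Compartment model {%s}: %d generators",
              paste(x$names, collapse = ","), length(x$generator_index)))
  if (!is.na(x$log_evidence))
    cat(sprintf(", log evidence %.3f (alpha %.3g, beta %.3g)",
                x$log_evidence, x$alpha, x$beta))
  cat("\n")
  invisible(x)
}

#' Enumerate compartment models up to a maximum size
#'
#' All nonempty compartment subsets of cardinality `<= max_size`, in
#' deterministic order (increasing size, lexicographic within size).
#'
#' @param space a [source_space()].
#' @param max_size maximum subset cardinality (>= 1).
#' @param cap guard on the total number of models (default 1000); exceeding it
#'   is an error suggesting a smaller `max_size`.
#' @return list of [compartment_model()]s.
#' @export
enumerate_models <- function(space, max_size = 2L, cap = 1000L) {
  stopifnot(inherits(space, "source_space"), max_size >= 1L)
  K <- length(space$atlas)
  max_size <- min(as.integer(max_size), K)
  total <- sum(choose(K, seq_len(max_size)))
  if (total > cap)
    stop(sprintf("model space has %d members (> cap %d); use a smaller max_size",
                 total, cap))
  ids <- as.integer(names(space$atlas))
  models <- list()
  for (sz in seq_len(max_size)) {
    combs <- utils::combn(ids, sz)
    for (j in seq_len(ncol(combs)))
      models[[length(models) + 1L]] <- compartment_model(space, combs[, j])
  }
  models
}

## Per-model precomputation shared across feature vectors:
## whitened gain W = K_M M^{-1/2} with M = kron(L^T L + eps I, I3) and its SVD.
.model_basis <- function(lf, space, model) {
  L <- graph_laplacian(space, model$compartments)
  gi <- attr(L, "generator_index")
  stopifnot(identical(gi, model$generator_index))
  LL <- crossprod(L)
  eps <- 1e-8 * max(mean(diag(LL)), 1)
  LLe <- LL + diag(eps, nrow(LL))
  eg <- eigen(LLe, symmetric = TRUE)
  if (min(eg$values) <= 0) stop("singular regularizer beyond jitter tolerance")
  ## LLe^{-1/2}
  Mih <- eg$vectors %*% (t(eg$vectors) / sqrt(eg$values))
  g <- length(gi)
  cols <- rep(3L * (gi - 1L), each = 3L) + rep(1:3, g)
  K <- lf$matrix[, cols, drop = FALSE]
  ## W = K kron(Mih, I3): per moment component k, W_k = K_k %*% Mih
  W <- matrix(0, nrow(K), ncol(K))
  for (k in 1:3) {
    idx <- seq(k, 3L * g, by = 3L)
    W[, idx] <- K[, idx, drop = FALSE] %*% Mih
  }
  sv <- svd(W, nu = min(dim(W)), nv = min(dim(W)))
  pos <- sv$d > max(sv$d) * 1e-12
  list(gi = gi, cols = cols, Mih = Mih, U = sv$u[, pos, drop = FALSE],
       s = sv$d[pos], V = sv$v[, pos, drop = FALSE], n_ch = nrow(K))
}

## log marginal likelihood at fixed hyperparameters, from the basis SVD
.log_ev_ab <- function(basis, u, vnorm2, alpha, beta) {
  ci <- 1 / beta + basis$s^2 / alpha
  resid2 <- vnorm2 - sum(u^2)
  -0.5 * (basis$n_ch * log(2 * pi) + sum(log(ci)) +
          (basis$n_ch - length(basis$s)) * log(1 / beta) +
          sum(u^2 / ci) + beta * max(resid2, 0))
}

## evidence maximisation: log-spaced grid search then Nelder-Mead refinement
.optimize_evidence <- function(basis, v, grid = 10^seq(-6, 6, length.out = 25)) {
  u <- drop(crossprod(basis$U, v))
  vnorm2 <- sum(v^2)
  ## vectorised grid evaluation: for each alpha, all betas at once
  resid2 <- max(vnorm2 - sum(u^2), 0)
  inv_b <- 1 / grid
  n_out <- basis$n_ch - length(basis$s)
  best <- c(-Inf, NA, NA)
  u2 <- u^2
  for (a in grid) {
    sa <- basis$s^2 / a
    ci <- outer(sa, inv_b, "+")                  # r x n_beta
    le_b <- -0.5 * (basis$n_ch * log(2 * pi) + colSums(log(ci)) +
                    n_out * log(inv_b) + colSums(u2 / ci) + grid * resid2)
    j <- which.max(le_b)
    if (le_b[j] > best[1]) best <- c(le_b[j], a, grid[j])
  }
  fn <- function(th) -.log_ev_ab(basis, u, vnorm2, exp(th[1]), exp(th[2]))
  opt <- stats::optim(log(best[2:3]), fn, method = "Nelder-Mead",
                      control = list(reltol = 1e-12, maxit = 500))
  if (opt$convergence != 0)
    warning("evidence optimisation did not fully converge; best value kept")
  list(log_evidence = -opt$value, alpha = exp(opt$par[1]),
       beta = exp(opt$par[2]))
}

#' LORETA inverse solution under one compartment model
#'
#' Posterior-mean estimate of the primary current density for the Gaussian
#' linear model `v = K_M j + e`, with noise precision `beta` and smoothness
#' prior precision `alpha * (L^T L + eps I)` applied blockwise to the three
#' moment components (`eps` is a small trace-scaled ridge making the graph
#' Laplacian full rank).  Equivalently
#' `j = argmin beta ||v - K_M j||^2 + alpha ||L~ j||^2`.
#'
#' @param feature numeric vector of referenced channel voltages (microvolts),
#'   one value per lead-field channel.
#' @param lf a [lead_field()].
#' @param space the [source_space()] the lead field was computed on.
#' @param model a [compartment_model()].
#' @param alpha,beta positive precisions.
#' @return list with `pcd` (full-length `3 * n_generators` vector in nA.m,
#'   zero outside the model), `magnitudes` (per-generator moment norm),
#'   `residual` (data minus fit), `fitted`.
#' @export
loreta_solve <- function(feature, lf, space, model, alpha, beta) {
  stopifnot(alpha > 0, beta > 0, inherits(model, "compartment_model"))
  basis <- .model_basis(lf, space, model)
  sol <- .loreta_from_basis(basis, as.numeric(feature), alpha, beta)
  pcd <- numeric(3L * lf$n_generators)
  pcd[basis$cols] <- sol
  fitted <- drop(lf$matrix %*% pcd)
  mags <- sqrt(colSums(matrix(pcd, 3L)^2))
  list(pcd = pcd, magnitudes = mags, residual = as.numeric(feature) - fitted,
       fitted = fitted)
}

## whitened-coordinate posterior mean, returned in model coordinates
.loreta_from_basis <- function(basis, v, alpha, beta) {
  u <- drop(crossprod(basis$U, v))
  gain <- beta * basis$s / (beta * basis$s^2 + alpha)
  jw <- drop(basis$V %*% (gain * u))          # whitened coordinates
  ## j = M^{-1/2} jw, blockwise over the 3 components
  g <- length(basis$gi)
  j <- numeric(3L * g)
  for (k in 1:3) {
    idx <- seq(k, 3L * g, by = 3L)
    j[idx] <- basis$Mih %*% jw[idx]
  }
  j
}

#' Log evidence of a compartment model
#'
#' Gaussian marginal likelihood `log p(v | M)` of the feature vector under the
#' model, with the prior precision `alpha` and noise precision `beta`
#' optimised by evidence maximisation (coarse log-grid search over
#' `10^-6..10^6` followed by Nelder-Mead refinement on the log scale).
#'
#' @inheritParams loreta_solve
#' @return the optimised log evidence, with attributes `alpha` and `beta`.
#' @export
log_evidence <- function(feature, lf, space, model) {
  basis <- .model_basis(lf, space, model)
  opt <- .optimize_evidence(basis, as.numeric(feature))
  structure(opt$log_evidence, alpha = opt$alpha, beta = opt$beta)
}
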