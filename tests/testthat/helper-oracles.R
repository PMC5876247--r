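# Independent oracles used to verify the implementation.  Each is written
# directly from the textbook formulation and shares no code with R/.

# Surface potential (V per A.m) of a current dipole inside a homogeneous
# conducting sphere with insulating exterior, referenced to `ref_unit`:
#   V = 1/(4 pi sigma R^2) sum_n (2n+1)/n (b/R)^(n-1)
#         [ n m_r P_n(cos th) + P_n'(cos th) (e_perp . m_t) ]
# evaluated by direct scalar summation to machine convergence.
oracle_sphere_potential <- function(R, sigma, elec_unit, ref_unit, p0, m,
                                    nmax = 400L) {
  pot <- function(eu) {
    b <- sqrt(sum(p0^2))
    er <- if (b > 0) p0 / b else c(0, 0, 1)
    mr <- sum(m * er)
    mt <- m - mr * er
    ct <- sum(eu * er)
    eperp <- eu - ct * er
    tot <- 0
    Pm2 <- 1; Pm1 <- ct; dPm2 <- 0; dPm1 <- 1
    for (n in 1:nmax) {
      if (n == 1) { Pn <- ct; dPn <- 1 } else {
        Pn <- ((2 * n - 1) * ct * Pm1 - (n - 1) * Pm2) / n
        dPn <- dPm2 + (2 * n - 1) * Pm1
        Pm2 <- Pm1; Pm1 <- Pn; dPm2 <- dPm1; dPm1 <- dPn
      }
      term <- (2 * n + 1) / n * (b / R)^(n - 1) *
        (n * mr * Pn + sum(eperp * mt) * dPn)
      tot <- tot + term
      if (n > 10 && abs(term) < 1e-16 * max(abs(tot), 1e-300)) break
    }
    tot / (4 * pi * sigma * R^2)
  }
  pot(elec_unit) - pot(ref_unit)
}

# Benjamini-Hochberg step-up computed by hand: largest k with
# p_(k) <= k q / m; reject the k smallest p-values.
oracle_bh_rejections <- function(p, q) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  k <- which(ps <= seq_len(m) * q / m)
  rej <- logical(m)
  if (length(k)) rej[o[seq_len(max(k))]] <- TRUE
  rej
}

# Brute-force evidence-weighted model average: recombines per-model LORETA
# solutions (computed through the public single-model solver at the stored
# hyperparameters) with softmax weights of the stored log evidences.
oracle_bma_average <- function(fit, lf, space) {
  le <- fit$posterior$log_evidence
  w <- exp(le - max(le)); w <- w / sum(w)
  pcd <- numeric(3 * lf$n_generators)
  for (i in seq_along(fit$models)) {
    mdl <- fit$models[[i]]
    sol <- loreta_solve(fit$feature, lf, space, mdl, mdl$alpha, mdl$beta)
    pcd <- pcd + w[i] * sol$pcd
  }
  sqrt(colSums(matrix(pcd, 3)^2))
}
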