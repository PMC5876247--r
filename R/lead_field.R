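#' Electric lead field of the three-sphere head model
#'
#' Computes the gain matrix linking dipolar primary current density at each
#' generator to nose-referenced potentials at the montage electrodes.  The
#' potential of a current dipole inside the innermost shell is expanded in
#' Legendre series; for each degree `n` the five interface conditions
#' (continuity of potential and of radial current at the brain/skull and
#' skull/scalp interfaces, vanishing radial current at the scalp surface) are
#' solved for the layer coefficients, and the series is truncated at
#' `head$n_terms` degrees.  The reference electrode's potential is subtracted
#' from every channel, so predicted potentials vanish at the reference.
#'
#' Units: entries are in microvolts per nA.m of dipole moment.
#'
#' @param head a [head_model()].
#' @param mon an [montage()] object; electrode unit vectors are scaled to the
#'   scalp radius.
#' @param space a [source_space()]; all generators must lie strictly inside
#'   the brain shell.
#' @return Object of class `lead_field`: list with `matrix` (channels x
#'   3*n_generators; generator-major column order x,y,z), `reference_applied`,
#'   `channels`, `n_generators`, `units`.
#' @examples
#' lf <- lead_field(head_model(n_terms = 30), montage(), source_space(50, 4))
#' dim(lf$matrix)
#' @export
lead_field <- function(head, mon, space) {
  stopifnot(inherits(head, "head_model"), inherits(mon, "eeg_montage"),
            inherits(space, "source_space"))
  b_all <- sqrt(rowSums(space$positions^2))
  if (any(b_all >= head$radii["brain"]))
    stop("generator(s) outside the brain shell")
  ## convergence of the truncated series is governed by (b/r_scalp)^n
  tail_ratio <- max(b_all) / head$radii["scalp"]
  if (tail_ratio^head$n_terms > 1e-4)
    warning(sprintf(
      "series tail term ~%.2g at n_terms=%d; increase n_terms for convergence",
      tail_ratio^head$n_terms, head$n_terms))

  pts <- rbind(mon$positions, mon$reference)      # electrodes + reference
  V <- .sphere_potentials(head, pts, space$positions, gains = .layer_gains(head))
  ## reference: subtract last row block from every channel row
  nch <- length(mon$names)
  ref <- V[nch + 1L, , drop = FALSE]
  M <- V[seq_len(nch), , drop = FALSE] - ref[rep(1L, nch), , drop = FALSE]
  dimnames(M) <- list(mon$names, NULL)
  structure(list(matrix = M * 1e-3,  # V/(A.m) -> uV/(nA.m)
                 reference_applied = TRUE,
                 channels = mon$names,
                 n_generators = space$n_generators,
                 units = "uV/nA.m"),
            class = "lead_field")
}

## Per-degree gain of the three-layer conductor.  Potential in each layer is
## A*(r/R)^n + B*(r/R)^-(n+1) with R the scalp radius; the dipole's primary
## term carries coefficient 1 in those scaled units.  Returns G_n such that
## the surface potential coefficient equals G_n times the primary coefficient.
.layer_gains <- function(head) {
  r <- head$radii / head$radii["scalp"]          # rho1, rho2, 1
  s <- head$conductivities
  n_terms <- head$n_terms
  G <- numeric(n_terms)
  for (n in seq_len(n_terms)) {
    rn1 <- r[1]^n; rm1 <- r[1]^(-(n + 1))
    rn2 <- r[2]^n; rm2 <- r[2]^(-(n + 1))
    ## unknowns: A1, A2, B2, A3, B3   (B1 = primary coefficient = 1)
    A <- matrix(0, 5, 5)
    y <- numeric(5)
    ## potential continuity at brain/skull interface
    A[1, ] <- c(rn1, -rn1, -rm1, 0, 0);              y[1] <- -rm1
    ## radial current continuity at brain/skull
    A[2, ] <- c(s[1] * n * rn1, -s[2] * n * rn1, s[2] * (n + 1) * rm1, 0, 0)
    y[2] <- s[1] * (n + 1) * rm1
    ## potential continuity at skull/scalp
    A[3, ] <- c(0, rn2, rm2, -rn2, -rm2);            y[3] <- 0
    ## radial current continuity at skull/scalp
    A[4, ] <- c(0, s[2] * n * rn2, -s[2] * (n + 1) * rm2,
                -s[3] * n * rn2, s[3] * (n + 1) * rm2); y[4] <- 0
    ## insulating scalp surface (rho = 1)
    A[5, ] <- c(0, 0, 0, n, -(n + 1));               y[5] <- 0
    x <- solve(A, y)
    G[n] <- x[4] + x[5]                              # A3 + B3 at the surface
  }
  G
}

## Potentials (V per A.m) at scalp-surface points for unit x/y/z moments at
## each generator.  `points` are unit vectors (scaled internally to the scalp
## radius); columns of the result are generator-major (x, y, z per generator).
.sphere_potentials <- function(head, points, gen_pos, gains) {
  R <- head$radii["scalp"]
  sigma1 <- head$conductivities["brain"]
  n_terms <- head$n_terms
  npts <- nrow(points)
  ngen <- nrow(gen_pos)
  out <- matrix(0, npts, 3L * ngen)
  E <- points / sqrt(rowSums(points^2))            # electrode unit vectors
  n_seq <- seq_len(n_terms)
  for (g in seq_len(ngen)) {
    p0 <- gen_pos[g, ]
    b <- sqrt(sum(p0^2))
    if (b < 1e-12) {
      ## generator at the centre: only the n = 1 term survives, direction-free
      er <- c(0, 0, 1); bR <- 0
    } else {
      er <- p0 / b; bR <- b / R
    }
    ct <- pmin(1, pmax(-1, drop(E %*% er)))        # cos(theta) per point
    ## Legendre P_n and P'_n by stable recurrences
    P <- matrix(0, npts, n_terms); dP <- matrix(0, npts, n_terms)
    Pm2 <- rep(1, npts); Pm1 <- ct                  # P_0, P_1
    dPm2 <- rep(0, npts); dPm1 <- rep(1, npts)      # P'_0, P'_1
    P[, 1] <- Pm1; dP[, 1] <- dPm1
    for (n in 1L + seq_len(n_terms - 1L)) {
      Pn <- ((2 * n - 1) * ct * Pm1 - (n - 1) * Pm2) / n
      dPn <- dPm2 + (2 * n - 1) * Pm1
      P[, n] <- Pn; dP[, n] <- dPn
      Pm2 <- Pm1; Pm1 <- Pn; dPm2 <- dPm1; dPm1 <- dPn
    }
    w <- gains * bR^(n_seq - 1L)                   # per-degree weight
    S_rad <- P %*% (w * n_seq)                     # radial-moment sum
    S_tan <- dP %*% w                              # tangential-moment sum
    const <- 1 / (4 * pi * sigma1 * R^2)
    Eperp <- E - drop(E %*% er) %o% er             # electrode vectors, comp. perp to er
    for (k in 1:3) {
      ek <- c(0, 0, 0); ek[k] <- 1
      mr <- sum(ek * er)
      tk <- ek - mr * er                           # tangential part of moment
      out[, 3L * (g - 1L) + k] <-
        const * (mr * S_rad + (Eperp %*% tk) * S_tan)
    }
  }
  out
}

#' Predict referenced scalp potentials from a primary current density vector
#'
#' @param object a `lead_field`.
#' @param pcd numeric vector of length `3 * n_generators` (nA.m, generator-major
#'   x,y,z order) or a matrix with that many rows.
#' @param ... unused.
#' @return vector (or matrix) of referenced channel potentials in microvolts.
#' @export
predict.lead_field <- function(object, pcd, ...) {
  drop(object$matrix %*% pcd)
}

#' @export
print.lead_field <- function(x, ...) {
  cat(sprintf("Lead field: %d channels x %d generators (x,y,z), %s, %s\n",
              nrow(x$matrix), x$n_generators, x$units,
              if (x$reference_applied) "referenced" else "unreferenced"))
  invisible(x)
}

#' Write / read a lead field as a binary array with a text sidecar header
#'
#' The gain matrix is stored as little-endian doubles in column order in
#' `<path>.bin`; `<path>.hdr` is a plain-text header recording dimensions,
#' channel names and units.
#'
#' @param lf a `lead_field`.
#' @param path base path (without extension).
#' @return [write_lead_field()] the base path, invisibly; [read_lead_field()]
#'   a `lead_field`.
#' @export
write_lead_field <- function(lf, path) {
  stopifnot(inherits(lf, "lead_field"))
  con <- file(paste0(path, ".bin"), "wb")
  writeBin(as.vector(lf$matrix), con, size = 8, endian = "little")
  close(con)
  writeLines(c(sprintf("channels %d", nrow(lf$matrix)),
               sprintf("generators %d", lf$n_generators),
               sprintf("units %s", lf$units),
               sprintf("reference_applied %d", as.integer(lf$reference_applied)),
               paste("channel_names", paste(lf$channels, collapse = " "))),
             paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname write_lead_field
#' @export
read_lead_field <- function(path) {
  hdr <- readLines(paste0(path, ".hdr"))
  get_field <- function(key) sub(paste0("^", key, " "), "",
                                 grep(paste0("^", key, " "), hdr, value = TRUE)[1])
  nch <- as.integer(get_field("channels"))
  ngen <- as.integer(get_field("generators"))
  con <- file(paste0(path, ".bin"), "rb")
  vals <- readBin(con, "double", n = nch * 3L * ngen, size = 8, endian = "little")
  close(con)
  M <- matrix(vals, nch, 3L * ngen)
  rownames(M) <- strsplit(get_field("channel_names"), " ")[[1]]
  structure(list(matrix = M,
                 reference_applied = as.integer(get_field("reference_applied")) == 1L,
                 channels = rownames(M),
                 n_generators = ngen,
                 units = get_field("units")),
            class = "lead_field")
}
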