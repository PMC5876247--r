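#' Study design of a simulated 2x2 ERP experiment
#'
#' Records the acquisition parameters of the synthetic study: epoch grid,
#' trial counts, sensor-noise model and between-subject variability.  The
#' defaults reproduce a 250 Hz, 256-sample epoch starting 200 ms before
#' stimulus onset, 40 trials per condition and 28 participants.
#'
#' @param n_subjects,n_trials counts (>= 1); trials are per condition.
#' @param fs sampling rate in Hz.
#' @param n_samples samples per epoch.
#' @param baseline pre-stimulus interval in ms (baseline-correction window).
#' @param noise_sd single-trial sensor noise standard deviation in microvolts.
#' @param noise_spatial_corr angular decay length (degrees of inter-electrode
#'   great-circle angle) of the exponential spatial noise correlation.
#' @param subject_sd between-subject multiplicative amplitude spread
#'   (standard deviation of the per-subject gain around 1).
#' @param artifact_prob per-trial probability of an artifact pulse exceeding
#'   +/-100 microvolts on a frontal channel.
#' @param seed integer seed.
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_subjects = 28L, n_trials = 40L, fs = 250,
                         n_samples = 256L, baseline = 200, noise_sd = 10,
                         noise_spatial_corr = 30, subject_sd = 0.2,
                         artifact_prob = 0.1, seed = 1L) {
  d <- list(n_subjects = as.integer(n_subjects), n_trials = as.integer(n_trials),
            fs = fs, n_samples = as.integer(n_samples), baseline = baseline,
            noise_sd = noise_sd, noise_spatial_corr = noise_spatial_corr,
            subject_sd = subject_sd, artifact_prob = artifact_prob,
            seed = as.integer(seed))
  if (d$n_subjects < 1L || d$n_trials < 1L || d$n_samples < 1L)
    stop("all counts must be >= 1")
  if (d$n_samples * (1000 / d$fs) <= d$baseline)
    stop("epoch does not cover the baseline plus a post-stimulus span")
  class(d) <- "study_design"
  d
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf(
    "Study design: %d subjects, %d trials/condition, %d samples @ %g Hz (baseline %g ms)\n",
    x$n_subjects, x$n_trials, x$n_samples, x$fs, x$baseline))
  invisible(x)
}

## epoch latency grid in ms: first sample at -baseline
.epoch_times <- function(design) {
  -design$baseline + (seq_len(design$n_samples) - 1L) * 1000 / design$fs
}

## spatially correlated noise: Sigma_ij = sd^2 * exp(-angle_ij / corr_len)
.noise_chol <- function(mon, noise_sd, corr_len_deg) {
  if (noise_sd <= 0) return(NULL)
  gram <- pmin(pmax(mon$positions %*% t(mon$positions), -1), 1)
  ang <- acos(gram) * 180 / pi
  diag(ang) <- 0                    # guard the self-angle against FP jitter
  Sigma <- noise_sd^2 * exp(-ang / corr_len_deg)
  chol(Sigma + diag(1e-10 * noise_sd^2, nrow(Sigma)))
}

#' Simulate raw epochs of a 2x2 ERP study
#'
#' Each trial is the sum over planted components of
#' `amplitude(condition) * subject gain * Gaussian time course * lead-field
#' projection of a dipole at the component's compartment centroid`, plus
#' spatially correlated Gaussian sensor noise, plus (with probability
#' `design$artifact_prob` per trial) a square artifact pulse exceeding
#' +/-100 microvolts on a random frontal channel.  Deterministic for a fixed
#' `design$seed`.
#'
#' @param design a [study_design()].
#' @param components list of [component_spec()].
#' @param head,mon,space forward-model pieces ([head_model()], [montage()],
#'   [source_space()]).
#' @param lf optional precomputed [lead_field()] (computed if missing).
#' @return Object of class `epoch_set`: `data` is a subject x condition x
#'   trial x channel x time array in microvolts, plus the design, montage
#'   names and latency grid.
#' @export
simulate_epochs <- function(design, components, head, mon, space, lf = NULL) {
  stopifnot(inherits(design, "study_design"))
  if (is.null(lf)) lf <- lead_field(head, mon, space)
  times <- .epoch_times(design)
  nch <- length(mon$names)
  scalp <- .component_scalp_patterns(components, space, lf)   # nch x ncomp
  amps <- vapply(components, function(cs) cs$amplitude, numeric(4)) # 4 x ncomp
  tc <- vapply(components, function(cs)
    cs$polarity * exp(-0.5 * ((times - cs$peak_latency) / cs$width)^2),
    numeric(length(times)))                                   # ntime x ncomp

  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(design$seed)
  ch_noise <- .noise_chol(mon, design$noise_sd, design$noise_spatial_corr)
  frontal <- grep("^(FP|AF|F)[0-9z]", mon$names)
  if (!length(frontal)) frontal <- seq_len(nch)

  dat <- array(0, dim = c(design$n_subjects, 4L, design$n_trials, nch,
                          design$n_samples))
  for (s in seq_len(design$n_subjects)) {
    gains <- 1 + stats::rnorm(length(components), 0, design$subject_sd)
    gains <- pmax(gains, 0.1)
    for (cond in 1:4) {
      ## signal common to all trials of this subject x condition
      sig <- scalp %*% (t(tc) * (amps[cond, ] * gains))       # nch x ntime
      nt <- design$n_samples; ntr <- design$n_trials
      ## all trials' noise in one draw: channels x (samples * trials)
      block <- if (is.null(ch_noise))
        matrix(0, nch, nt * ntr) else
        crossprod(ch_noise, matrix(stats::rnorm(nch * nt * ntr), nch))
      block <- block + as.vector(sig)               # recycles over trials
      if (design$artifact_prob > 0) {
        hit <- which(stats::runif(ntr) < design$artifact_prob)
        for (tr in hit) {
          ch <- frontal[sample.int(length(frontal), 1L)]
          t0 <- sample.int(nt - 10L, 1L)
          cidx <- (tr - 1L) * nt + t0:(t0 + 9L)
          block[ch, cidx] <- block[ch, cidx] +
            sample(c(-1, 1), 1L) * stats::runif(1, 120, 180)
        }
      }
      ## channels x samples x trials -> trials x channels x samples
      dim(block) <- c(nch, nt, ntr)
      dat[s, cond, , , ] <- aperm(block, c(3, 1, 2))
    }
  }
  structure(list(data = dat, design = design, channels = mon$names,
                 times = times, conditions = .cond_names),
            class = "epoch_set")
}

## referenced scalp pattern (uV per nA.m) of each component's unit dipole
.component_scalp_patterns <- function(components, space, lf) {
  pats <- vapply(components, function(cs) {
    id <- .resolve_compartments(space, cs$compartment)
    cent <- compartment_centroids(space, id)[1, ]
    ori <- if (identical(cs$orientation, "radial"))
      cent / sqrt(sum(cent^2)) else cs$orientation
    ## nearest generator to the centroid carries the dipole
    d2 <- rowSums((space$positions - matrix(cent, space$n_generators, 3,
                                            byrow = TRUE))^2)
    g <- which.min(d2)
    cols <- 3L * (g - 1L) + (1:3)
    drop(lf$matrix[, cols] %*% ori)
  }, numeric(nrow(lf$matrix)))
  matrix(pats, nrow = nrow(lf$matrix))
}

#' @export
print.epoch_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Epoch set: %d subjects x %d conditions x %d trials x %d channels x %d samples\n",
              d[1], d[2], d[3], d[4], d[5]))
  invisible(x)
}

#' Artifact rejection, trial equalisation and averaging
#'
#' Drops trials whose absolute amplitude exceeds `threshold` anywhere,
#' equalises the kept-trial count across conditions per subject by seeded
#' random subsampling, averages the kept trials, removes a linear trend per
#' channel from the average and subtracts the baseline-window mean.
#'
#' @param epochs an `epoch_set`.
#' @param threshold rejection threshold in microvolts (default 100).
#' @param min_kept minimum surviving trials per condition (default 24); fewer
#'   is an error naming the subject and condition.
#' @param equalize logical; equalise kept-trial counts across conditions.
#' @param seed seed for the equalisation subsample.
#' @return An `erp_set`: `data` is subject x condition x channel x time (uV),
#'   with `times`, `fs`, `baseline`, `conditions`, `channels`, and a
#'   `kept` matrix (subject x condition trial counts).
#' @export
reject_and_average <- function(epochs, threshold = 100, min_kept = 24L,
                               equalize = TRUE, seed = 1L) {
  stopifnot(inherits(epochs, "epoch_set"))
  d <- dim(epochs$data)
  ns <- d[1]; nc <- d[2]; nt <- d[3]; nch <- d[4]; nti <- d[5]
  min_kept <- min(as.integer(min_kept), nt)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  avg <- array(0, dim = c(ns, nc, nch, nti))
  kept_n <- matrix(0L, ns, nc)
  kept_idx <- vector("list", ns)
  for (s in seq_len(ns)) {
    keep <- lapply(seq_len(nc), function(cond) {
      flat <- abs(epochs$data[s, cond, , , ])
      dim(flat) <- c(nt, nch * nti)
      which(apply(flat, 1L, max) <= threshold)
    })
    nkeep <- lengths(keep)
    bad <- which(nkeep < min_kept)
    if (length(bad))
      stop(sprintf("subject %d, condition %s: only %d trials survive (< %d)",
                   s, epochs$conditions[bad[1]], nkeep[bad[1]], min_kept))
    if (equalize) {
      m <- min(nkeep)
      keep <- lapply(keep, function(k) if (length(k) > m) sort(sample(k, m)) else k)
    }
    kept_idx[[s]] <- keep
    for (cond in seq_len(nc)) {
      kept_n[s, cond] <- length(keep[[cond]])
      block <- epochs$data[s, cond, keep[[cond]], , , drop = FALSE]
      dim(block) <- c(length(keep[[cond]]), nch, nti)
      a <- colMeans(block)                        # nch x nti
      avg[s, cond, , ] <- .detrend_baseline(a, epochs$times)
    }
  }
  structure(list(data = avg, times = epochs$times, fs = epochs$design$fs,
                 baseline = epochs$design$baseline,
                 conditions = epochs$conditions, channels = epochs$channels,
                 subjects = seq_len(ns), kept = kept_n),
            class = "erp_set")
}

## linear detrend per channel, then zero the pre-stimulus baseline mean
.detrend_baseline <- function(a, times) {
  tt <- seq_along(times)
  X <- cbind(1, tt)
  coefs <- solve(crossprod(X), crossprod(X, t(a)))   # 2 x nch
  a <- a - t(X %*% coefs)
  bl <- times < 0
  if (any(bl)) a <- a - rowMeans(a[, bl, drop = FALSE])
  a
}

#' Construct an `erp_set` from an array
#'
#' Assembles averaged ERP data into the container used throughout the
#' package, for user-supplied data or tests.
#'
#' @param data subject x condition x channel x time array (microvolts).
#' @param times latency grid in ms (time 0 = stimulus onset).
#' @param fs sampling rate in Hz.
#' @param baseline pre-stimulus span in ms.
#' @param conditions condition labels (length 4 for the 2x2 design).
#' @param channels channel labels.
#' @return An `erp_set`.
#' @export
erp_set <- function(data, times, fs = 250, baseline = 200,
                    conditions = .cond_names,
                    channels = dimnames(data)[[3]]) {
  stopifnot(length(dim(data)) == 4L, dim(data)[4] == length(times))
  if (is.null(channels)) channels <- sprintf("ch%02d", seq_len(dim(data)[3]))
  structure(list(data = data, times = times, fs = fs, baseline = baseline,
                 conditions = conditions, channels = channels,
                 subjects = seq_len(dim(data)[1]), kept = NULL),
            class = "erp_set")
}

#' @export
print.erp_set <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("ERP set: %d subjects x %d conditions x %d channels x %d samples (%g..%g ms @ %g Hz)\n",
              d[1], d[2], d[3], d[4], min(x$times), max(x$times), x$fs))
  invisible(x)
}

#' Generate a complete synthetic ERP study
#'
#' Presets:
#' * `"paper_like"`: 28 subjects, 60 channels, 40 trials per condition,
#'   2x2 design; plants N170 sources in distinct compartments per task, P200
#'   and N250 in the intra-domain task only, and a task-specific N400-like
#'   mismatch source per task (330-440 ms window).
#' * `"null"`: identical acquisition, no components — all condition means are
#'   equal in expectation.
#' * `"small"`: a reduced variant of `"paper_like"` (fewer subjects/trials,
#'   coarse source space) for quick demonstrations.
#'
#' The returned ground-truth record lists the planted compartments and
#' amplitudes for recovery checks.
#'
#' @param preset `"paper_like"`, `"null"` or `"small"`.
#' @param seed integer seed (drives all randomness).
#' @param ... overrides forwarded to [study_design()] (e.g. `n_trials`,
#'   `n_samples` to scale the simulation down).
#' @param n_generators,n_compartments source-space size.
#' @return list with elements `erps` (an `erp_set`), `ground_truth` (planted
#'   compartments/amplitudes and forward-model objects) and `epochs_kept`.
#' @export
generate_study <- function(preset = c("paper_like", "null", "small"), seed = 1L,
                           ..., n_generators = 500L, n_compartments = 12L) {
  preset <- match.arg(preset)
  overrides <- list(...)
  base_args <- switch(preset,
    paper_like = list(),
    null = list(),
    small = list(n_subjects = 8L, n_trials = 12L, n_samples = 192L,
                 baseline = 200))
  design <- do.call(study_design,
                    utils::modifyList(c(base_args, list(seed = seed)), overrides))
  if (preset == "small") {
    n_generators <- min(n_generators, 150L); n_compartments <- min(n_compartments, 8L)
  }
  head <- head_model()
  mon <- montage()
  space <- source_space(n_generators, n_compartments, seed = 17L)
  lf <- lead_field(head, mon, space)
  comps <- if (preset == "null") list() else {
    ## the emulated components arise in posterior visual/occipitotemporal
    ## cortex: plant them in the six most posterior-superior compartments
    ## (deterministic; +x is the front of the head, +z the vertex), which also
    ## guarantees electrode coverage of the sources
    cent <- compartment_centroids(space)
    score <- -cent[, 1] + cent[, 3]
    ids <- as.integer(names(space$atlas))[order(score, decreasing = TRUE)]
    ids <- rep(ids[seq_len(min(6L, length(ids)))], length.out = 6L)
    default_components(c(n170_intra = ids[1], n170_cross = ids[2],
                         p200 = ids[3], n250 = ids[4],
                         n400_intra = ids[5], n400_cross = ids[6]))
  }
  ## stream per subject to bound memory
  one <- design; one$n_subjects <- 1L
  erp_dat <- array(0, dim = c(design$n_subjects, 4L, length(mon$names),
                              design$n_samples))
  kept <- matrix(0L, design$n_subjects, 4L)
  for (s in seq_len(design$n_subjects)) {
    ## per-subject substream; a subject whose recording loses too many trials
    ## to artifacts is re-recorded under a shifted substream (the study always
    ## delivers its full sample, like re-running a noisy session)
    for (attempt in 0:3) {
      one$seed <- (design$seed %% 1000000L) * 1000L + s + 250000L * attempt
      ep <- simulate_epochs(one, comps, head, mon, space, lf = lf)
      ## the 24-of-40 minimum of the full design, scaled to the trial count
      av <- tryCatch(
        reject_and_average(ep, threshold = 100,
                           min_kept = min(24L, ceiling(0.6 * design$n_trials)),
                           equalize = TRUE, seed = one$seed),
        error = function(e) if (attempt < 3) NULL else stop(e))
      if (!is.null(av)) break
    }
    erp_dat[s, , , ] <- av$data[1, , , ]
    kept[s, ] <- av$kept[1, ]
  }
  erps <- erp_set(erp_dat, .epoch_times(design), fs = design$fs,
                  baseline = design$baseline, channels = mon$names)
  gt <- list(preset = preset, seed = seed, design = design,
             components = comps, head = head, montage = mon, space = space,
             lead_field = lf,
             planted = if (length(comps))
               data.frame(name = vapply(comps, `[[`, "", "name"),
                          compartment = vapply(comps, function(cs)
                            .resolve_compartments(space, cs$compartment), 1L),
                          stringsAsFactors = FALSE) else NULL)
  list(erps = erps, ground_truth = gt, epochs_kept = kept)
}
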