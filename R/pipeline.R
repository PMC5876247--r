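#' Pipeline configuration
#'
#' Assembles and validates the configuration of the full analysis pipeline
#' (simulation, sensor statistics, feature extraction, BMA inversion, group
#' conjunction).  The configuration round-trips losslessly through
#' [write_pipeline_config()] / [read_pipeline_config()] (YAML).
#'
#' @param preset study preset forwarded to [generate_study()].
#' @param seed global integer seed; every stage derives its substream from it
#'   by a fixed offset scheme (stage index appended to the seed), so stages
#'   rerun standalone reproduce the pipeline exactly.
#' @param q FDR level for the sensor-level maps.
#' @param n400_window feature window in ms for the late mismatch effect.
#' @param n400_source `"mismatch"` inverts the mismatch-condition feature (the
#'   default); `"difference"` inverts mismatch minus match.
#' @param max_size,occam_window BMA settings (see [bma_solve()]).
#' @param lfdr_threshold binarization cut-off (see [binarize_lfdr()]).
#' @param n_iter,perm_q permutation iterations and FDR level for the
#'   difference-map threshold.
#' @param n_generators,n_compartments source-space size.
#' @param feature_set components to carry through inversion and conjunction:
#'   subset of `c("N400", "N170", "P200", "N250")`.
#' @param design_overrides named list forwarded to [study_design()].
#' @param out_dir output directory (`NULL` = no files written).
#' @return Object of class `pipeline_config` (a validated named list).
#' @export
pipeline_config <- function(preset = "paper_like", seed = 1L, q = 0.05,
                            n400_window = c(330, 440),
                            n400_source = c("mismatch", "difference"),
                            max_size = 2L, occam_window = 1 / 20,
                            lfdr_threshold = 0.2, n_iter = 10000L,
                            perm_q = 0.05, n_generators = 500L,
                            n_compartments = 12L,
                            feature_set = c("N400", "N170", "P200", "N250"),
                            design_overrides = list(), out_dir = NULL) {
  n400_source <- match.arg(n400_source)
  feature_set <- match.arg(feature_set, several.ok = TRUE)
  cfg <- list(preset = preset, seed = as.integer(seed), q = q,
              n400_window = as.numeric(n400_window), n400_source = n400_source,
              max_size = as.integer(max_size), occam_window = occam_window,
              lfdr_threshold = lfdr_threshold, n_iter = as.integer(n_iter),
              perm_q = perm_q, n_generators = as.integer(n_generators),
              n_compartments = as.integer(n_compartments),
              feature_set = feature_set,
              design_overrides = design_overrides, out_dir = out_dir)
  for (nm in c("q", "perm_q", "lfdr_threshold"))
    if (!(cfg[[nm]] > 0 && cfg[[nm]] < 1))
      stop(nm, " must lie in (0, 1)")
  if (length(cfg$n400_window) != 2L || diff(cfg$n400_window) <= 0)
    stop("n400_window must be an increasing pair of latencies (ms)")
  if (cfg$n_iter < 100L) stop("n_iter must be at least 100")
  class(cfg) <- "pipeline_config"
  cfg
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat(sprintf("Pipeline config: preset %s, seed %d, q %.3g, model size <= %d, n_iter %d\n",
              x$preset, x$seed, x$q, x$max_size, x$n_iter))
  invisible(x)
}

#' @rdname pipeline_config
#' @param cfg a `pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$design_overrides <- as.list(raw$design_overrides)
  if (!is.null(raw$feature_set)) raw$feature_set <- as.character(unlist(raw$feature_set))
  if (!is.null(raw$out_dir) && !nzchar(raw$out_dir)) raw$out_dir <- NULL
  do.call(pipeline_config, raw)
}

## stage substreams: a documented counter scheme on the global seed
.stage_seed <- function(seed, stage)
  (seed %% 1000000L) * 100L + stage

#' Run the full analysis pipeline
#'
#' Executes simulate -> sensor statistics -> feature extraction -> BMA
#' inversion -> group conjunction on a synthetic study (or user-supplied
#' `erps`).  With `out_dir` set, every product is written as delimited text
#' together with a `manifest.tsv` of files and MD5 hashes and a
#' `config.yaml` with the fully resolved configuration; identical config and
#' seed give identical numeric outputs.
#'
#' @param cfg a [pipeline_config()].
#' @param erps optional `erp_set` to analyse instead of simulating (the
#'   forward model and ground truth still come from the preset machinery).
#' @param verbose print stage timings.
#' @return list with `anova` (3 stat maps, FDR-selected), `posthoc`, `zmaps`,
#'   `features`, `ismaps` (per component/task, per subject `bma_loreta`
#'   fits), `conjunction` (per component/task `conjunction_map`),
#'   `difference` (signed permutation-thresholded maps, N170 and N400),
#'   `cluster_tables`, `ground_truth`, `config`, `log`.
#' @export
run_pipeline <- function(cfg, erps = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  t0 <- proc.time()[3]
  log <- character()
  say <- function(fmt, ...) {
    msg <- sprintf("[%7.2fs] %s", proc.time()[3] - t0, sprintf(fmt, ...))
    log <<- c(log, msg)
    if (verbose) message(msg)
  }

  ## stage 1: simulate (seed substream 1)
  say("simulate: preset %s", cfg$preset)
  study <- do.call(generate_study,
                   c(list(preset = cfg$preset, seed = .stage_seed(cfg$seed, 1L),
                          n_generators = cfg$n_generators,
                          n_compartments = cfg$n_compartments),
                     cfg$design_overrides))
  if (is.null(erps)) erps <- study$erps
  gt <- study$ground_truth
  space <- gt$space; lf <- gt$lead_field

  ## stage 2: sensor statistics
  say("sensor stats: RM-ANOVA over %d x %d points", dim(erps$data)[3],
      dim(erps$data)[4])
  anova <- rm_anova_2x2(erps)
  anova <- lapply(anova, fdr_select, q = cfg$q)
  posthoc <- posthoc_maps(erps, anova, q = cfg$q)
  zmaps <- lapply(anova, p_to_z)

  ## stage 3: features (window N400 per task; peaks for the early components)
  say("features: N400 window %g-%g ms (%s)", cfg$n400_window[1],
      cfg$n400_window[2], cfg$n400_source)
  n400_feature <- function(task) {
    mm <- extract_feature(erps, feature_window(cfg$n400_window[1],
                                               cfg$n400_window[2],
                                               paste0(task, ".mismatch")))
    if (cfg$n400_source == "difference") {
      ma <- extract_feature(erps, feature_window(cfg$n400_window[1],
                                                 cfg$n400_window[2],
                                                 paste0(task, ".match")))
      mm - ma
    } else mm
  }
  post_ch <- .posterior_channels(erps$channels)
  all_features <- list(
    N400.intra = function() n400_feature("intra"),
    N400.cross = function() n400_feature("cross"),
    N170.intra = function() extract_feature(erps,
      feature_peak("N170", -1, c(130, 200), post_ch, "intra.mismatch")),
    N170.cross = function() extract_feature(erps,
      feature_peak("N170", -1, c(130, 200), post_ch, "cross.mismatch")),
    P200.intra = function() extract_feature(erps,
      feature_peak("P200", +1, c(180, 250), post_ch, "intra.mismatch")),
    N250.intra = function() extract_feature(erps,
      feature_peak("N250", -1, c(230, 310), post_ch, "intra.mismatch")))
  wanted <- grepl(paste0("^(", paste(cfg$feature_set, collapse = "|"), ")\\."),
                  names(all_features))
  features <- lapply(all_features[wanted], function(f) f())

  ## stage 4: per-subject BMA inversion (shared model bases)
  models <- enumerate_models(space, cfg$max_size)
  say("inversion: %d models, %d feature sets", length(models), length(features))
  bases <- lapply(models, function(m) .model_basis(lf, space, m))
  ismaps <- lapply(features, function(fm) {
    lapply(seq_len(nrow(fm)), function(s) {
      if (anyNA(fm[s, ])) return(NULL)      # peak not found for this subject
      bma_solve(fm[s, ], lf, space, models = models,
                occam_window = cfg$occam_window, bases = bases)
    })
  })

  ## stage 5: binarization + conjunction
  say("conjunction: lfdr threshold %g", cfg$lfdr_threshold)
  binmaps <- lapply(ismaps, function(fits) {
    lapply(fits, function(f)
      if (is.null(f)) NULL else
        suppressWarnings(binarize_lfdr(f, cfg$lfdr_threshold)))
  })
  conj <- lapply(binmaps, function(bm) conjunction(Filter(Negate(is.null), bm)))

  ## stage 6: signed difference conjunctions between tasks + permutation
  say("difference maps: permutation n_iter %d, q %g", cfg$n_iter, cfg$perm_q)
  diff_pair <- function(a, b) {
    keep <- !vapply(binmaps[[a]], is.null, TRUE) &
            !vapply(binmaps[[b]], is.null, TRUE)
    permutation_threshold(binmaps[[a]][keep], binmaps[[b]][keep],
                          n_iter = cfg$n_iter, q = cfg$perm_q,
                          seed = .stage_seed(cfg$seed, 6L))
  }
  difference <- list()
  if (all(c("N170.intra", "N170.cross") %in% names(binmaps)))
    difference$N170 <- diff_pair("N170.intra", "N170.cross")
  if (all(c("N400.intra", "N400.cross") %in% names(binmaps)))
    difference$N400 <- diff_pair("N400.intra", "N400.cross")

  tables <- c(lapply(conj, cluster_table, space = space, min_value = 0.5),
              lapply(difference, cluster_table, space = space))

  res <- list(anova = anova, posthoc = posthoc, zmaps = zmaps,
              features = features, ismaps = ismaps, conjunction = conj,
              difference = difference, cluster_tables = tables,
              ground_truth = gt, config = cfg, log = log)
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(res, space, cfg$out_dir)
  res
}

.write_pipeline_outputs <- function(res, space, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  put <- function(writer, obj, name, ...) {
    p <- file.path(out_dir, name)
    writer(obj, ..., path = p)
    files <<- c(files, name)
  }
  for (nm in names(res$anova))
    put(write_stat_map, res$anova[[nm]], sprintf("anova_%s.csv", nm))
  for (nm in names(res$posthoc))
    put(write_stat_map, res$posthoc[[nm]], sprintf("posthoc_%s.csv", nm))
  for (nm in names(res$conjunction))
    put(write_conjunction_map, res$conjunction[[nm]],
        sprintf("conjunction_%s.csv", nm), space = space)
  for (nm in names(res$difference))
    put(write_conjunction_map, res$difference[[nm]],
        sprintf("difference_%s.csv", nm), space = space)
  for (nm in names(res$cluster_tables))
    put(write_cluster_table, res$cluster_tables[[nm]],
        sprintf("clusters_%s.csv", nm))
  cfg_path <- file.path(out_dir, "config.yaml")
  write_pipeline_config(res$config, cfg_path)
  writeLines(res$log, file.path(out_dir, "pipeline.log"))
  md5 <- tools::md5sum(file.path(out_dir, files))
  man <- data.frame(file = files, md5 = unname(md5))
  utils::write.table(man, file.path(out_dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
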