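#' Write / read an ERP set as delimited text with a manifest
#'
#' One whitespace-delimited matrix file per subject x condition
#' (`channels x time`; header row of latencies in ms, first column the channel
#' label), plus a tab-separated manifest `manifest.tsv` listing
#' `subject, task, match, file` rows and the sampling metadata as `#` header
#' comments.  The round trip preserves values to full double precision.
#'
#' @param erps an `erp_set`.
#' @param dir output directory (created if missing).
#' @return [write_erpset()] the manifest path, invisibly; [read_erpset()] an
#'   `erp_set`.
#' @export
write_erpset <- function(erps, dir) {
  stopifnot(inherits(erps, "erp_set"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(erps$data)
  rows <- list()
  for (s in seq_len(d[1])) for (cond in seq_len(d[2])) {
    tk <- strsplit(erps$conditions[cond], ".", fixed = TRUE)[[1]]
    fn <- sprintf("erp_s%02d_%s.txt", s, erps$conditions[cond])
    mat <- erps$data[s, cond, , ]
    lines <- c(paste(c("channel", formatC(erps$times, format = "g", digits = 17)),
                     collapse = " "),
               vapply(seq_len(d[3]), function(ch)
                 paste(c(erps$channels[ch],
                         formatC(mat[ch, ], format = "g", digits = 17)),
                       collapse = " "), ""))
    writeLines(lines, file.path(dir, fn))
    rows[[length(rows) + 1L]] <- data.frame(
      subject = s, task = tk[1], match = tk[2], file = fn,
      stringsAsFactors = FALSE)
  }
  man <- file.path(dir, "manifest.tsv")
  con <- file(man, "w")
  writeLines(c(sprintf("# fs %.17g", erps$fs),
               sprintf("# baseline %.17g", erps$baseline)), con)
  utils::write.table(do.call(rbind, rows), con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  close(con)
  invisible(man)
}

#' @rdname write_erpset
#' @param path manifest file path (or the directory containing
#'   `manifest.tsv`).
#' @export
read_erpset <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.tsv")
  if (!file.exists(path)) stop("manifest not found: ", path)
  hdr <- readLines(path, n = 10L)
  get_num <- function(key) {
    ln <- grep(paste0("^# ", key, " "), hdr, value = TRUE)
    if (!length(ln)) stop("manifest lacks '# ", key, "' header")
    as.numeric(sub(paste0("^# ", key, " "), "", ln[1]))
  }
  fs <- get_num("fs"); baseline <- get_num("baseline")
  man <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("subject", "task", "match", "file")
  if (!all(need %in% names(man))) stop("manifest needs columns: ",
                                       paste(need, collapse = ", "))
  man$condition <- paste(man$task, man$match, sep = ".")
  bad <- !(man$condition %in% .cond_names)
  if (any(bad))
    stop("unknown condition label(s): ", paste(unique(man$condition[bad]),
                                               collapse = ", "))
  subjects <- sort(unique(man$subject))
  base_dir <- dirname(path)
  first <- TRUE
  dat <- NULL; times <- NULL; channels <- NULL
  for (i in seq_len(nrow(man))) {
    f <- file.path(base_dir, man$file[i])
    if (!file.exists(f)) stop("manifest references a missing file: ", man$file[i])
    raw <- utils::read.table(f, header = FALSE, skip = 1L,
                             stringsAsFactors = FALSE)
    hd <- scan(f, what = character(), nlines = 1L, quiet = TRUE)
    tms <- as.numeric(hd[-1])
    ch <- raw[[1]]
    vals <- as.matrix(raw[, -1, drop = FALSE])
    if (ncol(vals) != length(tms))
      stop(sprintf("%s: %d data columns but %d latencies (line 1)",
                   man$file[i], ncol(vals), length(tms)))
    if (first) {
      times <- tms; channels <- ch
      dat <- array(NA_real_, c(length(subjects), 4L, length(ch), length(tms)))
      first <- FALSE
    } else {
      if (!isTRUE(all.equal(tms, times)))
        stop(man$file[i], ": latency grid differs from the first file")
      if (!identical(ch, channels)) {
        delta <- union(setdiff(channels, ch), setdiff(ch, channels))
        stop(man$file[i], ": channel set differs from the first file",
             if (length(delta)) paste0(" (", paste(delta, collapse = ", "), ")"))
      }
    }
    s <- match(man$subject[i], subjects)
    cond <- match(man$condition[i], .cond_names)
    dat[s, cond, , ] <- vals
  }
  if (anyNA(dat)) stop("manifest does not cover every subject x condition")
  erp_set(dat, times, fs = fs, baseline = baseline, channels = channels)
}
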