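#' @keywords internal
#' Spherical angles -> unit vector.  Coordinate frame: +x through the nasion
#' (front), +y through the left preauricular point, +z through the vertex.
#' `azimuth_deg` is measured from the front midline, positive towards the left;
#' `elevation_deg` is measured up from the horizontal (equator) plane.
.sph_to_unit <- function(azimuth_deg, elevation_deg) {
  az <- azimuth_deg * pi / 180
  el <- elevation_deg * pi / 180
  cbind(x = cos(el) * cos(az), y = cos(el) * sin(az), z = sin(el))
}

.unit_to_sph <- function(p) {
  el <- asin(pmin(1, pmax(-1, p[, 3]))) * 180 / pi
  az <- atan2(p[, 2], p[, 1]) * 180 / pi
  cbind(azimuth_deg = az, elevation_deg = el)
}

## Channel labels of the 60-channel extended 10/20 recording montage,
## anterior to posterior, left to right.
.paper60_labels <- c(
  "FP1", "FPz", "FP2", "AF3", "AF4",
  "F7", "F5", "F3", "F1", "Fz", "F2", "F4", "F6", "F8",
  "FT7", "FC5", "FC3", "FC1", "FCz", "FC2", "FC4", "FC6", "FT8",
  "T7", "C5", "C3", "C1", "Cz", "C2", "C4", "C6", "T8",
  "TP7", "CP5", "CP3", "CP1", "CPz", "CP2", "CP4", "CP6", "TP8",
  "P7", "P5", "P3", "P1", "Pz", "P2", "P4", "P6", "P8",
  "PO7", "PO5", "PO3", "POz", "PO4", "PO6", "PO8",
  "O1", "Oz", "O2")

## Spherical positions for the extended 10/20 layout, constructed from the
## scheme's arc geometry: the outer ring (Fp, F7/8, FT7/8, T7/8, TP7/8, P7/8,
## PO7/8, O sites) lies on the circle 72 degrees from the vertex, sampled every
## 18 degrees of azimuth; each coronal row runs from its midline site to its
## outer-ring site along a great circle, with intermediate electrodes at
## fractions 1/4, 1/2, 3/4 of that arc.
.paper60_positions <- function() {
  vertex <- c(0, 0, 1)
  ## great-circle interpolation between two unit vectors
  slerp <- function(a, b, f) {
    w <- acos(pmin(1, pmax(-1, sum(a * b))))
    if (w < 1e-12) return(a)
    (sin((1 - f) * w) * a + sin(f * w) * b) / sin(w)
  }
  ## point on the outer ring: azimuth from front midline (deg, +left)
  ring <- function(az) drop(.sph_to_unit(az, 90 - 72))
  ## midline point at `beta` degrees from the vertex, towards front (+) / back (-)
  midline <- function(beta) {
    az <- if (beta >= 0) 0 else 180
    drop(.sph_to_unit(az, 90 - abs(beta)))
  }
  ## row definition: midline inclination and outer-ring azimuth magnitude
  rows <- list(
    AF = list(beta = 54,  ring_az = 36),
    F  = list(beta = 36,  ring_az = 54),
    FC = list(beta = 18,  ring_az = 72),
    C  = list(beta = 0,   ring_az = 90),
    CP = list(beta = -18, ring_az = 108),
    P  = list(beta = -36, ring_az = 126),
    PO = list(beta = -54, ring_az = 144))
  ## lateral fraction along the row arc for each numeric suffix
  frac <- c("1" = 0.25, "2" = 0.25, "3" = 0.5, "4" = 0.5,
            "5" = 0.75, "6" = 0.75, "7" = 1, "8" = 1)
  pos <- matrix(NA_real_, length(.paper60_labels), 3,
                dimnames = list(.paper60_labels, c("x", "y", "z")))
  for (lab in .paper60_labels) {
    if (lab %in% c("FP1", "FPz", "FP2")) {
      az <- c(FP1 = 18, FPz = 0, FP2 = -18)[[lab]]
      pos[lab, ] <- ring(az)
    } else if (lab %in% c("O1", "Oz", "O2")) {
      az <- c(O1 = 162, Oz = 180, O2 = -162)[[lab]]
      pos[lab, ] <- ring(az)
    } else {
      ## split row prefix / lateral suffix; T7, T8, FT7... belong to the C / FC
      ## rows under the extended naming scheme
      m <- regmatches(lab, regexec("^([A-Z]+)([1-8z])$", lab))[[1]]
      prefix <- m[2]; suffix <- m[3]
      prefix <- c(T = "C", FT = "FC", TP = "CP")[prefix] %||% prefix
      row <- rows[[prefix]]
      if (suffix == "z") {
        pos[lab, ] <- midline(row$beta)
      } else {
        side <- if (as.integer(suffix) %% 2L == 1L) 1 else -1 # odd = left
        pos[lab, ] <- slerp(midline(row$beta), ring(side * row$ring_az),
                            frac[[suffix]])
      }
    }
  }
  pos
}

`%||%` <- function(a, b) if (is.null(a) || is.na(a)) b else a

## Nose-tip reference position: on the front midline, 20 degrees below the
## equator of the scalp sphere.
.nose_reference <- function() drop(.sph_to_unit(0, -20))

#' Electrode montage on the scalp sphere
#'
#' Builds an EEG electrode montage as unit direction vectors on the scalp
#' sphere plus a reference position (tip of the nose).  The `"paper60"` preset
#' reproduces a 60-channel extended 10/20 recording layout (labels from FP1 to
#' O2, nose reference); alternatively a data frame with columns `name`,
#' `azimuth_deg`, `elevation_deg` may be supplied (see [read_montage()] for the
#' file format and the angle conventions).
#'
#' @param preset `"paper60"`, or a data frame of channels.  A row named `REF`
#'   (any case) is used as the reference position; otherwise the nose default
#'   is used.
#' @return Object of class `eeg_montage` with elements `names`, `positions`
#'   (channels x 3 unit vectors), `reference` (unit vector).
#' @examples
#' mon <- montage()
#' head(mon$names)
#' @export
montage <- function(preset = "paper60") {
  if (is.character(preset) && length(preset) == 1L) {
    if (preset != "paper60") stop("unknown montage preset: ", preset)
    pos <- .paper60_positions()
    return(structure(list(names = rownames(pos),
                          positions = unname(pos),
                          reference = .nose_reference()),
                     class = "eeg_montage"))
  }
  tab <- as.data.frame(preset)
  need <- c("name", "azimuth_deg", "elevation_deg")
  if (!all(need %in% names(tab)))
    stop("montage table needs columns: ", paste(need, collapse = ", "))
  is_ref <- toupper(tab$name) == "REF"
  ref <- if (any(is_ref)) {
    drop(.sph_to_unit(tab$azimuth_deg[is_ref][1], tab$elevation_deg[is_ref][1]))
  } else .nose_reference()
  tab <- tab[!is_ref, , drop = FALSE]
  if (nrow(tab) < 1L) stop("montage table has no channels")
  if (anyDuplicated(tab$name))
    stop("duplicate channel labels: ",
         paste(unique(tab$name[duplicated(tab$name)]), collapse = ", "))
  pos <- .sph_to_unit(tab$azimuth_deg, tab$elevation_deg)
  nrm <- sqrt(rowSums(pos^2))
  if (any(abs(nrm - 1) > 1e-9)) {
    warning("non-unit channel positions normalized")
    pos <- pos / nrm
  }
  structure(list(names = as.character(tab$name),
                 positions = unname(pos),
                 reference = ref),
            class = "eeg_montage")
}

#' Read / write a montage file
#'
#' Plain-text format: one row per channel, `name azimuth_deg elevation_deg`,
#' whitespace-separated, `#` comments allowed; an optional row labelled `REF`
#' gives the reference position.  Azimuth is measured in degrees from the front
#' midline (positive to the left); elevation in degrees above the horizontal
#' plane of the scalp sphere.
#'
#' @param path file path.
#' @return [read_montage()] returns an `eeg_montage`; [write_montage()] returns
#'   `path` invisibly.
#' @export
read_montage <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           col.names = c("name", "azimuth_deg", "elevation_deg"),
                           colClasses = c("character", "numeric", "numeric"))
  montage(tab)
}

#' @rdname read_montage
#' @param mon an `eeg_montage`.
#' @export
write_montage <- function(mon, path) {
  stopifnot(inherits(mon, "eeg_montage"))
  sph <- .unit_to_sph(mon$positions)
  ref <- .unit_to_sph(matrix(mon$reference, 1))
  lines <- c("# EEG montage: name azimuth_deg elevation_deg",
             sprintf("%s %.6f %.6f", mon$names, sph[, 1], sph[, 2]),
             sprintf("REF %.6f %.6f", ref[1, 1], ref[1, 2]))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("EEG montage: %d channels (%s ... %s), reference at nose\n",
              length(x$names), x$names[1], x$names[length(x$names)]))
  invisible(x)
}
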