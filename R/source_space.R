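#' Compartment-labelled spherical source space
#'
#' Places generators quasi-uniformly on a spherical shell at 90% of the brain
#' radius (Fibonacci lattice) and partitions them into contiguous angular
#' compartments: `n_compartments` seed generators are drawn at random (seeded)
#' and every generator is assigned to the nearest seed by great-circle
#' distance, i.e. the compartments are spherical Voronoi cells.  Each
#' compartment plays the role of an anatomical parcel of the cortical surface.
#' A symmetric k-nearest-neighbour adjacency graph over the generators carries
#' the smoothness prior of the LORETA solver (see [graph_laplacian()]).
#'
#' @param n_generators number of source generators.
#' @param n_compartments number of compartments (<= `n_generators`).
#' @param seed integer seed controlling the Voronoi seed draw (deterministic).
#' @param brain_radius brain-shell radius in metres; generators are placed at
#'   `0.9 * brain_radius`.
#' @param k number of nearest neighbours in the adjacency graph.
#' @return Object of class `source_space` with elements `positions`
#'   (n x 3, metres), `n_generators`, `compartment_labels` (integer per
#'   generator), `atlas` (named character: label id -> compartment name),
#'   `neighbor_graph` (symmetric logical adjacency matrix), `radius`.
#' @examples
#' ss <- source_space(200, 8, seed = 1)
#' table(ss$compartment_labels)
#' @export
source_space <- function(n_generators, n_compartments, seed = 1L,
                         brain_radius = 0.08, k = 6L) {
  n_generators <- as.integer(n_generators)
  n_compartments <- as.integer(n_compartments)
  if (n_generators < 1L || n_compartments < 1L)
    stop("n_generators and n_compartments must be >= 1")
  if (n_compartments > n_generators)
    stop("n_compartments (", n_compartments, ") exceeds n_generators (",
         n_generators, ")")
  ## Fibonacci lattice on the unit sphere (deterministic)
  i <- seq_len(n_generators) - 0.5
  golden <- (1 + sqrt(5)) / 2
  z <- 1 - 2 * i / n_generators
  theta <- 2 * pi * i / golden
  r_xy <- sqrt(pmax(0, 1 - z^2))
  u <- cbind(r_xy * cos(theta), r_xy * sin(theta), z)
  radius <- 0.9 * brain_radius
  pos <- u * radius

  ## spherical Voronoi labels: seeds drawn among the generators so every
  ## compartment is nonempty by construction
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(seed)
  seed_idx <- sample.int(n_generators, n_compartments)
  cosdist <- u %*% t(u[seed_idx, , drop = FALSE]) # n x K, cos of angle
  labels <- max.col(cosdist, ties.method = "first")
  atlas <- stats::setNames(sprintf("C%02d", seq_len(n_compartments)),
                           seq_len(n_compartments))

  ## symmetric kNN adjacency
  k <- min(as.integer(k), n_generators - 1L)
  adj <- matrix(FALSE, n_generators, n_generators)
  if (k >= 1L) {
    gram <- u %*% t(u)
    diag(gram) <- -Inf
    for (g in seq_len(n_generators)) {
      nn <- order(gram[g, ], decreasing = TRUE)[seq_len(k)]
      adj[g, nn] <- TRUE
    }
    adj <- adj | t(adj)
  }
  structure(
    list(positions = pos, n_generators = n_generators,
         compartment_labels = labels, atlas = atlas,
         neighbor_graph = adj, radius = radius),
    class = "source_space")
}

#' Compartment centroids projected onto the generator shell
#'
#' @param space a `source_space`.
#' @param labels compartment ids (integer) or names; default all.
#' @return matrix of centroid positions (metres), one row per compartment.
#' @export
compartment_centroids <- function(space, labels = NULL) {
  stopifnot(inherits(space, "source_space"))
  ids <- as.integer(names(space$atlas))
  if (!is.null(labels)) ids <- .resolve_compartments(space, labels)
  cent <- t(vapply(ids, function(id) {
    p <- colMeans(space$positions[space$compartment_labels == id, , drop = FALSE])
    p / sqrt(sum(p^2)) * space$radius
  }, numeric(3)))
  rownames(cent) <- space$atlas[as.character(ids)]
  cent
}

## map compartment names or ids to integer ids, with validation
.resolve_compartments <- function(space, labels) {
  if (is.numeric(labels)) {
    ids <- as.integer(labels)
  } else {
    ids <- as.integer(names(space$atlas))[match(labels, space$atlas)]
  }
  if (any(is.na(ids)) || !all(ids %in% space$compartment_labels))
    stop("unknown compartment label(s): ",
         paste(labels[is.na(ids) | !(ids %in% space$compartment_labels)],
               collapse = ", "))
  ids
}

#' @export
print.source_space <- function(x, ...) {
  cat(sprintf("Source space: %d generators on a %.1f mm shell, %d compartments\n",
              x$n_generators, 1000 * x$radius, length(x$atlas)))
  invisible(x)
}

## RNG bookkeeping: seeded operations must not disturb the caller's stream
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
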