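## Channel layouts and spatial adjacency.
##
## A layout is a data.frame with columns name, x, y, z (unit-sphere head
## coordinates) and x2d, y2d (azimuthal projection for topographies).
## Adjacency is a distance-threshold graph on the 3-D positions; the
## published analyses used a manually curated neighbourhood, which is not
## public, so the threshold graph is a documented stand-in.

#' Read a channel layout CSV
#'
#' @param path CSV with columns `name,x,y,z,x2d,y2d`.
#' @return a `data.frame` layout.
#' @export
readChannelLayout <- function(path) {
  lay <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("name", "x", "y", "z", "x2d", "y2d")
  miss <- setdiff(need, names(lay))
  if (length(miss))
    stop(sprintf("layout is missing column(s): %s", paste(miss, collapse = ", ")))
  if (anyDuplicated(lay$name))
    stop("layout channel names must be unique")
  if (!all(is.finite(as.matrix(lay[, c("x", "y", "z")]))))
    stop("layout positions must be finite")
  lay
}

#' The packaged BioSemi ABC 128-electrode layout
#'
#' Unit-sphere head coordinates for the 128-channel BioSemi ABC montage
#' (names `A1`..`A32`, `B1`..`B32`, `C1`..`C32`, `D1`..`D32`) with an
#' azimuthal-equidistant 2-D projection for topography exports.
#'
#' @return a `data.frame` layout with 128 rows.
#' @export
biosemiLayout <- function() {
  readChannelLayout(system.file("extdata", "biosemi128_layout.csv",
                                package = "sherpa", mustWork = TRUE))
}

#' A synthetic spherical layout for reduced geometries
#'
#' Places `n` electrodes on the upper part of the unit sphere along a
#' Fibonacci spiral -- a plausible cap coverage for simulations that do
#' not use the packaged 128-channel montage.
#'
#' @param n number of electrodes (>= 2).
#' @param prefix name prefix; names are `E01`, `E02`, ...
#' @return a `data.frame` layout with `n` rows.
#' @export
sphericalLayout <- function(n, prefix = "E") {
  stopifnot(n >= 2)
  i <- seq_len(n)
  # z spans the upper cap only (electrodes do not cover the face/neck)
  z <- seq(0.98, -0.05, length.out = n)
  golden <- pi * (3 - sqrt(5))
  phi <- i * golden
  r <- sqrt(pmax(0, 1 - z^2))
  x <- r * cos(phi); y <- r * sin(phi)
  theta <- acos(pmin(1, pmax(-1, z)))
  data.frame(name = sprintf("%s%02d", prefix, i),
             x = x, y = y, z = z,
             x2d = theta * cos(atan2(y, x)),
             y2d = theta * sin(atan2(y, x)),
             stringsAsFactors = FALSE)
}

#' Build a channel adjacency graph from a layout
#'
#' Channels are neighbours iff their Euclidean 3-D distance on the unit
#' sphere is at most `maxDist`.  The default scales with the montage
#' density: 1.85 times the median nearest-neighbour distance, which on
#' the packaged 128-electrode layout equals about 0.355 and gives every
#' channel at least two neighbours -- the prerequisite of the
#' cluster-forming rule -- while sparser simulated layouts get a
#' proportionally wider neighbourhood.
#'
#' @param layout a layout `data.frame` (see [readChannelLayout()]).
#' @param maxDist positive distance threshold (unit-sphere units), or
#'   `NULL` for the density-adaptive default.
#' @return an object of class `AdjacencyGraph`: a named list mapping each
#'   channel to its character vector of neighbours.
#' @export
buildAdjacency <- function(layout, maxDist = NULL) {
  if (anyDuplicated(layout$name))
    stop("duplicate channel names in layout")
  if (nrow(layout) < 2L)
    stop("need at least 2 channels with finite positions")
  P <- as.matrix(layout[, c("x", "y", "z")])
  if (!all(is.finite(P)))
    stop("layout positions must be finite")
  D <- as.matrix(stats::dist(P))
  if (is.null(maxDist)) {
    diag(D) <- Inf
    maxDist <- 1.85 * stats::median(apply(D, 1L, min))
    diag(D) <- 0
  }
  .assertScalarNumber(maxDist, "maxDist", positive = TRUE)
  A <- D <= maxDist
  diag(A) <- FALSE
  g <- lapply(seq_len(nrow(A)), function(i) layout$name[A[i, ]])
  names(g) <- layout$name
  structure(g, class = "AdjacencyGraph")
}

#' @export
print.AdjacencyGraph <- function(x, ...) {
  deg <- lengths(x)
  cat(sprintf("AdjacencyGraph: %d channels, degree %d..%d (mean %.1f)\n",
              length(x), min(deg), max(deg), mean(deg)))
  invisible(x)
}

#' Export an adjacency graph as an edge list
#'
#' @param adjacency an `AdjacencyGraph`.
#' @return a `data.frame` with columns `from`, `to`, one row per
#'   undirected edge (`from < to` lexicographically).
#' @export
adjacencyEdges <- function(adjacency) {
  stopifnot(inherits(adjacency, "AdjacencyGraph"))
  from <- rep(names(adjacency), lengths(adjacency))
  to <- unlist(adjacency, use.names = FALSE)
  keep <- from < to
  data.frame(from = from[keep], to = to[keep], stringsAsFactors = FALSE)
}

#' The packaged 10-20 to BioSemi ABC electrode alias table
#'
#' Maps conventional 10-20 electrode names (P7, PO8, ...) to the nearest
#' electrode of the packaged 128-channel ABC layout.
#'
#' @return a `data.frame` with columns `alias`, `channel`, `distance`.
#' @export
electrodeAliases <- function() {
  read.csv(system.file("extdata", "electrode_aliases.csv",
                       package = "sherpa", mustWork = TRUE),
           stringsAsFactors = FALSE)
}
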