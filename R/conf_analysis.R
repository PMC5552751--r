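# Conformational-state analysis: pairwise superposed RMSD, classical MDS to
# 2-D, density-based clustering (DBSCAN), basin occupancies, medoids, and
# nearest-basin assignment of external structures.

#' Pairwise RMSD matrix of aligned conformations
#'
#' Kabsch-superposed RMSD over the chosen atom subset for every frame pair.
#' Alignment and measurement both use `subset` (the conformations are
#' compared as whole bodies on those atoms).
#'
#' @param confs list of conformations (or coordinate matrices) with equal
#'   atom counts.
#' @param subset 1-based atom indices to superpose and measure on (defaults
#'   to all atoms).
#' @return Object of class `egress_distmat`: list with `d` (symmetric matrix,
#'   Angstrom, zero diagonal) and `labels`.
#' @export
rmsd_matrix <- function(confs, subset = NULL) {
  n <- length(confs)
  if (n < 2) stop("need at least 2 conformations", call. = FALSE)
  xs <- lapply(confs, node_coords)
  subset <- subset %||% seq_len(nrow(xs[[1]]))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    al <- kabsch_align(xs[[i]][subset, , drop = FALSE],
                       xs[[j]][subset, , drop = FALSE],
                       seq_along(subset))
    d[i, j] <- d[j, i] <- al$rmsd
  }
  labels <- vapply(seq_len(n), function(i) {
    l <- if (inherits(confs[[i]], "egress_conformation")) confs[[i]]$label else ""
    if (nzchar(l)) l else paste0("frame", i)
  }, character(1))
  structure(list(d = d, labels = labels), class = "egress_distmat")
}

#' @export
print.egress_distmat <- function(x, ...) {
  cat(sprintf("<egress_distmat> %d frames, max distance %.3g A\n",
              nrow(x$d), max(x$d)))
  invisible(x)
}

#' Classical (Torgerson) multidimensional scaling to 2-D
#'
#' Double-centering eigendecomposition of the squared distance matrix; the
#' embedding reproduces the distances exactly when they are realizable in the
#' target dimension. Coordinates are min-max normalized to the unit square,
#' matching the convention in which basin centers are reported.
#'
#' @param dm an `egress_distmat` (or plain symmetric matrix).
#' @param dim embedding dimension (2).
#' @param normalize rescale each axis to [0, 1].
#' @return Matrix of embedding coordinates (frames x dim); the raw
#'   (unnormalized) embedding is in `attr(, "raw")`.
#' @export
classical_mds <- function(dm, dim = 2, normalize = TRUE) {
  d <- if (inherits(dm, "egress_distmat")) dm$d else as.matrix(dm)
  if (nrow(d) < 3) stop("need at least 3 frames for MDS", call. = FALSE)
  if (all(d == 0)) {
    y <- matrix(0, nrow(d), dim)
    attr(y, "raw") <- y
    return(y)
  }
  y <- stats::cmdscale(d, k = dim)
  if (ncol(y) < dim) y <- cbind(y, matrix(0, nrow(y), dim - ncol(y)))
  raw <- y
  if (normalize) {
    for (j in seq_len(dim)) {
      rng <- range(y[, j])
      y[, j] <- if (diff(rng) > 0) (y[, j] - rng[1]) / diff(rng) else 0.5
    }
  }
  attr(y, "raw") <- raw
  y
}

#' Density-based clustering (DBSCAN)
#'
#' Classic queue-expansion DBSCAN on 2-D (or any-dimensional) points. Noise
#' points get label -1; clusters are numbered 0, 1, ... in order of
#' discovery. Border points reachable from several clusters join the first
#' cluster that reaches them, so the labeling is deterministic for a fixed
#' point order.
#'
#' @param embedding numeric matrix (points x dim).
#' @param eps neighborhood radius (> 0).
#' @param min_pts minimum neighborhood size (self included) for a core point.
#' @return Integer label vector (noise = -1).
#' @export
dbscan_cluster <- function(embedding, eps, min_pts) {
  x <- as.matrix(embedding)
  if (eps <= 0) stop("eps must be > 0", call. = FALSE)
  if (min_pts < 1) stop("min_pts must be >= 1", call. = FALSE)
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, integer(1)) >= min_pts
  labels <- rep(NA_integer_, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!is.na(labels[i]) || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb[[i]], i)
    while (length(queue) > 0) {
      j <- queue[1]; queue <- queue[-1]
      if (is.na(labels[j])) {
        labels[j] <- cl
        if (core[j]) queue <- c(queue, nb[[j]][is.na(labels[nb[[j]]])])
      } else if (labels[j] == -1L && core[j]) {
        # previously noise, actually core (cannot happen: core handled above)
        labels[j] <- cl
      }
    }
  }
  labels[is.na(labels)] <- -1L
  labels
}

#' Suggest DBSCAN parameters from the k-distance curve
#'
#' Sorts the distance to the `min_pts`-th nearest neighbor and places eps at
#' the elbow (maximum second difference of the sorted curve). A heuristic
#' starting point — always overridable.
#'
#' @param embedding numeric matrix (points x dim).
#' @param min_pts neighborhood size used for the k-distance curve.
#' @return List with `eps` and `min_pts`.
#' @export
suggest_dbscan_eps <- function(embedding, min_pts = 5) {
  x <- as.matrix(embedding)
  d <- as.matrix(stats::dist(x))
  kd <- sort(apply(d, 1, function(r) sort(r)[min_pts]))
  if (length(kd) < 3) return(list(eps = max(kd), min_pts = min_pts))
  curv <- diff(diff(kd))
  i <- which.max(curv) + 1L
  list(eps = max(kd[i], 1e-6), min_pts = min_pts)
}

#' Occupancy fraction of each basin
#'
#' @param labels cluster labels (noise = -1).
#' @return Tibble with columns `cluster` and `occupancy`; fractions sum to 1
#'   (noise reported as cluster -1 when present).
#' @export
basin_occupancy <- function(labels) {
  if (length(labels) == 0) stop("empty label vector", call. = FALSE)
  tb <- table(labels)
  tibble::tibble(cluster = as.integer(names(tb)),
                 occupancy = as.numeric(tb) / length(labels)) |>
    dplyr::arrange(.data$cluster)
}

#' Medoid frame of each cluster
#'
#' The member minimizing the summed RMSD to the rest of its cluster; ties
#' break to the lowest frame index.
#'
#' @param dm an `egress_distmat`.
#' @param labels cluster labels (noise = -1, skipped).
#' @return Tibble with columns `cluster` and `medoid` (frame index).
#' @export
representative_conformer <- function(dm, labels) {
  d <- if (inherits(dm, "egress_distmat")) dm$d else as.matrix(dm)
  cls <- sort(unique(labels[labels >= 0]))
  med <- vapply(cls, function(cl) {
    idx <- which(labels == cl)
    sums <- rowSums(d[idx, idx, drop = FALSE])
    idx[which.min(sums)]
  }, integer(1))
  tibble::tibble(cluster = cls, medoid = med)
}

#' Assign an external structure to the nearest basin
#'
#' Computes the subset RMSD from `conf` to every non-noise frame and returns
#' the cluster of the nearest one (the rule used to place crystal structures
#' into the open/closed basins).
#'
#' @param conf the external conformation.
#' @param confs the clustered conformations.
#' @param labels their cluster labels.
#' @param subset atom subset for the RMSD (defaults to all atoms).
#' @return List with `cluster`, `distance` (A), and `frame` (index of the
#'   nearest frame).
#' @export
assign_external <- function(conf, confs, labels, subset = NULL) {
  keep <- which(labels >= 0)
  if (length(keep) == 0) stop("no non-noise frames to assign against", call. = FALSE)
  xc <- node_coords(conf)
  subset <- subset %||% seq_len(nrow(xc))
  dist <- vapply(keep, function(i) {
    kabsch_align(xc[subset, , drop = FALSE],
                 node_coords(confs[[i]])[subset, , drop = FALSE],
                 seq_along(subset))$rmsd
  }, numeric(1))
  j <- which.min(dist)
  list(cluster = labels[keep[j]], distance = dist[j], frame = keep[j])
}

#' Full conformational-state decomposition
#'
#' Chains [rmsd_matrix()], [classical_mds()] and [dbscan_cluster()] and
#' summarizes occupancies and medoids: the open/closed style state analysis
#' in one call.
#'
#' @param confs list of conformations.
#' @param subset atom subset for the RMSD.
#' @param eps,min_pts DBSCAN parameters; `eps = NULL` takes the k-distance
#'   elbow suggestion.
#' @return Object of class `egress_states`: list with `embedding` (tibble
#'   `frame`, `dim1`, `dim2`, `cluster`), `occupancy`, `medoids`, `dm`,
#'   `eps`, `min_pts`.
#' @export
state_decomposition <- function(confs, subset = NULL, eps = NULL, min_pts = 5) {
  dm <- rmsd_matrix(confs, subset)
  emb <- classical_mds(dm)
  if (is.null(eps)) eps <- suggest_dbscan_eps(emb, min_pts)$eps
  labels <- dbscan_cluster(emb, eps, min_pts)
  structure(list(
    embedding = tibble::tibble(frame = seq_len(nrow(emb)),
                               dim1 = emb[, 1], dim2 = emb[, 2],
                               cluster = labels),
    occupancy = basin_occupancy(labels),
    medoids = representative_conformer(dm, labels),
    dm = dm, eps = eps, min_pts = min_pts
  ), class = "egress_states")
}

#' @export
print.egress_states <- function(x, ...) {
  nc <- sum(x$occupancy$cluster >= 0)
  cat(sprintf("<egress_states> %d frames, %d clusters (eps = %.3g, minPts = %d)\n",
              nrow(x$embedding), nc, x$eps, x$min_pts))
  print(x$occupancy)
  invisible(x)
}
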