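# Path collective variables: progress s(R) along a discretized reference path
# and deviation z(R) from it, built from exponentially weighted mean-square
# deviations after rigid superposition on an alignment set.

#' Optimal rigid superposition (Kabsch algorithm)
#'
#' Least-squares rigid transform (proper rotation + translation, no
#' reflection) minimizing the alignment-set RMSD between two conformations;
#' the transform is then applied to all atoms of `mobile`.
#'
#' @param mobile,reference `egress_conformation`s (or coordinate matrices)
#'   with equal atom counts.
#' @param alignment_set 1-based atom indices used for the fit (>= 3,
#'   non-collinear).
#' @return List with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), `coords` (all atoms
#'   transformed) and `rmsd` (alignment-set RMSD, Angstrom).
#' @export
kabsch_align <- function(mobile, reference, alignment_set) {
  xm <- if (inherits(mobile, "egress_conformation")) mobile$coords else as.matrix(mobile)
  xr <- if (inherits(reference, "egress_conformation")) reference$coords else as.matrix(reference)
  if (length(alignment_set) < 3)
    stop("alignment set must contain at least 3 atoms", call. = FALSE)
  A <- xm[alignment_set, , drop = FALSE]
  B <- xr[alignment_set, , drop = FALSE]
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  # collinearity check: rank of the centered alignment coordinates
  sv_a <- svd(A0)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1))
    stop("degenerate (collinear) alignment set", call. = FALSE)
  H <- crossprod(A0, B0)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  tvec <- cb - as.numeric(R %*% ca)
  out <- sweep(xm %*% t(R), 2, tvec, "+")
  rmsd <- sqrt(mean(rowSums((out[alignment_set, , drop = FALSE] - B)^2)))
  list(rotation = R, translation = tvec, coords = out, rmsd = rmsd)
}

#' Mean-square displacement after superposition
#'
#' Aligns `conf` onto `node` using the alignment set, then returns the mean
#' squared coordinate difference over the displacement set. This is the
#' metric `||S(R) - S(k)||^2` underlying the path variables.
#'
#' @param conf,node conformations (or coordinate matrices).
#' @param alignment_set,displacement_set 1-based atom index sets; the two
#'   sets are used for fitting and measuring respectively.
#' @return Mean-square displacement, A^2.
#' @export
msd_displacement <- function(conf, node, alignment_set, displacement_set) {
  al <- kabsch_align(conf, node, alignment_set)
  xn <- if (inherits(node, "egress_conformation")) node$coords else as.matrix(node)
  d <- al$coords[displacement_set, , drop = FALSE] - xn[displacement_set, , drop = FALSE]
  mean(rowSums(d^2))
}

# Core evaluation shared by pcv_s / pcv_z: aligns every path node onto the
# current conformation (so gradients with respect to the conformation's
# displacement atoms are exact: the fit uses only alignment atoms, and the
# two sets are disjoint).
pcv_eval <- function(conf, path, gradients = FALSE) {
  x <- if (inherits(conf, "egress_conformation")) conf$coords else as.matrix(conf)
  N <- length(path$nodes)
  if (N < 2) stop("path must have at least 2 nodes", call. = FALSE)
  lam <- path$lambda
  if (is.null(lam) || lam <= 0) stop("path lambda must be > 0", call. = FALSE)
  ai <- path$alignment_set; di <- path$displacement_set
  nd <- length(di)
  msd <- numeric(N)
  ynodes <- vector("list", N)
  for (k in seq_len(N)) {
    nk <- node_coords(path$nodes[[k]])
    al <- kabsch_align(nk, x, ai)      # bring node into the current frame
    yk <- al$coords[di, , drop = FALSE]
    ynodes[[k]] <- yk
    d <- x[di, , drop = FALSE] - yk
    msd[k] <- mean(rowSums(d^2))
  }
  if (!all(is.finite(msd))) stop("non-finite MSD in path variable evaluation", call. = FALSE)
  m0 <- min(msd)
  wgt <- exp(-lam * (msd - m0))        # log-sum-exp stabilization
  Z <- sum(wgt)
  p <- wgt / Z
  s <- sum(seq_len(N) * p)
  z <- m0 - log(Z) / lam
  res <- list(s = s, z = z, sigma = (s - 1) / (N - 1), msd = msd, p = p)
  if (gradients) {
    ds <- matrix(0, nd, 3)
    dz <- matrix(0, nd, 3)
    for (k in seq_len(N)) {
      dmsd <- 2 / nd * (x[di, , drop = FALSE] - ynodes[[k]])
      ds <- ds - lam * (k - s) * p[k] * dmsd
      dz <- dz + p[k] * dmsd
    }
    res$ds_dx <- ds
    res$dz_dx <- dz
  }
  res
}

node_coords <- function(node) {
  if (inherits(node, "egress_conformation")) node$coords else as.matrix(node)
}

#' Progress along a reference path, s(R)
#'
#' The Boltzmann-weighted node index
#' \deqn{s(R) = \frac{\sum_k k\,e^{-\lambda\|S(R)-S(k)\|^2}}{\sum_k e^{-\lambda\|S(R)-S(k)\|^2}}}
#' computed with log-sum-exp stabilization so it is finite for any lambda and
#' distances. Always lies in [1, N].
#'
#' @param conf a conformation.
#' @param path an `egress_path` (see [build_path()] or [new_path()]).
#' @return Dimensionless progress variable in [1, N].
#' @export
pcv_s <- function(conf, path) pcv_eval(conf, path)$s

#' Deviation from a reference path, z(R)
#'
#' The soft-min distance
#' \deqn{z(R) = -\frac{1}{\lambda}\ln\sum_k e^{-\lambda\|S(R)-S(k)\|^2}}
#' in A^2; bounded by `min(MSD) - ln(N)/lambda <= z <= min(MSD)`.
#'
#' @inheritParams pcv_s
#' @return Deviation from the path, A^2.
#' @export
pcv_z <- function(conf, path) pcv_eval(conf, path)$z

#' Full path-variable evaluation
#'
#' Returns s, z, the scaled order parameter sigma, per-node MSDs and (if
#' requested) analytic gradients with respect to the displacement-set atoms.
#' Gradients use the standard fixed-rotation treatment: reference nodes are
#' aligned onto the current frame using the alignment set, which is disjoint
#' from the displacement set, so displacement-atom gradients carry no
#' rotation dependence.
#'
#' @inheritParams pcv_s
#' @param gradients logical; also compute `ds_dx`, `dz_dx` (rows = atoms of
#'   the displacement set).
#' @return List of class `egress_pcv` with elements `s`, `z`, `sigma`, `msd`
#'   and optionally `ds_dx`, `dz_dx`.
#' @export
pcv <- function(conf, path, gradients = FALSE) {
  r <- pcv_eval(conf, path, gradients = gradients)
  structure(r, class = "egress_pcv")
}

#' Scale s to the order parameter sigma in [0, 1]
#'
#' @param s progress variable in [1, N].
#' @param N number of path nodes (>= 2).
#' @return `(s - 1) / (N - 1)`, clamped to [0, 1].
#' @export
sigma_from_s <- function(s, N) {
  if (N < 2) stop("N must be >= 2", call. = FALSE)
  pmin(1, pmax(0, (s - 1) / (N - 1)))
}

#' Default lambda for path variables
#'
#' The standard heuristic lambda = 2.3 / <MSD> between consecutive nodes, so
#' that the exponential weight decays to about 0.1 at one node spacing. Any
#' user-supplied value overrides the rule.
#'
#' @param path an `egress_path` with `mean_neighbor_msd` set.
#' @param override optional user lambda (A^-2), returned verbatim.
#' @return lambda in A^-2.
#' @export
choose_lambda <- function(path, override = NULL) {
  if (!is.null(override)) return(override)
  m <- path$mean_neighbor_msd
  if (is.null(m) || !is.finite(m) || m <= 0)
    stop("mean neighbor MSD must be > 0 to choose lambda", call. = FALSE)
  2.3 / m
}
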