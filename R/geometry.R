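.unit <- function(v, tol = 1e-12) {
  n <- sqrt(sum(v^2))
  if (n < tol) stop("degenerate (near-zero) vector")
  v / n
}

.cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimizing the RMSD between
#' `mobile[selection, ]` and `reference[selection, ]`, and applies it to all
#' mobile atoms. Reflections are excluded.
#'
#' @param mobile `n x 3` coordinates to fit
#' @param reference `n x 3` (or `length(selection) x 3`) reference coordinates
#' @param selection integer atom indices used for the fit (default: all);
#'   must map 1:1 onto the reference rows used
#' @return list of class `nuc_transform` with `rotation` (3x3, applied to
#'   column vectors), `translation`, `rmsd` (over the fit selection) and
#'   `xyz` (all mobile atoms after fitting)
#' @export
superpose <- function(mobile, reference, selection = NULL) {
  if (is.null(selection)) selection <- seq_len(nrow(mobile))
  A <- mobile[selection, , drop = FALSE]
  B <- if (nrow(reference) == nrow(mobile))
    reference[selection, , drop = FALSE] else reference
  if (nrow(A) != nrow(B))
    stop("selection does not map 1:1 between mobile and reference")
  if (nrow(A) < 3L) stop("superposition needs at least 3 atoms")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2, ca); Bc <- sweep(B, 2, cb)
  sv_a <- svd(Ac)$d
  if (sv_a[2] < 1e-8 * max(sv_a[1], 1))
    stop("degenerate fit: selection atoms are collinear")
  H <- crossprod(Ac, Bc)
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  fitted_sel <- Ac %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted_sel - Bc)^2)))
  translation <- cb - as.numeric(R %*% ca)
  xyz <- sweep(mobile %*% t(R), 2, translation, `+`)
  structure(list(rotation = R, translation = translation, rmsd = rmsd,
                 xyz = xyz), class = "nuc_transform")
}

#' Apply a rigid transform to coordinates
#' @param transform a `nuc_transform` (or list with `rotation`, `translation`)
#' @param xyz `n x 3` coordinates
#' @return transformed `n x 3` coordinates
#' @export
apply_transform <- function(transform, xyz) {
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, `+`)
}

#' Fit every trajectory frame onto a reference
#'
#' @param traj a `nuc_trajectory`
#' @param annotation a `nuc_annotation`; the fit selection defaults to the
#'   histone-core heavy atoms
#' @param reference `n x 3` reference coordinates (default: topology model 1)
#' @param selection fit selection (atom indices)
#' @return a new `nuc_trajectory` with fitted coordinates
#' @export
fit_trajectory <- function(traj, annotation, reference = NULL,
                           selection = NULL) {
  if (is.null(selection))
    selection <- sel_histone_core(traj$topology, annotation)
  if (is.null(reference)) reference <- model_xyz(traj$topology)
  out <- traj$coords
  for (f in seq_len(n_frames(traj)))
    out[, , f] <- superpose(frame_xyz(traj, f), reference, selection)$xyz
  nuc_trajectory(traj$topology, out, traj$frame_interval_ps)
}

#' Build the dyad coordinate frame
#'
#' The frame has its origin at the dyad base-pair center. X points from the
#' inner-gyre centroid to the origin (the dyad axis). The superhelical axis
#' S is the normal of the best-fit plane through the inner-gyre base-pair
#' centers, with its sign fixed by the winding direction of the inner gyre
#' (deterministic and continuous across frames). Y = unit(X x S) and
#' Z = X x Y, giving a right-handed orthonormal triad in which the XY plane
#' is the nucleosome disc plane.
#'
#' @param structure a `nuc_structure` (topology)
#' @param xyz `n_atoms x 3` frame coordinates
#' @param annotation a `nuc_annotation`
#' @return object of class `nuc_dyad_frame`: list(origin, X, Y, Z)
#' @export
build_dyad_frame <- function(structure, xyz, annotation) {
  centers <- bp_centers(structure, xyz, annotation, annotation$inner)
  origin <- as.numeric(bp_centers(structure, xyz, annotation,
                                  annotation$dyad_bp))
  .dyad_frame_from_centers(centers, origin)
}

# core of the frame construction, shared with the synthetic generator
# (which calls it on exact base-pair centers)
.dyad_frame_from_centers <- function(centers, origin) {
  cen <- colMeans(centers)
  X <- .unit(origin - cen)
  M <- sweep(centers, 2, cen)
  sv <- svd(M)
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1))
    stop("degenerate plane fit: inner-gyre centers are collinear")
  S <- sv$v[, 3]
  # orient S along the winding normal of the inner-gyre path
  rel <- sweep(centers, 2, origin)
  w <- c(0, 0, 0)
  for (i in seq_len(nrow(rel) - 1L)) w <- w + .cross3(rel[i, ], rel[i + 1L, ])
  if (sum(S * w) < 0) S <- -S
  Y <- .unit(.cross3(X, S))
  Z <- .cross3(X, Y)
  structure(list(origin = origin, X = X, Y = Y, Z = Z),
            class = "nuc_dyad_frame")
}

#' Arm (linker DNA) direction vector
#'
#' Direction of the best-fit (total least squares) line through the arm's
#' base-pair centers, oriented from the hinge side toward the terminal base
#' pair. With exactly two base pairs this reduces to their normalized
#' difference. Set `endpoint = TRUE` to use the endpoint difference always.
#'
#' @param structure a `nuc_structure`
#' @param xyz frame coordinates
#' @param annotation a `nuc_annotation`
#' @param arm `"3p"` or `"5p"`
#' @param endpoint use terminal-minus-inner endpoint difference instead of
#'   the fitted line
#' @return unit 3-vector
#' @export
arm_vector <- function(structure, xyz, annotation, arm = c("3p", "5p"),
                       endpoint = FALSE) {
  arm <- match.arg(arm)
  bp <- if (arm == "3p") annotation$arm_3p else annotation$arm_5p
  centers <- bp_centers(structure, xyz, annotation, bp)
  # terminal bp: highest index on the 3' arm, lowest on the 5' arm
  ord <- order(bp, decreasing = (arm == "5p"))
  inner_c <- centers[ord[1], ]; term_c <- centers[ord[length(ord)], ]
  span <- term_c - inner_c
  if (sqrt(sum(span^2)) < 1e-9) stop("coincident arm base-pair centers")
  if (endpoint || length(bp) == 2L) return(.unit(span))
  M <- sweep(centers, 2, colMeans(centers))
  v <- svd(M)$v[, 1]
  if (sum(v * span) < 0) v <- -v
  .unit(v)
}

#' Linker-DNA opening angles in the dyad frame
#'
#' gamma1 is the signed angle, within the XZ plane, between the arm vector's
#' XZ projection and the Z axis (sign right-handed about +Y); gamma2 is the
#' signed angle, within the XY plane, between the XY projection and the Y
#' axis (sign right-handed about +Z). Angles are in degrees in (-180, 180].
#' A projection with near-zero norm yields `NA` for that angle.
#'
#' @inheritParams arm_vector
#' @param dyad_frame a `nuc_dyad_frame` (default: built from this frame)
#' @return named numeric vector `c(gamma1, gamma2)` in degrees
#' @export
compute_gamma <- function(structure, xyz, annotation, arm = c("3p", "5p"),
                          dyad_frame = NULL, endpoint = FALSE) {
  arm <- match.arg(arm)
  if (is.null(dyad_frame))
    dyad_frame <- build_dyad_frame(structure, xyz, annotation)
  v <- arm_vector(structure, xyz, annotation, arm, endpoint = endpoint)
  vx <- sum(v * dyad_frame$X)
  vy <- sum(v * dyad_frame$Y)
  vz <- sum(v * dyad_frame$Z)
  g1 <- if (sqrt(vx^2 + vz^2) < 1e-9) NA_real_ else
    atan2(vx, vz) * 180 / pi
  g2 <- if (sqrt(vx^2 + vy^2) < 1e-9) NA_real_ else
    atan2(-vx, vy) * 180 / pi
  c(gamma1 = g1, gamma2 = g2)
}

#' Radius of gyration
#'
#' `sqrt(sum(w_i |r_i - rbar|^2) / sum(w_i))` with weights `w` equal to the
#' atomic masses (default) or 1, and `rbar` the weighted centroid.
#'
#' @param structure a `nuc_structure`
#' @param xyz frame coordinates
#' @param selection atom indices (non-empty)
#' @param mass_weighted use atomic masses as weights
#' @return radius of gyration in Angstrom
#' @export
compute_rg <- function(structure, xyz, selection, mass_weighted = TRUE) {
  if (length(selection) == 0L) stop("empty selection for Rg")
  co <- xyz[selection, , drop = FALSE]
  w <- if (mass_weighted) structure$atoms$mass[selection]
       else rep(1, length(selection))
  cen <- colSums(co * w) / sum(w)
  d2 <- rowSums(sweep(co, 2, cen)^2)
  sqrt(sum(w * d2) / sum(w))
}

#' Per-frame breathing observables
#'
#' Computes, every `stride`-th frame, the opening angles of both arms and
#' the DNA radius of gyration. The dyad frame is rebuilt per frame, so the
#' observables are invariant under rigid motions of the trajectory.
#'
#' @param traj a `nuc_trajectory`
#' @param annotation a `nuc_annotation`
#' @param stride frame stride (default 1)
#' @param mass_weighted mass-weight the Rg
#' @return data.frame: frame, time_ps, gamma1_3p, gamma2_3p, gamma1_5p,
#'   gamma2_5p, rg
#' @export
breathing_series <- function(traj, annotation, stride = 1L,
                             mass_weighted = TRUE) {
  frames <- seq(1L, n_frames(traj), by = stride)
  dna <- sel_dna(traj$topology, annotation)
  out <- data.frame(frame = frames,
                    time_ps = (frames - 1L) * traj$frame_interval_ps,
                    gamma1_3p = NA_real_, gamma2_3p = NA_real_,
                    gamma1_5p = NA_real_, gamma2_5p = NA_real_,
                    rg = NA_real_)
  for (i in seq_along(frames)) {
    xyz <- frame_xyz(traj, frames[i])
    df <- build_dyad_frame(traj$topology, xyz, annotation)
    g3 <- compute_gamma(traj$topology, xyz, annotation, "3p", df)
    g5 <- compute_gamma(traj$topology, xyz, annotation, "5p", df)
    out$gamma1_3p[i] <- g3[1]; out$gamma2_3p[i] <- g3[2]
    out$gamma1_5p[i] <- g5[1]; out$gamma2_5p[i] <- g5[2]
    out$rg[i] <- compute_rg(traj$topology, xyz, dna, mass_weighted)
  }
  out
}

#' Two-dimensional histogram of the opening angles
#'
#' Bins the (gamma1, gamma2) pairs of one arm on a regular grid. The
#' occupied area is the number of bins holding at least `occupancy_min`
#' frames times the bin area, and the mode bin is the center of the most
#' populated bin (first in row-major order on ties).
#'
#' @param series data.frame from [breathing_series()] (or any data.frame
#'   with `gamma1_<arm>` / `gamma2_<arm>` columns)
#' @param arm `"3p"` or `"5p"`
#' @param bin_width bin width in degrees (default 2.5)
#' @param occupancy_min minimum frame count for a bin to count as occupied
#' @return object of class `nuc_gamma_hist`: counts matrix (gamma1 rows,
#'   gamma2 columns), bin edges, `occupied_area` (deg^2), `mode_bin`
#' @export
gamma_histogram2d <- function(series, arm = c("3p", "5p"), bin_width = 2.5,
                              occupancy_min = 1L) {
  arm <- match.arg(arm)
  if (bin_width <= 0) stop("bin_width must be positive")
  g1 <- series[[paste0("gamma1_", arm)]]
  g2 <- series[[paste0("gamma2_", arm)]]
  ok <- is.finite(g1) & is.finite(g2)
  if (!any(ok)) stop("no frames with defined angles")
  g1 <- g1[ok]; g2 <- g2[ok]
  edges <- function(x) {
    lo <- floor(min(x) / bin_width) * bin_width
    hi <- ceiling(max(x) / bin_width) * bin_width
    if (hi <= lo) hi <- lo + bin_width
    seq(lo, hi, by = bin_width)
  }
  e1 <- edges(g1); e2 <- edges(g2)
  i1 <- pmin(findInterval(g1, e1, rightmost.closed = TRUE), length(e1) - 1L)
  i2 <- pmin(findInterval(g2, e2, rightmost.closed = TRUE), length(e2) - 1L)
  counts <- matrix(0L, length(e1) - 1L, length(e2) - 1L)
  for (k in seq_along(i1)) counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1L
  occupied_area <- sum(counts >= occupancy_min) * bin_width^2
  m <- which(counts == max(counts), arr.ind = TRUE)[1, ]
  mode_bin <- c(gamma1 = e1[m[1]] + bin_width / 2,
                gamma2 = e2[m[2]] + bin_width / 2)
  structure(list(counts = counts, gamma1_edges = e1, gamma2_edges = e2,
                 bin_width = bin_width, occupancy_min = occupancy_min,
                 occupied_area = occupied_area, mode_bin = mode_bin,
                 n_frames = length(g1)),
            class = "nuc_gamma_hist")
}

#' @export
print.nuc_gamma_hist <- function(x, ...) {
  cat(sprintf(paste0("<nuc_gamma_hist> %d frames, %.1f deg bins, occupied ",
                     "area %.2f deg^2, mode (%.1f, %.1f)\n"),
              x$n_frames, x$bin_width, x$occupied_area,
              x$mode_bin[1], x$mode_bin[2]))
  invisible(x)
}
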