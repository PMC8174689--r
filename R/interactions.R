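# squared pairwise distances between two coordinate blocks
.pair_dist2 <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

#' Count atomic contacts between two selections
#'
#' A contact is a pair (a in A, b in B) of heavy (non-hydrogen) atoms closer
#' than the cutoff (strict `<`). Counting is symmetric in A and B. With
#' `unit = "atoms"` the number of distinct A atoms in contact is returned
#' instead of the pair count.
#'
#' @param structure a `nuc_structure`
#' @param xyz frame coordinates (`n_atoms x 3`)
#' @param sel_a,sel_b disjoint atom index sets
#' @param cutoff contact cutoff in Angstrom (default 4.5)
#' @param heavy_only drop hydrogens before counting
#' @param unit `"pairs"` (default) or `"atoms"`
#' @return integer contact count
#' @export
count_contacts <- function(structure, xyz, sel_a, sel_b, cutoff = 4.5,
                           heavy_only = TRUE, unit = c("pairs", "atoms")) {
  unit <- match.arg(unit)
  if (cutoff <= 0) stop("cutoff must be positive")
  if (heavy_only) {
    sel_a <- sel_heavy(structure, sel_a)
    sel_b <- sel_heavy(structure, sel_b)
  }
  if (length(sel_a) == 0L || length(sel_b) == 0L)
    stop("empty selection after heavy-atom filtering")
  if (length(intersect(sel_a, sel_b)) > 0L)
    stop("contact selections must be disjoint")
  d2 <- .pair_dist2(xyz[sel_a, , drop = FALSE], xyz[sel_b, , drop = FALSE])
  hit <- d2 < cutoff^2
  if (unit == "pairs") sum(hit) else sum(rowSums(hit) > 0L)
}

#' Inverse-power weighted mean distance between two atom groups
#'
#' Evaluates `d[n] = ((1/(N1*N2)) * sum_ij (1/|d_ij|)^n)^(-1/n)` for an even
#' exponent n. Small n approximates the average distance; large n approaches
#' the minimum pairwise distance from above (`d[n] >= min |d_ij|` always).
#' The sum is factored around the minimum distance so that large exponents
#' (n = 100) neither overflow nor underflow for distances spanning several
#' orders of magnitude.
#'
#' @param xyz frame coordinates
#' @param sel_a,sel_b non-empty atom index sets
#' @param n even integer exponent >= 2 (10 for the mean-like delta, 100 for
#'   the minimum-like delta_min)
#' @return weighted mean distance in Angstrom
#' @export
weighted_mean_distance <- function(xyz, sel_a, sel_b, n = 10) {
  if (n < 2 || n %% 2 != 0) stop("exponent n must be an even integer >= 2")
  if (length(sel_a) == 0L || length(sel_b) == 0L) stop("empty selection")
  d2 <- .pair_dist2(xyz[sel_a, , drop = FALSE], xyz[sel_b, , drop = FALSE])
  dmin2 <- min(d2)
  if (dmin2 < 1e-12) stop("coincident atoms: pairwise distance is zero")
  # (dmin/d_ij)^n lies in (0, 1]; underflow of far pairs is harmless
  s <- sum((dmin2 / d2)^(n / 2))
  sqrt(dmin2) * (s / length(d2))^(-1 / n)
}

#' Tail configuration series
#'
#' For one histone tail, computes every `stride`-th frame: the weighted mean
#' distance (n = 10) to the adjacent linker-DNA reference segment
#' (`delta_ldna`) and to the same-side dyad segment (`delta_dyad`), the
#' contact counts with the inner gyre (`nc_inner`) and with the same-side
#' outer gyre (`nc_outer`), and the tail radius of gyration (`tail_rg`).
#'
#' @param traj a `nuc_trajectory`
#' @param annotation a `nuc_annotation`
#' @param tail_id tail identifier, e.g. `"H3_3p"`; tail-less annotations are
#'   rejected
#' @param stride frame stride (default 1)
#' @param cutoff contact cutoff in Angstrom
#' @return data.frame: frame, time_ps, delta_ldna, delta_dyad, nc_inner,
#'   nc_outer, tail_rg
#' @export
tail_configuration_series <- function(traj, annotation, tail_id, stride = 1L,
                                      cutoff = 4.5) {
  st <- traj$topology
  tail <- sel_tail(st, annotation, tail_id)
  side <- annotation$tails$side[annotation$tails$tail_id == tail_id][1]
  ldna_bp <- if (side == "3p") annotation$ldna_3p else annotation$ldna_5p
  dyad_bp <- if (side == "3p") annotation$dyad_seg_3p else annotation$dyad_seg_5p
  ldna <- sel_bp(st, annotation, ldna_bp)
  dyad <- sel_bp(st, annotation, dyad_bp)
  inner <- sel_gyre(st, annotation, "inner")
  outer <- sel_gyre(st, annotation, paste0("outer_", side))
  frames <- seq(1L, n_frames(traj), by = stride)
  out <- data.frame(frame = frames,
                    time_ps = (frames - 1L) * traj$frame_interval_ps,
                    delta_ldna = NA_real_, delta_dyad = NA_real_,
                    nc_inner = NA_integer_, nc_outer = NA_integer_,
                    tail_rg = NA_real_)
  for (i in seq_along(frames)) {
    xyz <- frame_xyz(traj, frames[i])
    out$delta_ldna[i] <- weighted_mean_distance(xyz, tail, ldna, n = 10)
    out$delta_dyad[i] <- weighted_mean_distance(xyz, tail, dyad, n = 10)
    out$nc_inner[i] <- count_contacts(st, xyz, tail, inner, cutoff)
    out$nc_outer[i] <- count_contacts(st, xyz, tail, outer, cutoff)
    out$tail_rg[i] <- compute_rg(st, xyz, tail)
  }
  out
}

#' Default H3-tail residue groups
#'
#' Epigenetically modifiable lysines/arginines of the H3 tail grouped by
#' position: the tip of the tail, two central groups, and the anchor
#' residues that pin the linker DNA to the inner gyre.
#'
#' @return named list of residue labels (one-letter code + residue number)
#' @export
h3_residue_groups <- function() {
  list(tip = c("R2", "K4"),
       center_tip = c("R8", "K9", "K14"),
       center_anchor = c("R26", "K27"),
       anchor = c("K36", "K37", "R40", "R42"))
}

# resolve residue labels like "K36" to atom indices within a tail's chain
.resolve_residue <- function(structure, annotation, tail_id, label) {
  row <- annotation$tails[annotation$tails$tail_id == tail_id, ][1, ]
  m <- regmatches(label, regexec("^([A-Za-z])([0-9]+)$", label))[[1]]
  if (length(m) != 3L) stop("malformed residue label: ", label)
  resno <- as.integer(m[3])
  at <- structure$atoms
  idx <- which(at$chain == row$chain & at$resid == resno)
  if (length(idx) == 0L)
    stop("residue ", label, " not found in chain ", row$chain)
  code <- .aa3to1[toupper(at$resname[idx[1]])]
  if (is.na(code) || toupper(m[2]) != code)
    stop("residue label ", label, " does not match residue ",
         at$resname[idx[1]], resno, " in chain ", row$chain)
  sel_heavy(structure, idx)
}

#' Per-residue minimal-distance profiles
#'
#' For each labeled tail residue, the weighted mean distance with n = 100
#' (a smooth stand-in for the minimal distance) between the residue's heavy
#' atoms and the chosen DNA gyre, every `stride`-th frame.
#'
#' @param traj a `nuc_trajectory`
#' @param annotation a `nuc_annotation`
#' @param tail_id tail the residues belong to (fixes the chain)
#' @param residues character vector of labels like `"K36"`, or a named list
#'   of groups of such labels (default: [h3_residue_groups()])
#' @param gyre `"inner"` or `"outer"`; `"outer"` means the outer gyre on the
#'   tail's own side
#' @param stride frame stride
#' @return long-format data.frame: frame, time_ps, residue, group, gyre,
#'   delta_min
#' @export
residue_distance_profile <- function(traj, annotation, tail_id,
                                     residues = h3_residue_groups(),
                                     gyre = c("inner", "outer"), stride = 1L) {
  gyre <- match.arg(gyre)
  st <- traj$topology
  if (is.null(annotation$tails) ||
      !tail_id %in% annotation$tails$tail_id)
    stop("tail '", tail_id, "' is not present in this annotation")
  side <- annotation$tails$side[annotation$tails$tail_id == tail_id][1]
  if (!is.list(residues)) residues <- list(ungrouped = residues)
  labels <- unlist(residues, use.names = FALSE)
  groups <- rep(names(residues), lengths(residues))
  sels <- lapply(labels, function(l)
    .resolve_residue(st, annotation, tail_id, l))
  gsel <- sel_gyre(st, annotation,
                   if (gyre == "inner") "inner" else paste0("outer_", side))
  frames <- seq(1L, n_frames(traj), by = stride)
  out <- expand.grid(residue = labels, frame = frames,
                     stringsAsFactors = FALSE)
  out$group <- groups[match(out$residue, labels)]
  out$time_ps <- (out$frame - 1L) * traj$frame_interval_ps
  out$gyre <- gyre
  out$delta_min <- NA_real_
  for (i in seq_len(nrow(out))) {
    xyz <- frame_xyz(traj, out$frame[i])
    out$delta_min[i] <- weighted_mean_distance(
      xyz, sels[[match(out$residue[i], labels)]], gsel, n = 100)
  }
  out[, c("frame", "time_ps", "residue", "group", "gyre", "delta_min")]
}

#' Median per-residue distance by cluster
#'
#' Cross-tabulates a per-residue distance profile against a per-frame
#' cluster assignment: entry (residue, cluster) is the median `delta_min`
#' over the cluster's frames. Clusters with no sampled frames yield `NA`.
#'
#' @param profile data.frame from [residue_distance_profile()]
#' @param assignment per-frame cluster labels, named or indexed by frame
#'   number, or a `nuc_clusters` object
#' @return numeric matrix residues x clusters
#' @export
cluster_median_heatmap <- function(profile, assignment) {
  if (inherits(assignment, "nuc_clusters")) assignment <- assignment$assignment
  frames <- sort(unique(profile$frame))
  if (max(frames) > length(assignment))
    stop("assignment does not cover all profiled frames")
  residues <- unique(profile$residue)
  labels <- sort(unique(assignment))
  out <- matrix(NA_real_, length(residues), length(labels),
                dimnames = list(residues, paste0("cluster_", labels)))
  cl_of <- assignment[profile$frame]
  for (r in residues) for (j in seq_along(labels)) {
    v <- profile$delta_min[profile$residue == r & cl_of == labels[j]]
    if (length(v) > 0L) out[r, j] <- stats::median(v)
  }
  out
}
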