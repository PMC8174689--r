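.aa1to3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
             Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
             L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
             S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
.aa3to1 <- stats::setNames(names(.aa1to3), unname(.aa1to3))

# DNA backbone heavy-atom names (both canonical and PDBv3 primed forms)
.dna_backbone <- c("P", "OP1", "OP2", "O5'", "C5'", "C4'", "O4'", "C3'",
                   "O3'", "C2'", "C1'")
.protein_backbone <- c("N", "CA", "C", "O")

#' Load a nucleosome annotation profile
#'
#' A profile names the DNA chains, maps histone chains to histone types and
#' nucleosome sides, and lists the tail residue ranges per histone type.
#' Profiles `"human"`, `"drosophila"` and `"tailless"` ship with the package
#' (YAML under `extdata/profiles`); a file path or a ready-made list is also
#' accepted.
#'
#' @param profile profile name, YAML/JSON file path, or list
#' @return list with elements `name`, `dna_chains`, `chain_map`, `tails`
#' @export
nuc_profile <- function(profile = "human") {
  if (is.list(profile)) return(profile)
  path <- if (file.exists(profile)) profile else
    system.file("extdata", "profiles", paste0(profile, ".yml"),
                package = "nucbreathe")
  if (!nzchar(path) || !file.exists(path))
    stop("unknown annotation profile: ", profile)
  p <- yaml::read_yaml(path)
  p$chain_map <- as.data.frame(p$chain_map, stringsAsFactors = FALSE)
  p
}

.tail_ranges_of <- function(profile, histone) {
  tr <- profile$tails[[histone]]
  if (is.null(tr)) return(list())
  if (!is.null(tr$from)) tr <- list(tr)
  lapply(tr, function(r) list(from = as.integer(r$from),
                              to = as.integer(r$to),
                              terminus = if (is.null(r$terminus)) NA_character_
                                         else r$terminus))
}

#' Annotate a nucleosome structure
#'
#' Assigns every base pair and histone residue its role in the breathing
#' analysis: inner vs outer gyre (the outer gyres are the terminal 40 bp of
#' each end), linker-DNA reference segments (terminal 15 bp), the dyad and
#' its side segments, the base-pair ranges defining the 3' and 5' arm
#' vectors, and per-chain histone tail ranges (core = complement).
#'
#' Base pairs are indexed 1..L along the sense strand 5' to 3'; base pair i
#' pairs the i-th residue of the sense strand with the (L+1-i)-th residue of
#' the antisense strand.
#'
#' @param structure a [nuc_structure()]
#' @param profile annotation profile (see [nuc_profile()])
#' @param dyad_bp dyad base-pair index; defaults to the sequence midpoint and
#'   must be within 1 bp of it
#' @param arm_bp optional list with integer vectors `p5` and `p3` of base-pair
#'   indices defining the arm vectors; default: the terminal 15 bp of each arm
#' @param opening_arm which arm (`"3p"` or `"5p"`) is treated as the opening
#'   arm when selecting DNA features for clustering
#' @param dyad_half_width bp on each side of the dyad forming the same-side
#'   dyad segments (default 4, giving 5-bp segments including the dyad)
#' @return object of class `nuc_annotation`
#' @export
annotate_nucleosome <- function(structure, profile = "human", dyad_bp = NULL,
                                arm_bp = NULL, opening_arm = c("3p", "5p"),
                                dyad_half_width = 4L) {
  opening_arm <- match.arg(opening_arm)
  p <- nuc_profile(profile)
  at <- structure$atoms
  sense <- p$dna_chains[[1]]; anti <- p$dna_chains[[2]]
  res_i <- unique(at$resid[at$chain == sense])
  res_j <- unique(at$resid[at$chain == anti])
  if (length(res_i) == 0L || length(res_j) == 0L)
    stop("DNA chains ", sense, "/", anti, " not found in structure")
  if (length(res_i) != length(res_j))
    stop("DNA strands have unequal length (", length(res_i), " vs ",
         length(res_j), ")")
  L <- length(res_i)
  if (L < 81L) stop("need at least 81 bp to apply the 40-bp outer-gyre rule")
  mid <- (L + 1) / 2
  if (is.null(dyad_bp)) dyad_bp <- as.integer(ceiling(mid))
  if (abs(dyad_bp - mid) > 1)
    stop("dyad_bp (", dyad_bp, ") is more than 1 bp from the midpoint")
  bp_map <- data.frame(bp = seq_len(L), resid_i = res_i,
                       resid_j = rev(res_j))
  outer_5p <- 1:40
  outer_3p <- (L - 39L):L
  inner <- setdiff(seq_len(L), c(outer_5p, outer_3p))
  ldna_5p <- 1:15
  ldna_3p <- (L - 14L):L
  h <- as.integer(dyad_half_width)
  dyad_seg_5p <- (dyad_bp - h):dyad_bp
  dyad_seg_3p <- dyad_bp:(dyad_bp + h)
  if (is.null(arm_bp)) arm_bp <- list(p5 = ldna_5p, p3 = ldna_3p)
  if (length(arm_bp$p5) < 2L || length(arm_bp$p3) < 2L)
    stop("each arm definition needs at least 2 base pairs")

  # histone tails: one row per tail segment present in the structure
  tails <- NULL
  cm <- p$chain_map
  for (i in seq_len(nrow(cm))) {
    ch <- cm$chain[i]
    if (!any(at$chain == ch)) next
    span <- range(at$resid[at$chain == ch])
    ranges <- if (!is.null(p$tails_by_chain)) {
      tr <- p$tails_by_chain[[ch]]
      if (is.null(tr)) list() else
        lapply(tr, function(r) list(from = as.integer(r$from),
                                    to = as.integer(r$to),
                                    terminus = r$terminus))
    } else .tail_ranges_of(p, cm$histone[i])
    for (j in seq_along(ranges)) {
      r <- ranges[[j]]
      if (r$from < span[1] || r$to > span[2])
        stop("tail range ", r$from, "-", r$to, " outside chain ",
             ch, " span ", span[1], "-", span[2])
      terminus <- if (is.na(r$terminus)) {
        if (r$from <= span[1]) "N" else "C"
      } else r$terminus
      base <- toupper(cm$histone[i])
      id <- paste0(base, if (terminus == "C") "C" else "", "_", cm$side[i])
      tails <- rbind(tails, data.frame(
        tail_id = id, chain = ch, histone = base, side = cm$side[i],
        terminus = terminus, from = r$from, to = r$to,
        stringsAsFactors = FALSE))
    }
  }
  if (!is.null(tails)) rownames(tails) <- NULL

  ann <- structure(list(
    profile = p$name, dna_chains = c(sense = sense, anti = anti),
    n_bp = L, dyad_bp = dyad_bp, bp_map = bp_map,
    outer_5p = outer_5p, outer_3p = outer_3p, inner = inner,
    ldna_5p = ldna_5p, ldna_3p = ldna_3p,
    dyad_seg_5p = dyad_seg_5p, dyad_seg_3p = dyad_seg_3p,
    arm_5p = sort(arm_bp$p5), arm_3p = sort(arm_bp$p3),
    hinge_5p = 40L, hinge_3p = L - 39L,
    opening_arm = opening_arm,
    histone_chains = cm$chain[cm$chain %in% at$chain],
    chain_map = cm[cm$chain %in% at$chain, , drop = FALSE],
    tails = tails), class = "nuc_annotation")
  stopifnot(length(ann$inner) + length(ann$outer_5p) + length(ann$outer_3p)
            == L)
  ann
}

#' @export
print.nuc_annotation <- function(x, ...) {
  cat(sprintf(paste0("<nuc_annotation> profile %s: %d bp (dyad %d), ",
                     "outer gyres %d bp, inner %d bp, %d tail segment(s)\n"),
              x$profile, x$n_bp, x$dyad_bp,
              length(x$outer_5p) + length(x$outer_3p), length(x$inner),
              if (is.null(x$tails)) 0L else nrow(x$tails)))
  invisible(x)
}

# ---- selections ------------------------------------------------------------

#' Indices of heavy (non-hydrogen) atoms
#' @param structure a `nuc_structure`
#' @param idx optional subset of atom indices to filter
#' @return integer atom indices
#' @export
sel_heavy <- function(structure, idx = NULL) {
  if (is.null(idx)) idx <- seq_len(n_atoms(structure))
  idx[toupper(structure$atoms$element[idx]) != "H"]
}

#' Atom indices of a set of base pairs
#' @param structure a `nuc_structure`
#' @param annotation a `nuc_annotation`
#' @param bp integer base-pair indices
#' @param heavy keep heavy atoms only
#' @param backbone keep DNA backbone atoms only
#' @return integer atom indices (both strands)
#' @export
sel_bp <- function(structure, annotation, bp, heavy = TRUE, backbone = FALSE) {
  at <- structure$atoms
  m <- annotation$bp_map[annotation$bp_map$bp %in% bp, ]
  sense <- annotation$dna_chains["sense"]; anti <- annotation$dna_chains["anti"]
  idx <- which((at$chain == sense & at$resid %in% m$resid_i) |
               (at$chain == anti & at$resid %in% m$resid_j))
  if (backbone) idx <- idx[at$name[idx] %in% .dna_backbone]
  if (heavy) idx <- sel_heavy(structure, idx)
  idx
}

#' All DNA atom indices
#' @inheritParams sel_bp
#' @export
sel_dna <- function(structure, annotation, heavy = TRUE) {
  sel_bp(structure, annotation, seq_len(annotation$n_bp), heavy = heavy)
}

#' Atom indices of one histone tail
#' @inheritParams sel_bp
#' @param tail_id tail identifier as listed in `annotation$tails$tail_id`,
#'   e.g. `"H3_3p"` or `"H2AC_5p"`
#' @export
sel_tail <- function(structure, annotation, tail_id, heavy = TRUE) {
  tl <- annotation$tails
  if (is.null(tl) || !tail_id %in% tl$tail_id)
    stop("tail '", tail_id, "' is not present in this annotation",
         if (is.null(tl)) " (tail-less structure)" else "")
  row <- tl[tl$tail_id == tail_id, ][1, ]
  at <- structure$atoms
  idx <- which(at$chain == row$chain & at$resid >= row$from &
               at$resid <= row$to)
  if (length(idx) == 0L)
    stop("tail '", tail_id, "' resolves to an empty atom selection")
  if (heavy) idx <- sel_heavy(structure, idx)
  idx
}

#' Atom indices of the histone core (all histone residues outside tails)
#' @inheritParams sel_bp
#' @export
sel_histone_core <- function(structure, annotation, heavy = TRUE) {
  at <- structure$atoms
  idx <- which(at$chain %in% annotation$histone_chains)
  tl <- annotation$tails
  if (!is.null(tl)) {
    intail <- rep(FALSE, length(idx))
    for (i in seq_len(nrow(tl)))
      intail <- intail | (at$chain[idx] == tl$chain[i] &
                          at$resid[idx] >= tl$from[i] &
                          at$resid[idx] <= tl$to[i])
    idx <- idx[!intail]
  }
  if (length(idx) == 0L) stop("histone core selection is empty")
  if (heavy) idx <- sel_heavy(structure, idx)
  idx
}

#' Gyre atom selection
#' @inheritParams sel_bp
#' @param gyre `"inner"`, `"outer_3p"`, `"outer_5p"`, or `"outer"` (both)
#' @export
sel_gyre <- function(structure, annotation, gyre, heavy = TRUE) {
  bp <- switch(gyre,
    inner = annotation$inner,
    outer_3p = annotation$outer_3p,
    outer_5p = annotation$outer_5p,
    outer = c(annotation$outer_5p, annotation$outer_3p),
    stop("unknown gyre: ", gyre))
  sel_bp(structure, annotation, bp, heavy = heavy)
}

#' Base-pair centers
#'
#' The center of base pair i is the centroid of the C1' atoms of its two
#' paired residues; residues lacking C1' fall back to the centroid of all
#' their heavy atoms.
#'
#' @param structure a `nuc_structure`
#' @param xyz `n_atoms x 3` frame coordinates
#' @param annotation a `nuc_annotation`
#' @param bp integer base-pair indices
#' @return `length(bp) x 3` matrix of centers, rows in `bp` order
#' @export
bp_centers <- function(structure, xyz, annotation, bp) {
  at <- structure$atoms
  sense <- annotation$dna_chains["sense"]; anti <- annotation$dna_chains["anti"]
  m <- annotation$bp_map
  out <- matrix(NA_real_, length(bp), 3L)
  for (k in seq_along(bp)) {
    row <- m[m$bp == bp[k], ]
    idx <- which((at$chain == sense & at$resid == row$resid_i) |
                 (at$chain == anti & at$resid == row$resid_j))
    c1 <- idx[at$name[idx] == "C1'"]
    if (length(c1) >= 1L) idx <- c1 else idx <- sel_heavy(structure, idx)
    out[k, ] <- colMeans(xyz[idx, , drop = FALSE])
  }
  out
}

# annotation <-> JSON (used by the staged pipeline so each stage can be
# replayed from files)

#' Serialize an annotation to JSON
#' @param annotation a `nuc_annotation`
#' @param path output path
#' @export
write_annotation_json <- function(annotation, path) {
  jsonlite::write_json(unclass(annotation), path, auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Read an annotation written by [write_annotation_json()]
#' @param path JSON path
#' @export
read_annotation_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$dna_chains <- stats::setNames(as.character(unlist(x$dna_chains)),
                                  c("sense", "anti"))
  for (f in c("bp_map", "chain_map", "tails"))
    if (!is.null(x[[f]])) x[[f]] <- as.data.frame(x[[f]])
  for (f in c("outer_5p", "outer_3p", "inner", "ldna_5p", "ldna_3p",
              "dyad_seg_5p", "dyad_seg_3p", "arm_5p", "arm_3p"))
    x[[f]] <- as.integer(x[[f]])
  class(x) <- "nuc_annotation"
  x
}
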