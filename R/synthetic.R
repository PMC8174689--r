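# N-terminal (and H2A C-terminal) tail sequences used to name the synthetic
# tail beads, so that residue labels like "K36" resolve on generated
# structures exactly as on real ones
.tail_seqs <- list(
  H3  = "ARTKQTARKSTGGKAPRKQLATKAARKSAPATGGVKKPHRYRPGT",
  H4  = "SGRGKGGKGLGKGGAKRHRKVLRDNIQGITKP",
  H2A = "SGRGKQGGKARAKAKTRS",
  H2AC = "KTESHHKAKGK",
  H2B = "PEPAKSAPAPKKGSKKAVTKAQKKDGKKRKRSR")

.tail_modes <- c("bridge", "dyad_collapsed", "detached", "absent")

.default_tails <- function() {
  lens <- c(H3_3p = 45, H3_5p = 45, H4_3p = 32, H4_5p = 32,
            H2A_3p = 18, H2A_5p = 18, H2AC_3p = 11, H2AC_5p = 11,
            H2B_3p = 33, H2B_5p = 33)
  modes <- ifelse(grepl("^H3|^H2AC", names(lens)), "bridge", "dyad_collapsed")
  out <- list()
  for (i in seq_along(lens))
    out[[names(lens)[i]]] <- list(length = unname(lens[i]), mode = modes[i])
  out
}

#' Specification of a synthetic nucleosome
#'
#' Geometric parameters of the idealized coarse nucleosome model: DNA beads
#' on a left-handed superhelix (core) continued by straight B-DNA-like
#' linker arms, a histone-core bead ring, and one pseudo-heavy bead per tail
#' residue. Defaults resemble canonical nucleosome dimensions (superhelix
#' radius 41.9 A, pitch 25.9 A, 1.65 turns, 3.3 A rise per linker bp); they
#' are generator parameters, not measured values.
#'
#' @param core_bp wrapped core length in base pairs
#' @param linker_bp straight linker length per arm in base pairs
#' @param superhelix_radius superhelix radius, Angstrom
#' @param superhelix_pitch superhelix pitch, Angstrom per turn
#' @param wrap_turns superhelical turns spanned by the core
#' @param rise_per_bp linker rise, Angstrom per bp
#' @param beads_per_nucleotide DNA beads per nucleotide (>= 1)
#' @param strand_offset half distance between paired strand beads, Angstrom
#' @param core_beads_per_chain histone-core ring beads per histone chain
#' @param ring_radius histone-core ring radius, Angstrom
#' @param arm_elevation_deg angle between the closed arm direction and the
#'   dyad-frame Z axis, inside the frame's YZ plane (both opening angles are
#'   zero by construction for any value)
#' @param jitter_sd Gaussian positional noise applied per trajectory frame,
#'   Angstrom
#' @param tails named list `tail_id = list(length, mode)`; see
#'   [make_ideal_nucleosome()]. Modes: `"bridge"`, `"dyad_collapsed"`,
#'   `"detached"`, `"absent"`.
#' @param seed integer seed recorded in the output and used for jitter
#' @return list of class `nuc_synth_spec`
#' @export
synthetic_spec <- function(core_bp = 147L, linker_bp = 11L,
                           superhelix_radius = 41.9, superhelix_pitch = 25.9,
                           wrap_turns = 1.65, rise_per_bp = 3.3,
                           beads_per_nucleotide = 1L, strand_offset = 5,
                           core_beads_per_chain = 20L, ring_radius = 30,
                           arm_elevation_deg = 60, jitter_sd = 0.3,
                           tails = NULL, seed = 1L) {
  if (is.null(tails)) tails <- .default_tails()
  spec <- list(core_bp = as.integer(core_bp), linker_bp = as.integer(linker_bp),
               superhelix_radius = superhelix_radius,
               superhelix_pitch = superhelix_pitch, wrap_turns = wrap_turns,
               rise_per_bp = rise_per_bp,
               beads_per_nucleotide = as.integer(beads_per_nucleotide),
               strand_offset = strand_offset,
               core_beads_per_chain = as.integer(core_beads_per_chain),
               ring_radius = ring_radius,
               arm_elevation_deg = arm_elevation_deg,
               jitter_sd = jitter_sd, tails = tails, seed = as.integer(seed))
  with(spec, {
    if (core_bp <= 0 || linker_bp < 0 || superhelix_radius <= 0 ||
        superhelix_pitch <= 0 || wrap_turns <= 0 || rise_per_bp <= 0 ||
        beads_per_nucleotide < 1 || strand_offset <= 0 ||
        core_beads_per_chain < 3 || ring_radius <= 0 || jitter_sd < 0)
      stop("invalid synthetic spec: all lengths/radii must be positive")
  })
  for (id in names(spec$tails)) {
    t <- spec$tails[[id]]
    if (!t$mode %in% .tail_modes)
      stop("invalid tail mode '", t$mode, "' for ", id)
    if (t$mode != "absent" && t$length < 1)
      stop("tail ", id, " must have length >= 1")
  }
  class(spec) <- "nuc_synth_spec"
  spec
}

# rotation matrix about a unit axis (Rodrigues), angle in degrees
.rot_about <- function(axis, angle_deg) {
  a <- angle_deg * pi / 180
  u <- .unit(axis)
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# ---- base geometry ---------------------------------------------------------

# Builds everything frame-independent: bp centers of the closed structure,
# the generator dyad frame, atom tables, index maps, per-arm rotating atom
# sets and hinge points. Tail coordinates are placeholders (placed per frame).
.synth_base <- function(spec) {
  L <- spec$core_bp + 2L * spec$linker_bp
  core_lo <- spec$linker_bp + 1L
  core_hi <- spec$linker_bp + spec$core_bp
  dyad <- as.integer(ceiling((L + 1) / 2))
  R <- spec$superhelix_radius
  dtheta <- 2 * pi * spec$wrap_turns / (spec$core_bp - 1)

  centers <- matrix(NA_real_, L, 3L)
  udir <- matrix(NA_real_, L, 3L)  # strand-offset direction per bp
  for (b in core_lo:core_hi) {
    th <- (b - dyad) * dtheta
    centers[b, ] <- c(R * cos(th), R * sin(th),
                      -spec$superhelix_pitch * th / (2 * pi))
    udir[b, ] <- c(cos(th), sin(th), 0)
  }

  # generator dyad frame from the exact inner-gyre centers
  inner <- setdiff(seq_len(L), c(1:40, (L - 39L):L))
  gframe <- .dyad_frame_from_centers(centers[inner, , drop = FALSE],
                                     centers[dyad, ])

  # straight linkers along a fixed direction in the frame's YZ plane, so
  # that both opening angles of the closed structure are exactly zero
  phi <- spec$arm_elevation_deg * pi / 180
  v0f <- c(0, sin(phi), cos(phi))
  arm_dir <- as.numeric(cbind(gframe$X, gframe$Y, gframe$Z) %*% v0f)
  if (spec$linker_bp > 0) {
    for (b in (core_hi + 1L):L) {
      centers[b, ] <- centers[core_hi, ] + (b - core_hi) *
        spec$rise_per_bp * arm_dir
      udir[b, ] <- udir[core_hi, ]
    }
    for (b in seq_len(core_lo - 1L)) {
      centers[b, ] <- centers[core_lo, ] + (core_lo - b) *
        spec$rise_per_bp * arm_dir
      udir[b, ] <- udir[core_lo, ]
    }
  }

  bpn <- spec$beads_per_nucleotide
  w <- spec$strand_offset
  zhat <- c(0, 0, 1)
  dna_names_pool <- .dna_backbone[c(length(.dna_backbone),
                                    seq_len(length(.dna_backbone) - 1L))]
  dna_names <- dna_names_pool[((seq_len(bpn) - 1L) %%
                               length(dna_names_pool)) + 1L]  # C1' first
  nuc_xyz <- function(center, u, sgn) {
    base <- center + sgn * w * u
    out <- matrix(rep(base, bpn), ncol = 3, byrow = TRUE)
    if (bpn > 1L) out <- out + outer(seq_len(bpn) - 1L, zhat)
    out
  }
  rows <- list(); coords <- list()
  for (r in seq_len(L)) {  # sense strand I, resid r = bp r
    rows[[length(rows) + 1L]] <- data.frame(
      name = dna_names[seq_len(bpn)], resname = "DA", chain = "I",
      resid = r, element = "C", mass = 1, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- nuc_xyz(centers[r, ], udir[r, ], +1)
  }
  for (r in seq_len(L)) {  # antisense strand J, resid r = bp L + 1 - r
    b <- L + 1L - r
    rows[[length(rows) + 1L]] <- data.frame(
      name = dna_names[seq_len(bpn)], resname = "DT", chain = "J",
      resid = r, element = "C", mass = 1, stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <- nuc_xyz(centers[b, ], udir[b, ], -1)
  }

  # histone chains: N-tail beads, core ring beads, optional C-tail beads
  chain_map <- data.frame(
    chain = c("A", "B", "C", "D", "E", "F", "G", "H"),
    histone = rep(c("H3", "H4", "H2A", "H2B"), 2),
    side = rep(c("3p", "5p"), each = 4), stringsAsFactors = FALSE)
  nring <- spec$core_beads_per_chain
  ring_total <- 8L * nring
  ring_angles <- 2 * pi * (seq_len(ring_total) - 1L) / ring_total
  ring_xyz <- cbind(spec$ring_radius * cos(ring_angles),
                    spec$ring_radius * sin(ring_angles), 0)
  tail_info <- list()   # per tail id: chain, resid range, atom rows
  tails_by_chain <- list()
  k_ring <- 0L
  seq_beads <- function(histone, terminus, len) {
    sq <- .tail_seqs[[if (terminus == "C") paste0(histone, "C") else histone]]
    aa <- strsplit(sq, "")[[1]]
    if (len <= length(aa)) aa <- aa[seq_len(len)]
    else aa <- c(aa, rep("G", len - length(aa)))
    unname(.aa1to3[aa])
  }
  for (i in seq_len(nrow(chain_map))) {
    ch <- chain_map$chain[i]; hist <- chain_map$histone[i]
    side <- chain_map$side[i]
    nt_id <- paste0(hist, "_", side)
    nt <- spec$tails[[nt_id]]
    nt_len <- if (is.null(nt) || nt$mode == "absent") 0L else nt$length
    if (nt_len > 0L) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = "CA", resname = seq_beads(hist, "N", nt_len), chain = ch,
        resid = seq_len(nt_len), element = "C", mass = 1,
        stringsAsFactors = FALSE)
      coords[[length(coords) + 1L]] <- matrix(0, nt_len, 3L)  # placed later
      tail_info[[nt_id]] <- list(chain = ch, from = 1L, to = nt_len,
                                 side = side, len = nt_len,
                                 atom_from = sum(vapply(coords, nrow, 1L)) -
                                   nt_len + 1L)
      tails_by_chain[[ch]] <- c(tails_by_chain[[ch]],
                                list(list(terminus = "N", from = 1L,
                                          to = nt_len)))
    }
    rows[[length(rows) + 1L]] <- data.frame(
      name = "CA", resname = "ALA", chain = ch,
      resid = nt_len + seq_len(nring), element = "C", mass = 1,
      stringsAsFactors = FALSE)
    coords[[length(coords) + 1L]] <-
      ring_xyz[k_ring + seq_len(nring), , drop = FALSE]
    k_ring <- k_ring + nring
    if (hist == "H2A") {
      ct_id <- paste0("H2AC_", side)
      ct <- spec$tails[[ct_id]]
      ct_len <- if (is.null(ct) || ct$mode == "absent") 0L else ct$length
      if (ct_len > 0L) {
        rows[[length(rows) + 1L]] <- data.frame(
          name = "CA", resname = seq_beads(hist, "C", ct_len), chain = ch,
          resid = nt_len + nring + seq_len(ct_len), element = "C", mass = 1,
          stringsAsFactors = FALSE)
        coords[[length(coords) + 1L]] <- matrix(0, ct_len, 3L)
        tail_info[[ct_id]] <- list(chain = ch, from = nt_len + nring + 1L,
                                   to = nt_len + nring + ct_len, side = side,
                                   len = ct_len,
                                   atom_from = sum(vapply(coords, nrow, 1L)) -
                                     ct_len + 1L)
        tails_by_chain[[ch]] <- c(tails_by_chain[[ch]],
                                  list(list(terminus = "C",
                                            from = nt_len + nring + 1L,
                                            to = nt_len + nring + ct_len)))
      }
    }
  }

  atoms <- do.call(rbind, rows)
  xyz <- do.call(rbind, coords)
  # atom index of the first bead of each bp on each strand
  idx_I <- (seq_len(L) - 1L) * bpn + 1L
  idx_J <- L * bpn + (L - seq_len(L)) * bpn + 1L
  dna_atoms <- seq_len(2L * L * bpn)

  profile <- list(name = "synthetic", dna_chains = list("I", "J"),
                  chain_map = chain_map, tails = list(),
                  tails_by_chain = tails_by_chain)
  bp_per_turn <- as.integer(round((spec$core_bp - 1) / spec$wrap_turns))
  list(spec = spec, L = L, dyad = dyad, centers = centers, udir = udir,
       gframe = gframe, v0f = v0f, arm_dir = arm_dir,
       atoms = atoms, xyz = xyz, idx_I = idx_I, idx_J = idx_J,
       dna_atoms = dna_atoms, tail_info = tail_info, profile = profile,
       bp_per_turn = bp_per_turn,
       hinge_5p = 40L, hinge_3p = L - 39L,
       rot_bp_5p = 1:40, rot_bp_3p = (L - 39L):L,
       inner = setdiff(seq_len(L), c(1:40, (L - 39L):L)))
}

# atom indices (both strands, all beads) of a set of bp
.bp_atoms_synth <- function(base, bp) {
  bpn <- base$spec$beads_per_nucleotide
  idx <- c(outer(0:(bpn - 1L), base$idx_I[bp], `+`),
           outer(0:(bpn - 1L), base$idx_J[bp], `+`))
  sort(idx)
}

# exact opening angles of the rotated arm, from the applied rotation in
# generator-frame coordinates
.gamma_truth <- function(base, oop, ip) {
  v <- .rot_about(c(0, 0, 1), ip) %*% (.rot_about(c(0, 1, 0), oop) %*% base$v0f)
  c(gamma1 = atan2(v[1], v[3]) * 180 / pi,
    gamma2 = atan2(-v[1], v[2]) * 180 / pi)
}

# DNA coordinates with both arms rotated about their hinges; also returns
# current bp centers (needed for tail placement)
.rotated_dna <- function(base, oop_3p = 0, ip_3p = 0, oop_5p = 0, ip_5p = 0) {
  xyz <- base$xyz
  centers <- base$centers
  A <- cbind(base$gframe$X, base$gframe$Y, base$gframe$Z)
  for (side in c("3p", "5p")) {
    oop <- if (side == "3p") oop_3p else oop_5p
    ip <- if (side == "3p") ip_3p else ip_5p
    if (oop == 0 && ip == 0) next
    Rf <- .rot_about(c(0, 0, 1), ip) %*% .rot_about(c(0, 1, 0), oop)
    Rl <- A %*% Rf %*% t(A)
    hinge_bp <- if (side == "3p") base$hinge_3p else base$hinge_5p
    p <- centers[hinge_bp, ]
    bp <- if (side == "3p") base$rot_bp_3p else base$rot_bp_5p
    ai <- .bp_atoms_synth(base, bp)
    xyz[ai, ] <- sweep(sweep(xyz[ai, , drop = FALSE], 2, p) %*% t(Rl), 2, p, `+`)
    centers[bp, ] <- sweep(sweep(centers[bp, , drop = FALSE], 2, p) %*% t(Rl),
                           2, p, `+`)
  }
  list(xyz = xyz, centers = centers)
}

# place one tail's beads for a given mode, against the current DNA geometry
.place_tail <- function(base, id, mode, dna) {
  ti <- base$tail_info[[id]]
  len <- ti$len
  L <- base$L
  side <- ti$side
  if (mode == "bridge") {
    o_bp <- if (side == "3p") min(base$hinge_3p + 20L, L - 2L)
            else max(base$hinge_5p - 20L, 3L)
    i_bp <- if (side == "3p") o_bp - base$bp_per_turn
            else o_bp + base$bp_per_turn
    i_bp <- min(max(i_bp, min(base$inner)), max(base$inner))
    p_out <- dna$xyz[base$idx_I[o_bp], ]
    p_in <- dna$xyz[base$idx_I[i_bp], ]
    u <- .unit(p_out - p_in)
    a <- p_in + 2 * u
    b <- p_out - 2 * u
    tt <- if (len == 1L) 0.5 else (seq_len(len) - 1L) / (len - 1L)
    out <- matrix(NA_real_, len, 3L)
    for (k in seq_len(len)) out[k, ] <- a + tt[k] * (b - a)
    return(out)
  }
  if (mode == "dyad_collapsed") {
    h <- 4L
    seg <- if (side == "3p") base$dyad:(base$dyad + h)
           else (base$dyad - h):base$dyad
    nseg <- length(seg)
    out <- matrix(NA_real_, len, 3L)
    for (k in seq_len(len)) {
      b <- seg[((k - 1L) %% nseg) + 1L]
      layer <- (k - 1L) %/% nseg
      cc <- dna$centers[b, ]
      u <- base$udir[b, ]
      out[k, ] <- cc + (base$spec$strand_offset - 2 + 0.4 * layer) * u
    }
    return(out)
  }
  if (mode == "detached") {
    cen <- colMeans(dna$xyz[base$dna_atoms, , drop = FALSE])
    hinge_bp <- if (side == "3p") base$hinge_3p else base$hinge_5p
    u <- .unit(dna$centers[hinge_bp, ] - cen)
    proj <- as.numeric(dna$xyz[base$dna_atoms, , drop = FALSE] %*% u)
    base_pt <- cen + (max(proj - as.numeric(cen %*% u)) + 12) * u
    out <- matrix(rep(base_pt, len), ncol = 3, byrow = TRUE) +
      outer((seq_len(len) - 1L) * 3, u)
    return(out)
  }
  stop("cannot place tail in mode '", mode, "'")
}

# run code with a private RNG stream, restoring the caller's stream after
.with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  fn()
}

#' Generate an idealized closed nucleosome
#'
#' Lays the DNA beads of a `core_bp + 2 * linker_bp` base-pair nucleosome on
#' a superhelix with straight linker arms, builds the histone-core bead ring
#' and the tail bead chains (placed according to each tail's mode in the
#' spec), and returns the structure together with its ground truth (the
#' generator's dyad frame and the exact opening angles, zero for the closed
#' configuration) and a matching annotation. No noise is applied.
#'
#' @param spec a [synthetic_spec()]
#' @return list with elements `structure` ([nuc_structure()]),
#'   `ground_truth` (list: seed, spec echo, frame axes, angles, tail modes)
#'   and `annotation` ([annotate_nucleosome()] result whose arm vectors are
#'   the exactly straight linker base pairs)
#' @export
make_ideal_nucleosome <- function(spec = synthetic_spec()) {
  if (!inherits(spec, "nuc_synth_spec")) stop("spec must be a synthetic_spec()")
  base <- .synth_base(spec)
  dna <- list(xyz = base$xyz, centers = base$centers)
  xyz <- base$xyz
  modes <- list()
  for (id in names(base$tail_info)) {
    mode <- spec$tails[[id]]$mode
    modes[[id]] <- mode
    ti <- base$tail_info[[id]]
    xyz[ti$atom_from:(ti$atom_from + ti$len - 1L), ] <-
      .place_tail(base, id, mode, dna)
  }
  st <- nuc_structure(base$atoms, xyz)
  ann <- synthetic_annotation(spec, st, base)
  gt <- list(seed = spec$seed, spec = unclass(spec),
             frame = list(origin = base$gframe$origin, X = base$gframe$X,
                          Y = base$gframe$Y, Z = base$gframe$Z),
             angles = data.frame(frame = 1L,
                                 arm = c("3p", "5p"),
                                 oop = 0, ip = 0,
                                 gamma1_true = 0, gamma2_true = 0),
             tail_modes = if (length(modes))
               data.frame(frame = 1L, tail_id = names(modes),
                          mode = unlist(modes), row.names = NULL)
             else NULL)
  list(structure = st, ground_truth = gt, annotation = ann)
}

#' Annotation matching a synthetic nucleosome
#'
#' Same roles as [annotate_nucleosome()], with the arm-vector base pairs set
#' to the exactly straight linker segments of the generator.
#'
#' @param spec the [synthetic_spec()] used to generate the structure
#' @param structure the generated structure
#' @param base internal; reuse of precomputed geometry
#' @param opening_arm passed through to [annotate_nucleosome()]
#' @return a `nuc_annotation`
#' @export
synthetic_annotation <- function(spec, structure, base = NULL,
                                 opening_arm = "3p") {
  if (is.null(base)) base <- .synth_base(spec)
  L <- base$L
  arm_bp <- if (spec$linker_bp >= 2L)
    list(p5 = seq_len(spec$linker_bp), p3 = (L - spec$linker_bp + 1L):L)
  else NULL
  annotate_nucleosome(structure, base$profile, dyad_bp = base$dyad,
                      arm_bp = arm_bp, opening_arm = opening_arm)
}

#' Generate a breathing trajectory with known ground truth
#'
#' Each frame rigidly rotates each linker + outer-gyre arm about its hinge
#' (the base pair at the inner boundary of the outer gyre) by the prescribed
#' out-of-plane angle (about the generator frame's Y axis) followed by the
#' in-plane angle (about Z), repositions the tails according to the per-frame
#' mode schedule, and adds Gaussian positional jitter.
#'
#' The two opening angles are coupled through the arm vector's X component,
#' so an arbitrary (out-of-plane, in-plane) pair is not always realizable
#' exactly; the ground truth therefore records both the prescribed angles
#' and the exact analytic `gamma1`/`gamma2` of the rotated arm. Whenever one
#' prescribed angle is zero the other equals its gamma exactly.
#'
#' @param spec a [synthetic_spec()]
#' @param angle_series data.frame with one row per frame and any of the
#'   columns `oop_3p`, `ip_3p`, `oop_5p`, `ip_5p` (degrees, within
#'   (-90, 90); missing columns default to 0)
#' @param tail_schedule per-frame tail modes: `NULL` (each tail keeps its
#'   spec mode), a single mode name, or a data.frame/list with one column
#'   (vector) per tail id of length `n_frames`
#' @param seed jitter seed (default: `spec$seed`)
#' @param frame_interval_ps trajectory cadence, picoseconds
#' @return list with `trajectory` ([nuc_trajectory()]), `ground_truth`
#'   (seed, frame axes, per-frame angles with analytic gammas, per-frame
#'   tail modes) and `annotation`
#' @export
make_breathing_trajectory <- function(spec = synthetic_spec(), angle_series,
                                      tail_schedule = NULL, seed = NULL,
                                      frame_interval_ps = 20) {
  if (!inherits(spec, "nuc_synth_spec")) stop("spec must be a synthetic_spec()")
  if (is.null(seed)) seed <- spec$seed
  angle_series <- as.data.frame(angle_series)
  nf <- nrow(angle_series)
  if (nf < 1L) stop("angle_series must have at least one frame")
  for (col in c("oop_3p", "ip_3p", "oop_5p", "ip_5p")) {
    if (is.null(angle_series[[col]])) angle_series[[col]] <- 0
    if (any(abs(angle_series[[col]]) >= 90))
      stop("prescribed angles must lie within (-90, 90) degrees")
  }
  base <- .synth_base(spec)
  present <- names(base$tail_info)
  sched <- .normalize_schedule(tail_schedule, spec, present, nf)

  ideal <- make_ideal_nucleosome(spec)
  topo <- ideal$structure
  coords <- array(NA_real_, c(n_atoms(topo), 3L, nf))
  ang_rows <- vector("list", nf)
  .with_seed(seed, function() {
    for (f in seq_len(nf)) {
      a <- angle_series[f, ]
      dna <- .rotated_dna(base, a$oop_3p, a$ip_3p, a$oop_5p, a$ip_5p)
      xyz <- base$xyz
      xyz[base$dna_atoms, ] <- dna$xyz[base$dna_atoms, ]
      for (id in present) {
        ti <- base$tail_info[[id]]
        xyz[ti$atom_from:(ti$atom_from + ti$len - 1L), ] <-
          .place_tail(base, id, sched[[id]][f], dna)
      }
      if (spec$jitter_sd > 0)
        xyz <- xyz + matrix(stats::rnorm(length(xyz), 0, spec$jitter_sd),
                            ncol = 3L)
      coords[, , f] <<- xyz
      g3 <- .gamma_truth(base, a$oop_3p, a$ip_3p)
      g5 <- .gamma_truth(base, a$oop_5p, a$ip_5p)
      ang_rows[[f]] <<- data.frame(
        frame = f, arm = c("3p", "5p"),
        oop = c(a$oop_3p, a$oop_5p), ip = c(a$ip_3p, a$ip_5p),
        gamma1_true = c(g3[1], g5[1]), gamma2_true = c(g3[2], g5[2]))
    }
  })
  traj <- nuc_trajectory(topo, coords, frame_interval_ps)
  tail_modes <- if (length(present))
    do.call(rbind, lapply(seq_len(nf), function(f)
      data.frame(frame = f, tail_id = present,
                 mode = vapply(present, function(id) sched[[id]][f], ""),
                 row.names = NULL)))
  else NULL
  gt <- list(seed = seed, spec = unclass(spec),
             frame = list(origin = base$gframe$origin, X = base$gframe$X,
                          Y = base$gframe$Y, Z = base$gframe$Z),
             angles = do.call(rbind, ang_rows), tail_modes = tail_modes)
  list(trajectory = traj, ground_truth = gt, annotation = ideal$annotation)
}

.normalize_schedule <- function(tail_schedule, spec, present, nf) {
  sched <- list()
  if (is.null(tail_schedule)) {
    for (id in present) sched[[id]] <- rep(spec$tails[[id]]$mode, nf)
  } else if (is.character(tail_schedule) && length(tail_schedule) == 1L) {
    for (id in present) sched[[id]] <- rep(tail_schedule, nf)
  } else {
    tail_schedule <- as.list(tail_schedule)
    tail_schedule$frame <- NULL
    for (id in present) {
      v <- tail_schedule[[id]]
      if (is.null(v)) v <- rep(spec$tails[[id]]$mode, nf)
      if (length(v) == 1L) v <- rep(v, nf)
      if (length(v) != nf)
        stop("tail schedule for ", id, " has length ", length(v),
             ", expected ", nf)
      sched[[id]] <- as.character(v)
    }
    extra <- setdiff(names(tail_schedule), present)
    if (length(extra))
      stop("tail schedule names not present in structure: ",
           paste(extra, collapse = ", "))
  }
  for (id in present) {
    bad <- setdiff(unique(sched[[id]]), setdiff(.tail_modes, "absent"))
    if (length(bad))
      stop("invalid per-frame tail mode(s) for ", id, ": ",
           paste(bad, collapse = ", "))
  }
  sched
}

#' Remove all histone tail atoms from a structure
#'
#' Returns the structure with every atom of every annotated tail residue
#' removed; all other atoms (and all models) are unchanged. Applying it to
#' an already tail-less structure is a no-op.
#'
#' @param structure a `nuc_structure`
#' @param annotation a `nuc_annotation` marking the tail residues
#' @return a `nuc_structure` without tail atoms
#' @export
tailless_variant <- function(structure, annotation) {
  tl <- annotation$tails
  if (is.null(tl) || nrow(tl) == 0L) return(structure)
  at <- structure$atoms
  drop <- rep(FALSE, nrow(at))
  for (i in seq_len(nrow(tl)))
    drop <- drop | (at$chain == tl$chain[i] & at$resid >= tl$from[i] &
                    at$resid <= tl$to[i])
  keep <- which(!drop)
  nuc_structure(at[keep, , drop = FALSE],
                structure$xyz[keep, , , drop = FALSE])
}

#' Prescribed breathing scenarios
#'
#' Convenience builder for the angle series and tail schedules used in
#' validation and the worked examples.
#'
#' * `"constant"`: both arms closed at 0 degrees throughout.
#' * `"step"`: out-of-plane angle of one arm steps from 0 to `amplitude` at
#'   `step_frame`.
#' * `"sine"`: in-plane angle of one arm follows a sinusoid of the given
#'   `amplitude` and `period` (frames).
#' * `"coupled_opening"`: the H3 and H2AC tails on the opening side switch
#'   from `"bridge"` to `"detached"` at `tail_detach_frame`, then the arm's
#'   in-plane angle steps from 0 to `amplitude` at `dna_open_frame` (tail
#'   release precedes DNA opening by construction; positive in-plane
#'   opening increases the DNA radius of gyration).
#'
#' @param scenario scenario name
#' @param n_frames number of frames
#' @param arm arm the motion applies to
#' @param amplitude angle amplitude, degrees
#' @param step_frame first frame of the stepped angle
#' @param period sinusoid period in frames
#' @param tail_detach_frame first frame with detached tails
#' @param dna_open_frame first frame with the opened arm
#' @return list with `angles` (data.frame for
#'   [make_breathing_trajectory()]) and `tails` (schedule or `NULL`)
#' @export
breathing_scenario <- function(scenario = c("constant", "step", "sine",
                                            "coupled_opening"),
                               n_frames = 100L, arm = "3p", amplitude = 30,
                               step_frame = ceiling(n_frames / 2),
                               period = n_frames,
                               tail_detach_frame = ceiling(n_frames * 0.45),
                               dna_open_frame = ceiling(n_frames * 0.5)) {
  scenario <- match.arg(scenario)
  zero <- data.frame(oop_3p = numeric(n_frames), ip_3p = 0,
                     oop_5p = 0, ip_5p = 0)
  f <- seq_len(n_frames)
  if (scenario == "constant") return(list(angles = zero, tails = NULL))
  if (scenario == "step") {
    zero[[paste0("oop_", arm)]] <- ifelse(f >= step_frame, amplitude, 0)
    return(list(angles = zero, tails = NULL))
  }
  if (scenario == "sine") {
    zero[[paste0("ip_", arm)]] <- amplitude * sin(2 * pi * (f - 1) / period)
    return(list(angles = zero, tails = NULL))
  }
  # coupled_opening: open in the disc (XY) plane, where a positive angle
  # swings the arm away from the core and the DNA Rg increases
  if (tail_detach_frame >= dna_open_frame)
    stop("tail_detach_frame must precede dna_open_frame")
  zero[[paste0("ip_", arm)]] <- ifelse(f >= dna_open_frame, amplitude, 0)
  tails <- list()
  for (id in paste0(c("H3_", "H2AC_"), arm))
    tails[[id]] <- ifelse(f >= tail_detach_frame, "detached", "bridge")
  list(angles = zero, tails = tails)
}

#' Write generator ground truth to JSON
#' @param ground_truth the `ground_truth` element returned by the generators
#' @param path output path
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  jsonlite::write_json(ground_truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
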