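# atomic masses for the elements that occur in nucleosome heavy-atom work;
# unknown elements fall back to carbon so selections never gain NA weights
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, P = 30.974, S = 32.06,
  FE = 55.845, MG = 24.305, ZN = 65.38, NA. = 22.99, K = 39.098, CL = 35.45
)

.mass_of <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- .element_masses[key]
  m[is.na(m)] <- 12.011
  unname(m)
}

# two-letter elements that can appear as the leading characters of an atom
# name in PDB files lacking the element column
.two_letter_elements <- c("FE", "MG", "ZN", "CL", "BR", "MN", "CU")

.infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[^A-Za-z]*", "", atom_name)))
  two <- substr(nm, 1, 2)
  ifelse(two %in% .two_letter_elements, two, substr(nm, 1, 1))
}

#' Construct a structure model
#'
#' A structure model holds an atom table and one or more coordinate sets
#' (models). It is the in-memory form of a (possibly multi-model) PDB file
#' and the topology of a trajectory.
#'
#' @param atoms data.frame with columns `name`, `resname`, `chain`, `resid`
#'   and optionally `element` and `mass`. Missing elements are inferred from
#'   the atom name; missing masses are looked up from the element.
#' @param xyz numeric array of dimension `c(n_atoms, 3, n_models)` (a single
#'   `n_atoms x 3` matrix is promoted to one model), in Angstrom.
#' @return object of class `nuc_structure` with fields `atoms` and `xyz`.
#' @export
nuc_structure <- function(atoms, xyz) {
  if (is.matrix(xyz)) xyz <- array(xyz, c(nrow(xyz), ncol(xyz), 1L))
  stopifnot(length(dim(xyz)) == 3L, dim(xyz)[2] == 3L)
  if (dim(xyz)[1] != nrow(atoms))
    stop("atom table and coordinates disagree on atom count")
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  atoms <- as.data.frame(atoms, stringsAsFactors = FALSE)
  req <- c("name", "resname", "chain", "resid")
  if (!all(req %in% names(atoms)))
    stop("atom table must have columns: ", paste(req, collapse = ", "))
  if (is.null(atoms$element)) atoms$element <- .infer_element(atoms$name)
  blank <- is.na(atoms$element) | atoms$element == ""
  atoms$element[blank] <- .infer_element(atoms$name[blank])
  if (is.null(atoms$mass)) atoms$mass <- .mass_of(atoms$element)
  atoms$resid <- as.integer(atoms$resid)
  # residue indices must be non-decreasing within each chain
  for (ch in unique(atoms$chain)) {
    r <- atoms$resid[atoms$chain == ch]
    if (is.unsorted(r)) stop("residue indices decrease within chain ", ch)
  }
  structure(list(atoms = atoms, xyz = xyz), class = "nuc_structure")
}

#' @export
print.nuc_structure <- function(x, ...) {
  cat(sprintf("<nuc_structure> %d atoms, %d chain(s), %d model(s)\n",
              nrow(x$atoms), length(unique(x$atoms$chain)), dim(x$xyz)[3]))
  invisible(x)
}

n_atoms <- function(structure) nrow(structure$atoms)
n_models <- function(structure) dim(structure$xyz)[3]

#' Extract one model's coordinates as an n x 3 matrix
#' @param structure a `nuc_structure`
#' @param model model index (default 1)
#' @return numeric matrix `n_atoms x 3`
#' @export
model_xyz <- function(structure, model = 1L) {
  structure$xyz[, , model, drop = TRUE]
}

#' Read a structure from a PDB file
#'
#' Wraps [bio3d::read.pdb()]; multi-model files yield one coordinate set per
#' MODEL block. Elements missing from the PDB element column are inferred
#' from the atom name.
#'
#' @param path PDB file path
#' @param format only `"pdb"` is supported
#' @return a [nuc_structure()]
#' @export
read_structure <- function(path, format = "pdb") {
  format <- match.arg(format, "pdb")
  if (!file.exists(path)) stop("cannot read structure file: ", path)
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  keep <- pdb$atom$type == "ATOM"
  xyz_mat <- pdb$xyz
  if (is.null(dim(xyz_mat))) xyz_mat <- matrix(xyz_mat, nrow = 1L)
  nm <- nrow(xyz_mat)
  na <- nrow(at)
  idx <- which(keep)
  arr <- array(NA_real_, c(na, 3L, nm))
  for (m in seq_len(nm)) {
    co <- matrix(xyz_mat[m, ], ncol = 3L, byrow = TRUE)
    arr[, , m] <- co[idx, , drop = FALSE]
  }
  elem <- at$elesy
  if (is.null(elem)) elem <- rep("", na)
  atoms <- data.frame(
    name = trimws(at$elety), resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resid = at$resno, element = trimws(ifelse(is.na(elem), "", elem)),
    stringsAsFactors = FALSE)
  nuc_structure(atoms, arr)
}

#' Write a structure to a PDB file
#'
#' Multi-model structures are written as MODEL/ENDMDL blocks via
#' [bio3d::write.pdb()].
#'
#' @param structure a `nuc_structure`
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_structure <- function(structure, path) {
  at <- structure$atoms
  nm <- n_models(structure)
  xyz <- t(apply(structure$xyz, 3, function(co) as.numeric(t(co))))
  if (nm == 1L) xyz <- matrix(xyz, nrow = 1L)
  bio3d::write.pdb(
    file = path, xyz = xyz,
    resno = at$resid, resid = at$resname, eleno = seq_len(nrow(at)),
    elety = at$name, chain = at$chain, elesy = at$element, verbose = FALSE)
  invisible(path)
}

#' Construct a trajectory
#'
#' @param topology a `nuc_structure` describing the atoms
#' @param coords array `c(n_atoms, 3, n_frames)` of coordinates in Angstrom
#' @param frame_interval_ps time between stored frames, picoseconds
#' @return object of class `nuc_trajectory`
#' @export
nuc_trajectory <- function(topology, coords, frame_interval_ps = 20) {
  if (is.matrix(coords)) coords <- array(coords, c(nrow(coords), 3L, 1L))
  if (dim(coords)[1] != n_atoms(topology))
    stop("trajectory atom count does not match topology")
  if (frame_interval_ps <= 0) stop("frame_interval_ps must be > 0")
  structure(list(topology = topology, coords = coords,
                 frame_interval_ps = frame_interval_ps),
            class = "nuc_trajectory")
}

#' @export
print.nuc_trajectory <- function(x, ...) {
  cat(sprintf("<nuc_trajectory> %d frames x %d atoms, %.3g ps/frame\n",
              n_frames(x), dim(x$coords)[1], x$frame_interval_ps))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `nuc_trajectory`
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Coordinates of one trajectory frame
#' @param traj a `nuc_trajectory`
#' @param frame frame index
#' @return numeric matrix `n_atoms x 3`
#' @export
frame_xyz <- function(traj, frame) traj$coords[, , frame, drop = TRUE]

#' Read a trajectory from DCD or multi-model PDB
#'
#' @param topology `nuc_structure` whose atom count the trajectory must match
#' @param path trajectory file
#' @param format `"auto"` (by extension), `"dcd"` or `"pdb"`
#' @param frame_interval_ps time between frames, picoseconds
#' @return a [nuc_trajectory()]
#' @export
read_trajectory <- function(topology, path, format = c("auto", "dcd", "pdb"),
                            frame_interval_ps = 20) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  na <- n_atoms(topology)
  if (format == "dcd") {
    m <- bio3d::read.dcd(path, verbose = FALSE)
    if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
    if (ncol(m) != 3L * na)
      stop("trajectory atom count (", ncol(m) / 3,
           ") does not match topology (", na, ")")
    coords <- array(NA_real_, c(na, 3L, nrow(m)))
    for (f in seq_len(nrow(m)))
      coords[, , f] <- matrix(m[f, ], ncol = 3L, byrow = TRUE)
  } else {
    s <- read_structure(path)
    if (n_atoms(s) != na)
      stop("trajectory atom count (", n_atoms(s),
           ") does not match topology (", na, ")")
    coords <- s$xyz
  }
  nuc_trajectory(topology, coords, frame_interval_ps)
}

#' Write a trajectory to DCD or multi-model PDB
#'
#' The DCD writer emits the CHARMM-style format read back by
#' [bio3d::read.dcd()] (single precision; round trips are exact to about
#' 1e-4 Angstrom).
#'
#' @param traj a `nuc_trajectory`
#' @param path output file; `.dcd` selects DCD, anything else multi-model PDB
#' @param format `"auto"`, `"dcd"` or `"pdb"`
#' @return `path`, invisibly
#' @export
write_trajectory <- function(traj, path, format = c("auto", "dcd", "pdb")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.dcd$", path, ignore.case = TRUE)) "dcd" else "pdb"
  if (format == "pdb") {
    s <- traj$topology
    s$xyz <- traj$coords
    return(write_structure(s, path))
  }
  coords <- traj$coords
  na <- dim(coords)[1]; nf <- dim(coords)[3]
  con <- file(path, "wb"); on.exit(close(con))
  rec <- function(writer, nbytes) {
    writeBin(as.integer(nbytes), con, size = 4L, endian = "little")
    writer()
    writeBin(as.integer(nbytes), con, size = 4L, endian = "little")
  }
  icntrl <- integer(20)
  icntrl[1] <- nf; icntrl[2] <- 1L; icntrl[3] <- 1L; icntrl[4] <- nf
  # frame interval stored as the float bit pattern CHARMM uses
  icntrl[10] <- readBin(writeBin(as.numeric(traj$frame_interval_ps), raw(),
                                 size = 4L, endian = "little"),
                        "integer", size = 4L, endian = "little")
  icntrl[20] <- 24L
  rec(function() {
    writeChar("CORD", con, nchars = 4L, eos = NULL)
    writeBin(icntrl, con, size = 4L, endian = "little")
  }, 84L)
  title <- sprintf("%-80s", "written by nucbreathe")
  rec(function() {
    writeBin(1L, con, size = 4L, endian = "little")
    writeChar(title, con, nchars = 80L, eos = NULL)
  }, 84L)
  rec(function() writeBin(as.integer(na), con, size = 4L, endian = "little"), 4L)
  for (f in seq_len(nf)) for (d in 1:3)
    rec(function() writeBin(as.numeric(coords[, d, f]), con,
                            size = 4L, endian = "little"), 4L * na)
  invisible(path)
}

#' Write a per-frame observable series to CSV
#'
#' @param series non-empty data.frame; by convention the first columns are
#'   `frame` and `time_ps`, followed by one column per observable
#' @param path output CSV path
#' @return `path`, invisibly
#' @export
write_series_csv <- function(series, path) {
  if (!is.data.frame(series) || nrow(series) == 0L)
    stop("series is empty; nothing to write")
  utils::write.csv(series, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read back a CSV written by [write_series_csv()]
#' @param path CSV path
#' @return data.frame
#' @export
read_series_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
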