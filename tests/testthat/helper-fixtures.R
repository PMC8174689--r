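# fixtures are built in code at test time; nothing is stored on disk

# minimal hand-written PDB text with n atoms and optionally several models
write_tiny_pdb <- function(path, coords_per_model, chain = "A") {
  lines <- character(0)
  multi <- length(coords_per_model) > 1L
  for (m in seq_along(coords_per_model)) {
    co <- coords_per_model[[m]]
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", m))
    for (i in seq_len(nrow(co)))
      lines <- c(lines, sprintf(
        "ATOM  %5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
        i, c("N", "CA", "C", "O", "CB")[(i - 1L) %% 5L + 1L], "ALA", chain, i,
        co[i, 1], co[i, 2], co[i, 3],
        c("N", "C", "C", "O", "C")[(i - 1L) %% 5L + 1L]))
    if (multi) lines <- c(lines, "ENDMDL")
  }
  writeLines(c(lines, "END"), path)
  path
}

# bare-bones nucleosome-shaped structure (roles only, geometry arbitrary):
# DNA strands I/J of L residues and eight histone chains with realistic
# residue spans, one bead per residue
mock_nucleosome_structure <- function(L = 168L) {
  spans <- c(A = 135L, B = 102L, C = 129L, D = 125L,
             E = 135L, F = 102L, G = 129L, H = 125L)
  rows <- list()
  for (ch in c("I", "J"))
    rows[[length(rows) + 1L]] <- data.frame(
      name = "C1'", resname = "DA", chain = ch, resid = seq_len(L),
      element = "C", stringsAsFactors = FALSE)
  for (ch in names(spans))
    rows[[length(rows) + 1L]] <- data.frame(
      name = "CA", resname = "ALA", chain = ch, resid = seq_len(spans[[ch]]),
      element = "C", stringsAsFactors = FALSE)
  atoms <- do.call(rbind, rows)
  n <- nrow(atoms)
  xyz <- cbind(seq_len(n), (seq_len(n) * 7L) %% 23L, (seq_len(n) * 3L) %% 17L)
  nuc_structure(atoms, xyz * 1.0)
}

# small but fully featured synthetic nucleosome spec for fast tests
fast_spec <- function(...) {
  synthetic_spec(core_bp = 147L, linker_bp = 11L, core_beads_per_chain = 8L,
                 ...)
}

# adjusted Rand index (independent implementation for clustering checks)
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# sort-based linear-interpolation percentile oracle
percentile_oracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# brute-force weighted mean distance straight off the definition
wmd_oracle <- function(xyz, a, b, n) {
  s <- 0
  for (i in a) for (j in b) {
    d <- sqrt(sum((xyz[i, ] - xyz[j, ])^2))
    s <- s + (1 / d)^n
  }
  (s / (length(a) * length(b)))^(-1 / n)
}

# exhaustive O(N^2) contact-pair count
contact_oracle <- function(xyz, a, b, cutoff = 4.5) {
  cnt <- 0L
  for (i in a) for (j in b)
    if (sqrt(sum((xyz[i, ] - xyz[j, ])^2)) < cutoff) cnt <- cnt + 1L
  cnt
}

random_rotation <- function(seed) {
  set.seed(seed)
  qr_q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_q) < 0) qr_q[, 1] <- -qr_q[, 1]
  qr_q
}
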