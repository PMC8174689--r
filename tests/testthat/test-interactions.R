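make_point_structure <- function(xyz, element = "C") {
  at <- data.frame(name = "CA", resname = "ALA", chain = "A",
                   resid = seq_len(nrow(xyz)), element = element, mass = 1)
  nuc_structure(at, xyz)
}

test_that("contact counting uses a strict cutoff and matches brute force", {
  two <- function(d) make_point_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
  st <- two(4.49)
  expect_equal(count_contacts(st, model_xyz(st), 1L, 2L), 1L)
  st <- two(4.51)
  expect_equal(count_contacts(st, model_xyz(st), 1L, 2L), 0L)
  set.seed(10)
  for (i in 1:10) {
    xyz <- matrix(runif(3 * 60, 0, 20), 60, 3)
    st <- make_point_structure(xyz)
    a <- 1:30; b <- 31:60
    expect_identical(count_contacts(st, xyz, a, b),
                     contact_oracle(xyz, a, b))
    expect_identical(count_contacts(st, xyz, a, b),
                     count_contacts(st, xyz, b, a))  # symmetry
  }
})

test_that("contact selections must be disjoint, non-empty, and heavy", {
  xyz <- matrix(rnorm(30), 10, 3)
  st <- make_point_structure(xyz)
  expect_error(count_contacts(st, xyz, 1:5, 4:10), "disjoint")
  h_st <- make_point_structure(xyz, element = c(rep("H", 5), rep("C", 5)))
  expect_error(count_contacts(h_st, xyz, 1:5, 6:10), "empty selection")
  # hydrogens are excluded from counting
  mix <- make_point_structure(rbind(c(0, 0, 0), c(1, 0, 0), c(1.2, 0, 0)),
                              element = c("C", "H", "C"))
  expect_equal(count_contacts(mix, model_xyz(mix), 1:2, 3L), 1L)
})

test_that("the weighted mean distance reproduces hand-computed cases", {
  # single atoms: any exponent returns the plain distance
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0))
  for (n in c(2, 10, 100))
    expect_equal(weighted_mean_distance(xyz, 1L, 2L, n), 5, tolerance = 1e-12)
  # 1 atom vs 2 atoms at 2 and 4 A with n = 2:
  # ((1/2) (1/4 + 1/16))^(-1/2) = 2.5298221...
  xyz <- rbind(c(0, 0, 0), c(2, 0, 0), c(0, 4, 0))
  expect_equal(weighted_mean_distance(xyz, 1L, 2:3, n = 2),
               (0.5 * (1 / 4 + 1 / 16))^(-1 / 2), tolerance = 1e-9)
  expect_equal(weighted_mean_distance(xyz, 1L, 2:3, n = 2),
               wmd_oracle(xyz, 1L, 2:3, 2), tolerance = 1e-12)
  expect_error(weighted_mean_distance(xyz, 1L, 2:3, n = 3), "even")
  expect_error(weighted_mean_distance(rbind(xyz, c(0, 0, 0)), 1L, 4L),
               "coincident")
})

test_that("the weighted distance is monotone in n and bounded by the minimum", {
  # analytic envelope: dmin <= d[n] <= dmin * (N1*N2)^(1/n)
  set.seed(20)
  for (i in 1:25) {
    a_xyz <- matrix(rnorm(30, sd = 8), 10, 3)
    b_xyz <- matrix(rnorm(30, sd = 8) + 4, 10, 3)
    xyz <- rbind(a_xyz, b_xyz)
    a <- 1:10; b <- 11:20
    d2 <- weighted_mean_distance(xyz, a, b, 2)
    d10 <- weighted_mean_distance(xyz, a, b, 10)
    d100 <- weighted_mean_distance(xyz, a, b, 100)
    dmin <- sqrt(min(outer(rowSums(a_xyz^2), rowSums(b_xyz^2), `+`) -
                     2 * tcrossprod(a_xyz, b_xyz)))
    expect_true(d2 >= d10 && d10 >= d100)
    expect_gte(d100, dmin)
    expect_lte((d100 - dmin) / dmin, 100^(1 / 100) - 1 + 1e-9)
  }
  # small groups pin d[100] within 2% of the true minimum
  set.seed(21)
  for (i in 1:100) {
    n1 <- sample(1:2, 1); n2 <- sample(1:3, 1)
    xyz <- matrix(rnorm(3 * (n1 + n2), sd = 6), n1 + n2, 3)
    a <- seq_len(n1); b <- n1 + seq_len(n2)
    d100 <- weighted_mean_distance(xyz, a, b, 100)
    dmin <- min(vapply(a, function(i) min(vapply(b, function(j)
      sqrt(sum((xyz[i, ] - xyz[j, ])^2)), 1)), 1))
    expect_gte(d100, dmin - 1e-12)
    expect_lt((d100 - dmin) / dmin, 0.02)
  }
})

test_that("n = 100 stays finite and factored across 1-1000 A scales", {
  xyz <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(500, 0, 0), c(1000, 0, 0))
  d <- weighted_mean_distance(xyz, 1L, 2:4, n = 100)
  expect_true(is.finite(d))
  # against a high-precision oracle working in log space
  logs <- -100 * log(c(1.5, 500, 1000))
  m <- max(logs)
  oracle <- exp(-(m + log(sum(exp(logs - m)) / 3)) / 100)
  expect_equal(d, oracle, tolerance = 1e-6)
})

test_that("tail configuration series reflect the generator's tail modes", {
  tails <- list(H3_3p = list(length = 20, mode = "detached"),
                H3_5p = list(length = 20, mode = "bridge"))
  spec <- fast_spec(tails = tails, jitter_sd = 0.1)
  sc <- breathing_scenario("constant", n_frames = 10)
  gen <- make_breathing_trajectory(spec, sc$angles, seed = 3)
  det <- tail_configuration_series(gen$trajectory, gen$annotation, "H3_3p")
  expect_true(all(det$nc_outer == 0L))
  expect_true(all(det$delta_ldna >= 10))
  bri <- tail_configuration_series(gen$trajectory, gen$annotation, "H3_5p")
  expect_true(all(bri$nc_outer > 0L))
  expect_true(all(bri$nc_inner > 0L))
  # stride contract
  s5 <- tail_configuration_series(gen$trajectory, gen$annotation, "H3_5p",
                                  stride = 5L)
  expect_equal(nrow(s5), 2L)
  # tail-less annotation: explicit not-applicable error
  bald <- tailless_variant(gen$trajectory$topology, gen$annotation)
  ann_tl <- synthetic_annotation(
    fast_spec(tails = list(H3_3p = list(length = 1, mode = "absent"))),
    bald)
  expect_error(tail_configuration_series(gen$trajectory, ann_tl, "H3_3p"),
               "not present")
})

test_that("per-residue profiles approach the true minimal distance", {
  tails <- list(H3_3p = list(length = 45, mode = "detached"))
  spec <- fast_spec(tails = tails, jitter_sd = 0)
  sc <- breathing_scenario("constant", n_frames = 2)
  gen <- make_breathing_trajectory(spec, sc$angles, seed = 8)
  st <- gen$trajectory$topology; ann <- gen$annotation
  prof_out <- residue_distance_profile(gen$trajectory, ann, "H3_3p",
                                       gyre = "outer")
  expect_setequal(unique(prof_out$residue), unlist(h3_residue_groups()))
  expect_true(all(prof_out$delta_min >= 10))  # detached tail
  # delta_min sits in the analytic envelope above the exhaustive minimum
  outer_sel <- sel_gyre(st, ann, "outer_3p")
  xyz <- frame_xyz(gen$trajectory, 1)
  for (lab in c("R2", "K36")) {
    resno <- as.integer(sub("^[A-Z]", "", lab))
    idx <- which(st$atoms$chain == "A" & st$atoms$resid == resno)
    dmin <- min(sqrt(outer(rowSums(xyz[idx, , drop = FALSE]^2),
                           rowSums(xyz[outer_sel, ]^2), `+`) -
                     2 * tcrossprod(xyz[idx, , drop = FALSE],
                                    xyz[outer_sel, ])))
    got <- prof_out$delta_min[prof_out$residue == lab & prof_out$frame == 1]
    expect_gte(got, dmin - 1e-9)
    envelope <- (length(idx) * length(outer_sel))^(1 / 100) - 1
    expect_lte((got - dmin) / dmin, envelope + 1e-9)
  }
  # power-mean ordering: delta_min <= delta(n = 10), per residue and frame
  for (lab in unique(prof_out$residue)) {
    resno <- as.integer(sub("^[A-Z]", "", lab))
    idx <- which(st$atoms$chain == "A" & st$atoms$resid == resno)
    d10 <- weighted_mean_distance(xyz, idx, outer_sel, n = 10)
    got <- prof_out$delta_min[prof_out$residue == lab & prof_out$frame == 1]
    expect_lte(got, d10 + 1e-9)
  }
  expect_error(residue_distance_profile(gen$trajectory, ann, "H3_3p",
                                        residues = c("Q99")), "not found")
  expect_error(residue_distance_profile(gen$trajectory, ann, "H3_3p",
                                        residues = c("K2")), "does not match")
})

test_that("cluster median heatmaps match a sort-based median oracle", {
  prof <- data.frame(frame = rep(1:10, each = 2),
                     time_ps = 0, residue = rep(c("R2", "K4"), 10),
                     group = "tip", gyre = "inner")
  prof$delta_min <- ifelse(prof$residue == "R2", 3, 7)
  # single cluster: all entries equal the constant value
  h1 <- cluster_median_heatmap(prof, rep(1L, 10))
  expect_true(all(h1[, 1] %in% c(3, 7)))
  # two clusters with disjoint constants
  prof2 <- prof
  prof2$delta_min <- ifelse(prof2$frame <= 5, 2, 9)
  h2 <- cluster_median_heatmap(prof2, rep(c(1L, 2L), each = 5))
  expect_true(all(h2[, 1] == 2) && all(h2[, 2] == 9))
  # random series against stats::median on the raw values
  set.seed(30)
  prof3 <- data.frame(frame = rep(1:20, each = 3),
                      residue = rep(c("a", "b", "c"), 20),
                      delta_min = runif(60, 2, 40))
  cl <- sample(1:3, 20, replace = TRUE)
  h3 <- cluster_median_heatmap(prof3, cl)
  for (r in c("a", "b", "c")) for (k in 1:3) {
    v <- prof3$delta_min[prof3$residue == r & cl[prof3$frame] == k]
    expect_equal(unname(h3[r, paste0("cluster_", k)]),
                 if (length(v)) median(v) else NA_real_)
  }
  # a cluster with no profiled frames stays NA, not zero
  h4 <- cluster_median_heatmap(prof, c(rep(1L, 10), rep(3L, 10)))
  expect_true(all(is.na(h4[, "cluster_3"])))
  expect_true(all(!is.na(h4[, "cluster_1"])))
})
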