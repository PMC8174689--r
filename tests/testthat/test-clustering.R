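test_that("feature matrices have one fitted row per frame", {
  sc <- breathing_scenario("sine", n_frames = 10, amplitude = 15)
  gen <- make_breathing_trajectory(fast_spec(), sc$angles, seed = 6)
  fm <- build_feature_matrix(gen$trajectory, gen$annotation, "dna")
  sel <- attr(fm, "selection")
  expect_equal(dim(fm), c(10L, 3L * length(sel)))
  expect_identical(attr(fm, "frames"), seq(1L, 10L))
  # the non-opening (5') outer gyre is excluded from the DNA features
  st <- gen$trajectory$topology
  outer5 <- sel_gyre(st, gen$annotation, "outer_5p")
  expect_length(intersect(sel, outer5), 0L)
  inner <- sel_gyre(st, gen$annotation, "inner")
  expect_gt(length(intersect(sel, inner)), 0L)
})

test_that("frames that are rigid transforms collapse after superposition", {
  gen <- make_breathing_trajectory(fast_spec(jitter_sd = 0),
                                   breathing_scenario("constant",
                                                      n_frames = 4)$angles,
                                   seed = 2)
  traj <- gen$trajectory
  for (f in 2:4) {
    R <- random_rotation(f)
    traj$coords[, , f] <- sweep(frame_xyz(traj, 1) %*% t(R), 2,
                                c(f, -f, 2 * f), `+`)
  }
  fm <- build_feature_matrix(traj, gen$annotation, "dna")
  for (f in 2:4) expect_lt(max(abs(fm[f, ] - fm[1, ])), 1e-6)
})

test_that("the H2A feature selection excludes the N-terminal tail", {
  gen <- make_breathing_trajectory(fast_spec(),
                                   breathing_scenario("constant",
                                                      n_frames = 2)$angles,
                                   seed = 2)
  fm <- build_feature_matrix(gen$trajectory, gen$annotation, "h2ac")
  sel <- attr(fm, "selection")
  at <- gen$trajectory$topology$atoms
  expect_true(all(at$chain[sel] %in% c("C", "G")))
  expect_true(all(at$resid[sel] > 18L))  # synthetic H2A N-tail is 1-18
})

test_that("k-means recovers well-separated blobs and is deterministic", {
  set.seed(99)
  centers <- rbind(c(0, 0), c(10, 0), c(0, 10))
  truth <- rep(1:3, times = c(50, 30, 20))
  x <- centers[truth, ] + matrix(rnorm(200, sd = 0.1), 100, 2)
  m <- kmeans_cluster(x, k = 3, seed = 12)
  expect_equal(adjusted_rand_index(m$assignment, truth), 1.0)
  expect_identical(m$sizes, c(50L, 30L, 20L))  # ranked by size
  m2 <- kmeans_cluster(x, k = 3, seed = 12)
  expect_identical(m$assignment, m2$assignment)
  # all frames identical: one cluster with zero inertia
  same <- matrix(1, 10, 4)
  m3 <- kmeans_cluster(same, k = 1, seed = 1)
  expect_equal(m3$inertia, 0)
  expect_true(all(m3$assignment == 1L))
  expect_error(kmeans_cluster(x[1:2, ], k = 3), "cannot form")
})

test_that("size ranking permutes labels with stable ties", {
  model <- structure(list(k = 3L, assignment = rep(1:3, c(10, 50, 40)),
                          centroids = diag(3), sizes = c(10L, 50L, 40L),
                          inertia = 0, seed = 1L, selection_tag = NULL,
                          frames = NULL), class = "nuc_clusters")
  ranked <- rank_clusters(model)
  expect_identical(ranked$sizes, c(50L, 40L, 10L))
  expect_true(all(ranked$assignment[11:60] == 1L))
  expect_true(all(ranked$assignment[1:10] == 3L))
  # already ranked: identity
  expect_identical(rank_clusters(ranked)$assignment, ranked$assignment)
  # ties keep the lower original label first
  tie <- model; tie$sizes <- c(40L, 40L, 20L)
  tie$assignment <- rep(1:3, c(40, 40, 20))
  r2 <- rank_clusters(tie)
  expect_true(all(r2$assignment[1:40] == 1L))
  expect_true(all(r2$assignment[41:80] == 2L))
})

test_that("cross-tabulations are row-normalized percentages", {
  a <- rep(1:3, each = 10)
  ct <- cross_tabulate(a, a)
  expect_equal(unname(diag(ct)), rep(100, 3))
  expect_equal(unname(rowSums(ct)), rep(100, 3), tolerance = 1e-6)
  set.seed(14)
  b <- sample(1:4, 2000, replace = TRUE)
  c2 <- sample(1:4, 2000, replace = TRUE)
  ct2 <- cross_tabulate(b, c2)
  expect_equal(unname(rowSums(ct2)), rep(100, 4), tolerance = 1e-6)
  expect_error(cross_tabulate(a, a[1:20]), "different frame counts")
})

test_that("cluster gamma maps recover the regime means", {
  sc <- breathing_scenario("step", n_frames = 40, arm = "3p",
                           amplitude = 30, step_frame = 21)
  gen <- make_breathing_trajectory(fast_spec(), sc$angles, seed = 21)
  obs <- breathing_series(gen$trajectory, gen$annotation)
  fm <- build_feature_matrix(gen$trajectory, gen$annotation, "dna")
  m <- kmeans_cluster(fm, k = 2, seed = 3, selection_tag = "dna")
  gm <- map_clusters_to_gamma(m, obs, "3p")
  expect_equal(nrow(gm), 2L)
  expect_equal(sum(gm$size), 40L)
  got <- sort(gm$mean_gamma1)
  want <- sort(c(mean(obs$gamma1_3p[1:20]), mean(obs$gamma1_3p[21:40])))
  expect_lt(max(abs(got - want)), 2)
  # single cluster: mean equals the overall mean
  m1 <- kmeans_cluster(fm, k = 1, seed = 3)
  gm1 <- map_clusters_to_gamma(m1, obs, "3p")
  expect_equal(gm1$mean_gamma1, mean(obs$gamma1_3p), tolerance = 1e-9)
})

test_that("percentile summaries use linear interpolation", {
  s <- percentile_summary(0:100)
  expect_equal(s$p_lo, 5)
  expect_equal(s$p_hi, 95)
  s2 <- percentile_summary(rep(3.25, 12))
  expect_equal(c(s2$p_lo, s2$p_hi), c(3.25, 3.25))
  set.seed(40)
  for (i in 1:5) {
    x <- rnorm(73)
    s3 <- percentile_summary(x, lo = 5, hi = 95)
    expect_equal(s3$p_lo, percentile_oracle(x, 5), tolerance = 1e-9)
    expect_equal(s3$p_hi, percentile_oracle(x, 95), tolerance = 1e-9)
    expect_lte(s3$p_lo, s3$p_hi)
  }
  expect_error(percentile_summary(numeric(0)), "empty")
})
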