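test_that("superposition recovers constructed transforms", {
  set.seed(1)
  ref <- matrix(rnorm(60, sd = 8), 20, 3)
  # identity
  fit0 <- superpose(ref, ref)
  expect_lt(fit0$rmsd, 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  # 37 degrees about z plus a translation
  th <- 37 * pi / 180
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  mobile <- sweep(ref %*% t(R), 2, c(5, -3, 2), `+`)
  fit <- superpose(mobile, ref)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(fit$rotation %*% R, diag(3), tolerance = 1e-6)
  expect_lt(max(abs(fit$xyz - ref)), 1e-6)
})

test_that("noisy superposition matches an independent least-squares oracle", {
  set.seed(7)
  ref <- matrix(rnorm(90, sd = 10), 30, 3)
  mobile <- ref + matrix(rnorm(90, sd = 0.5), 30, 3)
  ours <- superpose(mobile, ref)$rmsd
  oracle <- bio3d::rmsd(as.numeric(t(ref)), as.numeric(t(mobile)),
                        fit = TRUE)
  expect_lt(abs(ours - oracle) / oracle, 0.05)
})

test_that("degenerate superpositions are rejected", {
  line <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(superpose(line, line + 0.1), "collinear")
  expect_error(superpose(line[1:2, ], line[1:2, ]), "at least 3")
})

test_that("the dyad frame is orthonormal, right-handed, and matches the generator", {
  out <- make_ideal_nucleosome(fast_spec())
  st <- out$structure
  fr <- build_dyad_frame(st, model_xyz(st), out$annotation)
  for (v in list(fr$X, fr$Y, fr$Z)) expect_equal(sum(v^2), 1, tolerance = 1e-9)
  expect_lt(abs(sum(fr$X * fr$Y)), 1e-9)
  expect_lt(abs(sum(fr$X * fr$Z)), 1e-9)
  expect_equal(fr$Z, c(fr$X[2] * fr$Y[3] - fr$X[3] * fr$Y[2],
                       fr$X[3] * fr$Y[1] - fr$X[1] * fr$Y[3],
                       fr$X[1] * fr$Y[2] - fr$X[2] * fr$Y[1]),
               tolerance = 1e-9)
  gt <- out$ground_truth$frame
  angle <- function(a, b) acos(pmin(1, sum(a * b))) * 180 / pi
  expect_lt(angle(fr$X, gt$X), 1)
  expect_lt(angle(fr$Y, gt$Y), 1)
  expect_lt(angle(fr$Z, gt$Z), 1)
})

test_that("the dyad frame is equivariant under rigid transforms", {
  out <- make_ideal_nucleosome(fast_spec())
  st <- out$structure; ann <- out$annotation
  xyz <- model_xyz(st)
  fr <- build_dyad_frame(st, xyz, ann)
  R <- random_rotation(3)
  moved <- sweep(xyz %*% t(R), 2, c(10, -4, 7), `+`)
  fr2 <- build_dyad_frame(st, moved, ann)
  expect_equal(fr2$X, as.numeric(R %*% fr$X), tolerance = 1e-6)
  expect_equal(fr2$Y, as.numeric(R %*% fr$Y), tolerance = 1e-6)
  expect_equal(fr2$Z, as.numeric(R %*% fr$Z), tolerance = 1e-6)
})

test_that("arm vectors follow the generator's linker direction", {
  spec <- fast_spec(jitter_sd = 0)
  out <- make_ideal_nucleosome(spec)
  st <- out$structure; ann <- out$annotation
  xyz <- model_xyz(st)
  # generator linkers run along sin(phi) Y + cos(phi) Z of the true frame
  gt <- out$ground_truth$frame
  phi <- spec$arm_elevation_deg * pi / 180
  d <- sin(phi) * gt$Y + cos(phi) * gt$Z
  for (arm in c("3p", "5p")) {
    v <- arm_vector(st, xyz, ann, arm)
    expect_gte(sum(v * d), 0.999)
    # endpoint mode agrees for an exactly straight arm
    v2 <- arm_vector(st, xyz, ann, arm, endpoint = TRUE)
    expect_gte(sum(v2 * v), 0.999)
  }
  # a 2-bp arm reduces to the normalized center difference
  ann2 <- ann
  ann2$arm_3p <- ann$arm_3p[(length(ann$arm_3p) - 1):length(ann$arm_3p)]
  cen <- bp_centers(st, xyz, ann2, ann2$arm_3p)
  v3 <- arm_vector(st, xyz, ann2, "3p")
  expect_equal(v3, (cen[2, ] - cen[1, ]) / sqrt(sum((cen[2, ] - cen[1, ])^2)),
               tolerance = 1e-9)
})

test_that("pure prescribed rotations are recovered exactly in their own angle", {
  spec <- fast_spec(jitter_sd = 0)
  gen <- make_breathing_trajectory(
    spec, data.frame(oop_3p = c(30, 0), ip_3p = c(0, 25)), seed = 1)
  st <- gen$trajectory$topology; ann <- gen$annotation
  g_oop <- compute_gamma(st, frame_xyz(gen$trajectory, 1), ann, "3p")
  g_ip <- compute_gamma(st, frame_xyz(gen$trajectory, 2), ann, "3p")
  expect_equal(unname(g_oop["gamma1"]), 30, tolerance = 1e-6)
  expect_equal(unname(g_ip["gamma2"]), 25, tolerance = 1e-6)
  # and both match the analytic ground truth including the coupled angle
  gt <- gen$ground_truth$angles
  expect_equal(unname(g_oop["gamma2"]),
               gt$gamma2_true[gt$frame == 1 & gt$arm == "3p"],
               tolerance = 1e-6)
  expect_equal(unname(g_ip["gamma1"]),
               gt$gamma1_true[gt$frame == 2 & gt$arm == "3p"],
               tolerance = 1e-6)
})

test_that("gamma series track the analytic ground truth under jitter", {
  sc <- breathing_scenario("step", n_frames = 60, arm = "3p",
                           amplitude = 30, step_frame = 31)
  gen <- make_breathing_trajectory(fast_spec(), sc$angles, seed = 9)
  bs <- breathing_series(gen$trajectory, gen$annotation)
  gt <- gen$ground_truth$angles
  g1_true <- gt$gamma1_true[gt$arm == "3p"]
  rms <- sqrt(mean((bs$gamma1_3p - g1_true)^2))
  expect_lt(rms, 2)
  # the step is localized at exactly the prescribed frame
  jump <- which.max(abs(diff(bs$gamma1_3p))) + 1L
  expect_equal(jump, 31L)
})

test_that("breathing observables are invariant under rigid motions", {
  sc <- breathing_scenario("sine", n_frames = 5, amplitude = 20)
  gen <- make_breathing_trajectory(fast_spec(jitter_sd = 0), sc$angles,
                                   seed = 4)
  traj <- gen$trajectory
  bs <- breathing_series(traj, gen$annotation)
  R <- random_rotation(11)
  moved <- traj
  for (f in seq_len(n_frames(traj)))
    moved$coords[, , f] <- sweep(frame_xyz(traj, f) %*% t(R), 2,
                                 c(-3, 8, 1), `+`)
  bs2 <- breathing_series(moved, gen$annotation)
  for (col in c("gamma1_3p", "gamma2_3p", "gamma1_5p", "gamma2_5p", "rg"))
    expect_equal(bs2[[col]], bs[[col]], tolerance = 1e-6)
})

test_that("Rg matches closed forms and the definition-based oracle", {
  # N equal-mass points on a circle of radius R
  th <- 2 * pi * (0:35) / 36
  circ <- cbind(3.7 * cos(th), 3.7 * sin(th), 0)
  at <- data.frame(name = "CA", resname = "ALA", chain = "A",
                   resid = seq_len(36), element = "C", mass = 1)
  st <- nuc_structure(at, circ)
  expect_equal(compute_rg(st, circ, 1:36), 3.7, tolerance = 1e-9)
  # square of side 2 -> sqrt(2)
  sq <- cbind(c(0, 2, 2, 0), c(0, 0, 2, 2), 0)
  st2 <- nuc_structure(at[1:4, ], sq)
  expect_equal(compute_rg(st2, sq, 1:4), sqrt(2), tolerance = 1e-12)
  # random sets against the brute-force definition, with masses
  set.seed(2)
  for (i in 1:5) {
    n <- 30
    xyz <- matrix(rnorm(3 * n, sd = 12), n, 3)
    mass <- runif(n, 1, 16)
    at3 <- data.frame(name = "X", resname = "X", chain = "A",
                      resid = seq_len(n), element = "C", mass = mass)
    st3 <- nuc_structure(at3, xyz)
    cen <- colSums(xyz * mass) / sum(mass)
    oracle <- sqrt(sum(mass * rowSums(sweep(xyz, 2, cen)^2)) / sum(mass))
    expect_equal(compute_rg(st3, xyz, seq_len(n)), oracle, tolerance = 1e-9)
  }
  expect_error(compute_rg(st, circ, integer(0)), "empty")
})

test_that("an opened nucleosome has a larger DNA Rg than a closed one", {
  spec <- fast_spec(jitter_sd = 0)
  closed <- make_breathing_trajectory(spec, data.frame(ip_3p = 0), seed = 1)
  open <- make_breathing_trajectory(spec, data.frame(ip_3p = 40), seed = 1)
  st <- closed$trajectory$topology; ann <- closed$annotation
  dna <- sel_dna(st, ann)
  expect_gt(compute_rg(st, frame_xyz(open$trajectory, 1), dna),
            compute_rg(st, frame_xyz(closed$trajectory, 1), dna))
})

test_that("gamma histograms count, measure area, and locate the mode", {
  s <- data.frame(gamma1_3p = rep(1, 40), gamma2_3p = rep(1, 40))
  h <- gamma_histogram2d(s, "3p", bin_width = 2.5)
  expect_equal(sum(h$counts), 40)
  expect_equal(h$occupied_area, 6.25)
  # k distinct bins occupied once each
  s2 <- data.frame(gamma1_3p = c(0.5, 3, 8, 12), gamma2_3p = c(0.5, 3, 8, 12))
  h2 <- gamma_histogram2d(s2, "3p", bin_width = 2.5)
  expect_equal(h2$occupied_area, 4 * 2.5^2)
  # Gaussian cloud: mode bin within one bin of the sample mean
  set.seed(5)
  s3 <- data.frame(gamma1_3p = rnorm(10000, 10, 5),
                   gamma2_3p = rnorm(10000, -5, 5))
  h3 <- gamma_histogram2d(s3, "3p", bin_width = 2.5)
  expect_equal(sum(h3$counts), 10000)
  expect_lt(abs(h3$mode_bin["gamma1"] - mean(s3$gamma1_3p)), 2 * 2.5)
  expect_lt(abs(h3$mode_bin["gamma2"] - mean(s3$gamma2_3p)), 2 * 2.5)
  expect_error(gamma_histogram2d(s, "3p", bin_width = 0), "positive")
})
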