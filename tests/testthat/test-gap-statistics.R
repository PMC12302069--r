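kB <- redox_constants$k_B

test_that("average gap matches direct summation and CLT behavior", {
  expect_equal(average_gap(gap_ensemble(c(5, 5, 5), "reduced")), 5)
  g <- c(9.0, 9.5, 9.1, 9.4, 9.6)
  expect_equal(average_gap(gap_ensemble(g, "reduced")), sum(g) / length(g))
  # synthetic reduced ensemble mimicking an aqueous aromatic: mean 9.32 eV
  set.seed(101)
  e <- gap_ensemble(rnorm(500, 9.32, 0.23), "reduced")
  expect_lt(abs(average_gap(e) - 9.32), 3 * 0.23 / sqrt(500))
  expect_error(gap_ensemble(numeric(0), "reduced"), "sample")
})

test_that("zwanzig free energy: degenerate cases and Gaussian closed form", {
  expect_equal(zwanzig_free_energy(gap_ensemble(c(3.3, 3.3, 3.3), "reduced")),
               3.3)
  expect_equal(zwanzig_free_energy(gap_ensemble(6.02, "oxidized")), 6.02)
  # no overflow at |dE|/kT ~ 400
  big <- 400 * kB * 310
  expect_true(is.finite(zwanzig_free_energy(gap_ensemble(c(big, big), "reduced"))))
  # Gaussian second-cumulant closed form, narrow-spread regime where the
  # exponential average genuinely converges (sd comparable to 2 kT)
  m <- 6.0; s <- 0.05; T <- 310; kT <- kB * T
  set.seed(7)
  est_f <- replicate(8, zwanzig_free_energy(
    gap_ensemble(rnorm(2e4, m, s), "reduced", T)))
  expect_equal(mean(est_f), m - s^2 / (2 * kT), tolerance = 2e-3)
  set.seed(8)
  est_r <- replicate(8, zwanzig_free_energy(
    gap_ensemble(rnorm(2e4, m, s), "oxidized", T)))
  expect_equal(mean(est_r), m + s^2 / (2 * kT), tolerance = 2e-3)
})

test_that("LRA fit reproduces tabulated worked examples exactly", {
  fit_of <- function(mr, mo) lra_free_energy(
    gap_ensemble(rep(mr, 4), "reduced"), gap_ensemble(rep(mo, 4), "oxidized"),
    n_boot = 0)
  # aqueous benzene, MM-sampled AVEGs at the widest QM cutoff
  f <- fit_of(9.32, 4.95)
  expect_equal(f$dG_ox, 7.135)
  expect_equal(f$lambda_reorg, 2.185)
  # lumiflavin analog
  expect_equal(fit_of(5.93, 2.31)$dG_ox, 4.12)
  # identical ensembles: zero reorganization
  same <- fit_of(3.3, 3.3)
  expect_equal(same$dG_ox, 3.3)
  expect_equal(same$lambda_reorg, 0)
})

test_that("LRA fit validates states and temperatures, flags negative lambda", {
  r <- gap_ensemble(c(5, 5.1), "reduced")
  o <- gap_ensemble(c(4, 4.1), "oxidized")
  expect_error(lra_free_energy(o, o, n_boot = 0), "reduced")
  expect_error(lra_free_energy(
    r, gap_ensemble(c(4, 4.1), "oxidized", temperature = 300), n_boot = 0),
    "temperatures")
  flip <- lra_free_energy(gap_ensemble(c(4, 4.1), "reduced"),
                          gap_ensemble(c(5, 5.1), "oxidized"), n_boot = 0)
  expect_true(flip$anomalous_lambda)
})

test_that("LRA invariants: exact identities, sign symmetry, CI scaling", {
  set.seed(21)
  for (k in 1:5) {
    mr <- runif(1, 5, 10); mo <- runif(1, 2, 5)
    r <- gap_ensemble(rnorm(200, mr, 0.2), "reduced")
    o <- gap_ensemble(rnorm(200, mo, 0.2), "oxidized")
    f <- lra_free_energy(r, o, n_boot = 200, seed = k)
    expect_identical(f$dG_ox, (f$mean_red + f$mean_ox) / 2)
    expect_identical(f$lambda_reorg, (f$mean_red - f$mean_ox) / 2)
    expect_true(f$ci_dG[1] <= f$dG_ox && f$dG_ox <= f$ci_dG[2])
    # exchange-and-negate symmetry: swapping states and negating gaps
    # negates the free energy
    r2 <- gap_ensemble(-o$gaps, "reduced")
    o2 <- gap_ensemble(-r$gaps, "oxidized")
    f2 <- lra_free_energy(r2, o2, n_boot = 0)
    expect_equal(f2$dG_ox, -f$dG_ox, tolerance = 1e-12)
  }
  # bootstrap CI width shrinks as 1/sqrt(n)
  width_at <- function(n, seed) {
    ens <- generate_gap_ensembles(synthetic_gap_config(5, 1, n_per_state = n,
                                                       seed = seed))
    f <- lra_free_energy(ens$reduced, ens$oxidized, n_boot = 400, seed = seed)
    diff(f$ci_dG)
  }
  w <- sapply(c(125, 500, 2000), function(n)
    mean(sapply(1:6, function(s) width_at(n, 100 * s))))
  expect_equal(w[1] / w[2], 2, tolerance = 0.25)
  expect_equal(w[2] / w[3], 2, tolerance = 0.25)
})

test_that("linear-response consistency: LRA and both exponential directions
           agree at narrow spread", {
  # choose a small lambda so sigma = sqrt(2 kT lambda) is ~kT and the
  # exponential averages converge at modest n
  T <- 310; kT <- kB * T
  cfg <- synthetic_gap_config(2.0, 0.02, temperature = T,
                              n_per_state = 4e4, seed = 33)
  ens <- generate_gap_ensembles(cfg)
  f <- lra_free_energy(ens$reduced, ens$oxidized, n_boot = 0)
  se <- sqrt(2 * kT * 0.02 / 4e4)
  expect_lt(abs(f$dG_ox - 2.0), 3 * se)
  expect_lt(abs(zwanzig_free_energy(ens$reduced) - 2.0), 0.01)
  expect_lt(abs(zwanzig_free_energy(ens$oxidized) - 2.0), 0.01)
})

test_that("marcus parabolas satisfy the gap identity and vertex values", {
  set.seed(5)
  for (k in 1:20) {
    mr <- runif(1, 4, 10); mo <- runif(1, 1, mr - 0.1)
    f <- lra_free_energy(gap_ensemble(rep(mr, 2), "reduced"),
                         gap_ensemble(rep(mo, 2), "oxidized"), n_boot = 0)
    p <- marcus_parabolas(f)
    x <- seq(mo - 3, mr + 3, length.out = 100)
    Gr <- p$G_red[1] + p$G_red[2] * x + p$G_red[3] * x^2
    Go <- p$G_ox[1] + p$G_ox[2] * x + p$G_ox[3] * x^2
    expect_lt(max(abs((Go - Gr) - x)), 1e-10)
    # vertices
    vr <- p$G_red[1] + p$G_red[2] * mr + p$G_red[3] * mr^2
    vo <- p$G_ox[1] + p$G_ox[2] * mo + p$G_ox[3] * mo^2
    expect_equal(vr, 0, tolerance = 1e-10)
    expect_equal(vo, f$dG_ox, tolerance = 1e-10)
  }
  # with the identity G_ox - G_red = x, the curves cross at x = 0
  f <- lra_free_energy(gap_ensemble(rep(9.32, 2), "reduced"),
                       gap_ensemble(rep(4.95, 2), "oxidized"), n_boot = 0)
  p <- marcus_parabolas(f)
  at0 <- function(cf) cf[1]
  expect_equal(at0(p$G_red), at0(p$G_ox), tolerance = 1e-12)
  expect_error(marcus_parabolas(lra_free_energy(
    gap_ensemble(rep(3, 2), "reduced"), gap_ensemble(rep(3, 2), "oxidized"),
    n_boot = 0)), "lambda")
})

test_that("running average is cumulative and consistent with the mean", {
  expect_equal(running_average(gap_ensemble(c(1, 2, 3), "reduced")),
               c(1, 1.5, 2))
  expect_equal(running_average(gap_ensemble(rep(4.2, 7), "reduced")),
               rep(4.2, 7))
  set.seed(9)
  e <- gap_ensemble(rnorm(300, 6, 0.3), "oxidized")
  ra <- running_average(e)
  expect_equal(ra[length(ra)], average_gap(e), tolerance = 1e-12)
})

test_that("histogram mode counting separates unimodal from bimodal gaps", {
  set.seed(12)
  # bin width chosen to hold ~40 counts per bin so Poisson noise does not
  # fake extra maxima
  uni <- gap_ensemble(rnorm(500, 7, 0.2), "reduced")
  expect_equal(gap_histogram_modes(uni, bin_width = 0.1)$n_modes, 1L)
  bi <- gap_ensemble(c(rnorm(250, 5, 0.1), rnorm(250, 9, 0.1)), "reduced")
  expect_equal(gap_histogram_modes(bi, bin_width = 0.1)$n_modes, 2L)
  const <- gap_ensemble(rep(2, 50), "reduced")
  expect_equal(gap_histogram_modes(const)$n_modes, 1L)
  # bin width wider than the data range degenerates to a single bin
  wide <- gap_histogram_modes(uni, bin_width = 100)
  expect_equal(wide$n_modes, 1L)
  expect_equal(wide$counts, 500L)
})

test_that("PCA decorrelation reports near-zero correlation for independent
           gaps and unit correlation for constructed ones", {
  cfg <- synthetic_box_config("ring6", n_waters = 5, box_edge = 30,
                              n_frames = 60, jitter_sd = 0.15, seed = 17)
  traj <- generate_solvated_box(cfg)
  set.seed(18)
  indep <- gap_ensemble(rnorm(60, 5, 0.2), "reduced")
  rep1 <- decorrelation_check(traj, indep)
  expect_lt(rep1$pc_gap_correlations[["pc1_gap"]], 0.35)
  expect_lt(rep1$pc_gap_correlations[["pc1_pc2"]], 1e-8)
  expect_equal(rep1$running_mean[60], mean(indep$gaps), tolerance = 1e-12)
  # gaps that ARE the PC1 projection must correlate perfectly
  sol <- which(traj$snapshots[[1]]$atoms$role == "solute")
  X <- t(sapply(traj$snapshots, function(s) {
    P <- as.matrix(s$atoms[sol, c("x", "y", "z")])
    as.vector(t(sweep(P, 2, colMeans(P))))
  }))
  # alignment is near-identity here (jitter only), so PC1 of raw centered
  # coordinates is a valid stand-in for the constructed signal
  pc1 <- prcomp(X)$x[, 1]
  dep <- gap_ensemble(5 + 0.1 * pc1, "reduced")
  rep2 <- decorrelation_check(traj, dep)
  expect_gt(rep2$pc_gap_correlations[["pc1_gap"]], 0.9)
  # translations only: no conformational variance, correlations 0 by
  # convention
  s1 <- traj$snapshots[[1]]
  shifted <- lapply(1:5, function(k) {
    s <- s1
    s$atoms$x <- s$atoms$x + 0.5 * k
    s$frame_index <- k
    s
  })
  t2 <- trajectory(shifted)
  rep3 <- decorrelation_check(t2, gap_ensemble(rnorm(5, 5, 0.1), "reduced"))
  expect_equal(unname(rep3$pc_gap_correlations), c(0, 0, 0))
})
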