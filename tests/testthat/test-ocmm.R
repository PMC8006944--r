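test_that("zero glucose excursion or zero responsivity gives no secretion", {
  kin <- vc_ref_kin()
  g <- constant_signal(5)
  sec <- secretion_params(k_d = 400, alpha = 0.03, beta = 12, h = 5)
  out <- simulate_ocmm(kin, sec, g, t_eval = seq(0, 180, 30), cp_basal = 450)
  expect_equal(out$cpeptide_pmol_L, rep(450, 7), tolerance = 1e-10)

  sec0 <- secretion_params(k_d = 0, alpha = 0.03, beta = 0, h = 5.2)
  out0 <- simulate_ocmm(kin, sec0, bump_signal(), seq(0, 210, 15), cp_basal = 380)
  expect_equal(out0$cpeptide_pmol_L, rep(380, 15), tolerance = 1e-8)
})

test_that("solver matches the matrix-exponential closed form under piecewise-constant forcing", {
  skip_if_not_installed("Matrix")
  set.seed(7)
  for (case in 1:20) {
    kin <- kinetic_params(0.06 * exp(rnorm(1, 0, 0.2)),
                          0.05 * exp(rnorm(1, 0, 0.2)),
                          0.055 * exp(rnorm(1, 0, 0.2)))
    n_seg <- sample(3:5, 1)
    breaks <- c(0, sort(sample(seq(10, 110, 10), n_seg - 1L)), 120)
    levels <- runif(n_seg, 0, 60)
    sig <- sr_forcing_signal(breaks, levels, t_end = 120)
    t_eval <- seq(0, 120, 10)
    got <- simulate_ocmm(kin, passthrough_secretion(), sig, t_eval)$cpeptide_pmol_L
    want <- matexp_cp1(kin, breaks, levels, t_eval)
    expect_lt(max(abs(got - want)) / max(want), 1e-6)
  }
})

test_that("response is superposition-linear in secretion and reaches SR/k01 at steady state", {
  kin <- vc_ref_kin()
  t_eval <- seq(0, 120, 15)
  sig_a <- sr_forcing_signal(c(0, 40, 120), c(30, 5), 120)
  sig_b <- sr_forcing_signal(c(0, 60, 120), c(10, 45), 120)
  sig_ab <- sr_forcing_signal(c(0, 40, 60, 120), c(40, 15, 50), 120)
  sec <- passthrough_secretion()
  ya <- simulate_ocmm(kin, sec, sig_a, t_eval)$cpeptide_pmol_L
  yb <- simulate_ocmm(kin, sec, sig_b, t_eval)$cpeptide_pmol_L
  yab <- simulate_ocmm(kin, sec, sig_ab, t_eval)$cpeptide_pmol_L
  expect_equal(yab, ya + yb, tolerance = 1e-8)

  const <- sr_forcing_signal(c(0, 3000), 20, 3000)
  tail_val <- simulate_ocmm(kin, sec, const, c(0, 2500, 3000))$cpeptide_pmol_L[3]
  expect_equal(tail_val, 20 / kin$k01, tolerance = 1e-6)
})

test_that("fast grid propagator agrees with the adaptive solver and converges quadratically", {
  kin <- vc_ref_kin()
  sec <- secretion_params(k_d = 500, alpha = 0.03, beta = 12, h = 5.2)
  g <- bump_signal()
  t_eval <- seq(0, 210, 15)
  ref <- simulate_ocmm(kin, sec, g, t_eval, cp_basal = 400)$cpeptide_pmol_L
  err <- vapply(c(1, 0.5), function(h) {
    max(abs(ocmm:::ocmm_predict_fast(kin, sec, g, t_eval, 400, h = h) - ref)) /
      max(ref)
  }, numeric(1))
  expect_lt(err[1], 1e-3)
  expect_lt(err[2], err[1] / 3)  # ~ O(h^2)
})

test_that("basal secretion is the clearance-balance product with guarded inputs", {
  expect_equal(basal_secretion(0.06, 500), 30)
  expect_equal(basal_secretion(0.0569, 700), 39.83)
  expect_error(basal_secretion(0, 500))
  expect_error(basal_secretion(0.06, -1))
})

test_that("responsivity indices collapse correctly in degenerate configurations", {
  kin <- vc_ref_kin()
  g <- constant_signal(5)
  sec <- secretion_params(k_d = 300, alpha = 0.03, beta = 10, h = 5)
  idx <- responsivity_indices(kin, sec, g, cp1_basal = 450)
  # constant glucose at threshold: phi_tot reduces exactly to phi_b
  expect_equal(idx$phi_tot, idx$phi_b, tolerance = 1e-12)
  expect_equal(idx$phi_b, 0.0569 * 450 / 5)

  # no static or dynamic component: phi_tot = phi_b * T G_b / int G
  sec00 <- secretion_params(k_d = 0, alpha = 0.03, beta = 0, h = 5.2)
  g2 <- bump_signal()
  idx2 <- responsivity_indices(kin, sec00, g2, cp1_basal = 450)
  grid <- seq(0, 300, 0.1)
  int_g <- sum(diff(grid) * (g2$G(grid)[-1] + g2$G(grid)[-length(grid)])) / 2
  expect_equal(idx2$phi_tot, idx2$phi_b * 300 * g2$G_b / int_g, tolerance = 1e-6)
})

test_that("total responsivity matches an independent quadrature and is grid-stable", {
  kin <- vc_ref_kin()
  sec <- secretion_params(k_d = 4000, alpha = 0.03, beta = 11, h = 5.2)
  g <- bump_signal()
  idx <- responsivity_indices(kin, sec, g, cp1_basal = 400)

  # independent trapezoid evaluation on a different (finer, shifted) grid
  grid <- seq(0, 300, length.out = 12001)
  gv <- g$G(grid)
  tz <- function(y) sum(diff(grid) * (y[-1] + y[-length(y)])) / 2
  phi_b <- kin$k01 * 400 / g$G_b
  want <- (sec$k_d * (g$G_max - g$G_b) + sec$beta * tz(gv - sec$h) +
             300 * phi_b * g$G_b) / tz(gv)
  expect_equal(idx$phi_tot, want, tolerance = 1e-5)
  expect_gt(idx$phi_tot, 0)
})

test_that("invalid kinetic and secretion parameters are rejected", {
  expect_error(kinetic_params(-0.1, 0.05, 0.05), "strictly positive")
  expect_error(kinetic_params(NA, 0.05, 0.05), "finite")
  expect_error(secretion_params(-1, 0.03, 10, 5))
  expect_error(secretion_params(100, 0, 10, 5))
  expect_error(simulate_ocmm(vc_ref_kin(), passthrough_secretion(),
                             constant_signal(), c(10, 20)),
               "start at 0")
})
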