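make_forward_subject <- function(kin, sec, signal, times, cp_basal,
                                 noise_cv = 0, seed = NULL) {
  sim <- simulate_ocmm(kin, sec, signal, t_eval = times, cp_basal = cp_basal)
  cp <- sim$cpeptide_pmol_L
  if (noise_cv > 0 && !is.null(seed)) {
    cp <- withr::with_seed(seed, cp * (1 + rnorm(length(cp), 0, noise_cv)))
  }
  tibble::tibble(time_min = times, glucose_mmol_L = signal$G(times),
                 cpeptide_pmol_L = cp)
}

flat_priors <- function() {
  stats::setNames(lapply(1:6, function(i) prior_flat()),
                  c("k_d", "alpha", "beta", "k01", "k12", "k21"))
}

test_that("objective is zero at a perfect fit and matches a hand-weighted RSS", {
  kin <- vc_ref_kin()
  sec <- secretion_params(k_d = 400, alpha = 0.04, beta = 10, h = 5.2)
  sig <- bump_signal()
  p <- list(k_d = 400, alpha = 0.04, beta = 10,
            k01 = kin$k01, k12 = kin$k12, k21 = kin$k21)
  yhat <- ocmm:::ocmm_predict_fast(kin, sec, sig, ogtt_times, cp_basal = 350,
                                   h = 0.5)
  d0 <- tibble::tibble(time_min = ogtt_times, cpeptide_pmol_L = yhat)
  expect_equal(neg_log_posterior(p, d0, sig, priors = flat_priors(),
                                 cp_basal = 350), 0, tolerance = 1e-12)

  # inject known residuals on the first three samples
  res <- c(1, -1, 2, rep(0, 7))
  d1 <- tibble::tibble(time_min = ogtt_times, cpeptide_pmol_L = yhat + res)
  err <- error_model(0.05)
  want <- 0.5 * sum((res / (err$cv * d1$cpeptide_pmol_L))^2)
  expect_equal(neg_log_posterior(p, d1, sig, priors = flat_priors(),
                                 error = err, cp_basal = 350),
               want, tolerance = 1e-8)
})

test_that("a log-normal prior adds nothing at its own median", {
  kin <- vc_ref_kin()
  sec <- secretion_params(k_d = 400, alpha = 0.04, beta = 10, h = 5.2)
  sig <- bump_signal()
  p <- list(k_d = 400, alpha = 0.04, beta = 10,
            k01 = kin$k01, k12 = kin$k12, k21 = kin$k21)
  yhat <- ocmm:::ocmm_predict_fast(kin, sec, sig, ogtt_times, 350, h = 0.5)
  d <- tibble::tibble(time_min = ogtt_times, cpeptide_pmol_L = yhat + 5)
  pri <- flat_priors()
  base <- neg_log_posterior(p, d, sig, priors = pri, cp_basal = 350)
  pri$alpha <- prior_lognormal(0.04, 0.5)
  expect_equal(neg_log_posterior(p, d, sig, priors = pri, cp_basal = 350),
               base, tolerance = 1e-12)
  # off the median the same prior adds the expected quadratic penalty
  p2 <- p; p2$alpha <- 0.08
  sdlog <- sqrt(log(1 + 0.25))
  extra <- 0.5 * (log(0.08 / 0.04) / sdlog)^2
  expect_equal(neg_log_posterior(p2, d, sig, priors = pri, cp_basal = 350) -
                 neg_log_posterior(p2, d, sig, priors = flat_priors(),
                                   cp_basal = 350),
               extra, tolerance = 1e-10)
})

test_that("VC self-consistency: secretion parameters recover when kinetics are correct", {
  demo <- list(age = 45, bmi = 26)
  kin <- as_vc <- vc_kinetics(tibble::tibble(age_years = 45, bmi_kg_m2 = 26))
  kin <- kinetic_params(as_vc$k01, as_vc$k12, as_vc$k21)
  sec <- secretion_params(k_d = 3000, alpha = 0.05, beta = 9, h = 5.2)
  sig <- bump_signal()
  d <- make_forward_subject(kin, sec, sig, ogtt_times, cp_basal = 400)
  fit <- fit_subject(d, "VC", age_years = 45, bmi_kg_m2 = 26, signal = sig,
                     control = fit_control(grid_step = 0.25))
  est <- fit$estimates[c("k_d", "alpha", "beta")]
  expect_lt(mard(est, c(3000, 0.05, 9)), 1)
  # fixed kinetics pass through untouched and report no precision entry
  expect_equal(unname(fit$estimates["k01"]), as_vc$k01)
  td <- tidy(fit)
  expect_true(all(is.na(td$cv_percent[td$fixed])))
  expect_false(any(td$fixed[td$term %in% c("k_d", "alpha", "beta")]))
})

test_that("faster-than-population kinetics are identified from noise-free data", {
  as_vc <- vc_kinetics(tibble::tibble(age_years = 45, bmi_kg_m2 = 26))
  kin_true <- kinetic_params(as_vc$k01 * 1.15, as_vc$k12, as_vc$k21)
  sec <- secretion_params(k_d = 3000, alpha = 0.05, beta = 9, h = 5.2)
  sig <- bump_signal()
  d <- make_forward_subject(kin_true, sec, sig, ogtt_times, cp_basal = 400)
  fit <- fit_subject(d, "DB", age_years = 45, bmi_kg_m2 = 26, signal = sig)
  expect_lt(abs(fit$estimates[["k01"]] - kin_true$k01) / kin_true$k01, 0.02)
})

test_that("VC misfit shows the under-peak / over-tail residual signature", {
  as_vc <- vc_kinetics(tibble::tibble(age_years = 45, bmi_kg_m2 = 26))
  kin_true <- kinetic_params(as_vc$k01 * 1.15, as_vc$k12 * 1.15, as_vc$k21 * 1.15)
  sec <- secretion_params(k_d = 3000, alpha = 0.05, beta = 9, h = 5.2)
  sig <- bump_signal()
  d <- make_forward_subject(kin_true, sec, sig, ogtt_times, cp_basal = 400)
  fit <- fit_subject(d, "VC", age_years = 45, bmi_kg_m2 = 26, signal = sig)
  r <- fit$prediction
  peak <- which.max(r$cpeptide_pmol_L)
  expect_gt(r$.resid[peak], 0)          # data peak above prediction
  expect_lt(r$.resid[nrow(r)], 0)       # data tail below prediction
})

test_that("tightening the kinetic priors reproduces the fixed-kinetics fit", {
  as_vc <- vc_kinetics(tibble::tibble(age_years = 45, bmi_kg_m2 = 26))
  kin_true <- kinetic_params(as_vc$k01 * 1.1, as_vc$k12, as_vc$k21)
  sec <- secretion_params(k_d = 3000, alpha = 0.05, beta = 9, h = 5.2)
  sig <- bump_signal()
  d <- make_forward_subject(kin_true, sec, sig, ogtt_times, cp_basal = 400)
  fit_vc <- fit_subject(d, "VC", age_years = 45, bmi_kg_m2 = 26, signal = sig)
  tight <- default_priors("DB", 45, 26, kinetic_gcv = 1e-4)
  fit_db <- fit_subject(d, "DB", age_years = 45, bmi_kg_m2 = 26, signal = sig,
                        priors = tight)
  # kinetics are pinned to the population prediction ...
  expect_equal(fit_db$estimates[["k01"]], as_vc$k01, tolerance = 1e-3)
  expect_equal(fit_db$estimates[["k12"]], as_vc$k12, tolerance = 1e-3)
  expect_equal(fit_db$estimates[["k21"]], as_vc$k21, tolerance = 1e-3)
  # ... and the fitted curve coincides with the fixed-kinetics fit; the
  # near-singular pinned directions leave the weakly identified alpha a few
  # percent of slack at the optimizer tolerance
  expect_equal(fit_db$prediction$.fitted, fit_vc$prediction$.fitted,
               tolerance = 0.02)
  expect_equal(fit_db$estimates[c("k_d", "beta")],
               fit_vc$estimates[c("k_d", "beta")], tolerance = 0.05)
  expect_equal(fit_db$estimates[["alpha"]], fit_vc$estimates[["alpha"]],
               tolerance = 0.15)
})

test_that("precision scales with the error model and estimates are start-stable", {
  as_vc <- vc_kinetics(tibble::tibble(age_years = 45, bmi_kg_m2 = 26))
  kin <- kinetic_params(as_vc$k01, as_vc$k12, as_vc$k21)
  sec <- secretion_params(k_d = 3000, alpha = 0.05, beta = 9, h = 5.2)
  sig <- bump_signal()
  d <- make_forward_subject(kin, sec, sig, ogtt_times, cp_basal = 400)
  pri <- flat_priors()
  pri$k01 <- prior_fixed(as_vc$k01)
  pri$k12 <- prior_fixed(as_vc$k12)
  pri$k21 <- prior_fixed(as_vc$k21)
  f1 <- fit_subject(d, "VC", 45, 26, signal = sig, priors = pri,
                    error = error_model(0.05))
  f2 <- fit_subject(d, "VC", 45, 26, signal = sig, priors = pri,
                    error = error_model(0.10))
  cv1 <- parameter_precision(f1)$cv_percent
  cv2 <- parameter_precision(f2)$cv_percent
  expect_equal(cv2 / cv1, rep(2, 3), tolerance = 0.05)

  f5 <- fit_subject(d, "VC", 45, 26, signal = sig,
                    control = fit_control(n_starts = 5))
  f1s <- fit_subject(d, "VC", 45, 26, signal = sig,
                     control = fit_control(n_starts = 1))
  expect_equal(f5$estimates, f1s$estimates, tolerance = 0.01)
  # the multi-start objective never worsens on the best optimum
  expect_lte(f5$objective, min(f5$start_objectives) + 1e-12)
})

test_that("fit accessors expose tidy, glance, augment and a plot", {
  as_vc <- vc_kinetics(tibble::tibble(age_years = 45, bmi_kg_m2 = 26))
  kin <- kinetic_params(as_vc$k01, as_vc$k12, as_vc$k21)
  sec <- secretion_params(k_d = 3000, alpha = 0.05, beta = 9, h = 5.2)
  sig <- bump_signal()
  d <- make_forward_subject(kin, sec, sig, ogtt_times, cp_basal = 400)
  fit <- fit_subject(d, "VC", 45, 26, signal = sig)
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 6)
  g <- glance(fit)
  expect_equal(g$approach, "VC")
  expect_true(all(c("phi_tot", "mcr") %in% names(g)))
  expect_equal(names(augment(fit)),
               c("time_min", "cpeptide_pmol_L", ".fitted", ".resid"))
  expect_s3_class(autoplot(fit), "ggplot")
})
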