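test_that("population moments follow the log triplets", {
  same <- tibble::tibble(k01 = rep(0.06, 4), k12 = rep(0.05, 4), k21 = rep(0.055, 4))
  pop <- fit_population(same)
  expect_equal(unname(pop$mu), log(c(0.06, 0.05, 0.055)))
  expect_equal(unname(pop$Sigma), matrix(0, 3, 3))

  only_k01 <- tibble::tibble(k01 = c(0.05, 0.06, 0.07, 0.08),
                             k12 = rep(0.05, 4), k21 = rep(0.055, 4))
  S <- fit_population(only_k01)$Sigma
  expect_equal(S["k01", "k12"], 0)
  expect_equal(S["k12", "k21"], 0)
  expect_gt(S["k01", "k01"], 0)

  expect_error(fit_population(same[1:2, ]), "at least 3")
})

test_that("population mean is recovered from a known log-normal at n = 22", {
  set.seed(31)
  mu <- log(c(k01 = 0.068, k12 = 0.055, k21 = 0.06))
  sd <- 0.15
  draws <- tibble::tibble(k01 = rlnorm(22, mu[1], sd),
                          k12 = rlnorm(22, mu[2], sd),
                          k21 = rlnorm(22, mu[3], sd))
  pop <- fit_population(draws)
  se <- sd / sqrt(22)
  expect_true(all(abs(pop$mu - mu) < 2 * se * 3))  # loose 2-sd-ish band per axis
})

test_that("mard matches hand-computed values and its zero law", {
  expect_equal(mard(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mard(1.1 * c(5, 50, 500), c(5, 50, 500)), 10)
  expect_equal(mard(c(0.05, 0.08), c(0.04, 0.10)), 22.5)
  expect_error(mard(c(1, 2), c(1, 0)), "nonzero")
  expect_error(mard(1:3, 1:2))
  set.seed(2)
  est <- runif(10); tru <- runif(10)
  expect_gte(mard(est, tru), 0)
  expect_gt(mard(est, tru), 0)  # equality only under elementwise identity
})

test_that("virtual cohorts have the right size, determinism and noiseless limit", {
  src <- generate_cohort(cohort_spec(n_subjects = 3, seed = 15))
  pop <- fit_population(cohort_truths(src))
  v1 <- generate_virtual_cohort(pop, src, n_per_subject = 4,
                                error = error_model(0.05), seed = 5)
  expect_equal(nrow(v1), 12)  # sources x replicates
  expect_equal(unique(v1$source_id), src$id)
  v2 <- generate_virtual_cohort(pop, src, n_per_subject = 4,
                                error = error_model(0.05), seed = 5)
  expect_identical(v1$data, v2$data)

  v0 <- generate_virtual_cohort(pop, src, n_per_subject = 1,
                                error = error_model(1e-9), seed = 5)
  tr <- v0$truth[[1]]
  sim <- simulate_ocmm(tr$kin, tr$sec, tr$signal, v0$data[[1]]$time_min,
                       cp_basal = tr$cp_basal)
  expect_equal(v0$data[[1]]$cpeptide_pmol_L, sim$cpeptide_pmol_L,
               tolerance = 1e-6)
})

test_that("assessment scores and orders approaches on a miniature cohort", {
  src <- generate_cohort(cohort_spec(n_subjects = 4, seed = 23))
  pop <- fit_population(cohort_truths(src))
  virt <- generate_virtual_cohort(pop, src, n_per_subject = 2,
                                  error = error_model(0.05), seed = 6)
  a <- run_assessment(virt, c("VC", "DB"), population = pop)
  expect_s3_class(a, "ocmm_assessment")
  expect_equal(sort(unique(a$scores$approach)), c("DB", "VC"))
  expect_equal(nrow(a$scores), 16)
  expect_true(all(a$scores$mard_mcr >= 0))

  # VC clearance estimates are a deterministic function of demographics:
  # identical across replicates of the same source subject
  vc_k01 <- a$results |>
    dplyr::filter(.data$approach == "VC", .data$parameter == "k01")
  spread <- tapply(vc_k01$estimate, sub("_r[0-9]+$", "", vc_k01$id),
                   function(x) diff(range(x)))
  expect_true(all(spread == 0))

  # truths drawn off the population prediction: data-based identification
  # should track clearance better than the fixed population value
  med <- a$summary[a$summary$score == "mard_mcr", ]
  expect_lt(med$median[med$approach == "DB"], med$median[med$approach == "VC"])

  expect_s3_class(glance(a), "tbl_df")
  expect_s3_class(tidy(a), "tbl_df")
  expect_s3_class(autoplot(a), "ggplot")
})

test_that("rank-based post-hoc comparisons behave under null and shifted groups", {
  set.seed(9)
  x <- c(rnorm(30), rnorm(30), rnorm(30) + 3)
  g <- rep(c("a", "b", "c"), each = 30)
  out <- dunn_sidak(x, g)
  expect_equal(nrow(out), 3)
  ab <- out$p_adjusted[out$comparison == "a vs b"]
  ac <- out$p_adjusted[out$comparison == "a vs c"]
  expect_gt(ab, 0.05)
  expect_lt(ac, 0.01)
  expect_true(all(out$p_adjusted >= out$p_value - 1e-12))
})
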