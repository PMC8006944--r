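# run code under a temporary RNG state so generators are reproducible
# without clobbering the caller's stream
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

rtrunc_norm <- function(n, mean, sd, lower) {
  out <- stats::rnorm(n, mean, sd)
  while (any(bad <- out < lower)) {
    out[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  out
}

rlnorm_gcv <- function(n, median, gcv) {
  stats::rlnorm(n, meanlog = log(median), sdlog = sqrt(log(1 + gcv^2)))
}

# standard sampling schedules, min
.schedules <- list(
  OGTT = c(0, 15, 30, 45, 60, 90, 120, 150, 180, 210),
  MMTT = c(0, 30, 60, 90, 120, 150, 180)
)

#' Post-gastric-bypass glucose excursion
#'
#' Builds a smooth glucose curve with the phenotype seen after gastric
#' bypass: a fast rise to an early peak (about 30-45 min) followed by an
#' overshoot to a late below-basal nadir (about 120-150 min) and relaxation
#' back to basal by 300 min. The curve is basal plus a positive and a
#' negative gamma-density-shaped kernel; the two amplitudes are solved
#' numerically so the maximum and minimum hit the requested peak and nadir.
#' With a seed, the kernel timings are jittered so no two subjects share the
#' exact same shape.
#'
#' @param test_type `"OGTT"` or `"MMTT"` (meal curves peak slightly later).
#' @param basal,peak,nadir Glucose levels, mmol/L (`nadir < basal < peak`).
#' @param seed Optional integer; jitters kernel timing reproducibly.
#' @return A `glucose_signal` with analytic `G` and `dG` on `[0, 300]`.
#' @examples
#' g <- generate_glucose_profile("OGTT", basal = 5, peak = 9.5, nadir = 2.7, seed = 1)
#' range(g$G(0:300))
#' @export
generate_glucose_profile <- function(test_type = c("OGTT", "MMTT"),
                                     basal = 5.2, peak = 9.5, nadir = 2.7,
                                     seed = NULL) {
  test_type <- match.arg(test_type)
  if (!(nadir < basal && basal < peak)) {
    stop("need nadir < basal < peak", call. = FALSE)
  }
  mode1_mean <- if (test_type == "OGTT") 35 else 42
  jit <- with_seed(seed, c(stats::rnorm(1, 0, 4), stats::rnorm(1, 0, 10)))
  mode1 <- min(max(mode1_mean + jit[1], 25), 48)
  mode2 <- min(max(135 + jit[2], 110), 165)

  k1 <- 3; th1 <- mode1 / (k1 - 1)
  k2 <- 8; th2 <- mode2 / (k2 - 1)
  kern <- function(t, k, th, mode) {
    f <- ifelse(t <= 0, 0, (t / mode)^(k - 1) * exp(-(t - mode) / th))
    f
  }
  dkern <- function(t, k, th, mode) {
    ifelse(t <= 0, 0, kern(t, k, th, mode) * ((k - 1) / pmax(t, 1e-12) - 1 / th))
  }

  grid <- seq(0, 300, by = 0.5)
  f1 <- kern(grid, k1, th1, mode1)
  f2 <- kern(grid, k2, th2, mode2)
  A1 <- peak - basal
  A2 <- basal - nadir
  for (i in 1:100) {
    gvals <- basal + A1 * f1 - A2 * f2
    e_max <- peak - max(gvals)
    e_min <- min(gvals) - nadir
    if (abs(e_max) < 1e-9 && abs(e_min) < 1e-9) break
    A1 <- A1 + e_max
    A2 <- A2 + e_min
  }

  G <- function(t) basal + A1 * kern(t, k1, th1, mode1) - A2 * kern(t, k2, th2, mode2)
  dG <- function(t) A1 * dkern(t, k1, th1, mode1) - A2 * dkern(t, k2, th2, mode2)
  new_glucose_signal(G, dG, G_b = basal, G_max = max(basal + A1 * f1 - A2 * f2),
                     t_end = 300)
}

#' Specification of a synthetic PHH cohort
#'
#' Defaults emulate the demographics of the two clinical cohorts this
#' package's study design is modelled on (n = 12 OGTT, age 42 +/- 9 y, BMI
#' 28.3 +/- 6.9; n = 10 MMTT, age 43 +/- 11 y, BMI 27.5 +/- 4.2), glucose
#' excursions with a late hypoglycemic nadir, C-peptide kinetics centred 15%
#' above the Van Cauter population prediction (the faster clearance this
#' population shows), and secretion parameters calibrated so the total
#' responsivity index has median near 16e-9 /min and the basal index near
#' 5e-9 /min.
#'
#' @param n_subjects Number of subjects.
#' @param test_type `"OGTT"` or `"MMTT"`; fixes the sampling schedule.
#' @param age_mean,age_sd,bmi_mean,bmi_sd Demographic distribution
#'   (truncated at age >= 18 y, BMI >= 18.5).
#' @param schedule Sampling times, min; defaults to the standard schedule of
#'   `test_type` (OGTT: every 15 min to 60, every 30 to 210; MMTT: every
#'   30 min to 180).
#' @param kinetics_offset Multiplicative offset of true kinetic parameters
#'   relative to the Van Cauter prediction (1 = population model correct).
#' @param kinetics_gcv Geometric CV of the log-normal jitter on each kinetic
#'   parameter.
#' @param kd_median,kd_gcv,alpha_median,alpha_gcv,beta_median,beta_gcv
#'   Log-normal secretion-parameter distributions (units as in
#'   [secretion_params()]).
#' @param phib_median,phib_gcv Basal responsivity distribution (1e-9 /min);
#'   basal C-peptide follows as `phi_b * G_b / k01`.
#' @param glucose_basal_mean,glucose_basal_sd,glucose_peak_mean,glucose_peak_sd,glucose_nadir_mean,glucose_nadir_sd
#'   Glucose landmark distributions, mmol/L.
#' @param noise_cv C-peptide measurement CV applied to the simulated samples.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   this specification object.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 12, test_type = c("OGTT", "MMTT"),
                        age_mean = 42, age_sd = 9,
                        bmi_mean = 28.3, bmi_sd = 6.9,
                        schedule = NULL,
                        kinetics_offset = 1.15, kinetics_gcv = 0.12,
                        kd_median = 4000, kd_gcv = 0.4,
                        alpha_median = 0.03, alpha_gcv = 0.3,
                        beta_median = 11, beta_gcv = 0.4,
                        phib_median = 5, phib_gcv = 0.25,
                        glucose_basal_mean = 5.2, glucose_basal_sd = 0.4,
                        glucose_peak_mean = 9.5, glucose_peak_sd = 1.0,
                        glucose_nadir_mean = 2.7, glucose_nadir_sd = 0.3,
                        noise_cv = 0.05, seed = 1L) {
  test_type <- match.arg(test_type)
  if (is.null(schedule)) schedule <- .schedules[[test_type]]
  stopifnot(n_subjects >= 1, schedule[1] == 0, all(diff(schedule) > 0),
            kinetics_offset > 0, noise_cv >= 0)
  structure(as.list(environment()), class = "cohort_spec")
}

#' Generate a synthetic PHH cohort
#'
#' Draws demographics, true model parameters and a subject-specific glucose
#' excursion per subject, simulates the C-peptide response with the forward
#' model, samples it at the schedule and corrupts the samples with
#' concentration-proportional Gaussian noise (draws that would make a
#' concentration non-positive are redrawn). The generating truth travels
#' with each record in a `truth` list-column that the fitting code never
#' reads.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble, one row per subject: `id`, `age_years`, `bmi_kg_m2`,
#'   `test_type`, `data` (list of sample tibbles with `time_min`,
#'   `glucose_mmol_L`, `cpeptide_pmol_L`) and `truth` (list of lists with
#'   elements `kin`, `sec`, `cp_basal`, `signal`, `indices`).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = 2, seed = 42))
#' cohort$data[[1]]
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_subjects
  with_seed(spec$seed, {
    age <- round(rtrunc_norm(n, spec$age_mean, spec$age_sd, 18))
    bmi <- round(rtrunc_norm(n, spec$bmi_mean, spec$bmi_sd, 18.5), 1)
    g_b <- rtrunc_norm(n, spec$glucose_basal_mean, spec$glucose_basal_sd, 3.8)
    g_pk <- pmax(rtrunc_norm(n, spec$glucose_peak_mean, spec$glucose_peak_sd, 7), g_b + 1.5)
    g_nd <- pmin(rtrunc_norm(n, spec$glucose_nadir_mean, spec$glucose_nadir_sd, 1.8),
                 g_b - 0.8)
    prof_seeds <- sample.int(.Machine$integer.max %/% 2L, n)
    noise_seeds <- sample.int(.Machine$integer.max %/% 2L, n)

    kin_vc <- vc_kinetics_one(age, classify_subject(bmi))
    sdlog_k <- sqrt(log(1 + spec$kinetics_gcv^2))

    rows <- purrr::map(seq_len(n), function(i) {
      signal <- generate_glucose_profile(spec$test_type, basal = g_b[i],
                                         peak = g_pk[i], nadir = g_nd[i],
                                         seed = prof_seeds[i])
      # rejection step: parameter draws whose noiseless C-peptide curve dips
      # to (or below) zero during the hypoglycemic phase are redrawn --
      # suppressed secretion may not push total C-peptide negative
      check_grid <- seq(0, 300, by = 2)
      for (attempt in 1:50) {
        jit <- stats::rlnorm(3, 0, sdlog_k)
        kin <- kinetic_params(kin_vc$k01[i] * spec$kinetics_offset * jit[1],
                              kin_vc$k12[i] * spec$kinetics_offset * jit[2],
                              kin_vc$k21[i] * spec$kinetics_offset * jit[3])
        sec <- secretion_params(rlnorm_gcv(1, spec$kd_median, spec$kd_gcv),
                                rlnorm_gcv(1, spec$alpha_median, spec$alpha_gcv),
                                rlnorm_gcv(1, spec$beta_median, spec$beta_gcv),
                                h = g_b[i])
        cp_basal <- rlnorm_gcv(1, spec$phib_median, spec$phib_gcv) *
          g_b[i] / kin$k01
        cp_check <- ocmm_predict_fast(kin, sec, signal, check_grid,
                                      cp_basal = cp_basal, h = 1)
        if (min(cp_check) > 0.05 * cp_basal) break
        if (attempt == 50L) {
          stop("could not draw a positive C-peptide trajectory for subject ",
               i, call. = FALSE)
        }
      }
      sim <- simulate_ocmm(kin, sec, signal, t_eval = spec$schedule,
                           cp_basal = cp_basal)
      cp_noisy <- with_seed(noise_seeds[i],
                            add_cv_noise(sim$cpeptide_pmol_L, spec$noise_cv))
      idx <- responsivity_indices(kin, sec, signal, cp1_basal = cp_basal)
      tibble::tibble(
        id = sprintf("S%02d", i),
        age_years = age[i], bmi_kg_m2 = bmi[i], test_type = spec$test_type,
        data = list(tibble::tibble(time_min = spec$schedule,
                                   glucose_mmol_L = signal$G(spec$schedule),
                                   cpeptide_pmol_L = cp_noisy)),
        truth = list(list(kin = kin, sec = sec, cp_basal = cp_basal,
                          signal = signal, indices = idx))
      )
    })
    dplyr::bind_rows(rows)
  })
}

# multiplicative-CV Gaussian noise with redraws keeping concentrations positive
add_cv_noise <- function(y, cv) {
  if (any(y <= 0)) {
    stop("cannot add positivity-preserving noise to non-positive values",
         call. = FALSE)
  }
  if (cv == 0) return(y)
  out <- y * (1 + stats::rnorm(length(y), 0, cv))
  while (any(bad <- out <= 0)) {
    out[bad] <- y[bad] * (1 + stats::rnorm(sum(bad), 0, cv))
  }
  out
}

#' True parameter table of a synthetic cohort
#'
#' Unnests the sealed truth attachments into a tidy table, one row per
#' subject.
#'
#' @param cohort A tibble from [generate_cohort()] or
#'   [generate_virtual_cohort()].
#' @return A tibble with the true kinetic and secretion parameters, basal
#'   C-peptide and responsivity indices.
#' @export
cohort_truths <- function(cohort) {
  stopifnot(is.data.frame(cohort), "truth" %in% names(cohort))
  purrr::map2_dfr(cohort$id, cohort$truth, function(id, tr) {
    tibble::tibble(id = id,
                   k01 = tr$kin$k01, k12 = tr$kin$k12, k21 = tr$kin$k21,
                   k_d = tr$sec$k_d, alpha = tr$sec$alpha, beta = tr$sec$beta,
                   h = tr$sec$h, cp_basal = tr$cp_basal,
                   phi_tot = tr$indices$phi_tot, phi_b = tr$indices$phi_b)
  })
}
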