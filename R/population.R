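#' Joint log-normal kinetic population
#'
#' Sample mean and covariance of the log kinetic triplets, defining the
#' log-normal population from which virtual subjects' kinetics are drawn and
#' from which the PHH prior is built.
#'
#' @param fits A list of `ocmm_fit` objects, or a data frame with columns
#'   `k01`, `k12`, `k21` (one row per subject). At least 3 rows/fits.
#' @return An object of class `kinetic_population`: list with `mu` (named
#'   3-vector of log-scale means) and `Sigma` (3x3 log-scale covariance).
#' @examples
#' fit_population(tibble::tibble(k01 = c(0.06, 0.07, 0.065),
#'                               k12 = c(0.05, 0.055, 0.048),
#'                               k21 = c(0.05, 0.06, 0.055)))
#' @export
fit_population <- function(fits) {
  if (is.data.frame(fits)) {
    stopifnot(all(.kin_names %in% names(fits)))
    K <- as.matrix(fits[, .kin_names])
  } else {
    stopifnot(is.list(fits), all(vapply(fits, inherits, logical(1), "ocmm_fit")))
    K <- do.call(rbind, lapply(fits, function(f) f$estimates[.kin_names]))
  }
  if (nrow(K) < 3L) stop("need at least 3 kinetic triplets", call. = FALSE)
  if (any(!is.finite(K)) || any(K <= 0)) {
    stop("kinetic triplets must be finite and positive", call. = FALSE)
  }
  L <- log(K)
  mu <- colMeans(L)
  Sigma <- stats::cov(L)
  if (any(!is.finite(Sigma))) {
    stop("degenerate log-kinetic covariance", call. = FALSE)
  }
  names(mu) <- .kin_names
  dimnames(Sigma) <- list(.kin_names, .kin_names)
  structure(list(mu = mu, Sigma = Sigma, n = nrow(K)),
            class = "kinetic_population")
}

#' @export
print.kinetic_population <- function(x, ...) {
  cat(sprintf(
    "<kinetic_population> n = %d; median k01 = %.4f, k12 = %.4f, k21 = %.4f min^-1\n",
    x$n, exp(x$mu[1]), exp(x$mu[2]), exp(x$mu[3])
  ))
  invisible(x)
}

# draw from exp(N(mu, Sigma)); eigen-based so a semi-definite Sigma is fine
rlnorm_mv <- function(n, mu, Sigma) {
  e <- eigen((Sigma + t(Sigma)) / 2, symmetric = TRUE)
  R <- e$vectors %*% diag(sqrt(pmax(e$values, 0)), length(mu))
  Z <- matrix(stats::rnorm(n * length(mu)), n)
  exp(sweep(Z %*% t(R), 2, mu, `+`))
}

#' Generate virtual subjects for the recovery study
#'
#' For each source subject, draws `n_per_subject` kinetic triplets from the
#' log-normal population, pairs each with the source's (true) secretion
#' parameters, basal C-peptide and glucose curve, simulates the C-peptide
#' response at the source sampling schedule and corrupts it with zero-mean
#' Gaussian noise of concentration-proportional variance (non-positive draws
#' are redrawn).
#'
#' @param pop A `kinetic_population`.
#' @param source_subjects A cohort tibble from [generate_cohort()] (needs the
#'   `truth` list-column for secretion parameters and glucose curves).
#' @param n_per_subject Replicates per source subject (>= 1).
#' @param error An [error_model()]; `cv = 0` gives noiseless samples.
#' @param seed Integer seed; subject `i` uses substream `seed + i`, so the
#'   cohort is reproducible and extendable.
#' @return A tibble like [generate_cohort()]'s, one row per virtual subject,
#'   with extra columns `source_id` and `replicate`.
#' @export
generate_virtual_cohort <- function(pop, source_subjects, n_per_subject = 5,
                                    error = error_model(), seed = 1L) {
  stopifnot(inherits(pop, "kinetic_population"), n_per_subject >= 1,
            is.data.frame(source_subjects),
            all(c("id", "data", "truth") %in% names(source_subjects)))
  rows <- purrr::map(seq_len(nrow(source_subjects)), function(i) {
    src <- source_subjects[i, ]
    tr <- src$truth[[1]]
    schedule <- src$data[[1]]$time_min
    with_seed(seed + i, {
      purrr::map(seq_len(n_per_subject), function(r) {
        cp_basal <- tr$cp_basal
        # redraw kinetic triplets whose noiseless curve would cross zero
        # (slow-clearance draws can over-suppress the hypoglycemic tail)
        for (attempt in 1:50) {
          K <- rlnorm_mv(1, pop$mu, pop$Sigma)
          kin <- kinetic_params(K[1, 1], K[1, 2], K[1, 3])
          cp_check <- ocmm_predict_fast(kin, tr$sec, tr$signal,
                                        seq(0, 300, by = 2),
                                        cp_basal = cp_basal, h = 1)
          if (min(cp_check) > 0.02 * cp_basal) break
          if (attempt == 50L) {
            stop("could not draw a positive virtual trajectory for source ",
                 src$id, call. = FALSE)
          }
        }
        sim <- simulate_ocmm(kin, tr$sec, tr$signal, t_eval = schedule,
                             cp_basal = cp_basal)
        cp <- if (error$cv > 0) add_cv_noise(sim$cpeptide_pmol_L, error$cv) else
          sim$cpeptide_pmol_L
        idx <- responsivity_indices(kin, tr$sec, tr$signal, cp1_basal = cp_basal)
        tibble::tibble(
          id = sprintf("%s_r%02d", src$id, r),
          source_id = src$id, replicate = r,
          age_years = src$age_years, bmi_kg_m2 = src$bmi_kg_m2,
          test_type = src$test_type,
          data = list(tibble::tibble(time_min = schedule,
                                     glucose_mmol_L = src$data[[1]]$glucose_mmol_L,
                                     cpeptide_pmol_L = cp)),
          truth = list(list(kin = kin, sec = tr$sec, cp_basal = cp_basal,
                            signal = tr$signal, indices = idx))
        )
      }) |> dplyr::bind_rows()
    })
  })
  dplyr::bind_rows(rows)
}

#' Mean absolute relative difference
#'
#' The recovery score of the simulation study:
#' `100 * mean(|estimate - truth| / |truth|)`, in percent.
#'
#' @param estimates,truths Equal-length numeric vectors; `truths` nonzero.
#' @return MARD in percent.
#' @examples
#' mard(c(0.05, 0.08), c(0.04, 0.10))
#' @export
mard <- function(estimates, truths) {
  stopifnot(length(estimates) == length(truths), length(truths) > 0)
  if (any(truths == 0)) stop("`truths` must be nonzero", call. = FALSE)
  100 * mean(abs(estimates - truths) / abs(truths))
}

#' Run the parameter-recovery assessment
#'
#' Fits every virtual subject with every requested identification approach
#' and scores recovery of the clearance rate (MCR = k01), the total
#' responsivity index, and the pooled six-parameter vector by absolute
#' relative difference. Approaches are compared with a Kruskal-Wallis test
#' and Dunn's post-hoc z-tests under Sidak correction.
#'
#' @param cohort A virtual cohort from [generate_virtual_cohort()] (or any
#'   cohort with a `truth` column).
#' @param approaches Subset of `c("VC", "DB", "PHH")`.
#' @param population `kinetic_population` used as the PHH prior.
#' @param error [error_model()] assumed during fitting.
#' @param control [fit_control()].
#' @return An object of class `ocmm_assessment`: list with `results` (tidy
#'   per-subject-per-approach-per-parameter tibble: `id`, `source_id`,
#'   `approach`, `parameter`, `estimate`, `truth`, `ard_percent`), `scores`
#'   (per-subject MARD table), `summary` (median [25th, 75th] by approach),
#'   `tests` (Kruskal-Wallis + Dunn-Sidak on each score), and `n_failed`.
#' @export
run_assessment <- function(cohort, approaches = c("VC", "DB", "PHH"),
                           population = NULL, error = error_model(),
                           control = fit_control()) {
  approaches <- match.arg(approaches, several.ok = TRUE)
  stopifnot(is.data.frame(cohort), all(c("data", "truth") %in% names(cohort)))
  if ("PHH" %in% approaches && is.null(population)) {
    stop("the PHH approach needs a `population` prior", call. = FALSE)
  }
  if (!"source_id" %in% names(cohort)) cohort$source_id <- cohort$id

  # replicates of a source share the same sampled glucose: build each input
  # signal once
  signals <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cohort))) {
    sid <- cohort$source_id[i]
    if (is.null(signals[[sid]])) {
      signals[[sid]] <- build_glucose_signal(cohort$data[[i]], t_end = 300,
                                             noise_cv = control$glucose_cv)
    }
  }

  res <- purrr::map(seq_len(nrow(cohort)), function(i) {
    row <- cohort[i, ]
    tr <- row$truth[[1]]
    true_p <- c(k_d = tr$sec$k_d, alpha = tr$sec$alpha, beta = tr$sec$beta,
                k01 = tr$kin$k01, k12 = tr$kin$k12, k21 = tr$kin$k21)
    purrr::map(approaches, function(ap) {
      fit <- tryCatch(
        fit_subject(row$data[[1]], approach = ap,
                    age_years = row$age_years, bmi_kg_m2 = row$bmi_kg_m2,
                    error = error, population = population, control = control,
                    signal = signals[[row$source_id]]),
        error = function(e) NULL
      )
      if (is.null(fit) || !fit$converged) {
        return(tibble::tibble(id = row$id, source_id = row$source_id,
                              approach = ap, parameter = "FAILED",
                              estimate = NA_real_, truth = NA_real_,
                              ard_percent = NA_real_))
      }
      est <- c(fit$estimates[.param_names], phi_tot = fit$indices$phi_tot)
      tru <- c(true_p, phi_tot = tr$indices$phi_tot)
      tibble::tibble(
        id = row$id, source_id = row$source_id, approach = ap,
        parameter = names(est), estimate = unname(est), truth = unname(tru),
        ard_percent = 100 * abs(est - tru) / abs(tru)
      )
    }) |> dplyr::bind_rows()
  }) |> dplyr::bind_rows()

  failed <- dplyr::filter(res, .data$parameter == "FAILED")
  ok <- dplyr::filter(res, .data$parameter != "FAILED")

  scores <- ok |>
    dplyr::group_by(.data$id, .data$source_id, .data$approach) |>
    dplyr::summarise(
      mard_mcr = .data$ard_percent[.data$parameter == "k01"],
      mard_phi_tot = .data$ard_percent[.data$parameter == "phi_tot"],
      mard_pooled = mean(.data$ard_percent[.data$parameter %in% .param_names]),
      .groups = "drop"
    )

  qfmt <- function(x) {
    q <- stats::quantile(x, c(0.5, 0.25, 0.75), na.rm = TRUE)
    sprintf("%.1f [%.1f, %.1f]", q[1], q[2], q[3])
  }
  summary_tbl <- scores |>
    tidyr::pivot_longer(dplyr::starts_with("mard_"), names_to = "score",
                        values_to = "value") |>
    dplyr::group_by(.data$approach, .data$score) |>
    dplyr::summarise(median = stats::median(.data$value),
                     q25 = unname(stats::quantile(.data$value, 0.25)),
                     q75 = unname(stats::quantile(.data$value, 0.75)),
                     label = qfmt(.data$value), .groups = "drop")

  tests <- NULL
  if (length(approaches) > 1L) {
    tests <- purrr::map(
      c(mard_mcr = "mard_mcr", mard_phi_tot = "mard_phi_tot",
        mard_pooled = "mard_pooled"),
      function(sc) {
        kw <- stats::kruskal.test(scores[[sc]], factor(scores$approach))
        list(kruskal = kw,
             dunn_sidak = dunn_sidak(scores[[sc]], factor(scores$approach)))
      }
    )
  }

  structure(list(results = res, scores = scores, summary = summary_tbl,
                 tests = tests, n_failed = nrow(failed) / max(length(approaches), 1)),
            class = "ocmm_assessment")
}

#' Dunn's post-hoc test with Sidak correction
#'
#' Pairwise rank-based z-tests following a Kruskal-Wallis test, with
#' tie-corrected pooled variance and Sidak-adjusted p-values.
#'
#' @param x Numeric response.
#' @param g Grouping factor.
#' @return A tibble with one row per pair: `comparison`, `z`, `p_value`,
#'   `p_adjusted`.
#' @export
dunn_sidak <- function(x, g) {
  g <- factor(g)
  ok <- is.finite(x)
  x <- x[ok]; g <- droplevels(g[ok])
  N <- length(x)
  r <- rank(x)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  pairs <- utils::combn(levels(g), 2, simplify = FALSE)
  m <- length(pairs)
  purrr::map_dfr(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    tibble::tibble(comparison = paste(pr, collapse = " vs "),
                   z = z, p_value = p,
                   p_adjusted = min(1, 1 - (1 - p)^m))
  })
}

#' @export
print.ocmm_assessment <- function(x, ...) {
  cat("<ocmm_assessment>", nrow(x$scores), "fits scored;",
      x$n_failed, "failed\n")
  s <- dplyr::filter(x$summary, .data$score %in% c("mard_mcr", "mard_phi_tot"))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %s %-12s MARD %% = %s\n", s$approach[i], s$score[i], s$label[i]))
  }
  invisible(x)
}
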