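#' Measurement error model
#'
#' C-peptide measurement error is taken as independent, zero-mean Gaussian
#' with standard deviation proportional to the measured concentration
#' (constant coefficient of variation).
#'
#' @param cv Fractional coefficient of variation (> 0). Default 5%.
#' @return An object of class `error_model`.
#' @examples
#' error_model(0.05)
#' @export
error_model <- function(cv = 0.05) {
  stopifnot(is.numeric(cv), length(cv) == 1L, is.finite(cv), cv > 0)
  structure(list(cv = cv), class = "error_model")
}

#' Prior specifications for MAP identification
#'
#' Each model parameter gets exactly one prior entry: fixed to a value,
#' flat (noninformative), or log-normal specified by its median and
#' geometric coefficient of variation. The kinetic triplet `(k01, k12, k21)`
#' may instead share a joint log-normal with full covariance on the log
#' scale. Log-normal penalties are evaluated as Gaussians on the log
#' parameters, so a prior contributes zero at its own median.
#'
#' @param value Fixed parameter value (> 0).
#' @param median Prior median (> 0).
#' @param gcv Geometric coefficient of variation (> 0); the log-scale sd is
#'   `sqrt(log(1 + gcv^2))`.
#' @param mu Named 3-vector of log-scale means for `k01`, `k12`, `k21`.
#' @param Sigma 3x3 log-scale covariance matrix.
#' @return A prior entry (a tagged list) for use in the `priors` list of
#'   [neg_log_posterior()] and [fit_subject()].
#' @name priors
NULL

#' @rdname priors
#' @export
prior_fixed <- function(value) {
  stopifnot(is.finite(value), value > 0)
  list(type = "fixed", value = value)
}

#' @rdname priors
#' @export
prior_flat <- function() list(type = "flat")

#' @rdname priors
#' @export
prior_lognormal <- function(median, gcv) {
  stopifnot(is.finite(median), median > 0, is.finite(gcv), gcv > 0)
  list(type = "lognormal", meanlog = log(median), sdlog = sqrt(log(1 + gcv^2)))
}

#' @rdname priors
#' @export
prior_joint_lognormal <- function(mu, Sigma) {
  stopifnot(length(mu) == 3L, is.matrix(Sigma), all(dim(Sigma) == 3L))
  if (is.null(names(mu))) names(mu) <- c("k01", "k12", "k21")
  Sigma <- (Sigma + t(Sigma)) / 2
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= max(ev) * 1e-10 || min(ev) <= 0) {
    stop("joint prior covariance must be positive definite", call. = FALSE)
  }
  list(type = "joint", mu = mu[c("k01", "k12", "k21")], Sigma = Sigma,
       Omega = solve(Sigma))
}

.param_names <- c("k_d", "alpha", "beta", "k01", "k12", "k21")
.kin_names <- c("k01", "k12", "k21")

# penalty (negative log prior, constants dropped) at the full parameter vector
prior_penalty <- function(p, priors) {
  pen <- 0
  for (nm in setdiff(names(priors), "kinetics")) {
    pr <- priors[[nm]]
    if (pr$type == "lognormal") {
      pen <- pen + 0.5 * ((log(p[[nm]]) - pr$meanlog) / pr$sdlog)^2
    }
  }
  if (!is.null(priors$kinetics)) {
    pr <- priors$kinetics
    d <- log(unlist(p[.kin_names])) - pr$mu
    pen <- pen + 0.5 * drop(d %*% pr$Omega %*% d)
  }
  pen
}

free_params <- function(priors) {
  fixed <- names(priors)[vapply(priors, function(e) identical(e$type, "fixed"),
                                logical(1))]
  setdiff(.param_names, fixed)
}

#' Negative log-posterior of the minimal model
#'
#' The MAP objective: half the weighted residual sum of squares of the
#' C-peptide prediction plus the negative log prior density of the free
#' parameters (additive constants dropped; log-normal priors evaluated as
#' Gaussians in log-parameter space). Measurement standard deviations come
#' from the error model evaluated at the measured concentrations.
#'
#' @param p Named vector or list with elements `k_d`, `alpha`, `beta`,
#'   `k01`, `k12`, `k21`, all strictly positive.
#' @param data Samples: data frame with `time_min` and `cpeptide_pmol_L`
#'   (>= 6 rows, starting at 0).
#' @param signal A `glucose_signal`.
#' @param priors Named list of prior entries (see [priors]); parameters
#'   without an entry are treated as flat. An entry named `kinetics` may hold
#'   a joint log-normal for the kinetic triplet.
#' @param error An [error_model()].
#' @param cp_basal Basal C-peptide added to the prediction; defaults to the
#'   first sample.
#' @return The scalar objective value.
#' @export
neg_log_posterior <- function(p, data, signal, priors = list(),
                              error = error_model(), cp_basal = NULL) {
  p <- as.list(p)
  stopifnot(all(.param_names %in% names(p)))
  if (any(unlist(p[.param_names]) <= 0 & names(p[.param_names]) != "k_d")) {
    stop("parameters must be strictly positive", call. = FALSE)
  }
  stopifnot(nrow(data) >= 6L)
  y <- data$cpeptide_pmol_L
  if (is.null(cp_basal)) cp_basal <- y[1]
  kin <- kinetic_params(p$k01, p$k12, p$k21)
  sec <- secretion_params(p$k_d, p$alpha, p$beta, h = signal$G_b)
  yhat <- tryCatch(
    ocmm_predict_fast(kin, sec, signal, data$time_min, cp_basal = cp_basal,
                      h = 0.5),
    error = function(e) NULL
  )
  if (is.null(yhat) || any(!is.finite(yhat))) {
    warning("model solution failed; returning penalized objective")
    return(1e10)
  }
  sd_y <- error$cv * y
  0.5 * sum(((y - yhat) / sd_y)^2) + prior_penalty(p, priors)
}

#' Default priors for the three identification approaches
#'
#' * `VC`: the kinetic triplet is fixed to the Van Cauter population
#'   prediction; of the secretion parameters only `alpha` carries a (weakly
#'   informative) log-normal prior, stabilizing an otherwise poorly
#'   identified time constant.
#' * `DB`: all six parameters are estimated; the kinetic parameters get
#'   independent log-normal priors centred at the Van Cauter prediction.
#' * `PHH`: as `DB`, but the kinetic prior is a joint log-normal taken from
#'   an empirical cohort distribution ([fit_population()]).
#'
#' @param approach `"VC"`, `"DB"` or `"PHH"`.
#' @param age_years,bmi_kg_m2 Demographics for the Van Cauter prediction.
#' @param population A `kinetic_population` (required for `"PHH"`).
#' @param alpha_median,alpha_gcv Log-normal prior on `alpha` (median 1/min,
#'   geometric CV).
#' @param kinetic_gcv Geometric CV of the `DB` kinetic priors.
#' @return Named list of prior entries.
#' @export
default_priors <- function(approach, age_years, bmi_kg_m2,
                           population = NULL,
                           alpha_median = 0.05, alpha_gcv = 0.5,
                           kinetic_gcv = 0.3) {
  approach <- match.arg(approach, c("VC", "DB", "PHH"))
  kin <- vc_kinetics_one(age_years, classify_subject(bmi_kg_m2))
  pri <- list(alpha = prior_lognormal(alpha_median, alpha_gcv),
              k_d = prior_flat(), beta = prior_flat())
  if (approach == "VC") {
    pri$k01 <- prior_fixed(kin$k01)
    pri$k12 <- prior_fixed(kin$k12)
    pri$k21 <- prior_fixed(kin$k21)
  } else if (approach == "DB") {
    pri$k01 <- prior_lognormal(kin$k01, kinetic_gcv)
    pri$k12 <- prior_lognormal(kin$k12, kinetic_gcv)
    pri$k21 <- prior_lognormal(kin$k21, kinetic_gcv)
  } else {
    if (is.null(population)) {
      stop("the PHH approach needs a `population` kinetic prior", call. = FALSE)
    }
    pri$kinetics <- prior_joint_lognormal(population$mu, population$Sigma)
  }
  pri
}

#' Optimizer settings for [fit_subject()]
#'
#' @param n_starts Number of multi-start points (deterministic log-space
#'   offsets around the prior centre).
#' @param jitter Log-space half-width of the start offsets.
#' @param nm_maxit,nm_reltol Nelder-Mead budget and relative tolerance.
#' @param bfgs_maxit Quasi-Newton refinement budget (0 disables).
#' @param grid_step Uniform grid step of the fast forward solver, min.
#' @param glucose_cv Glucose measurement CV used when smoothing the input.
#' @return A list of class `fit_control`.
#' @export
fit_control <- function(n_starts = 3, jitter = 0.3, nm_maxit = 400,
                        nm_reltol = 1e-9, bfgs_maxit = 100,
                        grid_step = 1, glucose_cv = 0.02) {
  structure(list(n_starts = n_starts, jitter = jitter, nm_maxit = nm_maxit,
                 nm_reltol = nm_reltol, bfgs_maxit = bfgs_maxit,
                 grid_step = grid_step, glucose_cv = glucose_cv),
            class = "fit_control")
}

# deterministic multi-start offset directions in log space (rows recycled)
.start_directions <- rbind(
  0,
  c(1, 1, 1, 1, 1, 1),
  c(-1, -1, -1, -1, -1, -1),
  c(1, -1, 1, -1, 1, -1),
  c(-1, 1, -1, 1, -1, 1),
  c(1, 1, -1, -1, 1, 1),
  c(-1, -1, 1, 1, -1, -1)
)

#' Fit the minimal model to one subject's oral-test data
#'
#' Maximum-a-posteriori estimation of the secretion (and, depending on the
#' approach, kinetic) parameters from a single OGTT/MMTT record.
#' Optimization runs in log-parameter space from several deterministic
#' start points (Nelder-Mead, then quasi-Newton refinement); the best
#' optimum is returned together with per-parameter precision (CV%, from the
#' inverse posterior curvature mapped through the log parameterization),
#' the fitted trajectory, and the responsivity indices.
#'
#' The glucose threshold `h` is fixed to basal glucose (first sample) and
#' basal C-peptide is the first C-peptide sample; the model is fitted to
#' total C-peptide with basal added to the above-basal prediction.
#'
#' @param data Data frame with columns `time_min`, `glucose_mmol_L`,
#'   `cpeptide_pmol_L`; >= 6 rows, first row at time 0.
#' @param approach `"VC"`, `"DB"` or `"PHH"`.
#' @param age_years,bmi_kg_m2 Demographics for the Van Cauter prediction.
#' @param error An [error_model()].
#' @param population A `kinetic_population` prior (PHH approach).
#' @param priors Optional full prior list overriding [default_priors()].
#' @param control A [fit_control()].
#' @param signal Optional pre-built `glucose_signal` (otherwise built from
#'   `data`).
#' @return An object of class `ocmm_fit`; see [tidy.ocmm_fit()],
#'   [glance.ocmm_fit()], [autoplot.ocmm_fit()].
#' @examples
#' \donttest{
#' cohort <- generate_cohort(cohort_spec(n_subjects = 1, seed = 7))
#' fit <- fit_subject(cohort$data[[1]], approach = "DB",
#'                    age_years = cohort$age_years[1],
#'                    bmi_kg_m2 = cohort$bmi_kg_m2[1])
#' tidy(fit)
#' }
#' @export
fit_subject <- function(data, approach = c("VC", "DB", "PHH"),
                        age_years, bmi_kg_m2,
                        error = error_model(),
                        population = NULL, priors = NULL,
                        control = fit_control(), signal = NULL) {
  approach <- match.arg(approach)
  stopifnot(is.data.frame(data),
            all(c("time_min", "cpeptide_pmol_L") %in% names(data)),
            nrow(data) >= 6L)
  if (is.null(signal)) {
    signal <- build_glucose_signal(data, t_end = 300,
                                   noise_cv = control$glucose_cv)
  }
  if (is.null(priors)) {
    priors <- default_priors(approach, age_years, bmi_kg_m2,
                             population = population)
  }
  free <- free_params(priors)
  fixed <- lapply(priors[setdiff(.param_names, free)], `[[`, "value")

  times <- data$time_min
  y <- data$cpeptide_pmol_L
  cp_basal <- y[1]
  sd_y <- error$cv * y
  h <- control$grid_step
  grid <- seq(0, max(times), by = h)
  if (grid[length(grid)] < max(times)) grid <- c(grid, max(times))
  Gv <- signal$G(grid)
  dGv <- signal$dG(grid)
  # linear-interpolation stencil from grid to sample times
  ii <- pmin(findInterval(times, grid), length(grid) - 1L)
  ww <- (times - grid[ii]) / (grid[ii + 1L] - grid[ii])

  predict_at <- function(p) {
    kin <- list(k01 = p[["k01"]], k12 = p[["k12"]], k21 = p[["k21"]])
    sec <- list(k_d = p[["k_d"]], alpha = p[["alpha"]], beta = p[["beta"]],
                h = signal$G_b)
    cp1 <- ocmm_cp1_grid(kin, sec, Gv, dGv, h)
    cp_basal + (1 - ww) * cp1[ii] + ww * cp1[ii + 1L]
  }
  objective <- function(logp) {
    p <- c(as.list(exp(logp)), fixed)
    yhat <- predict_at(p)
    if (any(!is.finite(yhat))) return(1e10)
    val <- 0.5 * sum(((y - yhat) / sd_y)^2) + prior_penalty(p, priors)
    if (!is.finite(val)) 1e10 else val
  }

  start <- log(start_values(priors, free, data, signal))
  n_starts <- max(1L, control$n_starts)
  dirs <- .start_directions[((seq_len(n_starts) - 1L) %% nrow(.start_directions)) + 1L, ,
                            drop = FALSE]
  best <- NULL
  start_obj <- numeric(n_starts)
  for (s in seq_len(n_starts)) {
    s0 <- start + control$jitter * dirs[s, seq_along(free)]
    names(s0) <- free
    opt <- stats::optim(s0, objective, method = "Nelder-Mead",
                        control = list(maxit = control$nm_maxit,
                                       reltol = control$nm_reltol))
    start_obj[s] <- opt$value
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # quasi-Newton polish from the best simplex optimum only
  if (control$bfgs_maxit > 0) {
    ref <- tryCatch(
      stats::optim(best$par, objective, method = "BFGS",
                   control = list(maxit = control$bfgs_maxit)),
      error = function(e) best
    )
    if (ref$value <= best$value) best <- ref
  }
  converged <- best$value < 1e9
  if (!converged) {
    warning("no start converged to a finite optimum; result flagged")
  }

  logp_hat <- best$par
  est <- c(as.list(exp(logp_hat)), fixed)[.param_names]
  hess <- tryCatch(stats::optimHess(logp_hat, objective), error = function(e) NULL)
  cv <- cv_from_hessian(hess, free)

  p_hat <- est
  yhat <- predict_at(p_hat)
  kin_hat <- kinetic_params(p_hat$k01, p_hat$k12, p_hat$k21)
  sec_hat <- secretion_params(p_hat$k_d, p_hat$alpha, p_hat$beta, signal$G_b)
  idx <- responsivity_indices(kin_hat, sec_hat, signal, cp1_basal = cp_basal,
                              t_end = signal$t_end)

  structure(
    list(
      estimates = unlist(est),
      free = free,
      cv_percent = cv,
      objective = best$value,
      converged = converged,
      start_objectives = start_obj,
      prediction = tibble::tibble(time_min = times,
                                  cpeptide_pmol_L = y,
                                  .fitted = yhat,
                                  .resid = y - yhat),
      indices = idx,
      approach = approach,
      priors = priors,
      error = error,
      cp_basal = cp_basal,
      signal = signal,
      logp_hessian = hess,
      demographics = c(age_years = age_years, bmi_kg_m2 = bmi_kg_m2)
    ),
    class = "ocmm_fit"
  )
}

# data-informed starting values at the prior centres where available
start_values <- function(priors, free, data, signal) {
  y0 <- data$cpeptide_pmol_L - data$cpeptide_pmol_L[1]
  tr <- function(x, y) sum(diff(x) * (y[-1] + y[-length(y)])) / 2
  grid <- seq(0, max(data$time_min), by = 1)
  gex <- pmax(signal$G(grid) - signal$G_b, 0)
  centre <- function(nm, fallback) {
    pr <- priors[[nm]]
    if (!is.null(pr) && pr$type == "lognormal") return(exp(pr$meanlog))
    if (!is.null(priors$kinetics) && nm %in% .kin_names) {
      return(exp(priors$kinetics$mu[[nm]]))
    }
    fallback
  }
  k01_0 <- centre("k01", 0.06)
  s_tot <- max(k01_0 * tr(data$time_min, pmax(y0, 0)), 1)
  out <- c(
    k_d = centre("k_d", max(0.5 * s_tot / max(signal$G_max - signal$G_b, 0.5), 1)),
    alpha = centre("alpha", 0.05),
    beta = centre("beta", max(0.5 * s_tot / max(tr(grid, gex), 10), 0.5)),
    k01 = k01_0, k12 = centre("k12", 0.05), k21 = centre("k21", 0.05)
  )
  out[free]
}

cv_from_hessian <- function(hess, free) {
  cv <- rep(NA_real_, length(free))
  names(cv) <- free
  if (!is.null(hess)) {
    cov_log <- tryCatch(solve(hess), error = function(e) NULL)
    if (!is.null(cov_log)) {
      d <- diag(cov_log)
      ok <- is.finite(d) & d > 0
      # delta method through the log parameterization: sd(x)/x = sd(log x)
      cv[ok] <- 100 * sqrt(d[ok])
    }
  }
  cv
}

#' Parameter precision of a converged fit
#'
#' Coefficients of variation of the estimated (non-fixed) parameters, from
#' the inverse curvature of the negative log-posterior at the optimum
#' (likelihood plus prior information), mapped through the log
#' parameterization: `CV% = 100 * sd(log p)`.
#'
#' @param fit An `ocmm_fit`.
#' @return A tibble with columns `term` and `cv_percent` (NA where the
#'   information matrix is singular).
#' @export
parameter_precision <- function(fit) {
  stopifnot(inherits(fit, "ocmm_fit"))
  tibble::tibble(term = fit$free,
                 cv_percent = unname(fit$cv_percent[fit$free]))
}

#' @export
print.ocmm_fit <- function(x, ...) {
  cat(sprintf("<ocmm_fit> %s approach; objective %.3f%s\n", x$approach,
              x$objective, if (x$converged) "" else " (NOT converged)"))
  est <- x$estimates
  cat(sprintf("  MCR (k01) = %.4f min^-1; phi_tot = %.1f x1e-9 min^-1\n",
              est[["k01"]], x$indices$phi_tot))
  invisible(x)
}
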