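# analytic input signals and an independent linear-ODE oracle shared by tests

constant_signal <- function(g_b = 5, t_end = 300) {
  new_glucose_signal(function(t) rep(g_b, length(t)),
                     function(t) rep(0, length(t)),
                     G_b = g_b, G_max = g_b, t_end = t_end)
}

# smooth post-bypass-like excursion with closed-form derivative; kernels are
# zeroed at t = 0 so G(0) equals the stated basal exactly
bump_signal <- function(g_b = 5.2, t_end = 300) {
  c1 <- exp(-(35 / 25)^2)
  c2 <- exp(-(135 / 55)^2)
  G <- function(t) {
    g_b + 4.3 * (exp(-((t - 35) / 25)^2) - c1) -
      2 * (exp(-((t - 135) / 55)^2) - c2)
  }
  dG <- function(t) {
    4.3 * exp(-((t - 35) / 25)^2) * (-2 * (t - 35) / 25^2) -
      2 * exp(-((t - 135) / 55)^2) * (-2 * (t - 135) / 55^2)
  }
  new_glucose_signal(G, dG, G_b = g_b, G_max = max(G(seq(0, 300, 0.5))),
                     t_end = t_end)
}

# wraps a piecewise-constant secretion rate as a "glucose" signal whose
# derivative equals the desired SR, so the forward model is driven directly
# (k_d = 1, beta = 0 turn off the provision pathway)
sr_forcing_signal <- function(breaks, levels, t_end) {
  stopifnot(length(levels) == length(breaks) - 1L, all(levels >= 0))
  dG <- function(t) {
    i <- pmin(pmax(findInterval(t, breaks, rightmost.closed = TRUE), 1L),
              length(levels))
    levels[i]
  }
  new_glucose_signal(function(t) rep(5, length(t)), dG,
                     G_b = 5, G_max = 5, t_end = t_end)
}

passthrough_secretion <- function() secretion_params(k_d = 1, alpha = 1e-4, beta = 0, h = 5)

# closed-form solution of the two-compartment system under piecewise-constant
# secretion, via the matrix exponential (independent of the package solver)
matexp_cp1 <- function(kin, breaks, levels, t_eval) {
  A <- matrix(c(-(kin$k01 + kin$k21), kin$k21,
                kin$k12, -kin$k12), 2, 2)
  step <- function(x0, b, dt) {
    E <- as.matrix(Matrix::expm(A * dt))
    drop(E %*% x0 + solve(A, (E - diag(2)) %*% c(b, 0)))
  }
  sol_at <- function(t) {
    x <- c(0, 0)
    t0 <- breaks[1]
    for (j in seq_along(levels)) {
      t1 <- min(breaks[j + 1L], t)
      if (t1 > t0) x <- step(x, levels[j], t1 - t0)
      t0 <- t1
      if (t0 >= t) break
    }
    x[1]
  }
  vapply(t_eval, sol_at, numeric(1))
}

# ogtt/mmtt schedules used across tests
ogtt_times <- c(0, 15, 30, 45, 60, 90, 120, 150, 180, 210)
mmtt_times <- seq(0, 180, 30)

vc_ref_kin <- function() kinetic_params(0.0569, 0.0486, 0.0543)

# paired OGTT+MMTT source cohort matching the two study arms' demographics
two_arm_cohort <- function(seed, ...) {
  co1 <- generate_cohort(cohort_spec(n_subjects = 12, test_type = "OGTT",
                                     seed = seed, ...))
  co2 <- generate_cohort(cohort_spec(n_subjects = 10, test_type = "MMTT",
                                     age_mean = 43, age_sd = 11,
                                     bmi_mean = 27.5, bmi_sd = 4.2,
                                     seed = seed + 1L, ...))
  co2$id <- sub("^S", "M", co2$id)
  dplyr::bind_rows(co1, co2)
}
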