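#' C-peptide kinetic parameters
#'
#' Constructor and validator for the rate constants of the linear
#' two-compartment model of C-peptide kinetics. `k01` is the fractional
#' clearance of the central (accessible) compartment and is reported in the
#' clinical literature as the C-peptide metabolic clearance rate (MCR);
#' `k21` and `k12` are the central-to-peripheral and peripheral-to-central
#' exchange rates.
#'
#' @param k01,k12,k21 Rate constants, 1/min. All must be finite and strictly
#'   positive.
#' @return An object of class `kinetic_params`: a named list with elements
#'   `k01`, `k12`, `k21`.
#' @examples
#' kinetic_params(0.0569, 0.0486, 0.0543)
#' @export
kinetic_params <- function(k01, k12, k21) {
  for (nm in c("k01", "k12", "k21")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("`", nm, "` must be a single finite number", call. = FALSE)
    }
    if (v <= 0) stop("`", nm, "` must be strictly positive", call. = FALSE)
  }
  structure(list(k01 = k01, k12 = k12, k21 = k21), class = "kinetic_params")
}

#' @export
print.kinetic_params <- function(x, ...) {
  cat(sprintf(
    "<kinetic_params> k01 (MCR) = %.4f, k12 = %.4f, k21 = %.4f min^-1\n",
    x$k01, x$k12, x$k21
  ))
  invisible(x)
}

#' Glucose-controlled secretion parameters
#'
#' Parameters of the secretion half of the oral C-peptide minimal model.
#' Above-basal secretion is the sum of a static component -- the provision
#' `Y(t)` relaxing with rate `alpha` towards `beta * (G - h)` -- and a dynamic
#' component `k_d * dG/dt` active only while glucose is rising.
#'
#' Units follow the project-wide convention (glucose mmol/L, C-peptide pmol/L,
#' time min), under which `beta` and `k_d` are numerically equal to the static
#' and dynamic responsivity indices on their conventional `1e-9` display scale
#' (pmol/L per mmol/L = 1e-9).
#'
#' @param k_d Dynamic responsivity (>= 0), dimensionless on the pmol-per-mmol
#'   scale.
#' @param alpha Inverse time constant of provision, 1/min (> 0).
#' @param beta Static responsivity, 1/min on the pmol-per-mmol scale (>= 0).
#' @param h Glucose threshold of the static component, mmol/L (> 0). By
#'   convention fixed to the pre-test basal glucose.
#' @return An object of class `secretion_params`.
#' @examples
#' secretion_params(k_d = 500, alpha = 0.03, beta = 12, h = 5.1)
#' @export
secretion_params <- function(k_d, alpha, beta, h) {
  vals <- c(k_d = k_d, alpha = alpha, beta = beta, h = h)
  if (!all(is.finite(vals))) stop("secretion parameters must be finite", call. = FALSE)
  if (k_d < 0) stop("`k_d` must be >= 0", call. = FALSE)
  if (alpha <= 0) stop("`alpha` must be > 0", call. = FALSE)
  if (beta < 0) stop("`beta` must be >= 0", call. = FALSE)
  if (h <= 0) stop("`h` must be > 0", call. = FALSE)
  structure(list(k_d = k_d, alpha = alpha, beta = beta, h = h),
            class = "secretion_params")
}

#' @export
print.secretion_params <- function(x, ...) {
  cat(sprintf(
    "<secretion_params> k_d = %.3g, alpha = %.4f min^-1, beta = %.3g min^-1, h = %.2f mmol/L\n",
    x$k_d, x$alpha, x$beta, x$h
  ))
  invisible(x)
}

as_kinetic_params <- function(x) {
  if (inherits(x, "kinetic_params")) return(x)
  if (is.numeric(x) && length(x) == 3L && !is.null(names(x))) {
    return(kinetic_params(x[["k01"]], x[["k12"]], x[["k21"]]))
  }
  if (is.list(x) && all(c("k01", "k12", "k21") %in% names(x))) {
    return(kinetic_params(x$k01, x$k12, x$k21))
  }
  stop("cannot interpret `x` as kinetic parameters", call. = FALSE)
}

as_secretion_params <- function(x) {
  if (inherits(x, "secretion_params")) return(x)
  if (is.list(x) && all(c("k_d", "alpha", "beta", "h") %in% names(x))) {
    return(secretion_params(x$k_d, x$alpha, x$beta, x$h))
  }
  stop("cannot interpret `x` as secretion parameters", call. = FALSE)
}
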