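#' Kinetic parameters of a homogeneous tissue
#'
#' Rate constants of the leucine model for one kinetically uniform tissue:
#' `K1` (plasma-to-tissue transport, mL/g/min), the lumped `k2k3` (efflux plus
#' the first two catabolic steps, 1/min), `k4` (incorporation into protein,
#' 1/min) and the blood volume fraction `Vb`.  The lumped turnover rate is
#' `beta = k2k3 + k4`.
#'
#' @param K1,k2k3,k4 non-negative rate constants (units above).
#' @param Vb blood volume fraction in `[0, 1]`.
#' @return An object of class `homogeneous_params`.
#' @export
#' @examples
#' h <- homogeneous_params(0.05, 0.1, 0.04, 0.05)
#' lambda_from_rates(h$k2k3, h$k4)
homogeneous_params <- function(K1, k2k3, k4, Vb = 0.05) {
  vals <- c(K1 = K1, k2k3 = k2k3, k4 = k4, Vb = Vb)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("all kinetic parameters must be finite and non-negative")
  if (Vb > 1) stop("'Vb' must lie in [0, 1]")
  structure(list(K1 = K1, k2k3 = k2k3, k4 = k4, Vb = Vb, beta = k2k3 + k4),
            class = "homogeneous_params")
}

#' Mixture of kinetically homogeneous subregions
#'
#' A heterogeneous voxel or region modelled as `n` homogeneous subregions
#' with fractional weights summing to 1 and a single shared blood volume
#' fraction.  With `n = 1` the mixture reduces exactly to the homogeneous
#' model.
#'
#' @param subregions list of [homogeneous_params()] (their individual `Vb`
#'   values are ignored; the mixture's `Vb` applies).
#' @param weights non-negative fractional weights, summing to 1.
#' @param Vb shared blood volume fraction.
#' @return An object of class `subregion_mixture`.
#' @export
subregion_mixture <- function(subregions, weights, Vb = 0.05) {
  if (!is.list(subregions) || length(subregions) < 1L ||
      !all(vapply(subregions, inherits, TRUE, "homogeneous_params")))
    stop("'subregions' must be a non-empty list of homogeneous_params")
  if (length(weights) != length(subregions))
    stop("one weight per subregion required")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (abs(sum(weights) - 1) > 1e-9) stop("weights must sum to 1")
  if (Vb < 0 || Vb > 1) stop("'Vb' must lie in [0, 1]")
  structure(list(subregions = subregions, weights = as.numeric(weights),
                 Vb = Vb, n = length(subregions)),
            class = "subregion_mixture")
}

#' Precursor-pool fraction lambda from rate constants
#'
#' `lambda = (k2 + k3) / (k2 + k3 + k4)`: the fraction of the tissue precursor
#' leucine pool derived from arterial plasma (the remainder comes from
#' proteolysis).
#'
#' @param k2k3 lumped efflux-plus-catabolism rate constant, 1/min.
#' @param k4 protein-incorporation rate constant, 1/min.
#' @return lambda in `[0, 1]`.  Vectorized.
#' @export
lambda_from_rates <- function(k2k3, k4) {
  if (any(k2k3 < 0) || any(k4 < 0)) stop("rates must be non-negative")
  if (any(k2k3 + k4 == 0)) stop("lambda is undefined when k2+k3 and k4 are both zero")
  k2k3 / (k2k3 + k4)
}

#' Regional rate of cerebral protein synthesis from rate constants
#'
#' `rCPS = K1 * k4 / (k2 + k3) * Cp`, in nmol/g/min; algebraically equal to
#' `K1 * (1 - lambda) / lambda * Cp`.
#'
#' @param K1 transport rate constant, mL/g/min.
#' @param k2k3 lumped efflux-plus-catabolism rate constant, 1/min; must be
#'   positive (a pure trap has no identifiable precursor turnover).
#' @param k4 protein-incorporation rate constant, 1/min.
#' @param cp unlabeled plasma leucine concentration, nmol/mL.
#' @return rCPS in nmol/g/min.  Vectorized.
#' @export
rcps_from_rates <- function(K1, k2k3, k4, cp) {
  if (any(K1 < 0) || any(k2k3 < 0) || any(k4 < 0) || any(cp < 0))
    stop("all inputs must be non-negative")
  if (any(k2k3 == 0))
    stop("degenerate kinetics: k2+k3 = 0 (pure trapping) leaves rCPS undefined")
  K1 * k4 / k2k3 * cp
}

# Convolution of cp with exp(-beta t) on the input's fine grid.  Piecewise
# analytic: exact for piecewise-linear cp, stable for large beta (no
# stiffness).  beta = 0 gives the running integral.  Uniform grids use a
# recursive filter; non-uniform grids fall back to a loop.
conv_exp <- function(time, cp, beta) {
  n <- length(time)
  h <- diff(time)
  if (beta == 0)
    return(c(0, cumsum((cp[-n] + cp[-1]) / 2 * h)))
  a <- cp[-n]
  b <- (cp[-1] - cp[-n]) / h
  uniform <- diff(range(h)) < 1e-12 * h[1]
  if (uniform) {
    hh <- h[1]
    E <- exp(-beta * hh)
    w <- (1 - E) / beta
    g <- a * w + b * (hh - w) / beta
    c(0, stats::filter(g, E, method = "recursive"))
  } else {
    E <- exp(-beta * h)
    w <- (1 - E) / beta
    g <- a * w + b * (h - w) / beta
    out <- numeric(n)
    for (k in seq_len(n - 1L)) out[k + 1L] <- E[k] * out[k] + g[k]
    out
  }
}

# Frame means of a fine-grid curve: (C(end) - C(start)) / dur with C the
# cumulative trapezoidal integral, interpolated at frame boundaries.
frame_average <- function(time, curve, schedule) {
  if (schedule$end[schedule$n] > max(time) + 1e-9)
    stop("frame schedule extends beyond the input time grid")
  n <- length(time)
  C <- c(0, cumsum((curve[-n] + curve[-1]) / 2 * diff(time)))
  Cs <- stats::approx(time, C, schedule$start)$y
  Ce <- stats::approx(time, C, schedule$end)$y
  (Ce - Cs) / schedule$dur
}

#' Tissue time-activity curve
#'
#' One frame-averaged, decay-corrected activity value per frame of a
#' [frame_schedule()].
#'
#' @param schedule a [frame_schedule()].
#' @param values numeric vector, one value per frame.
#' @return An object of class `tissue_tac`.
#' @export
tissue_tac <- function(schedule, values) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (length(values) != schedule$n)
    stop("'values' must have one entry per frame")
  structure(list(schedule = schedule, values = as.numeric(values)),
            class = "tissue_tac")
}

#' @export
print.tissue_tac <- function(x, ...) {
  cat(sprintf("Tissue TAC: %d frames, range [%.4g, %.4g]\n",
              x$schedule$n, min(x$values), max(x$values)))
  invisible(x)
}

#' Read / write a tissue TAC as delimited text
#'
#' Two columns: frame mid-time in seconds (`mid_s`) and the frame value
#' (`value`).  Reading requires the matching schedule.
#'
#' @param tac a [tissue_tac()].
#' @param path file path.
#' @param schedule the [frame_schedule()] the stored values refer to.
#' @return `read_tac` returns a [tissue_tac()]; `write_tac` returns `path`
#'   invisibly.
#' @export
write_tac <- function(tac, path) {
  stopifnot(inherits(tac, "tissue_tac"))
  utils::write.table(
    data.frame(mid_s = tac$schedule$mid * 60, value = tac$values),
    path, row.names = FALSE, quote = FALSE, sep = "\t"
  )
  invisible(path)
}

#' @rdname write_tac
#' @export
read_tac <- function(path, schedule) {
  tab <- utils::read.table(path, header = TRUE)
  if (!all(c("mid_s", "value") %in% names(tab)))
    stop("TAC table must have columns mid_s, value")
  if (nrow(tab) != schedule$n)
    stop("TAC table does not match the schedule's number of frames")
  if (max(abs(tab$mid_s / 60 - schedule$mid)) > 1e-6)
    stop("TAC frame mid-times do not match the schedule")
  tissue_tac(schedule, tab$value)
}

#' Basis curve: exponential convolution of the plasma input
#'
#' The frame-averaged convolution `integral_0^t Cp*(tau) exp(-beta (t - tau))
#' dtau`, the building block of both the forward models and the estimator
#' dictionaries.  `beta = 0` yields the running integral of `Cp*` (the
#' irreversible trapping column).
#'
#' @param beta rate constant, 1/min, >= 0.
#' @param input an [input_function_set()].
#' @param schedule a [frame_schedule()].
#' @return A [tissue_tac()] in units of `cp_star * min`.
#' @export
basis_curve <- function(beta, input, schedule) {
  stopifnot(inherits(input, "input_function_set"),
            inherits(schedule, "frame_schedule"), beta >= 0)
  conv <- conv_exp(input$time, input$cp_star, beta)
  tissue_tac(schedule, frame_average(input$time, conv, schedule))
}

# Blood contribution Vb*(Cb* - VD*Cc*) + VD*Cc* on the fine grid.
blood_curve <- function(input, Vb, VD) {
  Vb * (input$cb_star - VD * input$cc_star) + VD * input$cc_star
}

#' Forward model: homogeneous tissue TAC
#'
#' Total 11C activity for a kinetically homogeneous tissue:
#' \deqn{C_T^*(t) = (1-V_b)\frac{K_1 k_4}{\beta}\int_0^t C_p^* d\tau
#'   + (1-V_b)\frac{K_1(k_2+k_3)}{\beta}\int_0^t C_p^* e^{-\beta(t-\tau)} d\tau
#'   + V_b[C_b^* - V_D C_c^*] + V_D C_c^*}
#' with `beta = k2 + k3 + k4`, evaluated on the input's fine grid and averaged
#' within each frame.  With `cc_star = 0` (simulation mode) the blood term
#' reduces to `Vb * Cb*`.
#'
#' @param params a [homogeneous_params()].
#' @param input an [input_function_set()].
#' @param schedule a [frame_schedule()].
#' @param VD blood:brain equilibrium distribution volume of 11CO2 (fixed at
#'   0.41 in leucine studies).
#' @return A [tissue_tac()].
#' @export
#' @examples
#' inp <- make_input_functions(t_end = 91)
#' fs <- default_frame_schedule()
#' tac <- homogeneous_tac(homogeneous_params(0.05, 0.1, 0.04), inp, fs)
homogeneous_tac <- function(params, input, schedule, VD = 0.41) {
  stopifnot(inherits(params, "homogeneous_params"))
  heterogeneous_tac(subregion_mixture(list(params), 1, Vb = params$Vb),
                    input, schedule, VD = VD)
}

#' Forward model: heterogeneous tissue TAC
#'
#' Weighted sum of the tissue activities of `n` homogeneous subregions plus a
#' single shared blood term: the spectral form with trapping amplitude
#' `theta0`, equilibrating amplitudes `theta_i` at rates `beta_i`, and blood
#' coefficient `Vb` (see [spectrum_from_mixture()]).
#'
#' @param mix a [subregion_mixture()].
#' @inheritParams homogeneous_tac
#' @return A [tissue_tac()].
#' @export
heterogeneous_tac <- function(mix, input, schedule, VD = 0.41) {
  stopifnot(inherits(mix, "subregion_mixture"),
            inherits(input, "input_function_set"),
            inherits(schedule, "frame_schedule"))
  spec <- spectrum_from_mixture(mix)
  ct <- spec$theta0 * conv_exp(input$time, input$cp_star, 0)
  for (i in seq_along(spec$thetas))
    ct <- ct + spec$thetas[i] * conv_exp(input$time, input$cp_star,
                                         spec$betas[i])
  ct <- ct + blood_curve(input, mix$Vb, VD)
  tissue_tac(schedule, frame_average(input$time, ct, schedule))
}

#' Spectral representation of a tissue
#'
#' Amplitudes and rate constants of the spectral form of the heterogeneous
#' model: trapping amplitude `theta0 = (1-Vb) sum_i w_i K1i k4i / beta_i`,
#' equilibrating amplitudes `theta_i = (1-Vb) w_i K1i (k2i+k3i) / beta_i` at
#' rates `beta_i = k2i + k3i + k4i`.
#'
#' @param theta0 trapping amplitude, >= 0.
#' @param thetas equilibrating amplitudes, >= 0 (may be empty).
#' @param betas rate constants matching `thetas`, 1/min, > 0.
#' @param Vb blood volume fraction in `[0, 1]` (must be < 1 to recover macro
#'   parameters).
#' @param VD blood:brain 11CO2 distribution volume (default 0.41).
#' @return An object of class `spectral_representation`.
#' @export
spectral_representation <- function(theta0, thetas = numeric(), betas = numeric(),
                                    Vb = 0.05, VD = 0.41) {
  if (theta0 < 0 || any(thetas < 0)) stop("spectral amplitudes must be >= 0")
  if (length(thetas) != length(betas)) stop("'thetas' and 'betas' lengths differ")
  if (any(betas <= 0)) stop("equilibrating rate constants must be positive")
  if (Vb < 0 || Vb > 1) stop("'Vb' must lie in [0, 1]")
  structure(list(theta0 = theta0, thetas = as.numeric(thetas),
                 betas = as.numeric(betas), Vb = Vb, VD = VD),
            class = "spectral_representation")
}

#' @describeIn spectral_representation Spectral representation of a
#'   [subregion_mixture()] via the theta definitions.
#' @param mix a [subregion_mixture()].
#' @export
spectrum_from_mixture <- function(mix) {
  stopifnot(inherits(mix, "subregion_mixture"))
  K1 <- vapply(mix$subregions, `[[`, 0, "K1")
  k2k3 <- vapply(mix$subregions, `[[`, 0, "k2k3")
  k4 <- vapply(mix$subregions, `[[`, 0, "k4")
  beta <- k2k3 + k4
  if (any(beta == 0))
    stop("subregions with k2+k3+k4 = 0 have no spectral representation")
  w <- mix$weights
  spectral_representation(
    theta0 = (1 - mix$Vb) * sum(w * K1 * k4 / beta),
    thetas = (1 - mix$Vb) * w * K1 * k2k3 / beta,
    betas = beta, Vb = mix$Vb
  )
}

#' Macro parameters from a spectral representation
#'
#' Recovers the weighted-average influx rate constant
#' `K1 = (theta0 + sum(theta_i)) / (1 - Vb)`, the precursor fraction
#' `lambda = sum(theta_i) / (theta0 + sum(theta_i))` (assuming lambda is
#' common across subregions) and `rCPS = K1 (1-lambda)/lambda * Cp`.
#'
#' With no equilibrating mass (`sum(theta_i) = 0`) lambda is 0 and the fit is
#' flagged degenerate; rCPS then falls back to the net-uptake form
#' `theta0 / (1 - Vb) * Cp`.  `theta0 = 0` gives `lambda = 1`, `rCPS = 0`.
#'
#' @param spec a [spectral_representation()].
#' @param cp unlabeled plasma leucine, nmol/mL.
#' @return A list with `K1`, `lambda`, `rcps` and logical `degenerate`.
#' @export
macros_from_spectrum <- function(spec, cp) {
  stopifnot(inherits(spec, "spectral_representation"), cp >= 0)
  if (spec$Vb >= 1)
    stop("macro parameters are undefined for Vb >= 1 (no tissue fraction)")
  tot <- spec$theta0 + sum(spec$thetas)
  if (tot == 0)
    return(list(K1 = 0, lambda = 0, rcps = 0, degenerate = TRUE))
  K1 <- tot / (1 - spec$Vb)
  lambda <- sum(spec$thetas) / tot
  if (lambda == 0) {
    # pure trap: rCPS from the net uptake constant
    return(list(K1 = K1, lambda = 0,
                rcps = spec$theta0 / (1 - spec$Vb) * cp, degenerate = TRUE))
  }
  list(K1 = K1, lambda = lambda, rcps = K1 * (1 - lambda) / lambda * cp,
       degenerate = FALSE)
}
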