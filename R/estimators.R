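#' Logarithmic beta grid
#'
#' The grid of candidate turnover rates `beta = k2 + k3 + k4` shared by both
#' estimators: `n` values logarithmically spaced over `range`, endpoints
#' exact.  Defaults to the standard 100 values on [0.0037, 1.33] 1/min.
#'
#' @param n number of grid points.
#' @param range lower and upper grid endpoints, 1/min.
#' @return Numeric vector of class `beta_grid`, strictly increasing with a
#'   constant ratio between consecutive values.
#' @export
#' @examples
#' g <- beta_grid()
#' g[1]; g[100]          # 0.0037, 1.33
beta_grid <- function(n = 100, range = c(0.0037, 1.33)) {
  stopifnot(n >= 2, length(range) == 2, range[1] > 0, range[2] > range[1])
  g <- exp(seq(log(range[1]), log(range[2]), length.out = n))
  g[1] <- range[1]
  g[n] <- range[2]
  structure(g, class = "beta_grid")
}

#' Frame weights from the noise variance model
#'
#' Weights proportional to the inverse of the frame noise variance
#' `alpha * exp(gamma t_i) * CT_i / dt_i`:
#' `w_i = dt_i * exp(-gamma t_i) / max(CT_i, floor)`, normalized to mean 1
#' (`alpha` cancels in weighted least squares).  The positivity floor,
#' `floor_frac` times the TAC maximum, keeps weights finite for small or
#' negative observed frame values.
#'
#' @param tac a [tissue_tac()] (typically the observed, noisy TAC).
#' @param gamma decay constant, 1/min.
#' @param floor_frac positivity floor as a fraction of the TAC maximum.
#' @return Numeric vector of per-frame weights (mean 1).
#' @export
weights_from_variance <- function(tac, gamma = log(2) / 20.34,
                                  floor_frac = 0.01) {
  stopifnot(inherits(tac, "tissue_tac"))
  s <- tac$schedule
  mx <- max(tac$values)
  if (mx <= 0) return(rep(1, s$n))
  w <- s$dur * exp(-gamma * s$mid) / pmax(tac$values, floor_frac * mx)
  w / mean(w)
}

#' Precomputed estimator dictionary
#'
#' The frame-averaged model columns shared by every fit against one
#' (input, schedule, grid) combination: the trapping column (running integral
#' of `Cp*`), one exponential-convolution basis column per grid `beta`, the
#' blood column `Cb* - VD Cc*`, and the known additive term `VD Cc*` (zero in
#' simulation mode).  Building the dictionary once and passing it to
#' [bfm_fit()] / [saif_fit()] avoids recomputing convolutions per voxel.
#'
#' @param input an [input_function_set()].
#' @param schedule a [frame_schedule()].
#' @param grid a [beta_grid()].
#' @param VD blood:brain 11CO2 distribution volume.
#' @return An object of class `kinetic_dictionary`.
#' @export
kinetic_dictionary <- function(input, schedule, grid = beta_grid(),
                               VD = 0.41) {
  stopifnot(inherits(input, "input_function_set"),
            inherits(schedule, "frame_schedule"))
  tm <- input$time
  trap <- frame_average(tm, conv_exp(tm, input$cp_star, 0), schedule)
  B <- vapply(as.numeric(grid), function(b)
    frame_average(tm, conv_exp(tm, input$cp_star, b), schedule),
    numeric(schedule$n))
  blood <- frame_average(tm, input$cb_star - VD * input$cc_star, schedule)
  known <- frame_average(tm, VD * input$cc_star, schedule)
  structure(list(trap = trap, B = B, blood = blood, known = known,
                 grid = as.numeric(grid), schedule = schedule, VD = VD,
                 cp = input$cp_unlabeled),
            class = "kinetic_dictionary")
}

# Non-negative least squares with square-root-weight row scaling.
wnnls <- function(X, y, w) {
  sw <- sqrt(w)
  fit <- pracma::lsqnonneg(X * sw, y * sw)
  fit$x
}

# Outlier rule: non-physiological estimates.
is_outlier <- function(K1, Vb, rcps) {
  !is.finite(K1) || !is.finite(rcps) || K1 > 1 || Vb > 1 || rcps > 10
}

new_estimation_result <- function(method, K1, lambda, rcps, Vb, wrss,
                                  beta_hat = NA_real_,
                                  n_components = NA_integer_,
                                  degenerate = FALSE, theta = NULL) {
  structure(list(method = method, K1 = K1, lambda = lambda, rcps = rcps,
                 Vb = Vb, beta_hat = beta_hat, n_components = n_components,
                 wrss = wrss, outlier = is_outlier(K1, Vb, rcps),
                 degenerate = degenerate, theta = theta),
            class = "estimation_result")
}

#' @export
print.estimation_result <- function(x, ...) {
  cat(sprintf(
    "%s fit: K1 = %.4g mL/g/min, lambda = %.4g, rCPS = %.4g nmol/g/min, Vb = %.4g\n",
    toupper(x$method), x$K1, x$lambda, x$rcps, x$Vb))
  if (!is.na(x$beta_hat)) cat(sprintf("  beta = %.4g 1/min\n", x$beta_hat))
  if (!is.na(x$n_components))
    cat(sprintf("  equilibrating components: %d\n", x$n_components))
  cat(sprintf("  WRSS = %.4g%s%s\n", x$wrss,
              if (x$outlier) ", OUTLIER" else "",
              if (x$degenerate) ", degenerate" else ""))
  invisible(x)
}

#' Basis function method (BFM) fit
#'
#' Fits the homogeneous tissue model by grid search over the lumped turnover
#' rate `beta`: for each grid value, weighted linear least squares for the
#' three amplitudes (trapping `c1`, equilibrating `c2`, blood `Vb`) on the
#' columns `[integral Cp*, basis(beta), blood]`, with the known `VD Cc*` term
#' subtracted from the data.  Any `beta` whose unconstrained solution has a
#' negative coefficient is refit with non-negativity constraints, so all
#' reported estimates are non-negative.  The `beta` with minimal weighted
#' residual sum of squares wins.  Macro parameters:
#' `K1 = (c1 + c2)/(1 - Vb)`, `lambda = c2/(c1 + c2)`,
#' `k4 = beta c1/(c1 + c2)`, `rCPS = K1 (1-lambda)/lambda * Cp`.
#'
#' @param tac a [tissue_tac()] on the dictionary's schedule.
#' @param dict a [kinetic_dictionary()]; alternatively pass `input`, `grid`,
#'   `VD` to have one built.
#' @param weights per-frame weights (default from [weights_from_variance()]
#'   on the observed TAC).
#' @param cp unlabeled plasma leucine, nmol/mL; defaults to the dictionary's.
#' @param input,grid,VD used only when `dict` is `NULL`.
#' @return An `estimation_result`.
#' @export
bfm_fit <- function(tac, dict = NULL, weights = NULL, cp = NULL,
                    input = NULL, grid = beta_grid(), VD = 0.41) {
  stopifnot(inherits(tac, "tissue_tac"))
  if (is.null(dict)) dict <- kinetic_dictionary(input, tac$schedule, grid, VD)
  if (is.null(weights)) weights <- weights_from_variance(tac)
  if (is.null(cp)) cp <- dict$cp
  y <- tac$values - dict$known
  w <- weights
  nb <- length(dict$grid)
  # Vectorized weighted normal equations across the grid: columns
  # a = trap, b = basis(beta), c = blood.
  a <- dict$trap; bl <- dict$blood; B <- dict$B
  wa <- w * a; wbl <- w * bl; wy <- w * y
  saa <- sum(wa * a); sac <- sum(wa * bl); scc <- sum(wbl * bl)
  say <- sum(wa * y); scy <- sum(wbl * y); syy <- sum(wy * y)
  sbb <- colSums(B * (w * B)); sab <- colSums(B * wa)
  sbc <- colSums(B * wbl); sby <- colSums(B * wy)
  # Solve the 3x3 systems in closed form (adjugate), vectorized over beta.
  d11 <- sbb * scc - sbc * sbc
  d12 <- sab * scc - sbc * sac
  d13 <- sab * sbc - sbb * sac
  det <- saa * d11 - sab * d12 + sac * d13
  d22 <- saa * scc - sac * sac
  d23 <- saa * sbc - sab * sac
  d33 <- saa * sbb - sab * sab
  ok <- is.finite(det) & abs(det) > 1e-300
  c1 <- c2 <- c3 <- rep(NA_real_, nb)
  c1[ok] <- (d11[ok] * say - d12[ok] * sby[ok] + d13[ok] * scy) / det[ok]
  c2[ok] <- (-d12[ok] * say + d22 * sby[ok] - d23[ok] * scy) / det[ok]
  c3[ok] <- (d13[ok] * say - d23[ok] * sby[ok] + d33[ok] * scy) / det[ok]
  wrss <- syy - (c1 * say + c2 * sby + c3 * scy)
  wrss[!ok] <- Inf
  # Constrained (non-negative) refit wherever the unconstrained solution has
  # a negative coefficient.  With three columns the exact NNLS optimum is the
  # minimum-WRSS feasible solution over the seven support subsets, each a
  # closed-form solve on the precomputed cross products -- vectorized over
  # the whole grid.
  neg <- ok & (c1 < 0 | c2 < 0 | c3 < 0)
  if (any(neg)) {
    rp <- function(x) rep_len(x, nb)
    feas <- function(sol_wrss, ...) {
      f <- Reduce(`&`, lapply(list(...), function(v) is.finite(v) & v >= 0))
      ifelse(f & is.finite(sol_wrss), sol_wrss, Inf)
    }
    x1 <- rp(say / saa); x2 <- sby / sbb; x3 <- rp(scy / scc)
    p12 <- saa * sbb - sab^2
    u1 <- (sbb * say - sab * sby) / p12; v1 <- (saa * sby - sab * say) / p12
    p13 <- saa * scc - sac^2
    u2 <- rp((scc * say - sac * scy) / p13)
    v2 <- rp((saa * scy - sac * say) / p13)
    p23 <- sbb * scc - sbc^2
    u3 <- (scc * sby - sbc * scy) / p23; v3 <- (sbb * scy - sbc * sby) / p23
    sub_wrss <- cbind(
      feas(wrss, c1, c2, c3),                              # {a,b,c}
      feas(syy - say * x1, x1),                            # {a}
      feas(syy - sby * x2, x2),                            # {b}
      feas(syy - scy * x3, x3),                            # {c}
      feas(syy - say * u1 - sby * v1, u1, v1),             # {a,b}
      feas(syy - say * u2 - scy * v2, u2, v2),             # {a,c}
      feas(syy - sby * u3 - scy * v3, u3, v3),             # {b,c}
      rp(syy))                                             # empty
    pick <- max.col(-sub_wrss[neg, , drop = FALSE], ties.method = "first")
    sols <- list(NULL,
                 list(x1, 0, 0), list(0, x2, 0), list(0, 0, x3),
                 list(u1, v1, 0), list(u2, 0, v2), list(0, u3, v3),
                 list(0, 0, 0))
    for (s in unique(pick)) {
      jj <- which(neg)[pick == s]
      cc <- sols[[s]]
      if (!is.null(cc)) {
        c1[jj] <- rp(cc[[1]])[jj]
        c2[jj] <- rp(cc[[2]])[jj]
        c3[jj] <- rp(cc[[3]])[jj]
      }
      wrss[jj] <- sub_wrss[cbind(jj, s)]
    }
  }
  j <- which.min(wrss)
  beta <- dict$grid[j]
  c1j <- max(c1[j], 0); c2j <- max(c2[j], 0); Vb <- c3[j]
  tot <- c1j + c2j
  if (tot == 0 || Vb >= 1) {
    K1 <- if (Vb >= 1) tot / (1 - min(Vb, 1 - 1e-12)) else 0
    return(new_estimation_result("bfm", K1 = 0, lambda = 0, rcps = 0,
                                 Vb = Vb, wrss = wrss[j], beta_hat = beta,
                                 degenerate = TRUE))
  }
  K1 <- tot / (1 - Vb)
  lambda <- c2j / tot
  rcps <- if (lambda > 0) K1 * (1 - lambda) / lambda * cp
          else c1j / (1 - Vb) * cp
  new_estimation_result("bfm", K1 = K1, lambda = lambda, rcps = rcps,
                        Vb = Vb, wrss = wrss[j], beta_hat = beta,
                        degenerate = lambda == 0)
}

# Cluster nonzero in-band amplitudes: adjacent occupied grid points merge
# into one equilibrating component; clusters separated by >= 1 empty grid
# point are distinct.  A grid point counts as occupied when its contribution
# to the fitted curve exceeds numerical noise (1e-9 of the data scale);
# the NNLS solver can leave machine-precision dust on inactive columns.
count_components <- function(theta_inband, contrib_scale = NULL,
                             data_scale = NULL) {
  active <- theta_inband > 0
  if (!is.null(contrib_scale) && !is.null(data_scale) && data_scale > 0)
    active <- active & (theta_inband * contrib_scale > 1e-9 * data_scale)
  occ <- which(active)
  if (!length(occ)) return(0L)
  as.integer(sum(diff(occ) > 1) + 1L)
}

#' Spectral analysis with iterative filter (SAIF) fit
#'
#' Band-limited non-negative spectral decomposition: one weighted
#' non-negative least squares fit over the dictionary
#' `[trapping column, basis(beta) for grid betas inside the bandpass, blood
#' column]`, with the known `VD Cc*` term subtracted from the data.  The
#' bandpass separates the trapping component (`beta = 0`) and the blood
#' component from the equilibrating tissue components and suppresses
#' noise-induced phantom components outside it.  Macro parameters come from
#' [macros_from_spectrum()]; the number of equilibrating components is the
#' number of merged clusters of adjacent occupied grid points.
#'
#' @inheritParams bfm_fit
#' @param band bandpass `[low, high]` in 1/min for the equilibrating
#'   components; default `c(0.02, 0.3)`.
#' @return An `estimation_result` with `n_components` set and the fitted
#'   spectrum in `$theta` (named list: `theta0`, `thetas`, `betas`, `Vb`).
#' @export
saif_fit <- function(tac, dict = NULL, band = c(0.02, 0.3), weights = NULL,
                     cp = NULL, input = NULL, grid = beta_grid(), VD = 0.41) {
  stopifnot(inherits(tac, "tissue_tac"), length(band) == 2, band[1] < band[2])
  if (is.null(dict)) dict <- kinetic_dictionary(input, tac$schedule, grid, VD)
  if (is.null(weights)) weights <- weights_from_variance(tac)
  if (is.null(cp)) cp <- dict$cp
  inband <- which(dict$grid >= band[1] & dict$grid <= band[2])
  if (!length(inband)) stop("empty bandpass: no grid betas inside 'band'")
  X <- cbind(dict$trap, dict$B[, inband, drop = FALSE], dict$blood)
  y <- tac$values - dict$known
  cf <- wnnls(X, y, weights)
  k <- length(inband)
  theta0 <- cf[1]
  thetas <- cf[1 + seq_len(k)]
  Vb <- cf[k + 2]
  r <- y - X %*% cf
  wrss <- sum(weights * r * r)
  ncomp <- count_components(thetas,
                            contrib_scale = apply(dict$B[, inband,
                                                         drop = FALSE],
                                                  2, max),
                            data_scale = max(abs(y)))
  if (Vb >= 1) {
    return(new_estimation_result("saif", K1 = theta0 + sum(thetas),
                                 lambda = 0, rcps = 0, Vb = Vb, wrss = wrss,
                                 n_components = ncomp, degenerate = TRUE))
  }
  nz <- thetas > 0
  spec <- spectral_representation(theta0, thetas[nz], dict$grid[inband][nz],
                                  Vb = Vb, VD = dict$VD)
  m <- macros_from_spectrum(spec, cp)
  new_estimation_result("saif", K1 = m$K1, lambda = m$lambda, rcps = m$rcps,
                        Vb = Vb, wrss = wrss, n_components = ncomp,
                        degenerate = m$degenerate,
                        theta = list(theta0 = theta0, thetas = thetas,
                                     betas = dict$grid[inband], Vb = Vb,
                                     fitted = as.numeric(X %*% cf) + dict$known))
}

#' Tracer delay estimation by shifted-input grid search
#'
#' Estimates the delay between tracer arrival at the arterial sampling site
#' and in brain: for each candidate delay the input functions are shifted
#' later by that amount, the whole-brain TAC is fit with SAIF, and the delay
#' with the smallest weighted residual sum of squares wins (ties broken
#' toward the smaller delay).
#'
#' @param tac the whole-brain [tissue_tac()].
#' @param input an [input_function_set()].
#' @param candidates_s candidate delays in seconds (default 0 to 20 s in 1-s
#'   steps).
#' @param grid a [beta_grid()].
#' @param band SAIF bandpass, 1/min.
#' @param VD blood:brain 11CO2 distribution volume.
#' @return A list: `delay_s` (selected delay), `wrss` (per candidate),
#'   `candidates_s`.
#' @export
fit_delay <- function(tac, input, candidates_s = 0:20, grid = beta_grid(),
                      band = c(0.02, 0.3), VD = 0.41) {
  stopifnot(inherits(tac, "tissue_tac"), all(candidates_s >= 0))
  weights <- weights_from_variance(tac)
  wrss <- vapply(candidates_s, function(d) {
    dict <- kinetic_dictionary(shift_input(input, d), tac$schedule, grid, VD)
    saif_fit(tac, dict, band = band, weights = weights)$wrss
  }, 0)
  list(delay_s = candidates_s[which.min(wrss)], wrss = wrss,
       candidates_s = candidates_s)
}

#' Bootstrap classification of kinetic heterogeneity
#'
#' Residual-resampling bootstrap around an initial SAIF fit: the residuals
#' are normalized by the frame noise scale `s_i` (square root of
#' `exp(gamma t_i) CT_i / dt_i`, evaluated on the fitted curve), resampled
#' with replacement, rescaled and added back to the fitted curve; each
#' replicate is refit with SAIF.  The heterogeneity probability is the
#' fraction of replicates with two or more equilibrating components; the
#' voxel is flagged heterogeneous when the probability reaches `threshold`.
#'
#' @param tac the observed [tissue_tac()].
#' @param dict a [kinetic_dictionary()].
#' @param band SAIF bandpass, 1/min.
#' @param n_boot number of bootstrap replicates (default 50).
#' @param threshold probability threshold for the heterogeneity flag
#'   (default 0.80).
#' @param gamma decay constant used in the residual normalization, 1/min.
#' @param seed integer seed; results are reproducible given the seed.
#' @return A list: `probability`, `heterogeneous` (flag), `n_boot`,
#'   `threshold`, and the initial `fit`.
#' @export
bootstrap_heterogeneity <- function(tac, dict, band = c(0.02, 0.3),
                                    n_boot = 50, threshold = 0.80,
                                    gamma = log(2) / 20.34, seed = NULL) {
  if (n_boot < 1) stop("'n_boot' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  fit0 <- saif_fit(tac, dict, band = band)
  fitted <- if (!is.null(fit0$theta)) fit0$theta$fitted else tac$values
  s <- tac$schedule
  floor_val <- 0.01 * max(abs(fitted), 1e-12)
  si <- sqrt(exp(gamma * s$mid) * pmax(fitted, floor_val) / s$dur)
  z <- (tac$values - fitted) / si
  ncomp <- integer(n_boot)
  for (b in seq_len(n_boot)) {
    yb <- fitted + si * sample(z, s$n, replace = TRUE)
    ncomp[b] <- saif_fit(tissue_tac(s, yb), dict, band = band)$n_components
  }
  prob <- mean(ncomp >= 2)
  list(probability = prob, heterogeneous = prob >= threshold,
       n_boot = n_boot, threshold = threshold, fit = fit0,
       n_components = ncomp)
}
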