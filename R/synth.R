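#' Reference library of 19 regional parameter sets
#'
#' Nineteen homogeneous-tissue parameter sets standing in for the
#' inter-subject mean regional estimates (18 regions plus whole brain) of a
#' healthy-volunteer leucine study.  The sets are laid out by joint
#' deterministic interpolation across the physiologic ranges
#' `K1` 0.025--0.062 mL/g/min, `k2+k3` 0.054--0.157 1/min and
#' `k4` 0.027--0.053 1/min (endpoints included), with `Vb = 0.05` in every
#' set.  Low-index sets resemble white matter (slow transport and turnover),
#' high-index sets gray matter.
#'
#' @return A list of 19 [homogeneous_params()], names `set_01` ... `set_19`.
#' @export
#' @examples
#' lib <- reference_library()
#' range(vapply(lib, `[[`, 0, "K1"))   # 0.025 0.062
reference_library <- function() {
  u <- (0:18) / 18
  lib <- lapply(u, function(x)
    homogeneous_params(K1 = 0.025 + x * (0.062 - 0.025),
                       k2k3 = 0.054 + x * (0.157 - 0.054),
                       k4 = 0.027 + x * (0.053 - 0.027),
                       Vb = 0.05))
  names(lib) <- sprintf("set_%02d", 1:19)
  lib
}

#' Two-subregion heterogeneous counterpart of a homogeneous tissue
#'
#' Constructs the equal-weight two-subregion mixture used in the
#' heterogeneous simulation scenario.  The construction satisfies five
#' constraints: (i) weights 0.5/0.5; (ii) lambda equal in both subregions
#' (and equal to the homogeneous lambda); (iii) the weighted mean of the
#' subregion `K1` values equals the homogeneous `K1`; (iv) the turnover
#' `beta = k2+k3+k4` of the first subregion is 5 times that of the second;
#' (v) the product `K1 (k2+k3)` of the first subregion is 25 times that of
#' the second.  Together with the anchor that the weighted mean `beta`
#' equals the homogeneous `beta` (the absolute `beta` scale is otherwise
#' undetermined), the closed form is `K1a = 5 K1 / 3`, `K1b = K1 / 3`,
#' `beta_a = 5 beta / 3`, `beta_b = beta / 3`, and within each subregion
#' `k2+k3 = lambda * beta_i`, `k4 = (1 - lambda) * beta_i`.  Constraints
#' (ii) and (iii) guarantee that the weighted rCPS of the mixture equals the
#' rCPS of the homogeneous tissue.
#'
#' @param h a [homogeneous_params()] with `k2k3 > 0` and `k4 > 0`.
#' @return A [subregion_mixture()] with two subregions, weights 0.5/0.5 and
#'   the same `Vb` as `h`.
#' @export
#' @examples
#' mix <- derive_heterogeneous(homogeneous_params(0.05, 0.1, 0.04))
#' mix$subregions[[1]]$K1    # 5/3 * 0.05
derive_heterogeneous <- function(h) {
  stopifnot(inherits(h, "homogeneous_params"))
  if (h$k2k3 <= 0 || h$k4 <= 0)
    stop("degenerate homogeneous parameters: k2+k3 and k4 must be positive")
  lam <- lambda_from_rates(h$k2k3, h$k4)
  beta <- c(5, 1) / 3 * h$beta
  K1 <- c(5, 1) / 3 * h$K1
  subs <- lapply(1:2, function(i)
    homogeneous_params(K1 = K1[i], k2k3 = lam * beta[i],
                       k4 = (1 - lam) * beta[i], Vb = h$Vb))
  subregion_mixture(subs, weights = c(0.5, 0.5), Vb = h$Vb)
}

#' Frame-based Gaussian noise model
#'
#' Measurement noise on a decay-corrected frame value is zero-mean Gaussian
#' with variance `alpha * exp(gamma * t_i) * CT*(t_i) / dt_i`, where `t_i` is
#' the frame mid-time, `dt_i` the frame duration, `gamma` the 11C decay
#' constant and `alpha` a proportionality coefficient calibrating the noise
#' level ("voxel" or "ROI" scale; see [calibrate_alpha()]).
#'
#' @param alpha proportionality coefficient, >= 0.
#' @param gamma decay constant, 1/min; default `log(2) / 20.34` for 11C
#'   (half-life 20.34 min).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(alpha, gamma = log(2) / 20.34) {
  if (!is.numeric(alpha) || alpha < 0) stop("'alpha' must be >= 0")
  if (gamma < 0) stop("'gamma' must be >= 0")
  structure(list(alpha = alpha, gamma = gamma), class = "noise_model")
}

# Per-frame noise SD for a noise-free TAC under a noise model.
noise_sd <- function(tac, model) {
  sqrt(model$alpha * exp(model$gamma * tac$schedule$mid) *
         pmax(tac$values, 0) / tac$schedule$dur)
}

#' Calibrate the noise coefficient alpha
#'
#' Chooses `alpha` so that the relative standard deviation of the
#' highest-activity frame of the mid-library homogeneous TAC equals a target:
#' 25% for voxel-level data, 5% for ROI-level data.  Given the variance model
#' `alpha * exp(gamma t) * CT / dt`, this gives
#' `alpha = rel^2 * CT_peak * dt_peak * exp(-gamma t_peak)`.
#'
#' @param level `"voxel"` or `"roi"`.
#' @param input an [input_function_set()].
#' @param schedule a [frame_schedule()].
#' @param gamma decay constant, 1/min.
#' @param rel optional explicit relative SD target overriding the level
#'   default.
#' @return A [noise_model()] with the calibrated `alpha`.
#' @export
calibrate_alpha <- function(level = c("voxel", "roi"), input, schedule,
                            gamma = log(2) / 20.34, rel = NULL) {
  level <- match.arg(level)
  if (is.null(rel)) rel <- switch(level, voxel = 0.25, roi = 0.05)
  mid <- reference_library()[[10]]
  tac <- homogeneous_tac(mid, input, schedule)
  i <- which.max(tac$values)
  alpha <- rel^2 * tac$values[i] * schedule$dur[i] *
    exp(-gamma * schedule$mid[i])
  noise_model(alpha, gamma)
}

#' Add Gaussian frame noise to a TAC
#'
#' Draws `n_reps` independent noisy realizations of a noise-free TAC under a
#' [noise_model()].  The variance is computed from the noise-free curve
#' (ground truth, available in simulation).  Realizations may be negative.
#'
#' @param tac a [tissue_tac()] (noise-free).
#' @param model a [noise_model()].
#' @param n_reps number of realizations, >= 1.
#' @param seed integer seed; realizations are reproducible given
#'   `(seed, n_reps)`.
#' @return A matrix with one row per frame and one column per realization.
#' @export
add_noise <- function(tac, model, n_reps, seed = NULL) {
  stopifnot(inherits(tac, "tissue_tac"), inherits(model, "noise_model"))
  if (n_reps < 1) stop("'n_reps' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  sd <- noise_sd(tac, model)
  nf <- tac$schedule$n
  tac$values + matrix(stats::rnorm(nf * n_reps, sd = rep(sd, n_reps)),
                      nrow = nf)
}

#' Specification of a 3D brain-like phantom
#'
#' A small synthetic volume with background (label 0), gray-matter shell
#' (label 1) and white-matter core (label 2): an outer ellipsoid of gray
#' matter enclosing an inner ellipsoid of white matter.  Each class is
#' kinetically homogeneous; by default gray matter takes the fastest and
#' white matter the slowest entry of [reference_library()], so true rCPS in
#' white matter is below gray matter.
#'
#' @param dim integer grid dimensions in voxels (default `c(48, 48, 24)`).
#' @param voxel_mm voxel size in mm (default `c(1.21, 1.21, 1.23)`).
#' @param gray,white [homogeneous_params()] for the two tissue classes.
#' @param brain_frac,white_frac semi-axes of the brain and white-matter
#'   ellipsoids as fractions of the half-dimensions.
#' @return An object of class `phantom_spec` with a `labels` 3D array.
#' @export
phantom_spec <- function(dim = c(48, 48, 24), voxel_mm = c(1.21, 1.21, 1.23),
                         gray = reference_library()[[19]],
                         white = reference_library()[[1]],
                         brain_frac = 0.85, white_frac = 0.55) {
  stopifnot(length(dim) == 3, all(dim >= 4), length(voxel_mm) == 3,
            all(voxel_mm > 0), inherits(gray, "homogeneous_params"),
            inherits(white, "homogeneous_params"),
            brain_frac > white_frac, white_frac > 0, brain_frac <= 1)
  ctr <- (dim + 1) / 2
  half <- (dim - 1) / 2
  r2 <- function(frac) {
    x <- ((seq_len(dim[1]) - ctr[1]) / (frac * half[1]))^2
    y <- ((seq_len(dim[2]) - ctr[2]) / (frac * half[2]))^2
    z <- ((seq_len(dim[3]) - ctr[3]) / (frac * half[3]))^2
    outer(outer(x, y, `+`), z, `+`)
  }
  labels <- array(0L, dim)
  labels[r2(brain_frac) <= 1] <- 1L
  labels[r2(white_frac) <= 1] <- 2L
  structure(list(dim = as.integer(dim), voxel_mm = voxel_mm, labels = labels,
                 classes = list(gray = gray, white = white)),
            class = "phantom_spec")
}

#' Build a dynamic 4D phantom with per-voxel ground truth
#'
#' Evaluates the class TACs of a [phantom_spec()] on a frame schedule, fills
#' the 4D dynamic image voxelwise (each voxel kinetically homogeneous before
#' any smoothing), optionally adds frame noise independently per voxel, and
#' tabulates per-voxel ground truth.
#'
#' @param spec a [phantom_spec()].
#' @param input an [input_function_set()].
#' @param schedule a [frame_schedule()].
#' @param noise optional [noise_model()]; `NULL` for a noise-free phantom.
#' @param seed integer seed for the noise.
#' @param VD blood:brain 11CO2 distribution volume.
#' @return A list of class `phantom_4d`: `img` (4D array, x,y,z,frame),
#'   `labels`, `voxel_mm`, `schedule`, `class_tacs` (named list of
#'   [tissue_tac()]), and `truth` (data frame with one row per brain voxel:
#'   `i`, `j`, `k`, `class`, `K1`, `lambda`, `rcps`).
#' @export
build_phantom <- function(spec, input, schedule, noise = NULL, seed = NULL,
                          VD = 0.41) {
  stopifnot(inherits(spec, "phantom_spec"))
  classes <- list(`1` = spec$classes$gray, `2` = spec$classes$white)
  class_tacs <- lapply(classes, homogeneous_tac, input = input,
                       schedule = schedule, VD = VD)
  names(class_tacs) <- c("gray", "white")
  nf <- schedule$n
  img <- array(0, c(spec$dim, nf))
  if (!is.null(seed)) set.seed(seed)
  lab_vec <- as.integer(spec$labels)
  nvox <- length(lab_vec)
  mat <- matrix(0, nvox, nf)  # voxels x frames
  for (cl in 1:2) {
    idx <- which(lab_vec == cl)
    if (!length(idx)) next
    vals <- class_tacs[[cl]]$values
    mat[idx, ] <- matrix(vals, length(idx), nf, byrow = TRUE)
    if (!is.null(noise)) {
      sd <- noise_sd(class_tacs[[cl]], noise)
      mat[idx, ] <- mat[idx, ] +
        matrix(stats::rnorm(length(idx) * nf, sd = rep(sd, each = length(idx))),
               length(idx), nf)
    }
  }
  img <- array(mat, c(spec$dim, nf))
  brain <- which(lab_vec > 0L)
  ijk <- arrayInd(brain, spec$dim)
  cl <- lab_vec[brain]
  p <- lapply(classes, function(h)
    c(h$K1, lambda_from_rates(h$k2k3, h$k4),
      rcps_from_rates(h$K1, h$k2k3, h$k4, input$cp_unlabeled)))
  pm <- do.call(rbind, p)[cl, , drop = FALSE]
  truth <- data.frame(i = ijk[, 1], j = ijk[, 2], k = ijk[, 3],
                      class = c("gray", "white")[cl],
                      K1 = pm[, 1], lambda = pm[, 2], rcps = pm[, 3])
  structure(list(img = img, labels = spec$labels, voxel_mm = spec$voxel_mm,
                 schedule = schedule, class_tacs = class_tacs, truth = truth),
            class = "phantom_4d")
}
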