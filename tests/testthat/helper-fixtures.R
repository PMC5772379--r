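# Shared fixtures, built lazily and memoized for the whole test run.
.fx <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (!exists(name, envir = .fx)) assign(name, force(expr), envir = .fx)
  get(name, envir = .fx)
}

fx_input <- function() memo("input", make_input_functions())
fx_schedule <- function() memo("schedule", default_frame_schedule())
fx_dict <- function() memo("dict",
  kinetic_dictionary(fx_input(), fx_schedule()))
fx_library <- function() memo("library", reference_library())

# A homogeneous parameter set whose beta = k2k3 + k4 falls exactly on the
# default grid (used for exact-recovery tests).
fx_ongrid_params <- function() memo("ongrid", {
  g <- beta_grid()
  beta <- g[which.min(abs(g - 0.14))]
  lam <- 0.1 / 0.14
  homogeneous_params(K1 = 0.05, k2k3 = lam * beta, k4 = (1 - lam) * beta,
                     Vb = 0.05)
})
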