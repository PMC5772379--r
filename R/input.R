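#' Arterial input function set
#'
#' Container for the blood curves driving the leucine model: labeled plasma
#' leucine `cp_star`, total whole-blood 11C `cb_star`, whole-blood 11CO2
#' `cc_star`, and the (scalar) unlabeled plasma leucine concentration
#' `cp_unlabeled` in nmol/mL.  Curves are stored on a fine, strictly
#' increasing time grid in minutes; model evaluation requires a grid no
#' coarser than 1 s, so coarser tables are interpolated at construction.
#'
#' @param time time grid, minutes, starting at 0.
#' @param cp_star,cb_star,cc_star activity curves on `time` (decay-corrected,
#'   arbitrary activity-concentration units, typically kBq/mL).  `cc_star`
#'   defaults to zero (simulation mode: brain 11CO2 neglected).
#' @param cp_unlabeled scalar unlabeled plasma leucine, nmol/mL.
#' @param dt target internal grid spacing in minutes (default 1/60, i.e. 1 s).
#'
#' @return An object of class `input_function_set`.
#' @export
input_function_set <- function(time, cp_star, cb_star,
                               cc_star = rep(0, length(time)),
                               cp_unlabeled, dt = 1 / 60) {
  time <- as.numeric(time)
  n <- length(time)
  if (n < 2L || any(diff(time) <= 0))
    stop("'time' must be a strictly increasing grid of length >= 2")
  if (abs(time[1]) > 1e-9) stop("'time' must start at 0")
  for (nm in c("cp_star", "cb_star", "cc_star")) {
    v <- get(nm)
    if (length(v) != n) stop("'", nm, "' must match the time grid length")
    if (any(v < -1e-9)) stop("'", nm, "' must be non-negative")
    if (abs(v[1]) > 1e-9) stop("'", nm, "' must be zero at t = 0")
  }
  if (!is.numeric(cp_unlabeled) || length(cp_unlabeled) != 1L ||
      cp_unlabeled < 0)
    stop("'cp_unlabeled' must be a non-negative scalar (nmol/mL)")
  if (max(diff(time)) > dt + 1e-9) {
    grid <- seq(0, time[n], by = dt)
    cp_star <- stats::approx(time, cp_star, grid)$y
    cb_star <- stats::approx(time, cb_star, grid)$y
    cc_star <- stats::approx(time, cc_star, grid)$y
    time <- grid
  }
  structure(
    list(time = time, cp_star = pmax(cp_star, 0), cb_star = pmax(cb_star, 0),
         cc_star = pmax(cc_star, 0), cp_unlabeled = cp_unlabeled),
    class = "input_function_set"
  )
}

#' @export
print.input_function_set <- function(x, ...) {
  cat(sprintf(
    "Input function set: 0-%.4g min (%d samples), peak Cp* = %.4g, Cp = %.4g nmol/mL\n",
    max(x$time), length(x$time), max(x$cp_star), x$cp_unlabeled))
  invisible(x)
}

#' Synthetic arterial input functions for a 2-min leucine infusion
#'
#' Generates the blood curves of a bolus-infusion leucine study: labeled
#' plasma leucine rises linearly over the infusion to its peak at the end of
#' infusion, then decays as a sum of exponentials; whole-blood activity is a
#' fixed fraction of plasma activity; whole-blood 11CO2 is zero in simulation
#' mode.  Deterministic given its arguments.
#'
#' @param infusion_min infusion duration, minutes (default 2).
#' @param peak peak plasma activity at end of infusion (activity units,
#'   default 100).
#' @param tail_halftimes half-times of the post-infusion exponential tail,
#'   minutes.
#' @param tail_fracs amplitude of each tail component as a fraction of peak;
#'   must sum to 1 so the curve is continuous at end of infusion.
#' @param wb_ratio whole-blood : plasma activity ratio (default 0.8).
#' @param cp_unlabeled unlabeled plasma leucine, nmol/mL (default 120).
#' @param t_end end of the generated grid, minutes; must extend past the last
#'   frame of the schedule it will be used with (default 91).
#' @param dt grid spacing, minutes (default 1 s).
#'
#' @return An [input_function_set()].
#' @export
#' @examples
#' inp <- make_input_functions()
#' max(inp$cp_star)                       # = peak, at end of infusion
make_input_functions <- function(infusion_min = 2, peak = 100,
                                 tail_halftimes = c(1.5, 8, 45),
                                 tail_fracs = c(0.6, 0.3, 0.1),
                                 wb_ratio = 0.8, cp_unlabeled = 120,
                                 t_end = 91, dt = 1 / 60) {
  if (infusion_min <= 0) stop("'infusion_min' must be positive")
  if (peak <= 0) stop("'peak' must be positive")
  if (length(tail_halftimes) != length(tail_fracs))
    stop("'tail_halftimes' and 'tail_fracs' must have equal length")
  if (abs(sum(tail_fracs) - 1) > 1e-9)
    stop("'tail_fracs' must sum to 1")
  time <- seq(0, t_end, by = dt)
  cp <- numeric(length(time))
  rising <- time <= infusion_min
  cp[rising] <- peak * time[rising] / infusion_min
  ts <- time[!rising] - infusion_min
  cp[!rising] <- peak * colSums(tail_fracs * exp(-log(2) *
    outer(1 / tail_halftimes, ts)))
  input_function_set(time, cp, wb_ratio * cp, cp_unlabeled = cp_unlabeled,
                     dt = dt)
}

#' Delay an input function in time
#'
#' Shifts all blood curves later by `delay_s` seconds (tracer arrives at the
#' tissue later than at the arterial sampling site), padding with zero before
#' the shift.  Used by [fit_delay()] and for simulating delayed data.
#'
#' @param input an [input_function_set()].
#' @param delay_s delay in seconds, >= 0.
#' @return A shifted [input_function_set()] on the same time grid.
#' @export
shift_input <- function(input, delay_s) {
  stopifnot(inherits(input, "input_function_set"), delay_s >= 0)
  if (delay_s == 0) return(input)
  d <- delay_s / 60
  shift1 <- function(v)
    stats::approx(input$time + d, v, input$time, yleft = 0, rule = 2)$y
  input_function_set(input$time, shift1(input$cp_star), shift1(input$cb_star),
                     shift1(input$cc_star), input$cp_unlabeled)
}

#' Read / write a blood-data table
#'
#' The table is delimited text (whitespace, tab or comma separated) with a
#' header and columns `time_s` (or `time_min` with `unit = "min"`),
#' `cp_star`, `cb_star` and optionally `cc_star` (assumed zero when absent).
#' Curves are linearly interpolated to the internal 1-s grid.  The unlabeled
#' plasma leucine concentration is not part of the table and is supplied as
#' `cp_unlabeled`.
#'
#' @param path file path.
#' @param cp_unlabeled scalar unlabeled plasma leucine, nmol/mL.
#' @param unit time unit of the time column: `"s"` (default) or `"min"`.
#' @param input an [input_function_set()] (for writing).
#' @return `read_blood_table` returns an [input_function_set()];
#'   `write_blood_table` returns `path` invisibly.
#' @export
read_blood_table <- function(path, cp_unlabeled, unit = c("s", "min")) {
  unit <- match.arg(unit)
  header <- readLines(path, n = 1L)
  sep <- if (grepl(",", header, fixed = TRUE)) "," else ""
  tab <- utils::read.table(path, header = TRUE, sep = sep)
  tcol <- if (unit == "s") "time_s" else "time_min"
  need <- c(tcol, "cp_star", "cb_star")
  if (!all(need %in% names(tab)))
    stop("blood table must have columns ", paste(need, collapse = ", "))
  time <- tab[[tcol]]
  if (unit == "s") time <- time / 60
  if (any(diff(time) <= 0)) stop("blood table time column must be strictly increasing")
  if (any(tab$cp_star < 0) || any(tab$cb_star < 0))
    stop("blood table activities must be non-negative")
  cc <- if ("cc_star" %in% names(tab)) tab$cc_star else rep(0, nrow(tab))
  if (any(cc < 0)) stop("blood table activities must be non-negative")
  input_function_set(time, tab$cp_star, tab$cb_star, cc,
                     cp_unlabeled = cp_unlabeled)
}

#' @rdname read_blood_table
#' @export
write_blood_table <- function(input, path) {
  stopifnot(inherits(input, "input_function_set"))
  utils::write.table(
    data.frame(time_s = input$time * 60, cp_star = input$cp_star,
               cb_star = input$cb_star, cc_star = input$cc_star),
    path, row.names = FALSE, quote = FALSE, sep = "\t"
  )
  invisible(path)
}
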