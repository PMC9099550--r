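#' Construct a 3-axis acceleration trace
#'
#' An `accel_trace` holds one timed 3-axis acceleration recording of a single
#' transport event, in units of g, as logged by a tube-mounted accelerometer.
#'
#' @param timestamps Numeric vector of sampling times in seconds, strictly
#'   increasing.
#' @param ax,ay,az Numeric per-axis accelerations in g, same length as
#'   `timestamps`.
#' @param sample_rate Nominal sampling rate in Hz. Defaults to the reciprocal
#'   median sampling interval.
#' @param clip_limit Per-axis sensor saturation limit in g (default 16).
#' @return An object of class `accel_trace`.
#' @examples
#' tr <- accel_trace(seq(0, 1, by = 0.04), rnorm(26, 0, 0.1),
#'                   rnorm(26, 0, 0.1), 1 + rnorm(26, 0, 0.1))
#' @export
accel_trace <- function(timestamps, ax, ay, az, sample_rate = NULL,
                        clip_limit = 16) {
  timestamps <- as.numeric(timestamps)
  ax <- as.numeric(ax); ay <- as.numeric(ay); az <- as.numeric(az)
  n <- length(timestamps)
  if (n < 2L)
    stop("accel_trace needs at least 2 samples", call. = FALSE)
  if (length(ax) != n || length(ay) != n || length(az) != n)
    stop("axis sequences must match the timestamp length", call. = FALSE)
  if (any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (any(abs(c(ax, ay, az)) > clip_limit + 1e-9))
    stop("axis values exceed the sensor clip limit", call. = FALSE)
  if (is.null(sample_rate))
    sample_rate <- 1 / stats::median(diff(timestamps))
  structure(list(timestamps = timestamps, ax = ax, ay = ay, az = az,
                 sample_rate = sample_rate, clip_limit = clip_limit),
            class = "accel_trace")
}

#' @export
print.accel_trace <- function(x, ...) {
  cat(sprintf("accel_trace: %d samples, %.1f s at %.1f Hz (clip %.0f g)\n",
              length(x$timestamps), diff(range(x$timestamps)),
              x$sample_rate, x$clip_limit))
  invisible(x)
}

#' Read / write acceleration traces
#'
#' CSV with header `t,ax,ay,az`; times in seconds, accelerations in g.
#'
#' @param path File path.
#' @param ... Passed to [accel_trace()].
#' @return `read_accel_trace` returns an `accel_trace`.
#' @export
read_accel_trace <- function(path, ...) {
  d <- utils::read.csv(path)
  need <- c("t", "ax", "ay", "az")
  if (!all(need %in% names(d)))
    stop("trace CSV must have columns t,ax,ay,az", call. = FALSE)
  accel_trace(d$t, d$ax, d$ay, d$az, ...)
}

#' @param trace An `accel_trace`.
#' @rdname read_accel_trace
#' @export
write_accel_trace <- function(trace, path) {
  utils::write.csv(data.frame(t = trace$timestamps, ax = trace$ax,
                              ay = trace$ay, az = trace$az),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Gravity-removed dynamic acceleration magnitude
#'
#' Subtracts the static component of each axis (its median over the trace,
#' dominated by gravity plus sensor offset) and returns the Euclidean norm of
#' the residual 3-axis signal at every sample. All transport metrics are
#' computed on this magnitude.
#'
#' @param trace An [accel_trace()].
#' @return Numeric vector of dynamic magnitudes in g, one per sample.
#' @export
dynamic_magnitude <- function(trace) {
  if (!inherits(trace, "accel_trace"))
    stop("expected an accel_trace", call. = FALSE)
  dx <- trace$ax - stats::median(trace$ax)
  dy <- trace$ay - stats::median(trace$ay)
  dz <- trace$az - stats::median(trace$az)
  sqrt(dx^2 + dy^2 + dz^2)
}

#' Mean Teager-Kaiser energy of a signal
#'
#' Discrete instantaneous-energy operator psi(n) = x(n)^2 - x(n-1) x(n+1),
#' averaged over the interior samples; an estimator of the mean energy of an
#' oscillatory signal (units g^2 for acceleration input).
#'
#' @param signal Numeric vector, length >= 3.
#' @return Scalar mean Teager-Kaiser energy.
#' @export
mean_teager_kaiser <- function(signal) {
  n <- length(signal)
  if (n < 3L) stop("Teager-Kaiser needs at least 3 samples", call. = FALSE)
  x <- as.numeric(signal)
  psi <- x[2:(n - 1)]^2 - x[1:(n - 2)] * x[3:n]
  mean(psi)
}

#' Root mean square of a signal
#'
#' @param signal Numeric vector, length >= 1.
#' @return sqrt(mean(signal^2)).
#' @export
rms <- function(signal) {
  if (length(signal) < 1L) stop("rms of an empty signal", call. = FALSE)
  sqrt(mean(as.numeric(signal)^2))
}

#' Vibration dose value
#'
#' Fourth root of the time integral of the fourth power of acceleration
#' (rectangle rule), in g s^(1/4); emphasizes shocks over sustained
#' oscillation.
#'
#' @param signal Numeric vector of accelerations in g.
#' @param dt Sampling interval in seconds (> 0).
#' @return Scalar VDV.
#' @export
vdv <- function(signal, dt) {
  if (length(signal) < 1L) stop("vdv of an empty signal", call. = FALSE)
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a positive scalar", call. = FALSE)
  (sum(as.numeric(signal)^4) * dt)^0.25
}

#' Count shock events above a threshold
#'
#' A shock is one maximal contiguous run of samples strictly above the
#' threshold, so a single physical excursion spanning several samples counts
#' once.
#'
#' @param signal Numeric vector (dynamic magnitude in g).
#' @param threshold Shock threshold in g (default 2.5).
#' @return Integer number of excursions.
#' @export
count_shocks <- function(signal, threshold = 2.5) {
  if (!is.numeric(threshold) || threshold <= 0)
    stop("threshold must be positive", call. = FALSE)
  above <- as.numeric(signal) > threshold
  if (!length(above)) return(0L)
  # count rising edges of the above-threshold indicator
  sum(above & !c(FALSE, above[-length(above)]))
}

# Resample a magnitude signal onto a uniform grid (linear interpolation);
# returns list(x, dt). Traces from the sensor are near-uniform already.
# raw = TRUE uses the unsubtracted vector magnitude |a|: an oscillation
# riding on gravity keeps its sign there, whereas gravity removal would
# rectify it and double its apparent frequency.
.uniform_signal <- function(trace, raw = FALSE) {
  m <- if (raw) sqrt(trace$ax^2 + trace$ay^2 + trace$az^2)
       else dynamic_magnitude(trace)
  t <- trace$timestamps
  dt <- stats::median(diff(t))
  if (max(abs(diff(t) - dt)) < 1e-9 * max(dt, 1)) {
    return(list(x = m, t = t, dt = dt))
  }
  grid <- seq(t[1], t[length(t)], by = dt)
  list(x = stats::approx(t, m, xout = grid)$y, t = grid, dt = dt)
}

#' Dominant ground frequency of an oscillatory trace
#'
#' Fourier-transforms the mean-removed acceleration magnitude within a
#' window and returns the frequency of the maximal discrete-Fourier
#' magnitude, searched in (0.2 Hz, Nyquist]. The lower bound excludes slow
#' drift. The spectrum is taken on the raw vector magnitude (not the
#' gravity-removed one): a vertical gait oscillation rides on the 1 g
#' baseline and keeps its sign there, whereas rectifying it by gravity
#' removal would double its apparent frequency. Carrier walks show a stable
#' gait line near 4 Hz; pneumatic-tube traces have no dominant line.
#'
#' @param trace An [accel_trace()].
#' @param window Numeric `c(start, end)` in seconds, duration between 0.5 and
#'   3 minutes, inside the trace. `NULL` picks the most stationary 60 s
#'   segment (minimal variance of short-window RMS).
#' @return Dominant frequency in Hz.
#' @export
ground_frequency <- function(trace, window = NULL) {
  u <- .uniform_signal(trace, raw = TRUE)
  if (is.null(window)) window <- default_window(trace)
  if (length(window) != 2L || diff(window) < 30 - 1e-9 ||
      diff(window) > 180 + 1e-9)
    stop("window duration must be between 0.5 and 3 minutes", call. = FALSE)
  if (window[1] < u$t[1] - 1e-9 || window[2] > u$t[length(u$t)] + 1e-9)
    stop("window lies outside the trace", call. = FALSE)
  sel <- u$t >= window[1] & u$t <= window[2]
  x <- u$x[sel]
  x <- x - mean(x)
  if (all(abs(x) < 1e-12))
    stop("no dominant frequency: window signal is constant", call. = FALSE)
  n <- length(x)
  spec <- Mod(stats::fft(x))[seq_len(floor(n / 2) + 1)]
  freq <- (seq_along(spec) - 1) / (n * u$dt)
  nyq <- 1 / (2 * u$dt)
  band <- freq > 0.2 & freq <= nyq + 1e-12
  if (!any(band))
    stop("no dominant frequency: empty search band", call. = FALSE)
  freq[band][which.max(spec[band])]
}

#' Default ground-frequency window
#'
#' The 60 s segment of the trace whose short-window (5 s) RMS values have
#' minimal variance, i.e. the most stationary stretch of the recording;
#' shorter traces fall back to the whole trace (if it spans at least 30 s).
#'
#' @param trace An [accel_trace()].
#' @return Numeric `c(start, end)` in seconds.
#' @export
default_window <- function(trace) {
  u <- .uniform_signal(trace)
  total <- u$t[length(u$t)] - u$t[1]
  if (total < 30)
    stop("trace too short for a ground-frequency window", call. = FALSE)
  wlen <- min(60, total)
  sub <- max(1L, round(5 / u$dt))      # 5 s RMS sub-windows
  nw <- max(1L, floor((total - wlen) / 1) + 1L)
  starts <- u$t[1] + (seq_len(nw) - 1) * 1
  best <- starts[1]; best_v <- Inf
  for (s in starts) {
    sel <- which(u$t >= s & u$t <= s + wlen)
    if (length(sel) < 2 * sub) next
    chunks <- split(u$x[sel], (seq_along(sel) - 1) %/% sub)
    v <- stats::var(vapply(chunks, rms, numeric(1)))
    if (is.finite(v) && v < best_v) { best_v <- v; best <- s }
  }
  c(best, best + wlen)
}

#' Summarize a transport event
#'
#' Computes the transport metrics on the gravity-removed dynamic magnitude:
#' mean Teager-Kaiser energy (g^2), RMS (g), vibration dose value
#' (g s^0.25), duration (minutes), maximum and median amplitude (g), number
#' of shocks above `shock_threshold`, and -- when a window is given or
#' `ground_freq = TRUE` -- the dominant ground frequency (Hz).
#'
#' @param trace An [accel_trace()].
#' @param window Optional `c(start, end)` seconds for the ground-frequency
#'   estimate; `NULL` with `ground_freq = TRUE` uses [default_window()].
#' @param ground_freq Estimate the ground frequency? Defaults to `TRUE` when
#'   a window is supplied.
#' @param shock_threshold Shock threshold in g (default 2.5).
#' @return A `transport_metrics` object (named list; `ground_frequency` is
#'   `NA` when not requested).
#' @export
summarize_transport <- function(trace, window = NULL,
                                ground_freq = !is.null(window),
                                shock_threshold = 2.5) {
  u <- .uniform_signal(trace)
  gf <- NA_real_
  if (isTRUE(ground_freq)) gf <- ground_frequency(trace, window)
  structure(list(
    tk = mean_teager_kaiser(u$x),
    rms = rms(u$x),
    vdv = vdv(u$x, u$dt),
    duration = diff(range(trace$timestamps)) / 60,
    max_amplitude = max(u$x),
    median_amplitude = stats::median(u$x),
    shock_count = count_shocks(u$x, shock_threshold),
    ground_frequency = gf
  ), class = "transport_metrics")
}

#' @export
print.transport_metrics <- function(x, ...) {
  cat(sprintf(paste0("transport_metrics: TK %.4g g^2, RMS %.4g g, ",
                     "VDV %.4g g.s^0.25\n  duration %.2f min, max %.2f g, ",
                     "median %.3f g, %d shocks > threshold"),
              x$tk, x$rms, x$vdv, x$duration, x$max_amplitude,
              x$median_amplitude, x$shock_count))
  if (is.finite(x$ground_frequency))
    cat(sprintf(", ground frequency %.2f Hz", x$ground_frequency))
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.transport_metrics <- function(x, ...) {
  data.frame(tk = x$tk, rms = x$rms, vdv = x$vdv, duration = x$duration,
             max_amplitude = x$max_amplitude,
             median_amplitude = x$median_amplitude,
             shock_count = x$shock_count,
             ground_frequency = x$ground_frequency)
}
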