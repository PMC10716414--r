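#' Construct a force trace
#'
#' A `force_trace` holds one uniformly sampled isometric force recording from
#' an in vitro syringeal muscle preparation, either a single twitch or a
#' tetanic contraction. Time is carried in seconds and force in millinewtons;
#' recordings are typically digitized at 20 or 40 kHz.
#'
#' @param force numeric vector of force samples (mN).
#' @param time optional numeric vector of sample times (s), strictly
#'   increasing and uniformly spaced. If omitted it is derived from
#'   `sample_rate`.
#' @param sample_rate sampling rate in Hz. Derived from `time` when omitted.
#' @param kind `"twitch"` or `"tetanus"`.
#' @param stimulus_onset stimulation onset time (s); the baseline window of
#'   downstream metrics ends here.
#' @return An object of class `force_trace` with elements `time`, `force`,
#'   `sample_rate`, `kind`, `stimulus_onset`.
#' @examples
#' tr <- force_trace(c(0, 0, 1, 2, 1, 0, 0), sample_rate = 1000,
#'                   kind = "twitch", stimulus_onset = 0.001)
#' tr
#' @export
force_trace <- function(force, time = NULL, sample_rate = NULL,
                        kind = c("twitch", "tetanus"), stimulus_onset = 0) {
  kind <- match.arg(kind)
  force <- as.numeric(force)
  if (length(force) < 3L)
    stop("force trace needs at least 3 samples")
  if (!all(is.finite(force)))
    stop("force must be finite")
  if (is.null(time)) {
    if (is.null(sample_rate) || sample_rate <= 0)
      stop("either 'time' or a positive 'sample_rate' is required")
    time <- (seq_along(force) - 1L) / sample_rate
  } else {
    time <- as.numeric(time)
    if (length(time) != length(force))
      stop("'time' and 'force' lengths differ")
    dt <- diff(time)
    if (any(dt <= 0))
      stop("time must be strictly increasing")
    if (diff(range(dt)) > 1e-6 * mean(dt))
      stop("time must be uniformly sampled")
    if (is.null(sample_rate)) sample_rate <- 1 / mean(dt)
  }
  structure(list(time = time, force = force, sample_rate = sample_rate,
                 kind = kind, stimulus_onset = stimulus_onset),
            class = "force_trace")
}

#' @export
print.force_trace <- function(x, ...) {
  cat(sprintf("<force_trace: %s, %d samples @ %.4g kHz, %.1f ms, peak %.3g mN>\n",
              x$kind, length(x$force), x$sample_rate / 1000,
              1000 * (x$time[length(x$time)] - x$time[1]), max(x$force)))
  invisible(x)
}

#' @export
plot.force_trace <- function(x, ...) {
  graphics::plot(x$time * 1000, x$force, type = "l",
                 xlab = "time (ms)", ylab = "force (mN)",
                 main = sprintf("%s trace", x$kind), ...)
  graphics::abline(v = x$stimulus_onset * 1000, lty = 3)
  invisible(x)
}

#' Read a force trace from a CSV/TSV file
#'
#' Expects columns `time_s` and `force_mN` (comma- or tab-separated,
#' autodetected).
#'
#' @param path file path.
#' @inheritParams force_trace
#' @return A [force_trace].
#' @export
read_force_csv <- function(path, kind = c("twitch", "tetanus"),
                           stimulus_onset = 0) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep)
  if (!all(c("time_s", "force_mN") %in% names(df)))
    stop("expected columns time_s, force_mN")
  force_trace(df$force_mN, time = df$time_s, kind = kind,
              stimulus_onset = stimulus_onset)
}

# Mean force over the pre-stimulus window [onset - window, onset).
.baseline <- function(trace, baseline_window) {
  sel <- trace$time >= trace$stimulus_onset - baseline_window &
    trace$time < trace$stimulus_onset
  if (!any(sel)) sel <- seq_len(min(5L, length(trace$force)))
  mean(trace$force[sel])
}

# First crossing of `level` in direction `dir` (+1 upward, -1 downward)
# starting at index `from`, with linear interpolation between samples.
# Returns the crossing time or NA.
.cross_time <- function(time, force, level, from, dir) {
  n <- length(force)
  if (from >= n) return(NA_real_)
  f <- force[from:n] - level
  idx <- if (dir > 0) which(f[-length(f)] < 0 & f[-1] >= 0)
         else         which(f[-length(f)] >= 0 & f[-1] < 0)
  if (length(idx) == 0L) return(NA_real_)
  i <- from + idx[1L] - 1L
  # interpolate between samples i and i+1
  f1 <- force[i] - level; f2 <- force[i + 1L] - level
  if (f2 == f1) return(time[i])
  time[i] + (time[i + 1L] - time[i]) * (0 - f1) / (f2 - f1)
}

#' Twitch contraction speed: full width at half maximum force
#'
#' Contraction speed of a single twitch is summarized as the full width at
#' half maximal force (FWHM, also called t\eqn{_{50-50}}): the interval from
#' the first upward crossing of 50% of the force rise above baseline to the
#' first subsequent downward crossing. Crossings are located with linear
#' interpolation between adjacent samples, so the estimate has sub-sample
#' precision. Baseline is the mean force over a pre-stimulus window.
#'
#' @param trace a [force_trace] with `kind = "twitch"`.
#' @param baseline_window length (s) of the pre-stimulus window used for the
#'   baseline estimate; default 10 ms.
#' @return An object of class `twitch_metrics`: list with `fwhm` (ms),
#'   `peak_force` (mN), `baseline` (mN).
#' @examples
#' tr <- simulate_twitch_trace(target_fwhm = 5, seed = 1)
#' compute_fwhm(tr$trace)
#' @export
compute_fwhm <- function(trace, baseline_window = 0.010) {
  stopifnot(inherits(trace, "force_trace"))
  if (trace$kind != "twitch") stop("compute_fwhm expects a twitch trace")
  b <- .baseline(trace, baseline_window)
  pk <- max(trace$force)
  if (pk - b <= 0) stop("no contraction")
  half <- b + 0.5 * (pk - b)
  start <- which(trace$time >= trace$stimulus_onset)[1L]
  if (is.na(start)) start <- 1L
  t_up <- .cross_time(trace$time, trace$force, half, start, +1)
  if (is.na(t_up)) stop("incomplete twitch")
  i_up <- findInterval(t_up, trace$time)
  t_dn <- .cross_time(trace$time, trace$force, half, i_up + 1L, -1)
  if (is.na(t_dn)) stop("incomplete twitch")
  structure(list(fwhm = 1000 * (t_dn - t_up), peak_force = pk, baseline = b),
            class = "twitch_metrics")
}

#' @export
print.twitch_metrics <- function(x, ...) {
  cat(sprintf("<twitch_metrics: FWHM %.3f ms, peak %.3g mN, baseline %.3g mN>\n",
              x$fwhm, x$peak_force, x$baseline))
  invisible(x)
}

#' Summarize a session of twitch contractions
#'
#' A recording session typically yields several twitches (the in vitro
#' protocol collects seven); per-twitch metrics are reported alongside their
#' arithmetic mean.
#'
#' @param traces list of twitch [force_trace]s.
#' @inheritParams compute_fwhm
#' @return list with `per_twitch` (data.frame of fwhm/peak/baseline) and
#'   `mean_fwhm` (ms).
#' @export
summarize_twitch_session <- function(traces, baseline_window = 0.010) {
  m <- lapply(traces, compute_fwhm, baseline_window = baseline_window)
  df <- data.frame(twitch = seq_along(m),
                   fwhm = vapply(m, `[[`, 0, "fwhm"),
                   peak_force = vapply(m, `[[`, 0, "peak_force"),
                   baseline = vapply(m, `[[`, 0, "baseline"))
  list(per_twitch = df, mean_fwhm = mean(df$fwhm))
}

#' Preparation geometry and muscle cross-sectional area
#'
#' Muscle cross-sectional area (CSA) is estimated from the preparation's
#' optimal (resting) length \eqn{L_0}, its dry mass (converted to wet mass
#' with a dry-to-wet factor, default 5) and fibre density (default
#' 1060 kg/m\eqn{^3}): CSA = wet volume / \eqn{L_0}.
#'
#' @param optimal_length_L0 resting length \eqn{L_0} (mm).
#' @param dry_mass dry mass (mg).
#' @param dry_wet_factor dry-to-wet mass conversion factor (default 5).
#' @param density fibre density (kg/m^3, default 1060).
#' @return An object of class `preparation_geometry` with a `csa` field
#'   (mm^2) filled in by [estimate_csa()].
#' @examples
#' g <- preparation_geometry(optimal_length_L0 = 5, dry_mass = 1.06)
#' g$csa  # 1.0 mm^2
#' @export
preparation_geometry <- function(optimal_length_L0, dry_mass,
                                 dry_wet_factor = 5, density = 1060) {
  g <- structure(list(optimal_length_L0 = optimal_length_L0,
                      dry_mass = dry_mass, dry_wet_factor = dry_wet_factor,
                      density = density, csa = NA_real_),
                 class = "preparation_geometry")
  estimate_csa(g)
}

#' Estimate muscle cross-sectional area from preparation geometry
#'
#' CSA (mm^2) = wet mass / (density x L0), with wet mass = dry mass x
#' dry-to-wet factor. With dry mass in mg, L0 in mm and density in kg/m^3 the
#' conversion is CSA = dry_mass x factor x 1000 / (density x L0).
#'
#' @param geometry a [preparation_geometry].
#' @return the geometry with `csa` (mm^2) stored.
#' @export
estimate_csa <- function(geometry) {
  stopifnot(inherits(geometry, "preparation_geometry"))
  with(geometry, {
    if (any(c(optimal_length_L0, dry_mass, dry_wet_factor, density) <= 0))
      stop("invalid geometry")
  })
  wet_mg <- geometry$dry_mass * geometry$dry_wet_factor
  # 1 mg = 1e-6 kg and 1 m^3 = 1e9 mm^3, so vol[mm^3] = mg * 1000 / (kg/m^3)
  vol_mm3 <- wet_mg * 1000 / geometry$density
  geometry$csa <- vol_mm3 / geometry$optimal_length_L0
  geometry
}

#' @export
print.preparation_geometry <- function(x, ...) {
  cat(sprintf("<preparation_geometry: L0 %.3g mm, dry %.3g mg (x%g), density %g kg/m^3, CSA %.4g mm^2>\n",
              x$optimal_length_L0, x$dry_mass, x$dry_wet_factor, x$density, x$csa))
  invisible(x)
}

#' Maximal isometric stress from a tetanic contraction
#'
#' Maximal isometric stress (MIS) is the maximal baseline-subtracted tetanic
#' force divided by the muscle cross-sectional area, reported in mN/mm^2.
#' The maximum is the global maximum of the trace (no plateau fitting).
#'
#' @param trace a [force_trace] with `kind = "tetanus"`.
#' @param geometry a [preparation_geometry] with a positive `csa`.
#' @inheritParams compute_fwhm
#' @return An object of class `tetanus_metrics`: list with `max_force` (mN)
#'   and `mis` (mN/mm^2).
#' @export
compute_mis <- function(trace, geometry, baseline_window = 0.010) {
  stopifnot(inherits(trace, "force_trace"),
            inherits(geometry, "preparation_geometry"))
  if (trace$kind != "tetanus") stop("compute_mis expects a tetanus trace")
  if (!is.finite(geometry$csa) || geometry$csa <= 0)
    stop("csa must be positive; run estimate_csa()")
  b <- .baseline(trace, baseline_window)
  max_force <- max(trace$force - b)
  if (max_force < 0) max_force <- 0
  structure(list(max_force = max_force, mis = max_force / geometry$csa),
            class = "tetanus_metrics")
}

#' @export
print.tetanus_metrics <- function(x, ...) {
  cat(sprintf("<tetanus_metrics: max force %.4g mN, MIS %.4g mN/mm^2>\n",
              x$max_force, x$mis))
  invisible(x)
}
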