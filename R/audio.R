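#' Construct a calibrated audio recording
#'
#' Wraps a sampled sound-pressure signal. `samples` are digital units that
#' are converted to pascal with the `calibration` constant (Pa per digital
#' unit), obtained from a 1 Pa / 1 kHz calibration tone of the recording
#' chain. Pass `calibration = 1` if `samples` are already in Pa.
#'
#' @param samples numeric vector of samples (digital units).
#' @param sample_rate sampling rate (Hz), default 44100; must exceed twice
#'   the 12 kHz analysis band edge.
#' @param calibration Pa per digital unit, positive.
#' @return object of class `audio_recording` with `samples` in Pa.
#' @export
audio_recording <- function(samples, sample_rate = 44100, calibration = 1) {
  if (sample_rate <= 2 * 12000)
    stop("sample_rate must exceed 24 kHz for the 200-12,000 Hz band")
  if (calibration <= 0) stop("calibration must be positive")
  structure(list(samples = as.numeric(samples) * calibration,
                 sample_rate = sample_rate, calibration = calibration),
            class = "audio_recording")
}

#' @export
print.audio_recording <- function(x, ...) {
  cat(sprintf("<audio_recording: %.3f s @ %g Hz, calibration %.3g Pa/unit>\n",
              length(x$samples) / x$sample_rate, x$sample_rate, x$calibration))
  invisible(x)
}

#' Read / write 16-bit PCM WAV files
#'
#' A plain RIFF/WAVE codec for uncompressed 16-bit PCM mono files (multi-
#' channel files are averaged to mono on read).
#'
#' @param path file path.
#' @param calibration Pa per digital full-scale unit (sample values are
#'   scaled to \[-1, 1\] before calibration).
#' @return `read_wav`: an [audio_recording]. `write_wav`: `path`, invisibly.
#' @export
read_wav <- function(path, calibration = 1) {
  con <- file(path, "rb"); on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (!identical(riff, "RIFF")) stop("not a RIFF file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  if (!identical(readChar(con, 4, useBytes = TRUE), "WAVE"))
    stop("not a WAVE file")
  sample_rate <- NULL; n_channels <- 1L; bits <- 16L; data <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0L || nchar(id) < 4) break
    sz <- readBin(con, "integer", 1, 4, endian = "little")
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "integer", sz %/% 2, 2, endian = "little",
                     signed = FALSE)
      if (fmt[1] != 1L) stop("only PCM WAV is supported")
      n_channels <- fmt[2]
      sample_rate <- fmt[3] + 65536 * fmt[4]
      bits <- fmt[8]
      if (bits != 16L) stop("only 16-bit PCM is supported")
    } else if (identical(id, "data")) {
      data <- readBin(con, "integer", sz %/% 2, 2, endian = "little")
      break
    } else {
      invisible(readBin(con, "raw", sz))
    }
  }
  if (is.null(data) || is.null(sample_rate)) stop("malformed WAV file")
  x <- data / 32768
  if (n_channels > 1L)
    x <- rowMeans(matrix(x, ncol = n_channels, byrow = TRUE))
  audio_recording(x, sample_rate, calibration)
}

#' @param samples numeric vector in \[-1, 1\] (clipped otherwise), or an
#'   [audio_recording] whose Pa samples are rescaled by its calibration.
#' @param sample_rate sampling rate (Hz); taken from the recording if one is
#'   given.
#' @rdname read_wav
#' @export
write_wav <- function(samples, path, sample_rate = 44100) {
  if (inherits(samples, "audio_recording")) {
    sample_rate <- samples$sample_rate
    samples <- samples$samples / samples$calibration
  }
  x <- as.integer(round(pmin(1, pmax(-1, samples)) * 32767))
  con <- file(path, "wb"); on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * length(x)), con, 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, 4, endian = "little")
  writeBin(as.integer(c(1, 1)), con, 2, endian = "little")       # PCM, mono
  writeBin(as.integer(sample_rate), con, 4, endian = "little")
  writeBin(as.integer(sample_rate * 2), con, 4, endian = "little")
  writeBin(as.integer(c(2, 16)), con, 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * length(x)), con, 4, endian = "little")
  writeBin(x, con, 2, endian = "little")
  invisible(path)
}

#' Acoustic analysis parameters
#'
#' Frame grid and estimator settings for [compute_frame_features()]. The
#' signal is bandpass filtered once per recording with a 2nd-order zero-phase
#' Butterworth (forward-backward), then analysed in 4 ms windows advanced in
#' 0.5 ms steps.
#'
#' @param window analysis window (s), default 0.004.
#' @param hop hop between frames (s), default 0.0005.
#' @param band bandpass edges (Hz), default `c(200, 12000)`.
#' @param f0_range Yin search range (Hz), default `c(300, 8000)`. The Yin
#'   window is extended beyond the 4 ms bin when the maximum lag requires it.
#' @param yin_threshold Yin absolute threshold on the cumulative-mean-
#'   normalized difference, default 0.15.
#' @param nfft FFT length for the Wiener-entropy spectrum, default 512
#'   (Hann-windowed frame, zero-padded).
#' @return list of class `frame_params`.
#' @export
frame_params <- function(window = 0.004, hop = 0.0005,
                         band = c(200, 12000), f0_range = c(300, 8000),
                         yin_threshold = 0.15, nfft = 512) {
  structure(list(window = window, hop = hop, band = band,
                 f0_range = f0_range, yin_threshold = yin_threshold,
                 nfft = nfft),
            class = "frame_params")
}

# reference pressure squared, (20 uPa)^2
.P_REF2 <- (20e-6)^2

.bandpass <- function(x, fs, band) {
  bf <- signal::butter(2, band / (fs / 2), type = "pass")
  signal::filtfilt(bf, x)
}

# Yin on one segment: seg has length >= W + tau_max, integration window W.
# Returns c(f0, aperiodicity); NA f0 when the frame is silent.
.yin_frame <- function(seg, fs, tau_min, tau_max, threshold) {
  W <- tau_max
  N <- W + tau_max
  if (length(seg) < N) return(c(NA_real_, NA_real_))
  seg <- seg[seq_len(N)]
  nfft <- 2^ceiling(log2(N))
  X <- stats::fft(c(seg, numeric(nfft - N)))
  Xw <- stats::fft(c(seg[seq_len(W)], numeric(nfft - W)))
  cc <- Re(stats::fft(X * Conj(Xw), inverse = TRUE)) / nfft
  cum <- cumsum(seg^2)
  E0 <- cum[W]
  if (E0 <= 0) return(c(NA_real_, NA_real_))
  taus <- seq_len(tau_max)
  Etau <- cum[taus + W] - cum[taus]
  d <- E0 + Etau - 2 * cc[taus + 1L]
  d[d < 0] <- 0
  dp <- d * taus / pmax(cumsum(d), .Machine$double.xmin)
  lo <- max(2L, tau_min)
  below <- which(dp[lo:tau_max] < threshold)
  if (length(below) > 0L) {
    tau <- lo + below[1L] - 1L
    while (tau < tau_max && dp[tau + 1L] < dp[tau]) tau <- tau + 1L
  } else {
    tau <- lo + which.min(dp[lo:tau_max]) - 1L
  }
  ap <- dp[tau]
  ti <- tau
  if (tau > 1L && tau < tau_max) {
    a <- dp[tau - 1L]; b <- dp[tau]; c2 <- dp[tau + 1L]
    den <- a - 2 * b + c2
    if (den > 0) {
      delta <- 0.5 * (a - c2) / den
      ti <- tau + max(-0.5, min(0.5, delta))
      ap <- b - 0.25 * (a - c2) * delta
    }
  }
  c(fs / ti, max(0, min(1, ap)))
}

#' Per-frame acoustic features
#'
#' Bandpass filters the recording (2nd-order Butterworth, zero-phase
#' forward-backward), then computes per 4 ms frame (0.5 ms hop): mean squared
#' pressure (power, Pa^2); source level `10*log10(power / (20 uPa)^2)` in
#' dB re 20 uPa (at 1 m via the recording-chain calibration); Wiener entropy
#' `10*log10(geometric mean / arithmetic mean)` of the Hann-windowed power
#' spectrum restricted to the passband bins (the mandatory bandpass filter
#' empties out-of-band bins, which would otherwise dominate the geometric
#' mean); fundamental frequency by the Yin algorithm (difference function,
#' cumulative-mean-normalized difference, absolute threshold, parabolic
#' interpolation), with the window extended beyond the 4 ms bin as the
#' maximum lag requires; and aperiodicity, the cumulative-mean-normalized
#' difference minimum at the chosen lag (0 = perfectly periodic).
#'
#' @param audio an [audio_recording].
#' @param params a [frame_params].
#' @param compute_f0 set `FALSE` to skip the (costlier) Yin pass.
#' @return data.frame of class `acoustic_frames` with columns `time` (frame
#'   start, s), `power`, `source_level`, `wiener_entropy`, `f0`,
#'   `aperiodicity`, and attributes `hop` and `window`. Silent frames have
#'   `source_level = -Inf` and missing `f0`.
#' @export
compute_frame_features <- function(audio, params = frame_params(),
                                   compute_f0 = TRUE) {
  stopifnot(inherits(audio, "audio_recording"))
  fs <- audio$sample_rate
  x <- .bandpass(audio$samples, fs, params$band)
  win_n <- max(2L, round(params$window * fs))
  n <- length(x)
  starts <- seq(0, by = params$hop,
                length.out = max(0L, floor((n - win_n) / (params$hop * fs)) + 1L))
  si <- round(starts * fs) + 1L
  nf <- length(si)
  power <- numeric(nf); went <- rep(NA_real_, nf)
  f0 <- rep(NA_real_, nf); ap <- rep(NA_real_, nf)
  hann <- 0.5 - 0.5 * cos(2 * pi * seq_len(win_n) / (win_n + 1))
  nfft <- params$nfft
  freqs <- (seq_len(nfft %/% 2) - 1L) * fs / nfft
  bandsel <- freqs >= params$band[1] & freqs <= params$band[2]
  tau_max <- floor(fs / params$f0_range[1])
  tau_min <- max(2L, floor(fs / params$f0_range[2]))
  for (k in seq_len(nf)) {
    fr <- x[si[k]:(si[k] + win_n - 1L)]
    power[k] <- mean(fr^2)
    if (power[k] > 0) {
      sp <- Mod(stats::fft(c(fr * hann, numeric(nfft - win_n))))^2
      sp <- sp[seq_len(nfft %/% 2)][bandsel]
      sp <- sp / mean(sp)
      sp <- pmax(sp, 1e-12)
      went[k] <- 10 * log10(exp(mean(log(sp))) / mean(sp))
      if (compute_f0) {
        seg <- x[si[k]:min(n, si[k] + 2L * tau_max - 1L)]
        r <- .yin_frame(seg, fs, tau_min, tau_max, params$yin_threshold)
        f0[k] <- r[1]; ap[k] <- r[2]
      }
    }
  }
  sl <- ifelse(power > 0, 10 * log10(power / .P_REF2), -Inf)
  out <- data.frame(time = starts, power = power, source_level = sl,
                    wiener_entropy = went, f0 = f0, aperiodicity = ap)
  attr(out, "hop") <- params$hop
  attr(out, "window") <- params$window
  class(out) <- c("acoustic_frames", "data.frame")
  out
}
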