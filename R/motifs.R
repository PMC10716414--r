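# Sliding RMS envelope at full sample rate.
.envelope <- function(x, fs, smooth = 0.002) {
  w <- max(3L, round(smooth * fs))
  e2 <- stats::filter(x^2, rep(1 / w, w), sides = 2)
  e2[is.na(e2)] <- 0
  sqrt(pmax(0, as.numeric(e2)))
}

# Normalized (mean-removed, Pearson) cross-correlation of the template
# envelope against every window of the signal envelope, via FFT.
.ncc <- function(env, tenv) {
  n <- length(env); m <- length(tenv)
  t0 <- tenv - mean(tenv)
  tn <- sqrt(sum(t0^2))
  nfft <- 2^ceiling(log2(n + m))
  num <- Re(stats::fft(stats::fft(c(env, numeric(nfft - n))) *
                       Conj(stats::fft(c(t0, numeric(nfft - m)))),
                       inverse = TRUE)) / nfft
  num <- num[seq_len(n - m + 1L)]          # sum(env_w * t0) per window
  cs <- cumsum(c(0, env))
  cs2 <- cumsum(c(0, env^2))
  wsum <- cs[(m + 1L):(n + 1L)] - cs[seq_len(n - m + 1L)]
  wss <- cs2[(m + 1L):(n + 1L)] - cs2[seq_len(n - m + 1L)]
  wvar <- pmax(0, wss - wsum^2 / m)
  out <- numeric(n - m + 1L)
  ok <- wvar > 1e-20 & tn > 0
  out[ok] <- num[ok] / (sqrt(wvar[ok]) * tn)
  out
}

#' Detect and align motif instances by template cross-correlation
#'
#' Candidate motifs are found as peaks of the normalized cross-correlation
#' between the template's amplitude envelope and the recording's, with
#' greedy non-overlap suppression (one template length around each accepted
#' peak). Each candidate is then refined by shifting it to the lag that
#' maximizes the correlation of its source-level trace with the session
#' reference (the strongest detection). When `sl_threshold` is supplied, the
#' detections are additionally syllable-segmented and only motifs sharing
#' the most common syntax (modal syllable count plus coarse-quantized
#' durations) are kept.
#'
#' @param audio an [audio_recording].
#' @param template an [audio_recording] (or numeric Pa vector) holding one
#'   motif; must be shorter than the recording.
#' @param threshold detection threshold on the normalized cross-correlation,
#'   default 0.5.
#' @param sl_threshold optional source-level threshold (dB) enabling the
#'   modal-syntax filter.
#' @param max_shift maximum source-level alignment shift (s), default 0.01.
#' @param params a [frame_params] for the source-level traces.
#' @return data.frame of class `motif_set`: `onset` (s, envelope detection),
#'   `onset_aligned` (s, after source-level alignment), `aligned_offset`
#'   (frames), `score`. Attribute `"slices"` holds the aligned Pa slices.
#' @export
detect_and_align_motifs <- function(audio, template, threshold = 0.5,
                                    sl_threshold = NULL, max_shift = 0.01,
                                    params = frame_params()) {
  stopifnot(inherits(audio, "audio_recording"))
  fs <- audio$sample_rate
  tx <- if (inherits(template, "audio_recording")) template$samples
        else as.numeric(template)
  if (length(tx) >= length(audio$samples))
    stop("template must be shorter than the recording")
  x <- .bandpass(audio$samples, fs, params$band)
  txf <- .bandpass(tx, fs, params$band)
  env <- .envelope(x, fs); tenv <- .envelope(txf, fs)
  cc <- .ncc(env, tenv)
  m <- length(tx)
  onsets <- integer(0); scores <- numeric(0)
  work <- cc
  repeat {
    i <- which.max(work)
    if (length(i) == 0L || work[i] < threshold) break
    onsets <- c(onsets, i); scores <- c(scores, work[i])
    lo <- max(1L, i - m + 1L); hi <- min(length(work), i + m - 1L)
    work[lo:hi] <- -Inf
  }
  if (length(onsets) == 0L) {
    out <- data.frame(onset = numeric(), onset_aligned = numeric(),
                      aligned_offset = integer(), score = numeric())
    attr(out, "slices") <- list()
    class(out) <- c("motif_set", "data.frame")
    return(out)
  }
  ord <- order(onsets)
  onsets <- onsets[ord]; scores <- scores[ord]

  # source-level traces per candidate; reference = strongest detection
  slice_of <- function(i) {
    s <- audio$samples[i:min(length(audio$samples), i + m - 1L)]
    audio_recording(s, fs, 1)
  }
  sl_traces <- lapply(onsets, function(i)
    compute_frame_features(slice_of(i), params, compute_f0 = FALSE)$source_level)
  ref <- sl_traces[[which.max(scores)]]
  hop_n <- round(params$hop * fs)
  max_fr <- max(0L, round(max_shift / params$hop))
  align <- vapply(sl_traces, function(sl) {
    best <- 0L; bestr <- -Inf
    for (lag in -max_fr:max_fr) {
      if (lag >= 0) { a <- sl[(1 + lag):length(sl)]; b <- ref[seq_along(a)] }
      else { a <- sl[seq_len(length(sl) + lag)]; b <- ref[(1 - lag):length(ref)][seq_along(a)] }
      ok <- is.finite(a) & is.finite(b)
      if (sum(ok) > 3 && stats::sd(a[ok]) > 0 && stats::sd(b[ok]) > 0) {
        r <- stats::cor(a[ok], b[ok])
        if (r > bestr) { bestr <- r; best <- lag }
      }
    }
    best
  }, integer(1))
  onset_aligned <- (onsets - 1L + align * hop_n) / fs
  out <- data.frame(onset = (onsets - 1L) / fs,
                    onset_aligned = onset_aligned,
                    aligned_offset = align, score = scores)
  slices <- lapply(seq_len(nrow(out)), function(k) {
    i <- onsets[k] + align[k] * hop_n
    i <- max(1L, i)
    audio$samples[i:min(length(audio$samples), i + m - 1L)]
  })
  if (!is.null(sl_threshold)) {
    keys <- vapply(slices, function(s) {
      fr <- compute_frame_features(audio_recording(s, fs, 1), params,
                                   compute_f0 = FALSE)
      sy <- segment_syllables(fr, sl_threshold)
      if (nrow(sy$syllables) == 0L) return("none")
      paste(nrow(sy$syllables),
            paste(round(sy$syllables$duration / 20), collapse = "-"),
            sep = ":")
    }, character(1))
    modal <- names(sort(table(keys), decreasing = TRUE))[1L]
    keep <- keys == modal & keys != "none"
    out <- out[keep, , drop = FALSE]
    slices <- slices[keep]
    rownames(out) <- NULL
  }
  attr(out, "slices") <- slices
  class(out) <- c("motif_set", "data.frame")
  out
}

#' Apply the minimum-duration rules to a binary sound/silence sequence
#'
#' Removes sound runs shorter than `min_sound` first, then removes interior
#' silence runs shorter than `min_silence`, merging the flanking sounds.
#' Leading and trailing silence is never merged. This is the cleaning step of
#' syllable segmentation, exposed so it can be verified in isolation; it is
#' idempotent.
#'
#' @param sound logical vector, one element per frame.
#' @param hop frame hop (s).
#' @param min_sound,min_silence minimum run durations (s), defaults 0.030
#'   and 0.040.
#' @return cleaned logical vector.
#' @export
apply_duration_rules <- function(sound, hop, min_sound = 0.030,
                                 min_silence = 0.040) {
  sound <- as.logical(sound)
  if (length(sound) == 0L) return(sound)
  r <- rle(sound)
  drop <- r$values & r$lengths * hop < min_sound
  r$values[drop] <- FALSE
  sound <- inverse.rle(r)
  r <- rle(sound)
  if (length(r$lengths) > 2L) {
    interior <- seq_along(r$values) > 1L & seq_along(r$values) < length(r$values)
    merge <- !r$values & interior & r$lengths * hop < min_silence
    r$values[merge] <- TRUE
  }
  inverse.rle(r)
}

#' Segment syllables within an aligned motif
#'
#' Frames are classified sound/silence by a fixed per-individual source-level
#' threshold; sound runs shorter than 30 ms and interior silence runs shorter
#' than 40 ms are removed (in that order, see [apply_duration_rules()]).
#' Surviving sound runs are the syllables; motif duration is the summed
#' duration of all syllables and the gaps between them.
#'
#' @param frames an `acoustic_frames` table covering one motif.
#' @param sl_threshold source-level threshold (dB re 20 uPa).
#' @param min_sound,min_silence minimum durations (s).
#' @return list of class `syllable_segmentation`: `syllables` (data.frame
#'   `index, onset, offset, duration, gap_after`, durations in ms, onsets in
#'   s relative to the frame table), `motif_duration` (s; `NA` and an empty
#'   table if no sound survives), `sound` (the cleaned binary frame vector).
#' @export
segment_syllables <- function(frames, sl_threshold, min_sound = 0.030,
                              min_silence = 0.040) {
  hop <- attr(frames, "hop")
  if (is.null(hop)) hop <- stats::median(diff(frames$time))
  sound <- is.finite(frames$source_level) & frames$source_level > sl_threshold
  sound <- apply_duration_rules(sound, hop, min_sound, min_silence)
  r <- rle(sound)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  si <- which(r$values)
  if (length(si) == 0L) {
    return(list(syllables = data.frame(index = integer(), onset = numeric(),
                                       offset = numeric(), duration = numeric(),
                                       gap_after = numeric()),
                motif_duration = NA_real_, sound = sound))
  }
  onset <- frames$time[starts[si]]
  offset <- frames$time[ends[si]] + hop
  gap_after <- c(onset[-1L], NA) - offset
  df <- data.frame(index = seq_along(si), onset = onset, offset = offset,
                   duration = (offset - onset) * 1000,
                   gap_after = gap_after * 1000)
  list(syllables = df,
       motif_duration = offset[length(offset)] - onset[1L],
       sound = sound)
}

#' Per-syllable fundamental-frequency statistics with trace cleaning
#'
#' Within each syllable the f0 trace is cleaned before summary statistics:
#' the trace is split wherever adjacent frames jump by more than 100 Hz (or
#' at missing frames), segments shorter than 5 ms are dropped, and if the
#' surviving frames cover less than `min_coverage` of the syllable's frames
#' the syllable is marked `robust_pitch = FALSE` and its f0 statistics are
#' omitted. Otherwise mean, min, max and range of f0 over surviving frames
#' are reported, along with the mean Wiener entropy over all syllable frames.
#'
#' @param frames the `acoustic_frames` the syllables were segmented from.
#' @param syllables the `syllables` data.frame from [segment_syllables()].
#' @param max_jump maximum allowed adjacent-frame jump (Hz), default 100.
#' @param min_segment minimum surviving segment duration (s), default 0.005.
#' @param min_coverage robustness fraction of syllable frames, default 0.5.
#' @return `syllables` with added columns `f0_mean, f0_min, f0_max, f0_range,
#'   wiener_entropy_mean, robust_pitch`.
#' @export
syllable_f0_stats <- function(frames, syllables, max_jump = 100,
                              min_segment = 0.005, min_coverage = 0.5) {
  hop <- attr(frames, "hop")
  if (is.null(hop)) hop <- stats::median(diff(frames$time))
  n <- nrow(syllables)
  out <- cbind(syllables,
               f0_mean = NA_real_, f0_min = NA_real_, f0_max = NA_real_,
               f0_range = NA_real_, wiener_entropy_mean = NA_real_,
               robust_pitch = FALSE)
  for (k in seq_len(n)) {
    sel <- frames$time >= syllables$onset[k] & frames$time < syllables$offset[k]
    f0 <- frames$f0[sel]
    out$wiener_entropy_mean[k] <- mean(frames$wiener_entropy[sel], na.rm = TRUE)
    if (length(f0) == 0L) next
    # segment ids: increment at missing frames or jumps > max_jump
    jump <- c(TRUE, is.na(f0[-length(f0)]) | is.na(f0[-1L]) |
                abs(diff(f0)) > max_jump)
    seg <- cumsum(jump)
    seg[is.na(f0)] <- NA
    keep <- rep(FALSE, length(f0))
    for (s in unique(seg[!is.na(seg)])) {
      i <- which(seg == s & !is.na(seg))
      if (length(i) * hop >= min_segment) keep[i] <- TRUE
    }
    if (sum(keep) / length(f0) >= min_coverage) {
      v <- f0[keep]
      out$robust_pitch[k] <- TRUE
      out$f0_mean[k] <- mean(v); out$f0_min[k] <- min(v)
      out$f0_max[k] <- max(v); out$f0_range[k] <- max(v) - min(v)
    }
  }
  out
}

#' Compare pre/post song acoustics
#'
#' Syllable-level features (`f0_mean`, `f0_range`, `wiener_entropy_mean`) are
#' compared between conditions with unpaired two-sided t-tests per syllable
#' index, categorized as `increase`, `decrease` or `ns` at `alpha`. When
#' per-animal motif tables (columns `animal`, `motif_duration`,
#' `source_level`) are supplied, per-animal means of motif duration and motif
#' source level are compared with paired two-sided t-tests. The post
#' condition should be restricted to the window immediately after release
#' from singing prevention (0--2 h) by the caller.
#'
#' @param pre,post lists with `$syllables` (data.frame with a `syllable`
#'   index column and the three feature columns, one row per motif x
#'   syllable) and optionally `$motifs` (per-motif data.frame with `animal`,
#'   `motif_duration`, `source_level`).
#' @param alpha significance level, default 0.05.
#' @return list of class `prepost_comparison`: `syllable_tests` (data.frame
#'   `syllable, feature, mean_pre, mean_post, p, category`),
#'   `category_fractions` (per feature), and `animal_tests` (paired t-tests,
#'   or `NULL`).
#' @export
compare_pre_post <- function(pre, post, alpha = 0.05) {
  feats <- c("f0_mean", "f0_range", "wiener_entropy_mean")
  sp <- pre$syllables; sq <- post$syllables
  stopifnot("syllable" %in% names(sp), "syllable" %in% names(sq))
  res <- list()
  for (syl in sort(unique(c(sp$syllable, sq$syllable)))) {
    for (f in feats) {
      if (!f %in% names(sp) || !f %in% names(sq)) next
      a <- sp[[f]][sp$syllable == syl]; a <- a[is.finite(a)]
      b <- sq[[f]][sq$syllable == syl]; b <- b[is.finite(b)]
      if (length(a) < 2L || length(b) < 2L) {
        warning(sprintf("syllable %s, %s: < 2 motifs in a condition; excluded",
                        syl, f))
        next
      }
      tt <- stats::t.test(b, a)
      cat_ <- if (tt$p.value >= alpha) "ns"
              else if (mean(b) > mean(a)) "increase" else "decrease"
      res[[length(res) + 1L]] <-
        data.frame(syllable = syl, feature = f, mean_pre = mean(a),
                   mean_post = mean(b), p = tt$p.value, category = cat_)
    }
  }
  st <- if (length(res)) do.call(rbind, res) else
    data.frame(syllable = integer(), feature = character(),
               mean_pre = numeric(), mean_post = numeric(), p = numeric(),
               category = character())
  st$category <- factor(st$category, levels = c("increase", "decrease", "ns"))
  frac <- if (nrow(st) > 0)
    do.call(rbind, lapply(split(st, st$feature), function(d)
      data.frame(feature = d$feature[1L],
                 increase = mean(d$category == "increase"),
                 decrease = mean(d$category == "decrease"),
                 ns = mean(d$category == "ns"))))
  else NULL
  animal_tests <- NULL
  if (!is.null(pre$motifs) && !is.null(post$motifs) &&
      all(c("animal", "motif_duration", "source_level") %in% names(pre$motifs))) {
    agg <- function(d) stats::aggregate(
      d[, c("motif_duration", "source_level")], list(animal = d$animal), mean)
    a <- agg(pre$motifs); b <- agg(post$motifs)
    common <- intersect(a$animal, b$animal)
    if (length(common) >= 2L) {
      a <- a[match(common, a$animal), ]; b <- b[match(common, b$animal), ]
      animal_tests <- data.frame(
        measure = c("motif_duration", "source_level"),
        mean_pre = c(mean(a$motif_duration), mean(a$source_level)),
        mean_post = c(mean(b$motif_duration), mean(b$source_level)),
        p = c(stats::t.test(b$motif_duration, a$motif_duration,
                            paired = TRUE)$p.value,
              stats::t.test(b$source_level, a$source_level,
                            paired = TRUE)$p.value))
    }
  }
  structure(list(syllable_tests = st, category_fractions = frac,
                 animal_tests = animal_tests, alpha = alpha),
            class = "prepost_comparison")
}

#' @export
print.prepost_comparison <- function(x, ...) {
  cat(sprintf("<prepost_comparison: %d syllable-level tests at alpha = %g>\n",
              nrow(x$syllable_tests), x$alpha))
  if (!is.null(x$category_fractions)) print(x$category_fractions)
  if (!is.null(x$animal_tests)) {
    cat("paired per-animal tests:\n"); print(x$animal_tests)
  }
  invisible(x)
}

#' Motif source level (energy-weighted mean of frame source levels)
#'
#' The motif's source level is computed as `10*log10` of the mean frame
#' power over the given frames (an energy mean, so loud frames dominate).
#'
#' @param frames `acoustic_frames` covering the motif.
#' @param sound optional logical frame selector (e.g. the cleaned `sound`
#'   vector from [segment_syllables()]).
#' @return dB re 20 uPa.
#' @export
motif_source_level <- function(frames, sound = NULL) {
  p <- frames$power
  if (!is.null(sound)) p <- p[sound]
  10 * log10(mean(p) / .P_REF2)
}

#' Splice a motif into a song bout with cosine cross-fades
#'
#' Replaces `bout[at : at+length(motif)-1]` with `motif`, blending both
#' boundaries with raised-cosine cross-fades so stimulus bouts keep a natural
#' envelope.
#'
#' @param bout,motif numeric sample vectors (same rate).
#' @param at 1-based sample index of the replacement start.
#' @param fade fade duration (s), default 0.005.
#' @param fs sample rate (Hz), default 44100.
#' @return the spliced bout.
#' @export
splice_motif <- function(bout, motif, at, fade = 0.005, fs = 44100) {
  m <- length(motif)
  stopifnot(at >= 1L, at + m - 1L <= length(bout))
  nf <- min(round(fade * fs), m %/% 2L)
  w <- if (nf > 0) 0.5 - 0.5 * cos(pi * seq_len(nf) / (nf + 1)) else numeric(0)
  out <- bout
  idx <- at:(at + m - 1L)
  repl <- motif
  if (nf > 0) {
    repl[seq_len(nf)] <- w * motif[seq_len(nf)] +
      (1 - w) * bout[idx[seq_len(nf)]]
    tail_i <- (m - nf + 1L):m
    repl[tail_i] <- rev(w) * motif[tail_i] + (1 - rev(w)) * bout[idx[tail_i]]
  }
  out[idx] <- repl
  out
}
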