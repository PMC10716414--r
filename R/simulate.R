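# Evaluate expr under a fixed seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

# --- twitch / tetanus -------------------------------------------------------

# FWHM of the unit two-exponential shape exp(-t/r) - exp(-t), solved to
# high precision with uniroot on the closed form.
.twoexp_fwhm_unit <- function(r) {
  f <- function(t) exp(-t / r) - exp(-t)
  tp <- r / (r - 1) * log(r)
  half <- f(tp) / 2
  up <- stats::uniroot(function(t) f(t) - half, c(1e-12, tp),
                       tol = 1e-12)$root
  hi <- tp
  while (f(hi) > half) hi <- hi * 2
  dn <- stats::uniroot(function(t) f(t) - half, c(tp, hi), tol = 1e-12)$root
  c(fwhm = dn - up, t_peak = tp, v_peak = f(tp))
}

#' Simulate a twitch force trace with known FWHM
#'
#' Emits a two-exponential force transient
#' `A * (exp(-t/tau2) - exp(-t/tau1))` whose time constants are tuned so the
#' true full width at half maximum equals `target_fwhm` exactly (the shape's
#' FWHM scales linearly with the time constants at fixed ratio, so the tuning
#' is a closed-form rescale). Optional additive Gaussian noise.
#'
#' @param target_fwhm true FWHM (ms), default 4.89.
#' @param peak peak force (mN), default 1.
#' @param tau_ratio ratio `tau2/tau1` of decay to rise constants, default 4.
#' @param sample_rate Hz, default 40000.
#' @param stimulus_onset s, default 0.01.
#' @param noise_sd additive Gaussian noise (mN), default 0.
#' @param baseline baseline force (mN), default 0.
#' @param seed RNG seed for the noise (caller RNG untouched).
#' @return list: `trace` (a [force_trace]) and `truth`
#'   (`fwhm`, `peak`, `tau1_ms`, `tau2_ms`).
#' @export
simulate_twitch_trace <- function(target_fwhm = 4.89, peak = 1,
                                  tau_ratio = 4, sample_rate = 40000,
                                  stimulus_onset = 0.01, noise_sd = 0,
                                  baseline = 0, seed = NULL) {
  if (target_fwhm <= 0) stop("unattainable FWHM")
  if (tau_ratio <= 1) stop("tau_ratio must exceed 1")
  u <- .twoexp_fwhm_unit(tau_ratio)
  tau1_ms <- target_fwhm / u["fwhm"]
  tau2_ms <- tau_ratio * tau1_ms
  dur <- stimulus_onset + 8 * tau2_ms / 1000
  t <- seq(0, dur, by = 1 / sample_rate)
  ts <- pmax(0, t - stimulus_onset) * 1000   # ms since onset
  shape <- exp(-ts / tau2_ms) - exp(-ts / tau1_ms)
  # normalize by the sampled maximum so the noiseless trace peak is exact;
  # FWHM is invariant under this amplitude scaling
  force <- baseline + peak * shape / max(shape)
  if (noise_sd > 0)
    force <- force + .with_seed(seed, stats::rnorm(length(force), 0, noise_sd))
  list(trace = force_trace(force, time = t, kind = "twitch",
                           stimulus_onset = stimulus_onset),
       truth = list(fwhm = target_fwhm, peak = peak,
                    tau1_ms = unname(tau1_ms), tau2_ms = unname(tau2_ms)))
}

#' Simulate a tetanic force trace
#'
#' Exponential rise to a plateau during a 100 ms stimulation, exponential
#' relaxation afterwards.
#'
#' @param amplitude plateau force (mN), default 12.
#' @param stim_duration stimulation duration (s), default 0.1.
#' @param tau_rise,tau_decay rise/decay constants (s).
#' @inheritParams simulate_twitch_trace
#' @return list: `trace` ([force_trace], kind tetanus) and `truth`
#'   (`amplitude`).
#' @export
simulate_tetanus_trace <- function(amplitude = 12, stim_duration = 0.1,
                                   tau_rise = 0.005, tau_decay = 0.015,
                                   sample_rate = 40000, stimulus_onset = 0.01,
                                   noise_sd = 0, baseline = 0, seed = NULL) {
  dur <- stimulus_onset + stim_duration + 6 * tau_decay
  t <- seq(0, dur, by = 1 / sample_rate)
  ts <- t - stimulus_onset
  f <- numeric(length(t))
  on <- ts >= 0 & ts <= stim_duration
  f[on] <- amplitude * (1 - exp(-ts[on] / tau_rise))
  off <- ts > stim_duration
  f_end <- amplitude * (1 - exp(-stim_duration / tau_rise))
  f[off] <- f_end * exp(-(ts[off] - stim_duration) / tau_decay)
  force <- baseline + f
  if (noise_sd > 0)
    force <- force + .with_seed(seed, stats::rnorm(length(force), 0, noise_sd))
  list(trace = force_trace(force, time = t, kind = "tetanus",
                           stimulus_onset = stimulus_onset),
       truth = list(amplitude = amplitude))
}

#' Simulate a full recording session (seven twitches, three tetani)
#'
#' Mirrors the in vitro protocol: seven twitch contractions followed by
#' three 100 ms tetanic contractions.
#'
#' @param n_twitch,n_tetanus protocol counts, defaults 7 and 3.
#' @param target_fwhm,peak,tetanus_amplitude passed to the per-trace
#'   generators.
#' @param noise_sd additive noise (mN).
#' @param seed RNG seed.
#' @return list with `twitches` and `tetani` (lists of generator outputs).
#' @export
simulate_twitch_session <- function(n_twitch = 7, n_tetanus = 3,
                                    target_fwhm = 4.89, peak = 1,
                                    tetanus_amplitude = 12, noise_sd = 0,
                                    seed = NULL) {
  .with_seed(seed, {
    tw <- lapply(seq_len(n_twitch), function(i)
      simulate_twitch_trace(target_fwhm, peak, noise_sd = noise_sd))
    te <- lapply(seq_len(n_tetanus), function(i)
      simulate_tetanus_trace(tetanus_amplitude, noise_sd = noise_sd))
    list(twitches = tw, tetani = te)
  })
}

# --- section image ----------------------------------------------------------

#' Simulate a two-channel muscle section with ground truth
#'
#' Lays fibres out on a jittered grid (each cell sized so a fibre never
#' touches its neighbours), draws each as a smooth star-convex blob whose
#' pixel area lands inside the configured range for its type, and renders:
#' a laminin channel that is bright on the inter-fibre matrix and dark
#' inside fibres (with a smooth illumination gain so contrast equalization
#' has something to do), and a MY-32 channel with a per-fibre mean intensity
#' drawn from the type's distribution. Superfast fibres have areas in
#' `area_superfast` and dim MY-32 (~N(20, 8^2), clipped at 0); fast fibres
#' are smaller (`area_fast`) and bright (~N(120, 30^2), clipped at 255).
#'
#' @param n_fibres number of fibres, default 300.
#' @param superfast_fraction probability a fibre is superfast, default 0.66.
#' @param microns_per_pixel um/px, default 1.
#' @param area_superfast,area_fast area ranges (um^2).
#' @param my32_superfast,my32_fast `c(mean, sd)` of the per-fibre MY-32
#'   intensity.
#' @param pixel_noise channel noise SD, default 8.
#' @param seed RNG seed.
#' @return list: `image` (a [section_image]), `labels` (ground-truth integer
#'   label matrix) and `truth` (data.frame `fibre_id, fibre_type, area,
#'   my32_intensity`).
#' @export
simulate_section_image <- function(n_fibres = 300, superfast_fraction = 0.66,
                                   microns_per_pixel = 1,
                                   area_superfast = c(200, 1000),
                                   area_fast = c(100, 400),
                                   my32_superfast = c(20, 8),
                                   my32_fast = c(120, 30),
                                   pixel_noise = 8, seed = 1L) {
  if (n_fibres < 1) stop("n_fibres must be >= 1")
  if (superfast_fraction < 0 || superfast_fraction > 1)
    stop("superfast_fraction must be in [0, 1]")
  .with_seed(seed, {
    mpp <- microns_per_pixel
    rmax <- sqrt(max(area_superfast, area_fast) / pi) / mpp
    cell <- ceiling(2 * rmax * 1.15 + 6)
    ncol_c <- ceiling(sqrt(n_fibres))
    nrow_c <- ceiling(n_fibres / ncol_c)
    H <- nrow_c * cell + 8L; W <- ncol_c * cell + 8L
    lab <- matrix(0L, H, W)
    type <- ifelse(stats::runif(n_fibres) < superfast_fraction,
                   "superfast", "fast")
    # target areas drawn away from the range edges so pixelation stays inside
    tgt <- numeric(n_fibres)
    for (i in seq_len(n_fibres)) {
      rg <- if (type[i] == "superfast") area_superfast else area_fast
      pad <- 0.08 * diff(rg)
      tgt[i] <- stats::runif(1, rg[1] + pad, rg[2] - pad)
    }
    theta <- seq(0, 2 * pi, length.out = 73)[-73]
    areas_px <- numeric(n_fibres)
    for (i in seq_len(n_fibres)) {
      ci <- (i - 1L) %/% ncol_c; cj <- (i - 1L) %% ncol_c
      r0 <- sqrt(tgt[i] / pi) / mpp
      jit <- (cell / 2 - r0 * 1.15 - 2)
      cy <- 4 + ci * cell + cell / 2 + stats::runif(1, -jit, jit)
      cx <- 4 + cj * cell + cell / 2 + stats::runif(1, -jit, jit)
      # star-convex blob: low-order harmonic perturbation, area-renormalized
      amp <- stats::runif(2, 0, 0.08)
      ph <- stats::runif(2, 0, 2 * pi)
      rr <- 1 + amp[1] * cos(2 * theta + ph[1]) + amp[2] * cos(3 * theta + ph[2])
      rr <- rr / sqrt(mean(rr^2))           # keep polar area = pi r0^2
      rad <- r0 * rr
      box <- ceiling(max(rad)) + 1L
      ys <- max(1L, floor(cy) - box):min(H, ceiling(cy) + box)
      xs <- max(1L, floor(cx) - box):min(W, ceiling(cx) + box)
      dy <- ys - cy
      dx <- xs - cx
      dyg <- matrix(dy, length(ys), length(xs))
      dxg <- matrix(dx, length(ys), length(xs), byrow = TRUE)
      d <- sqrt(dyg^2 + dxg^2)
      a <- atan2(dxg, dyg) %% (2 * pi)
      rlim <- rad[pmin(length(theta), floor(a / (2 * pi) * length(theta)) + 1L)]
      inside <- d <= matrix(rlim, length(ys), length(xs))
      lab[ys, xs][inside] <- i
      areas_px[i] <- sum(inside)
    }
    my32_int <- ifelse(
      type == "superfast",
      pmax(0, stats::rnorm(n_fibres, my32_superfast[1], my32_superfast[2])),
      pmin(255, stats::rnorm(n_fibres, my32_fast[1], my32_fast[2])))
    gain <- outer(seq_len(H), seq_len(W), function(y, x)
      1 + 0.15 * sin(2 * pi * x / W) * cos(2 * pi * y / H))
    lam <- matrix(180, H, W)
    lam[lab > 0] <- 35
    lam <- lam * gain + stats::rnorm(H * W, 0, pixel_noise)
    lam[lam < 0] <- 0; lam[lam > 255] <- 255
    my <- matrix(10, H, W)
    my[lab > 0] <- my32_int[lab[lab > 0]]
    my <- my + stats::rnorm(H * W, 0, 3)
    my[my < 0] <- 0; my[my > 255] <- 255
    mask <- matrix(TRUE, H, W)
    mask[c(1:2, (H - 1):H), ] <- FALSE
    mask[, c(1:2, (W - 1):W)] <- FALSE
    img <- section_image(lam, my, mask, mpp)
    truth <- data.frame(fibre_id = seq_len(n_fibres),
                        fibre_type = factor(type,
                                            levels = c("superfast", "fast")),
                        area = areas_px * mpp^2,
                        my32_intensity = my32_int)
    list(image = img, labels = lab, truth = truth)
  })
}

# --- song audio -------------------------------------------------------------

#' Default syllable layout for simulated motifs
#'
#' Three harmonic-stack syllables of 80/100/120 ms separated by 50 ms gaps,
#' with constant or sweeping fundamentals.
#'
#' @return data.frame with columns `duration` (ms), `gap_after` (ms),
#'   `f0_start`, `f0_end` (Hz), `amplitude` (Pa RMS), `harmonics`.
#' @export
default_motif_spec <- function() {
  data.frame(duration = c(80, 100, 120), gap_after = c(50, 50, NA),
             f0_start = c(720, 600, 900), f0_end = c(720, 900, 650),
             amplitude = c(0.05, 0.08, 0.06), harmonics = c(8, 8, 8))
}

#' Simulate a harmonic-stack song motif with known truth
#'
#' Renders a motif as a sequence of harmonic stacks (amplitudes rolling off
#' as 1/k over `harmonics` partials) with raised-cosine onset/offset ramps,
#' constant or linearly sweeping fundamental, and configurable per-syllable
#' RMS pressure. Syllable and gap durations are snapped to the 0.5 ms frame
#' grid. Truth (onsets, durations, f0 end points, per-syllable source
#' levels, motif duration) is returned alongside the audio.
#'
#' @param motif_spec data.frame like [default_motif_spec()].
#' @param sample_rate Hz, default 44100.
#' @param pad silence before/after (s), default 0.1.
#' @param ramp raised-cosine ramp duration (s), default 0.005.
#' @param noise_rms additive broadband background (Pa RMS), default 0.
#' @param seed RNG seed (used only when `noise_rms > 0`).
#' @return list: `audio` (an [audio_recording], calibration 1) and `truth`
#'   (data.frame of syllable onsets/durations/gaps/f0/source levels plus
#'   attribute `motif_duration` in s).
#' @export
simulate_song_audio <- function(motif_spec = default_motif_spec(),
                                sample_rate = 44100, pad = 0.1,
                                ramp = 0.005, noise_rms = 0, seed = NULL) {
  ms <- motif_spec
  ms$duration <- round(ms$duration * 2) / 2
  ms$gap_after <- round(ms$gap_after * 2) / 2
  if (any(ms$gap_after < 0, na.rm = TRUE)) stop("overlapping syllables")
  n <- nrow(ms)
  fs <- sample_rate
  onset <- pad + c(0, cumsum(ms$duration[-n] + ms$gap_after[-n])) / 1000
  total <- pad + sum(ms$duration, na.rm = TRUE) / 1000 +
    sum(ms$gap_after, na.rm = TRUE) / 1000 + pad
  x <- numeric(ceiling(total * fs))
  sl <- numeric(n)
  for (i in seq_len(n)) {
    d <- ms$duration[i] / 1000
    nn <- round(d * fs)
    t <- (seq_len(nn) - 1) / fs
    f0 <- ms$f0_start[i] + (ms$f0_end[i] - ms$f0_start[i]) * t / d
    phase <- 2 * pi * cumsum(f0) / fs
    K <- ms$harmonics[i]
    s <- numeric(nn)
    # partials above the 12 kHz analysis band (or Nyquist) are not rendered
    for (k in seq_len(K))
      if (k * max(f0) <= min(12000, fs / 2)) s <- s + sin(k * phase) / k
    nr <- max(2L, round(ramp * fs))
    env <- rep(1, nn)
    w <- 0.5 - 0.5 * cos(pi * seq_len(nr) / (nr + 1))
    env[seq_len(nr)] <- w
    env[(nn - nr + 1):nn] <- rev(w)
    s <- s * env
    s <- s * ms$amplitude[i] / sqrt(mean(s^2))
    i0 <- round(onset[i] * fs)
    x[i0 + seq_len(nn)] <- x[i0 + seq_len(nn)] + s
    sl[i] <- 20 * log10(sqrt(mean(s^2)) / 20e-6)
  }
  if (noise_rms > 0)
    x <- x + .with_seed(seed, stats::rnorm(length(x), 0, noise_rms))
  truth <- data.frame(index = seq_len(n), onset = onset,
                      duration = ms$duration, gap_after = ms$gap_after,
                      f0_start = ms$f0_start, f0_end = ms$f0_end,
                      source_level = sl)
  attr(truth, "motif_duration") <-
    (sum(ms$duration, na.rm = TRUE) + sum(ms$gap_after, na.rm = TRUE)) / 1000
  list(audio = audio_recording(x, fs, 1), truth = truth)
}

# --- peptide tables ---------------------------------------------------------

#' Default synthetic proteome composition
#'
#' A small muscle-like protein panel: Histone H4 (normalization anchor),
#' MYH13 carrying 92% of the myosin pool with the fast-cluster pseudo-protein
#' (`MYH-fast`, flagged shared peptides) at 8%, plus sarcomeric,
#' calcium-handling and mitochondrial proteins. Abundances are arbitrary
#' units. Accessions are synthetic except the Histone H4 anchor.
#'
#' @return data.frame `accession, gene, category, abundance,
#'   myh_fast_cluster`.
#' @export
default_proteome <- function() {
  data.frame(
    accession = c(h4_accession(), "SYN-MYH13", "SYN-MYHF", "SYN-ACTA1",
                  "SYN-TNNT3", "SYN-MYBPC2", "SYN-PVALB", "SYN-ATP2A1",
                  "SYN-CASQ1", "SYN-ATP5F1A", "SYN-CS", "SYN-COX4",
                  "SYN-ALDOA", "SYN-ALB"),
    gene = c("H4", "MYH13", "MYH-fast", "ACTA1", "TNNT3", "MYBPC2",
             "PVALB", "ATP2A1", "CASQ1", "ATP5F1A", "CS", "COX4", "ALDOA",
             "ALB"),
    category = c("other", "sarcomeric", "sarcomeric", "sarcomeric",
                 "sarcomeric", "sarcomeric", "ca_handling", "ca_handling",
                 "ca_handling", "mitochondrial", "mitochondrial",
                 "mitochondrial", "other", "other"),
    abundance = c(5, 92, 8, 60, 12, 9, 25, 18, 6, 30, 12, 9, 14, 4),
    myh_fast_cluster = c(FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE,
                         FALSE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE))
}

#' Simulate paired peptide LC-peak tables with known fold changes
#'
#' For each protein, `n_peptides` peptides receive areas proportional to the
#' protein's abundance times fixed per-peptide ionization weights, perturbed
#' by log-normal noise of the given coefficient of variation. Treated
#' samples scale each protein by its fold change from `fc_map`. Optionally
#' injects decoy rows carrying the five red-blood-cell contaminant
#' accessions.
#'
#' @param proteome data.frame like [default_proteome()].
#' @param fc_map named numeric vector accession -> fold change; proteins not
#'   named keep FC 1. Negative values error.
#' @param n_pairs number of intact/treated pairs, default 3.
#' @param cv log-normal coefficient of variation, default 0.10.
#' @param n_peptides peptides per protein, default 4.
#' @param rbc_decoys inject contaminant rows, default FALSE.
#' @param seed RNG seed.
#' @return list: `intact`, `treated` (lists of peptide tables, one per
#'   pair, columns `accession, gene, peptide, area, sample,
#'   myh_fast_cluster`) and `truth` (the fold-change map and composition).
#' @export
simulate_peptide_tables <- function(proteome = default_proteome(),
                                    fc_map = NULL, n_pairs = 3, cv = 0.10,
                                    n_peptides = 4, rbc_decoys = FALSE,
                                    seed = 1L) {
  fc <- rep(1, nrow(proteome)); names(fc) <- proteome$accession
  if (!is.null(fc_map)) {
    if (any(fc_map < 0)) stop("negative fold change")
    fc[names(fc_map)] <- fc_map
  }
  w <- 1 / seq_len(n_peptides)          # fixed ionization weights
  sdlog <- sqrt(log(1 + cv^2))
  .with_seed(seed, {
    make <- function(cond, pair) {
      rows <- lapply(seq_len(nrow(proteome)), function(i) {
        base <- proteome$abundance[i] * w * 100
        if (cond == "treated") base <- base * fc[i]
        noise <- if (cv > 0)
          stats::rlnorm(n_peptides, -sdlog^2 / 2, sdlog) else rep(1, n_peptides)
        data.frame(accession = proteome$accession[i],
                   gene = proteome$gene[i],
                   peptide = sprintf("%s_pep%d", proteome$gene[i],
                                     seq_len(n_peptides)),
                   area = base * noise,
                   sample = sprintf("%s_%d", cond, pair),
                   myh_fast_cluster = proteome$myh_fast_cluster[i])
      })
      tab <- do.call(rbind, rows)
      if (rbc_decoys) {
        dec <- data.frame(accession = rbc_accessions(),
                          gene = paste0("RBC", seq_len(5)),
                          peptide = paste0("RBC_pep", seq_len(5)),
                          area = stats::runif(5, 50, 500),
                          sample = tab$sample[1],
                          myh_fast_cluster = FALSE)
        tab <- rbind(tab, dec)
      }
      tab
    }
    intact <- lapply(seq_len(n_pairs), function(p) make("intact", p))
    treated <- lapply(seq_len(n_pairs), function(p) make("treated", p))
    list(intact = intact, treated = treated,
         truth = list(fc_map = fc, composition = proteome))
  })
}

# --- keypeck logs -----------------------------------------------------------

#' Simulate an operant keypeck log with known preference
#'
#' Each peck chooses the focal ("pre") stimulus with probability `p`; the
#' chosen stimulus is mapped to a key through the nightly-switching
#' assignment over 4 test days (left carries "pre" on day 1).
#'
#' @param p probability of pecking for the focal (pre) stimulus.
#' @param n_per_day pecks per day (length 1 or 4), default 100.
#' @param seed RNG seed.
#' @return list: `log` (a [keypeck_log]) and `truth` (`p`).
#' @export
simulate_keypeck_log <- function(p = 0.66, n_per_day = 100, seed = 1L) {
  if (p < 0 || p > 1) stop("p must be in [0, 1]")
  n_per_day <- rep(n_per_day, length.out = 4)
  assignment <- data.frame(
    day = 1:4,
    left_stimulus = c("pre", "post", "pre", "post"),
    right_stimulus = c("post", "pre", "post", "pre"))
  .with_seed(seed, {
    ev <- lapply(1:4, function(d) {
      n <- n_per_day[d]
      choice <- ifelse(stats::runif(n) < p, "pre", "post")
      key <- ifelse(choice == assignment$left_stimulus[d], "left", "right")
      data.frame(timestamp = d - 1 + sort(stats::runif(n)),
                 key = key, day = d)
    })
    list(log = keypeck_log(do.call(rbind, ev), assignment),
         truth = list(p = p))
  })
}
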