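# build an acoustic_frames-like table from a binary envelope on the 0.5 ms grid
frames_from_binary <- function(sound, hop = 5e-4, hi = 60, lo = 20) {
  df <- data.frame(time = (seq_along(sound) - 1) * hop,
                   power = ifelse(sound, 1e-4, 1e-8),
                   source_level = ifelse(sound, hi, lo),
                   wiener_entropy = -10, f0 = NA_real_, aperiodicity = NA_real_)
  attr(df, "hop") <- hop
  class(df) <- c("acoustic_frames", "data.frame")
  df
}

run_vec <- function(...) {
  # run-length spec in ms: c(sound_ms, silence_ms, sound_ms, ...) starting
  # with silence = FALSE? here: alternating starting with silence
  lens <- c(...)
  out <- logical(0)
  state <- FALSE
  for (l in lens) {
    out <- c(out, rep(state, l * 2))   # 0.5 ms frames
    state <- !state
  }
  out
}

test_that("two syllables with a wide gap are kept and motif duration sums", {
  sound <- run_vec(100, 80, 50, 100, 30)  # silence 100, sound 80, gap 50, sound 100
  fr <- frames_from_binary(sound)
  seg <- segment_syllables(fr, sl_threshold = 40)
  expect_equal(nrow(seg$syllables), 2)
  expect_equal(seg$syllables$duration, c(80, 100))
  expect_equal(seg$motif_duration, 0.230, tolerance = 1e-9)
  expect_equal(seg$syllables$gap_after[1], 50)
})

test_that("short sounds are dropped first, then short gaps merged", {
  # 20 ms blip, 100 ms silence, then a syllable split by a 30 ms gap
  sound <- run_vec(50, 20, 100, 60, 30, 60, 50)
  fr <- frames_from_binary(sound)
  seg <- segment_syllables(fr, sl_threshold = 40)
  expect_equal(nrow(seg$syllables), 1)           # blip gone, gap merged
  expect_equal(seg$syllables$duration, 150)      # 60 + 30 + 60
})

test_that("no surviving sound yields an empty, flagged motif", {
  sound <- run_vec(50, 20, 50)                   # only a 20 ms blip
  seg <- segment_syllables(frames_from_binary(sound), 40)
  expect_equal(nrow(seg$syllables), 0)
  expect_true(is.na(seg$motif_duration))
})

test_that("duration rules match the brute-force applier on random envelopes and are idempotent", {
  set.seed(12)
  hop <- 5e-4
  for (i in 1:200) {
    sound <- runif(sample(50:300, 1)) < 0.5
    got <- apply_duration_rules(sound, hop)
    want <- oracle_duration_rules(sound, hop)
    expect_identical(got, as.logical(want))
    expect_identical(apply_duration_rules(got, hop), got)
  }
})

test_that("motif duration equals the sum of syllable and gap durations", {
  set.seed(8)
  for (i in 1:20) {
    # run-structured envelope: alternating silence/sound runs of 5-100 ms
    lens <- sample(10:200, 12, replace = TRUE)
    raw <- unlist(lapply(seq_along(lens),
                         function(k) rep(k %% 2 == 0, lens[k])))
    sound <- apply_duration_rules(raw, 5e-4)
    seg <- segment_syllables(frames_from_binary(sound), 40)
    if (nrow(seg$syllables) == 0) next
    s <- sum(seg$syllables$duration) +
      sum(seg$syllables$gap_after, na.rm = TRUE)
    expect_equal(seg$motif_duration, s / 1000, tolerance = 1e-9)
  }
})

test_that("f0 cleaning: constant traces, the 100 Hz / 5 ms rules, never adds frames", {
  hop <- 5e-4
  mk <- function(f0) {
    n <- length(f0)
    df <- data.frame(time = (seq_len(n) - 1) * hop, power = 1e-4,
                     source_level = 60, wiener_entropy = -10, f0 = f0,
                     aperiodicity = 0.1)
    attr(df, "hop") <- hop
    df
  }
  syl <- function(n) data.frame(index = 1, onset = 0, offset = n * hop,
                                duration = n * hop * 1000, gap_after = NA)
  # constant 500 Hz
  st <- syllable_f0_stats(mk(rep(500, 80)), syl(80))
  expect_true(st$robust_pitch)
  expect_equal(st$f0_mean, 500)
  expect_equal(st$f0_range, 0)
  # 500, 510, 700, 710: jump splits; both segments < 5 ms -> not robust
  st2 <- syllable_f0_stats(mk(c(500, 510, 700, 710)), syl(4))
  expect_false(st2$robust_pitch)
  expect_true(is.na(st2$f0_mean))
  # surviving frames are a subset: stats bounded by observed values
  f0 <- c(rep(600, 30), 2000, rep(610, 30))
  st3 <- syllable_f0_stats(mk(f0), syl(61))
  expect_true(st3$robust_pitch)
  expect_gte(st3$f0_min, 600)
  expect_lte(st3$f0_max, 610)
})

test_that("a linear sweep's f0 statistics track the generator truth", {
  spec <- data.frame(duration = 60, gap_after = NA, f0_start = 600,
                     f0_end = 900, amplitude = 0.08, harmonics = 8)
  sim <- simulate_song_audio(spec, ramp = 0.002)
  fr <- compute_frame_features(sim$audio)
  seg <- segment_syllables(fr, 40)
  st <- syllable_f0_stats(fr, seg$syllables)
  expect_true(st$robust_pitch[1])
  expect_equal(st$f0_mean[1], 750, tolerance = 0.02)
  # the ~4 ms analysis windows average the 5 Hz/ms chirp at the syllable
  # edges, so min/max pull inward by up to ~20 Hz each
  expect_equal(st$f0_range[1], 300, tolerance = 0.15)
  expect_gt(st$f0_max[1], 860)
  expect_lt(st$f0_min[1], 640)
  # per-frame tracking against the time-shifted truth over the interior
  on <- seg$syllables$onset[1]
  sel <- fr$time > on + 0.005 & fr$time < on + 0.048 & !is.na(fr$f0)
  truth <- 600 + 5000 * (fr$time[sel] + 0.0022 - sim$truth$onset[1])
  expect_lt(max(abs(fr$f0[sel] - truth) / truth), 0.02)
})
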