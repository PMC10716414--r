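test_that("generators are deterministic: same seed, identical output", {
  a <- simulate_section_image(n_fibres = 30, seed = 7)
  b <- simulate_section_image(n_fibres = 30, seed = 7)
  expect_identical(a$image$laminin, b$image$laminin)
  expect_identical(a$labels, b$labels)
  expect_identical(a$truth, b$truth)
  expect_false(identical(
    a$image$laminin, simulate_section_image(n_fibres = 30, seed = 8)$image$laminin))
  s1 <- simulate_song_audio(noise_rms = 1e-4, seed = 3)
  s2 <- simulate_song_audio(noise_rms = 1e-4, seed = 3)
  expect_identical(s1$audio$samples, s2$audio$samples)
  k1 <- simulate_keypeck_log(seed = 5); k2 <- simulate_keypeck_log(seed = 5)
  expect_identical(k1$log$events, k2$log$events)
  p1 <- simulate_peptide_tables(seed = 9); p2 <- simulate_peptide_tables(seed = 9)
  expect_identical(p1$intact[[2]]$area, p2$intact[[2]]$area)
  t1 <- simulate_twitch_trace(noise_sd = 0.01, seed = 4)
  t2 <- simulate_twitch_trace(noise_sd = 0.01, seed = 4)
  expect_identical(t1$trace$force, t2$trace$force)
  # the caller's RNG stream is not disturbed
  set.seed(123); before <- runif(1)
  set.seed(123); invisible(simulate_section_image(n_fibres = 5, seed = 1))
  expect_identical(runif(1), before)
})

test_that("twitch generator hits the requested FWHM and peak exactly", {
  for (target in c(2, 4.89, 9.13)) {
    sim <- simulate_twitch_trace(target_fwhm = target, peak = 3)
    expect_equal(max(sim$trace$force), 3, tolerance = 1e-6)
    got <- oracle_fwhm_sampled(sim$trace$time, sim$trace$force, 0)
    expect_equal(got, target, tolerance = 0.01)
  }
  expect_error(simulate_twitch_trace(target_fwhm = -1), "unattainable")
})

test_that("a session emits the protocol counts: 7 twitches, 3 tetani of 100 ms", {
  sess <- simulate_twitch_session(seed = 2)
  expect_length(sess$twitches, 7)
  expect_length(sess$tetani, 3)
  te <- sess$tetani[[1]]$trace
  above <- te$time[te$force > 0.95 * max(te$force)]
  expect_equal(diff(range(above)), 0.1, tolerance = 0.1)
})

test_that("section truth: areas inside the configured ranges, binomial type counts", {
  sim <- simulate_section_image(n_fibres = 300, superfast_fraction = 0.66,
                                seed = 11)
  sf <- sim$truth$fibre_type == "superfast"
  expect_true(all(sim$truth$area[sf] >= 200 & sim$truth$area[sf] <= 1000))
  expect_true(all(sim$truth$area[!sf] >= 100 & sim$truth$area[!sf] <= 400))
  # exact binomial 99% interval for the superfast count
  ci <- qbinom(c(0.005, 0.995), 300, 0.66)
  expect_gte(sum(sf), ci[1]); expect_lte(sum(sf), ci[2])
  one <- simulate_section_image(n_fibres = 1, seed = 1)
  expect_equal(max(one$labels), 1L)
  expect_error(simulate_section_image(superfast_fraction = 1.3), "fraction")
})

test_that("song truth: durations on the 0.5 ms grid, motif duration sums, envelope onsets", {
  sim <- simulate_song_audio()
  expect_true(all(sim$truth$duration %% 0.5 == 0))
  expect_equal(attr(sim$truth, "motif_duration"), 0.400)
  expect_equal(attr(sim$truth, "motif_duration"),
               (sum(sim$truth$duration) +
                  sum(sim$truth$gap_after, na.rm = TRUE)) / 1000)
  # oracle envelope threshold recovers onsets within 1 ms (short ramps so
  # the crossing sits at the syllable edge)
  simr <- simulate_song_audio(ramp = 0.001)
  fs <- simr$audio$sample_rate
  env <- abs(simr$audio$samples)
  env <- stats::filter(env, rep(1 / 23, 23), sides = 2)
  env[is.na(env)] <- 0
  on <- env > 0.03 * max(env)
  starts <- which(diff(c(FALSE, on)) == 1) / fs
  got <- vapply(simr$truth$onset, function(o) starts[which.min(abs(starts - o))], 0)
  expect_true(all(abs(got - simr$truth$onset) < 1e-3))
  expect_error(simulate_song_audio(
    data.frame(duration = c(50, 50), gap_after = c(-10, NA), f0_start = 700,
               f0_end = 700, amplitude = 0.05, harmonics = 8)), "overlap")
})

test_that("peptide generator: defaults give MYH13 92% of the myosin pool, decoys injectable", {
  comp <- default_proteome()
  myh <- comp$abundance[comp$gene %in% c("MYH13", "MYH-fast")]
  expect_equal(comp$abundance[comp$gene == "MYH13"] / sum(myh), 0.92)
  sim <- simulate_peptide_tables(rbc_decoys = TRUE, seed = 4)
  expect_true(all(rbc_accessions() %in% sim$intact[[1]]$accession))
  prof <- quantify_and_normalize(sim$intact[[1]])
  expect_false(any(rbc_accessions() %in% prof$protein))
  expect_error(simulate_peptide_tables(fc_map = c("SYN-CS" = -1)), "negative")
})

test_that("keypeck generator: 4 days, nightly switches, binomial truth recovery", {
  sim <- simulate_keypeck_log(p = 0.66, n_per_day = 100, seed = 21)
  ev <- sim$log$events
  expect_equal(sort(unique(ev$day)), 1:4)
  asg <- sim$log$assignment
  expect_true(all(asg$left_stimulus != asg$right_stimulus))
  expect_true(all(asg$left_stimulus[-1] != asg$left_stimulus[-4]))  # 3 switches
  res <- analyze_preference(sim$log)
  ci <- qbinom(c(0.005, 0.995), 400, 0.66) / 400
  expect_gte(res$preference, ci[1]); expect_lte(res$preference, ci[2])
  all_pre <- simulate_keypeck_log(p = 1, seed = 2)
  expect_equal(analyze_preference(all_pre$log)$preference, 1)
  # both key sides used when p = 1 (assignment alternates)
  expect_setequal(unique(all_pre$log$events$key), c("left", "right"))
})
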