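# helpers to build tiny synthetic sections / label maps by hand
blank_section <- function(H, W, mpp = 1, lam = 20, my = 0) {
  section_image(matrix(lam, H, W), matrix(my, H, W),
                microns_per_pixel = mpp)
}

disc_mask <- function(H, W, cy, cx, r) {
  outer(seq_len(H), seq_len(W), function(y, x) (y - cy)^2 + (x - cx)^2 <= r^2)
}

test_that("one bright laminin ring around a dark disc yields exactly one fibre", {
  H <- W <- 120
  inner <- disc_mask(H, W, 60, 60, 25)
  ring <- disc_mask(H, W, 60, 60, 28) & !inner
  lam <- matrix(15, H, W); lam[ring] <- 230
  set.seed(1); lam <- lam + matrix(rnorm(H * W, 0, 3), H, W)
  img <- section_image(lam, matrix(0, H, W), microns_per_pixel = 1)
  lab <- segment_fibres(img)
  expect_equal(max(lab), 1L)
  expect_lt(abs(sum(lab == 1) - sum(inner)) / sum(inner), 0.10)
})

test_that("an all-zero mask yields an empty label map; a flat image errors", {
  H <- W <- 60
  img <- section_image(matrix(100, H, W), matrix(0, H, W),
                       mask = matrix(FALSE, H, W), microns_per_pixel = 1)
  lab <- segment_fibres(img)
  expect_true(all(lab == 0L))
  flat <- blank_section(H, W, lam = 100)
  expect_error(segment_fibres(flat), "no borders detected")
})

test_that("label maps are deterministic partitions inside the mask", {
  sim <- simulate_section_image(n_fibres = 60, seed = 5)
  lab1 <- segment_fibres(sim$image)
  lab2 <- segment_fibres(sim$image)
  expect_identical(lab1[, ], lab2[, ])
  expect_true(all(lab1[!sim$image$mask] == 0L))
  expect_true(all(lab1 >= 0L))
})

test_that("shape features: disc, ellipse, and hull-oracle solidity", {
  H <- W <- 100
  img <- blank_section(H, W, my = 40)
  # disc of radius 20
  lab <- matrix(0L, H, W); lab[disc_mask(H, W, 50, 50, 20)] <- 1L
  rec <- extract_fibre_features(lab, img)
  expect_equal(nrow(rec), 1)
  expect_lte(rec$eccentricity, 0.1)
  expect_gte(rec$circularity, 0.9)
  expect_equal(rec$area, pi * 20^2, tolerance = 0.02)
  expect_equal(rec$mean_my32, 40)
  # 40 x 20 px filled ellipse: axis ratio 2
  lab2 <- matrix(0L, H, W)
  ell <- outer(seq_len(H), seq_len(W),
               function(y, x) ((y - 50) / 20)^2 + ((x - 50) / 10)^2 <= 1)
  lab2[ell] <- 1L
  rec2 <- extract_fibre_features(lab2, img)
  expect_equal(rec2$axis_ratio, 2.0, tolerance = 0.05)
  # plus-shaped region: solidity against the point-counting hull oracle
  lab3 <- matrix(0L, H, W)
  lab3[40:60, 20:80] <- 1L
  lab3[20:80, 40:60] <- 1L
  rec3 <- extract_fibre_features(
    lab3, img, feature_constraints(min_solidity = 0, min_circularity = 0))
  pos <- which(lab3 == 1L)
  r <- (pos - 1) %% H + 1; c <- (pos - 1) %/% H + 1
  want <- length(pos) / oracle_hull_area(r, c)
  expect_equal(rec3$solidity, want, tolerance = 0.01)
})

test_that("feature constraints drop false detections and empty input is fine", {
  H <- W <- 80
  img <- blank_section(H, W)
  lab <- matrix(0L, H, W)
  lab[disc_mask(H, W, 25, 25, 3)] <- 1L    # 28 px^2: below min area
  lab[disc_mask(H, W, 55, 55, 12)] <- 2L   # kept
  expect_message(rec <- extract_fibre_features(lab, img), "dropped 1")
  expect_equal(rec$fibre_id, 2L)
  expect_equal(nrow(attr(rec, "dropped")), 1)
  expect_equal(nrow(extract_fibre_features(matrix(0L, H, W), img)), 0)
})

test_that("MY-32 classification threshold is strict at 50 and flips across it", {
  rec <- data.frame(mean_my32 = c(49.999, 50, 50.001, 51, 0, 255))
  out <- classify_fibres(rec)
  expect_equal(as.character(out$fibre_type),
               c("superfast", "superfast", "fast", "fast", "superfast", "fast"))
  allzero <- classify_fibres(data.frame(mean_my32 = rep(0, 10)))
  expect_equal(mean(allzero$fibre_type == "superfast"), 1.0)
  # other bit depths are rescaled to 0-255 before the cutoff
  hi <- classify_fibres(data.frame(mean_my32 = c(0.19, 0.21) * 65535 / 255 * 255),
                        intensity_range = c(0, 65535))
  expect_equal(as.character(hi$fibre_type), c("superfast", "fast"))
})

test_that("hemisyrinx summary: pdfs normalize and dilation is extensive", {
  sim <- simulate_section_image(n_fibres = 80, seed = 3)
  lab <- segment_fibres(sim$image)
  rec <- classify_fibres(extract_fibre_features(lab))
  s <- summarize_hemisyrinx(rec, lab)
  expect_equal(s$n_superfast + s$n_fast, s$n_fibres)
  expect_equal(sum(s$area_pdf$density) * s$area_binwidth, 1, tolerance = 1e-9)
  expect_equal(sum(s$my32_pdf$density) * s$my32_binwidth, 1, tolerance = 1e-9)
  expect_gte(s$hemisyrinx_csa, sum(rec$area))
})

test_that("fibre number is preserved and median-area ratio recovered under simulated atrophy", {
  n <- 100
  intact <- simulate_section_image(
    n_fibres = n, superfast_fraction = 0.66, seed = 21,
    area_superfast = c(300, 500), area_fast = c(300, 500))
  denerv <- simulate_section_image(
    n_fibres = n, superfast_fraction = 0.20, seed = 22,
    area_superfast = c(150, 250), area_fast = c(150, 250),
    my32_superfast = c(60, 10))
  li <- segment_fibres(intact$image); ld <- segment_fibres(denerv$image)
  ri <- extract_fibre_features(li); rd <- extract_fibre_features(ld)
  expect_lte(abs(nrow(ri) - n) / n, 0.05)
  expect_lte(abs(nrow(rd) - n) / n, 0.05)
  si <- summarize_hemisyrinx(classify_fibres(ri), li)
  sd_ <- summarize_hemisyrinx(classify_fibres(rd), ld)
  # generated with median areas 400 vs 200 um^2
  expect_equal(sd_$median_area / si$median_area, 0.5, tolerance = 0.05)
})

test_that("section images round-trip through TIFF/PNG files", {
  sim <- simulate_section_image(n_fibres = 12, seed = 2)
  lp <- withr::local_tempfile(fileext = ".tif")
  mp <- withr::local_tempfile(fileext = ".tif")
  kp <- withr::local_tempfile(fileext = ".png")
  tiff::writeTIFF(sim$image$laminin / 255, lp, bits.per.sample = 16)
  tiff::writeTIFF(sim$image$my32 / 255, mp, bits.per.sample = 16)
  png::writePNG(sim$image$mask * 1, kp)
  img <- read_section_image(lp, mp, kp, microns_per_pixel = 1)
  expect_equal(img$laminin, sim$image$laminin, tolerance = 0.01)
  expect_identical(img$mask, sim$image$mask)
  lab <- segment_fibres(img)
  tp <- withr::local_tempfile(fileext = ".tif")
  write_label_tiff(lab, tp)
  back <- round(tiff::readTIFF(tp) * max(lab))
  expect_equal(max(back), max(lab))
})
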