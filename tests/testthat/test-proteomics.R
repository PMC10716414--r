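toy_table <- function() {
  data.frame(accession = c(rep("P1", 4), rep("B5FXC8", 3), rep("P2", 2)),
             gene = c(rep("G1", 4), rep("H4", 3), rep("G2", 2)),
             peptide = c(paste0("a", 1:4), paste0("h", 1:3), paste0("b", 1:2)),
             area = c(1, 2, 3, 4, 10, 20, 30, 5, 7),
             sample = "s1",
             myh_fast_cluster = FALSE)
}

test_that("top-3 quantification sums the three largest peptide areas", {
  prof <- quantify_and_normalize(toy_table())
  expect_equal(prof$raw_top3[prof$protein == "P1"], 9)      # 4 + 3 + 2
  expect_equal(prof$raw_top3[prof$protein == "B5FXC8"], 60) # all 3
  expect_equal(prof$raw_top3[prof$protein == "P2"], 12)     # both
  # adding a 4th, smaller peptide never changes top-3
  tb <- rbind(toy_table(),
              data.frame(accession = "P2", gene = "G2", peptide = "b3",
                         area = 1, sample = "s1", myh_fast_cluster = FALSE))
  prof2 <- quantify_and_normalize(tb)
  expect_equal(prof2$raw_top3[prof2$protein == "P2"], 13)   # 7 + 5 + 1
  tb$area[nrow(tb)] <- 0.5
  expect_equal(quantify_and_normalize(tb)$raw_top3[prof2$protein == "P2"], 12.5)
})

test_that("normalizations: total sums to one, Histone H4 anchors rel_h4 at 1", {
  set.seed(6)
  sim <- simulate_peptide_tables(seed = 6)
  prof <- quantify_and_normalize(sim$intact[[1]])
  expect_equal(sum(prof$rel_total), 1, tolerance = 1e-12)
  expect_equal(prof$rel_h4[prof$protein == h4_accession()], 1)
  # absent H4 warns and omits rel_h4
  tb <- toy_table()
  tb <- tb[tb$accession != "B5FXC8", ]
  expect_warning(p2 <- quantify_and_normalize(tb), "Histone H4")
  expect_true(all(is.na(p2$rel_h4)))
  expect_error(quantify_and_normalize(toy_table()[0, ]), "empty")
})

test_that("red-blood-cell accessions are excluded by exact match only", {
  tb <- rbind(toy_table(),
              data.frame(accession = c("B5FXM1", "B5FXM1-like"),
                         gene = c("RBC", "NOTRBC"),
                         peptide = c("r1", "r2"), area = c(100, 100),
                         sample = "s1", myh_fast_cluster = FALSE))
  prof <- quantify_and_normalize(tb)
  expect_false("B5FXM1" %in% prof$protein)
  expect_true("B5FXM1-like" %in% prof$protein)   # no substring matching
})

test_that("fast-MyHC cluster peptides pool into MYH-fast before top-3", {
  tb <- rbind(toy_table(),
              data.frame(accession = c("MYHA", "MYHB", "MYHC"),
                         gene = c("MYHA", "MYHB", "MYHC"),
                         peptide = c("m1", "m2", "m3"),
                         area = c(8, 6, 4),
                         sample = "s1", myh_fast_cluster = TRUE))
  prof <- quantify_and_normalize(tb)
  expect_true("MYH-fast" %in% prof$protein)
  expect_false(any(c("MYHA", "MYHB", "MYHC") %in% prof$protein))
  expect_equal(prof$raw_top3[prof$protein == "MYH-fast"], 18)
  expect_true(prof$is_myh_fast_aggregate[prof$protein == "MYH-fast"])
})

test_that("categories come from the map with 'other' as default", {
  prof <- quantify_and_normalize(
    toy_table(), category_map = data.frame(accession = "P1",
                                           category = "sarcomeric"))
  expect_equal(prof$category[prof$protein == "P1"], "sarcomeric")
  expect_equal(prof$category[prof$protein == "P2"], "other")
})

test_that("identical pairs give exactly zero log2 fold change", {
  sim <- simulate_peptide_tables(cv = 0, seed = 1)
  pi_ <- lapply(sim$intact, quantify_and_normalize)
  pt_ <- lapply(sim$treated, quantify_and_normalize)
  # FC map is 1 and cv = 0: treated tables equal intact tables
  expect_equal(sim$intact[[1]]$area, sim$treated[[1]]$area)
  da <- differential_abundance(pi_, pt_)
  expect_true(all(da$proteins$log2fc == 0))
})

test_that("noiseless fold change is recovered exactly; Welch option runs", {
  fc <- c("SYN-PVALB" = 0.25, "SYN-CS" = 2)
  sim <- simulate_peptide_tables(fc_map = fc, cv = 0, seed = 2)
  da <- differential_abundance(lapply(sim$intact, quantify_and_normalize),
                               lapply(sim$treated, quantify_and_normalize))
  expect_equal(da$proteins$mean_ratio[da$proteins$protein == "SYN-PVALB"],
               0.25, tolerance = 1e-9)
  expect_equal(da$proteins$mean_ratio[da$proteins$protein == "SYN-CS"],
               2, tolerance = 1e-9)
  daw <- differential_abundance(lapply(sim$intact, quantify_and_normalize),
                                lapply(sim$treated, quantify_and_normalize),
                                method = "welch", bh = TRUE)
  expect_true("p_adj" %in% names(daw$proteins))
})

test_that("broad down-regulation yields mostly 'decreased' significant proteins", {
  acc <- default_proteome()$accession
  fc <- setNames(rep(0.6, length(acc)), acc)
  fc[h4_accession()] <- 1
  sim <- simulate_peptide_tables(fc_map = fc, n_pairs = 4, cv = 0.05, seed = 3)
  da <- differential_abundance(lapply(sim$intact, quantify_and_normalize),
                               lapply(sim$treated, quantify_and_normalize))
  sig <- da$proteins[!is.na(da$proteins$p) & da$proteins$p < 0.05, ]
  expect_gt(nrow(sig), 0)
  expect_gt(mean(sig$log2fc < 0), 0.5)
  # report schema: volcano and category rollups are present and aligned
  expect_equal(nrow(da$volcano), nrow(da$proteins))
  expect_setequal(unique(da$categories$condition), c("intact", "treated"))
})
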