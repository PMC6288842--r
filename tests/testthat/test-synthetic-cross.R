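test_that("map-distance functions satisfy their closed forms and limits", {
  expect_equal(haldane_rf(0), 0)
  expect_lt(abs(haldane_rf(1e6) - 0.5), 1e-12)
  expect_equal(haldane_rf(25.541), 0.2, tolerance = 1e-4)
  expect_equal(haldane_cM(0.2), -50 * log(0.6))
  r <- c(0.01, 0.1, 0.25, 0.4)
  expect_equal(haldane_rf(haldane_cM(r)), r)
  expect_equal(kosambi_rf(kosambi_cM(r)), r)
})

test_that("simulate_true_map honours its invariants and degenerate cases", {
  cfg <- sim_config(n_groups = 3, markers_per_group = 20, seed = 7)
  tm <- simulate_true_map(cfg)
  expect_equal(nrow(tm), 60)
  expect_false(anyDuplicated(tm$marker) > 0)
  for (g in unique(tm$group)) {
    sub <- tm[tm$group == g, ]
    expect_equal(sub$female_cM[1], 0)
    expect_equal(sub$male_cM[1], 0)
    expect_true(all(diff(sub$female_cM) >= 0))
    expect_true(all(diff(sub$male_cM) >= 0))
  }

  # identity when expansion is 1; zero length for one-marker groups
  tm1 <- simulate_true_map(sim_config(n_groups = 2, markers_per_group = 10,
                                      female_expansion = 1, seed = 3))
  expect_equal(tm1$female_cM, tm1$male_cM)
  tm0 <- simulate_true_map(sim_config(n_groups = 4, markers_per_group = 1,
                                      seed = 3))
  expect_true(all(tm0$female_cM == 0) && all(tm0$male_cM == 0))

  # determinism
  expect_identical(simulate_true_map(cfg), simulate_true_map(cfg))
})

test_that("female map is the male map scaled by the expansion factor", {
  tm <- simulate_true_map(sim_config(n_groups = 1, markers_per_group = 25,
                                     female_expansion = 1.5, seed = 5))
  expect_equal(tm$female_cM, 1.5 * tm$male_cM)
})

test_that("invalid simulator configurations error", {
  expect_error(sim_config(n_offspring = 0), "n_offspring")
  expect_error(sim_config(seg_mix = c(0.5, 0.5, 0.5)), "sum to 1")
  expect_error(sim_config(error_rate = 1.2), "probabilities")
})

test_that("gamete switch probabilities follow the Haldane model", {
  # two markers at a distance giving r = 0.1; count switches directly
  d <- haldane_cM(0.1)
  tm <- tibble::tibble(marker = c("a", "b"), group = "LG01", order = 1:2,
                       rad_locus = c("r1", "r2"),
                       female_cM = c(0, d), male_cM = c(0, d),
                       seg_type = "MAT_INF")
  class(tm) <- c("true_map", class(tm))
  n <- 10000
  gam <- simulate_gametes(tm, "mother", n = n, seed = 42)[["LG01"]]
  f <- mean(gam[, 1] != gam[, 2])
  expect_lt(abs(f - 0.1), 3 * sqrt(0.1 * 0.9 / n))

  # d = 0 never switches
  tm$female_cM <- c(0, 0)
  gam0 <- simulate_gametes(tm, "mother", n = 500, seed = 1)[["LG01"]]
  expect_true(all(gam0[, 1] == gam0[, 2]))
})

test_that("offspring genotypes segregate Mendelian without error or missingness", {
  cross <- small_cross(seed = 2, n_groups = 1, markers_per_group = 40,
                       spacing = 10, error = 0, missing = 0)
  seg <- classify_segregation(cross$geno)
  off <- as.matrix(cross$geno[, grep("^off_", names(cross$geno))])
  n <- ncol(off)
  for (i in which(seg$seg_type == "MAT_INF")) {
    counts <- table(factor(off[i, ], 0:2))
    expect_equal(unname(counts[["2"]]), 0)
    expect_gt(stats::chisq.test(counts[1:2], p = c(.5, .5))$p.value, 1e-6)
  }
  i <- which(seg$seg_type == "BOTH_INF")[1]
  counts <- table(factor(off[i, ], 0:2))
  expect_gt(stats::chisq.test(counts, p = c(.25, .5, .25))$p.value, 1e-6)
})

test_that("simulation with a fixed seed is byte-identical on disk", {
  cfg <- sim_config(n_groups = 2, markers_per_group = 15, seed = 99)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_cross_vcf(sim_cross(cfg)$geno, f1)
  write_cross_vcf(sim_cross(cfg)$geno, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("VCF round trip preserves genotypes, parents and RAD loci", {
  cross <- small_cross(seed = 4, n_groups = 1, markers_per_group = 12,
                       missing = 0.1)
  f <- withr::local_tempfile(fileext = ".vcf")
  write_cross_vcf(cross$geno, f)
  back <- read_cross_vcf(f)
  expect_equal(back$marker, cross$geno$marker)
  expect_equal(back$rad_locus, cross$geno$rad_locus)
  expect_equal(back$mother, cross$geno$mother)
  expect_equal(back$father, cross$geno$father)
  off <- grep("^off_", names(cross$geno), value = TRUE)
  for (s in off) expect_equal(back[[s]], cross$geno[[s]])
})

test_that("truth tables are written alongside the cross", {
  cross <- small_cross(seed = 5, n_groups = 1, markers_per_group = 8)
  dir <- withr::local_tempdir()
  paths <- write_truth(cross, dir)
  expect_true(all(file.exists(paths)))
  tm <- readr::read_tsv(paths[["map"]], show_col_types = FALSE)
  expect_equal(nrow(tm), 8)
})
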