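two_group_map <- function() {
  tibble::tibble(marker = sprintf("m%02d", 1:20),
                 group = rep(c("LG01", "LG02"), each = 10))
}

test_that("MAPQ filtering is strictly greater-than and map-aware", {
  rec <- tibble::tibble(marker = c("m01", "m02", "m03", "zz"),
                        chrom = "Ssa01", pos = 1e6,
                        mapq = c(30, 31, 60, 60))
  out <- filter_mappings(rec, two_group_map(), min_mapq = 30)
  expect_setequal(out$marker, c("m02", "m03"))
  log <- attr(out, "filter_log")
  expect_setequal(log$reason[log$marker == "zz"], "not_in_map")
  expect_true("low_mapq" %in% log$reason)

  # count check on a larger synthetic set
  set.seed(1)
  n <- 1000
  rec2 <- tibble::tibble(marker = sprintf("m%02d", sample(1:20, n, TRUE)),
                         chrom = "Ssa01", pos = 1,
                         mapq = c(rep(60, 600), rep(15, 400))[sample(n)])
  expect_equal(nrow(filter_mappings(rec2, two_group_map())), 600)
})

test_that("homolog assignment takes the majority chromosome", {
  map <- two_group_map()
  rec <- dplyr::bind_rows(
    tibble::tibble(marker = sprintf("m%02d", 1:9),
                   chrom = c(rep("Ssa05", 5), rep("Ssa02", 4)),
                   pos = seq(1e6, 9e6, length.out = 9), mapq = 60),
    tibble::tibble(marker = sprintf("m%02d", 11:15),
                   chrom = "Ssa01", pos = seq(1e6, 5e6, length.out = 5),
                   mapq = 60))
  asn <- suppressWarnings(assign_homologs(map, rec))
  g <- asn$groups
  expect_equal(g$homolog[g$group == "LG01"], "Ssa05")
  expect_equal(g$n_discordant[g$group == "LG01"], 4)
  expect_equal(g$n_concordant[g$group == "LG02"], 5)
  # W-names follow reference chromosome order
  expect_equal(g$w_name[g$group == "LG02"], "W01")
  expect_equal(g$w_name[g$group == "LG01"], "W02")
  expect_equal(sum(asn$hits$concordant), 10)
})

test_that("tied homologs break to the lower chromosome and are flagged", {
  map <- tibble::tibble(marker = sprintf("m%02d", 1:10), group = "LG01")
  rec <- tibble::tibble(marker = sprintf("m%02d", 1:10),
                        chrom = rep(c("Ssa07", "Ssa03"), each = 5),
                        pos = 1e6, mapq = 60)
  expect_warning(asn <- assign_homologs(map, rec), "tied")
  expect_equal(asn$groups$homolog, "Ssa03")
  expect_true(asn$groups$ambiguous)
})

test_that("groups without retained hits get NA homologs and no W-name", {
  map <- two_group_map()
  rec <- tibble::tibble(marker = sprintf("m%02d", 1:5), chrom = "Ssa01",
                        pos = 1e6, mapq = 60)
  expect_warning(asn <- assign_homologs(map, rec), "no retained hits")
  g <- asn$groups
  expect_true(is.na(g$homolog[g$group == "LG02"]))
  expect_true(is.na(g$w_name[g$group == "LG02"]))
})

test_that("expected counts are proportional to arm length and conserved", {
  arms <- tibble::tibble(arm = c("a", "b"), chrom = c("c1", "c2"),
                         start = 0, end = c(100, 300),
                         class = c("AORe", "LORe"),
                         length = c(100, 300))
  rec <- tibble::tibble(marker = sprintf("m%d", 1:40),
                        chrom = rep(c("c1", "c2"), times = c(10, 30)),
                        pos = 50, mapq = 60)
  out <- arm_ratio_test(rec, arms)
  expect_equal(out$arms$expected, c(10, 30))
  expect_equal(out$arms$ratio, c(1, 1))
  expect_equal(sum(out$arms$expected), 40)
})

test_that("mixed arms are excluded before the denominator is computed", {
  arms <- load_arm_table()
  expect_equal(as.integer(table(arms$class)[c("AORe", "LORe", "mixed")]),
               c(30L, 14L, 6L))
  cross_map <- tibble::tibble(marker = sprintf("m%04d", 1:2000),
                              group = "LG01")
  rec <- sim_mapping_records(cross_map, arms, scheme = "by_arm_rate",
                             prop_mapped = 0.8, lore_rate = 1,
                             low_mapq_rate = 0, seed = 3)
  out <- arm_ratio_test(rec, arms)
  expect_false(any(out$arms$class == "mixed"))
  on_included <- sum(out$arms$observed)
  expect_equal(sum(out$arms$expected), on_included)   # conservation
})

test_that("ratios are invariant to rescaling all arm lengths", {
  arms <- load_arm_table()
  rec <- sim_mapping_records(tibble::tibble(marker = sprintf("m%04d", 1:3000),
                                            group = "LG01"),
                             arms, scheme = "by_arm_rate", prop_mapped = 0.5,
                             low_mapq_rate = 0, seed = 4)
  a <- arm_ratio_test(rec, arms)
  arms2 <- arms
  arms2$start <- arms2$start * 3
  arms2$end <- arms2$end * 3
  arms2$length <- arms2$length * 3
  rec2 <- rec
  rec2$pos <- rec2$pos * 3
  b <- arm_ratio_test(rec2, arms2)
  expect_equal(a$arms$ratio, b$arms$ratio)
  expect_equal(a$statistic, b$statistic)
})

test_that("the rank-sum test matches exact enumeration on tie-free inputs", {
  set.seed(55)
  for (i in 1:40) {
    n1 <- sample(2:6, 1)
    n2 <- sample(2:6, 1)
    x <- round(runif(n1, 0, 10), 6)
    y <- round(runif(n2, 0, 10), 6)
    ref <- enum_ranksum(x, y)
    wt <- wilcox.test(x, y)
    expect_equal(unname(wt$statistic), ref$statistic)
    expect_equal(wt$p.value, ref$p_value, tolerance = 1e-12)
  }
  # complete separation of two tie-free triples: one-sided 1/20, two-sided 0.1
  ref <- enum_ranksum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ref$statistic, 0)
  expect_equal(ref$p_value, 0.1)
})

test_that("LORe depletion yields complete separation and the extreme statistic", {
  arms <- load_arm_table()
  rec <- sim_mapping_records(tibble::tibble(marker = sprintf("m%05d", 1:20000),
                                            group = "LG01"),
                             arms, scheme = "by_arm_rate", prop_mapped = 0.5,
                             lore_rate = 0.2, low_mapq_rate = 0.2, seed = 5)
  out <- arm_ratio_test(filter_mappings(rec, NULL, 30), arms)
  aore <- out$arms$ratio[out$arms$class == "AORe"]
  lore <- out$arms$ratio[out$arms$class == "LORe"]
  expect_true(min(lore, na.rm = TRUE) > max(aore, na.rm = TRUE))
  expect_equal(out$statistic, 0)       # W counts AORe-over-LORe pairs
  expect_lt(out$p_value, 1e-6)
})

test_that("a single-class arm table skips the test gracefully", {
  arms <- tibble::tibble(arm = c("a", "b"), chrom = c("c1", "c2"),
                         start = 0, end = 100, class = "AORe",
                         length = 100)
  rec <- tibble::tibble(marker = "m1", chrom = "c1", pos = 5, mapq = 60)
  expect_message(out <- arm_ratio_test(rec, arms), "skipped")
  expect_true(is.na(out$statistic))
})

test_that("mapping records survive a TSV round trip", {
  rec <- tibble::tibble(marker = c("a", "b"), chrom = c("Ssa01", "Ssa02"),
                        pos = c(100, 200), mapq = c(45, 12))
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(rec, f)
  expect_equal(as.data.frame(read_mapping_records(f)), as.data.frame(rec))
})
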