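test_that("segregation classification follows the parental genotypes", {
  g <- make_geno(c("m1", "m2", "m3", "m4", "m5"),
                 mother = c(1, 0, 1, 2, NA),
                 father = c(0, 1, 1, 0, 0),
                 offspring = list(geno_counts(60, 60), geno_counts(60, 60),
                                  geno_counts(30, 60, 30), geno_counts(0, 120),
                                  geno_counts(60, 60)))
  seg <- classify_segregation(g)
  expect_equal(as.character(seg$seg_type),
               c("MAT_INF", "PAT_INF", "BOTH_INF", "UNINFORMATIVE",
                 "UNINFORMATIVE"))
  # heterozygous offspring of an intercross marker are phase-uninformative
  expect_equal(seg$n_informative[3], 60)
  expect_equal(seg$n_informative[4], 0)
})

test_that("uninformative markers are dropped and logged", {
  g <- make_geno(c("a", "b"), mother = c(1, 0), father = c(0, 0),
                 offspring = list(geno_counts(5, 5), geno_counts(10)))
  out <- drop_uninformative(g)
  expect_equal(out$marker, "a")
  expect_equal(filter_log(out)$reason, "uninformative")
})

test_that("RAD-locus thinning keeps one SNP from 2-3 SNP loci and drops >3", {
  rad <- c("L1", rep("L2", 2), rep("L3", 3), rep("L4", 4))
  g <- make_geno(sprintf("m%02d", 1:10), mother = rep(1, 10),
                 father = rep(0, 10),
                 offspring = replicate(10, geno_counts(5, 5), simplify = FALSE),
                 rad = rad)
  out <- thin_rad_loci(g, seed = 1)
  kept <- table(out$rad_locus)
  expect_equal(as.integer(kept[c("L1", "L2", "L3")]), c(1L, 1L, 1L))
  expect_false("L4" %in% out$rad_locus)
  expect_true(all(c("rad_locus_gt3_snps", "rad_locus_thinned") %in%
                    filter_log(out)$reason))

  # 1000 two-SNP loci: exactly one survivor each, reproducibly
  rad2 <- rep(sprintf("R%04d", 1:1000), each = 2)
  g2 <- make_geno(sprintf("s%04d", 1:2000), mother = rep(1, 2000),
                  father = rep(0, 2000),
                  offspring = replicate(2000, geno_counts(2, 2),
                                        simplify = FALSE),
                  rad = rad2)
  t1 <- thin_rad_loci(g2, seed = 8)
  t2 <- thin_rad_loci(g2, seed = 8)
  expect_equal(nrow(t1), 1000)
  expect_identical(t1$marker, t2$marker)
  expect_false(identical(t1$marker, thin_rad_loci(g2, seed = 9)$marker))
})

test_that("missingness filter applies a strict 20% threshold", {
  g <- make_geno(c("keep31", "drop32", "keep0"),
                 mother = rep(1, 3), father = rep(0, 3),
                 offspring = list(geno_counts(63, 62, 0, 31),
                                  geno_counts(62, 62, 0, 32),
                                  geno_counts(78, 78)))
  out <- filter_missingness(g, max_missing = 0.20)
  expect_setequal(out$marker, c("keep31", "keep0"))
  expect_equal(filter_log(out)$marker, "drop32")
  expect_equal(filter_log(out)$statistic, 32 / 156, tolerance = 1e-12)
})

test_that("distortion filter removes markers failing the chi-square test", {
  g <- make_geno(c("balanced", "distorted", "intercross"),
                 mother = c(1, 1, 1), father = c(0, 0, 1),
                 offspring = list(geno_counts(78, 78),
                                  geno_counts(36, 120),
                                  geno_counts(39, 78, 39)))
  out <- filter_distortion(g, tolerance = 0.001, both_inf_classes = "three")
  expect_setequal(out$marker, c("balanced", "intercross"))
  log <- filter_log(out)
  # chi-square = (120-78)^2/78 + (36-78)^2/78 = 45.23 => p ~ 1.7e-11
  expect_equal(log$statistic,
               pchisq(2 * 42^2 / 78, df = 1, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_lt(log$statistic, 1e-10)

  # a perfectly balanced marker has p = 1
  seg <- classify_segregation(g)
  p <- whitemap:::distortion_pvalues(g, seg$seg_type, "three")
  expect_equal(p[1], 1)
  expect_equal(p[3], 1)
})

test_that("markers with zero informative offspring are removed with a warning", {
  g <- make_geno(c("allmiss", "ok"), mother = c(1, 1), father = c(0, 0),
                 offspring = list(geno_counts(nmiss = 10), geno_counts(5, 5)))
  expect_warning(out <- filter_distortion(g), "no informative offspring")
  expect_equal(out$marker, "ok")
})

test_that("filters are idempotent and order-insensitive on survivors", {
  cross <- small_cross(seed = 6, n_groups = 2, markers_per_group = 25,
                       error = 0.02, missing = 0.15)
  g <- cross$geno
  m1 <- filter_missingness(g)
  expect_identical(as.data.frame(filter_missingness(m1)), as.data.frame(m1))
  d1 <- filter_distortion(g)
  expect_identical(as.data.frame(filter_distortion(d1)), as.data.frame(d1))
  # missingness then distortion vs distortion then missingness
  a <- filter_distortion(filter_missingness(g))
  b <- filter_missingness(filter_distortion(g))
  expect_identical(a$marker, b$marker)
})

test_that("the full filter cascade reports an auditable funnel", {
  cross <- sim_cross(sim_config(n_groups = 2, markers_per_group = 40,
                                mean_spacing_cM = 1, seed = 3))
  msgs <- capture.output(
    out <- filter_genotypes(cross$geno, verbose = TRUE),
    type = "message")
  expect_length(msgs, 5)
  expect_match(msgs[1], "input")
  expect_match(msgs[5], "distortion")
  expect_true(nrow(out) < nrow(cross$geno))  # thinning always removes some
  expect_true(all(filter_log(out)$fate == "removed"))
  expect_equal(nrow(cross$geno) - nrow(out), nrow(filter_log(out)))
})
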