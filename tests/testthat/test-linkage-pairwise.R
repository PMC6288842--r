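test_that("two-point LOD follows its closed form at the limits", {
  tp <- whitemap:::two_point_lod
  # no recombinants among 156 meioses
  est <- tp(0, 156)
  expect_equal(est$rf, 0)
  expect_equal(est$lod, 156 * log10(2), tolerance = 1e-10)
  # free recombination
  est <- tp(78, 156)
  expect_equal(est$rf, 0.5)
  expect_equal(est$lod, 0)
  # k = 10 of n = 100
  est <- tp(10, 100)
  expect_equal(est$rf, 0.1)
  expect_equal(est$lod, 10 * log10(0.2) + 90 * log10(1.8), tolerance = 1e-10)
  expect_equal(est$lod, 15.9848, tolerance = 1e-4)
})

test_that("pairwise estimates are symmetric and invariant to allele relabeling", {
  cross <- small_cross(seed = 3, n_groups = 1, markers_per_group = 15)
  seg <- classify_segregation(cross$geno)
  est <- whitemap:::rf_lod_matrices(cross$geno, seg, "joint")
  expect_equal(est$rf, t(est$rf))
  expect_equal(est$lod, t(est$lod))
  expect_true(all(est$rf >= 0 & est$rf <= 0.5, na.rm = TRUE))
  expect_true(all(est$lod >= 0, na.rm = TRUE))

  # swap REF/ALT at every marker: dosage g -> 2 - g
  flip <- cross$geno
  for (cc in setdiff(names(flip), c("marker", "rad_locus"))) {
    flip[[cc]] <- 2L - flip[[cc]]
  }
  est2 <- whitemap:::rf_lod_matrices(flip, classify_segregation(flip), "joint")
  expect_equal(est2$rf, est$rf, tolerance = 1e-12)
  expect_equal(est2$lod, est$lod, tolerance = 1e-10)
})

test_that("counting and EM agree where transmissions are fully observed", {
  cross <- small_cross(seed = 8, n_groups = 1, markers_per_group = 20)
  seg <- classify_segregation(cross$geno)
  mat <- seg$marker[seg$seg_type == "MAT_INF"][1:2]
  pe <- pair_estimate(cross$geno, seg, mat[1], mat[2], context = "maternal")
  pw <- pairwise_rf_lod(cross$geno, seg, context = "maternal")
  row <- pw[(pw$marker1 == mat[1] & pw$marker2 == mat[2]) |
              (pw$marker1 == mat[2] & pw$marker2 == mat[1]), ]
  expect_equal(pe$rf, row$rf)
  expect_equal(pe$lod, row$lod)
  expect_equal(pe$n_meioses, row$n_meioses)
})

test_that("the intercross-pair EM matches a brute-force likelihood oracle", {
  # simulate a pure intercross group so every pair is BOTH x BOTH
  cfg <- sim_config(n_offspring = 200, n_groups = 1, markers_per_group = 6,
                    mean_spacing_cM = 8, seg_mix = c(0, 0, 1), error_rate = 0,
                    missing_rate = 0, rad_multi_snp = c(1, 0, 0, 0), seed = 21)
  cross <- sim_cross(cfg)
  seg <- classify_segregation(cross$geno)
  G <- as.matrix(cross$geno[, grep("^off_", names(cross$geno))])
  rownames(G) <- cross$geno$marker

  oracle <- function(m1, m2) {
    counts <- table(factor(G[m1, ], 0:2), factor(G[m2, ], 0:2))
    ll <- function(r, pm, pf) {
      coef <- whitemap:::bb_coeffs(pm, pf)
      s <- 0
      for (a in 0:2) for (b in 0:2) {
        c <- a + 3 * b + 1
        p <- 0.25 * (coef[c, 1, 1] * (1 - r)^2 +
                       (coef[c, 2, 1] + coef[c, 1, 2]) * r * (1 - r) +
                       coef[c, 2, 2] * r^2)
        s <- s + counts[a + 1, b + 1] * log(p)
      }
      s
    }
    fits <- expand.grid(pm = 1:2, pf = 1:2)
    best <- NULL
    for (i in seq_len(nrow(fits))) {
      o <- stats::optimize(function(r) -ll(r, fits$pm[i], fits$pf[i]),
                           c(1e-7, 0.5))
      if (is.null(best) || -o$objective > best$ll) {
        best <- list(rf = o$minimum, ll = -o$objective)
      }
    }
    best$lod <- (best$ll - ll(0.5, 1, 1)) / log(10)
    best
  }

  markers <- cross$geno$marker
  for (pair in list(c(1, 2), c(2, 5), c(1, 6))) {
    m1 <- markers[pair[1]]; m2 <- markers[pair[2]]
    pe <- pair_estimate(cross$geno, seg, m1, m2, context = "joint")
    ref <- oracle(m1, m2)
    expect_equal(pe$rf, ref$rf, tolerance = 1e-3)
    expect_equal(pe$lod, ref$lod, tolerance = 1e-2)
  }
})

test_that("the EM recovers the simulated recombination fraction of intercross pairs", {
  d <- haldane_cM(0.15)
  cfg <- sim_config(n_offspring = 5000, n_groups = 1, markers_per_group = 2,
                    mean_spacing_cM = d, female_expansion = 1,
                    seg_mix = c(0, 0, 1), error_rate = 0, missing_rate = 0,
                    rad_multi_snp = c(1, 0, 0, 0), seed = 31)
  cross <- sim_cross(cfg)
  seg <- classify_segregation(cross$geno)
  m <- cross$geno$marker
  true_r <- haldane_rf(cross$true_map$male_cM[2])
  pe <- pair_estimate(cross$geno, seg, m[1], m[2], context = "joint")
  expect_lt(abs(pe$rf - true_r), 3 * sqrt(true_r * (1 - true_r) / 10000))
})

test_that("pairs with no shared informative meioses are skipped", {
  g <- make_geno(c("mat", "pat"), mother = c(1, 0), father = c(0, 1),
                 offspring = list(geno_counts(40, 40), geno_counts(40, 40)))
  seg <- classify_segregation(g)
  expect_equal(nrow(pair_estimate(g, seg, "mat", "pat", "joint")), 0)
  expect_equal(nrow(pairwise_rf_lod(g, seg, "joint")), 0)
})
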