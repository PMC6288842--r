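#' Simulate the true genetic map of a synthetic F1 cross
#'
#' Lays out `n_groups` linkage groups of RAD loci. Adjacent RAD loci are
#' separated by male-map distances drawn from an exponential distribution with
#' mean `mean_spacing_cM`; the female distance of every interval is the male
#' distance times `female_expansion`. RAD loci carry 1-4+ SNPs (per
#' `rad_multi_snp`) simulated at 0 cM spacing, so multi-SNP loci are fully
#' linked clusters, as in real RAD data. Each SNP is assigned one of the three
#' informative segregation types from `seg_mix`.
#'
#' @param cfg A [sim_config()].
#' @return A `true_map` tibble with columns `marker`, `group`, `order`,
#'   `rad_locus`, `female_cM`, `male_cM`, `seg_type`. The first marker of each
#'   group sits at 0 cM on both sex maps and positions are non-decreasing.
#' @examples
#' tm <- simulate_true_map(sim_config(n_groups = 2, markers_per_group = 10, seed = 3))
#' @export
simulate_true_map <- function(cfg) {
  validate_sim_config(cfg)
  with_seed(cfg$seed, {
    groups <- purrr::map(seq_len(cfg$n_groups), function(g) {
      m <- cfg$markers_per_group
      # RAD locus sizes drawn until the group has m SNPs; last locus truncated
      sizes <- integer(0)
      while (sum(sizes) < m) {
        k <- sample(1:4, 1L, prob = cfg$rad_multi_snp)
        if (k == 4L) k <- k + rpois(1L, 1)
        sizes <- c(sizes, k)
      }
      excess <- sum(sizes) - m
      sizes[length(sizes)] <- sizes[length(sizes)] - excess
      sizes <- sizes[sizes > 0L]

      locus_id <- rep(seq_along(sizes), sizes)
      # exponential male spacing between RAD loci, 0 cM within a locus
      gap_male <- c(0, rexp(length(sizes) - 1L, rate = 1 / cfg$mean_spacing_cM))
      if (cfg$mean_spacing_cM == 0) gap_male <- rep(0, length(sizes))
      locus_male <- cumsum(gap_male)
      male_cM <- locus_male[locus_id]
      female_cM <- male_cM * cfg$female_expansion

      tibble(
        marker = sprintf("LG%02d_M%04d", g, seq_len(m)),
        group = sprintf("LG%02d", g),
        order = seq_len(m),
        rad_locus = sprintf("LG%02d_R%04d", g, locus_id),
        female_cM = female_cM,
        male_cM = male_cM,
        seg_type = sample(names(cfg$seg_mix), m, replace = TRUE, prob = cfg$seg_mix)
      )
    })
    out <- bind_rows(groups)
    class(out) <- c("true_map", class(out))
    out
  })
}

#' Simulate gametes (haplotype-origin sequences) from a true map
#'
#' For one parent, draws `n` meioses per linkage group. Each gamete is a
#' binary haplotype-origin sequence along the group's marker order: the origin
#' at the first marker is uniform, and between adjacent markers at
#' sex-specific distance `d` cM the origin switches with probability
#' `r = (1 - exp(-2 d / 100)) / 2` independently across intervals (Haldane
#' model, no crossover interference).
#'
#' @param true_map A `true_map` from [simulate_true_map()].
#' @param parent `"mother"` (uses `female_cM`) or `"father"` (`male_cM`).
#' @param n Number of gametes (offspring) to draw, `>= 1`.
#' @param seed Optional integer seed.
#' @return A named list, one element per group: an `n x markers` integer
#'   matrix of haplotype origins (0 = first parental haplotype, 1 = second).
#' @export
simulate_gametes <- function(true_map, parent = c("mother", "father"), n, seed = NULL) {
  parent <- match.arg(parent)
  stopifnot(n >= 1)
  pos_col <- if (parent == "mother") "female_cM" else "male_cM"
  with_seed(seed, {
    split_map <- split(true_map, true_map$group)
    out <- purrr::map(split_map, function(gm) {
      gm <- gm[order(gm$order), ]
      m <- nrow(gm)
      r <- haldane_rf(diff(gm[[pos_col]]))
      start <- rbinom(n, 1L, 0.5)
      if (m == 1L) {
        return(matrix(as.integer(start), ncol = 1L,
                      dimnames = list(NULL, gm$marker)))
      }
      switches <- matrix(rbinom(n * (m - 1L), 1L, rep(r, each = n)), nrow = n)
      orig <- matrixStats_rowCumsums(cbind(start, switches)) %% 2L
      colnames(orig) <- gm$marker
      orig
    })
    out[unique(true_map$group)]
  })
}

# cumulative sums along rows without extra deps
matrixStats_rowCumsums <- function(x) {
  t(apply(x, 1L, cumsum))
}

#' Simulate parent and offspring genotypes for a synthetic cross
#'
#' Parents' genotypes follow each marker's segregation type (`MAT_INF`:
#' mother Aa x father aa; `PAT_INF`: aa x Aa; `BOTH_INF`: Aa x Aa). Each
#' heterozygous parent receives a random linkage phase, gametes are drawn with
#' [simulate_gametes()], and each offspring genotype is the sum of the
#' inherited maternal and paternal alleles (ALT-dosage coding 0/1/2). With
#' probability `error_rate` a call is replaced by a uniformly chosen different
#' genotype; with probability `missing_rate` it is set missing.
#'
#' @param true_map A `true_map`.
#' @param cfg The [sim_config()] used (supplies `n_offspring`, error and
#'   missing rates, and the seed).
#' @return A `sim_cross` list with elements `geno` (genotype tibble: `marker`,
#'   `rad_locus`, `mother`, `father`, then one column per offspring),
#'   `true_map`, and `origins` (per-parent true haplotype-origin matrices,
#'   markers x offspring).
#' @export
simulate_offspring_genotypes <- function(true_map, cfg) {
  validate_sim_config(cfg)
  n <- cfg$n_offspring
  with_seed(cfg$seed + 1L, {
    gam_m <- simulate_gametes(true_map, "mother", n)
    gam_f <- simulate_gametes(true_map, "father", n)
    # markers x offspring origin matrices, rows in true_map order
    O_m <- t(do.call(cbind, gam_m))[true_map$marker, , drop = FALSE]
    O_f <- t(do.call(cbind, gam_f))[true_map$marker, , drop = FALSE]

    st <- true_map$seg_type
    mother_g <- ifelse(st == "PAT_INF", 0L, 1L)
    father_g <- ifelse(st == "MAT_INF", 0L, 1L)

    # random linkage phase per heterozygous parent: hap1 allele ~ Bern(0.5)
    phase1_m <- ifelse(mother_g == 1L, rbinom(nrow(true_map), 1L, 0.5), mother_g %/% 2L)
    phase2_m <- ifelse(mother_g == 1L, 1L - phase1_m, phase1_m)
    phase1_f <- ifelse(father_g == 1L, rbinom(nrow(true_map), 1L, 0.5), father_g %/% 2L)
    phase2_f <- ifelse(father_g == 1L, 1L - phase1_f, phase1_f)

    allele_m <- phase1_m * (1L - O_m) + phase2_m * O_m
    allele_f <- phase1_f * (1L - O_f) + phase2_f * O_f
    G <- allele_m + allele_f

    if (cfg$error_rate > 0) {
      err <- matrix(runif(length(G)) < cfg$error_rate, nrow = nrow(G))
      shift <- matrix(sample(1:2, length(G), replace = TRUE), nrow = nrow(G))
      G[err] <- (G[err] + shift[err]) %% 3L
    }
    if (cfg$missing_rate > 0) {
      G[matrix(runif(length(G)) < cfg$missing_rate, nrow = nrow(G))] <- NA_integer_
    }

    off <- as_tibble(as.data.frame(G))
    names(off) <- sprintf("off_%03d", seq_len(n))
    geno <- bind_cols(
      tibble(marker = true_map$marker, rad_locus = true_map$rad_locus,
             mother = as.integer(mother_g), father = as.integer(father_g)),
      off
    )
    structure(
      list(geno = geno, true_map = true_map,
           origins = list(mother = O_m, father = O_f)),
      class = "sim_cross"
    )
  })
}

#' Simulate a complete synthetic cross in one call
#'
#' Convenience wrapper: [simulate_true_map()] followed by
#' [simulate_offspring_genotypes()].
#'
#' @param cfg A [sim_config()].
#' @return A `sim_cross` list (see [simulate_offspring_genotypes()]).
#' @examples
#' cross <- sim_cross(sim_config(n_groups = 2, markers_per_group = 12, seed = 1))
#' head(cross$geno[, 1:6])
#' @export
sim_cross <- function(cfg = sim_config()) {
  simulate_offspring_genotypes(simulate_true_map(cfg), cfg)
}

#' @export
print.sim_cross <- function(x, ...) {
  cat(sprintf("<sim_cross> %d markers x %d offspring, %d linkage groups\n",
              nrow(x$geno), length(offspring_cols(x$geno)),
              length(unique(x$true_map$group))))
  invisible(x)
}

#' Write the simulation truth tables
#'
#' Writes `true_map.tsv` (marker, group, order, rad locus, sex-specific cM,
#' segregation type) and one haplotype-origin TSV per parent.
#'
#' @param cross A `sim_cross`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(cross, dir) {
  stopifnot(inherits(cross, "sim_cross"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    map = file.path(dir, "true_map.tsv"),
    mother = file.path(dir, "true_origins_mother.tsv"),
    father = file.path(dir, "true_origins_father.tsv")
  )
  readr::write_tsv(cross$true_map, paths["map"])
  for (p in c("mother", "father")) {
    om <- as_tibble(as.data.frame(cross$origins[[p]]), rownames = "marker")
    readr::write_tsv(om, paths[[p]])
  }
  invisible(paths)
}
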