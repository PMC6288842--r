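SEG_LEVELS <- c("MAT_INF", "PAT_INF", "BOTH_INF", "UNINFORMATIVE")

#' Classify the segregation type of every marker
#'
#' In an F1 outbred cross only markers with at least one heterozygous parent
#' are informative: one parent Aa and the other homozygous gives a 1:1
#' pseudo-testcross marker informative for the heterozygous parent
#' (`MAT_INF` / `PAT_INF`); both parents Aa gives a 1:2:1 intercross marker
#' (`BOTH_INF`) whose heterozygous offspring are phase-uninformative (the
#' parental origin of their alleles is unknown). Markers with a missing
#' parent genotype, or with no heterozygous parent, are `UNINFORMATIVE`.
#'
#' @param geno Genotype tibble.
#' @return A tibble (`marker`, `seg_type`, `n_informative`) where
#'   `n_informative` counts offspring whose genotypes carry phase information
#'   (non-missing for 1:1 markers; homozygous for `BOTH_INF` markers).
#' @examples
#' g <- tibble::tibble(marker = "m1", rad_locus = "r1", mother = 1L,
#'                     father = 0L, o1 = 1L, o2 = 0L)
#' classify_segregation(g)
#' @export
classify_segregation <- function(geno) {
  assert_geno_tbl(geno)
  off <- offspring_matrix(geno)
  mo <- geno$mother
  fa <- geno$father
  type <- rep("UNINFORMATIVE", nrow(geno))
  type[!is.na(mo) & !is.na(fa) & mo == 1L & fa != 1L] <- "MAT_INF"
  type[!is.na(mo) & !is.na(fa) & mo != 1L & fa == 1L] <- "PAT_INF"
  type[!is.na(mo) & !is.na(fa) & mo == 1L & fa == 1L] <- "BOTH_INF"
  n_inf <- rowSums(!is.na(off))
  both <- type == "BOTH_INF"
  n_inf[both] <- rowSums(off[both, , drop = FALSE] != 1L, na.rm = TRUE)
  n_inf[type == "UNINFORMATIVE"] <- 0L
  tibble(marker = geno$marker, seg_type = factor(type, SEG_LEVELS),
         n_informative = as.integer(n_inf))
}

#' Drop uninformative markers
#'
#' Removes markers classified `UNINFORMATIVE` (missing parent genotype or no
#' heterozygous parent); they carry no linkage information in an F1 cross.
#'
#' @inheritParams classify_segregation
#' @param segcalls Output of [classify_segregation()]; computed if `NULL`.
#' @return The filtered genotype tibble, with a `filter_log` attribute.
#' @export
drop_uninformative <- function(geno, segcalls = NULL) {
  segcalls <- segcalls %||% classify_segregation(geno)
  drop <- segcalls$seg_type == "UNINFORMATIVE"
  add_filter_log(geno[!drop, , drop = FALSE],
                 log_entries(geno$marker[drop], "removed", "uninformative"),
                 geno)
}

#' Thin RAD loci to at most one SNP where they carry several
#'
#' RAD loci with more than three SNPs are removed entirely (such loci are
#' enriched for paralog collapse); loci with two or three SNPs contribute a
#' single SNP chosen uniformly at random; single-SNP loci are untouched.
#'
#' @inheritParams classify_segregation
#' @param seed Integer seed controlling the random choice.
#' @return The filtered genotype tibble, with a `filter_log` attribute.
#' @export
thin_rad_loci <- function(geno, seed = 1L) {
  assert_geno_tbl(geno)
  if (is.null(geno$rad_locus)) abort("`geno` lacks a rad_locus column")
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(geno)), geno$rad_locus), function(idx) {
      k <- length(idx)
      if (k == 1L) idx
      else if (k > 3L) integer(0)
      else idx[sample.int(k, 1L)]
    }), use.names = FALSE)
    keep <- sort(keep)
    dropped <- setdiff(seq_len(nrow(geno)), keep)
    sizes <- table(geno$rad_locus)
    reason <- ifelse(sizes[geno$rad_locus[dropped]] > 3L,
                     "rad_locus_gt3_snps", "rad_locus_thinned")
    add_filter_log(geno[keep, , drop = FALSE],
                   log_entries(geno$marker[dropped], "removed", reason), geno)
  })
}

#' Remove markers with excessive offspring missingness
#'
#' Markers whose offspring missing fraction strictly exceeds `max_missing`
#' are removed; a fraction exactly at the threshold is kept.
#'
#' @inheritParams classify_segregation
#' @param max_missing Maximum tolerated offspring missing fraction
#'   (default 0.20).
#' @return The filtered genotype tibble, with a `filter_log` attribute.
#' @export
filter_missingness <- function(geno, max_missing = 0.20) {
  assert_geno_tbl(geno)
  off <- offspring_matrix(geno)
  frac <- rowMeans(is.na(off))
  drop <- frac > max_missing
  add_filter_log(geno[!drop, , drop = FALSE],
                 log_entries(geno$marker[drop], "removed", "missingness",
                             frac[drop]), geno)
}

#' Remove markers with significant segregation distortion
#'
#' Tests each marker's offspring genotype counts (missing calls excluded)
#' against its Mendelian expectation with a Pearson chi-square goodness-of-fit
#' test: 1:1 over the two expected genotypes for single-parent-informative
#' markers, 1:2:1 (or 1:1 over homozygotes only, see `both_inf_classes`) for
#' intercross markers. Markers with p below `tolerance` are removed.
#'
#' @inheritParams drop_uninformative
#' @param tolerance P-value threshold below which a marker is removed
#'   (default 0.001).
#' @param both_inf_classes For `BOTH_INF` markers, `"homozygous"` (default)
#'   tests AA:aa against 1:1 over the phase-informative homozygotes;
#'   `"three"` tests AA:Aa:aa against 1:2:1. The homozygote variant is the
#'   default because heterozygous offspring of an intercross marker carry no
#'   phase information, and because the df = 2 Pearson tail is measurably
#'   anti-conservative at the 0.001 tolerance (see the methods vignette).
#' @return The filtered genotype tibble, with a `filter_log` attribute
#'   recording the chi-square p-value of every removed marker.
#' @export
filter_distortion <- function(geno, segcalls = NULL, tolerance = 0.001,
                              both_inf_classes = c("homozygous", "three")) {
  assert_geno_tbl(geno)
  both_inf_classes <- match.arg(both_inf_classes)
  segcalls <- segcalls %||% classify_segregation(geno)
  segcalls <- segcalls[match(geno$marker, segcalls$marker), ]
  p <- distortion_pvalues(geno, segcalls$seg_type, both_inf_classes)
  empty <- is.na(p)
  if (any(empty)) {
    warn(sprintf("%d marker(s) with no informative offspring removed", sum(empty)))
  }
  drop <- empty | p < tolerance
  add_filter_log(geno[!drop, , drop = FALSE],
                 log_entries(geno$marker[drop], "removed",
                             ifelse(empty[drop], "no_informative_offspring",
                                    "segregation_distortion"),
                             p[drop]), geno)
}

# vectorised per-marker chi-square p-values against Mendelian ratios
distortion_pvalues <- function(geno, seg_type, both_inf_classes = "three") {
  off <- offspring_matrix(geno)
  n0 <- rowSums(off == 0L, na.rm = TRUE)
  n1 <- rowSums(off == 1L, na.rm = TRUE)
  n2 <- rowSums(off == 2L, na.rm = TRUE)
  p <- rep(NA_real_, nrow(geno))

  one_one <- seg_type %in% c("MAT_INF", "PAT_INF")
  if (any(one_one)) {
    # the two expected classes are het and the parental homozygote; rare
    # opposite-homozygote error calls are pooled with the homozygote class
    a <- n1[one_one]
    b <- n0[one_one] + n2[one_one]
    n <- a + b
    chi <- (a - n / 2)^2 / (n / 2) + (b - n / 2)^2 / (n / 2)
    p[one_one] <- ifelse(n > 0, pchisq(chi, df = 1L, lower.tail = FALSE), NA_real_)
  }

  both <- seg_type == "BOTH_INF"
  if (any(both)) {
    if (both_inf_classes == "three") {
      n <- n0[both] + n1[both] + n2[both]
      e <- cbind(n / 4, n / 2, n / 4)
      o <- cbind(n0[both], n1[both], n2[both])
      chi <- rowSums((o - e)^2 / e)
      p[both] <- ifelse(n > 0, pchisq(chi, df = 2L, lower.tail = FALSE), NA_real_)
    } else {
      n <- n0[both] + n2[both]
      chi <- (n0[both] - n / 2)^2 / (n / 2) + (n2[both] - n / 2)^2 / (n / 2)
      p[both] <- ifelse(n > 0, pchisq(chi, df = 1L, lower.tail = FALSE), NA_real_)
    }
  }
  p
}

#' Run the full informative-marker filter cascade
#'
#' Applies, in order: segregation-type classification with removal of
#' uninformative markers, RAD-locus thinning, the missingness filter and the
#' segregation-distortion filter. The per-stage marker counts are reported
#' with [base::message()] so the attrition funnel can be audited.
#'
#' @inheritParams filter_distortion
#' @inheritParams filter_missingness
#' @inheritParams thin_rad_loci
#' @param verbose Print the per-stage funnel (default TRUE).
#' @return The filtered genotype tibble; `filter_log(x)` returns the combined
#'   log of all removals.
#' @examples
#' cross <- sim_cross(sim_config(n_groups = 2, markers_per_group = 15, seed = 2))
#' filtered <- filter_genotypes(cross$geno, verbose = FALSE)
#' nrow(filtered)
#' @export
filter_genotypes <- function(geno, tolerance = 0.001, max_missing = 0.20,
                             both_inf_classes = "homozygous", seed = 1L,
                             verbose = TRUE) {
  assert_geno_tbl(geno)
  say <- function(stage, x) {
    if (verbose) inform(sprintf("%-22s %d markers", stage, nrow(x)))
  }
  say("input", geno)
  g <- drop_uninformative(geno)
  say("informative", g)
  g <- thin_rad_loci(g, seed = seed)
  say("rad-thinned", g)
  g <- filter_missingness(g, max_missing = max_missing)
  say("missingness", g)
  g <- filter_distortion(g, tolerance = tolerance,
                         both_inf_classes = both_inf_classes)
  say("distortion", g)
  g   # each filter extends the cumulative filter_log attribute
}

#' Retrieve the filter log of a filtered genotype table
#'
#' @param geno A genotype tibble returned by one of the filter functions.
#' @return A tibble (`marker`, `fate`, `reason`, `statistic`).
#' @export
filter_log <- function(geno) {
  attr(geno, "filter_log") %||%
    tibble(marker = character(), fate = character(), reason = character(),
           statistic = numeric())
}

log_entries <- function(markers, fate, reason, statistic = NA_real_) {
  if (length(markers) == 0L) {
    return(tibble(marker = character(), fate = character(),
                  reason = character(), statistic = numeric()))
  }
  tibble(marker = markers, fate = fate, reason = as.character(reason),
         statistic = as.numeric(statistic))
}

add_filter_log <- function(new, entries, old) {
  attr(new, "filter_log") <- bind_rows(attr(old, "filter_log"), entries)
  new
}
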