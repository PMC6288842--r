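#' Configuration for the synthetic F1 cross simulator
#'
#' Bundles every knob of the synthetic-cross generator. The defaults emulate
#' the study design the package targets: a single outbred F1 family with 156
#' offspring, 40 linkage groups of ~135 SNPs, a male map of roughly 57 cM per
#' group, a genome-wide female:male expansion of 1.09, RAD loci that may carry
#' several tightly linked SNPs, and realistic genotyping error and missingness.
#'
#' @param n_offspring Number of F1 offspring (default 156).
#' @param n_groups Number of linkage groups / chromosomes (default 40).
#' @param markers_per_group SNPs per linkage group (default 135).
#' @param mean_spacing_cM Mean male-map distance between adjacent RAD loci, in
#'   cM; adjacent spacings are drawn from an exponential distribution with
#'   this mean (default 0.42, giving ~56 cM male groups at 135 markers).
#' @param female_expansion Factor applied to every male inter-locus distance to
#'   obtain the female distance (default 1.09, the genome-wide female:male
#'   map-length ratio reported for European whitefish).
#' @param seg_mix Length-3 numeric, proportions of the three informative
#'   segregation types `MAT_INF` (mother Aa x father aa), `PAT_INF`
#'   (aa x Aa) and `BOTH_INF` (Aa x Aa); must sum to 1.
#' @param error_rate Probability that a non-missing offspring call is replaced
#'   by a uniformly chosen *different* genotype (default 0.01).
#' @param missing_rate Probability that an offspring call is set missing
#'   (default 0.05; per-locus missingness stays well under the 20% filter).
#' @param rad_multi_snp Length-4 numeric, proportions of RAD loci carrying
#'   1, 2, 3 and 4+ SNPs; must sum to 1. SNPs within a RAD locus are simulated
#'   at 0 cM spacing (fully linked).
#' @param seed Integer seed; a fixed seed makes the simulator byte-identical.
#' @return A `sim_config` list.
#' @examples
#' cfg <- sim_config(n_groups = 5, markers_per_group = 20, seed = 1)
#' @export
sim_config <- function(n_offspring = 156L,
                       n_groups = 40L,
                       markers_per_group = 135L,
                       mean_spacing_cM = 0.42,
                       female_expansion = 1.09,
                       seg_mix = c(MAT_INF = 1 / 3, PAT_INF = 1 / 3, BOTH_INF = 1 / 3),
                       error_rate = 0.01,
                       missing_rate = 0.05,
                       rad_multi_snp = c(`1` = 0.55, `2` = 0.25, `3` = 0.12, `4+` = 0.08),
                       seed = 1L) {
  cfg <- list(
    n_offspring = as.integer(n_offspring),
    n_groups = as.integer(n_groups),
    markers_per_group = as.integer(markers_per_group),
    mean_spacing_cM = as.numeric(mean_spacing_cM),
    female_expansion = as.numeric(female_expansion),
    seg_mix = setNames(as.numeric(seg_mix), c("MAT_INF", "PAT_INF", "BOTH_INF")),
    error_rate = as.numeric(error_rate),
    missing_rate = as.numeric(missing_rate),
    rad_multi_snp = setNames(as.numeric(rad_multi_snp), c("1", "2", "3", "4+")),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  if (cfg$n_offspring < 1L) abort("n_offspring must be >= 1")
  if (cfg$n_groups < 1L) abort("n_groups must be >= 1")
  if (cfg$markers_per_group < 1L) abort("markers_per_group must be >= 1")
  if (cfg$mean_spacing_cM < 0) abort("mean_spacing_cM must be >= 0")
  if (cfg$female_expansion < 0) abort("female_expansion must be >= 0")
  probs <- c(cfg$error_rate, cfg$missing_rate, cfg$seg_mix, cfg$rad_multi_snp)
  if (any(probs < 0 | probs > 1)) abort("all probabilities must lie in [0, 1]")
  if (abs(sum(cfg$seg_mix) - 1) > 1e-8) abort("seg_mix must sum to 1")
  if (abs(sum(cfg$rad_multi_snp) - 1) > 1e-8) abort("rad_multi_snp must sum to 1")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d offspring, %d groups x %d markers\n",
              x$n_offspring, x$n_groups, x$markers_per_group))
  cat(sprintf("  male spacing Exp(mean %.3g cM), female expansion %.3g\n",
              x$mean_spacing_cM, x$female_expansion))
  cat(sprintf("  seg mix %s\n",
              paste(names(x$seg_mix), round(x$seg_mix, 3), collapse = " ")))
  cat(sprintf("  error %.3g, missing %.3g, seed %d\n",
              x$error_rate, x$missing_rate, x$seed))
  invisible(x)
}
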