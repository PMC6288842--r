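# shared in-code fixtures for the test suite

# a small simulated cross used by several files; single-SNP loci so marker
# counts are stable under thinning
small_cross <- function(seed = 1, n_groups = 2, markers_per_group = 30,
                        spacing = 3, error = 0, missing = 0.05,
                        expansion = 1.5, n_offspring = 156) {
  sim_cross(sim_config(
    n_offspring = n_offspring, n_groups = n_groups,
    markers_per_group = markers_per_group, mean_spacing_cM = spacing,
    female_expansion = expansion, error_rate = error, missing_rate = missing,
    rad_multi_snp = c(1, 0, 0, 0), seed = seed))
}

# genotype tibble built from explicit offspring genotype vectors
make_geno <- function(markers, mother, father, offspring, rad = NULL) {
  stopifnot(length(unique(lengths(offspring))) == 1L)
  off <- do.call(rbind, offspring)
  out <- tibble::tibble(marker = markers,
                        rad_locus = rad %||% markers,
                        mother = as.integer(mother),
                        father = as.integer(father))
  off_tbl <- tibble::as_tibble(as.data.frame(off))
  names(off_tbl) <- sprintf("off_%03d", seq_len(ncol(off)))
  dplyr::bind_cols(out, off_tbl)
}

# genotype vector with fixed counts of each dosage (order irrelevant to the
# statistics under test)
geno_counts <- function(n0 = 0, n1 = 0, n2 = 0, nmiss = 0) {
  as.integer(c(rep(0, n0), rep(1, n1), rep(2, n2), rep(NA, nmiss)))
}

# all permutations of 1..n (n small), one per row
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, ifelse(sub >= k, sub + 1L, sub))
  }))
}

# exhaustive minimum SARF over all marker orders (orientation-agnostic)
brute_force_sarf <- function(markers, R) {
  perms <- all_perms(length(markers))
  scores <- apply(perms, 1L, function(p) sarf(markers[p], R))
  min(scores)
}

# two-sided exact rank-sum p-value by enumeration of all group assignments
# (doubling rule, as in the exact Wilcoxon test)
enum_ranksum <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  ranks <- rank(pooled)
  w_obs <- sum(ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2
  splits <- utils::combn(length(pooled), n1)
  w_all <- apply(splits, 2L, function(i) {
    sum(ranks[i]) - n1 * (n1 + 1) / 2
  })
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  list(statistic = w_obs, p_value = min(1, 2 * min(p_le, p_ge)))
}
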