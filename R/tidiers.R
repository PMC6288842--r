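#' Tidy a genetic map
#'
#' @param x A `genetic_map`.
#' @param ... Unused.
#' @return One row per marker: `marker`, `group`, `order`, `female_cM`,
#'   `male_cM`, `avg_cM`.
#' @method tidy genetic_map
#' @export
tidy.genetic_map <- function(x, ...) {
  as_tibble(x)
}

#' One-row summary of a genetic map
#'
#' @inheritParams tidy.genetic_map
#' @return A one-row tibble with group/marker counts, the three total map
#'   lengths and the total-length female:male ratio.
#' @method glance genetic_map
#' @export
glance.genetic_map <- function(x, ...) {
  map_summary(x)$global %>%
    select("n_groups", "n_snps", "total_avg_cM", "total_female_cM",
           "total_male_cM", "fm_ratio_total")
}

#' @method tidy map_summary
#' @export
tidy.map_summary <- function(x, ...) x$by_group

#' @method glance map_summary
#' @export
glance.map_summary <- function(x, ...) x$global

#' @method tidy synteny_assignment
#' @export
tidy.synteny_assignment <- function(x, ...) x$groups

#' @method tidy arm_ratio_test
#' @export
tidy.arm_ratio_test <- function(x, ...) x$arms

#' @method glance arm_ratio_test
#' @export
glance.arm_ratio_test <- function(x, ...) {
  tibble(statistic = x$statistic, p_value = x$p_value,
         n_aore = x$n_aore, n_lore = x$n_lore)
}

#' @method tidy recovery_result
#' @export
tidy.recovery_result <- function(x, ...) x$per_seed

#' @method glance recovery_result
#' @export
glance.recovery_result <- function(x, ...) {
  tibble(mean_ari = x$mean_ari, all_ari_one = x$all_ari_one,
         mean_abs_rel_len_error = x$mean_abs_rel_len_error,
         fm_ratio = x$fm_ratio, fm_target = x$fm_target)
}
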