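TABLE1_MD5 <- "bf1972bc3369099a61a50be874a460dc"

#' Load the packaged European whitefish linkage-map summary table
#'
#' Returns the published per-linkage-group statistics of the *C. sp.
#' "Albock"* maps (40 linkage groups; SNP counts; sex-averaged, female and
#' male lengths and marker densities; homologous Atlantic Salmon chromosome;
#' W-name; female:male ratio). The printed "SNPs/cM" columns are in fact
#' cM-per-marker (each equals length / SNP count, e.g. 75.96/253 = 0.30), so
#' the fixture names them `*_cM_per_marker`. The packaged copy is
#' checksum-verified; a mismatch is an error.
#'
#' @param path Optional path to an alternative copy (no checksum applied).
#' @return A `map_table` tibble of 40 rows.
#' @examples
#' t1 <- load_table1()
#' sum(t1$n_snps)   # 5395
#' @export
load_table1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "albock_map_table.csv", package = "whitemap",
                        mustWork = TRUE)
    check_table_integrity(path, TABLE1_MD5)
  }
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           linkage_group = "c", homolog_chrom = "c",
                           w_name = "c", .default = "d"))
  out$n_snps <- as.integer(out$n_snps)
  class(out) <- c("map_table", class(out))
  out
}

check_table_integrity <- function(path, expected) {
  if (!identical(unname(tools::md5sum(path)), expected)) {
    abort("packaged map table failed its integrity checksum")
  }
  invisible(path)
}

#' Summary statistics of a genetic map
#'
#' Computes the standard per-group and global map statistics: SNP count,
#' length (the last cM position) per map, cM-per-marker, and female:male
#' length ratio per group; globally, totals, per-group means, the
#' total-length female:male ratio, and the mean per-group female:male ratio
#' over groups with positive length in both sex maps (a group of
#' single-parent markers has length 0 in the other sex's map and an undefined
#' ratio, so it is excluded). The global marker spacing is reported both as
#' the unweighted mean of per-group cM-per-marker (`mean_cM_per_marker`) and
#' as total length / total SNPs (`overall_cM_per_marker`).
#'
#' @param x A `genetic_map` (per-marker positions) or a per-group statistics
#'   table such as [load_table1()] (columns `n_snps`, `avg_length_cM`,
#'   `female_length_cM`, `male_length_cM`).
#' @param digits Decimal places for the rounded columns of the printed
#'   summary (full precision is always retained; default 2).
#' @return A `map_summary` list with tibbles `by_group` and `global`.
#' @examples
#' s <- map_summary(load_table1())
#' s$global$fm_ratio_total      # 1.09
#' @export
map_summary <- function(x, digits = 2) {
  UseMethod("map_summary")
}

#' @export
map_summary.genetic_map <- function(x, digits = 2) {
  if (nrow(x) == 0L) abort("empty map")
  by_group <- x %>%
    group_by(.data$group) %>%
    summarise(n_snps = n(),
              avg_length_cM = max(.data$avg_cM),
              female_length_cM = max(.data$female_cM),
              male_length_cM = max(.data$male_cM),
              .groups = "drop") %>%
    rename(linkage_group = "group")
  summarise_groups(by_group, digits)
}

#' @export
map_summary.data.frame <- function(x, digits = 2) {
  need <- c("n_snps", "avg_length_cM", "female_length_cM", "male_length_cM")
  if (!all(need %in% names(x))) {
    abort(sprintf("expected columns: %s", paste(need, collapse = ", ")))
  }
  if (nrow(x) == 0L) abort("empty map table")
  if (is.null(x$linkage_group)) x$linkage_group <- sprintf("LG%02d", seq_len(nrow(x)))
  summarise_groups(x[, c("linkage_group", need)], digits)
}

summarise_groups <- function(by_group, digits) {
  by_group <- by_group %>%
    mutate(
      avg_cM_per_marker = .data$avg_length_cM / .data$n_snps,
      female_cM_per_marker = .data$female_length_cM / .data$n_snps,
      male_cM_per_marker = .data$male_length_cM / .data$n_snps,
      fm_ratio = if_else(.data$female_length_cM > 0 & .data$male_length_cM > 0,
                         .data$female_length_cM / .data$male_length_cM,
                         NA_real_)
    )
  both_pos <- !is.na(by_group$fm_ratio)
  tot_m <- sum(by_group$male_length_cM)
  global <- tibble(
    n_groups = nrow(by_group),
    n_snps = sum(by_group$n_snps),
    mean_snps_per_group = mean(by_group$n_snps),
    total_avg_cM = sum(by_group$avg_length_cM),
    total_female_cM = sum(by_group$female_length_cM),
    total_male_cM = tot_m,
    mean_group_avg_cM = mean(by_group$avg_length_cM),
    mean_group_female_cM = mean(by_group$female_length_cM),
    mean_group_male_cM = mean(by_group$male_length_cM),
    mean_cM_per_marker = mean(by_group$avg_cM_per_marker),
    overall_cM_per_marker = sum(by_group$avg_length_cM) / sum(by_group$n_snps),
    fm_ratio_total = if_else(tot_m > 0, sum(by_group$female_length_cM) / tot_m,
                             NA_real_),
    fm_ratio_per_group = if (any(both_pos)) mean(by_group$fm_ratio[both_pos])
                         else NA_real_,
    n_groups_in_fm_per_group = sum(both_pos)
  )
  structure(list(by_group = by_group, global = global, digits = digits),
            class = "map_summary")
}

#' @export
print.map_summary <- function(x, ...) {
  g <- x$global
  d <- x$digits
  cat("<map_summary>\n")
  cat(sprintf("  %d linkage groups, %d SNPs (mean %s per group)\n",
              g$n_groups, g$n_snps, fmt(g$mean_snps_per_group, d)))
  cat(sprintf("  total length (cM): sex-averaged %s, female %s, male %s\n",
              fmt(g$total_avg_cM, d), fmt(g$total_female_cM, d),
              fmt(g$total_male_cM, d)))
  cat(sprintf("  mean group length (cM): %s / %s / %s\n",
              fmt(g$mean_group_avg_cM, d), fmt(g$mean_group_female_cM, d),
              fmt(g$mean_group_male_cM, d)))
  cat(sprintf("  mean cM per marker: %s (overall %s)\n",
              fmt(g$mean_cM_per_marker, d), fmt(g$overall_cM_per_marker, d)))
  cat(sprintf("  female:male ratio: total %s, per-group mean %s (%d groups)\n",
              fmt(g$fm_ratio_total, d), fmt(g$fm_ratio_per_group, d),
              g$n_groups_in_fm_per_group))
  invisible(x)
}

fmt <- function(x, digits) {
  ifelse(is.na(x), "NA", formatC(x, format = "f", digits = digits))
}
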