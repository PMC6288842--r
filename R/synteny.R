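#' Load a chromosome-arm annotation table
#'
#' An arm table gives, for each reference chromosome arm, its bp interval
#' (0-based, half-open `[start, end)`) on its chromosome and its
#' rediploidization class: `AORe` (ohnolog resolution in the common salmonid
#' ancestor), `LORe` (lineage-specific resolution) or `mixed` (arms with a
#' minor LORe proportion, excluded from the AORe/LORe contrast). The packaged
#' default is a *synthetic* stand-in for the Atlantic Salmon arm annotation
#' with the published class structure — 30 AORe and 14 LORe arms plus 6 mixed
#' arms — and plausible (not measured) arm lengths.
#'
#' @param path CSV path (`arm`, `chrom`, `start`, `end`, `class`); default is
#'   the packaged synthetic table.
#' @return An `arm_table` tibble with an added `length` column (bp).
#' @export
load_arm_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "salmon_arms_synthetic.csv",
                                package = "whitemap", mustWork = TRUE)
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(arm = "c", chrom = "c",
                                                 start = "d", end = "d",
                                                 class = "c"))
  if (!all(out$class %in% c("AORe", "LORe", "mixed"))) {
    abort("arm classes must be AORe, LORe or mixed")
  }
  out$length <- out$end - out$start
  if (any(out$length <= 0)) abort("arm lengths must be positive")
  class(out) <- c("arm_table", class(out))
  out
}

#' Read marker-to-reference mapping records
#'
#' A mapping table stands in for an alignment of RAD marker sequences to a
#' reference genome: one row per marker with its best-hit chromosome, bp
#' position and phred-scaled mapping quality. Any aligner can regenerate it
#' (the columns correspond to SAM RNAME/POS/MAPQ for the primary alignment).
#'
#' @param path TSV path with columns `marker`, `chrom`, `pos`, `mapq`.
#' @return A tibble of mapping records.
#' @export
read_mapping_records <- function(path) {
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  col_types = readr::cols(marker = "c", chrom = "c",
                                          pos = "d", mapq = "d"))
}

#' Filter mapping records by mapping quality and map membership
#'
#' Keeps records with `MAPQ` strictly greater than `min_mapq` (a MAPQ of
#' exactly `min_mapq` is removed) whose marker is present in the linkage map.
#' Records for markers outside the map are dropped and logged.
#'
#' @param records Mapping-record tibble (`marker`, `chrom`, `pos`, `mapq`).
#' @param map A `genetic_map` (or any tibble with a `marker` column), or a
#'   character vector of marker ids; `NULL` skips the membership filter.
#' @param min_mapq MAPQ threshold (default 30, i.e. retain MAPQ > 30).
#' @return The retained records; `attr(x, "filter_log")` records drops.
#' @export
filter_mappings <- function(records, map = NULL, min_mapq = 30) {
  log <- list()
  if (!is.null(map)) {
    ids <- if (is.character(map)) map else map$marker
    out_of_map <- !(records$marker %in% ids)
    if (any(out_of_map)) {
      log <- c(log, list(log_entries(records$marker[out_of_map], "removed",
                                     "not_in_map")))
    }
    records <- records[!out_of_map, , drop = FALSE]
  }
  low <- records$mapq <= min_mapq
  log <- c(log, list(log_entries(records$marker[low], "removed", "low_mapq",
                                 records$mapq[low])))
  out <- records[!low, , drop = FALSE]
  attr(out, "filter_log") <- bind_rows(log)
  out
}

chrom_number <- function(chrom) {
  as.integer(stringr::str_extract(chrom, "[0-9]+"))
}

#' Assign each linkage group a homologous reference chromosome
#'
#' The homolog of a linkage group is the reference chromosome receiving the
#' most of its retained hits (majority rule). Hits to the homolog are flagged
#' concordant, others discordant. Groups are then ranked by (homolog
#' chromosome number, median position of their concordant hits) and renamed
#' `W01`, `W02`, ... so group names follow reference chromosome order. A
#' tied majority is resolved toward the lower chromosome number and flagged
#' `ambiguous`; a group with no retained hits gets an `NA` homolog and no
#' W-name.
#'
#' @param map A `genetic_map` or tibble with `marker` and `group` columns.
#' @param records Filtered mapping records (see [filter_mappings()]).
#' @return A `synteny_assignment` list: `$groups` (per-group homolog, hit
#'   counts, `ambiguous` flag, `w_name`) and `$hits` (records annotated with
#'   `group` and `concordant`).
#' @export
assign_homologs <- function(map, records) {
  stopifnot(all(c("marker", "group") %in% names(map)))
  hits <- records %>%
    left_join(as_tibble(map)[, c("marker", "group")], by = "marker") %>%
    filter(!is.na(.data$group))

  per_chrom <- hits %>%
    count(.data$group, .data$chrom, name = "n_hits") %>%
    mutate(chrom_num = chrom_number(.data$chrom))
  best <- per_chrom %>%
    group_by(.data$group) %>%
    arrange(desc(.data$n_hits), .data$chrom_num, .by_group = TRUE) %>%
    summarise(homolog = first(.data$chrom),
              n_support = first(.data$n_hits),
              ambiguous = sum(.data$n_hits == max(.data$n_hits)) > 1L,
              .groups = "drop")
  if (any(best$ambiguous)) {
    warn(sprintf("tied majority hit count in group(s): %s",
                 paste(best$group[best$ambiguous], collapse = ", ")))
  }

  groups <- tibble(group = sort(unique(map$group))) %>%
    left_join(best, by = "group")
  no_hits <- is.na(groups$homolog)
  if (any(no_hits)) {
    warn(sprintf("group(s) with no retained hits, no W-name assigned: %s",
                 paste(groups$group[no_hits], collapse = ", ")))
  }

  hits <- hits %>%
    left_join(groups[, c("group", "homolog")], by = "group") %>%
    mutate(concordant = .data$chrom == .data$homolog) %>%
    select(-"homolog")
  groups <- groups %>%
    left_join(
      hits %>% group_by(.data$group) %>%
        summarise(n_hits_total = n(),
                  n_concordant = sum(.data$concordant),
                  n_discordant = sum(!.data$concordant),
                  median_hit_pos = median(.data$pos[.data$concordant]),
                  .groups = "drop"),
      by = "group")

  ranked <- groups %>%
    filter(!is.na(.data$homolog)) %>%
    arrange(chrom_number(.data$homolog), .data$median_hit_pos, .data$group) %>%
    mutate(w_name = sprintf("W%02d", row_number()))
  groups <- groups %>%
    left_join(ranked[, c("group", "w_name")], by = "group")

  structure(list(groups = groups, hits = hits), class = "synteny_assignment")
}

#' @export
print.synteny_assignment <- function(x, ...) {
  cat(sprintf("<synteny_assignment> %d groups, %d retained hits (%d concordant)\n",
              nrow(x$groups), nrow(x$hits), sum(x$hits$concordant)))
  invisible(x)
}

# locate each hit's chromosome arm (0-based half-open intervals)
assign_arm <- function(records, arms) {
  hit_arm <- rep(NA_character_, nrow(records))
  for (i in seq_len(nrow(arms))) {
    sel <- records$chrom == arms$chrom[i] &
      records$pos >= arms$start[i] & records$pos < arms$end[i]
    hit_arm[sel] <- arms$arm[i]
  }
  hit_arm
}

#' Expected/observed mapping ratio per chromosome arm and AORe/LORe contrast
#'
#' Distributes the total number of retained mappings over chromosome arms in
#' proportion to arm length (`expected = N * length / sum(length)`), computes
#' the per-arm ratio `expected / observed`, and contrasts the AORe and LORe
#' ratio sets with a two-sided Wilcoxon rank-sum test. `mixed`-class arms are
#' excluded *before* the expected counts are computed, so expected counts sum
#' exactly to the hits that land on included arms. Arms with zero observed
#' hits have an infinite ratio, reported `NA` and excluded from the test.
#' The test uses exact enumeration when both classes have at most 50 tie-free
#' values, otherwise the normal approximation with tie and continuity
#' correction (the \code{\link[stats]{wilcox.test}} conventions). The
#' reported statistic `W` counts AORe-over-LORe pairs, so complete separation
#' with every LORe ratio above every AORe ratio gives `W = 0`.
#'
#' @param records Filtered mapping records.
#' @param arms An [load_arm_table()] tibble.
#' @return An `arm_ratio_test` list: `arms` (per-arm observed, expected,
#'   ratio), `statistic` (W), `p_value`, `n_aore`, `n_lore`, `excluded`
#'   (mixed arms and zero-observed arms left out of the test).
#' @export
arm_ratio_test <- function(records, arms) {
  stopifnot(inherits(arms, "data.frame"))
  records <- records %>% mutate(arm = assign_arm(records, arms))
  unplaced <- sum(is.na(records$arm))
  if (unplaced > 0L) {
    warn(sprintf("%d hit(s) outside any annotated arm ignored", unplaced))
  }
  included <- arms %>% filter(.data$class != "mixed")
  obs <- records %>% filter(!is.na(.data$arm)) %>% count(.data$arm, name = "observed")
  per_arm <- included %>%
    left_join(obs, by = "arm") %>%
    mutate(observed = if_else(is.na(.data$observed), 0L, as.integer(.data$observed)))
  n_total <- sum(per_arm$observed)
  per_arm <- per_arm %>%
    mutate(expected = n_total * .data$length / sum(.data$length),
           ratio = if_else(.data$observed > 0, .data$expected / .data$observed,
                           NA_real_)) %>%
    select("arm", "chrom", "class", "length", "observed", "expected", "ratio")

  aore <- per_arm$ratio[per_arm$class == "AORe" & !is.na(per_arm$ratio)]
  lore <- per_arm$ratio[per_arm$class == "LORe" & !is.na(per_arm$ratio)]
  if (length(aore) == 0L || length(lore) == 0L) {
    inform("only one rediploidization class has usable ratios; test skipped")
    wt <- list(statistic = c(W = NA_real_), p.value = NA_real_)
  } else {
    wt <- suppressWarnings(
      wilcox.test(aore, lore, alternative = "two.sided", correct = TRUE))
  }
  structure(list(
    arms = per_arm,
    statistic = unname(wt$statistic),
    p_value = wt$p.value,
    n_aore = length(aore),
    n_lore = length(lore),
    excluded = list(mixed = arms$arm[arms$class == "mixed"],
                    zero_observed = per_arm$arm[is.na(per_arm$ratio)])
  ), class = "arm_ratio_test")
}

#' @export
print.arm_ratio_test <- function(x, ...) {
  cat("<arm_ratio_test>\n")
  cat(sprintf("  %d AORe vs %d LORe arms; W = %s, two-sided p = %s\n",
              x$n_aore, x$n_lore, format(x$statistic), format(x$p_value)))
  if (length(x$excluded$zero_observed)) {
    cat(sprintf("  arms with 0 observed hits (excluded): %s\n",
                paste(x$excluded$zero_observed, collapse = ", ")))
  }
  invisible(x)
}

#' Full synteny analysis of a genetic map
#'
#' Filters mapping records ([filter_mappings()]), assigns homologs and
#' W-names ([assign_homologs()]), and runs the per-arm expected/observed
#' contrast ([arm_ratio_test()]).
#'
#' @inheritParams assign_homologs
#' @inheritParams filter_mappings
#' @param arms An arm table ([load_arm_table()]).
#' @return A `synteny_result` list: `assignment`, `ratio_test`,
#'   `n_input_records`, `n_retained`.
#' @export
synteny_analysis <- function(map, records, arms, min_mapq = 30) {
  retained <- filter_mappings(records, map, min_mapq = min_mapq)
  structure(list(
    assignment = assign_homologs(map, retained),
    ratio_test = arm_ratio_test(retained, arms),
    n_input_records = nrow(records),
    n_retained = nrow(retained)
  ), class = "synteny_result")
}

#' @export
print.synteny_result <- function(x, ...) {
  cat(sprintf("<synteny_result> %d of %d mappings retained\n",
              x$n_retained, x$n_input_records))
  print(x$assignment)
  print(x$ratio_test)
  invisible(x)
}

#' Simulate marker-to-reference mapping records
#'
#' Generates a synthetic mapping table for the markers of a map, for testing
#' the synteny stage without an aligner. Two schemes:
#'
#' * `"by_group"`: each linkage group is assigned a home chromosome
#'   (cycling through the arm table's chromosomes); each mapped marker hits
#'   the home chromosome with probability `concordance` (uniform position on
#'   it) and a random other chromosome otherwise — mimics true homology with
#'   occasional discordant mappings.
#' * `"by_arm_rate"`: hits land on arms with probability proportional to
#'   arm length times a class rate (`1` for AORe and mixed, `lore_rate` for
#'   LORe) — mimics the depletion of confident mappings in LORe regions.
#'
#' MAPQ is drawn uniformly on 31..60 with probability `1 - low_mapq_rate`,
#' otherwise uniformly on 0..30 (removed by the default filter).
#'
#' @param map A `genetic_map` or tibble with `marker` and `group`.
#' @param arms An arm table.
#' @param scheme `"by_group"` or `"by_arm_rate"`.
#' @param prop_mapped Probability a marker has a mapping record at all
#'   (default 0.3: cross-species mapping is sparse).
#' @param concordance Probability a `"by_group"` hit lands on the home
#'   chromosome (default 0.9).
#' @param lore_rate Relative hit rate of LORe arms under `"by_arm_rate"`
#'   (default 0.2).
#' @param low_mapq_rate Fraction of records with MAPQ <= 30 (default 0.2).
#' @param seed Integer seed.
#' @return A mapping-record tibble (`marker`, `chrom`, `pos`, `mapq`).
#' @export
sim_mapping_records <- function(map, arms, scheme = c("by_group", "by_arm_rate"),
                                prop_mapped = 0.3, concordance = 0.9,
                                lore_rate = 0.2, low_mapq_rate = 0.2,
                                seed = 1L) {
  scheme <- match.arg(scheme)
  with_seed(seed, {
    tbl <- as_tibble(map)[, c("marker", "group")]
    tbl <- tbl[runif(nrow(tbl)) < prop_mapped, , drop = FALSE]
    n <- nrow(tbl)
    chroms <- unique(arms$chrom)
    if (scheme == "by_group") {
      groups <- sort(unique(map$group))
      home <- setNames(rep_len(chroms, length(groups)), groups)
      conc <- runif(n) < concordance
      chrom <- ifelse(conc, home[tbl$group],
                      sample(chroms, n, replace = TRUE))
      chrom_len <- tapply(arms$end, arms$chrom, max)
      pos <- floor(runif(n) * chrom_len[chrom])
    } else {
      w <- arms$length * ifelse(arms$class == "LORe", lore_rate, 1)
      arm_i <- sample.int(nrow(arms), n, replace = TRUE, prob = w)
      chrom <- arms$chrom[arm_i]
      pos <- floor(arms$start[arm_i] +
                     runif(n) * (arms$end[arm_i] - arms$start[arm_i]))
    }
    mapq <- ifelse(runif(n) < low_mapq_rate,
                   sample(0:30, n, replace = TRUE),
                   sample(31:60, n, replace = TRUE))
    tibble(marker = tbl$marker, chrom = unname(chrom), pos = unname(pos),
           mapq = as.numeric(mapq))
  })
}
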