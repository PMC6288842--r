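#' Form linkage groups by single-linkage clustering at a LOD threshold
#'
#' Builds a graph over markers with an edge wherever the pairwise LOD is at
#' least `lod_limit` (the threshold is inclusive) and takes connected
#' components — the transitive closure of significant linkage. Components
#' with fewer than `min_markers` markers are dissolved into an unassigned
#' singleton pool (`group = NA`), not force-merged. Retained groups are
#' labelled `LG01`, `LG02`, ... by decreasing marker count (ties broken by
#' first marker id).
#'
#' @param pairs Pairwise estimates from [pairwise_rf_lod()] (joint context
#'   recommended), or any tibble with `marker1`, `marker2`, `lod`.
#' @param markers Character vector of all markers to partition (markers with
#'   no significant pair still appear, unassigned). Defaults to the markers
#'   present in `pairs`.
#' @param lod_limit Minimum LOD to link two markers (default 16).
#' @param min_markers Minimum markers per retained group (default 25).
#' @return A tibble (`marker`, `group`), `group` NA for unassigned markers.
#' @export
separate_groups <- function(pairs, markers = NULL, lod_limit = 16,
                            min_markers = 25) {
  markers <- markers %||% unique(c(pairs$marker1, pairs$marker2))
  keep <- !is.na(pairs$lod) & pairs$lod >= lod_limit
  g <- igraph::graph_from_data_frame(
    pairs[keep, c("marker1", "marker2")],
    directed = FALSE,
    vertices = data.frame(name = markers)
  )
  comp <- igraph::components(g)
  membership <- comp$membership[markers]
  sizes <- table(membership)
  big <- names(sizes)[sizes >= min_markers]
  membership[!(membership %in% as.integer(big))] <- NA_integer_

  out <- tibble(marker = markers, component = as.integer(membership))
  ranking <- out %>%
    filter(!is.na(.data$component)) %>%
    group_by(.data$component) %>%
    summarise(n = n(), first_marker = min(.data$marker), .groups = "drop") %>%
    arrange(desc(.data$n), .data$first_marker) %>%
    mutate(group = sprintf("LG%02d", row_number()))
  out %>%
    left_join(ranking[, c("component", "group")], by = "component") %>%
    select("marker", "group")
}
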