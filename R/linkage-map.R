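#' Map positions along an ordered linkage group
#'
#' Converts two-point recombination fractions into cumulative cM positions
#' along a given marker order. For a sex-specific map the walk runs over the
#' markers informative for that parent (pseudo-testcross markers of that
#' parent plus intercross markers): each consecutive informative pair
#' contributes the Haldane (or Kosambi) distance of the recombination
#' fraction counted from that parent's meioses, and markers not informative
#' for the sex inherit the running position (they cannot recombine in that
#' parent's map). A group with no informative meioses for the sex therefore
#' has length 0. Intervals whose estimate hits `rf >= 0.5`, or whose mapped
#' distance exceeds `max_interval_cM`, are capped at `max_interval_cM` with a
#' warning; intervals with no shared informative meiosis contribute 0 cM.
#'
#' The sex-averaged map (`sex = "averaged"`) is by default the per-marker
#' mean of the completed female and male positions
#' (`averaged_method = "mean_sex"`). The alternative `"pooled"` walks all
#' informative markers and estimates each interval from the two parents'
#' pooled recombinant/total counts; it returns 0 cM across junctions between
#' oppositely single-parent-informative markers, where pooled counting has no
#' information, and therefore underestimates group length when both
#' pseudo-testcross types are interleaved.
#'
#' @param geno Genotype tibble.
#' @param order Character vector: the group's marker order.
#' @param segcalls Output of [classify_segregation()]; computed if `NULL`.
#' @param sex `"female"`, `"male"` or `"averaged"`.
#' @param max_interval_cM Cap on a single interval's distance (default 50).
#' @param map_function `"haldane"` (default) or `"kosambi"`.
#' @param averaged_method `"mean_sex"` (default) or `"pooled"`; see Details.
#' @param edge_lod Minimum LOD for a pairwise estimate to serve as an edge
#'   in the distance graph (default 3).
#' @return A tibble (`marker`, `position`) in order, positions non-decreasing
#'   from 0.
#' @export
map_positions <- function(geno, order, segcalls = NULL,
                          sex = c("female", "male", "averaged"),
                          max_interval_cM = 50,
                          map_function = c("haldane", "kosambi"),
                          averaged_method = c("mean_sex", "pooled"),
                          edge_lod = 3) {
  sex <- match.arg(sex)
  map_function <- match.arg(map_function)
  averaged_method <- match.arg(averaged_method)
  segcalls <- segcalls %||% classify_segregation(geno)
  if (!all(order %in% geno$marker)) abort("order contains unknown markers")

  if (sex == "averaged" && averaged_method == "mean_sex") {
    f <- map_positions(geno, order, segcalls, "female", max_interval_cM,
                       map_function, edge_lod = edge_lod)
    m <- map_positions(geno, order, segcalls, "male", max_interval_cM,
                       map_function, edge_lod = edge_lod)
    return(tibble(marker = order, position = (f$position + m$position) / 2))
  }

  sub <- geno[match(order, geno$marker), , drop = FALSE]
  context <- switch(sex, female = "maternal", male = "paternal",
                    averaged = "joint")
  est <- rf_lod_matrices(sub, segcalls, context)
  own <- switch(sex, female = "MAT_INF", male = "PAT_INF",
                averaged = c("MAT_INF", "PAT_INF"))
  seg <- segcalls$seg_type[match(order, segcalls$marker)]
  informative <- seg %in% c(own, "BOTH_INF")

  # distances travel along supported pairs (LOD >= edge_lod): the direct
  # two-point estimate of an adjacent pair can be nearly uninformative for
  # the requested sex (opposite-phase intercross pairs), and an
  # ill-determined rf near 0.5 would blow up the mapped interval; the
  # shortest Haldane-path distance through supported pairs is used instead
  to_cM <- map_fun_cM(map_function)
  D <- supported_path_distances(est, to_cM, edge_lod)

  pos <- numeric(length(order))
  cur <- 0
  anchor <- NA_character_
  capped <- 0L
  unreachable <- 0L
  for (idx in seq_along(order)) {
    m <- order[idx]
    if (!informative[idx]) {
      pos[idx] <- cur
      next
    }
    if (!is.na(anchor)) {
      d_cM <- D[anchor, m]
      if (!is.finite(d_cM)) {
        if (est$n[anchor, m] > 0) {
          # meioses exist but the estimate is at free recombination and no
          # supported path bridges the pair: cap, as for any huge interval
          d_cM <- max_interval_cM
          capped <- capped + 1L
        } else {
          unreachable <- unreachable + 1L
          d_cM <- 0
        }
      } else if (d_cM > max_interval_cM) {
        d_cM <- max_interval_cM
        capped <- capped + 1L
      }
      cur <- cur + d_cM
    }
    pos[idx] <- cur
    anchor <- m
  }
  if (capped > 0L) {
    warn(sprintf("%d interval(s) capped at %g cM", capped, max_interval_cM))
  }
  if (unreachable > 0L) {
    warn(sprintf("%d interval(s) without informative meioses contribute 0 cM",
                 unreachable))
  }
  tibble(marker = order, position = pos)
}

#' Build a complete genetic map from filtered genotypes
#'
#' Runs the linkage-mapping core end to end: joint two-point estimates for
#' all marker pairs, linkage-group formation at `lod_limit` with a minimum
#' group size, marker ordering with `n_runs` seeded restarts per group
#' ([order_markers()]), and female / male / sex-averaged positions
#' ([map_positions()]).
#'
#' @inheritParams map_positions
#' @inheritParams separate_groups
#' @param n_runs Ordering restarts per group (default 3).
#' @param seed Integer seed for the ordering restarts.
#' @param verbose Print progress messages.
#' @return A `genetic_map` tibble: `marker`, `group`, `order`, `female_cM`,
#'   `male_cM`, `avg_cM`. Attributes: `unassigned` (markers in no retained
#'   group), `ordering` (per-group SARF scores), `params`.
#' @examples
#' cross <- sim_cross(sim_config(n_groups = 2, markers_per_group = 30,
#'                               mean_spacing_cM = 3, seed = 5))
#' gm <- build_map(filter_genotypes(cross$geno, verbose = FALSE),
#'                 min_markers = 10, verbose = FALSE)
#' head(gm)
#' @export
build_map <- function(geno, segcalls = NULL, lod_limit = 16, min_markers = 25,
                      n_runs = 3L, seed = 1L, max_interval_cM = 50,
                      map_function = c("haldane", "kosambi"),
                      averaged_method = c("mean_sex", "pooled"),
                      verbose = TRUE) {
  map_function <- match.arg(map_function)
  averaged_method <- match.arg(averaged_method)
  segcalls <- segcalls %||% classify_segregation(geno)
  est <- rf_lod_matrices(geno, segcalls, "joint")
  pairs <- pairwise_tbl_from_matrices(est, min_lod = lod_limit)
  grouping <- separate_groups(pairs, markers = geno$marker,
                              lod_limit = lod_limit, min_markers = min_markers)
  groups <- sort(unique(grouping$group[!is.na(grouping$group)]))
  if (verbose) {
    inform(sprintf("%d linkage group(s), %d of %d markers assigned",
                   length(groups), sum(!is.na(grouping$group)), nrow(geno)))
  }
  if (length(groups) == 0L) {
    warn("no linkage group reached the minimum marker count")
  }

  rows <- list()
  scores <- list()
  for (gi in seq_along(groups)) {
    g <- groups[gi]
    mk <- grouping$marker[!is.na(grouping$group) & grouping$group == g]
    ord <- order_markers(mk, est$rf, n_runs = n_runs, seed = seed + gi,
                         group_label = g)
    f <- map_positions(geno, ord$order, segcalls, "female", max_interval_cM,
                       map_function)
    m <- map_positions(geno, ord$order, segcalls, "male", max_interval_cM,
                       map_function)
    a <- if (averaged_method == "mean_sex") {
      tibble(position = (f$position + m$position) / 2)
    } else {
      map_positions(geno, ord$order, segcalls, "averaged", max_interval_cM,
                    map_function, averaged_method)
    }
    rows[[gi]] <- tibble(marker = ord$order, group = g,
                         order = seq_along(ord$order),
                         female_cM = f$position, male_cM = m$position,
                         avg_cM = a$position)
    scores[[gi]] <- tibble(group = g, sarf = ord$sarf,
                           run_scores = list(ord$run_scores))
  }
  out <- bind_rows(rows)
  class(out) <- c("genetic_map", class(out))
  attr(out, "unassigned") <- grouping$marker[is.na(grouping$group)]
  attr(out, "ordering") <- bind_rows(scores)
  attr(out, "params") <- list(lod_limit = lod_limit, min_markers = min_markers,
                              n_runs = n_runs, seed = seed,
                              max_interval_cM = max_interval_cM,
                              map_function = map_function,
                              averaged_method = averaged_method)
  out
}

# all-pairs shortest Haldane-path distances over supported estimates
supported_path_distances <- function(est, to_cM, edge_lod) {
  ok <- upper.tri(est$n) & est$n > 0 & !is.na(est$lod) & est$lod >= edge_lod &
    est$rf < 0.5
  idx <- which(ok, arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = est$markers[idx[, 1L]], to = est$markers[idx[, 2L]],
               weight = to_cM(est$rf[idx])),
    directed = FALSE, vertices = data.frame(name = est$markers))
  igraph::distances(g)[est$markers, est$markers]
}

# sparse pair list from LOD matrices; keeps pairs at/above min_lod
pairwise_tbl_from_matrices <- function(est, min_lod) {
  idx <- which(upper.tri(est$lod) & !is.na(est$lod) & est$lod >= min_lod,
               arr.ind = TRUE)
  tibble(marker1 = est$markers[idx[, 1L]],
         marker2 = est$markers[idx[, 2L]],
         rf = est$rf[idx], lod = est$lod[idx],
         n_meioses = as.integer(est$n[idx]))
}

#' Write / read a genetic map as TSV
#'
#' The file carries a one-line schema header (`#schema: ...`) followed by a
#' tab-separated table.
#'
#' @param map A `genetic_map` tibble.
#' @param path Output path.
#' @return `write_map` invisibly returns `path`; `read_map` returns a
#'   `genetic_map` tibble.
#' @export
write_map <- function(map, path) {
  writeLines("#schema: whitemap/genetic_map v1", path)
  readr::write_tsv(as_tibble(map), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  class(out) <- c("genetic_map", class(out))
  out
}

#' @export
print.genetic_map <- function(x, ...) {
  cat(sprintf("<genetic_map> %d markers in %d linkage groups\n",
              nrow(x), length(unique(x$group))))
  NextMethod()
}
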