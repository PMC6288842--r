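#' Sum of adjacent recombination fractions of an order
#'
#' The ordering criterion minimised by [order_markers()]: the sum of the
#' pairwise recombination fractions between consecutive markers. Pairs with
#' no estimate count as 0.5 (free recombination), the maximal penalty.
#'
#' @param order Character vector of marker ids.
#' @param rf Symmetric recombination-fraction matrix with marker dimnames.
#' @return The SARF value (numeric scalar).
#' @export
sarf <- function(order, rf) {
  if (length(order) < 2L) return(0)
  r <- rf[cbind(order[-length(order)], order[-1L])]
  sum(ifelse(is.na(r), 0.5, r))
}

#' Order the markers of a linkage group
#'
#' Heuristic seriation minimising the sum of adjacent recombination fractions
#' (SARF). Each run builds a path from the farthest marker pair (largest
#' `rf`), greedily inserts the remaining markers at the position with the
#' smallest SARF increase, then polishes to a local optimum with 2-opt
#' reversals and segment relocations, followed by a few double-bridge kicks
#' with re-polish (iterated local search), keeping the best order found.
#' The first run inserts markers in their given order; further runs use
#' seeded random insertion orders. The best (lowest
#' SARF) order wins, ties broken by run index, and the orientation is
#' canonicalised so the first marker id sorts before the last.
#'
#' @param markers Character vector of marker ids (>= 2).
#' @param rf Symmetric recombination-fraction matrix covering `markers`
#'   (e.g. from the joint context); NA entries (pairs with no shared
#'   informative meiosis) are imputed from the shortest Haldane-distance
#'   path through estimated pairs before ordering.
#' @param n_runs Number of restarts (default 3).
#' @param seed Integer seed for the random insertion orders.
#' @param group_label Optional group name used in error messages.
#' @return A list: `order` (marker ids), `sarf` (criterion of the returned
#'   order), `run_scores` (criterion of every run).
#' @export
order_markers <- function(markers, rf, n_runs = 3L, seed = 1L,
                          group_label = NULL) {
  if (length(markers) < 2L) {
    return(list(order = markers, sarf = 0, run_scores = numeric(0)))
  }
  R <- rf[markers, markers, drop = FALSE]
  # a group whose estimate graph is disconnected cannot be ordered coherently
  conn <- igraph::graph_from_adjacency_matrix(
    (!is.na(R) & row(R) != col(R)) * 1, mode = "undirected")
  if (igraph::components(conn)$no > 1L) {
    abort(sprintf("estimate graph of group %s is disconnected",
                  group_label %||% "<unnamed>"))
  }
  R <- complete_rf_matrix(R)
  diag(R) <- 0

  runs <- with_seed(seed, {
    lapply(seq_len(n_runs), function(run) {
      ins <- if (run == 1L) markers else sample(markers)
      path <- polish_order(greedy_insertion(ins, R), R)
      # iterated local search: a few double-bridge kicks, keep the best
      for (kick in 1:4) {
        cand <- polish_order(double_bridge(path), R)
        if (sarf(cand, R) < sarf(path, R) - 1e-12) path <- cand
      }
      list(order = path, sarf = sarf(path, R))
    })
  })
  scores <- vapply(runs, `[[`, numeric(1), "sarf")
  best <- runs[[which.min(scores)]]      # ties: lowest run index wins
  ord <- best$order
  if (ord[1L] > ord[length(ord)]) ord <- rev(ord)
  list(order = ord, sarf = best$sarf, run_scores = scores)
}

# classic 4-segment reconnection; escapes local optima that 2-opt and
# segment relocation cannot
double_bridge <- function(path) {
  L <- length(path)
  if (L < 4L) return(rev(path))
  cuts <- sort(sample(seq_len(L - 1L), 3L))
  c(path[1:cuts[1L]],
    path[(cuts[2L] + 1L):cuts[3L]],
    path[(cuts[1L] + 1L):cuts[2L]],
    path[(cuts[3L] + 1L):L])
}

# fill pairs without an estimate (e.g. maternal x paternal pseudo-testcross
# markers, which share no informative meiosis) with the recombination
# fraction implied by the shortest Haldane-distance path through estimated
# pairs; estimated entries are left untouched
complete_rf_matrix <- function(R) {
  miss <- is.na(R)
  if (!any(miss)) return(R)
  idx <- which(upper.tri(R) & !is.na(R), arr.ind = TRUE)
  g <- igraph::graph_from_data_frame(
    data.frame(from = rownames(R)[idx[, 1L]], to = colnames(R)[idx[, 2L]],
               weight = haldane_cM(pmin(R[idx], 0.4999))),
    directed = FALSE, vertices = data.frame(name = rownames(R)))
  D <- igraph::distances(g)[rownames(R), colnames(R)]
  R[miss] <- haldane_rf(D[miss])
  R
}

# farthest-pair endpoints, then greedy insertion minimising the SARF increase
greedy_insertion <- function(markers, R) {
  if (length(markers) == 2L) return(markers)
  Rm <- R[markers, markers]
  far <- which(Rm == max(Rm), arr.ind = TRUE)[1L, ]
  path <- markers[sort(c(far[1L], far[2L]))]
  rest <- setdiff(markers, path)
  for (m in rest) {
    L <- length(path)
    # cost of inserting m at slot s (before position s), s in 1..L+1
    cost <- numeric(L + 1L)
    cost[1L] <- R[m, path[1L]]
    cost[L + 1L] <- R[m, path[L]]
    if (L >= 2L) {
      prev <- path[1:(L - 1L)]
      nxt <- path[2:L]
      cost[2:L] <- R[m, prev] + R[m, nxt] - R[cbind(prev, nxt)]
    }
    s <- which.min(cost)
    path <- append(path, m, after = s - 1L)
  }
  path
}

# alternate 2-opt reversals and segment relocations to a local optimum;
# small groups afford the exhaustive 1-3 marker segment moves, large groups
# use vectorised single-marker relocation
polish_order <- function(path, R) {
  small <- length(path) <= 12L
  repeat {
    s0 <- sarf(path, R)
    path <- two_opt(path, R)
    path <- if (small) or_opt(path, R) else relocate1(path, R)
    if (sarf(path, R) >= s0 - 1e-12) break
  }
  path
}

# move single markers to their best position while that lowers SARF
relocate1 <- function(path, R) {
  L <- length(path)
  if (L < 3L) return(path)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(L)) {
      rest <- path[-i]
      cost <- numeric(L)
      cost[1L] <- R[path[i], rest[1L]]
      cost[L] <- R[path[i], rest[L - 1L]]
      prev <- rest[1:(L - 2L)]
      nxt <- rest[2:(L - 1L)]
      cost[2:(L - 1L)] <- R[path[i], prev] + R[path[i], nxt] -
        R[cbind(prev, nxt)]
      s <- which.min(cost)
      cand <- append(rest, path[i], after = s - 1L)
      if (sarf(cand, R) < sarf(path, R) - 1e-12) {
        path <- cand
        improved <- TRUE
      }
    }
  }
  path
}

# or-opt: relocate segments of 1-3 markers (either orientation) wherever
# that lowers SARF
or_opt <- function(path, R) {
  L <- length(path)
  if (L < 3L) return(path)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (len in 1:min(3L, L - 1L)) {
      for (i in seq_len(L - len + 1L)) {
        seg <- path[i:(i + len - 1L)]
        rest <- path[-(i:(i + len - 1L))]
        s_cur <- sarf(path, R)
        for (s in 0:length(rest)) {
          for (seg_o in if (len > 1L) list(seg, rev(seg)) else list(seg)) {
            cand <- append(rest, seg_o, after = s)
            if (sarf(cand, R) < s_cur - 1e-12) {
              path <- cand
              improved <- TRUE
              break
            }
          }
          if (improved) break
        }
        if (improved) break
      }
      if (improved) break
    }
  }
  path
}

# 2-opt: reverse segments while any reversal lowers SARF
two_opt <- function(path, R) {
  L <- length(path)
  if (L < 3L) return(path)
  improved <- TRUE
  while (improved) {
    improved <- FALSE
    for (i in seq_len(L - 1L)) {
      for (j in seq(i + 1L, L)) {
        left <- if (i > 1L) R[path[i - 1L], path[j]] - R[path[i - 1L], path[i]] else 0
        right <- if (j < L) R[path[i], path[j + 1L]] - R[path[j], path[j + 1L]] else 0
        if (left + right < -1e-12) {
          path[i:j] <- path[j:i]
          improved <- TRUE
        }
      }
    }
  }
  path
}
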