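#' Per-parent transmission matrices
#'
#' For one parent, recodes offspring genotypes as the allele that parent
#' transmitted (0/1), where determinable. For a pseudo-testcross marker
#' (parent het, other parent homozygous) every non-missing offspring is
#' informative; for an intercross marker only homozygous offspring are
#' (heterozygotes do not reveal allele origin). Returns NA where the
#' transmission cannot be determined (missing, uninformative, or a genotype
#' impossible under the parental pair, i.e. a genotyping error).
#'
#' @keywords internal
#' @noRd
transmission_matrix <- function(geno, segcalls, parent = c("mother", "father")) {
  parent <- match.arg(parent)
  off <- offspring_matrix(geno)
  seg <- segcalls$seg_type[match(geno$marker, segcalls$marker)]
  own <- if (parent == "mother") "MAT_INF" else "PAT_INF"
  hom_other <- if (parent == "mother") geno$father else geno$mother

  T <- matrix(NA_integer_, nrow(off), ncol(off), dimnames = dimnames(off))
  i <- which(seg == own)
  if (length(i)) {
    # other parent homozygous: transmitted allele = offspring dosage minus
    # the other parent's contributed allele
    contrib <- hom_other[i] %/% 2L
    t_i <- off[i, , drop = FALSE] - contrib
    t_i[t_i < 0L | t_i > 1L] <- NA_integer_
    T[i, ] <- t_i
  }
  j <- which(seg == "BOTH_INF")
  if (length(j)) {
    t_j <- off[j, , drop = FALSE]
    t_j[t_j == 1L] <- NA_integer_   # het offspring: origin unknown
    t_j <- t_j %/% 2L
    T[j, ] <- t_j
  }
  T
}

# folded recombinant/total counts between all marker pairs for one parent
pair_counts <- function(T) {
  V <- !is.na(T)
  A <- T
  A[!V] <- 0L                       # 1 where transmitted allele = 1
  B <- V - A                        # 1 where transmitted allele = 0
  storage.mode(A) <- "double"
  storage.mode(B) <- "double"
  Vn <- matrix(as.double(V), nrow(T), dimnames = dimnames(T))
  N <- Vn %*% t(Vn)
  D <- A %*% t(B) + B %*% t(A)      # discordant transmissions
  K <- pmin(D, N - D)               # phase-unknown folding, per parent
  list(K = K, N = N)
}

two_point_lod <- function(k, n) {
  r <- ifelse(n > 0, k / n, NA_real_)
  t1 <- ifelse(!is.na(k) & k > 0, k * log10(2 * r), 0)
  t2 <- ifelse(!is.na(n) & n - k > 0, (n - k) * log10(2 * (1 - r)), 0)
  lod <- t1 + t2
  lod[is.na(r)] <- NA_real_
  list(rf = r, lod = lod)
}

## ---- intercross x intercross (BOTH_INF pairs): EM on the 9-cell table ----
##
## When both markers segregate Aa x Aa, the doubly homozygous offspring that
## the counting estimator conditions on are not a random subset of meioses:
## with opposite parental phases they are enriched for recombinants, which
## both starves and biases the counting estimate. These pairs are therefore
## estimated by EM over the full two-locus transmission likelihood of the
## 3 x 3 offspring genotype table, maximised over the unknown pair of
## parental linkage phases.

# coefficient array for one phase pair: coef[cell, rho_m + 1, rho_f + 1]
# counts the transmission routes landing in each genotype cell, where each
# route has probability 1/4 * r_m-term * r_f-term
bb_coeffs <- function(phase_m, phase_f) {
  rm_ <- parent_routes(c(1L, 1L), phase_m)
  rf_ <- parent_routes(c(1L, 1L), phase_f)
  coef <- array(0, dim = c(9L, 2L, 2L))
  for (i in seq_len(4L)) for (j in seq_len(4L)) {
    cell <- (rm_$a1[i] + rf_$a1[j]) + 3L * (rm_$a2[i] + rf_$a2[j]) + 1L
    coef[cell, rm_$rho[i] + 1L, rf_$rho[j] + 1L] <-
      coef[cell, rm_$rho[i] + 1L, rf_$rho[j] + 1L] + 1
  }
  coef
}

# haplotype route table for one parent: 4 routes (haplotype choice x
# recombination), each with transmitted alleles (a1, a2) and indicator rho
parent_routes <- function(g, phase) {
  h1 <- c(if (g[1] == 1L) 1L else g[1] %/% 2L,
          if (g[2] == 1L) (if (phase == 1L) 1L else 0L) else g[2] %/% 2L)
  h2 <- c(if (g[1] == 1L) 0L else g[1] %/% 2L,
          if (g[2] == 1L) (if (phase == 1L) 0L else 1L) else g[2] %/% 2L)
  hap <- rbind(h1, h2)
  out <- expand.grid(h = 1:2, rho = 0:1)
  out$a1 <- hap[out$h, 1L]
  out$a2 <- hap[cbind(ifelse(out$rho == 1L, 3L - out$h, out$h), 2L)]
  out
}

# 9-cell count matrices for all pairs of intercross markers: counts[[cell]]
# is a B x B matrix, cell index = g1 + 3*g2 + 1
bb_cell_counts <- function(G) {
  ind <- lapply(0:2, function(a) {
    I <- (G == a)
    I[is.na(I)] <- FALSE
    storage.mode(I) <- "double"
    I
  })
  counts <- vector("list", 9L)
  for (g1 in 0:2) for (g2 in 0:2) {
    counts[[g1 + 3L * g2 + 1L]] <- ind[[g1 + 1L]] %*% t(ind[[g2 + 1L]])
  }
  counts
}

# elementwise EM for all pairs under one phase family.
# share = TRUE fits a single r for both parents (joint context);
# fix_m / fix_f pin a parameter at 0.5 (for profile LODs).
bb_em_family <- function(counts, coef, share = TRUE,
                         fix_m = FALSE, fix_f = FALSE,
                         tol = 1e-6, max_iter = 100L) {
  Ntot <- Reduce(`+`, counts)
  dims <- dim(Ntot)
  rm_ <- matrix(if (fix_m) 0.5 else 0.25, dims[1L], dims[2L])
  rf_ <- matrix(if (fix_f) 0.5 else 0.25, dims[1L], dims[2L])
  if (share) rf_ <- rm_

  cell_terms <- function(rm_, rf_) {
    um <- 1 - rm_; uf <- 1 - rf_
    P <- num_m <- num_f <- 0
    for (c in 1:9) {
      p_c <- 0.25 * (coef[c, 1, 1] * um * uf + coef[c, 2, 1] * rm_ * uf +
                       coef[c, 1, 2] * um * rf_ + coef[c, 2, 2] * rm_ * rf_)
      nm_c <- 0.25 * (coef[c, 2, 1] * rm_ * uf + coef[c, 2, 2] * rm_ * rf_)
      nf_c <- 0.25 * (coef[c, 1, 2] * um * rf_ + coef[c, 2, 2] * rm_ * rf_)
      ok <- p_c > 0
      P <- P + counts[[c]] * log(ifelse(ok, p_c, 1))
      num_m <- num_m + counts[[c]] * ifelse(ok, nm_c / p_c, 0)
      num_f <- num_f + counts[[c]] * ifelse(ok, nf_c / p_c, 0)
    }
    list(loglik = P, num_m = num_m, num_f = num_f)
  }

  for (it in seq_len(max_iter)) {
    ct <- cell_terms(rm_, rf_)
    if (share) {
      r_new <- (ct$num_m + ct$num_f) / (2 * Ntot)
      r_new <- pmin(pmax(r_new, 1e-9), 0.5)
      r_new[Ntot == 0] <- NA_real_
      delta <- max(abs(r_new - rm_), na.rm = TRUE)
      rm_ <- rf_ <- r_new
    } else {
      m_new <- if (fix_m) rm_ else pmin(pmax(ct$num_m / Ntot, 1e-9), 0.5)
      f_new <- if (fix_f) rf_ else pmin(pmax(ct$num_f / Ntot, 1e-9), 0.5)
      m_new[Ntot == 0] <- NA_real_
      f_new[Ntot == 0] <- NA_real_
      delta <- max(abs(m_new - rm_), abs(f_new - rf_), na.rm = TRUE)
      rm_ <- m_new; rf_ <- f_new
    }
    if (!is.finite(delta) || delta < tol) break
  }
  ll <- cell_terms(rm_, rf_)$loglik
  list(rm = rm_, rf = rf_, loglik = ll, n = Ntot)
}

# best fit across phase families; returns elementwise argmax
bb_em <- function(counts, share = TRUE, fix_m = FALSE, fix_f = FALSE,
                  tol = 1e-6, max_iter = 100L) {
  fams <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  best <- NULL
  for (ph in fams) {
    fit <- bb_em_family(counts, bb_coeffs(ph[1L], ph[2L]), share = share,
                        fix_m = fix_m, fix_f = fix_f,
                        tol = tol, max_iter = max_iter)
    if (is.null(best)) {
      best <- fit
    } else {
      upd <- !is.na(fit$loglik) & (is.na(best$loglik) | fit$loglik > best$loglik)
      best$rm[upd] <- fit$rm[upd]
      best$rf[upd] <- fit$rf[upd]
      best$loglik[upd] <- fit$loglik[upd]
    }
  }
  best
}

# log-likelihood at independence (r = 0.5); identical for every phase family
bb_ll_half <- function(counts) {
  coef <- bb_coeffs(1L, 1L)
  p_half <- vapply(1:9, function(c) 0.0625 * sum(coef[c, , ]), numeric(1))
  ll <- 0
  for (c in 1:9) ll <- ll + counts[[c]] * log(p_half[c])
  ll
}

# overwrite the BOTH_INF x BOTH_INF block of counting-based matrices with
# the EM estimates appropriate for the context
bb_overwrite <- function(est, geno, segcalls, context,
                         tol = 1e-6, max_iter = 100L) {
  seg <- segcalls$seg_type[match(geno$marker, segcalls$marker)]
  b <- which(seg == "BOTH_INF")
  if (length(b) < 2L) return(est)
  G <- offspring_matrix(geno)[b, , drop = FALSE]
  counts <- bb_cell_counts(G)
  ll_half <- bb_ll_half(counts)

  if (context == "joint") {
    fit <- bb_em(counts, share = TRUE, tol = tol, max_iter = max_iter)
    rf <- fit$rm
    lod <- (fit$loglik - ll_half) / log(10)
    n <- 2 * fit$n
  } else {
    fit <- bb_em(counts, share = FALSE, tol = tol, max_iter = max_iter)
    if (context == "maternal") {
      fit0 <- bb_em(counts, share = FALSE, fix_m = TRUE,
                    tol = tol, max_iter = max_iter)
      rf <- fit$rm
    } else {
      fit0 <- bb_em(counts, share = FALSE, fix_f = TRUE,
                    tol = tol, max_iter = max_iter)
      rf <- fit$rf
    }
    lod <- (fit$loglik - fit0$loglik) / log(10)
    n <- fit$n
  }
  lod <- pmax(lod, 0)
  zero <- fit$n == 0
  rf[zero] <- NA_real_
  lod[zero] <- NA_real_
  est$rf[b, b] <- rf
  est$lod[b, b] <- lod
  est$n[b, b] <- n
  diag(est$rf)[b] <- 0
  diag(est$lod)[b] <- NA_real_
  diag(est$n)[b] <- 0
  est
}

# all-pairs recombination fraction / LOD matrices for one parent context
rf_lod_matrices <- function(geno, segcalls,
                            context = c("joint", "maternal", "paternal"),
                            tol = 1e-6, max_iter = 100L) {
  context <- match.arg(context)
  parents <- switch(context, maternal = "mother", paternal = "father",
                    joint = c("mother", "father"))
  K <- N <- NULL
  for (p in parents) {
    pc <- pair_counts(transmission_matrix(geno, segcalls, p))
    if (is.null(K)) { K <- pc$K; N <- pc$N } else { K <- K + pc$K; N <- N + pc$N }
  }
  est <- two_point_lod(K, N)
  est <- list(rf = est$rf, lod = est$lod, n = N,
              markers = geno$marker, context = context)
  est <- bb_overwrite(est, geno, segcalls, context, tol, max_iter)
  diag(est$rf) <- 0
  diag(est$lod) <- NA_real_
  diag(est$n) <- 0
  est
}

#' Two-point recombination fraction and LOD for all marker pairs
#'
#' Phase-unknown two-point estimation. For pairs where at least one marker
#' is a pseudo-testcross marker, the parental transmissions of informative
#' offspring are fully determined, so recombinants are counted directly
#' under the likelihood-maximising phase (`k = min(k, n - k)`); in the
#' `"joint"` context the folded counts of the two parents are pooled. The
#' estimate is `rf = k / n` and
#' `LOD = k log10(2 rf) + (n - k) log10(2 (1 - rf))`, which equals
#' `n log10(2)` at `rf = 0` and 0 at `rf = 0.5`. Pairs of two intercross
#' (Aa x Aa) markers are instead fitted by EM over the full two-locus
#' transmission likelihood of the 9-cell genotype table, maximised over the
#' four parental phase pairings, because there the doubly homozygous subset
#' that direct counting relies on is not representative of all meioses.
#'
#' @param geno Genotype tibble.
#' @param segcalls Output of [classify_segregation()]; computed if `NULL`.
#' @param context `"joint"` (both parents' meioses pooled; used for
#'   linkage-group formation), `"maternal"` or `"paternal"`.
#' @return A tibble (`marker1`, `marker2`, `rf`, `lod`, `n_meioses`) over
#'   all pairs with at least one informative meiosis.
#' @export
pairwise_rf_lod <- function(geno, segcalls = NULL,
                            context = c("joint", "maternal", "paternal")) {
  context <- match.arg(context)
  segcalls <- segcalls %||% classify_segregation(geno)
  est <- rf_lod_matrices(geno, segcalls, context)
  idx <- which(upper.tri(est$n) & est$n > 0, arr.ind = TRUE)
  tibble(
    marker1 = est$markers[idx[, 1L]],
    marker2 = est$markers[idx[, 2L]],
    rf = est$rf[idx],
    lod = est$lod[idx],
    n_meioses = as.integer(est$n[idx])
  )
}

#' Two-point estimate for a single marker pair
#'
#' Single-pair interface to the estimator behind [pairwise_rf_lod()]:
#' direct recombinant counting where the pair's transmissions are fully
#' determined, and the phase-maximised EM over the two-locus transmission
#' likelihood (tolerance `tol` on `|delta rf|`, at most `max_iter`
#' iterations) for intercross x intercross pairs.
#'
#' @inheritParams pairwise_rf_lod
#' @param marker1,marker2 Marker ids.
#' @param tol EM convergence tolerance on `|delta rf|` (default 1e-6).
#' @param max_iter Maximum EM iterations (default 100).
#' @return A one-row tibble (`marker1`, `marker2`, `context`, `rf`, `lod`,
#'   `n_meioses`), or a zero-row tibble if the pair carries no informative
#'   meioses.
#' @export
pair_estimate <- function(geno, segcalls = NULL, marker1, marker2,
                          context = c("joint", "maternal", "paternal"),
                          tol = 1e-6, max_iter = 100L) {
  context <- match.arg(context)
  segcalls <- segcalls %||% classify_segregation(geno)
  i <- match(c(marker1, marker2), geno$marker)
  if (anyNA(i)) abort("marker not found in `geno`")
  sub <- geno[i, , drop = FALSE]
  est <- rf_lod_matrices(sub, segcalls, context, tol = tol,
                         max_iter = max_iter)
  if (est$n[1L, 2L] == 0) {
    return(tibble(marker1 = character(), marker2 = character(),
                  context = character(), rf = numeric(), lod = numeric(),
                  n_meioses = integer()))
  }
  tibble(marker1 = marker1, marker2 = marker2, context = context,
         rf = est$rf[1L, 2L], lod = est$lod[1L, 2L],
         n_meioses = as.integer(est$n[1L, 2L]))
}
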