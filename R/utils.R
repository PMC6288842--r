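#' Map-distance functions
#'
#' Convert between a recombination fraction `r` and a map distance `d` in
#' centimorgans. The Haldane function assumes crossovers occur without
#' interference (`d = -50 * log(1 - 2r)`); Kosambi allows for moderate
#' positive interference. The inverse functions give the recombination
#' fraction expected across an interval of `d` cM.
#'
#' @param r Recombination fraction(s) in `[0, 0.5]`.
#' @param d Map distance(s) in cM, `>= 0`.
#' @return A numeric vector (cM for the `*_cM` functions, recombination
#'   fractions for the `*_rf` functions).
#' @examples
#' haldane_cM(0.2)        # 25.54 cM
#' haldane_rf(25.541)     # ~0.2
#' @name map_function
NULL

#' @rdname map_function
#' @export
haldane_cM <- function(r) {
  stopifnot(all(r >= 0 & r <= 0.5, na.rm = TRUE))
  -50 * log(1 - 2 * r)
}

#' @rdname map_function
#' @export
haldane_rf <- function(d) {
  stopifnot(all(d >= 0, na.rm = TRUE))
  0.5 * (1 - exp(-2 * d / 100))
}

#' @rdname map_function
#' @export
kosambi_cM <- function(r) {
  stopifnot(all(r >= 0 & r <= 0.5, na.rm = TRUE))
  25 * log((1 + 2 * r) / (1 - 2 * r))
}

#' @rdname map_function
#' @export
kosambi_rf <- function(d) {
  stopifnot(all(d >= 0, na.rm = TRUE))
  0.5 * tanh(2 * d / 100)
}

map_fun_cM <- function(map_function = c("haldane", "kosambi")) {
  switch(match.arg(map_function), haldane = haldane_cM, kosambi = kosambi_cM)
}

# Genotypes are stored as ALT-allele dosages: 0 = aa, 1 = Aa, 2 = AA, NA
# missing. These helpers translate to/from VCF GT strings.
GENO_GT <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")

gt_to_dosage <- function(gt) {
  gt <- sub("\\|", "/", gt)
  gt[gt == "1/0"] <- "0/1"
  out <- rep(NA_integer_, length(gt))
  out[gt == "0/0"] <- 0L
  out[gt == "0/1"] <- 1L
  out[gt == "1/1"] <- 2L
  out
}

dosage_to_gt <- function(x) {
  ifelse(is.na(x), "./.", GENO_GT[as.character(x)])
}

offspring_cols <- function(geno) {
  setdiff(names(geno), c("marker", "rad_locus", "mother", "father"))
}

offspring_matrix <- function(geno) {
  cols <- offspring_cols(geno)
  m <- as.matrix(geno[, cols])
  storage.mode(m) <- "integer"
  rownames(m) <- geno$marker
  m
}

assert_geno_tbl <- function(geno) {
  need <- c("marker", "mother", "father")
  if (!is.data.frame(geno) || !all(need %in% names(geno))) {
    abort("`geno` must be a data frame with columns marker, mother, father and one column per offspring.")
  }
  if (anyDuplicated(geno$marker)) abort("marker ids must be unique")
  if (length(offspring_cols(geno)) == 0L) abort("no offspring columns found")
  invisible(geno)
}

# local seeded RNG that restores the caller's random state
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}
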