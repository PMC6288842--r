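#' Write a genotype table as a GT-only VCF
#'
#' Emits a minimal VCF v4.2 with one biallelic SNP record per marker. The
#' contig (`CHROM`) is the RAD locus and `POS` the 1-based SNP index within
#' it, mirroring de novo RAD assemblies where each locus is its own contig.
#' Sample order is mother, father, then offspring.
#'
#' @param geno Genotype tibble (`marker`, `rad_locus`, `mother`, `father`,
#'   offspring columns; ALT-dosage coding).
#' @param path Output `.vcf` path.
#' @return Invisibly, `path`.
#' @export
write_cross_vcf <- function(geno, path) {
  assert_geno_tbl(geno)
  rad <- geno$rad_locus %||% geno$marker
  pos <- stats::ave(seq_along(rad), rad, FUN = seq_along)
  samples <- c("mother", "father", offspring_cols(geno))
  gt <- vapply(samples, function(s) dosage_to_gt(geno[[s]]), character(nrow(geno)))
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=whitemap",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  body <- paste(rad, pos, geno$marker, "A", "C", ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read an F1-cross VCF into a genotype tibble
#'
#' Parses a VCF (via \pkg{vcfR}), keeps biallelic SNP records only, and
#' returns the package's genotype-table layout with ALT-allele dosage coding
#' (0/1/2, NA missing). The two parent samples are identified by name and
#' placed in the `mother`/`father` columns; all other samples become
#' offspring columns.
#'
#' @param path VCF path (plain or gzipped).
#' @param mother,father Sample names of the two parents.
#' @return A genotype tibble (`marker`, `rad_locus`, `mother`, `father`,
#'   offspring columns).
#' @export
read_cross_vcf <- function(path, mother = "mother", father = "father") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  biallelic <- !is.na(fix$ALT) & !grepl(",", fix$ALT) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L
  if (!all(biallelic)) {
    warn(sprintf("dropping %d non-biallelic/non-SNP records", sum(!biallelic)))
  }
  gt <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  fix <- fix[biallelic, , drop = FALSE]
  samples <- colnames(gt)
  if (!all(c(mother, father) %in% samples)) {
    abort("mother/father sample names not found in VCF")
  }
  ids <- fix$ID
  if (any(is.na(ids) | ids == ".")) {
    ids <- paste0(fix$CHROM, "_", fix$POS)
  }
  dos <- apply(gt, 2L, gt_to_dosage)
  off <- setdiff(samples, c(mother, father))
  out <- bind_cols(
    tibble(marker = ids, rad_locus = fix$CHROM,
           mother = dos[, mother], father = dos[, father]),
    as_tibble(as.data.frame(dos[, off, drop = FALSE]))
  )
  assert_geno_tbl(out)
}
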