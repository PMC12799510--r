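## Plain-text interchange: dosage matrices with variant metadata, optional
## VCF with a per-genotype dosage field, and GRM text output in the id-pair
## layout used by common GREML tools.

#' Write a GenotypeMatrix as dosage TSV + variant metadata TSV
#'
#' @param g a [GenotypeMatrix-class].
#' @param dosagePath path for the variants x persons dosage table (first
#'   column `variant_id`, then one column per person).
#' @param variantPath path for the variant metadata table.
#' @return the two paths, invisibly.
#' @export
writeDosageTsv <- function(g, dosagePath, variantPath) {
  d <- as.data.frame(dosages(g))
  writeTsv(cbind(variant_id = variantInfo(g)$variant_id, d), dosagePath)
  writeTsv(variantInfo(g), variantPath)
  invisible(c(dosagePath, variantPath))
}

#' Read a GenotypeMatrix from dosage TSV + variant metadata TSV
#'
#' @param dosagePath,variantPath paths written by [writeDosageTsv()].
#' @return a [GenotypeMatrix-class].
#' @export
readDosageTsv <- function(dosagePath, variantPath) {
  dd <- readTsv(dosagePath)
  vi <- readTsv(variantPath)
  vi$chrom <- as.character(vi$chrom)
  d <- as.matrix(dd[, -1, drop = FALSE])
  rownames(d) <- dd$variant_id
  GenotypeMatrix(d, vi, data.frame(person_id = colnames(d)))
}

#' Write a minimal VCF with a DS (dosage) genotype field
#'
#' @param g a [GenotypeMatrix-class].
#' @param path output path (uncompressed `.vcf`).
#' @return the path, invisibly.
#' @export
writeVcf <- function(g, path) {
  vi <- variantInfo(g)
  d <- dosages(g)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of the ALT allele\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", personIds(g)), collapse = "\t")), con)
  gtOf <- function(x) {
    out <- rep("./.", length(x))
    out[!is.na(x)] <- c("0/0", "0/1", "1/1")[round(x[!is.na(x)]) + 1]
    out
  }
  for (i in seq_len(nrow(d))) {
    ds <- ifelse(is.na(d[i, ]), ".", format(d[i, ], trim = TRUE))
    writeLines(paste(c(vi$chrom[i], vi$pos[i], vi$variant_id[i], vi$ref[i],
                       vi$alt[i], ".", "PASS", ".", "GT:DS",
                       paste(gtOf(d[i, ]), ds, sep = ":")),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotypes from a VCF (DS dosage field preferred, else GT hard calls)
#'
#' Uses `VariantAnnotation` when available.
#'
#' @param path VCF path.
#' @return a [GenotypeMatrix-class].
#' @export
readVcfDosage <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    stop("readVcfDosage requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  gen <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(gen)) {
    d <- gen$DS
    storage.mode(d) <- "double"
  } else {
    gt <- gen$GT
    d <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
    d[gt %in% c("0/0", "0|0")] <- 0
    d[gt %in% c("0/1", "1/0", "0|1", "1|0")] <- 1
    d[gt %in% c("1/1", "1|1")] <- 2
  }
  rr <- SummarizedExperiment::rowRanges(vcf)
  vi <- data.frame(
    variant_id = names(rr),
    chrom = as.character(GenomeInfoDb::seqnames(rr)),
    pos = BiocGenerics::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(rr$ALT, function(a) as.character(a)[1], ""))
  GenotypeMatrix(d, vi, data.frame(person_id = colnames(d)))
}

#' Write a RelationshipMatrix as id-pair text and as a square TSV
#'
#' The id-pair layout has one row per pair (j >= k): `id1 id2 nVariants
#' relatedness`, the layout consumed by common GREML tools.
#'
#' @param grm a [RelationshipMatrix-class].
#' @param pairPath,squarePath output paths (either may be `NULL` to skip).
#' @return the paths, invisibly.
#' @export
writeGrm <- function(grm, pairPath = NULL, squarePath = NULL) {
  a <- as(grm, "matrix")
  ids <- rownames(a)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(a)))
  if (!is.null(pairPath)) {
    idx <- which(lower.tri(a, diag = TRUE), arr.ind = TRUE)
    writeTsv(data.frame(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                        n_variants = grm@nVariants,
                        relatedness = a[idx]), pairPath)
  }
  if (!is.null(squarePath))
    writeTsv(cbind(person_id = ids, as.data.frame(a)), squarePath)
  invisible(c(pairPath, squarePath))
}
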