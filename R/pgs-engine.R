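## Polygenic score engine: PGS Catalog scoring-file I/O, allele harmonization
## against cohort genotypes, and weighted/unweighted score computation with
## score-tool-compatible semantics (missing dosages mean-imputed to twice the
## effect-allele frequency).

AUTOSOMES <- as.character(1:22)

#' Read a PGS Catalog scoring file
#'
#' Parses the standard layout: '#'-prefixed header metadata followed by a
#' tab-separated body with columns `rsID`, `chr_name`, `chr_position`,
#' `effect_allele`, `other_allele`, `effect_weight`. Variants with weight
#' exactly 0 and variants on non-autosomal chromosomes (X, Y, MT) are
#' dropped and counted.
#'
#' @param path scoring-file path.
#' @param name score name; defaults to the `pgs_id` header field or the
#'   file name.
#' @param orientation +1 or -1 (see [ScoreSet-class]).
#' @return a [ScoreSet-class]; dropped-row counts are in
#'   `harmonizationLog()$parse`.
#' @export
readScoreFile <- function(path, name = NULL, orientation = 1) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  if (is.null(name)) {
    id <- sub("^#\\s*pgs_id\\s*=\\s*", "", grep("pgs_id", hdr, value = TRUE))
    name <- if (length(id)) id[1] else basename(path)
  }
  body <- lines[!grepl("^#", lines)]
  df <- utils::read.table(text = body, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE,
                          colClasses = c(chr_name = "character"))
  need <- c("effect_allele", "effect_weight")
  miss <- setdiff(need, colnames(df))
  if (length(miss))
    stop("scoring file lacks required column(s): ", paste(miss, collapse = ", "))
  if (!"rsID" %in% colnames(df) &&
      !all(c("chr_name", "chr_position") %in% colnames(df)))
    stop("scoring file needs 'rsID' or both 'chr_name' and 'chr_position'")
  for (col in c("rsID", "chr_name", "chr_position", "other_allele"))
    if (!col %in% colnames(df)) df[[col]] <- NA
  nZero <- sum(df$effect_weight == 0)
  df <- df[df$effect_weight != 0, ]
  nonAuto <- !is.na(df$chr_name) & !df$chr_name %in% AUTOSOMES
  nNonAuto <- sum(nonAuto)
  df <- df[!nonAuto, ]
  out <- ScoreSet(df[c("rsID", "chr_name", "chr_position", "effect_allele",
                       "other_allele", "effect_weight")],
                  name = name, orientation = orientation)
  out@log <- list(parse = list(zero_weight = nZero, non_autosomal = nNonAuto))
  out
}

#' Write a ScoreSet in PGS Catalog scoring-file layout
#'
#' @param score a [ScoreSet-class].
#' @param path output path.
#' @return the path, invisibly. Weights are written at full precision.
#' @export
writeScoreFile <- function(score, path) {
  v <- score@variants[c("rsID", "chr_name", "chr_position", "effect_allele",
                        "other_allele", "effect_weight")]
  v$effect_weight <- sprintf("%.17g", v$effect_weight)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# pgs_id=", score@name),
               paste0("# orientation=", score@orientation),
               "# format=PGS-catalog-like scoring file"), con)
  utils::write.table(v, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

isAmbiguousPair <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C")
}

#' Harmonize a score against cohort genotypes
#'
#' Variants are matched by id, with a chrom:pos fallback. When the effect
#' allele is the genotype alternate allele the dosage is used directly; when
#' it is the reference allele the complement `2 - dosage` is used; other
#' allele pairs are dropped as mismatches. Strand-ambiguous (A/T, C/G)
#' variants are kept but counted separately. Coverage is reported as
#' `round(100 * matched / total)`, matching the integer percentages of
#' published score-coverage tables.
#'
#' @param score a [ScoreSet-class].
#' @param g a [GenotypeMatrix-class] whose rowData carries `ref`/`alt`.
#' @return the harmonized [ScoreSet-class] (`g_index`, `flip`, `ambiguous`
#'   columns added; log populated).
#' @export
harmonizeScore <- function(score, g) {
  v <- score@variants
  vi <- variantInfo(g)
  idx <- match(v$rsID, vi$variant_id)
  usePos <- is.na(idx) & !is.na(v$chr_name) & !is.na(v$chr_position)
  if (any(usePos)) {
    key <- paste(vi$chrom, vi$pos)
    idx[usePos] <- match(paste(v$chr_name, v$chr_position)[usePos], key)
  }
  total <- nrow(v)
  found <- !is.na(idx)
  ref <- vi$ref[idx]; alt <- vi$alt[idx]
  direct <- found & v$effect_allele == alt & (is.na(v$other_allele) |
                                              v$other_allele == ref)
  flip <- found & v$effect_allele == ref & (is.na(v$other_allele) |
                                            v$other_allele == alt)
  matched <- direct | flip
  mismatched <- found & !matched
  ambiguous <- matched & isAmbiguousPair(v$effect_allele,
                                         ifelse(flip, alt, ref))
  v$g_index <- ifelse(matched, idx, NA_integer_)
  v$flip <- flip
  v$ambiguous <- ambiguous
  score@variants <- v[matched, ]
  score@harmonized <- TRUE
  score@log <- c(score@log, list(
    matched = sum(matched), flipped = sum(flip), ambiguous = sum(ambiguous),
    mismatched = sum(mismatched), missing = sum(!matched), total = total,
    coverage_pct = as.integer(round(100 * sum(matched) / total))))
  validObject(score)
  score
}

#' Compute weighted and unweighted polygenic scores
#'
#' `weighted_j = sum_i w_i d_ij` and `unweighted_j = sum_i d_ij` over the
#' harmonized variants, where `d_ij` is the effect-allele dosage (flipped to
#' `2 - dosage` where the effect allele is the reference allele), missing
#' dosages are imputed to twice the effect-allele frequency, and the
#' orientation flag is applied to the weights before summing.
#'
#' @param score a harmonized [ScoreSet-class].
#' @param g the [GenotypeMatrix-class] used for harmonization.
#' @return data.frame with `person_id`, `weighted`, `unweighted`,
#'   `n_variants`.
#' @export
computeScores <- function(score, g) {
  if (!score@harmonized) stop("harmonize the score first (harmonizeScore)")
  v <- score@variants
  if (!nrow(v)) stop("harmonized score set is empty")
  d <- dosages(g)[v$g_index, , drop = FALSE]
  d[v$flip, ] <- 2 - d[v$flip, ]
  eaf <- rowMeans(d, na.rm = TRUE) / 2
  if (anyNA(d)) {
    fill <- which(is.na(d), arr.ind = TRUE)
    d[fill] <- 2 * eaf[fill[, 1]]
  }
  w <- v$effect_weight * score@orientation
  data.frame(person_id = personIds(g),
             weighted = drop(crossprod(d, w)),
             unweighted = colSums(d),
             n_variants = nrow(v))
}

#' Scale polygenic scores to zero mean and unit variance
#'
#' Replaces the `weighted` column by its cohort z-score (idempotent).
#'
#' @param results score table from [computeScores()].
#' @return the table with `weighted` standardized.
#' @export
scaleScores <- function(results) {
  if (nrow(results) < 2) stop("need at least 2 persons to scale")
  s <- stats::sd(results$weighted)
  if (s == 0) stop("scores have zero variance")
  results$weighted <- (results$weighted - mean(results$weighted)) / s
  results
}
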