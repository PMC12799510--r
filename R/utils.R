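#' Derive a named substream seed from a master seed
#'
#' All stochastic operations in the package draw their seed from a master seed
#' plus a stream name, so one master seed reproduces an entire run while
#' individual stages remain independently replayable.
#'
#' @param master integer master seed.
#' @param stream character stream name.
#' @return an integer seed in \[0, 2^31).
#' @export
streamSeed <- function(master, stream) {
  h <- 0
  for (ch in utf8ToInt(stream)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) + h) %% 2147483647)
}

# sample skewness (g1, moment definition)
sampleSkewness <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 values for skewness")
  s <- stats::sd(x)
  if (s < 1e-10 * (1 + abs(mean(x))))
    stop("skewness undefined for (near-)constant values")
  mean((x - mean(x))^3) / s^3
}

# write a data.frame as TSV (the package's tabular interchange format)
writeTsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

readTsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}
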