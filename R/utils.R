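#' Derive a reproducible substream seed from a global seed and a stage name
#'
#' The pipeline fans one global seed out to named per-stage substreams so a
#' stage can be re-run in isolation with unchanged results.
#'
#' @param seed Integer global seed.
#' @param name Stage name (character).
#' @return An integer seed in [0, 2^31 - 1).
#' @export
substream_seed <- function(seed, name) {
  m <- 2147483647
  h <- 0
  for (k in utf8ToInt(name)) h <- (h * 131 + k) %% m
  as.integer((as.numeric(seed) %% m * 48271 + h) %% m)
}

# Evaluate `expr` under a local RNG state seeded with `seed`; the caller's
# .Random.seed is restored afterwards.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Read / write the pipeline's tab-delimited dialect
#'
#' All tables are tab-delimited UTF-8 with a header row and `NA` for missing.
#'
#' @param path File path.
#' @return A data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' @param x Data frame to write.
#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA", fileEncoding = "UTF-8")
  invisible(path)
}

# genotype table (subject_id + one column per rsid) -> integer matrix
geno_matrix <- function(genotypes) {
  stopifnot("subject_id" %in% names(genotypes))
  m <- as.matrix(genotypes[, setdiff(names(genotypes), "subject_id"), drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- genotypes$subject_id
  m
}

geno_table <- function(m, subject_id = rownames(m)) {
  out <- data.frame(subject_id = subject_id, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(m, stringsAsFactors = FALSE))
}
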