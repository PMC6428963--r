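DNA_ALPHABET <- c("A", "C", "G", "T")

# Run `code` under a fixed seed when one is supplied, leaving the caller's
# RNG state untouched; with seed = NULL the ambient RNG stream is used.
with_seed_opt <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Reverse-complement DNA strings
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AAGCTT")  # palindromic site
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  sample(DNA_ALPHABET, n, replace = TRUE)
}

# substitute `k ~ Binom(len, rate)` positions of each sequence (character
# vectors of single bases) with a uniformly chosen different base
mutate_bases <- function(bases, rate) {
  if (rate <= 0) return(bases)
  n_mut <- rbinom(1L, length(bases), rate)
  if (n_mut == 0L) return(bases)
  pos <- sample.int(length(bases), n_mut)
  bases[pos] <- vapply(bases[pos], function(b) {
    sample(setdiff(DNA_ALPHABET, b), 1L)
  }, character(1))
  bases
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("`%s` must be a single value in [0, 1]", name)
  x
}

check_positive <- function(x, name, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stopf("`%s` must be a single positive number", name)
  if (integer) as.integer(round(x)) else x
}

# deterministic TSV writer (LF line endings, no quoting, full precision)
write_tsv_file <- function(df, path) {
  old <- options(scipen = 15L)
  on.exit(options(old), add = TRUE)
  con <- file(path, open = "wb")
  on.exit(close(con), add = TRUE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = TRUE, eol = "\n")
  invisible(path)
}

read_tsv_file <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             colClasses = NA, comment.char = "")
}
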