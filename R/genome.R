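#' Parameters for synthetic genome generation
#'
#' Describes a single linear chromosome with a configurable fraction of
#' repetitive sequence organised into repeat families.  The default
#' repeat fraction of 0.85 mirrors the repeat content typical of very
#' large legume genomes such as pea; desk-scale work uses genome lengths
#' of 0.5--10 Mbp rather than the Gbp scale.
#'
#' Repeat copies are near-identical instances of a family consensus:
#' each copy carries independent per-base substitutions at
#' `copy_mutation_rate`, so some copies share identical tag-length
#' substrings while others do not -- exactly the regime that stresses
#' pooled-tag deconvolution.
#'
#' @param length_bp genome length in base pairs (positive integer).
#' @param repeat_fraction target fraction of the genome covered by
#'   repeat copies, in `[0, 1]`; default 0.85.
#' @param n_repeat_families number of distinct repeat family consensus
#'   sequences.
#' @param family_length_range length-2 integer vector `(min_bp, max_bp)`
#'   of family consensus lengths.  The minimum must be at least 51 bp
#'   (the tag length) so that repeat copies can carry whole tags.
#' @param copy_mutation_rate per-base substitution probability applied
#'   independently to every repeat copy (default 0.02).
#' @param seed integer RNG seed, or `NULL` to use the ambient RNG.
#' @return an object of class `wgp_genome_params`.
#' @seealso [generate_genome()]
#' @export
genome_params <- function(length_bp,
                          repeat_fraction = 0.85,
                          n_repeat_families = 20L,
                          family_length_range = c(500L, 5000L),
                          copy_mutation_rate = 0.02,
                          seed = NULL) {
  length_bp <- check_positive(length_bp, "length_bp", integer = TRUE)
  check_fraction(repeat_fraction, "repeat_fraction")
  n_repeat_families <- check_positive(n_repeat_families, "n_repeat_families",
                                      integer = TRUE)
  if (length(family_length_range) != 2L ||
      family_length_range[1] > family_length_range[2])
    stopf("`family_length_range` must be (min_bp, max_bp) with min <= max")
  family_length_range <- as.integer(round(family_length_range))
  if (repeat_fraction > 0 && family_length_range[1] < 51L)
    stopf("family_length_range minimum must be >= 51 bp (one tag length)")
  check_fraction(copy_mutation_rate, "copy_mutation_rate")
  structure(
    list(length_bp = length_bp,
         repeat_fraction = repeat_fraction,
         n_repeat_families = n_repeat_families,
         family_length_range = family_length_range,
         copy_mutation_rate = copy_mutation_rate,
         seed = seed),
    class = "wgp_genome_params")
}

#' Generate a synthetic repeat-rich genome
#'
#' Builds one linear chromosome: a uniform-random background sequence
#' into which repeat-family copies are laid down left to right, each
#' copy followed by a background gap drawn from an exponential law whose
#' mean is chosen so that repeat coverage converges on
#' `repeat_fraction`.  Copies never overlap.  Each copy is the family
#' consensus with independent substitutions at the per-copy mutation
#' rate.  Fully deterministic given the seed.
#'
#' @param params a [genome_params()] object.
#' @return an object of class `wgp_genome`: a list with `sequence`
#'   (single character string), `length_bp`, `repeats` (data.frame
#'   `family_id`, `start`, `end`; 0-based half-open intervals) and
#'   `realized_repeat_fraction` (union of repeat intervals / length).
#' @export
#' @examples
#' g <- generate_genome(genome_params(10000, repeat_fraction = 0, seed = 1))
#' nchar(g$sequence)
generate_genome <- function(params) {
  stopifnot(inherits(params, "wgp_genome_params"))
  with_seed_opt(params$seed, {
    L <- params$length_bp
    f <- params$repeat_fraction
    chars <- random_dna(L)
    reps <- data.frame(family_id = integer(), start = integer(),
                       end = integer())
    if (f > 0) {
      flr <- params$family_length_range
      if (flr[1] > L)
        stopf(paste0("repeat_fraction %.2f is infeasible: minimum family ",
                     "length %d exceeds genome length %d"), f, flr[1], L)
      n_fam <- params$n_repeat_families
      fam_len <- if (flr[1] == flr[2]) rep(flr[1], n_fam) else
        sample(seq.int(flr[1], flr[2]), n_fam, replace = TRUE)
      fam_seq <- lapply(fam_len, random_dna)
      # mean background gap giving coverage f in the copy/gap renewal process
      gap_mean <- if (f >= 1) 0 else mean(fam_len) * (1 - f) / f
      draw_gap <- function() {
        if (gap_mean <= 0) 0L else as.integer(round(rexp(1L, 1 / gap_mean)))
      }
      fam_ids <- integer(0); starts <- integer(0); ends <- integer(0)
      pos <- draw_gap()                       # 0-based cursor
      while (pos + min(fam_len) <= L) {
        fid <- sample.int(n_fam, 1L)
        if (pos + fam_len[fid] > L) {
          fits <- which(fam_len <= L - pos)
          if (length(fits) == 0L) break
          fid <- fits[sample.int(length(fits), 1L)]
        }
        l <- fam_len[fid]
        copy <- mutate_bases(fam_seq[[fid]], params$copy_mutation_rate)
        chars[(pos + 1L):(pos + l)] <- copy
        fam_ids <- c(fam_ids, fid); starts <- c(starts, pos)
        ends <- c(ends, pos + l)
        pos <- pos + l + draw_gap()
      }
      if (length(starts) == 0L)
        stopf("repeat_fraction %.2f is infeasible with the given family length bounds", f)
      reps <- data.frame(family_id = fam_ids, start = starts, end = ends)
    }
    covered <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(start = reps$start + 1L, end = reps$end))))
    structure(
      list(sequence = paste(chars, collapse = ""),
           length_bp = L,
           repeats = reps,
           realized_repeat_fraction = covered / L,
           params = params),
      class = "wgp_genome")
  })
}

#' @export
print.wgp_genome <- function(x, ...) {
  cat(sprintf("wgp_genome: %s bp, %d repeat copies, repeat fraction %.3f\n",
              format(x$length_bp, big.mark = ","), nrow(x$repeats),
              x$realized_repeat_fraction))
  invisible(x)
}

#' Write / read a genome as FASTA and its repeat annotation as BED
#'
#' `write_genome_fasta()` writes the chromosome as a single FASTA record
#' (80-column wrapping); `read_genome_fasta()` reads it back as a plain
#' character string.  `write_repeats_bed()` emits the repeat intervals
#' as 0-based half-open BED (`chrom`, `start`, `end`, `name`).
#'
#' @param genome a `wgp_genome`.
#' @param path output file path.
#' @param chrom chromosome name used in the FASTA header / BED lines.
#' @return the path, invisibly (`read_genome_fasta()` returns the
#'   sequence string).
#' @export
write_genome_fasta <- function(genome, path, chrom = "chr1") {
  ss <- Biostrings::DNAStringSet(genome$sequence)
  names(ss) <- chrom
  Biostrings::writeXStringSet(ss, filepath = path, width = 80L)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  as.character(ss[[1L]])
}

#' @rdname write_genome_fasta
#' @export
write_repeats_bed <- function(genome, path, chrom = "chr1") {
  bed <- data.frame(chrom = chrom,
                    start = genome$repeats$start,
                    end = genome$repeats$end,
                    name = sprintf("family_%d", genome$repeats$family_id))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(bed, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE, eol = "\n")
  invisible(path)
}
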