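#' Parameters for BAC library sampling
#'
#' Defaults follow the library used for the pea map: 95-kb mean insert
#' size at 6.7-fold genome coverage.  When `n_clones` is not given it is
#' `round(coverage_fold * genome_length / insert_mean_bp)`.
#'
#' @param coverage_fold target fold-coverage of the genome (default 6.7).
#' @param insert_mean_bp mean insert length in bp (default 95000).
#' @param insert_sd_bp standard deviation of the insert length
#'   (truncated normal; 0 gives fixed-length inserts).
#' @param chimera_rate fraction of clones whose insert is a chimera of
#'   two independent genomic segments (default 0).
#' @param n_clones optional explicit clone count overriding the
#'   coverage-derived count.
#' @param seed integer RNG seed, or `NULL`.
#' @return object of class `wgp_library_params`.
#' @export
bac_library_params <- function(coverage_fold = 6.7,
                               insert_mean_bp = 95000L,
                               insert_sd_bp = 0L,
                               chimera_rate = 0,
                               n_clones = NULL,
                               seed = NULL) {
  check_positive(coverage_fold, "coverage_fold")
  insert_mean_bp <- check_positive(insert_mean_bp, "insert_mean_bp",
                                   integer = TRUE)
  if (insert_sd_bp < 0) stopf("`insert_sd_bp` must be >= 0")
  check_fraction(chimera_rate, "chimera_rate")
  if (!is.null(n_clones))
    n_clones <- check_positive(n_clones, "n_clones", integer = TRUE)
  structure(
    list(coverage_fold = coverage_fold,
         insert_mean_bp = insert_mean_bp,
         insert_sd_bp = as.integer(round(insert_sd_bp)),
         chimera_rate = chimera_rate,
         n_clones = n_clones,
         seed = seed),
    class = "wgp_library_params")
}

#' Sample a BAC library from a genome
#'
#' Clone starts are uniform over valid positions; insert lengths are
#' drawn from a normal law truncated to
#' `[insert_mean_bp / 2, genome length]`.  A fraction `chimera_rate` of
#' clones receives two independently placed segments whose lengths sum
#' to the drawn insert length (the split point is uniform over the
#' middle half of the insert).  Deterministic given the seed.
#'
#' @param genome a `wgp_genome`.
#' @param params a [bac_library_params()] object.
#' @return a data.frame of class `wgp_bac_library` with one row per
#'   segment: `clone_id`, `segment` (1 or 2), `chrom`, `start`, `end`
#'   (0-based half-open), `is_chimeric`.
#' @export
sample_bac_library <- function(genome, params) {
  stopifnot(inherits(genome, "wgp_genome"),
            inherits(params, "wgp_library_params"))
  L <- genome$length_bp
  if (params$insert_mean_bp >= L)
    stopf("insert_mean_bp (%d) must be smaller than the genome (%d bp)",
          params$insert_mean_bp, L)
  with_seed_opt(params$seed, {
    n <- params$n_clones %||%
      as.integer(round(params$coverage_fold * L / params$insert_mean_bp))
    lens <- if (params$insert_sd_bp == 0L) rep(params$insert_mean_bp, n) else
      as.integer(round(rnorm(n, params$insert_mean_bp, params$insert_sd_bp)))
    lens <- pmin(pmax(lens, as.integer(ceiling(params$insert_mean_bp / 2))), L)
    is_chim <- runif(n) < params$chimera_rate
    ids <- sprintf("BAC%06d", seq_len(n))

    seg_rows <- vector("list", n)
    for (i in seq_len(n)) {
      if (!is_chim[i]) {
        s <- as.integer(floor(runif(1L, 0, L - lens[i] + 1)))
        seg_rows[[i]] <- data.frame(clone_id = ids[i], segment = 1L,
                                    chrom = "chr1", start = s,
                                    end = s + lens[i],
                                    is_chimeric = FALSE)
      } else {
        l1 <- as.integer(round(lens[i] * runif(1L, 0.25, 0.75)))
        l1 <- min(max(l1, 1L), lens[i] - 1L)
        l2 <- lens[i] - l1
        s1 <- as.integer(floor(runif(1L, 0, L - l1 + 1)))
        s2 <- as.integer(floor(runif(1L, 0, L - l2 + 1)))
        seg_rows[[i]] <- data.frame(clone_id = ids[i], segment = 1:2,
                                    chrom = "chr1",
                                    start = c(s1, s2),
                                    end = c(s1 + l1, s2 + l2),
                                    is_chimeric = TRUE)
      }
    }
    clones <- do.call(rbind, seg_rows)
    rownames(clones) <- NULL
    class(clones) <- c("wgp_bac_library", "data.frame")
    clones
  })
}

#' Extract insert sequences of library clones
#'
#' Chimeric inserts are the concatenation of their two segments (the
#' physical junction a chimeric clone carries).
#'
#' @param genome a `wgp_genome`.
#' @param clones a `wgp_bac_library` data.frame.
#' @return named character vector, one insert sequence per clone.
#' @export
clone_sequences <- function(genome, clones) {
  segs <- clones[order(clones$clone_id, clones$segment), , drop = FALSE]
  seqs <- substring(genome$sequence, segs$start + 1L, segs$end)
  vapply(split(seqs, segs$clone_id), paste, character(1), collapse = "")
}

#' Write library clones as TSV
#'
#' Columns `clone_id`, `chrom`, `start`, `end`, `segment_index`,
#' `is_chimeric`; intervals 0-based half-open.
#'
#' @param clones a `wgp_bac_library`.
#' @param path output path.
#' @export
write_clones_tsv <- function(clones, path) {
  write_tsv_file(data.frame(clone_id = clones$clone_id,
                            chrom = clones$chrom,
                            start = clones$start,
                            end = clones$end,
                            segment_index = clones$segment,
                            is_chimeric = clones$is_chimeric), path)
}
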