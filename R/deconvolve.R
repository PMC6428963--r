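#' Deconvolution parameters
#'
#' @param min_reads_per_pool minimum read count for a pool to "detect"
#'   a tag (default 2; stands in for sequencing-quality filtering).
#' @param tag_length_nt expected tag length (default 51); reads of a
#'   different length are rejected.
#' @return object of class `wgp_deconvolution_params`.
#' @export
deconvolution_params <- function(min_reads_per_pool = 2L,
                                 tag_length_nt = 51L) {
  min_reads_per_pool <- check_positive(min_reads_per_pool,
                                       "min_reads_per_pool", integer = TRUE)
  tag_length_nt <- check_positive(tag_length_nt, "tag_length_nt",
                                  integer = TRUE)
  structure(list(min_reads_per_pool = min_reads_per_pool,
                 tag_length_nt = tag_length_nt),
            class = "wgp_deconvolution_params")
}

#' Deconvolve pooled tag observations to individual clones
#'
#' Works per block and per distinct tag sequence.  A pool *detects* a
#' tag when its read count is at least `min_reads_per_pool`.  With
#' `R`, `C`, `B` the sets of detecting pools in the row, column and box
#' dimensions of one block, the tag is assigned to the clone at the
#' pool intersection iff `|R| = |C| = |B| = 1` and the triple resolves
#' -- the exactly-one-pool-per-dimension rule.  A tag may be assigned
#' to at most one clone per block, but to one clone in each of several
#' blocks.  Reads are counted as deconvolvable when they belong to a
#' (tag, pool) pair participating in an assignment.
#'
#' Per-(block, tag) statuses: `ASSIGNED`, `AMBIGUOUS_DIMENSION` (some
#' dimension detects the tag in more than one pool),
#' `INCONSISTENT_TRIPLE` (one pool per dimension but the pools do not
#' intersect in a clone), `BELOW_SUPPORT` (the tag has reads in the
#' block but fewer than three dimensions detect it).
#'
#' @param pooled_reads a `wgp_pooled_reads` or a data.frame with
#'   columns `pool_id`, `tag_sequence`, `count`.
#' @param design the `wgp_pooling_design` the reads were pooled under.
#' @param params a [deconvolution_params()].
#' @return object of class `wgp_deconvolution`: list with
#'   `assignments` (data.frame `block`, `tag_sequence`, `clone_id`),
#'   `status` (data.frame `block`, `tag_sequence`, `status`),
#'   `n_reads_total`, `n_reads_deconvolvable`.
#' @export
deconvolve <- function(pooled_reads, design, params = deconvolution_params()) {
  stopifnot(inherits(design, "wgp_pooling_design"),
            inherits(params, "wgp_deconvolution_params"))
  reads <- if (inherits(pooled_reads, "wgp_pooled_reads"))
    pooled_reads$reads else pooled_reads
  empty <- function() structure(
    list(assignments = data.frame(block = integer(),
                                  tag_sequence = character(),
                                  clone_id = character()),
         status = data.frame(block = integer(), tag_sequence = character(),
                             status = character()),
         n_reads_total = 0, n_reads_deconvolvable = 0),
    class = "wgp_deconvolution")
  if (is.null(reads) || nrow(reads) == 0L) return(empty())

  bad_len <- nchar(reads$tag_sequence) != params$tag_length_nt
  if (any(bad_len)) {
    warning(sprintf("dropping %d read group(s) whose length differs from tag_length_nt",
                    sum(bad_len)))
    reads <- reads[!bad_len, , drop = FALSE]
    if (nrow(reads) == 0L) return(empty())
  }
  unknown <- setdiff(unique(reads$pool_id), design$pools$pool_id)
  if (length(unknown))
    stopf("pool id(s) not in the design: %s",
          paste(head(unknown, 5L), collapse = ", "))

  dt <- data.table::as.data.table(reads)
  dt <- dt[, list(count = sum(count)), by = list(pool_id, tag_sequence)]
  pi <- match(dt$pool_id, design$pools$pool_id)
  dt[, `:=`(block = design$pools$block[pi], dim_ = design$pools$dim[pi])]
  n_total <- sum(dt$count)

  det <- dt[count >= params$min_reads_per_pool]
  if (nrow(det) == 0L) {
    seen <- unique(dt[, list(block, tag_sequence)])
    seen$status <- "BELOW_SUPPORT"
    data.table::setorder(seen, block, tag_sequence)
    return(structure(
      list(assignments = data.frame(block = integer(),
                                    tag_sequence = character(),
                                    clone_id = character()),
           status = as.data.frame(seen),
           n_reads_total = n_total,
           n_reads_deconvolvable = 0),
      class = "wgp_deconvolution"))
  }
  # per (block, tag, dimension): number of detecting pools and the pool
  per_dim <- det[, list(n_pools = .N, pool_id = pool_id[1L]),
                 by = list(block, tag_sequence, dim_)]
  wide <- data.table::dcast(per_dim, block + tag_sequence ~ dim_,
                            value.var = c("n_pools", "pool_id"), fill = 0L)
  for (cn in c("n_pools_row", "n_pools_col", "n_pools_box"))
    if (!cn %in% names(wide)) wide[[cn]] <- 0L
  for (cn in c("pool_id_row", "pool_id_col", "pool_id_box"))
    if (!cn %in% names(wide)) wide[[cn]] <- NA_character_

  cand <- wide[wide$n_pools_row == 1L & wide$n_pools_col == 1L &
                 wide$n_pools_box == 1L, ]
  # resolve triples in bulk against the design table
  tabdt <- data.table::as.data.table(design$table)
  res <- tabdt[cand, on = c(row_pool = "pool_id_row",
                            col_pool = "pool_id_col",
                            box_pool = "pool_id_box")]
  assigned <- res[!is.na(res$clone_id),
                  list(block = i.block, tag_sequence, clone_id)]

  status <- wide[, list(block, tag_sequence)]
  status$status <- ifelse(
    wide$n_pools_row > 1L | wide$n_pools_col > 1L | wide$n_pools_box > 1L,
    "AMBIGUOUS_DIMENSION",
    ifelse(wide$n_pools_row == 0L | wide$n_pools_col == 0L |
             wide$n_pools_box == 0L,
           "BELOW_SUPPORT", "INCONSISTENT_TRIPLE"))
  ak <- paste(assigned$block, assigned$tag_sequence)
  status$status[paste(status$block, status$tag_sequence) %in% ak] <- "ASSIGNED"
  # tags with reads in a block but no detecting pool at all
  seen <- dt[, list(block, tag_sequence)]
  seen <- seen[!duplicated(seen)]
  missing <- seen[!paste(seen$block, seen$tag_sequence) %in%
                    paste(status$block, status$tag_sequence), ]
  if (nrow(missing)) {
    missing$status <- "BELOW_SUPPORT"
    status <- rbind(status, missing)
  }
  data.table::setorder(status, block, tag_sequence)

  # deconvolvable reads: counts of the three detecting pools of each
  # assigned (block, tag)
  if (nrow(assigned)) {
    trip <- res[!is.na(res$clone_id),
                list(block = i.block, tag_sequence,
                     row_pool, col_pool, box_pool)]
    long <- rbind(
      trip[, list(block, tag_sequence, pool_id = row_pool)],
      trip[, list(block, tag_sequence, pool_id = col_pool)],
      trip[, list(block, tag_sequence, pool_id = box_pool)])
    dc <- dt[long, on = c("block", "tag_sequence", "pool_id")]
    n_deconv <- sum(dc$count, na.rm = TRUE)
  } else n_deconv <- 0

  data.table::setorder(assigned, block, tag_sequence)
  structure(
    list(assignments = as.data.frame(assigned),
         status = as.data.frame(status),
         n_reads_total = n_total,
         n_reads_deconvolvable = n_deconv),
    class = "wgp_deconvolution")
}

#' @export
print.wgp_deconvolution <- function(x, ...) {
  cat(sprintf(paste0("wgp_deconvolution: %d assignments, %d/%d reads ",
                     "deconvolvable (%.1f%%)\n"),
              nrow(x$assignments), x$n_reads_deconvolvable, x$n_reads_total,
              if (x$n_reads_total > 0)
                100 * x$n_reads_deconvolvable / x$n_reads_total else 0))
  invisible(x)
}

#' Summarize deconvolution from explicit counts
#'
#' The arithmetic layer under [deconvolution_summary()]: takes the
#' sequencing-run totals directly, so published run summaries can be
#' fed through the same computation.  Percentages are carried at full
#' precision in `*` fields and rounded to one decimal in the
#' corresponding `*_reported` fields (the conventional reporting
#' style).
#'
#' @param n_reads_total total high-quality reads.
#' @param n_reads_deconvolvable reads participating in assignments.
#' @param n_unique_tags distinct assigned tag sequences.
#' @param n_tagged_clones clones with at least one assigned tag.
#' @param n_assignments total (tag, clone) assignment pairs.
#' @param n_clones_in_library clones in the library (denominator for
#'   percent tagged clones).
#' @return object of class `wgp_deconvolution_summary` (named list).
#' @export
summarize_deconvolution_counts <- function(n_reads_total,
                                           n_reads_deconvolvable,
                                           n_unique_tags = NA_real_,
                                           n_tagged_clones = NA_real_,
                                           n_assignments = NA_real_,
                                           n_clones_in_library = NA_real_) {
  zero_reads <- !is.na(n_reads_total) && n_reads_total == 0
  if (zero_reads) warning("zero reads: percentages reported as 0")
  pct_deconv <- if (zero_reads) 0 else
    100 * n_reads_deconvolvable / n_reads_total
  pct_tagged <- if (!is.na(n_tagged_clones) && !is.na(n_clones_in_library) &&
                    n_clones_in_library > 0)
    100 * n_tagged_clones / n_clones_in_library else NA_real_
  avg_tags <- if (!is.na(n_assignments) && !is.na(n_tagged_clones) &&
                  n_tagged_clones > 0)
    n_assignments / n_tagged_clones else NA_real_
  avg_reads_tag <- if (!is.na(n_unique_tags) && n_unique_tags > 0)
    n_reads_deconvolvable / n_unique_tags else NA_real_
  structure(
    list(n_reads_total = n_reads_total,
         n_reads_deconvolvable = n_reads_deconvolvable,
         pct_deconvolvable = pct_deconv,
         pct_deconvolvable_reported = round(pct_deconv, 1),
         n_unique_tags = n_unique_tags,
         n_tagged_clones = n_tagged_clones,
         n_assignments = n_assignments,
         pct_tagged_clones = pct_tagged,
         pct_tagged_clones_reported = round(pct_tagged, 1),
         avg_tags_per_clone = avg_tags,
         avg_tags_per_clone_reported = round(avg_tags, 1),
         avg_reads_per_tag = avg_reads_tag,
         avg_reads_per_tag_reported = round(avg_reads_tag, 1),
         zero_reads = zero_reads),
    class = "wgp_deconvolution_summary")
}

#' Summarize a deconvolution result
#'
#' Computes the run-summary statistics (total and deconvolvable reads,
#' unique tags, tagged clones, average tags per clone, average reads
#' per tag, percentages) from a [deconvolve()] result.
#'
#' @param result a `wgp_deconvolution`.
#' @param n_clones_in_library library size used as the percent-tagged
#'   denominator.
#' @return object of class `wgp_deconvolution_summary`.
#' @export
deconvolution_summary <- function(result, n_clones_in_library = NA_real_) {
  stopifnot(inherits(result, "wgp_deconvolution"))
  a <- result$assignments
  summarize_deconvolution_counts(
    n_reads_total = result$n_reads_total,
    n_reads_deconvolvable = result$n_reads_deconvolvable,
    n_unique_tags = length(unique(a$tag_sequence)),
    n_tagged_clones = length(unique(a$clone_id)),
    n_assignments = nrow(a),
    n_clones_in_library = n_clones_in_library)
}

#' @export
print.wgp_deconvolution_summary <- function(x, ...) {
  fmt <- function(v) ifelse(is.na(v), "-", format(v, big.mark = ","))
  cat("WGP deconvolution summary\n")
  cat(sprintf("  Reads total               %s\n", fmt(x$n_reads_total)))
  cat(sprintf("  Reads deconvolvable       %s\n", fmt(x$n_reads_deconvolvable)))
  cat(sprintf("  Percent deconvolvable     %.1f\n", x$pct_deconvolvable))
  cat(sprintf("  Unique tags               %s\n", fmt(x$n_unique_tags)))
  cat(sprintf("  Tagged clones             %s\n", fmt(x$n_tagged_clones)))
  if (!is.na(x$pct_tagged_clones))
    cat(sprintf("  Percent tagged clones     %.1f\n", x$pct_tagged_clones))
  if (!is.na(x$avg_tags_per_clone))
    cat(sprintf("  Avg tags per clone        %.1f\n", x$avg_tags_per_clone))
  if (!is.na(x$avg_reads_per_tag))
    cat(sprintf("  Avg reads per tag         %.1f\n", x$avg_reads_per_tag))
  invisible(x)
}

#' Fingerprints from deconvolution assignments
#'
#' A clone's fingerprint is its set of assigned tag identities (the
#' tag sequences themselves).
#'
#' @param result a `wgp_deconvolution`.
#' @return named list: clone id -> character vector of tags.
#' @export
fingerprints_from_assignments <- function(result) {
  stopifnot(inherits(result, "wgp_deconvolution"))
  lapply(split(result$assignments$tag_sequence,
               result$assignments$clone_id), unique)
}
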