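#' Read-simulation parameters
#'
#' @param read_length_nt sequencing read length (default 100 nt; reads
#'   are truncated to the tag length downstream, so only the tag-length
#'   prefix is simulated).
#' @param depth_mean mean reads per (tag, clone) occurrence per pool
#'   (Poisson), default 20.
#' @param error_rate per-base substitution probability (default 0).
#' @param fixed_depth if `TRUE` every occurrence gets exactly
#'   `round(depth_mean)` reads (degenerate Poisson) -- useful for
#'   noiseless tests.
#' @param seed integer RNG seed, or `NULL`.
#' @return object of class `wgp_read_params`.
#' @export
read_sim_params <- function(read_length_nt = 100L,
                            depth_mean = 20,
                            error_rate = 0,
                            fixed_depth = FALSE,
                            seed = NULL) {
  read_length_nt <- check_positive(read_length_nt, "read_length_nt",
                                   integer = TRUE)
  check_positive(depth_mean, "depth_mean")
  check_fraction(error_rate, "error_rate")
  structure(list(read_length_nt = read_length_nt,
                 depth_mean = depth_mean,
                 error_rate = error_rate,
                 fixed_depth = isTRUE(fixed_depth),
                 seed = seed),
            class = "wgp_read_params")
}

#' Simulate pooled tag sequencing
#'
#' For each pool, each member clone and each of that clone's tag
#' occurrences, emits `Poisson(depth_mean)` reads (or a fixed count);
#' each read is the tag sequence with independent per-base
#' substitutions at `error_rate`.  Every clone contributes to its
#' three pools (row, column, box).  The truth map (which clone emitted
#' which reads into which pool) is retained for tests.  Deterministic
#' given the seed.
#'
#' @param tags_per_clone named list: clone id -> character vector of
#'   tag sequences (occurrences; duplicates allowed).
#' @param design a [build_pooling_design()] result covering every clone.
#' @param params a [read_sim_params()].
#' @return object of class `wgp_pooled_reads`: list with `reads`
#'   (data.frame `pool_id`, `tag_sequence`, `count`) and `truth`
#'   (data.frame `pool_id`, `tag_sequence`, `clone_id`, `count`,
#'   where `tag_sequence` is the *observed* read sequence).
#' @export
simulate_pool_reads <- function(tags_per_clone, design, params = read_sim_params()) {
  stopifnot(inherits(design, "wgp_pooling_design"),
            inherits(params, "wgp_read_params"))
  missing <- setdiff(names(tags_per_clone), design$table$clone_id)
  if (length(missing))
    stopf("clone(s) missing from the pooling design: %s",
          paste(missing, collapse = ", "))
  tl <- unique(nchar(unlist(tags_per_clone, use.names = FALSE)))
  if (length(tl) > 1L) stopf("all tag sequences must have the same length")
  if (length(tl) == 1L && tl > params$read_length_nt)
    stopf("tag length exceeds read length")

  with_seed_opt(params$seed, {
    cl <- names(tags_per_clone)
    ntags <- lengths(tags_per_clone)
    occ <- data.table::data.table(
      clone_id = rep(cl, ntags),
      tag_sequence = unlist(tags_per_clone, use.names = FALSE))
    idx <- match(occ$clone_id, design$table$clone_id)
    occ <- rbind(
      occ[, list(clone_id, tag_sequence, pool_id = design$table$row_pool[idx])],
      occ[, list(clone_id, tag_sequence, pool_id = design$table$col_pool[idx])],
      occ[, list(clone_id, tag_sequence, pool_id = design$table$box_pool[idx])])
    data.table::setorder(occ, pool_id, clone_id, tag_sequence)
    occ$count <- if (params$fixed_depth)
      rep(as.integer(round(params$depth_mean)), nrow(occ))
    else rpois(nrow(occ), params$depth_mean)
    occ <- occ[occ$count > 0L, ]

    if (params$error_rate > 0 && nrow(occ) > 0L) {
      # expand to individual reads and mutate each independently
      reads <- occ[rep(seq_len(nrow(occ)), occ$count),
                   list(pool_id, clone_id, tag_sequence)]
      n_mut <- rbinom(nrow(reads), tl, params$error_rate)
      hit <- which(n_mut > 0L)
      if (length(hit)) {
        mutated <- vapply(hit, function(j) {
          b <- strsplit(reads$tag_sequence[j], "", fixed = TRUE)[[1L]]
          pos <- sample.int(tl, n_mut[j])
          b[pos] <- vapply(b[pos], function(x)
            sample(setdiff(DNA_ALPHABET, x), 1L), character(1))
          paste(b, collapse = "")
        }, character(1))
        reads$tag_sequence[hit] <- mutated
      }
      truth <- reads[, list(count = .N),
                     by = list(pool_id, tag_sequence, clone_id)]
    } else {
      truth <- occ[, list(count = sum(count)),
                   by = list(pool_id, tag_sequence, clone_id)]
    }
    pooled <- truth[, list(count = sum(count)),
                    by = list(pool_id, tag_sequence)]
    data.table::setorder(pooled, pool_id, tag_sequence)
    data.table::setorder(truth, pool_id, tag_sequence, clone_id)
    structure(list(reads = as.data.frame(pooled),
                   truth = as.data.frame(truth)),
              class = "wgp_pooled_reads")
  })
}

#' Write pooled reads as TSV
#'
#' Columns `pool_id`, `tag_sequence`, `count`.
#'
#' @param pooled a `wgp_pooled_reads` (or a compatible data.frame).
#' @param path output path.
#' @export
write_pooled_reads_tsv <- function(pooled, path) {
  df <- if (inherits(pooled, "wgp_pooled_reads")) pooled$reads else pooled
  write_tsv_file(df, path)
}

#' Read pooled reads from TSV
#'
#' @param path TSV with columns `pool_id`, `tag_sequence`, `count`.
#' @return a `wgp_pooled_reads` with an empty truth map.
#' @export
read_pooled_reads_tsv <- function(path) {
  df <- read_tsv_file(path)
  need <- c("pool_id", "tag_sequence", "count")
  if (!all(need %in% names(df)))
    stopf("pooled-read TSV must have columns %s", paste(need, collapse = ", "))
  structure(list(reads = df[, need],
                 truth = NULL),
            class = "wgp_pooled_reads")
}
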