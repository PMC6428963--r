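test_that("no-repeat genome has exact length and empty annotation", {
  g <- generate_genome(genome_params(10000, repeat_fraction = 0, seed = 1))
  expect_equal(nchar(g$sequence), 10000)
  expect_equal(nrow(g$repeats), 0)
  expect_equal(g$realized_repeat_fraction, 0)
  expect_true(grepl("^[ACGT]+$", g$sequence))
})

test_that("realized repeat coverage tracks the target fraction", {
  g <- generate_genome(genome_params(1e6, repeat_fraction = 0.85, seed = 3))
  # independent interval-union arithmetic on the emitted annotation
  r <- g$repeats[order(g$repeats$start), ]
  expect_true(all(r$start >= 0 & r$end <= 1e6 & r$end > r$start))
  covered <- 0; cur_s <- -1; cur_e <- -1
  for (i in seq_len(nrow(r))) {
    if (r$start[i] > cur_e) {
      covered <- covered + max(cur_e - cur_s, 0)
      cur_s <- r$start[i]; cur_e <- r$end[i]
    } else cur_e <- max(cur_e, r$end[i])
  }
  covered <- covered + max(cur_e - cur_s, 0)
  frac <- covered / 1e6
  expect_equal(frac, g$realized_repeat_fraction)
  expect_gte(frac, 0.83)
  expect_lte(frac, 0.87)
})

test_that("genome defaults and reproducibility", {
  expect_equal(formals(genome_params)$repeat_fraction, 0.85)
  p <- genome_params(50000, repeat_fraction = 0.4, seed = 11)
  g1 <- generate_genome(p)
  g2 <- generate_genome(p)
  expect_identical(g1$sequence, g2$sequence)
  expect_identical(g1$repeats, g2$repeats)
})

test_that("infeasible repeat configurations error explicitly", {
  expect_error(
    generate_genome(genome_params(1000, repeat_fraction = 0.5,
                                  family_length_range = c(2000, 3000),
                                  seed = 1)),
    "infeasible")
  expect_error(genome_params(1000, repeat_fraction = 0.5,
                             family_length_range = c(10, 100)),
               "51")
})

test_that("repeat copies never overlap", {
  g <- generate_genome(genome_params(2e5, repeat_fraction = 0.6, seed = 5))
  r <- g$repeats[order(g$repeats$start), ]
  expect_true(all(r$start[-1] >= r$end[-nrow(r)]))
})

test_that("library size follows coverage and inserts are clipped", {
  g <- generate_genome(genome_params(1e6, repeat_fraction = 0, seed = 2))
  cl <- sample_bac_library(g, bac_library_params(seed = 1))
  ids <- unique(cl$clone_id)
  expect_equal(length(ids), 71)            # round(6.7e6 / 95000)
  expect_true(all(cl$segment == 1))        # chimera off
  expect_true(all(cl$start >= 0 & cl$end <= 1e6))
  # coverage invariant: sd = 0, chimera 0 -> within 2%
  cov <- sum(cl$end - cl$start) / 1e6
  expect_lt(abs(cov - 6.7) / 6.7, 0.02)
  expect_equal(formals(bac_library_params)$insert_mean_bp, 95000L)
  expect_equal(formals(bac_library_params)$coverage_fold, 6.7)
})

test_that("chimeric clones carry two segments summing to the insert", {
  g <- generate_genome(genome_params(5e5, repeat_fraction = 0, seed = 2))
  cl <- sample_bac_library(g, bac_library_params(chimera_rate = 1,
                                                 insert_mean_bp = 40000,
                                                 seed = 3))
  per <- split(cl, cl$clone_id)
  expect_true(all(vapply(per, nrow, integer(1)) == 2))
  expect_true(all(vapply(per, function(d) sum(d$end - d$start),
                         numeric(1)) == 40000))
  expect_true(all(cl$is_chimeric))
  expect_error(sample_bac_library(g, bac_library_params(coverage_fold = -1)),
               "positive")
})

test_that("noiseless fixed-depth pools contain exactly the member tags", {
  tags <- list(BAC000001 = c("AAAA", "CCCC"), BAC000002 = c("GGGG"))
  design <- build_pooling_design(c("BAC000001", "BAC000002"),
                                 plate_rows = 2, plate_cols = 3,
                                 box_rows = 1, box_cols = 1)
  pooled <- simulate_pool_reads(tags, design,
                                read_sim_params(read_length_nt = 4,
                                                depth_mean = 3,
                                                fixed_depth = TRUE, seed = 1))
  expect_true(all(pooled$reads$count == 3))
  # each pool's multiset is the union of its member clones' tags
  t <- design$table
  for (p in unique(pooled$reads$pool_id)) {
    members <- t$clone_id[t$row_pool == p | t$col_pool == p |
                            t$box_pool == p]
    want <- unique(unlist(tags[intersect(members, names(tags))]))
    got <- pooled$reads$tag_sequence[pooled$reads$pool_id == p]
    expect_setequal(got, want)
  }
})

test_that("Poisson pool totals match the depth model", {
  tags <- list(BAC000001 = replicate(40, paste(sample(c("A", "C", "G", "T"),
                                                      8, TRUE),
                                               collapse = "")))
  design <- build_pooling_design("BAC000001", plate_rows = 2,
                                 plate_cols = 3, box_rows = 1, box_cols = 1)
  pooled <- simulate_pool_reads(tags, design,
                                read_sim_params(read_length_nt = 8,
                                                depth_mean = 50, seed = 4))
  per_pool <- tapply(pooled$reads$count, pooled$reads$pool_id, sum)
  # 40 occurrences at depth 50: mean 2000, sd sqrt(2000)
  expect_true(all(abs(per_pool - 2000) <= 3 * sqrt(2000)))
})

test_that("read provenance stays within the emitting pool", {
  sim <- small_wgp_sim(genome_len = 2e5, repeat_fraction = 0.2,
                       insert_mean = 20000, seed = 21)
  truth <- sim$pooled$truth
  t <- sim$design$table
  member <- paste(truth$pool_id, truth$clone_id) %in%
    c(paste(t$row_pool, t$clone_id), paste(t$col_pool, t$clone_id),
      paste(t$box_pool, t$clone_id))
  expect_true(all(member))
})

test_that("clones absent from the design are reported by name", {
  design <- build_pooling_design("BAC000001", plate_rows = 2,
                                 plate_cols = 3, box_rows = 1, box_cols = 1)
  expect_error(simulate_pool_reads(list(BAC000009 = "AAAA"), design,
                                   read_sim_params(read_length_nt = 4)),
               "BAC000009")
})

test_that("genome FASTA and BED round-trip", {
  g <- generate_genome(genome_params(20000, repeat_fraction = 0.3, seed = 8))
  fa <- tempfile(fileext = ".fasta")
  bed <- tempfile(fileext = ".bed")
  write_genome_fasta(g, fa)
  write_repeats_bed(g, bed)
  expect_identical(read_genome_fasta(fa), g$sequence)
  b <- read.table(bed, sep = "\t")
  expect_equal(b$V2, g$repeats$start)
  expect_equal(b$V3, g$repeats$end)
  unlink(c(fa, bed))
})
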