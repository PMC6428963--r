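tagv <- function(...) paste0("t", c(...))

test_that("identical fingerprints bury with '=', boundary cases with '~'", {
  fps <- list(P = tagv(1:30), Q = tagv(1:30))
  b <- bury_clones(fps)
  expect_equal(nrow(b$burials), 1)
  expect_identical(b$burials$child_clone, "Q")  # tie -> lexicographic keep P
  expect_identical(b$burials$marker, "=")
  expect_setequal(b$superbacs$P, tagv(1:30))

  # child of 8 tags sharing 6 with a 30-tag parent: 6/8 = 0.75, buried "~"
  fps2 <- list(P = tagv(1:30), C = tagv(c(1:6, 98, 99)))
  b2 <- bury_clones(fps2)
  expect_identical(b2$burials$child_clone, "C")
  expect_identical(b2$burials$marker, "~")
  expect_setequal(b2$superbacs$P, tagv(c(1:30, 98, 99)))  # union of members

  # 5/8 < 0.75: no burial
  fps3 <- list(P = tagv(1:30), C = tagv(c(1:5, 97, 98, 99)))
  expect_equal(nrow(bury_clones(fps3)$burials), 0)

  # disjoint fingerprints never bury
  expect_equal(nrow(bury_clones(list(A = tagv(1:5),
                                     B = tagv(6:10)))$burials), 0)
})

test_that("burying conserves clones between SuperBACs and burials", {
  set.seed(13)
  for (rep in 1:5) {
    fps <- lapply(setNames(1:20, sprintf("c%02d", 1:20)), function(i)
      paste0("t", sample(60, sample(5:25, 1))))
    b <- bury_clones(fps)
    expect_setequal(c(names(b$superbacs), b$burials$child_clone), names(fps))
    expect_equal(length(unlist(b$members)), length(fps))
  }
})

test_that("single linkage joins through intermediates", {
  # A-B and B-C overlap strongly, A-C do not
  fps <- list(A = tagv(1:20), B = tagv(11:30), C = tagv(21:40))
  res <- build_contigs(fps, cutoff = 1e-6, universe_size = 5000)
  expect_equal(length(res$contigs), 1)
  expect_identical(res$contigs[[1]], c("A", "B", "C"))
  expect_length(res$singletons, 0)
  # a cutoff below every pairwise score leaves all singletons
  res2 <- build_contigs(fps, cutoff = 1e-40, universe_size = 5000)
  expect_equal(length(res2$contigs), 0)
  expect_setequal(res2$singletons, c("A", "B", "C"))
})

test_that("partitions refine as the cutoff tightens", {
  set.seed(77)
  fps <- lapply(setNames(1:15, sprintf("c%02d", 1:15)), function(i)
    paste0("t", sample(120, 25)))
  prev <- NULL
  for (cutoff in c(1e-12, 1e-6, 1e-3, 1e-1)) {
    res <- build_contigs(fps, cutoff, universe_size = 120)
    part <- c(res$contigs, as.list(res$singletons))
    if (!is.null(prev)) {
      for (unit in prev) {
        inside <- vapply(part, function(u) all(unit %in% u), logical(1))
        expect_equal(sum(inside), 1)       # each finer unit nests in one coarser
      }
    }
    prev <- part
  }
})

test_that("a length-1 schedule reduces stepwise assembly to single linkage", {
  set.seed(101)
  fps <- lapply(setNames(1:12, sprintf("c%02d", 1:12)), function(i)
    paste0("t", sample(100, 20)))
  ap <- assembly_params(cutoff_schedule = 1e-3, universe_size = 100)
  asm <- stepwise_assembly(fps, ap)
  ref <- build_contigs(fps, 1e-3, universe_size = 100)
  expect_equal(lapply(asm$contigs, function(ct) ct$members), ref$contigs)
  expect_equal(sort(asm$singletons), sort(ref$singletons))
})

test_that("a constructed pair joins exactly when the schedule passes its score", {
  # 25-tag fingerprints sharing 3 tags in a 5000-tag universe
  fps <- list(A = tagv(1:25), B = tagv(c(1:3, 101:122)))
  s <- sulston_score(fps$A, fps$B, 5000)
  sched <- c(1e-50, 1e-40, 1e-30, 1e-20, 1e-15, 1e-10, 1e-05, 1e-02, 1e-01)
  expect_true(s > 1e-5 && s <= 1e-2)       # joins at the 1e-2 step
  before <- assembly_params(cutoff_schedule = sched[sched < s],
                            universe_size = 5000)
  after <- assembly_params(cutoff_schedule = sched, universe_size = 5000)
  asm_before <- stepwise_assembly(fps, before)
  expect_length(asm_before$contigs, 0)
  asm_after <- stepwise_assembly(fps, after)
  expect_length(asm_after$contigs, 1)
  expect_identical(asm_after$contigs[[1]]$members, c("A", "B"))
})

test_that("default schedule endpoints span 1e-50 to 1e-01", {
  sched <- assembly_params()$cutoff_schedule
  expect_equal(sched[1], 1e-50)
  expect_equal(sched[length(sched)], 1e-01)
  expect_error(assembly_params(cutoff_schedule = c(1e-2, 1e-10)),
               "increasing")
})

test_that("a perfect tiling assembles into one contig", {
  g <- generate_genome(genome_params(3e5, repeat_fraction = 0, seed = 41))
  starts <- seq(0, 3e5 - 40000, by = 10000)
  clones <- data.frame(clone_id = sprintf("BAC%06d", seq_along(starts)),
                       segment = 1L, chrom = "chr1",
                       start = starts, end = starts + 40000,
                       is_chimeric = FALSE)
  fps <- tags_by_clone(clone_wgp_tags(g, clones))
  # the tag universe is small (~100), so the match probability p is large
  # and sparse-overlap neighbors only reach ~2e-3; the schedule's final
  # relaxed cutoff regime (1e-2) links every true neighbor
  res <- build_contigs(fps, cutoff = 1e-2)
  expect_equal(length(res$contigs), 1)
  expect_length(res$singletons, 0)
  expect_equal(length(res$contigs[[1]]), length(starts))
})

test_that("CB maps have union length and exact spans", {
  one <- cb_map(list(A = tagv(1:9)))
  expect_equal(one$length_cb, 9)
  expect_equal(one$spans$left, 1)
  expect_equal(one$spans$right, 9)

  two <- cb_map(list(A = tagv(1:10), B = tagv(8:15)), universe_size = 500)
  expect_equal(two$length_cb, 10 + 8 - 3)   # n1 + n2 - s
  expect_equal(two$total_clone_span, 18)    # both clones contiguous
  # every member tag maps into its clone span
  for (cl in c("A", "B")) {
    i <- match(cl, two$spans$clone_id)
    tags <- list(A = tagv(1:10), B = tagv(8:15))[[cl]]
    expect_true(all(two$cb[tags] >= two$spans$left[i] &
                      two$cb[tags] <= two$spans$right[i]))
  }
  expect_error(cb_map(list(A = tagv(1:4), B = tagv(10:14))),
               "not connected")
})

test_that("CB length is bounded by the largest member, with nesting equality", {
  nested <- cb_map(list(A = tagv(1:12), B = tagv(3:8), C = tagv(5:6)),
                   universe_size = 500)
  expect_equal(nested$length_cb, 12)        # all members nested in A
  g <- cb_map(list(A = tagv(1:12), B = tagv(9:18)), universe_size = 500)
  expect_gte(g$length_cb, 12)
})

test_that("greedy CB seriation attains the brute-force optimum (sample)", {
  for (s in 1:25) {
    fps <- gen_c1p_instance(s)
    got <- suppressWarnings(cb_map(fps))
    expect_equal(got$total_clone_span, brute_min_clone_span(fps),
                 info = sprintf("instance seed %d", s))
  }
})

test_that("assembly categories partition the FPC-ready clones", {
  sim <- small_wgp_sim(genome_len = 4e5, repeat_fraction = 0.4,
                       insert_mean = 50000, plate_rows = 1, plate_cols = 2,
                       seed = 55)
  fps <- tags_by_clone(sim$tags)
  asm <- assemble_clones(fps, assembly_params())
  in_contigs <- unlist(lapply(asm$contigs, function(ct) ct$members))
  cats <- c(in_contigs, asm$singletons, asm$burials$child_clone)
  expect_setequal(cats, names(fps))
  expect_equal(length(cats), length(fps))   # exactly one category each
})
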