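test_that("cut sites are found at site start plus offset", {
  expect_identical(find_cut_sites("GGGG", hindiii()), integer(0))
  expect_identical(find_cut_sites("GGAAGCTTGGTTAACC", hindiii()), 3L)
  expect_identical(find_cut_sites("GGAAGCTTGGTTAACC", msei()), 11L)
  expect_identical(find_cut_sites("AAGCTTAAGCTT", hindiii()), c(1L, 7L))
  expect_identical(find_cut_sites("TTAATTAA", msei()), c(1L, 5L))
  expect_identical(find_cut_sites("AANCTT", hindiii()), integer(0))  # N never matches
})

test_that("non-palindromic enzymes are rejected", {
  expect_error(restriction_enzyme("BspMI", "ACCTGC", 4), "palindromic")
})

test_that("double digest partitions the sequence with labeled ends", {
  f0 <- double_digest("GGGGGGG")
  expect_equal(nrow(f0), 1)
  expect_equal(f0$start, 0)
  expect_equal(f0$end, 7)
  expect_equal(f0$left_end, "SEQ_START")
  expect_equal(f0$right_end, "SEQ_END")

  f <- double_digest("GGAAGCTTGGTTAACC")
  expect_equal(f$start, c(0, 3, 11))
  expect_equal(f$end, c(3, 11, 16))
  expect_equal(f$left_end, c("SEQ_START", "HINDIII", "MSEI"))
  expect_equal(f$right_end, c("HINDIII", "MSEI", "SEQ_END"))

  fm <- double_digest("TTAATTAA")
  expect_equal(fm$start, c(0, 1, 5))
  expect_equal(fm$end, c(1, 5, 8))
  expect_true(all(fm$left_end[-1] == "MSEI"))
  expect_true(all(fm$right_end[-3] == "MSEI"))
})

test_that("fragment subsequences reconstruct the input exactly", {
  set.seed(42)
  for (i in 1:10) {
    s <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
    f <- double_digest(s)
    expect_identical(
      paste(substring(s, f$start + 1, f$end), collapse = ""), s)
    # internal boundaries coincide and alternate consistently
    expect_identical(f$end[-nrow(f)], f$start[-1])
    expect_identical(f$right_end[-nrow(f)], f$left_end[-1])
  }
})

test_that("tags come from HindIII ends only, in the right orientation", {
  p4 <- tag_params(tag_length_nt = 4, read_length_nt = 10)
  frag <- data.frame(start = 0, end = 8,
                     left_end = "HINDIII", right_end = "MSEI")
  expect_equal(extract_tags(frag, "AGCTTGGT", p4)$tag_sequence, "AGCT")

  frag2 <- data.frame(start = 0, end = 8,
                      left_end = "MSEI", right_end = "SEQ_END")
  expect_equal(nrow(extract_tags(frag2, "TAGGTGGT", p4)), 0)

  frag3 <- data.frame(start = 0, end = 10,
                      left_end = "HINDIII", right_end = "HINDIII")
  got <- extract_tags(frag3, "AGCTTGGGGA", p4)$tag_sequence
  expect_setequal(got, c("AGCT", "TCCC"))  # prefix + revcomp of suffix GGGA
})

test_that("short fragments and N-containing tags are skipped and counted", {
  p4 <- tag_params(tag_length_nt = 4, read_length_nt = 10)
  frags <- data.frame(start = c(0, 3), end = c(3, 11),
                      left_end = c("SEQ_START", "HINDIII"),
                      right_end = c("HINDIII", "MSEI"))
  out <- extract_tags(frags, "GGGAGCTTGGT", p4)
  expect_equal(out$tag_sequence, "AGCT")
  expect_equal(attr(out, "skipped")[["short_fragment"]], 1)

  fragsN <- data.frame(start = 0, end = 8,
                       left_end = "HINDIII", right_end = "MSEI")
  outN <- extract_tags(fragsN, "AGNTTGGT", p4)
  expect_equal(nrow(outN), 0)
  expect_equal(attr(outN, "skipped")[["n_containing"]], 1)
})

test_that("HindIII-HindIII double tagging is flag-controlled", {
  p4 <- tag_params(tag_length_nt = 4, read_length_nt = 10,
                   hindiii_hindiii_both = FALSE)
  frag <- data.frame(start = 0, end = 10,
                     left_end = "HINDIII", right_end = "HINDIII")
  expect_equal(extract_tags(frag, "AGCTTGGGGA", p4)$tag_sequence, "AGCT")
})

test_that("whole-clone tag extraction is deterministic and in corridor", {
  g <- generate_genome(genome_params(6e5, repeat_fraction = 0, seed = 31))
  cl <- sample_bac_library(g, bac_library_params(seed = 32))
  t1 <- clone_wgp_tags(g, cl)
  t2 <- clone_wgp_tags(g, cl)
  expect_identical(t1, t2)
  per_clone <- table(t1$clone_id)
  # 95-kb inserts with HindIII/MseI: tens of tags per clone
  expect_gt(mean(per_clone), 10)
  expect_lt(mean(per_clone), 60)
  # every anchor is a HindIII cut position of its insert
  seqs <- clone_sequences(g, cl)
  one <- t1[t1$clone_id == cl$clone_id[1], ]
  cuts <- find_cut_sites(seqs[[cl$clone_id[1]]], hindiii())
  expect_true(all(one$anchor %in% cuts))
})
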