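# shared fixtures and independent oracles ------------------------------

# enumeration oracle for the Sulston score: sum the probability of every
# {match, miss}^nL outcome with at least m matches (no binomial
# coefficients, independent of the pbinom-based implementation)
sulston_enum_oracle <- function(na, nb, m, N) {
  nh <- max(na, nb)
  nl <- min(na, nb)
  p <- nh / N
  if (p >= 1) return(1)
  if (m <= 0) return(1)
  total <- 0
  for (mask in 0:(2^nl - 1)) {
    hits <- sum(bitwAnd(mask, 2^(0:(nl - 1))) > 0)
    if (hits >= m) total <- total + p^hits * (1 - p)^(nl - hits)
  }
  total
}

# closed-form oracle for N50: the largest size s present in the list
# with sum(sizes >= s) covering at least half the total
n50_oracle <- function(sizes) {
  max(sizes[vapply(sizes, function(s)
    sum(sizes[sizes >= s]) >= sum(sizes) / 2, logical(1))])
}

# random consecutive-ones-feasible fingerprint instance: tags are points
# on a line, clones are intervals, connected via shared tags
gen_c1p_instance <- function(seed, tag_range = 4:7, clone_range = 2:5) {
  set.seed(seed)
  T <- sample(tag_range, 1)
  nc <- sample(clone_range, 1)
  tags <- paste0("t", sprintf("%02d", sample(100, T)))
  repeat {
    fps <- lapply(seq_len(nc), function(i) {
      a <- sample(T, 1)
      b <- min(T, a + sample(0:(T - 1), 1))
      tags[a:b]
    })
    names(fps) <- paste0("c", seq_len(nc))
    if (!all(tags %in% unlist(fps))) next
    adj <- vapply(seq_len(nc), function(i) vapply(seq_len(nc), function(j)
      i != j && length(intersect(fps[[i]], fps[[j]])) > 0, logical(1)),
      logical(nc))
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    if (igraph::components(g)$no == 1) return(fps)
  }
}

# exhaustive minimum total clone span over all tag orderings
perm_matrix_cache <- new.env(parent = emptyenv())
all_perm_matrix <- function(T) {
  key <- as.character(T)
  if (!is.null(perm_matrix_cache[[key]])) return(perm_matrix_cache[[key]])
  perms <- function(v) {
    if (length(v) <= 1) return(matrix(v, nrow = 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], perms(v[-i]))))
  }
  m <- perms(seq_len(T))
  perm_matrix_cache[[key]] <- m
  m
}

brute_min_clone_span <- function(fps) {
  tags <- sort(unique(unlist(fps)))
  T <- length(tags)
  pos <- all_perm_matrix(T)             # row r: position of tag k = pos[r, k]
  total <- numeric(nrow(pos))
  for (tagset in fps) {
    idx <- match(tagset, tags)
    sub <- pos[, idx, drop = FALSE]
    total <- total + (apply(sub, 1, max) - apply(sub, 1, min) + 1)
  }
  min(total)
}

# a small end-to-end simulation shared by deconvolution tests: returns
# genome, clones, per-clone tag occurrences, pooling design, pooled reads
small_wgp_sim <- function(genome_len = 5e5, repeat_fraction = 0.3,
                          insert_mean = 95000, coverage = 6.7,
                          depth_mean = 20, error_rate = 0,
                          fixed_depth = FALSE,
                          plate_rows = 2, plate_cols = 3,
                          box_rows = 1, box_cols = 1,
                          seed = 7) {
  genome <- generate_genome(genome_params(genome_len,
                                          repeat_fraction = repeat_fraction,
                                          seed = seed))
  clones <- sample_bac_library(genome, bac_library_params(
    coverage_fold = coverage, insert_mean_bp = insert_mean,
    seed = seed + 1))
  tags <- clone_wgp_tags(genome, clones)
  design <- build_pooling_design(sort(unique(clones$clone_id)),
                                 plate_rows = plate_rows,
                                 plate_cols = plate_cols,
                                 box_rows = box_rows, box_cols = box_cols)
  pooled <- simulate_pool_reads(split(tags$tag_sequence, tags$clone_id),
                                design,
                                read_sim_params(depth_mean = depth_mean,
                                                error_rate = error_rate,
                                                fixed_depth = fixed_depth,
                                                seed = seed + 2))
  list(genome = genome, clones = clones, tags = tags, design = design,
       pooled = pooled)
}

# truth: which clones of each block genuinely carry each tag (from the
# digest table, independent of the deconvolution path)
block_tag_truth <- function(tags, design) {
  blk <- design$table$block[match(tags$clone_id, design$table$clone_id)]
  df <- unique(data.frame(block = blk, tag_sequence = tags$tag_sequence,
                          clone_id = tags$clone_id))
  df
}
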