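#' Assembly parameters
#'
#' @param similarity_threshold burial threshold (default 0.75).
#' @param cutoff_schedule strictly increasing vector of Sulston-score
#'   cutoffs walked from most to least stringent; default
#'   `1e-50 ... 1e-01`.
#' @param universe_size tag universe `N`; `NULL` means "count the
#'   distinct tags in the input".
#' @param end_clone_window how many outermost clones at each contig end
#'   are eligible for merge tests during cutoff relaxation (default 3).
#' @return object of class `wgp_assembly_params`.
#' @export
assembly_params <- function(similarity_threshold = 0.75,
                            cutoff_schedule = c(1e-50, 1e-40, 1e-30, 1e-20,
                                                1e-15, 1e-10, 1e-05, 1e-02,
                                                1e-01),
                            universe_size = NULL,
                            end_clone_window = 3L) {
  check_fraction(similarity_threshold, "similarity_threshold")
  if (similarity_threshold <= 0) stopf("similarity_threshold must be > 0")
  if (length(cutoff_schedule) < 1L || any(cutoff_schedule <= 0) ||
      any(cutoff_schedule > 1))
    stopf("cutoff_schedule entries must lie in (0, 1]")
  if (is.unsorted(cutoff_schedule, strictly = TRUE))
    stopf("cutoff_schedule must be strictly increasing (stringent to relaxed)")
  if (!is.null(universe_size))
    universe_size <- check_positive(universe_size, "universe_size",
                                    integer = TRUE)
  end_clone_window <- check_positive(end_clone_window, "end_clone_window",
                                     integer = TRUE)
  structure(list(similarity_threshold = similarity_threshold,
                 cutoff_schedule = cutoff_schedule,
                 universe_size = universe_size,
                 end_clone_window = end_clone_window),
            class = "wgp_assembly_params")
}

# shared-tag counts for all fingerprint pairs with at least one common
# tag: data.frame (a, b, m) with a < b lexicographically
pair_shared_counts <- function(fps) {
  long <- data.table::data.table(
    clone = rep(names(fps), lengths(fps)),
    tag = unlist(fps, use.names = FALSE))
  if (nrow(long) == 0L)
    return(data.frame(a = character(), b = character(), m = integer()))
  j <- long[long, on = "tag", allow.cartesian = TRUE, nomatch = NULL]
  # columns: clone (from x), i.clone (from i); keep each unordered pair once
  j <- j[j$clone < j$i.clone, ]
  if (nrow(j) == 0L)
    return(data.frame(a = character(), b = character(), m = integer()))
  cnt <- data.table::data.table(a = j$clone, b = j$i.clone)[
    , list(m = .N), by = list(a, b)]
  data.table::setorder(cnt, a, b)
  as.data.frame(cnt)
}

# attach Sulston scores to a pair table
score_pairs <- function(pairs, fps, N) {
  if (nrow(pairs) == 0L) {
    pairs$score <- numeric(0)
    return(pairs)
  }
  na <- lengths(fps)[pairs$a]
  nb <- lengths(fps)[pairs$b]
  pairs$score <- sulston_score_counts(na, nb, pairs$m, N)
  pairs
}

#' Single-linkage contig building at one cutoff
#'
#' Clusters fingerprints by single linkage over the edge set
#' `{(A, B): sulston_score(A, B) <= cutoff}`.  Components of size one
#' are singletons.  Output is deterministic: contigs are ordered by
#' their smallest member id and members are sorted.
#'
#' @param superbacs named list: clone/SuperBAC id -> tag set.
#' @param cutoff score cutoff in `(0, 1]`.
#' @param universe_size tag universe `N` (default: distinct tags in
#'   `superbacs`).
#' @return list with `contigs` (list of member-id vectors), `singletons`
#'   (character vector) and `universe_size`.
#' @export
build_contigs <- function(superbacs, cutoff, universe_size = NULL) {
  if (cutoff <= 0 || cutoff > 1) stopf("cutoff must lie in (0, 1]")
  fps <- lapply(superbacs, unique)
  N <- universe_size %||% length(unique(unlist(fps, use.names = FALSE)))
  pairs <- score_pairs(pair_shared_counts(fps), fps, N)
  edges <- pairs[pairs$score <= cutoff, , drop = FALSE]
  g <- igraph::make_empty_graph(directed = FALSE) +
    igraph::vertices(names(fps))
  if (nrow(edges))
    g <- igraph::add_edges(g, rbind(edges$a, edges$b))
  comp <- igraph::components(g)
  groups <- split(names(fps), comp$membership)
  groups <- lapply(groups, sort)
  groups <- groups[order(vapply(groups, `[`, character(1), 1L))]
  sizes <- lengths(groups)
  list(contigs = unname(groups[sizes >= 2L]),
       singletons = as.character(sort(unlist(groups[sizes == 1L],
                                             use.names = FALSE))),
       universe_size = N)
}

# total clone span of a layout: sum over clones of (CB span width)
layout_objective <- function(layout, fps) {
  pos <- seq_along(layout)
  names(pos) <- layout
  total <- 0L
  for (tags in fps) {
    p <- pos[tags]
    total <- total + (max(p) - min(p) + 1L)
  }
  total
}

# greedy seriation from a seed clone pair: place remaining clones in
# order of strongest overlap with the placed tags, inserting unshared
# tags as a block on the side of the shared span that keeps the total
# clone span smaller
greedy_seriation <- function(fps, a, b) {
  shared <- sort(intersect(fps[[a]], fps[[b]]))
  layout <- c(sort(setdiff(fps[[a]], fps[[b]])), shared,
              sort(setdiff(fps[[b]], fps[[a]])))
  placed <- c(a, b)
  remaining <- setdiff(names(fps), placed)
  while (length(remaining)) {
    ov <- vapply(remaining, function(cl)
      length(intersect(fps[[cl]], layout)), integer(1))
    if (max(ov) == 0L)
      stopf("members are not connected via shared tags")
    nxt <- sort(remaining[ov == max(ov)])[1L]
    tags <- fps[[nxt]]
    ns <- sort(setdiff(tags, layout))
    if (length(ns)) {
      pos <- match(intersect(tags, layout), layout)
      lo <- min(pos); hi <- max(pos)
      sub_fps <- fps[c(placed, nxt)]
      cand <- list(append(layout, ns, after = lo - 1L),
                   append(layout, ns, after = hi))
      objs <- vapply(cand, layout_objective, numeric(1), fps = sub_fps)
      layout <- cand[[if (objs[2L] <= objs[1L]) 2L else 1L]]
    }
    placed <- c(placed, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  layout
}

# re-place one clone's exclusive tags as a block next to its shared span
reinsert_clone <- function(layout, fps, cl) {
  tags <- fps[[cl]]
  other <- unique(unlist(fps[setdiff(names(fps), cl)], use.names = FALSE))
  excl <- sort(setdiff(tags, other))
  if (length(excl) == 0L || length(excl) == length(tags)) return(layout)
  base <- setdiff(layout, excl)
  pos <- match(intersect(tags, base), base)
  lo <- min(pos); hi <- max(pos)
  cand <- list(append(base, excl, after = lo - 1L),
               append(base, excl, after = hi))
  objs <- vapply(cand, layout_objective, numeric(1), fps = fps)
  best <- which.min(objs)
  if (objs[best] < layout_objective(layout, fps)) cand[[best]] else layout
}

# first-improvement descent over block relocations (length 1-3) and
# segment reversals; small layouts only
refine_tag_moves <- function(layout, fps, max_iter = 500L) {
  T <- length(layout)
  cur <- layout_objective(layout, fps)
  for (iter in seq_len(max_iter)) {
    improved <- FALSE
    for (bl in 1:min(3L, T - 1L)) {          # relocate a contiguous block
      for (ti in seq_len(T - bl + 1L)) {
        block <- layout[ti:(ti + bl - 1L)]
        rest <- layout[-(ti:(ti + bl - 1L))]
        for (at in 0:length(rest)) {
          cand <- append(rest, block, after = at)
          o <- layout_objective(cand, fps)
          if (o < cur) {
            layout <- cand; cur <- o; improved <- TRUE
            break
          }
        }
        if (improved) break
      }
      if (improved) break
    }
    if (!improved) {                         # reverse a segment (2-opt)
      for (i in seq_len(T - 1L)) {
        for (j in (i + 1L):T) {
          cand <- layout
          cand[i:j] <- rev(cand[i:j])
          o <- layout_objective(cand, fps)
          if (o < cur) {
            layout <- cand; cur <- o; improved <- TRUE
            break
          }
        }
        if (improved) break
      }
    }
    if (!improved) break
  }
  layout
}

#' Consensus-band (CB) map of one contig
#'
#' Greedy seriation of a connected set of tag fingerprints: the
#' best-scoring (lowest Sulston score) pair seeds the layout; the
#' remaining clones are placed in order of strongest total overlap with
#' the already-placed tags, each clone's unshared tags entering as a
#' block adjacent to the end of its shared-tag span that yields the
#' smaller total clone span.  A local-improvement phase then re-inserts
#' clone-exclusive blocks (iterated to convergence) and, for small
#' layouts, relocates single tags while the total clone span decreases.
#' Every tag receives exactly one integer CB coordinate (1-based,
#' consecutive); a clone's span is the `[min, max]` of its tag
#' coordinates.
#'
#' @param member_fps named list: member id -> tag set; must be
#'   connected via shared tags.
#' @param universe_size tag universe `N` used for the seed-pair score
#'   (default: distinct tags of the members).
#' @param refine_tag_limit layouts with at most this many tags also get
#'   the single-tag relocation descent (default 16).
#' @return object of class `wgp_cb_map`: list with `order` (tags in CB
#'   order), `cb` (named integer coordinates), `spans` (data.frame
#'   `clone_id`, `left`, `right`, `n_tags`), `length_cb` (number of
#'   occupied CB coordinates) and `total_clone_span` (the seriation
#'   objective; equals `sum(n_tags)` iff every clone is contiguous).
#' @export
cb_map <- function(member_fps, universe_size = NULL, refine_tag_limit = 16L) {
  fps <- lapply(member_fps, unique)
  if (length(fps) == 0L) stopf("no members")
  N <- universe_size %||% length(unique(unlist(fps, use.names = FALSE)))

  n_tags_total <- length(unique(unlist(fps, use.names = FALSE)))
  small <- n_tags_total <= refine_tag_limit
  if (length(fps) == 1L) {
    layout <- sort(fps[[1L]])
  } else {
    pairs <- suppressWarnings(score_pairs(pair_shared_counts(fps), fps, N))
    if (nrow(pairs) == 0L)
      stopf("members are not connected via shared tags")
    pairs <- pairs[order(pairs$score, -pairs$m, pairs$a, pairs$b), ,
                   drop = FALSE]
    # small layouts restart the descent from several seed pairs and keep
    # the best layout; large ones use the single best-scoring seed
    n_seeds <- if (small) min(3L, nrow(pairs)) else 1L
    layout <- NULL
    best_obj <- Inf
    for (si in seq_len(n_seeds)) {
      cand <- greedy_seriation(fps, pairs$a[si], pairs$b[si])
      for (pass in 1:10) {                  # clone re-insertion passes
        before <- layout_objective(cand, fps)
        for (cl in sort(names(fps)))
          cand <- reinsert_clone(cand, fps, cl)
        if (layout_objective(cand, fps) >= before) break
      }
      if (small) cand <- refine_tag_moves(cand, fps)
      o <- layout_objective(cand, fps)
      if (o < best_obj) {
        layout <- cand
        best_obj <- o
      }
    }
  }

  cb <- setNames(seq_along(layout), layout)
  spans <- data.frame(
    clone_id = names(fps),
    left = vapply(fps, function(t) min(cb[t]), numeric(1)),
    right = vapply(fps, function(t) max(cb[t]), numeric(1)),
    n_tags = lengths(fps))
  spans <- spans[order(spans$left, spans$right, spans$clone_id), ,
                 drop = FALSE]
  rownames(spans) <- NULL
  structure(list(order = layout,
                 cb = cb,
                 spans = spans,
                 length_cb = length(layout),
                 total_clone_span = layout_objective(layout, fps)),
            class = "wgp_cb_map")
}

# end clones of a unit: the `window` outermost clones at each end of its
# CB map (all clones when the unit is small)
end_clones <- function(cbm, window) {
  ids <- cbm$spans$clone_id
  if (length(ids) <= 2L * window) return(ids)
  unique(c(head(ids, window), tail(ids, window)))
}

#' Stepwise contig assembly with cutoff relaxation
#'
#' Builds contigs at the most stringent cutoff of the schedule by full
#' single linkage, then walks the schedule toward the relaxed end: at
#' each subsequent cutoff only *end clones* (the `end_clone_window`
#' outermost clones of each contig's CB map; a singleton is a one-clone
#' contig whose clone is an end clone) are tested against end clones of
#' other contigs, and any pair scoring at or below the current cutoff
#' merges its contigs.  Merging repeats at a cutoff until no eligible
#' pair remains, and CB maps are recomputed for merged contigs, so the
#' partition coarsens monotonically along the schedule.
#'
#' @param superbacs named list: SuperBAC id -> tag set (use
#'   [bury_clones()] first, or raw fingerprints).
#' @param params an [assembly_params()].
#' @param burials optional burial data.frame from [bury_clones()]
#'   carried into the result for accounting.
#' @return object of class `wgp_assembly`: list with `contigs` (each a
#'   list `contig_id`, `members`, `cb`, `spans`, `length_cb`,
#'   `total_clone_span`), `singletons`, `burials`, `superbacs`,
#'   `universe_size`, `params` and `partition_trace` (the partition
#'   after each schedule step, for coarsening checks).
#' @export
stepwise_assembly <- function(superbacs, params = assembly_params(),
                              burials = NULL) {
  stopifnot(inherits(params, "wgp_assembly_params"))
  fps <- lapply(superbacs, unique)
  N <- params$universe_size %||%
    length(unique(unlist(fps, use.names = FALSE)))
  sched <- params$cutoff_schedule
  w <- params$end_clone_window

  first <- build_contigs(fps, sched[1L], N)
  units <- c(first$contigs, as.list(first$singletons))
  cbs <- lapply(units, function(ms) cb_map(fps[ms], N))
  trace <- list(lapply(units, sort))

  for (cutoff in sched[-1L]) {
    repeat {
      ends <- lapply(cbs, end_clones, window = w)
      unit_of <- rep(seq_along(units), lengths(ends))
      names(unit_of) <- unlist(ends, use.names = FALSE)
      ec <- names(unit_of)
      pairs <- score_pairs(pair_shared_counts(fps[ec]), fps, N)
      if (nrow(pairs)) {
        pairs <- pairs[unit_of[pairs$a] != unit_of[pairs$b], , drop = FALSE]
        pairs <- pairs[pairs$score <= cutoff, , drop = FALSE]
      }
      if (nrow(pairs) == 0L) break
      pairs <- pairs[order(pairs$score, pairs$a, pairs$b), , drop = FALSE]
      # union-find over units
      parent <- seq_along(units)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (k in seq_len(nrow(pairs))) {
        ra <- find(unit_of[pairs$a[k]]); rb <- find(unit_of[pairs$b[k]])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      root <- vapply(seq_along(units), find, integer(1))
      merged <- split(seq_along(units), root)
      new_units <- lapply(merged, function(ix)
        sort(unlist(units[ix], use.names = FALSE)))
      changed <- lengths(merged) > 1L
      new_cbs <- vector("list", length(new_units))
      for (i in seq_along(new_units)) {
        new_cbs[[i]] <- if (changed[i]) cb_map(fps[new_units[[i]]], N)
        else cbs[[merged[[i]][1L]]]
      }
      units <- unname(new_units)
      cbs <- unname(new_cbs)
    }
    trace <- c(trace, list(lapply(units, sort)))
  }

  sizes <- lengths(units)
  ord <- order(vapply(units, `[`, character(1), 1L))
  units <- units[ord]; cbs <- cbs[ord]; sizes <- sizes[ord]
  is_ctg <- sizes >= 2L
  contigs <- list()
  k <- 0L
  for (i in which(is_ctg)) {
    k <- k + 1L
    contigs[[k]] <- list(contig_id = sprintf("ctg%d", k),
                         members = units[[i]],
                         cb = cbs[[i]]$cb,
                         spans = cbs[[i]]$spans,
                         length_cb = cbs[[i]]$length_cb,
                         total_clone_span = cbs[[i]]$total_clone_span)
  }
  singles <- as.character(sort(unlist(units[!is_ctg], use.names = FALSE)))
  structure(list(contigs = contigs,
                 singletons = singles,
                 burials = burials %||%
                   data.frame(child_clone = character(),
                              parent_clone = character(),
                              marker = character()),
                 superbacs = fps,
                 universe_size = N,
                 params = params,
                 partition_trace = trace),
            class = "wgp_assembly")
}

#' @export
print.wgp_assembly <- function(x, ...) {
  cat(sprintf(paste0("wgp_assembly: %d contigs (%d SuperBACs), ",
                     "%d singletons, %d buried clones\n"),
              length(x$contigs),
              sum(vapply(x$contigs, function(ct) length(ct$members),
                         integer(1))),
              length(x$singletons), nrow(x$burials)))
  invisible(x)
}

#' Bury and assemble fingerprints in one call
#'
#' Runs [bury_clones()] then [stepwise_assembly()].
#'
#' @param fingerprints named list: clone id -> tag set.
#' @param params an [assembly_params()].
#' @return a `wgp_assembly`.
#' @export
assemble_clones <- function(fingerprints, params = assembly_params()) {
  bur <- bury_clones(fingerprints, params$similarity_threshold)
  res <- stepwise_assembly(bur$superbacs, params, burials = bur$burials)
  res$fingerprints <- lapply(fingerprints, unique)
  res
}

#' Map every clone to its assembly unit
#'
#' Returns the contig id for contig members and their buried children,
#' and `"singleton:<representative>"` for singleton representatives and
#' clones buried into them, so that clones grouped by burying share a
#' unit label.
#'
#' @param assembly a `wgp_assembly`.
#' @return named character vector: clone id -> unit label.
#' @export
clone_contig_map <- function(assembly) {
  out <- character(0)
  bur <- assembly$burials
  kids <- split(bur$child_clone, bur$parent_clone)
  for (ct in assembly$contigs) {
    ms <- ct$members
    all_ms <- c(ms, unlist(kids[ms], use.names = FALSE))
    out[all_ms] <- ct$contig_id
  }
  for (s in assembly$singletons) {
    all_s <- c(s, kids[[s]])
    out[all_s] <- paste0("singleton:", s)
  }
  out
}
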