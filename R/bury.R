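#' Bury near-redundant clones into SuperBACs
#'
#' FPC-style burying: similarity between two fingerprints is
#' `|A intersect B| / min(|A|, |B|)` (the smaller clone is measured
#' against the larger).  Clones are processed in descending tag count
#' (ties broken by clone id); each clone is buried into the *first*
#' already-retained clone with similarity at or above the threshold,
#' marked `"="` when the tag sets are identical and `"~"` when nearly
#' identical.  A SuperBAC's tag set is the union over its
#' representative and all clones buried into it.
#'
#' @param fingerprints named list: clone id -> character vector of tag
#'   identities (non-empty).
#' @param similarity_threshold burial threshold in `(0, 1]`
#'   (default 0.75).
#' @return object of class `wgp_burial`: list with `superbacs` (named
#'   list: representative -> union tag set), `burials` (data.frame
#'   `child_clone`, `parent_clone`, `marker`) and `members` (named
#'   list: representative -> member clone ids, representative first).
#' @export
bury_clones <- function(fingerprints, similarity_threshold = 0.75) {
  if (length(fingerprints) == 0L) stopf("`fingerprints` must be non-empty")
  if (is.null(names(fingerprints)) || anyDuplicated(names(fingerprints)))
    stopf("`fingerprints` must be a uniquely named list")
  check_fraction(similarity_threshold, "similarity_threshold")
  if (similarity_threshold <= 0) stopf("similarity_threshold must be > 0")
  fps <- lapply(fingerprints, unique)
  sizes <- lengths(fps)
  if (any(sizes == 0L)) stopf("fingerprints must be non-empty tag sets")
  ord <- names(fps)[order(-sizes, names(fps))]

  retained <- character(0)
  tag_index <- new.env(parent = emptyenv())   # tag -> retained clone ids
  parent <- character(0); child <- character(0); marker <- character(0)

  for (cl in ord) {
    tags <- fps[[cl]]
    cand <- unique(unlist(mget(tags, envir = tag_index, ifnotfound = list(NULL)),
                          use.names = FALSE))
    if (length(cand)) {
      cand <- cand[order(match(cand, retained))]   # retention order
      buried <- FALSE
      for (p in cand) {
        m <- length(intersect(tags, fps[[p]]))
        if (m / min(length(tags), length(fps[[p]])) >= similarity_threshold) {
          child <- c(child, cl); parent <- c(parent, p)
          marker <- c(marker, if (setequal(tags, fps[[p]])) "=" else "~")
          buried <- TRUE
          break
        }
      }
      if (buried) next
    }
    retained <- c(retained, cl)
    for (t in tags)
      assign(t, c(tag_index[[t]], cl), envir = tag_index)
  }

  burials <- data.frame(child_clone = child, parent_clone = parent,
                        marker = marker)
  members <- lapply(setNames(retained, retained), function(r)
    c(r, sort(child[parent == r])))
  superbacs <- lapply(members, function(ms)
    sort(unique(unlist(fps[ms], use.names = FALSE))))
  structure(list(superbacs = superbacs, burials = burials,
                 members = members,
                 similarity_threshold = similarity_threshold),
            class = "wgp_burial")
}

#' @export
print.wgp_burial <- function(x, ...) {
  cat(sprintf("wgp_burial: %d SuperBACs, %d buried clones (threshold %.2f)\n",
              length(x$superbacs), nrow(x$burials), x$similarity_threshold))
  invisible(x)
}
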