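#' Restriction enzymes for in-silico digestion
#'
#' Only palindromic recognition sites are supported, which covers the
#' WGP enzyme pair: HindIII (`AAGCTT`, cutting after the first base on
#' the top strand) and MseI (`TTAA`, likewise).  A blunt-cut
#' simplification is used throughout: the 4-nt 5' overhangs are
#' ignored and every cut is modelled at its top-strand coordinate.
#'
#' @param name enzyme name.
#' @param site recognition site (uppercase DNA, palindromic).
#' @param cut_offset cut position in bases from the site start on the
#'   top strand.
#' @return object of class `wgp_enzyme`.
#' @export
restriction_enzyme <- function(name, site, cut_offset) {
  site <- toupper(site)
  if (!grepl("^[ACGT]+$", site)) stopf("recognition site must be ACGT only")
  if (site != revcomp(site))
    stopf("unsupported enzyme `%s`: recognition site %s is not palindromic",
          name, site)
  if (cut_offset < 0 || cut_offset > nchar(site))
    stopf("cut_offset must lie within the recognition site")
  structure(list(name = name, site = site,
                 cut_offset = as.integer(cut_offset)),
            class = "wgp_enzyme")
}

#' @rdname restriction_enzyme
#' @export
hindiii <- function() restriction_enzyme("HindIII", "AAGCTT", 1L)

#' @rdname restriction_enzyme
#' @export
msei <- function() restriction_enzyme("MseI", "TTAA", 1L)

#' Find cut positions of an enzyme in a sequence
#'
#' Scans the top strand for exact occurrences of the recognition site
#' (overlapping occurrences included; palindromy makes the bottom
#' strand redundant) and returns the 0-based cut coordinates
#' `occurrence_start + cut_offset`, sorted ascending.  `N` bases never
#' match.
#'
#' @param sequence DNA string (uppercase ACGT, `N` allowed).
#' @param enzyme a [restriction_enzyme()].
#' @return sorted integer vector of 0-based cut positions.
#' @export
#' @examples
#' find_cut_sites("GGAAGCTTGGTTAACC", hindiii())  # 3
#' find_cut_sites("GGAAGCTTGGTTAACC", msei())     # 11
find_cut_sites <- function(sequence, enzyme) {
  stopifnot(inherits(enzyme, "wgp_enzyme"))
  if (!is.character(sequence) || length(sequence) != 1L || nchar(sequence) == 0L)
    stopf("`sequence` must be a single non-empty DNA string")
  if (nchar(sequence) < nchar(enzyme$site)) return(integer(0))
  hits <- Biostrings::matchPattern(enzyme$site,
                                   Biostrings::DNAString(sequence))
  sort(BiocGenerics::start(hits) - 1L + enzyme$cut_offset)
}

#' Double digest a sequence into labeled fragments
#'
#' Merges the cut positions of all enzymes (HindIII and MseI cuts can
#' never coincide: their sites cannot overlap so as to share a cut
#' coordinate) and partitions `[0, len)` at those cuts.  Each internal
#' fragment end is labeled with the enzyme that produced the cut; the
#' outer ends are `SEQ_START` / `SEQ_END`.
#'
#' @param sequence DNA string.
#' @param enzymes list of [restriction_enzyme()] objects (default
#'   HindIII + MseI).
#' @return data.frame with columns `start`, `end` (0-based half-open)
#'   and `left_end`, `right_end` (one of `SEQ_START`, `HINDIII`,
#'   `MSEI`, `SEQ_END`, or the upper-cased enzyme name).
#' @export
#' @examples
#' double_digest("GGAAGCTTGGTTAACC")
double_digest <- function(sequence, enzymes = list(hindiii(), msei())) {
  cuts <- integer(0)
  labels <- character(0)
  for (e in enzymes) {
    p <- find_cut_sites(sequence, e)
    cuts <- c(cuts, p)
    labels <- c(labels, rep(toupper(e$name), length(p)))
  }
  # drop cuts at the very ends (no zero-length fragments)
  len <- nchar(sequence)
  keep <- cuts > 0L & cuts < len
  cuts <- cuts[keep]; labels <- labels[keep]
  o <- order(cuts)
  cuts <- cuts[o]; labels <- labels[o]
  starts <- c(0L, cuts)
  ends <- c(cuts, len)
  data.frame(start = starts,
             end = ends,
             left_end = c("SEQ_START", labels),
             right_end = c(labels, "SEQ_END"))
}

#' Tag extraction parameters
#'
#' @param tag_length_nt tag length in nucleotides (default 51, the
#'   prefix of a 100-nt read retained as the tag).
#' @param read_length_nt sequencing read length (default 100); must be
#'   at least `tag_length_nt`.
#' @param min_fragment_bp minimum fragment length eligible for tag
#'   extraction (default: the tag length).
#' @param hindiii_hindiii_both should a fragment with HindIII cuts at
#'   both ends yield tags from both ends (default `TRUE`)?
#' @return object of class `wgp_tag_params`.
#' @export
tag_params <- function(tag_length_nt = 51L,
                       read_length_nt = 100L,
                       min_fragment_bp = tag_length_nt,
                       hindiii_hindiii_both = TRUE) {
  tag_length_nt <- check_positive(tag_length_nt, "tag_length_nt", integer = TRUE)
  read_length_nt <- check_positive(read_length_nt, "read_length_nt", integer = TRUE)
  if (tag_length_nt > read_length_nt)
    stopf("tag_length_nt must not exceed read_length_nt")
  min_fragment_bp <- check_positive(min_fragment_bp, "min_fragment_bp",
                                    integer = TRUE)
  structure(list(tag_length_nt = tag_length_nt,
                 read_length_nt = read_length_nt,
                 min_fragment_bp = min_fragment_bp,
                 hindiii_hindiii_both = isTRUE(hindiii_hindiii_both)),
            class = "wgp_tag_params")
}

#' Extract WGP tags from digested fragments
#'
#' Sequencing runs from the HindIII cut into the fragment, so tags are
#' anchored at HindIII ends only: for a fragment whose *left* end is a
#' HindIII cut, the tag is the first `tag_length_nt` bases of the
#' fragment (beginning with the `AGCTT` site remnant under the
#' blunt-cut convention); for a HindIII *right* end, the reverse
#' complement of the last `tag_length_nt` bases.  MseI-only fragments
#' and sequence ends yield nothing; a HindIII--HindIII fragment yields
#' two tags (flag-controlled).  Fragments shorter than
#' `min_fragment_bp` are skipped and counted, as are tags containing
#' `N`.
#'
#' @param fragments data.frame from [double_digest()] of
#'   `insert_sequence`.
#' @param insert_sequence the digested sequence.
#' @param params a [tag_params()] object.
#' @return data.frame with columns `tag_sequence`, `anchor` (0-based
#'   cut coordinate within the insert), `direction` (`"+"` for a
#'   left-end tag, `"-"` for a right-end tag).  Attribute `skipped`
#'   holds counts of short-fragment and N-containing skips.
#' @export
extract_tags <- function(fragments, insert_sequence, params = tag_params()) {
  stopifnot(inherits(params, "wgp_tag_params"))
  tl <- params$tag_length_nt
  flen <- fragments$end - fragments$start
  skipped_short <- 0L

  seqs <- character(0); anchors <- integer(0); dirs <- character(0)
  left_h <- fragments$left_end == "HINDIII"
  right_h <- fragments$right_end == "HINDIII"
  if (!params$hindiii_hindiii_both)
    right_h <- right_h & !left_h
  eligible <- flen >= max(params$min_fragment_bp, tl)
  skipped_short <- sum((left_h | right_h) & !eligible)

  li <- which(left_h & eligible)
  if (length(li)) {
    seqs <- c(seqs, substring(insert_sequence, fragments$start[li] + 1L,
                              fragments$start[li] + tl))
    anchors <- c(anchors, fragments$start[li])
    dirs <- c(dirs, rep("+", length(li)))
  }
  ri <- which(right_h & eligible)
  if (length(ri)) {
    seqs <- c(seqs, revcomp(substring(insert_sequence,
                                      fragments$end[ri] - tl + 1L,
                                      fragments$end[ri])))
    anchors <- c(anchors, fragments$end[ri])
    dirs <- c(dirs, rep("-", length(ri)))
  }
  has_n <- grepl("N", seqs, fixed = TRUE)
  out <- data.frame(tag_sequence = seqs[!has_n],
                    anchor = anchors[!has_n],
                    direction = dirs[!has_n])
  o <- order(out$anchor, out$direction)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- c(short_fragment = skipped_short,
                            n_containing = sum(has_n))
  out
}

#' Digest every clone of a library and extract its WGP tags
#'
#' Convenience wrapper: extracts each clone's insert sequence, double
#' digests it with HindIII/MseI and extracts HindIII-anchored tags.
#'
#' @param genome a `wgp_genome`.
#' @param clones a `wgp_bac_library`.
#' @param params a [tag_params()].
#' @param enzymes enzyme list passed to [double_digest()].
#' @return data.frame `clone_id`, `tag_sequence`, `anchor`,
#'   `direction`; one row per tag occurrence.
#' @export
clone_wgp_tags <- function(genome, clones, params = tag_params(),
                           enzymes = list(hindiii(), msei())) {
  seqs <- clone_sequences(genome, clones)
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    tags <- extract_tags(double_digest(seqs[[i]], enzymes), seqs[[i]], params)
    if (nrow(tags))
      out[[i]] <- data.frame(clone_id = names(seqs)[i], tags)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(clone_id = character(), tag_sequence = character(),
                      anchor = integer(), direction = character())
  rownames(res) <- NULL
  res
}

#' Per-clone tag sets from a tag table
#'
#' @param tag_table data.frame with `clone_id` and `tag_sequence`
#'   columns ([clone_wgp_tags()] output or deconvolution assignments).
#' @param unique_tags drop duplicate tag occurrences within a clone
#'   (default `TRUE`; fingerprints are tag *sets*).
#' @return named list mapping clone id to a character vector of tags.
#' @export
tags_by_clone <- function(tag_table, unique_tags = TRUE) {
  sp <- split(tag_table$tag_sequence, tag_table$clone_id)
  if (unique_tags) sp <- lapply(sp, unique)
  sp
}

#' Count genome-wide tag anchors
#'
#' Number of WGP tags the full genome sequence yields under the given
#' digestion/extraction parameters; used for the CB-unit to bp
#' conversion via [mean_tag_distance()].
#'
#' @inheritParams clone_wgp_tags
#' @return integer tag-anchor count.
#' @export
genome_tag_anchors <- function(genome, params = tag_params(),
                               enzymes = list(hindiii(), msei())) {
  frags <- double_digest(genome$sequence, enzymes)
  nrow(extract_tags(frags, genome$sequence, params))
}

#' Build an SM1-style tag table
#'
#' Assigns stable ids (`WGP0000001`, ...) to the distinct tag sequences
#' in lexicographic order.
#'
#' @param tag_sequences character vector of tag sequences.
#' @return data.frame `tag_id`, `tag_sequence`.
#' @export
tag_table <- function(tag_sequences) {
  u <- sort(unique(tag_sequences))
  data.frame(tag_id = sprintf("WGP%07d", seq_along(u)), tag_sequence = u)
}
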