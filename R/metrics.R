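#' Mean distance between WGP tag anchors
#'
#' The bp-per-CB-unit conversion constant: genome length divided by the
#' number of tag anchors it yields.  In real-data mode a user-supplied
#' constant replaces this computation.
#'
#' @param genome_length_bp genome length in bp.
#' @param n_tag_anchors number of tag anchors (>= 1), e.g. from
#'   [genome_tag_anchors()].
#' @return bp per CB unit.
#' @export
#' @examples
#' mean_tag_distance(1e6, 250)  # 4000 bp
mean_tag_distance <- function(genome_length_bp, n_tag_anchors) {
  check_positive(genome_length_bp, "genome_length_bp")
  if (n_tag_anchors < 1) stopf("n_tag_anchors must be >= 1")
  genome_length_bp / n_tag_anchors
}

#' N50 of a size list
#'
#' Sizes are sorted descending; the N50 is the first size at which the
#' running sum reaches at least half the total.
#'
#' @param sizes non-empty vector of positive sizes.
#' @return the N50, in the units of `sizes`.
#' @export
#' @examples
#' n50(c(4, 2, 1, 1))  # 4
#' n50(c(3, 3, 2))     # 3
n50 <- function(sizes) {
  if (length(sizes) == 0L) stopf("`sizes` must be non-empty")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stopf("`sizes` must be positive and finite")
  s <- sort(sizes, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1L]]
}

#' Library fold-coverage from clone counts
#'
#' @param n_clones clone count.
#' @param insert_mean_bp mean insert length in bp.
#' @param genome_bp genome size in bp.
#' @return fold coverage (`n_clones * insert_mean_bp / genome_bp`).
#' @export
library_coverage <- function(n_clones, insert_mean_bp, genome_bp) {
  check_positive(genome_bp, "genome_bp")
  n_clones * insert_mean_bp / genome_bp
}

#' Physical-map metrics from explicit counts
#'
#' The arithmetic layer under [assembly_metrics()], usable directly on
#' published map summaries.  Percentages and averages carry full
#' precision, with `*_reported` companions rounded in the conventional
#' style (one decimal for percentages and BAC averages, three decimals
#' for Mbp sizes, nearest integer for contigs per Mbp).
#'
#' @param n_contigs number of contigs.
#' @param n_clones_in_contigs BAC clones in contigs (buried clones
#'   counted as members).
#' @param n_singletons singleton BAC clones.
#' @param total_span_mbp summed contig span in Mbp (optional).
#' @param contig_sizes_bacs optional per-contig clone counts (enables
#'   `n50_bacs`).
#' @param contig_sizes_mbp optional per-contig spans in Mbp (enables
#'   `n50_mbp`).
#' @param library_size clones in the sequenced library (optional).
#' @param fpc_ready_count clones with usable fingerprints (optional).
#' @return object of class `wgp_map_metrics` (named list).
#' @export
map_metrics <- function(n_contigs,
                        n_clones_in_contigs,
                        n_singletons,
                        total_span_mbp = NA_real_,
                        contig_sizes_bacs = NULL,
                        contig_sizes_mbp = NULL,
                        library_size = NA_real_,
                        fpc_ready_count = NA_real_) {
  flag_empty <- n_contigs == 0
  if (flag_empty) warning("zero contigs: averages reported as 0")
  div <- function(num, den) if (is.na(den) || den == 0) 0 else num / den
  avg_bacs <- div(n_clones_in_contigs, n_contigs)
  avg_mbp <- if (is.na(total_span_mbp)) NA_real_ else
    div(total_span_mbp, n_contigs)
  contigs_per_mbp <- if (is.na(total_span_mbp) || total_span_mbp == 0)
    NA_real_ else n_contigs / total_span_mbp
  pct_fpc <- if (is.na(fpc_ready_count) || fpc_ready_count == 0) NA_real_ else
    100 * n_clones_in_contigs / fpc_ready_count
  pct_lib <- if (is.na(library_size) || library_size == 0) NA_real_ else
    100 * n_clones_in_contigs / library_size
  pct_lib_absent <- if (is.na(pct_lib)) NA_real_ else 100 - pct_lib
  structure(
    list(n_contigs = n_contigs,
         n_clones_in_contigs = n_clones_in_contigs,
         n_singletons = n_singletons,
         avg_contig_bacs = avg_bacs,
         avg_contig_bacs_reported = round(avg_bacs, 1),
         n50_bacs = if (length(contig_sizes_bacs)) n50(contig_sizes_bacs)
         else NA_real_,
         total_span_mbp = total_span_mbp,
         avg_contig_mbp = avg_mbp,
         avg_contig_mbp_reported = round(avg_mbp, 3),
         n50_mbp = if (length(contig_sizes_mbp)) n50(contig_sizes_mbp)
         else NA_real_,
         contigs_per_mbp = contigs_per_mbp,
         contigs_per_mbp_reported = round(contigs_per_mbp),
         pct_fpc_clones_in_contigs = pct_fpc,
         pct_fpc_clones_in_contigs_reported = round(pct_fpc, 1),
         pct_library_in_contigs = pct_lib,
         pct_library_in_contigs_reported = round(pct_lib, 1),
         pct_library_absent = pct_lib_absent,
         pct_library_absent_reported = round(pct_lib_absent, 1),
         library_size = library_size,
         fpc_ready_count = fpc_ready_count,
         empty_assembly = flag_empty),
    class = "wgp_map_metrics")
}

#' Map metrics of an assembly
#'
#' Counts contig members together with the clones buried into them
#' (buried clones count toward contig BAC totals; clones buried into a
#' singleton representative follow it into the singleton count), then
#' converts CB lengths to Mbp via `mbp_per_cb_unit` and delegates the
#' arithmetic to [map_metrics()].
#'
#' @param assembly a `wgp_assembly`.
#' @param mbp_per_cb_unit Mbp per CB unit (mean tag distance / 1e6),
#'   e.g. `mean_tag_distance(...) / 1e6`; `NA` skips Mbp metrics.
#' @param library_size,fpc_ready_count optional denominators (the
#'   FPC-ready count defaults to the clones present in the assembly).
#' @return a `wgp_map_metrics`.
#' @export
assembly_metrics <- function(assembly, mbp_per_cb_unit = NA_real_,
                             library_size = NA_real_,
                             fpc_ready_count = NULL) {
  stopifnot(inherits(assembly, "wgp_assembly"))
  bur <- assembly$burials
  n_buried_under <- table(bur$parent_clone)
  unit_bacs <- function(members)
    length(members) + sum(n_buried_under[members], na.rm = TRUE)
  sizes_bacs <- vapply(assembly$contigs, function(ct) unit_bacs(ct$members),
                       numeric(1))
  n_in_contigs <- sum(sizes_bacs)
  n_singletons <- length(assembly$singletons) +
    sum(n_buried_under[assembly$singletons], na.rm = TRUE)
  lengths_cb <- vapply(assembly$contigs, function(ct) ct$length_cb,
                       numeric(1))
  sizes_mbp <- if (is.na(mbp_per_cb_unit)) NULL else
    lengths_cb * mbp_per_cb_unit
  if (is.null(fpc_ready_count))
    fpc_ready_count <- length(assembly$superbacs) + nrow(bur)
  map_metrics(
    n_contigs = length(assembly$contigs),
    n_clones_in_contigs = n_in_contigs,
    n_singletons = n_singletons,
    total_span_mbp = if (is.null(sizes_mbp)) NA_real_ else sum(sizes_mbp),
    contig_sizes_bacs = if (length(sizes_bacs)) sizes_bacs else NULL,
    contig_sizes_mbp = sizes_mbp,
    library_size = library_size,
    fpc_ready_count = fpc_ready_count)
}

#' @export
print.wgp_map_metrics <- function(x, ...) {
  cat("WGP physical-map metrics\n")
  cat(sprintf("  Contigs                     %s\n",
              format(x$n_contigs, big.mark = ",")))
  cat(sprintf("  BACs in contigs             %s\n",
              format(x$n_clones_in_contigs, big.mark = ",")))
  cat(sprintf("  Singleton BACs              %s\n",
              format(x$n_singletons, big.mark = ",")))
  cat(sprintf("  Average contig size (BACs)  %.1f\n", x$avg_contig_bacs))
  if (!is.na(x$n50_bacs))
    cat(sprintf("  N50 contig size (BACs)      %g\n", x$n50_bacs))
  if (!is.na(x$total_span_mbp)) {
    cat(sprintf("  Total span (Mbp)            %.1f\n", x$total_span_mbp))
    cat(sprintf("  Average contig size (Mbp)   %.3f\n", x$avg_contig_mbp))
    if (!is.na(x$n50_mbp))
      cat(sprintf("  N50 contig size (Mbp)       %.3f\n", x$n50_mbp))
    cat(sprintf("  Contigs per Mbp             %.1f\n", x$contigs_per_mbp))
  }
  if (!is.na(x$pct_fpc_clones_in_contigs))
    cat(sprintf("  %% FPC-ready in contigs      %.1f\n",
                x$pct_fpc_clones_in_contigs))
  if (!is.na(x$pct_library_in_contigs)) {
    cat(sprintf("  %% library in contigs        %.1f\n",
                x$pct_library_in_contigs))
    cat(sprintf("  %% library absent            %.1f\n",
                x$pct_library_absent))
  }
  invisible(x)
}

#' Metrics as a two-column data.frame
#'
#' Flattens a `wgp_map_metrics` or `wgp_deconvolution_summary` into
#' `(metric, value)` rows for TSV export.
#'
#' @param x the metrics object.
#' @return data.frame with columns `metric`, `value`.
#' @export
metrics_table <- function(x) {
  keep <- vapply(x, function(v) is.numeric(v) && length(v) == 1L,
                 logical(1))
  data.frame(metric = names(x)[keep],
             value = vapply(x[keep], as.numeric, numeric(1)),
             row.names = NULL)
}
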