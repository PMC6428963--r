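#' Sulston overlap score for tag fingerprints
#'
#' Probability that two clones share at least the observed number of
#' fingerprint elements by chance, adapted from the classic FPC clone
#' overlap test to exact sequence-tag matching: with
#' `nH = max(|A|, |B|)`, `nL = min(|A|, |B|)`, `m = |A intersect B|`
#' and match probability `p = nH / N` for a tag universe of size `N`,
#'
#'   score = sum_{k = m}^{nL} C(nL, k) p^k (1 - p)^(nL - k)
#'
#' i.e. the upper binomial tail `P(X >= m)`, `X ~ Binomial(nL, p)`.
#' There is no band-mobility tolerance window: tags either match
#' exactly or not at all.  Small scores indicate true overlap.  The
#' score is symmetric in its arguments; `m = 0` gives 1.  A degenerate
#' universe (`p >= 1`) returns 1 with a warning.
#'
#' @param a,b fingerprints: character vectors of tag identities (sets;
#'   duplicates are ignored).
#' @param universe_size `N`, the number of distinct tags in the
#'   experiment.
#' @return the score, a probability in `(0, 1]`.
#' @seealso [sulston_score_counts()] for the count-level kernel.
#' @export
#' @examples
#' sulston_score(c("t1", "t2", "t3"), c("t2", "t3", "t4"), 100)
sulston_score <- function(a, b, universe_size) {
  a <- unique(a); b <- unique(b)
  sulston_score_counts(length(a), length(b),
                       length(intersect(a, b)), universe_size)
}

#' Sulston score from fingerprint sizes
#'
#' Vectorized over `na`, `nb`, `m`.
#'
#' @param na,nb fingerprint sizes.
#' @param m shared-tag count; requires `N >= na + nb - m`.
#' @param N tag universe size (`>= 1`).
#' @return numeric vector of scores.
#' @export
sulston_score_counts <- function(na, nb, m, N) {
  n <- max(length(na), length(nb), length(m), length(N))
  na <- rep_len(na, n); nb <- rep_len(nb, n)
  m <- rep_len(m, n); N <- rep_len(N, n)
  if (any(N < 1)) stopf("universe size N must be >= 1")
  if (any(m > pmin(na, nb)))
    stopf("shared count m cannot exceed the smaller fingerprint")
  if (any(N < na + nb - m))
    stopf("universe size N must be at least |A| + |B| - m")
  nh <- pmax(na, nb)
  nl <- pmin(na, nb)
  p <- nh / N
  out <- numeric(length(p))
  degen <- p >= 1
  if (any(degen)) {
    warning("degenerate universe (p >= 1); returning score 1")
    out[degen] <- 1
  }
  zero <- !degen & m <= 0
  out[zero] <- 1
  rest <- !degen & !zero
  if (any(rest))
    out[rest] <- pbinom(m[rest] - 1, nl[rest], p[rest], lower.tail = FALSE)
  out
}
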