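# Background-expected score of each column: used for N bases, which
# contribute the expectation rather than disqualifying the window.
expected_col_scores <- function(sm, bg = sm$bg) {
  as.numeric(bg %*% sm$scores)
}

#' Score a single k-mer against a score matrix
#'
#' Sums the per-position log-odds scores of the k-mer's bases. An `N` (or any
#' other ambiguity letter) contributes the background-expected score of its
#' column instead of a base score.
#'
#' @param sm A [score_matrix()].
#' @param kmer Character string of length `sm$width` over A, C, G, T, N.
#' @return The raw log-odds score (a single number).
#' @export
score_kmer <- function(sm, kmer) {
  codes <- dna_codes(kmer)
  if (length(codes) != sm$width) {
    rlang::abort(sprintf(
      "`kmer` must have length %d (motif width); got %d.", sm$width, length(codes)
    ))
  }
  exp_scores <- expected_col_scores(sm)
  vals <- sm$scores[cbind(codes, seq_along(codes))]
  vals[is.na(codes)] <- exp_scores[is.na(codes)]
  sum(vals)
}

# Raw scores of every k-length window of a coded sequence (codes 1..4, NA
# for ambiguous bases). Returns a numeric vector of length L - k + 1.
scan_scores <- function(sm, codes) {
  k <- sm$width
  n <- length(codes) - k + 1L
  exp_scores <- expected_col_scores(sm)
  out <- numeric(n)
  for (i in seq_len(n)) {
    idx <- codes[i:(i + k - 1L)]
    vals <- sm$scores[cbind(idx, seq_len(k))]
    vals[is.na(idx)] <- exp_scores[is.na(idx)]
    out[i] <- sum(vals)
  }
  out
}

normalize_score <- function(sm, raw) {
  if (sm$s_max > sm$s_min) (raw - sm$s_min) / (sm$s_max - sm$s_min) else rep(1, length(raw))
}

#' Best motif match in a sequence
#'
#' Scans every placement of the motif over the requested strands and returns
#' the highest-scoring match. Ties are broken by lower position, then the
#' plus strand, so output is deterministic. Minus-strand placements are
#' scored with the reverse-complemented matrix on the forward sequence;
#' `matched_seq` is always the forward-strand segment.
#'
#' @param sm A [score_matrix()].
#' @param sequence Character string, length >= motif width.
#' @param strands Subset of `c("+", "-")` to scan.
#' @param dists Optional precomputed score distributions, a list with
#'   elements `"+"` and `"-"` from [score_distribution()]; used for the
#'   p-value. Computed on the fly when absent.
#' @param granularity Passed to [score_distribution()] when `dists` is
#'   absent.
#' @return A one-row tibble: `position` (0-based offset of the match start),
#'   `strand`, `raw_score`, `norm_score` (min-max normalized to \[0, 1\]),
#'   `pvalue`, `matched_seq`.
#' @export
best_match <- function(sm, sequence, strands = c("+", "-"), dists = NULL,
                       granularity = NULL) {
  strands <- match.arg(strands, c("+", "-"), several.ok = TRUE)
  codes <- dna_codes(sequence)
  k <- sm$width
  if (length(codes) < k) {
    rlang::abort(sprintf(
      "`sequence` (length %d) is shorter than the motif width (%d).",
      length(codes), k
    ))
  }
  mats <- list("+" = sm, "-" = reverse_complement(sm))
  cand <- lapply(strands, function(st) {
    raw <- scan_scores(mats[[st]], codes)
    tibble::tibble(position = seq_along(raw) - 1L, strand = st, raw_score = raw)
  })
  cand <- dplyr::bind_rows(cand)
  # ties: lower position first, then "+" strand (locale-independent)
  best <- cand[order(-cand$raw_score, cand$position, match(cand$strand, c("+", "-"))), ][1, ]
  if (is.null(dists)) {
    dists <- lapply(mats[strands], score_distribution, granularity = granularity)
  }
  d <- dists[[best$strand]]
  best$norm_score <- normalize_score(sm, best$raw_score)
  best$pvalue <- pvalue_from_distribution(d, best$raw_score)
  best$matched_seq <- substr(toupper(sequence), best$position + 1L, best$position + k)
  best[, c("position", "strand", "raw_score", "norm_score", "pvalue", "matched_seq")]
}

#' Exact score distribution of a motif under a background model
#'
#' Convolves the per-position score distributions of the matrix by dynamic
#' programming over positions, giving the exact distribution of the score of
#' a random k-mer drawn i.i.d. from the background. Partial sums that
#' coincide are merged at every step; while the state count stays below
#' `max_states` the attained values are kept exactly, beyond that they are
#' collapsed onto a lattice of spacing `granularity`. The object records the
#' resulting worst-case score slack so that tail queries can absorb the
#' discretization error.
#'
#' @param sm A [score_matrix()].
#' @param bg Background model; defaults to the one stored in `sm`.
#' @param granularity Lattice spacing used when collapsing; default
#'   `(s_max - s_min) / 1e5`.
#' @param max_states Maximum number of exact states kept before collapsing
#'   to the lattice. Default `4^9`.
#' @return An object of class `score_distribution`: list with sorted
#'   `values`, matching `probs`, `tail` (P(score >= value)), `slack`,
#'   `granularity`, and `width`.
#' @export
score_distribution <- function(sm, bg = sm$bg, granularity = NULL,
                               max_states = 262144L) {
  bg <- validate_bg(bg)
  range <- sm$s_max - sm$s_min
  g <- granularity %||% (if (range > 0) range / 1e5 else 1e-9)
  if (g <= 0) rlang::abort("`granularity` must be > 0.")
  vals <- 0
  probs <- 1
  n_collapsed <- 0L
  for (j in seq_len(sm$width)) {
    col <- sm$scores[, j]
    nv <- as.vector(outer(col, vals, "+"))
    np <- as.vector(outer(bg, probs, "*"))
    if (length(nv) > max_states) {
      key <- round(nv / g)
      agg <- rowsum(np, key, reorder = TRUE)
      vals <- as.numeric(rownames(agg)) * g
      probs <- as.vector(agg)
      n_collapsed <- n_collapsed + 1L
    } else {
      o <- order(nv)
      nv <- nv[o]
      np <- np[o]
      grp <- cumsum(c(TRUE, diff(nv) != 0))
      vals <- nv[!duplicated(grp)]
      probs <- as.vector(rowsum(np, grp, reorder = FALSE))
    }
  }
  tail <- rev(cumsum(rev(probs)))
  structure(
    list(
      values = vals, probs = probs, tail = pmin(tail, 1),
      slack = n_collapsed * g / 2, granularity = g, width = sm$width
    ),
    class = "score_distribution"
  )
}

# Tail probability P(score >= threshold) of a score_distribution, with the
# distribution's discretization slack treated as qualifying. Clamped into
# (0, 1]: a threshold above every attained value reports the probability of
# the top state rather than 0.
pvalue_from_distribution <- function(dist, threshold) {
  q <- dist$values >= threshold - dist$slack - 1e-12
  p <- if (any(q)) dist$tail[which(q)[1]] else dist$probs[length(dist$probs)]
  min(max(p, .Machine$double.xmin), 1)
}

#' Exact p-value of a motif match score
#'
#' Probability that a random k-mer drawn i.i.d. from the background model
#' scores at least `raw_score` against the matrix, computed from the exact
#' DP score distribution of [score_distribution()].
#'
#' @inheritParams score_distribution
#' @param raw_score The score threshold.
#' @param dist Optional precomputed [score_distribution()] (must match `sm`
#'   and `bg`); avoids recomputation in scans.
#' @return A p-value in (0, 1].
#' @export
match_pvalue <- function(sm, raw_score, bg = sm$bg, granularity = NULL,
                         dist = NULL) {
  if (raw_score <= sm$s_min) return(1)
  d <- dist %||% score_distribution(sm, bg = bg, granularity = granularity)
  pvalue_from_distribution(d, raw_score)
}

#' Brute-force p-value by k-mer enumeration
#'
#' Enumerates all 4^k k-mers, scores each, and sums the background
#' probabilities of those scoring at least `raw_score`. Exact but
#' exponential; restricted to k <= 10. Serves as an independent oracle for
#' [match_pvalue()].
#'
#' @inheritParams match_pvalue
#' @return A p-value in \[0, 1\].
#' @export
brute_force_pvalue <- function(sm, raw_score, bg = sm$bg) {
  k <- sm$width
  if (k > 10L) rlang::abort("brute-force enumeration is limited to width <= 10.")
  bg <- validate_bg(bg)
  grid <- as.matrix(expand.grid(rep(list(1:4), k), KEEP.OUT.ATTRS = FALSE))
  score_mat <- matrix(0, nrow(grid), k)
  prob_mat <- matrix(0, nrow(grid), k)
  for (j in seq_len(k)) {
    score_mat[, j] <- sm$scores[grid[, j], j]
    prob_mat[, j] <- bg[grid[, j]]
  }
  scores <- rowSums(score_mat)
  probs <- apply(prob_mat, 1, prod)
  sum(probs[scores >= raw_score])
}
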