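#' Genomic span of a reference-side motif match
#'
#' Converts a 0-based match offset within a window's reference sequence into
#' a 1-based inclusive genomic interval.
#'
#' @param match_start 0-based offset of the match start within `ref_seq`.
#' @param k Motif width.
#' @param w One-row window tibble from [build_windows()].
#' @return Integer vector `c(start1, end1)`.
#' @export
genomic_span <- function(match_start, k, w) {
  if (match_start < 0L || match_start + k > nchar(w$ref_seq)) {
    rlang::abort("`match_start` lies outside the reference window.")
  }
  start1 <- w$window_start1 + as.integer(match_start)
  c(start1, start1 + as.integer(k) - 1L)
}

#' Indel-edge-relative coordinates of an alternate-allele motif match
#'
#' Locates a motif match relative to the edges of the variant: the first
#' number is the displacement of the motif start from the variant's first
#' base (negative = upstream, positive = downstream, 0 = coincident with the
#' edge base), the second the displacement of the motif end from the
#' variant's last base under the same convention. For insertions (and
#' delins/SNVs) the edges are the first and last alternate-allele base in
#' `alt_seq`; for deletions they are the first and last deleted base in
#' `ref_seq`, which keeps the coordinates genome-interpretable, and the
#' match offset (given in `alt_seq`) is mapped across the deletion junction.
#'
#' @param match_start 0-based offset of the match start within `alt_seq`.
#' @param k Motif width.
#' @param w One-row window tibble from [build_windows()].
#' @param var_class One of `"snv"`, `"insertion"`, `"deletion"`, `"delins"`.
#' @return Integer vector `c(start_offset, end_offset)`.
#' @export
relative_coords <- function(match_start, k, w, var_class) {
  m1 <- as.integer(match_start) + 1L
  if (m1 < 1L || m1 + k - 1L > nchar(w$alt_seq)) {
    rlang::abort("`match_start` lies outside the alternate window.")
  }
  if (var_class == "deletion") {
    lo <- w$ref_span_lo
    hi <- w$ref_span_hi
    if (hi < lo) rlang::abort("window carries no deleted segment; not a deletion.")
    del_len <- hi - lo + 1L
    start_ref <- if (m1 < lo) m1 else m1 + del_len
    end_alt <- m1 + as.integer(k) - 1L
    end_ref <- if (end_alt < lo) end_alt else end_alt + del_len
    c(start_ref - lo, end_ref - hi)
  } else {
    lo <- w$alt_span_lo
    hi <- w$alt_span_hi
    if (hi < lo) rlang::abort("variant has an empty alternate allele; no edges defined.")
    c(m1 - lo, (m1 + as.integer(k) - 1L) - hi)
  }
}

n_fraction <- function(seq) {
  if (!nzchar(seq)) return(0)
  sum(strsplit(seq, "", fixed = TRUE)[[1]] == "N") / nchar(seq)
}

#' Score variants against a motif library
#'
#' The core engine. For every variant x motif pair it builds the paired
#' ref/alt allele windows, finds the best motif match on each allele over
#' both strands, computes exact match p-values, and reports the pair when at
#' least one allele's best match passes the p-value threshold. The effect
#' size is `score_ref - score_alt` in min-max-normalized score units:
#' positive means the alternate allele weakens (disrupts) the best motif
#' match, negative means it creates a better one.
#'
#' Variants whose window cannot be built (missing contig, reference
#' mismatch) are skipped with a warning, not fatal; the skip tally is
#' attached as `attr(result, "stats")`. Windows with more than `max_n_frac`
#' ambiguous bases are skipped likewise.
#'
#' @param variants Variant tibble from [read_vcf()] or
#'   [read_bed_variants()].
#' @param motifs Motif library from [read_motifs()].
#' @param genome Genome from [read_genome()].
#' @param bg Background base frequencies. Default uniform.
#' @param p_threshold Report a pair when `min(pvalue_ref, pvalue_alt)` is at
#'   most this. Default 1e-4.
#' @param strong_cut `|effect_size|` at or above which the effect is classed
#'   `"strong"` rather than `"weak"`. Default 0.4.
#' @param floor Zero-probability floor for log-odds scores. Default 1e-6.
#' @param granularity Score-distribution lattice spacing (see
#'   [score_distribution()]).
#' @param max_n_frac Maximum tolerated fraction of N bases in a window.
#' @return A tibble of class `motif_breakage`, ordered by variant input
#'   order then `motif_id`, with one row per reported variant x motif pair:
#'   variant fields, motif identity, reported `strand`, raw and normalized
#'   scores and p-values for both alleles, `effect_size`, `effect_class`,
#'   the genomic span of the reference-side best match
#'   (`ref_start1`/`ref_end1`), indel-relative coordinates of the
#'   alternate-side best match (`rel_start`/`rel_end`, NA for SNVs), and the
#'   matched sequences with their per-allele strands.
#' @export
analyze_variants <- function(variants, motifs, genome, bg = uniform_bg(),
                             p_threshold = 1e-4, strong_cut = 0.4,
                             floor = 1e-6, granularity = NULL,
                             max_n_frac = 0.2) {
  bg <- validate_bg(bg)
  if (p_threshold <= 0 || p_threshold >= 1) rlang::abort("`p_threshold` must lie in (0, 1).")
  if (strong_cut <= 0 || strong_cut >= 1) rlang::abort("`strong_cut` must lie in (0, 1).")
  motifs <- motifs[order(motifs$motif_id), ]
  engines <- purrr::pmap(
    motifs[, c("motif_id", "tf_name", "ppm")],
    function(motif_id, tf_name, ppm) {
      sm <- score_matrix(ppm, bg = bg, floor = floor,
                         motif_id = motif_id, tf_name = tf_name)
      list(
        sm = sm,
        dists = list(
          "+" = score_distribution(sm, granularity = granularity),
          "-" = score_distribution(reverse_complement(sm), granularity = granularity)
        )
      )
    }
  )
  skips <- list()
  rows <- list()
  n_pairs <- 0L
  for (vi in seq_len(nrow(variants))) {
    v <- variants[vi, ]
    failed <- FALSE
    for (eng in engines) {
      sm <- eng$sm
      k <- sm$width
      w <- tryCatch(
        build_window(genome, v$chrom, v$pos1, v$ref, v$alt, k, var_id = v$var_id),
        error = function(e) e
      )
      if (inherits(w, "error")) {
        reason <- if (inherits(w, "motifdisrupt_missing_contig")) "missing_contig"
                  else if (inherits(w, "motifdisrupt_ref_mismatch")) "ref_mismatch"
                  else "window_error"
        rlang::warn(paste0("skipping variant ", v$var_id, ": ", conditionMessage(w)))
        skips[[length(skips) + 1L]] <- tibble::tibble(
          var_id = v$var_id, chrom = v$chrom, reason = reason,
          detail = conditionMessage(w)
        )
        failed <- TRUE
        break
      }
      if (nchar(w$ref_seq) < k || nchar(w$alt_seq) < k) {
        skips[[length(skips) + 1L]] <- tibble::tibble(
          var_id = v$var_id, chrom = v$chrom, reason = "window_too_short",
          detail = paste0("window shorter than motif ", sm$motif_id)
        )
        next
      }
      if (n_fraction(w$ref_seq) > max_n_frac || n_fraction(w$alt_seq) > max_n_frac) {
        rlang::warn(paste0(
          "skipping variant ", v$var_id, " x motif ", sm$motif_id,
          ": window exceeds ", max_n_frac * 100, "% N bases"
        ))
        skips[[length(skips) + 1L]] <- tibble::tibble(
          var_id = v$var_id, chrom = v$chrom, reason = "ambiguous_window",
          detail = sm$motif_id
        )
        next
      }
      n_pairs <- n_pairs + 1L
      bm_ref <- best_match(sm, w$ref_seq, dists = eng$dists)
      bm_alt <- best_match(sm, w$alt_seq, dists = eng$dists)
      if (min(bm_ref$pvalue, bm_alt$pvalue) > p_threshold) next
      effect <- bm_ref$norm_score - bm_alt$norm_score
      strand <- if (bm_ref$pvalue > p_threshold && bm_alt$pvalue <= p_threshold) {
        bm_alt$strand
      } else {
        bm_ref$strand
      }
      span <- genomic_span(bm_ref$position, k, w)
      rel <- if (v$var_class == "snv") c(NA_integer_, NA_integer_) else {
        relative_coords(bm_alt$position, k, w, v$var_class)
      }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        var_id = v$var_id, chrom = v$chrom, pos1 = v$pos1,
        ref = v$ref, alt = v$alt, var_class = v$var_class,
        motif_id = sm$motif_id, tf_name = sm$tf_name, strand = strand,
        raw_ref = bm_ref$raw_score, raw_alt = bm_alt$raw_score,
        score_ref = bm_ref$norm_score, score_alt = bm_alt$norm_score,
        pvalue_ref = bm_ref$pvalue, pvalue_alt = bm_alt$pvalue,
        effect_size = effect,
        effect_class = if (abs(effect) >= strong_cut) "strong" else "weak",
        ref_start1 = span[1], ref_end1 = span[2],
        rel_start = as.integer(rel[1]), rel_end = as.integer(rel[2]),
        matched_ref_seq = bm_ref$matched_seq, matched_alt_seq = bm_alt$matched_seq,
        strand_ref = bm_ref$strand, strand_alt = bm_alt$strand
      )
    }
    if (failed) next
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    out <- tibble::tibble(
      var_id = character(), chrom = character(), pos1 = integer(),
      ref = character(), alt = character(), var_class = character(),
      motif_id = character(), tf_name = character(), strand = character(),
      raw_ref = numeric(), raw_alt = numeric(),
      score_ref = numeric(), score_alt = numeric(),
      pvalue_ref = numeric(), pvalue_alt = numeric(),
      effect_size = numeric(), effect_class = character(),
      ref_start1 = integer(), ref_end1 = integer(),
      rel_start = integer(), rel_end = integer(),
      matched_ref_seq = character(), matched_alt_seq = character(),
      strand_ref = character(), strand_alt = character()
    )
  }
  attr(out, "stats") <- list(
    n_variants = nrow(variants),
    n_pairs_scored = n_pairs,
    n_emitted = nrow(out),
    p_threshold = p_threshold,
    strong_cut = strong_cut,
    skipped = if (length(skips)) dplyr::bind_rows(skips) else tibble::tibble(
      var_id = character(), chrom = character(), reason = character(),
      detail = character()
    )
  )
  class(out) <- c("motif_breakage", class(out))
  out
}
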