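# Columns serialized to the analyst table, in order. Numeric columns are
# written with fixed 6-decimal formatting for reproducible diffs.
TABLE_NUMERIC <- c("raw_ref", "raw_alt", "score_ref", "score_alt",
                   "pvalue_ref", "pvalue_alt", "effect_size")

flatten_results <- function(results) {
  out <- tibble::as_tibble(results)
  out$rel_coord <- ifelse(
    is.na(out$rel_start), "",
    paste0(out$rel_start, ",", out$rel_end)
  )
  out$rel_start <- NULL
  out$rel_end <- NULL
  for (col in c("peak_match_level", "peak_biotypes")) {
    if (!col %in% names(out)) out[[col]] <- ""
  }
  if (!"peak_n" %in% names(out)) out$peak_n <- 0L
  for (col in intersect(TABLE_NUMERIC, names(out))) {
    out[[col]] <- sprintf("%.6f", out[[col]])
  }
  out
}

#' Write breakage results as a TSV/CSV table
#'
#' One row per result with all fields flattened: indel-relative coordinates
#' as `start,end` in a `rel_coord` column, peak annotation as match level,
#' peak count and semicolon-joined biotypes. Numeric fields use fixed
#' 6-decimal formatting. Lines starting `#` before the header carry optional
#' run parameters and are skipped by [read_results_table()].
#'
#' @param results A `motif_breakage` tibble (peak columns optional).
#' @param path Output path.
#' @param format `"tsv"` (default) or `"csv"`.
#' @param params Optional named list echoed as `# key: value` header
#'   comment lines.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(results, path, format = c("tsv", "csv"),
                                params = NULL) {
  format <- rlang::arg_match(format)
  flat <- flatten_results(results)
  con <- file(path, open = "wt")
  if (!is.null(params)) {
    writeLines(sprintf("# %s: %s", names(params),
                       vapply(params, function(x) paste(format(x), collapse = ","), character(1))),
               con)
  }
  close(con)
  if (format == "tsv") {
    readr::write_tsv(flat, path, append = !is.null(params), col_names = TRUE,
                     progress = FALSE)
  } else {
    readr::write_csv(flat, path, append = !is.null(params), col_names = TRUE,
                     progress = FALSE)
  }
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#'
#' @param path Path to the table.
#' @param format `"tsv"` or `"csv"`; default guessed from the extension.
#' @return A tibble with numeric columns re-parsed as numbers.
#' @export
read_results_table <- function(path, format = NULL) {
  format <- format %||% (if (grepl("\\.csv$", path)) "csv" else "tsv")
  reader <- if (format == "csv") readr::read_csv else readr::read_tsv
  reader(path, comment = "#", show_col_types = FALSE, progress = FALSE)
}

# Greyscale ramp: intensity 0 -> (224,224,224), 1000 -> (0,0,0); darker =
# stronger.
grey_ramp <- function(score1000) {
  v <- round(224 * (1 - score1000 / 1000))
  sprintf("%d,%d,%d", v, v, v)
}

bed_score <- function(results, color_by, p_threshold) {
  s <- if (color_by == "score") {
    round(1000 * abs(results$effect_size))
  } else {
    pmin_val <- pmin(results$pvalue_ref, results$pvalue_alt)
    round(1000 * (1 - pmin_val / p_threshold))
  }
  pmax(0L, pmin(1000L, as.integer(s)))
}

#' Write breakage results as a color-coded BED9 browser track
#'
#' Emits one BED9 feature per result whose reference-allele best match
#' passes the p-value threshold, spanning the reference-side motif match;
#' the feature name is `varid|motif_id|tf`. The display score is
#' `round(1000 * |effect_size|)` when coloring by score, or
#' `round(1000 * (1 - pvalue_min / p_threshold))` when coloring by p-value,
#' and itemRgb follows a greyscale ramp from (224,224,224) at 0 to (0,0,0)
#' at 1000 — darker means stronger. Results that pass only on the alternate
#' allele (motifs created by indels, which have no reference-genome
#' coordinates) are routed to a companion table with their indel-relative
#' coordinates serialized as `start,end`.
#'
#' @param results A `motif_breakage` tibble.
#' @param path Output BED path.
#' @param color_by `"score"` (default) or `"pvalue"`.
#' @param top_n Optional: keep only the top n rows by `sort_key`.
#' @param sort_key `"effect_size"` (descending `|effect_size|`) or
#'   `"pvalue_min"` (ascending).
#' @param p_threshold Reporting threshold used for the p-value ramp and for
#'   deciding which side passed. Default 1e-4.
#' @param alt_path Path of the companion table for alternate-only results;
#'   default `paste0(path, ".alt_only.tsv")`.
#' @return `path`, invisibly.
#' @export
write_results_bed <- function(results, path, color_by = c("score", "pvalue"),
                              top_n = NULL, sort_key = c("effect_size", "pvalue_min"),
                              p_threshold = 1e-4,
                              alt_path = paste0(path, ".alt_only.tsv")) {
  color_by <- rlang::arg_match(color_by)
  sort_key <- rlang::arg_match(sort_key)
  if (!is.null(top_n) && top_n <= 0) rlang::abort("`top_n` must be > 0 when given.")
  addressable <- results$pvalue_ref <= p_threshold
  alt_only <- results[!addressable, ]
  emit <- results[addressable, ]
  if (nrow(alt_only) > 0L) {
    write_results_table(alt_only, alt_path)
  }
  emit <- switch(sort_key,
    effect_size = emit[order(-abs(emit$effect_size)), ],
    pvalue_min = emit[order(pmin(emit$pvalue_ref, emit$pvalue_alt)), ]
  )
  if (!is.null(top_n)) emit <- utils::head(emit, top_n)
  score <- bed_score(emit, color_by, p_threshold)
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t%s",
    emit$chrom,
    emit$ref_start1 - 1L, emit$ref_end1,
    paste(emit$var_id, emit$motif_id, emit$tf_name, sep = "|"),
    score, emit$strand,
    emit$ref_start1 - 1L, emit$ref_start1 - 1L,
    grey_ramp(score)
  )
  writeLines(lines, path)
  invisible(path)
}
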