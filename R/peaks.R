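# Split a ReMap-style dotted name field `EXPERIMENT.TF.BIOTYPE` with a
# right-anchored rule: last field = biotype, second-to-last = TF, everything
# before (which may itself contain dots) = experiment. Names with fewer than
# three fields are kept with tf = whole name and empty biotype.
parse_peak_name <- function(name) {
  parts <- strsplit(name, ".", fixed = TRUE)
  purrr::map2_dfr(parts, name, function(p, raw) {
    n <- length(p)
    if (n >= 3L) {
      tibble::tibble(
        experiment = paste(p[1:(n - 2L)], collapse = "."),
        tf = p[n - 1L], biotype = p[n], malformed = FALSE
      )
    } else {
      tibble::tibble(experiment = "", tf = raw, biotype = "", malformed = TRUE)
    }
  })
}

#' Build a local TF ChIP-seq peak database from a BED file
#'
#' Reads a BED4+ peaks file whose name field follows the ReMap
#' non-redundant-peaks dialect `EXPERIMENT.TF.BIOTYPE` and builds an
#' interval-indexed database for overlap queries. Malformed name fields are
#' logged and the record kept with the whole name as the TF and an empty
#' biotype. With `cache = TRUE` the built index is serialized next to the
#' source file, keyed by its md5 checksum, and reused on later builds.
#'
#' @param bed_path Path to the BED file (0-based half-open, >= 4 columns).
#' @param cache Write/reuse a `<bed_path>.peakdb.rds` sidecar. Default
#'   FALSE.
#' @return An object of class `peak_db`: list with `peaks` (tibble with
#'   `chrom`, `start0`, `end0`, `experiment`, `tf`, `biotype`), `gr` (the
#'   `GRanges` interval index), `source`, and `n`.
#' @export
build_peak_db <- function(bed_path, cache = FALSE) {
  if (!file.exists(bed_path)) rlang::abort(paste0("peaks BED not found: ", bed_path))
  sidecar <- paste0(bed_path, ".peakdb.rds")
  checksum <- unname(tools::md5sum(bed_path))
  if (cache && file.exists(sidecar)) {
    db <- readRDS(sidecar)
    if (identical(db$checksum, checksum)) return(db)
  }
  raw <- readr::read_tsv(
    bed_path,
    col_names = FALSE, comment = "#",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  )
  if (nrow(raw) > 0L && ncol(raw) < 4L) {
    rlang::abort(paste0(bed_path, ": peaks BED needs >= 4 columns (chrom, start, end, name)."))
  }
  peaks <- if (nrow(raw) == 0L) {
    tibble::tibble(
      chrom = character(), start0 = integer(), end0 = integer(),
      experiment = character(), tf = character(), biotype = character()
    )
  } else {
    parsed <- parse_peak_name(raw[[4]])
    if (any(parsed$malformed)) {
      rlang::warn(paste0(
        sum(parsed$malformed), " peak name(s) not in EXPERIMENT.TF.BIOTYPE form; ",
        "kept with tf = whole name."
      ))
    }
    tibble::tibble(
      chrom = raw[[1]],
      start0 = as.integer(raw[[2]]),
      end0 = as.integer(raw[[3]]),
      experiment = parsed$experiment,
      tf = parsed$tf,
      biotype = parsed$biotype
    )
  }
  if (any(peaks$start0 >= peaks$end0)) {
    rlang::abort(paste0(bed_path, ": peak intervals must satisfy start < end."))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = peaks$chrom,
    ranges = IRanges::IRanges(start = peaks$start0 + 1L, end = peaks$end0)
  )
  db <- structure(
    list(peaks = peaks, gr = gr, source = bed_path, n = nrow(peaks),
         checksum = checksum),
    class = "peak_db"
  )
  if (cache) saveRDS(db, sidecar)
  db
}

#' @export
print.peak_db <- function(x, ...) {
  cat(sprintf("<peak_db> %d peaks from %s (%d TFs)\n",
              x$n, x$source, dplyr::n_distinct(x$peaks$tf)))
  invisible(x)
}

#' Read a TF family map
#'
#' Two-column tab-separated text: a TF name, then a comma-separated list of
#' the TF names in its family. Lookup of a TF absent from the map yields the
#' singleton set containing itself.
#'
#' @param path Path to the family map file.
#' @return A named list of character vectors (names uppercased).
#' @export
read_family_map <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("family map not found: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(stringr::str_trim(lines)) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 2L)
  if (length(bad)) {
    rlang::abort(paste0(path, ": line(s) ", paste(bad, collapse = ", "),
                        " lack the two tab-separated columns TF<TAB>members."))
  }
  fam <- lapply(fields, function(f) toupper(stringr::str_trim(strsplit(f[2], ",")[[1]])))
  names(fam) <- toupper(vapply(fields, `[[`, character(1), 1))
  fam
}

family_members <- function(fam, tf) {
  key <- toupper(tf)
  if (!is.null(fam) && key %in% names(fam)) fam[[key]] else key
}

#' Query peaks overlapping an interval for a given TF
#'
#' Finds database peaks overlapping the 0-based half-open query interval.
#' Peaks whose TF equals the query TF (case-insensitive) are direct matches;
#' when there are none and a family map is supplied, peaks of any TF in the
#' query TF's family are family matches. Direct matches always take
#' precedence.
#'
#' @param db A [build_peak_db()] database.
#' @param chrom Chromosome of the query.
#' @param start0,end0 0-based half-open query interval.
#' @param tf TF name to match.
#' @param fam Optional family map from [read_family_map()].
#' @return A list: `peaks` (tibble of supporting peaks), `match_level` (one
#'   of `"direct"`, `"family"`, `"none"`), `biotypes` (de-duplicated, sorted
#'   biotypes of the supporting peaks).
#' @export
query_peaks <- function(db, chrom, start0, end0, tf, fam = NULL) {
  if (end0 < start0) rlang::abort("query interval must satisfy start0 <= end0.")
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start = start0 + 1L, end = end0))
  hits <- suppressWarnings(GenomicRanges::findOverlaps(q, db$gr))
  idx <- S4Vectors::subjectHits(hits)
  overlapping <- db$peaks[idx, ]
  direct <- overlapping[toupper(overlapping$tf) == toupper(tf), ]
  if (nrow(direct) > 0L) {
    support <- direct
    level <- "direct"
  } else if (!is.null(fam)) {
    members <- family_members(fam, tf)
    famhits <- overlapping[toupper(overlapping$tf) %in% members, ]
    if (nrow(famhits) > 0L) {
      support <- famhits
      level <- "family"
    } else {
      support <- overlapping[0, ]
      level <- "none"
    }
  } else {
    support <- overlapping[0, ]
    level <- "none"
  }
  list(
    peaks = support,
    match_level = level,
    biotypes = sort(unique(support$biotype[nzchar(support$biotype)]))
  )
}

# 0-based half-open reference footprint of a variant: its deleted/substituted
# bases, or for a pure insertion the two flanking bases around the insertion
# point.
variant_footprint0 <- function(pos1, ref) {
  ref_len <- nchar(ref)
  if (ref_len > 0L) {
    c(pos1 - 1L, pos1 - 1L + ref_len)
  } else {
    c(max(pos1 - 2L, 0L), pos1)
  }
}

#' Attach ChIP-seq peak evidence to breakage results
#'
#' Annotates each result with the peaks of the matching TF (directly or via
#' the TF family) that overlap the variant's reference-genome footprint —
#' evidence that the TF in question binds over the disrupting variant. For
#' pure insertions the zero-length insertion point is expanded to the two
#' flanking bases. With `query_by = "motif"` the reference-side motif match
#' interval is queried instead.
#'
#' @param results A `motif_breakage` tibble from [analyze_variants()].
#' @param db A [build_peak_db()] database.
#' @param fam Optional family map from [read_family_map()].
#' @param query_by Query the `"variant"` footprint (default) or the
#'   `"motif"` match interval.
#' @return `results` with three added columns: `peak_match_level`, `peak_n`
#'   (number of supporting peaks), and `peak_biotypes` (semicolon-joined,
#'   de-duplicated, sorted). Input order is preserved.
#' @export
attach_peak_evidence <- function(results, db, fam = NULL,
                                 query_by = c("variant", "motif")) {
  query_by <- rlang::arg_match(query_by)
  if (nrow(results) == 0L) {
    results$peak_match_level <- character()
    results$peak_n <- integer()
    results$peak_biotypes <- character()
    return(results)
  }
  ann <- purrr::map(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    iv <- if (query_by == "variant") {
      variant_footprint0(r$pos1, r$ref)
    } else {
      c(r$ref_start1 - 1L, r$ref_end1)
    }
    query_peaks(db, r$chrom, iv[1], iv[2], r$tf_name, fam = fam)
  })
  results$peak_match_level <- vapply(ann, `[[`, character(1), "match_level")
  results$peak_n <- vapply(ann, function(a) nrow(a$peaks), integer(1))
  results$peak_biotypes <- vapply(
    ann, function(a) paste(a$biotypes, collapse = ";"), character(1)
  )
  results
}
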