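#' Convert base counts to a position probability matrix
#'
#' Applies per-column pseudocount smoothing: the total pseudocount is split
#' equally over the four bases and added per column, so entry (b, j) becomes
#' (count + pseudocount/4) / (column_total + pseudocount). With pseudocount 0
#' the result is the plain column proportions.
#'
#' @param counts Numeric 4 x k matrix of non-negative base counts, rows in
#'   A, C, G, T order (row names optional).
#' @param pseudocount Non-negative total pseudocount per column. Default 0.8.
#' @return A 4 x k position probability matrix with rows named A, C, G, T;
#'   every column sums to 1.
#' @export
#' @examples
#' normalize_counts(matrix(c(8, 0, 0, 0), nrow = 4), pseudocount = 0.8)
normalize_counts <- function(counts, pseudocount = 0.8) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) {
    rlang::abort("`counts` must have 4 rows (A, C, G, T).")
  }
  if (any(counts < 0) || anyNA(counts)) {
    rlang::abort("`counts` must be non-negative and free of missing values.")
  }
  if (length(pseudocount) != 1L || pseudocount < 0) {
    rlang::abort("`pseudocount` must be a single non-negative number.")
  }
  totals <- colSums(counts) + pseudocount
  if (any(totals <= 0)) {
    rlang::abort("every column must have a positive total after adding the pseudocount.")
  }
  ppm <- sweep(counts + pseudocount / 4, 2, totals, "/")
  rownames(ppm) <- DNA_BASES
  validate_ppm(ppm)
  ppm
}

#' Validate a position probability matrix
#'
#' Checks the invariants of a PPM: 4 rows (A, C, G, T), width >= 1, all
#' entries in \[0, 1\], and every column summing to 1 within 1e-9.
#'
#' @param ppm Numeric 4 x k matrix.
#' @return The validated matrix, invisibly, with rows named A, C, G, T.
#' @export
validate_ppm <- function(ppm) {
  if (!is.matrix(ppm) || nrow(ppm) != 4L || ncol(ppm) < 1L) {
    rlang::abort("a PPM must be a 4-row matrix with at least one column.")
  }
  if (anyNA(ppm) || any(ppm < 0) || any(ppm > 1)) {
    rlang::abort("PPM entries must be probabilities in [0, 1].")
  }
  bad <- which(abs(colSums(ppm) - 1) > 1e-9)
  if (length(bad)) {
    rlang::abort(paste0(
      "PPM columns must sum to 1 (within 1e-9); offending column(s): ",
      paste(bad, collapse = ", ")
    ))
  }
  rownames(ppm) <- DNA_BASES
  invisible(ppm)
}

new_motif_library <- function(tbl, source = NA_character_) {
  if (anyDuplicated(tbl$motif_id)) {
    dup <- unique(tbl$motif_id[duplicated(tbl$motif_id)])
    rlang::abort(paste0("duplicate motif_id in library: ", paste(dup, collapse = ", ")))
  }
  attr(tbl, "source") <- source
  class(tbl) <- c("motif_library", class(tbl))
  tbl
}

#' Read a motif library from MEME minimal or JASPAR PFM text
#'
#' Loads one or more motifs into a tibble with one row per motif and the
#' probability matrix held in a list-column. JASPAR files carry counts, which
#' are smoothed with [normalize_counts()]; MEME minimal files already carry
#' probabilities and are validated as-is. The TF name falls back to the motif
#' id when the file does not provide one.
#'
#' @param path Path to the motif file.
#' @param format `"meme"`, `"jaspar"`, or `"auto"` (detected from the first
#'   non-blank line).
#' @param pseudocount Total pseudocount used when converting JASPAR counts;
#'   ignored for MEME input. Default 0.8.
#' @return A tibble of class `motif_library` with columns `motif_id`,
#'   `tf_name`, `width`, and `ppm` (list of 4 x k matrices).
#' @export
read_motifs <- function(path, format = c("auto", "meme", "jaspar"), pseudocount = 0.8) {
  format <- rlang::arg_match(format)
  if (!file.exists(path)) {
    rlang::abort(paste0("motif file not found: ", path))
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "auto") {
    first <- stringr::str_trim(lines[nzchar(stringr::str_trim(lines))][1])
    format <- if (is.na(first)) {
      rlang::abort(paste0("empty motif file: ", path))
    } else if (startsWith(first, "MEME version")) "meme" else "jaspar"
  }
  tbl <- switch(format,
    meme = parse_meme(lines, path),
    jaspar = parse_jaspar(lines, path, pseudocount)
  )
  if (nrow(tbl) == 0L) {
    rlang::abort(paste0("no motifs found in ", path))
  }
  for (p in tbl$ppm) validate_ppm(p)
  new_motif_library(tbl, source = path)
}

parse_meme <- function(lines, path) {
  trimmed <- stringr::str_trim(lines)
  if (!any(startsWith(trimmed, "MEME version"))) {
    rlang::abort(paste0(path, ": not a MEME minimal file (missing 'MEME version' header, line 1)"))
  }
  motif_idx <- which(startsWith(trimmed, "MOTIF"))
  out <- vector("list", length(motif_idx))
  for (i in seq_along(motif_idx)) {
    at <- motif_idx[i]
    toks <- strsplit(trimmed[at], "\\s+")[[1]]
    motif_id <- if (length(toks) >= 2) toks[2] else rlang::abort(
      paste0(path, ": MOTIF line ", at, " carries no identifier")
    )
    tf_name <- if (length(toks) >= 3) toks[3] else motif_id
    stop_at <- if (i < length(motif_idx)) motif_idx[i + 1] - 1L else length(trimmed)
    mat_at <- at + which(startsWith(trimmed[(at + 1):stop_at], "letter-probability matrix"))[1]
    if (is.na(mat_at)) {
      rlang::abort(paste0(path, ": motif ", motif_id, " has no 'letter-probability matrix:' block"))
    }
    w <- stringr::str_match(trimmed[mat_at], "w=\\s*(\\d+)")[, 2]
    rows <- list()
    j <- mat_at + 1L
    while (j <= stop_at) {
      line <- trimmed[j]
      if (!nzchar(line)) {
        if (length(rows)) break else { j <- j + 1L; next }
      }
      vals <- suppressWarnings(as.numeric(strsplit(line, "\\s+")[[1]]))
      if (anyNA(vals)) break
      if (length(vals) != 4L) {
        rlang::abort(paste0(path, ": line ", j, ": expected 4 probabilities, got ", length(vals)))
      }
      if (abs(sum(vals) - 1) > 1e-4) {
        rlang::abort(paste0(path, ": line ", j, ": probabilities sum to ", sum(vals), ", not 1"))
      }
      rows[[length(rows) + 1L]] <- vals / sum(vals) # absorb printed rounding
      j <- j + 1L
    }
    if (!is.na(w) && length(rows) != as.integer(w)) {
      rlang::abort(paste0(
        path, ": motif ", motif_id, " declares w=", w,
        " but has ", length(rows), " matrix rows (line ", mat_at, ")"
      ))
    }
    if (!length(rows)) {
      rlang::abort(paste0(path, ": motif ", motif_id, " has an empty probability matrix"))
    }
    ppm <- t(do.call(rbind, rows))
    rownames(ppm) <- DNA_BASES
    out[[i]] <- tibble::tibble(
      motif_id = motif_id, tf_name = tf_name,
      width = ncol(ppm), ppm = list(ppm)
    )
  }
  dplyr::bind_rows(out)
}

parse_jaspar <- function(lines, path, pseudocount) {
  trimmed <- stringr::str_trim(lines)
  hdr_idx <- which(startsWith(trimmed, ">"))
  if (!length(hdr_idx)) {
    rlang::abort(paste0(path, ": not a JASPAR PFM file (no '>' header line)"))
  }
  out <- vector("list", length(hdr_idx))
  for (i in seq_along(hdr_idx)) {
    at <- hdr_idx[i]
    toks <- strsplit(sub("^>\\s*", "", trimmed[at]), "\\s+")[[1]]
    motif_id <- toks[1]
    tf_name <- if (length(toks) >= 2) toks[2] else motif_id
    stop_at <- if (i < length(hdr_idx)) hdr_idx[i + 1] - 1L else length(trimmed)
    block <- trimmed[(at + 1):stop_at]
    block <- block[nzchar(block)]
    rows <- stats::setNames(vector("list", 4), DNA_BASES)
    for (line in block) {
      base <- toupper(substr(line, 1, 1))
      body <- line
      if (base %in% DNA_BASES) body <- sub("^[ACGTacgt]\\s*", "", line)
      body <- gsub("\\[|\\]", " ", body)
      vals <- suppressWarnings(as.numeric(strsplit(stringr::str_trim(body), "\\s+")[[1]]))
      if (anyNA(vals) || !length(vals)) {
        rlang::abort(paste0(path, ": cannot parse count row near motif ", motif_id, ": '", line, "'"))
      }
      if (base %in% DNA_BASES) {
        rows[[base]] <- vals
      } else {
        slot <- DNA_BASES[which(vapply(rows, is.null, logical(1)))[1]]
        rows[[slot]] <- vals
      }
    }
    if (any(vapply(rows, is.null, logical(1)))) {
      rlang::abort(paste0(path, ": motif ", motif_id, " is missing one or more of the 4 base rows"))
    }
    widths <- lengths(rows)
    if (length(unique(widths)) != 1L) {
      rlang::abort(paste0(path, ": motif ", motif_id, " has ragged count rows"))
    }
    counts <- do.call(rbind, rows)
    ppm <- normalize_counts(counts, pseudocount = pseudocount)
    out[[i]] <- tibble::tibble(
      motif_id = motif_id, tf_name = tf_name,
      width = ncol(ppm), ppm = list(ppm)
    )
  }
  dplyr::bind_rows(out)
}

#' Write a motif library as MEME minimal text
#'
#' @param motifs A `motif_library` tibble from [read_motifs()] or
#'   [as_motif_library()].
#' @param path Output file path.
#' @param bg Background model written into the header. Default uniform.
#' @return `path`, invisibly.
#' @export
write_motifs_meme <- function(motifs, path, bg = uniform_bg()) {
  bg <- validate_bg(bg)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "MEME version 4", "",
    "ALPHABET= ACGT", "",
    "strands: + -", "",
    "Background letter frequencies",
    paste(sprintf("%s %.6f", DNA_BASES, bg), collapse = " "),
    ""
  ), con)
  for (i in seq_len(nrow(motifs))) {
    ppm <- motifs$ppm[[i]]
    writeLines(paste("MOTIF", motifs$motif_id[i], motifs$tf_name[i]), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0", ncol(ppm)), con)
    for (j in seq_len(ncol(ppm))) {
      writeLines(paste(sprintf("%.8f", ppm[, j]), collapse = " "), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Build a motif library tibble from a list of matrices
#'
#' @param ppms Named list of 4 x k probability matrices; names become motif
#'   ids.
#' @param tf_names Optional character vector of TF names (recycled from the
#'   motif ids when absent).
#' @return A `motif_library` tibble.
#' @export
as_motif_library <- function(ppms, tf_names = NULL) {
  if (is.null(names(ppms)) || any(!nzchar(names(ppms)))) {
    rlang::abort("`ppms` must be a fully named list; names become motif ids.")
  }
  tf_names <- tf_names %||% names(ppms)
  ppms <- lapply(ppms, function(p) { validate_ppm(p); rownames(p) <- DNA_BASES; p })
  new_motif_library(tibble::tibble(
    motif_id = names(ppms),
    tf_name = tf_names,
    width = vapply(ppms, ncol, integer(1)),
    ppm = unname(ppms)
  ))
}

#' Log-odds score matrix for a motif
#'
#' Converts a position probability matrix into per-position log2-odds scores
#' against a background model: score(b, j) = log2(max(p(b, j), floor) /
#' bg(b)). The floor replaces zero probabilities so that no k-mer scores
#' negative infinity; this matters for junction sequences created by indels.
#'
#' @param ppm 4 x k position probability matrix (rows A, C, G, T).
#' @param bg Background base frequencies. Default uniform.
#' @param floor Small positive probability substituted for entries below it
#'   before the log. Default 1e-6.
#' @param motif_id,tf_name Identity metadata carried into results.
#' @return An object of class `score_matrix`: a list with elements `scores`
#'   (4 x k), `s_min`/`s_max` (sums of per-column minima/maxima), `width`,
#'   `bg`, `floor`, and the identity fields.
#' @export
score_matrix <- function(ppm, bg = uniform_bg(), floor = 1e-6,
                         motif_id = "motif", tf_name = motif_id) {
  validate_ppm(ppm)
  bg <- validate_bg(bg)
  if (length(floor) != 1L || floor <= 0) {
    rlang::abort("`floor` must be a single positive probability.")
  }
  scores <- log2(pmax(ppm, floor) / bg)
  rownames(scores) <- DNA_BASES
  structure(
    list(
      motif_id = motif_id, tf_name = tf_name, width = ncol(scores),
      scores = scores,
      s_min = sum(apply(scores, 2, min)),
      s_max = sum(apply(scores, 2, max)),
      bg = bg, floor = floor
    ),
    class = "score_matrix"
  )
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf(
    "<score_matrix> %s (TF %s), width %d, score range [%.4f, %.4f]\n",
    x$motif_id, x$tf_name, x$width, x$s_min, x$s_max
  ))
  invisible(x)
}

#' Reverse complement of a motif
#'
#' Reverses the column order and swaps the A/T and C/G rows, producing the
#' motif as read on the opposite strand. Applying it twice returns the
#' original object.
#'
#' @param x A 4 x k probability matrix or a `score_matrix`.
#' @return An object of the same type as `x`.
#' @export
reverse_complement <- function(x) UseMethod("reverse_complement")

rc_matrix <- function(m) {
  out <- m[c("T", "G", "C", "A"), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' @export
reverse_complement.matrix <- function(x) {
  validate_ppm(x)
  rc_matrix(x)
}

#' @export
reverse_complement.score_matrix <- function(x) {
  x$scores <- rc_matrix(x$scores)
  x
}
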