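#' Read a genome from FASTA
#'
#' Loads a (plain or indexed) FASTA file as a `DNAStringSet`, keeping only
#' the first whitespace-separated token of each header as the contig name.
#' Soft-masked lowercase bases are uppercased so that masking does not leak
#' into scoring.
#'
#' @param path Path to a FASTA file.
#' @return A named `Biostrings::DNAStringSet`.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) rlang::abort(paste0("genome FASTA not found: ", path))
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  Biostrings::DNAStringSet(toupper(g))
}

# Build the paired ref/alt window for one variant and one motif width.
# Flanks are exactly k - 1 bases so that the scan covers precisely every
# motif placement overlapping the variant; truncated (never N-padded) at
# contig edges. Spans are 1-based inclusive indices into the respective
# sequence; an empty allele is marked by hi = lo - 1.
build_window <- function(genome, chrom, pos1, ref, alt, k, var_id = NA_character_) {
  if (!chrom %in% names(genome)) {
    rlang::abort(
      paste0("contig '", chrom, "' not found in genome (variant ", var_id, ")"),
      class = "motifdisrupt_missing_contig"
    )
  }
  contig <- genome[[chrom]]
  clen <- length(contig)
  ref_len <- nchar(ref)
  if (pos1 < 1L || pos1 + max(ref_len - 1L, 0L) > clen) {
    rlang::abort(
      paste0("variant ", var_id, " span lies outside contig ", chrom),
      class = "motifdisrupt_missing_contig"
    )
  }
  left_start <- max(1L, pos1 - (k - 1L))
  right_end <- min(clen, pos1 + ref_len + k - 2L)
  left <- if (pos1 > left_start) {
    as.character(Biostrings::subseq(contig, left_start, pos1 - 1L))
  } else ""
  genome_ref <- if (ref_len > 0L) {
    as.character(Biostrings::subseq(contig, pos1, pos1 + ref_len - 1L))
  } else ""
  if (ref_len > 0L && genome_ref != toupper(ref)) {
    rlang::abort(
      paste0(
        "reference allele of variant ", var_id, " ('", ref,
        "') does not match the genome at ", chrom, ":", pos1, " ('", genome_ref, "')"
      ),
      class = "motifdisrupt_ref_mismatch"
    )
  }
  right <- if (right_end >= pos1 + ref_len) {
    as.character(Biostrings::subseq(contig, pos1 + ref_len, right_end))
  } else ""
  left_len <- nchar(left)
  tibble::tibble(
    var_id = var_id, chrom = chrom,
    window_start1 = left_start,
    ref_seq = paste0(left, genome_ref, right),
    alt_seq = paste0(left, toupper(alt), right),
    ref_span_lo = left_len + 1L, ref_span_hi = left_len + ref_len,
    alt_span_lo = left_len + 1L, alt_span_hi = left_len + nchar(alt),
    k = as.integer(k)
  )
}

#' Build ref/alt allele windows around variants
#'
#' For each variant, extracts the reference sequence with `k - 1` flanking
#' bases on each side of the variant span and splices in the alternate
#' allele to form the paired alternate sequence. Every motif placement that
#' overlaps the variant — and no placement that cannot differ between
#' alleles — lies inside the window. Windows are truncated at contig edges.
#'
#' @param variants Variant tibble (see [read_vcf()]).
#' @param genome Genome from [read_genome()].
#' @param k Motif width (integer >= 1).
#' @return A tibble with one row per variant: `var_id`, `chrom`,
#'   `window_start1` (1-based genomic start), `ref_seq`, `alt_seq`, the
#'   1-based inclusive spans of the variant alleles within each sequence
#'   (`*_span_lo`/`*_span_hi`; `hi = lo - 1` marks an empty allele), and
#'   `k`.
#' @export
build_windows <- function(variants, genome, k) {
  if (k < 1L) rlang::abort("`k` must be >= 1.")
  rows <- purrr::pmap(
    variants[, c("chrom", "pos1", "ref", "alt", "var_id")],
    function(chrom, pos1, ref, alt, var_id) {
      build_window(genome, chrom, pos1, ref, alt, k, var_id = var_id)
    }
  )
  dplyr::bind_rows(rows)
}
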