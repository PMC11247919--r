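# Variant classification from trimmed alleles. Total and mutually
# exclusive: snv (1 bp vs 1 bp), insertion (empty ref), deletion (empty
# alt), delins (everything else).
classify_alleles <- function(ref, alt) {
  dplyr::case_when(
    nchar(ref) == 1L & nchar(alt) == 1L ~ "snv",
    nchar(ref) == 0L ~ "insertion",
    nchar(alt) == 0L ~ "deletion",
    .default = "delins"
  )
}

genome_base <- function(genome, chrom, pos) {
  as.character(Biostrings::subseq(genome[[chrom]], pos, pos))
}

#' Trim and normalize one ref/alt allele pair
#'
#' Removes the shared leading bases (advancing the position), then the
#' shared trailing bases. Pure insertions and deletions are then left-aligned
#' against the genome: the indel is shifted upstream while the base preceding
#' it equals its last base, so that identical indels written differently by
#' different sources normalize to the same record. Coordinates are 1-based;
#' an insertion with `pos1 = p` sits between positions `p - 1` and `p`.
#'
#' @param chrom Chromosome name.
#' @param pos1 1-based position of the first reference allele base.
#' @param ref,alt Allele strings (A/C/G/T; `""` allowed after trimming).
#' @param genome Optional genome (a `DNAStringSet` from [read_genome()]);
#'   required for left-alignment, which is skipped when absent.
#' @param var_id Variant identifier carried through.
#' @return A one-row tibble with `chrom`, `pos1`, `ref`, `alt`, `var_id`,
#'   `var_class`, or `NULL` (with a warning) when ref and alt are identical.
#' @export
trim_and_normalize <- function(chrom, pos1, ref, alt, genome = NULL,
                               var_id = NA_character_) {
  ref <- toupper(ref)
  alt <- toupper(alt)
  if (identical(ref, alt)) {
    rlang::warn(paste0("variant ", var_id %||% "", " at ", chrom, ":", pos1,
                       " has identical ref and alt; skipped."))
    return(NULL)
  }
  # shared leading bases
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, 1, 1) == substr(alt, 1, 1)) {
    ref <- substr(ref, 2, nchar(ref))
    alt <- substr(alt, 2, nchar(alt))
    pos1 <- pos1 + 1L
  }
  # shared trailing bases
  while (nchar(ref) > 0L && nchar(alt) > 0L &&
         substr(ref, nchar(ref), nchar(ref)) == substr(alt, nchar(alt), nchar(alt))) {
    ref <- substr(ref, 1, nchar(ref) - 1L)
    alt <- substr(alt, 1, nchar(alt) - 1L)
  }
  if (!nzchar(ref) && !nzchar(alt)) {
    rlang::warn(paste0("variant ", var_id %||% "", " trims to empty/empty; skipped."))
    return(NULL)
  }
  cls <- classify_alleles(ref, alt)
  if (!is.null(genome) && chrom %in% names(genome)) {
    if (cls == "deletion") {
      len <- nchar(ref)
      # only shift when the stated deleted bases actually match the genome
      if (pos1 + len - 1L <= length(genome[[chrom]]) &&
          as.character(Biostrings::subseq(genome[[chrom]], pos1, pos1 + len - 1L)) == ref) {
        while (pos1 > 1L &&
               genome_base(genome, chrom, pos1 - 1L) == substr(ref, len, len)) {
          ref <- paste0(genome_base(genome, chrom, pos1 - 1L), substr(ref, 1, len - 1L))
          pos1 <- pos1 - 1L
        }
      }
    } else if (cls == "insertion") {
      len <- nchar(alt)
      while (pos1 > 1L &&
             genome_base(genome, chrom, pos1 - 1L) == substr(alt, len, len)) {
        alt <- paste0(substr(alt, len, len), substr(alt, 1, len - 1L))
        pos1 <- pos1 - 1L
      }
    }
  }
  tibble::tibble(
    chrom = chrom, pos1 = as.integer(pos1), ref = ref, alt = alt,
    var_id = var_id %||% NA_character_, var_class = cls
  )
}

#' Split multi-allelic records into one record per alternate allele
#'
#' @param records Tibble with columns `chrom`, `pos1`, `ref`, `alt`,
#'   `var_id`; `alt` may hold several comma-separated alleles.
#' @return The expanded tibble, one row per (site, alt allele), in input
#'   order. When a site has more than one alternate allele, each output
#'   `var_id` is suffixed with `:<allele index>`.
#' @export
split_multiallelic <- function(records) {
  alts <- strsplit(records$alt, ",", fixed = TRUE)
  n <- lengths(alts)
  out <- records[rep(seq_len(nrow(records)), n), ]
  out$alt <- unlist(alts)
  idx <- unlist(lapply(n, seq_len))
  multi <- rep(n > 1L, n)
  out$var_id <- ifelse(multi, paste0(out$var_id, ":", idx), out$var_id)
  out
}

# Normalize a tibble of raw (chrom, pos1, ref, alt, var_id) records:
# multi-allelic split, symbolic-allele filtering, trimming, left-alignment,
# classification.
normalize_records <- function(records, genome = NULL) {
  records <- split_multiallelic(records)
  symbolic <- grepl("[<>\\[\\]]", records$alt) | grepl("[<>\\[\\]]", records$ref) |
    grepl("[^ACGTNacgtn]", records$alt) | grepl("[^ACGTNacgtn]", records$ref)
  if (any(symbolic)) {
    rlang::warn(paste0(
      sum(symbolic), " symbolic or non-sequence allele record(s) skipped: ",
      paste(utils::head(records$var_id[symbolic], 5), collapse = ", ")
    ))
    records <- records[!symbolic, ]
  }
  rows <- purrr::pmap(
    records[, c("chrom", "pos1", "ref", "alt", "var_id")],
    function(chrom, pos1, ref, alt, var_id) {
      trim_and_normalize(chrom, pos1, ref, alt, genome = genome, var_id = var_id)
    }
  )
  dplyr::bind_rows(rows)
}

#' Read variants from a VCF file
#'
#' Reads site-level records from a VCF 4.x file, splits multi-allelic sites
#' into one record per alternate allele, trims shared allele bases, and
#' (when a genome is supplied) left-aligns pure indels. Symbolic alleles and
#' breakends are skipped with a warning. Genotype columns are ignored.
#'
#' @param path Path to an (uncompressed or bgzipped) VCF file.
#' @param genome Optional genome from [read_genome()], enabling indel
#'   left-alignment.
#' @return A tibble with columns `chrom`, `pos1`, `ref`, `alt`, `var_id`,
#'   `var_class`.
#' @export
read_vcf <- function(path, genome = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("VCF file not found: ", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) rlang::abort(paste0("cannot parse VCF ", path, ": ", conditionMessage(e)))
  )
  fix <- vcf@fix
  if (is.null(fix) || nrow(fix) == 0L) {
    return(tibble::tibble(
      chrom = character(), pos1 = integer(), ref = character(),
      alt = character(), var_id = character(), var_class = character()
    ))
  }
  records <- tibble::tibble(
    chrom = fix[, "CHROM"],
    pos1 = as.integer(fix[, "POS"]),
    ref = fix[, "REF"],
    alt = fix[, "ALT"],
    var_id = ifelse(is.na(fix[, "ID"]) | fix[, "ID"] == ".",
                    paste0(fix[, "CHROM"], ":", fix[, "POS"]),
                    fix[, "ID"])
  )
  records <- records[!is.na(records$alt) & nzchar(records$alt), ]
  normalize_records(records, genome = genome)
}

#' Read variants from the 5-column BED-derived custom format
#'
#' Each line is `chrom  start0  end0  name  REF/ALT`, tab-separated, with
#' 0-based half-open coordinates; either allele side may be `-` for empty
#' (`-/TTTT` is an insertion between `start0` and `start0 + 1`,
#' `ACGTA/-` a deletion). The interval length must equal the REF length.
#'
#' @inheritParams read_vcf
#' @return A tibble with columns `chrom`, `pos1`, `ref`, `alt`, `var_id`,
#'   `var_class`.
#' @export
read_bed_variants <- function(path, genome = NULL) {
  if (!file.exists(path)) rlang::abort(paste0("variant BED file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(stringr::str_trim(lines)) & !startsWith(lines, "#") &
    !startsWith(lines, "track") & !startsWith(lines, "browser")
  lineno <- which(keep)
  if (!length(lineno)) {
    return(tibble::tibble(
      chrom = character(), pos1 = integer(), ref = character(),
      alt = character(), var_id = character(), var_class = character()
    ))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 5L)
  if (length(bad)) {
    rlang::abort(paste0(
      path, ": expected >= 5 tab-separated columns; offending line(s): ",
      paste(lineno[bad], collapse = ", ")
    ))
  }
  recs <- purrr::map2(fields, lineno, function(f, ln) {
    start0 <- suppressWarnings(as.integer(f[2]))
    end0 <- suppressWarnings(as.integer(f[3]))
    spec <- strsplit(f[5], "/", fixed = TRUE)[[1]]
    if (length(spec) != 2L || is.na(start0) || is.na(end0)) {
      rlang::abort(paste0(path, ": line ", ln, ": cannot parse interval or REF/ALT allele spec"))
    }
    ref <- if (spec[1] == "-") "" else toupper(spec[1])
    alt <- if (spec[2] == "-") "" else toupper(spec[2])
    if (end0 - start0 != nchar(ref)) {
      rlang::abort(paste0(
        path, ": line ", ln, ": interval length ", end0 - start0,
        " does not match REF allele length ", nchar(ref)
      ))
    }
    tibble::tibble(chrom = f[1], pos1 = start0 + 1L, ref = ref, alt = alt, var_id = f[4])
  })
  records <- dplyr::bind_rows(recs)
  records$alt[records$alt == ""] <- ""
  rows <- purrr::pmap(
    records,
    function(chrom, pos1, ref, alt, var_id) {
      trim_and_normalize(chrom, pos1, ref, alt, genome = genome, var_id = var_id)
    }
  )
  dplyr::bind_rows(rows)
}

#' Write variants in the 5-column BED-derived custom format
#'
#' Inverse of [read_bed_variants()] on the `(chrom, pos1, ref, alt)` fields.
#'
#' @param variants Variant tibble as returned by [read_vcf()] or
#'   [read_bed_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed_variants <- function(variants, path) {
  lines <- sprintf(
    "%s\t%d\t%d\t%s\t%s/%s",
    variants$chrom,
    variants$pos1 - 1L,
    variants$pos1 - 1L + nchar(variants$ref),
    variants$var_id,
    ifelse(nzchar(variants$ref), variants$ref, "-"),
    ifelse(nzchar(variants$alt), variants$alt, "-")
  )
  writeLines(lines, path)
  invisible(path)
}
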