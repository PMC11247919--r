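# ---- synthetic fixture bundle -------------------------------------------
#
# Generates a fully self-contained test bundle: a random background genome,
# strict-ish consensus motifs, variants planted so that their effect on each
# motif is known by construction (disruptions, creations, the four
# indel/motif overlap topologies, a multi-allelic site), ChIP-seq-style
# peaks over a known subset of variants, a TF family map, and a manifest of
# the planted truths. Everything is driven by one seed and written as plain
# text, so two calls with the same seed produce byte-identical files.

random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")

# Strict-ish consensus PPM: the consensus base at `major`, the rest split
# evenly. Unique column maximizer, so only the exact consensus scores s_max.
consensus_ppm <- function(consensus, major = 0.94) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  ppm <- matrix((1 - major) / 3, nrow = 4, ncol = length(bases),
                dimnames = list(DNA_BASES, NULL))
  ppm[cbind(match(bases, DNA_BASES), seq_along(bases))] <- major
  ppm
}

contains_motif <- function(seq, consensus) {
  grepl(consensus, seq, fixed = TRUE) || grepl(revcomp_chr(consensus), seq, fixed = TRUE)
}

#' Generate a deterministic synthetic fixture bundle
#'
#' Builds a complete input set for the pipeline with planted ground truth:
#' a random genome carrying exact consensus occurrences of strict-ish
#' consensus motifs; SNVs that flip a central consensus base (expected to
#' disrupt, effect sign +); insertions that write a full consensus into
#' background sequence devoid of it (expected to create, effect sign -);
#' insertion scenarios realizing the four ways an indel can interrupt a
#' motif (splicing it, overlapping its start, containing it — including the
#' coextensive case — and overlapping its end) with hand-enumerated
#' indel-relative coordinates; one multi-allelic site; and peaks placed over
#' a known subset of variants with matching, family-related, and unrelated
#' TF names. Every claim in the manifest is verified at generation time by
#' direct string checks on the assembled windows, and locally re-randomized
#' until it holds.
#'
#' @param out_dir Directory to write the bundle into (created if needed).
#' @param seed Integer seed fixing all randomness.
#' @param n_contigs,contig_len Genome shape. `contig_len` must be >= 200.
#' @param n_motifs Number of motifs in the library (>= 5; widths cycle over
#'   7-10 so every consensus match passes the default p-value threshold).
#' @param n_disruptions,n_creations Number of planted SNV disruptions and
#'   insertion creations.
#' @return A list with the file paths (`genome`, `motifs`, `variants`,
#'   `peaks`, `family_map`, `manifest_path`) and the `manifest` tibble
#'   (columns `var_id`, `motif_id`, `tf_name`, `scenario`, `expected_sign`,
#'   `expected_rel_start`, `expected_rel_end`, `expected_match_level`).
#' @export
generate_fixtures <- function(out_dir, seed = 1L, n_contigs = 2L,
                              contig_len = 10000L, n_motifs = 6L,
                              n_disruptions = 24L, n_creations = 6L) {
  if (contig_len < 200L) rlang::abort("`contig_len` must be >= 200.")
  if (n_motifs < 5L) rlang::abort("`n_motifs` must be >= 5 (topology scenarios need 5 motifs).")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  with_seed(seed, generate_fixtures_impl(
    out_dir, n_contigs, contig_len, n_motifs, n_disruptions, n_creations
  ))
}

generate_fixtures_impl <- function(out_dir, n_contigs, contig_len, n_motifs,
                                   n_disruptions, n_creations) {
  widths <- rep(c(8L, 7L, 9L, 10L), length.out = n_motifs)
  consensus <- character(n_motifs)
  for (i in seq_len(n_motifs)) {
    repeat {
      c_i <- random_dna(widths[i])
      # distinct consensi, no reverse-complement palindromes
      if (!c_i %in% consensus && c_i != revcomp_chr(c_i)) { consensus[i] <- c_i; break }
    }
  }
  tf_names <- sprintf("SYNTF%d", seq_len(n_motifs))
  motif_ids <- sprintf("SYN%03d", seq_len(n_motifs))
  motifs <- as_motif_library(
    stats::setNames(lapply(consensus, consensus_ppm), motif_ids),
    tf_names = tf_names
  )

  contigs <- sprintf("ctg%d", seq_len(n_contigs))
  genome_chars <- lapply(seq_len(n_contigs), function(i) {
    sample(DNA_BASES, contig_len, replace = TRUE)
  })
  names(genome_chars) <- contigs

  # candidate loci, spaced so event neighbourhoods never interact
  slots <- do.call(rbind, lapply(contigs, function(ct) {
    data.frame(contig = ct, pos = seq(80L, contig_len - 80L, by = 70L),
               stringsAsFactors = FALSE)
  }))
  n_events <- n_disruptions + n_creations + 5L + 1L
  if (n_events > nrow(slots)) rlang::abort("genome too small for the requested number of events.")
  slots <- slots[sample(nrow(slots), n_events), ]
  slot_i <- 0L
  next_slot <- function() {
    slot_i <<- slot_i + 1L
    slots[slot_i, ]
  }
  protected <- lapply(genome_chars, function(g) logical(length(g)))
  protect <- function(ct, at) protected[[ct]][at] <<- TRUE
  plant <- function(ct, at, seq) {
    genome_chars[[ct]][at] <<- strsplit(seq, "", fixed = TRUE)[[1]]
    protect(ct, at)
  }
  redraw_unprotected <- function(ct, lo, hi) {
    lo <- max(1L, lo); hi <- min(length(genome_chars[[ct]]), hi)
    idx <- lo:hi
    idx <- idx[!protected[[ct]][idx]]
    if (length(idx)) genome_chars[[ct]][idx] <<- sample(DNA_BASES, length(idx), replace = TRUE)
  }
  window_ref <- function(ct, from, to) {
    from <- max(1L, from); to <- min(length(genome_chars[[ct]]), to)
    paste(genome_chars[[ct]][from:to], collapse = "")
  }
  other_base <- function(b) DNA_BASES[(match(b, DNA_BASES)) %% 4L + 1L]

  manifest <- list()
  vcf_rows <- list()
  add_manifest <- function(var_id, motif_i, scenario, sign,
                           rel = c(NA_integer_, NA_integer_), level = NA_character_,
                           ct = NA_character_, pos1 = NA_integer_) {
    manifest[[length(manifest) + 1L]] <<- tibble::tibble(
      var_id = var_id, motif_id = motif_ids[motif_i], tf_name = tf_names[motif_i],
      scenario = scenario, expected_sign = sign,
      expected_rel_start = rel[1], expected_rel_end = rel[2],
      expected_match_level = level, contig = ct, pos1 = pos1
    )
  }
  add_snv_row <- function(ct, pos, ref, alt, id) {
    vcf_rows[[length(vcf_rows) + 1L]] <<- sprintf(
      "%s\t%d\t%s\t%s\t%s\t.\t.\t.", ct, pos, id, ref, alt
    )
  }
  add_ins_row <- function(ct, p, ins, id) {
    anchor <- genome_chars[[ct]][p - 1L]
    vcf_rows[[length(vcf_rows) + 1L]] <<- sprintf(
      "%s\t%d\t%s\t%s\t%s\t.\t.\t.", ct, p - 1L, id, anchor, paste0(anchor, ins)
    )
  }

  # Verify a planted SNV: the alternate window must carry no exact consensus
  # occurrence on either strand (the reference window carries the planted
  # one by construction). Re-randomizes unprotected neighbourhood bases
  # until it holds.
  settle_snv <- function(ct, snv_pos, alt_bases, m, k) {
    for (try in 1:40) {
      win <- window_ref(ct, snv_pos - (k - 1L), snv_pos + (k - 1L))
      ok <- all(vapply(alt_bases, function(b) {
        alt_win <- win
        substr(alt_win, k, k) <- b
        !contains_motif(alt_win, consensus[m])
      }, logical(1)))
      if (ok) return(invisible(NULL))
      redraw_unprotected(ct, snv_pos - (k + 5L), snv_pos + (k + 5L))
    }
    rlang::abort("fixture generation failed to settle an SNV scenario.")
  }

  # Verify a planted insertion: the reference window must lack the
  # consensus; the alternate window must carry it exactly once, at the
  # expected 1-based offset, with no reverse-complement occurrence; and the
  # base before the insertion point must differ from the insertion's last
  # base so that VCF left-alignment cannot shift the record. Returns the
  # settled insertion sequence and protects the anchor base.
  settle_insertion <- function(ct, p, make_ins, m, k, expect_at) {
    for (try in 1:60) {
      ins <- make_ins()
      last_b <- substr(ins, nchar(ins), nchar(ins))
      if (genome_chars[[ct]][p - 1L] == last_b) {
        if (protected[[ct]][p - 1L]) next # need an insertion with another tail
        genome_chars[[ct]][p - 1L] <<- other_base(last_b)
      }
      ref_win <- window_ref(ct, p - (k - 1L), p + k - 2L)
      left <- window_ref(ct, p - (k - 1L), p - 1L)
      right <- window_ref(ct, p, p + k - 2L)
      alt_win <- paste0(left, ins, right)
      hit <- gregexpr(consensus[m], alt_win, fixed = TRUE)[[1]]
      ok <- !contains_motif(ref_win, consensus[m]) &&
        length(hit) == 1L && hit[1] == expect_at &&
        !grepl(revcomp_chr(consensus[m]), alt_win, fixed = TRUE)
      if (ok) {
        protect(ct, p - 1L)
        return(ins)
      }
      redraw_unprotected(ct, p - (k + 14L), p + k + 14L)
    }
    rlang::abort("fixture generation failed to settle an insertion scenario.")
  }

  # Like settle_insertion but for an insertion that splices (destroys) a
  # planted reference motif: the alternate window must lose the consensus.
  settle_splice <- function(ct, p, m, k, ins_len) {
    for (try in 1:60) {
      ins <- random_dna(ins_len)
      if (substr(ins, ins_len, ins_len) == genome_chars[[ct]][p - 1L]) next
      left <- window_ref(ct, p - (k - 1L), p - 1L)
      right <- window_ref(ct, p, p + k - 2L)
      alt_win <- paste0(left, ins, right)
      if (!contains_motif(alt_win, consensus[m])) return(ins)
    }
    rlang::abort("fixture generation failed to settle the splice scenario.")
  }

  disruption_sites <- list()
  # --- SNV disruptions -----------------------------------------------------
  for (i in seq_len(n_disruptions)) {
    m <- (i - 1L) %% n_motifs + 1L
    k <- widths[m]
    s <- next_slot()
    L <- s$pos
    plant(s$contig, L:(L + k - 1L), consensus[m])
    j0 <- as.integer(ceiling(k / 2))
    snv_pos <- L + j0 - 1L
    ref_b <- substr(consensus[m], j0, j0)
    alt_b <- other_base(ref_b)
    settle_snv(s$contig, snv_pos, alt_b, m, k)
    id <- sprintf("dis%03d", i)
    add_snv_row(s$contig, snv_pos, ref_b, alt_b, id)
    add_manifest(id, m, "disruption", +1, ct = s$contig, pos1 = snv_pos)
    disruption_sites[[i]] <- list(id = id, motif_i = m, contig = s$contig, pos = snv_pos)
  }

  # --- insertion creations (motif coextensive with the insertion) ----------
  for (i in seq_len(n_creations)) {
    m <- (i - 1L) %% n_motifs + 1L
    k <- widths[m]
    s <- next_slot()
    p <- s$pos
    ins <- settle_insertion(s$contig, p, function() consensus[m], m, k, expect_at = k)
    id <- sprintf("cre%03d", i)
    add_ins_row(s$contig, p, ins, id)
    add_manifest(id, m, "creation", -1, rel = c(0L, 0L), ct = s$contig, pos1 = p)
  }

  # --- the four indel/motif overlap topologies -----------------------------
  # (1) coextensive insertion: the insertion is exactly the motif -> (0, 0)
  {
    m <- 1L; k <- widths[m]
    s <- next_slot(); p <- s$pos
    ins <- settle_insertion(s$contig, p, function() consensus[m], m, k, expect_at = k)
    add_ins_row(s$contig, p, ins, "top_coextensive")
    add_manifest("top_coextensive", m, "topology_coextensive", -1,
                 rel = c(0L, 0L), ct = s$contig, pos1 = p)
  }
  # (2) motif strictly inside a longer insertion: width-k motif at inserted
  # bases 3..(k + 2) of a (k + 4)-base insertion -> (+2, -2)
  {
    m <- 2L; k <- widths[m]
    s <- next_slot(); p <- s$pos
    ins <- settle_insertion(
      s$contig, p,
      function() paste0(random_dna(2L), consensus[m], random_dna(2L)),
      m, k, expect_at = k + 2L
    )
    add_ins_row(s$contig, p, ins, "top_contained")
    add_manifest("top_contained", m, "topology_contained", -1,
                 rel = c(2L, -2L), ct = s$contig, pos1 = p)
  }
  # (3) motif overlapping the start of the insertion: the 3 reference bases
  # before the insertion point are the first 3 consensus bases, the first
  # k - 3 inserted bases the rest -> (-3, -(ins_len - (k - 3)))
  {
    m <- 3L; k <- widths[m]
    ins_len <- k + 2L
    s <- next_slot(); p <- s$pos
    plant(s$contig, (p - 3L):(p - 1L), substr(consensus[m], 1L, 3L))
    ins <- settle_insertion(
      s$contig, p,
      function() paste0(substr(consensus[m], 4L, k), random_dna(ins_len - (k - 3L))),
      m, k, expect_at = k - 3L
    )
    add_ins_row(s$contig, p, ins, "top_start_overlap")
    add_manifest("top_start_overlap", m, "topology_start_overlap", -1,
                 rel = c(-3L, -(ins_len - (k - 3L))), ct = s$contig, pos1 = p)
  }
  # (4) motif overlapping the end of the insertion: the last k - 3 inserted
  # bases are the first k - 3 consensus bases, the 3 reference bases after
  # the insertion point the rest; the motif starts at inserted base
  # ins_len - (k - 3) + 1, i.e. offset +(ins_len - (k - 3)) from the first
  # inserted base, and ends 3 bases past the last -> (+(ins_len - (k - 3)), +3)
  {
    m <- 4L; k <- widths[m]
    ins_len <- k + 2L
    s <- next_slot(); p <- s$pos
    plant(s$contig, p:(p + 2L), substr(consensus[m], k - 2L, k))
    ins <- settle_insertion(
      s$contig, p,
      function() paste0(random_dna(ins_len - (k - 3L)), substr(consensus[m], 1L, k - 3L)),
      m, k, expect_at = k + ins_len - (k - 3L)
    )
    add_ins_row(s$contig, p, ins, "top_end_overlap")
    add_manifest("top_end_overlap", m, "topology_end_overlap", -1,
                 rel = c(ins_len - (k - 3L), 3L), ct = s$contig, pos1 = p)
  }
  # (5) motif spliced (destroyed) by an insertion dropped into its middle
  {
    m <- 5L; k <- widths[m]
    s <- next_slot(); L <- s$pos
    plant(s$contig, L:(L + k - 1L), consensus[m])
    p <- L + as.integer(floor(k / 2)) # insertion point inside the motif
    ins <- settle_splice(s$contig, p, m, k, ins_len = 10L)
    add_ins_row(s$contig, p, ins, "top_spliced")
    add_manifest("top_spliced", m, "topology_spliced", +1, ct = s$contig, pos1 = p)
  }

  # --- one multi-allelic disruption ---------------------------------------
  {
    m <- 1L; k <- widths[m]
    s <- next_slot(); L <- s$pos
    plant(s$contig, L:(L + k - 1L), consensus[m])
    j0 <- as.integer(ceiling(k / 2))
    snv_pos <- L + j0 - 1L
    ref_b <- substr(consensus[m], j0, j0)
    alts <- setdiff(DNA_BASES, ref_b)[1:2]
    settle_snv(s$contig, snv_pos, alts, m, k)
    add_snv_row(s$contig, snv_pos, ref_b, paste(alts, collapse = ","), "mal001")
    add_manifest("mal001:1", m, "disruption_multiallelic", +1, ct = s$contig, pos1 = snv_pos)
    add_manifest("mal001:2", m, "disruption_multiallelic", +1, ct = s$contig, pos1 = snv_pos)
  }

  # --- peaks over a known subset of the disruption variants ----------------
  peak_rows <- list()
  biotypes <- c("colon", "liver", "HCT116")
  for (i in seq_len(min(6L, n_disruptions))) {
    d <- disruption_sites[[i]]
    tf <- tf_names[d$motif_i]
    peak_tf <- if (i <= 2L) tf else if (i <= 4L) paste0(tf, "B") else "UNRELATEDTF"
    bt <- biotypes[(i - 1L) %% length(biotypes) + 1L]
    peak_rows[[length(peak_rows) + 1L]] <- sprintf(
      "%s\t%d\t%d\tEXP%03d.%s.%s\t%d\t.",
      d$contig, d$pos - 26L, d$pos + 25L, i, peak_tf, bt, 500L
    )
    level <- if (i <= 2L) "direct" else if (i <= 4L) "family" else "none"
    idx <- which(vapply(manifest, function(mm) identical(mm$var_id, d$id), logical(1)))
    manifest[[idx]]$expected_match_level <- level
  }
  if (n_disruptions >= 7L) {
    d <- disruption_sites[[7L]]
    idx <- which(vapply(manifest, function(mm) identical(mm$var_id, d$id), logical(1)))
    manifest[[idx]]$expected_match_level <- "none" # no peak at all
  }
  # background peaks, well clear of every event neighbourhood (events sit at
  # positions >= 80)
  for (i in 1:15) {
    ct <- contigs[(i - 1L) %% n_contigs + 1L]
    at <- 3L + i * 4L
    peak_rows[[length(peak_rows) + 1L]] <- sprintf(
      "%s\t%d\t%d\tBGEXP%03d.BGTF%d.%s\t%d\t.",
      ct, at, at + 8L, i, i %% 4L, biotypes[i %% 3L + 1L], 100L
    )
  }

  # --- write the bundle ----------------------------------------------------
  genome <- Biostrings::DNAStringSet(vapply(genome_chars, paste, character(1), collapse = ""))
  names(genome) <- contigs
  genome_path <- file.path(out_dir, "genome.fa")
  Biostrings::writeXStringSet(genome, genome_path)

  motifs_path <- file.path(out_dir, "motifs.meme")
  write_motifs_meme(motifs, motifs_path)

  vcf_path <- file.path(out_dir, "variants.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs, contig_len),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    unlist(vcf_rows)
  ), vcf_path)

  peaks_path <- file.path(out_dir, "peaks.bed")
  writeLines(unlist(peak_rows), peaks_path)

  fam_path <- file.path(out_dir, "family_map.tsv")
  writeLines(sprintf("%s\t%s,%sB", tf_names, tf_names, tf_names), fam_path)

  manifest_tbl <- dplyr::bind_rows(manifest)
  manifest_path <- file.path(out_dir, "manifest.tsv")
  readr::write_tsv(manifest_tbl, manifest_path, progress = FALSE)

  list(
    genome = genome_path, motifs = motifs_path, variants = vcf_path,
    peaks = peaks_path, family_map = fam_path,
    manifest = manifest_tbl, manifest_path = manifest_path
  )
}
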