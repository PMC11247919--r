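make_ins_window <- function(k, ins_len, flank = NULL) {
  # synthetic insertion window: flanks of k-1, inserted segment in the middle
  flank <- flank %||% (k - 1L)
  left <- rand_dna(flank)
  right <- rand_dna(flank)
  ins <- rand_dna(ins_len)
  tibble::tibble(
    var_id = "v", chrom = "chr1", window_start1 = 101L,
    ref_seq = paste0(left, right), alt_seq = paste0(left, ins, right),
    ref_span_lo = flank + 1L, ref_span_hi = flank,
    alt_span_lo = flank + 1L, alt_span_hi = flank + ins_len, k = as.integer(k)
  )
}

test_that("indel-relative coordinates reproduce hand-enumerated placements", {
  set.seed(51)
  # width-6 motif occupying inserted bases 3-8 of a 10-base insertion
  w <- make_ins_window(k = 6L, ins_len = 10L)
  m1 <- w$alt_span_lo + 2L # 1-based start at inserted base 3
  expect_equal(relative_coords(m1 - 1L, 6L, w, "insertion"), c(2L, -2L))
  # motif coextensive with the insertion
  w2 <- make_ins_window(k = 8L, ins_len = 8L)
  expect_equal(relative_coords(w2$alt_span_lo - 1L, 8L, w2, "insertion"), c(0L, 0L))
  # width-8 motif starting 3 bases upstream of a 10-base insertion and
  # ending at inserted base 5
  w3 <- make_ins_window(k = 8L, ins_len = 10L)
  m3 <- w3$alt_span_lo - 3L
  expect_equal(relative_coords(m3 - 1L, 8L, w3, "insertion"), c(-3L, -5L))
  # deletion: edges live on the deleted reference segment; a width-6 motif
  # spanning the junction 3 bases before it maps across the deletion
  del <- tibble::tibble(
    var_id = "d", chrom = "chr1", window_start1 = 101L,
    ref_seq = paste0(rand_dna(5), rand_dna(5), rand_dna(5)),
    alt_seq = paste0(rand_dna(5), rand_dna(5)),
    ref_span_lo = 6L, ref_span_hi = 10L,
    alt_span_lo = 6L, alt_span_hi = 5L, k = 6L
  )
  expect_equal(relative_coords(2L, 6L, del, "deletion"), c(-3L, 3L))
})

test_that("genomic spans convert window offsets to 1-based inclusive intervals", {
  w <- tibble::tibble(
    var_id = "v", chrom = "chr1", window_start1 = 95L,
    ref_seq = rand_dna(20), alt_seq = rand_dna(20),
    ref_span_lo = 8L, ref_span_hi = 8L, alt_span_lo = 8L, alt_span_hi = 8L,
    k = 8L
  )
  expect_equal(genomic_span(0L, 8L, w), c(95L, 102L))
  expect_equal(genomic_span(3L, 8L, w), c(98L, 105L))
  expect_equal(genomic_span(12L, 8L, w), c(107L, 114L)) # full-window match
  expect_error(genomic_span(13L, 8L, w), "outside")
})

test_that("planted SNV disruption and insertion creation are detected with correct signs", {
  set.seed(52)
  cons <- "ACGTTGCA"
  lib <- as_motif_library(list(M1 = strict_ppm(cons)), tf_names = "TF1")
  flank <- function(n) rand_dna(n)
  left <- flank(80)
  right <- flank(80)
  genome <- make_genome(chr1 = paste0(left, cons, right))
  # flip the 4th consensus base (T -> G) at genomic position 84
  snv <- tibble::tibble(chrom = "chr1", pos1 = 84L, ref = "T", alt = "G",
                        var_id = "snv1", var_class = "snv")
  res <- analyze_variants(snv, lib, genome, p_threshold = 1e-3)
  expect_equal(nrow(res), 1L)
  expect_equal(res$score_ref, 1)
  expect_lt(res$score_alt, 1)
  expect_gt(res$effect_size, 0)
  expect_equal(res$ref_start1, 81L)
  expect_equal(res$ref_end1, 88L)
  expect_equal(res$pvalue_ref, 4^-8)
  # insertion writing the full consensus into background devoid of it
  genome2 <- make_genome(chr1 = gsub(cons, rand_dna(8), as.character(genome[[1]]), fixed = TRUE))
  ins <- tibble::tibble(chrom = "chr1", pos1 = 120L, ref = "", alt = cons,
                        var_id = "ins1", var_class = "insertion")
  res2 <- analyze_variants(ins, lib, genome2, p_threshold = 1e-3)
  expect_equal(nrow(res2), 1L)
  expect_equal(res2$score_alt, 1)
  expect_lt(res2$score_ref, 1)
  expect_lt(res2$effect_size, 0)
  expect_equal(c(res2$rel_start, res2$rel_end), c(0L, 0L))
})

test_that("an SNV analyzed as a length-1 delins gives identical scores and spans", {
  set.seed(53)
  genome <- make_genome(chr1 = rand_dna(2000))
  lib <- as_motif_library(list(A = rand_ppm(6), B = rand_ppm(8)), tf_names = c("TFA", "TFB"))
  gstr <- as.character(genome[[1]])
  pos <- sample(100:1900, 40)
  vars <- tibble::tibble(
    chrom = "chr1", pos1 = pos,
    ref = substring(gstr, pos, pos),
    alt = NA_character_, var_id = paste0("s", seq_along(pos)), var_class = "snv"
  )
  vars$alt <- vapply(vars$ref, function(b) setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  as_delins <- dplyr::mutate(vars, var_class = "delins")
  r1 <- analyze_variants(vars, lib, genome, p_threshold = 0.999)
  r2 <- analyze_variants(as_delins, lib, genome, p_threshold = 0.999)
  expect_equal(nrow(r1), nrow(r2))
  same <- c("var_id", "motif_id", "raw_ref", "raw_alt", "score_ref", "score_alt",
            "pvalue_ref", "pvalue_alt", "effect_size", "ref_start1", "ref_end1")
  expect_equal(r1[, same], r2[, same])
  # the delins path additionally carries relative coordinates
  expect_true(all(is.na(r1$rel_start)))
  expect_true(all(!is.na(r2$rel_start)))
})

test_that("exchanging ref and alt alleles negates the effect and swaps allele fields", {
  set.seed(54)
  genome <- make_genome(g1 = rand_dna(4000))
  lib <- as_motif_library(list(A = rand_ppm(7)), tf_names = "TFA")
  gstr <- as.character(genome[[1]])
  pos <- seq(100L, 3800L, by = 80L)[1:30]
  cls <- rep(c("snv", "insertion", "deletion"), length.out = 30)
  vars <- purrr::map_dfr(seq_along(pos), function(i) {
    p <- pos[i]
    switch(cls[i],
      snv = tibble::tibble(chrom = "g1", pos1 = p, ref = substr(gstr, p, p),
                           alt = setdiff(c("A", "C", "G", "T"), substr(gstr, p, p))[1],
                           var_id = paste0("v", i), var_class = "snv"),
      insertion = tibble::tibble(chrom = "g1", pos1 = p, ref = "", alt = rand_dna(5),
                                 var_id = paste0("v", i), var_class = "insertion"),
      deletion = tibble::tibble(chrom = "g1", pos1 = p, ref = substr(gstr, p, p + 3),
                                alt = "", var_id = paste0("v", i), var_class = "deletion")
    )
  })
  alt_genome <- apply_variants_to_genome(genome, vars)
  swapped <- swap_variants(vars)
  fwd <- analyze_variants(vars, lib, genome, p_threshold = 0.999)
  rev <- analyze_variants(swapped, lib, alt_genome, p_threshold = 0.999)
  expect_equal(nrow(fwd), nrow(rev))
  expect_equal(rev$effect_size, -fwd$effect_size)
  expect_equal(rev$score_ref, fwd$score_alt)
  expect_equal(rev$score_alt, fwd$score_ref)
  expect_equal(rev$pvalue_ref, fwd$pvalue_alt)
  expect_equal(rev$pvalue_alt, fwd$pvalue_ref)
})

test_that("matched sequences rescore to the reported raw scores", {
  set.seed(55)
  genome <- make_genome(chr1 = rand_dna(1500))
  lib <- as_motif_library(list(A = rand_ppm(6), B = rand_ppm(9)),
                          tf_names = c("TFA", "TFB"))
  gstr <- as.character(genome[[1]])
  pos <- seq(60L, 1400L, by = 90L)
  vars <- tibble::tibble(
    chrom = "chr1", pos1 = pos, ref = substring(gstr, pos, pos),
    alt = vapply(substring(gstr, pos, pos),
                 function(b) setdiff(c("A", "C", "G", "T"), b)[1], character(1)),
    var_id = paste0("v", seq_along(pos)), var_class = "snv"
  )
  res <- analyze_variants(vars, lib, genome, p_threshold = 0.999)
  expect_gt(nrow(res), 0)
  for (i in seq_len(nrow(res))) {
    r <- res[i, ]
    m <- lib[lib$motif_id == r$motif_id, ]
    sm <- score_matrix(m$ppm[[1]], motif_id = m$motif_id)
    sm_ref <- if (r$strand_ref == "+") sm else reverse_complement(sm)
    sm_alt <- if (r$strand_alt == "+") sm else reverse_complement(sm)
    expect_identical(score_kmer(sm_ref, r$matched_ref_seq), r$raw_ref)
    expect_identical(score_kmer(sm_alt, r$matched_alt_seq), r$raw_alt)
  }
})

test_that("results appear only when one allele passes the p-value threshold", {
  set.seed(56)
  genome <- make_genome(chr1 = rand_dna(500))
  cons <- "ACGTTGCA"
  lib <- as_motif_library(list(M = strict_ppm(cons)), tf_names = "TF")
  gstr <- as.character(genome[[1]])
  v <- tibble::tibble(chrom = "chr1", pos1 = 250L, ref = substr(gstr, 250, 250),
                      alt = setdiff(c("A", "C", "G", "T"), substr(gstr, 250, 250))[1],
                      var_id = "bgv", var_class = "snv")
  # a background SNV nowhere near the (absent) consensus: neither allele can
  # reach p <= 1e-4 against a strict 8-mer unless the consensus is present
  if (!grepl(cons, gstr, fixed = TRUE) && !grepl(revcomp_str(cons), gstr, fixed = TRUE)) {
    res <- analyze_variants(v, lib, genome, p_threshold = 1e-4)
    expect_equal(nrow(res), 0L)
  }
  # with a permissive threshold the same pair is reported
  res2 <- analyze_variants(v, lib, genome, p_threshold = 0.999)
  expect_equal(nrow(res2), 1L)
})
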