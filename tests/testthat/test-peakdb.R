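write_peaks_bed <- function(lines) {
  path <- withr::local_tempfile(fileext = ".bed", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("ReMap-style dotted names split right-anchored", {
  path <- write_peaks_bed(c(
    "chr1\t100\t200\tGSE123.CTCF.colon\t900\t.",
    "chr1\t300\t400\tA.B.CTCF.HCT116\t800\t.",
    "chr1\t500\t600\tjustaname\t700\t."
  ))
  expect_warning(db <- build_peak_db(path), "EXPERIMENT.TF.BIOTYPE")
  expect_equal(db$n, 3L)
  expect_equal(db$peaks$tf, c("CTCF", "CTCF", "justaname"))
  expect_equal(db$peaks$biotype, c("colon", "HCT116", ""))
  expect_equal(db$peaks$experiment, c("GSE123", "A.B", ""))
})

test_that("queries respect overlap, TF identity, and family fallback", {
  path <- write_peaks_bed(c(
    "chr1\t100\t200\tGSE1.CTCF.colon\t900\t.",
    "chr1\t150\t260\tGSE2.CTCF.liver\t900\t.",
    "chr1\t100\t200\tGSE3.GATA1.colon\t900\t."
  ))
  db <- build_peak_db(path)
  # 1-bp query inside the first peak only ([149,150) ends before the
  # second peak starts), case-insensitive TF match
  q <- query_peaks(db, "chr1", 149, 150, "ctcf")
  expect_equal(q$match_level, "direct")
  expect_equal(nrow(q$peaks), 1L)
  expect_equal(q$biotypes, "colon")
  # widening by one base reaches the second CTCF peak too
  q2 <- query_peaks(db, "chr1", 149, 151, "CTCF")
  expect_equal(nrow(q2$peaks), 2L)
  expect_equal(q2$biotypes, c("colon", "liver")) # de-duplicated, sorted
  # unknown TF without a family map
  expect_equal(query_peaks(db, "chr1", 149, 150, "NOPE")$match_level, "none")
  # family expansion only when no direct match
  fam <- list(CTCFL = c("CTCF", "CTCFL"))
  qf <- query_peaks(db, "chr1", 149, 150, "CTCFL", fam = fam)
  expect_equal(qf$match_level, "family")
  # direct beats family even when the family set also matches
  qd <- query_peaks(db, "chr1", 149, 150, "GATA1", fam = list(GATA1 = c("GATA1", "CTCF")))
  expect_equal(qd$match_level, "direct")
  expect_equal(nrow(qd$peaks), 1L)
  # unknown chromosome is an empty annotation, not an error
  expect_equal(query_peaks(db, "chrZ", 0, 10, "CTCF")$match_level, "none")
  # non-overlapping interval
  expect_equal(query_peaks(db, "chr1", 260, 300, "CTCF")$match_level, "none")
})

test_that("interval index equals a linear scan on random queries", {
  set.seed(61)
  n <- 5000
  chroms <- sample(paste0("chr", 1:4), n, replace = TRUE)
  start0 <- sample.int(1e6, n)
  width <- sample(50:500, n, replace = TRUE)
  tfs <- sample(c("CTCF", "GATA1", "TP53", "MYC"), n, replace = TRUE)
  bts <- sample(c("colon", "liver", "blood"), n, replace = TRUE)
  lines <- sprintf("%s\t%d\t%d\tE%d.%s.%s\t0\t.", chroms, start0, start0 + width,
                   seq_len(n), tfs, bts)
  path <- write_peaks_bed(sample(lines)) # insertion order must not matter
  db <- build_peak_db(path)
  peaks <- db$peaks
  for (i in 1:250) {
    qc <- sample(paste0("chr", 1:5), 1)
    qs <- sample.int(1e6, 1)
    qe <- qs + sample(1:400, 1)
    tf <- sample(c("CTCF", "GATA1", "ABSENT"), 1)
    got <- query_peaks(db, qc, qs, qe, tf)
    lin <- peaks[peaks$chrom == qc & peaks$start0 < qe & peaks$end0 > qs &
                   toupper(peaks$tf) == tf, ]
    expect_equal(nrow(got$peaks), nrow(lin))
    if (nrow(lin)) {
      expect_equal(got$match_level, "direct")
      expect_equal(sort(got$peaks$experiment), sort(lin$experiment))
    } else {
      expect_equal(got$match_level, "none")
    }
  }
})

test_that("family map files parse and unknown TFs map to themselves", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("CTCFL\tCTCF,CTCFL", "GATA1\tGATA1, GATA2 ,GATA3"), path)
  fam <- read_family_map(path)
  expect_equal(fam$CTCFL, c("CTCF", "CTCFL"))
  expect_equal(fam$GATA1, c("GATA1", "GATA2", "GATA3"))
  expect_equal(motifdisrupt:::family_members(fam, "gata1"), c("GATA1", "GATA2", "GATA3"))
  expect_equal(motifdisrupt:::family_members(fam, "NEW"), "NEW")
  bad <- withr::local_tempfile()
  writeLines("no-tab-here", bad)
  expect_error(read_family_map(bad), "two tab-separated")
})

test_that("peak evidence attaches on the variant footprint with insertions expanded", {
  set.seed(62)
  cons <- "ACGTTGCA"
  lib <- as_motif_library(list(M = strict_ppm(cons)), tf_names = "CTCF")
  genome <- make_genome(chr1 = paste0(rand_dna(80), cons, rand_dna(80)))
  snv <- tibble::tibble(chrom = "chr1", pos1 = 84L, ref = substr(cons, 4, 4),
                        alt = setdiff(c("A", "C", "G", "T"), substr(cons, 4, 4))[1],
                        var_id = "v1", var_class = "snv")
  res <- analyze_variants(snv, lib, genome, p_threshold = 1e-3)
  peaks <- write_peaks_bed(c(
    "chr1\t60\t120\tE1.CTCF.colon\t0\t.",
    "chr1\t60\t120\tE2.CTCF.liver\t0\t.",
    "chr1\t60\t120\tE3.CTCF.colon\t0\t."
  ))
  db <- build_peak_db(peaks)
  ann <- attach_peak_evidence(res, db)
  expect_equal(ann$peak_match_level, "direct")
  expect_equal(ann$peak_n, 3L)
  expect_equal(ann$peak_biotypes, "colon;liver") # de-duplicated, sorted
  # a variant outside every peak
  far_peaks <- write_peaks_bed("chr1\t1\t10\tE1.CTCF.colon\t0\t.")
  ann2 <- attach_peak_evidence(res, build_peak_db(far_peaks))
  expect_equal(ann2$peak_match_level, "none")
  expect_equal(ann2$peak_n, 0L)
  # pure insertion footprint expands to the two flanking bases
  expect_equal(motifdisrupt:::variant_footprint0(101L, ""), c(99L, 101L))
  expect_equal(motifdisrupt:::variant_footprint0(101L, "ACG"), c(100L, 103L))
})
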