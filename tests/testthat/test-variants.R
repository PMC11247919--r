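test_that("trimming removes shared bases and classifies the remainder", {
  # SNV passes through
  v <- trim_and_normalize("chr1", 100L, "A", "C", var_id = "v")
  expect_equal(v$var_class, "snv")
  expect_equal(v$pos1, 100L)
  # leading then trailing trim: CAG>CG is a 1-bp deletion at 101
  v <- trim_and_normalize("chr1", 100L, "CAG", "CG", var_id = "v")
  expect_equal(v[, c("pos1", "ref", "alt", "var_class")],
               tibble::tibble(pos1 = 101L, ref = "A", alt = "", var_class = "deletion"))
  # anchor-base insertion
  v <- trim_and_normalize("chr1", 100L, "A", "ATTTT", var_id = "v")
  expect_equal(v[, c("pos1", "ref", "alt", "var_class")],
               tibble::tibble(pos1 = 101L, ref = "", alt = "TTTT", var_class = "insertion"))
  # identical alleles are skipped with a warning
  expect_warning(out <- trim_and_normalize("chr1", 5L, "AC", "AC", var_id = "x"),
                 "identical")
  expect_null(out)
})

test_that("classification is total and mutually exclusive on random allele pairs", {
  set.seed(31)
  for (i in 1:200) {
    ref <- rand_dna(sample(0:4, 1))
    alt <- rand_dna(sample(0:4, 1))
    if (ref == alt) next
    cls <- motifdisrupt:::classify_alleles(ref, alt)
    expect_true(cls %in% c("snv", "insertion", "deletion", "delins"))
    expect_equal(cls == "snv", nchar(ref) == 1 && nchar(alt) == 1)
    expect_equal(cls == "insertion", nchar(ref) == 0)
    expect_equal(cls == "deletion", nchar(alt) == 0 && nchar(ref) > 0)
  }
})

test_that("indels are left-aligned against the genome (brute-force shift oracle)", {
  genome <- make_genome(chr1 = "CCAGAGTTTAAACCAGAGT")
  # deletion of AG inside ...CAGAG...: brute-force the leftmost equivalent
  brute_leftmost_del <- function(gstr, pos1, len) {
    target <- paste0(substr(gstr, 1, pos1 - 1), substr(gstr, pos1 + len, nchar(gstr)))
    cand <- pos1
    for (p in seq_len(pos1)) {
      alt <- paste0(substr(gstr, 1, p - 1), substr(gstr, p + len, nchar(gstr)))
      if (alt == target) { cand <- p; break }
    }
    cand
  }
  gstr <- as.character(genome[[1]])
  v <- trim_and_normalize("chr1", 5L, substr(gstr, 5, 6), "", genome = genome, var_id = "d")
  expect_equal(v$var_class, "deletion")
  expect_equal(v$pos1, brute_leftmost_del(gstr, 5L, 2L))
  # left-aligned insertion: inserting AG after position 6 == after position 2
  vi <- trim_and_normalize("chr1", 7L, "", "AG", genome = genome, var_id = "i")
  vi_ref <- trim_and_normalize("chr1", 7L, "", "AG", var_id = "i") # no genome: unshifted
  expect_lt(vi$pos1, vi_ref$pos1)
  # shifting the insertion back into the genome reproduces the same haplotype
  splice <- function(gstr, pos1, ins) {
    paste0(substr(gstr, 1, pos1 - 1), ins, substr(gstr, pos1, nchar(gstr)))
  }
  expect_equal(splice(gstr, vi$pos1, vi$alt), splice(gstr, 7L, "AG"))
  # normalization is idempotent
  v2 <- trim_and_normalize(v$chrom, v$pos1, v$ref, v$alt, genome = genome, var_id = "d")
  expect_equal(v2[, c("pos1", "ref", "alt", "var_class")],
               v[, c("pos1", "ref", "alt", "var_class")])
})

test_that("multi-allelic records split into per-allele records with suffixed ids", {
  recs <- tibble::tibble(
    chrom = c("chr1", "chr1"), pos1 = c(10L, 50L),
    ref = c("A", "A"), alt = c("C", "C,ATT"), var_id = c("one", "two")
  )
  out <- split_multiallelic(recs)
  expect_equal(nrow(out), 3L)
  expect_equal(out$var_id, c("one", "two:1", "two:2"))
  expect_equal(out$alt, c("C", "C", "ATT"))
})

test_that("read_vcf normalizes records and skips symbolic alleles", {
  path <- write_tmp_vcf(c(
    "chr1\t100\trs1\tA\tC\t.\t.\t.",
    "chr1\t100\t.\tA\tATTTT\t.\t.\t.",
    "chr1\t100\t.\tA\tC,T\t.\t.\t.",
    "chr1\t200\tsv1\tA\t<DEL>\t.\t.\t."
  ))
  expect_warning(vars <- read_vcf(path), "symbolic")
  expect_equal(nrow(vars), 4L)
  expect_equal(vars$var_class, c("snv", "insertion", "snv", "snv"))
  expect_equal(vars$var_id[1], "rs1")
  expect_equal(vars$pos1[2], 101L)
  expect_equal(vars$alt[2], "TTTT")
  expect_equal(vars$var_id[3:4], c("chr1:100:1", "chr1:100:2"))
  # empty VCF body yields an empty, well-typed tibble
  empty <- write_tmp_vcf(character())
  out <- read_vcf(empty)
  expect_equal(nrow(out), 0L)
  expect_named(out, c("chrom", "pos1", "ref", "alt", "var_id", "var_class"))
})

test_that("BED-derived custom variants read with half-open convention and round-trip", {
  path <- withr::local_tempfile(fileext = ".bed")
  writeLines(c(
    "chr1\t99\t100\tv1\tA/C",
    "chr1\t100\t100\tv2\t-/TTTT",
    "chr1\t99\t104\tv3\tACGTA/-"
  ), path)
  vars <- read_bed_variants(path)
  expect_equal(vars$var_class, c("snv", "insertion", "deletion"))
  expect_equal(vars$pos1, c(100L, 101L, 100L))
  expect_equal(vars$ref, c("A", "", "ACGTA"))
  # write-then-read is the identity on the allele fields
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed_variants(vars, out)
  back <- read_bed_variants(out)
  expect_equal(back[, c("chrom", "pos1", "ref", "alt", "var_class")],
               vars[, c("chrom", "pos1", "ref", "alt", "var_class")])
  # interval/allele length mismatch is a per-line error
  bad <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t99\t104\tv4\tAC/-", bad)
  expect_error(read_bed_variants(bad), "line 1")
})
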