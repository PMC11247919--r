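# Shared builders for in-code fixtures. Everything is generated at test
# time; no data files are stored.

rand_ppm <- function(k) {
  cts <- matrix(stats::rexp(4 * k), nrow = 4)
  ppm <- sweep(cts, 2, colSums(cts), "/")
  rownames(ppm) <- c("A", "C", "G", "T")
  ppm
}

# Probability matrix with probability 1 on the consensus base at every
# position: only the exact consensus attains s_max.
strict_ppm <- function(consensus) {
  bases <- strsplit(consensus, "", fixed = TRUE)[[1]]
  ppm <- matrix(0, nrow = 4, ncol = length(bases),
                dimnames = list(c("A", "C", "G", "T"), NULL))
  ppm[cbind(match(bases, c("A", "C", "G", "T")), seq_along(bases))] <- 1
  ppm
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_genome <- function(...) {
  seqs <- c(...)
  g <- Biostrings::DNAStringSet(seqs)
  names(g) <- names(seqs)
  g
}

revcomp_str <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

write_tmp_vcf <- function(rows, contigs = c(chr1 = 1000L)) {
  path <- withr::local_tempfile(fileext = ".vcf", .local_envir = parent.frame())
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    rows
  ), path)
  path
}

# Apply a set of non-overlapping variants to a genome, producing the
# alternate haplotype. Used to test ref/alt exchange symmetry end to end.
apply_variants_to_genome <- function(genome, variants) {
  out <- lapply(names(genome), function(ct) {
    chars <- strsplit(as.character(genome[[ct]]), "")[[1]]
    v <- variants[variants$chrom == ct, ]
    v <- v[order(-v$pos1), ] # edit right-to-left so positions stay valid
    for (i in seq_len(nrow(v))) {
      pos <- v$pos1[i]
      ref_len <- nchar(v$ref[i])
      alt_chars <- if (nzchar(v$alt[i])) strsplit(v$alt[i], "")[[1]] else character()
      before <- if (pos > 1) chars[1:(pos - 1)] else character()
      after_start <- pos + ref_len
      after <- if (after_start <= length(chars)) chars[after_start:length(chars)] else character()
      chars <- c(before, alt_chars, after)
    }
    paste(chars, collapse = "")
  })
  g <- Biostrings::DNAStringSet(unlist(out))
  names(g) <- names(genome)
  g
}

# Positions of swapped variants on the alternate haplotype (valid when
# variants are sorted by position and non-overlapping per contig).
swap_variants <- function(variants) {
  sw <- variants
  sw$ref <- variants$alt
  sw$alt <- variants$ref
  sw$var_class <- ifelse(
    nchar(sw$ref) == 1 & nchar(sw$alt) == 1, "snv",
    ifelse(nchar(sw$ref) == 0, "insertion",
           ifelse(nchar(sw$alt) == 0, "deletion", "delins"))
  )
  for (ct in unique(sw$chrom)) {
    idx <- which(sw$chrom == ct)
    idx <- idx[order(variants$pos1[idx])]
    shift <- 0L
    for (i in idx) {
      sw$pos1[i] <- variants$pos1[i] + shift
      shift <- shift + nchar(variants$alt[i]) - nchar(variants$ref[i])
    }
  }
  sw
}
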