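DNA_BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Uniform nucleotide background
#'
#' Convenience constructor for the default background model: each of A, C, G
#' and T at frequency 0.25.
#'
#' @return A named numeric vector of four frequencies summing to 1.
#' @export
#' @examples
#' uniform_bg()
uniform_bg <- function() {
  c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)
}

# Validate a background model: four strictly positive frequencies over
# A,C,G,T summing to 1 within 1e-9. Accepts unnamed vectors in ACGT order.
validate_bg <- function(bg) {
  if (!is.numeric(bg) || length(bg) != 4L) {
    rlang::abort("`bg` must be a numeric vector of 4 base frequencies (A, C, G, T).")
  }
  if (is.null(names(bg))) {
    names(bg) <- DNA_BASES
  }
  bg <- bg[DNA_BASES]
  if (anyNA(bg)) {
    rlang::abort("`bg` must be named with bases A, C, G, T (or unnamed, in that order).")
  }
  if (any(bg <= 0)) {
    rlang::abort("all background frequencies must be > 0.")
  }
  if (abs(sum(bg) - 1) > 1e-9) {
    rlang::abort("background frequencies must sum to 1 (within 1e-9).")
  }
  bg
}

# Reverse complement of a plain character DNA string (A/C/G/T/N).
revcomp_chr <- function(x) {
  vapply(x, function(s) {
    if (nchar(s) == 0L) return("")
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    comp <- COMPLEMENT[chars]
    comp[is.na(comp)] <- "N"
    paste(rev(comp), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Map a DNA string to integer codes 1..4 (A,C,G,T); anything else
# (N and other IUPAC ambiguity letters) becomes NA.
dna_codes <- function(s) {
  match(strsplit(toupper(s), "", fixed = TRUE)[[1]], DNA_BASES)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
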