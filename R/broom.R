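#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a score matrix into a long tibble
#'
#' @param x A [score_matrix()].
#' @param ... Unused.
#' @return A tibble with one row per (position, base): `motif_id`,
#'   `position`, `base`, `score`.
#' @method tidy score_matrix
#' @export
tidy.score_matrix <- function(x, ...) {
  tibble::tibble(
    motif_id = x$motif_id,
    position = rep(seq_len(x$width), each = 4L),
    base = rep(DNA_BASES, x$width),
    score = as.vector(x$scores)
  )
}

#' One-row summary of a score matrix
#'
#' @param x A [score_matrix()].
#' @param ... Unused.
#' @return A one-row tibble: identity, width, score range, and the
#'   information content of the underlying probabilities implied by the
#'   scores' background.
#' @method glance score_matrix
#' @export
glance.score_matrix <- function(x, ...) {
  tibble::tibble(
    motif_id = x$motif_id, tf_name = x$tf_name, width = x$width,
    s_min = x$s_min, s_max = x$s_max
  )
}

#' Tidy a motif library into a long tibble of probabilities
#'
#' @param x A `motif_library` from [read_motifs()].
#' @param ... Unused.
#' @return A tibble with one row per (motif, position, base): `motif_id`,
#'   `tf_name`, `position`, `base`, `prob`.
#' @method tidy motif_library
#' @export
tidy.motif_library <- function(x, ...) {
  purrr::pmap_dfr(
    x[, c("motif_id", "tf_name", "ppm")],
    function(motif_id, tf_name, ppm) {
      tibble::tibble(
        motif_id = motif_id, tf_name = tf_name,
        position = rep(seq_len(ncol(ppm)), each = 4L),
        base = rep(DNA_BASES, ncol(ppm)),
        prob = as.vector(ppm)
      )
    }
  )
}

#' One-row summary of a breakage result set
#'
#' @param x A `motif_breakage` tibble from [analyze_variants()].
#' @param ... Unused.
#' @return A one-row tibble: counts of variants scored, results emitted,
#'   strong effects, disruptions (positive effect) and creations (negative
#'   effect).
#' @method glance motif_breakage
#' @export
glance.motif_breakage <- function(x, ...) {
  stats <- attr(x, "stats")
  tibble::tibble(
    n_variants = stats$n_variants %||% NA_integer_,
    n_results = nrow(x),
    n_strong = sum(x$effect_class == "strong"),
    n_disrupted = sum(x$effect_size > 0),
    n_created = sum(x$effect_size < 0)
  )
}
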