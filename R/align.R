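#' Banded semi-global pairwise alignment
#'
#' Aligns a fragment (query, global) inside a near-full-length reference
#' (local: leading/trailing reference sequence is skipped for free), using
#' affine gap scoring within a diagonal band. Scoring follows match = +1,
#' mismatch = -1, gap open = -2, gap extension = -1; a gap of length L costs
#' `|gap_open| + L * |gap_ext|`.
#'
#' The band is centred on the seeded diagonal: the most frequent
#' reference-minus-query offset among shared words. With no shared words the
#' alignment falls back to an unbanded computation.
#'
#' @param query,reference DNA strings, both non-empty.
#' @param band Half-width of the diagonal band, default 32.
#' @param offset Optional diagonal (reference position minus query position)
#'   to centre the band on; seeded from shared words when `NULL`.
#' @param seed_k Word length used for seeding the diagonal.
#' @param match,mismatch,gap_open,gap_ext Scoring parameters.
#' @param query_id,ref_id Optional ids carried into the result.
#' @return A `pairwise_alignment` object: aligned strings with `-` gaps,
#'   per-column `ops` (`match`, `mismatch`, `insertion` in query, `deletion`
#'   from query), 0-based half-open `query_start`/`query_end` and
#'   `ref_start`/`ref_end`, and the alignment `score`.
#' @examples
#' aln <- align_pair("ACGTACGT", "TTTTACGTACGTTTTT")
#' aln$score
#' @export
align_pair <- function(query, reference, band = 32, offset = NULL,
                       seed_k = 8, match = 1, mismatch = -1,
                       gap_open = -2, gap_ext = -1,
                       query_id = NULL, ref_id = NULL) {
  if (band < 1) abort("band must be >= 1")
  if (!nzchar(query) || !nzchar(reference)) abort("sequences must be non-empty")
  if (is.null(offset)) {
    seed <- seed_diagonal(query, reference, seed_k)
    if (is.null(seed)) {
      # no shared words: centre on 0 and widen to cover the full matrix
      offset <- 0L
      band <- nchar(query) + nchar(reference)
    } else {
      offset <- seed
    }
  }
  res <- tryCatch(
    banded_semiglobal_align(
      query, reference, as.integer(band), as.integer(offset),
      as.integer(match), as.integer(mismatch),
      as.integer(abs(gap_open)), as.integer(abs(gap_ext))
    ),
    error = function(e) {
      # a misleading seed (e.g. on repetitive sequence) can leave the band
      # without a query-global path; recompute unbanded
      banded_semiglobal_align(
        query, reference, nchar(query) + nchar(reference), 0L,
        as.integer(match), as.integer(mismatch),
        as.integer(abs(gap_open)), as.integer(abs(gap_ext))
      )
    }
  )
  structure(
    c(res, list(query_id = query_id, ref_id = ref_id,
                band = band, offset = offset)),
    class = "pairwise_alignment"
  )
}

# Most frequent (ref position - query position) offset among shared words.
seed_diagonal <- function(query, reference, k = 8) {
  n_q <- nchar(query)
  n_r <- nchar(reference)
  if (n_q < k || n_r < k) return(NULL)
  q_starts <- seq_len(n_q - k + 1L)
  q_words <- substring(query, q_starts, q_starts + k - 1L)
  r_starts <- seq_len(n_r - k + 1L)
  r_words <- substring(reference, r_starts, r_starts + k - 1L)
  hit <- match(q_words, r_words)
  ok <- !is.na(hit)
  if (!any(ok)) return(NULL)
  offsets <- (hit[ok] - q_starts[ok])
  as.integer(names(which.max(table(offsets))))
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  n_mm <- sum(x$ops == "mismatch")
  n_ins <- sum(x$ops == "insertion")
  n_del <- sum(x$ops == "deletion")
  cat(sprintf(
    "<pairwise_alignment> score %d | query [%d,%d) on ref [%d,%d) | %d mismatch, %d ins, %d del\n",
    x$score, x$query_start, x$query_end, x$ref_start, x$ref_end,
    n_mm, n_ins, n_del
  ))
  width <- 60
  for (s in seq(1, nchar(x$aligned_query), by = width)) {
    cat(substr(x$aligned_query, s, s + width - 1), "\n")
    cat(substr(x$aligned_ref, s, s + width - 1), "\n")
  }
  invisible(x)
}

# Reference coordinate (0-based) consumed at each alignment column, NA for
# insertion columns; used by variable-region screening and the primer audit.
alignment_ref_positions <- function(alignment) {
  consumes <- alignment$ops != "insertion"
  pos <- rep(NA_integer_, length(alignment$ops))
  pos[consumes] <- alignment$ref_start + seq_len(sum(consumes)) - 1L
  pos
}
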