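#' Reference-based chimera detection for amplicon reads
#'
#' A read is flagged chimeric when splitting it at some breakpoint lets two
#' *different* references explain its prefix and suffix substantially better
#' than any single reference explains the whole read. For each candidate
#' breakpoint `b` (scanned at word-length steps, at least `min_segment`
#' bases from either end) the score is
#' `min(best prefix similarity, best suffix similarity) - best full-read
#' similarity`; the verdict is chimeric when the best such score reaches
#' `min_improvement` and the best prefix and suffix parents differ.
#' Similarities are the fraction of a segment's words found in a reference's
#' word set. Both strands are evaluated, so the verdict is invariant to
#' reverse complementation; breakpoints are reported in forward-read
#' coordinates.
#'
#' Reads shorter than `2 * min_segment` get status `"too_short"` and are
#' never flagged.
#'
#' @param unique_reads Tibble with `sequence` and optionally `id`, `count`.
#' @param index A [build_word_index()] result.
#' @param min_segment Minimum bases on each side of a breakpoint, default 60.
#' @param min_improvement Minimum similarity improvement over the best
#'   single reference, default 0.10.
#' @return Verdict tibble: `id`, `is_chimera`, `status` (`ok`, `chimeric`,
#'   `too_short`), `parent_a`, `parent_b`, `breakpoint` (forward query
#'   coordinate), `score` (improvement), `full_similarity`.
#' @export
detect_chimeras <- function(unique_reads, index, min_segment = 60,
                            min_improvement = 0.10) {
  ids <- col_or(unique_reads, "id", sprintf("seq%06d", seq_len(nrow(unique_reads))))
  rows <- purrr::map(seq_len(nrow(unique_reads)), function(i) {
    v <- chimera_verdict_one(unique_reads$sequence[i], index,
                             min_segment, min_improvement)
    v$id <- ids[i]
    v
  })
  dplyr::bind_rows(rows) |>
    dplyr::select("id", dplyr::everything())
}

chimera_verdict_one <- function(seq, index, min_segment, min_improvement) {
  k <- index$word_length
  if (min_segment < k) abort("min_segment must be >= the index word length")
  len <- nchar(seq)
  blank <- tibble(
    is_chimera = FALSE, status = "ok",
    parent_a = NA_character_, parent_b = NA_character_,
    breakpoint = NA_integer_, score = NA_real_, full_similarity = NA_real_
  )
  if (len < 2 * min_segment) {
    blank$status <- "too_short"
    return(blank)
  }

  best <- list(score = -Inf, bp = NA_integer_, pa = NA_character_,
               pb = NA_character_, full = 0)
  for (strand in c("forward", "reverse")) {
    s <- if (strand == "forward") seq else reverse_complement(seq)
    words <- kmer_sequence(s, k)
    W <- length(words)
    member <- vapply(index$word_sets,
                     function(ws) !is.na(words) & words %in% ws,
                     logical(W))
    if (is.null(dim(member))) member <- matrix(member, nrow = W)
    cum <- apply(member, 2, cumsum)
    if (is.null(dim(cum))) cum <- matrix(cum, nrow = W)
    totals <- cum[W, ]
    full <- max(totals) / W
    best$full <- max(best$full, full)

    bps <- seq(min_segment, len - min_segment, by = k)
    for (b in bps) {
      p <- b - k + 1L            # words fully inside [0, b)
      s_n <- W - b               # words fully inside [b, len)
      if (p < 1 || s_n < 1) next
      pre_sim <- cum[p, ] / p
      suf_sim <- (totals - cum[b, ]) / s_n
      ia <- which.max(pre_sim)
      ib <- which.max(suf_sim)
      sc <- min(pre_sim[ia], suf_sim[ib])
      if (sc > best$score ||
          (sc == best$score && is.na(best$bp))) {
        bp_fwd <- if (strand == "forward") b else len - b
        best$score <- sc
        best$bp <- as.integer(bp_fwd)
        best$pa <- index$ref_ids[ia]
        best$pb <- index$ref_ids[ib]
      }
    }
  }
  improvement <- best$score - best$full
  blank$full_similarity <- best$full
  blank$score <- improvement
  if (is.finite(improvement) && improvement >= min_improvement &&
      !is.na(best$pa) && !is.na(best$pb) && best$pa != best$pb) {
    blank$is_chimera <- TRUE
    blank$status <- "chimeric"
    blank$parent_a <- best$pa
    blank$parent_b <- best$pb
    blank$breakpoint <- best$bp
  }
  blank
}
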