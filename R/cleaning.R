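#' Salvage high-quality regions from reads
#'
#' Instead of discarding a read whose quality dips, this extracts every
#' maximal run of consecutive bases with Phred quality at or above
#' `min_quality`, keeping runs of at least `min_length` bases as sub-reads.
#' Bases below the threshold never appear in the output. Reads without
#' qualities pass through whole, flagged in the `whole_read` column.
#'
#' @param reads Tibble with `id`, `sequence` and a `qualities` list-column
#'   (integer Phred scores per base; `NULL` entries allowed).
#' @param min_quality Phred threshold a base must meet, default 20.
#' @param min_length Minimum salvaged region length, default 50.
#' @return Tibble of sub-reads: `id` (parent id plus coordinates),
#'   `parent_id`, `start`, `end` (0-based half-open on the parent),
#'   `sequence`, `qualities`, `whole_read`.
#' @examples
#' reads <- tibble::tibble(
#'   id = "r1", sequence = strrep("A", 15),
#'   qualities = list(c(rep(40L, 6), rep(2L, 3), rep(40L, 6)))
#' )
#' extract_quality_regions(reads, min_quality = 20, min_length = 5)
#' @export
extract_quality_regions <- function(reads, min_quality = 20, min_length = 50) {
  if (min_length < 1) abort("min_length must be >= 1")
  empty <- tibble(
    id = character(), parent_id = character(),
    start = integer(), end = integer(),
    sequence = character(), qualities = list(), whole_read = logical()
  )
  if (nrow(reads) == 0) return(empty)
  quals <- if ("qualities" %in% names(reads)) reads$qualities else vector("list", nrow(reads))
  pieces <- purrr::pmap(
    list(reads$id, reads$sequence, quals),
    function(id, seq, q) {
      len <- nchar(seq)
      if (is.null(q)) {
        return(tibble(
          id = id, parent_id = id, start = 0L, end = len,
          sequence = seq, qualities = list(NULL), whole_read = TRUE
        ))
      }
      if (length(q) != len) {
        abort(sprintf("read '%s': %d qualities for %d bases", id, length(q), len))
      }
      r <- rle(q >= min_quality)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= min_length
      if (!any(keep)) return(NULL)
      s <- starts[keep]
      e <- ends[keep]
      tibble(
        id = sprintf("%s/%d-%d", id, s - 1L, e),
        parent_id = id,
        start = s - 1L,
        end = e,
        sequence = substring(seq, s, e),
        qualities = purrr::map2(s, e, ~ q[.x:.y]),
        whole_read = FALSE
      )
    }
  )
  out <- dplyr::bind_rows(pieces)
  if (nrow(out) == 0) empty else out
}

#' Filter reads or sub-reads by length (and optionally ambiguity content)
#'
#' Keeps items whose sequence length lies in `[min_len, max_len]`, preserving
#' input order. When `max_n_frac` is set, items whose fraction of `N` bases
#' exceeds it are also dropped -- base-calling ambiguity is handled here
#' rather than conflated with quality trimming.
#'
#' @param items Tibble with a `sequence` column.
#' @param min_len Minimum length, >= 1.
#' @param max_len Optional maximum length (`NULL` for none).
#' @param max_n_frac Optional maximum tolerated fraction of `N` bases.
#' @return The surviving rows, same columns, same order.
#' @export
filter_length <- function(items, min_len = 50, max_len = NULL, max_n_frac = NULL) {
  if (min_len < 1) abort("min_len must be >= 1")
  if (!is.null(max_len) && min_len > max_len) abort("min_len exceeds max_len")
  if (nrow(items) == 0) return(items)
  len <- nchar(items$sequence)
  keep <- len >= min_len
  if (!is.null(max_len)) keep <- keep & len <= max_len
  if (!is.null(max_n_frac)) {
    n_count <- stringr::str_count(items$sequence, stringr::fixed("N"))
    keep <- keep & (n_count / len) <= max_n_frac
  }
  items[keep, , drop = FALSE]
}

#' Dereplicate reads into unique sequences with counts
#'
#' Exact-sequence dereplication on the forward strand: identical sequences
#' collapse to one record carrying a multiplicity count and the contributing
#' ids. Strand canonicalisation happens later, in similarity search, so
#' dereplication stays order-independent.
#'
#' @param items Tibble with `id` and `sequence` columns.
#' @return Tibble of unique reads: `sequence`, `count`, `member_ids`
#'   (list-column), sorted by descending count then sequence.
#' @examples
#' reads <- tibble::tibble(id = paste0("r", 1:3),
#'                         sequence = c("ACGT", "TTTT", "ACGT"))
#' dereplicate(reads)
#' @export
dereplicate <- function(items) {
  if (nrow(items) == 0) {
    return(tibble(sequence = character(), count = integer(), member_ids = list()))
  }
  items |>
    dplyr::group_by(sequence = .data$sequence) |>
    dplyr::summarise(
      count = dplyr::n(),
      member_ids = list(.data$id),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$sequence)
}
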