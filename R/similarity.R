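#' Distinct k-mers of a sequence
#'
#' Words containing ambiguous (non-ACGT) bases contribute no k-mers.
#'
#' @param sequence DNA string.
#' @param k Word length.
#' @return Character vector of distinct k-mers, in order of first occurrence.
#' @export
kmer_set <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1L)
  words <- substring(sequence, starts, starts + k - 1L)
  unique(words[!grepl("[^ACGT]", words)])
}

# k-mers in positional order (duplicates kept, ambiguous words NA) -- used by
# the chimera breakpoint scan, which needs word coordinates.
kmer_sequence <- function(sequence, k) {
  n <- nchar(sequence)
  if (n < k) return(character())
  starts <- seq_len(n - k + 1L)
  words <- substring(sequence, starts, starts + k - 1L)
  words[grepl("[^ACGT]", words)] <- NA_character_
  words
}

#' Build a word (k-mer) index over a reference set
#'
#' Indexes the forward strand of every reference; queries are searched on
#' both strands by [search_index()]. Default `k = 8`: long enough to be
#' discriminative on ~1.5 kb SSU rRNA references, short enough that ~100 nt
#' fragments still carry tens of words.
#'
#' @param references Tibble with `ref_id` and `sequence` columns (e.g. from
#'   [read_reference_set()]).
#' @param word_length Word length k, default 8.
#' @return A `word_index` object.
#' @export
build_word_index <- function(references, word_length = 8) {
  if (word_length < 1) abort("word_length must be >= 1")
  short <- which(nchar(references$sequence) < word_length)
  if (length(short) > 0) {
    abort(sprintf(
      "reference '%s' is shorter than the word length %d",
      references$ref_id[short[1]], word_length
    ))
  }
  word_sets <- purrr::map(references$sequence, kmer_set, k = word_length)
  names(word_sets) <- references$ref_id
  postings <- split(
    rep(seq_along(word_sets), lengths(word_sets)),
    unlist(word_sets)
  )
  structure(
    list(
      word_length = word_length,
      ref_ids = references$ref_id,
      word_sets = word_sets,
      word_counts = lengths(word_sets),
      postings = postings
    ),
    class = "word_index"
  )
}

#' @export
print.word_index <- function(x, ...) {
  cat(sprintf(
    "<word_index> k = %d, %d references, %d distinct words\n",
    x$word_length, length(x$ref_ids), length(x$postings)
  ))
  invisible(x)
}

#' Word-set similarity between a query and a reference
#'
#' Fraction of the query's distinct k-mers found among the reference's
#' distinct k-mers. Query-normalised by design (not Jaccard): fragments are
#' much shorter than the near-full-length references, and an exact substring
#' should score 1.
#'
#' @param query,reference DNA strings.
#' @param k Word length.
#' @return Similarity in \[0, 1\].
#' @examples
#' word_similarity("ACGTACGTAC", "ACGTACGTTTTT", k = 8)  # 1/3
#' @export
word_similarity <- function(query, reference, k = 8) {
  qw <- kmer_set(query, k)
  if (length(qw) == 0) abort("query shorter than the word length (or all-ambiguous)")
  rw <- kmer_set(reference, k)
  sum(qw %in% rw) / length(qw)
}

# Shared-word counts of one word multiset against the index, via postings.
shared_counts <- function(words, index) {
  hits <- unlist(index$postings[unique(words)], use.names = FALSE)
  if (is.null(hits)) hits <- integer()
  tabulate(hits, nbins = length(index$ref_ids))
}

#' Search a query against a word index
#'
#' Evaluates the query and its reverse complement, keeps the better strand
#' per reference, and returns hits at or above `min_similarity` ranked by
#' descending similarity (ties by reference id).
#'
#' @param query DNA string.
#' @param index A [build_word_index()] result.
#' @param min_similarity Minimum query-normalised similarity to report.
#' @param max_hits Maximum number of hits returned.
#' @return Tibble with `ref_id`, `similarity`, `shared_words`, `strand`
#'   (`"forward"`/`"reverse"`).
#' @export
search_index <- function(query, index, min_similarity = 0.4, max_hits = 25) {
  k <- index$word_length
  qw_f <- kmer_set(query, k)
  if (length(qw_f) == 0) abort("query shorter than the word length (or all-ambiguous)")
  qw_r <- kmer_set(reverse_complement(query), k)
  shared_f <- shared_counts(qw_f, index)
  shared_r <- shared_counts(qw_r, index)
  sim_f <- shared_f / length(qw_f)
  sim_r <- if (length(qw_r) > 0) shared_r / length(qw_r) else rep(0, length(shared_r))
  use_rev <- sim_r > sim_f
  sim <- ifelse(use_rev, sim_r, sim_f)
  shared <- ifelse(use_rev, shared_r, shared_f)
  keep <- which(sim >= min_similarity & shared > 0)
  out <- tibble(
    ref_id = index$ref_ids[keep],
    similarity = sim[keep],
    shared_words = as.integer(shared[keep]),
    strand = ifelse(use_rev[keep], "reverse", "forward")
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$similarity), .data$ref_id)
  head(out, max_hits)
}
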