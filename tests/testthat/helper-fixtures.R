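# Shared fixture builders and independent oracles. Everything is generated
# in code; no data files.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Brute-force word similarity: explicit double loop over query words,
# independent of the package's set-based implementation.
oracle_word_similarity <- function(query, reference, k) {
  q_words <- unique(vapply(seq_len(nchar(query) - k + 1),
                           function(i) substr(query, i, i + k - 1),
                           character(1)))
  r_words <- vapply(seq_len(nchar(reference) - k + 1),
                    function(i) substr(reference, i, i + k - 1),
                    character(1))
  hits <- 0
  for (w in q_words) {
    if (any(r_words == w)) hits <- hits + 1  # linear scan, no set machinery
  }
  hits / length(q_words)
}

# Unbanded semi-global alignment score via Biostrings (full dynamic
# programme; query global, reference local; same gap cost convention).
oracle_alignment_score <- function(query, reference) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  Biostrings::score(Biostrings::pairwiseAlignment(
    query, reference, type = "global-local",
    substitutionMatrix = mat, gapOpening = 2, gapExtension = 1
  ))
}

# A pair of references of bounded identity: mutate a common root twice.
divergent_ref_pair <- function(length = 400, divergence = 0.12, seed = 1) {
  refs <- generate_reference_set(n_taxa = 2, length = length,
                                 divergence = divergence, seed = seed)
  refs
}

# 50/50 two-parent chimeras from a reference tibble.
make_chimeras <- function(references, n, segment = 150, seed = 1) {
  withr::with_seed(seed, {
    pairs <- replicate(n, sample(nrow(references), 2))
    tibble::tibble(
      id = sprintf("chim%04d", seq_len(n)),
      sequence = vapply(seq_len(n), function(i) {
        a <- references$sequence[pairs[1, i]]
        b <- references$sequence[pairs[2, i]]
        start <- sample(nchar(a) - 2 * segment, 1)
        paste0(substr(a, start, start + segment - 1),
               substr(b, start + segment, start + 2 * segment - 1))
      }, character(1))
    )
  })
}

# Reads tibble from bare sequences.
reads_tbl <- function(sequences, ids = sprintf("r%03d", seq_along(sequences))) {
  tibble::tibble(id = ids, sequence = sequences)
}
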