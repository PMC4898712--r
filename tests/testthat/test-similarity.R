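test_that("word similarity handles identity, disjoint and partial overlap", {
  expect_equal(word_similarity("ACGTACGTAC", "ACGTACGTAC", k = 8), 1.0)
  expect_equal(word_similarity("ACGTACGTAC", "TTTTTTTTTT", k = 8), 0.0)
  # query has 3 distinct 8-mers, only ACGTACGT occurs in the reference
  expect_equal(word_similarity("ACGTACGTAC", "ACGTACGTTTTT", k = 8), 1 / 3)
  expect_error(word_similarity("ACGT", "ACGTACGTAC", k = 8), "word length")
})

test_that("word similarity equals the brute-force set-intersection oracle", {
  withr::with_seed(101, {
    for (k in c(6, 8, 10)) {
      for (rep in 1:40) {
        q <- random_dna(sample(k:200, 1))
        r <- random_dna(sample(k:200, 1))
        expect_equal(word_similarity(q, r, k), oracle_word_similarity(q, r, k))
      }
    }
  })
})

test_that("the word index posts every word of every reference", {
  refs <- tibble::tibble(ref_id = c("a", "b"),
                         sequence = c("ACGTACGTA", "TTACGTACGT"))
  idx <- build_word_index(refs, word_length = 8)
  expect_setequal(idx$postings[["ACGTACGT"]], c(1L, 2L))
  expect_equal(idx$ref_ids[idx$postings[["CGTACGTA"]]], "a")
  expect_equal(idx$ref_ids[idx$postings[["TTACGTAC"]]], "b")
  expect_error(build_word_index(refs, word_length = 11), "'a'")
})

test_that("search retrieves references on either strand and ranks by similarity", {
  refs <- generate_reference_set(n_taxa = 4, length = 500, divergence = 0.2,
                                 seed = 5)
  idx <- build_word_index(refs)
  # self-retrieval: every reference finds itself at similarity 1, forward
  for (i in seq_len(nrow(refs))) {
    hits <- search_index(refs$sequence[i], idx)
    expect_equal(hits$ref_id[1], refs$ref_id[i])
    expect_equal(hits$similarity[1], 1.0)
    expect_equal(hits$strand[1], "forward")
  }
  # a reverse-complemented fragment hits its source on the reverse strand
  frag <- reverse_complement(substr(refs$sequence[2], 100, 260))
  hits <- search_index(frag, idx)
  expect_equal(hits$ref_id[1], refs$ref_id[2])
  expect_equal(hits$similarity[1], 1.0)
  expect_equal(hits$strand[1], "reverse")
  # an unrelated random sequence stays far below the similarity floor
  withr::with_seed(9, foreign <- random_dna(120))
  expect_equal(nrow(search_index(foreign, idx, min_similarity = 0.4)), 0)
})

test_that("banded alignment reproduces substring, substitution and deletion structure", {
  withr::with_seed(33, {
    ref <- random_dna(300)

    q <- substr(ref, 51, 170)
    aln <- align_pair(q, ref)
    expect_equal(unique(aln$ops), "match")
    expect_equal(c(aln$ref_start, aln$ref_end), c(50, 170))
    expect_equal(aln$score, 120)

    # one substitution: exactly one mismatch column
    qc <- strsplit(q, "")[[1]]
    qc[60] <- setdiff(c("A", "C", "G", "T"), qc[60])[1]
    aln <- align_pair(paste(qc, collapse = ""), ref)
    expect_equal(sum(aln$ops == "mismatch"), 1)
    expect_equal(sum(aln$ops %in% c("insertion", "deletion")), 0)

    # one deleted base: exactly one deletion column
    aln <- align_pair(paste(strsplit(q, "")[[1]][-60], collapse = ""), ref)
    expect_equal(sum(aln$ops == "deletion"), 1)
    expect_equal(sum(aln$ops == "mismatch"), 0)
  })
})

test_that("banded alignment score equals the unbanded full-DP oracle", {
  withr::with_seed(77, {
    for (rep in 1:60) {
      n_r <- sample(60:300, 1)
      r <- random_dna(n_r)
      qs <- sample(seq_len(n_r - 40), 1)
      ql <- sample(30:min(200, n_r - qs + 1), 1)
      qc <- strsplit(substr(r, qs, qs + ql - 1), "")[[1]]
      n_sub <- sample(0:6, 1)
      idx <- sample(length(qc), n_sub)
      qc[idx] <- sample(c("A", "C", "G", "T"), n_sub, replace = TRUE)
      if (runif(1) < 0.4 && length(qc) > 12) qc <- qc[-sample(length(qc), 2)]
      q <- paste(qc, collapse = "")
      expect_equal(align_pair(q, r)$score, oracle_alignment_score(q, r))
    }
  })
})

test_that("alignment projections reproduce the input substrings", {
  withr::with_seed(55, {
    for (rep in 1:10) {
      r <- random_dna(200)
      q <- substr(r, 31, 150)
      qc <- strsplit(q, "")[[1]]
      qc[sample(length(qc), 3)] <- sample(c("A", "C", "G", "T"), 3, TRUE)
      q <- paste(qc[-5], collapse = "")
      aln <- align_pair(q, r)
      expect_equal(gsub("-", "", aln$aligned_query), q)
      expect_equal(gsub("-", "", aln$aligned_ref),
                   substr(r, aln$ref_start + 1, aln$ref_end))
      expect_equal(nchar(aln$aligned_query), length(aln$ops))
    }
  })
})
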