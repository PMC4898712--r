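make_taxonomy <- function() {
  taxonomy_table(
    ref_id = c("t1", "t2", "t3", "t4"),
    lineage = c(
      "Bacteria;Spirochaetes;Spirochaetia;Spirochaetales;Spirochaetaceae;Treponema",
      "Bacteria;PhylX;ClassX;OrderX;FamX;GenA",
      "Bacteria;PhylX;ClassX;OrderX;FamX;GenB",
      "Bacteria;PhylY;ClassY;OrderY;FamY;GenC"
    )
  )
}

hit_tbl <- function(ref_id, similarity) {
  tibble::tibble(ref_id = ref_id, similarity = similarity,
                 shared_words = 10L,
                 strand = rep("forward", length(ref_id)))
}

test_that("taxonomy projection assigns by LCA over the top window", {
  tax <- make_taxonomy()

  single <- project_to_taxonomy(hit_tbl("t1", 0.95), tax)
  expect_equal(single$status, "classified")
  expect_equal(single$genus, "Treponema")
  expect_equal(single$depth, 6L)
  expect_equal(single$score, 0.95)

  # two near-tied genera sharing a family resolve to the family
  fam <- project_to_taxonomy(hit_tbl(c("t2", "t3"), c(0.90, 0.89)), tax)
  expect_equal(fam$status, "classified")
  expect_equal(fam$family, "FamX")
  expect_true(is.na(fam$genus))
  expect_equal(fam$depth, 5L)

  # the second hit outside the window does not vote
  deep <- project_to_taxonomy(hit_tbl(c("t2", "t3"), c(0.90, 0.85)), tax)
  expect_equal(deep$genus, "GenA")

  # low-similarity and empty hit sets are reported, not dropped
  expect_equal(project_to_taxonomy(hit_tbl("t1", 0.30), tax,
                                   min_similarity = 0.5)$status,
               "unclassified")
  expect_equal(project_to_taxonomy(hit_tbl(character(), numeric()), tax)$status,
               "unclassified")

  expect_error(project_to_taxonomy(hit_tbl("nope", 0.9), tax), "nope")
})

test_that("adding a voting hit never deepens the assignment (LCA monotonicity)", {
  tax <- make_taxonomy()
  withr::with_seed(13, {
    for (rep in 1:25) {
      ids <- sample(tax$ref_id, sample(1:4, 1))
      sims <- sort(runif(length(ids), 0.6, 1.0), decreasing = TRUE)
      base <- project_to_taxonomy(hit_tbl(ids, sims), tax, top_window = 1)
      extra_id <- sample(tax$ref_id, 1)
      more <- project_to_taxonomy(
        hit_tbl(c(ids, extra_id), c(sims, min(sims))), tax, top_window = 1
      )
      expect_lte(more$depth, base$depth)
    }
  })
})

test_that("variable-region screening measures reference-footprint overlap", {
  withr::with_seed(99, ref <- random_dna(400))
  q <- substr(ref, 101, 200)  # aligns to [100, 200)
  aln <- align_pair(q, ref)
  expect_equal(c(aln$ref_start, aln$ref_end), c(100, 200))

  fully_inside <- tibble::tibble(start = 50L, end = 300L)
  sc <- screen_variable_region(aln, fully_inside)
  expect_equal(sc$overlap_fraction, 1.0)
  expect_true(sc$informative)

  outside <- tibble::tibble(start = 300L, end = 380L)
  sc <- screen_variable_region(aln, outside)
  expect_equal(sc$overlap_fraction, 0.0)
  expect_false(sc$informative)

  # 25 of the 100 aligned positions fall inside regions
  quarter <- tibble::tibble(start = c(110L, 150L), end = c(120L, 165L))
  sc <- screen_variable_region(aln, quarter, min_overlap = 0.25)
  expect_equal(sc$overlap_fraction, 0.25)
  expect_true(sc$informative)

  bad <- tibble::tibble(start = c(10L, 5L), end = c(20L, 9L))
  expect_error(screen_variable_region(aln, bad), "sorted")
})

test_that("abundance aggregation reproduces density arithmetic", {
  ass <- tibble::tibble(
    id = paste0("r", 1:3), weight = c(9953, 1, 46),
    status = "classified", score = 0.9,
    lineage = c("Bacteria", "Archaea", "Eukarya"),
    domain = c("Bacteria", "Archaea", "Eukarya"),
    phylum = NA_character_, class = NA_character_, order = NA_character_,
    family = NA_character_, genus = NA_character_, depth = 1L
  )
  tab <- aggregate_taxa(ass, rank = "domain", group = "all")
  expect_equal(tab$density[match(c("Bacteria", "Archaea", "Eukarya"), tab$taxon)],
               c(99.53, 0.01, 0.46))

  one <- aggregate_taxa(ass[1, ], rank = "domain", group = "all")
  expect_equal(one$density, 100)
})

test_that("five dominant phyla of a constructed community sum to 92.5%", {
  phyla <- c("Actinobacteria", "Bacteroidetes", "Firmicutes",
             "Proteobacteria", "Spirochaetes", "Other")
  weights <- c(36, 262, 108, 416, 103, 75)
  ass <- tibble::tibble(
    id = paste0("r", seq_along(phyla)), weight = weights,
    status = "classified", score = 0.9,
    lineage = paste0("Bacteria;", phyla),
    domain = "Bacteria", phylum = phyla,
    class = NA_character_, order = NA_character_, family = NA_character_,
    genus = NA_character_, depth = 2L
  )
  tab <- aggregate_taxa(ass, rank = "phylum", group = "within_domain")
  top5 <- tab$density[tab$taxon != "Other"]
  expect_equal(sum(top5), 92.5)
})

test_that("densities sum to 100 within every normalisation group", {
  refs <- generate_reference_set(n_taxa = 6, length = 600, divergence = 0.15,
                                 split_rank = "phylum", seed = 3)
  idx <- build_word_index(refs)
  withr::with_seed(17, {
    fr <- fragment_reads(refs, 300, min_length = 60, max_length = 200, seed = 17)
    ass <- classify_reads(dereplicate(fr$reads), idx, refs)
    for (rank in c("domain", "phylum", "genus")) {
      tab <- aggregate_taxa(ass, rank = rank, group = "within_domain")
      grp <- if ("domain" %in% names(tab)) tab$domain else rep("all", nrow(tab))
      sums <- tapply(tab$density, grp, sum)
      expect_true(all(abs(sums - 100) < 0.01))
    }
  })
})

test_that("assignments shallower than the rank pool under their parent", {
  ass <- tibble::tibble(
    id = c("a", "b"), weight = c(3, 1),
    status = "classified", score = 0.8,
    lineage = c("Bacteria;PhylX", "Bacteria"),
    domain = "Bacteria", phylum = c("PhylX", NA),
    class = NA_character_, order = NA_character_, family = NA_character_,
    genus = NA_character_, depth = c(2L, 1L)
  )
  tab <- aggregate_taxa(ass, rank = "phylum", group = "within_domain")
  expect_setequal(tab$taxon, c("PhylX", "unclassified Bacteria"))
  expect_equal(sum(tab$density), 100)
})
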