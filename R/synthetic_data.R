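#' Generate a synthetic SSU rRNA-like reference set
#'
#' Draws a random root sequence and mutates it independently per taxon to a
#' target divergence (each taxon differs from the root at exactly
#' `round(divergence * length)` positions). Lineages share all ranks above
#' `split_rank` and are distinct from `split_rank` downward, so taxa are
#' separable at exactly the chosen rank.
#'
#' @param n_taxa Number of reference taxa, >= 1.
#' @param length Reference length in nt (~1500 emulates a full-length SSU
#'   rRNA gene).
#' @param divergence Per-taxon fraction of mutated positions, in
#'   \[0, 0.5\].
#' @param split_rank Rank at which lineages diverge, default `"genus"`.
#' @param seed Seed; identical seeds give identical reference sets.
#' @return Tibble with `ref_id`, `sequence`, `lineage` and rank columns
#'   (the [read_reference_set()] shape).
#' @export
generate_reference_set <- function(n_taxa = 5, length = 1500,
                                   divergence = 0.10, split_rank = "genus",
                                   seed = 1) {
  if (n_taxa < 1) abort("n_taxa must be >= 1")
  if (divergence < 0 || divergence > 0.5) abort("divergence must lie in [0, 0.5]")
  split_rank <- match.arg(split_rank, TAXONOMIC_RANKS)
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    root <- sample(bases, length, replace = TRUE)
    n_mut <- round(divergence * length)
    seqs <- vapply(seq_len(n_taxa), function(i) {
      s <- root
      if (n_mut > 0) {
        pos <- sample.int(length, n_mut)
        s[pos] <- vapply(s[pos], function(b) sample(setdiff(bases, b), 1),
                         character(1))
      }
      paste(s, collapse = "")
    }, character(1))
    si <- match(split_rank, TAXONOMIC_RANKS)
    lineages <- vapply(seq_len(n_taxa), function(i) {
      shared <- c("Bacteria", paste0("Synth",
                                     tools::toTitleCase(TAXONOMIC_RANKS[-1])))
      ranks <- shared
      if (si <= length(TAXONOMIC_RANKS)) {
        deep <- seq(si, length(TAXONOMIC_RANKS))
        ranks[deep] <- sprintf("%s_%02d", tools::toTitleCase(TAXONOMIC_RANKS[deep]), i)
      }
      paste(ranks, collapse = ";")
    }, character(1))
    dplyr::bind_cols(
      tibble(ref_id = sprintf("ref_%02d", seq_len(n_taxa)), sequence = seqs),
      taxonomy_table(sprintf("ref_%02d", seq_len(n_taxa)), lineages)[-1]
    )
  })
}

#' Generate randomly fragmented reads from a reference set
#'
#' Emulates random-primed reverse transcription of rRNA: each read comes
#' from a reference drawn by the composition proportions, starts at a
#' uniformly random position, takes its length from the configured
#' distribution (clipped at the reference end), and is reverse-complemented
#' with probability `strand_mix` (0.5 by default, since second-strand
#' synthesis yields both strands). Truth labels are recorded in a sidecar
#' table.
#'
#' @param references Reference tibble (`ref_id`, `sequence`).
#' @param n_reads Number of reads to generate.
#' @param proportions Per-reference composition, summing to 1; uniform when
#'   `NULL`.
#' @param length_dist `"uniform"` or `"normal"`.
#' @param min_length,max_length Bounds of the uniform length distribution
#'   (also truncation bounds for `"normal"`).
#' @param length_mean,length_sd Parameters for `length_dist = "normal"`.
#' @param strand_mix Probability a read is emitted as the reverse
#'   complement.
#' @param seed Seed; identical seeds give identical read sets.
#' @return List with `reads` (tibble `id`, `sequence`) and `truth` (tibble
#'   `id`, `ref_id`, `start`, `end` 0-based half-open on the reference,
#'   `strand`).
#' @export
fragment_reads <- function(references, n_reads, proportions = NULL,
                           length_dist = c("uniform", "normal"),
                           min_length = 60, max_length = 400,
                           length_mean = 200, length_sd = 60,
                           strand_mix = 0.5, seed = 1) {
  length_dist <- match.arg(length_dist)
  if (n_reads < 1) abort("n_reads must be >= 1")
  if (min_length < 1) abort("fragment length must be positive")
  n_ref <- nrow(references)
  if (is.null(proportions)) proportions <- rep(1 / n_ref, n_ref)
  if (length(proportions) != n_ref) abort("one proportion per reference required")
  if (abs(sum(proportions) - 1) > 1e-9) abort("proportions must sum to 1")
  ref_len <- nchar(references$sequence)
  withr::with_seed(seed, {
    src <- sample.int(n_ref, n_reads, replace = TRUE, prob = proportions)
    len <- switch(length_dist,
      uniform = sample(seq(min_length, max_length), n_reads, replace = TRUE),
      normal = pmin(max_length, pmax(min_length,
        round(rnorm(n_reads, length_mean, length_sd))))
    )
    start <- floor(runif(n_reads) * ref_len[src])  # 0-based
    end <- pmin(start + len, ref_len[src])
    rc <- runif(n_reads) < strand_mix
    frag <- substring(references$sequence[src], start + 1, end)
    frag[rc] <- reverse_complement(frag[rc])
    ids <- sprintf("read%06d", seq_len(n_reads))
    list(
      reads = tibble(id = ids, sequence = frag),
      truth = tibble(
        id = ids, ref_id = references$ref_id[src],
        start = as.integer(start), end = as.integer(end),
        strand = ifelse(rc, "reverse", "forward")
      )
    )
  })
}

#' Apply a sequencing error and quality model to reads
#'
#' Per-base substitutions and indels at the given rates, plus emitted Phred
#' qualities: base qualities are drawn around `quality_mean`, and with
#' probability `dropout_rate` per read a contiguous low-quality stretch
#' (quality `dropout_quality`) is injected, emulating the local quality
#' collapses that the salvage stage of the cleaning module is built for.
#' Zero rates leave sequences unchanged.
#'
#' @param reads Tibble with `id`, `sequence`.
#' @param substitution_rate,indel_rate Per-base event probabilities.
#' @param quality_mean,quality_sd Phred quality distribution of ordinary
#'   bases.
#' @param dropout_rate Per-read probability of a low-quality stretch.
#' @param dropout_quality Phred score inside a dropout stretch.
#' @param dropout_length Range (min, max) of dropout stretch lengths.
#' @param seed Seed.
#' @return Tibble with `id`, `sequence`, `qualities` list-column.
#' @export
apply_errors <- function(reads, substitution_rate = 0.01, indel_rate = 0.001,
                         quality_mean = 35, quality_sd = 3,
                         dropout_rate = 0, dropout_quality = 5,
                         dropout_length = c(10, 30), seed = 1) {
  if (substitution_rate < 0 || substitution_rate > 1 ||
      indel_rate < 0 || indel_rate > 1) {
    abort("rates must lie in [0, 1]")
  }
  bases <- c("A", "C", "G", "T")
  withr::with_seed(seed, {
    out <- purrr::map(reads$sequence, function(seq) {
      s <- strsplit(seq, "")[[1]]
      n <- length(s)
      if (substitution_rate > 0) {
        sub_at <- which(runif(n) < substitution_rate)
        s[sub_at] <- vapply(s[sub_at], function(b) {
          sample(setdiff(bases, b), 1)
        }, character(1))
      }
      if (indel_rate > 0) {
        ind_at <- which(runif(length(s)) < indel_rate)
        for (p in rev(ind_at)) {  # right-to-left keeps positions valid
          if (runif(1) < 0.5 && length(s) > 1) {
            s <- s[-p]
          } else {
            s <- append(s, sample(bases, 1), after = p)
          }
        }
      }
      n <- length(s)
      q <- pmin(40L, pmax(2L, as.integer(round(rnorm(n, quality_mean, quality_sd)))))
      if (dropout_rate > 0 && runif(1) < dropout_rate && n > dropout_length[1]) {
        dl <- min(n, sample(seq(dropout_length[1], dropout_length[2]), 1))
        dstart <- sample.int(n - dl + 1, 1)
        q[dstart:(dstart + dl - 1)] <- as.integer(dropout_quality)
      }
      list(sequence = paste(s, collapse = ""), qualities = q)
    })
    tibble(
      id = reads$id,
      sequence = purrr::map_chr(out, "sequence"),
      qualities = purrr::map(out, "qualities")
    )
  })
}

#' Synthetic community presets
#'
#' `"five_genus"`: five equally long references diverging at genus rank,
#' mixed at uneven proportions -- the workhorse configuration for
#' composition-recovery checks. `"table1_like"`: thirteen phylum-level taxa
#' whose proportions echo a realistic oral-microbiome phylum profile (five
#' dominant phyla plus eight minor ones), for end-to-end demonstrations.
#'
#' @param name Preset name.
#' @param seed Seed forwarded to reference generation.
#' @return List with `references`, `proportions` and the `split_rank` used.
#' @export
synth_preset <- function(name = c("five_genus", "table1_like"), seed = 1) {
  name <- match.arg(name)
  if (name == "five_genus") {
    refs <- generate_reference_set(n_taxa = 5, length = 1500,
                                   divergence = 0.10, split_rank = "genus",
                                   seed = seed)
    props <- c(0.30, 0.25, 0.20, 0.15, 0.10)
  } else {
    props <- c(3.6, 0.1, 26.2, 1.5, 0.4, 3.0, 0.3, 10.8, 0.5, 41.6, 10.3,
               0.9, 0.5)
    props <- props / sum(props)
    refs <- generate_reference_set(n_taxa = length(props), length = 1500,
                                   divergence = 0.12, split_rank = "phylum",
                                   seed = seed)
  }
  list(references = refs, proportions = props,
       split_rank = attr(refs, "split_rank") %||%
         (if (name == "five_genus") "genus" else "phylum"))
}
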