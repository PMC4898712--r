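#' Project similarity hits onto the reference taxonomy
#'
#' Implements lowest-common-ancestor (LCA) assignment: all hits whose
#' similarity lies within `top_window` of the best hit vote, and the read is
#' assigned the deepest rank on which all voting references agree. Fragment
#' similarity scores are coarse-grained, so near-ties share the vote rather
#' than letting the single best hit decide.
#'
#' @param hits Tibble of hits sorted by descending similarity (from
#'   [search_index()]).
#' @param taxonomy Taxonomy tibble with `ref_id` and rank columns (from
#'   [read_taxonomy()] or [taxonomy_table()]).
#' @param top_window Similarity window below the top hit within which hits
#'   vote, default 0.02.
#' @param min_similarity Below this top similarity the read is reported
#'   unclassified rather than dropped, default 0.40.
#' @return One-row tibble: `status` (`classified`/`unclassified`), `score`,
#'   `lineage` string, one column per rank, and `depth` (number of resolved
#'   ranks).
#' @export
project_to_taxonomy <- function(hits, taxonomy, top_window = 0.02,
                                min_similarity = 0.4) {
  unclassified <- tibble(
    status = "unclassified", score = if (nrow(hits) > 0) hits$similarity[1] else NA_real_,
    lineage = NA_character_, depth = 0L
  )
  unclassified[TAXONOMIC_RANKS] <- NA_character_
  if (nrow(hits) == 0 || hits$similarity[1] < min_similarity) {
    return(unclassified)
  }
  top <- hits$similarity[1]
  voters <- hits$ref_id[hits$similarity >= top - top_window]
  missing <- setdiff(voters, taxonomy$ref_id)
  if (length(missing) > 0) {
    abort(sprintf("reference '%s' missing from taxonomy", missing[1]))
  }
  lin <- taxonomy[match(voters, taxonomy$ref_id), TAXONOMIC_RANKS, drop = FALSE]
  consensus <- character()
  for (rank in TAXONOMIC_RANKS) {
    vals <- lin[[rank]]
    if (anyNA(vals) || length(unique(vals)) != 1) break
    consensus <- c(consensus, vals[1])
  }
  if (length(consensus) == 0) return(unclassified)
  out <- tibble(
    status = "classified", score = top,
    lineage = paste(consensus, collapse = ";"),
    depth = length(consensus)
  )
  out[TAXONOMIC_RANKS] <- NA_character_
  out[TAXONOMIC_RANKS[seq_along(consensus)]] <- as.list(consensus)
  out
}

#' Classify dereplicated reads against a word index
#'
#' Searches each unique sequence on both strands and projects the hits onto
#' the taxonomy by LCA. Sequences shorter than the word length are reported
#' unclassified.
#'
#' @param unique_reads Tibble with `sequence` and optionally `count` (weight,
#'   default 1) and `id` columns (e.g. from [dereplicate()]).
#' @param index A [build_word_index()] result.
#' @param taxonomy Taxonomy tibble covering the indexed references.
#' @inheritParams project_to_taxonomy
#' @param max_hits Maximum hits per read considered.
#' @return Assignment tibble: `id`, `weight`, `status`, `score`, `lineage`,
#'   rank columns, `depth`, `top_ref` (best reference id), `strand`.
#' @export
classify_reads <- function(unique_reads, index, taxonomy,
                           min_similarity = 0.4, top_window = 0.02,
                           max_hits = 25) {
  ids <- col_or(unique_reads, "id",
    if ("member_ids" %in% names(unique_reads)) {
      purrr::map_chr(unique_reads$member_ids, 1)
    } else {
      sprintf("seq%06d", seq_len(nrow(unique_reads)))
    })
  weights <- col_or(unique_reads, "count", rep(1L, nrow(unique_reads)))
  rows <- purrr::map(seq_len(nrow(unique_reads)), function(i) {
    seq <- unique_reads$sequence[i]
    if (nchar(seq) < index$word_length) {
      hits <- tibble(ref_id = character(), similarity = numeric(),
                     shared_words = integer(), strand = character())
    } else {
      hits <- search_index(seq, index, min_similarity = 0, max_hits = max_hits)
    }
    ass <- project_to_taxonomy(hits, taxonomy, top_window, min_similarity)
    ass$top_ref <- if (nrow(hits) > 0) hits$ref_id[1] else NA_character_
    ass$strand <- if (nrow(hits) > 0) hits$strand[1] else NA_character_
    ass
  })
  dplyr::bind_cols(
    tibble(id = ids, weight = weights),
    dplyr::bind_rows(rows)
  )
}

#' Read a BED-like variable-region map
#'
#' Three tab-separated columns without header: reference id, 0-based start,
#' end (half-open), marking variable regions (e.g. V1-V9) on a named
#' reference coordinate system.
#'
#' @param path Path to the interval file.
#' @return Tibble with `ref_id`, `start`, `end`.
#' @export
read_region_map <- function(path) {
  readr::read_tsv(
    path,
    col_names = c("ref_id", "start", "end"),
    col_types = readr::cols(
      ref_id = readr::col_character(),
      start = readr::col_integer(),
      end = readr::col_integer()
    )
  )
}

#' Screen an alignment against variable-region intervals
#'
#' Short fragments covering only conserved rRNA stretches carry little
#' phylogenetic signal. This measures how much of an alignment's reference
#' footprint falls inside user-defined variable regions. The result is a
#' flag plus a fraction, not a hard filter.
#'
#' @param alignment A [align_pair()] result.
#' @param regions Tibble of 0-based half-open `start`/`end` intervals on the
#'   aligned reference, sorted and non-overlapping.
#' @param min_overlap Fraction of aligned reference positions that must fall
#'   inside variable regions for the read to count as informative.
#' @return One-row tibble: `overlap_fraction`, `informative`.
#' @export
screen_variable_region <- function(alignment, regions, min_overlap = 0.25) {
  if (nrow(regions) > 0) {
    if (is.unsorted(regions$start) ||
        any(regions$end[-nrow(regions)] > regions$start[-1]) ||
        any(regions$end <= regions$start)) {
      abort("variable-region intervals must be sorted and non-overlapping")
    }
  }
  pos <- alignment_ref_positions(alignment)
  pos <- pos[!is.na(pos)]
  if (length(pos) == 0) {
    return(tibble(overlap_fraction = 0, informative = FALSE))
  }
  inside <- rep(FALSE, length(pos))
  for (i in seq_len(nrow(regions))) {
    inside <- inside | (pos >= regions$start[i] & pos < regions$end[i])
  }
  frac <- mean(inside)
  tibble(overlap_fraction = frac, informative = frac >= min_overlap)
}

#' Aggregate assignments into a rank-level abundance table
#'
#' Sums dereplication weights per taxon at the requested rank, reporting
#' read density (percentage of the group's classified weight). Assignments
#' resolved shallower than the rank pool under `"unclassified <parent>"`.
#' With `group = "within_domain"` densities are percentages of each domain's
#' total (the two-level presentation used for domain/phylum overviews);
#' `group = "all"` normalises over everything classified at once.
#'
#' @param assignments Assignment tibble from [classify_reads()].
#' @param rank Target rank, one of [TAXONOMIC_RANKS].
#' @param group `"within_domain"` or `"all"`.
#' @return An `abundance_table` tibble: grouping columns, `taxon`, `weight`,
#'   `density` (percent, summing to 100 within each group).
#' @export
aggregate_taxa <- function(assignments, rank = "phylum",
                           group = c("within_domain", "all")) {
  group <- match.arg(group)
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  classified <- dplyr::filter(assignments, .data$status == "classified")
  ri <- match(rank, TAXONOMIC_RANKS)
  if (nrow(classified) == 0) {
    out <- tibble(domain = character(), taxon = character(),
                  weight = numeric(), density = numeric())
    if (group == "all" || rank == "domain") out$domain <- NULL
    return(new_abundance_table(out, rank, group))
  }
  taxon <- classified[[rank]]
  shallow <- is.na(taxon)
  if (any(shallow)) {
    # deepest resolved name becomes "unclassified <parent>"
    parent <- purrr::map_chr(which(shallow), function(i) {
      vals <- unlist(classified[i, TAXONOMIC_RANKS[seq_len(ri - 1)]])
      vals <- vals[!is.na(vals)]
      if (length(vals) == 0) "root" else vals[length(vals)]
    })
    taxon[shallow] <- paste("unclassified", parent)
  }
  tab <- tibble(
    domain = col_or(classified, "domain", NA_character_),
    taxon = taxon,
    weight = classified$weight
  )
  if (group == "within_domain" && rank != "domain") {
    tab$domain[is.na(tab$domain)] <- "unclassified root"
    out <- tab |>
      dplyr::group_by(.data$domain, .data$taxon) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop_last") |>
      dplyr::mutate(density = 100 * .data$weight / sum(.data$weight)) |>
      dplyr::ungroup() |>
      dplyr::arrange(.data$domain, dplyr::desc(.data$weight))
  } else {
    out <- tab |>
      dplyr::group_by(.data$taxon) |>
      dplyr::summarise(weight = sum(.data$weight), .groups = "drop") |>
      dplyr::mutate(density = 100 * .data$weight / sum(.data$weight)) |>
      dplyr::arrange(dplyr::desc(.data$weight))
  }
  new_abundance_table(out, rank, group)
}

new_abundance_table <- function(x, rank, group) {
  structure(x, class = c("abundance_table", class(tibble())),
            rank = rank, group = group)
}
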