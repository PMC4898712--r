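#' Run the RT-rRNA fragment classification pipeline
#'
#' End-to-end processing for randomly fragmented, PCR-free rRNA reads:
#' quality-region salvage -> length/ambiguity filter -> exact dereplication
#' -> word-similarity search -> LCA taxonomy projection -> abundance
#' aggregation, with optional variable-region screening and primer-site
#' auditing. Chimera detection is skipped: chimeras are a PCR artefact and
#' this mode is for non-amplified data (see [run_amplicon_pipeline()]).
#' Everything downstream of the inputs is deterministic.
#'
#' @param reads Read tibble (`id`, `sequence`, optional `qualities`
#'   list-column), e.g. from [read_sequences()].
#' @param references Reference tibble with `ref_id`, `sequence` and rank
#'   columns, e.g. from [read_reference_set()].
#' @param min_quality,min_length Quality-salvage parameters
#'   ([extract_quality_regions()]).
#' @param max_length,max_n_frac Length filter parameters ([filter_length()]).
#' @param word_length Index word length.
#' @param min_similarity,top_window,max_hits Classification parameters
#'   ([classify_reads()]).
#' @param ranks Ranks at which abundance tables are produced.
#' @param primers Optional [primer_spec()] tibble; when given, primer sites
#'   are audited and rolled up per phylum.
#' @param region_map Optional variable-region tibble (`ref_id`, `start`,
#'   `end`); when given, classified reads are screened and flagged.
#' @param min_overlap Variable-region overlap threshold.
#' @return A `pipeline_result`: list with `assignments`, `tables` (one
#'   [aggregate_taxa()] result per rank), `audit`, `audit_summary`,
#'   `screening`, `report` and `params`.
#' @export
run_rtrna_pipeline <- function(reads, references,
                               min_quality = 20, min_length = 50,
                               max_length = NULL, max_n_frac = 0.1,
                               word_length = 8, min_similarity = 0.4,
                               top_window = 0.02, max_hits = 25,
                               ranks = c("domain", "phylum"),
                               primers = NULL, region_map = NULL,
                               min_overlap = 0.25) {
  run_pipeline_impl(reads, references, chimera = FALSE,
                    min_quality = min_quality, min_length = min_length,
                    max_length = max_length, max_n_frac = max_n_frac,
                    word_length = word_length, min_similarity = min_similarity,
                    top_window = top_window, max_hits = max_hits,
                    ranks = ranks, primers = primers, region_map = region_map,
                    min_overlap = min_overlap,
                    min_segment = 60, min_improvement = 0.10)
}

#' Run the PCR amplicon classification pipeline
#'
#' Same stages as [run_rtrna_pipeline()] plus reference-based chimera
#' detection between dereplication and search; chimeric weight is excluded
#' from abundance tables but counted in the run report.
#'
#' @inheritParams run_rtrna_pipeline
#' @param min_segment,min_improvement Chimera parameters
#'   ([detect_chimeras()]).
#' @return A `pipeline_result`, additionally carrying `chimera_verdicts`.
#' @export
run_amplicon_pipeline <- function(reads, references,
                                  min_quality = 20, min_length = 50,
                                  max_length = NULL, max_n_frac = 0.1,
                                  word_length = 8, min_similarity = 0.4,
                                  top_window = 0.02, max_hits = 25,
                                  ranks = c("domain", "phylum"),
                                  min_segment = 60, min_improvement = 0.10,
                                  primers = NULL, region_map = NULL,
                                  min_overlap = 0.25) {
  run_pipeline_impl(reads, references, chimera = TRUE,
                    min_quality = min_quality, min_length = min_length,
                    max_length = max_length, max_n_frac = max_n_frac,
                    word_length = word_length, min_similarity = min_similarity,
                    top_window = top_window, max_hits = max_hits,
                    ranks = ranks, primers = primers, region_map = region_map,
                    min_overlap = min_overlap,
                    min_segment = min_segment,
                    min_improvement = min_improvement)
}

run_pipeline_impl <- function(reads, references, chimera,
                              min_quality, min_length, max_length, max_n_frac,
                              word_length, min_similarity, top_window,
                              max_hits, ranks, primers, region_map,
                              min_overlap, min_segment, min_improvement) {
  params <- list(
    mode = if (chimera) "amplicon" else "rtrna",
    min_quality = min_quality, min_length = min_length,
    max_length = max_length, max_n_frac = max_n_frac,
    word_length = word_length, min_similarity = min_similarity,
    top_window = top_window, max_hits = max_hits,
    min_segment = min_segment, min_improvement = min_improvement
  )
  taxonomy <- dplyr::select(references, "ref_id",
                            dplyr::any_of(c("lineage", TAXONOMIC_RANKS)))
  index <- build_word_index(references, word_length)

  n_input <- nrow(reads)
  cleaned <- extract_quality_regions(reads, min_quality, min_length)
  filtered <- filter_length(cleaned, min_length, max_length, max_n_frac)
  n_filtered_out <- nrow(cleaned) - nrow(filtered)
  derep <- dereplicate(filtered)

  chimera_verdicts <- NULL
  weight_chimeric <- 0
  to_classify <- derep
  if (chimera && nrow(derep) > 0) {
    chimera_verdicts <- detect_chimeras(derep, index, min_segment,
                                        min_improvement)
    flagged <- chimera_verdicts$is_chimera
    weight_chimeric <- sum(derep$count[flagged])
    to_classify <- derep[!flagged, , drop = FALSE]
  }

  assignments <- if (nrow(to_classify) > 0) {
    classify_reads(to_classify, index, taxonomy,
                   min_similarity = min_similarity,
                   top_window = top_window, max_hits = max_hits)
  } else {
    dplyr::bind_cols(
      tibble(id = character(), weight = integer()),
      tibble(status = character(), score = numeric(),
             lineage = character(), depth = integer()),
      as_tibble(setNames(rep(list(character()), length(TAXONOMIC_RANKS)),
                         TAXONOMIC_RANKS)),
      tibble(top_ref = character(), strand = character())
    )
  }

  screening <- NULL
  if (!is.null(region_map) && nrow(assignments) > 0) {
    screening <- screen_assignments(assignments, to_classify, references,
                                    region_map, min_overlap)
    assignments <- dplyr::left_join(assignments, screening, by = "id")
  }

  tables <- purrr::map(setNames(ranks, ranks), function(r) {
    aggregate_taxa(assignments, rank = r,
                   group = if (r == "domain") "all" else "within_domain")
  })

  audit <- NULL
  audit_summary <- NULL
  if (!is.null(primers) && nrow(to_classify) > 0) {
    audit_reads_in <- tibble(
      id = assignments$id,
      sequence = to_classify$sequence
    )
    audit <- audit_reads(audit_reads_in, references, index, primers,
                         min_similarity = min_similarity)
    audit_summary <- taxon_mismatch_ratio(audit, assignments, rank = "phylum")
  }

  weight_classified <- sum(assignments$weight[assignments$status == "classified"])
  weight_unclassified <- sum(assignments$weight[assignments$status == "unclassified"])
  report <- tibble(
    metric = c("input_reads", "cleaned_subreads", "filtered_out",
               "dereplicated_unique", "weight_total", "classified",
               "unclassified", "chimeric"),
    value = c(n_input, nrow(cleaned), n_filtered_out, nrow(derep),
              nrow(filtered), weight_classified, weight_unclassified,
              weight_chimeric)
  )
  # conservation: every sub-read surviving the filter ends in exactly one bin
  stopifnot(weight_classified + weight_unclassified + weight_chimeric ==
              nrow(filtered))

  structure(
    list(assignments = assignments, tables = tables,
         chimera_verdicts = chimera_verdicts, audit = audit,
         audit_summary = audit_summary, screening = screening,
         report = report, params = params),
    class = "pipeline_result"
  )
}

# Align each classified unique read to its best reference and measure
# variable-region overlap.
screen_assignments <- function(assignments, unique_reads, references,
                               region_map, min_overlap) {
  rows <- purrr::map(seq_len(nrow(assignments)), function(i) {
    if (assignments$status[i] != "classified") {
      return(tibble(id = assignments$id[i],
                    region_overlap = NA_real_, informative = NA))
    }
    ref_id <- assignments$top_ref[i]
    regions <- region_map[region_map$ref_id == ref_id, c("start", "end")]
    query <- unique_reads$sequence[i]
    if (assignments$strand[i] == "reverse") query <- reverse_complement(query)
    aln <- align_pair(query,
                      references$sequence[references$ref_id == ref_id][1])
    sc <- screen_variable_region(aln, regions, min_overlap)
    tibble(id = assignments$id[i],
           region_overlap = sc$overlap_fraction,
           informative = sc$informative)
  })
  dplyr::bind_rows(rows)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> mode = %s\n", x$params$mode))
  rep <- setNames(x$report$value, x$report$metric)
  cat(sprintf(
    "  reads in: %d | sub-reads kept: %d | unique: %d\n",
    rep[["input_reads"]], rep[["weight_total"]], rep[["dereplicated_unique"]]
  ))
  cat(sprintf(
    "  weight classified: %d | unclassified: %d | chimeric: %d\n",
    rep[["classified"]], rep[["unclassified"]], rep[["chimeric"]]
  ))
  for (r in names(x$tables)) {
    cat(sprintf("  %s-level table: %d taxa\n", r, nrow(x$tables[[r]])))
  }
  invisible(x)
}

#' Write all tables of a pipeline result to a directory
#'
#' Emits one TSV per abundance rank plus the run report, chimera verdicts,
#' primer audit and screening tables where present.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pipeline_result <- function(result, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (r in names(result$tables)) {
    write_tsv_report(result$tables[[r]],
                     file.path(dir, sprintf("abundance_%s.tsv", r)))
  }
  write_tsv_report(result$report, file.path(dir, "run_report.tsv"))
  ass <- dplyr::select(result$assignments, -dplyr::any_of("member_ids"))
  write_tsv_report(ass, file.path(dir, "assignments.tsv"))
  if (!is.null(result$chimera_verdicts)) {
    write_tsv_report(result$chimera_verdicts,
                     file.path(dir, "chimera_verdicts.tsv"))
  }
  if (!is.null(result$audit)) {
    write_tsv_report(result$audit, file.path(dir, "primer_audit.tsv"))
    write_tsv_report(result$audit_summary,
                     file.path(dir, "primer_audit_summary.tsv"))
  }
  invisible(dir)
}
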