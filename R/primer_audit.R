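#' Reverse complement of IUPAC DNA
#'
#' Standard complement with full IUPAC ambiguity mapping, reversed.
#' Vectorised over its input.
#'
#' @param sequence Character vector of IUPAC DNA strings.
#' @return Character vector of reverse complements.
#' @examples
#' reverse_complement("ATTACCGCGGCTGCTGG")
#' @export
reverse_complement <- function(sequence) {
  out <- tryCatch(
    as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(sequence))),
    error = function(e) abort(sprintf("invalid IUPAC DNA: %s", conditionMessage(e)))
  )
  unname(out)
}

# Does the (possibly ambiguous) primer base cover the template base?
# Returns a logical vector over aligned character vectors.
iupac_covers <- function(primer_chars, template_chars) {
  map <- Biostrings::IUPAC_CODE_MAP
  p_sets <- map[primer_chars]
  t_sets <- map[template_chars]
  ok <- !is.na(p_sets) & !is.na(t_sets)
  res <- rep(FALSE, length(primer_chars))
  res[ok] <- purrr::map2_lgl(
    strsplit(t_sets[ok], ""), strsplit(p_sets[ok], ""),
    ~ all(.x %in% .y)
  )
  res
}

#' Read a primer specification table
#'
#' Tab-separated file with header columns `name`, `sequence` (5'->3') and
#' `orientation` (`forward`/`reverse`).
#'
#' @param path Path to the TSV.
#' @return Tibble with `name`, `sequence`, `orientation`.
#' @export
read_primers <- function(path) {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("name", "sequence", "orientation") %in% names(tab))) {
    abort("primer table must have columns 'name', 'sequence', 'orientation'")
  }
  primer_spec(tab$name, tab$sequence, tab$orientation)
}

#' Build a primer specification tibble
#'
#' @param name Primer names.
#' @param sequence Primer sequences, 5'->3' as ordered.
#' @param orientation `"forward"` or `"reverse"` per primer.
#' @return Tibble with `name`, `sequence`, `orientation`.
#' @examples
#' universal_v1v3_primers()
#' @export
primer_spec <- function(name, sequence, orientation) {
  sequence <- normalise_sequence(sequence)
  bad <- !grepl("^[ACGTRYSWKMBDHVN]+$", sequence)
  if (any(bad)) abort(sprintf("primer '%s' has a non-IUPAC sequence", name[bad][1]))
  if (!all(orientation %in% c("forward", "reverse"))) {
    abort("orientation must be 'forward' or 'reverse'")
  }
  tibble(name = name, sequence = sequence, orientation = orientation)
}

#' The universal bacterial V1-V3 primer pair
#'
#' The 63f / 518r 16S rRNA gene primer pair commonly used to amplify the
#' V1-V3 region.
#'
#' @return A [primer_spec()] tibble with both primers.
#' @export
universal_v1v3_primers <- function() {
  primer_spec(
    name = c("63f", "518r"),
    sequence = c("GCCTAACACATGCAAGTC", "ATTACCGCGGCTGCTGG"),
    orientation = c("forward", "reverse")
  )
}

#' Locate primer binding windows on reference sequences
#'
#' Scans each reference (forward strand) for the best-matching window of
#' each primer under IUPAC-aware Hamming distance; reverse primers are
#' matched as their reverse complement. Ties go to the leftmost window. The
#' default mismatch cap is generous (5) because real binding sites can carry
#' many mismatches and still be the site of interest.
#'
#' @param references Tibble with `ref_id`, `sequence`.
#' @param primers A [primer_spec()] tibble.
#' @param max_mismatches Maximum Hamming mismatches for a window to qualify.
#' @return Tibble with `ref_id`, `primer`, `start`, `end` (0-based
#'   half-open), `mismatches`, `site_sequence` (the primer as it reads on
#'   the reference forward strand). References without a qualifying window
#'   for a primer have no row for it.
#' @export
locate_primer_windows <- function(references, primers, max_mismatches = 5) {
  rows <- purrr::map(seq_len(nrow(primers)), function(pi) {
    oriented <- if (primers$orientation[pi] == "reverse") {
      reverse_complement(primers$sequence[pi])
    } else {
      primers$sequence[pi]
    }
    purrr::map(seq_len(nrow(references)), function(ri) {
      w <- locate_window_one(references$sequence[ri], oriented, max_mismatches)
      if (is.null(w)) return(NULL)
      tibble(
        ref_id = references$ref_id[ri],
        primer = primers$name[pi],
        start = w$start, end = w$end, mismatches = w$mismatches,
        site_sequence = oriented
      )
    })
  })
  out <- dplyr::bind_rows(purrr::flatten(rows))
  if (nrow(out) == 0) {
    out <- tibble(ref_id = character(), primer = character(),
                  start = integer(), end = integer(),
                  mismatches = integer(), site_sequence = character())
  }
  out
}

locate_window_one <- function(reference, oriented_primer, max_mismatches) {
  L <- nchar(oriented_primer)
  n <- nchar(reference)
  if (n <= L) return(NULL)
  hits <- Biostrings::matchPattern(
    oriented_primer, Biostrings::DNAString(reference),
    max.mismatch = max_mismatches, with.indels = FALSE,
    fixed = c(pattern = FALSE, subject = TRUE)
  )
  if (length(hits) == 0) return(NULL)
  p_chars <- strsplit(oriented_primer, "")[[1]]
  mm <- vapply(BiocGenerics::start(hits), function(s) {
    t_chars <- strsplit(substr(reference, s, s + L - 1), "")[[1]]
    sum(!iupac_covers(p_chars, t_chars))
  }, integer(1))
  best <- which(mm == min(mm))[1]  # leftmost among minimal (hits are ordered)
  s <- BiocGenerics::start(hits)[best]
  list(start = s - 1L, end = s - 1L + L, mismatches = mm[best])
}

#' Audit primer binding sites covered by one alignment
#'
#' For each primer window fully covered by the alignment's reference span,
#' counts the events a PCR primer would face on this read: mismatches
#' between the aligned query base and the primer base at that position
#' (IUPAC-aware, so a primer ambiguity covering the read base is a match),
#' deletions (primer positions the read lacks) and insertions (extra read
#' bases flanked by in-window reference positions). Windows not fully
#' covered report `site_covered = FALSE` with zero counts.
#'
#' @param alignment A [align_pair()] result against the reference carrying
#'   the windows.
#' @param windows Rows of [locate_primer_windows()] for that reference.
#' @return Tibble with one row per window: `primer`, `site_covered`,
#'   `mismatches`, `insertions`, `deletions`.
#' @export
audit_read <- function(alignment, windows) {
  ref_pos <- alignment_ref_positions(alignment)
  q_chars <- strsplit(alignment$aligned_query, "")[[1]]
  purrr::map(seq_len(nrow(windows)), function(wi) {
    s <- windows$start[wi]
    e <- windows$end[wi]
    if (e <= s) abort("primer window is empty or inverted")
    covered <- alignment$ref_start <= s && alignment$ref_end >= e
    if (!covered) {
      return(tibble(primer = windows$primer[wi], site_covered = FALSE,
                    mismatches = 0L, insertions = 0L, deletions = 0L))
    }
    site_chars <- strsplit(windows$site_sequence[wi], "")[[1]]
    in_win <- !is.na(ref_pos) & ref_pos >= s & ref_pos < e
    aligned_cols <- which(in_win & alignment$ops %in% c("match", "mismatch"))
    mm <- sum(!iupac_covers(
      site_chars[ref_pos[aligned_cols] - s + 1L],
      q_chars[aligned_cols]
    ))
    dels <- sum(in_win & alignment$ops == "deletion")
    # an insertion belongs to the window when flanked by in-window positions
    ins_cols <- which(alignment$ops == "insertion")
    ins <- 0L
    for (col in ins_cols) {
      prev <- ref_pos[seq_len(col - 1)]
      prev <- prev[!is.na(prev)]
      nxt <- ref_pos[seq(col, length(ref_pos))]
      nxt <- nxt[!is.na(nxt)]
      if (length(prev) > 0 && length(nxt) > 0 &&
          prev[length(prev)] >= s && prev[length(prev)] < e &&
          nxt[1] >= s && nxt[1] < e) {
        ins <- ins + 1L
      }
    }
    tibble(primer = windows$primer[wi], site_covered = TRUE,
           mismatches = as.integer(mm), insertions = ins,
           deletions = as.integer(dels))
  }) |>
    dplyr::bind_rows()
}

#' Audit primer sites across a read set
#'
#' Pipeline wrapper: each read is searched against the index, aligned to its
#' best-matching reference (on the reported strand), and its covered primer
#' windows audited with [audit_read()].
#'
#' @param reads Tibble with `id`, `sequence`.
#' @param references Reference tibble (`ref_id`, `sequence`).
#' @param index Word index over `references`.
#' @param primers A [primer_spec()] tibble.
#' @param max_mismatches Window-location mismatch cap, see
#'   [locate_primer_windows()].
#' @param min_similarity Reads whose best hit falls below this are skipped.
#' @param band Alignment band half-width.
#' @return Per read x primer tibble: `id`, `ref_id`, `primer`,
#'   `site_covered`, `mismatches`, `insertions`, `deletions`.
#' @export
audit_reads <- function(reads, references, index, primers,
                        max_mismatches = 5, min_similarity = 0.4,
                        band = 32) {
  windows <- locate_primer_windows(references, primers, max_mismatches)
  rows <- purrr::map(seq_len(nrow(reads)), function(i) {
    if (nchar(reads$sequence[i]) < index$word_length) return(NULL)
    hits <- search_index(reads$sequence[i], index,
                         min_similarity = min_similarity, max_hits = 1)
    if (nrow(hits) == 0) return(NULL)
    ref_id <- hits$ref_id[1]
    win <- windows[windows$ref_id == ref_id, , drop = FALSE]
    if (nrow(win) == 0) return(NULL)
    query <- if (hits$strand[1] == "reverse") {
      reverse_complement(reads$sequence[i])
    } else {
      reads$sequence[i]
    }
    aln <- align_pair(query,
                      references$sequence[references$ref_id == ref_id][1],
                      band = band)
    rep <- audit_read(aln, win)
    dplyr::bind_cols(tibble(id = reads$id[i], ref_id = ref_id), rep)
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(id = character(), ref_id = character(), primer = character(),
                  site_covered = logical(), mismatches = integer(),
                  insertions = integer(), deletions = integer())
  }
  out
}

#' Roll primer-site reports up into per-taxon mismatch ratios
#'
#' Joins per-read primer-site reports to taxonomic assignments and
#' summarises per taxon at the requested rank. Two ratio orientations are
#' reported because both conventions are used in the field:
#' `ratio_reads_per_event` divides reads carrying a primer site by the total
#' mismatch/indel events inside those sites, and `ratio_events_per_read`
#' divides total events by the number of reads showing at least one event.
#' Either is `NA` when its denominator is zero.
#'
#' @param reports Output of [audit_reads()].
#' @param assignments Assignment tibble from [classify_reads()] (joined on
#'   `id`).
#' @param rank Taxonomic rank for the roll-up.
#' @return Tibble per taxon: `taxon`, `reads_with_site`, `total_events`,
#'   `reads_with_any_event`, `ratio_reads_per_event`,
#'   `ratio_events_per_read`.
#' @export
taxon_mismatch_ratio <- function(reports, assignments, rank = "phylum") {
  rank <- match.arg(rank, TAXONOMIC_RANKS)
  joined <- dplyr::inner_join(
    reports,
    dplyr::select(assignments, "id", taxon = dplyr::all_of(rank)),
    by = "id"
  )
  joined$taxon[is.na(joined$taxon)] <- "unclassified"
  per_read <- joined |>
    dplyr::group_by(.data$taxon, .data$id) |>
    dplyr::summarise(
      has_site = any(.data$site_covered),
      events = sum((.data$mismatches + .data$insertions + .data$deletions) *
                     .data$site_covered),
      .groups = "drop"
    )
  per_read |>
    dplyr::group_by(.data$taxon) |>
    dplyr::summarise(
      reads_with_site = sum(.data$has_site),
      total_events = sum(.data$events),
      reads_with_any_event = sum(.data$events > 0),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      ratio_reads_per_event = ifelse(.data$total_events > 0,
                                     .data$reads_with_site / .data$total_events,
                                     NA_real_),
      ratio_events_per_read = ifelse(.data$reads_with_any_event > 0,
                                     .data$total_events / .data$reads_with_any_event,
                                     NA_real_)
    )
}
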