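#' Taxonomic rank ladder used throughout the package
#'
#' Lineages are resolved over six ranks, domain through genus; genus is the
#' deepest rank at which short rRNA fragments can be assigned reliably.
#'
#' @format Character vector of rank names, shallowest first.
#' @export
TAXONOMIC_RANKS <- c("domain", "phylum", "class", "order", "family", "genus")

valid_dna_pattern <- "^[ACGTRYSWKMBDHVN]*$"

normalise_sequence <- function(x) {
  x <- toupper(x)
  # rRNA-derived references may arrive in RNA alphabet
  chartr("U", "T", x)
}

check_dna <- function(x, what = "sequence") {
  bad <- which(!grepl(valid_dna_pattern, x))
  if (length(bad) > 0) {
    abort(sprintf("invalid IUPAC DNA character in %s (record %d)", what, bad[1]))
  }
  invisible(x)
}

#' Read sequences from FASTA or FASTQ
#'
#' Parses a FASTA or FASTQ file into a tibble of reads. Sequences are
#' uppercased and RNA `U` is normalised to `T`. FASTQ quality strings are
#' decoded to integer Phred scores (offset 33 by default, or 64 for legacy
#' data).
#'
#' @param path Path to the sequence file.
#' @param format `"auto"` (from file extension), `"fasta"` or `"fastq"`.
#' @param quality_encoding `"phred33"` (modern default) or `"phred64"`.
#' @return A tibble with columns `id`, `sequence` and, for FASTQ, a
#'   `qualities` list-column of integer Phred scores (one per base).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">r1", "ACGT"), fa)
#' read_sequences(fa)
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq"),
                           quality_encoding = c("phred33", "phred64")) {
  format <- match.arg(format)
  quality_encoding <- match.arg(quality_encoding)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) {
      "fastq"
    } else {
      "fasta"
    }
  }
  # read as raw strings so RNA/lowercase input survives until normalisation
  if (format == "fastq") {
    validate_fastq_lines(path)
    ss <- Biostrings::readBStringSet(path, format = "fastq", with.qualities = TRUE)
    offset <- if (quality_encoding == "phred33") 33L else 64L
    quals <- purrr::map(
      as.character(S4Vectors::mcols(ss)$qualities),
      ~ unname(utf8ToInt(.x) - offset)
    )
    neg <- purrr::map_lgl(quals, ~ any(.x < 0))
    if (any(neg)) {
      abort(sprintf(
        "negative Phred score decoded for record %d: wrong quality encoding?",
        which(neg)[1]
      ))
    }
    out <- tibble(
      id = unname(names(ss)),
      sequence = normalise_sequence(unname(as.character(ss))),
      qualities = quals
    )
  } else {
    ss <- tryCatch(
      Biostrings::readBStringSet(path, format = "fasta"),
      error = function(e) abort(sprintf("FASTA parse error in %s: %s", path, conditionMessage(e)))
    )
    out <- tibble(
      id = unname(names(ss)),
      sequence = normalise_sequence(unname(as.character(ss)))
    )
  }
  check_dna(out$sequence)
  out
}

# Cheap structural scan so malformed FASTQ errors can name the line.
validate_fastq_lines <- function(path) {
  lines <- readr::read_lines(path)
  n <- length(lines)
  if (n == 0) return(invisible(TRUE))
  if (n %% 4 != 0) {
    abort(sprintf("FASTQ parse error in %s: truncated record at line %d", path, n + 1))
  }
  for (i in seq(1, n, by = 4)) {
    if (!startsWith(lines[i], "@")) {
      abort(sprintf("FASTQ parse error in %s: missing '@' header at line %d", path, i))
    }
    if (!startsWith(lines[i + 2], "+")) {
      abort(sprintf("FASTQ parse error in %s: missing '+' separator at line %d", path, i + 2))
    }
    if (nchar(lines[i + 1]) != nchar(lines[i + 3])) {
      abort(sprintf(
        "FASTQ parse error in %s: sequence/quality length mismatch at line %d",
        path, i + 3
      ))
    }
  }
  invisible(TRUE)
}

#' Write sequences to FASTA or FASTQ
#'
#' @param reads Tibble with `id`, `sequence` and optionally a `qualities`
#'   list-column (required for FASTQ output).
#' @param path Output path.
#' @param format `"auto"` (from extension), `"fasta"` or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(reads, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)$", path, ignore.case = TRUE)) "fastq" else "fasta"
  }
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- reads$id
  if (format == "fastq") {
    if (is.null(reads$qualities) || any(purrr::map_lgl(reads$qualities, is.null))) {
      abort("FASTQ output requires qualities for every read")
    }
    qs <- Biostrings::BStringSet(
      purrr::map_chr(reads$qualities, ~ intToUtf8(.x + 33L))
    )
    qss <- Biostrings::QualityScaledDNAStringSet(ss, Biostrings::PhredQuality(qs))
    Biostrings::writeQualityScaledXStringSet(qss, path)
  } else {
    Biostrings::writeXStringSet(ss, path)
  }
  invisible(path)
}

#' Parse a delimited lineage string
#'
#' Splits a SILVA/RDP-style lineage string ("Domain;Phylum;...;Genus") into a
#' named character vector over the fixed rank ladder domain -> genus. Fewer
#' tokens than six ranks yield a truncated lineage.
#'
#' @param x A single lineage string.
#' @param delimiter Rank delimiter, default `";"`.
#' @return Named character vector (names from [TAXONOMIC_RANKS]).
#' @examples
#' parse_lineage("Bacteria;Spirochaetes;Spirochaetia")
#' @export
parse_lineage <- function(x, delimiter = ";") {
  if (length(x) != 1 || is.na(x) || !nzchar(x)) {
    abort("empty lineage string")
  }
  tokens <- stringr::str_trim(strsplit(x, delimiter, fixed = TRUE)[[1]])
  if (length(tokens) == 0 || !nzchar(tokens[1])) {
    abort("lineage string has an empty leading token")
  }
  tokens <- tokens[seq_len(min(length(tokens), length(TAXONOMIC_RANKS)))]
  setNames(tokens, TAXONOMIC_RANKS[seq_along(tokens)])
}

#' Join a lineage back into a delimited string
#'
#' Inverse of [parse_lineage()].
#'
#' @param lineage Named character vector of taxon names, shallowest first.
#' @param delimiter Rank delimiter.
#' @return A single lineage string.
#' @export
lineage_string <- function(lineage, delimiter = ";") {
  paste(unname(lineage), collapse = delimiter)
}

# Expand a vector of lineage strings into rank columns (NA where truncated).
lineage_columns <- function(lineages, delimiter = ";") {
  mat <- matrix(NA_character_, nrow = length(lineages),
                ncol = length(TAXONOMIC_RANKS),
                dimnames = list(NULL, TAXONOMIC_RANKS))
  for (i in seq_along(lineages)) {
    lin <- parse_lineage(lineages[i], delimiter)
    mat[i, seq_along(lin)] <- unname(lin)
  }
  as_tibble(mat)
}

#' Read a reference taxonomy table
#'
#' Reads a two-column TSV (`ref_id`, `lineage`) and expands the lineage into
#' one column per rank.
#'
#' @param path Path to the TSV. A header line naming the two columns is
#'   expected.
#' @param delimiter Lineage delimiter inside the second column.
#' @return Tibble with `ref_id`, `lineage` and columns `domain` ... `genus`.
#' @export
read_taxonomy <- function(path, delimiter = ";") {
  tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("ref_id", "lineage") %in% names(tab))) {
    abort("taxonomy table must have columns 'ref_id' and 'lineage'")
  }
  dplyr::bind_cols(tab[, c("ref_id", "lineage")], lineage_columns(tab$lineage, delimiter))
}

#' Build a taxonomy tibble from in-memory lineage strings
#'
#' @param ref_id Character vector of reference ids.
#' @param lineage Character vector of lineage strings, same length.
#' @param delimiter Lineage delimiter.
#' @return Same shape as [read_taxonomy()].
#' @export
taxonomy_table <- function(ref_id, lineage, delimiter = ";") {
  stopifnot(length(ref_id) == length(lineage))
  dplyr::bind_cols(
    tibble(ref_id = as.character(ref_id), lineage = as.character(lineage)),
    lineage_columns(lineage, delimiter)
  )
}

#' Read a reference set (FASTA plus taxonomy TSV)
#'
#' @param fasta_path Reference sequences in FASTA.
#' @param taxonomy_path Matching taxonomy TSV (`ref_id`, `lineage`).
#' @return Tibble with `ref_id`, `sequence`, `lineage` and rank columns.
#' @export
read_reference_set <- function(fasta_path, taxonomy_path) {
  seqs <- read_sequences(fasta_path, format = "fasta")
  tax <- read_taxonomy(taxonomy_path)
  missing <- setdiff(seqs$id, tax$ref_id)
  if (length(missing) > 0) {
    abort(sprintf("reference '%s' missing from taxonomy table", missing[1]))
  }
  dplyr::left_join(
    dplyr::rename(seqs, ref_id = "id"),
    tax,
    by = "ref_id"
  )
}

#' Write a tab-separated report
#'
#' Writes any tabular result as TSV with a header line. Double columns
#' (densities, ratios) are printed with two decimals; integer columns are
#' left untouched.
#'
#' @param rows A data frame.
#' @param path Output path.
#' @return `rows`, invisibly, so the call can sit inside a pipe.
#' @export
write_tsv_report <- function(rows, path) {
  out <- as_tibble(rows)
  dbl <- vapply(out, is.double, logical(1))
  out[dbl] <- lapply(out[dbl], function(x) {
    ifelse(is.na(x), NA_character_, sprintf("%.2f", x))
  })
  readr::write_tsv(out, path, na = "NA")
  invisible(rows)
}
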