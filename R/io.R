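# FASTA and table I/O

#' Read and write FASTA
#'
#' FASTA parsing and writing are delegated to Biostrings; every record is
#' validated against the declared alphabet and invalid characters are reported
#' with their record and position. Span annotations are carried in a sidecar
#' TSV (see [write_spans()]).
#'
#' @param path File path.
#' @param alphabet Alphabet the records must conform to.
#' @return `read_fasta()` returns a named list of [bio_seq()] (empty list for
#'   an empty file); `write_fasta()` returns `path` invisibly.
#' @export
read_fasta <- function(path, alphabet = protein_alphabet()) {
  if (file.info(path)$size == 0) return(list())
  set <- Biostrings::readBStringSet(path)
  seqs <- purrr::map2(as.character(set), names(set), function(res, id) {
    bio_seq(res, alphabet, id = id)
  })
  names(seqs) <- names(set)
  seqs
}

#' @rdname read_fasta
#' @param seqs Named list of [bio_seq()] (unnamed entries fall back to their
#'   `id` field or a positional identifier).
#' @export
write_fasta <- function(seqs, path) {
  ids <- seq_ids(seqs)
  set <- Biostrings::BStringSet(purrr::map_chr(seqs, "residues"))
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Span annotations as a sidecar TSV
#'
#' Serializes the labeled spans of a sequence set with columns
#' `sequence_id`, `span_label`, `start`, `end` (1-based, inclusive).
#'
#' @param seqs Named list of [bio_seq()].
#' @param path File path.
#' @return `write_spans()` returns `path` invisibly; `read_spans()` returns
#'   the tibble.
#' @export
write_spans <- function(seqs, path) {
  ids <- seq_ids(seqs)
  tbl <- purrr::map2_dfr(seqs, ids, function(s, id) {
    if (nrow(s$spans) == 0) return(NULL)
    tibble::tibble(sequence_id = id, span_label = s$spans$label,
                   start = s$spans$start, end = s$spans$end)
  })
  if (nrow(tbl) == 0) {
    tbl <- tibble::tibble(sequence_id = character(), span_label = character(),
                          start = integer(), end = integer())
  }
  readr::write_tsv(tbl, path)
  invisible(path)
}

#' @rdname write_spans
#' @export
read_spans <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sequence_id = readr::col_character(), span_label = readr::col_character(),
    start = readr::col_integer(), end = readr::col_integer()
  ))
}

#' Write a probe result as TSV plus a JSON quantile summary
#'
#' The TSV holds the raw long-format rows (always retained); the JSON records
#' per-condition distribution quantiles of the value column, the probe name,
#' model and seed.
#'
#' @param result A `probe_result`.
#' @param path TSV output path; the JSON summary is written alongside with
#'   extension `.summary.json`.
#' @param value_col Column summarised in the JSON (default auto-detected).
#' @return `path`, invisibly.
#' @export
write_probe_result <- function(result, path, value_col = NULL) {
  stopifnot(inherits(result, "probe_result"))
  readr::write_tsv(tibble::as_tibble(result), path)
  if (is.null(value_col)) {
    value_col <- intersect(c("value", "entropy", "preference", "probability"),
                           names(result))[1]
  }
  group_cols <- intersect(c("condition", "context", "unit_size",
                            "multiplicity", "needle_size", "haystack_size",
                            "rate"), names(result))
  summ <- if (!is.na(value_col) && length(group_cols) > 0) {
    result |>
      tibble::as_tibble() |>
      dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
      dplyr::summarise(
        n = dplyr::n(),
        q25 = stats::quantile(.data[[value_col]], 0.25),
        median = stats::median(.data[[value_col]]),
        q75 = stats::quantile(.data[[value_col]], 0.75),
        .groups = "drop"
      )
  } else NULL
  jsonlite::write_json(
    list(probe = attr(result, "probe"),
         model = result$model[1], seed = result$seed[1],
         value = value_col, quantiles = summ),
    sub("\\.tsv$", "", path) |> paste0(".summary.json"),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
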