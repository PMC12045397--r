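#' Annotated biological sequences
#'
#' A `bio_seq` couples a residue string with the alphabet it is written over
#' and an optional table of labeled spans (1-based, closed intervals) that
#' annotate structure such as repeat units, needles or insertion loci.
#'
#' @param residues A single character string; every character must belong to
#'   `alphabet`.
#' @param alphabet A [new_alphabet()] object.
#' @param spans Optional tibble/data frame with columns `label`, `start`,
#'   `end` (1-based, inclusive, within the sequence).
#' @param id Optional sequence identifier.
#'
#' @return An object of class `bio_seq`.
#' @examples
#' bio_seq("ACDEF", protein_alphabet(), id = "toy")
#' @export
bio_seq <- function(residues, alphabet, spans = NULL, id = NULL) {
  stopifnot(is.character(residues), length(residues) == 1)
  chars <- strsplit(residues, "")[[1]]
  bad <- which(!chars %in% alphabet$symbols)
  if (length(bad) > 0) {
    stop(
      sprintf(
        "invalid symbol '%s' at position %d for alphabet '%s'%s",
        chars[bad[1]], bad[1], alphabet$name,
        if (is.null(id)) "" else sprintf(" in record '%s'", id)
      ),
      call. = FALSE
    )
  }
  spans <- if (is.null(spans)) {
    tibble::tibble(label = character(), start = integer(), end = integer())
  } else {
    spans <- tibble::as_tibble(spans)
    stopifnot(all(c("label", "start", "end") %in% names(spans)))
    if (nrow(spans) > 0 &&
        (any(spans$start < 1) || any(spans$end > nchar(residues)) ||
         any(spans$start > spans$end))) {
      stop("spans must lie within [1, length] with start <= end", call. = FALSE)
    }
    spans
  }
  structure(
    list(residues = residues, alphabet = alphabet, spans = spans, id = id),
    class = "bio_seq"
  )
}

#' @export
print.bio_seq <- function(x, ...) {
  n <- seq_length(x)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf(
    "<bio_seq%s> %d %s residues: %s\n",
    if (is.null(x$id)) "" else paste0(" ", x$id), n, x$alphabet$name, shown
  ))
  if (nrow(x$spans) > 0) {
    cat(sprintf(
      "  spans: %s\n",
      paste(sprintf("%s[%d-%d]", x$spans$label, x$spans$start, x$spans$end),
            collapse = " ")
    ))
  }
  invisible(x)
}

#' @export
as.character.bio_seq <- function(x, ...) x$residues

#' Sequence length in residues
#' @param seq A [bio_seq()].
#' @return Integer length.
#' @export
seq_length <- function(seq) nchar(seq$residues)

#' Extract a labeled span from a sequence
#' @param seq A [bio_seq()].
#' @param label Span label to look up (first match).
#' @return Integer vector `c(start, end)`, 1-based inclusive.
#' @export
seq_span <- function(seq, label) {
  i <- match(label, seq$spans$label)
  if (is.na(i)) stop(sprintf("no span labeled '%s'", label), call. = FALSE)
  c(seq$spans$start[i], seq$spans$end[i])
}

# residues as 1-based integer codes over the alphabet
seq_ints <- function(seq) {
  match(strsplit(seq$residues, "")[[1]], seq$alphabet$symbols)
}

ints_to_string <- function(ints, alphabet) {
  paste(alphabet$symbols[ints], collapse = "")
}

#' Concatenate two sequences over the same alphabet
#'
#' Spans of both inputs are retained; spans of `b` are shifted to the
#' concatenated coordinates.
#' @param a,b [bio_seq()] objects over the same alphabet.
#' @param id Optional identifier for the result.
#' @return A [bio_seq()].
#' @export
seq_concat <- function(a, b, id = NULL) {
  stopifnot(identical(a$alphabet$symbols, b$alphabet$symbols))
  off <- seq_length(a)
  spans <- dplyr::bind_rows(
    a$spans,
    dplyr::mutate(b$spans, start = .data$start + off, end = .data$end + off)
  )
  bio_seq(paste0(a$residues, b$residues), a$alphabet, spans = spans, id = id)
}

#' Extract a subsequence
#' @param seq A [bio_seq()].
#' @param start,end 1-based inclusive bounds.
#' @return A [bio_seq()] with no spans.
#' @export
seq_subseq <- function(seq, start, end) {
  stopifnot(start >= 1, end <= seq_length(seq), start <= end)
  bio_seq(substr(seq$residues, start, end), seq$alphabet, id = seq$id)
}
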