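#' Sequence alphabets
#'
#' An alphabet is an ordered set of single-character symbols, optionally with a
#' complement map (nucleic-acid alphabets only). All sequences, prediction
#' profiles and embeddings in this package are expressed over one of these
#' canonical alphabets.
#'
#' `protein_alphabet()` is the 20 canonical amino acids in alphabetical
#' one-letter order (`ACDEFGHIKLMNPQRSTVWY`). `rna_alphabet()` is `A`, `C`,
#' `G`, `U` with the Watson-Crick complement map (A-U, C-G).
#'
#' @param name Identifier for the alphabet.
#' @param symbols Character vector of unique single characters.
#' @param complement_map Optional named character vector mapping each symbol to
#'   its complement. Must be a self-inverse bijection on `symbols`.
#'
#' @return An object of class `seq_alphabet`.
#' @examples
#' protein_alphabet()
#' rna_alphabet()
#' @export
new_alphabet <- function(name, symbols, complement_map = NULL) {
  stopifnot(is.character(name), length(name) == 1)
  symbols <- as.character(symbols)
  if (anyDuplicated(symbols) || any(nchar(symbols) != 1)) {
    stop("alphabet symbols must be unique single characters", call. = FALSE)
  }
  if (!is.null(complement_map)) {
    if (!setequal(names(complement_map), symbols) ||
        !setequal(unname(complement_map), symbols)) {
      stop("complement_map must be a bijection on the alphabet symbols", call. = FALSE)
    }
    # self-inverse: applying the map twice must return the original symbol
    twice <- unname(complement_map[unname(complement_map[symbols])])
    if (!identical(twice, symbols)) {
      stop("complement_map must be self-inverse", call. = FALSE)
    }
    complement_map <- complement_map[symbols]
  }
  structure(
    list(name = name, symbols = symbols, complement_map = complement_map),
    class = "seq_alphabet"
  )
}

#' @rdname new_alphabet
#' @export
protein_alphabet <- function() {
  new_alphabet("protein", strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]])
}

#' @rdname new_alphabet
#' @export
rna_alphabet <- function() {
  new_alphabet(
    "rna", c("A", "C", "G", "U"),
    complement_map = c(A = "U", C = "G", G = "C", U = "A")
  )
}

#' @export
print.seq_alphabet <- function(x, ...) {
  cat("<seq_alphabet> ", x$name, ": ", paste(x$symbols, collapse = ""), sep = "")
  if (!is.null(x$complement_map)) cat(" (complemented)")
  cat("\n")
  invisible(x)
}

alphabet_size <- function(alphabet) length(alphabet$symbols)

#' @export
format.seq_alphabet <- function(x, ...) {
  paste0(x$name, "[", length(x$symbols), "]")
}

# integer complement permutation (index -> index), or NULL
complement_perm <- function(alphabet) {
  if (is.null(alphabet$complement_map)) return(NULL)
  match(unname(alphabet$complement_map), alphabet$symbols)
}
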