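#' @keywords internal
#' @noRd
with_rng_seed <- function(seed, code) {
  # generators are pure functions of (arguments, seed): isolate the global RNG
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Random sequence over an alphabet
#'
#' Draws `length` residues i.i.d. from `weights` (uniform by default). The
#' output is a pure function of the arguments including `seed`.
#'
#' @param length Number of residues (>= 1).
#' @param alphabet A [new_alphabet()] object; defaults to the 20-letter protein
#'   alphabet.
#' @param weights Optional probability vector over the alphabet (summing to 1).
#' @param seed Integer seed.
#' @param id Optional identifier.
#' @return A [bio_seq()].
#' @examples
#' random_sequence(30, protein_alphabet(), seed = 7)
#' @export
random_sequence <- function(length, alphabet = protein_alphabet(),
                            weights = NULL, seed = 1, id = NULL) {
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  k <- alphabet_size(alphabet)
  if (!is.null(weights)) {
    if (length(weights) != k) {
      stop("weights must have one entry per alphabet symbol", call. = FALSE)
    }
    if (abs(sum(weights) - 1) > 1e-8) {
      stop("weights must sum to 1", call. = FALSE)
    }
  }
  ints <- with_rng_seed(seed, {
    sample.int(k, size = length, replace = TRUE, prob = weights)
  })
  bio_seq(ints_to_string(ints, alphabet), alphabet, id = id)
}

#' Tandem repeat of a unit sequence
#'
#' Concatenates `multiplicity` copies of `unit`; each copy is annotated with a
#' `unit_<k>` span.
#'
#' @param unit A [bio_seq()], the repeating unit.
#' @param multiplicity Integer >= 1 number of copies.
#' @return A [bio_seq()] of length `multiplicity * seq_length(unit)`.
#' @examples
#' tandem_repeat(random_sequence(20, seed = 1), 2)
#' @export
tandem_repeat <- function(unit, multiplicity) {
  if (multiplicity < 1) stop("multiplicity must be >= 1", call. = FALSE)
  multiplicity <- as.integer(multiplicity)
  u <- seq_length(unit)
  spans <- tibble::tibble(
    label = paste0("unit_", seq_len(multiplicity)),
    start = (seq_len(multiplicity) - 1L) * u + 1L,
    end = seq_len(multiplicity) * u
  )
  bio_seq(strrep(unit$residues, multiplicity), unit$alphabet,
          spans = spans, id = unit$id)
}

#' Mutated copy of a sequence
#'
#' Each position is independently mutated with probability `rate`; on mutation
#' one of the allowed operations is chosen uniformly. Substitutions draw
#' uniformly from the other symbols (so a substitution always changes the
#' residue); insertions insert a random residue before the current position;
#' deletions remove the residue. Mutations are applied left to right in a
#' single pass, so with indels the output length may differ from the input.
#'
#' @param seq A [bio_seq()].
#' @param rate Per-position mutation probability in `[0, 1]`.
#' @param ops Non-empty subset of `c("substitution", "insertion", "deletion")`.
#' @param seed Integer seed.
#' @return A mutated [bio_seq()] copy (no spans).
#' @examples
#' mutate_copy(random_sequence(50, seed = 1), rate = 0.5,
#'             ops = "substitution", seed = 2)
#' @export
mutate_copy <- function(seq, rate,
                        ops = c("substitution", "insertion", "deletion"),
                        seed = 1) {
  stopifnot(rate >= 0, rate <= 1)
  ops <- match.arg(ops, several.ok = TRUE)
  if (length(ops) == 0) stop("ops must be non-empty", call. = FALSE)
  if (seq_length(seq) == 0) stop("seq must be non-empty", call. = FALSE)
  k <- alphabet_size(seq$alphabet)
  ints <- seq_ints(seq)
  out <- with_rng_seed(seed, {
    n <- length(ints)
    hit <- stats::runif(n) < rate
    # draw the op and any auxiliary symbol per position up front so the
    # realized mutations are independent of how earlier indels shift indices
    op <- sample(ops, n, replace = TRUE)
    sub_pick <- sample.int(k - 1L, n, replace = TRUE)
    ins_pick <- sample.int(k, n, replace = TRUE)
    res <- vector("list", n)
    for (i in seq_len(n)) {
      if (!hit[i]) {
        res[[i]] <- ints[i]
      } else if (op[i] == "substitution") {
        others <- setdiff(seq_len(k), ints[i])
        res[[i]] <- others[sub_pick[i]]
      } else if (op[i] == "insertion") {
        res[[i]] <- c(ins_pick[i], ints[i])
      } else {
        res[[i]] <- integer(0)
      }
    }
    unlist(res)
  })
  if (length(out) == 0) {
    stop("all residues deleted; lower the rate or allow other ops", call. = FALSE)
  }
  bio_seq(ints_to_string(out, seq$alphabet), seq$alphabet, id = seq$id)
}

#' Needle-in-a-haystack construction
#'
#' Two identical copies of a random needle flank an unrelated random haystack:
#' layout `[needle][haystack][needle]`. Both needle spans and the haystack span
#' are annotated.
#'
#' @param needle_length Needle size in residues (>= 1).
#' @param haystack_length Haystack size in residues (>= 0).
#' @param alphabet Alphabet to draw from.
#' @param seed Integer seed.
#' @return A [bio_seq()] of length `2 * needle_length + haystack_length` with
#'   spans `needle_1`, `haystack`, `needle_2`.
#' @examples
#' needle_haystack(10, 300, protein_alphabet(), seed = 3)
#' @export
needle_haystack <- function(needle_length, haystack_length,
                            alphabet = protein_alphabet(), seed = 1) {
  if (needle_length < 1) stop("needle_length must be >= 1", call. = FALSE)
  if (haystack_length < 0) stop("haystack_length must be >= 0", call. = FALSE)
  k <- alphabet_size(alphabet)
  parts <- with_rng_seed(seed, {
    list(
      needle = sample.int(k, needle_length, replace = TRUE),
      hay = if (haystack_length > 0) {
        sample.int(k, haystack_length, replace = TRUE)
      } else integer(0)
    )
  })
  n <- needle_length
  h <- haystack_length
  spans <- tibble::tibble(
    label = c("needle_1", if (h > 0) "haystack", "needle_2"),
    start = as.integer(c(1, if (h > 0) n + 1, n + h + 1)),
    end = as.integer(c(n, if (h > 0) n + h, 2 * n + h))
  )
  bio_seq(ints_to_string(c(parts$needle, parts$hay, parts$needle), alphabet),
          alphabet, spans = spans)
}

#' One-skip sequence pair
#'
#' Concatenates two equal-length halves that agree exactly at alternating
#' positions: residues at odd positions (1, 3, 5, ...) match across halves and
#' residues at even positions always differ. The pair shares strong global
#' similarity but contains no long perfectly matching chunk.
#'
#' @param unit_length Length of each half (>= 2).
#' @param alphabet Alphabet to draw from.
#' @param seed Integer seed.
#' @return A [bio_seq()] of length `2 * unit_length` with spans `half_1`,
#'   `half_2`.
#' @examples
#' one_skip_pair(6, protein_alphabet(), seed = 1)
#' @export
one_skip_pair <- function(unit_length, alphabet = protein_alphabet(), seed = 1) {
  if (unit_length < 2) stop("unit_length must be >= 2", call. = FALSE)
  k <- alphabet_size(alphabet)
  halves <- with_rng_seed(seed, {
    s1 <- sample.int(k, unit_length, replace = TRUE)
    s2 <- s1
    odd_shift <- sample.int(k - 1L, unit_length, replace = TRUE)
    for (i in seq_len(unit_length)) {
      if (i %% 2 == 0) {
        # even 1-based positions must differ across halves
        s2[i] <- setdiff(seq_len(k), s1[i])[odd_shift[i]]
      }
    }
    list(s1 = s1, s2 = s2)
  })
  spans <- tibble::tibble(
    label = c("half_1", "half_2"),
    start = c(1L, unit_length + 1L),
    end = c(unit_length, 2L * unit_length)
  )
  bio_seq(ints_to_string(c(halves$s1, halves$s2), alphabet), alphabet,
          spans = spans)
}

#' Complement, reverse and reverse complement
#'
#' `seq_complement()` replaces each residue by its complement (requires an
#' alphabet with a complement map, i.e. RNA); `seq_reverse()` reverses the
#' residue order; `seq_reverse_complement()` composes both, producing the
#' pairing arm of an RNA hairpin.
#'
#' @param seq A [bio_seq()].
#' @return A transformed [bio_seq()] (spans dropped).
#' @examples
#' seq_reverse_complement(bio_seq("CGGAU", rna_alphabet()))
#' @export
seq_complement <- function(seq) {
  perm <- complement_perm(seq$alphabet)
  if (is.null(perm)) {
    stop(sprintf("alphabet '%s' has no complement map", seq$alphabet$name),
         call. = FALSE)
  }
  bio_seq(ints_to_string(perm[seq_ints(seq)], seq$alphabet), seq$alphabet,
          id = seq$id)
}

#' @rdname seq_complement
#' @export
seq_reverse <- function(seq) {
  bio_seq(ints_to_string(rev(seq_ints(seq)), seq$alphabet), seq$alphabet,
          id = seq$id)
}

#' @rdname seq_complement
#' @export
seq_reverse_complement <- function(seq) seq_reverse(seq_complement(seq))

#' Contra-lateral two-residue insertion construct
#'
#' Doubles `unit` and edits the second copy at the locus equivalent to
#' `mask_position`: the original residue there is removed and the pair
#' `(left_symbol, right_symbol)` is inserted in its place, giving the model two
#' candidate retrieval sources for a mask placed at `mask_position` in the
#' first copy. Total length is `2 * L + 1`. The inserted positions are
#' annotated as spans `left_insert` (index `L + mask_position`) and
#' `right_insert` (index `L + mask_position + 1`).
#'
#' @param unit A [bio_seq()] of length L.
#' @param mask_position Position in `[1, L]` to be probed in the first copy.
#' @param left_symbol,right_symbol Single symbols from the unit's alphabet.
#' @return A [bio_seq()] with spans `copy_1`, `left_insert`, `right_insert`.
#' @export
contralateral_construct <- function(unit, mask_position, left_symbol,
                                    right_symbol) {
  L <- seq_length(unit)
  if (mask_position < 1 || mask_position > L) {
    stop("mask_position out of range", call. = FALSE)
  }
  syms <- unit$alphabet$symbols
  if (!left_symbol %in% syms || !right_symbol %in% syms) {
    stop("inserted symbols must belong to the unit's alphabet", call. = FALSE)
  }
  u <- strsplit(unit$residues, "")[[1]]
  second <- c(
    u[seq_len(mask_position - 1)],
    left_symbol, right_symbol,
    if (mask_position < L) u[(mask_position + 1):L]
  )
  spans <- tibble::tibble(
    label = c("copy_1", "left_insert", "right_insert"),
    start = c(1L, L + as.integer(mask_position), L + as.integer(mask_position) + 1L),
    end = c(L, L + as.integer(mask_position), L + as.integer(mask_position) + 1L)
  )
  bio_seq(paste0(unit$residues, paste(second, collapse = "")), unit$alphabet,
          spans = spans)
}
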