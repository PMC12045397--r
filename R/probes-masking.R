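# probes that manipulate masks and the equivalent position of a doubled unit:
# equivalent/non-equivalent masking, substitution flips, contra-lateral inserts

#' Equivalent-position masking probe
#'
#' Measures the model's uncertainty (entropy of the predictive distribution)
#' at a masked position under four conditions: the unit alone (`single`), the
#' doubled unit (`doubled`), the doubled unit with the *equivalent* position in
#' the second copy also masked (`doubled_equiv_masked`), and the doubled unit
#' with a *non-equivalent* second-copy position masked
#' (`doubled_nonequiv_masked`). Retrieval is diagnosed when only masking the
#' equivalent position restores the uncertainty.
#'
#' For a mask at position `i` of a length-`L` unit, the equivalent position in
#' the second copy is `i + L`; the non-equivalent mask defaults to position
#' `i + 3` of the second copy, wrapped within it (recorded in the output).
#'
#' @inheritParams probe_doubling
#' @param length Unit length.
#' @param mask_position Position probed in the first copy (default: middle).
#' @param nonequiv_offset Offset (within the second copy, wrapped) of the
#'   non-equivalent mask relative to the equivalent position.
#' @return A `probe_result` tibble with columns `sequence_id`, `condition`,
#'   `mask_position`, `second_mask`, `entropy`, `p_true`, `model`, `seed`.
#' @export
probe_equivalent_mask <- function(model, n_sequences = 20, length = 30,
                                  mask_position = NULL, nonequiv_offset = 3,
                                  seed = 1) {
  stopifnot(length >= 4, n_sequences >= 1)
  i <- if (is.null(mask_position)) ceiling(length / 2) else as.integer(mask_position)
  stopifnot(i >= 1, i <= length)
  wrapped <- ((i - 1 + nonequiv_offset) %% length) + 1L
  if (wrapped == i) stop("non-equivalent mask collides with the equivalent position",
                         call. = FALSE)
  nonequiv <- length + wrapped
  rows <- purrr::map_dfr(seq_len(n_sequences), function(r) {
    unit <- random_sequence(length, model_alphabet(model),
                            seed = probe_seed(seed, 11L, r))
    doubled <- tandem_repeat(unit, 2)
    cases <- list(
      single = list(s = unit, masks = i),
      doubled = list(s = doubled, masks = i),
      doubled_equiv_masked = list(s = doubled, masks = c(i, i + length)),
      doubled_nonequiv_masked = list(s = doubled, masks = c(i, nonequiv))
    )
    purrr::imap_dfr(cases, function(case, condition) {
      prof <- predict_masked(model, case$s, masked_positions = case$masks)
      row <- match(i, prof$positions)
      tibble::tibble(
        sequence_id = sprintf("seq_%03d", r),
        condition = condition,
        mask_position = i,
        second_mask = if (length(case$masks) > 1) case$masks[2] else NA_integer_,
        entropy = entropy(prof$prob[row, ]),
        p_true = profile_true_prob(prof, case$s)[row]
      )
    })
  })
  new_probe_result(rows, "equivalent_mask", model, seed)
}

#' Substitution flip profile
#'
#' For each sequence, the equivalent position of the second copy of a doubled
#' unit is substituted to every alphabet symbol in turn, and the model's
#' prediction at the masked first-copy position is recorded. Rows of the
#' averaged matrix are the predicted distributions conditional on the
#' substituted symbol; a retrieval-dominated model concentrates the mass on
#' the diagonal.
#'
#' @inheritParams probe_equivalent_mask
#' @return A `probe_result` tibble in long format with columns
#'   `substituted_symbol`, `predicted_symbol`, `probability` (averaged over
#'   sequences), `model`, `seed`. The averaged matrix is attached as attribute
#'   `"matrix"` and the mean diagonal mass as attribute `"diagonal_mass"`.
#' @export
probe_flip_profile <- function(model, n_sequences = 20, length = 30,
                               mask_position = NULL, seed = 1) {
  stopifnot(length >= 2, n_sequences >= 1)
  ab <- model_alphabet(model)
  k <- alphabet_size(ab)
  i <- if (is.null(mask_position)) ceiling(length / 2) else as.integer(mask_position)
  stopifnot(i >= 1, i <= length)
  total <- matrix(0, nrow = k, ncol = k)
  for (r in seq_len(n_sequences)) {
    unit <- random_sequence(length, ab, seed = probe_seed(seed, 12L, r))
    doubled <- tandem_repeat(unit, 2)
    chars <- strsplit(doubled$residues, "")[[1]]
    for (a in seq_len(k)) {
      chars[i + length] <- ab$symbols[a]
      flipped <- bio_seq(paste(chars, collapse = ""), ab)
      prof <- predict_masked(model, flipped, masked_positions = i)
      total[a, ] <- total[a, ] + prof$prob[1, ]
    }
  }
  avg <- total / n_sequences
  dimnames(avg) <- list(substituted = ab$symbols, predicted = ab$symbols)
  rows <- tibble::tibble(
    substituted_symbol = rep(ab$symbols, each = k),
    predicted_symbol = rep(ab$symbols, times = k),
    probability = as.vector(t(avg))
  )
  out <- new_probe_result(rows, "flip_profile", model, seed)
  attr(out, "matrix") <- avg
  attr(out, "diagonal_mass") <- mean(diag(avg))
  out
}

#' Diagonal mass of a flip profile
#' @param x A result of [probe_flip_profile()].
#' @return Mean of the diagonal entries of the averaged flip matrix.
#' @export
flip_diagonal_mass <- function(x) {
  dm <- attr(x, "diagonal_mass")
  if (is.null(dm)) stop("not a flip_profile probe result", call. = FALSE)
  dm
}

#' Contra-lateral retrieval preference probe
#'
#' Builds [contralateral_construct()] sequences — a doubled unit whose second
#' copy offers two adjacent candidate residues at the locus equivalent to the
#' mask — and sweeps the mask across the first copy, recording the probability
#' assigned to the left- and right-inserted symbols. The preference is
#' `p(right) - p(left)`; swapping the inserted symbols negates it.
#'
#' @inheritParams probe_equivalent_mask
#' @param positions Mask positions to sweep (default: all of the first copy).
#' @param left_symbol,right_symbol Fix the inserted symbols for every sequence
#'   (must differ); by default a random distinct pair is drawn per sequence.
#'   Fixing them allows swap experiments: retrieval that keys on the insert's
#'   *side* leaves the positional preference invariant under a swap, which is
#'   the same thing as the fixed-symbol readout changing sign.
#' @return A `probe_result` tibble with columns `sequence_id`, `position`,
#'   `left_symbol`, `right_symbol`, `p_left`, `p_right`, `preference`,
#'   `model`, `seed`.
#' @export
probe_contralateral <- function(model, n_sequences = 10, length = 30,
                                positions = NULL, left_symbol = NULL,
                                right_symbol = NULL, seed = 1) {
  stopifnot(length >= 4, n_sequences >= 1)
  ab <- model_alphabet(model)
  k <- alphabet_size(ab)
  if (xor(is.null(left_symbol), is.null(right_symbol))) {
    stop("supply both inserted symbols or neither", call. = FALSE)
  }
  if (!is.null(left_symbol) && identical(left_symbol, right_symbol)) {
    stop("inserted symbols must differ (preference undefined otherwise)",
         call. = FALSE)
  }
  positions <- if (is.null(positions)) seq_len(length) else as.integer(positions)
  stopifnot(all(positions >= 1), all(positions <= length))
  rows <- purrr::map_dfr(seq_len(n_sequences), function(r) {
    unit <- random_sequence(length, ab, seed = probe_seed(seed, 13L, r))
    if (is.null(left_symbol)) {
      pair <- with_rng_seed(probe_seed(seed, 14L, r), sample.int(k, 2))
      left <- ab$symbols[pair[1]]
      right <- ab$symbols[pair[2]]
    } else {
      left <- left_symbol
      right <- right_symbol
    }
    purrr::map_dfr(positions, function(p) {
      s <- contralateral_construct(unit, p, left, right)
      prof <- predict_masked(model, s, masked_positions = p)
      pv <- prof$prob[1, ]
      tibble::tibble(
        sequence_id = sprintf("seq_%03d", r), position = p,
        left_symbol = left, right_symbol = right,
        p_left = pv[[left]], p_right = pv[[right]],
        preference = pv[[right]] - pv[[left]]
      )
    })
  })
  new_probe_result(rows, "contralateral", model, seed)
}
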