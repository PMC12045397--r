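# probes built on repeated-motif constructions: doubling, multiplicity sweeps,
# imperfect repeats, needle-in-a-haystack, one-skip pairs, RNA contexts

new_probe_result <- function(tbl, probe, model, seed) {
  tbl <- tibble::as_tibble(tbl)
  tbl$model <- model_name(model)
  tbl$seed <- as.integer(seed)
  structure(tbl, probe = probe,
            class = c("probe_result", class(tibble::tibble())))
}

#' @export
print.probe_result <- function(x, ...) {
  cat(sprintf("# Probe result: %s\n", attr(x, "probe")))
  NextMethod()
}

probe_seed <- function(seed, stream, index) {
  # independent deterministic substreams below 2^31
  (as.integer(seed) * 1009L + stream * 97L + index) %% 2147483629L
}

#' Doubling experiment
#'
#' For each generated sequence, computes the one-at-a-time pseudo-perplexity of
#' the sequence itself (1x) and of the sequence appended to itself (2x). A
#' retrieval-capable model collapses the 2x score toward 1 while the 1x score
#' of random sequences stays at the prior perplexity.
#'
#' @param model A model implementing the prediction contract.
#' @param n_sequences Number of random sequences.
#' @param length Residues per sequence.
#' @param seed Integer seed; together with the configuration it fully
#'   determines the output.
#' @param exclude_first As in [pseudo_perplexity()].
#' @return A `probe_result` tibble with columns `sequence_id`, `condition`
#'   (`"1x"`/`"2x"`), `value` (pseudo-perplexity), `model`, `seed`.
#' @examples
#' probe_doubling(mock_model(), n_sequences = 3, length = 20, seed = 1)
#' @export
probe_doubling <- function(model, n_sequences = 50, length = 30, seed = 1,
                           exclude_first = FALSE) {
  stopifnot(n_sequences >= 1, length >= 2)
  ab <- model_alphabet(model)
  rows <- purrr::map_dfr(seq_len(n_sequences), function(r) {
    unit <- random_sequence(length, ab, seed = probe_seed(seed, 1L, r))
    doubled <- tandem_repeat(unit, 2)
    tibble::tibble(
      sequence_id = sprintf("seq_%03d", r),
      condition = c("1x", "2x"),
      value = c(
        pseudo_perplexity(one_at_a_time_profile(model, unit), unit,
                          exclude_first = exclude_first),
        pseudo_perplexity(one_at_a_time_profile(model, doubled), doubled,
                          exclude_first = exclude_first)
      )
    )
  })
  new_probe_result(rows, "doubling", model, seed)
}

#' Repeat-multiplicity sweep
#'
#' One-at-a-time pseudo-perplexity over a full grid of repeating-unit sizes and
#' multiplicities. The grid is covered exhaustively; every cell appears in the
#' output.
#'
#' @inheritParams probe_doubling
#' @param unit_sizes Integer vector of repeating-unit sizes (residues).
#' @param multiplicities Integer vector of copy numbers (>= 1).
#' @param n_sequences Sequences per grid cell.
#' @return A `probe_result` tibble with columns `unit_size`, `multiplicity`,
#'   `sequence_id`, `value`, `model`, `seed`.
#' @export
probe_multiplicity <- function(model, unit_sizes = c(20, 70, 100),
                               multiplicities = c(1, 2, 4), n_sequences = 5,
                               seed = 1, exclude_first = FALSE) {
  stopifnot(length(unit_sizes) > 0, length(multiplicities) > 0,
            all(multiplicities >= 1), n_sequences >= 1)
  grid <- tidyr::expand_grid(unit_size = as.integer(unit_sizes),
                             multiplicity = as.integer(multiplicities),
                             replicate = seq_len(n_sequences))
  ab <- model_alphabet(model)
  rows <- purrr::pmap_dfr(grid, function(unit_size, multiplicity, replicate) {
    unit <- random_sequence(unit_size, ab,
                            seed = probe_seed(seed, 2L, replicate * 131L + unit_size))
    s <- tandem_repeat(unit, multiplicity)
    tibble::tibble(
      unit_size = unit_size, multiplicity = multiplicity,
      sequence_id = sprintf("u%d_seq_%03d", unit_size, replicate),
      value = pseudo_perplexity(one_at_a_time_profile(model, s), s,
                                exclude_first = exclude_first)
    )
  })
  new_probe_result(rows, "multiplicity", model, seed)
}

#' Imperfect-repeat probe
#'
#' For each sequence and mutation rate, the mutated copy is scored by local
#' single-pass pseudo-perplexity (a) in isolation and (b) concatenated after
#' the original, giving a paired table. Retrieval shows up as condition (b)
#' scoring systematically below condition (a) even when a large fraction of
#' positions differ.
#'
#' The probe's default matching parameters (window half-width 4, threshold
#' 0.45, retrieval strength 0.5) are tuned to *partial*-context retrieval:
#' windows around a position in a half-mutated copy agree with the original at
#' about half their residues, and a retrieval event concentrates only moderate
#' mass, since an aggressive winner-take-all retrieval at a mutated position
#' would be retrieving the wrong residue. See the methods vignette for the
#' derivation.
#'
#' @inheritParams probe_doubling
#' @param rates Mutation rates in `[0, 1]`.
#' @param length Length of the original sequence.
#' @param ops Mutation operations, as in [mutate_copy()].
#' @param model A model; if a [mock_model()] with default doubling settings is
#'   supplied, consider `imperfect_repeat_mock()` for parameters suited to
#'   partial matches.
#' @return A `probe_result` tibble with columns `rate`, `sequence_id`,
#'   `condition` (`"alone"`/`"with_original"`), `value`, `model`, `seed`.
#' @export
probe_imperfect_repeat <- function(model, rates = c(0, 0.5, 1),
                                   n_sequences = 25, length = 100,
                                   ops = "substitution", seed = 1) {
  stopifnot(all(rates >= 0), all(rates <= 1), n_sequences >= 1)
  ab <- model_alphabet(model)
  grid <- tidyr::expand_grid(rate = rates, replicate = seq_len(n_sequences))
  rows <- purrr::pmap_dfr(grid, function(rate, replicate) {
    orig <- random_sequence(length, ab, seed = probe_seed(seed, 3L, replicate))
    mut <- mutate_copy(orig, rate = rate, ops = ops,
                       seed = probe_seed(seed, 4L, replicate))
    paired <- seq_concat(orig, mut)
    m_len <- seq_length(mut)
    tibble::tibble(
      rate = rate,
      sequence_id = sprintf("seq_%03d", replicate),
      condition = c("alone", "with_original"),
      value = c(
        ofs_pseudo_perplexity(model, mut),
        ofs_pseudo_perplexity(model, paired,
                              span = c(length + 1L, length + m_len))
      )
    )
  })
  new_probe_result(rows, "imperfect_repeat", model, seed)
}

#' Mock model parameterized for partial-context retrieval
#'
#' Matching parameters suited to imperfect repeats: a slightly wider window
#' (half-width 4) stabilizes agreement estimates at the lenient threshold
#' (0.45), and a moderate retrieval strength (0.5) reflects that retrieval
#' from a half-matching context should shift, not annihilate, the prior.
#'
#' @param alphabet Alphabet for the model.
#' @param ... Overrides passed to [mock_model()].
#' @return A [mock_model()].
#' @export
imperfect_repeat_mock <- function(alphabet = protein_alphabet(), ...) {
  args <- utils::modifyList(
    list(alphabet = alphabet, window_halfwidth = 4, match_threshold = 0.45,
         retrieval_strength = 0.5, name = "mock-partial"),
    list(...)
  )
  do.call(mock_model, args)
}

#' Needle-in-a-haystack sweep
#'
#' Local single-pass pseudo-perplexity of the *first* needle over a grid of
#' needle and haystack sizes. Retrieval of the first needle can only come from
#' the second needle at the far end, so the sweep maps the model's operational
#' memory: cells whose needle-to-needle offset exceeds it stay at prior-level
#' perplexity.
#'
#' @inheritParams probe_doubling
#' @param needle_sizes,haystack_sizes Integer grids (non-empty).
#' @param n_sequences Sequences per cell.
#' @param collapse_threshold Optional pseudo-perplexity cutoff; when supplied,
#'   a logical `recognized` column (`value < collapse_threshold`) is added.
#'   The raw values are always retained.
#' @return A `probe_result` tibble with columns `needle_size`, `haystack_size`,
#'   `sequence_id`, `value` (and optionally `recognized`), `model`, `seed`.
#' @export
probe_needle_sweep <- function(model, needle_sizes = c(10, 20),
                               haystack_sizes = c(0, 100, 300), n_sequences = 5,
                               seed = 1, collapse_threshold = NULL) {
  stopifnot(length(needle_sizes) > 0, length(haystack_sizes) > 0,
            n_sequences >= 1)
  ab <- model_alphabet(model)
  grid <- tidyr::expand_grid(needle_size = as.integer(needle_sizes),
                             haystack_size = as.integer(haystack_sizes),
                             replicate = seq_len(n_sequences))
  rows <- purrr::pmap_dfr(grid, function(needle_size, haystack_size, replicate) {
    s <- needle_haystack(needle_size, haystack_size, ab,
                         seed = probe_seed(seed, 5L,
                                           replicate * 257L + needle_size + haystack_size))
    tibble::tibble(
      needle_size = needle_size, haystack_size = haystack_size,
      sequence_id = sprintf("n%d_h%d_seq_%03d", needle_size, haystack_size,
                            replicate),
      value = ofs_pseudo_perplexity(model, s, span = seq_span(s, "needle_1"))
    )
  })
  if (!is.null(collapse_threshold)) {
    rows$recognized <- rows$value < collapse_threshold
  }
  new_probe_result(rows, "needle_sweep", model, seed)
}

#' One-skip probe
#'
#' For each position of the first half of a one-skip pair, records the
#' probability mass the model places on (i) the residue at the equivalent
#' position of the second half and (ii) the true residue, from one-at-a-time
#' masked predictions. A control condition uses two unrelated random halves.
#' On a retrieval-capable model with tolerant matching, the equivalent-residue
#' profile is high throughout while the correct-residue profile spikes at the
#' alternating positions where the halves agree.
#'
#' @inheritParams probe_doubling
#' @param unit_length Length of each half.
#' @return A `probe_result` tibble with columns `condition`
#'   (`"skip"`/`"control"`), `sequence_id`, `position`, `p_equivalent`,
#'   `p_correct`, `model`, `seed`.
#' @export
probe_skip <- function(model, unit_length = 30, n_sequences = 10, seed = 1) {
  stopifnot(unit_length >= 2, n_sequences >= 1)
  ab <- model_alphabet(model)
  one_condition <- function(s, condition, r) {
    u <- unit_length
    prof <- one_at_a_time_profile(model, s, positions = seq_len(u))
    ints <- seq_ints(s)
    tibble::tibble(
      condition = condition,
      sequence_id = sprintf("%s_seq_%03d", condition, r),
      position = seq_len(u),
      p_equivalent = prof$prob[cbind(seq_len(u), ints[seq_len(u) + u])],
      p_correct = prof$prob[cbind(seq_len(u), ints[seq_len(u)])]
    )
  }
  rows <- purrr::map_dfr(seq_len(n_sequences), function(r) {
    skip <- one_skip_pair(unit_length, ab, seed = probe_seed(seed, 6L, r))
    ctrl <- seq_concat(
      random_sequence(unit_length, ab, seed = probe_seed(seed, 7L, r)),
      random_sequence(unit_length, ab, seed = probe_seed(seed, 8L, r))
    )
    dplyr::bind_rows(one_condition(skip, "skip", r),
                     one_condition(ctrl, "control", r))
  })
  new_probe_result(rows, "skip", model, seed)
}

#' Mock model parameterized for RNA context probes
#'
#' Over the 4-letter RNA alphabet a window of +/-3 residues matches by chance
#' far too often (chance agreement is 1/4 per residue), so the RNA mock widens
#' the matching window to +/-5 and enables both the identity and the
#' reverse-complement transform, reproducing the behaviour of a large RNA
#' model that recognizes hairpin-like motifs.
#'
#' @param ... Overrides passed to [mock_model()].
#' @return A [mock_model()] over [rna_alphabet()].
#' @export
rna_context_mock <- function(...) {
  args <- utils::modifyList(
    list(alphabet = rna_alphabet(), window_halfwidth = 5,
         transforms = c("identity", "reverse_complement"), name = "mock-rna"),
    list(...)
  )
  do.call(mock_model, args)
}

#' RNA context probe
#'
#' Appends different transformations of a random RNA segment to itself and
#' measures the one-at-a-time pseudo-perplexity of the *original* segment under
#' each context: an unrelated random sequence, a direct repeat, the
#' complement, the reversed sequence, and the reverse complement (the
#' hairpin-like motif). Which contexts trigger a collapse reveals which
#' transforms the model's retrieval machinery recognizes.
#'
#' @inheritParams probe_doubling
#' @param context_types Subset of `c("random", "repeat", "complement",
#'   "reversed", "reverse_complement")`.
#' @param length Length of the original segment (and of each context).
#' @return A `probe_result` tibble with columns `context`, `sequence_id`,
#'   `value`, `model`, `seed`.
#' @export
probe_rna_context <- function(model,
                              context_types = c("random", "repeat",
                                                "complement", "reversed",
                                                "reverse_complement"),
                              length = 30, n_sequences = 10, seed = 1) {
  ab <- model_alphabet(model)
  if (is.null(ab$complement_map)) {
    stop("probe_rna_context requires a model over a complemented (RNA) alphabet",
         call. = FALSE)
  }
  context_types <- match.arg(context_types,
                             c("random", "repeat", "complement", "reversed",
                               "reverse_complement"), several.ok = TRUE)
  rows <- purrr::map_dfr(seq_len(n_sequences), function(r) {
    orig <- random_sequence(length, ab, seed = probe_seed(seed, 9L, r))
    purrr::map_dfr(context_types, function(ctx) {
      context <- switch(ctx,
        random = random_sequence(length, ab, seed = probe_seed(seed, 10L, r)),
        "repeat" = orig,
        complement = seq_complement(orig),
        reversed = seq_reverse(orig),
        reverse_complement = seq_reverse_complement(orig)
      )
      s <- seq_concat(orig, context)
      tibble::tibble(
        context = ctx,
        sequence_id = sprintf("seq_%03d", r),
        value = pseudo_perplexity(
          one_at_a_time_profile(model, s, positions = seq_len(length)), s,
          positions = seq_len(length)
        )
      )
    })
  })
  new_probe_result(rows, "rna_context", model, seed)
}
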