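#' One-at-a-time masked profile
#'
#' For each requested position, a separate masked prediction with only that
#' position masked; the rows are assembled into a single profile. This is the
#' reference (slow) way to obtain per-position predictive distributions from a
#' masked language model.
#'
#' @param model A model implementing [predict_masked()].
#' @param seq A [bio_seq()].
#' @param positions Optional integer subset of positions; defaults to all.
#' @return A [prediction_profile()] over the requested positions.
#' @export
one_at_a_time_profile <- function(model, seq, positions = NULL) {
  L <- seq_length(seq)
  positions <- if (is.null(positions)) seq_len(L) else as.integer(positions)
  stopifnot(all(positions >= 1), all(positions <= L))
  rows <- lapply(positions, function(i) {
    predict_masked(model, seq, masked_positions = i)$prob
  })
  prediction_profile(positions, do.call(rbind, rows), model_alphabet(model))
}

#' Pseudo-perplexity of a sequence under a prediction profile
#'
#' `exp(-mean(log p_i(x_i)))` over the scored positions, where `p_i(x_i)` is
#' the probability the profile assigns to the true residue at position `i`.
#' A value of 1 means complete certainty about every scored residue; the
#' maximum useful value is the perplexity of the model's prior. When the
#' profile assigns zero probability to a true residue the result is `Inf`
#' (propagated with a warning, never clipped).
#'
#' @param profile A [prediction_profile()] covering the scored positions.
#' @param seq The [bio_seq()] the profile was computed for.
#' @param positions Optional subset of the profile's positions to score;
#'   defaults to all profile positions.
#' @param exclude_first Drop position 1 from the score set (useful for natural
#'   protein sequences, where the initiator methionine biases the first
#'   position; off by default for synthetic and RNA inputs).
#' @return A single numeric value `>= 1`.
#' @examples
#' m <- mock_model()
#' s <- random_sequence(20, seed = 1)
#' pseudo_perplexity(one_at_a_time_profile(m, s), s)
#' @export
pseudo_perplexity <- function(profile, seq, positions = NULL,
                              exclude_first = FALSE) {
  scored <- if (is.null(positions)) profile$positions else as.integer(positions)
  if (exclude_first) scored <- setdiff(scored, 1L)
  if (length(scored) == 0) stop("no positions to score", call. = FALSE)
  idx <- match(scored, profile$positions)
  if (anyNA(idx)) stop("profile does not cover all requested positions",
                       call. = FALSE)
  p_true <- profile_true_prob(profile, seq)[idx]
  if (any(p_true == 0)) {
    warning("zero probability on a true residue; pseudo-perplexity is Inf")
    return(Inf)
  }
  exp(-mean(log(p_true)))
}

#' Single-pass pseudo-perplexity
#'
#' Applies the pseudo-perplexity formula to the profile obtained from one
#' unmasked forward evaluation ([predict_unmasked_profile()]), optionally
#' restricted to a span. With `span` set to a sub-interval (e.g. the first
#' needle of a needle-in-a-haystack construction) this is the *local*
#' pseudo-perplexity of that region.
#'
#' @param model A model implementing [predict_unmasked_profile()].
#' @param seq A [bio_seq()].
#' @param span Optional `c(start, end)` (1-based, inclusive) restriction.
#' @param exclude_first As in [pseudo_perplexity()].
#' @return A single numeric value `>= 1`.
#' @export
ofs_pseudo_perplexity <- function(model, seq, span = NULL,
                                  exclude_first = FALSE) {
  L <- seq_length(seq)
  positions <- if (is.null(span)) {
    seq_len(L)
  } else {
    stopifnot(length(span) == 2, span[1] >= 1, span[2] <= L, span[1] <= span[2])
    seq.int(span[1], span[2])
  }
  profile <- predict_unmasked_profile(model, seq, positions = positions)
  pseudo_perplexity(profile, seq, exclude_first = exclude_first)
}

#' Left-to-right (autoregressive) perplexity
#'
#' `exp(-mean(log p(x_i | x_{<i})))`: each position is predicted from the
#' preceding context only. For models exposing the masked-prediction contract
#' this is evaluated by masking position `i` together with everything to its
#' right, so the prediction at `i` can draw on left context alone. The first
#' position is predicted from an empty context (the prior, for the mock).
#'
#' @param model A model implementing [predict_masked()].
#' @param seq A [bio_seq()].
#' @return A single numeric value `>= 1`.
#' @export
autoregressive_perplexity <- function(model, seq) {
  L <- seq_length(seq)
  if (L == 0) stop("sequence must be non-empty", call. = FALSE)
  logp <- vapply(seq_len(L), function(i) {
    prof <- predict_masked(model, seq, masked_positions = seq.int(i, L))
    log(profile_true_prob(prof, seq)[match(i, prof$positions)])
  }, numeric(1))
  exp(-mean(logp))
}

#' Shannon entropy of a probability vector (nats)
#'
#' `-sum(p * log(p))` with the convention `0 * log(0) = 0`. For a distribution
#' over an alphabet of size `k` the value lies in `[0, log(k)]`.
#'
#' @param p A probability vector (must sum to 1 within 1e-6), or a matrix of
#'   row distributions.
#' @return A numeric scalar, or a vector of row entropies for matrix input.
#' @examples
#' entropy(rep(1 / 20, 20)) # log(20)
#' @export
entropy <- function(p) {
  if (is.matrix(p)) return(apply(p, 1, entropy))
  if (abs(sum(p) - 1) > 1e-6 || any(p < -1e-12)) {
    stop("p must be a normalized probability vector", call. = FALSE)
  }
  terms <- ifelse(p > 0, p * log(p), 0)
  -sum(terms)
}

#' Score a set of sequences into a tidy table
#'
#' Convenience wrapper computing one or more scalar scores per sequence and
#' returning the long-format score table used by the pipeline writers.
#'
#' @param model A model object.
#' @param seqs A list of [bio_seq()] (named or with `id` fields).
#' @param scores Subset of `c("ppl_one_at_a_time", "ppl_ofs",
#'   "ppl_autoregressive")`.
#' @param exclude_first As in [pseudo_perplexity()].
#' @return A tibble with columns `sequence_id`, `score_name`, `span_start`,
#'   `span_end`, `value`, `model`.
#' @export
score_sequences <- function(model, seqs,
                            scores = c("ppl_one_at_a_time", "ppl_ofs"),
                            exclude_first = FALSE) {
  scores <- match.arg(scores, c("ppl_one_at_a_time", "ppl_ofs",
                                "ppl_autoregressive"), several.ok = TRUE)
  ids <- seq_ids(seqs)
  purrr::map2_dfr(seqs, ids, function(s, id) {
    vals <- purrr::map_dbl(scores, function(sc) {
      switch(sc,
        ppl_one_at_a_time = pseudo_perplexity(
          one_at_a_time_profile(model, s), s, exclude_first = exclude_first),
        ppl_ofs = ofs_pseudo_perplexity(model, s,
                                        exclude_first = exclude_first),
        ppl_autoregressive = autoregressive_perplexity(model, s)
      )
    })
    tibble::tibble(
      sequence_id = id, score_name = scores,
      span_start = 1L, span_end = seq_length(s),
      value = vals, model = model_name(model)
    )
  })
}

seq_ids <- function(seqs) {
  ids <- names(seqs)
  if (is.null(ids)) ids <- rep(NA_character_, length(seqs))
  fallback <- purrr::map_chr(seq_along(seqs), function(i) {
    id <- seqs[[i]]$id
    if (is.null(id)) sprintf("seq_%03d", i) else id
  })
  ifelse(is.na(ids) | ids == "", fallback, ids)
}

#' Filter sequences the way natural-domain probes expect
#'
#' Keeps sequences whose length lies in `[min_length, max_length]` and whose
#' single-pass pseudo-perplexity under `model` exceeds `min_ofs_ppl`. The
#' perplexity floor removes inputs that already contain repeated motifs, which
#' would contaminate retrieval probes with pre-collapsed baselines.
#'
#' @param seqs List of [bio_seq()].
#' @param model Model used for the baseline score (NULL skips that filter).
#' @param min_length,max_length Length bounds in residues.
#' @param min_ofs_ppl Baseline single-pass pseudo-perplexity floor (NULL skips).
#' @return The filtered list.
#' @export
apply_baseline_filters <- function(seqs, model = NULL, min_length = 20,
                                   max_length = 1000, min_ofs_ppl = 5) {
  keep <- purrr::map_lgl(seqs, function(s) {
    n <- seq_length(s)
    if (n < min_length || n > max_length) return(FALSE)
    if (!is.null(model) && !is.null(min_ofs_ppl)) {
      if (ofs_pseudo_perplexity(model, s) <= min_ofs_ppl) return(FALSE)
    }
    TRUE
  })
  seqs[keep]
}
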