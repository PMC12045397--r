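#' Per-position prediction profiles
#'
#' The universal currency between models and scores: for each queried position,
#' a probability vector over the canonical alphabet. Rows are validated to be
#' non-negative and to sum to 1 within 1e-6 on construction.
#'
#' @param positions Integer vector of 1-based sequence positions.
#' @param prob Numeric matrix, one row per position, one column per alphabet
#'   symbol (in alphabet order).
#' @param alphabet The [new_alphabet()] the columns refer to.
#' @return An object of class `prediction_profile`.
#' @export
prediction_profile <- function(positions, prob, alphabet) {
  prob <- as.matrix(prob)
  stopifnot(length(positions) == nrow(prob),
            ncol(prob) == alphabet_size(alphabet))
  if (any(prob < -1e-12)) stop("probabilities must be non-negative", call. = FALSE)
  sums <- rowSums(prob)
  if (any(abs(sums - 1) > 1e-6)) {
    stop("profile rows must sum to 1 within 1e-6", call. = FALSE)
  }
  colnames(prob) <- alphabet$symbols
  structure(
    list(positions = as.integer(positions), prob = prob, alphabet = alphabet),
    class = "prediction_profile"
  )
}

#' @export
print.prediction_profile <- function(x, ...) {
  cat(sprintf("<prediction_profile> %d positions over %s\n",
              length(x$positions), format(x$alphabet)))
  invisible(x)
}

#' @export
as.data.frame.prediction_profile <- function(x, ...) {
  as.data.frame(tidy_profile(x))
}

#' Tidy a prediction profile into long format
#' @param profile A [prediction_profile()].
#' @return A tibble with columns `position`, `symbol`, `probability`.
#' @export
tidy_profile <- function(profile) {
  tibble::tibble(
    position = rep(profile$positions, each = ncol(profile$prob)),
    symbol = rep(colnames(profile$prob), times = nrow(profile$prob)),
    probability = as.vector(t(profile$prob))
  )
}

# probability assigned to the true residues of `seq` at the profile positions
profile_true_prob <- function(profile, seq) {
  ints <- seq_ints(seq)
  profile$prob[cbind(seq_along(profile$positions), ints[profile$positions])]
}

#' Masked prediction contract
#'
#' `predict_masked()` asks a model for the predictive distribution at each
#' masked position, with all unmasked positions visible as context. The call is
#' stateless; rows are normalized over the canonical alphabet. Adapters for
#' external pretrained models must drop any model-specific special tokens,
#' renormalize over the canonical alphabet, and map their coordinates to 1-based
#' sequence positions before returning.
#'
#' @param model A model object (e.g. [mock_model()] or a registered adapter).
#' @param seq A [bio_seq()].
#' @param masked_positions Non-empty integer vector of 1-based positions.
#' @param ... Passed to methods.
#' @return A [prediction_profile()] with one row per masked position.
#' @export
predict_masked <- function(model, seq, masked_positions, ...) {
  UseMethod("predict_masked")
}

#' Single-pass (unmasked) prediction profile
#'
#' One forward evaluation with no masks, returning a full per-position profile.
#' This is the single-pass approximation to the one-at-a-time masked profile
#' that underlies fast pseudo-perplexity scoring.
#'
#' @inheritParams predict_masked
#' @param positions Optional subset of positions (default: all).
#' @return A [prediction_profile()].
#' @export
predict_unmasked_profile <- function(model, seq, positions = NULL, ...) {
  UseMethod("predict_unmasked_profile")
}

#' Residue-level embeddings
#'
#' One real vector of fixed dimension per residue position.
#'
#' @inheritParams predict_masked
#' @return A numeric matrix with `seq_length(seq)` rows.
#' @export
embed_sequence <- function(model, seq, ...) {
  UseMethod("embed_sequence")
}

#' Alphabet a model predicts over
#' @param model A model object.
#' @return A [new_alphabet()] object.
#' @export
model_alphabet <- function(model) UseMethod("model_alphabet")

#' Model display name
#' @param model A model object.
#' @return A single string used to label result tables.
#' @export
model_name <- function(model) UseMethod("model_name")

#' @export
model_name.default <- function(model) class(model)[1]

# ---- adapter registry -------------------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Adapter registry
#'
#' Models are registered under a name so configuration files can refer to them;
#' `get_adapter()` fails loudly when the name is unknown. The built-in `"mock"`
#' entry is constructed on the fly from mock parameters in the config block.
#'
#' @param name Adapter name.
#' @param model A model object implementing the prediction contract.
#' @return `register_adapter()` returns the model invisibly; `get_adapter()`
#'   returns the registered model; `list_adapters()` returns a character vector.
#' @export
register_adapter <- function(name, model) {
  stopifnot(is.character(name), length(name) == 1)
  assign(name, model, envir = the_registry)
  invisible(model)
}

#' @rdname register_adapter
#' @export
get_adapter <- function(name) {
  if (!exists(name, envir = the_registry, inherits = FALSE)) {
    stop(sprintf("no adapter registered under name '%s'", name), call. = FALSE)
  }
  get(name, envir = the_registry)
}

#' @rdname register_adapter
#' @export
list_adapters <- function() ls(the_registry)
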