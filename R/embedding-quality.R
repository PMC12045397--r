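# embedding-information regression: predict a sequence's one-at-a-time masked
# profile from residue-level embeddings, comparing repeat multiplicities
# against length-matched controls and a one-hot baseline

#' Internal-repeat sequence generator for the regression task
#'
#' Emulates a natural-like sequence with context-dependent structure: a random
#' half followed by a substitution-mutated copy of it (default rate 0.3). On a
#' retrieval-capable model, positions of such a sequence retrieve across the
#' internal imperfect repeat, so the one-at-a-time profile varies by position
#' instead of sitting at the flat prior — a prerequisite for the regression
#' task to have anything to learn.
#'
#' @param length Total length (even; the two halves are `length / 2`).
#' @param rate Substitution rate between the halves.
#' @param alphabet Alphabet to draw from.
#' @param seed Integer seed.
#' @return A [bio_seq()] with spans `half_1`, `half_2`.
#' @export
internal_repeat_sequence <- function(length, rate = 0.3,
                                     alphabet = protein_alphabet(), seed = 1) {
  stopifnot(length >= 4, length %% 2 == 0)
  half <- length %/% 2
  a <- random_sequence(half, alphabet, seed = seed)
  b <- mutate_copy(a, rate = rate, ops = "substitution", seed = seed + 1L)
  spans <- tibble::tibble(label = c("half_1", "half_2"),
                          start = c(1L, half + 1L),
                          end = c(half, as.integer(length)))
  bio_seq(paste0(a$residues, b$residues), alphabet, spans = spans)
}

#' Mock model parameterized for the regression task
#'
#' Matching threshold 0.6 admits internal imperfect repeats at substitution
#' rate 0.3 (expected window agreement about 0.72) while keeping chance
#' matches against random padding negligible.
#'
#' @param alphabet Alphabet for the model.
#' @param ... Overrides passed to [mock_model()].
#' @return A [mock_model()].
#' @export
regression_mock <- function(alphabet = protein_alphabet(), ...) {
  args <- utils::modifyList(
    list(alphabet = alphabet, window_halfwidth = 3, match_threshold = 0.6,
         retrieval_strength = 0.9, name = "mock-regression"),
    list(...)
  )
  do.call(mock_model, args)
}

regression_groups <- function(max_multiplicity = 5) {
  c("one_hot", "1x", paste0(2:max_multiplicity, "x"),
    paste0("control_", 2:max_multiplicity, "x"))
}

#' Build a regression dataset for one input group
#'
#' Inputs are per-position vectors; targets are always the one-at-a-time
#' masked profile of the *1x* sequence, so any degradation in loss is
#' attributable to the inputs. Groups: `"one_hot"` (identity coding of the
#' residue), `"1x"` (embeddings of the sequence itself), `"<m>x"` (embeddings
#' of the first repeating unit of the m-fold tandem repeat), and
#' `"control_<m>x"` (embeddings of the sequence prefix of the sequence padded
#' with random residues to m times its length).
#'
#' @param model A model implementing [embed_sequence()] and [predict_masked()].
#' @param sequences List of [bio_seq()] (the 1x sequences).
#' @param group One of [regression_groups()].
#' @param seed Integer seed (controls the random padding of control groups).
#' @return An object of class `regression_dataset`: a list with matrices
#'   `inputs` and `targets` (aligned row for row), `group`, and per-row
#'   `sequence_id` and `position` vectors.
#' @export
build_regression_dataset <- function(model, sequences, group, seed = 1) {
  stopifnot(length(sequences) > 0)
  valid <- regression_groups(99)
  if (!group %in% valid) {
    stop(sprintf("unknown group '%s'", group), call. = FALSE)
  }
  ab <- model_alphabet(model)
  k <- alphabet_size(ab)
  ids <- seq_ids(sequences)
  parts <- purrr::map2(sequences, seq_along(sequences), function(s, idx) {
    L <- seq_length(s)
    target <- one_at_a_time_profile(model, s)$prob
    inputs <- if (group == "one_hot") {
      oh <- matrix(0, nrow = L, ncol = k,
                   dimnames = list(NULL, ab$symbols))
      oh[cbind(seq_len(L), seq_ints(s))] <- 1
      oh
    } else if (group == "1x") {
      embed_sequence(model, s)
    } else if (grepl("^control_", group)) {
      m <- as.integer(sub("^control_(\\d+)x$", "\\1", group))
      pad <- random_sequence((m - 1L) * L, ab,
                             seed = probe_seed(seed, 15L, idx))
      embed_sequence(model, seq_concat(s, pad))[seq_len(L), , drop = FALSE]
    } else {
      m <- as.integer(sub("^(\\d+)x$", "\\1", group))
      embed_sequence(model, tandem_repeat(s, m))[seq_len(L), , drop = FALSE]
    }
    stopifnot(nrow(inputs) == nrow(target))
    list(inputs = inputs, targets = target,
         sequence_id = rep(ids[idx], L), position = seq_len(L))
  })
  structure(
    list(
      inputs = do.call(rbind, purrr::map(parts, "inputs")),
      targets = do.call(rbind, purrr::map(parts, "targets")),
      group = group,
      sequence_id = unlist(purrr::map(parts, "sequence_id")),
      position = unlist(purrr::map(parts, "position"))
    ),
    class = "regression_dataset"
  )
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf("<regression_dataset '%s'> %d rows, input dim %d, target dim %d\n",
              x$group, nrow(x$inputs), ncol(x$inputs), ncol(x$targets)))
  invisible(x)
}

#' Cross-entropy between target distributions and predictions (nats)
#'
#' `-mean over rows of sum(target * log(prediction))`. When the prediction
#' equals the target this is the target's own entropy — the achievable floor
#' of the regression task.
#'
#' @param target,prediction Matrices of row distributions (or single vectors).
#' @return A single numeric value.
#' @export
cross_entropy <- function(target, prediction) {
  if (!is.matrix(target)) target <- matrix(target, nrow = 1)
  if (!is.matrix(prediction)) prediction <- matrix(prediction, nrow = 1)
  stopifnot(identical(dim(target), dim(prediction)))
  eps <- 1e-12
  -mean(rowSums(target * log(pmax(prediction, eps))))
}

# ---- single-hidden-layer softmax readout ------------------------------------
# plain matrix-op MLP trained with full-batch Adam; exposes the per-epoch
# validation loss curve, which is the quantity this module reports

.mlp_init <- function(d_in, d_hidden, d_out, seed) {
  with_rng_seed(seed, {
    list(
      W1 = matrix(stats::rnorm(d_in * d_hidden, sd = sqrt(2 / d_in)),
                  d_in, d_hidden),
      b1 = rep(0, d_hidden),
      W2 = matrix(stats::rnorm(d_hidden * d_out, sd = sqrt(2 / d_hidden)),
                  d_hidden, d_out),
      b2 = rep(0, d_out)
    )
  })
}

.mlp_forward <- function(par, X) {
  H <- pmax(sweep(X %*% par$W1, 2, par$b1, "+"), 0) # ReLU
  Z <- sweep(H %*% par$W2, 2, par$b2, "+")
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  P <- E / rowSums(E)
  list(H = H, P = P)
}

.mlp_train <- function(X, Y, X_val, Y_val, hidden, epochs, lr = 0.01,
                       seed = 1) {
  d_in <- ncol(X); d_out <- ncol(Y); n <- nrow(X)
  par <- .mlp_init(d_in, hidden, d_out, seed)
  ms <- lapply(par, function(p) p * 0)
  vs <- lapply(par, function(p) p * 0)
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  loss_train <- numeric(epochs); loss_val <- numeric(epochs)
  for (e in seq_len(epochs)) {
    fw <- .mlp_forward(par, X)
    dZ <- (fw$P - Y) / n
    grads <- list(
      W1 = NULL, b1 = NULL,
      W2 = crossprod(fw$H, dZ), b2 = colSums(dZ)
    )
    dH <- dZ %*% t(par$W2)
    dH[fw$H <= 0] <- 0
    grads$W1 <- crossprod(X, dH)
    grads$b1 <- colSums(dH)
    for (nm in names(par)) {
      ms[[nm]] <- b1 * ms[[nm]] + (1 - b1) * grads[[nm]]
      vs[[nm]] <- b2 * vs[[nm]] + (1 - b2) * grads[[nm]]^2
      mhat <- ms[[nm]] / (1 - b1^e)
      vhat <- vs[[nm]] / (1 - b2^e)
      par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + adam_eps)
    }
    loss_train[e] <- cross_entropy(Y, fw$P)
    loss_val[e] <- cross_entropy(Y_val, .mlp_forward(par, X_val)$P)
  }
  list(par = par, loss_train = loss_train, loss_val = loss_val)
}

#' Train the readout ensemble over dataset groups
#'
#' Trains one single-hidden-layer softmax readout per group per run,
#' minimizing the cross-entropy between the predicted and target
#' distributions. Within a run every group shares the same training/validation
#' split indices (a paired design), so group comparisons are not confounded by
#' the split. Per-epoch training and validation losses are recorded; there is
#' no early stopping, the full curves are reported.
#'
#' @param datasets Named list of [build_regression_dataset()] results with
#'   equal row counts.
#' @param split Training fraction in (0, 1) (default 0.8).
#' @param runs Number of independent runs (fresh split + initialization).
#' @param epochs Epochs per run.
#' @param hidden_multiplier Hidden width as a multiple of the input dimension.
#' @param learning_rate Adam step size.
#' @param seed Integer seed.
#' @return An object of class `embedding_regression`: list with `curves` (a
#'   tibble `group`, `run`, `epoch`, `split`, `loss`), `val_indices` (per-run
#'   validation row indices), and the call parameters.
#' @export
train_ensemble <- function(datasets, split = 0.8, runs = 5, epochs = 60,
                           hidden_multiplier = 4, learning_rate = 0.01,
                           seed = 1) {
  stopifnot(split > 0, split < 1, runs >= 1, epochs >= 1)
  stopifnot(length(datasets) >= 1, !is.null(names(datasets)))
  n <- unique(purrr::map_int(datasets, ~ nrow(.x$inputs)))
  if (length(n) != 1) {
    stop("all dataset groups must have the same number of rows (paired design)",
         call. = FALSE)
  }
  curves <- list()
  val_indices <- list()
  for (r in seq_len(runs)) {
    train_idx <- with_rng_seed(probe_seed(seed, 16L, r), {
      sort(sample.int(n, size = floor(split * n)))
    })
    val_idx <- setdiff(seq_len(n), train_idx)
    val_indices[[r]] <- val_idx
    for (g in names(datasets)) {
      ds <- datasets[[g]]
      fit <- .mlp_train(
        X = ds$inputs[train_idx, , drop = FALSE],
        Y = ds$targets[train_idx, , drop = FALSE],
        X_val = ds$inputs[val_idx, , drop = FALSE],
        Y_val = ds$targets[val_idx, , drop = FALSE],
        hidden = hidden_multiplier * ncol(ds$inputs),
        epochs = epochs, lr = learning_rate,
        seed = probe_seed(seed, 17L, r * 131L + match(g, names(datasets)))
      )
      if (!all(is.finite(fit$loss_val))) {
        warning(sprintf("non-finite validation loss for group '%s', run %d",
                        g, r))
      }
      curves[[length(curves) + 1]] <- tibble::tibble(
        group = g, run = r, epoch = rep(seq_len(epochs), 2),
        split = rep(c("train", "validation"), each = epochs),
        loss = c(fit$loss_train, fit$loss_val)
      )
    }
  }
  structure(
    list(
      curves = dplyr::bind_rows(curves),
      val_indices = val_indices,
      split = split, runs = runs, epochs = epochs,
      hidden_multiplier = hidden_multiplier,
      learning_rate = learning_rate, seed = as.integer(seed),
      groups = names(datasets)
    ),
    class = "embedding_regression"
  )
}

#' @export
print.embedding_regression <- function(x, ...) {
  cat(sprintf(
    "<embedding_regression> %d groups x %d runs x %d epochs (split %.0f/%.0f)\n",
    length(x$groups), x$runs, x$epochs, 100 * x$split, 100 * (1 - x$split)
  ))
  print(compare_groups(x))
  invisible(x)
}

#' Compare validation losses across groups
#'
#' Final-epoch and best-epoch validation loss per group, averaged over runs,
#' with bootstrap intervals over runs, plus a monotonicity summary for the
#' multiplicity groups.
#'
#' @param run An [train_ensemble()] result.
#' @param conf Bootstrap interval coverage.
#' @param bootstrap_samples Bootstrap resamples over runs.
#' @param seed Seed for the bootstrap.
#' @param monotone_tol Slack (nats) allowed when judging whether final loss is
#'   non-decreasing across multiplicities; beyond the corruption induced by the
#'   first extra copy the groups carry equal information, so their losses are
#'   expected to differ only by training noise.
#' @return A tibble with columns `group`, `final_loss`, `best_loss`,
#'   `conf_low`, `conf_high`; the attribute `"multiplicity_monotone"` reports
#'   whether final loss is non-decreasing across the `<m>x` groups (within
#'   `monotone_tol`).
#' @export
compare_groups <- function(run, conf = 0.95, bootstrap_samples = 200,
                           seed = 1, monotone_tol = 0.02) {
  stopifnot(inherits(run, "embedding_regression"))
  val <- dplyr::filter(run$curves, .data$split == "validation")
  finals <- val |>
    dplyr::filter(.data$epoch == max(.data$epoch)) |>
    dplyr::select("group", "run", final = "loss")
  bests <- val |>
    dplyr::group_by(.data$group, .data$run) |>
    dplyr::summarise(best = min(.data$loss), .groups = "drop")
  boot_ci <- function(x) {
    if (length(x) < 2) return(c(mean(x), mean(x)))
    draws <- with_rng_seed(seed, {
      vapply(seq_len(bootstrap_samples),
             function(b) mean(sample(x, replace = TRUE)), numeric(1))
    })
    stats::quantile(draws, probs = c((1 - conf) / 2, 1 - (1 - conf) / 2),
                    names = FALSE)
  }
  out <- finals |>
    dplyr::left_join(bests, by = c("group", "run")) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      final_loss = mean(.data$final),
      best_loss = mean(.data$best),
      conf_low = boot_ci(.data$final)[1],
      conf_high = boot_ci(.data$final)[2],
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$group, run$groups))
  mult <- out$final_loss[grepl("^\\d+x$", out$group) & out$group != "1x"]
  attr(out, "multiplicity_monotone") <-
    if (length(mult) >= 2) all(diff(mult) >= -monotone_tol) else NA
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the loss curves of an embedding regression
#' @param x An `embedding_regression` object.
#' @param ... Unused.
#' @return The curves tibble (`group`, `run`, `epoch`, `split`, `loss`).
#' @export
tidy.embedding_regression <- function(x, ...) x$curves

#' One-row summary of an embedding regression
#' @param x An `embedding_regression` object.
#' @param ... Unused.
#' @return A one-row tibble with run dimensions and the best group.
#' @export
glance.embedding_regression <- function(x, ...) {
  cmp <- compare_groups(x)
  tibble::tibble(
    n_groups = length(x$groups), runs = x$runs, epochs = x$epochs,
    split = x$split,
    best_group = cmp$group[which.min(cmp$final_loss)],
    min_final_loss = min(cmp$final_loss),
    max_final_loss = max(cmp$final_loss)
  )
}

#' End-to-end embedding-information experiment
#'
#' Generates internal-repeat sequences, builds all requested groups, and
#' trains the readout ensemble.
#'
#' @param model A model (default [regression_mock()]).
#' @param n_sequences Number of 1x sequences.
#' @param length Length of each 1x sequence (even).
#' @param multiplicities Repeat multiplicities to compare (each with its
#'   length-matched control).
#' @param internal_rate Substitution rate of the internal repeat.
#' @param seed Integer seed.
#' @inheritParams train_ensemble
#' @return An [train_ensemble()] result.
#' @export
run_embedding_experiment <- function(model = regression_mock(),
                                     n_sequences = 30, length = 30,
                                     multiplicities = 2:5,
                                     internal_rate = 0.3, split = 0.8,
                                     runs = 5, epochs = 60, seed = 1) {
  seqs <- purrr::map(seq_len(n_sequences), function(r) {
    internal_repeat_sequence(length, rate = internal_rate,
                             alphabet = model_alphabet(model),
                             seed = probe_seed(seed, 18L, r))
  })
  groups <- c("one_hot", "1x", paste0(multiplicities, "x"),
              paste0("control_", multiplicities, "x"))
  datasets <- purrr::map(groups, function(g) {
    build_regression_dataset(model, seqs, g, seed = seed)
  })
  names(datasets) <- groups
  train_ensemble(datasets, split = split, runs = runs, epochs = epochs,
                 seed = seed)
}
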