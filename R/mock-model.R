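#' Configurable mock retrieval model
#'
#' A deterministic stand-in for a masked sequence language model that performs
#' in-context retrieval by explicit window matching. For a queried position it
#' scans every candidate source position within `memory_limit` residues (under
#' the allowed transforms), scores the agreement of the surrounding windows,
#' and, when a candidate passes `match_threshold`, concentrates probability
#' mass on the retrieved symbol; otherwise it returns its `prior`. All
#' behaviour is a pure function of the inputs: no hidden state, no randomness.
#'
#' Matching windows never involve the queried position itself, on either side
#' of the comparison. This mirrors masking semantics (the model must not see
#' the answer), and it makes the unmasked single-pass profile *exactly* equal
#' to the one-at-a-time masked profile — a documented property used as a
#' regression check for the single-pass scoring path.
#'
#' In `"collapse"` mode the prediction at a retrieving position is
#' `(1 - eps) * delta(retrieved symbol) + eps * prior` with
#' `eps = 1 - retrieval_strength`. In `"progressive"` mode with `k` candidates
#' supporting the retrieved symbol, the retrieved-symbol weight is
#' `1 - (1 - retrieval_strength)^k`, the remainder spread as the prior, so
#' confidence grows with the number of supporting copies.
#'
#' @param alphabet Alphabet the model predicts over.
#' @param prior Probability vector over the alphabet used in the absence of a
#'   match (default uniform).
#' @param window_halfwidth Half-width (residues) of the matching window around
#'   a position.
#' @param match_threshold Minimum fraction of agreeing symbols for a candidate
#'   to count, in `[0, 1]`.
#' @param memory_limit Maximum offset (residues) at which matching is
#'   attempted; the mock analogue of a model's operational memory.
#' @param retrieval_strength Fraction in `[0, 1]` controlling how much mass is
#'   moved onto a retrieved symbol.
#' @param mode `"collapse"` (winner-take-all certainty) or `"progressive"`
#'   (confidence accumulates over supporting copies).
#' @param transforms Subset of `c("identity", "reverse_complement")`; the
#'   reverse-complement transform requires a complemented alphabet.
#' @param min_comparisons Minimum number of valid window comparisons a
#'   candidate needs before its score counts (default: the window half-width).
#'   Clipped windows at sequence ends can otherwise reach a perfect score from
#'   one or two chance agreements.
#' @param name Display name used in result tables.
#' @return An object of class `mock_model`.
#' @examples
#' m <- mock_model()
#' s <- tandem_repeat(random_sequence(20, seed = 1), 2)
#' predict_masked(m, s, masked_positions = 5)
#' @export
mock_model <- function(alphabet = protein_alphabet(), prior = NULL,
                       window_halfwidth = 3, match_threshold = 0.9,
                       memory_limit = 1000, retrieval_strength = 0.95,
                       mode = c("collapse", "progressive"),
                       transforms = "identity",
                       min_comparisons = window_halfwidth, name = "mock") {
  mode <- match.arg(mode)
  k <- alphabet_size(alphabet)
  if (is.null(prior)) prior <- rep(1 / k, k)
  stopifnot(length(prior) == k, all(prior >= 0), abs(sum(prior) - 1) < 1e-8)
  stopifnot(match_threshold >= 0, match_threshold <= 1,
            retrieval_strength >= 0, retrieval_strength <= 1,
            memory_limit >= 1, window_halfwidth >= 1, min_comparisons >= 1)
  transforms <- match.arg(transforms, c("identity", "reverse_complement"),
                          several.ok = TRUE)
  if ("reverse_complement" %in% transforms && is.null(alphabet$complement_map)) {
    stop("reverse_complement transform requires a complemented alphabet",
         call. = FALSE)
  }
  structure(
    list(
      alphabet = alphabet, prior = as.numeric(prior),
      window_halfwidth = as.integer(window_halfwidth),
      match_threshold = match_threshold,
      memory_limit = as.integer(memory_limit),
      retrieval_strength = retrieval_strength,
      mode = mode, transforms = transforms,
      min_comparisons = as.integer(min_comparisons), name = name
    ),
    class = c("mock_model", "seq_model")
  )
}

#' @export
print.mock_model <- function(x, ...) {
  cat(sprintf(
    "<mock_model '%s'> %s mode, window +/-%d, threshold %.2f, memory %d, strength %.2f, transforms: %s\n",
    x$name, x$mode, x$window_halfwidth, x$match_threshold, x$memory_limit,
    x$retrieval_strength, paste(x$transforms, collapse = "+")
  ))
  invisible(x)
}

#' @export
model_alphabet.mock_model <- function(model) model$alphabet

#' @export
model_name.mock_model <- function(model) model$name

# ---- matching engine --------------------------------------------------------

# clipped moving-window sums: out[i] = sum(x[max(1,i-w) : min(n,i+w)])
.window_sums <- function(x, w) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + w, n)
  lo <- pmax(seq_len(n) - w, 1L)
  cs[hi + 1L] - cs[lo]
}

# Candidate scan, vectorized over queries one offset at a time.
# s: integer codes; u: 0/1 unmasked indicator; returns a data.frame of
# candidates with score >= threshold and unmasked source.
.scan_all <- function(s, u, params, queries) {
  L <- length(s)
  w <- params$window_halfwidth
  mc <- params$min_comparisons %||% 1L
  acc <- list()
  n_acc <- 0L
  push <- function(i, j, transform, score) {
    n_acc <<- n_acc + 1L
    acc[[n_acc]] <<- data.frame(i = i, j = j, transform = transform,
                                score = score)
  }
  max_m <- min(params$memory_limit, L - 1L)
  if ("identity" %in% params$transforms && max_m >= 1) {
    for (m in seq_len(max_m)) {
      p <- seq_len(L - m)
      g <- numeric(L)
      v <- numeric(L)
      v[p] <- u[p] * u[p + m]
      g[p] <- (s[p] == s[p + m]) * v[p]
      G <- .window_sums(g, w)
      V <- .window_sums(v, w)
      gm <- function(idx) ifelse(idx >= 1 & idx <= L, g[pmax(idx, 1L)], 0)
      vm <- function(idx) ifelse(idx >= 1 & idx <= L, v[pmax(idx, 1L)], 0)
      excl <- as.numeric(m <= w)
      # forward offset +m
      q <- queries[queries + m <= L]
      if (length(q) > 0) {
        num <- G[q] - g[q] - excl * gm(q - m)
        den <- V[q] - v[q] - excl * vm(q - m)
        ok <- den >= mc & u[q + m] == 1 & (num / pmax(den, 1)) >= params$match_threshold
        if (any(ok)) push(q[ok], q[ok] + m, "identity", (num / den)[ok])
      }
      # backward offset -m
      q <- queries[queries - m >= 1]
      if (length(q) > 0) {
        num <- G[q - m] - g[q - m] - excl * gm(q)
        den <- V[q - m] - v[q - m] - excl * vm(q)
        ok <- den >= mc & u[q - m] == 1 & (num / pmax(den, 1)) >= params$match_threshold
        if (any(ok)) push(q[ok], q[ok] - m, "identity", (num / den)[ok])
      }
    }
  }
  if ("reverse_complement" %in% params$transforms) {
    comp <- complement_perm(params$alphabet)
    sc <- comp[s]
    for (cc in 3:(2L * L - 1L)) {
      p <- seq.int(max(1L, cc - L), min(L, cc - 1L))
      g <- numeric(L)
      v <- numeric(L)
      v[p] <- u[p] * u[cc - p]
      g[p] <- (s[p] == sc[cc - p]) * v[p]
      G <- .window_sums(g, w)
      V <- .window_sums(v, w)
      q <- queries[cc - queries >= 1 & cc - queries <= L & cc != 2L * queries]
      if (length(q) == 0) next
      o <- cc - 2L * q
      q <- q[abs(o) <= params$memory_limit]
      if (length(q) == 0) next
      o <- cc - 2L * q
      j <- cc - q
      excl <- as.numeric(abs(o) <= w)
      num <- G[q] - g[q] - excl * g[j]
      den <- V[q] - v[q] - excl * v[j]
      ok <- den >= mc & u[j] == 1 & (num / pmax(den, 1)) >= params$match_threshold
      if (any(ok)) push(q[ok], j[ok], "reverse_complement", (num / den)[ok])
    }
  }
  if (n_acc == 0) {
    return(data.frame(i = integer(), j = integer(), transform = character(),
                      score = numeric()))
  }
  do.call(rbind, acc[seq_len(n_acc)])
}

# Candidate scan, looping offsets for a single query (cheap when few queries).
.scan_query <- function(s, u, params, i) {
  L <- length(s)
  w <- params$window_halfwidth
  mc <- params$min_comparisons %||% 1L
  max_m <- min(params$memory_limit, L - 1L)
  out_i <- integer(0); out_j <- integer(0)
  out_t <- character(0); out_s <- numeric(0)
  if ("identity" %in% params$transforms && max_m >= 1) {
    for (o in c(-rev(seq_len(max_m)), seq_len(max_m))) {
      j <- i + o
      if (j < 1 || j > L || u[j] != 1) next
      d <- setdiff(seq.int(-w, w), c(0L, -o))
      p <- i + d
      q <- j + d
      keep <- p >= 1 & p <= L & q >= 1 & q <= L
      p <- p[keep]; q <- q[keep]
      keep2 <- u[p] == 1 & u[q] == 1
      p <- p[keep2]; q <- q[keep2]
      if (length(p) < mc) next
      score <- mean(s[p] == s[q])
      if (score >= params$match_threshold) {
        out_i <- c(out_i, i); out_j <- c(out_j, j)
        out_t <- c(out_t, "identity"); out_s <- c(out_s, score)
      }
    }
  }
  if ("reverse_complement" %in% params$transforms) {
    comp <- complement_perm(params$alphabet)
    for (o in c(-rev(seq_len(max_m)), seq_len(max_m))) {
      j <- i + o
      if (j < 1 || j > L || u[j] != 1) next
      d <- setdiff(seq.int(-w, w), c(0L, o))
      p <- i + d
      q <- j - d
      keep <- p >= 1 & p <= L & q >= 1 & q <= L
      p <- p[keep]; q <- q[keep]
      keep2 <- u[p] == 1 & u[q] == 1
      p <- p[keep2]; q <- q[keep2]
      if (length(p) < mc) next
      score <- mean(s[p] == comp[s[q]])
      if (score >= params$match_threshold) {
        out_i <- c(out_i, i); out_j <- c(out_j, j)
        out_t <- c(out_t, "reverse_complement"); out_s <- c(out_s, score)
      }
    }
  }
  data.frame(i = out_i, j = out_j, transform = out_t, score = out_s)
}

.scan_candidates <- function(s, u, params, queries) {
  L <- length(s)
  w <- params$window_halfwidth
  # vectorized path amortizes one cumsum per offset over all queries
  if (length(queries) > max(4, L / (4 * w))) {
    .scan_all(s, u, params, sort(unique(queries)))
  } else {
    do.call(rbind, lapply(queries, function(i) .scan_query(s, u, params, i)))
  }
}

# canonical candidate ordering: score desc, |offset| asc, source asc,
# identity before reverse_complement
.order_candidates <- function(cand) {
  absoff <- abs(cand$j - cand$i)
  trank <- match(cand$transform, c("identity", "reverse_complement"))
  cand[order(-cand$score, absoff, cand$j, trank), , drop = FALSE]
}

#' Search for retrieval sources matching a position
#'
#' For every candidate source position `j != i` within the model's memory
#' limit and every allowed transform, scores the fraction of agreeing symbols
#' between the windows around `i` and (the transformed window around) `j`.
#' Pairs involving `i` itself or any masked position are ignored. Candidates
#' scoring at least the match threshold are returned sorted by score
#' (descending), then absolute offset, then source position, then transform
#' (identity first).
#'
#' @param seq A [bio_seq()].
#' @param i Query position (1-based).
#' @param params A [mock_model()] carrying the matching parameters.
#' @param masked_positions Positions treated as masked (ignored in windows;
#'   excluded as sources).
#' @return A tibble with columns `position`, `transform`, `score`.
#' @export
match_search <- function(seq, i, params, masked_positions = integer()) {
  L <- seq_length(seq)
  if (i < 1 || i > L) stop("query position out of range", call. = FALSE)
  stopifnot(identical(seq$alphabet$symbols, params$alphabet$symbols))
  s <- seq_ints(seq)
  u <- rep(1, L)
  u[masked_positions] <- 0
  cand <- .order_candidates(.scan_query(s, u, params, as.integer(i)))
  tibble::tibble(position = cand$j, transform = cand$transform,
                 score = cand$score)
}

# ---- prediction -------------------------------------------------------------

.mock_profile <- function(model, seq, masked, queries) {
  L <- seq_length(seq)
  stopifnot(all(queries >= 1), all(queries <= L))
  s <- seq_ints(seq)
  u <- rep(1, L)
  u[masked] <- 0
  k <- alphabet_size(model$alphabet)
  comp <- complement_perm(model$alphabet)
  cand <- .scan_candidates(s, u, model, as.integer(queries))
  prob <- matrix(model$prior, nrow = length(queries), ncol = k, byrow = TRUE)
  if (nrow(cand) > 0) {
    cand <- .order_candidates(cand)
    cand$sym <- ifelse(cand$transform == "identity", s[cand$j], comp[s[cand$j]])
    by_query <- split(cand, factor(cand$i, levels = queries))
    eps <- 1 - model$retrieval_strength
    for (r in seq_along(queries)) {
      cc <- by_query[[r]]
      if (is.null(cc) || nrow(cc) == 0) next
      sym <- cc$sym[1]
      weight <- if (model$mode == "collapse") {
        1 - eps
      } else {
        1 - eps^sum(cc$sym == sym)
      }
      row <- (1 - weight) * model$prior
      row[sym] <- row[sym] + weight
      prob[r, ] <- row
    }
  }
  prediction_profile(queries, prob, model$alphabet)
}

#' @export
predict_masked.mock_model <- function(model, seq, masked_positions, ...) {
  masked_positions <- as.integer(masked_positions)
  if (length(masked_positions) == 0) {
    stop("masked_positions must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(masked_positions)) {
    stop("masked_positions must be distinct", call. = FALSE)
  }
  .mock_profile(model, seq, masked = masked_positions,
                queries = masked_positions)
}

#' @export
predict_unmasked_profile.mock_model <- function(model, seq, positions = NULL, ...) {
  L <- seq_length(seq)
  if (L == 0) stop("sequence must be non-empty", call. = FALSE)
  positions <- if (is.null(positions)) seq_len(L) else as.integer(positions)
  .mock_profile(model, seq, masked = integer(0), queries = positions)
}

#' @export
embed_sequence.mock_model <- function(model, seq, ...) {
  L <- seq_length(seq)
  s <- seq_ints(seq)
  k <- alphabet_size(model$alphabet)
  comp <- complement_perm(model$alphabet)
  u <- rep(1, L)
  cand <- .scan_candidates(s, u, model, seq_len(L))
  emb <- matrix(0, nrow = L, ncol = 2 * k)
  emb[cbind(seq_len(L), s)] <- 1
  if (nrow(cand) > 0) {
    cand <- .order_candidates(cand)
    best <- cand[!duplicated(cand$i), , drop = FALSE]
    sym <- ifelse(best$transform == "identity", s[best$j], comp[s[best$j]])
    emb[cbind(best$i, k + sym)] <- 1
  }
  colnames(emb) <- c(paste0("own_", model$alphabet$symbols),
                     paste0("ret_", model$alphabet$symbols))
  emb
}
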