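test_that("profiles are normalized and prediction is deterministic", {
  m <- mock_model()
  s <- tandem_repeat(random_sequence(25, seed = 1), 2)
  prof <- predict_masked(m, s, masked_positions = c(3, 10, 40))
  expect_equal(rowSums(prof$prob), rep(1, 3), tolerance = 1e-9)
  expect_true(all(prof$prob >= 0))
  prof2 <- predict_masked(m, s, masked_positions = c(3, 10, 40))
  expect_identical(prof$prob, prof2$prob)
  expect_error(predict_masked(m, s, masked_positions = integer()), "non-empty")
  expect_error(prediction_profile(1, matrix(rep(0.1, 20), 1),
                                  protein_alphabet()), "sum to 1")
})

test_that("retrieval-disabled mock returns exactly the prior", {
  m <- mock_model(retrieval_strength = 0)
  s <- tandem_repeat(random_sequence(20, seed = 2), 2)
  prof <- predict_masked(m, s, masked_positions = 5)
  # strength 0 => retrieved weight 0 even when a match exists
  expect_equal(unname(prof$prob[1, ]), m$prior, tolerance = 1e-12)
  # and so does an impossible threshold
  m2 <- mock_model(match_threshold = 1)
  r <- random_sequence(40, seed = 3)
  prof2 <- predict_masked(m2, r, masked_positions = 10)
  expect_equal(unname(prof2$prob[1, ]), m2$prior, tolerance = 1e-12)
})

test_that("doubled sequences retrieve the equivalent residue at full score", {
  m <- mock_model()
  u <- random_sequence(30, seed = 4)
  d <- tandem_repeat(u, 2)
  for (i in c(1, 7, 15, 30)) {
    cand <- match_search(d, i, m)
    expect_equal(cand$position[1], i + 30)
    expect_equal(cand$score[1], 1)
  }
  # prediction concentrates retrieval_strength-close to 1 on the true symbol
  prof <- predict_masked(m, d, masked_positions = 8)
  sym <- seq_chars(d)[8]
  expect_gte(prof$prob[1, sym], m$retrieval_strength)
})

test_that("match_search agrees with the brute-force oracle on varied inputs", {
  set.seed(42)
  for (rep in 1:25) {
    is_rna <- rep %% 2 == 0
    ab <- if (is_rna) rna_alphabet() else protein_alphabet()
    L <- sample(12:60, 1)
    base <- random_sequence(L, ab, seed = rep)
    s <- if (rep %% 3 == 0) {
      seq_concat(base, if (is_rna) seq_reverse_complement(base) else base)
    } else if (rep %% 3 == 1) {
      tandem_repeat(base, 2)
    } else base
    params <- mock_model(
      alphabet = ab,
      window_halfwidth = sample(2:5, 1),
      match_threshold = sample(c(0.4, 0.6, 0.9, 1.0), 1),
      memory_limit = sample(c(5, 20, 1000), 1),
      transforms = if (is_rna) c("identity", "reverse_complement") else "identity"
    )
    masked <- if (rep %% 4 == 0) sample(seq_length(s), 3) else integer()
    i <- sample(setdiff(seq_len(seq_length(s)), masked), 1)
    got <- as.data.frame(match_search(s, i, params, masked_positions = masked))
    want <- oracle_match_search(s, i, params, masked = masked)
    expect_equal(got, want, tolerance = 1e-12,
                 info = sprintf("rep %d, i = %d", rep, i))
  }
})

test_that("memory limit cuts retrieval off beyond the configured offset", {
  u <- random_sequence(50, seed = 5)
  d <- tandem_repeat(u, 2)
  near <- mock_model(memory_limit = 50)
  far <- mock_model(memory_limit = 49)
  expect_equal(match_search(d, 10, near)$position[1], 60L)
  expect_equal(nrow(match_search(d, 10, far)), 0L)
  prof <- predict_masked(far, d, masked_positions = seq_len(10))
  expect_equal(unname(prof$prob),
               matrix(far$prior, 10, 20, byrow = TRUE), tolerance = 1e-12)
})

test_that("masking the source makes the mock fall back to the prior", {
  m <- mock_model()
  d <- tandem_repeat(random_sequence(30, seed = 6), 2)
  i <- 12
  both <- predict_masked(m, d, masked_positions = c(i, i + 30))
  expect_equal(unname(both$prob[1, ]), m$prior, tolerance = 1e-12)
  # masking a non-equivalent position leaves the match intact
  other <- predict_masked(m, d, masked_positions = c(i, i + 33))
  sym <- seq_chars(d)[i]
  expect_gte(other$prob[1, sym], m$retrieval_strength)
})

test_that("substituting the equivalent residue redirects the prediction", {
  m <- mock_model()
  u <- random_sequence(30, seed = 7)
  ch <- rep(seq_chars(u), 2)
  i <- 13
  ch[i + 30] <- "K"
  flipped <- bio_seq(paste(ch, collapse = ""), protein_alphabet())
  prof <- predict_masked(m, flipped, masked_positions = i)
  expect_gte(prof$prob[1, "K"], m$retrieval_strength)
})

test_that("progressive mode accumulates confidence over supporting copies", {
  m <- mock_model(mode = "progressive", retrieval_strength = 0.5,
                  memory_limit = 1000)
  u <- random_sequence(10, seed = 8)
  masses <- vapply(c(2, 3, 4, 6), function(mult) {
    s <- tandem_repeat(u, mult)
    prof <- predict_masked(m, s, masked_positions = 5)
    prof$prob[1, seq_chars(u)[5]]
  }, numeric(1))
  expect_true(all(diff(masses) > 0))
  # closed form: weight = 1 - (1 - strength)^(mult - 1), plus prior remainder
  expect_equal(unname(masses),
               (1 - 0.5^(c(2, 3, 4, 6) - 1)) +
                 0.5^(c(2, 3, 4, 6) - 1) * (1 / 20),
               tolerance = 1e-12)
})

test_that("reverse-complement contexts are matched only under the rc transform", {
  s <- random_sequence(20, rna_alphabet(), seed = 9)
  x <- seq_concat(s, seq_reverse_complement(s))
  with_rc <- rna_context_mock()
  without <- rna_context_mock(transforms = "identity")
  cand <- match_search(x, 8, with_rc)
  expect_identical(cand$transform[1], "reverse_complement")
  expect_identical(cand$position[1], 40L - 8L + 1L)
  expect_equal(cand$score[1], 1)
  expect_false("reverse_complement" %in% match_search(x, 8, without)$transform)
  # retrieved symbol is the complement of the source, i.e. the true residue
  prof <- predict_masked(with_rc, x, masked_positions = 8)
  expect_gte(prof$prob[1, seq_chars(s)[8]], with_rc$retrieval_strength)
})

test_that("mock embeddings encode own and best retrieved symbol", {
  m <- mock_model()
  r <- random_sequence(25, seed = 10)
  emb <- embed_sequence(m, r)
  expect_equal(dim(emb), c(25, 40))
  # no matches in a random sequence: retrieved block is all zero
  expect_true(all(emb[, 21:40] == 0))
  expect_equal(rowSums(emb[, 1:20]), rep(1, 25))
  d <- tandem_repeat(r, 2)
  emb_d <- embed_sequence(m, d)
  # equivalent positions in the two copies embed identically
  expect_identical(emb_d[1:25, ], emb_d[26:50, ])
  expect_equal(rowSums(emb_d[, 21:40]), rep(1, 50))
})
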