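test_that("probe results are reproducible from (config, seed) and well labeled", {
  m <- mock_model()
  a <- probe_doubling(m, n_sequences = 4, length = 20, seed = 11)
  b <- probe_doubling(m, n_sequences = 4, length = 20, seed = 11)
  expect_identical(as.data.frame(a), as.data.frame(b))
  # collapse-mode doubling values are sequence-independent constants, so a
  # value-level seed check needs a probe whose values vary with the input
  mi <- imperfect_repeat_mock()
  c1 <- probe_imperfect_repeat(mi, rates = 0.5, n_sequences = 3,
                               length = 60, seed = 11)
  c2 <- probe_imperfect_repeat(mi, rates = 0.5, n_sequences = 3,
                               length = 60, seed = 12)
  expect_false(identical(c1$value, c2$value))
  expect_probe_columns(a, c("sequence_id", "condition", "value"))
  expect_identical(attr(a, "probe"), "doubling")
})

test_that("doubling collapses under retrieval and not without it", {
  on <- probe_doubling(mock_model(), n_sequences = 10, length = 30, seed = 1)
  med <- tapply(on$value, on$condition, median)
  expect_lte(med[["2x"]], 1.1)
  expect_gte(med[["1x"]], 19)
  off <- probe_doubling(mock_model(retrieval_strength = 0), n_sequences = 6,
                        length = 30, seed = 1)
  w <- tidyr::pivot_wider(tibble::as_tibble(off), id_cols = "sequence_id",
                          names_from = "condition", values_from = "value")
  expect_equal(w$`1x`, w$`2x`, tolerance = 1e-9)
})

test_that("multiplicity sweep covers the grid and shows the memory transition", {
  m <- mock_model(memory_limit = 85)
  res <- probe_multiplicity(m, unit_sizes = c(20, 70, 100),
                            multiplicities = c(1, 2), n_sequences = 2, seed = 1)
  expect_equal(nrow(res), 3 * 2 * 2)
  expect_equal(nrow(dplyr::distinct(tibble::as_tibble(res),
                                    unit_size, multiplicity)), 6)
  med <- tibble::as_tibble(res) |>
    dplyr::filter(multiplicity == 2) |>
    dplyr::group_by(unit_size) |>
    dplyr::summarise(med = median(value))
  # units within the memory window collapse, the 100-residue unit cannot
  expect_lte(med$med[med$unit_size == 20], 1.1)
  expect_lte(med$med[med$unit_size == 70], 1.1)
  expect_gte(med$med[med$unit_size == 100], 19)
  # multiplicity 1 sits at the prior perplexity
  m1 <- tibble::as_tibble(res) |> dplyr::filter(multiplicity == 1)
  expect_equal(median(m1$value), 20, tolerance = 1e-6)
})

test_that("progressive mode declines strictly with multiplicity", {
  m <- mock_model(mode = "progressive", retrieval_strength = 0.5)
  res <- probe_multiplicity(m, unit_sizes = 10, multiplicities = c(1, 2, 4, 8),
                            n_sequences = 3, seed = 1)
  med <- tibble::as_tibble(res) |>
    dplyr::group_by(multiplicity) |>
    dplyr::summarise(med = median(value)) |>
    dplyr::arrange(multiplicity)
  expect_true(all(diff(med$med) < 0))
  # closed form for the retrieved-symbol mass with k = m - 1 supporting copies
  expect_equal(med$med[med$multiplicity == 2],
               1 / (0.5 + 0.5 / 20), tolerance = 1e-9)
})

test_that("only the equivalent-position mask restores uncertainty", {
  m <- mock_model()
  res <- tibble::as_tibble(
    probe_equivalent_mask(m, n_sequences = 8, length = 30, seed = 1)
  )
  med <- res |>
    dplyr::group_by(condition) |>
    dplyr::summarise(entropy = median(entropy), p_true = median(p_true))
  prior_h <- log(20)
  expect_equal(med$entropy[med$condition == "single"], prior_h,
               tolerance = 1e-9)
  expect_equal(med$entropy[med$condition == "doubled_equiv_masked"], prior_h,
               tolerance = 1e-9)
  expect_lt(med$entropy[med$condition == "doubled"], 0.5)
  # closed form for the collapse-mode mixture entropy
  eps <- 1 - m$retrieval_strength
  p <- rep(eps / 20, 20)
  p[1] <- p[1] + (1 - eps)
  expect_equal(med$entropy[med$condition == "doubled"], entropy(p),
               tolerance = 1e-9)
  expect_equal(med$entropy[med$condition == "doubled_nonequiv_masked"],
               med$entropy[med$condition == "doubled"], tolerance = 1e-9)
  expect_error(probe_equivalent_mask(m, length = 30, nonequiv_offset = 0),
               "collides")
})

test_that("flip profile is row-normalized with retrieval-dominated diagonal", {
  m <- mock_model()
  res <- probe_flip_profile(m, n_sequences = 5, length = 20, seed = 1)
  mat <- attr(res, "matrix")
  expect_equal(dim(mat), c(20, 20))
  expect_equal(unname(rowSums(mat)), rep(1, 20), tolerance = 1e-6)
  expect_gte(flip_diagonal_mass(res), m$retrieval_strength)
  # closed form: diagonal = strength + (1 - strength) * prior
  expect_equal(unname(diag(mat)), rep(0.95 + 0.05 / 20, 20), tolerance = 1e-9)
  # retrieval disabled: every row equals the prior
  off <- probe_flip_profile(mock_model(retrieval_strength = 0),
                            n_sequences = 2, length = 20, seed = 1)
  expect_equal(unname(attr(off, "matrix")),
               matrix(1 / 20, 20, 20), tolerance = 1e-9)
  expect_equal(flip_diagonal_mass(off), 1 / 20, tolerance = 1e-9)
})

test_that("contra-lateral preference is symmetric in the interior and positional at the ends", {
  m <- mock_model()
  res <- tibble::as_tibble(
    probe_contralateral(m, n_sequences = 6, length = 20, seed = 1)
  )
  by_pos <- res |>
    dplyr::group_by(position) |>
    dplyr::summarise(pref = mean(preference))
  # interior positions: both candidates score ~0.5 < threshold, prior wins
  expect_true(all(abs(by_pos$pref[by_pos$position %in% 6:15]) < 1e-9))
  # leftmost mask: only the right insert aligns with the visible window
  expect_gte(by_pos$pref[by_pos$position == 1], 0.9)
  # swapping the inserted symbols leaves the positional preference invariant
  # (equivalently, the fixed-symbol readout changes sign)
  orig <- tibble::as_tibble(
    probe_contralateral(m, n_sequences = 3, length = 20, positions = 1,
                        left_symbol = "K", right_symbol = "R", seed = 2)
  )
  swap <- tibble::as_tibble(
    probe_contralateral(m, n_sequences = 3, length = 20, positions = 1,
                        left_symbol = "R", right_symbol = "K", seed = 2)
  )
  expect_equal(orig$preference, swap$preference, tolerance = 1e-9)
  expect_equal(orig$p_right - orig$p_left, -(swap$p_left - swap$p_right),
               tolerance = 1e-9)
  expect_error(probe_contralateral(m, left_symbol = "K", right_symbol = "K"),
               "differ")
})

test_that("imperfect repeats score lower alongside their original", {
  m <- imperfect_repeat_mock()
  res <- tibble::as_tibble(
    probe_imperfect_repeat(m, rates = c(0, 0.5), n_sequences = 8,
                           length = 100, seed = 1)
  )
  w <- tidyr::pivot_wider(res, id_cols = c("rate", "sequence_id"),
                          names_from = "condition", values_from = "value")
  # perfect copies reduce to the doubling experiment at this model's
  # moderate retrieval strength: p(true) = 0.5 + 0.5/20 per position
  r0 <- dplyr::filter(w, rate == 0)
  expect_equal(median(r0$with_original), 1 / 0.525, tolerance = 1e-6)
  # the lenient partial-match threshold admits occasional chance matches, so
  # the isolated copy sits near (not exactly at) the prior perplexity
  expect_gt(median(r0$alone), 15)
  r5 <- dplyr::filter(w, rate == 0.5)
  expect_true(all(r5$with_original < r5$alone))
})

test_that("needle sweep maps the operational memory boundary", {
  m <- mock_model(memory_limit = 300)
  res <- tibble::as_tibble(probe_needle_sweep(
    m, needle_sizes = 10, haystack_sizes = c(0, 200, 320),
    n_sequences = 3, seed = 1, collapse_threshold = 1.5
  ))
  expect_equal(nrow(res), 9)
  med <- res |>
    dplyr::group_by(haystack_size) |>
    dplyr::summarise(med = median(value), rec = all(recognized))
  # needle + haystack offset within memory: collapse; beyond: prior
  expect_lte(med$med[med$haystack_size == 0], 1.1)
  expect_lte(med$med[med$haystack_size == 200], 1.1)
  expect_gte(med$med[med$haystack_size == 320], 19)
  expect_identical(med$rec, c(TRUE, TRUE, FALSE))
})

test_that("skip pairs retrieve the equivalent residue without contiguous matches", {
  m <- mock_model(window_halfwidth = 2, match_threshold = 0.45)
  res <- tibble::as_tibble(probe_skip(m, unit_length = 20, n_sequences = 6,
                                      seed = 1))
  skip <- dplyr::filter(res, condition == "skip")
  ctrl <- dplyr::filter(res, condition == "control")
  expect_gt(mean(skip$p_equivalent), 0.4)
  # correct-residue mass spikes exactly where the halves agree (odd positions)
  odd <- dplyr::filter(skip, position %% 2 == 1)
  even <- dplyr::filter(skip, position %% 2 == 0)
  expect_gt(mean(odd$p_correct), 0.4)
  expect_lt(mean(even$p_correct), 0.1)
  expect_gt(mean(odd$p_correct), 10 * mean(even$p_correct))
  # unrelated halves stay flat near the prior
  expect_lt(mean(ctrl$p_equivalent), 0.15)
  expect_lt(mean(ctrl$p_correct), 0.15)
  # strict matching cannot use alternating agreement: behaves like control
  strict <- tibble::as_tibble(probe_skip(
    mock_model(window_halfwidth = 2, match_threshold = 1),
    unit_length = 20, n_sequences = 4, seed = 1
  ))
  expect_lt(mean(dplyr::filter(strict, condition == "skip")$p_equivalent),
            0.15)
})

test_that("RNA contexts collapse only for transforms the model recognizes", {
  both <- rna_context_mock()
  res <- tibble::as_tibble(probe_rna_context(both, length = 30,
                                             n_sequences = 6, seed = 1))
  med <- res |>
    dplyr::group_by(context) |>
    dplyr::summarise(med = median(value))
  collapse <- med$med[med$context %in% c("repeat", "reverse_complement")]
  stay <- med$med[med$context %in% c("random", "complement", "reversed")]
  expect_true(all(collapse <= 1.1))
  expect_true(all(stay >= 3))
  # identity-only matching: the hairpin arm is no longer recognized
  ident <- rna_context_mock(transforms = "identity")
  res2 <- tibble::as_tibble(probe_rna_context(
    ident, context_types = c("repeat", "reverse_complement"),
    length = 30, n_sequences = 4, seed = 1
  ))
  med2 <- res2 |>
    dplyr::group_by(context) |>
    dplyr::summarise(med = median(value))
  expect_lte(med2$med[med2$context == "repeat"], 1.1)
  expect_gte(med2$med[med2$context == "reverse_complement"], 3)
  expect_error(probe_rna_context(mock_model(), seed = 1), "complemented")
})
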