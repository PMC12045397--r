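test_that("random_sequence honours length, alphabet, weights and seed", {
  s <- random_sequence(30, protein_alphabet(), seed = 7)
  expect_equal(seq_length(s), 30)
  expect_true(all(seq_chars(s) %in% protein_alphabet()$symbols))
  # byte-identical under the same seed, including length-1 edge case
  expect_identical(as.character(random_sequence(30, seed = 7)),
                   as.character(s))
  expect_identical(as.character(random_sequence(1, rna_alphabet(), seed = 0)),
                   as.character(random_sequence(1, rna_alphabet(), seed = 0)))
  expect_error(random_sequence(0, seed = 1), "length")
  expect_error(random_sequence(5, weights = rep(0.5, 2), seed = 1), "entry")
  expect_error(random_sequence(5, weights = rep(1, 20), seed = 1), "sum to 1")
  # a generator call must not disturb the session RNG stream
  set.seed(99); before <- .Random.seed
  random_sequence(10, seed = 5)
  expect_identical(.Random.seed, before)
})

test_that("uniform draws have symbol frequencies within the binomial bound", {
  # n = 1e4, p = 1/20: sd = sqrt(n p (1-p)) = 21.79; 5 sigma = 108.97
  s <- random_sequence(1e4, protein_alphabet(), seed = 3)
  counts <- table(factor(seq_chars(s), levels = protein_alphabet()$symbols))
  expect_true(all(abs(counts - 500) <= 5 * sqrt(1e4 * 0.05 * 0.95)))
})

test_that("tandem_repeat concatenates annotated copies", {
  u <- random_sequence(20, seed = 1)
  d <- tandem_repeat(u, 2)
  expect_equal(seq_length(d), 40)
  expect_identical(as.character(d), strrep(as.character(u), 2))
  expect_identical(as.character(tandem_repeat(u, 1)), as.character(u))
  expect_error(tandem_repeat(u, 0), "multiplicity")
  # every unit span recovers the unit
  u5 <- random_sequence(5, seed = 2)
  big <- tandem_repeat(u5, 32)
  expect_equal(seq_length(big), 160)
  for (k in seq_len(32)) {
    sp <- seq_span(big, paste0("unit_", k))
    expect_identical(as.character(seq_subseq(big, sp[1], sp[2])),
                     as.character(u5))
  }
})

test_that("mutate_copy respects rate, ops and determinism", {
  s <- random_sequence(100, seed = 1)
  expect_identical(as.character(mutate_copy(s, rate = 0, seed = 2)),
                   as.character(s))
  all_sub <- mutate_copy(s, rate = 1, ops = "substitution", seed = 3)
  expect_equal(hamming(s, all_sub), 100)
  m1 <- mutate_copy(s, rate = 0.5, seed = 4)
  expect_identical(as.character(m1),
                   as.character(mutate_copy(s, rate = 0.5, seed = 4)))
  # substitution-only preserves length; indels may change it
  expect_equal(seq_length(mutate_copy(s, 0.5, "substitution", seed = 5)), 100)
  expect_error(mutate_copy(s, 0.5, ops = character(0)), "arg")
})

test_that("substitution-only hamming distance matches the binomial expectation", {
  # Monte-Carlo oracle: mean over 1000 seeds of Bin(100, 0.5) draws;
  # sd of the mean = sqrt(100 * .25) / sqrt(1000) = 0.158, 3 sigma = 0.474
  s <- random_sequence(100, seed = 10)
  d <- vapply(seq_len(1000), function(seed) {
    hamming(s, mutate_copy(s, rate = 0.5, ops = "substitution", seed = seed))
  }, numeric(1))
  expect_lt(abs(mean(d) - 50), 3 * sqrt(100 * 0.25 / 1000))
})

test_that("needle_haystack lays out identical flanking needles", {
  s <- needle_haystack(10, 300, protein_alphabet(), seed = 4)
  expect_equal(seq_length(s), 320)
  expect_identical(substr(as.character(s), 1, 10),
                   substr(as.character(s), 311, 320))
  expect_equal(seq_span(s, "needle_1"), c(1, 10))
  expect_equal(seq_span(s, "haystack"), c(11, 310))
  expect_equal(seq_span(s, "needle_2"), c(311, 320))
  # degenerate haystack is a doubled needle
  d <- needle_haystack(5, 0, seed = 5)
  expect_equal(seq_length(d), 10)
  expect_identical(substr(as.character(d), 1, 5),
                   substr(as.character(d), 6, 10))
  expect_error(needle_haystack(0, 10, seed = 1), "needle_length")
  expect_error(needle_haystack(5, -1, seed = 1), "haystack_length")
})

test_that("one_skip_pair halves agree exactly at alternating positions", {
  for (u in c(2, 6, 7, 30)) {
    s <- one_skip_pair(u, protein_alphabet(), seed = u)
    ch <- seq_chars(s)
    s1 <- ch[seq_len(u)]
    s2 <- ch[u + seq_len(u)]
    matches <- s1 == s2
    expect_identical(matches, seq_len(u) %% 2 == 1)
    expect_equal(sum(matches), ceiling(u / 2))
    # exhaustive window scan: no aligned window of length >= 2 matches exactly
    for (a in seq_len(u - 1)) {
      for (l in 2:min(4, u - a + 1)) {
        expect_false(all(s1[a:(a + l - 1)] == s2[a:(a + l - 1)]))
      }
    }
  }
  expect_error(one_skip_pair(1, seed = 1), "unit_length")
})

test_that("complement, reverse and reverse complement follow Watson-Crick", {
  expect_identical(
    as.character(seq_reverse_complement(bio_seq("CGGAU", rna_alphabet()))),
    "AUCCG"
  )
  expect_identical(
    as.character(seq_complement(bio_seq("UAGGC", rna_alphabet()))),
    "AUCCG"
  )
  expect_identical(
    as.character(seq_reverse(bio_seq("GCCUA", rna_alphabet()))),
    "AUCCG"
  )
  # involutions on arbitrary RNA
  for (seed in 1:5) {
    x <- random_sequence(25, rna_alphabet(), seed = seed)
    expect_identical(as.character(seq_reverse(seq_reverse(x))),
                     as.character(x))
    expect_identical(as.character(seq_complement(seq_complement(x))),
                     as.character(x))
    expect_identical(
      as.character(seq_reverse_complement(seq_reverse_complement(x))),
      as.character(x)
    )
  }
  expect_error(seq_complement(random_sequence(5, seed = 1)), "complement map")
})

test_that("contralateral_construct inserts the candidate pair at the equivalent locus", {
  unit <- random_sequence(23, seed = 6)
  s <- contralateral_construct(unit, 13, "K", "R")
  expect_equal(seq_length(s), 47)
  ch <- seq_chars(s)
  expect_identical(ch[23 + 13], "K")
  expect_identical(ch[23 + 14], "R")
  expect_equal(seq_span(s, "left_insert"), c(36, 36))
  expect_equal(seq_span(s, "right_insert"), c(37, 37))
  # removing the insert and restoring the original symbol recovers the double
  restored <- c(ch[1:(23 + 12)], seq_chars(unit)[13], ch[(23 + 15):47])
  expect_identical(paste(restored, collapse = ""),
                   strrep(as.character(unit), 2))
  # second copy differs from the first only at the insertion locus
  expect_identical(ch[24:35], seq_chars(unit)[1:12])
  expect_identical(ch[38:47], seq_chars(unit)[14:23])
  expect_error(contralateral_construct(unit, 0, "K", "R"), "range")
  expect_error(contralateral_construct(unit, 5, "K", "B"), "alphabet")
})
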