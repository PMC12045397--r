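# Independent reference implementations used as oracles. These are written
# directly against the documented matching definition (plain double loops over
# characters), never against the package's scanning code paths.

oracle_match_search <- function(seq, i, params, masked = integer()) {
  chars <- strsplit(as.character(seq), "")[[1]]
  L <- length(chars)
  w <- params$window_halfwidth
  mc <- params$min_comparisons
  cmap <- params$alphabet$complement_map
  rows <- list()
  for (transform in params$transforms) {
    for (j in seq_len(L)) {
      if (j == i || abs(j - i) > params$memory_limit || j %in% masked) next
      npair <- 0L
      nmatch <- 0L
      for (d in setdiff(seq.int(-w, w), 0L)) {
        p <- i + d
        q <- if (transform == "identity") j + d else j - d
        if (p < 1 || p > L || q < 1 || q > L) next
        if (p == i || q == i) next
        if (p %in% masked || q %in% masked) next
        b <- if (transform == "identity") chars[q] else unname(cmap[chars[q]])
        npair <- npair + 1L
        if (chars[p] == b) nmatch <- nmatch + 1L
      }
      if (npair >= mc && nmatch / npair >= params$match_threshold) {
        rows[[length(rows) + 1L]] <- data.frame(
          position = j, transform = transform, score = nmatch / npair
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(position = integer(), transform = character(),
                      score = numeric()))
  }
  out <- do.call(rbind, rows)
  trank <- match(out$transform, c("identity", "reverse_complement"))
  out <- out[order(-out$score, abs(out$position - i), out$position, trank), ]
  rownames(out) <- NULL
  out
}

# residues of a bio_seq as a character vector
seq_chars <- function(seq) strsplit(as.character(seq), "")[[1]]

# hamming distance between equal-length residue strings
hamming <- function(a, b) {
  ca <- strsplit(as.character(a), "")[[1]]
  cb <- strsplit(as.character(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  sum(ca != cb)
}

expect_probe_columns <- function(result, cols) {
  expect_s3_class(result, "probe_result")
  expect_true(all(c(cols, "model", "seed") %in% names(result)))
}
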