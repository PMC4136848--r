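# shared fixture builders and independent oracles

AA20_T <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

random_protein <- function(len, cys_rate = 0.15) {
  ch <- sample(setdiff(AA20_T, "C"), len, replace = TRUE)
  ch[runif(len) < cys_rate] <- "C"
  paste(ch, collapse = "")
}

# independent exhaustive oracle: test every tuple of n consecutive
# cysteines against the gap and span constraints, one tuple at a time
oracle_cys_tuples <- function(seq, n_cys = 6L, min_first_gap = 6L,
                              min_inner_gap = 1L, max_inner_gap = Inf,
                              window_max = 120, window_min = 0) {
  pos <- which(strsplit(seq, "")[[1]] == "C") - 1L
  anchors <- integer()
  if (length(pos) >= n_cys) {
    for (i in seq_len(length(pos) - n_cys + 1L)) {
      tuple <- pos[i:(i + n_cys - 1L)]
      gaps <- diff(tuple) - 1L
      ok <- gaps[1] >= min_first_gap
      for (g in gaps[-1]) ok <- ok && g >= min_inner_gap && g <= max_inner_gap
      span <- tuple[n_cys] - tuple[1] + 1L
      ok <- ok && span >= window_min && span <= window_max
      if (ok) anchors <- c(anchors, tuple[1])
    }
  }
  anchors
}

# random unrooted tree with positive branch lengths and its additive
# (path-length) distance matrix; oracle for NJ correctness
random_additive_case <- function(n) {
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- runif(length(tr$edge.length), 0.1, 1)
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

expect_valid_matches <- function(matches, seq, params) {
  ch <- strsplit(seq, "")[[1]]
  for (i in seq_len(nrow(matches))) {
    cp <- matches$cys_positions[[i]]
    expect_true(all(ch[cp + 1L] == "C"))
    # no cysteine strictly between consecutive motif cysteines
    for (k in seq_len(length(cp) - 1L)) {
      if (cp[k + 1L] - cp[k] > 1L) {
        expect_false(any(ch[(cp[k] + 2L):cp[k + 1L]] == "C"))
      }
    }
    gaps <- matches$gaps[[i]]
    expect_gte(gaps[1], params$min_first_gap)
    expect_true(all(gaps[-1] >= params$min_inner_gap))
    expect_true(all(gaps[-1] <= params$max_inner_gap))
    expect_gte(matches$span[i], params$window_min)
    expect_lte(matches$span[i], params$window_max)
  }
}
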