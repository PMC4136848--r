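# align: simple progressive multiple aligner.
#
# Pairwise guide distances come from global pairwise alignment identity
# (Biostrings); profiles are merged along a neighbor-joining guide tree
# with an affine-gap (Gotoh) profile-profile alignment whose column score
# is the frequency-weighted substitution score f1' B f2. This is a plain
# progressive aligner: no iterative refinement, no ClustalX emulation.
# Externally computed alignments can always be supplied via read_msa().

get_submat <- function(name = "BLOSUM62") {
  if (is.matrix(name)) return(name)
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  as.matrix(get(name, envir = e))
}

# column frequency matrix (21 x width); gap columns contribute nothing,
# so sparsely occupied columns are down-weighted automatically
profile_freq <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  w <- ncol(m)
  f <- matrix(0, nrow = length(AA21), ncol = w, dimnames = list(AA21, NULL))
  for (a in AA21) f[a, ] <- colSums(m == a)
  f / nrow(m)
}

merge_profiles <- function(rows1, rows2, B, gap_open, gap_extend) {
  f1 <- profile_freq(rows1)
  f2 <- profile_freq(rows2)
  B21 <- B[AA21, AA21]
  S <- t(f1) %*% B21 %*% f2
  al <- .gotoh_align(S, gap_open, gap_extend)
  expand <- function(rows, path) {
    m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
    out <- matrix("-", nrow = nrow(m), ncol = length(path))
    out[, path > 0L] <- m[, path[path > 0L], drop = FALSE]
    apply(out, 1L, paste, collapse = "")
  }
  c(expand(rows1, al$path1), expand(rows2, al$path2))
}

#' Progressive multiple sequence alignment
#'
#' Aligns protein records with a simple progressive strategy: pairwise
#' global alignments (affine gaps, `substitution_matrix`) give percent
#' identity, the identity distances give a neighbor-joining guide tree,
#' and profiles are merged in guide-tree order with an affine-gap
#' profile-profile alignment. Sequences longer than `length_filter`
#' times the median length are excluded with a warning (they cannot be
#' aligned meaningfully).
#'
#' @param records A [protein_records()] data frame (>= 2 rows).
#' @param substitution_matrix Matrix name in Biostrings (default
#'   `"BLOSUM62"`) or a numeric substitution matrix.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param length_filter Multiple of the median length above which a
#'   sequence is excluded (`NULL` disables the filter).
#' @return Named character vector of equal-length aligned sequences, in
#'   input order of the retained records.
#' @export
align_msa <- function(records, substitution_matrix = "BLOSUM62",
                      gap_open = 10, gap_extend = 0.2,
                      length_filter = 5) {
  if (nrow(records) < 2L) stop_format("alignment needs >= 2 sequences")
  if (!is.null(length_filter)) {
    lens <- nchar(records$sequence)
    med <- stats::median(lens)
    drop <- lens > length_filter * med
    if (any(drop)) {
      warning(sprintf("excluded %d sequence(s) longer than %gx the median length: %s",
                      sum(drop), length_filter,
                      paste(records$id[drop], collapse = ", ")), call. = FALSE)
      records <- records[!drop, , drop = FALSE]
    }
    if (nrow(records) < 2L) stop_format("fewer than 2 sequences left after length filter")
  }
  B <- get_submat(substitution_matrix)
  ids <- records$id
  n <- nrow(records)

  aa <- Biostrings::AAStringSet(stats::setNames(records$sequence, ids))
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    pa <- Biostrings::pairwiseAlignment(
      rep(aa[i], n - i), aa[(i + 1L):n],
      substitutionMatrix = B, gapOpening = gap_open,
      gapExtension = gap_extend, type = "global")
    d <- 1 - Biostrings::pid(pa, type = "PID1") / 100
    D[i, (i + 1L):n] <- d
    D[(i + 1L):n, i] <- d
  }

  # merge order from the guide tree (postorder); n = 2 is a single merge
  profiles <- lapply(seq_len(n), function(i) stats::setNames(records$sequence[i], ids[i]))
  names(profiles) <- ids
  if (n == 2L) {
    merged <- merge_profiles(profiles[[1L]], profiles[[2L]], B, gap_open, gap_extend)
    names(merged) <- c(ids[1L], ids[2L])
    return(merged[ids])
  }
  guide <- nj_tree(D)
  merged <- merge_along_tree(guide, profiles, B, gap_open, gap_extend)
  merged[ids[ids %in% names(merged)]]
}

# postorder merge of leaf profiles along an (unrooted, trifurcating) tree
merge_along_tree <- function(tree, profiles, B, gap_open, gap_extend) {
  nt <- length(tree$tip.label)
  nodes <- vector("list", nt + tree$Nnode)
  for (i in seq_len(nt)) nodes[[i]] <- profiles[[tree$tip.label[i]]]
  # process internal nodes children-first
  ord <- rev(unique(tree$edge[order(tree$edge[, 2L]), 1L]))
  ord <- sort(unique(tree$edge[, 1L]), decreasing = TRUE)
  for (nd in ord) {
    kids <- tree$edge[tree$edge[, 1L] == nd, 2L]
    prof <- nodes[[kids[1L]]]
    for (k in kids[-1L]) {
      m <- merge_profiles(prof, nodes[[k]], B, gap_open, gap_extend)
      names(m) <- c(names(prof), names(nodes[[k]]))
      prof <- m
    }
    nodes[[nd]] <- prof
  }
  nodes[[nt + 1L]]
}
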