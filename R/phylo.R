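# phylo_classify: distances from an MSA, neighbor-joining with a
# deterministic tie-break, bootstrap supports by column resampling, and
# clade-based subtype assignment against labelled references.

msa_char_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

#' Pairwise distance matrix from a multiple alignment
#'
#' `p` is the proportion of mismatching residues over columns where both
#' sequences are ungapped; `poisson` is `-ln(1 - p)`, capped at
#' `max_distance` as `p` approaches 1.
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param model `"p"` or `"poisson"`.
#' @param max_distance Cap for the Poisson transform.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
distance_matrix <- function(msa, model = c("p", "poisson"), max_distance = 10) {
  model <- match.arg(model)
  if (length(unique(nchar(msa))) != 1L) stop_format("aligned rows have unequal lengths")
  m <- msa_char_matrix(msa)
  n <- nrow(m)
  ids <- rownames(m)
  D <- matrix(0, n, n, dimnames = list(ids, ids))
  nongap <- m != "-"
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      shared <- nongap[i, ] & nongap[j, ]
      ns <- sum(shared)
      if (ns == 0L) {
        stop_format("no shared non-gap columns between %s and %s", ids[i], ids[j])
      }
      p <- sum(m[i, shared] != m[j, shared]) / ns
      d <- if (model == "p") p else min(max_distance, -log(max(1 - p, exp(-max_distance))))
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# escape nothing: taxon labels must be Newick-safe
check_taxa_labels <- function(labs) {
  bad <- grepl("[(),:;[:space:]]", labs)
  if (any(bad)) {
    stop_format("taxon label(s) contain Newick-reserved characters: %s",
                paste(labs[bad], collapse = ", "))
  }
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration with the standard Q criterion. Ties in Q are
#' broken by the lexicographically smallest pair of cluster labels
#' (a cluster is labelled by its smallest member taxon), making the
#' topology independent of input order. Negative branch lengths are
#' clamped to zero. The result is unrooted (trifurcating root node).
#'
#' @param D Symmetric distance matrix with taxon dimnames (n >= 3), or
#'   a `dist` object.
#' @return An [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  if (inherits(D, "dist")) D <- as.matrix(D)
  stopifnot(is.matrix(D), !is.null(rownames(D)))
  n <- nrow(D)
  if (n < 3L) stop_format("neighbor joining needs >= 3 taxa (got %d)", n)
  if (any(abs(D - t(D)) > 1e-8)) stop_format("distance matrix is not symmetric")
  check_taxa_labels(rownames(D))

  nwk <- rownames(D)        # newick fragment per active cluster
  rep_lab <- rownames(D)    # smallest member taxon per active cluster
  fmt <- function(x) sprintf("%.10g", max(0, x))

  while (nrow(D) > 3L) {
    nn <- nrow(D)
    r <- rowSums(D)
    Q <- (nn - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys1 <- pmin(rep_lab[cand[, 1L]], rep_lab[cand[, 2L]])
    keys2 <- pmax(rep_lab[cand[, 1L]], rep_lab[cand[, 2L]])
    pick <- order(keys1, keys2)[1L]
    i <- cand[pick, 1L]; j <- cand[pick, 2L]

    li <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (nn - 2))
    lj <- D[i, j] - li
    new_nwk <- sprintf("(%s:%s,%s:%s)", nwk[i], fmt(li), nwk[j], fmt(lj))
    new_rep <- min(rep_lab[i], rep_lab[j])
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    keep <- setdiff(seq_len(nn), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    labs <- c(rownames(D)[keep], new_rep)
    dimnames(D2) <- list(labs, labs)
    D <- D2
    nwk <- c(nwk[keep], new_nwk)
    rep_lab <- c(rep_lab[keep], new_rep)
  }

  la <- 0.5 * (D[1, 2] + D[1, 3] - D[2, 3])
  lb <- 0.5 * (D[1, 2] + D[2, 3] - D[1, 3])
  lc <- 0.5 * (D[1, 3] + D[2, 3] - D[1, 2])
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nwk[1], fmt(la), nwk[2], fmt(lb),
                 nwk[3], fmt(lc))
  ape::read.tree(text = txt)
}

# canonical bipartition keys for internal edges of an (arbitrarily rooted)
# phylo; key = sorted tip labels of the side NOT containing the globally
# smallest label; trivial splits excluded
tree_bipartitions <- function(tree) {
  nt <- length(tree$tip.label)
  all_tips <- sort(tree$tip.label)
  anchor <- all_tips[1L]
  desc <- phangorn::Descendants(tree, (nt + 1L):(nt + tree$Nnode), type = "tips")
  keys <- character(tree$Nnode)
  for (k in seq_len(tree$Nnode)) {
    side <- sort(tree$tip.label[desc[[k]]])
    if (anchor %in% side) side <- setdiff(all_tips, side)
    keys[k] <- if (length(side) >= 2L && length(side) <= nt - 2L) {
      paste(side, collapse = "|")
    } else {
      NA_character_   # trivial or root split
    }
  }
  names(keys) <- as.character((nt + 1L):(nt + tree$Nnode))
  keys
}

#' Bootstrap supports for a neighbor-joining tree
#'
#' Builds the tree from the full alignment, then resamples alignment
#' columns with replacement `n_replicates` times, rebuilds the NJ tree
#' on each replicate, and reports for every internal edge of the
#' original tree the percentage of replicates containing the same
#' bipartition. Supports are stored in `tree$node.label` (empty for the
#' root) and reproducible under a fixed seed.
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param n_replicates Number of bootstrap replicates (>= 1).
#' @param seed Integer seed (mandatory; resampling is stochastic).
#' @param model Distance model, see [distance_matrix()].
#' @return An [ape::phylo] tree with bootstrap percentages as internal
#'   node labels.
#' @export
bootstrap_supports <- function(msa, n_replicates = 1000L, seed, model = "p") {
  if (n_replicates < 1L) stop_format("n_replicates must be >= 1")
  if (missing(seed) || is.null(seed)) stop_format("an explicit seed is required")
  tree <- nj_tree(distance_matrix(msa, model = model))
  keys <- tree_bipartitions(tree)
  valid <- !is.na(keys)
  counts <- stats::setNames(numeric(sum(valid)), keys[valid])
  m <- msa_char_matrix(msa)
  L <- ncol(m)
  idx <- with_seed(seed, matrix(sample.int(L, n_replicates * L, replace = TRUE),
                                nrow = n_replicates))
  n_used <- 0L
  for (b in seq_len(n_replicates)) {
    mb <- m[, idx[b, ], drop = FALSE]
    msab <- stats::setNames(apply(mb, 1L, paste, collapse = ""), rownames(m))
    tb <- tryCatch(nj_tree(distance_matrix(msab, model = model)),
                   error = function(e) NULL)
    if (is.null(tb)) next   # e.g. a pair lost all shared columns
    n_used <- n_used + 1L
    kb <- tree_bipartitions(tb)
    hit <- names(counts)[names(counts) %in% kb]
    counts[hit] <- counts[hit] + 1
  }
  if (n_used == 0L) stop_format("all bootstrap replicates failed")
  if (n_used < n_replicates) {
    warning(sprintf("%d of %d bootstrap replicates failed and were skipped",
                    n_replicates - n_used, n_replicates), call. = FALSE)
  }
  sup <- round(100 * counts / n_used, 1)
  labels <- rep("", length(keys))
  labels[valid] <- sprintf("%g", sup[keys[valid]])
  tree$node.label <- labels
  tree
}

node_supports <- function(tree) {
  nt <- length(tree$tip.label)
  lab <- tree$node.label
  if (is.null(lab)) lab <- rep("", tree$Nnode)
  sup <- suppressWarnings(as.numeric(lab))
  stats::setNames(sup, as.character((nt + 1L):(nt + tree$Nnode)))
}

#' Assign subtypes to candidate leaves by clade membership
#'
#' The tree is midpoint rooted. For each candidate (a leaf not in the
#' reference set), the smallest ancestral clade containing at least one
#' reference is located; ancestors are then ascended while the
#' references they contain remain a single subtype, and the subtype is
#' assigned at the first edge whose bootstrap support reaches
#' `min_support`. If no such edge exists, the starred (sister-group)
#' rule applies: when the candidate's maximal reference-free clade is
#' sister to a clade whose references are a single subtype and whose
#' edge support reaches `min_support`, the starred subtype (`"H*"`,
#' `"L*"`, `"J*"`) is assigned. Otherwise the candidate is
#' `unclassified`.
#'
#' @param tree An [ape::phylo] with bootstrap supports as node labels
#'   (see [bootstrap_supports()]).
#' @param refs A [reference_set()] or a named character vector of
#'   subtype labels (names = reference leaf ids).
#' @param min_support Minimum bootstrap percentage of the assigning
#'   edge.
#' @return Data frame: `candidate_id`, `subtype`, `support`.
#' @export
assign_subtypes <- function(tree, refs, min_support = 40) {
  labels <- if (inherits(refs, "reference_set")) refs$labels else refs
  missing <- setdiff(names(labels), tree$tip.label)
  if (length(missing)) {
    stop_format("reference(s) absent from tree: %s", paste(missing, collapse = ", "))
  }
  rtree <- phangorn::midpoint(tree, node.labels = "support")
  nt <- length(rtree$tip.label)
  desc <- phangorn::Descendants(rtree, seq_len(nt + rtree$Nnode), type = "tips")
  sup <- node_supports(rtree)
  root <- nt + 1L
  is_ref <- rtree$tip.label %in% names(labels)
  candidates <- rtree$tip.label[!is_ref]

  refs_in <- function(node) {
    tips <- rtree$tip.label[desc[[node]]]
    labels[intersect(tips, names(labels))]
  }
  support_of <- function(node) {
    if (node == root) return(NA_real_)
    unname(sup[as.character(node)])
  }

  assign_one <- function(cand) {
    tip <- match(cand, rtree$tip.label)
    anc <- phangorn::Ancestors(rtree, tip, type = "all")  # parent ... root
    prev <- tip
    # smallest reference-containing ancestor
    k <- which(vapply(anc, function(a) length(refs_in(a)) > 0L, TRUE))[1L]
    if (is.na(k)) return(list(subtype = "unclassified", support = NA_real_))
    A <- anc[k]
    free_clade <- prev <- if (k == 1L) tip else anc[k - 1L]
    # ascend while references stay a single subtype, take first supported edge
    for (a in anc[k:length(anc)]) {
      rl <- refs_in(a)
      if (length(unique(rl)) > 1L) break
      s <- support_of(a)
      if (!is.na(s) && s >= min_support) {
        return(list(subtype = unique(rl), support = s))
      }
    }
    # starred rule at the smallest reference-containing ancestor
    kids <- rtree$edge[rtree$edge[, 1L] == A, 2L]
    sibs <- setdiff(kids, free_clade)
    sib_has_ref <- vapply(sibs, function(s) length(refs_in(s)) > 0L, TRUE)
    if (sum(sib_has_ref) == 1L) {
      S <- sibs[sib_has_ref]
      rl <- refs_in(S)
      s <- if (S <= nt) NA_real_ else support_of(S)
      if (length(unique(rl)) == 1L && !is.na(s) && s >= min_support) {
        return(list(subtype = paste0(unique(rl), "*"), support = s))
      }
    }
    list(subtype = "unclassified", support = NA_real_)
  }

  rows <- lapply(candidates, function(cand) {
    a <- assign_one(cand)
    data.frame(candidate_id = cand, subtype = a$subtype, support = a$support,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(candidate_id = character(), subtype = character(),
               support = numeric(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
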