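# genome_context: tandem arrays of candidate genes on scaffolds.
#
# Adjacency is measured in gene rank (position in the scaffold's gene
# order), not base pairs, so assembly gaps between genes do not split
# arrays. An array is a maximal run of >= 2 candidates in which
# consecutive candidates are separated by at most max_intervening
# non-candidate genes.

#' Detect tandem arrays of candidate genes
#'
#' @param loci A [gene_loci()] data frame covering candidates and other
#'   genes.
#' @param candidate_ids Character vector of candidate gene ids; every id
#'   must have a locus.
#' @param max_intervening Maximum number of non-candidate genes allowed
#'   between consecutive array members.
#' @return A `tandem_arrays` data frame: `array_id`, `scaffold_id`,
#'   `n_members`, `n_intervening`, `orientation_consistent`, and
#'   list-columns `member_ids` (ascending by start) and `strands`.
#' @export
detect_tandem_arrays <- function(loci, candidate_ids, max_intervening = 1L) {
  missing <- setdiff(candidate_ids, loci$gene_id)
  if (length(missing)) {
    stop_format("candidate id(s) with no locus: %s", paste(missing, collapse = ", "))
  }
  rows <- list()
  for (scf in unique(loci$scaffold_id)) {
    sl <- loci[loci$scaffold_id == scf, , drop = FALSE]
    sl <- sl[order(sl$start), , drop = FALSE]
    is_cand <- sl$gene_id %in% candidate_ids
    pos <- which(is_cand)
    if (length(pos) == 0L) next
    run_start <- 1L
    runs <- list()
    if (length(pos) > 1L) {
      between <- diff(pos) - 1L   # non-candidates between consecutive candidates
      brk <- which(between > max_intervening)
      bounds <- c(0L, brk, length(pos))
      runs <- lapply(seq_len(length(bounds) - 1L), function(i)
        pos[(bounds[i] + 1L):bounds[i + 1L]])
    } else {
      runs <- list(pos)
    }
    for (run in runs) {
      if (length(run) < 2L) next
      members <- sl$gene_id[run]
      span_rows <- run[1L]:run[length(run)]
      rows[[length(rows) + 1L]] <- data.frame(
        scaffold_id = scf,
        n_members = length(members),
        n_intervening = sum(!is_cand[span_rows]),
        orientation_consistent = length(unique(sl$strand[run])) == 1L,
        member_ids = I(list(members)),
        strands = I(list(sl$strand[run])),
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(scaffold_id = character(), n_members = integer(),
               n_intervening = integer(), orientation_consistent = logical(),
               member_ids = I(list()), strands = I(list()),
               stringsAsFactors = FALSE)
  out <- cbind(array_id = if (nrow(out)) sprintf("%s-%d", out$scaffold_id,
                 stats::ave(seq_len(nrow(out)), out$scaffold_id, FUN = seq_along))
               else character(), out, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("tandem_arrays", "data.frame")
  out
}

#' Summary statistics over tandem arrays
#'
#' @param arrays Output of [detect_tandem_arrays()].
#' @param all_candidates Character vector of all candidate gene ids
#'   (members and singletons).
#' @param assignments Optional subtype assignments
#'   (see [assign_subtypes()]); enables per-array homogeneity.
#' @param loci Optional [gene_loci()]; enables the count of scaffolds
#'   carrying candidates.
#' @return List: `n_candidates`, `n_in_arrays`, `tandem_fraction`,
#'   `n_arrays`, `n_scaffolds_with_candidates`,
#'   `orientation_consistent_fraction`, and (with assignments)
#'   `array_homogeneity` (data frame: `array_id`, `subtypes`, `pure`).
#' @export
tandem_summary <- function(arrays, all_candidates, assignments = NULL,
                           loci = NULL) {
  members <- unlist(arrays$member_ids)
  n_in <- sum(all_candidates %in% members)
  res <- list(
    n_candidates = length(all_candidates),
    n_in_arrays = n_in,
    tandem_fraction = if (length(all_candidates)) n_in / length(all_candidates) else 0,
    n_arrays = nrow(arrays),
    n_scaffolds_with_candidates = if (is.null(loci)) NA_integer_ else
      length(unique(loci$scaffold_id[loci$gene_id %in% all_candidates])),
    orientation_consistent_fraction =
      if (nrow(arrays)) mean(arrays$orientation_consistent) else NA_real_)
  if (!is.null(assignments)) {
    sub <- stats::setNames(assignments$subtype, assignments$candidate_id)
    res$array_homogeneity <- data.frame(
      array_id = arrays$array_id,
      subtypes = vapply(arrays$member_ids, function(ids) {
        s <- sub[ids]; s[is.na(s)] <- "unclassified"
        paste(sort(unique(s)), collapse = ",")
      }, ""),
      pure = vapply(arrays$member_ids, function(ids) {
        s <- sub[ids]; s[is.na(s)] <- "unclassified"
        length(unique(s)) == 1L
      }, TRUE),
      stringsAsFactors = FALSE)
  }
  res
}
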