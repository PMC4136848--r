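# motif_scan: periodic cysteine-block pattern search.
#
# The grammar is C X(>=f) C X(g..G) C ... C with n_cys cysteines, where X is
# any residue except cysteine. Because X excludes C, every match is a run of
# n_cys *consecutive* cysteines of the sequence, so scanning reduces to
# checking the gap and span constraints on each consecutive-cysteine tuple.

#' Cysteine-block pattern parameters
#'
#' Defaults encode the published final criterion: 6 cysteines, first
#' inter-cysteine gap "more than 5" residues (>= 6), remaining gaps at
#' least 1 residue, whole motif spanning at most 120 residues. The
#' exploratory grammar (`CXlongCXshortC`) is expressed by `n_cys = 4`,
#' `max_inner_gap = 5` and `window_min = 30`.
#'
#' @param n_cys Number of cysteines in the motif (4 or 6).
#' @param min_first_gap Minimum residues strictly between the first
#'   cysteine pair.
#' @param min_inner_gap,max_inner_gap Bounds on residues between the
#'   remaining cysteine pairs (`max_inner_gap = Inf` means unbounded).
#' @param window_max,window_min Inclusive bounds on the motif span
#'   (last cysteine - first cysteine + 1).
#' @return A `cys_pattern_params` list.
#' @export
cys_pattern_params <- function(n_cys = 6L, min_first_gap = 6L,
                               min_inner_gap = 1L, max_inner_gap = Inf,
                               window_max = 120L, window_min = 0L) {
  n_cys <- as.integer(n_cys)
  if (!n_cys %in% c(4L, 6L)) stop_format("n_cys must be 4 or 6 (got %d)", n_cys)
  if (min_first_gap < 1L) stop_format("min_first_gap must be >= 1")
  if (min_inner_gap < 0L || max_inner_gap < min_inner_gap) {
    stop_format("need 0 <= min_inner_gap <= max_inner_gap")
  }
  if (window_min > window_max) stop_format("window_min must be <= window_max")
  structure(list(n_cys = n_cys,
                 min_first_gap = as.integer(min_first_gap),
                 min_inner_gap = as.integer(min_inner_gap),
                 max_inner_gap = max_inner_gap,
                 window_max = as.numeric(window_max),
                 window_min = as.numeric(window_min)),
            class = "cys_pattern_params")
}

empty_matches <- function(protein_id = character()) {
  data.frame(protein_id = protein_id[0], anchor = integer(), span = integer(),
             cys_positions = I(list()), gaps = I(list()),
             stringsAsFactors = FALSE)
}

#' Find cysteine-block motif matches in one protein
#'
#' Reports one match per anchor cysteine beginning a run of `n_cys`
#' consecutive cysteines that satisfies the gap and span constraints.
#' Matches are reported in ascending anchor order; overlaps are allowed.
#' Positions are 0-based.
#'
#' @param record A single protein record (one row of
#'   [protein_records()], a `list(id=, sequence=)`, or a bare string).
#' @param params A [cys_pattern_params()] object.
#' @return Data frame with columns `protein_id`, `anchor` (0-based),
#'   `span`, and list-columns `cys_positions`, `gaps`.
#' @export
find_cys_blocks <- function(record, params = cys_pattern_params()) {
  rec <- as_record(record)
  pos <- gregexpr("C", rec$sequence, fixed = TRUE)[[1L]]
  if (pos[1L] == -1L) return(empty_matches())
  pos <- as.integer(pos) - 1L               # 0-based
  n <- params$n_cys
  if (length(pos) < n) return(empty_matches())
  m <- length(pos) - n + 1L
  P <- vapply(seq_len(n), function(k) pos[seq_len(m) + k - 1L], integer(m))
  if (m == 1L) P <- matrix(P, nrow = 1L)
  gaps <- P[, -1L, drop = FALSE] - P[, -n, drop = FALSE] - 1L
  ok <- gaps[, 1L] >= params$min_first_gap
  if (n > 2L) {
    inner <- gaps[, -1L, drop = FALSE]
    ok <- ok & apply(inner >= params$min_inner_gap &
                       inner <= params$max_inner_gap, 1L, all)
  }
  span <- P[, n] - P[, 1L] + 1L
  ok <- ok & span >= params$window_min & span <= params$window_max
  if (!any(ok)) return(empty_matches())
  idx <- which(ok)
  data.frame(protein_id = rep(rec$id, length(idx)),
             anchor = P[idx, 1L], span = span[idx],
             cys_positions = I(lapply(idx, function(i) P[i, ])),
             gaps = I(lapply(idx, function(i) gaps[i, ])),
             stringsAsFactors = FALSE)
}

#' Scan a whole proteome for the cysteine-block motif
#'
#' A protein is a hit if it carries at least one motif match.
#'
#' @param records A [protein_records()] data frame with unique ids.
#' @param params A [cys_pattern_params()] object.
#' @return A `screen_result` list: `matches` (named list of per-protein
#'   match data frames, hit proteins only), `hits` (ids in input order),
#'   `n_proteins`, `params`.
#' @export
screen_proteome <- function(records, params = cys_pattern_params()) {
  if (anyDuplicated(records$id)) {
    stop_format("duplicate protein id(s): %s",
                paste(unique(records$id[duplicated(records$id)]), collapse = ", "))
  }
  matches <- lapply(seq_len(nrow(records)), function(i)
    find_cys_blocks(records[i, , drop = FALSE], params))
  names(matches) <- records$id
  has_hit <- vapply(matches, nrow, 0L) > 0L
  structure(list(matches = matches[has_hit],
                 hits = records$id[has_hit],
                 n_proteins = nrow(records),
                 params = params),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat(sprintf("proteome screen: %d / %d proteins carry the cysteine-block motif\n",
              length(x$hits), x$n_proteins))
  invisible(x)
}

#' Hit counts over a grid of pattern parameters
#'
#' Used to explore saturation of the hit count as the grammar is relaxed
#' or tightened.
#'
#' @param records A [protein_records()] data frame.
#' @param param_grid Non-empty list of [cys_pattern_params()] objects.
#' @return Data frame with one row per grid point: the parameter values
#'   and `n_hits`.
#' @export
saturation_scan <- function(records, param_grid) {
  if (!is.list(param_grid) || length(param_grid) == 0L) {
    stop_format("param_grid must be a non-empty list of cys_pattern_params")
  }
  if (inherits(param_grid, "cys_pattern_params")) param_grid <- list(param_grid)
  rows <- lapply(param_grid, function(p) {
    stopifnot(inherits(p, "cys_pattern_params"))
    sr <- screen_proteome(records, p)
    data.frame(n_cys = p$n_cys, min_first_gap = p$min_first_gap,
               min_inner_gap = p$min_inner_gap, max_inner_gap = p$max_inner_gap,
               window_min = p$window_min, window_max = p$window_max,
               n_hits = length(sr$hits), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
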