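# repeat_blocks: decompose a pattern-positive protein into repeat blocks.
#
# The block period is estimated from the spacings between successive
# non-overlapping motif anchors (greedy left-to-right chain). Each distinct
# chain spacing is evaluated as a candidate period by the fraction of
# period-tiled block starts that coincide with an anchor (within the
# tolerance); the best-supported spacing wins, with ties broken by chain
# frequency and then by the smallest value. The consistency score is needed
# because a motif may also start at the *last* cysteines of a block and
# reach into the next one, injecting spurious short spacings into the
# chain. Blocks are then tiled anchor-to-anchor: from the
# first anchor, each next boundary is the anchor nearest to
# current + period within +/- tolerance*period; when no such anchor exists
# a final block of exactly one period is emitted if it fits, and the tiling
# stops. Trailing partial blocks are dropped; any leading offset before the
# first anchor is kept outside block 1. Cysteines per block count ALL
# cysteines inside the block interval, so subtypes with extra cysteine
# pairs (8 or 10 per block) report their full count even though the scan
# motif only requires 6.

empty_decomposition <- function(protein_id) {
  structure(list(protein_id = protein_id, period = NA_integer_,
                 blocks = data.frame(start = integer(), end = integer()),
                 cys_per_block = integer(),
                 modal_cys_per_block = NA_integer_,
                 block_length_range = c(NA_integer_, NA_integer_),
                 n_blocks = 0L),
            class = "repeat_blocks")
}

#' Decompose a protein into repeat blocks
#'
#' @param record A single protein record (see [find_cys_blocks()]).
#' @param matches Motif matches from [find_cys_blocks()]; computed with
#'   `params` if `NULL`.
#' @param params Pattern parameters used when `matches` is `NULL`.
#' @param min_blocks Minimum number of consistently tiled blocks for a
#'   non-empty decomposition.
#' @param tolerance Fractional deviation from the period at which the
#'   tiling breaks.
#' @return A `repeat_blocks` list: `protein_id`, `period`, `blocks`
#'   (data frame of 0-based half-open `start`/`end`), `cys_per_block`,
#'   `modal_cys_per_block`, `block_length_range`, `n_blocks`. Empty
#'   decomposition (`n_blocks = 0`) when the protein has no motif or
#'   fewer than `min_blocks` blocks tile consistently.
#' @export
decompose_repeats <- function(record, matches = NULL,
                              params = cys_pattern_params(),
                              min_blocks = 2L, tolerance = 0.25) {
  rec <- as_record(record)
  if (is.null(matches)) matches <- find_cys_blocks(rec, params)
  if (nrow(matches) == 0L) return(empty_decomposition(rec$id))
  anchors <- matches$anchor
  last_cys <- vapply(matches$cys_positions, function(p) p[length(p)], 0L)
  o <- order(anchors)
  anchors <- anchors[o]; last_cys <- last_cys[o]

  # greedy non-overlapping chain
  chain <- anchors[1L]; cur_end <- last_cys[1L]
  repeat {
    nxt <- which(anchors > cur_end)
    if (length(nxt) == 0L) break
    i <- nxt[1L]
    chain <- c(chain, anchors[i]); cur_end <- last_cys[i]
  }
  if (length(chain) < 2L) return(empty_decomposition(rec$id))
  L <- nchar(rec$sequence)
  spac <- diff(chain)
  cands <- sort(unique(spac))
  tile_score <- function(p) {
    tolp <- tolerance * p
    if (anchors[1L] > L - p) return(0)
    starts <- seq(anchors[1L], L - p, by = p)
    hit <- vapply(starts, function(s) any(abs(anchors - s) <= tolp), TRUE)
    mean(hit)
  }
  scores <- vapply(cands, tile_score, 0)
  freq <- vapply(cands, function(p) sum(spac == p), 0L)
  best <- order(-scores, -freq, cands)[1L]
  period <- as.integer(cands[best])
  tol <- tolerance * period

  starts <- anchors[1L]; ends <- integer()
  cur <- anchors[1L]
  repeat {
    target <- cur + period
    cand <- anchors[anchors >= target - tol & anchors <= target + tol &
                      anchors > cur]
    if (length(cand)) {
      nxt <- cand[which.min(abs(cand - target))]
      ends <- c(ends, nxt)
      starts <- c(starts, nxt)
      cur <- nxt
    } else {
      if (cur + period <= L) {
        ends <- c(ends, cur + period)
      } else {
        starts <- starts[-length(starts)]   # trailing partial block dropped
      }
      break
    }
  }
  if (length(starts) < min_blocks) return(empty_decomposition(rec$id))

  ch <- strsplit(rec$sequence, "", fixed = TRUE)[[1L]]
  is_c <- ch == "C"
  cys_per_block <- vapply(seq_along(starts), function(i)
    sum(is_c[(starts[i] + 1L):ends[i]]), 0L)  # 0-based half-open -> 1-based
  lens <- ends - starts
  structure(list(protein_id = rec$id, period = period,
                 blocks = data.frame(start = starts, end = ends),
                 cys_per_block = cys_per_block,
                 modal_cys_per_block =
                   if (length(cys_per_block) >= 2L)
                     as.integer(mode_smallest(cys_per_block)) else NA_integer_,
                 block_length_range = as.integer(range(lens)),
                 n_blocks = length(starts)),
            class = "repeat_blocks")
}

#' @export
print.repeat_blocks <- function(x, ...) {
  if (x$n_blocks == 0L) {
    cat(sprintf("%s: no repeat-block decomposition\n", x$protein_id))
  } else {
    cat(sprintf("%s: %d blocks, period %d aa, modal %d Cys/block, lengths %d-%d\n",
                x$protein_id, x$n_blocks, x$period, x$modal_cys_per_block,
                x$block_length_range[1], x$block_length_range[2]))
  }
  invisible(x)
}

#' Tabulate repeat decompositions for many proteins
#'
#' @param records A [protein_records()] data frame.
#' @param params,min_blocks,tolerance Passed to [decompose_repeats()].
#' @return Data frame with one row per protein: `protein_id`, `period`,
#'   `n_blocks`, `modal_cys_per_block`, `min_len`, `max_len`.
#' @export
decompose_proteome <- function(records, params = cys_pattern_params(),
                               min_blocks = 2L, tolerance = 0.25) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    d <- decompose_repeats(records[i, , drop = FALSE], params = params,
                           min_blocks = min_blocks, tolerance = tolerance)
    data.frame(protein_id = d$protein_id, period = d$period,
               n_blocks = d$n_blocks,
               modal_cys_per_block = d$modal_cys_per_block,
               min_len = d$block_length_range[1],
               max_len = d$block_length_range[2],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
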