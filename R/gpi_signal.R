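# gpi_signal: rule-based classifier for the C-terminal GPI anchor signal.
#
# The signal anatomy is tripartite: the omega attachment site (a small
# residue), an unconstrained omega+1/omega+2, a polar spacer at
# omega+3..omega+8, and a hydrophobic tail from omega+9 to the C-terminus.
# This is a deterministic stand-in for trained HMM predictors whose class
# vocabulary (highly probable / probable / weakly probable) it preserves.

#' Kyte-Doolittle hydropathy scale
#'
#' Named numeric vector over the 20 amino acids plus `X` (0).
#' Positive = hydrophobic. "Polar" is operationalized as hydropathy < 0.
#'
#' @return Named numeric vector of length 21.
#' @export
kyte_doolittle <- function() {
  c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
    G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
    P = -1.6, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3, X = 0)
}

#' GPI anchor signal parameters
#'
#' @param omega_residues Residues allowed at the omega site (small
#'   amino acids; defaults to the conventional transamidase-compatible
#'   set).
#' @param omega_search_window Allowed distances (residues) from the
#'   omega site to the C-terminus.
#' @param min_polar_spacer Minimum number of the 6 spacer residues
#'   (omega+3..omega+8) with hydropathy < 0.
#' @param min_tail_len Minimum hydrophobic-region length (from omega+9
#'   to the C-terminus).
#' @param min_tail_hydropathy Minimum mean Kyte-Doolittle hydropathy of
#'   the tail.
#' @param hydropathy_scale Residue-to-hydropathy map covering the 20
#'   amino acids plus `X`.
#' @return A `gpi_params` list.
#' @export
gpi_params <- function(omega_residues = c("G", "A", "S", "N", "D", "C"),
                       omega_search_window = 11:34,
                       min_polar_spacer = 4L,
                       min_tail_len = 8L,
                       min_tail_hydropathy = 1.0,
                       hydropathy_scale = kyte_doolittle()) {
  if (!all(AA21 %in% names(hydropathy_scale))) {
    stop_format("hydropathy_scale must cover the 20 amino acids plus X")
  }
  if (any(!is.finite(hydropathy_scale))) stop_format("hydropathy values must be finite")
  stopifnot(all(omega_search_window >= 1L), min_tail_len >= 1L)
  structure(list(omega_residues = omega_residues,
                 omega_search_window = sort(as.integer(omega_search_window)),
                 min_polar_spacer = as.integer(min_polar_spacer),
                 min_tail_len = as.integer(min_tail_len),
                 min_tail_hydropathy = min_tail_hydropathy,
                 hydropathy_scale = hydropathy_scale),
            class = "gpi_params")
}

gpi_classes <- c("highly_probable", "probable", "weakly_probable", "none")

#' Score the GPI anchor signal of one protein
#'
#' Every C-terminal position within `omega_search_window` (distance from
#' the candidate omega site to the C-terminus) is evaluated as a
#' candidate omega site; at least one residue must precede omega. A
#' candidate passes the hard rules iff the omega residue is in
#' `omega_residues`, at least `min_polar_spacer` of the 6 spacer
#' residues are polar (hydropathy < 0), the tail has at least
#' `min_tail_len` residues and mean tail hydropathy is at least
#' `min_tail_hydropathy`. The best passing candidate is reported with
#' `score` = mean of three normalized margins (spacer polar fraction,
#' tail hydropathy margin, tail length margin), each clipped to
#' `[0, 1]`; classes: `highly_probable` (score >= 0.5), `probable`
#' (>= 0.25), else `weakly_probable`; `none` when no candidate passes.
#'
#' Sequences shorter than `min_tail_len + 11` cannot host the anatomy
#' and are classed `none` (not an error).
#'
#' @param record A single protein record (see [find_cys_blocks()]).
#' @param params A [gpi_params()] object.
#' @return One-row data frame: `protein_id`, `omega_index` (0-based, NA
#'   if none), `spacer_polar_count`, `tail_len`, `tail_hydropathy`,
#'   `score`, `gpi_class`.
#' @export
score_gpi_signal <- function(record, params = gpi_params()) {
  rec <- as_record(record)
  kd <- params$hydropathy_scale
  res_none <- data.frame(protein_id = rec$id, omega_index = NA_integer_,
                         spacer_polar_count = NA_integer_, tail_len = NA_integer_,
                         tail_hydropathy = NA_real_, score = 0,
                         gpi_class = "none", stringsAsFactors = FALSE)
  L <- nchar(rec$sequence)
  if (L < params$min_tail_len + 11L) return(res_none)
  ch <- strsplit(rec$sequence, "", fixed = TRUE)[[1L]]
  h <- unname(kd[ch])
  best <- NULL
  for (dist in params$omega_search_window) {
    w <- L - dist                              # 1-based omega index
    if (w < 2L) next                           # need >= 1 residue of body
    tail_len <- dist - 8L
    if (tail_len < params$min_tail_len) next
    if (!ch[w] %in% params$omega_residues) next
    spacer <- h[(w + 3L):(w + 8L)]
    polar <- sum(spacer < 0)
    if (polar < params$min_polar_spacer) next
    tail_kd <- mean(h[(w + 9L):L])
    if (tail_kd < params$min_tail_hydropathy) next
    kd_max <- max(kd)
    score <- mean(c(
      clip01(polar / 6),
      clip01((tail_kd - params$min_tail_hydropathy) /
               (kd_max - params$min_tail_hydropathy)),
      clip01((tail_len - params$min_tail_len) / params$min_tail_len)))
    if (is.null(best) || score > best$score) {
      best <- list(omega_index = w - 1L, polar = polar, tail_len = tail_len,
                   tail_kd = tail_kd, score = score)
    }
  }
  if (is.null(best)) return(res_none)
  cls <- if (best$score >= 0.5) "highly_probable"
         else if (best$score >= 0.25) "probable" else "weakly_probable"
  data.frame(protein_id = rec$id, omega_index = best$omega_index,
             spacer_polar_count = best$polar, tail_len = best$tail_len,
             tail_hydropathy = best$tail_kd, score = best$score,
             gpi_class = cls, stringsAsFactors = FALSE)
}

#' Classify GPI signals for many proteins
#'
#' @param records A [protein_records()] data frame.
#' @param params A [gpi_params()] object.
#' @return Data frame with one row per input protein (input order).
#' @export
gpi_classify <- function(records, params = gpi_params()) {
  out <- do.call(rbind, lapply(seq_len(nrow(records)), function(i)
    score_gpi_signal(records[i, , drop = FALSE], params)))
  rownames(out) <- NULL
  out
}

#' Keep pattern-positive proteins with a highly probable GPI signal
#'
#' Mirrors the published selection gate: of the proteins that pass the
#' cysteine-pattern screen, only those classified `highly_probable` are
#' retained as family candidates; `probable` and `weakly_probable` are
#' excluded. Input order is preserved.
#'
#' @param records A [protein_records()] data frame (already
#'   pattern-positive).
#' @param params A [gpi_params()] object.
#' @return Subset of `records`.
#' @export
filter_candidates <- function(records, params = gpi_params()) {
  cls <- gpi_classify(records, params)
  out <- records[cls$gpi_class == "highly_probable", , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(records)
  out
}
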