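# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
stop_format <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

# evaluate expr under a temporary RNG state seeded with `seed`;
# seed = NULL means "use the current RNG stream" (caller controls it)
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(expr)
}

# most frequent value; ties broken by the smallest value
mode_smallest <- function(x) {
  stopifnot(length(x) > 0)
  ux <- sort(unique(x))
  ux[which.max(tabulate(match(x, ux)))]
}

clip01 <- function(x) pmin(1, pmax(0, x))

# deterministic TSV writer: fixed column order, "\n" endings, full-precision
# numeric formatting so round-trips are exact
write_tsv_det <- function(df, path) {
  fmt_col <- function(col) {
    if (is.double(col)) {
      out <- sprintf("%.17g", col)
      out[is.na(col)] <- "NA"
      out
    } else {
      as.character(col)
    }
  }
  cells <- vapply(df, fmt_col, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(
    paste(names(df), collapse = "\t"),
    if (nrow(df)) apply(cells, 1L, paste, collapse = "\t")
  )
  writeLines(lines, path)
  invisible(path)
}
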