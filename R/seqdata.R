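# seqdata: domain types and readers/writers for FASTA, GFF3/BED and
# expression TSV. No science here; every reader is total over well-formed
# input and fails loudly otherwise.

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA21 <- c(AA20, "X")

#' Canonical expression condition labels
#'
#' The 20 developmental conditions an expression matrix must carry, in
#' canonical order: growth at low/medium/high density (`Ll`, `Lm`, `Lh`),
#' starvation time points (`S0`-`S24`, hours) and conjugation time points
#' (`C0`-`C18`, hours).
#'
#' @return Character vector of length 20.
#' @export
canonical_conditions <- function() {
  c("Ll", "Lm", "Lh",
    "S0", "S3", "S6", "S9", "S12", "S15", "S24",
    "C0", "C2", "C4", "C6", "C8", "C10", "C12", "C14", "C16", "C18")
}

# map letters outside the 20 AA + X alphabet to X (with a warning);
# X never counts as cysteine anywhere downstream
normalize_sequence <- function(seq, context = "sequence") {
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)
  bad <- 0L
  chars <- lapply(chars, function(ch) {
    out <- ch %in% AA21
    if (!all(out)) {
      bad <<- bad + sum(!out)
      ch[!out] <- "X"
    }
    ch
  })
  if (bad > 0L) {
    warning(sprintf("%d non-standard residue(s) in %s mapped to X",
                    bad, context), call. = FALSE)
  }
  vapply(chars, paste, "", collapse = "")
}

#' Construct a collection of protein records
#'
#' @param id Character vector of unique sequence identifiers.
#' @param sequence Character vector of amino-acid sequences (uppercased;
#'   letters outside the 20-letter alphabet plus `X` are mapped to `X`
#'   with a warning).
#' @param description Optional free-text descriptions.
#' @return A `protein_records` data frame with columns `id`,
#'   `description`, `sequence`.
#' @export
protein_records <- function(id, sequence, description = "") {
  id <- as.character(id)
  sequence <- as.character(sequence)
  if (length(id) != length(sequence)) {
    stop_format("id and sequence lengths differ (%d vs %d)",
                length(id), length(sequence))
  }
  if (anyDuplicated(id)) {
    stop_format("duplicate protein id(s): %s",
                paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(grepl("\\s", sequence))) {
    stop_format("whitespace in sequence for id(s): %s",
                paste(id[grepl("\\s", sequence)], collapse = ", "))
  }
  sequence <- normalize_sequence(sequence)
  if (any(nchar(sequence) < 1L)) {
    stop_format("empty sequence for id(s): %s",
                paste(id[nchar(sequence) < 1L], collapse = ", "))
  }
  out <- data.frame(id = id,
                    description = rep_len(as.character(description), length(id)),
                    sequence = sequence,
                    stringsAsFactors = FALSE)
  class(out) <- c("protein_records", "data.frame")
  out
}

# coerce one row / list to a simple record list(id=, sequence=)
as_record <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    list(id = x$id, sequence = x$sequence)
  } else if (is.list(x) && !is.null(x$sequence)) {
    list(id = x$id %||% "seq", sequence = x$sequence)
  } else if (is.character(x) && length(x) == 1L) {
    list(id = if (!is.null(names(x))) names(x) else "seq",
         sequence = unname(x))
  } else {
    stop_format("cannot interpret input as a protein record")
  }
}

#' Read protein sequences from a FASTA file
#'
#' Sequences are uppercased; gap (`-`) and stop (`*`) characters are
#' stripped with a warning; residues outside the 20-letter alphabet plus
#' `X` are mapped to `X` with a warning.
#'
#' @param path Path to a FASTA file.
#' @return A [protein_records()] data frame (zero rows for an empty file).
#' @export
read_fasta <- function(path) {
  rec <- parse_fasta(path)
  n_gap <- sum(vapply(rec$sequence, function(s)
    nchar(s) - nchar(gsub("[*-]", "", s)), 0))
  if (n_gap > 0) {
    warning(sprintf("stripped %d gap/stop character(s) ('-', '*') from %s",
                    n_gap, path), call. = FALSE)
    rec$sequence <- gsub("[*-]", "", rec$sequence)
  }
  if (length(rec$id) == 0L) {
    out <- protein_records(character(), character())
    return(out)
  }
  protein_records(rec$id, rec$sequence, rec$description)
}

#' Read a multiple sequence alignment from aligned FASTA
#'
#' Unlike [read_fasta()], gap characters are kept. All rows must have
#' equal aligned length.
#'
#' @param path Path to an aligned FASTA file.
#' @return Named character vector of equal-length aligned sequences.
#' @export
read_msa <- function(path) {
  rec <- parse_fasta(path)
  if (length(rec$id) < 2L) stop_format("alignment in %s has < 2 sequences", path)
  seqs <- toupper(rec$sequence)
  if (length(unique(nchar(seqs))) != 1L) {
    stop_format("aligned sequences in %s have unequal lengths", path)
  }
  stats::setNames(seqs, rec$id)
}

# line-accurate FASTA parser (error messages name the offending line)
parse_fasta <- function(path) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  ids <- character(); desc <- character(); seqs <- character()
  cur <- NULL; buf <- character(); header_line <- 0L
  flush <- function() {
    if (!is.null(cur)) {
      s <- paste(buf, collapse = "")
      if (nchar(s) == 0L) {
        stop_format("FASTA format error: empty sequence for header at line %d of %s",
                    header_line, path)
      }
      ids[length(ids) + 1L] <<- cur$id
      desc[length(desc) + 1L] <<- cur$desc
      seqs[length(seqs) + 1L] <<- s
    }
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (nchar(ln) == 0L) next
    if (startsWith(ln, ">")) {
      flush()
      hdr <- sub("^>", "", ln)
      if (nchar(trimws(hdr)) == 0L) {
        stop_format("FASTA format error: empty header at line %d of %s", i, path)
      }
      sp <- regmatches(hdr, regexpr("\\s", hdr))
      if (length(sp) == 0L) {
        cur <- list(id = hdr, desc = "")
      } else {
        pos <- regexpr("\\s", hdr)
        cur <- list(id = substr(hdr, 1L, pos - 1L),
                    desc = trimws(substr(hdr, pos + 1L, nchar(hdr))))
      }
      header_line <- i
      buf <- character()
    } else {
      if (is.null(cur)) {
        stop_format("FASTA format error: sequence data before any header at line %d of %s",
                    i, path)
      }
      if (grepl("\\s", ln)) ln <- gsub("\\s+", "", ln)
      buf[length(buf) + 1L] <- ln
    }
  }
  flush()
  list(id = ids, description = desc, sequence = seqs)
}

#' Write protein records to FASTA
#'
#' @param records A [protein_records()] data frame.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  lines <- unlist(lapply(seq_len(nrow(records)), function(i) {
    hdr <- if (nzchar(records$description[i])) {
      paste0(">", records$id[i], " ", records$description[i])
    } else {
      paste0(">", records$id[i])
    }
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    c(hdr, substring(s, starts, pmin(starts + width - 1L, nchar(s))))
  }))
  if (is.null(lines)) lines <- character()
  writeLines(lines, path)
  invisible(path)
}

#' Write a multiple sequence alignment to aligned FASTA
#'
#' @param msa Named character vector of equal-length aligned sequences.
#' @param path Output path.
#' @param width Line wrap width.
#' @return `path`, invisibly.
#' @export
write_msa <- function(msa, path, width = 60L) {
  rec <- data.frame(id = names(msa), description = "", sequence = unname(msa),
                    stringsAsFactors = FALSE)
  write_fasta(rec, path, width = width)
}

#' Construct gene loci
#'
#' Internal coordinate convention is 0-based half-open on the forward
#' strand of a scaffold (BED-like).
#'
#' @param gene_id,scaffold_id Character vectors.
#' @param start,end Integer 0-based half-open coordinates, `start < end`.
#' @param strand Character vector of `"+"` / `"-"`.
#' @return A `gene_loci` data frame sorted by (scaffold, start).
#' @export
gene_loci <- function(gene_id, scaffold_id, start, end, strand) {
  out <- data.frame(gene_id = as.character(gene_id),
                    scaffold_id = as.character(scaffold_id),
                    start = as.integer(start), end = as.integer(end),
                    strand = as.character(strand),
                    stringsAsFactors = FALSE)
  if (anyDuplicated(out$gene_id)) {
    stop_format("duplicate gene id(s) in loci: %s",
                paste(unique(out$gene_id[duplicated(out$gene_id)]), collapse = ", "))
  }
  bad <- out$end <= out$start
  if (any(bad)) {
    stop_format("locus end <= start for gene(s): %s",
                paste(out$gene_id[bad], collapse = ", "))
  }
  if (!all(out$strand %in% c("+", "-"))) {
    stop_format("strand must be '+' or '-' (got: %s)",
                paste(setdiff(unique(out$strand), c("+", "-")), collapse = ", "))
  }
  out <- out[order(out$scaffold_id, out$start), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gene_loci", "data.frame")
  out
}

#' Read gene loci from GFF3 or BED
#'
#' Coordinates are normalized to 0-based half-open regardless of the
#' source dialect (GFF3 is 1-based inclusive). For GFF3, `gene` features
#' are used when present (all features otherwise); the `ID` (or `Name`)
#' attribute provides the gene id. Output is sorted by (scaffold, start).
#'
#' @param path Input path.
#' @param format `"auto"` (by extension), `"gff3"` or `"bed"`.
#' @return A [gene_loci()] data frame.
#' @export
read_loci <- function(path, format = c("auto", "gff3", "bed")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_format("file not found: %s", path)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gff3"
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (format == "gff3") "gff3" else "bed"),
    error = function(e) stop_format("%s format error in %s: %s",
                                    toupper(format), path, conditionMessage(e)))
  df <- as.data.frame(gr)
  if (format == "gff3") {
    if ("type" %in% names(df) && any(df$type == "gene")) {
      df <- df[df$type == "gene", , drop = FALSE]
    }
    gid <- df$ID
    if (is.null(gid) || anyNA(gid)) {
      alt <- df$Name
      if (is.null(gid)) gid <- alt else if (!is.null(alt)) gid[is.na(gid)] <- alt[is.na(gid)]
    }
    if (is.null(gid) || anyNA(gid)) {
      stop_format("GFF3 format error in %s: gene feature without ID/Name attribute", path)
    }
  } else {
    gid <- df$name
    if (is.null(gid) || anyNA(gid)) {
      stop_format("BED format error in %s: name column (4th) is required", path)
    }
  }
  # GRanges is 1-based inclusive for both dialects after import
  gene_loci(gene_id = gid, scaffold_id = as.character(df$seqnames),
            start = df$start - 1L, end = df$end,
            strand = as.character(df$strand))
}

#' Write gene loci to GFF3 or BED
#'
#' @param loci A [gene_loci()] data frame.
#' @param path Output path.
#' @param format `"gff3"` or `"bed"`.
#' @return `path`, invisibly.
#' @export
write_loci <- function(loci, path, format = c("gff3", "bed")) {
  format <- match.arg(format)
  if (format == "gff3") {
    lines <- c("##gff-version 3",
               sprintf("%s\tserscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       loci$scaffold_id, loci$start + 1L, loci$end,
                       loci$strand, loci$gene_id))
  } else {
    lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                     loci$scaffold_id, loci$start, loci$end,
                     loci$gene_id, loci$strand)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix from TSV
#'
#' First column holds gene ids; the header row must contain exactly the
#' 20 canonical condition labels (any order; reordered to canonical).
#' Values are log2-scale expression.
#'
#' @param path Input path.
#' @param impute_median If `TRUE`, missing values are imputed with the
#'   row median; the default is to reject missing values.
#' @return Numeric matrix (genes x 20 conditions) with dimnames.
#' @export
read_expression <- function(path, impute_median = FALSE) {
  if (!file.exists(path)) stop_format("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_format("expression format error in %s: need gene id + conditions", path)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop_format("duplicate gene id(s) in %s: %s", path,
                paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  labs <- names(df)[-1L]
  canon <- canonical_conditions()
  unknown <- setdiff(labs, canon)
  if (length(unknown)) {
    stop_format("unknown condition label(s) in %s: %s", path,
                paste(unknown, collapse = ", "))
  }
  missing <- setdiff(canon, labs)
  if (length(missing)) {
    stop_format("missing condition label(s) in %s: %s", path,
                paste(missing, collapse = ", "))
  }
  x <- as.matrix(df[, canon, drop = FALSE])
  storage.mode(x) <- "double"
  rownames(x) <- ids
  if (anyNA(x)) {
    if (!impute_median) {
      stop_format("missing values in %s (use impute_median = TRUE to impute row medians)", path)
    }
    for (i in which(rowSums(is.na(x)) > 0L)) {
      med <- stats::median(x[i, ], na.rm = TRUE)
      if (is.na(med)) stop_format("gene %s in %s has no observed values", rownames(x)[i], path)
      x[i, is.na(x[i, ])] <- med
    }
  }
  x
}

#' Write an expression matrix to TSV
#'
#' Values are written at full double precision so that a write/read
#' round trip is exact.
#'
#' @param x Numeric matrix with gene ids as rownames and the canonical
#'   condition labels as colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(gene_id = rownames(x), stringsAsFactors = FALSE)
  for (j in colnames(x)) df[[j]] <- x[, j]
  write_tsv_det(df, path)
}

#' Construct a labelled reference sequence set
#'
#' @param records A [protein_records()] data frame of reference proteins.
#' @param labels Named character vector mapping record id to subtype
#'   (e.g. `"H"`, `"L"`, `"J"`).
#' @return A `reference_set` list with elements `records` and `labels`.
#' @export
reference_set <- function(records, labels) {
  labels <- stats::setNames(as.character(labels), names(labels))
  if (is.null(names(labels)) || any(!nzchar(names(labels)))) {
    stop_format("labels must be a named character vector (names = record ids)")
  }
  missing <- setdiff(names(labels), records$id)
  if (length(missing)) {
    stop_format("label(s) refer to unknown record(s): %s",
                paste(missing, collapse = ", "))
  }
  if (any(!nzchar(labels))) stop_format("empty subtype label")
  out <- list(records = records[match(names(labels), records$id), , drop = FALSE],
              labels = labels)
  class(out) <- "reference_set"
  out
}
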