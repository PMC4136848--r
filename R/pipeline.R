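# pipeline: orchestrate scan -> GPI filter -> blocks -> classify ->
# tandem -> cluster with deterministic outputs and a JSON run report.

#' Pipeline configuration
#'
#' @param fasta Proteome FASTA path (mandatory).
#' @param outdir Output directory (created if missing).
#' @param seed Integer seed (mandatory; classification and clustering
#'   are stochastic).
#' @param loci Optional GFF3/BED path (enables the tandem stage).
#' @param expression Optional expression TSV path (enables clustering).
#' @param reference_fasta,reference_labels Optional reference FASTA and
#'   a 2-column TSV (id, subtype) (enable classification).
#' @param msa Optional pre-computed aligned FASTA of candidates plus
#'   references; when given, the bundled aligner is skipped.
#' @param stages `NULL` for automatic stage selection (scan, gpi, blocks
#'   always; classify/tandem/cluster when their inputs are present), or
#'   an explicit character vector; a requested stage with a missing
#'   input is an error before any work is done.
#' @param scan [cys_pattern_params()] for the motif scan.
#' @param gpi [gpi_params()] for the GPI filter.
#' @param blocks List: `min_blocks`, `tolerance`.
#' @param classify List: `n_replicates`, `min_support`, `model`,
#'   `gap_open`, `gap_extend`.
#' @param tandem List: `max_intervening`.
#' @param cluster List: `k`, `restarts`, `max_iter`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(fasta, outdir, seed,
                            loci = NULL, expression = NULL,
                            reference_fasta = NULL, reference_labels = NULL,
                            msa = NULL, stages = NULL,
                            scan = cys_pattern_params(),
                            gpi = gpi_params(),
                            blocks = list(min_blocks = 2L, tolerance = 0.25),
                            classify = list(n_replicates = 100L,
                                            min_support = 40,
                                            model = "p",
                                            gap_open = 10, gap_extend = 0.2),
                            tandem = list(max_intervening = 1L),
                            cluster = list(k = 30L, restarts = 10L,
                                           max_iter = 100L)) {
  if (missing(seed) || is.null(seed)) stop_format("an explicit seed is required")
  cfg <- list(fasta = fasta, outdir = outdir, seed = as.integer(seed),
              loci = loci, expression = expression,
              reference_fasta = reference_fasta,
              reference_labels = reference_labels, msa = msa,
              stages = stages, scan = scan, gpi = gpi,
              blocks = utils::modifyList(list(min_blocks = 2L, tolerance = 0.25), blocks),
              classify = utils::modifyList(list(n_replicates = 100L, min_support = 40,
                                                model = "p", gap_open = 10,
                                                gap_extend = 0.2), classify),
              tandem = utils::modifyList(list(max_intervening = 1L), tandem),
              cluster = utils::modifyList(list(k = 30L, restarts = 10L,
                                               max_iter = 100L), cluster))
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_stage_inputs <- function(cfg) {
  list(scan = cfg$fasta, gpi = cfg$fasta, blocks = cfg$fasta,
       classify = if (is.null(cfg$reference_fasta) ||
                      is.null(cfg$reference_labels)) NULL else "ok",
       tandem = cfg$loci, cluster = cfg$expression)
}

#' Run the prediction pipeline
#'
#' Stage order mirrors the published funnel: cysteine-pattern scan over
#' the whole proteome, GPI-signal filter of the pattern hits
#' (highly-probable class only), repeat-block decomposition of the
#' candidates, then the optional downstream stages (subtype
#' classification against references, tandem-array detection on loci,
#' expression clustering). Writes per-stage TSVs, a Newick tree and a
#' JSON run report into `config$outdir`; reruns with the same
#' configuration and seed are byte-identical.
#'
#' @param config A [pipeline_config()].
#' @return The run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  avail <- pipeline_stage_inputs(config)
  stages <- config$stages %||% names(avail)[!vapply(avail, is.null, TRUE)]
  unknown <- setdiff(stages, names(avail))
  if (length(unknown)) stop_format("unknown stage(s): %s", paste(unknown, collapse = ", "))
  missing_in <- stages[vapply(avail[stages], is.null, TRUE)]
  if (length(missing_in)) {
    stop_format("stage(s) requested without mandatory input: %s",
                paste(missing_in, collapse = ", "))
  }
  for (p in c(config$fasta, config$loci, config$expression,
              config$reference_fasta, config$reference_labels, config$msa)) {
    if (!is.null(p) && !file.exists(p)) stop_format("input file not found: %s", p)
  }
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  report <- list(package = "serscan",
                 seed = config$seed,
                 stages = as.list(stages),
                 parameters = list(
                   scan = lapply(unclass(config$scan), function(v)
                     if (is.numeric(v) && any(!is.finite(v))) as.character(v) else v),
                   gpi = unclass(config$gpi)[setdiff(names(config$gpi), "hydropathy_scale")],
                   blocks = config$blocks, classify = config$classify,
                   tandem = config$tandem, cluster = config$cluster),
                 counts = list())

  records <- read_fasta(config$fasta)
  report$counts$n_proteins <- nrow(records)

  ## scan
  sr <- screen_proteome(records, config$scan)
  scan_df <- do.call(rbind, c(lapply(sr$matches, function(m)
    data.frame(protein_id = m$protein_id, anchor = m$anchor,
               cys_positions = vapply(m$cys_positions, paste, "", collapse = ","),
               span = m$span, stringsAsFactors = FALSE)),
    list(make.row.names = FALSE)))
  if (is.null(scan_df)) {
    scan_df <- data.frame(protein_id = character(), anchor = integer(),
                          cys_positions = character(), span = integer())
  }
  write_tsv_det(scan_df, out("scan_hits.tsv"))
  report$counts$n_pattern_hits <- length(sr$hits)
  hit_records <- records[records$id %in% sr$hits, , drop = FALSE]

  ## gpi
  candidates <- hit_records
  if ("gpi" %in% stages) {
    gpi_df <- gpi_classify(hit_records, config$gpi)
    write_tsv_det(gpi_df, out("gpi.tsv"))
    candidates <- hit_records[gpi_df$gpi_class == "highly_probable", , drop = FALSE]
    rownames(candidates) <- NULL
    write_fasta(candidates, out("candidates.fasta"))
    report$counts$n_candidates <- nrow(candidates)
  }

  ## blocks
  if ("blocks" %in% stages) {
    blocks_df <- decompose_proteome(candidates, params = config$scan,
                                    min_blocks = config$blocks$min_blocks,
                                    tolerance = config$blocks$tolerance)
    write_tsv_det(blocks_df, out("blocks.tsv"))
    report$counts$n_decomposed <- sum(blocks_df$n_blocks > 0L)
  }

  assignments <- NULL
  if ("classify" %in% stages) {
    refs <- reference_set(read_fasta(config$reference_fasta),
                          read_label_table(config$reference_labels))
    pool <- rbind(candidates[!candidates$id %in% refs$records$id, , drop = FALSE],
                  refs$records)
    msa <- if (!is.null(config$msa)) read_msa(config$msa) else
      align_msa(pool, gap_open = config$classify$gap_open,
                gap_extend = config$classify$gap_extend)
    tree <- bootstrap_supports(msa, n_replicates = config$classify$n_replicates,
                               seed = config$seed, model = config$classify$model)
    ape::write.tree(tree, out("tree.nwk"))
    assignments <- assign_subtypes(tree, refs,
                                   min_support = config$classify$min_support)
    write_tsv_det(assignments, out("assignments.tsv"))
    report$counts$n_classified <- sum(assignments$subtype != "unclassified")
    report$counts$fraction_classified <-
      if (nrow(assignments)) round(mean(assignments$subtype != "unclassified"), 4) else NA
  }

  if ("tandem" %in% stages) {
    loci <- read_loci(config$loci)
    cand_ids <- intersect(candidates$id, loci$gene_id)
    arrays <- detect_tandem_arrays(loci, cand_ids,
                                   max_intervening = config$tandem$max_intervening)
    arr_df <- data.frame(array_id = arrays$array_id,
                         scaffold_id = arrays$scaffold_id,
                         n_members = arrays$n_members,
                         n_intervening = arrays$n_intervening,
                         orientation_consistent = arrays$orientation_consistent,
                         member_ids = vapply(arrays$member_ids, paste, "", collapse = ","),
                         strands = vapply(arrays$strands, paste, "", collapse = ","),
                         stringsAsFactors = FALSE)
    write_tsv_det(arr_df, out("arrays.tsv"))
    summ <- tandem_summary(arrays, cand_ids, assignments = assignments, loci = loci)
    jsonlite::write_json(summ, out("tandem_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = 10)
    report$counts$n_arrays <- nrow(arrays)
    report$counts$tandem_fraction <- round(summ$tandem_fraction, 4)
  }

  if ("cluster" %in% stages) {
    X <- read_expression(config$expression)
    keep <- intersect(rownames(X), candidates$id)
    if (length(keep) == 0L) {
      stop_format("expression matrix shares no gene ids with the candidate set")
    }
    X <- X[keep, , drop = FALSE]
    k <- min(config$cluster$k, nrow(X))
    cl <- kmeans_pearson(X, k = k, seed = config$seed,
                         restarts = config$cluster$restarts,
                         max_iter = config$cluster$max_iter)
    write_tsv_det(data.frame(gene_id = names(cl$assignments),
                             cluster = unname(cl$assignments),
                             stringsAsFactors = FALSE),
                  out("clusters.tsv"))
    cent <- data.frame(cluster = rownames(cl$centroids), stringsAsFactors = FALSE)
    for (j in colnames(cl$centroids)) cent[[j]] <- cl$centroids[, j]
    write_tsv_det(cent, out("centroids.tsv"))
    write_expression(median_center(X), out("median_centered.tsv"))
    report$counts$n_expression_genes <- nrow(X)
    report$counts$n_clusters <- cl$k
  }

  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = 10)
  invisible(report)
}

# 2-column TSV (id, subtype), with or without a header line
read_label_table <- function(path) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_format("label table %s needs 2 columns (id, subtype)", path)
  if (tolower(df[1, 2]) %in% c("subtype", "label")) df <- df[-1, , drop = FALSE]
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}
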