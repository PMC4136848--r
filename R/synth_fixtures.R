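# synth_fixtures: deterministic generators for synthetic proteomes,
# scaffold layouts and expression matrices with machine-readable truth.
# The planted world encodes the family's published anatomy: repeat blocks
# of 55-100 aa carrying 6 (subtype L), 8 (subtype H) or 10 (subtype J)
# cysteines whose first six satisfy the scan grammar, and a compliant
# C-terminal GPI signal. Decoys violate exactly one criterion.

AA19 <- setdiff(AA20, "C")          # background alphabet without cysteine
POLAR6 <- c("N", "Q", "S", "T", "D", "E")
HYDRO4 <- c("L", "I", "V", "F")

#' Subtype specification for the protein generator
#'
#' @param name Subtype name (e.g. `"H"`, `"L"`, `"J"`).
#' @param cys_per_block Cysteines per repeat block (6, 8 or 10).
#' @param block_len_range Repeat block length range (aa).
#' @param n_blocks_range Number of repeat blocks range.
#' @return A `subtype_spec` list.
#' @export
subtype_spec <- function(name, cys_per_block,
                         block_len_range = c(55L, 100L),
                         n_blocks_range = c(3L, 8L)) {
  if (!cys_per_block %in% c(6L, 8L, 10L)) {
    stop_format("cys_per_block must be 6, 8 or 10")
  }
  # minimal offsets: first gap 6, remaining gaps 1 residue each
  min_span <- 7L + 2L * (cys_per_block - 2L) + 1L
  if (block_len_range[1] < min_span) {
    stop_format("block length %d too short for %d cysteines (need >= %d)",
                block_len_range[1], cys_per_block, min_span)
  }
  structure(list(name = name, cys_per_block = as.integer(cys_per_block),
                 block_len_range = as.integer(block_len_range),
                 n_blocks_range = as.integer(n_blocks_range)),
            class = "subtype_spec")
}

sample_range <- function(r) if (r[1] == r[2]) r[1] else sample(r[1]:r[2], 1L)

# cysteine offsets within a block: first six satisfy the scan grammar
# (first gap >= 6, inner gaps >= 1), extra cysteines follow with short gaps
block_cys_offsets <- function(cys_per_block) {
  gaps <- c(sample(6:10, 1L), sample(1:3, cys_per_block - 2L, replace = TRUE))
  cumsum(c(0L, gaps + 1L))
}

build_block <- function(block_len, offsets) {
  ch <- sample(AA19, block_len, replace = TRUE)
  ch[offsets + 1L] <- "C"
  paste(ch, collapse = "")
}

# compliant C-terminal GPI signal: omega + 2 unconstrained + 6 polar spacer
# + 12 hydrophobic tail (21 residues, distance omega..C-terminus = 20)
build_gpi_signal <- function(tail_residues = HYDRO4) {
  paste(c(sample(c("G", "A", "S"), 1L),
          sample(AA19, 2L, replace = TRUE),
          sample(POLAR6, 6L, replace = TRUE),
          sample(tail_residues, 12L, replace = TRUE)), collapse = "")
}

ser_body <- function(spec) {
  B <- sample_range(spec$block_len_range)
  n <- sample_range(spec$n_blocks_range)
  offsets <- block_cys_offsets(spec$cys_per_block)
  while (offsets[length(offsets)] > B - 1L) offsets <- block_cys_offsets(spec$cys_per_block)
  blocks <- vapply(seq_len(n), function(i) build_block(B, offsets), "")
  list(seq = paste(blocks, collapse = ""), period = B, n_blocks = n)
}

#' Generate one synthetic Ser-like protein
#'
#' The protein consists of `n_blocks` identical-period repeat blocks
#' (cysteine layout shared across blocks, first six cysteines satisfying
#' the scan grammar) followed by a compliant GPI anchor signal.
#' Deterministic under a fixed seed.
#'
#' @param spec A [subtype_spec()].
#' @param seed Integer seed, or `NULL` to draw from the current RNG
#'   stream.
#' @param id Record id.
#' @return List with elements `record` (one-row [protein_records()]) and
#'   `truth` (class, subtype, period, n_blocks, cys_per_block).
#' @export
generate_ser_protein <- function(spec, seed = NULL, id = "ser_1") {
  with_seed(seed, {
    body <- ser_body(spec)
    rec <- protein_records(id, paste0(body$seq, build_gpi_signal()),
                           description = sprintf("synthetic ser subtype %s", spec$name))
    list(record = rec,
         truth = list(class = "ser", subtype = spec$name, period = body$period,
                      n_blocks = body$n_blocks,
                      cys_per_block = spec$cys_per_block))
  })
}

default_subtype_specs <- function() {
  list(H = subtype_spec("H", 8L), L = subtype_spec("L", 6L), J = subtype_spec("J", 10L))
}

random_background_seq <- function(len, cys_rate) {
  ch <- sample(AA19, len, replace = TRUE)
  is_c <- runif(len) < cys_rate
  ch[is_c] <- "C"
  paste(ch, collapse = "")
}

#' Generate a synthetic proteome with ground truth
#'
#' Classes: `ser` (planted family members, per subtype mix),
#' `decoy_no_gpi` (intact repeat body, compliant signal whose tail is
#' replaced by acidic residues of equal length), `decoy_no_pattern`
#' (cysteine-free body with a compliant GPI signal) and `background`
#' (random sequence with a low cysteine rate). Background sequences that
#' would pass both the pattern screen and the highly-probable GPI gate
#' are regenerated, since they would contradict their own truth label.
#'
#' @param config List overriding defaults: `n_ser` (200),
#'   `n_decoy_no_gpi` (200), `n_decoy_no_pattern` (200), `n_background`
#'   (400), `subtype_mix` (H .4, L .4, J .2), `cys_rate` (0.02),
#'   `background_len_range` (100-800).
#' @param seed Integer seed (mandatory).
#' @return List: `records` ([protein_records()]), `truth` (data frame:
#'   `id`, `class`, `subtype`, `period`, `n_blocks`, `cys_per_block`).
#' @export
generate_proteome <- function(config = list(), seed) {
  if (missing(seed) || is.null(seed)) stop_format("an explicit seed is required")
  cfg <- utils::modifyList(list(
    n_ser = 200L, n_decoy_no_gpi = 200L, n_decoy_no_pattern = 200L,
    n_background = 400L, subtype_mix = c(H = 0.4, L = 0.4, J = 0.2),
    cys_rate = 0.02, background_len_range = c(100L, 800L)), config)
  specs <- default_subtype_specs()
  scan_params <- cys_pattern_params()
  gpi <- gpi_params()

  with_seed(seed, {
    ids <- character(); seqs <- character(); truth <- list()
    add <- function(id, seq, class, subtype = NA_character_,
                    period = NA_integer_, n_blocks = NA_integer_,
                    cys = NA_integer_) {
      ids[length(ids) + 1L] <<- id
      seqs[length(seqs) + 1L] <<- seq
      truth[[length(truth) + 1L]] <<- data.frame(
        id = id, class = class, subtype = subtype, period = period,
        n_blocks = n_blocks, cys_per_block = cys, stringsAsFactors = FALSE)
    }

    if (cfg$n_ser > 0L) {
      mix <- cfg$subtype_mix / sum(cfg$subtype_mix)
      subtypes <- sample(names(mix), cfg$n_ser, replace = TRUE, prob = mix)
      for (i in seq_len(cfg$n_ser)) {
        sp <- specs[[subtypes[i]]]
        body <- ser_body(sp)
        add(sprintf("SER_%04d", i), paste0(body$seq, build_gpi_signal()),
            "ser", sp$name, body$period, body$n_blocks, sp$cys_per_block)
      }
    }
    for (i in seq_len(cfg$n_decoy_no_gpi)) {
      sp <- specs[[sample(names(specs), 1L)]]
      body <- ser_body(sp)
      sig <- paste(c(sample(c("G", "A", "S"), 1L), sample(AA19, 2L, replace = TRUE),
                     sample(POLAR6, 6L, replace = TRUE),
                     sample(c("D", "E"), 12L, replace = TRUE)), collapse = "")
      add(sprintf("DNG_%04d", i), paste0(body$seq, sig), "decoy_no_gpi",
          sp$name, body$period, body$n_blocks, sp$cys_per_block)
    }
    for (i in seq_len(cfg$n_decoy_no_pattern)) {
      len <- sample(150:400, 1L)
      add(sprintf("DNP_%04d", i),
          paste0(paste(sample(AA19, len, replace = TRUE), collapse = ""),
                 build_gpi_signal()),
          "decoy_no_pattern")
    }
    for (i in seq_len(cfg$n_background)) {
      for (try in 1:100) {
        len <- sample(cfg$background_len_range[1]:cfg$background_len_range[2], 1L)
        s <- random_background_seq(len, cfg$cys_rate)
        rec <- list(id = "bg", sequence = s)
        is_candidate <- nrow(find_cys_blocks(rec, scan_params)) > 0L &&
          score_gpi_signal(rec, gpi)$gpi_class == "highly_probable"
        if (!is_candidate) break
      }
      add(sprintf("BG_%04d", i), s, "background")
    }
    list(records = protein_records(ids, seqs),
         truth = do.call(rbind, truth))
  })
}

#' Generate a synthetic scaffold layout with planted tandem arrays
#'
#' Emits disjoint gene loci: per scaffold one or more tandem arrays of
#' same-subtype candidate genes (shared strand, configurable antisense
#' exceptions, interspersed non-candidate filler genes at a configurable
#' rate), plus singleton candidates and flanking filler genes.
#'
#' @param config List overriding defaults: `n_scaffolds` (6),
#'   `arrays_per_scaffold` (1), `array_size_range` (3-8),
#'   `intervening_rate` (0.2; probability of one filler gene between
#'   consecutive members), `antisense_rate` (0), `n_singletons` (4),
#'   `subtypes` (H/L/J), `gene_len_range`, `gap_range`, `candidate_ids`
#'   (optional ids to use for planted candidates, in placement order;
#'   autogenerated once exhausted).
#' @param seed Integer seed (mandatory).
#' @return List: `loci` ([gene_loci()]), `truth` (list with `arrays`,
#'   `gene_subtypes`, `singletons`, `candidate_ids`).
#' @export
generate_genome_layout <- function(config = list(), seed) {
  if (missing(seed) || is.null(seed)) stop_format("an explicit seed is required")
  cfg <- utils::modifyList(list(
    n_scaffolds = 6L, arrays_per_scaffold = 1L, array_size_range = c(3L, 8L),
    intervening_rate = 0.2, antisense_rate = 0, n_singletons = 4L,
    subtypes = c("H", "L", "J"), gene_len_range = c(900L, 3000L),
    gap_range = c(200L, 2000L), candidate_ids = NULL), config)

  with_seed(seed, {
    gid <- 0L; fid <- 0L
    id_queue <- cfg$candidate_ids
    next_candidate_id <- function() {
      gid <<- gid + 1L
      if (gid <= length(id_queue)) id_queue[gid] else sprintf("SERG_%04d", gid)
    }
    rows <- list(); arrays <- list(); subtype_of <- character()
    new_gene <- function(scaffold, pos, id, strand) {
      len <- sample_range(cfg$gene_len_range)
      start <- pos + sample_range(cfg$gap_range)
      rows[[length(rows) + 1L]] <<- data.frame(
        gene_id = id, scaffold_id = scaffold, start = start,
        end = start + len, strand = strand, stringsAsFactors = FALSE)
      start + len
    }
    filler <- function(scaffold, pos, n = 1L) {
      for (i in seq_len(n)) {
        fid <<- fid + 1L
        pos <- new_gene(scaffold, pos, sprintf("FILLER_%04d", fid),
                        sample(c("+", "-"), 1L))
      }
      pos
    }
    for (s in seq_len(cfg$n_scaffolds)) {
      scf <- sprintf("scf_%02d", s)
      pos <- filler(scf, 0L, 2L)
      for (a in seq_len(cfg$arrays_per_scaffold)) {
        size <- sample_range(cfg$array_size_range)
        subtype <- sample(cfg$subtypes, 1L)
        strand <- sample(c("+", "-"), 1L)
        members <- character(size); strands <- character(size)
        for (m in seq_len(size)) {
          if (m > 1L && runif(1) < cfg$intervening_rate) pos <- filler(scf, pos, 1L)
          id <- next_candidate_id()
          st <- if (runif(1) < cfg$antisense_rate) setdiff(c("+", "-"), strand) else strand
          pos <- new_gene(scf, pos, id, st)
          members[m] <- id; strands[m] <- st
          subtype_of[id] <- subtype
        }
        arrays[[length(arrays) + 1L]] <- list(scaffold_id = scf,
                                              member_ids = members,
                                              subtype = subtype,
                                              strands = strands)
        pos <- filler(scf, pos, 3L)
      }
    }
    singletons <- character(cfg$n_singletons)
    for (i in seq_len(cfg$n_singletons)) {
      scf <- sprintf("scf_s%02d", i)
      pos <- filler(scf, 0L, 2L)
      id <- next_candidate_id()
      subtype_of[id] <- sample(cfg$subtypes, 1L)
      pos <- new_gene(scf, pos, id, sample(c("+", "-"), 1L))
      filler(scf, pos, 2L)
      singletons[i] <- id
    }
    loci <- do.call(rbind, rows)
    loci <- gene_loci(loci$gene_id, loci$scaffold_id, loci$start, loci$end,
                      loci$strand)
    list(loci = loci,
         truth = list(arrays = arrays, gene_subtypes = subtype_of,
                      singletons = singletons,
                      candidate_ids = names(subtype_of)))
  })
}

# k distinct centroid shapes over the 20 conditions: sinusoids of
# increasing frequency in anti-correlated sign pairs, unit variance
cluster_shapes <- function(k, n_cond = 20L) {
  t <- seq(0, 1, length.out = n_cond)
  shapes <- vapply(seq_len(k), function(j) {
    f <- ceiling(j / 2)
    s <- sin(2 * pi * f * t + pi / 5) * (if (j %% 2 == 0) -1 else 1)
    (s - mean(s)) / stats::sd(s)
  }, numeric(n_cond))
  t(shapes)
}

#' Generate a synthetic expression matrix with planted clusters
#'
#' Gene profiles are `baseline + amplitude * shape[cluster] + noise`
#' over the 20 canonical conditions, where the k shapes are unit-variance
#' sinusoids in anti-correlated pairs.
#'
#' @param config List overriding defaults: `n_genes` (100), `k` (5),
#'   `noise_sd` (0.5), `amplitude` (2), `baseline_range` (6-12, log2
#'   units), `gene_ids` (autogenerated), `arrays` (optional list of
#'   member-id vectors), `p_share` (1; probability that an array member
#'   takes its array's cluster).
#' @param seed Integer seed (mandatory).
#' @return List: `matrix` (genes x 20, dimnames set), `truth` (data
#'   frame `gene_id`, `cluster`).
#' @export
generate_expression <- function(config = list(), seed) {
  if (missing(seed) || is.null(seed)) stop_format("an explicit seed is required")
  cfg <- utils::modifyList(list(
    n_genes = 100L, k = 5L, noise_sd = 0.5, amplitude = 2,
    baseline_range = c(6, 12), gene_ids = NULL, arrays = NULL, p_share = 1),
    config)
  with_seed(seed, {
    gene_ids <- cfg$gene_ids %||% sprintf("GENE_%04d", seq_len(cfg$n_genes))
    n <- length(gene_ids)
    cl <- sample.int(cfg$k, n, replace = TRUE)
    names(cl) <- gene_ids
    if (!is.null(cfg$arrays)) {
      for (members in cfg$arrays) {
        members <- intersect(members, gene_ids)
        if (!length(members)) next
        shared <- sample.int(cfg$k, 1L)
        take <- runif(length(members)) < cfg$p_share
        cl[members[take]] <- shared
      }
    }
    shapes <- cluster_shapes(cfg$k)
    X <- t(vapply(seq_len(n), function(i) {
      runif(1, cfg$baseline_range[1], cfg$baseline_range[2]) +
        cfg$amplitude * shapes[cl[i], ] +
        rnorm(20L, sd = cfg$noise_sd)
    }, numeric(20L)))
    dimnames(X) <- list(gene_ids, canonical_conditions())
    list(matrix = X,
         truth = data.frame(gene_id = gene_ids, cluster = unname(cl),
                            stringsAsFactors = FALSE))
  })
}

mutate_seq <- function(seq, rate, alphabet = AA20, mutable = NULL) {
  ch <- strsplit(seq, "", fixed = TRUE)[[1L]]
  idx <- which(if (is.null(mutable)) rep(TRUE, length(ch)) else mutable)
  hit <- idx[runif(length(idx)) < rate]
  for (i in hit) ch[i] <- sample(setdiff(alphabet, ch[i]), 1L)
  paste(ch, collapse = "")
}

#' Generate a reference-anchored subtype classification fixture
#'
#' Builds one random centroid sequence per subtype, then derives
#' references and candidates as independently mutated copies, so
#' within-subtype similarity is high and between-subtype similarity is
#' at the random-sequence level. Truth is the generating subtype.
#'
#' @param config List overriding defaults: `seq_len` (200),
#'   `ref_counts` (H 6, J 1, L 6), `n_candidates_per_subtype` (20),
#'   `ref_mut_rate` (0.10), `cand_mut_rate` (0.15).
#' @param seed Integer seed (mandatory).
#' @return List: `refs` ([reference_set()]), `candidates`
#'   ([protein_records()]), `truth` (named subtype vector per
#'   candidate).
#' @export
generate_classification_fixture <- function(config = list(), seed) {
  if (missing(seed) || is.null(seed)) stop_format("an explicit seed is required")
  cfg <- utils::modifyList(list(
    seq_len = 200L, ref_counts = c(H = 6L, J = 1L, L = 6L),
    n_candidates_per_subtype = 20L, ref_mut_rate = 0.10,
    cand_mut_rate = 0.15), config)
  with_seed(seed, {
    subtypes <- names(cfg$ref_counts)
    centroids <- stats::setNames(vapply(subtypes, function(s)
      paste(sample(AA20, cfg$seq_len, replace = TRUE), collapse = ""), ""),
      subtypes)
    rid <- character(); rseq <- character(); rlab <- character()
    for (s in subtypes) {
      for (i in seq_len(cfg$ref_counts[[s]])) {
        rid <- c(rid, sprintf("REF_%s%d", s, i))
        rseq <- c(rseq, mutate_seq(centroids[[s]], cfg$ref_mut_rate))
        rlab <- c(rlab, s)
      }
    }
    refs <- reference_set(protein_records(rid, rseq),
                          stats::setNames(rlab, rid))
    cid <- character(); cseq <- character(); ctruth <- character()
    for (s in subtypes) {
      for (i in seq_len(cfg$n_candidates_per_subtype)) {
        cid <- c(cid, sprintf("CAND_%s_%02d", s, i))
        cseq <- c(cseq, mutate_seq(centroids[[s]], cfg$cand_mut_rate))
        ctruth <- c(ctruth, s)
      }
    }
    list(refs = refs, candidates = protein_records(cid, cseq),
         truth = stats::setNames(ctruth, cid))
  })
}

#' Synthetic stand-in for the 13 labelled reference Ser proteins
#'
#' The published reference panel (six subtype-H, one subtype-J and six
#' subtype-L proteins) cannot be redistributed, so this builds a
#' SYNTHETIC panel with the same composition and anatomy: per subtype a
#' centroid Ser-like body (8, 10 or 6 cysteines per block for H, J, L),
#' with each reference a mutated copy whose cysteine skeleton and GPI
#' signal are preserved. Every member passes the cysteine-pattern screen
#' and decomposes to its subtype's cysteine count.
#'
#' @param seed Integer seed.
#' @return A [reference_set()] of 13 synthetic references.
#' @export
synthetic_reference_set <- function(seed = 1L) {
  specs <- default_subtype_specs()
  counts <- c(H = 6L, J = 1L, L = 6L)
  with_seed(seed, {
    ids <- character(); seqs <- character(); labs <- character()
    for (s in names(counts)) {
      centroid <- generate_ser_protein(specs[[s]], seed = NULL,
                                       id = sprintf("CENT_%s", s))
      cseq <- centroid$record$sequence
      ch <- strsplit(cseq, "", fixed = TRUE)[[1L]]
      # mutable: non-cysteine body positions, signal (last 21) untouched
      mutable <- ch != "C"
      mutable[(length(ch) - 20L):length(ch)] <- FALSE
      for (i in seq_len(counts[[s]])) {
        ids <- c(ids, sprintf("SYNREF_%s%d", s, i))
        seqs <- c(seqs, mutate_seq(cseq, 0.10, alphabet = AA19,
                                   mutable = mutable))
        labs <- c(labs, s)
      }
    }
    reference_set(protein_records(ids, seqs,
                                  description = "synthetic reference (stand-in)"),
                  stats::setNames(labs, ids))
  })
}
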