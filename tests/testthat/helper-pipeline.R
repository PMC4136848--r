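write_pipeline_fixture <- function(dir, seed = 4, n_ser = 12) {
  pr <- generate_proteome(list(n_ser = n_ser, n_decoy_no_gpi = 8,
                               n_decoy_no_pattern = 8, n_background = 15),
                          seed = seed)
  write_fasta(pr$records, file.path(dir, "prot.fasta"))
  refs <- synthetic_reference_set(seed = 1)
  write_fasta(refs$records, file.path(dir, "refs.fasta"))
  writeLines(sprintf("%s\t%s", names(refs$labels), refs$labels),
             file.path(dir, "labels.tsv"))
  ser <- pr$truth$id[pr$truth$class == "ser"]
  gl <- generate_genome_layout(list(n_scaffolds = 2, n_singletons = 2,
                                    array_size_range = c(3, 4),
                                    candidate_ids = ser), seed = seed + 1)
  write_loci(gl$loci, file.path(dir, "loci.gff3"))
  ex <- generate_expression(list(gene_ids = ser, k = 3), seed = seed + 2)
  write_expression(ex$matrix, file.path(dir, "expr.tsv"))
  list(proteome = pr, layout = gl, expression = ex, ser = ser)
}

make_config <- function(dir, outdir, seed = 7) {
  pipeline_config(
    fasta = file.path(dir, "prot.fasta"), outdir = outdir, seed = seed,
    loci = file.path(dir, "loci.gff3"),
    expression = file.path(dir, "expr.tsv"),
    reference_fasta = file.path(dir, "refs.fasta"),
    reference_labels = file.path(dir, "labels.tsv"),
    classify = list(n_replicates = 20), cluster = list(k = 3))
}
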