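test_that("read_fasta normalizes case, strips gaps/stops, reports lines", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "acdef"), f)
  rec <- read_fasta(f)
  expect_equal(rec$id, "a")
  expect_equal(rec$sequence, "ACDEF")

  writeLines(c(">a desc here", "ACD-EF*"), f)
  expect_warning(rec <- read_fasta(f), "gap/stop")
  expect_equal(rec$sequence, "ACDEF")
  expect_equal(rec$description, "desc here")

  writeLines(character(), f)
  expect_equal(nrow(read_fasta(f)), 0L)

  writeLines(c(">a", "ACD", ">b"), f)
  expect_error(read_fasta(f), "empty sequence.*line 3")
  writeLines(c("ACD", ">b", "DEF"), f)
  expect_error(read_fasta(f), "line 1")
})

test_that("fasta write/read round-trips random records", {
  withr::local_seed(42)
  f <- withr::local_tempfile(fileext = ".fasta")
  recs <- protein_records(sprintf("p%02d", 1:50),
                          vapply(1:50, function(i)
                            random_protein(sample(10:300, 1)), ""),
                          description = sample(c("", "some text"), 50, TRUE))
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(back, recs)
})

test_that("protein_records enforces invariants and maps odd letters to X", {
  expect_error(protein_records(c("a", "a"), c("ACD", "ACD")), "duplicate")
  expect_error(protein_records("a", "AC D"), "whitespace")
  expect_error(protein_records("a", ""), "empty")
  expect_warning(rec <- protein_records("a", "ACDUZ"), "mapped to X")
  expect_equal(rec$sequence, "ACDXX")
})

test_that("read_loci normalizes GFF3 and BED to 0-based half-open, sorted", {
  g <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "scf2\tsrc\tgene\t101\t200\t.\t+\t.\tID=g2",
               "scf1\tsrc\tgene\t51\t150\t.\t-\t.\tID=g1"), g)
  loci <- read_loci(g)
  expect_equal(loci$gene_id, c("g1", "g2"))      # sorted by (scaffold, start)
  expect_equal(loci$start, c(50L, 100L))
  expect_equal(loci$end, c(150L, 200L))
  expect_equal(loci$strand, c("-", "+"))

  b <- withr::local_tempfile(fileext = ".bed")
  writeLines("scf1\t100\t200\tgx\t0\t+", b)
  lb <- read_loci(b)
  expect_equal(lb$start, 100L)
  expect_equal(lb$end, 200L)
})

test_that("loci round-trip through both formats and reject bad coordinates", {
  withr::local_seed(7)
  starts <- sort(sample.int(100000, 30))
  loci <- gene_loci(sprintf("g%02d", 1:30),
                    sample(c("s1", "s2", "s3"), 30, TRUE),
                    starts, starts + sample(100:1000, 30, TRUE),
                    sample(c("+", "-"), 30, TRUE))
  for (fmt in c("gff3", "bed")) {
    f <- withr::local_tempfile(fileext = paste0(".", fmt))
    write_loci(loci, f, format = fmt)
    back <- read_loci(f, format = fmt)
    expect_equal(back, loci, ignore_attr = TRUE)
  }
  expect_error(gene_loci("g", "s", 100, 100, "+"), "end <= start")
  expect_error(gene_loci("g", "s", 100, 200, "."), "strand")
})

test_that("read_expression enforces the canonical 20 conditions", {
  f <- withr::local_tempfile(fileext = ".tsv")
  canon <- canonical_conditions()
  x <- matrix(rnorm(40), 2, 20, dimnames = list(c("g1", "g2"), canon))
  write_expression(x, f)
  expect_equal(read_expression(f), x)            # full-precision round trip

  shuffled <- x[, sample(20)]
  write_expression(shuffled, f)
  expect_equal(read_expression(f), x[, canon])   # reordered to canonical

  colnames(shuffled)[3] <- "BAD"
  write_expression(shuffled, f)
  expect_error(read_expression(f), "unknown condition")

  bad <- x; bad[1, 4] <- NA
  write_expression(bad, f)
  expect_error(read_expression(f), "missing values")
  imp <- read_expression(f, impute_median = TRUE)
  expect_equal(imp[1, 4], median(bad[1, ], na.rm = TRUE))

  writeLines(c(paste(c("gene_id", canon), collapse = "\t"),
               paste(c("g1", rnorm(20)), collapse = "\t"),
               paste(c("g1", rnorm(20)), collapse = "\t")), f)
  expect_error(read_expression(f), "duplicate gene")
})

test_that("reference_set validates label/record consistency", {
  recs <- protein_records(c("r1", "r2"), c("ACDEF", "ACDFF"))
  rs <- reference_set(recs, c(r1 = "H", r2 = "L"))
  expect_equal(unname(rs$labels), c("H", "L"))
  expect_error(reference_set(recs, c(r3 = "H")), "unknown record")
})
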