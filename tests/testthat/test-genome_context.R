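mk_loci <- function(ids, scf, strand = "+") {
  n <- length(ids)
  starts <- seq(0L, by = 2000L, length.out = n)
  gene_loci(ids, rep_len(scf, n), starts, starts + 1000L, rep_len(strand, n))
}

test_that("adjacent candidates form one array; gaps beyond the limit split", {
  loci <- mk_loci(c("c1", "c2", "c3"), "s1")
  arr <- detect_tandem_arrays(loci, c("c1", "c2", "c3"))
  expect_equal(nrow(arr), 1L)
  expect_equal(arr$member_ids[[1]], c("c1", "c2", "c3"))
  expect_equal(arr$n_intervening, 0L)

  # two candidates separated by 2 fillers with max_intervening = 1: no array
  loci2 <- mk_loci(c("c1", "f1", "f2", "c2"), "s1")
  expect_equal(nrow(detect_tandem_arrays(loci2, c("c1", "c2"))), 0L)
  # but a single interspersed filler is tolerated and counted
  loci3 <- mk_loci(c("c1", "f1", "c2"), "s1")
  arr3 <- detect_tandem_arrays(loci3, c("c1", "c2"))
  expect_equal(arr3$n_members, 2L)
  expect_equal(arr3$n_intervening, 1L)

  expect_error(detect_tandem_arrays(loci, c("c1", "ghost")), "no locus")
})

test_that("orientation consistency reflects member strands", {
  loci <- mk_loci(c("c1", "c2", "c3"), "s1", strand = c("+", "+", "-"))
  arr <- detect_tandem_arrays(loci, c("c1", "c2", "c3"))
  expect_false(arr$orientation_consistent)
  loci2 <- mk_loci(c("c1", "c2"), "s1", strand = "-")
  expect_true(detect_tandem_arrays(loci2, c("c1", "c2"))$orientation_consistent)
})

test_that("array membership is invariant to coordinate translation", {
  loci <- mk_loci(c("f0", "c1", "c2", "f1", "c3"), "s1")
  shifted <- loci
  shifted$start <- shifted$start + 123456L
  shifted$end <- shifted$end + 123456L
  a1 <- detect_tandem_arrays(loci, c("c1", "c2", "c3"))
  a2 <- detect_tandem_arrays(shifted, c("c1", "c2", "c3"))
  expect_equal(a1$member_ids, a2$member_ids)
})

test_that("planted layouts are recovered exactly and partition candidates", {
  for (seed in c(2, 19, 71)) {
    gl <- generate_genome_layout(list(n_scaffolds = 4, arrays_per_scaffold = 2,
                                      n_singletons = 3, antisense_rate = 0.1),
                                 seed = seed)
    arr <- detect_tandem_arrays(gl$loci, gl$truth$candidate_ids)
    expect_equal(nrow(arr), length(gl$truth$arrays))
    got <- lapply(arr$member_ids, identity)
    planted <- lapply(gl$truth$arrays, `[[`, "member_ids")
    expect_setequal(vapply(got, paste, "", collapse = ","),
                    vapply(planted, paste, "", collapse = ","))
    # members + singletons partition the candidate set
    members <- unlist(arr$member_ids)
    singles <- setdiff(gl$truth$candidate_ids, members)
    expect_setequal(singles, gl$truth$singletons)
    expect_equal(length(members) + length(singles),
                 length(gl$truth$candidate_ids))
  }
  # zero rates mean gap-free, orientation-consistent arrays
  gl0 <- generate_genome_layout(list(intervening_rate = 0, antisense_rate = 0),
                                seed = 3)
  arr0 <- detect_tandem_arrays(gl0$loci, gl0$truth$candidate_ids)
  expect_true(all(arr0$n_intervening == 0L))
  expect_true(all(arr0$orientation_consistent))
})

test_that("tandem_summary reports fractions, purity and orientation", {
  loci <- mk_loci(c("c1", "c2", "x1", "x2", "c3"), "s1")
  arr <- detect_tandem_arrays(loci, c("c1", "c2", "c3"))
  s <- tandem_summary(arr, c("c1", "c2", "c3"), loci = loci)
  expect_equal(s$n_in_arrays, 2L)
  expect_equal(s$tandem_fraction, 2 / 3)
  expect_equal(s$n_scaffolds_with_candidates, 1L)

  empty <- detect_tandem_arrays(mk_loci("c1", "s1"), "c1")
  expect_equal(tandem_summary(empty, "c1")$tandem_fraction, 0)

  asg <- data.frame(candidate_id = c("c1", "c2"), subtype = c("H", "H"),
                    support = c(90, 85))
  s2 <- tandem_summary(arr, c("c1", "c2", "c3"), assignments = asg)
  expect_true(s2$array_homogeneity$pure)
  asg$subtype[2] <- "L"
  s3 <- tandem_summary(arr, c("c1", "c2", "c3"), assignments = asg)
  expect_false(s3$array_homogeneity$pure)
})

test_that("planted 86/100 tandem fraction is reported exactly", {
  # 86 candidates in arrays + 14 singletons, by construction
  gl <- generate_genome_layout(
    list(n_scaffolds = 2, arrays_per_scaffold = 1,
         array_size_range = c(43, 43), n_singletons = 14,
         intervening_rate = 0), seed = 9)
  arr <- detect_tandem_arrays(gl$loci, gl$truth$candidate_ids)
  s <- tandem_summary(arr, gl$truth$candidate_ids)
  expect_equal(s$tandem_fraction, 0.86)
})
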