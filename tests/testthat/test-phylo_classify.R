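test_that("align_msa basics: identical pairs, short gap case, equal widths", {
  two <- protein_records(c("a", "b"), c("ACDEFGHIKL", "ACDEFGHIKL"))
  msa <- align_msa(two)
  expect_equal(unname(msa), c("ACDEFGHIKL", "ACDEFGHIKL"))   # zero gaps

  # one-gap case, checked against Biostrings as the independent oracle
  pair <- protein_records(c("a", "b"), c("ACDE", "ACE"))
  msa2 <- align_msa(pair)
  expect_equal(unique(nchar(msa2)), 4L)
  expect_equal(sum(strsplit(msa2[["b"]], "")[[1]] == "-"), 1L)
  # independent oracle: Biostrings global alignment of the same pair
  ora <- Biostrings::pairwiseAlignment(
    Biostrings::AAString("ACDE"), Biostrings::AAString("ACE"),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.2,
    type = "global")
  expect_equal(msa2[["a"]], as.character(Biostrings::alignedPattern(ora)))
  expect_equal(msa2[["b"]], as.character(Biostrings::alignedSubject(ora)))
  expect_error(align_msa(pair[1, ]), ">= 2")
})

test_that("aligned rows always have equal length (property)", {
  withr::local_seed(19)
  for (i in 1:10) {
    n <- sample(3:8, 1)
    recs <- protein_records(sprintf("s%d", 1:n),
                            vapply(1:n, function(j)
                              random_protein(sample(30:120, 1), 0.05), ""))
    msa <- align_msa(recs)
    expect_equal(length(unique(nchar(msa))), 1L)
    expect_setequal(names(msa), recs$id)
    # ungapped content preserved
    for (id in recs$id) {
      expect_equal(gsub("-", "", msa[[id]]),
                   recs$sequence[recs$id == id])
    }
  }
})

test_that("overlong sequences are excluded with a warning", {
  recs <- protein_records(c("a", "b", "c", "huge"),
                          c(random_protein(100), random_protein(100),
                            random_protein(100), random_protein(900)))
  expect_warning(msa <- align_msa(recs), "huge")
  expect_setequal(names(msa), c("a", "b", "c"))
})

test_that("distance_matrix: p and poisson models", {
  msa <- c(x = "AAAAAAAAAA", y = "AAAAACCCCC", z = "AAAAAAAAAA")
  D <- distance_matrix(msa)
  expect_equal(D["x", "z"], 0)
  expect_equal(D["x", "y"], 0.5)                 # 5 of 10 shared columns differ
  Dp <- distance_matrix(msa, model = "poisson")
  expect_equal(Dp["x", "y"], -log(0.5))          # closed form
  expect_error(distance_matrix(c(a = "A--", b = "-CC")), "no shared")
})

test_that("nj_tree: closed-form 3-taxon branch lengths", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(D)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(bl[c("a", "b", "c")], c(a = 1, b = 2, c = 3))
  expect_error(nj_tree(D[1:2, 1:2]), ">= 3")
})

test_that("nj recovers random additive trees exactly (RF = 0)", {
  withr::local_seed(47)
  for (i in 1:100) {
    case <- random_additive_case(sample(4:8, 1))
    tr <- nj_tree(case$D)
    expect_equal(phangorn::RF.dist(tr, case$tree), 0,
                 label = sprintf("trial %d", i))
  }
})

test_that("nj topology is invariant to taxon input order", {
  withr::local_seed(8)
  case <- random_additive_case(7)
  perm <- sample(rownames(case$D))
  t1 <- nj_tree(case$D)
  t2 <- nj_tree(case$D[perm, perm])
  expect_equal(phangorn::RF.dist(t1, t2), 0)
})

test_that("bootstrap: saturated signal gives 100%, fixed seed reproduces", {
  # 100 identical copies of one informative column pattern
  pat <- c(a = "A", b = "A", c = "C", d = "C", e = "G", f = "G")
  msa <- vapply(pat, function(ch) strrep(ch, 100), "")
  # add a second informative site so taxa are not identical within groups
  msa <- paste0(msa, c("A", "T", "A", "T", "A", "T"))
  names(msa) <- names(pat)
  tr <- bootstrap_supports(msa, n_replicates = 50, seed = 5)
  sup <- suppressWarnings(as.numeric(tr$node.label))
  expect_true(all(sup[!is.na(sup)] == 100))

  tr2 <- bootstrap_supports(msa, n_replicates = 50, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
  expect_error(bootstrap_supports(msa, n_replicates = 0, seed = 1), ">= 1")
})

test_that("two diverged planted groups get strong support", {
  withr::local_seed(21)
  g1 <- random_protein(150, 0.05)
  g2 <- paste(sample(strsplit(random_protein(150, 0.05), "")[[1]]), collapse = "")
  mut <- function(s, rate = 0.05) {
    ch <- strsplit(s, "")[[1]]
    idx <- which(runif(length(ch)) < rate)
    for (i in idx) ch[i] <- sample(setdiff(AA20_T, ch[i]), 1)
    paste(ch, collapse = "")
  }
  msa <- c(a1 = mut(g1), a2 = mut(g1), a3 = mut(g1), a4 = mut(g1),
           b1 = mut(g2), b2 = mut(g2), b3 = mut(g2), b4 = mut(g2))
  tr <- bootstrap_supports(msa, n_replicates = 100, seed = 2)
  # the a|b bipartition must exist with support >= 95
  nt <- length(tr$tip.label)
  desc <- phangorn::Descendants(tr, (nt + 1):(nt + tr$Nnode), "tips")
  found <- FALSE
  for (k in seq_along(desc)) {
    tips <- sort(tr$tip.label[desc[[k]]])
    if (identical(tips, c("a1", "a2", "a3", "a4")) ||
        identical(tips, c("b1", "b2", "b3", "b4"))) {
      sup <- suppressWarnings(as.numeric(tr$node.label[k]))
      if (!is.na(sup)) {
        found <- TRUE
        expect_gte(sup, 95)
      }
    }
  }
  expect_true(found)
})

test_that("assign_subtypes: pure clade, mixed clade, starred and support gates", {
  # hand-built tree: ((cand1,(H1,H2))hi, ((L1,L2),(J1,J2)), out)
  txt <- "((cand1:1,(H1:1,H2:1)90:1)80:1,((L1:1,L2:1)95:1,(J1:1,J2:1)99:1)70:1,out:9);"
  tr <- ape::read.tree(text = txt)
  refs <- c(H1 = "H", H2 = "H", L1 = "L", L2 = "L", J1 = "J", J2 = "J")
  as <- assign_subtypes(tr, refs, min_support = 40)
  a <- setNames(as$subtype, as$candidate_id)
  expect_equal(a[["cand1"]], "H")
  # 'out' attaches at the root: mixed references, no supported pure edge
  expect_equal(a[["out"]], "unclassified")
  expect_error(assign_subtypes(tr, c(MISSING = "H")), "absent")
})

test_that("starred subtypes require a supported pure sister clade", {
  # candidate-only clade sister to the pure J reference clade; the edge
  # joining them is below the support gate, so the plain rule cannot fire
  txt <- "(((c1:1,c2:1)88:1,(J1:1,J2:1)91:1)35:1,((H1:1,H2:1)97:2,(L1:1,L2:1)96:2)85:1);"
  tr <- ape::read.tree(text = txt)
  refs <- c(J1 = "J", J2 = "J", H1 = "H", H2 = "H", L1 = "L", L2 = "L")
  as <- assign_subtypes(tr, refs, min_support = 40)
  a <- setNames(as$subtype, as$candidate_id)
  expect_equal(unname(a[c("c1", "c2")]), c("J*", "J*"))
  sup <- setNames(as$support, as$candidate_id)
  expect_equal(unname(sup[c("c1", "c2")]), c(91, 91))
  # raising the gate above the sister support forbids the starred call
  as2 <- assign_subtypes(tr, refs, min_support = 92)
  a2 <- setNames(as2$subtype, as2$candidate_id)
  expect_equal(unname(a2[c("c1", "c2")]), c("unclassified", "unclassified"))
})

test_that("synthetic 3-subtype dataset is assigned correctly", {
  fx <- generate_classification_fixture(
    list(n_candidates_per_subtype = 8, seq_len = 150), seed = 33)
  pool <- rbind(fx$candidates, fx$refs$records)
  msa <- align_msa(pool)
  tr <- bootstrap_supports(msa, n_replicates = 50, seed = 17)
  as <- assign_subtypes(tr, fx$refs, min_support = 40)
  acc <- mean(as$subtype[match(names(fx$truth), as$candidate_id)] == fx$truth)
  expect_gte(acc, 0.95)
})
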