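test_that("pearson_distance matches the closed form and rejects constants", {
  x <- c(1, 2, 3); y <- c(1, 2, 4)
  expect_equal(pearson_distance(x, x), 0)
  expect_equal(pearson_distance(x, -x), 2)
  expect_equal(pearson_distance(x, y), 1 - cor(x, y))
  expect_equal(round(pearson_distance(x, y), 4), 0.018)
  expect_error(pearson_distance(c(1, 1, 1), y), "constant")
})

test_that("pearson_distance is invariant to positive affine transforms", {
  withr::local_seed(15)
  for (i in 1:20) {
    x <- rnorm(20); y <- rnorm(20)
    a <- runif(1, 0.1, 5); b <- rnorm(1)
    expect_equal(pearson_distance(a * x + b, y), pearson_distance(x, y))
  }
})

test_that("kmeans_pearson degenerate ks behave as specified", {
  withr::local_seed(4)
  X <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("g%02d", 1:10), canonical_conditions()))
  one <- kmeans_pearson(X, k = 1, seed = 1)
  expect_equal(unname(unique(one$assignments)), 1L)
  all_own <- kmeans_pearson(X, k = 10, seed = 1)
  expect_equal(sort(unname(all_own$assignments)), 1:10)
  expect_equal(all_own$inertia, 0, tolerance = 1e-12)
  expect_error(kmeans_pearson(X, k = 11, seed = 1), "exceeds")
})

test_that("constant profiles are dropped with a warning", {
  X <- matrix(rnorm(5 * 20), 5, 20,
              dimnames = list(sprintf("g%d", 1:5), canonical_conditions()))
  X[3, ] <- 7
  expect_warning(cl <- kmeans_pearson(X, k = 2, seed = 1), "constant")
  expect_equal(cl$dropped, "g3")
  expect_false("g3" %in% names(cl$assignments))
})

test_that("planted clusters are recovered (ARI) and runs are deterministic", {
  ex <- generate_expression(list(n_genes = 100, k = 5, noise_sd = 0.5), seed = 6)
  cl1 <- kmeans_pearson(ex$matrix, k = 5, seed = 10)
  cl2 <- kmeans_pearson(ex$matrix, k = 5, seed = 10)
  expect_identical(cl1$assignments, cl2$assignments)   # bitwise under fixed seed
  ari <- adjusted_rand_index(cl1$assignments[ex$truth$gene_id], ex$truth$cluster)
  expect_gte(ari, 0.9)
  # noise-free case separates perfectly
  ex0 <- generate_expression(list(n_genes = 60, k = 4, noise_sd = 0), seed = 6)
  cl0 <- kmeans_pearson(ex0$matrix, k = 4, seed = 2)
  expect_equal(adjusted_rand_index(cl0$assignments[ex0$truth$gene_id],
                                   ex0$truth$cluster), 1)
})

test_that("inertia traces are non-increasing in every restart", {
  ex <- generate_expression(list(n_genes = 80, k = 4, noise_sd = 1.5), seed = 8)
  cl <- kmeans_pearson(ex$matrix, k = 4, seed = 3, restarts = 8)
  for (tr in cl$inertia_trace) {
    expect_true(all(diff(tr) <= 1e-9))
  }
  # best-of-restarts is no worse than any single run's final inertia
  finals <- vapply(cl$inertia_trace, function(tr) tr[length(tr)], 0)
  expect_lte(cl$inertia, min(finals) + 1e-9)
})

test_that("median_center subtracts row medians and is idempotent", {
  X <- rbind(c(1, 2, 9), c(5, 5, 5))
  out <- median_center(X)
  expect_equal(out[1, ], c(-1, 0, 7))
  expect_equal(out[2, ], c(0, 0, 0))
  expect_equal(median_center(out), out)
})

test_that("cluster/array concordance finds planted co-expression", {
  arrays_list <- list(sprintf("GENE_%04d", 1:13), sprintf("GENE_%04d", 14:19))
  ex <- generate_expression(list(n_genes = 60, k = 5, noise_sd = 0.3,
                                 arrays = arrays_list, p_share = 1), seed = 12)
  cl <- kmeans_pearson(ex$matrix, k = 5, seed = 5)
  arr <- data.frame(array_id = c("a1", "a2"), scaffold_id = c("s1", "s2"),
                    n_members = c(13L, 6L), n_intervening = 0L,
                    orientation_consistent = TRUE,
                    member_ids = I(arrays_list),
                    strands = I(list(rep("+", 13), rep("+", 6))))
  class(arr) <- c("tandem_arrays", "data.frame")
  conc <- cluster_array_concordance(cl, arr)
  expect_equal(conc$largest_same_cluster, c(13L, 6L))

  # planted assignment scores higher than a random permutation (sanity)
  withr::local_seed(1)
  rand <- cl
  rand$assignments <- setNames(sample(cl$assignments), names(cl$assignments))
  conc_rand <- cluster_array_concordance(rand, arr)
  expect_gt(sum(conc$largest_same_cluster), sum(conc_rand$largest_same_cluster))
})

test_that("a 10-of-13 planted co-expression subset is reported as 10", {
  # array of 13 whose first 10 members share a cluster by construction
  withr::local_seed(44)
  shapes_k <- 5
  ex <- generate_expression(list(n_genes = 40, k = shapes_k, noise_sd = 0.1),
                            seed = 25)
  X <- ex$matrix
  ids <- rownames(X)[1:13]
  truth_cl <- ex$truth$cluster[match(rownames(X), ex$truth$gene_id)]
  # force members 1..10 onto cluster shape 1 and 11..13 onto shapes 2..4
  base <- generate_expression(list(n_genes = 13, k = 5, noise_sd = 0.1,
                                   gene_ids = ids,
                                   arrays = list(ids[1:10]), p_share = 1),
                              seed = 31)
  X[ids, ] <- base$matrix
  cl <- kmeans_pearson(X, k = 5, seed = 7)
  arr <- data.frame(array_id = "a", scaffold_id = "s", n_members = 13L,
                    n_intervening = 0L, orientation_consistent = TRUE,
                    member_ids = I(list(ids)), strands = I(list(rep("+", 13))))
  class(arr) <- c("tandem_arrays", "data.frame")
  conc <- cluster_array_concordance(cl, arr)
  shared <- base$truth$cluster[match(ids[1:10], base$truth$gene_id)]
  # the 10 genes planted into one cluster must be reported together
  expect_gte(conc$largest_same_cluster, 10L)
})

test_that("adjusted_rand_index behaves at the boundaries", {
  a <- rep(1:3, each = 10)
  expect_equal(adjusted_rand_index(a, a), 1)
  b <- rep(c(2, 3, 1), each = 10)                 # same partition, renamed
  expect_equal(adjusted_rand_index(a, b), 1)
  withr::local_seed(2)
  r <- sample(1:3, 30, TRUE)
  expect_lt(abs(adjusted_rand_index(a, r)), 0.35) # near zero for random
})
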