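# expression_cluster: k-means under Pearson correlation distance.
#
# Profiles are row-standardized internally (centered, unit L2 norm), where
# 1 - r(x, y) equals 1 - <zx, zy>. Iteration is spherical k-means:
# assignment to the nearest centroid direction, update to the normalized
# mean direction (the exact minimizer of the within-cluster Pearson
# distance for a fixed assignment), which makes the inertia provably
# non-increasing at every half-step. Reported centroids are value-space
# means of member profiles.

#' Pearson correlation distance
#'
#' `d = 1 - r`, in `[0, 2]`. Errors on constant vectors (correlation is
#' undefined); the clustering entry point drops constant profiles with a
#' warning instead.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Scalar distance.
#' @export
pearson_distance <- function(x, y) {
  if (length(x) != length(y)) stop_format("profiles have different lengths")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_format("Pearson distance undefined for a constant profile")
  }
  1 - stats::cor(x, y)
}

# rows -> centered unit vectors; returns NULL rows for constant profiles
standardize_rows <- function(X) {
  ctr <- X - rowMeans(X)
  nrm <- sqrt(rowSums(ctr^2))
  list(Z = ctr / ifelse(nrm == 0, 1, nrm), constant = nrm == 0)
}

#' K-means clustering with Pearson distance
#'
#' Deterministic under a fixed seed: k-means++-style seeding, assignment
#' to the minimum Pearson distance centroid, normalized-mean centroid
#' update, empty clusters repaired by seizing the point farthest from
#' its centroid, best of `restarts` runs by inertia.
#'
#' @param X Numeric genes x conditions matrix with rownames (e.g. from
#'   [read_expression()]). Constant rows are dropped with a warning.
#' @param k Number of clusters (`1 <= k <=` number of genes).
#' @param seed Integer seed (mandatory).
#' @param restarts Number of independent restarts.
#' @param max_iter Iteration cap per restart.
#' @param tol Relative inertia-improvement stop threshold.
#' @return A `cluster_result` list: `assignments` (named integer, ids
#'   `1..k` contiguous), `centroids` (k x conditions value-space means),
#'   `inertia`, `n_iter`, `inertia_trace` (list, one non-increasing
#'   numeric vector per restart), `dropped` (constant gene ids).
#' @export
kmeans_pearson <- function(X, k, seed, restarts = 10L, max_iter = 100L,
                           tol = 1e-8) {
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  if (missing(seed) || is.null(seed)) stop_format("an explicit seed is required")
  st <- standardize_rows(X)
  dropped <- rownames(X)[st$constant]
  if (length(dropped)) {
    warning(sprintf("dropped %d constant expression profile(s): %s",
                    length(dropped), paste(dropped, collapse = ", ")),
            call. = FALSE)
    X <- X[!st$constant, , drop = FALSE]
  }
  Z <- standardize_rows(X)$Z
  n <- nrow(Z)
  if (k > n) stop_format("k (%d) exceeds the number of usable genes (%d)", k, n)
  if (k < 1L) stop_format("k must be >= 1")

  run_once <- function() {
    # k-means++ seeding in Pearson-distance space
    centers <- integer(k)
    centers[1L] <- sample.int(n, 1L)
    if (k > 1L) {
      d2 <- (1 - drop(Z %*% Z[centers[1L], ]))^2
      for (j in 2L:k) {
        p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        centers[j] <- sample.int(n, 1L, prob = p)
        d2 <- pmin(d2, (1 - drop(Z %*% Z[centers[j], ]))^2)
      }
    }
    C <- Z[centers, , drop = FALSE]
    trace <- numeric()
    assign <- rep(0L, n)
    for (it in seq_len(max_iter)) {
      sim <- Z %*% t(C)                      # n x k dot products
      new_assign <- max.col(sim, ties.method = "first")
      # empty-cluster repair: seize the globally worst-fit point and move
      # the centroid onto it (keeps the inertia trace non-increasing)
      for (j in which(tabulate(new_assign, k) == 0L)) {
        fit <- sim[cbind(seq_len(n), new_assign)]
        worst <- which.min(fit)
        new_assign[worst] <- j
        C[j, ] <- Z[worst, ]
        sim[worst, ] <- NA
      }
      inertia <- sum(1 - rowSums(Z * C[new_assign, , drop = FALSE]))
      trace <- c(trace, inertia)
      converged <- identical(new_assign, assign) ||
        (length(trace) > 1L &&
           trace[length(trace) - 1L] - inertia <= tol * max(1, abs(inertia)))
      assign <- new_assign
      # update: normalized mean direction per cluster
      for (j in seq_len(k)) {
        mu <- colSums(Z[assign == j, , drop = FALSE])
        nm <- sqrt(sum(mu^2))
        if (nm > 0) C[j, ] <- mu / nm        # zero mean direction: keep centroid
      }
      if (converged) break
    }
    inertia <- sum(1 - rowSums(Z * C[assign, , drop = FALSE]))
    list(assign = assign, inertia = inertia, n_iter = it, trace = trace)
  }

  best <- NULL
  traces <- vector("list", restarts)
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      res <- run_once()
      traces[[r]] <- res$trace
      if (is.null(best) || res$inertia < best$inertia) best <- res
    }
  })

  # relabel clusters 1..k by first occurrence for contiguous ids
  lev <- unique(best$assign)
  assignments <- stats::setNames(match(best$assign, lev), rownames(X))
  kk <- length(lev)
  centroids <- t(vapply(seq_len(kk), function(j)
    colMeans(X[assignments == j, , drop = FALSE]), numeric(ncol(X))))
  dimnames(centroids) <- list(as.character(seq_len(kk)), colnames(X))
  structure(list(assignments = assignments, centroids = centroids,
                 inertia = best$inertia, n_iter = best$n_iter,
                 inertia_trace = traces, k = kk, dropped = dropped),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("pearson k-means: %d genes in %d clusters, inertia %.4f (%d iterations)\n",
              length(x$assignments), x$k, x$inertia, x$n_iter))
  invisible(x)
}

#' Median-center an expression matrix
#'
#' Subtracts the row median from each gene profile. This is the display
#' transform behind above/below-median heat maps; clustering operates on
#' the raw log2 values. Idempotent.
#'
#' @param X Numeric matrix.
#' @return Matrix of the same shape.
#' @export
median_center <- function(X) {
  X - apply(X, 1L, stats::median)
}

#' Concordance between expression clusters and tandem arrays
#'
#' @param result A [kmeans_pearson()] result.
#' @param arrays A [detect_tandem_arrays()] data frame.
#' @return Data frame, one row per array: `array_id`, `scaffold_id`,
#'   `n_members`, `n_with_expression`, `largest_same_cluster`,
#'   `top_cluster`, `composition` (cluster:count, comma-joined).
#' @export
cluster_array_concordance <- function(result, arrays) {
  rows <- lapply(seq_len(nrow(arrays)), function(i) {
    ids <- intersect(arrays$member_ids[[i]], names(result$assignments))
    cl <- result$assignments[ids]
    tab <- sort(table(cl), decreasing = TRUE)
    data.frame(array_id = arrays$array_id[i],
               scaffold_id = arrays$scaffold_id[i],
               n_members = arrays$n_members[i],
               n_with_expression = length(ids),
               largest_same_cluster = if (length(tab)) as.integer(tab[1L]) else 0L,
               top_cluster = if (length(tab)) as.integer(names(tab)[1L]) else NA_integer_,
               composition = paste(sprintf("%s:%d", names(tab), as.integer(tab)),
                                   collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows) %||%
    data.frame(array_id = character(), scaffold_id = character(),
               n_members = integer(), n_with_expression = integer(),
               largest_same_cluster = integer(), top_cluster = integer(),
               composition = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 for identical partitions, approximately 0 for independent ones.
#'
#' @param a,b Vectors of cluster labels (same length, same item order).
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
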