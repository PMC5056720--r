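test_that("kernel extraction intersects targets with DE genes", {
  repo <- interaction_repository(tibble::tibble(
    tf = "T", tg = c("B", "C", "D", "E"), species = "human",
    rank = c(1L, 1L, 1L, 2L)
  ))
  k <- extract_kernel(repo, "T", c("C", "D", "E", "Q"))
  expect_equal(k$members, c("C", "D"))
  expect_equal(k$rank_used, 1L)
  # widening the rank can only grow the kernel
  k2 <- extract_kernel(repo, "T", c("C", "D", "E", "Q"), rank = 2)
  expect_true(all(k$members %in% k2$members))
  expect_true("E" %in% k2$members)
  expect_warning(extract_kernel(repo, "T", c("Q", "R")), "empty kernel")
  expect_warning(expect_warning(extract_kernel(repo, "ZZ", "C"), "empty kernel"),
                 "not found")
})

test_that("the correlation threshold inverts the one-sided t-test p-value", {
  # approaches 1 as alpha -> 0
  expect_gt(lambda_for_pvalue(1e-12, 10), 0.999)
  # decreases with more conditions at fixed alpha
  l <- vapply(c(5, 10, 20, 50), function(n) lambda_for_pvalue(0.01, n), 0)
  expect_true(all(diff(l) < 0))
  # matches bisection against the t CDF
  for (n in c(6, 10, 20)) {
    for (a in c(0.01, 0.05)) {
      expect_equal(lambda_for_pvalue(a, n), oracle_lambda(a, n),
                   tolerance = 1e-9)
    }
  }
  expect_error(lambda_for_pvalue(0.01, 2), class = "tfconcord_domain_error")
})

test_that("identical profiles collapse into a single cluster", {
  X <- block_profiles(4, 1)
  cs <- cluster_kernel(X, rownames(X), cluster_params(lambda_c = 0.6))
  expect_equal(length(cs$clusters), 1)
  expect_equal(cs$clusters[[1]], rownames(X))
  expect_equal(length(cs$singletons), 0)
})

test_that("mutually uncorrelated noise yields no prevalent clusters", {
  withr::with_seed(3, {
    X <- matrix(rnorm(6 * 20), nrow = 6,
                dimnames = list(paste0("N", 1:6), NULL))
    # seed chosen so that no pairwise correlation reaches 0.6 (checked below)
    expect_true(max(cor(t(X))[upper.tri(diag(6))]) < 0.6)
    cs <- suppressWarnings(
      cluster_kernel(X, rownames(X), cluster_params(lambda_c = 0.6)))
    expect_equal(length(cs$clusters), 0)
    expect_equal(sort(cs$singletons), sort(rownames(X)))
  })
})

test_that("anti-correlated blocks split into two clusters with outliers isolated", {
  withr::with_seed(31, {
    base <- rnorm(20)
    mk <- function(sign, k) t(vapply(seq_len(k), function(i)
      sign * base + rnorm(20, sd = 0.15), numeric(20)))
    X <- rbind(mk(1, 4), mk(-1, 4), matrix(rnorm(20), 1))
    rownames(X) <- c(paste0("P", 1:4), paste0("M", 1:4), "W1")
    cs <- cluster_kernel(X, rownames(X), cluster_params(lambda_c = 0.6))
    expect_equal(length(cs$clusters), 2)
    expect_equal(cs$singletons, "W1")
    sets <- unname(lapply(cs$clusters, sort))
    expect_setequal(vapply(sets, paste, "", collapse = ","),
                    c(paste(paste0("M", 1:4), collapse = ","),
                      paste(paste0("P", 1:4), collapse = ",")))
  })
})

test_that("the prevalent/singleton split matches the exhaustive-partition oracle", {
  fixtures <- list(
    list(sizes = c(2, 2), signs = c(1, -1), extra = FALSE),
    list(sizes = c(3, 2), signs = c(1, -1), extra = FALSE),
    list(sizes = c(4, 3), signs = c(1, -1), extra = TRUE),
    list(sizes = c(3, 3), signs = c(1, 1), extra = TRUE),
    list(sizes = c(5, 2), signs = c(-1, 1), extra = FALSE)
  )
  for (f in fixtures) {
    X <- block_profiles(f$sizes, f$signs, n_cond = 10,
                        extra_orthogonal = f$extra)
    cs <- cluster_kernel(X, rownames(X), cluster_params(lambda_c = 0.6))
    oracle <- oracle_block_split(X, 0.6)
    expect_equal(unname(lapply(cs$clusters, sort)), oracle$clusters)
    expect_equal(sort(cs$singletons), oracle$singletons)
  }
})

test_that("clusters plus singletons partition the kernel exactly", {
  withr::with_seed(77, {
    for (i in 1:5) {
      n <- sample(5:12, 1)
      X <- matrix(rnorm(n * 12), nrow = n,
                  dimnames = list(sprintf("G%02d", 1:n), NULL))
      cs <- suppressWarnings(
        cluster_kernel(X, rownames(X), cluster_params(lambda_c = 0.5)))
      got <- sort(c(unlist(cs$clusters, use.names = FALSE), cs$singletons))
      expect_equal(got, sort(rownames(X)))
      expect_true(all(lengths(cs$clusters) >= 2))
      # centroids are arithmetic means of member profiles
      for (nm in names(cs$clusters)) {
        expect_equal(unname(cs$centroids[nm, ]),
                     unname(colMeans(X[cs$clusters[[nm]], , drop = FALSE])))
      }
      # no admissible merge remains at the final level
      if (length(cs$clusters) >= 2) {
        C <- cor(t(cs$centroids))
        expect_true(all(C[upper.tri(C)] < cs$lambda_final))
      }
    }
  })
})

test_that("clustering is deterministic and tolerates degenerate inputs", {
  withr::with_seed(13, {
    X <- matrix(rnorm(8 * 10), nrow = 8,
                dimnames = list(sprintf("G%02d", 1:8), NULL))
  })
  p <- cluster_params(lambda_c = 0.4)
  a <- suppressWarnings(cluster_kernel(X, rownames(X), p))
  b <- suppressWarnings(cluster_kernel(X, rownames(X), p))
  expect_identical(a$clusters, b$clusters)
  expect_identical(a$singletons, b$singletons)
  # zero-variance member demoted with a warning
  X2 <- rbind(X, FLAT = rep(1, 10))
  expect_warning(cs <- cluster_kernel(X2, rownames(X2), p), "zero-variance")
  expect_true("FLAT" %in% cs$singletons)
  # fewer than two clusterable members: everything a singleton
  X3 <- X[1, , drop = FALSE]
  expect_warning(cs3 <- cluster_kernel(X3, rownames(X3), p), "fewer than 2")
  expect_equal(cs3$singletons, rownames(X3))
  expect_equal(length(cs3$clusters), 0)
})

test_that("tidy and glance summarise a cluster set", {
  X <- block_profiles(c(3, 2), c(1, -1), extra_orthogonal = TRUE)
  cs <- cluster_kernel(X, rownames(X), cluster_params(lambda_c = 0.6))
  td <- tidy(cs)
  expect_equal(nrow(td), nrow(X))
  expect_equal(sum(td$role == "singleton"), 1)
  gl <- glance(cs)
  expect_equal(gl$n_clusters, 2L)
  expect_equal(gl$n_singletons, 1L)
  expect_equal(gl$lambda_c, 0.6)
})
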