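test_that("cluster concordance is the Pearson correlation with the centroid", {
  cent <- c(1, 3, 2, 5, 4, 6)
  expect_equal(cluster_concordance(cent, cent), 1)
  expect_equal(cluster_concordance(-cent, cent), -1)
  # centroid plus an orthogonal (mean-centred) perturbation of known size:
  # r = |c - mean(c)| / sqrt(|c - mean(c)|^2 + |o|^2) by the Pearson formula
  cc <- cent - mean(cent)
  u <- c(1, -1, -1, 1, 1, -1) * 2
  o <- u - cc * sum(u * cc) / sum(cc * cc)   # project out the centroid
  stopifnot(abs(sum(o)) < 1e-12, abs(sum(cc * o)) < 1e-12)
  prof <- cent + o
  expected <- sqrt(sum(cc^2)) / sqrt(sum(cc^2) + sum(o^2))
  expect_equal(cluster_concordance(prof, cent), expected, tolerance = 1e-12)
  expect_error(cluster_concordance(1:4, 1:5), class = "tfconcord_domain_error")
  expect_warning(z <- cluster_concordance(rep(1, 6), cent), "zero-variance")
  expect_equal(z, 0)
})

two_cluster_fixture <- function() {
  X <- block_profiles(c(3, 3), c(1, -1), n_cond = 12)
  cluster_kernel(X, rownames(X), cluster_params(lambda_c = 0.6))
}

test_that("KSC takes the maximum concordance over prevalent clusters", {
  cs <- two_cluster_fixture()
  v <- cs$centroids[1, ]
  got <- ksc(v, cs)
  expect_equal(got$score, 1)
  expect_equal(got$best_cluster, 1L)
  got2 <- ksc(-v, cs)
  expect_equal(got2$score, 1)
  expect_equal(got2$best_cluster, 2L)
  # the maximum dominates every per-cluster concordance
  withr::with_seed(2, {
    for (i in 1:10) {
      p <- rnorm(12)
      s <- ksc(p, cs)$score
      deltas <- vapply(1:2, function(l)
        cluster_concordance(p, cs$centroids[l, ]), 0)
      expect_gte(s, max(deltas) - 1e-12)
    }
  })
  empty <- suppressWarnings(cluster_kernel(
    matrix(rnorm(40), 2, 20, dimnames = list(c("A1", "A2"), NULL)),
    c("A1", "A2"), cluster_params(lambda0 = 0.999, lambda_c = 0.99)))
  if (n_clusters(empty) == 0) {
    expect_error(ksc(rnorm(20), empty), "singleton",
                 class = "tfconcord_domain_error")
  }
})

test_that("permutation nulls are reproducible from their seed", {
  withr::with_seed(8, {
    X <- matrix(rnorm(100 * 10), nrow = 100,
                dimnames = list(sprintf("G%03d", 1:100), NULL))
  })
  kernel <- sprintf("G%03d", 1:8)
  p <- cluster_params(lambda_c = 0.5)
  n1 <- suppressWarnings(permutation_null(X, kernel, p, B = 1, seed = 99))
  n2 <- suppressWarnings(permutation_null(X, kernel, p, B = 1, seed = 99))
  expect_identical(n1$scores, n2$scores)
  cs <- suppressWarnings(cluster_kernel(X, kernel, p))
  if (n_clusters(cs) > 0) {
    f1 <- permutation_null(X, B = 50, seed = 7, mode = "fixed-clusters",
                           clusters = cs)
    f2 <- permutation_null(X, B = 50, seed = 7, mode = "fixed-clusters",
                           clusters = cs)
    expect_identical(f1$scores, f2$scores)
  }
})

test_that("the fixed-clusters null mean matches an independent Monte-Carlo oracle", {
  # i.i.d. noise matrix large enough that drawing a kernel row is rare
  withr::with_seed(21, {
    X <- matrix(rnorm(1000 * 12), nrow = 1000,
                dimnames = list(sprintf("G%04d", 1:1000), NULL))
    # fixed centroids: two arbitrary smooth profiles
    cents <- rbind(sin(1:12), cos(1:12))
    cs <- structure(list(
      clusters = list(C1 = c("G0001", "G0002"), C2 = c("G0003", "G0004")),
      centroids = cents, singletons = character(),
      members = sprintf("G%04d", 1:4), lambda_c = 0.5, lambda_final = 0.5,
      params = cluster_params(lambda_c = 0.5), tf = NULL
    ), class = "cluster_set")
    null <- permutation_null(X, B = 2000, mode = "fixed-clusters",
                             clusters = cs)
    # oracle: fresh noise profiles, max of the two correlations, by hand
    oracle <- vapply(1:2000, function(i) {
      z <- rnorm(12)
      max(cor(z, cents[1, ]), cor(z, cents[2, ]))
    }, 0)
    se <- sqrt(var(null$scores) / 2000 + var(oracle) / 2000)
    expect_lt(abs(mean(null$scores) - mean(oracle)), 3 * se)
  })
})

test_that("full and fixed-clusters nulls agree marginally without structure", {
  # The fixed-clusters score distribution conditions on one clustering
  # realisation, so the comparison must marginalise the fixed side over
  # clustering realisations to be statistically well-posed.
  withr::with_seed(14, {
    X <- matrix(rnorm(400 * 12), nrow = 400,
                dimnames = list(sprintf("G%03d", 1:400), NULL))
    kernel <- sprintf("G%03d", 1:12)
    p <- cluster_params(lambda_c = lambda_for_pvalue(0.05, 12))
    full <- suppressWarnings(
      permutation_null(X, kernel, p, B = 2000, mode = "full"))
    fixed_scores <- c()
    while (length(fixed_scores) < 2000) {
      rows <- sample(nrow(X), length(kernel))
      Xk <- X[rows, , drop = FALSE]
      rownames(Xk) <- kernel
      cs <- suppressWarnings(cluster_kernel(Xk, kernel, p))
      if (n_clusters(cs) == 0) next
      nb <- permutation_null(X, B = 20, mode = "fixed-clusters",
                             clusters = cs)
      fixed_scores <- c(fixed_scores, nb$scores)
    }
    ks <- suppressWarnings(stats::ks.test(full$scores, fixed_scores[1:2000]))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("permutation p-values follow the proportion definition", {
  obs <- tibble::tibble(gene = c("hi", "mid", "lo"),
                        score = c(2, 0.5, -2), best_cluster = 1L)
  null <- structure(list(scores = seq(-1, 1, length.out = 1000), B = 1000L,
                         seed = NULL, mode = "fixed-clusters", n_redraws = 0L),
                    class = "ksc_null")
  res <- ksc_pvalues(obs, null)
  expect_equal(res$p[res$gene == "hi"], 0)       # above every null value
  expect_equal(res$p[res$gene == "lo"], 1)       # below every null value
  expect_equal(res$p[res$gene == "mid"], mean(null$scores >= 0.5))
  expect_equal(res$gene, c("hi", "mid", "lo"))   # sorted ascending by p
  resc <- ksc_pvalues(obs, null, add_one = TRUE)
  expect_equal(resc$p[resc$gene == "hi"], 1 / 1001)
  # counting by binary search equals direct counting on random data
  withr::with_seed(4, {
    ns <- rnorm(500)
    null2 <- structure(list(scores = ns, B = 500L, seed = NULL,
                            mode = "fixed-clusters", n_redraws = 0L),
                       class = "ksc_null")
    obs2 <- tibble::tibble(gene = paste0("g", 1:50),
                           score = c(rnorm(47), ns[c(3, 9, 27)]),
                           best_cluster = 1L)
    res2 <- ksc_pvalues(obs2, null2)
    direct <- vapply(res2$score, function(s) mean(ns >= s), 0)
    expect_equal(res2$p, direct)
    # p non-increasing in score
    ord <- order(res2$score)
    expect_true(all(diff(res2$p[ord]) <= 0))
  })
})

test_that("stratification reports per-bin marker density and strata correlation", {
  res <- structure(tibble::tibble(
    gene = sprintf("g%02d", 1:20),
    score = seq(1, -1, length.out = 20),
    best_cluster = 1L,
    p = seq(0.025, 0.975, length.out = 20)
  ), class = c("ksc_result", class(tibble::tibble())))
  s_all <- stratify_by_membership(res, res$gene, bin_width = 0.1)
  expect_true(all(s_all$histogram$frac_member[s_all$histogram$n > 0] == 1))
  expect_equal(sum(s_all$histogram$n), 20)
  # low-stratum profiles are the negatives of high-stratum profiles
  prof <- sin(1:8)
  expr <- rbind(matrix(rep(prof, 2), 2, byrow = TRUE),
                matrix(rep(-prof, 2), 2, byrow = TRUE))
  rownames(expr) <- c("g01", "g02", "g19", "g20")  # low pair +prof, high pair -prof
  res4 <- res[res$gene %in% rownames(expr), ]
  res4$p <- c(0.01, 0.02, 0.97, 0.99)
  s <- stratify_by_membership(res4, "g01", bin_width = 0.1, expr = expr)
  expect_equal(s$strata_correlation, -1, tolerance = 1e-12)
  expect_error(stratify_by_membership(res[0, ], "g01"),
               class = "tfconcord_domain_error")
  expect_error(stratify_by_membership(res, "g01", bin_width = 0.3),
               class = "tfconcord_domain_error")
})
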