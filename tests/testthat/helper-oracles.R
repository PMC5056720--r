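# Independent oracles used to check the implementation. These deliberately
# avoid the code paths they verify.

# Upper-tail hypergeometric by direct summation of binomial terms.
oracle_hyper_tail <- function(N, K, n, k) {
  hi <- min(n, K)
  if (k > hi) return(0)
  sum(vapply(k:hi, function(i) {
    choose(K, i) * choose(N - K, n - i)
  }, 0)) / choose(N, n)
}

# Correlation threshold for a one-sided p-value by bisection on the t CDF.
oracle_lambda <- function(alpha, n_points) {
  df <- n_points - 2
  pval <- function(r) {
    t <- r * sqrt(df / (1 - r^2))
    stats::pt(t, df, lower.tail = FALSE)
  }
  lo <- 0; hi <- 1 - 1e-12
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (pval(mid) <= alpha) hi <- mid else lo <- mid
  }
  hi
}

# AUC by brute-force over all positive/negative pairs (ties count 1/2),
# positives "win" a pair when their p-value is lower.
oracle_auc <- function(positive, negative) {
  wins <- 0
  for (p in positive) {
    for (q in negative) {
      wins <- wins + (p < q) + 0.5 * (p == q)
    }
  }
  wins / (length(positive) * length(negative))
}

# All set partitions of n elements as restricted-growth assignment vectors.
oracle_partitions <- function(n) {
  out <- list()
  recurse <- function(a, i, m) {
    if (i > n) {
      out[[length(out) + 1]] <<- a
      return(invisible())
    }
    for (v in seq_len(m + 1)) {
      a[i] <- v
      recurse(a, i + 1, max(m, v))
    }
  }
  recurse(integer(n), 1L, 0L)
  out
}

# Exhaustive prevalent/singleton split for noiseless block fixtures: among
# all partitions, keep those where every multi-member block is internally
# coherent (all pairwise correlations >= lambda_c), distinct multi-block
# centroids correlate < lambda_c, and no singleton correlates >= lambda_c
# with any multi-block centroid; prefer fewest singletons, then fewest
# blocks. Returns list(clusters = list of sorted id vectors sorted by
# size/leader, singletons = sorted ids).
oracle_block_split <- function(X, lambda_c) {
  ids <- rownames(X)
  n <- nrow(X)
  best <- NULL
  best_key <- c(Inf, Inf)
  for (a in oracle_partitions(n)) {
    blocks <- split(seq_len(n), a)
    multi <- blocks[lengths(blocks) >= 2]
    single <- unlist(blocks[lengths(blocks) == 1], use.names = FALSE)
    ok <- TRUE
    for (b in multi) {
      C <- stats::cor(t(X[b, , drop = FALSE]))
      if (any(C[upper.tri(C)] < lambda_c)) { ok <- FALSE; break }
    }
    if (ok && length(multi) >= 1) {
      cents <- do.call(rbind, lapply(multi, function(b)
        colMeans(X[b, , drop = FALSE])))
      if (length(multi) >= 2) {
        C <- stats::cor(t(cents))
        if (any(C[upper.tri(C)] >= lambda_c)) ok <- FALSE
      }
      if (ok && length(single) > 0) {
        S <- stats::cor(t(X[single, , drop = FALSE]), t(cents))
        if (any(S >= lambda_c)) ok <- FALSE
      }
    }
    if (ok) {
      key <- c(length(single), length(blocks))
      if (key[1] < best_key[1] ||
          (key[1] == best_key[1] && key[2] < best_key[2])) {
        best_key <- key
        best <- list(
          clusters = lapply(multi, function(b) sort(ids[b])),
          singletons = sort(ids[single])
        )
      }
    }
  }
  ord <- order(-lengths(best$clusters),
               vapply(best$clusters, `[[`, "", 1))
  best$clusters <- unname(best$clusters[ord])
  best
}
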