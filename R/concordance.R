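#' Cluster-based concordance of one profile with one centroid
#'
#' The signed Pearson correlation between a candidate gene's expression
#' vector and a cluster centroid. A zero-variance candidate profile yields
#' 0 with a warning (no co-expression evidence either way).
#'
#' @param profile,centroid Numeric vectors of equal length >= 3.
#' @return Correlation in `[-1, 1]`.
#' @export
cluster_concordance <- function(profile, centroid) {
  if (length(profile) != length(centroid)) {
    domain_error("profile and centroid lengths differ")
  }
  if (length(profile) < 3) domain_error("need >= 3 conditions")
  if (stats::sd(centroid) == 0) domain_error("centroid has zero variance")
  if (stats::sd(profile) == 0) {
    warn("cluster_concordance: zero-variance profile; concordance set to 0")
    return(0)
  }
  as.numeric(stats::cor(profile, centroid))
}

#' Kernel-set concordance (KSC) of one profile
#'
#' The KSC score of a gene is the maximum of its cluster-based concordances
#' over all prevalent clusters: a gene agrees with the kernel set if it is
#' highly correlated with at least one co-regulated subgroup, not
#' necessarily with the kernel average.
#'
#' @param profile Numeric expression vector.
#' @param clusters A [cluster_kernel()] result with >= 1 prevalent cluster.
#' @return List with `score` and `best_cluster` (index of the maximising
#'   cluster; ties go to the lowest index).
#' @export
ksc <- function(profile, clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (n_clusters(clusters) == 0) {
    domain_error(paste0(
      "no prevalent clusters to score against; retain singletons or ",
      "enlarge the kernel"
    ))
  }
  deltas <- vapply(seq_len(nrow(clusters$centroids)), function(l) {
    cluster_concordance(profile, clusters$centroids[l, ])
  }, 0)
  list(score = max(deltas), best_cluster = which.max(deltas))
}

#' KSC scores for many genes at once
#'
#' Vectorised [ksc()] over rows of an expression matrix.
#'
#' @param expr Expression matrix containing the genes.
#' @param genes Character vector of gene identifiers to score.
#' @param clusters A `cluster_set` with >= 1 prevalent cluster.
#' @return Tibble with columns `gene`, `score`, `best_cluster`.
#' @export
ksc_scores <- function(expr, genes, clusters) {
  stopifnot(inherits(clusters, "cluster_set"))
  if (n_clusters(clusters) == 0) {
    domain_error(paste0(
      "no prevalent clusters to score against; retain singletons or ",
      "enlarge the kernel"
    ))
  }
  expr <- as_expression_matrix(expr)
  genes <- unique(genes)
  absent <- setdiff(genes, rownames(expr))
  if (length(absent) > 0) {
    domain_error(paste0("gene(s) missing from expression matrix: ",
                        paste(head(absent, 5), collapse = ", ")))
  }
  S <- suppressWarnings(row_cor(expr[genes, , drop = FALSE], clusters$centroids))
  if (anyNA(S)) {
    warn("ksc_scores: zero-variance profile(s); their scores set to 0")
    S[is.na(S)] <- 0
  }
  tibble(gene = genes,
         score = apply(S, 1, max),
         best_cluster = apply(S, 1, which.max))
}

#' Permutation null distribution of KSC scores
#'
#' Calibrates KSC scores under the null hypothesis that gene labels do not
#' matter, by randomly permuting the assignment of expression profiles to
#' gene identifiers across the entire matrix. In mode `"full"` (the
#' faithful procedure) every iteration re-extracts the kernel's (now
#' random) profiles, re-clusters them with the same parameters, and records
#' the KSC score of one randomly drawn non-kernel candidate gene against
#' the re-derived centroids. Mode `"fixed-clusters"` keeps the observed
#' cluster centroids and scores one randomly drawn profile per iteration —
#' a fast approximation that skips the re-clustering.
#'
#' Iterations in which the permuted kernel degenerates (no cluster of >= 2
#' members) are redrawn and counted; more than 20% redraws triggers a
#' warning.
#'
#' @param expr Expression matrix (the whole dataset, kernel included).
#' @param kernel Kernel members ([extract_kernel()] result or character);
#'   required for mode `"full"`.
#' @param params [cluster_params()] used for re-clustering (mode `"full"`).
#' @param B Number of permutation iterations (reference default 10000).
#' @param seed Optional integer seed; the null sample is reproducible from
#'   it.
#' @param mode `"full"` or `"fixed-clusters"`.
#' @param clusters Observed `cluster_set` (required for
#'   `"fixed-clusters"`).
#' @return A list of class `ksc_null`: `scores` (length `B`), `B`, `seed`,
#'   `mode`, `n_redraws`.
#' @export
permutation_null <- function(expr, kernel = NULL, params = cluster_params(),
                             B = 10000, seed = NULL,
                             mode = c("full", "fixed-clusters"),
                             clusters = NULL) {
  mode <- match.arg(mode)
  expr <- as_expression_matrix(expr)
  if (!is_scalar_number(B) || B < 1) domain_error("B must be >= 1")
  B <- as.integer(B)
  n_genes <- nrow(expr)
  scores <- numeric(B)
  n_redraws <- 0L
  if (mode == "fixed-clusters") {
    stopifnot(inherits(clusters, "cluster_set"))
    if (n_clusters(clusters) == 0) domain_error("clusters has no prevalent cluster")
    scores <- with_seed_if(seed, {
      rows <- sample.int(n_genes, B, replace = TRUE)
      S <- suppressWarnings(row_cor(expr[rows, , drop = FALSE], clusters$centroids))
      S[is.na(S)] <- 0
      if (ncol(S) == 1) as.numeric(S) else apply(S, 1, max)
    })
  } else {
    members <- if (inherits(kernel, "kernel_set")) kernel$members else
      sort(unique(norm_symbol(kernel)))
    if (length(members) < 2) domain_error("mode 'full' needs a kernel of >= 2")
    kn <- length(members)
    if (kn + 1 > n_genes) domain_error("matrix too small for the kernel")
    lambda_c <- resolve_lambda_c(params, ncol(expr))
    scores <- with_seed_if(seed, {
      out <- numeric(B)
      for (b in seq_len(B)) {
        repeat {
          rows <- sample.int(n_genes, kn + 1L)
          Xk <- expr[rows[seq_len(kn)], , drop = FALSE]
          rownames(Xk) <- members
          keep <- apply(Xk, 1, stats::sd) > 0
          if (sum(keep) >= 2) {
            res <- agglomerate_profiles(Xk[keep, , drop = FALSE],
                                        params$lambda0, params$epsilon,
                                        lambda_c)
            sizes <- lengths(res$assignment)
            if (any(sizes >= 2)) {
              cents <- do.call(rbind, lapply(
                res$assignment[sizes >= 2],
                function(m) colMeans(Xk[m, , drop = FALSE])))
              cand <- expr[rows[kn + 1L], ]
              if (stats::sd(cand) == 0) {
                out[b] <- 0
              } else {
                cc <- suppressWarnings(row_cor(matrix(cand, nrow = 1), cents))
                cc[is.na(cc)] <- 0
                out[b] <- max(cc)
              }
              break
            }
          }
          n_redraws <- n_redraws + 1L
          if (n_redraws > 100L * B) {
            domain_error("permutation null: too many degenerate redraws")
          }
        }
      }
      out
    })
    if (n_redraws > 0.2 * B) {
      warn(sprintf("permutation_null: %d redraws for %d iterations (> 20%%)",
                   n_redraws, B))
    }
  }
  structure(list(scores = scores, B = B, seed = seed, mode = mode,
                 n_redraws = n_redraws),
            class = "ksc_null")
}

#' @export
print.ksc_null <- function(x, ...) {
  cat(sprintf("<ksc_null> B = %d (%s mode), mean = %.3f, %d redraw(s)\n",
              x$B, x$mode, mean(x$scores), x$n_redraws))
  invisible(x)
}

#' Permutation p-values for observed KSC scores
#'
#' `p(g)` is the proportion of null permutation scores greater than or
#' equal to the observed score (so `p = 0` is attainable); with
#' `add_one = TRUE` the positively-biased estimator `(b + 1) / (B + 1)` is
#' used instead, guaranteeing `p > 0`. Results are sorted by ascending
#' p-value; genes passing a chosen significance level are the putative
#' targets.
#'
#' @param observed Tibble from [ksc_scores()] (columns `gene`, `score`,
#'   `best_cluster`).
#' @param null A [permutation_null()] result.
#' @param add_one Use the add-one small-sample correction?
#' @return Tibble of class `ksc_result` with an added `p` column, sorted by
#'   ascending `p` (ties by descending score, then gene).
#' @export
ksc_pvalues <- function(observed, null, add_one = FALSE) {
  stopifnot(inherits(null, "ksc_null"))
  if (length(null$scores) == 0) domain_error("null sample is empty")
  ns <- sort(null$scores)
  B <- length(ns)
  # count of null >= s via binary search on the sorted sample
  ge <- B - findInterval(observed$score, ns, left.open = TRUE)
  p <- if (add_one) (ge + 1) / (B + 1) else ge / B
  out <- observed %>%
    mutate(p = p) %>%
    arrange(.data$p, dplyr::desc(.data$score), .data$gene)
  attr(out, "B") <- B
  attr(out, "mode") <- null$mode
  attr(out, "add_one") <- add_one
  class(out) <- c("ksc_result", class(tibble()))
  out
}

#' Stratify KSC results by membership in a marker set
#'
#' Bins the scored genes by KSC p-value and reports, per bin, the count and
#' fraction of genes belonging to `member_set` (e.g. the TF's Rank-2
#' targets, used as orthogonal validation of predictions). Also compares
#' the low-p stratum (`p < alpha_low`) with the high-p stratum
#' (`p > 1 - alpha_low`): the Pearson correlation between the two strata's
#' mean expression profiles reveals whether high-p marker genes are
#' anti-regulated mirror images of the concordant ones.
#'
#' @param results A [ksc_pvalues()] tibble.
#' @param member_set Character vector of marker gene symbols.
#' @param bin_width Bin width; must divide 1 evenly (default 0.1).
#' @param expr Expression matrix for the mean-profile comparison; if
#'   `NULL` the strata correlation is reported as `NA`.
#' @param alpha_low Stratum cut-off (default 0.05, i.e. p < 0.05 vs
#'   p > 0.95).
#' @return A list of class `ksc_strata`: `histogram` (tibble `bin`, `p_lo`,
#'   `p_hi`, `n`, `n_member`, `frac_member`), `member_extreme_fraction`
#'   (share of marker genes in the first or last bin), `low_genes`,
#'   `high_genes`, `strata_correlation`, `mean_low`, `mean_high`,
#'   `alpha_low`.
#' @export
stratify_by_membership <- function(results, member_set, bin_width = 0.1,
                                   expr = NULL, alpha_low = 0.05) {
  if (nrow(results) == 0) domain_error("results must be non-empty")
  nb <- 1 / bin_width
  if (!is_scalar_number(bin_width) || abs(nb - round(nb)) > 1e-9) {
    domain_error("bin_width must divide 1 evenly")
  }
  nb <- as.integer(round(nb))
  member_set <- unique(norm_symbol(member_set))
  bin <- pmin(floor(results$p / bin_width) + 1L, nb)
  is_member <- norm_symbol(results$gene) %in% member_set
  hist <- tibble(bin = seq_len(nb),
                 p_lo = (seq_len(nb) - 1) * bin_width,
                 p_hi = seq_len(nb) * bin_width) %>%
    left_join(tibble(bin = bin, member = is_member) %>%
                group_by(.data$bin) %>%
                summarise(n = n(), n_member = sum(.data$member),
                          .groups = "drop"),
              by = "bin") %>%
    mutate(n = dplyr::coalesce(.data$n, 0L),
           n_member = dplyr::coalesce(.data$n_member, 0L),
           frac_member = ifelse(.data$n > 0, .data$n_member / .data$n, NA_real_))
  total_members <- sum(is_member)
  extreme <- if (total_members > 0) {
    sum(hist$n_member[c(1L, nb)]) / total_members
  } else {
    NA_real_
  }
  low_genes <- results$gene[results$p < alpha_low]
  high_genes <- results$gene[results$p > 1 - alpha_low]
  mean_low <- mean_high <- NULL
  strata_cor <- NA_real_
  if (!is.null(expr) && length(low_genes) > 0 && length(high_genes) > 0) {
    expr <- as_expression_matrix(expr)
    mean_low <- colMeans(expr[low_genes, , drop = FALSE])
    mean_high <- colMeans(expr[high_genes, , drop = FALSE])
    strata_cor <- as.numeric(stats::cor(mean_low, mean_high))
  } else if (length(low_genes) == 0 || length(high_genes) == 0) {
    inform("stratify_by_membership: an extreme stratum is empty; correlation undefined")
  }
  structure(list(histogram = hist, member_extreme_fraction = extreme,
                 low_genes = low_genes, high_genes = high_genes,
                 strata_correlation = strata_cor,
                 mean_low = mean_low, mean_high = mean_high,
                 alpha_low = alpha_low),
            class = "ksc_strata")
}
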