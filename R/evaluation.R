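#' Leave-one-out recovery of kernel genes
#'
#' Validates the concordance machinery on the kernel itself: each kernel
#' gene is held out, the remaining members are re-clustered, the held-out
#' gene's KSC score against the reduced cluster set is computed, and its
#' permutation p-value calibrated. A held-out gene with `p >= alpha` is a
#' false negative; `error(alpha)` is the fraction of (evaluable) kernel
#' genes not recovered at that level.
#'
#' `null_mode = "full"` recomputes a faithful permutation null (with
#' re-clustering) per held-out gene; `"fixed-clusters"` scores random
#' profiles against the reduced centroids — far faster and adequate when
#' the matrix is large relative to the kernel.
#'
#' @param expr Expression matrix containing the kernel and the background.
#' @param kernel [extract_kernel()] result or character vector (>= 4
#'   members so each reduced kernel can still cluster).
#' @param params [cluster_params()].
#' @param null_B Permutation iterations per held-out gene.
#' @param seed Optional integer seed (whole procedure reproducible).
#' @param alpha_grid Significance levels at which to report error rates.
#' @param null_mode `"fixed-clusters"` (default) or `"full"`.
#' @return A list of class `loocv_report`: `per_gene` (tibble `gene`,
#'   `score`, `p`, `evaluable`), `error_rates` (tibble `alpha`, `error`),
#'   `n_evaluable`, `null_mode`, `null_B`, `seed`.
#' @export
loocv <- function(expr, kernel, params = cluster_params(), null_B = 1000,
                  seed = NULL, alpha_grid = c(0.01, 0.05, 0.1, 0.2, 0.5),
                  null_mode = c("fixed-clusters", "full")) {
  null_mode <- match.arg(null_mode)
  expr <- as_expression_matrix(expr)
  members <- if (inherits(kernel, "kernel_set")) kernel$members else
    sort(unique(norm_symbol(kernel)))
  if (length(members) < 4) domain_error("loocv needs a kernel of >= 4 members")
  res <- with_seed_if(seed, {
    purrr::map_dfr(members, function(g) {
      reduced <- setdiff(members, g)
      cs <- suppressWarnings(cluster_kernel(expr, reduced, params))
      if (n_clusters(cs) == 0) {
        warn(paste0("loocv: reduced kernel degenerate for ", g,
                    "; gene unevaluable"))
        return(tibble(gene = g, score = NA_real_, p = NA_real_,
                      evaluable = FALSE))
      }
      sc <- ksc_scores(expr, g, cs)
      null <- if (null_mode == "full") {
        permutation_null(expr, kernel = reduced, params = params, B = null_B,
                         mode = "full")
      } else {
        permutation_null(expr, B = null_B, mode = "fixed-clusters",
                         clusters = cs)
      }
      p <- ksc_pvalues(sc, null)$p
      tibble(gene = g, score = sc$score, p = p, evaluable = TRUE)
    })
  })
  eval_p <- res$p[res$evaluable]
  errors <- tibble(alpha = alpha_grid,
                   error = vapply(alpha_grid,
                                  function(a) mean(eval_p >= a), 0))
  structure(list(per_gene = res, error_rates = errors,
                 n_evaluable = sum(res$evaluable), null_mode = null_mode,
                 null_B = null_B, seed = seed),
            class = "loocv_report")
}

#' @export
print.loocv_report <- function(x, ...) {
  cat(sprintf("<loocv_report> %d/%d kernel gene(s) evaluable (%s null, B = %d)\n",
              x$n_evaluable, nrow(x$per_gene), x$null_mode, x$null_B))
  print(x$error_rates)
  invisible(x)
}

#' Error rate of a LOOCV report at a significance level
#'
#' @param report A [loocv()] result.
#' @param alpha Significance level.
#' @return Fraction of evaluable kernel genes with `p >= alpha`.
#' @export
loocv_error <- function(report, alpha) {
  stopifnot(inherits(report, "loocv_report"))
  p <- report$per_gene$p[report$per_gene$evaluable]
  vapply(alpha, function(a) mean(p >= a), 0)
}

# AUC as the Mann-Whitney probability that a random positive has a lower
# p-value than a random negative; ties count one half.
auc_rank <- function(positive, negative) {
  np <- length(positive); nn <- length(negative)
  stopifnot(np > 0, nn > 0)
  r <- rank(c(positive, negative), ties.method = "average")
  # sum of positive ranks relates to the number of (neg < pos) pairs
  u_pos_lower <- np * nn + np * (np + 1) / 2 - sum(r[seq_len(np)])
  u_pos_lower / (np * nn)
}

#' Resampled-negative ROC AUC for KSC p-values
#'
#' Estimates how well KSC p-values separate true targets from background.
#' Positives are the kernel genes' held-out p-values (outliers removed);
#' for each of `R` resamples an equally-sized negative set is drawn without
#' replacement from the candidate pool's p-values, and the AUC is computed
#' as the normalised Mann-Whitney statistic (probability that a random
#' positive has a lower p than a random negative, ties counting one half)
#' — equivalent to the area under the ROC curve over p-value cut-offs and
#' robust to ties. Reports the mean AUC and a 95% confidence half-width
#' `1.96 * sd / sqrt(R)` over the resamples.
#'
#' @param positive_pvalues Numeric vector of positive-class p-values.
#' @param candidate_pool_pvalues Numeric vector to resample negatives from
#'   (at least as long as the positive set).
#' @param R Number of negative resamples (default 100).
#' @param seed Optional integer seed.
#' @return A list of class `auc_report`: `aucs` (length `R`), `mean_auc`,
#'   `ci_half_width` (`NA` when `R < 2`), `R`, `seed`.
#' @export
roc_auc <- function(positive_pvalues, candidate_pool_pvalues, R = 100,
                    seed = NULL) {
  positive_pvalues <- positive_pvalues[!is.na(positive_pvalues)]
  np <- length(positive_pvalues)
  if (np < 1) domain_error("no positive p-values")
  if (length(candidate_pool_pvalues) < np) {
    domain_error("candidate pool smaller than the positive set")
  }
  aucs <- with_seed_if(seed, {
    vapply(seq_len(R), function(r) {
      neg <- sample(candidate_pool_pvalues, np)
      auc_rank(positive_pvalues, neg)
    }, 0)
  })
  ci <- if (R >= 2) 1.96 * stats::sd(aucs) / sqrt(R) else NA_real_
  if (R < 2) inform("roc_auc: R < 2, confidence interval undefined")
  structure(list(aucs = aucs, mean_auc = mean(aucs), ci_half_width = ci,
                 R = R, seed = seed),
            class = "auc_report")
}

#' @export
print.auc_report <- function(x, ...) {
  cat(sprintf("<auc_report> mean AUC = %.4f +/- %.4f (R = %d)\n",
              x$mean_auc, x$ci_half_width, x$R))
  invisible(x)
}
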