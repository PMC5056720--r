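# ggplot2 autoplot methods for result objects.

#' Plot TF enrichment results
#'
#' Horizontal bars of `-log10(p)` for the top TFs, with the Bonferroni
#' significance threshold marked.
#'
#' @param object A `tf_enrichment` tibble.
#' @param n_top Number of TFs to show.
#' @param alpha Nominal significance level drawn as a reference line.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tf_enrichment <- function(object, n_top = 20, alpha = 0.01, ...) {
  d <- head(as_tibble(object), n_top) %>%
    mutate(tf = stats::reorder(.data$tf, -.data$p),
           neglogp = -log10(pmax(.data$p, 1e-300)))
  ggplot(d, aes(x = .data$tf, y = .data$neglogp)) +
    geom_col(fill = "steelblue") +
    geom_hline(yintercept = -log10(alpha), linetype = "dashed") +
    coord_flip() +
    labs(x = NULL, y = expression(-log[10](p)),
         title = "TF target over-representation") +
    theme_minimal()
}

#' Plot a clustered kernel set
#'
#' Centroid profiles per prevalent cluster; with `expr` supplied, member
#' profiles are drawn underneath and singleton profiles shown in grey.
#'
#' @param object A `cluster_set`.
#' @param expr Optional expression matrix with the member profiles.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cluster_set <- function(object, expr = NULL, ...) {
  conds <- colnames(object$centroids)
  cent <- purrr::imap_dfr(object$clusters, function(m, nm) {
    tibble(cluster = nm, condition = factor(conds, levels = conds),
           value = object$centroids[nm, ], gene = paste0("centroid_", nm),
           role = "centroid")
  })
  layers <- cent
  if (!is.null(expr)) {
    expr <- as_expression_matrix(expr)
    mem <- purrr::imap_dfr(object$clusters, function(m, nm) {
      purrr::map_dfr(m, function(g)
        tibble(cluster = nm, condition = factor(conds, levels = conds),
               value = expr[g, ], gene = g, role = "member"))
    })
    sing <- purrr::map_dfr(object$singletons, function(g)
      tibble(cluster = "singletons", condition = factor(conds, levels = conds),
             value = expr[g, ], gene = g, role = "singleton"))
    layers <- bind_rows(mem, sing, cent)
  }
  ggplot(layers, aes(x = .data$condition, y = .data$value,
                     group = .data$gene)) +
    geom_line(data = ~ filter(.x, .data$role != "centroid"),
              colour = "grey60", linewidth = 0.3) +
    geom_line(data = ~ filter(.x, .data$role == "centroid"),
              aes(colour = .data$cluster), linewidth = 1) +
    facet_wrap(~cluster) +
    labs(x = "condition", y = "expression",
         title = "Kernel-set clusters and centroids") +
    theme_minimal() +
    theme(axis.text.x = element_blank(), legend.position = "none")
}

#' Plot the KSC p-value distribution
#'
#' @param object A `ksc_result` tibble.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ksc_result <- function(object, bins = 20, ...) {
  ggplot(as_tibble(object), aes(x = .data$p)) +
    geom_histogram(bins = bins, boundary = 0, fill = "steelblue",
                   colour = "white") +
    labs(x = "KSC permutation p-value", y = "genes",
         title = "Candidate concordance p-values") +
    theme_minimal()
}

#' Plot a marker-set stratification
#'
#' Bar chart of the fraction of marker genes (e.g. Rank-2 targets) per KSC
#' p-value bin; a U shape indicates markers concentrated at both extremes.
#'
#' @param object A `ksc_strata`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ksc_strata <- function(object, ...) {
  d <- object$histogram %>% mutate(mid = (.data$p_lo + .data$p_hi) / 2)
  ggplot(d, aes(x = .data$mid, y = .data$frac_member)) +
    geom_col(width = d$p_hi[1] - d$p_lo[1], fill = "steelblue",
             colour = "white") +
    labs(x = "KSC p-value bin", y = "marker fraction",
         title = "Marker density across the p-value spectrum") +
    theme_minimal()
}

#' Plot LOOCV error rates
#'
#' @param object A `loocv_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.loocv_report <- function(object, ...) {
  ggplot(object$error_rates, aes(x = .data$alpha, y = .data$error)) +
    geom_step() + geom_point() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "significance level", y = "error rate",
         title = "Leave-one-out kernel recovery") +
    theme_minimal()
}

#' Plot the resampled AUC distribution
#'
#' @param object An `auc_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.auc_report <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$auc)) +
    geom_histogram(bins = 20, fill = "steelblue", colour = "white") +
    geom_vline(xintercept = object$mean_auc, linetype = "dashed") +
    labs(x = "AUC", y = "resamples",
         title = sprintf("Resampled-negative ROC AUC (mean %.3f)",
                         object$mean_auc)) +
    theme_minimal()
}
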