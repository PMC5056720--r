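# broom-style tidiers for the package's result objects.

#' Tidy a cluster set
#'
#' @param x A `cluster_set`.
#' @param ... Unused.
#' @return Tibble with one row per kernel member: `gene`, `cluster` (label,
#'   `NA` for singletons), `role` (`"prevalent"`/`"singleton"`).
#' @export
tidy.cluster_set <- function(x, ...) {
  rows <- purrr::imap_dfr(x$clusters, function(m, nm)
    tibble(gene = m, cluster = nm, role = "prevalent"))
  bind_rows(rows,
            tibble(gene = x$singletons, cluster = NA_character_,
                   role = "singleton")) %>%
    arrange(.data$gene)
}

#' @rdname tidy.cluster_set
#' @return For `glance()`: one row with `n_members`, `n_clusters`,
#'   `n_singletons`, `largest_cluster`, `lambda_c`, `lambda_final`.
#' @export
glance.cluster_set <- function(x, ...) {
  tibble(n_members = length(x$members),
         n_clusters = length(x$clusters),
         n_singletons = length(x$singletons),
         largest_cluster = if (length(x$clusters)) max(lengths(x$clusters)) else 0L,
         lambda_c = x$lambda_c,
         lambda_final = x$lambda_final)
}

#' Tidy a KSC prediction run
#'
#' @param x A `ksc_run` from [run_application_2()].
#' @param ... Unused.
#' @return The predictions tibble (`gene`, `score`, `best_cluster`, `p`).
#' @export
tidy.ksc_run <- function(x, ...) as_tibble(x$predictions)

#' @rdname tidy.ksc_run
#' @return For `glance()`: the run's counts funnel and parameters.
#' @export
glance.ksc_run <- function(x, ...) {
  m <- x$manifest
  tibble(tf = m$tf, n_de_genes = m$n_de_genes, n_kernel = m$n_kernel,
         n_clusters = m$n_clusters, n_singletons = m$n_singletons,
         n_candidates = m$n_candidates, B = m$B, mode = m$mode,
         lambda_c = m$lambda_c,
         n_significant = sum(x$predictions$p < 0.05))
}

#' Tidy a LOOCV report
#'
#' @param x A `loocv_report`.
#' @param ... Unused.
#' @return Per-gene tibble: `gene`, `score`, `p`, `evaluable`.
#' @export
tidy.loocv_report <- function(x, ...) x$per_gene

#' @rdname tidy.loocv_report
#' @return For `glance()`: `n_kernel`, `n_evaluable`, error rates at 0.01
#'   and 0.05, `null_mode`, `null_B`.
#' @export
glance.loocv_report <- function(x, ...) {
  tibble(n_kernel = nrow(x$per_gene), n_evaluable = x$n_evaluable,
         error_0.01 = loocv_error(x, 0.01), error_0.05 = loocv_error(x, 0.05),
         null_mode = x$null_mode, null_B = x$null_B)
}

#' Tidy an AUC report
#'
#' @param x An `auc_report`.
#' @param ... Unused.
#' @return Tibble with `resample`, `auc`.
#' @export
tidy.auc_report <- function(x, ...) {
  tibble(resample = seq_along(x$aucs), auc = x$aucs)
}

#' @rdname tidy.auc_report
#' @return For `glance()`: `mean_auc`, `ci_half_width`, `R`.
#' @export
glance.auc_report <- function(x, ...) {
  tibble(mean_auc = x$mean_auc, ci_half_width = x$ci_half_width, R = x$R)
}

#' Tidy a p-value stratification
#'
#' @param x A `ksc_strata`.
#' @param ... Unused.
#' @return The per-bin histogram tibble.
#' @export
tidy.ksc_strata <- function(x, ...) x$histogram

#' @rdname tidy.ksc_strata
#' @return For `glance()`: `member_extreme_fraction`,
#'   `strata_correlation`, stratum sizes, `alpha_low`.
#' @export
glance.ksc_strata <- function(x, ...) {
  tibble(member_extreme_fraction = x$member_extreme_fraction,
         strata_correlation = x$strata_correlation,
         n_low = length(x$low_genes), n_high = length(x$high_genes),
         alpha_low = x$alpha_low)
}
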