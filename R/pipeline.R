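#' Application 1: identify modulated TFs in a DE gene list
#'
#' Runs [enrich_tfs()] and, when `out_dir` is given, writes the ranked
#' enrichment table (`enrichment.tsv`) plus a JSON run manifest recording
#' inputs, parameters and package version, so the run is reproducible from
#' the manifest alone.
#'
#' @param repo A `tf_repo`.
#' @param de_genes Character vector of DE gene symbols.
#' @param max_rank,universe_mode,restrict_query Passed to [enrich_tfs()].
#' @param out_dir Optional output directory.
#' @return The `tf_enrichment` tibble, invisibly carrying the manifest as
#'   attribute `manifest`.
#' @export
run_application_1 <- function(repo, de_genes, max_rank = 3,
                              universe_mode = "interactions",
                              restrict_query = FALSE, out_dir = NULL) {
  if (missing(repo) || !inherits(repo, "tf_repo")) {
    usage_error("run_application_1: a tf_repo is required")
  }
  if (missing(de_genes) || length(de_genes) == 0) {
    usage_error("run_application_1: a non-empty DE gene list is required")
  }
  res <- enrich_tfs(repo, de_genes, max_rank = max_rank,
                    universe_mode = universe_mode,
                    restrict_query = restrict_query)
  manifest <- list(
    application = 1, n_records = nrow(repo), n_de_genes = length(unique(de_genes)),
    max_rank = max_rank, universe_mode = universe_mode,
    restrict_query = restrict_query, n_tfs_tested = nrow(res),
    package_version = as.character(utils::packageVersion("tfconcord"))
  )
  attr(res, "manifest") <- manifest
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(as_tibble(res), file.path(out_dir, "enrichment.tsv"),
                     progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Application 2: predict novel context-specific targets of a TF
#'
#' The full kernel-set concordance pipeline: extract the kernel
#' ([extract_kernel()]), cluster it ([cluster_kernel()]), score every
#' other DE gene against the prevalent-cluster centroids ([ksc_scores()]),
#' and calibrate permutation p-values ([permutation_null()],
#' [ksc_pvalues()]). When the repository holds Rank-2 targets for the TF,
#' the result includes their p-value stratification
#' ([stratify_by_membership()]) as orthogonal validation. Stage-boundary
#' messages report the gene counts funnel (DE -> kernel -> clusters ->
#' candidates).
#'
#' @param expr Expression matrix covering kernel and candidate genes.
#' @param repo A `tf_repo`.
#' @param tf Focal TF symbol.
#' @param de_genes DE gene symbols.
#' @param params [cluster_params()].
#' @param rank Evidence rank defining the kernel (default 1).
#' @param B Permutation iterations (reference default 10000).
#' @param seed Optional integer seed (run fully reproducible).
#' @param mode Permutation mode, `"full"` (faithful; default) or
#'   `"fixed-clusters"` (fast).
#' @param add_one Use add-one p-value correction?
#' @param min_kernel Refuse kernels smaller than this (default 3).
#' @param out_dir Optional output directory for `predictions.tsv` and
#'   `manifest.json`.
#' @return A list of class `ksc_run`: `kernel`, `clusters`, `predictions`
#'   (a `ksc_result` sorted by p), `null`, `strata` (or `NULL`), `tf`,
#'   `params`, `manifest`.
#' @export
run_application_2 <- function(expr, repo, tf, de_genes,
                              params = cluster_params(), rank = 1,
                              B = 10000, seed = NULL,
                              mode = c("full", "fixed-clusters"),
                              add_one = FALSE, min_kernel = 3,
                              out_dir = NULL) {
  mode <- match.arg(mode)
  expr <- as_expression_matrix(expr)
  kernel <- extract_kernel(repo, tf, de_genes, rank = rank)
  inform(sprintf("stage kernel: %d DE genes -> %d kernel member(s)",
                 length(unique(de_genes)), length(kernel$members)))
  if (length(kernel$members) < min_kernel) {
    domain_error(sprintf(
      "stage kernel: only %d member(s) (< %d) for TF %s; cannot proceed",
      length(kernel$members), min_kernel, kernel$tf))
  }
  clusters <- cluster_kernel(expr, kernel, params)
  inform(sprintf("stage clustering: %d prevalent cluster(s), %d singleton(s)",
                 n_clusters(clusters), length(clusters$singletons)))
  if (n_clusters(clusters) == 0) {
    domain_error("stage clustering: no prevalent clusters; kernel too heterogeneous")
  }
  candidates <- setdiff(sort(unique(norm_symbol(de_genes))), kernel$members)
  candidates <- intersect(candidates, rownames(expr))
  inform(sprintf("stage scoring: %d candidate gene(s)", length(candidates)))
  observed <- ksc_scores(expr, candidates, clusters)
  null <- if (mode == "full") {
    permutation_null(expr, kernel = kernel, params = params, B = B,
                     seed = seed, mode = "full")
  } else {
    permutation_null(expr, B = B, seed = seed, mode = "fixed-clusters",
                     clusters = clusters)
  }
  predictions <- ksc_pvalues(observed, null, add_one = add_one)
  rank2 <- setdiff(query_targets(repo, tf, max_rank = 2),
                   query_targets(repo, tf, max_rank = 1))
  strata <- NULL
  if (length(intersect(rank2, predictions$gene)) > 0) {
    strata <- stratify_by_membership(predictions, rank2, expr = expr)
  }
  manifest <- list(
    application = 2, tf = kernel$tf, rank = rank, B = B, seed = seed,
    mode = mode, add_one = add_one,
    lambda0 = params$lambda0, epsilon = params$epsilon,
    lambda_c = clusters$lambda_c,
    n_de_genes = length(unique(de_genes)),
    n_kernel = length(kernel$members),
    n_clusters = n_clusters(clusters),
    n_singletons = length(clusters$singletons),
    n_candidates = length(candidates),
    n_redraws = null$n_redraws,
    package_version = as.character(utils::packageVersion("tfconcord"))
  )
  out <- structure(
    list(kernel = kernel, clusters = clusters, predictions = predictions,
         null = null, strata = strata, tf = kernel$tf, params = params,
         manifest = manifest),
    class = "ksc_run"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(as_tibble(predictions),
                     file.path(out_dir, "predictions.tsv"), progress = FALSE)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' @export
print.ksc_run <- function(x, ...) {
  m <- x$manifest
  cat(sprintf(
    "<ksc_run> TF %s: kernel %d -> %d cluster(s) + %d singleton(s); %d candidates (B = %d, %s)\n",
    x$tf, m$n_kernel, m$n_clusters, m$n_singletons, m$n_candidates, m$B, m$mode))
  print(head(as_tibble(x$predictions), 5))
  invisible(x)
}

#' Significant predictions of a KSC run
#'
#' @param run A [run_application_2()] result.
#' @param alpha KSC p-value cut-off (reference level 0.05).
#' @return Tibble of predicted targets with `p < alpha`.
#' @export
predicted_targets <- function(run, alpha = 0.05) {
  stopifnot(inherits(run, "ksc_run"))
  filter(as_tibble(run$predictions), .data$p < alpha)
}
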