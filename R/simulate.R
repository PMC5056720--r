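#' Simulate an expression matrix with planted co-expression clusters
#'
#' Builds a gene-by-condition matrix in which each planted cluster shares a
#' common base profile (standard-normal across conditions) up to a sign
#' flip, plus independent Gaussian member noise; background genes are
#' i.i.d. standard normal. With base-profile variance 1, the expected
#' within-cluster Pearson correlation is `rho = 1 / (1 + noise_sd^2)`, so
#' `noise_sd` can be chosen analytically for a target correlation (1/3 for
#' rho = 0.9). Two clusters of opposite sign are mutually anti-correlated
#' — the heterogeneity ("directionality") the kernel clustering is built to
#' resolve.
#'
#' @param n_background Number of i.i.d. noise background genes.
#' @param cluster_spec Data frame with columns `size` (>= 2) and `sign`
#'   (+1 or -1), one row per planted cluster; `NULL` for none.
#' @param n_conditions Number of conditions (>= 6).
#' @param noise_sd Member noise standard deviation.
#' @param seed Optional integer seed.
#' @return List with `expr` (matrix) and `truth` (a `synthetic_truth`:
#'   focal TF name, planted cluster membership with signs, background ids,
#'   base profile and generator parameters).
#' @export
simulate_expression <- function(n_background, cluster_spec = NULL,
                                n_conditions = 20, noise_sd = 1 / 3,
                                seed = NULL) {
  if (!is_scalar_number(n_conditions) || n_conditions < 6) {
    domain_error("n_conditions must be >= 6")
  }
  if (!is_scalar_number(noise_sd) || noise_sd < 0) {
    domain_error("noise_sd must be >= 0")
  }
  if (!is.null(cluster_spec)) {
    cluster_spec <- as_tibble(cluster_spec)
    stopifnot(all(c("size", "sign") %in% names(cluster_spec)))
    if (any(cluster_spec$size < 2)) domain_error("cluster sizes must be >= 2")
    if (!all(cluster_spec$sign %in% c(-1, 1))) {
      domain_error("cluster signs must be +1 or -1")
    }
  }
  with_seed_if(seed, {
    base <- stats::rnorm(n_conditions)
    rows <- list()
    memb <- tibble(gene = character(), cluster = integer(), sign = double())
    if (!is.null(cluster_spec)) {
      for (c_i in seq_len(nrow(cluster_spec))) {
        sz <- cluster_spec$size[c_i]
        sg <- cluster_spec$sign[c_i]
        ids <- sprintf("K%02d_%02d", c_i, seq_len(sz))
        prof <- matrix(sg * base, nrow = sz, ncol = n_conditions,
                       byrow = TRUE) +
          matrix(stats::rnorm(sz * n_conditions, sd = noise_sd), nrow = sz)
        rownames(prof) <- ids
        rows[[length(rows) + 1]] <- prof
        memb <- bind_rows(memb, tibble(gene = ids, cluster = c_i, sign = sg))
      }
    }
    if (n_background > 0) {
      bg_ids <- sprintf("BG%04d", seq_len(n_background))
      bg <- matrix(stats::rnorm(n_background * n_conditions),
                   nrow = n_background, dimnames = list(bg_ids, NULL))
      rows[[length(rows) + 1]] <- bg
    } else {
      bg_ids <- character()
    }
    expr <- do.call(rbind, rows)
    colnames(expr) <- sprintf("S%02d", seq_len(n_conditions))
    truth <- structure(
      list(focal_tf = "TF1", clusters = memb, background = bg_ids,
           rank1_targets = memb$gene,
           rank2_targets = tibble(gene = character(), group = character()),
           base_profile = base, n_conditions = n_conditions,
           noise_sd = noise_sd, rho_expected = 1 / (1 + noise_sd^2),
           seed = seed),
      class = "synthetic_truth"
    )
    list(expr = expr, truth = truth)
  })
}

#' Simulate an interaction repository from a synthetic truth
#'
#' The focal TF receives its planted Rank-1 targets (`truth$rank1_targets`)
#' and Rank-2 targets (`truth$rank2_targets$gene`); each decoy TF receives
#' random background targets at ranks drawn from 1..3. The result
#' round-trips through the flat-file reader/writer.
#'
#' @param truth A `synthetic_truth` (see [simulate_expression()]).
#' @param n_decoy_tfs Number of decoy TFs.
#' @param decoy_targets_per_tf Random background targets per decoy TF.
#' @param seed Optional integer seed.
#' @return A `tf_repo`.
#' @export
simulate_repository <- function(truth, n_decoy_tfs = 0,
                                decoy_targets_per_tf = 0, seed = NULL) {
  stopifnot(inherits(truth, "synthetic_truth"))
  with_seed_if(seed, {
    recs <- tibble(
      tf = truth$focal_tf,
      tg = truth$rank1_targets,
      species = "synthetic",
      rank = 1L,
      source = "simulated",
      evidence = "planted-rank1",
      reference = ""
    )
    if (nrow(truth$rank2_targets) > 0) {
      recs <- bind_rows(recs, tibble(
        tf = truth$focal_tf, tg = truth$rank2_targets$gene,
        species = "synthetic", rank = 2L, source = "simulated",
        evidence = "planted-rank2", reference = ""
      ))
    }
    if (n_decoy_tfs > 0 && decoy_targets_per_tf > 0) {
      pool <- truth$background
      for (d in seq_len(n_decoy_tfs)) {
        tg <- sample(pool, min(decoy_targets_per_tf, length(pool)))
        recs <- bind_rows(recs, tibble(
          tf = sprintf("DTF%02d", d), tg = tg, species = "synthetic",
          rank = sample(1:3, length(tg), replace = TRUE),
          source = "simulated", evidence = "decoy", reference = ""
        ))
      }
    }
    interaction_repository(recs)
  })
}

make_noisy_profiles <- function(ids, sign, base, noise_sd) {
  n <- length(base)
  prof <- matrix(sign * base, nrow = length(ids), ncol = n, byrow = TRUE) +
    matrix(stats::rnorm(length(ids) * n, sd = noise_sd), nrow = length(ids))
  rownames(prof) <- ids
  prof
}

#' Simulate a complete case-study bundle
#'
#' Seeded end-to-end fixtures for the prediction pipeline, at desk scale:
#'
#' * `"multi-condition"` — 20 conditions; two anti-correlated kernel
#'   clusters of 15 (within-cluster rho ~ 0.9) plus one uncorrelated
#'   kernel outlier; 1000 background genes of which 200 are DE decoys;
#'   Rank-2 targets: 20 concordant (10 per sign) and 20 uncorrelated.
#'   Mimics a rich multi-comparison design; critical cut-off
#'   `lambda_c = 0.6`.
#' * `"single-contrast"` — 6 conditions; one kernel cluster of 10
#'   (rho ~ 0.95); 300 background / 60 DE decoys; Rank-2: 10 concordant +
#'   5 uncorrelated. `lambda_c` from correlation p <= 0.01 (~0.88).
#' * `"null"` — 20 conditions, no planted structure: 1030 i.i.d. noise
#'   genes; 230 random DE genes; the focal TF's 150 targets are assigned
#'   so that exactly 30 are DE (kernel size 30, candidate pool 200) while
#'   target status stays independent of expression.
#' * `"two-sided"` — like multi-condition but with a single kernel cluster
#'   of 15 (one sign) and Rank-2 targets split 20 concordant / 20
#'   anti-concordant, producing the U-shaped p-value pattern in which
#'   high-p Rank-2 genes mirror the kernel.
#'
#' @param preset One of `"multi-condition"`, `"single-contrast"`,
#'   `"null"`, `"two-sided"`.
#' @param seed Optional integer seed; the whole bundle is reproducible
#'   from it.
#' @return A list of class `case_study`: `expr`, `repo`, `de_genes`,
#'   `truth`, `params` (a [cluster_params()] suited to the preset),
#'   `preset`, `seed`.
#' @export
simulate_case_study <- function(preset = c("multi-condition",
                                           "single-contrast", "null",
                                           "two-sided"),
                                seed = NULL) {
  preset <- tryCatch(match.arg(preset),
                     error = function(e) usage_error("unknown preset token"))
  bundle <- with_seed_if(seed, {
    switch(
      preset,
      "multi-condition" = build_planted_bundle(
        n_conditions = 20, noise_sd = 1 / 3,
        cluster_spec = tibble(size = c(15, 15), sign = c(1, -1)),
        n_background = 1000, n_de_decoys = 200, n_outliers = 1,
        rank2_concordant = 20, rank2_anti = 0, rank2_noise = 20,
        extra_rank1 = 10, n_decoy_tfs = 20, decoy_targets = 30,
        params = cluster_params(lambda_c = 0.6)
      ),
      "two-sided" = build_planted_bundle(
        n_conditions = 20, noise_sd = 1 / 3,
        cluster_spec = tibble(size = 15, sign = 1),
        n_background = 1000, n_de_decoys = 200, n_outliers = 0,
        rank2_concordant = 20, rank2_anti = 20, rank2_noise = 0,
        extra_rank1 = 5, n_decoy_tfs = 20, decoy_targets = 30,
        params = cluster_params(lambda_c = 0.6)
      ),
      "single-contrast" = build_planted_bundle(
        n_conditions = 6, noise_sd = sqrt(0.05 / 0.95),
        cluster_spec = tibble(size = 10, sign = 1),
        n_background = 300, n_de_decoys = 60, n_outliers = 0,
        rank2_concordant = 10, rank2_anti = 0, rank2_noise = 5,
        extra_rank1 = 5, n_decoy_tfs = 10, decoy_targets = 20,
        params = cluster_params(alpha_c = 0.01)
      ),
      "null" = build_null_bundle()
    )
  })
  bundle$preset <- preset
  bundle$seed <- seed
  class(bundle) <- "case_study"
  bundle
}

# Shared construction for the planted presets.
build_planted_bundle <- function(n_conditions, noise_sd, cluster_spec,
                                 n_background, n_de_decoys, n_outliers,
                                 rank2_concordant, rank2_anti, rank2_noise,
                                 extra_rank1, n_decoy_tfs, decoy_targets,
                                 params) {
  sim <- simulate_expression(n_background, cluster_spec, n_conditions,
                             noise_sd)
  expr <- sim$expr
  truth <- sim$truth
  base <- truth$base_profile
  extra <- list()
  if (n_outliers > 0) {
    ids <- sprintf("OUT%02d", seq_len(n_outliers))
    extra$out <- matrix(stats::rnorm(n_outliers * n_conditions),
                        nrow = n_outliers, dimnames = list(ids, NULL))
  }
  signs <- cluster_spec$sign
  r2 <- tibble(gene = character(), group = character())
  if (rank2_concordant > 0) {
    ids <- sprintf("R2C%02d", seq_len(rank2_concordant))
    sg <- rep_len(signs, rank2_concordant)
    extra$r2c <- do.call(rbind, lapply(seq_along(ids), function(i)
      make_noisy_profiles(ids[i], sg[i], base, noise_sd)))
    r2 <- bind_rows(r2, tibble(gene = ids, group = "concordant"))
  }
  if (rank2_anti > 0) {
    ids <- sprintf("R2A%02d", seq_len(rank2_anti))
    extra$r2a <- make_noisy_profiles(ids, -signs[1], base, noise_sd)
    r2 <- bind_rows(r2, tibble(gene = ids, group = "anti"))
  }
  if (rank2_noise > 0) {
    ids <- sprintf("R2N%02d", seq_len(rank2_noise))
    extra$r2n <- matrix(stats::rnorm(rank2_noise * n_conditions),
                        nrow = rank2_noise, dimnames = list(ids, NULL))
    r2 <- bind_rows(r2, tibble(gene = ids, group = "noise"))
  }
  if (length(extra) > 0) {
    add <- do.call(rbind, unname(extra))
    colnames(add) <- colnames(expr)
    expr <- rbind(expr, add)
  }
  outlier_ids <- if (n_outliers > 0) sprintf("OUT%02d", seq_len(n_outliers))
                 else character()
  non_de_bg <- sample(truth$background, extra_rank1)
  truth$rank1_targets <- c(truth$clusters$gene, outlier_ids)
  truth$rank1_extra_non_de <- non_de_bg
  truth$rank2_targets <- r2
  truth$outliers <- outlier_ids
  de_decoys <- sample(setdiff(truth$background, non_de_bg), n_de_decoys)
  de_genes <- sort(c(truth$clusters$gene, outlier_ids, r2$gene, de_decoys))
  truth$de_decoys <- de_decoys
  repo <- simulate_repository(truth, n_decoy_tfs, decoy_targets)
  # focal TF also has validated targets that did not respond in this context
  if (extra_rank1 > 0) {
    repo <- interaction_repository(bind_rows(
      as_tibble(repo),
      tibble(tf = truth$focal_tf, tg = non_de_bg, species = "synthetic",
             rank = 1L, source = "simulated", evidence = "planted-rank1",
             reference = "", row = NA_integer_)
    ))
  }
  list(expr = expr, repo = repo, de_genes = de_genes, truth = truth,
       params = params)
}

build_null_bundle <- function() {
  n_conditions <- 20
  sim <- simulate_expression(1030, NULL, n_conditions, noise_sd = 1 / 3)
  expr <- sim$expr
  truth <- sim$truth
  all_genes <- rownames(expr)
  de_genes <- sort(sample(all_genes, 230))
  kernel_targets <- sample(de_genes, 30)
  other_targets <- sample(setdiff(all_genes, de_genes), 120)
  truth$rank1_targets <- sort(c(kernel_targets, other_targets))
  truth$rank2_targets <- tibble(gene = sort(sample(setdiff(
    all_genes, truth$rank1_targets), 40)), group = "noise")
  truth$de_decoys <- setdiff(de_genes, kernel_targets)
  truth$outliers <- character()
  repo <- simulate_repository(truth, n_decoy_tfs = 20,
                              decoy_targets_per_tf = 30)
  list(expr = expr, repo = repo, de_genes = de_genes, truth = truth,
       params = cluster_params(alpha_c = 0.01))
}

#' @export
print.case_study <- function(x, ...) {
  cat(sprintf(
    "<case_study> preset %s: %d genes x %d conditions, %d DE, kernel %d\n",
    x$preset, nrow(x$expr), ncol(x$expr), length(x$de_genes),
    length(intersect(query_targets(x$repo, x$truth$focal_tf, 1), x$de_genes))))
  invisible(x)
}

#' Write a case-study bundle to disk
#'
#' Emits `repository.tsv` (flat-file dialect), `expression.tsv`,
#' `de_genes.txt` (one symbol per line) and `truth.json`. Output is
#' byte-identical for identical bundles.
#'
#' @param bundle A [simulate_case_study()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_case_study <- function(bundle, dir) {
  stopifnot(inherits(bundle, "case_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_interactions(bundle$repo, file.path(dir, "repository.tsv"))
  write_expression(bundle$expr, file.path(dir, "expression.tsv"))
  writeLines(bundle$de_genes, file.path(dir, "de_genes.txt"))
  truth <- bundle$truth
  truth$base_profile <- round(truth$base_profile, 12)
  jsonlite::write_json(
    list(preset = bundle$preset, seed = bundle$seed,
         focal_tf = truth$focal_tf,
         clusters = truth$clusters, rank2_targets = truth$rank2_targets,
         outliers = truth$outliers,
         n_conditions = truth$n_conditions, noise_sd = truth$noise_sd),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
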