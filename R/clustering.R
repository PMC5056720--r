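#' Extract the kernel set of a TF
#'
#' The kernel set is the intersection of the focal TF's repository targets
#' (by default Rank-1, i.e. low-throughput-validated) with the
#' differentially-expressed genes of the experiment: the TF's known targets
#' that actually responded in this context. Kernel profiles seed the
#' clustering and concordance stages.
#'
#' @param repo A `tf_repo`.
#' @param tf Focal TF symbol.
#' @param de_genes Character vector of DE gene symbols.
#' @param rank Maximum evidence rank for targets (default 1).
#' @param species Optional species filter.
#' @return A list of class `kernel_set` with `tf`, `members`
#'   (lexicographically sorted) and `rank_used`. Warns if the TF is absent
#'   from the repository or the kernel is empty.
#' @export
extract_kernel <- function(repo, tf, de_genes, rank = 1, species = NULL) {
  stopifnot(inherits(repo, "tf_repo"))
  tf <- norm_symbol(tf)
  if (!tf %in% repo$tf) {
    warn(paste0("extract_kernel: TF ", tf, " not found in repository"))
  }
  targets <- query_targets(repo, tf, max_rank = rank, species = species)
  members <- sort(intersect(targets, unique(norm_symbol(de_genes))))
  if (length(members) == 0) {
    warn(paste0("extract_kernel: empty kernel for TF ", tf))
  }
  structure(list(tf = tf, members = members, rank_used = as.integer(rank)),
            class = "kernel_set")
}

#' @export
print.kernel_set <- function(x, ...) {
  cat(sprintf("<kernel_set> TF %s: %d member(s) at rank <= %d\n",
              x$tf, length(x$members), x$rank_used))
  invisible(x)
}

#' Correlation threshold for a one-sided correlation p-value
#'
#' The smallest Pearson correlation `r >= 0` whose one-sided p-value, under
#' the t-distribution with `n_points - 2` degrees of freedom
#' (`t = r * sqrt((n - 2) / (1 - r^2))`), is `<= alpha`. Used to translate
#' a significance level for co-expression (e.g. 0.01) into the critical
#' clustering cut-off `lambda_c` for a given number of conditions.
#'
#' @param alpha Significance level in (0, 1).
#' @param n_points Number of conditions (>= 3).
#' @return Correlation threshold in `[0, 1)`.
#' @examples
#' lambda_for_pvalue(0.01, 6)  # ~0.88: few conditions need high correlation
#' lambda_for_pvalue(0.01, 20) # ~0.52
#' @export
lambda_for_pvalue <- function(alpha, n_points) {
  if (!is_scalar_number(n_points) || n_points < 3) {
    domain_error("n_points must be >= 3")
  }
  if (!is_scalar_number(alpha) || alpha <= 0 || alpha >= 1) {
    domain_error("alpha must be in (0, 1)")
  }
  df <- n_points - 2
  tcrit <- stats::qt(1 - alpha, df)
  max(0, tcrit / sqrt(df + tcrit^2))
}

#' Clustering parameters
#'
#' Controls for the threshold-relaxation clustering of [cluster_kernel()].
#' The defaults are the reference settings: start stringent at
#' `lambda0 = 0.9` (an upper bound on mutual kernel correlations), relax in
#' steps of `epsilon = 0.05`, and stop at the critical cut-off `lambda_c`
#' — either given directly or derived from `alpha_c` (correlation p-value
#' `<= 0.01`) and the number of conditions via [lambda_for_pvalue()].
#'
#' @param lambda0 Initial correlation cut-off, `lambda_c < lambda0 <= 1`.
#' @param epsilon Reduction step, `> 0`.
#' @param lambda_c Critical cut-off; `NULL` to derive from `alpha_c`.
#' @param alpha_c Correlation p-value defining `lambda_c` when `lambda_c`
#'   is `NULL`.
#' @param min_profile_points Minimum conditions required of profiles.
#' @param tie_break Within-level merge tie rule; only
#'   `"lexicographic"` (smallest member identifier wins) is implemented.
#' @return A list of class `cluster_params`.
#' @export
cluster_params <- function(lambda0 = 0.9, epsilon = 0.05, lambda_c = NULL,
                           alpha_c = 0.01, min_profile_points = 3,
                           tie_break = "lexicographic") {
  if (!is_scalar_number(lambda0) || lambda0 <= 0 || lambda0 > 1) {
    domain_error("lambda0 must be in (0, 1]")
  }
  if (!is_scalar_number(epsilon) || epsilon <= 0) {
    domain_error("epsilon must be > 0")
  }
  if (!is.null(lambda_c)) {
    if (!is_scalar_number(lambda_c) || lambda_c <= 0 || lambda_c >= lambda0) {
      domain_error("need 0 < lambda_c < lambda0")
    }
  }
  tie_break <- match.arg(tie_break, "lexicographic")
  structure(list(lambda0 = lambda0, epsilon = epsilon, lambda_c = lambda_c,
                 alpha_c = alpha_c, min_profile_points = min_profile_points,
                 tie_break = tie_break),
            class = "cluster_params")
}

resolve_lambda_c <- function(params, n_conditions) {
  lc <- params$lambda_c %||% lambda_for_pvalue(params$alpha_c, n_conditions)
  if (lc >= params$lambda0) {
    domain_error("derived lambda_c >= lambda0; lower alpha_c or raise lambda0")
  }
  lc
}

# Core agglomeration over a profile matrix X (members x conditions, all
# rows with nonzero variance). Starts from singletons at lambda0; at each
# threshold level repeatedly merges the pair of clusters with the highest
# centroid-centroid Pearson correlation >= lambda (ties: the pair whose
# sorted leader pair is lexicographically smallest), recomputing centroids
# as the arithmetic mean of member profiles; then relaxes lambda by epsilon
# and stops after processing the first level with lambda <= lambda_c.
# Returns list(assignment = list of member-id vectors, lambda_final).
agglomerate_profiles <- function(X, lambda0, epsilon, lambda_c, tol = 1e-9) {
  members <- rownames(X)
  cl <- as.list(members)
  cent <- X
  lambda <- lambda0
  repeat {
    repeat {
      if (length(cl) < 2) break
      C <- suppressWarnings(row_cor(cent, cent))
      C[!is.finite(C)] <- -Inf
      diag(C) <- -Inf
      best <- max(C)
      if (best < lambda - tol) break
      cand <- which(C >= best - 1e-12, arr.ind = TRUE)
      cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
      leaders <- vapply(cl, `[[`, "", 1)
      keys <- vapply(seq_len(nrow(cand)), function(r) {
        sort(c(leaders[cand[r, 1]], leaders[cand[r, 2]]))
      }, character(2))
      pick <- order(keys[1, ], keys[2, ])[1]
      i <- cand[pick, 1]; j <- cand[pick, 2]
      merged <- sort(c(cl[[i]], cl[[j]]))
      cl[[i]] <- merged
      cl[[j]] <- NULL
      cent <- rbind(cent[-j, , drop = FALSE])
      cent[i - (i > j), ] <- colMeans(X[merged, , drop = FALSE])
      # keep clusters ordered by leader for deterministic indexing
      ord <- order(vapply(cl, `[[`, "", 1))
      cl <- cl[ord]
      cent <- cent[ord, , drop = FALSE]
    }
    if (lambda <= lambda_c + tol) break
    lambda <- lambda - epsilon
  }
  list(assignment = cl, lambda_final = lambda)
}

#' Cluster a kernel set by iterative correlation-threshold relaxation
#'
#' Partitions the kernel members into *prevalent clusters* (co-expressed
#' subgroups of >= 2 genes, each with a centroid profile) and *singletons*
#' (outliers). Unlike K-means, hierarchical cutting or SOM, the procedure
#' does not need the number of clusters in advance, may legitimately return
#' a single cluster, and leaves outliers unassigned instead of forcing them
#' into a group.
#'
#' Starting with every member as its own cluster at the stringent cut-off
#' `lambda0`, each level repeatedly merges the pair of clusters whose
#' centroid profiles have the highest signed Pearson correlation at or
#' above the current threshold, recomputing centroids (arithmetic mean of
#' member profiles) after every merge. The threshold is then relaxed by
#' `epsilon`, and the process stops after the first level at or below the
#' critical cut-off `lambda_c`. Correlation is signed, not absolute:
#' anti-regulated subsets of the kernel end up in different clusters.
#'
#' Members with zero-variance profiles are demoted to singletons before
#' clustering (their correlation is undefined).
#'
#' @param expr Expression matrix ([as_expression_matrix()]) containing a
#'   profile for every kernel member.
#' @param kernel A [extract_kernel()] result or a character vector of
#'   member gene identifiers.
#' @param params A [cluster_params()].
#' @return A list of class `cluster_set`: `clusters` (list of member-id
#'   vectors, sorted by decreasing size then leader), `centroids` (matrix,
#'   one row per cluster), `singletons`, `members`, `lambda_c`,
#'   `lambda_final`, `params`, `tf`.
#' @export
cluster_kernel <- function(expr, kernel, params = cluster_params()) {
  expr <- as_expression_matrix(expr)
  tf <- NULL
  if (inherits(kernel, "kernel_set")) {
    tf <- kernel$tf
    members <- kernel$members
  } else {
    members <- sort(unique(norm_symbol(kernel)))
  }
  absent <- setdiff(members, rownames(expr))
  if (length(absent) > 0) {
    domain_error(paste0("kernel member(s) missing from expression matrix: ",
                        paste(head(absent, 5), collapse = ", ")))
  }
  if (ncol(expr) < params$min_profile_points) {
    domain_error("too few conditions for the configured min_profile_points")
  }
  lambda_c <- resolve_lambda_c(params, ncol(expr))
  X <- expr[members, , drop = FALSE]
  vars <- apply(X, 1, stats::sd)
  zerovar <- members[vars == 0 | !is.finite(vars)]
  if (length(zerovar) > 0) {
    warn(paste0("cluster_kernel: zero-variance member(s) demoted to singletons: ",
                paste(zerovar, collapse = ", ")))
  }
  active <- setdiff(members, zerovar)
  if (length(active) < 2) {
    warn("cluster_kernel: fewer than 2 clusterable members; all singletons")
    return(new_cluster_set(list(), expr, c(active, zerovar), members,
                           lambda_c, params$lambda0, params, tf))
  }
  res <- agglomerate_profiles(X[active, , drop = FALSE],
                              params$lambda0, params$epsilon, lambda_c)
  sizes <- lengths(res$assignment)
  singles <- unlist(res$assignment[sizes == 1], use.names = FALSE)
  clusters <- res$assignment[sizes >= 2]
  ord <- order(-lengths(clusters), vapply(clusters, `[[`, "", 1))
  clusters <- clusters[ord]
  new_cluster_set(clusters, expr, sort(c(singles, zerovar)), members,
                  lambda_c, res$lambda_final, params, tf)
}

new_cluster_set <- function(clusters, expr, singletons, members,
                            lambda_c, lambda_final, params, tf) {
  centroids <- if (length(clusters) > 0) {
    do.call(rbind, lapply(clusters, function(m)
      colMeans(expr[m, , drop = FALSE])))
  } else {
    matrix(numeric(0), nrow = 0, ncol = ncol(expr),
           dimnames = list(NULL, colnames(expr)))
  }
  if (length(clusters) > 0) {
    rownames(centroids) <- names(clusters) <- paste0("C", seq_along(clusters))
  }
  structure(list(clusters = clusters, centroids = centroids,
                 singletons = singletons, members = members,
                 lambda_c = lambda_c, lambda_final = lambda_final,
                 params = params, tf = tf),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf(
    "<cluster_set> %d prevalent cluster(s) [%s], %d singleton(s); lambda_c = %.3f\n",
    length(x$clusters), paste(lengths(x$clusters), collapse = ", "),
    length(x$singletons), x$lambda_c))
  invisible(x)
}

#' @describeIn cluster_kernel Number of prevalent clusters.
#' @param x A `cluster_set`.
#' @export
n_clusters <- function(x) length(x$clusters)
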