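#' Upper-tail hypergeometric probability
#'
#' `P[X >= k]` for `X ~ Hypergeometric(N, K, n)`: the probability of seeing
#' `k` or more annotated genes in a draw of `n` from a universe of `N`
#' containing `K` annotated genes. This is the p-value of the right-sided
#' Fisher's exact test and the primitive behind [enrich_tfs()] and
#' [enrich_gene_sets()]. Computed through the hypergeometric survival
#' function ([stats::phyper()]), which works in a numerically stable way
#' for large parameters; the result is clamped to `[0, 1]`.
#'
#' @param N Universe size.
#' @param K Number of annotated elements in the universe.
#' @param n Query (draw) size.
#' @param k Observed overlap.
#' @return Probability in `[0, 1]`. Vectorised over all four arguments.
#' @examples
#' hypergeometric_tail(10, 5, 5, 5) # = 1 / choose(10, 5)
#' @export
hypergeometric_tail <- function(N, K, n, k) {
  args <- vctrs_recycle(N = N, K = K, n = n, k = k)
  with(args, {
    check <- function(cond, name) {
      if (any(!cond)) domain_error(paste0("invalid parameter: ", name))
    }
    check(is.finite(N) & N >= 0, "N")
    check(is.finite(K) & K >= 0 & K <= N, "K (need 0 <= K <= N)")
    check(is.finite(n) & n >= 0 & n <= N, "n (need 0 <= n <= N)")
    check(is.finite(k) & k >= 0 & k <= pmin(n, K), "k (need 0 <= k <= min(n, K))")
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    pmin(pmax(p, 0), 1)
  })
}

# Minimal common-length recycling for scalar-or-vector numeric args.
vctrs_recycle <- function(...) {
  xs <- list(...)
  len <- max(vapply(xs, length, 1L))
  lapply(xs, rep_len, length.out = len)
}

#' TF over-representation in a DE gene list
#'
#' For every TF with at least one annotated target at `rank <= max_rank`,
#' tests whether its targets are over-represented among the supplied
#' differentially-expressed (DE) genes with an upper-tail hypergeometric
#' test, Bonferroni-corrected over the TFs tested.
#'
#' Two universe conventions are supported. `"interactions"` (default) sets
#' `N` to the total number of distinct (tf, tg) interaction pairs at
#' `rank <= max_rank` — each TF's target list is a draw from the pooled
#' interaction universe. `"genes"` sets `N` to the number of distinct TGs
#' in the repository, the more common gene-universe convention.
#'
#' By default `n` counts all supplied DE genes; with
#' `restrict_query = TRUE` only DE genes present among the repository's
#' TGs (at `rank <= max_rank`) are counted and intersected.
#'
#' @param repo A `tf_repo`.
#' @param de_genes Character vector of DE gene symbols (non-empty).
#' @param max_rank Maximum evidence rank for target annotation.
#' @param universe_mode `"interactions"` or `"genes"`.
#' @param restrict_query Restrict the query to genes in the universe?
#' @return Tibble of class `tf_enrichment`, one row per TF, sorted by
#'   ascending `p`, with columns `tf`, `N`, `n`, `K`, `k`, `p`, `p_adj`.
#' @export
enrich_tfs <- function(repo, de_genes, max_rank = 3,
                       universe_mode = c("interactions", "genes"),
                       restrict_query = FALSE) {
  stopifnot(inherits(repo, "tf_repo"))
  universe_mode <- match.arg(universe_mode)
  de_genes <- unique(norm_symbol(de_genes))
  de_genes <- de_genes[de_genes != ""]
  if (length(de_genes) == 0) usage_error("de_genes must be non-empty")
  x <- filter_rank(repo, max_rank)
  pairs <- distinct(x, .data$tf, .data$tg)
  if (nrow(pairs) == 0) {
    warn("enrich_tfs: repository has no interactions at this rank; empty result")
    return(structure(
      tibble(tf = character(), N = integer(), n = integer(), K = integer(),
             k = integer(), p = double(), p_adj = double()),
      class = c("tf_enrichment", class(tibble()))
    ))
  }
  if (restrict_query) de_genes <- intersect(de_genes, unique(pairs$tg))
  N <- if (universe_mode == "interactions") nrow(pairs) else n_distinct(pairs$tg)
  n <- length(de_genes)
  if (n > N) {
    domain_error(paste0(
      "query size n = ", n, " exceeds universe N = ", N,
      "; use restrict_query = TRUE or universe_mode = 'interactions'"
    ))
  }
  res <- pairs %>%
    group_by(.data$tf) %>%
    summarise(K = n(), k = sum(.data$tg %in% de_genes), .groups = "drop") %>%
    mutate(N = N, n = n, p = hypergeometric_tail(N, .data$K, n, .data$k))
  m <- nrow(res)
  res <- res %>%
    mutate(p_adj = pmin(1, .data$p * m)) %>%
    select("tf", "N", "n", "K", "k", "p", "p_adj") %>%
    arrange(.data$p, .data$tf)
  class(res) <- c("tf_enrichment", class(tibble()))
  res
}

#' Read a GMT gene-set collection
#'
#' Tab-delimited GMT: set name, description, then member genes. Member
#' symbols are uppercased and trimmed.
#'
#' @param file Path to a `.gmt` file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(file) {
  sets <- fgsea::gmtPathways(file)
  lapply(sets, norm_symbol)
}

#' Gene-set over-representation for a query gene list
#'
#' Upper-tail hypergeometric test of each gene set against a query, within
#' an explicit gene universe: `N = |universe|`, `K = |set ∩ universe|`,
#' `n = |query|`, `k = |set ∩ query|`; Bonferroni correction over the sets
#' tested. Used e.g. to ask, per candidate gene, whether the functional
#' terms of a kernel set are over-represented among the gene's annotations.
#'
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param query Character vector of query gene symbols; must lie within
#'   `universe`.
#' @param universe Character vector defining the gene universe.
#' @return Tibble with columns `set`, `N`, `K`, `n`, `k`, `p`, `p_adj`,
#'   sorted by ascending `p`.
#' @export
enrich_gene_sets <- function(collection, query, universe) {
  universe <- unique(norm_symbol(universe))
  universe <- universe[universe != ""]
  if (length(universe) == 0) domain_error("universe must be non-empty")
  query <- unique(norm_symbol(query))
  if (!all(query %in% universe)) {
    domain_error("query must be a subset of the universe")
  }
  stopifnot(is.list(collection), !is.null(names(collection)))
  N <- length(universe)
  n <- length(query)
  res <- purrr::map2_dfr(collection, names(collection), function(genes, nm) {
    genes <- intersect(unique(norm_symbol(genes)), universe)
    k <- length(intersect(genes, query))
    tibble(set = nm, N = N, K = length(genes), n = n, k = k,
           p = hypergeometric_tail(N, length(genes), n, k))
  })
  m <- nrow(res)
  res %>%
    mutate(p_adj = pmin(1, .data$p * m)) %>%
    arrange(.data$p, .data$set)
}
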