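#' Time-course DE gene sets
#'
#' Bundles per-time-point differentially-expressed gene sets with a strict
#' time ordering, the input to [windowed_de_union()] and [build_cascade()].
#'
#' @param sets Named list of character vectors, one per time point, in
#'   temporal order; names are the time labels (e.g. `"1h"`). Labels must
#'   be unique.
#' @return A list of class `timecourse_de`.
#' @export
timecourse_de <- function(sets) {
  stopifnot(is.list(sets))
  if (length(sets) == 0) domain_error("time course must have >= 1 time point")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(names(sets) == "")) {
    domain_error("time labels must be present and unique")
  }
  sets <- lapply(sets, function(g) sort(unique(norm_symbol(g))))
  structure(sets, class = "timecourse_de")
}

#' Union DE genes over sliding windows of time points
#'
#' Combines the DE sets of `width` consecutive time points into one set per
#' window (e.g. width 2 joins 1h+2h, 2h+4h, ...), giving each window enough
#' genes for a stable enrichment test while retaining temporal resolution.
#'
#' @param tc A [timecourse_de()].
#' @param width Number of consecutive time points per window (>= 1, <=
#'   number of time points).
#' @return Tibble with columns `window` (label, member labels joined by
#'   `-`), `first_time`, `genes` (list-column of character vectors).
#' @export
windowed_de_union <- function(tc, width = 2) {
  stopifnot(inherits(tc, "timecourse_de"))
  nt <- length(tc)
  if (!is_scalar_number(width) || width < 1 || width > nt) {
    domain_error("width must be between 1 and the number of time points")
  }
  labels <- names(tc)
  starts <- seq_len(nt - width + 1)
  tibble(
    window = vapply(starts, function(s)
      paste(labels[s:(s + width - 1)], collapse = "-"), ""),
    first_time = labels[starts],
    genes = lapply(starts, function(s)
      sort(unique(unlist(tc[s:(s + width - 1)], use.names = FALSE))))
  )
}

#' Assemble a temporal transcriptional-cascade network
#'
#' Per window, TFs whose targets are over-represented among the window's DE
#' genes (nominal hypergeometric `p < enrich_alpha` via [enrich_tfs()]) are
#' cascade candidates; a candidate is retained only if it was itself DE at
#' the time point immediately preceding the window — the signature of a
#' regulator acting earlier than its targets. Edges then connect each
#' retained TF to its repository targets (at `rank <= max_rank`) that are
#' DE in the window, including targets that are themselves retained TFs
#' (TF->TF cascade links).
#'
#' "Preceding" means the latest time point strictly before the window's
#' first member; the first window falls back to `baseline` if given, else
#' to its own first time point.
#'
#' @param repo A `tf_repo`.
#' @param windows Output of [windowed_de_union()].
#' @param tc The [timecourse_de()] the windows came from.
#' @param enrich_alpha Nominal enrichment cut-off in (0, 1); default 0.05.
#' @param max_rank Maximum evidence rank for edges.
#' @param baseline Optional character vector: DE genes at the pre-course
#'   baseline, used as the "previous time point" of the first window.
#' @param require_tf_enriched If `TRUE`, an edge onto a gene that is itself
#'   a TF in the repository is kept only when that TF also passed the
#'   window's enrichment filter (stricter TF->TF rule); default `FALSE`
#'   requires the downstream TF merely to be DE in the window.
#' @param universe_mode,restrict_query Passed to [enrich_tfs()].
#' @return A list of class `cascade_network` with elements `edges` (tibble
#'   `tf`, `tg`, `window`), `nodes` (tibble `gene`, `is_tf`, `is_tg`),
#'   `windows` (per-window bookkeeping: DE size, enriched and retained TFs)
#'   and the parameters used.
#' @export
build_cascade <- function(repo, windows, tc, enrich_alpha = 0.05, max_rank = 3,
                          baseline = NULL, require_tf_enriched = FALSE,
                          universe_mode = "interactions",
                          restrict_query = FALSE) {
  stopifnot(inherits(repo, "tf_repo"), inherits(tc, "timecourse_de"))
  if (!is_scalar_number(enrich_alpha) || enrich_alpha <= 0 || enrich_alpha >= 1) {
    domain_error("enrich_alpha must be in (0, 1)")
  }
  labels <- names(tc)
  repo_pairs <- distinct(filter_rank(repo, max_rank), .data$tf, .data$tg)
  edges <- tibble(tf = character(), tg = character(), window = character())
  book <- vector("list", nrow(windows))
  for (i in seq_len(nrow(windows))) {
    w <- windows$window[i]
    genes_w <- windows$genes[[i]]
    if (length(genes_w) == 0) {
      inform(paste0("build_cascade: window ", w, " has no DE genes; skipped"))
      book[[i]] <- tibble(window = w, n_de = 0L, enriched = list(character()),
                          retained = list(character()))
      next
    }
    enr <- enrich_tfs(repo, genes_w, max_rank = max_rank,
                      universe_mode = universe_mode,
                      restrict_query = restrict_query)
    enriched <- enr$tf[enr$p < enrich_alpha]
    pos <- match(windows$first_time[i], labels)
    prev_genes <- if (pos > 1) {
      tc[[pos - 1]]
    } else if (!is.null(baseline)) {
      sort(unique(norm_symbol(baseline)))
    } else {
      tc[[pos]]
    }
    retained <- intersect(enriched, prev_genes)
    if (length(retained) > 0) {
      new_edges <- repo_pairs %>%
        filter(.data$tf %in% retained, .data$tg %in% genes_w) %>%
        mutate(window = w)
      if (require_tf_enriched) {
        all_tfs <- unique(repo_pairs$tf)
        new_edges <- new_edges %>%
          filter(!(.data$tg %in% all_tfs) | .data$tg %in% enriched)
      }
      edges <- bind_rows(edges, new_edges)
    }
    book[[i]] <- tibble(window = w, n_de = length(genes_w),
                        enriched = list(enriched), retained = list(retained))
  }
  edges <- distinct(edges) %>% arrange(.data$tf, .data$tg, .data$window)
  nodes <- tibble(gene = sort(unique(c(edges$tf, edges$tg)))) %>%
    mutate(is_tf = .data$gene %in% edges$tf, is_tg = .data$gene %in% edges$tg)
  structure(
    list(edges = edges, nodes = nodes, windows = bind_rows(book),
         params = list(enrich_alpha = enrich_alpha, max_rank = max_rank,
                       require_tf_enriched = require_tf_enriched)),
    class = "cascade_network"
  )
}

#' Export a cascade network as text
#'
#' Deterministic, lexicographically sorted output. `"tsv"` emits the
#' edge-list dialect read back by [read_network()]; `"circos"` emits
#' Circos-style link lines (two unit segments per interaction, the window
#' label as an option field) for external rendering.
#'
#' @param net A `cascade_network`.
#' @param format `"tsv"` or `"circos"`.
#' @return A single string.
#' @export
export_network <- function(net, format = c("tsv", "circos")) {
  stopifnot(inherits(net, "cascade_network"))
  format <- tryCatch(match.arg(format),
                     error = function(e) usage_error("unknown format token"))
  e <- arrange(net$edges, .data$tf, .data$tg, .data$window)
  if (format == "tsv") {
    lines <- c("tf\ttg\twindow",
               sprintf("%s\t%s\t%s", e$tf, e$tg, e$window))
  } else {
    lines <- sprintf("%s 0 1 %s 0 1 window=%s", e$tf, e$tg, e$window)
  }
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' Write a cascade network to a file
#'
#' @inheritParams export_network
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_network <- function(net, file, format = c("tsv", "circos")) {
  writeLines(sub("\n$", "", export_network(net, format)), file)
  invisible(file)
}

#' Read an edge-list TSV back into a cascade network
#'
#' Only the edges (and the nodes derivable from them) survive a round-trip;
#' window bookkeeping and parameters are not serialised.
#'
#' @param file Path to a file written by [write_network()] (tsv format).
#' @return A `cascade_network` with empty `windows`/`params`.
#' @export
read_network <- function(file) {
  e <- readr::read_tsv(file, col_types = "ccc", progress = FALSE) %>%
    arrange(.data$tf, .data$tg, .data$window)
  nodes <- tibble(gene = sort(unique(c(e$tf, e$tg)))) %>%
    mutate(is_tf = .data$gene %in% e$tf, is_tg = .data$gene %in% e$tg)
  structure(list(edges = e, nodes = nodes, windows = tibble(), params = list()),
            class = "cascade_network")
}

#' @export
print.cascade_network <- function(x, ...) {
  cat(sprintf("<cascade_network> %d edges, %d nodes, %d windows\n",
              nrow(x$edges), nrow(x$nodes), nrow(x$windows)))
  invisible(x)
}
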