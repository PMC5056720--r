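#' Interaction repository objects
#'
#' A repository is a tibble of evidence-level interaction records, one row
#' per piece of evidence that a transcription factor (TF) regulates a target
#' gene (TG). Several records may describe the same logical interaction
#' (same TF, TG and species) with different sources or evidence ranks; the
#' logical view, in which each (tf, tg, species) triple appears once at its
#' best (minimum) rank with all provenance retained, is given by
#' [interactions()].
#'
#' Ranks encode evidence quality: `1` low-throughput validated (e.g. EMSA,
#' reporter assay), `2` high-throughput (e.g. ChIP-Seq), `3` indirect
#' (motif prediction or differential expression alone).
#'
#' @param records A data frame with columns `tf`, `tg`, `species`, `rank`,
#'   `source`, `evidence`, `reference` (the last three may be missing and
#'   default to `""`). Symbols are uppercased and trimmed.
#' @return A tibble of class `tf_repo`.
#' @examples
#' repo <- interaction_repository(tibble::tibble(
#'   tf = c("A", "A", "D"), tg = c("B", "C", "C"),
#'   species = "human", rank = c(1, 2, 1), source = "demo"
#' ))
#' query_targets(repo, "A", max_rank = 2)
#' @export
interaction_repository <- function(records) {
  records <- as_tibble(records)
  for (col in c("species", "source", "evidence", "reference")) {
    if (!col %in% names(records)) records[[col]] <- ""
  }
  needed <- c("tf", "tg", "species", "rank", "source", "evidence", "reference")
  missing_cols <- setdiff(c("tf", "tg", "rank"), names(records))
  if (length(missing_cols) > 0) {
    domain_error(paste0(
      "interaction records lack mandatory column(s): ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  records <- records[c(needed, intersect("row", names(records)))]
  records$tf <- norm_symbol(records$tf)
  records$tg <- norm_symbol(records$tg)
  records$species <- trimws(as.character(records$species))
  records$rank <- as.integer(records$rank)
  for (col in c("source", "evidence", "reference")) {
    records[[col]] <- as.character(records[[col]])
    records[[col]][is.na(records[[col]])] <- ""
  }
  bad_rank <- which(is.na(records$rank) | !records$rank %in% 1:3)
  if (length(bad_rank) > 0) {
    domain_error(paste0(
      "rank must be 1, 2 or 3 (violated at record ",
      paste(head(bad_rank, 5), collapse = ", "), ")"
    ))
  }
  bad_sym <- which(records$tf == "" | records$tg == "")
  if (length(bad_sym) > 0) {
    domain_error(paste0(
      "tf and tg symbols must be non-empty (violated at record ",
      paste(head(bad_sym, 5), collapse = ", "), ")"
    ))
  }
  if (!"row" %in% names(records)) records$row <- seq_len(nrow(records))
  class(records) <- c("tf_repo", class(tibble()))
  records
}

#' Default flat-file column mapping
#'
#' Maps the seven record fields onto the header names of the tab-delimited
#' repository dialect. Override entries to read files with other headers,
#' e.g. `repo_dialect(tf = "TF_symbol")`.
#'
#' @param tf,tg,species,rank,source,evidence,reference Header names.
#' @return Named character vector of length 7.
#' @export
repo_dialect <- function(tf = "TF", tg = "TG", species = "SPECIES",
                         rank = "RANK", source = "SOURCE",
                         evidence = "EVIDENCE", reference = "REFERENCE") {
  c(tf = tf, tg = tg, species = species, rank = rank,
    source = source, evidence = evidence, reference = reference)
}

#' Read a tab-delimited interaction table
#'
#' Parses a flat file with a header row into an interaction repository.
#' Symbols are uppercased and whitespace-trimmed; the originating data-row
#' number is kept in column `row` for error reporting.
#'
#' @param file Path or connection to a tab-delimited file with a header row.
#' @param dialect Column mapping from [repo_dialect()]. The `reference`
#'   column is optional in the file; all others are mandatory.
#' @param lenient If `FALSE` (default) a record with an invalid rank or an
#'   empty symbol aborts the read with its row number; if `TRUE` such
#'   records are skipped with a message.
#' @return A [interaction_repository()] tibble.
#' @export
read_interactions <- function(file, dialect = repo_dialect(), lenient = FALSE) {
  raw <- readr::read_tsv(file, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  mandatory <- setdiff(names(dialect), "reference")
  absent <- dialect[mandatory][!dialect[mandatory] %in% names(raw)]
  if (length(absent) > 0) {
    usage_error(paste0(
      "input file lacks mandatory column(s): ", paste(absent, collapse = ", ")
    ))
  }
  recs <- tibble(
    tf = raw[[dialect[["tf"]]]],
    tg = raw[[dialect[["tg"]]]],
    species = raw[[dialect[["species"]]]],
    rank = suppressWarnings(as.integer(raw[[dialect[["rank"]]]])),
    source = raw[[dialect[["source"]]]],
    evidence = raw[[dialect[["evidence"]]]],
    reference = if (dialect[["reference"]] %in% names(raw)) {
      raw[[dialect[["reference"]]]]
    } else {
      ""
    },
    row = seq_len(nrow(raw))
  )
  recs$tf <- norm_symbol(recs$tf)
  recs$tg <- norm_symbol(recs$tg)
  bad <- which(is.na(recs$rank) | !recs$rank %in% 1:3 |
                 is.na(recs$tf) | recs$tf == "" |
                 is.na(recs$tg) | recs$tg == "")
  if (length(bad) > 0) {
    if (!lenient) {
      domain_error(paste0(
        "invalid record (rank outside 1..3 or empty symbol) at data row ",
        paste(head(bad, 5), collapse = ", "),
        if (length(bad) > 5) " ..." else ""
      ))
    }
    inform(paste0("read_interactions: skipped ", length(bad),
                  " invalid record(s) at data row(s) ",
                  paste(head(bad, 10), collapse = ", ")))
    recs <- recs[-bad, ]
  }
  interaction_repository(recs)
}

#' Write a repository in the flat-file dialect
#'
#' One line per evidence record; [read_interactions()] of the result
#' reproduces the same logical interaction set (round-trip).
#'
#' @param repo A `tf_repo`.
#' @param file Output path.
#' @param dialect Column mapping from [repo_dialect()].
#' @return `file`, invisibly.
#' @export
write_interactions <- function(repo, file, dialect = repo_dialect()) {
  stopifnot(inherits(repo, "tf_repo"))
  out <- tibble(
    a = repo$tf, b = repo$tg, c = repo$species, d = repo$rank,
    e = repo$source, f = repo$evidence, g = repo$reference
  )
  names(out) <- unname(dialect[c("tf", "tg", "species", "rank",
                                 "source", "evidence", "reference")])
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}

#' Alias tables for symbol canonicalisation
#'
#' An offline alias-to-official-symbol map used when merging repositories.
#' Canonical symbols always map to themselves (identity rows are added).
#' An alias listed with two different canonical symbols is ambiguous: it is
#' removed from the map and flagged, and records using it are quarantined
#' rather than silently dropped during [merge_interactions()].
#'
#' @param map A data frame with columns `alias` and `canonical`. A row with
#'   `canonical = NA` explicitly marks the alias as ambiguous.
#' @return A list of class `alias_table` with elements `map` (tibble) and
#'   `ambiguous` (character).
#' @export
alias_table <- function(map) {
  map <- as_tibble(map)
  stopifnot(all(c("alias", "canonical") %in% names(map)))
  map$alias <- norm_symbol(map$alias)
  map$canonical <- ifelse(is.na(map$canonical), NA_character_,
                          norm_symbol(map$canonical))
  explicit_amb <- unique(map$alias[is.na(map$canonical)])
  map <- map[!is.na(map$canonical), , drop = FALSE]
  map <- distinct(map, .data$alias, .data$canonical)
  multi <- map %>% count(.data$alias) %>% filter(.data$n > 1) %>% pull(.data$alias)
  ambiguous <- sort(unique(c(explicit_amb, multi)))
  map <- map[!map$alias %in% ambiguous, , drop = FALSE]
  idents <- tibble(alias = setdiff(unique(map$canonical), map$alias),
                   canonical = setdiff(unique(map$canonical), map$alias))
  map <- bind_rows(map, idents) %>% arrange(.data$alias)
  structure(list(map = map, ambiguous = ambiguous), class = "alias_table")
}

resolve_alias <- function(symbols, aliases) {
  idx <- match(symbols, aliases$map$alias)
  out <- ifelse(is.na(idx), symbols, aliases$map$canonical[idx])
  out
}

#' Merge interaction repositories
#'
#' Canonicalises symbols through an alias table, pools the records of all
#' repositories, and drops duplicated provenance entries, so duplicate
#' (tf, tg, species) triples collapse to a single logical interaction whose
#' rank is the best (minimum) observed while all distinct source/evidence
#' entries are retained (see [interactions()]). Records whose TF or TG is
#' an ambiguous alias are quarantined, not dropped: retrieve them with
#' [merge_quarantine()].
#'
#' Merging is idempotent and commutative at the logical-interaction level.
#'
#' @param ... `tf_repo` objects (or a single list of them).
#' @param aliases An [alias_table()], or `NULL` for the identity mapping.
#' @return A merged `tf_repo` with a `quarantine` attribute.
#' @export
merge_interactions <- function(..., aliases = NULL) {
  repos <- list(...)
  if (length(repos) == 1 && is.list(repos[[1]]) && !inherits(repos[[1]], "tf_repo")) {
    repos <- repos[[1]]
  }
  stopifnot(length(repos) >= 1, all(vapply(repos, inherits, TRUE, "tf_repo")))
  pooled <- bind_rows(lapply(repos, as_tibble))
  quarantine <- pooled[0, , drop = FALSE]
  if (!is.null(aliases)) {
    stopifnot(inherits(aliases, "alias_table"))
    amb <- pooled$tf %in% aliases$ambiguous | pooled$tg %in% aliases$ambiguous
    quarantine <- pooled[amb, , drop = FALSE]
    pooled <- pooled[!amb, , drop = FALSE]
    pooled$tf <- resolve_alias(pooled$tf, aliases)
    pooled$tg <- resolve_alias(pooled$tg, aliases)
  }
  pooled <- distinct(pooled, .data$tf, .data$tg, .data$species, .data$rank,
                     .data$source, .data$evidence, .data$reference) %>%
    arrange(.data$tf, .data$tg, .data$species, .data$rank, .data$source)
  pooled$row <- seq_len(nrow(pooled))
  out <- interaction_repository(pooled)
  attr(out, "quarantine") <- as_tibble(quarantine)
  out
}

#' Quarantined records from the last merge
#'
#' @param repo A repository returned by [merge_interactions()].
#' @return Tibble of records whose symbols were ambiguous aliases.
#' @export
merge_quarantine <- function(repo) {
  attr(repo, "quarantine") %||% as_tibble(repo)[0, , drop = FALSE]
}

#' Logical-interaction view of a repository
#'
#' Collapses evidence records to one row per (tf, tg, species) triple with
#' `rank` equal to the best (minimum) rank observed and `n_evidence` the
#' number of distinct provenance entries.
#'
#' @param repo A `tf_repo`.
#' @return Tibble with columns `tf`, `tg`, `species`, `rank`, `n_evidence`.
#' @export
interactions <- function(repo) {
  stopifnot(inherits(repo, "tf_repo"))
  as_tibble(repo) %>%
    group_by(.data$tf, .data$tg, .data$species) %>%
    summarise(rank = min(.data$rank), n_evidence = n(), .groups = "drop") %>%
    arrange(.data$tf, .data$tg, .data$species)
}

filter_rank <- function(repo, max_rank, species = NULL) {
  if (!is_scalar_number(max_rank) || !max_rank %in% 1:3) {
    domain_error("max_rank must be 1, 2 or 3")
  }
  x <- as_tibble(repo) %>% filter(.data$rank <= max_rank)
  if (!is.null(species)) x <- filter(x, .data$species == !!species)
  x
}

#' Query the distinct targets of a TF
#'
#' Returns the TG symbols of interactions with the given TF at evidence
#' rank `<= max_rank` (optionally restricted to one species; the default
#' pools every species, reflecting conservation of regulation across
#' mammalian model systems). An absent TF is a valid empty query. The
#' result is non-decreasing in `max_rank`.
#'
#' @param repo A `tf_repo`.
#' @param tf TF gene symbol.
#' @param max_rank Maximum evidence rank to accept (1, 2 or 3).
#' @param species Optional species token.
#' @return Sorted character vector of distinct TG symbols.
#' @export
query_targets <- function(repo, tf, max_rank = 3, species = NULL) {
  stopifnot(inherits(repo, "tf_repo"))
  x <- filter_rank(repo, max_rank, species)
  sort(unique(x$tg[x$tf == norm_symbol(tf)]))
}

#' Query the distinct regulators of a target gene
#'
#' The reverse of [query_targets()]: TF symbols with an interaction onto
#' `tg` at rank `<= max_rank`.
#'
#' @inheritParams query_targets
#' @param tg TG gene symbol.
#' @return Sorted character vector of distinct TF symbols.
#' @export
query_regulators <- function(repo, tg, max_rank = 3, species = NULL) {
  stopifnot(inherits(repo, "tf_repo"))
  x <- filter_rank(repo, max_rank, species)
  sort(unique(x$tf[x$tg == norm_symbol(tg)]))
}

#' Summarise a repository at a rank cut-off
#'
#' Counts distinct TFs, distinct TGs and distinct (tf, tg) pairs among
#' interactions at rank `<= max_rank` — the headline numbers usually quoted
#' for an interaction database at a given evidence stringency.
#'
#' @inheritParams query_targets
#' @return One-row tibble with `max_rank`, `n_tfs`, `n_tgs`, `n_pairs`.
#' @export
summarize_interactions <- function(repo, max_rank = 3) {
  stopifnot(inherits(repo, "tf_repo"))
  x <- filter_rank(repo, max_rank)
  pairs <- distinct(x, .data$tf, .data$tg)
  tibble(max_rank = as.integer(max_rank),
         n_tfs = n_distinct(pairs$tf),
         n_tgs = n_distinct(pairs$tg),
         n_pairs = nrow(pairs))
}

#' @export
print.tf_repo <- function(x, ...) {
  s <- summarize_interactions(x, 3)
  cat(sprintf("<tf_repo> %d records; %d TFs, %d TGs, %d pairs (rank <= 3)\n",
              nrow(x), s$n_tfs, s$n_tgs, s$n_pairs))
  NextMethod()
}
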