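# Small fixtures built in code.

# The canonical 3-interaction repository: A->B (rank 1), A->C (rank 2),
# D->C (rank 1).
tiny_repo <- function() {
  interaction_repository(tibble::tibble(
    tf = c("A", "A", "D"), tg = c("B", "C", "C"),
    species = "human", rank = c(1L, 2L, 1L),
    source = c("src1", "src1", "src2"),
    evidence = "assay", reference = c("r1", "r2", "r3")
  ))
}

# Noiseless block profiles: each block is sign * base exactly. `extra`
# optionally appends one profile orthogonal to base.
block_profiles <- function(sizes, signs, n_cond = 10, extra_orthogonal = FALSE) {
  base <- sin(seq_len(n_cond))
  rows <- list()
  ids <- character()
  g <- 0
  for (b in seq_along(sizes)) {
    for (j in seq_len(sizes[b])) {
      g <- g + 1
      id <- sprintf("G%02d", g)
      rows[[id]] <- signs[b] * base
      ids <- c(ids, id)
    }
  }
  if (extra_orthogonal) {
    # a phase-shifted profile nearly uncorrelated with base
    rows[["ZZ_SINGLE"]] <- cos(seq_len(n_cond))
  }
  X <- do.call(rbind, rows)
  colnames(X) <- paste0("S", seq_len(n_cond))
  X
}

# Write a repository flat file with given rows (character matrix interface).
write_flatfile <- function(lines, path = withr::local_tempfile(fileext = ".tsv",
                                                               .local_envir = parent.frame())) {
  writeLines(lines, path)
  path
}
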