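# Repo in which TF A targets B and C and a decoy TF has 5 targets, so a
# window containing {B, C} enriches A at p = 1/choose(7,2) ~ 0.048 < 0.05.
cascade_repo <- function() {
  interaction_repository(tibble::tibble(
    tf = c("A", "A", rep("E", 5)),
    tg = c("B", "C", paste0("N", 1:5)),
    species = "human", rank = 1L
  ))
}

test_that("sliding windows union DE genes of adjacent time points", {
  tc <- timecourse_de(list(`1h` = "a", `2h` = "b", `4h` = "c"))
  w2 <- windowed_de_union(tc, 2)
  expect_equal(w2$window, c("1h-2h", "2h-4h"))
  expect_equal(w2$genes, list(c("A", "B"), c("B", "C")))
  w1 <- windowed_de_union(tc, 1)
  expect_equal(w1$genes, list("A", "B", "C"))
  w3 <- windowed_de_union(tc, 3)
  expect_equal(w3$genes, list(c("A", "B", "C")))
  expect_error(windowed_de_union(tc, 4), class = "tfconcord_domain_error")
  expect_error(timecourse_de(list()), class = "tfconcord_domain_error")
})

test_that("an enriched, previously-DE TF contributes edges to its DE targets", {
  repo <- cascade_repo()
  tc <- timecourse_de(list(`0h` = "A", `1h` = c("B", "C"), `2h` = c("B", "C")))
  wins <- windowed_de_union(tc, 2)
  # window 1h-2h = {B, C}; previous time 0h has A DE -> A retained
  net <- build_cascade(repo, wins[2, ], tc, enrich_alpha = 0.05, max_rank = 1)
  expect_equal(net$edges$tf, c("A", "A"))
  expect_equal(net$edges$tg, c("B", "C"))
  expect_equal(unique(net$edges$window), "1h-2h")
})

test_that("an enriched TF that was not previously DE contributes no edges", {
  repo <- cascade_repo()
  tc <- timecourse_de(list(`0h` = "Q", `1h` = c("B", "C"), `2h` = "B"))
  wins <- windowed_de_union(tc, 2)
  net <- build_cascade(repo, wins[2, ], tc, enrich_alpha = 0.05, max_rank = 1)
  expect_equal(nrow(net$edges), 0)
})

test_that("retained TFs link to downstream TFs that are DE in the window", {
  # A regulates TF B; both A's targets (B, C) are DE in the window
  repo <- interaction_repository(tibble::tibble(
    tf = c("A", "A", "B", rep("E", 5)),
    tg = c("B", "C", "X", paste0("N", 1:5)),
    species = "human", rank = 1L
  ))
  tc <- timecourse_de(list(`0h` = "A", `1h` = c("B", "C"), `2h` = "B"))
  wins <- windowed_de_union(tc, 2)
  net <- build_cascade(repo, wins[2, ], tc, enrich_alpha = 0.10, max_rank = 1)
  expect_true(any(net$edges$tf == "A" & net$edges$tg == "B"))  # TF-TF edge
  # stricter rule: downstream TF must itself be enriched
  net2 <- build_cascade(repo, wins[2, ], tc, enrich_alpha = 0.10, max_rank = 1,
                        require_tf_enriched = TRUE)
  expect_false(any(net2$edges$tg == "B" & !"B" %in% unlist(net2$windows$enriched)))
})

test_that("every cascade edge is certified by repo, enrichment and prior-DE rules", {
  withr::with_seed(9, {
    for (rep in 1:3) {
      recs <- tibble::tibble(
        tf = sample(LETTERS[1:5], 40, replace = TRUE),
        tg = sample(paste0("G", 1:15), 40, replace = TRUE),
        species = "human", rank = sample(1:3, 40, replace = TRUE)
      )
      repo <- interaction_repository(recs)
      pool <- c(LETTERS[1:5], paste0("G", 1:15))
      tc <- timecourse_de(list(
        t1 = sample(pool, 8), t2 = sample(pool, 8),
        t3 = sample(pool, 8), t4 = sample(pool, 8)
      ))
      wins <- windowed_de_union(tc, 2)
      net <- build_cascade(repo, wins, tc, enrich_alpha = 0.3, max_rank = 2)
      if (nrow(net$edges) == 0) next
      pairs <- dplyr::distinct(as_tibble(repo)[as_tibble(repo)$rank <= 2, ],
                               tf, tg)
      for (i in seq_len(nrow(net$edges))) {
        e <- net$edges[i, ]
        # (a) repository membership at the configured rank
        expect_true(any(pairs$tf == e$tf & pairs$tg == e$tg))
        wrow <- net$windows[net$windows$window == e$window, ]
        # (b) enrichment in the window, (c) DE at the previous time point
        expect_true(e$tf %in% wrow$retained[[1]])
        pos <- match(wins$first_time[wins$window == e$window], names(tc))
        prev <- if (pos > 1) tc[[pos - 1]] else tc[[pos]]
        expect_true(e$tf %in% prev)
      }
    }
  })
})

test_that("tightening the enrichment cut-off never adds edges", {
  repo <- cascade_repo()
  tc <- timecourse_de(list(`0h` = "A", `1h` = c("B", "C"), `2h` = c("B", "C")))
  wins <- windowed_de_union(tc, 2)
  loose <- build_cascade(repo, wins, tc, enrich_alpha = 0.10, max_rank = 1)
  tight <- build_cascade(repo, wins, tc, enrich_alpha = 0.01, max_rank = 1)
  key <- function(n) paste(n$edges$tf, n$edges$tg, n$edges$window)
  expect_true(all(key(tight) %in% key(loose)))
})

test_that("network export is deterministic, sorted, and round-trips", {
  repo <- cascade_repo()
  tc <- timecourse_de(list(`0h` = "A", `1h` = c("B", "C"), `2h` = c("B", "C")))
  net <- build_cascade(repo, windowed_de_union(tc, 2), tc,
                       enrich_alpha = 0.05, max_rank = 1)
  txt1 <- export_network(net, "tsv")
  txt2 <- export_network(net, "tsv")
  expect_identical(txt1, txt2)
  lines <- strsplit(txt1, "\n")[[1]]
  expect_equal(lines[1], "tf\ttg\twindow")
  expect_equal(lines[-1], sort(lines[-1]))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$edges, net$edges)
  # circos link text has one line per edge
  circ <- export_network(net, "circos")
  expect_equal(length(strsplit(circ, "\n")[[1]]), nrow(net$edges))
  expect_error(export_network(net, "dot"), class = "tfconcord_usage_error")
  empty <- build_cascade(cascade_repo(),
                         windowed_de_union(timecourse_de(list(a = "Q", b = "Q")), 2),
                         timecourse_de(list(a = "Q", b = "Q")))
  expect_equal(strsplit(export_network(empty, "tsv"), "\n")[[1]], "tf\ttg\twindow")
})
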