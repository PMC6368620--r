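test_that("module-set algebra obeys inclusion-exclusion on all inputs", {
  ms <- module_sets(letters[1:5], letters[6:10])
  expect_length(ms$core, 0)
  expect_length(ms$spectrum, 10)
  same <- module_sets(letters[1:5], letters[1:5])
  expect_setequal(same$core, same$spectrum)
  set.seed(3)
  for (rep in 1:20) {
    a <- sample(letters, sample(3:20, 1))
    b <- sample(letters, sample(3:20, 1))
    ms <- module_sets(a, b)
    expect_equal(length(ms$spectrum), length(ms$cmt2) + length(ms$hsp) - length(ms$core))
    expect_equal(length(ms$spectrum) + length(ms$core),
                 length(ms$cmt2) + length(ms$hsp))
    expect_length(intersect(ms$cmt2_only, ms$core), 0)
    expect_length(intersect(ms$cmt2_only, ms$hsp_only), 0)
  }
})

test_that("GMT parsing handles duplicates, blanks, and malformed lines", {
  f <- tempfile(fileext = ".gmt")
  writeLines(c(
    "set1\tdesc\tg1\tg2\tg3",
    "set2\tdesc\tg2\tg2\tg4",
    "",
    "set3\tdesc\tg5"
  ), f)
  db <- suppressWarnings(read_gmt(f))
  expect_length(db$sets, 3)
  expect_equal(length(db$sets$set2), 2)  # duplicate collapsed
  expect_warning(read_gmt(f), "empty line")
  bad <- tempfile(fileext = ".gmt")
  writeLines(c("set1\tdesc\tg1", "broken\tonlydesc"), bad)
  expect_error(read_gmt(bad), "line 2")
  # round-trip
  f2 <- tempfile(fileext = ".gmt")
  write_gmt(db, f2)
  expect_identical(read_gmt(f2)$sets, db$sets)
})

test_that("ora reproduces the exact hypergeometric tail", {
  bg <- paste0("g", 1:20)
  db <- pathway_db(list(pw = bg[1:5]), background = bg)
  rows <- ora(bg[c(1:3, 11, 12)], db)
  expect_equal(rows$overlap, 3)
  expect_equal(rows$p_value, (1050 + 75 + 1) / 15504)
  expect_equal(rows$p_value, ora_p_enum(20, 5, 5, 3))
  # zero overlap: p = 1, ratio 0
  rows0 <- ora(bg[11:15], db)
  expect_equal(rows0$p_value, 1)
  expect_equal(rows0$enrichment_ratio, 0)
  expect_error(ora(c("x1", "x2"), db), "share no genes")
})

test_that("ora matches exhaustive enumeration across small backgrounds", {
  set.seed(13)
  for (rep in 1:10) {
    n_bg <- sample(10:22, 1)
    bg <- paste0("g", seq_len(n_bg))
    set_size <- sample(3:(n_bg - 2), 1)
    q_size <- sample(2:5, 1)
    db <- pathway_db(list(pw = bg[seq_len(set_size)]), background = bg)
    query <- sample(bg, q_size)
    rows <- ora(query, db)
    expect_equal(rows$p_value, ora_p_enum(n_bg, set_size, q_size, rows$overlap),
                 tolerance = 1e-12)
  }
})

test_that("a fully recovered pathway outranks decoys", {
  db <- generate_gmt(10, 8, 300, rng_seed = 5)
  query <- db$sets$PW0003
  rows <- ora(query, db)
  expect_equal(rows$pathway[1], "PW0003")
  expect_equal(rows$overlap[1], 8)
})

test_that("BH adjustment is monotone and fdr bounds p", {
  db <- generate_gmt(25, 10, 400, rng_seed = 7)
  query <- c(db$sets$PW0001[1:6], paste0("bg0", sprintf("%03d", 1:6)))
  rows <- suppressMessages(ora(unique(query), db))
  expect_true(all(rows$fdr >= rows$p_value - 1e-12))
  sorted <- dplyr::arrange(rows, p_value)
  expect_true(all(diff(sorted$fdr) >= -1e-12))
})

test_that("FDR filtering is inclusive at the threshold", {
  rows <- tibble::tibble(pathway = c("a", "b", "c"), fdr = c(0.05, 0.2, 0.4))
  expect_equal(filter_fdr(rows)$pathway, c("a", "b"))
  expect_equal(nrow(filter_fdr(rows, 0.01)), 0)
  expect_equal(nrow(filter_fdr(rows, 1.0)), 3)
})

test_that("Jaccard grouping links pathways above the strict threshold", {
  sets <- list(
    p1 = c("a", "b", "c", "d"),
    p2 = c("c", "d", "e", "f"),   # J(p1,p2) = 2/6 > 0.1
    p3 = c("x", "y", "z"),        # disjoint from both
    p4 = c("a", "b", "c", "d")    # identical to p1
  )
  db <- pathway_db(sets)
  rows <- tibble::tibble(pathway = names(sets))
  groups <- pathway_jaccard_groups(rows, db, j_min = 0.1)
  comp <- stats::setNames(groups$component, groups$pathway)
  expect_equal(comp[["p1"]], comp[["p2"]])
  expect_equal(comp[["p1"]], comp[["p4"]])
  expect_false(comp[["p3"]] == comp[["p1"]])
  # strictness: J exactly at threshold does not link
  db2 <- pathway_db(list(q1 = letters[1:2], q2 = c("a", "x", "y", "z"),
                         q3 = c("m", "n")))  # J(q1,q2) = 1/5 = 0.2
  g2 <- pathway_jaccard_groups(tibble::tibble(pathway = c("q1", "q2", "q3")),
                               db2, j_min = 0.2)
  expect_length(unique(g2$component), 3)
  expect_error(pathway_jaccard_groups(tibble::tibble(pathway = character(0)), db),
               "no significant")
})

test_that("dominance assignment follows the documented decision table", {
  mk <- function(sig) tibble::tibble(pathway = names(sig), fdr = ifelse(sig, 0.01, 0.9))
  paths <- c("pA", "pB", "pC", "pD", "pE")
  res <- list(
    cmt2 = mk(c(pA = FALSE, pB = FALSE, pC = FALSE, pD = TRUE, pE = FALSE)),
    hsp = mk(c(pA = FALSE, pB = FALSE, pC = FALSE, pD = FALSE, pE = FALSE)),
    core = mk(c(pA = FALSE, pB = FALSE, pC = TRUE, pD = FALSE, pE = FALSE)),
    spectrum = mk(c(pA = FALSE, pB = FALSE, pC = FALSE, pD = FALSE, pE = FALSE)),
    cmt2_only = mk(c(pA = TRUE, pB = FALSE, pC = FALSE, pD = FALSE, pE = TRUE)),
    hsp_only = mk(c(pA = FALSE, pB = TRUE, pC = FALSE, pD = FALSE, pE = TRUE))
  )
  dom <- assign_dominance(res)
  got <- stats::setNames(dom$dominance, dom$pathway)
  expect_equal(got[["pA"]], "CMT2-dominant")  # exclusive-set significance
  expect_equal(got[["pB"]], "HSP-dominant")
  expect_equal(got[["pC"]], "AXONO")          # core only
  expect_equal(got[["pD"]], "AXONO")          # full-module only
  expect_equal(got[["pE"]], "AXONO")          # both exclusive sets
  # a pathway significant nowhere is excluded
  expect_false("pF" %in% dom$pathway)
  expect_error(assign_dominance(list(cmt2 = res$cmt2)), "cmt2_only")
})
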