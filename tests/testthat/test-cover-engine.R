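test_that("standard score counts uncovered genes", {
  expect_equal(score_standard(c("a", "b"), c("a", "b", "c")), 2)
  expect_equal(score_standard(c("b", "c"), "a"), 0)
  expect_equal(score_standard(c("x", "y"), character()), 0)
})

test_that("proportional score follows the size-regularised formula", {
  # |s| = 4, 2 uncovered, mean 8/3: 0.5 + 1/((4 - 8/3) * 1e4)
  expect_equal(
    score_proportional(letters[1:4], letters[1:2], mean_size = 8 / 3),
    0.5 + 1 / ((4 - 8 / 3) * 10000)
  )
  # size equal to the mean triggers the 0.5 divisor guard
  expect_equal(
    score_proportional(letters[1:3], letters[1:3], mean_size = 3),
    1 + 1 / (0.5 * 10000)
  )
  # fully covered pathway keeps only the size term
  expect_equal(
    score_proportional(letters[1:5], character(), mean_size = 4),
    1 / (1 * 10000)
  )
})

test_that("hitting score averages uncovered gene rarity over pathway size", {
  f <- c(g1 = 1, g2 = 2, g3 = 2)
  expect_equal(score_hitting(c("g1", "g2"), c("g1", "g2"), f), 0.75)
  expect_equal(score_hitting("g3", "g3", f), 0.5)
  expect_equal(score_hitting(c("g1", "g2"), character(), f), 0)
  expect_error(score_hitting(c("g1", "gX"), "g1", f), "gX")
  # the tibble form from gene_frequencies() is accepted too
  col <- collection_of(A = c("g1", "g2"), B = "g2")
  expect_equal(
    score_hitting(c("g1", "g2"), c("g1", "g2"), gene_frequencies(col)),
    0.75
  )
})

test_that("gene_frequencies counts pathway membership with set semantics", {
  col <- collection_of(A = c("a", "b"), B = c("b", "c"))
  f <- gene_frequencies(col)
  expect_equal(
    tibble::deframe(f)[c("a", "b", "c")],
    c(a = 1L, b = 2L, c = 1L)
  )
  expect_equal(gene_frequencies(collection_of(X = "x"))$n_pathways, 1L)
  dup <- geneset_collection(
    tibble::tibble(id = "A", genes = list(c("a", "a", "b")))
  )
  expect_equal(tibble::deframe(gene_frequencies(dup))[["a"]], 1L)
})

test_that("standard greedy cover replays the worked example", {
  res <- greedy_cover(four_set_collection(), "standard")
  expect_equal(res$selections$id, c("S1", "S3", "S4"))
  expect_equal(res$selections$new_genes, c(4L, 2L, 1L))
  # step 2 ties S3/S4 at score 2; lexicographically smaller id wins
  expect_equal(res$selections$score[2], 2)
  expect_setequal(res$covered_genes, as.character(1:7))
  expect_true(res$complete)
})

test_that("a pathway equal to the universe dominates under standard scoring", {
  col <- collection_of(
    Whole = letters[1:10], Sub1 = letters[1:4], Sub2 = letters[5:9]
  )
  for (alg in c("standard", "hitting", "proportional")) {
    res <- greedy_cover(col, alg)
    expect_setequal(res$covered_genes, letters[1:10])
  }
  expect_equal(greedy_cover(col, "standard")$selections$id, "Whole")
})

test_that("the GC target stops the loop early", {
  col <- collection_of(
    S1 = as.character(1:4), S2 = as.character(5:6),
    S3 = as.character(7:8)
  )
  res <- greedy_cover(col, "standard", gc_fraction = 0.5)
  # ceil(0.5 * 8) = 4 genes reached by the first selection
  expect_equal(nrow(res$selections), 1L)
  expect_equal(res$selections$id, "S1")
  expect_equal(length(res$covered_genes), 4L)
  expect_true(res$complete)
})

test_that("selection logs always record progress (candidate rule)", {
  for (seed in 1:20) {
    col <- random_instance(seed, max_pathways = 25, max_genes = 80)
    for (alg in c("standard", "proportional", "hitting")) {
      res <- greedy_cover(col, alg)
      expect_true(all(res$selections$new_genes >= 1L))
      expect_equal(sum(res$selections$new_genes),
                   length(res$covered_genes))
      expect_false(anyDuplicated(res$selections$id) > 0)
      expect_setequal(
        res$covered_genes,
        intersect(unique(unlist(res$pathways$genes)), gene_universe(col))
      )
    }
  }
})

test_that("coverage contract and prefix property hold across GC settings", {
  gcs <- c(0.9, 0.95, 1.0)
  for (seed in 21:40) {
    col <- random_instance(seed, max_pathways = 30, max_genes = 100)
    u <- length(gene_universe(col))
    for (alg in c("standard", "proportional", "hitting")) {
      sels <- lapply(gcs, function(g) {
        res <- greedy_cover(col, alg, gc_fraction = g)
        expect_gte(length(res$covered_genes), ceiling(g * u))
        res$selections$id
      })
      expect_identical(sels[[1]], sels[[2]][seq_along(sels[[1]])])
      expect_identical(sels[[2]], sels[[3]][seq_along(sels[[2]])])
    }
  }
})

test_that("optimized engine matches the naive full-rescan reference", {
  for (seed in 1:30) {
    col <- random_instance(seed)
    for (alg in c("standard", "proportional", "hitting")) {
      expect_identical(
        greedy_cover(col, alg)$selections$id,
        naive_greedy_cover(col, alg),
        info = sprintf("seed %d, %s", seed, alg)
      )
    }
  }
})

test_that("random tie policy is seed-reproducible and needs a seed", {
  col <- four_set_collection()
  expect_error(greedy_cover(col, "standard", tie_policy = "random"),
               "seed")
  a <- greedy_cover(col, "standard", tie_policy = "random", seed = 7L)
  b <- greedy_cover(col, "standard", tie_policy = "random", seed = 7L)
  expect_identical(a$selections, b$selections)
  # across seeds, tied selections can diverge while coverage is preserved
  ids <- vapply(1:20, function(s) {
    paste(greedy_cover(col, "standard", tie_policy = "random",
                       seed = s)$selections$id, collapse = ",")
  }, character(1))
  expect_true(length(unique(ids)) >= 1L)
  expect_setequal(a$covered_genes, as.character(1:7))
})

test_that("an uncoverable restricted universe flags, warns, and stops", {
  col <- collection_of(S1 = c("a", "b"))
  expect_warning(
    res <- greedy_cover(col, "standard",
                        universe = c("a", "b", "zz")),
    "no remaining pathway"
  )
  expect_false(res$complete)
  expect_setequal(res$covered_genes, c("a", "b"))
})

test_that("invalid engine parameters are rejected", {
  col <- four_set_collection()
  expect_error(greedy_cover(col, "standard", gc_fraction = 0), "\\(0, 1\\]")
  expect_error(greedy_cover(col, "standard", gc_fraction = 1.5), "\\(0, 1\\]")
  expect_error(greedy_cover(col, "standard", k = -1), "positive")
  expect_error(greedy_cover(col, "nope"))
})

test_that("tidy and glance summarise a cover result", {
  res <- greedy_cover(four_set_collection(), "standard")
  expect_identical(tidy(res), res$selections)
  g <- glance(res)
  expect_equal(g$n_selected, 3L)
  expect_equal(g$coverage, 1)
  expect_true(g$complete)
  expect_s3_class(autoplot(res), "ggplot")
})
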