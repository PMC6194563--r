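small_recipe <- function(seed, ...) {
  collection_recipe(
    n_modules = 12, module_size_range = c(3L, 10L), n_pathways = 60,
    size_meanlog = 2.2, size_sdlog = 0.6, seed = seed, ...
  )
}

test_that("generation is a pure function of the recipe (byte-identical GMT)", {
  r <- small_recipe(11)
  a <- generate_collection(r)
  b <- generate_collection(r)
  fa <- write_tmp_gmt(a)
  fb <- write_tmp_gmt(b)
  expect_identical(readLines(fa), readLines(fb))
  # a different seed changes the output
  fc <- write_tmp_gmt(generate_collection(small_recipe(12)))
  expect_false(identical(readLines(fa), readLines(fc)))
})

test_that("zero overlap intensity yields near-disjoint collections", {
  col <- generate_collection(
    small_recipe(3, overlap_intensity = 0, subset_rate = 0)
  )
  expect_lt(overlap_score(col), 1.2)
})

test_that("subset generation plants high-Jaccard pairs", {
  col <- generate_collection(collection_recipe(
    n_modules = 20, module_size_range = c(3L, 12L), n_pathways = 200,
    size_meanlog = 2.5, size_sdlog = 0.6, subset_rate = 0.5, seed = 5
  ))
  expect_gt(jaccard_distribution(col)$max, 0.5)
})

test_that("overlap score trends upward with overlap intensity", {
  mean_score <- function(intensity) {
    mean(vapply(1:20, function(seed) {
      overlap_score(generate_collection(
        small_recipe(seed, overlap_intensity = intensity, subset_rate = 0)
      ))
    }, numeric(1)))
  }
  scores <- vapply(c(0.1, 0.5, 0.9), mean_score, numeric(1))
  expect_true(all(diff(scores) > 0))
})

test_that("the benchmark recipe produces a heavily redundant collection", {
  col <- generate_collection(cpdb_like_recipe())
  expect_equal(nrow(col), 600L)
  expect_gt(overlap_score(col), 5)
  # long-tailed gene frequencies: singleton genes coexist with very
  # frequent ones
  f <- gene_frequencies(col)$n_pathways
  expect_gt(sum(f == 1), 0)
  expect_gt(max(f), 20)
  # several source databases are represented
  expect_gt(nrow(source_composition(col)), 5)
})

test_that("infeasible or invalid recipes are rejected", {
  expect_error(collection_recipe(n_pathways = 0), "at least 1")
  expect_error(collection_recipe(module_size_range = c(10L, 3L)),
               "increasing")
  expect_error(collection_recipe(overlap_intensity = 1.4), "\\[0, 1\\]")
  expect_error(
    collection_recipe(module_size_range = c(5000L, 6000L),
                      size_meanlog = 1, size_sdlog = 0.1),
    "Infeasible"
  )
})

test_that("enrichment studies assign hypergeometric tail p-values", {
  col <- generate_collection(small_recipe(8))
  study <- generate_enrichment_study(
    col, enrichment_recipe(n_de_genes = 40, enriched_module_ids = 1:3,
                           de_noise_rate = 0.1, seed = 2)
  )
  expect_equal(nrow(study$table), nrow(col))
  expect_true(all(study$table$p_adjusted >= 0 & study$table$p_adjusted <= 1))
  expect_false(is.unsorted(study$table$p_adjusted))
  # deterministic under the recipe seed
  study2 <- generate_enrichment_study(
    col, enrichment_recipe(n_de_genes = 40, enriched_module_ids = 1:3,
                           de_noise_rate = 0.1, seed = 2)
  )
  expect_identical(study, study2)
  # independent oracle for one pathway's p-value
  u <- length(gene_universe(col))
  i <- 5
  x <- length(intersect(col$genes[[i]], study$de_genes))
  m <- length(col$genes[[i]])
  expect_equal(
    study$table$p_adjusted[study$table$pathway_id == col$id[i]],
    phyper(x - 1, m, u - m, length(study$de_genes), lower.tail = FALSE)
  )
})

test_that("extreme DE overlaps pin the ends of the p-value scale", {
  col <- collection_of(
    M1 = sprintf("m%02d", 1:8),                 # identical to the DE set
    PART = c(sprintf("m%02d", 1:3), "x1", "x2"),
    DISJOINT = c("z1", "z2", "z3"),
    FILLER = sprintf("y%02d", 1:10)
  )
  attr(col, "modules") <- list(sprintf("m%02d", 1:8))
  study <- generate_enrichment_study(
    col, enrichment_recipe(n_de_genes = 8, enriched_module_ids = 1,
                           de_noise_rate = 0, seed = 1)
  )
  expect_setequal(study$de_genes, sprintf("m%02d", 1:8))
  tab <- study$table
  # the pathway equal to the DE set gets the minimum p-value
  expect_equal(tab$pathway_id[1], "M1")
  expect_lt(tab$p_adjusted[1], min(tab$p_adjusted[-1]))
  # disjoint pathways sit at p = 1 under the upper-tail convention
  expect_equal(tab$p_adjusted[tab$pathway_id == "DISJOINT"], 1)
  expect_equal(tab$p_adjusted[tab$pathway_id == "FILLER"], 1)
})

test_that("a planted subset pathway is removed by the enrichment cover", {
  # build a study where pathway SUB's DE genes are a strict subset of the
  # more-enriched SUPER's
  super <- sprintf("d%02d", 1:10)
  sub <- super[1:4]
  col <- collection_of(
    SUPER = super, SUB = sub, OTHER = c("d11", "d12", super[1])
  )
  ep <- enriched_pathways(
    tibble::tibble(pathway_id = c("SUPER", "SUB", "OTHER"),
                   p_adjusted = c(1e-6, 1e-4, 1e-3)),
    col, de_genes = c(super, "d11", "d12")
  )
  res <- enrichment_cover(ep)
  expect_equal(res$removed$id, "SUB")
  expect_equal(res$removed$covered_by, "SUPER")
  expect_true(all(res$retained$new_de_genes >= 1L))
})

test_that("recipes round-trip through YAML and JSON", {
  r <- small_recipe(4)
  ty <- withr::local_tempfile(fileext = ".yaml")
  r_yaml <- unclass(r)
  r_yaml$source_labels <- as.list(r_yaml$source_labels)  # YAML map, not seq
  yaml::write_yaml(r_yaml, ty)
  ry <- read_recipe(ty, "collection")
  expect_identical(
    write_tmp_gmt(generate_collection(ry)) |> readLines(),
    write_tmp_gmt(generate_collection(r)) |> readLines()
  )
  tj <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(r_yaml, tj, auto_unbox = TRUE, digits = NA)
  rj <- read_recipe(tj, "collection")
  expect_equal(rj$seed, r$seed)
  er <- enrichment_recipe(n_de_genes = 10, seed = 9)
  te <- withr::local_tempfile(fileext = ".yml")
  yaml::write_yaml(unclass(er), te)
  expect_equal(read_recipe(te, "enrichment")$n_de_genes, 10L)
})
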