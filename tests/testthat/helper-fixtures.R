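# Small in-code fixtures shared across test files.

collection_of <- function(...) {
  sets <- list(...)
  ids <- names(sets)
  if (is.null(ids)) ids <- sprintf("P%d", seq_along(sets))
  geneset_collection(tibble::tibble(id = ids, genes = sets))
}

# The four-set worked example: cover [S1, S3, S4] under standard scoring.
four_set_collection <- function() {
  collection_of(
    S1 = c("1", "2", "3", "4"),
    S2 = c("3", "4", "5"),
    S3 = c("5", "6"),
    S4 = c("6", "7")
  )
}

# Random instance for oracle / property tests: pathway gene sets sampled from
# a common pool so overlap and score ties are frequent.
random_instance <- function(seed, max_pathways = 50, max_genes = 200) {
  withr::with_seed(seed, {
    n_gene <- sample(20:max_genes, 1)
    n_path <- sample(5:max_pathways, 1)
    pool <- sprintf("g%03d", seq_len(n_gene))
    geneset_collection(tibble::tibble(
      id = sprintf("P%03d", seq_len(n_path)),
      genes = lapply(seq_len(n_path), function(i) {
        sample(pool, sample.int(min(30, n_gene), 1))
      })
    ))
  })
}

# Random enrichment study over a small shared gene pool, distinct p-values.
random_enriched <- function(seed) {
  withr::with_seed(seed, {
    n_gene <- sample(15:40, 1)
    n_path <- sample(5:25, 1)
    pool <- sprintf("g%02d", seq_len(n_gene))
    collection <- geneset_collection(tibble::tibble(
      id = sprintf("E%03d", seq_len(n_path)),
      genes = lapply(seq_len(n_path), function(i) {
        sample(pool, sample.int(min(12, n_gene), 1))
      })
    ))
    de <- sample(pool, sample(5:n_gene, 1))
    tab <- tibble::tibble(
      pathway_id = collection$id,
      p_adjusted = runif(n_path)
    )
    enriched_pathways(tab, collection, de)
  })
}

write_tmp_gmt <- function(collection) {
  path <- withr::local_tempfile(
    fileext = ".gmt", .local_envir = parent.frame()
  )
  write_gmt(collection, path)
  path
}
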