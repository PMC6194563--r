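#' Run a set-cover reduction end to end
#'
#' Reads a GMT collection, runs [greedy_cover()], and writes the artifacts
#' a reproducible run needs: the cover set as GMT (`cover.gmt`), the
#' selection log as TSV (`cover_steps.tsv`), before/after metrics reports
#' (`metrics_before.json`, `metrics_after.json`) and a provenance record
#' (`provenance.json`) echoing the full configuration and package version.
#'
#' @param gmt Path to the input GMT file.
#' @param out_dir Output directory (created if absent).
#' @inheritParams greedy_cover
#' @return Invisibly, a list with the `pathway_cover` result and the paths
#'   written.
#' @export
run_cover <- function(gmt, out_dir,
                      algorithm = c("hitting", "standard", "proportional"),
                      gc_fraction = 1, k = 10000,
                      tie_policy = c("deterministic", "random"),
                      seed = NULL) {
  algorithm <- arg_match(algorithm)
  tie_policy <- arg_match(tie_policy)
  collection <- read_gmt(gmt)
  res <- greedy_cover(collection, algorithm, gc_fraction = gc_fraction,
                      k = k, tie_policy = tie_policy, seed = seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    cover_gmt = file.path(out_dir, "cover.gmt"),
    steps = file.path(out_dir, "cover_steps.tsv"),
    metrics_before = file.path(out_dir, "metrics_before.json"),
    metrics_after = file.path(out_dir, "metrics_after.json"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_gmt(res$pathways, paths$cover_gmt)
  steps <- res$selections
  names(steps) <- c("step", "pathway_id", "score", "new_genes",
                    "cumulative_coverage_fraction")
  readr::write_tsv(steps, paths$steps)
  prov <- list(
    input = gmt, algorithm = algorithm, gc_fraction = gc_fraction, k = k,
    tie_policy = tie_policy, seed = seed
  )
  write_metrics_report(
    metrics_report(collection, provenance = prov), paths$metrics_before
  )
  write_metrics_report(
    metrics_report(res, provenance = prov), paths$metrics_after
  )
  write_provenance(paths$provenance, c(list(subcommand = "cover"), prov))
  invisible(list(result = res, paths = paths))
}

#' Run enrichment set cover end to end
#'
#' Reads a GMT collection, an enrichment table and a DE gene list, runs
#' [enrichment_cover()], and writes: the retained/removed table
#' (`enrichment_cover.tsv`), asymmetric-overlap matrices over the top
#' `top_n` pathways before and after the cover (`overlap_before.tsv`,
#' `overlap_after.tsv`), the coverage trace (`coverage_trace.tsv`) and a
#' provenance record.
#'
#' @param gmt Path to the GMT file.
#' @param enrichment_table Path to the TSV of `pathway_id`, `p_adjusted`.
#' @param de_genes Path to the DE gene list (one symbol per line).
#' @param out_dir Output directory.
#' @param top_n Number of top pathways in the overlap matrices.
#' @return Invisibly, a list with the `enrichment_cover` result and the
#'   paths written.
#' @export
run_enrich <- function(gmt, enrichment_table, de_genes, out_dir,
                       top_n = 10L) {
  collection <- read_gmt(gmt)
  de <- read_gene_list(de_genes)
  enriched <- read_enrichment_table(enrichment_table, collection, de)
  res <- enrichment_cover(enriched)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    table = file.path(out_dir, "enrichment_cover.tsv"),
    overlap_before = file.path(out_dir, "overlap_before.tsv"),
    overlap_after = file.path(out_dir, "overlap_after.tsv"),
    trace = file.path(out_dir, "coverage_trace.tsv"),
    provenance = file.path(out_dir, "provenance.json")
  )
  readr::write_tsv(tidy(res), paths$table)
  n_before <- min(top_n, nrow(enriched))
  write_matrix_tsv(
    asymmetric_overlap_matrix(enriched, enriched$id[seq_len(n_before)]),
    paths$overlap_before
  )
  n_after <- min(top_n, nrow(res$retained))
  write_matrix_tsv(
    asymmetric_overlap_matrix(enriched, res$retained$id[seq_len(n_after)]),
    paths$overlap_after
  )
  readr::write_tsv(coverage_trace(res), paths$trace)
  write_provenance(paths$provenance, list(
    subcommand = "enrich", gmt = gmt,
    enrichment_table = enrichment_table, de_genes = de_genes, top_n = top_n
  ))
  invisible(list(result = res, paths = paths))
}

#' Compute and write metrics for a GMT collection
#'
#' @param gmt Path to the GMT file.
#' @param out_dir Output directory; writes `metrics.json`,
#'   `jaccard_histogram.tsv` and `source_composition.tsv`.
#' @return Invisibly, the `metrics_report` and the paths written.
#' @export
run_metrics <- function(gmt, out_dir) {
  collection <- read_gmt(gmt)
  rep <- metrics_report(collection, provenance = list(input = gmt))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    metrics = file.path(out_dir, "metrics.json"),
    jaccard = file.path(out_dir, "jaccard_histogram.tsv"),
    sources = file.path(out_dir, "source_composition.tsv"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_metrics_report(rep, paths$metrics)
  if (!is.null(rep$jaccard_histogram)) {
    readr::write_tsv(rep$jaccard_histogram, paths$jaccard)
  }
  readr::write_tsv(source_composition(collection), paths$sources)
  write_provenance(paths$provenance, list(subcommand = "metrics", input = gmt))
  invisible(list(report = rep, paths = paths))
}

#' Generate a synthetic collection and enrichment study on disk
#'
#' @param out_dir Output directory; writes `collection.gmt`,
#'   `de_genes.txt`, `enrichment.tsv` and `provenance.json`.
#' @param recipe A [collection_recipe()], or a path readable by
#'   [read_recipe()]; defaults to [cpdb_like_recipe()].
#' @param enrichment An [enrichment_recipe()] (or `NULL` to skip the
#'   enrichment study).
#' @param seed Optional integer overriding both recipe seeds.
#' @return Invisibly, the generated collection and the paths written.
#' @export
run_simulate <- function(out_dir, recipe = cpdb_like_recipe(),
                         enrichment = enrichment_recipe(), seed = NULL) {
  if (is.character(recipe)) recipe <- read_recipe(recipe, "collection")
  if (is.character(enrichment)) {
    enrichment <- read_recipe(enrichment, "enrichment")
  }
  if (!is.null(seed)) {
    recipe$seed <- as.integer(seed)
    if (!is.null(enrichment)) enrichment$seed <- as.integer(seed)
  }
  collection <- generate_collection(recipe)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list(
    gmt = file.path(out_dir, "collection.gmt"),
    provenance = file.path(out_dir, "provenance.json")
  )
  write_gmt(collection, paths$gmt)
  if (!is.null(enrichment)) {
    study <- generate_enrichment_study(collection, enrichment)
    paths$de_genes <- file.path(out_dir, "de_genes.txt")
    paths$enrichment <- file.path(out_dir, "enrichment.tsv")
    readr::write_lines(study$de_genes, paths$de_genes)
    readr::write_tsv(study$table, paths$enrichment)
  }
  write_provenance(paths$provenance, list(
    subcommand = "simulate",
    recipe = unclass(recipe),
    enrichment_recipe = if (is.null(enrichment)) NULL else unclass(enrichment)
  ))
  invisible(list(collection = collection, paths = paths))
}

write_matrix_tsv <- function(m, path) {
  df <- as_tibble(m, rownames = "pathway_id")
  readr::write_tsv(df, path)
  invisible(path)
}

write_provenance <- function(path, config) {
  jsonlite::write_json(
    c(config, list(
      tool = "pathcover",
      version = as.character(utils::packageVersion("pathcover")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
    )),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}
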