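#' Build an enriched-pathway set from a results table
#'
#' Pairs a table of enrichment results (pathway id + adjusted p-value) with
#' the pathway collection it was computed against and the list of
#' differentially expressed (DE) genes. Pathways sharing no gene with the DE
#' list are dropped; the remaining entries are sorted ascending by
#' `(p_adjusted, id)`. The DE universe -- the DE genes present in at least
#' one retained pathway -- is attached as an attribute and is the gene
#' universe used by [enrichment_cover()].
#'
#' @param table A data frame with columns `pathway_id` and `p_adjusted`.
#' @param collection The [geneset_collection()] the enrichment was run
#'   against; every `pathway_id` must resolve in it.
#' @param de_genes Character vector of DE gene symbols (non-empty).
#' @return An `enriched_pathways` tibble with columns `id`, `source`,
#'   `p_adjusted`, `genes` (full gene set) and `de_genes` (gene set
#'   restricted to the DE list), carrying the DE universe as an attribute
#'   (see [gene_universe()]).
#' @export
enriched_pathways <- function(table, collection, de_genes) {
  if (!is.data.frame(table) ||
      !all(c("pathway_id", "p_adjusted") %in% names(table))) {
    abort("`table` must have columns `pathway_id` and `p_adjusted`.")
  }
  de_genes <- unique(as.character(de_genes))
  if (length(de_genes) == 0L) {
    abort("`de_genes` must contain at least one gene symbol.")
  }
  ids <- as.character(table$pathway_id)
  p <- as.numeric(table$p_adjusted)
  missing <- setdiff(ids, collection$id)
  if (length(missing) > 0L) {
    abort(paste0(
      "Enrichment table references pathway id(s) absent from the ",
      "collection: ", paste(missing, collapse = ", ")
    ))
  }
  bad_p <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad_p) > 0L) {
    abort(sprintf(
      "Adjusted p-value out of [0, 1] for pathway '%s': %s",
      ids[bad_p[1]], format(p[bad_p[1]])
    ))
  }
  idx <- match(ids, collection$id)
  out <- tibble(
    id = ids,
    source = collection$source[idx],
    p_adjusted = p,
    genes = collection$genes[idx],
    de_genes = map(collection$genes[idx], intersect, y = de_genes)
  )
  out <- out[lengths(out$de_genes) > 0L, ]
  if (nrow(out) == 0L) {
    abort("No enriched pathway shares a gene with `de_genes`.")
  }
  out <- out[order(out$p_adjusted, out$id, method = "radix"), ]
  attr(out, "universe") <- sort(unique(unlist(out$de_genes, use.names = FALSE)))
  class(out) <- c("enriched_pathways", class(tibble()))
  out
}

#' Read an enrichment-result table from a TSV file
#'
#' Thin wrapper around [enriched_pathways()]: reads a tab-delimited table
#' with header columns `pathway_id` and `p_adjusted` and pairs it with a
#' collection and DE gene list.
#'
#' @param path Path to the TSV file.
#' @inheritParams enriched_pathways
#' @return An `enriched_pathways` tibble; see [enriched_pathways()].
#' @export
read_enrichment_table <- function(path, collection, de_genes) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  enriched_pathways(tab, collection, de_genes)
}

#' @export
print.enriched_pathways <- function(x, ...) {
  cat(sprintf(
    "# Enriched pathways: %d entries, %d DE genes in the universe\n",
    nrow(x), length(gene_universe(x))
  ))
  NextMethod()
}
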