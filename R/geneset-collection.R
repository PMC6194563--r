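#' Construct a pathway gene-set collection
#'
#' A `geneset_collection` is a tibble with one row per pathway and columns
#' `id` (unique pathway identifier), `source` (origin database label, e.g.
#' `"KEGG"`, or `"unknown"`), `genes` (a list-column of character vectors,
#' duplicate-free) and `n_genes`. The collection carries its gene *universe*
#' -- the union of all pathway gene sets -- as an attribute, retrievable with
#' [gene_universe()].
#'
#' @param x A data frame with columns `id` and `genes` (list-column of
#'   character vectors); an optional `source` column defaults to `"unknown"`.
#' @return A `geneset_collection` tibble.
#' @examples
#' gc <- geneset_collection(tibble::tibble(
#'   id = c("P1", "P2"),
#'   genes = list(c("TP53", "BRCA1"), c("BRCA1", "EGFR"))
#' ))
#' gene_universe(gc)
#' @export
geneset_collection <- function(x) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame with columns `id` and `genes`.")
  }
  x <- as_tibble(x)
  if (!all(c("id", "genes") %in% names(x))) {
    abort("`x` must have columns `id` and `genes`.")
  }
  if (!"source" %in% names(x)) x$source <- "unknown"
  x$id <- as.character(x$id)
  x$source <- as.character(x$source)
  x$genes <- unname(map(x$genes, function(g) unique(as.character(g))))
  x <- x[, c("id", "source", "genes")]
  x$n_genes <- lengths(x$genes)
  validate_collection(x)
  new_geneset_collection(x)
}

new_geneset_collection <- function(x) {
  attr(x, "universe") <- sort(unique(unlist(x$genes, use.names = FALSE)))
  class(x) <- c("geneset_collection", class(tibble()))
  x
}

validate_collection <- function(x) {
  if (nrow(x) < 1L) {
    abort("A gene-set collection must contain at least one pathway.")
  }
  if (anyNA(x$id) || any(!nzchar(x$id))) {
    abort("Pathway ids must be non-empty.")
  }
  dup <- unique(x$id[duplicated(x$id)])
  if (length(dup) > 0L) {
    abort(paste0(
      "Duplicate pathway id(s): ", paste(dup, collapse = ", ")
    ))
  }
  empty <- x$id[lengths(x$genes) == 0L]
  if (length(empty) > 0L) {
    abort(paste0(
      "Pathway(s) with empty gene sets: ", paste(empty, collapse = ", ")
    ))
  }
  invisible(x)
}

#' Gene universe of a collection
#'
#' The set of all distinct gene symbols appearing in at least one pathway.
#'
#' @param x A [geneset_collection()] or an `enriched_pathways` table (for the
#'   latter the DE-gene universe is returned).
#' @return A character vector of gene symbols.
#' @export
gene_universe <- function(x) {
  u <- attr(x, "universe", exact = TRUE)
  if (is.null(u)) {
    u <- sort(unique(unlist(x$genes, use.names = FALSE)))
  }
  u
}

#' Subset a collection to a set of pathways
#'
#' Returns a new collection containing only the requested pathways, in the
#' requested order, with the universe recomputed over the subset. Useful for
#' computing metrics on a cover result.
#'
#' @param collection A [geneset_collection()].
#' @param ids Character vector of pathway ids; all must resolve.
#' @return A `geneset_collection` restricted to `ids`.
#' @export
select_pathways <- function(collection, ids) {
  missing <- setdiff(ids, collection$id)
  if (length(missing) > 0L) {
    abort(paste0(
      "Unknown pathway id(s): ", paste(missing, collapse = ", ")
    ))
  }
  idx <- match(ids, collection$id)
  out <- as_tibble(collection)[idx, ]
  new_geneset_collection(out)
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf(
    "# A gene-set collection: %d pathways, %d genes in the universe\n",
    nrow(x), length(gene_universe(x))
  ))
  NextMethod()
}
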