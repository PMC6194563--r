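#' Set cover over pathway-enrichment results
#'
#' Reduces redundancy among enriched pathways while preserving the ranking
#' given by the enrichment p-values. The universe is the set of
#' differentially expressed (DE) genes mappable to at least one enriched
#' pathway, and every pathway counts only its DE genes. Walking the entries
#' in ascending p-value order, a pathway is retained iff it still contains
#' at least one uncovered DE gene; otherwise all of its DE genes are already
#' covered by more-enriched pathways and it is removed. Equivalently, the
#' procedure repeatedly takes the argmax of `(1 - p) * b`, where `b`
#' indicates a non-empty intersection with the uncovered set; both
#' formulations are implemented (`method`) and produce identical results
#' when p-values are distinct (ties are ordered by `(p, id)`).
#'
#' @param enriched An [enriched_pathways()] table (sorted ascending by
#'   p-value, as the constructor guarantees).
#' @param method `"walk"` (sequential scan, default) or `"argmax"` (literal
#'   repeated argmax of the score). Both yield the same cover; two routes
#'   are kept so they can be cross-checked.
#' @return An `enrichment_cover` object: a list with `retained` (tibble of
#'   rank, id, p_adjusted, new_de_genes), `removed` (tibble of id,
#'   p_adjusted, covered_by -- the earliest retained pathway whose set,
#'   together with the retained pathways before it, covers the removed
#'   one), `de_covered`, and `enriched` (the input). Supports [tidy()],
#'   [glance()] and [autoplot()].
#' @examples
#' gc <- geneset_collection(tibble::tibble(
#'   id = c("A", "B", "C"),
#'   genes = list(c("g1", "g2", "g3"), c("g2", "g3"), c("g3", "g4"))
#' ))
#' ep <- enriched_pathways(
#'   tibble::tibble(pathway_id = c("A", "B", "C"),
#'                  p_adjusted = c(0.001, 0.002, 0.003)),
#'   gc, de_genes = c("g1", "g2", "g3", "g4")
#' )
#' enrichment_cover(ep)$retained
#' @export
enrichment_cover <- function(enriched, method = c("walk", "argmax")) {
  method <- arg_match(method)
  de_universe <- gene_universe(enriched)
  if (length(de_universe) == 0L) {
    abort("The DE universe is empty; nothing to cover.")
  }
  de_sets <- map(enriched$de_genes, intersect, y = de_universe)

  keep <- logical(nrow(enriched))
  new_counts <- integer(nrow(enriched))
  if (method == "walk") {
    uncovered <- de_universe
    for (i in seq_len(nrow(enriched))) {
      new <- intersect(de_sets[[i]], uncovered)
      if (length(new) > 0L) {
        keep[i] <- TRUE
        new_counts[i] <- length(new)
        uncovered <- setdiff(uncovered, new)
      }
    }
  } else {
    uncovered <- de_universe
    remaining <- seq_len(nrow(enriched))
    while (length(remaining) > 0L) {
      b <- map_lgl(de_sets[remaining],
                   function(s) length(intersect(s, uncovered)) > 0L)
      if (!any(b)) break
      v <- (1 - enriched$p_adjusted[remaining]) * b
      v[!b] <- -Inf   # b = 0 bars selection even when p = 1 makes v ties at 0
      # ties on v resolve to the entry order, i.e. ascending (p, id)
      pick <- remaining[which.max(v)]
      keep[pick] <- TRUE
      new_counts[pick] <- length(intersect(de_sets[[pick]], uncovered))
      uncovered <- setdiff(uncovered, de_sets[[pick]])
      remaining <- setdiff(remaining, pick)
    }
  }

  retained <- tibble(
    rank = seq_len(sum(keep)),
    id = enriched$id[keep],
    p_adjusted = enriched$p_adjusted[keep],
    new_de_genes = new_counts[keep]
  )
  removed_idx <- which(!keep)
  covered_by <- map_chr(removed_idx, function(i) {
    target <- de_sets[[i]]
    acc <- character(0)
    for (r in seq_len(nrow(retained))) {
      acc <- union(acc, de_sets[[which(enriched$id == retained$id[r])]])
      if (all(target %in% acc)) return(retained$id[r])
    }
    NA_character_
  })
  removed <- tibble(
    id = enriched$id[removed_idx],
    p_adjusted = enriched$p_adjusted[removed_idx],
    covered_by = covered_by
  )
  structure(
    list(
      retained = retained,
      removed = removed,
      de_covered = sort(unique(unlist(de_sets[keep], use.names = FALSE))),
      enriched = enriched
    ),
    class = "enrichment_cover"
  )
}

#' Asymmetric overlap matrix between enriched pathways
#'
#' Entry (A, B) is the proportion of pathway A's DE genes that also belong
#' to pathway B: `|A ∩ B ∩ DE| / |A ∩ DE|`. The diagonal is 1 and the
#' matrix is generally not symmetric -- a subset pathway has a full row of
#' 1 against its superset, while the superset's entry is the size ratio.
#'
#' @param enriched An [enriched_pathways()] table.
#' @param ids Pathway ids (rows/columns, in order); each must resolve in
#'   `enriched` and intersect the DE universe.
#' @return A square numeric matrix with `ids` as dimnames.
#' @export
asymmetric_overlap_matrix <- function(enriched, ids) {
  missing <- setdiff(ids, enriched$id)
  if (length(missing) > 0L) {
    abort(paste0(
      "Unknown enriched pathway id(s): ", paste(missing, collapse = ", ")
    ))
  }
  de_universe <- gene_universe(enriched)
  sets <- map(
    enriched$de_genes[match(ids, enriched$id)],
    intersect, y = de_universe
  )
  empty <- ids[lengths(sets) == 0L]
  if (length(empty) > 0L) {
    abort(paste0(
      "Pathway(s) without DE genes: ", paste(empty, collapse = ", ")
    ))
  }
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (a in seq_len(n)) {
    for (b in seq_len(n)) {
      m[a, b] <- length(intersect(sets[[a]], sets[[b]])) / length(sets[[a]])
    }
  }
  m
}

#' Fraction of DE genes covered by the top pathways
#'
#' The share of the DE universe contained in the union of the first
#' `min(top_n, length(ids))` pathways. Comparing this quantity for the
#' original p-ordered list and for the retained list of an
#' [enrichment_cover()] shows how much more of the DE gene set the same
#' number of top pathways describes after redundancy removal.
#'
#' @param enriched An [enriched_pathways()] table.
#' @param ids Ordered pathway ids.
#' @param top_n Number of leading pathways to pool (>= 1); values beyond
#'   `length(ids)` are clamped.
#' @return A fraction in \[0, 1\].
#' @export
coverage_fraction <- function(enriched, ids, top_n) {
  stopifnot(top_n >= 1L)
  missing <- setdiff(ids, enriched$id)
  if (length(missing) > 0L) {
    abort(paste0(
      "Unknown enriched pathway id(s): ", paste(missing, collapse = ", ")
    ))
  }
  de_universe <- gene_universe(enriched)
  use <- ids[seq_len(min(top_n, length(ids)))]
  pool <- unique(unlist(
    enriched$de_genes[match(use, enriched$id)],
    use.names = FALSE
  ))
  length(intersect(pool, de_universe)) / length(de_universe)
}

#' Coverage trace before vs after enrichment set cover
#'
#' For every n up to the input list length, the DE-gene coverage of the
#' first n pathways in original p order (`coverage_before`) and in the
#' retained order (`coverage_after`, clamped at the retained list length).
#'
#' @param cover An [enrichment_cover()] result.
#' @return A tibble with columns `n`, `coverage_before`, `coverage_after`.
#' @export
coverage_trace <- function(cover) {
  enriched <- cover$enriched
  n_max <- nrow(enriched)
  tibble(
    n = seq_len(n_max),
    coverage_before = map_dbl(
      seq_len(n_max),
      function(n) coverage_fraction(enriched, enriched$id, n)
    ),
    coverage_after = map_dbl(
      seq_len(n_max),
      function(n) coverage_fraction(enriched, cover$retained$id, n)
    )
  )
}

#' @export
print.enrichment_cover <- function(x, ...) {
  cat(sprintf(
    "# Enrichment set cover: %d of %d pathways retained; %d/%d DE genes covered\n",
    nrow(x$retained), nrow(x$enriched),
    length(x$de_covered), length(gene_universe(x$enriched))
  ))
  print(x$retained, ...)
  invisible(x)
}

#' @describeIn enrichment_cover All input pathways with their status:
#'   columns rank (in the input p order), id, p_adjusted, status
#'   (`"retained"`/`"removed"`), new_de_genes, covered_by.
#' @param x An `enrichment_cover` object.
#' @param ... Unused.
#' @export
tidy.enrichment_cover <- function(x, ...) {
  status <- ifelse(x$enriched$id %in% x$retained$id, "retained", "removed")
  out <- tibble(
    rank = seq_len(nrow(x$enriched)),
    id = x$enriched$id,
    p_adjusted = x$enriched$p_adjusted,
    status = status
  )
  out <- left_join(
    out,
    x$retained[, c("id", "new_de_genes")],
    by = "id"
  )
  left_join(out, x$removed[, c("id", "covered_by")], by = "id")
}

#' @describeIn enrichment_cover One-row summary: input/retained counts and
#'   top-10 DE coverage before and after.
#' @export
glance.enrichment_cover <- function(x, ...) {
  tibble(
    n_input = nrow(x$enriched),
    n_retained = nrow(x$retained),
    n_removed = nrow(x$removed),
    de_genes = length(gene_universe(x$enriched)),
    top10_coverage_before = coverage_fraction(x$enriched, x$enriched$id, 10L),
    top10_coverage_after = coverage_fraction(x$enriched, x$retained$id, 10L)
  )
}

#' @describeIn enrichment_cover Coverage-vs-n curves before and after the
#'   cover.
#' @param object An `enrichment_cover` object.
#' @export
autoplot.enrichment_cover <- function(object, ...) {
  tr <- tidyr::pivot_longer(
    coverage_trace(object), -"n",
    names_to = "stage", names_prefix = "coverage_",
    values_to = "coverage"
  )
  ggplot2::ggplot(
    tr, ggplot2::aes(x = .data$n, y = .data$coverage, colour = .data$stage)
  ) +
    ggplot2::geom_step() +
    ggplot2::labs(
      x = "Top n pathways", y = "Fraction of DE genes covered",
      colour = NULL
    ) +
    ggplot2::ylim(0, 1)
}

#' Heat-map of an asymmetric overlap matrix
#'
#' @param m A matrix from [asymmetric_overlap_matrix()].
#' @return A ggplot object.
#' @export
plot_overlap_matrix <- function(m) {
  df <- as_tibble(as.table(m), .name_repair = "minimal")
  names(df) <- c("row_pathway", "col_pathway", "overlap")
  df$row_pathway <- factor(df$row_pathway, levels = rev(rownames(m)))
  df$col_pathway <- factor(df$col_pathway, levels = colnames(m))
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$col_pathway, y = .data$row_pathway,
                 fill = .data$overlap)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "red3",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Overlap") +
    ggplot2::theme(
      axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)
    )
}
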