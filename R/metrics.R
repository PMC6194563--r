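#' Overlap score of a pathway collection
#'
#' The mean number of pathways that each gene appears in, computed as the
#' total pathway size divided by the number of distinct genes:
#' `sum(|s_i|) / |union(s_i)|`. A pairwise-disjoint collection scores
#' exactly 1, so the score measures redundancy above the discrete
#' baseline. For a cover result, the denominator counts only genes covered
#' by the selected pathways (genes left uncovered by a GC target below
#' 100% are excluded, keeping the score's floor at 1).
#'
#' @param x A [geneset_collection()] or a `pathway_cover` result.
#' @param ... Unused.
#' @return A single number >= 1.
#' @export
overlap_score <- function(x, ...) {
  UseMethod("overlap_score")
}

#' @export
overlap_score.geneset_collection <- function(x, ...) {
  validate_collection(x)
  sum(lengths(x$genes)) / length(gene_universe(x))
}

#' @export
overlap_score.pathway_cover <- function(x, ...) {
  if (is.null(x$pathways)) abort("Empty cover result.")
  overlap_score(x$pathways)
}

#' @export
overlap_score.default <- function(x, ...) {
  overlap_score(geneset_collection(x))
}

#' Redundancy reduction percentage
#'
#' Normalised drop in overlap score between an original collection and a
#' reduced one: `100 * (original - new) / (original - 1)`. The `- 1`
#' anchors the scale at a completely discrete pathway set (overlap score
#' 1), which constitutes 100% reduction; reducing nothing scores 0.
#'
#' @param original_score Overlap score of the original collection (> 1).
#' @param new_score Overlap score of the reduced collection (>= 1).
#' @return The reduction percentage (conventionally reported rounded to
#'   the nearest whole percent).
#' @examples
#' round(reduction_percent(12.4, 4.1)) # 73
#' @export
reduction_percent <- function(original_score, new_score) {
  if (original_score <= 1) {
    abort("`original_score` must exceed 1 for a reduction to be defined.")
  }
  if (new_score < 1) abort("`new_score` cannot fall below 1.")
  100 * (original_score - new_score) / (original_score - 1)
}

#' Jaccard similarity between two gene sets
#'
#' `|a ∩ b| / |a ∪ b|`.
#'
#' @param a,b Character vectors (at least one non-empty).
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) abort("Jaccard similarity of two empty sets is undefined.")
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard distribution of a collection
#'
#' Scores every unordered pathway pair and summarises the distribution as
#' a histogram over \[0, 1\] (right-closed bins, with exactly-zero pairs
#' counted in a separate first row) plus the maximum.
#'
#' @param collection A [geneset_collection()] with >= 2 pathways.
#' @param bins Number of equal-width bins over (0, 1]; default 20.
#' @return A `jaccard_distribution` list: `histogram` (tibble of
#'   `bin_lower`, `bin_upper`, `count`), `max`, `n_pairs`. Supports
#'   [autoplot()].
#' @export
jaccard_distribution <- function(collection, bins = 20) {
  validate_collection(collection)
  n <- nrow(collection)
  if (n < 2L) {
    abort("At least two pathways are needed for a pairwise distribution.")
  }
  sets <- map(collection$genes, unique)
  pair_idx <- combn(n, 2L)
  vals <- vapply(seq_len(ncol(pair_idx)), function(j) {
    jaccard(sets[[pair_idx[1, j]]], sets[[pair_idx[2, j]]])
  }, numeric(1))
  breaks <- seq(0, 1, length.out = bins + 1L)
  pos <- vals[vals > 0]
  cnt <- if (length(pos) > 0L) {
    tabulate(cut(pos, breaks = breaks, include.lowest = FALSE), nbins = bins)
  } else {
    integer(bins)
  }
  hist <- tibble(
    bin_lower = c(0, breaks[-length(breaks)]),
    bin_upper = c(0, breaks[-1]),
    count = c(sum(vals == 0), cnt)
  )
  structure(
    list(histogram = hist, max = max(vals), n_pairs = length(vals)),
    class = "jaccard_distribution"
  )
}

#' @export
print.jaccard_distribution <- function(x, ...) {
  cat(sprintf(
    "# Jaccard distribution over %d pathway pairs (max %.3f)\n",
    x$n_pairs, x$max
  ))
  print(x$histogram, ...)
  invisible(x)
}

#' @export
autoplot.jaccard_distribution <- function(object, ...) {
  h <- object$histogram
  h$mid <- (h$bin_lower + h$bin_upper) / 2
  ggplot2::ggplot(h, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(range(h$mid)) / nrow(h) * 0.9) +
    ggplot2::labs(x = "Jaccard similarity", y = "Pathway pairs")
}

#' Pathway size statistics
#'
#' Mean, sample standard deviation (n - 1 denominator), maximum and median
#' of the pathway sizes `|s_i|`.
#'
#' @param collection A [geneset_collection()].
#' @return A one-row tibble with columns `n_pathways`, `size_mean`,
#'   `size_sd`, `size_max`, `size_median`.
#' @export
size_stats <- function(collection) {
  validate_collection(collection)
  sizes <- lengths(collection$genes)
  tibble(
    n_pathways = length(sizes),
    size_mean = mean(sizes),
    size_sd = if (length(sizes) > 1L) sd(sizes) else 0,
    size_max = max(sizes),
    size_median = median(sizes)
  )
}

#' Source-database composition
#'
#' Share of pathways contributed by each source database.
#'
#' @param collection A [geneset_collection()].
#' @return A tibble with columns `source`, `n`, `proportion` (summing to
#'   1), sorted by decreasing proportion.
#' @export
source_composition <- function(collection) {
  validate_collection(collection)
  out <- count(as_tibble(collection), .data$source, name = "n")
  out$proportion <- out$n / sum(out$n)
  arrange(out, dplyr::desc(.data$proportion), .data$source)
}

#' Full redundancy-metrics report
#'
#' Bundles the redundancy and structure metrics for a collection (or the
#' selected sub-collection of a cover result): overlap score, pathway and
#' covered-gene counts, size statistics, Jaccard distribution and source
#' composition, plus any provenance fields supplied.
#'
#' @param x A [geneset_collection()] or `pathway_cover`.
#' @param bins Histogram bins for the Jaccard distribution.
#' @param provenance Optional named list echoed into the report (input
#'   file, algorithm, gc_fraction, seed, ...).
#' @return A `metrics_report` list; serialise with
#'   [write_metrics_report()].
#' @export
metrics_report <- function(x, bins = 20, provenance = list()) {
  collection <- if (inherits(x, "pathway_cover")) x$pathways else x
  validate_collection(collection)
  jd <- if (nrow(collection) >= 2L) {
    jaccard_distribution(collection, bins = bins)
  } else {
    NULL
  }
  structure(
    list(
      overlap_score = overlap_score(collection),
      n_pathways = nrow(collection),
      n_genes_covered = length(gene_universe(collection)),
      size = size_stats(collection),
      jaccard_max = if (is.null(jd)) NA_real_ else jd$max,
      jaccard_histogram = if (is.null(jd)) NULL else jd$histogram,
      source_composition = source_composition(collection),
      provenance = provenance
    ),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "# Metrics: %d pathways, %d genes, overlap score %.3f, max Jaccard %s\n",
    x$n_pathways, x$n_genes_covered, x$overlap_score,
    ifelse(is.na(x$jaccard_max), "NA", sprintf("%.3f", x$jaccard_max))
  ))
  print(x$size, ...)
  invisible(x)
}

#' @describeIn metrics_report Write the report as JSON.
#' @param report A `metrics_report`.
#' @param path Output path.
#' @export
write_metrics_report <- function(report, path) {
  jsonlite::write_json(
    unclass(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}
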