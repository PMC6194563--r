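#' Greedy set cover over a pathway collection
#'
#' Iteratively selects pathways until at least `ceiling(gc_fraction * |U|)`
#' genes of the universe `U` are covered (or no pathway can add a new gene).
#' At every step, only *candidate* pathways -- those contributing at least
#' one uncovered gene -- are scored, and the argmax of the chosen scoring
#' rule is selected:
#'
#' * `"standard"`: number of uncovered genes ([score_standard()]);
#' * `"proportional"`: proportion of uncovered genes plus a mean-size
#'   preference term ([score_proportional()]);
#' * `"hitting"`: rarity-weighted uncovered-gene value divided by pathway
#'   size ([score_hitting()]).
#'
#' The mean pathway size and the gene frequencies are computed once over the
#' full input collection and frozen for the run. Scores are compared with a
#' relative tolerance of 1e-12 so the argmax is stable across platforms;
#' residual ties are broken by the largest newly-covered count, then the
#' lexicographically smallest pathway id (`tie_policy = "deterministic"`,
#' the default) or uniformly at random under a mandatory seed
#' (`tie_policy = "random"`).
#'
#' Lowering `gc_fraction` below 1 stops the algorithm before the last, most
#' redundant selections; under deterministic ties the result for a smaller
#' fraction is a prefix of the result for a larger one.
#'
#' @param collection A [geneset_collection()].
#' @param algorithm One of `"standard"`, `"proportional"`, `"hitting"`.
#' @param gc_fraction Gene-coverage target in (0, 1]: the fraction of the
#'   universe that must be covered before stopping. Default 1.
#' @param k Size-term constant for the proportional score; default 10000.
#' @param tie_policy `"deterministic"` (default) or `"random"`.
#' @param seed Integer seed, required when `tie_policy = "random"`.
#' @param universe Optional character vector restricting the target
#'   universe; defaults to the collection universe. If the collection cannot
#'   cover the requested number of universe genes, the run terminates with
#'   a warning and the result is flagged `complete = FALSE`.
#' @return A `pathway_cover` object: a list with `selections` (tibble of
#'   step, id, score, new_genes, coverage), `covered_genes`, `pathways`
#'   (the selected sub-collection), `algorithm`, `parameters` and
#'   `complete`. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' gc <- geneset_collection(tibble::tibble(
#'   id = c("S1", "S2", "S3", "S4"),
#'   genes = list(c("1", "2", "3", "4"), c("3", "4", "5"),
#'                c("5", "6"), c("6", "7"))
#' ))
#' greedy_cover(gc, "standard")$selections
#' @export
greedy_cover <- function(collection,
                         algorithm = c("hitting", "standard", "proportional"),
                         gc_fraction = 1, k = 10000,
                         tie_policy = c("deterministic", "random"),
                         seed = NULL, universe = NULL) {
  algorithm <- arg_match(algorithm)
  tie_policy <- arg_match(tie_policy)
  stopifnot(is.numeric(gc_fraction), length(gc_fraction) == 1L)
  if (gc_fraction <= 0 || gc_fraction > 1) {
    abort("`gc_fraction` must lie in (0, 1].")
  }
  if (k <= 0) abort("`k` must be positive.")
  if (tie_policy == "random" && is.null(seed)) {
    abort("`tie_policy = \"random\"` requires an integer `seed`.")
  }
  validate_collection(collection)

  if (is.null(universe)) {
    universe <- gene_universe(collection)
  } else {
    universe <- sort(unique(as.character(universe)))
    if (length(universe) == 0L) abort("`universe` must be non-empty.")
  }
  run <- function() {
    greedy_cover_engine(collection, algorithm, gc_fraction, k,
                        tie_policy, universe)
  }
  res <- if (tie_policy == "random") withr::with_seed(seed, run()) else run()

  params <- list(
    algorithm = algorithm, gc_fraction = gc_fraction, k = k,
    tie_policy = tie_policy, seed = seed,
    mean_size = mean(lengths(collection$genes)),
    n_pathways_in = nrow(collection), universe_size = length(universe),
    target_genes = as.integer(ceiling(gc_fraction * length(universe)))
  )
  out <- structure(
    list(
      selections = res$selections,
      covered_genes = res$covered,
      pathways = if (nrow(res$selections) > 0L) {
        select_pathways(collection, res$selections$id)
      } else {
        NULL
      },
      algorithm = algorithm,
      parameters = params,
      complete = res$complete
    ),
    class = "pathway_cover"
  )
  if (!res$complete) {
    warn(sprintf(
      "Cover stopped at %d of the %d targeted genes: no remaining pathway covers a new universe gene.",
      length(res$covered), params$target_genes
    ))
  }
  out
}

# Incremental engine: per-pathway uncovered counts (and rarity-weighted sums
# for the hitting score) are updated through a gene -> pathway inverted index
# instead of rescanning every pathway each iteration.
greedy_cover_engine <- function(collection, algorithm, gc_fraction, k,
                                tie_policy, universe) {
  n_path <- nrow(collection)
  ids <- collection$id
  sizes <- lengths(collection$genes)
  n_univ <- length(universe)
  target <- as.integer(ceiling(gc_fraction * n_univ))

  # gene sets as indices into `universe`; genes outside it never count
  gene_idx <- map(collection$genes, function(g) {
    m <- match(g, universe)
    m[!is.na(m)]
  })
  inv <- split(
    rep(seq_len(n_path), lengths(gene_idx)),
    factor(unlist(gene_idx), levels = seq_len(n_univ))
  )

  # frozen run constants (full-collection mean size and frequencies)
  mean_size <- mean(sizes)
  freq_tab <- gene_frequencies(collection)
  freq_all <- setNames(as.numeric(freq_tab$n_pathways), freq_tab$gene)
  gene_value <- 1 / freq_all[universe]          # NA for genes absent: impossible
  size_term <- 1 / (pmax(abs(sizes - mean_size), 0.5) * k)

  uncovered <- rep(TRUE, n_univ)
  uncov_count <- vapply(gene_idx, length, integer(1))
  uncov_wsum <- if (algorithm == "hitting") {
    vapply(gene_idx, function(g) sum(gene_value[g]), numeric(1))
  } else {
    NULL
  }

  covered_n <- 0L
  sel_id <- character(0)
  sel_score <- numeric(0)
  sel_new <- integer(0)
  sel_cov <- numeric(0)

  while (covered_n < target) {
    cand <- which(uncov_count > 0L)
    if (length(cand) == 0L) break
    score <- switch(algorithm,
      standard = as.numeric(uncov_count[cand]),
      proportional = uncov_count[cand] / sizes[cand] + size_term[cand],
      hitting = uncov_wsum[cand] / sizes[cand]
    )
    best <- max(score)
    ties <- cand[score >= best - abs(best) * 1e-12]
    if (length(ties) > 1L) {
      if (tie_policy == "deterministic") {
        nn <- uncov_count[ties]
        ties <- ties[nn == max(nn)]
        pick <- ties[order(ids[ties], method = "radix")[1]]
      } else {
        pick <- ties[sample.int(length(ties), 1L)]
      }
    } else {
      pick <- ties
    }

    newly <- gene_idx[[pick]][uncovered[gene_idx[[pick]]]]
    uncovered[newly] <- FALSE
    covered_n <- covered_n + length(newly)
    for (g in newly) {
      ps <- inv[[g]]
      uncov_count[ps] <- uncov_count[ps] - 1L
      if (!is.null(uncov_wsum)) {
        uncov_wsum[ps] <- uncov_wsum[ps] - gene_value[g]
      }
    }
    # guard against float drift driving a sum slightly negative
    if (!is.null(uncov_wsum)) uncov_wsum[uncov_wsum < 0] <- 0

    sel_id <- c(sel_id, ids[pick])
    sel_score <- c(sel_score, best)
    sel_new <- c(sel_new, length(newly))
    sel_cov <- c(sel_cov, covered_n / n_univ)
  }

  list(
    selections = tibble(
      step = seq_along(sel_id), id = sel_id, score = sel_score,
      new_genes = sel_new, coverage = sel_cov
    ),
    covered = universe[!uncovered],
    complete = covered_n >= target
  )
}

#' @export
print.pathway_cover <- function(x, ...) {
  p <- x$parameters
  cat(sprintf(
    "# %s set cover: %d pathways selected, %d/%d genes covered (GC target %.0f%%)%s\n",
    x$algorithm, nrow(x$selections), length(x$covered_genes),
    p$universe_size, 100 * p$gc_fraction,
    if (x$complete) "" else " [incomplete]"
  ))
  print(x$selections, ...)
  invisible(x)
}

#' @describeIn greedy_cover Step-by-step selection log as a tibble.
#' @param x A `pathway_cover` object.
#' @param ... Unused.
#' @export
tidy.pathway_cover <- function(x, ...) {
  x$selections
}

#' @describeIn greedy_cover One-row summary (algorithm, pathways selected,
#'   genes covered, coverage fraction, completeness).
#' @export
glance.pathway_cover <- function(x, ...) {
  tibble(
    algorithm = x$algorithm,
    gc_fraction = x$parameters$gc_fraction,
    n_selected = nrow(x$selections),
    n_genes_covered = length(x$covered_genes),
    coverage = length(x$covered_genes) / x$parameters$universe_size,
    complete = x$complete
  )
}

#' @describeIn greedy_cover Cumulative gene-coverage curve over selection
#'   steps.
#' @param object A `pathway_cover` object.
#' @export
autoplot.pathway_cover <- function(object, ...) {
  ggplot2::ggplot(
    object$selections,
    ggplot2::aes(x = .data$step, y = .data$coverage)
  ) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(
      yintercept = object$parameters$gc_fraction, linetype = "dashed"
    ) +
    ggplot2::labs(
      x = "Selection step", y = "Fraction of universe covered",
      title = sprintf("%s set cover", object$algorithm)
    ) +
    ggplot2::ylim(0, 1)
}
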