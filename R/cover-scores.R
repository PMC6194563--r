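#' Per-pathway gene membership counts
#'
#' Counts, for every gene in the collection universe, the number of pathways
#' whose gene set contains it. These frequencies drive the hitting-set score
#' ([score_hitting()]), where a gene's value is the reciprocal of its
#' frequency.
#'
#' @param collection A [geneset_collection()].
#' @return A tibble with columns `gene` and `n_pathways`, one row per
#'   universe gene, sorted by gene; every count is at least 1.
#' @export
gene_frequencies <- function(collection) {
  genes <- unlist(collection$genes, use.names = FALSE)
  tab <- table(genes)
  tibble(
    gene = names(tab),
    n_pathways = as.integer(tab)
  )
}

#' Standard set-cover score
#'
#' The number of still-uncovered genes a pathway contains. The standard
#' greedy algorithm repeatedly selects the pathway maximising this count.
#'
#' @param genes Character vector: the pathway's gene set.
#' @param uncovered Character vector of currently uncovered genes.
#' @return The count of `genes` present in `uncovered`, as a double.
#' @export
score_standard <- function(genes, uncovered) {
  as.numeric(length(intersect(genes, uncovered)))
}

#' Proportional set-cover score
#'
#' Ranks a pathway by the *proportion* of its genes that are still
#' uncovered, plus a small size-regularising term that prefers pathways
#' close to the collection's mean size:
#' `|s ∩ R| / |s| + 1 / (max(abs(|s| - mean_size), 0.5) * k)`.
#' The divisor guard (0.5, the smallest nonzero distance between an integer
#' size and a mean) bounds the second term when a pathway's size equals the
#' mean exactly; with the default `k = 10000` the term never exceeds 2e-4,
#' so it only arbitrates among pathways whose uncovered proportions are
#' essentially tied.
#'
#' @inheritParams score_standard
#' @param mean_size Mean pathway size of the full input collection, frozen
#'   for the run.
#' @param k Large positive constant limiting the influence of the size
#'   term; default 10000.
#' @return The proportional score (first term in \[0, 1\]).
#' @export
score_proportional <- function(genes, uncovered, mean_size, k = 10000) {
  size <- length(genes)
  stopifnot(size >= 1L, mean_size > 0, k > 0)
  prop <- length(intersect(genes, uncovered)) / size
  prop + 1 / (max(abs(size - mean_size), 0.5) * k)
}

#' Hitting set-cover score
#'
#' The dual (set-hitting) view values each gene by the rarity `1 / f_j`,
#' where `f_j` is the number of pathways containing gene `j` across the full
#' collection; a pathway's score is the summed value of its uncovered genes
#' divided by its size. Scores lie in \[0, 1\], reaching 1 only when every
#' gene of the pathway is uncovered and unique to it.
#'
#' @inheritParams score_standard
#' @param gene_freq Named numeric vector (or the tibble returned by
#'   [gene_frequencies()]) giving `f_j` for every gene of the pathway.
#' @return The hitting score in \[0, 1\].
#' @export
score_hitting <- function(genes, uncovered, gene_freq) {
  freq <- as_freq_vector(gene_freq)
  size <- length(genes)
  stopifnot(size >= 1L)
  missing <- setdiff(genes, names(freq))
  if (length(missing) > 0L) {
    abort(paste0(
      "No pathway frequency recorded for gene(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  hit <- intersect(genes, uncovered)
  sum(1 / freq[hit]) / size
}

as_freq_vector <- function(gene_freq) {
  if (is.data.frame(gene_freq)) {
    return(setNames(as.numeric(gene_freq$n_pathways), gene_freq$gene))
  }
  gene_freq
}
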