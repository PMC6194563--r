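# Independent reference implementations used as oracles. These deliberately
# rescan and rescore every pathway from scratch at every iteration with plain
# set operations, sharing no code with the package's incremental engine.

naive_greedy_cover <- function(collection, algorithm, gc_fraction = 1,
                               k = 10000) {
  ids <- collection$id
  sets <- collection$genes
  universe <- sort(unique(unlist(sets)))
  target <- ceiling(gc_fraction * length(universe))
  mean_size <- mean(lengths(sets))
  freq <- table(unlist(lapply(sets, unique)))

  uncovered <- universe
  selected <- character(0)
  while (length(universe) - length(uncovered) < target) {
    new_counts <- vapply(
      sets, function(s) length(intersect(s, uncovered)), numeric(1)
    )
    cand <- setdiff(which(new_counts > 0), match(selected, ids))
    if (length(cand) == 0) break
    score <- vapply(cand, function(i) {
      s <- sets[[i]]
      switch(algorithm,
        standard = new_counts[i],
        proportional = new_counts[i] / length(s) +
          1 / (max(abs(length(s) - mean_size), 0.5) * k),
        hitting = sum(1 / as.numeric(freq[intersect(s, uncovered)])) /
          length(s)
      )
    }, numeric(1))
    best <- max(score)
    ties <- cand[score >= best - abs(best) * 1e-12]
    if (length(ties) > 1) {
      ties <- ties[new_counts[ties] == max(new_counts[ties])]
      ties <- ties[order(ids[ties])]
    }
    pick <- ties[1]
    selected <- c(selected, ids[pick])
    uncovered <- setdiff(uncovered, sets[[pick]])
  }
  selected
}

# Exact minimum cover size by subset enumeration (instances of <= 12 sets).
brute_force_min_cover <- function(collection) {
  sets <- collection$genes
  universe <- sort(unique(unlist(sets)))
  n <- length(sets)
  for (size in seq_len(n)) {
    combos <- utils::combn(n, size)
    for (j in seq_len(ncol(combos))) {
      u <- unique(unlist(sets[combos[, j]]))
      if (length(u) == length(universe)) return(size)
    }
  }
  n
}

harmonic <- function(n) sum(1 / seq_len(n))

# Reference enrichment cover: literal scan over a (p, id)-sorted table.
naive_enrichment_cover <- function(enriched) {
  uncovered <- gene_universe(enriched)
  kept <- character(0)
  for (i in seq_len(nrow(enriched))) {
    s <- intersect(enriched$de_genes[[i]], gene_universe(enriched))
    if (length(intersect(s, uncovered)) > 0) {
      kept <- c(kept, enriched$id[i])
      uncovered <- setdiff(uncovered, s)
    }
  }
  kept
}
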