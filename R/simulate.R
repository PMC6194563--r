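#' Recipe for a synthetic pathway collection
#'
#' Describes how to generate a pathway collection with the redundancy
#' structure typical of consolidated pathway databases: a layer of latent
#' functional gene modules shared across pathways (producing partial
#' overlap and a long-tailed gene-frequency distribution), log-normally
#' distributed pathway sizes, strict-subset pathways (the redundancy the
#' cover algorithms remove), and multiple source-database labels.
#' Generation is a pure function of the recipe: the same recipe yields a
#' byte-identical collection.
#'
#' @param n_modules Number of latent gene modules.
#' @param module_size_range Integer interval of module sizes.
#' @param n_pathways Number of pathways to generate.
#' @param size_meanlog,size_sdlog Log-normal parameters of the intended
#'   pathway sizes.
#' @param overlap_intensity Fraction in \[0, 1\] of each pathway's genes
#'   drawn from shared modules rather than freshly minted; higher values
#'   give higher overlap scores.
#' @param subset_rate Probability in \[0, 1\] that a pathway is generated
#'   as a random strict subset of an earlier pathway.
#' @param source_labels Named numeric vector of source labels and sampling
#'   weights; defaults to [cpdb_source_weights()].
#' @param seed Integer seed; part of the recipe.
#' @return A `collection_recipe` list.
#' @export
collection_recipe <- function(n_modules = 80,
                              module_size_range = c(4L, 40L),
                              n_pathways = 600,
                              size_meanlog = 3.4, size_sdlog = 0.9,
                              overlap_intensity = 0.9,
                              subset_rate = 0.15,
                              source_labels = cpdb_source_weights(),
                              seed = 1L) {
  r <- list(
    n_modules = as.integer(n_modules),
    module_size_range = as.integer(module_size_range),
    n_pathways = as.integer(n_pathways),
    size_meanlog = size_meanlog, size_sdlog = size_sdlog,
    overlap_intensity = overlap_intensity,
    subset_rate = subset_rate,
    source_labels = source_labels,
    seed = as.integer(seed)
  )
  if (r$n_modules < 1L || r$n_pathways < 1L) {
    abort("`n_modules` and `n_pathways` must be at least 1.")
  }
  if (length(r$module_size_range) != 2L ||
      r$module_size_range[1] < 1L ||
      r$module_size_range[2] < r$module_size_range[1]) {
    abort("`module_size_range` must be an increasing positive interval.")
  }
  if (r$overlap_intensity < 0 || r$overlap_intensity > 1 ||
      r$subset_rate < 0 || r$subset_rate > 1) {
    abort("`overlap_intensity` and `subset_rate` must lie in [0, 1].")
  }
  if (r$size_sdlog < 0) abort("`size_sdlog` must be non-negative.")
  if (r$overlap_intensity > 0 &&
      r$module_size_range[1] > ceiling(exp(r$size_meanlog + 3 * r$size_sdlog))) {
    abort("Infeasible recipe: module sizes exceed plausible pathway sizes.")
  }
  if (is.null(names(r$source_labels)) || any(r$source_labels < 0) ||
      sum(r$source_labels) <= 0) {
    abort("`source_labels` must be a named vector of non-negative weights.")
  }
  structure(r, class = "collection_recipe")
}

#' Source-label sampling weights
#'
#' Default per-database weights for synthetic collections, proportional to
#' the database shares observed in a ConsensusPathDB-style consolidated
#' collection.
#'
#' @return Named numeric vector of weights (percentages).
#' @export
cpdb_source_weights <- function() {
  c(
    BioCarta = 6.3, EHMN = 1.6, HumanCyc = 8.2, INOH = 2.3, KEGG = 7.2,
    NetPath = 0.9, PharmGKB = 2.8, PID = 5.2, Reactome = 39.6,
    Signalink = 0.4, SMPDB = 16.7, Wikipathways = 8.8
  )
}

#' The fixed benchmark recipe
#'
#' The default `collection_recipe()` scaled to 600 pathways with heavy
#' module sharing and subset pathways, sized so that its overlap score is
#' well above 5 -- enough redundancy for the cover algorithms to have
#' meaningful work, at desk scale.
#'
#' @param seed Integer seed (default 20150924).
#' @return A `collection_recipe`.
#' @export
cpdb_like_recipe <- function(seed = 20150924L) {
  collection_recipe(seed = seed)
}

#' Generate a synthetic pathway collection
#'
#' Each pathway draws an intended size from the log-normal, then is built
#' either as a strict subset of an earlier pathway (with probability
#' `subset_rate`) or as a union of genes sampled from latent modules
#' (an `overlap_intensity` share of the size) plus freshly minted genes
#' unique to the pathway. Gene symbols are synthetic tokens
#' (`"G000001"` ...), making no claim of biological identity. The latent
#' module gene sets are attached as attribute `"modules"` for downstream
#' enrichment simulation.
#'
#' @param recipe A [collection_recipe()].
#' @return A [geneset_collection()] with attributes `modules` and
#'   `recipe`.
#' @export
generate_collection <- function(recipe) {
  if (!inherits(recipe, "collection_recipe")) {
    recipe <- do.call(collection_recipe, as.list(recipe))
  }
  withr::with_seed(recipe$seed, generate_collection_impl(recipe))
}

generate_collection_impl <- function(recipe) {
  gene_counter <- 0L
  mint <- function(n) {
    ids <- sprintf("G%06d", gene_counter + seq_len(n))
    gene_counter <<- gene_counter + n
    ids
  }
  lo <- recipe$module_size_range[1]
  hi <- recipe$module_size_range[2]
  modules <- map(seq_len(recipe$n_modules), function(m) {
    mint(lo + sample.int(hi - lo + 1L, 1L) - 1L)
  })

  n <- recipe$n_pathways
  sizes <- pmax(1L, as.integer(round(
    rlnorm(n, recipe$size_meanlog, recipe$size_sdlog)
  )))

  # Peripheral (non-module) genes come from a lazily growing shared pool:
  # each draw reuses an existing pool gene with probability proportional to
  # overlap_intensity and the gene's current frequency (a Chinese-
  # restaurant-process scheme yielding the long-tailed gene-frequency
  # distribution of consolidated databases), otherwise mints a new token.
  # At overlap_intensity = 0 every peripheral gene is fresh, so the
  # collection is pairwise disjoint in expectation.
  tail_pool <- character(0)
  tail_counts <- numeric(0)
  tail_draws <- 0
  crp_alpha <- max(1, 0.25 * n)
  draw_tail <- function(n_draw, exclude) {
    out <- character(0)
    for (d in seq_len(n_draw)) {
      p_reuse <- recipe$overlap_intensity *
        tail_draws / (tail_draws + crp_alpha)
      avail <- setdiff(tail_pool, c(exclude, out))
      if (length(avail) > 0L && runif(1) < p_reuse) {
        w <- tail_counts[match(avail, tail_pool)]
        g <- avail[sample.int(length(avail), 1L, prob = w)]
        tail_counts[match(g, tail_pool)] <<- tail_counts[match(g, tail_pool)] + 1
      } else {
        g <- mint(1L)
        tail_pool <<- c(tail_pool, g)
        tail_counts <<- c(tail_counts, 1)
      }
      tail_draws <<- tail_draws + 1
      out <- c(out, g)
    }
    out
  }

  genes <- vector("list", n)
  for (i in seq_len(n)) {
    prev_ok <- which(lengths(genes[seq_len(i - 1L)]) >= 2L)
    if (length(prev_ok) > 0L && runif(1) < recipe$subset_rate) {
      parent <- genes[[prev_ok[sample.int(length(prev_ok), 1L)]]]
      sub_size <- sample.int(length(parent) - 1L, 1L)
      genes[[i]] <- sample(parent, sub_size)
    } else {
      target <- sizes[i]
      n_mod <- round(recipe$overlap_intensity * target)
      picked <- character(0)
      if (n_mod > 0L) {
        pool <- character(0)
        guard <- 0L
        while (length(pool) < n_mod && guard < 10L * recipe$n_modules) {
          m <- sample.int(recipe$n_modules, 1L)
          pool <- union(pool, modules[[m]])
          guard <- guard + 1L
        }
        picked <- sample(pool, min(n_mod, length(pool)))
      }
      n_tail <- max(target - length(picked), if (n_mod == 0L) 1L else 0L)
      genes[[i]] <- c(picked, draw_tail(n_tail, exclude = picked))
      if (length(genes[[i]]) == 0L) genes[[i]] <- mint(1L)
    }
  }

  src <- sample(
    names(recipe$source_labels), n, replace = TRUE,
    prob = recipe$source_labels / sum(recipe$source_labels)
  )
  out <- geneset_collection(tibble(
    id = sprintf("PW%05d", seq_len(n)),
    source = src,
    genes = genes
  ))
  attr(out, "modules") <- modules
  attr(out, "recipe") <- recipe
  out
}

#' Recipe for a synthetic enrichment study
#'
#' @param n_de_genes Number of differentially expressed genes to draw
#'   (must not exceed the collection universe).
#' @param enriched_module_ids Indices of latent modules whose genes are
#'   preferentially differentially expressed.
#' @param de_noise_rate Fraction in \[0, 1\] of DE genes drawn uniformly
#'   from the whole universe instead of the enriched modules.
#' @param seed Integer seed.
#' @return An `enrichment_recipe` list.
#' @export
enrichment_recipe <- function(n_de_genes = 300,
                              enriched_module_ids = 1:6,
                              de_noise_rate = 0.15,
                              seed = 1L) {
  r <- list(
    n_de_genes = as.integer(n_de_genes),
    enriched_module_ids = as.integer(enriched_module_ids),
    de_noise_rate = de_noise_rate,
    seed = as.integer(seed)
  )
  if (r$n_de_genes < 1L) abort("`n_de_genes` must be at least 1.")
  if (r$de_noise_rate < 0 || r$de_noise_rate > 1) {
    abort("`de_noise_rate` must lie in [0, 1].")
  }
  structure(r, class = "enrichment_recipe")
}

#' Generate a synthetic enrichment study
#'
#' Draws a DE gene set concentrated in the designated latent modules (plus
#' uniform noise) and assigns every pathway an over-representation p-value
#' from the one-sided upper hypergeometric tail of its DE overlap, given
#' the universe size, the DE count and the pathway size. A pathway
#' disjoint from the DE genes receives p = 1. The output table is sorted
#' ascending by `(p, pathway_id)`.
#'
#' @param collection A collection from [generate_collection()] (the
#'   latent-module attribute is required to target enrichment).
#' @param recipe An [enrichment_recipe()].
#' @return A list with `de_genes` (character vector) and `table` (tibble
#'   of `pathway_id`, `p_adjusted`).
#' @export
generate_enrichment_study <- function(collection, recipe) {
  if (!inherits(recipe, "enrichment_recipe")) {
    recipe <- do.call(enrichment_recipe, as.list(recipe))
  }
  modules <- attr(collection, "modules", exact = TRUE)
  if (is.null(modules)) {
    abort(paste0(
      "`collection` carries no latent-module attribute; ",
      "use a collection from generate_collection()."
    ))
  }
  if (any(recipe$enriched_module_ids < 1L) ||
      any(recipe$enriched_module_ids > length(modules))) {
    abort("`enriched_module_ids` out of range for this collection.")
  }
  universe <- gene_universe(collection)
  if (recipe$n_de_genes > length(universe)) {
    abort("`n_de_genes` exceeds the size of the collection universe.")
  }
  withr::with_seed(recipe$seed, {
    signal_pool <- intersect(
      unique(unlist(modules[recipe$enriched_module_ids], use.names = FALSE)),
      universe
    )
    n_signal <- min(
      round((1 - recipe$de_noise_rate) * recipe$n_de_genes),
      length(signal_pool)
    )
    de <- sample(signal_pool, n_signal)
    noise_pool <- setdiff(universe, de)
    n_noise <- min(recipe$n_de_genes - n_signal, length(noise_pool))
    de <- sort(c(de, sample(noise_pool, n_noise)))

    n_univ <- length(universe)
    n_de <- length(de)
    p <- map_dbl(collection$genes, function(s) {
      x <- length(intersect(s, de))
      m <- length(s)
      phyper(x - 1, m, n_univ - m, n_de, lower.tail = FALSE)
    })
    tab <- tibble(pathway_id = collection$id, p_adjusted = p)
    tab <- tab[order(tab$p_adjusted, tab$pathway_id, method = "radix"), ]
    list(de_genes = de, table = tab)
  })
}

#' Read a recipe from a YAML or JSON file
#'
#' Field names mirror the arguments of [collection_recipe()] (or, with
#' `type = "enrichment"`, [enrichment_recipe()]).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @param type `"collection"` or `"enrichment"`.
#' @return A recipe object.
#' @export
read_recipe <- function(path, type = c("collection", "enrichment")) {
  type <- arg_match(type)
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.null(raw$source_labels)) {
    raw$source_labels <- unlist(raw$source_labels)
  }
  if (type == "collection") {
    do.call(collection_recipe, raw)
  } else {
    do.call(enrichment_recipe, raw)
  }
}
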