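#' Source databases recognised in GMT description fields
#'
#' The default vocabulary of source-database labels. When the second (GMT
#' description) field of a line matches one of these labels exactly, it is
#' recorded as the pathway's source; otherwise the source is `"unknown"`.
#' These are the databases contributing pathways to ConsensusPathDB-style
#' consolidated collections.
#'
#' @return A character vector of database labels.
#' @export
cpdb_sources <- function() {
  c(
    "BioCarta", "EHMN", "HumanCyc", "INOH", "KEGG", "NetPath",
    "PharmGKB", "PID", "Reactome", "Signalink", "SMPDB", "Wikipathways"
  )
}

#' Read a GMT gene-set file
#'
#' Parses the tab-delimited GMT convention (one gene set per line:
#' identifier, description, then gene symbols). Blank lines and lines
#' starting with `#` are skipped; within-line duplicate gene symbols are
#' collapsed; the description field is interpreted as the source-database
#' label when it matches `source_vocab`, otherwise `"unknown"`.
#'
#' @param path Path to a GMT file (or a connection readable by
#'   [readr::read_lines()]).
#' @param source_vocab Character vector of recognised source labels;
#'   defaults to [cpdb_sources()] plus `"unknown"`.
#' @param uppercase If `TRUE`, gene symbols are upper-cased at parse time.
#'   Symbols are otherwise matched as exact case-sensitive strings.
#' @return A [geneset_collection()].
#' @examples
#' tf <- tempfile(fileext = ".gmt")
#' writeLines("P1\tKEGG\tTP53\tBRCA1", tf)
#' read_gmt(tf)
#' @export
read_gmt <- function(path, source_vocab = c(cpdb_sources(), "unknown"),
                     uppercase = FALSE) {
  lines <- readr::read_lines(path)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")
  line_no <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    abort("GMT input contains no gene-set lines.")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "GMT line %d has fewer than 3 tab-separated fields.", line_no[bad[1]]
    ))
  }
  ids <- map_chr(fields, 1L)
  desc <- map_chr(fields, 2L)
  genes <- map(fields, function(f) {
    g <- f[-(1:2)]
    g <- g[nzchar(g)]
    unique(g)
  })
  empty <- which(lengths(genes) == 0L)
  if (length(empty) > 0L) {
    abort(sprintf(
      "GMT line %d (pathway '%s') contains zero genes.",
      line_no[empty[1]], ids[empty[1]]
    ))
  }
  if (uppercase) genes <- map(genes, toupper)
  geneset_collection(tibble(
    id = ids,
    source = ifelse(desc %in% source_vocab, desc, "unknown"),
    genes = genes
  ))
}

#' Write a collection to a GMT file
#'
#' One line per pathway in collection order; the source label is emitted as
#' the description field and genes are emitted in lexicographic order, so
#' output bytes are stable and `read_gmt(write_gmt(x))` reproduces the ids,
#' sources and gene sets of `x`.
#'
#' @param collection A [geneset_collection()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  validate_collection(collection)
  lines <- vapply(seq_len(nrow(collection)), function(i) {
    paste(
      c(
        collection$id[i], collection$source[i],
        sort(collection$genes[[i]], method = "radix")
      ),
      collapse = "\t"
    )
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a differentially-expressed gene list
#'
#' One gene symbol per line; blank lines and `#` comments are skipped and
#' duplicates collapsed.
#'
#' @param path Path to the gene-list file.
#' @param uppercase Upper-case symbols at read time.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path, uppercase = FALSE) {
  lines <- trimws(sub("\r$", "", readr::read_lines(path)))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (uppercase) lines <- toupper(lines)
  unique(lines)
}
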