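#' Read gene sets in GMT format
#'
#' Standard tab-delimited gene-set format: one set per line — name,
#' description, then member genes.
#'
#' @param path GMT file.
#' @return named list of character vectors (set name -> member genes), with
#'   descriptions in attribute `descriptions`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    stop("format error: GMT line(s) with fewer than 3 fields: ",
         paste(which(bad), collapse = ", "))
  }
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[`, "", 1)
  attr(sets, "descriptions") <- setNames(vapply(parts, `[`, "", 2),
                                         names(sets))
  sets
}

#' Over-representation of gene sets in a query list (Fisher's exact test)
#'
#' One-sided (enrichment) hypergeometric test per set: with universe size
#' N, set size K (after intersecting the set with the universe), query size
#' n and overlap k, p = P(X >= k) for X hypergeometric(N, K, n). q-values
#' are Benjamini-Hochberg across all tested sets; results are sorted by p.
#'
#' @param query_genes character vector of genes of interest (must be a
#'   subset of `universe`).
#' @param universe background gene list (e.g. all genes on the filtered
#'   mRNA matrix).
#' @param gene_sets named list of gene sets (see [read_gmt()]).
#' @param alternative "greater" (over-representation, default) or
#'   "two.sided" (delegated to [stats::fisher.test()]).
#' @return data.frame: set_name, k, K, n, N, odds_ratio, p_value, q_value.
#' @export
fisher_enrichment <- function(query_genes, universe, gene_sets,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  query_genes <- unique(query_genes)
  universe <- unique(universe)
  outside <- setdiff(query_genes, universe)
  if (length(outside)) {
    stop("consistency error: query gene(s) outside the universe: ",
         paste(outside, collapse = ", "))
  }
  N <- length(universe)
  n <- length(query_genes)
  rows <- lapply(names(gene_sets), function(nm) {
    set <- intersect(gene_sets[[nm]], universe)
    K <- length(set)
    k <- length(intersect(set, query_genes))
    p <- if (alternative == "greater") {
      phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    } else {
      stats::fisher.test(matrix(c(k, K - k, n - k, N - K - n + k), 2),
                         alternative = "two.sided")$p.value
    }
    or <- (k * (N - K - n + k)) / ((K - k) * (n - k))
    data.frame(set_name = nm, k = k, K = K, n = n, N = N,
               odds_ratio = or, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}
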