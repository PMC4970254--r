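#' Combine DE selections, correlations and target predictions into
#' negative-regulation miRNA-mRNA pairs
#'
#' Keeps (miRNA probe, mRNA probe) pairs whose expression correlation is
#' negative with p < `p_max` and BH q < `q_max` over the correlation family,
#' and which are supported by sequence-based target evidence. Probe ids are
#' mapped to mature miRNA names / gene ids before the target lookup.
#'
#' @param de_mirna,de_mrna DE selections ([select_de()] output) whose probe
#'   ids define the correlation family.
#' @param corr correlation family from [correlate_all()] over exactly those
#'   probes (id_a = miRNA probe, id_b = mRNA probe).
#' @param targets predicted pairs from [predict_targets()].
#' @param p_max,q_max strict thresholds on the correlation p and q.
#' @param mirna_map named vector probe id -> mature name (default identity).
#' @param gene_map named vector mRNA probe id -> gene id (default identity).
#' @return list with `pairs` (kept rows of `corr` plus mature/gene columns
#'   and the matched target evidence) and `summary` (n_pairs,
#'   n_unique_genes, n_unique_mirnas, thresholds).
#' @export
integrate_de_pairs <- function(de_mirna, de_mrna, corr, targets,
                               p_max = 0.05, q_max = 0.05,
                               mirna_map = NULL, gene_map = NULL) {
  extra_a <- setdiff(unique(corr$id_a), de_mirna$probe_id)
  extra_b <- setdiff(unique(corr$id_b), de_mrna$probe_id)
  if (length(extra_a) || length(extra_b)) {
    stop("consistency error: correlation family contains ids outside the DE ",
         "selections: ", paste(head(c(extra_a, extra_b), 5), collapse = ", "))
  }
  if (is.null(corr$q)) stop("correlation family lacks q-values")
  if (is.null(mirna_map)) {
    mirna_map <- setNames(unique(corr$id_a), unique(corr$id_a))
  }
  if (is.null(gene_map)) {
    gene_map <- setNames(unique(corr$id_b), unique(corr$id_b))
  }
  kept <- corr[!is.na(corr$r) & corr$r < 0 &
                 corr$p < p_max & corr$q < q_max, , drop = FALSE]
  kept$mature_name <- unname(mirna_map[kept$id_a])
  kept$gene_id <- unname(gene_map[kept$id_b])
  tkey <- paste(targets$mirna_id, targets$gene_id)
  m <- match(paste(kept$mature_name, kept$gene_id), tkey)
  kept <- cbind(kept[!is.na(m), , drop = FALSE],
                targets[m[!is.na(m)],
                        c("evidence", "region", "site_type", "mfe"),
                        drop = FALSE])
  rownames(kept) <- NULL
  list(pairs = kept,
       summary = list(n_pairs = nrow(kept),
                      n_unique_genes = length(unique(kept$gene_id)),
                      n_unique_mirnas = length(unique(kept$mature_name)),
                      p_max = p_max, q_max = q_max))
}

#' Assemble miRNA-gene-trait triads
#'
#' A triad (miRNA probe, gene probe, trait) is reported when all three
#' criteria hold: (1) both the miRNA and the gene correlate with the trait
#' at p < `p_max`; (2) the miRNA and gene expressions correlate negatively
#' at p < `p_max`; (3) the gene is a computationally predicted target of the
#' miRNA.
#'
#' @param mirna_pheno,gene_pheno per-probe-per-trait correlation results
#'   (`results` element of [correlate_with_phenotypes()]).
#' @param mirna_gene miRNA-vs-gene correlation family
#'   ([correlate_all()] output; id_a = miRNA probe, id_b = gene probe).
#' @param targets predicted pairs from [predict_targets()].
#' @param p_max strict p threshold applied to all three correlations.
#' @param mirna_map,gene_map probe id -> mature / gene id maps
#'   (default identity).
#' @return data.frame of triads: mirna probe/mature, gene probe/id, trait,
#'   the three correlations and p-values.
#' @export
build_triads <- function(mirna_pheno, gene_pheno, mirna_gene, targets,
                         p_max = 0.05, mirna_map = NULL, gene_map = NULL) {
  if (is.null(mirna_map)) {
    ids <- unique(mirna_gene$id_a)
    mirna_map <- setNames(ids, ids)
  }
  if (is.null(gene_map)) {
    ids <- unique(mirna_gene$id_b)
    gene_map <- setNames(ids, ids)
  }
  mg <- mirna_gene[!is.na(mirna_gene$r) & mirna_gene$r < 0 &
                     mirna_gene$p < p_max, , drop = FALSE]
  if (nrow(mg) == 0) return(.empty_triads())
  mg$mature_name <- unname(mirna_map[mg$id_a])
  mg$gene_id <- unname(gene_map[mg$id_b])
  tkey <- paste(targets$mirna_id, targets$gene_id)
  mg <- mg[paste(mg$mature_name, mg$gene_id) %in% tkey, , drop = FALSE]
  if (nrow(mg) == 0) return(.empty_triads())

  mp <- mirna_pheno[!is.na(mirna_pheno$p) & mirna_pheno$p < p_max, ,
                    drop = FALSE]
  gp <- gene_pheno[!is.na(gene_pheno$p) & gene_pheno$p < p_max, ,
                   drop = FALSE]
  rows <- list()
  for (k in seq_len(nrow(mg))) {
    tr_m <- mp[mp$probe_id == mg$id_a[k], , drop = FALSE]
    tr_g <- gp[gp$probe_id == mg$id_b[k], , drop = FALSE]
    shared <- intersect(tr_m$trait, tr_g$trait)
    for (trait in shared) {
      im <- match(trait, tr_m$trait); ig <- match(trait, tr_g$trait)
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_probe = mg$id_a[k], mature_name = mg$mature_name[k],
        gene_probe = mg$id_b[k], gene_id = mg$gene_id[k],
        trait = trait,
        mirna_gene_r = mg$r[k], mirna_gene_p = mg$p[k],
        mirna_trait_r = tr_m$r[im], mirna_trait_p = tr_m$p[im],
        gene_trait_r = tr_g$r[ig], gene_trait_p = tr_g$p[ig],
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else .empty_triads()
  attr(out, "p_max") <- p_max
  out
}

.empty_triads <- function() {
  data.frame(mirna_probe = character(0), mature_name = character(0),
             gene_probe = character(0), gene_id = character(0),
             trait = character(0),
             mirna_gene_r = numeric(0), mirna_gene_p = numeric(0),
             mirna_trait_r = numeric(0), mirna_trait_p = numeric(0),
             gene_trait_r = numeric(0), gene_trait_p = numeric(0),
             stringsAsFactors = FALSE)
}

#' Top miRNA-mRNA pairs per trait
#'
#' Ranks a trait's triads by ascending miRNA-gene correlation p-value, ties
#' broken by |r| descending, then lexicographic (mature, gene) ids — a
#' deterministic ordering recorded with the output.
#'
#' @param triads [build_triads()] output.
#' @param n pairs reported per trait.
#' @return data.frame of the per-trait top pairs with a `rank` column;
#'   the rank key is stored in attribute `rank_key`.
#' @export
top_pairs_per_trait <- function(triads, n = 10L) {
  if (nrow(triads) == 0) {
    out <- cbind(triads, rank = integer(0))
    attr(out, "rank_key") <- "p asc, |r| desc, ids"
    return(out)
  }
  parts <- split(triads, triads$trait)
  out <- do.call(rbind, lapply(parts, function(d) {
    o <- order(d$mirna_gene_p, -abs(d$mirna_gene_r),
               d$mature_name, d$gene_id)
    d <- d[o[seq_len(min(n, nrow(d)))], , drop = FALSE]
    d$rank <- seq_len(nrow(d))
    d
  }))
  rownames(out) <- NULL
  attr(out, "rank_key") <- "p asc, |r| desc, ids"
  out
}

#' Cross-list correlation matrix between two gene panels
#'
#' Full grid of Pearson correlations (with t-transform p-values and
#' p < 0.05 significance flags) between every gene of list A and every gene
#' of list B, e.g. mitochondria-related vs ubiquitin-proteasome-system
#' genes.
#'
#' @param expr probes-by-samples matrix containing all listed genes.
#' @param genes_a,genes_b character vectors of row ids of `expr`.
#' @param p_threshold significance flag cutoff.
#' @return list with matrices `r`, `p`, `n`, `significant` (rows = list A,
#'   columns = list B) and the long-format `table`.
#' @export
crosslist_correlation <- function(expr, genes_a, genes_b,
                                  p_threshold = 0.05) {
  missing_ids <- setdiff(c(genes_a, genes_b), rownames(expr))
  if (length(missing_ids)) {
    stop("gene id(s) not in expression matrix: ",
         paste(missing_ids, collapse = ", "))
  }
  res <- correlate_all(expr[genes_a, , drop = FALSE],
                       expr[genes_b, , drop = FALSE], family_fdr = FALSE)
  r <- matrix(res$r, length(genes_a), length(genes_b),
              dimnames = list(genes_a, genes_b))
  p <- matrix(res$p, length(genes_a), length(genes_b),
              dimnames = list(genes_a, genes_b))
  nmat <- matrix(res$n, length(genes_a), length(genes_b),
                 dimnames = list(genes_a, genes_b))
  list(r = r, p = p, n = nmat, significant = !is.na(p) & p < p_threshold,
       table = res)
}

#' Export a regulatory network to GraphML or SIF
#'
#' Nodes carry a `type` attribute (miRNA / gene / trait) and, when supplied,
#' a breed-direction attribute; edges carry the relation (targets /
#' correlates) and the correlation sign. GraphML files round-trip through
#' [igraph::read_graph()]; SIF lists one `source relation target` line per
#' edge.
#'
#' @param x pair table ([integrate_de_pairs()] `pairs`) or triad table
#'   ([build_triads()]); needs `mature_name` and `gene_id` columns, and
#'   `trait` for triads.
#' @param path output file.
#' @param format "graphml" or "sif".
#' @param directions optional named vector node id -> breed direction label
#'   (e.g. "up_in_Duroc"), stored as node attribute `direction`.
#' @return the igraph object, invisibly.
#' @export
export_graph <- function(x, path, format = c("graphml", "sif"),
                         directions = NULL) {
  format <- match.arg(format)
  edges <- data.frame(from = x$mature_name, to = x$gene_id,
                      relation = rep("targets", length(x$mature_name)),
                      stringsAsFactors = FALSE)
  edges$r <- if (!is.null(x$mirna_gene_r)) x$mirna_gene_r else
    if (!is.null(x$r)) x$r else NA_real_
  if (!is.null(x$trait)) {
    edges <- rbind(
      edges,
      data.frame(from = x$gene_id, to = x$trait,
                 relation = rep("correlates", length(x$trait)),
                 r = x$gene_trait_r),
      data.frame(from = x$mature_name, to = x$trait,
                 relation = rep("correlates", length(x$trait)),
                 r = x$mirna_trait_r))
  }
  edges <- unique(edges)
  if (format == "sif" && nrow(edges) == 0) {
    stop("SIF export needs a non-empty edge set")
  }
  node_ids <- unique(c(x$mature_name, x$gene_id,
                       if (!is.null(x$trait)) x$trait))
  types <- rep("gene", length(node_ids))
  types[node_ids %in% x$mature_name] <- "miRNA"
  if (!is.null(x$trait)) types[node_ids %in% x$trait] <- "trait"
  nodes <- data.frame(name = node_ids, type = types,
                      stringsAsFactors = FALSE)
  nodes$direction <- if (is.null(directions)) {
    rep(NA_character_, nrow(nodes))
  } else {
    unname(directions[nodes$name])
  }
  g <- igraph::graph_from_data_frame(edges, directed = TRUE,
                                     vertices = nodes)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    writeLines(paste(edges$from, edges$relation, edges$to), path)
  }
  invisible(g)
}
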