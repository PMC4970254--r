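# small deterministic fixture used across the integration tests:
# 2 DE miRNA probes x 3 DE gene probes, one pair (m1, g1) with a strong
# negative correlation and seed evidence
toy_integration <- function() {
  de_mirna <- data.frame(probe_id = c("m1", "m2"),
                         direction = c("up_in_Duroc", "up_in_PiNN"))
  de_mrna <- data.frame(probe_id = c("g1", "g2", "g3"),
                        direction = c("up_in_PiNN", "up_in_Duroc",
                                      "up_in_Duroc"))
  corr <- expand.grid(id_a = de_mirna$probe_id, id_b = de_mrna$probe_id,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  corr$n <- 20
  corr$r <- c(-0.9, 0.1, 0.9, -0.1, 0.2, -0.05)
  corr$p <- pearson_pvalue(corr$r, corr$n)
  corr$q <- bh_fdr(corr$p)
  targets <- data.frame(mirna_id = c("m1", "m1"), gene_id = c("g1", "g2"),
                        evidence = "seed", region = "3UTR",
                        site_type = "7mer-m8", mfe = NA_real_)
  list(de_mirna = de_mirna, de_mrna = de_mrna, corr = corr,
       targets = targets)
}

test_that("integration keeps negative, significant, target-supported pairs", {
  fx <- toy_integration()
  out <- integrate_de_pairs(fx$de_mirna, fx$de_mrna, fx$corr, fx$targets)
  expect_equal(out$summary$n_pairs, 1)
  expect_equal(out$summary$n_unique_genes, 1)
  expect_equal(out$summary$n_unique_mirnas, 1)
  expect_identical(out$pairs$id_a, "m1")
  expect_identical(out$pairs$gene_id, "g1")
  # m1-g2: predicted target but r = +0.9 -> excluded by the sign rule
  expect_false("g2" %in% out$pairs$gene_id)
})

test_that("a negative correlation without target evidence is excluded", {
  fx <- toy_integration()
  fx$corr$r[fx$corr$id_a == "m2" & fx$corr$id_b == "g1"] <- -0.95
  fx$corr$p <- pearson_pvalue(fx$corr$r, fx$corr$n)
  fx$corr$q <- bh_fdr(fx$corr$p)
  out <- integrate_de_pairs(fx$de_mirna, fx$de_mrna, fx$corr, fx$targets)
  expect_false("m2" %in% out$pairs$id_a) # m2 has no predicted target
})

test_that("a correlation family outside the DE sets is a consistency error", {
  fx <- toy_integration()
  fx$corr$id_a[1] <- "rogue"
  expect_error(integrate_de_pairs(fx$de_mirna, fx$de_mrna, fx$corr,
                                  fx$targets),
               "consistency error")
})

test_that("tightening integration thresholds never adds pairs", {
  fx <- toy_integration()
  loose <- integrate_de_pairs(fx$de_mirna, fx$de_mrna, fx$corr, fx$targets,
                              p_max = 0.05, q_max = 0.1)
  tight <- integrate_de_pairs(fx$de_mirna, fx$de_mrna, fx$corr, fx$targets,
                              p_max = 0.01, q_max = 0.01)
  key <- function(d) paste(d$pairs$id_a, d$pairs$id_b)
  expect_true(all(key(tight) %in% key(loose)))
})

toy_triad_inputs <- function(gene_trait_r = 0.9) {
  mirna_pheno <- data.frame(probe_id = "m1", trait = c("STO", "ATP"),
                            n = 20, r = c(-0.8, -0.75))
  mirna_pheno$p <- pearson_pvalue(mirna_pheno$r, 20)
  gene_pheno <- data.frame(probe_id = "g1", trait = c("STO", "ATP"),
                           n = 20, r = c(gene_trait_r, 0.85))
  gene_pheno$p <- pearson_pvalue(gene_pheno$r, 20)
  mirna_gene <- data.frame(id_a = "m1", id_b = "g1", n = 20, r = -0.9)
  mirna_gene$p <- pearson_pvalue(mirna_gene$r, 20)
  targets <- data.frame(mirna_id = "m1", gene_id = "g1")
  list(mp = mirna_pheno, gp = gene_pheno, mg = mirna_gene, tg = targets)
}

test_that("triads require all three correlations and target evidence", {
  fx <- toy_triad_inputs()
  tri <- build_triads(fx$mp, fx$gp, fx$mg, fx$tg)
  # all criteria hold for both traits -> two per-trait records
  expect_equal(nrow(tri), 2)
  expect_setequal(tri$trait, c("STO", "ATP"))

  # weak gene-trait correlation on one trait removes that triad
  fx2 <- toy_triad_inputs(gene_trait_r = 0.3) # p = 0.2-ish, > 0.05
  tri2 <- build_triads(fx2$mp, fx2$gp, fx2$mg, fx2$tg)
  expect_identical(tri2$trait, "ATP")

  # positive miRNA-gene correlation removes everything
  fx3 <- toy_triad_inputs()
  fx3$mg$r <- 0.9
  expect_equal(nrow(build_triads(fx3$mp, fx3$gp, fx3$mg, fx3$tg)), 0)

  # no target evidence removes everything
  fx4 <- toy_triad_inputs()
  fx4$tg <- fx4$tg[0, , drop = FALSE]
  expect_equal(nrow(build_triads(fx4$mp, fx4$gp, fx4$mg, fx4$tg)), 0)
})

test_that("triad count is monotone non-increasing in the p threshold", {
  fx <- toy_triad_inputs()
  n_loose <- nrow(build_triads(fx$mp, fx$gp, fx$mg, fx$tg, p_max = 0.05))
  n_tight <- nrow(build_triads(fx$mp, fx$gp, fx$mg, fx$tg, p_max = 1e-6))
  expect_lte(n_tight, n_loose)
})

test_that("top pairs per trait are ranked by p, then |r|, then ids", {
  set.seed(40)
  tri <- data.frame(
    mirna_probe = sprintf("m%02d", 1:25), mature_name = sprintf("m%02d", 1:25),
    gene_probe = sprintf("g%02d", 1:25), gene_id = sprintf("g%02d", 1:25),
    trait = "STO",
    mirna_gene_r = -runif(25, 0.5, 0.99), mirna_gene_p = runif(25, 0, 0.05),
    mirna_trait_r = 0.7, mirna_trait_p = 0.01,
    gene_trait_r = 0.7, gene_trait_p = 0.01)
  top <- top_pairs_per_trait(tri, n = 10)
  expect_equal(nrow(top), 10)
  expect_equal(top$mirna_gene_p, sort(tri$mirna_gene_p)[1:10])
  expect_equal(top$rank, 1:10)

  few <- top_pairs_per_trait(tri[1:4, ], n = 10)
  expect_equal(nrow(few), 4)

  # equal p: |r| descending, then ids; stable across repeated calls
  tie <- tri[1:2, ]
  tie$mirna_gene_p <- 0.01
  tie$mirna_gene_r <- c(-0.6, -0.9)
  t1 <- top_pairs_per_trait(tie, n = 2)
  expect_identical(t1$mature_name, c("m02", "m01"))
  expect_identical(t1, top_pairs_per_trait(tie, n = 2))
})

test_that("cross-list correlation produces the full significance grid", {
  set.seed(41)
  genes_a <- sprintf("MITO%d", 1:8)
  genes_b <- sprintf("UPS%d", 1:6)
  expr <- matrix(rnorm(14 * 20), 14, 20,
                 dimnames = list(c(genes_a, genes_b), sprintf("S%02d", 1:20)))
  cl <- crosslist_correlation(expr, genes_a, genes_b)
  expect_equal(dim(cl$r), c(8, 6))
  expect_equal(length(cl$table$r), 48)
  expect_equal(cl$p["MITO3", "UPS2"],
               pearson_pvalue(cor(expr["MITO3", ], expr["UPS2", ]), 20))
  expect_identical(cl$significant, !is.na(cl$p) & cl$p < 0.05)
  # same gene on both sides correlates perfectly
  cl_self <- crosslist_correlation(expr, genes_a[1], genes_a[1])
  expect_equal(cl_self$r[1, 1], 1)
  expect_error(crosslist_correlation(expr, "nope", genes_b), "not in")
})

test_that("GraphML export round-trips with node and edge attributes", {
  fx <- toy_triad_inputs()
  tri <- build_triads(fx$mp, fx$gp, fx$mg, fx$tg)
  path <- withr::local_tempfile(fileext = ".graphml")
  g <- export_graph(tri, path, format = "graphml",
                    directions = c(m1 = "up_in_PiNN", g1 = "up_in_Duroc"))
  back <- igraph::read_graph(path, format = "graphml")
  expect_true(igraph::isomorphic(g, back))
  expect_setequal(igraph::V(back)$type[match(c("m1", "g1"),
                                             igraph::V(back)$name)],
                  c("miRNA", "gene"))
  expect_equal(igraph::V(back)$direction[igraph::V(back)$name == "m1"],
               "up_in_PiNN")
  expect_equal(igraph::ecount(back), igraph::ecount(g))

  # an empty triad set still writes a valid (empty) GraphML file
  empty_path <- withr::local_tempfile(fileext = ".graphml")
  export_graph(tri[0, ], empty_path, format = "graphml")
  empty_back <- igraph::read_graph(empty_path, format = "graphml")
  expect_equal(igraph::vcount(empty_back), 0)
})

test_that("SIF export lists one labelled edge per line; pairs stay bipartite", {
  fx <- toy_integration()
  out <- integrate_de_pairs(fx$de_mirna, fx$de_mrna, fx$corr, fx$targets)
  path <- withr::local_tempfile(fileext = ".sif")
  g <- export_graph(out$pairs, path, format = "sif")
  lines <- readLines(path)
  expect_equal(length(lines), 1)
  expect_identical(lines, "m1 targets g1")
  # bipartite: every edge goes miRNA -> gene
  el <- igraph::as_edgelist(g)
  types <- setNames(igraph::V(g)$type, igraph::V(g)$name)
  expect_true(all(types[el[, 1]] == "miRNA" & types[el[, 2]] == "gene"))
  expect_error(export_graph(out$pairs[0, ], path, format = "sif"),
               "non-empty")
})

test_that("summary counts stay consistent with the pair list under recount", {
  fx <- toy_integration()
  out <- integrate_de_pairs(fx$de_mirna, fx$de_mrna, fx$corr, fx$targets)
  expect_equal(out$summary$n_pairs, nrow(out$pairs))
  expect_equal(out$summary$n_unique_genes, length(unique(out$pairs$gene_id)))
  expect_equal(out$summary$n_unique_mirnas,
               length(unique(out$pairs$mature_name)))
})
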