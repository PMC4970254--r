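test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 42, n_mirna_probes = 20, n_mrna_probes = 30,
                    n_de_mirna = 5, n_de_mrna = 8, n_planted_pairs = 6)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
  cfg2 <- sim_config(seed = 43, n_mirna_probes = 20, n_mrna_probes = 30,
                     n_de_mirna = 5, n_de_mrna = 8, n_planted_pairs = 6)
  expect_false(identical(generate_dataset(cfg)$mirna,
                         generate_dataset(cfg2)$mirna))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_per_group = 2), "n_per_group")
  expect_error(sim_config(n_de_mirna = 100, n_mirna_probes = 10), "n_de")
  expect_error(sim_config(presence_rate = 1.2), "rates")
  expect_error(sim_config(n_planted_pairs = 60, n_mirna_probes = 20,
                          n_mrna_probes = 30, n_de_mirna = 2,
                          n_de_mrna = 2), "planted")
})

test_that("every planted pair carries a seed-complementary site in its stated region", {
  cfg <- sim_config(seed = 9, n_mirna_probes = 70, n_mrna_probes = 60,
                    n_de_mirna = 10, n_de_mrna = 10, n_planted_pairs = 50)
  b <- generate_dataset(cfg)
  pp <- b$truth$planted_pairs
  expect_equal(nrow(pp), 50)
  for (k in seq_len(nrow(pp))) {
    tr <- b$transcripts[[pp$gene_id[k]]]
    reg <- tr$regions[[pp$region[k]]]
    rlen <- reg[2] - reg[1]
    expect_true(pp$site_start[k] >= 0 &&
                  pp$site_start[k] + pp$site_length[k] <= rlen)
    seed_rc <- revcomp_rna(seed_of(b$mirna_sequences[[pp$mirna_id[k]]]))
    found <- substr(region_seq(tr, pp$region[k]),
                    pp$seed_site_start[k] + 1, pp$seed_site_start[k] + 7)
    expect_identical(found, seed_rc)
  }
})

test_that("reg_strength = 0 leaves planted pairs uncorrelated on average", {
  cfg <- sim_config(seed = 5, n_mirna_probes = 250, n_mrna_probes = 210,
                    n_de_mirna = 0, n_de_mrna = 0, n_planted_pairs = 200,
                    reg_strength = 0)
  b <- generate_dataset(cfg)
  pp <- b$truth$planted_pairs
  probe_of <- setNames(b$mirna_annotation$probe_id,
                       b$mirna_annotation$mature_name)
  rs <- vapply(seq_len(nrow(pp)), function(k) {
    cor(b$mirna[probe_of[[pp$mirna_id[k]]], ], b$mrna[pp$gene_id[k], ])
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 / sqrt(nrow(pp) * ncol(b$mirna)))
})

test_that("planted pairs correlate negatively with magnitude set by reg_strength", {
  cfg <- sim_config(seed = 6, n_mirna_probes = 80, n_mrna_probes = 80,
                    n_de_mirna = 0, n_de_mrna = 0, n_planted_pairs = 60,
                    reg_strength = 0.8)
  b <- generate_dataset(cfg)
  pp <- b$truth$planted_pairs
  probe_of <- setNames(b$mirna_annotation$probe_id,
                       b$mirna_annotation$mature_name)
  rs <- vapply(seq_len(nrow(pp)), function(k) {
    cor(b$mirna[probe_of[[pp$mirna_id[k]]], ], b$mrna[pp$gene_id[k], ])
  }, numeric(1))
  expect_lt(mean(rs), -0.7)  # expectation is -sqrt(0.8) ~ -0.89
})

test_that("plant_target_site writes the reverse complement of positions 2-8", {
  tr <- toy_transcript(utr3 = strrep("A", 40))[[1]]
  out <- plant_target_site(tr, "UGAGGUAGUAGGUUGUAUAGUU", "3UTR", 5)
  expect_identical(substr(region_seq(out, "3UTR"), 6, 12), "CUACCUC")
  # planting twice at disjoint offsets keeps both motifs
  out2 <- plant_target_site(out, "UGAGGUAGUAGGUUGUAUAGUU", "3UTR", 20)
  expect_identical(substr(region_seq(out2, "3UTR"), 6, 12), "CUACCUC")
  expect_identical(substr(region_seq(out2, "3UTR"), 21, 27), "CUACCUC")
  # 8mer anchoring appends an A opposite position 1
  out3 <- plant_target_site(tr, "UGAGGUAGUAGGUUGUAUAGUU", "3UTR", 5,
                            a1_anchor = TRUE)
  expect_identical(substr(region_seq(out3, "3UTR"), 6, 13), "CUACCUCA")
})

test_that("plant_target_site rejects sites that do not fit the region", {
  tr <- toy_transcript(utr3 = "ACGUAC")[[1]]  # 6-nt region
  expect_error(plant_target_site(tr, "UGAGGUAGUAGGUUGUAUAGUU", "3UTR", 0),
               "bounds")
  tr2 <- toy_transcript(utr3 = strrep("A", 30))[[1]]
  expect_error(plant_target_site(tr2, "UGAGGUAGUAGGUUGUAUAGUU", "3UTR", 25),
               "bounds")
})

test_that("simulate_phenotypes reproduces drivers exactly at zero noise", {
  set.seed(1)
  expr <- matrix(rnorm(40), 2, 20,
                 dimnames = list(c("p1", "p2"), sprintf("S%02d", 1:20)))
  ph <- simulate_phenotypes(expr, list(T1 = c(p1 = 1)), noise_sd = 0)
  expect_equal(unname(ph["T1", ]), unname(expr["p1", ]))
  ph2 <- simulate_phenotypes(expr, list(T1 = c(p2 = -1)), noise_sd = 0)
  expect_equal(cor(ph2["T1", ], expr["p2", ]), -1)
  expect_error(simulate_phenotypes(expr, list(T1 = c(nope = 1))), "unknown")
})

test_that("trait-driver correlation matches the configured link strength", {
  # Monte-Carlo across seeded replicates: with link 0.8 and n = 20, the
  # sample |r| between a single-driver trait and its driver exceeds 0.5 in
  # at least 90% of replicates
  hits <- 0L
  n_rep <- 100L
  for (s in seq_len(n_rep)) {
    cfg <- sim_config(seed = 1000 + s, n_mirna_probes = 5, n_mrna_probes = 8,
                      n_de_mirna = 0, n_de_mrna = 0, n_planted_pairs = 4,
                      pheno_link_strength = 0.8)
    b <- generate_dataset(cfg)
    ld <- b$truth$pheno_loadings
    ok <- vapply(names(ld)[lengths(ld) == 1], function(trait) {
      abs(cor(b$phenotypes[trait, ], b$mrna[ld[[trait]], ])) > 0.5
    }, logical(1))
    hits <- hits + all(ok)
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("phenotype table uses the 19 canonical trait names, standardized", {
  b <- generate_dataset(sim_config(seed = 3, n_mirna_probes = 20,
                                   n_mrna_probes = 30, n_de_mirna = 2,
                                   n_de_mrna = 2, n_planted_pairs = 5))
  expect_identical(rownames(b$phenotypes), muscle_trait_names())
  expect_equal(unname(rowMeans(b$phenotypes)), rep(0, 19), tolerance = 1e-10)
  expect_equal(unname(apply(b$phenotypes, 1, sd)), rep(1, 19),
               tolerance = 1e-10)
})

test_that("planted DE probes differ in group means by the configured effect", {
  cfg <- sim_config(seed = 8, n_mirna_probes = 40, n_mrna_probes = 30,
                    n_de_mirna = 12, n_de_mrna = 5, n_planted_pairs = 5,
                    effect_size_log2 = 2, noise_sd_log2 = 0.3)
  b <- generate_dataset(cfg)
  duroc <- b$samples$sample_id[b$samples$breed == "Duroc"]
  pinn <- b$samples$sample_id[b$samples$breed == "PiNN"]
  deltas <- rowMeans(b$mirna[b$truth$de_mirna_ids, duroc]) -
    rowMeans(b$mirna[b$truth$de_mirna_ids, pinn])
  expect_equal(mean(deltas), 2, tolerance = 0.2)
  null_ids <- setdiff(rownames(b$mirna), b$truth$de_mirna_ids)
  null_delta <- rowMeans(b$mirna[null_ids, duroc]) -
    rowMeans(b$mirna[null_ids, pinn])
  expect_lt(abs(mean(null_delta)), 0.2)
})

test_that("a written bundle round-trips through the readers", {
  b <- generate_dataset(sim_config(seed = 21, n_mirna_probes = 10,
                                   n_mrna_probes = 12, n_de_mirna = 2,
                                   n_de_mrna = 2, n_planted_pairs = 3,
                                   n_low_presence = 2))
  dir <- withr::local_tempdir()
  write_dataset(b, dir)
  expect_equal(read_expression(file.path(dir, "mirna_expression.tsv")),
               b$mirna, tolerance = 1e-6)
  expect_identical(read_presence(file.path(dir, "mrna_presence.tsv")),
                   b$mrna_presence)
  tr <- read_transcripts(file.path(dir, "transcripts.fa"),
                         file.path(dir, "transcript_regions.tsv"))
  expect_identical(lapply(tr, `[[`, "seq"),
                   lapply(b$transcripts, `[[`, "seq"))
  ann <- read_probe_annotation(file.path(dir, "mirna_annotation.tsv"))
  expect_identical(ann$sequence, b$mirna_annotation$sequence)
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_identical(sort(truth$de_mirna_ids), b$truth$de_mirna_ids)
})
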