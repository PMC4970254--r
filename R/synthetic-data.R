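#' Names of the 19 muscle phenotypic traits
#'
#' Fiber-type composition (STO, FTO, FTG), mitochondrial respiration
#' (states 3/4, respiratory control indices), metabolic enzyme activities
#' (GP, PFK, LDH, CS), electron-transport-chain complexes and adenine
#' nucleotide concentrations.
#'
#' @return character(19) of trait names.
#' @export
muscle_trait_names <- function() {
  c("STO", "FTO", "FTG",
    "State3_pyruvate", "State3_succinate", "State4_CAT",
    "RCI_pyruvate", "RCI_succinate",
    "GP", "PFK", "LDH", "CS",
    "ComplexI", "ComplexII", "ComplexIV",
    "IMP", "AMP", "ADP", "ATP")
}

#' Configuration for the synthetic two-breed study generator
#'
#' Defaults emulate the real study design: two breed groups (Duroc, PiNN)
#' of 10 animals each, probe-level log2 intensities with planted breed
#' effects of one log2 unit, miRNA->target negative regulation with
#' sequence-level complementary sites, and 19 latent-factor-driven
#' phenotypic traits.
#'
#' @param seed integer RNG seed.
#' @param n_per_group samples per breed (>= 3).
#' @param n_mirna_probes,n_mrna_probes probe counts.
#' @param n_de_mirna,n_de_mrna planted differential probes per matrix.
#' @param n_planted_pairs true miRNA->target regulations (with planted
#'   complementary sites).
#' @param effect_size_log2 planted breed shift in log2 units.
#' @param reg_strength fraction of a target's variance explained by its
#'   miRNA (expected miRNA-target correlation -sqrt(reg_strength)).
#' @param noise_sd_log2 residual SD on the log2 scale.
#' @param presence_rate probability a probe is called present per sample.
#' @param n_low_presence probes per matrix forced to a low (0.3) presence
#'   rate, for exercising the presence filter.
#' @param n_phenotypes number of traits (19 gives the named trait panel).
#' @param pheno_link_strength target correlation between a planted chain's
#'   gene and its trait.
#' @param sex_effect_log2 optional additive sex effect (0 = none).
#' @return validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L, n_per_group = 10L,
                       n_mirna_probes = 60L, n_mrna_probes = 120L,
                       n_de_mirna = 15L, n_de_mrna = 40L,
                       n_planted_pairs = 20L,
                       effect_size_log2 = 1, reg_strength = 0.6,
                       noise_sd_log2 = 0.5, presence_rate = 0.9,
                       n_low_presence = 0L,
                       n_phenotypes = 19L, pheno_link_strength = 0.7,
                       sex_effect_log2 = 0) {
  cfg <- list(seed = as.integer(seed), n_per_group = as.integer(n_per_group),
              n_mirna_probes = as.integer(n_mirna_probes),
              n_mrna_probes = as.integer(n_mrna_probes),
              n_de_mirna = as.integer(n_de_mirna),
              n_de_mrna = as.integer(n_de_mrna),
              n_planted_pairs = as.integer(n_planted_pairs),
              effect_size_log2 = effect_size_log2,
              reg_strength = reg_strength,
              noise_sd_log2 = noise_sd_log2,
              presence_rate = presence_rate,
              n_low_presence = as.integer(n_low_presence),
              n_phenotypes = as.integer(n_phenotypes),
              pheno_link_strength = pheno_link_strength,
              sex_effect_log2 = sex_effect_log2)
  if (cfg$n_per_group < 3) stop("configuration error: n_per_group must be >= 3")
  if (cfg$n_de_mirna > cfg$n_mirna_probes ||
      cfg$n_de_mrna > cfg$n_mrna_probes) {
    stop("configuration error: n_de_* must not exceed the probe count")
  }
  if (cfg$reg_strength < 0 || cfg$reg_strength > 1 ||
      cfg$presence_rate < 0 || cfg$presence_rate > 1) {
    stop("configuration error: rates must lie in [0, 1]")
  }
  if (cfg$n_planted_pairs > cfg$n_mrna_probes ||
      cfg$n_planted_pairs > floor(0.8 * cfg$n_mirna_probes)) {
    stop("configuration error: too many planted pairs for the probe counts")
  }
  class(cfg) <- "sim_config"
  cfg
}

.random_rna <- function(n_seq, len) {
  vapply(seq_len(n_seq), function(i) {
    paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Plant a complementary miRNA target site into a transcript region
#'
#' Overwrites the region at `position` (0-based offset within the region)
#' with the reverse complement of miRNA positions 2..`extent`, optionally
#' followed by an A opposite miRNA position 1 (8mer-style anchoring). With
#' the default `extent = 8` the planted substring is exactly the 7-nt
#' reverse complement of the seed (positions 2-8).
#'
#' @param transcript one element of a transcript set.
#' @param mirna_seq RNA sequence (>= `extent` nt).
#' @param region "5UTR", "CDS" or "3UTR".
#' @param position 0-based offset of the site within the region.
#' @param extent last miRNA position included in the complementary stretch.
#' @param a1_anchor append an A opposite miRNA position 1?
#' @return the modified transcript (same structure).
#' @export
plant_target_site <- function(transcript, mirna_seq, region, position,
                              extent = 8L, a1_anchor = FALSE) {
  mirna_seq <- as_rna(mirna_seq)
  if (nchar(mirna_seq) < extent) stop("miRNA shorter than requested extent")
  site <- revcomp_rna(substr(mirna_seq, 2, extent))
  if (a1_anchor) site <- paste0(site, "A")
  r <- transcript$regions[[region]]
  if (is.null(r)) stop("unknown region ", region)
  rlen <- r[2] - r[1]
  if (position < 0 || position + nchar(site) > rlen) {
    stop("bounds error: site of ", nchar(site), " nt at offset ", position,
         " does not fit region ", region, " of length ", rlen)
  }
  at <- r[1] + position # 0-based on the transcript
  substr(transcript$seq, at + 1L, at + nchar(site)) <- site
  transcript
}

#' Simulate phenotypic traits as linear combinations of probe expression
#'
#' Each trait is a loading-weighted sum of its driver probes' expression
#' rows plus Gaussian noise. With zero noise and a single driver of loading
#' 1 the trait equals the driver's expression row exactly.
#'
#' @param expr probes-by-samples matrix.
#' @param loadings named list: trait name -> named numeric vector of
#'   loadings (names = probe ids in `expr`).
#' @param noise_sd Gaussian noise SD added per trait.
#' @param standardize scale each trait to mean 0, SD 1?
#' @return traits-by-samples numeric matrix.
#' @export
simulate_phenotypes <- function(expr, loadings, noise_sd = 0,
                                standardize = FALSE) {
  out <- matrix(0, length(loadings), ncol(expr),
                dimnames = list(names(loadings), colnames(expr)))
  for (trait in names(loadings)) {
    lv <- loadings[[trait]]
    missing_ids <- setdiff(names(lv), rownames(expr))
    if (length(missing_ids)) {
      stop("unknown probe id(s) in loadings: ",
           paste(missing_ids, collapse = ", "))
    }
    v <- as.vector(lv %*% expr[names(lv), , drop = FALSE])
    if (noise_sd > 0) v <- v + rnorm(ncol(expr), 0, noise_sd)
    if (standardize) v <- as.vector(scale(v))
    out[trait, ] <- v
  }
  out
}

#' Generate a complete synthetic two-breed study with planted ground truth
#'
#' Produces, under a single seeded RNG stream with a fixed draw order
#' (reproducible independent of downstream calls): miRNA and mRNA
#' probes-by-samples log2 matrices with planted breed effects, presence
#' call matrices, a miRNA probe annotation with mature names and sequences,
#' a transcript set with 5'UTR/CDS/3'UTR boundaries carrying planted
#' complementary target sites, a sample table, a standardized phenotype
#' table, and the ground truth needed to score every downstream stage.
#'
#' Planted regulations: each planted (miRNA, gene) pair gets (i) an
#' extended complementary site (reverse complement of miRNA positions 2-19
#' plus an A anchor) written into one transcript region, so both the
#' seed-match and the duplex-energy route detect it, and (ii) an expression
#' coupling in which the miRNA explains `reg_strength` of the target's
#' variance with negative sign. Planted chains drive phenotypes: each
#' planted gene loads on one of the traits (round-robin over the panel)
#' with per-trait noise calibrated so a single driver correlates
#' ~`pheno_link_strength` with its trait.
#'
#' @param config a [sim_config()].
#' @return list with elements `mirna`, `mirna_presence`, `mrna`,
#'   `mrna_presence`, `mirna_annotation`, `transcripts`, `samples`,
#'   `phenotypes`, `truth` (list: de_mirna_ids, de_mrna_ids, planted_pairs
#'   data.frame, pheno_loadings) and `config`.
#' @export
generate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- 2L * config$n_per_group
  breeds <- rep(c("Duroc", "PiNN"), each = config$n_per_group)
  sex <- rep_len(c("F", "M"), n)
  samples <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n)),
    breed = breeds, sex = sex, stringsAsFactors = FALSE)

  # --- step 1: identities and sequences (fixed draw order) ---
  n_mature <- max(config$n_planted_pairs,
                  as.integer(ceiling(0.8 * config$n_mirna_probes)))
  mature_names <- sprintf("ssc-miR-%d", 100L + seq_len(n_mature))
  mature_seqs <- setNames(.random_rna(n_mature, 22L), mature_names)
  probe_ids <- sprintf("miR_probe_%03d", seq_len(config$n_mirna_probes))
  probe_mature <- c(mature_names,
                    sample(mature_names,
                           config$n_mirna_probes - n_mature, replace = TRUE))
  mirna_annotation <- data.frame(
    probe_id = probe_ids, mature_name = probe_mature,
    sequence = unname(mature_seqs[probe_mature]),
    stringsAsFactors = FALSE)
  mirna_annotation$length <- nchar(mirna_annotation$sequence)

  gene_ids <- sprintf("GENE%04d", seq_len(config$n_mrna_probes))
  utr5_len <- sample(25:40, config$n_mrna_probes, replace = TRUE)
  cds_len <- sample(60:120, config$n_mrna_probes, replace = TRUE)
  utr3_len <- sample(60:120, config$n_mrna_probes, replace = TRUE)
  seqs <- setNames(.random_rna(config$n_mrna_probes, 1L), gene_ids)
  regions <- NULL
  for (k in seq_along(gene_ids)) {
    total <- utr5_len[k] + cds_len[k] + utr3_len[k]
    seqs[k] <- .random_rna(1L, total)
    regions <- rbind(regions, data.frame(
      gene_id = gene_ids[k],
      region = c("5UTR", "CDS", "3UTR"),
      start = c(0L, utr5_len[k], utr5_len[k] + cds_len[k]),
      end = c(utr5_len[k], utr5_len[k] + cds_len[k], total)))
  }
  transcripts <- transcript_set(seqs, regions)

  # --- step 2: planted pairs and sites ---
  planted_mirna <- sample(mature_names, config$n_planted_pairs)
  planted_gene <- sample(gene_ids, config$n_planted_pairs)
  site_len <- 19L # revcomp of positions 2-19 plus A anchor
  planted <- data.frame(mirna_id = character(0), gene_id = character(0),
                        region = character(0), site_start = integer(0),
                        site_length = integer(0),
                        seed_site_start = integer(0),
                        stringsAsFactors = FALSE)
  for (k in seq_len(config$n_planted_pairs)) {
    region <- sample(c("3UTR", "CDS", "5UTR"), 1, prob = c(0.6, 0.3, 0.1))
    tr <- transcripts[[planted_gene[k]]]
    rlen <- tr$regions[[region]][2] - tr$regions[[region]][1]
    if (rlen < site_len) region <- "3UTR"
    rlen <- tr$regions[[region]][2] - tr$regions[[region]][1]
    pos <- sample.int(rlen - site_len + 1L, 1) - 1L
    transcripts[[planted_gene[k]]] <- plant_target_site(
      tr, mature_seqs[[planted_mirna[k]]], region, pos,
      extent = 19L, a1_anchor = TRUE)
    planted <- rbind(planted, data.frame(
      mirna_id = planted_mirna[k], gene_id = planted_gene[k],
      region = region, site_start = pos, site_length = site_len,
      seed_site_start = pos + site_len - 8L, # 7-nt seed revcomp offset
      stringsAsFactors = FALSE))
  }

  # --- step 3: expression matrices ---
  # breed effects are planted on genes that are NOT regulation targets, so
  # a planted pair's miRNA-target correlation is governed by reg_strength
  # alone (a breed shift on the target would dilute or cancel it)
  de_gene_pool <- setdiff(gene_ids, planted$gene_id)
  if (config$n_de_mrna > length(de_gene_pool)) {
    stop("configuration error: n_de_mrna exceeds the number of genes not ",
         "used as planted regulation targets")
  }
  de_mirna_ids <- sample(probe_ids, config$n_de_mirna)
  de_mrna_ids <- sample(de_gene_pool, config$n_de_mrna)
  breed_sign <- ifelse(breeds == "Duroc", 0.5, -0.5)
  sex_sign <- ifelse(sex == "F", 0.5, -0.5)

  base_mirna <- rnorm(config$n_mirna_probes, 8, 1.5)
  mirna <- matrix(base_mirna, config$n_mirna_probes, n,
                  dimnames = list(probe_ids, samples$sample_id))
  shift <- (probe_ids %in% de_mirna_ids) * config$effect_size_log2
  mirna <- mirna + outer(shift, breed_sign) +
    config$sex_effect_log2 * outer(rep(1, config$n_mirna_probes), sex_sign) +
    matrix(rnorm(config$n_mirna_probes * n, 0, config$noise_sd_log2),
           config$n_mirna_probes, n)

  base_mrna <- rnorm(config$n_mrna_probes, 9, 1.5)
  mrna <- matrix(base_mrna, config$n_mrna_probes, n,
                 dimnames = list(gene_ids, samples$sample_id))
  shift_g <- (gene_ids %in% de_mrna_ids) * config$effect_size_log2
  mrna <- mrna + outer(shift_g, breed_sign) +
    config$sex_effect_log2 * outer(rep(1, config$n_mrna_probes), sex_sign)
  noise_g <- matrix(rnorm(config$n_mrna_probes * n, 0, 1),
                    config$n_mrna_probes, n)
  # regulated targets: miRNA explains reg_strength of residual variance,
  # with negative sign; regulator signal = the mature's first probe row
  mature_to_probe <- mirna_annotation$probe_id[
    match(mature_names, mirna_annotation$mature_name)]
  names(mature_to_probe) <- mature_names
  reg <- config$reg_strength
  for (k in seq_len(config$n_planted_pairs)) {
    g <- planted$gene_id[k]
    mp <- mature_to_probe[[planted$mirna_id[k]]]
    z <- as.vector(scale(mirna[mp, ]))
    mrna[g, ] <- mrna[g, ] + config$noise_sd_log2 *
      (-sqrt(reg) * z + sqrt(1 - reg) * noise_g[match(g, gene_ids), ])
  }
  unreg <- setdiff(gene_ids, planted$gene_id)
  mrna[unreg, ] <- mrna[unreg, ] +
    config$noise_sd_log2 * noise_g[match(unreg, gene_ids), ]

  # --- step 4: presence calls ---
  rate_mirna <- rep(config$presence_rate, config$n_mirna_probes)
  rate_mrna <- rep(config$presence_rate, config$n_mrna_probes)
  if (config$n_low_presence > 0) {
    rate_mirna[seq_len(min(config$n_low_presence,
                           config$n_mirna_probes))] <- 0.3
    rate_mrna[seq_len(min(config$n_low_presence,
                          config$n_mrna_probes))] <- 0.3
  }
  mirna_presence <- matrix(
    rbinom(config$n_mirna_probes * n, 1, rep(rate_mirna, n)) == 1,
    config$n_mirna_probes, n, dimnames = dimnames(mirna))
  mrna_presence <- matrix(
    rbinom(config$n_mrna_probes * n, 1, rep(rate_mrna, n)) == 1,
    config$n_mrna_probes, n, dimnames = dimnames(mrna))

  # --- step 5: phenotypes driven by planted genes (round-robin traits) ---
  trait_names <- if (config$n_phenotypes == 19L) muscle_trait_names() else
    sprintf("trait_%02d", seq_len(config$n_phenotypes))
  drivers <- split(planted$gene_id,
                   trait_names[(seq_len(config$n_planted_pairs) - 1L) %%
                                 config$n_phenotypes + 1L])
  phenotypes <- matrix(rnorm(config$n_phenotypes * n),
                       config$n_phenotypes, n,
                       dimnames = list(trait_names, samples$sample_id))
  link <- config$pheno_link_strength
  pheno_loadings <- setNames(vector("list", config$n_phenotypes),
                             trait_names)
  for (trait in names(drivers)) {
    gs <- drivers[[trait]]
    K <- length(gs)
    noise_var <- max(1 / link^2 - K, 0.05)
    v <- rep(0, n)
    for (g in gs) v <- v + as.vector(scale(mrna[g, ]))
    v <- v + rnorm(n, 0, sqrt(noise_var))
    phenotypes[trait, ] <- v
    pheno_loadings[[trait]] <- gs
  }
  phenotypes <- t(apply(phenotypes, 1, function(v) as.vector(scale(v))))
  colnames(phenotypes) <- samples$sample_id

  list(mirna = mirna, mirna_presence = mirna_presence,
       mrna = mrna, mrna_presence = mrna_presence,
       mirna_annotation = mirna_annotation,
       mirna_sequences = mature_seqs,
       transcripts = transcripts, samples = samples,
       phenotypes = phenotypes,
       truth = list(de_mirna_ids = sort(de_mirna_ids),
                    de_mrna_ids = sort(de_mrna_ids),
                    planted_pairs = planted,
                    pheno_loadings = pheno_loadings),
       config = config)
}

#' Write a synthetic bundle to a directory of plain-text files
#'
#' Expression and presence TSVs, probe annotation TSV, transcript FASTA plus
#' region table, sample TSV, phenotype TSV and ground-truth JSON.
#'
#' @param bundle result of [generate_dataset()].
#' @param dir output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  fp <- function(f) file.path(dir, f)
  write_expression(bundle$mirna, fp("mirna_expression.tsv"))
  write_expression(bundle$mrna, fp("mrna_expression.tsv"))
  write_expression(bundle$mirna_presence * 1, fp("mirna_presence.tsv"))
  write_expression(bundle$mrna_presence * 1, fp("mrna_presence.tsv"))
  write.table(bundle$mirna_annotation, fp("mirna_annotation.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_transcripts(bundle$transcripts, fp("transcripts.fa"),
                    fp("transcript_regions.tsv"))
  write.table(bundle$samples, fp("samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression(bundle$phenotypes, fp("phenotypes.tsv"),
                   id_column = "trait")
  jsonlite::write_json(bundle$truth, fp("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
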