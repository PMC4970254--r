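#' Duplex energy parameters
#'
#' Loads the nearest-neighbor energy table used by the duplex
#' minimum-free-energy dynamic program: doublet stacking free energies
#' (Watson-Crick values from the standard RNA nearest-neighbor set; G:U
#' wobble doublets interpolated from the two Watson-Crick substitutions and
#' damped), bulge/interior loop penalties up to `max_loop_per_side`
#' nucleotides per side, a duplex initiation term and an AU/GU terminal-pair
#' penalty. All energies are in kcal/mol at 37 degrees C. The table is a
#' plain TSV and can be swapped for a different parameterisation.
#'
#' @param path TSV parameter file; default is the bundled table.
#' @return list with `stack` (6x6 matrix over pairs AU, UA, CG, GC, GU, UG),
#'   `loop` (5x5 matrix indexed by unpaired counts 0..4 per side),
#'   `duplex_init`, `au_end_penalty`, `max_loop_per_side`.
#' @export
duplex_params <- function(path = system.file("extdata",
                                             "duplex_energy_params.tsv",
                                             package = "mirtriad")) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  pairs <- c("AU", "UA", "CG", "GC", "GU", "UG")
  st <- tab[tab$type == "stack", ]
  stack <- matrix(NA_real_, 6, 6, dimnames = list(pairs, pairs))
  stack[cbind(match(st$key1, pairs), match(st$key2, pairs))] <- st$value
  if (anyNA(stack)) stop("incomplete energy table: missing stacking doublets")
  lo <- tab[tab$type == "loop", ]
  loop <- matrix(NA_real_, 5, 5)
  loop[cbind(as.integer(lo$key1) + 1L, as.integer(lo$key2) + 1L)] <- lo$value
  loop[1, 1] <- 0 # (0,0) is a stack, never consulted as a loop
  if (anyNA(loop)) stop("incomplete energy table: missing loop penalties")
  if (any(loop[-1] <= 0, na.rm = TRUE) || any(loop[1, -1] <= 0)) {
    stop("loop penalties must be positive")
  }
  sc <- tab[tab$type == "scalar", ]
  val <- function(k) sc$value[match(k, sc$key1)]
  list(stack = stack, loop = loop,
       duplex_init = val("duplex_init"),
       au_end_penalty = val("au_end_penalty"),
       max_loop_per_side = as.integer(val("max_loop_per_side")))
}

.encode_rna <- function(seq) {
  match(strsplit(as_rna(seq), "")[[1]], c("A", "C", "G", "U")) - 1L
}

.duplex_result <- function(res, mirna_seq, target_seq) {
  if (!is.finite(res$mfe)) {
    return(list(mfe = Inf, n_pairs = 0L,
                pairs = data.frame(mirna_pos = integer(0),
                                   target_pos = integer(0)),
                target_start = NA_integer_, target_end = NA_integer_,
                pairing_string = NA_character_))
  }
  mp <- res$mirna_pos; tp <- res$target_pos
  mchr <- rep(".", nchar(mirna_seq)); mchr[mp] <- "("
  tchr <- rep(".", nchar(target_seq)); tchr[tp] <- ")"
  list(mfe = res$mfe, n_pairs = length(mp),
       pairs = data.frame(mirna_pos = mp, target_pos = tp),
       target_start = min(tp) - 1L, target_end = max(tp),
       pairing_string = paste0(paste(mchr, collapse = ""), "&",
                               paste(tchr, collapse = "")))
}

#' Minimum-free-energy intermolecular duplex between two RNAs
#'
#' Dynamic program over intermolecular base pairs only (no intramolecular
#' structure, no pseudoknots): consecutive pairs score nearest-neighbor
#' stacking terms, bulge/interior loops are allowed up to
#' `max_loop_per_side` unpaired nucleotides per side, and the optimum adds
#' the duplex initiation term and AU/GU end penalties. If the sequences
#' share no pairable (Watson-Crick or G:U) combination the energy is `Inf`
#' (no duplex).
#'
#' @param mirna_seq,target_seq RNA sequences (5'->3').
#' @param params energy parameters from [duplex_params()].
#' @return list with `mfe` (kcal/mol), `n_pairs`, `pairs` (1-based paired
#'   positions), `target_start`/`target_end` (0-based half-open span of
#'   paired target positions) and `pairing_string` (dot-bracket, the two
#'   strands joined by "&").
#' @export
duplex_mfe <- function(mirna_seq, target_seq, params = duplex_params()) {
  res <- .duplex_mfe_cpp(.encode_rna(mirna_seq), .encode_rna(target_seq),
                         params$stack, params$loop, params$duplex_init,
                         params$au_end_penalty, params$max_loop_per_side)
  .duplex_result(res, mirna_seq, target_seq)
}

#' Best duplex hit over a long target, scanned in overlapping windows
#'
#' Long targets are scanned with overlapping windows (default 60 nt, step
#' 20) and the single best-energy hit is kept; ties are broken by smaller
#' target start, then longer helix.
#'
#' @inheritParams duplex_mfe
#' @param window,step window length and offset step in nt.
#' @return as [duplex_mfe()], with target coordinates on the full sequence.
#' @export
scan_duplex <- function(mirna_seq, target_seq, params = duplex_params(),
                        window = 60L, step = 20L) {
  res <- .duplex_scan_cpp(.encode_rna(mirna_seq), .encode_rna(target_seq),
                          params$stack, params$loop, params$duplex_init,
                          params$au_end_penalty, params$max_loop_per_side,
                          as.integer(window), as.integer(step))
  .duplex_result(res, mirna_seq, target_seq)
}

#' Seed of a miRNA: positions 2-8 from the 5' end
#'
#' @param mirna_seq RNA sequence, length >= 8.
#' @return the 7-nt seed (5'->3').
#' @examples
#' seed_of("UGAGGUAGUAGGUUGUAUAGUU")  # "GAGGUAG"
#' @export
seed_of <- function(mirna_seq) {
  mirna_seq <- as_rna(mirna_seq)
  if (nchar(mirna_seq) < 8) stop("miRNA sequence must be at least 8 nt")
  substr(mirna_seq, 2, 8)
}

.find_motif <- function(text, motif) {
  # all 0-based start positions of exact matches
  if (nchar(motif) == 0 || nchar(text) < nchar(motif)) return(integer(0))
  hits <- gregexpr(motif, text, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  # gregexpr skips overlapping matches; rescan manually
  out <- integer(0)
  p <- 1L
  while (p <= nchar(text) - nchar(motif) + 1L) {
    h <- regexpr(motif, substr(text, p, nchar(text)), fixed = TRUE)
    if (h == -1) break
    out <- c(out, p + h - 2L)
    p <- p + h
  }
  out
}

#' Find canonical seed-match sites of a miRNA on a transcript
#'
#' Scans the 5'UTR, CDS and 3'UTR for exact Watson-Crick reverse
#' complements of the seed (miRNA positions 2-8; no G:U allowed in seed
#' pairing) and classifies each site: 6mer (positions 2-7), 7mer-m8
#' (2-8), 7mer-A1 (2-7 plus an A opposite miRNA position 1) or 8mer (2-8
#' plus the A). Overlapping classifications report the strongest type only
#' (8mer > 7mer-m8 > 7mer-A1 > 6mer).
#'
#' @param mirna_seq miRNA sequence (>= 8 nt).
#' @param transcript one element of a transcript set (see
#'   [read_transcripts()]).
#' @param site_types site types to report.
#' @return data.frame with region, start, end (0-based half-open on the
#'   region) and site_type; zero rows when there is no match.
#' @export
find_seed_matches <- function(mirna_seq, transcript,
                              site_types = c("8mer", "7mer-m8", "7mer-A1",
                                             "6mer")) {
  mirna_seq <- as_rna(mirna_seq)
  seed7 <- seed_of(mirna_seq)
  match7 <- revcomp_rna(seed7)            # target site for miRNA 2-8
  match6 <- revcomp_rna(substr(mirna_seq, 2, 7))
  rows <- list()
  for (region in c("5UTR", "CDS", "3UTR")) {
    s <- region_seq(transcript, region)
    if (nchar(s) < 6) next
    chars <- strsplit(s, "")[[1]]
    p7 <- .find_motif(s, match7)
    for (p in p7) {
      has_a <- p + 7 < nchar(s) && chars[p + 8] == "A"
      if (has_a) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, start = p, end = p + 8L, site_type = "8mer")
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, start = p, end = p + 7L, site_type = "7mer-m8")
      }
    }
    p6 <- .find_motif(s, match6)
    for (p in p6) {
      # skip if the site extends to an m8 match (already reported above):
      # position p-1 opposite miRNA position 8
      if (p >= 1 && (p - 1) %in% p7) next
      has_a <- p + 6 < nchar(s) && chars[p + 7] == "A"
      if (has_a) {
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, start = p, end = p + 7L, site_type = "7mer-A1")
      } else {
        rows[[length(rows) + 1L]] <- data.frame(
          region = region, start = p, end = p + 6L, site_type = "6mer")
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(region = character(0), start = integer(0), end = integer(0),
               site_type = character(0))
  out <- out[out$site_type %in% site_types, , drop = FALSE]
  rownames(out) <- NULL
  out
}

.site_type_rank <- c("8mer" = 1, "7mer-m8" = 2, "7mer-A1" = 3, "6mer" = 4)

#' Predict miRNA targets by seed match and/or duplex energy
#'
#' For every (miRNA, transcript) combination, collects seed-match evidence
#' from [find_seed_matches()] and energy evidence from the windowed duplex
#' scan ([scan_duplex()]); the energy route keeps at most one hit per
#' transcript (the best-energy one) and calls it evidence when its minimum
#' free energy is at or below `energy_cutoff`. Evidence is combined per
#' `mode`: `"union"` (either source suffices, default) or `"intersection"`
#' (both required).
#'
#' @param mirnas named character vector of miRNA sequences (names = ids).
#' @param transcripts transcript set (see [read_transcripts()]).
#' @param mode evidence combination rule.
#' @param energy_cutoff kcal/mol threshold for energy evidence
#'   (default -25).
#' @param hits_per_target duplex hits retained per transcript (only 1
#'   supported, matching the single-best-site convention).
#' @param site_types seed site types considered.
#' @param params,window,step duplex scan settings.
#' @return data.frame of target pairs: mirna_id, gene_id, evidence
#'   ("seed", "energy" or "seed+energy"), best seed site columns (region,
#'   site_start, site_end, site_type) and duplex columns (mfe, duplex_start,
#'   duplex_end, n_pairs).
#' @export
predict_targets <- function(mirnas, transcripts,
                            mode = c("union", "intersection"),
                            energy_cutoff = -25, hits_per_target = 1L,
                            site_types = c("8mer", "7mer-m8", "7mer-A1",
                                           "6mer"),
                            params = duplex_params(),
                            window = 60L, step = 20L) {
  mode <- match.arg(mode)
  if (hits_per_target != 1L) stop("only hits_per_target = 1 is supported")
  rows <- list()
  for (mid in names(mirnas)) {
    mseq <- as_rna(mirnas[[mid]])
    for (gid in names(transcripts)) {
      tr <- transcripts[[gid]]
      seeds <- find_seed_matches(mseq, tr, site_types = site_types)
      hit <- scan_duplex(mseq, tr$seq, params = params,
                         window = window, step = step)
      has_seed <- nrow(seeds) > 0
      has_energy <- is.finite(hit$mfe) && hit$mfe <= energy_cutoff
      keep <- if (mode == "union") has_seed || has_energy else
        has_seed && has_energy
      if (!keep) next
      best_seed <- if (has_seed) {
        seeds[order(.site_type_rank[seeds$site_type], seeds$start), ][1, ]
      } else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mid, gene_id = gid,
        evidence = paste(c("seed", "energy")[c(has_seed, has_energy)],
                         collapse = "+"),
        region = if (has_seed) best_seed$region else NA_character_,
        site_start = if (has_seed) best_seed$start else NA_integer_,
        site_end = if (has_seed) best_seed$end else NA_integer_,
        site_type = if (has_seed) best_seed$site_type else NA_character_,
        mfe = if (is.finite(hit$mfe)) hit$mfe else NA_real_,
        duplex_start = hit$target_start, duplex_end = hit$target_end,
        n_pairs = hit$n_pairs,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(mirna_id = character(0), gene_id = character(0),
               evidence = character(0), region = character(0),
               site_start = integer(0), site_end = integer(0),
               site_type = character(0), mfe = numeric(0),
               duplex_start = integer(0), duplex_end = integer(0),
               n_pairs = integer(0))
  rownames(out) <- NULL
  out
}
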