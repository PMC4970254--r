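#' Read a probe-by-sample expression matrix from TSV
#'
#' The expected layout is a header row of sample ids, a first column of probe
#' ids, and numeric log2 intensities. Duplicate probe or sample ids, ragged
#' rows and non-numeric cells are format errors naming the offending row.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix, probes as rows (rownames), samples as columns.
#' @seealso [write_expression()], [read_presence()]
#' @export
read_expression <- function(path) {
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2) stop("format error: expected probe id column plus samples")
  probe_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  if (anyDuplicated(probe_ids)) {
    stop("format error: duplicated probe id(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  }
  if (anyDuplicated(sample_ids)) {
    stop("format error: duplicated sample id(s): ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  }
  raw <- as.matrix(df[-1])
  vals <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(df),
                                  dimnames = list(probe_ids, sample_ids)))
  bad <- is.na(vals) & !(raw %in% c("NA", ""))
  if (any(bad)) {
    stop("format error: non-numeric cell(s) in row(s): ",
         paste(unique(probe_ids[which(rowSums(bad) > 0)]), collapse = ", "))
  }
  vals
}

#' Write an expression (or presence) matrix to TSV
#'
#' @param mat numeric matrix with probe rownames and sample colnames.
#' @param path output path.
#' @param id_column header for the probe id column.
#' @export
write_expression <- function(mat, path, id_column = "probe_id") {
  df <- data.frame(rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df)[1] <- id_column
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_expression
#' @details `read_presence()` reads 0/1 presence calls in the same layout and
#'   returns a logical matrix; values other than 0/1 are a format error.
#' @export
read_presence <- function(path) {
  m <- read_expression(path)
  if (!all(m %in% c(0, 1))) stop("format error: presence calls must be 0/1")
  mode(m) <- "logical"
  m
}

#' Read the sample table (sample_id, breed, optional sex)
#'
#' @param path TSV with columns `sample_id` and `breed` (and optionally `sex`).
#' @return data.frame.
#' @export
read_samples <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (!all(c("sample_id", "breed") %in% colnames(df))) {
    stop("format error: sample table needs columns sample_id, breed")
  }
  if (anyDuplicated(df$sample_id)) stop("format error: duplicated sample ids")
  df
}

#' Read probe annotation (probe_id, mature_name, sequence)
#'
#' Sequences are normalised to the RNA alphabet (T transcribed to U) and a
#' `length` column in nucleotides is added.
#'
#' @param path TSV with columns probe_id, mature_name, sequence.
#' @return data.frame with columns probe_id, mature_name, sequence, length.
#' @export
read_probe_annotation <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("probe_id", "mature_name", "sequence")
  if (!all(need %in% colnames(df))) {
    stop("format error: annotation needs columns ", paste(need, collapse = ", "))
  }
  df$sequence <- as_rna(df$sequence)
  df$length <- nchar(df$sequence)
  df
}

#' Filter probes on detection/presence calls within each group
#'
#' A probe is kept when the fraction of samples in which it is called present
#' reaches `min_fraction` (inclusive, `>=`) in every breed (`rule =
#' "all_groups"`, default) or in at least one breed (`rule = "any_group"`).
#' The default 0.70 mirrors the common microarray practice of discarding
#' probes detected in less than 70% of samples within each group.
#'
#' @param mat probes-by-samples numeric matrix.
#' @param presence logical/0-1 matrix of the same shape (detection calls).
#' @param samples sample table with `sample_id`, `breed`.
#' @param min_fraction minimum present fraction per group, in (0, 1].
#' @param rule `"all_groups"` (conjunctive) or `"any_group"` (disjunctive).
#' @return list with `matrix` (kept rows), `presence` (kept rows of the call
#'   matrix) and `report` (per-probe per-group fractions and kept status).
#' @export
presence_filter <- function(mat, presence, samples,
                            min_fraction = 0.70,
                            rule = c("all_groups", "any_group")) {
  rule <- match.arg(rule)
  if (is.null(presence)) stop("presence calls are required for presence_filter")
  stopifnot(all(dim(mat) == dim(presence)))
  if (min_fraction < 0 || min_fraction > 1) stop("min_fraction must be in [0, 1]")
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$breed)) stop("samples missing from sample table")
  groups <- split(seq_len(ncol(mat)), samples$breed)
  frac <- vapply(groups, function(idx) {
    rowMeans(presence[, idx, drop = FALSE] != 0)
  }, numeric(nrow(mat)))
  frac <- matrix(frac, nrow = nrow(mat),
                 dimnames = list(rownames(mat), names(groups)))
  keep <- if (rule == "all_groups") {
    apply(frac >= min_fraction, 1, all)
  } else {
    apply(frac >= min_fraction, 1, any)
  }
  report <- data.frame(probe_id = rownames(mat), frac,
                       kept = keep, row.names = NULL, check.names = FALSE)
  list(matrix = mat[keep, , drop = FALSE],
       presence = presence[keep, , drop = FALSE],
       report = report)
}

#' Filter probes on annotated sequence length
#'
#' Keeps probes whose annotated sequence length is at most `max_len`
#' nucleotides. The default 29 drops sequences of 30 nt or longer, the usual
#' cutoff separating mature miRNAs from hairpin precursors on miRNA arrays.
#'
#' @param annotations data.frame with `probe_id` and `length` (or `sequence`).
#' @param max_len maximum length kept (inclusive).
#' @return the kept subset of `annotations`.
#' @export
length_filter <- function(annotations, max_len = 29) {
  if (is.null(annotations$length)) {
    annotations$length <- nchar(annotations$sequence)
  }
  annotations[annotations$length <= max_len, , drop = FALSE]
}

#' Read transcript sequences with 5'UTR/CDS/3'UTR boundaries
#'
#' @param fasta_path FASTA of transcript sequences (DNA accepted, transcribed
#'   to RNA on read).
#' @param regions_path TSV with columns gene_id, region (5UTR/CDS/3UTR),
#'   start, end — 0-based half-open coordinates on the transcript.
#' @return a named list of transcripts; each element is a list with `seq`
#'   (full RNA sequence) and `regions` (named list of c(start, end)).
#'   Missing region rows yield empty regions.
#' @export
read_transcripts <- function(fasta_path, regions_path) {
  seqs <- Biostrings::readBStringSet(fasta_path)
  seqs <- setNames(as_rna(as.character(seqs)),
                   sub("\\s.*$", "", names(seqs)))
  reg <- read.delim(regions_path, sep = "\t", stringsAsFactors = FALSE)
  need <- c("gene_id", "region", "start", "end")
  if (!all(need %in% colnames(reg))) {
    stop("format error: region table needs columns ", paste(need, collapse = ", "))
  }
  transcript_set(seqs, reg)
}

#' Assemble a transcript set from sequences and a region table
#'
#' @param seqs named character vector of RNA sequences.
#' @param regions data.frame(gene_id, region, start, end), 0-based half-open.
#' @return named list of transcripts (see [read_transcripts()]).
#' @export
transcript_set <- function(seqs, regions) {
  if (!all(regions$region %in% c("5UTR", "CDS", "3UTR"))) {
    stop("format error: region must be one of 5UTR, CDS, 3UTR")
  }
  if (!all(regions$gene_id %in% names(seqs))) {
    stop("format error: region rows reference unknown gene id(s): ",
         paste(setdiff(regions$gene_id, names(seqs)), collapse = ", "))
  }
  out <- lapply(names(seqs), function(g) {
    s <- seqs[[g]]
    n <- nchar(s)
    rows <- regions[regions$gene_id == g, , drop = FALSE]
    if (anyDuplicated(rows$region)) {
      stop("format error: duplicated region rows for ", g)
    }
    regs <- list(`5UTR` = c(0L, 0L), CDS = c(0L, 0L), `3UTR` = c(0L, 0L))
    for (k in seq_len(nrow(rows))) {
      st <- rows$start[k]; en <- rows$end[k]
      if (st < 0 || en > n || st > en) {
        stop("format error: region ", rows$region[k], " of ", g,
             " out of range [0, ", n, ")")
      }
      regs[[rows$region[k]]] <- c(as.integer(st), as.integer(en))
    }
    occupied <- rows[order(rows$start), , drop = FALSE]
    if (nrow(occupied) > 1 &&
        any(occupied$start[-1] < occupied$end[-nrow(occupied)])) {
      stop("format error: overlapping regions on ", g)
    }
    list(seq = s, regions = regs)
  })
  names(out) <- names(seqs)
  class(out) <- "transcript_set"
  out
}

#' Extract one region's subsequence from a transcript
#'
#' @param transcript one element of a transcript set.
#' @param region "5UTR", "CDS" or "3UTR".
#' @return the region's RNA subsequence (possibly empty).
#' @export
region_seq <- function(transcript, region) {
  r <- transcript$regions[[region]]
  if (is.null(r) || r[2] <= r[1]) return("")
  substr(transcript$seq, r[1] + 1L, r[2])
}

#' Write a transcript set as FASTA plus region table
#'
#' @param transcripts a transcript set.
#' @param fasta_path,regions_path output paths.
#' @export
write_transcripts <- function(transcripts, fasta_path, regions_path) {
  seqs <- Biostrings::BStringSet(vapply(transcripts, `[[`, "", "seq"))
  names(seqs) <- names(transcripts)
  Biostrings::writeXStringSet(seqs, fasta_path)
  rows <- do.call(rbind, lapply(names(transcripts), function(g) {
    regs <- transcripts[[g]]$regions
    keep <- vapply(regs, function(r) r[2] > r[1], logical(1))
    if (!any(keep)) return(NULL)
    data.frame(gene_id = g, region = names(regs)[keep],
               start = vapply(regs[keep], `[`, 0L, 1),
               end = vapply(regs[keep], `[`, 0L, 2))
  }))
  write.table(rows, regions_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta_path)
}
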