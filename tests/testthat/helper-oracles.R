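# Independent brute-force oracles used to validate the package's
# implementations on small inputs. These deliberately share no code with
# the functions they check.

# Minimum duplex energy by exhaustive enumeration of all antiparallel,
# non-crossing intermolecular pair chains (loop sides <= max per side),
# scored with the same nearest-neighbor cost model.
oracle_duplex_mfe <- function(mirna_seq, target_seq, params) {
  mch <- strsplit(as_rna(mirna_seq), "")[[1]]
  tch <- strsplit(as_rna(target_seq), "")[[1]]
  pr <- c("AU", "UA", "CG", "GC", "GU", "UG")
  P <- matrix(NA_integer_, length(mch), length(tch))
  for (i in seq_along(mch)) for (j in seq_along(tch)) {
    P[i, j] <- match(paste0(mch[i], tch[j]), pr)
  }
  maxl <- params$max_loop_per_side
  term <- function(p) {
    if (p %in% c(1, 2, 5, 6)) params$au_end_penalty else 0
  }
  best <- Inf
  rec <- function(i, j, acc) {
    closing <- acc + term(P[i, j]) + params$duplex_init
    if (closing < best) best <<- closing
    i2s <- seq(i + 1, length.out = max(0, min(maxl + 1, length(mch) - i)))
    j2s <- seq(j - 1, by = -1, length.out = max(0, min(maxl + 1, j - 1)))
    for (i2 in i2s) for (j2 in j2s) {
      p2 <- P[i2, j2]
      if (is.na(p2)) next
      li <- i2 - i - 1
      lj <- j - j2 - 1
      cost <- if (li == 0 && lj == 0) params$stack[P[i, j], p2] else
        params$loop[li + 1, lj + 1]
      rec(i2, j2, acc + cost)
    }
  }
  for (i in seq_along(mch)) for (j in seq_along(tch)) {
    if (!is.na(P[i, j])) rec(i, j, term(P[i, j]))
  }
  best
}

# Step-up FDR by the min-over-tails definition applied literally.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(m * ps[i:m] / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Upper-tail hypergeometric probability P(X >= k) by direct summation of
# fixed-margin 2x2 table probabilities.
oracle_hyper_tail <- function(N, K, n, k) {
  kk <- max(k, 0):min(K, n)
  if (length(kk) == 0 || k > min(K, n)) return(0)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

# single-transcript set with given region sequences
toy_transcript <- function(utr5 = "", cds = "", utr3 = "", gene = "G1") {
  s <- paste0(utr5, cds, utr3)
  b1 <- nchar(utr5)
  b2 <- b1 + nchar(cds)
  regions <- data.frame(gene_id = gene,
                        region = c("5UTR", "CDS", "3UTR"),
                        start = c(0L, b1, b2),
                        end = c(b1, b2, nchar(s)))
  regions <- regions[regions$end > regions$start, , drop = FALSE]
  transcript_set(setNames(s, gene), regions)
}
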