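#' Pearson correlation on pairwise-complete observations
#'
#' @param x,y numeric vectors of equal length.
#' @return list with `r`, `n_used` and `defined` (FALSE when either vector is
#'   constant over the complete pairs, in which case `r` is NA and the pair
#'   should be excluded downstream).
#' @export
pearson_r <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  n <- sum(ok)
  if (n < 3) stop("need at least 3 paired finite values")
  x <- x[ok]; y <- y[ok]
  if (sd(x) == 0 || sd(y) == 0) {
    return(list(r = NA_real_, n_used = n, defined = FALSE))
  }
  list(r = cor(x, y), n_used = n, defined = TRUE)
}

#' Two-sided p-value for a Pearson correlation
#'
#' Uses the t transform t = r * sqrt(n - 2) / sqrt(1 - r^2) with n - 2
#' degrees of freedom; |r| = 1 gives p = 0.
#'
#' @param r correlation coefficient(s), |r| <= 1.
#' @param n number(s) of paired observations, >= 3.
#' @return two-sided p-value(s).
#' @examples
#' pearson_pvalue(0.543, 20)   # 0.0134 at 4 dp
#' @export
pearson_pvalue <- function(r, n) {
  if (any(n < 3)) stop("need n >= 3")
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1")
  r <- pmin(pmax(r, -1), 1)
  p <- ifelse(abs(r) == 1, 0,
              2 * pt(abs(r) * sqrt(n - 2) / sqrt(1 - r^2), df = n - 2,
                     lower.tail = FALSE))
  unname(p)
}

# correlation + n over shared samples for two probe matrices
.corr_grid <- function(a, b) {
  shared <- intersect(colnames(a), colnames(b))
  if (length(shared) < 3) stop("need at least 3 shared samples")
  a <- a[, shared, drop = FALSE]
  b <- b[, shared, drop = FALSE]
  r <- suppressWarnings(cor(t(a), t(b), use = "pairwise.complete.obs"))
  n <- tcrossprod(!is.na(a) * 1, !is.na(b) * 1)
  list(r = r, n = n)
}

#' All pairwise correlations between two expression matrices
#'
#' Computes the full rows(a) x rows(b) grid of Pearson correlations over the
#' shared samples (pairwise-complete), with t-transform p-values and,
#' optionally, Benjamini-Hochberg q-values over the whole family.
#'
#' @param mat_a,mat_b probes-by-samples matrices (e.g. miRNA and mRNA).
#' @param family_fdr compute BH q-values over all pairs?
#' @return data.frame with columns id_a, id_b, n, r, t, p (and q).
#' @export
correlate_all <- function(mat_a, mat_b, family_fdr = TRUE) {
  g <- .corr_grid(mat_a, mat_b)
  out <- data.frame(
    id_a = rep(rownames(mat_a), times = nrow(mat_b)),
    id_b = rep(rownames(mat_b), each = nrow(mat_a)),
    n = as.vector(g$n),
    r = as.vector(g$r),
    stringsAsFactors = FALSE)
  out$t <- out$r * sqrt(out$n - 2) / sqrt(pmax(1 - out$r^2, 0))
  out$p <- ifelse(is.na(out$r), NA_real_, pearson_pvalue(out$r, out$n))
  if (family_fdr) {
    out$q <- NA_real_
    ok <- !is.na(out$p)
    out$q[ok] <- bh_fdr(out$p[ok])
  }
  out
}

#' Correlate every probe with every phenotypic trait
#'
#' @param mat probes-by-samples expression matrix.
#' @param phenotypes traits-by-samples numeric matrix (one row per trait).
#' @param p_threshold cutoff used for the per-probe summary.
#' @return list with `results` (one row per probe x trait: id, trait, n, r,
#'   p) and `summary` (probes significant for at least one trait at
#'   `p_threshold`; both correlation signs retained).
#' @export
correlate_with_phenotypes <- function(mat, phenotypes, p_threshold = 0.05) {
  res <- correlate_all(mat, phenotypes, family_fdr = FALSE)
  colnames(res)[colnames(res) == "id_b"] <- "trait"
  colnames(res)[colnames(res) == "id_a"] <- "probe_id"
  sig <- res[!is.na(res$p) & res$p < p_threshold, , drop = FALSE]
  list(results = res,
       summary = list(
         significant_probes = unique(sig$probe_id),
         n_significant_pairs = nrow(sig),
         p_threshold = p_threshold))
}

#' Relative expression from qPCR Ct values
#'
#' Delta-Ct normalisation against the arithmetic mean of two reference-gene
#' Ct values (equivalently, the geometric mean of their linear-scale
#' levels): delta_ct = ct_target - mean(ct_ref_5S, ct_ref_U6) and
#' rel_expr = 2^(-delta_ct).
#'
#' @param ct_target,ct_ref_5S,ct_ref_U6 cycle-threshold vectors.
#' @return data.frame with delta_ct and rel_expr.
#' @export
qpcr_relative <- function(ct_target, ct_ref_5S, ct_ref_U6) {
  delta <- ct_target - (ct_ref_5S + ct_ref_U6) / 2
  data.frame(delta_ct = delta, rel_expr = 2^(-delta))
}

#' Concordance between qPCR and array measurements of a miRNA
#'
#' Correlates linear-scale qPCR relative expression (2^-deltaCt) with the
#' array's log2 signal across matched samples.
#'
#' @param qpcr data.frame with `sample_id` and either `rel_expr` or the Ct
#'   columns `ct_target`, `ct_ref_5S`, `ct_ref_U6`.
#' @param chip_signal named numeric vector of array log2 signals
#'   (names = sample ids).
#' @return data.frame row with n, r and p.
#' @export
qpcr_concordance <- function(qpcr, chip_signal) {
  if (is.null(qpcr$rel_expr)) {
    qpcr <- cbind(qpcr, qpcr_relative(qpcr$ct_target, qpcr$ct_ref_5S,
                                      qpcr$ct_ref_U6))
  }
  shared <- intersect(qpcr$sample_id, names(chip_signal))
  if (length(shared) < 3) stop("need at least 3 matched samples")
  x <- qpcr$rel_expr[match(shared, qpcr$sample_id)]
  y <- chip_signal[shared]
  pr <- pearson_r(x, y)
  data.frame(n = pr$n_used, r = pr$r,
             p = if (pr$defined) pearson_pvalue(pr$r, pr$n_used) else NA_real_)
}
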