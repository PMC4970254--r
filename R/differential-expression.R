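#' Per-probe fixed-effect ANOVA between breeds
#'
#' Fits a one-way fixed-effect model per probe (group = breed) and returns
#' the F statistic F = MS_between / MS_within with df (g-1, n-g) and its
#' upper-tail p-value. With exactly two groups F equals the square of the
#' pooled two-sample t statistic. Rows with missing values use complete
#' samples only and the per-probe n is recorded. An optional additive
#' covariate (e.g. sex) adjusts the group comparison; least-squares means
#' then equal the adjusted means at the covariate average, and reduce to the
#' plain group means in the balanced one-factor default.
#'
#' @param mat probes-by-samples log2 expression matrix.
#' @param samples sample table with `sample_id` and `breed` (and the
#'   covariate column if requested).
#' @param covariate optional name of an additive covariate column in
#'   `samples` (factor or numeric).
#' @return data.frame with one row per probe: lsmean per group,
#'   `delta_log2` (first group minus second, for two groups), `fold_change`,
#'   `direction`, `F_stat`, `p_value`, `q_value` (Benjamini-Hochberg over all
#'   probes) and `n_used`.
#' @export
anova_fixed_effect <- function(mat, samples, covariate = NULL) {
  samples <- samples[match(colnames(mat), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$breed)) stop("samples missing from sample table")
  grp <- factor(samples$breed)
  g <- nlevels(grp)
  if (g < 2) stop("need at least 2 groups")
  if (any(table(grp) < 2)) stop("each group needs at least 2 samples")

  two_groups <- g == 2 && is.null(covariate)
  res <- if (two_groups && !anyNA(mat)) {
    .anova_vectorized(mat, grp)
  } else {
    .anova_rowwise(mat, grp, if (is.null(covariate)) NULL else samples[[covariate]])
  }

  lev <- levels(grp)
  delta <- res$means[, 1] - res$means[, 2]
  fc <- fold_change(delta)
  out <- data.frame(probe_id = rownames(mat), res$means,
                    delta_log2 = delta,
                    fold_change = fc$fold_change,
                    direction = .direction_label(delta, lev),
                    F_stat = res$F_stat, p_value = res$p,
                    q_value = bh_fdr(res$p), n_used = res$n,
                    row.names = NULL, check.names = FALSE)
  colnames(out)[2:(1 + g)] <- paste0("lsmean_", lev)
  out
}

.direction_label <- function(delta, lev) {
  ifelse(delta > 0, paste0("up_in_", lev[1]),
         ifelse(delta < 0, paste0("up_in_", lev[2]), "none"))
}

# balanced complete-data path: closed-form one-way F for all probes at once
.anova_vectorized <- function(mat, grp) {
  idx <- split(seq_len(ncol(mat)), grp)
  n_g <- lengths(idx)
  n <- ncol(mat)
  means <- vapply(idx, function(i) rowMeans(mat[, i, drop = FALSE]),
                  numeric(nrow(mat)))
  means <- matrix(means, nrow = nrow(mat))
  grand <- rowMeans(mat)
  ssb <- as.vector((means - grand)^2 %*% n_g)
  ssw <- rowSums(mat^2) - as.vector(means^2 %*% n_g)
  ssw <- pmax(ssw, 0)
  df1 <- length(idx) - 1L
  df2 <- n - length(idx)
  F_stat <- (ssb / df1) / (ssw / df2)
  # degenerate rows: zero within-group variance
  F_stat[ssw == 0 & ssb == 0] <- 0
  F_stat[ssw == 0 & ssb > 0] <- Inf
  p <- pf(F_stat, df1, df2, lower.tail = FALSE)
  p[F_stat == 0] <- 1
  list(means = means, F_stat = F_stat, p = p, n = rep(n, nrow(mat)))
}

.anova_rowwise <- function(mat, grp, covar) {
  n_probe <- nrow(mat)
  g <- nlevels(grp)
  means <- matrix(NA_real_, n_probe, g)
  F_stat <- p <- rep(NA_real_, n_probe)
  n_used <- integer(n_probe)
  for (i in seq_len(n_probe)) {
    y <- mat[i, ]
    ok <- !is.na(y)
    n_used[i] <- sum(ok)
    gi <- droplevels(grp[ok])
    if (nlevels(gi) < 2 || any(table(gi) < 2)) {
      stop("probe ", rownames(mat)[i], ": a group has < 2 complete samples")
    }
    if (is.null(covar)) {
      fit_full <- stats::lm(y[ok] ~ gi)
      fit_red <- stats::lm(y[ok] ~ 1)
      means[i, ] <- tapply(y[ok], grp[ok], mean)[levels(grp)]
    } else {
      ci <- covar[ok]
      fit_full <- stats::lm(y[ok] ~ gi + ci)
      fit_red <- stats::lm(y[ok] ~ ci)
      # adjusted means at the covariate average
      cbar <- if (is.numeric(ci)) mean(ci) else NULL
      cf <- stats::coef(fit_full)
      base <- cf[1] + if (is.numeric(ci)) cf[length(cf)] * cbar else
        mean(c(0, cf[grep("^ci", names(cf))]))
      adj <- c(base, base + cf[grep("^gi", names(cf))])
      means[i, ] <- adj
    }
    a <- stats::anova(fit_red, fit_full)
    rss_red <- a$RSS[1]; rss_full <- a$RSS[2]
    df1 <- a$Df[2]; df2 <- fit_full$df.residual
    if (rss_full <= .Machine$double.eps * abs(rss_red + 1)) {
      if (rss_red - rss_full <= .Machine$double.eps) {
        F_stat[i] <- 0; p[i] <- 1
      } else {
        F_stat[i] <- Inf; p[i] <- 0
      }
    } else {
      F_stat[i] <- ((rss_red - rss_full) / df1) / (rss_full / df2)
      p[i] <- pf(F_stat[i], df1, df2, lower.tail = FALSE)
    }
  }
  list(means = means, F_stat = F_stat, p = p, n = n_used)
}

#' Benjamini-Hochberg step-up q-values
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' q(i) = min over j >= i of m * p(j) / j, returned in input order and capped
#' at 1. Delegates to [stats::p.adjust()] (method "BH").
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values in the input order.
#' @export
bh_fdr <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Fold change and direction from a log2 difference
#'
#' Fold change is reported on the linear scale as 2^|delta_log2| (always
#' >= 1) with the direction carried separately, so a halving and a doubling
#' both read as fold change 2 in opposite directions.
#'
#' @param delta_log2 numeric vector of log2 group differences
#'   (first group minus second).
#' @param groups character(2) of group labels used for direction names.
#' @return data.frame with `fold_change` and `direction`.
#' @export
fold_change <- function(delta_log2, groups = c("Duroc", "PiNN")) {
  stopifnot(all(is.finite(delta_log2)))
  data.frame(fold_change = 2^abs(delta_log2),
             direction = .direction_label(delta_log2, groups))
}

#' Select differentially expressed probes
#'
#' Applies the strict thresholds p < `p_threshold` and q < `q_threshold`
#' (both exclusive). Conventional defaults in this pipeline are FDR < 0.2
#' for miRNA probes and FDR < 0.05 for mRNA probes.
#'
#' @param de result of [anova_fixed_effect()].
#' @param p_threshold,q_threshold strict cutoffs.
#' @return `de` restricted to selected probes, with the thresholds attached
#'   as attributes `p_threshold` / `q_threshold`.
#' @export
select_de <- function(de, p_threshold = 0.05, q_threshold = 0.2) {
  sel <- de[de$p_value < p_threshold & de$q_value < q_threshold, , drop = FALSE]
  attr(sel, "p_threshold") <- p_threshold
  attr(sel, "q_threshold") <- q_threshold
  sel
}

#' Collapse selected probes to unique mature miRNA names per direction
#'
#' Several array probes can interrogate the same mature miRNA; reporting is
#' at the mature level. Matures whose probes disagree in direction are
#' flagged inconsistent (and counted in neither direction).
#'
#' @param selected data.frame with `probe_id` and `direction`
#'   (e.g. [select_de()] output).
#' @param annotations probe annotation with `probe_id`, `mature_name`.
#' @return list with `n_unique_mature`, `per_direction` (named counts),
#'   `inconsistent` (character vector of mature names) and `mature_table`.
#' @export
collapse_to_mature <- function(selected, annotations) {
  if (nrow(selected) == 0) {
    return(list(n_unique_mature = 0L, per_direction = integer(0),
                inconsistent = character(0),
                mature_table = data.frame(mature_name = character(0),
                                          direction = character(0))))
  }
  m <- match(selected$probe_id, annotations$probe_id)
  if (anyNA(m)) {
    stop("unannotated probe(s): ",
         paste(selected$probe_id[is.na(m)], collapse = ", "))
  }
  mature <- annotations$mature_name[m]
  tab <- unique(data.frame(mature_name = mature,
                           direction = selected$direction,
                           stringsAsFactors = FALSE))
  dup <- tab$mature_name[duplicated(tab$mature_name)]
  consistent <- tab[!tab$mature_name %in% dup, , drop = FALSE]
  list(n_unique_mature = length(unique(tab$mature_name)),
       per_direction = table(consistent$direction),
       inconsistent = unique(dup),
       mature_table = tab[order(tab$mature_name), , drop = FALSE])
}
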