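#' Exact Fisher test for a 2x2 table
#'
#' Enumerates the full hypergeometric distribution over tables with the
#' observed margins. The two-sided p-value uses the minimum-likelihood rule:
#' the sum of probabilities of all tables whose point probability does not
#' exceed that of the observed table.
#'
#' @param table 2x2 integer matrix, or a length-4 vector `c(a, b, c, d)`
#'   read row-wise
#' @param sided one of `"two"`, `"one-greater"` (top-left cell at least as
#'   large as observed), `"one-less"`
#' @return p-value
#' @export
fisher_exact_2x2 <- function(table, sided = c("two", "one-greater", "one-less")) {
  sided <- match.arg(sided)
  if (is.matrix(table)) {
    if (!all(dim(table) == c(2L, 2L))) stop("table must be 2x2", call. = FALSE)
    a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  } else {
    if (length(table) != 4L) stop("table must have 4 counts", call. = FALSE)
    a <- table[1]; b <- table[2]; c_ <- table[3]; d <- table[4]
  }
  cnt <- c(a, b, c_, d)
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != round(cnt)))
    stop("counts must be nonnegative integers", call. = FALSE)
  if (sum(cnt) == 0) stop("table has no observations", call. = FALSE)
  m <- a + c_        # column 1 margin
  n2 <- b + d        # column 2 margin
  k <- a + b         # row 1 margin
  lo <- max(0, k - n2); hi <- min(k, m)
  x <- lo:hi
  probs <- stats::dhyper(x, m, n2, k)
  pobs <- stats::dhyper(a, m, n2, k)
  p <- switch(sided,
    "two"         = sum(probs[probs <= pobs * (1 + 1e-7)]),
    "one-greater" = sum(probs[x >= a]),
    "one-less"    = sum(probs[x <= a]))
  min(1, p)
}

# Exact distribution of the positive-rank sum W+ for arbitrary rank values
# (handles average ranks from ties). Ranks are doubled to integers; returns
# counts over 2*W+ = 0 .. 2*sum(ranks), one count per sign assignment.
signrank_counts <- function(ranks) {
  dr <- as.integer(round(2 * ranks))
  total <- sum(dr)
  counts <- numeric(total + 1L)
  counts[1L] <- 1
  for (v in dr) {
    shifted <- c(numeric(v), counts[seq_len(total + 1L - v)])
    counts <- counts + shifted
  }
  counts
}

#' Wilcoxon signed-rank test for paired data
#'
#' Exact null distribution (enumeration over sign assignments, with average
#' ranks under ties) for up to `exact_max` nonzero differences; normal
#' approximation with tie correction and continuity correction above that.
#'
#' @param x numeric vector of differences, or first members of pairs
#' @param y optional second members; differences are `x - y`
#' @param sided `"two"`, `"greater"` (positive shift) or `"less"`
#' @param zero_policy `"discard"` drops zero differences (classic Wilcoxon);
#'   `"pratt"` ranks them with the rest and then drops their ranks
#' @param exact_max largest n for which the exact distribution is used
#' @return list with `statistic` (W+, the positive-rank sum), `p.value`,
#'   `n` (differences used) and `method`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL,
                                 sided = c("two", "greater", "less"),
                                 zero_policy = c("discard", "pratt"),
                                 exact_max = 25L) {
  sided <- match.arg(sided)
  zero_policy <- match.arg(zero_policy)
  d <- if (is.null(y)) as.numeric(x) else as.numeric(x) - as.numeric(y)
  if (anyNA(d)) stop("NA differences are not allowed", call. = FALSE)
  if (zero_policy == "discard") {
    d <- d[d != 0]
    r_all <- rank(abs(d))
    r_nz <- r_all
    sign_nz <- sign(d)
  } else {
    r_all <- rank(abs(d))
    nz <- d != 0
    r_nz <- r_all[nz]
    sign_nz <- sign(d[nz])
  }
  n <- length(r_nz)
  if (n == 0L)
    return(list(statistic = 0, p.value = 1, n = 0L, method = "degenerate"))
  w <- sum(r_nz[sign_nz > 0])
  if (n <= exact_max) {
    counts <- signrank_counts(r_nz)
    tot <- sum(counts)
    vals <- seq_along(counts) - 1L         # 2 * W+
    w2 <- round(2 * w)
    p_ge <- sum(counts[vals >= w2]) / tot
    p_le <- sum(counts[vals <= w2]) / tot
    method <- "exact"
  } else {
    mu <- sum(r_nz) / 2
    sigma <- sqrt(sum(r_nz^2) / 4)
    p_ge <- stats::pnorm((w - mu - 0.5) / sigma, lower.tail = FALSE)
    p_le <- stats::pnorm((w - mu + 0.5) / sigma)
    method <- "normal-approximation"
  }
  p <- switch(sided,
    "greater" = p_ge,
    "less"    = p_le,
    "two"     = min(1, 2 * min(p_ge, p_le)))
  list(statistic = w, p.value = p, n = n, method = method)
}

#' Pearson chi-squared test for an r x c contingency table
#'
#' @param table integer matrix of counts
#' @param correct apply the Yates continuity correction (2x2 only)
#' @return list with `statistic`, `df`, `p.value`, `expected`
#' @export
chi_squared_contingency <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (anyNA(table) || any(table < 0))
    stop("counts must be nonnegative", call. = FALSE)
  rs <- rowSums(table); cs <- colSums(table); N <- sum(table)
  if (any(rs == 0) || any(cs == 0))
    stop("table has a zero margin", call. = FALSE)
  expected <- outer(rs, cs) / N
  if (correct && all(dim(table) == 2L)) {
    stat <- sum((abs(table - expected) - 0.5)^2 / expected)
  } else {
    stat <- sum((table - expected)^2 / expected)
  }
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  list(statistic = stat, df = df,
       p.value = stats::pchisq(stat, df, lower.tail = FALSE),
       expected = expected)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up procedure with monotonicity enforcement; stable under
#' input order (the result is returned in the input order).
#' @param p numeric vector of raw p-values in `[0, 1]`
#' @return adjusted p-values, same length and order as `p`
#' @export
benjamini_hochberg <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  n <- length(p)
  o <- order(p, decreasing = TRUE)
  ro <- order(o)
  pmin(1, cummin(n / (n:1) * p[o]))[ro]
}

#' Structural-variant allele frequency
#'
#' AF is the number of breakpoint-supporting reads divided by the mean of
#' the whole-read coverage at the two partner loci, clipped to `[0, 1]`.
#'
#' @param supporting_reads reads containing the breakpoint
#' @param coverage_locus1,coverage_locus2 whole-read coverage at each locus
#' @return allele frequency in `[0, 1]` (vectorized)
#' @export
sv_allele_frequency <- function(supporting_reads, coverage_locus1,
                                coverage_locus2) {
  if (any(supporting_reads < 0 | coverage_locus1 < 0 | coverage_locus2 < 0,
          na.rm = TRUE))
    stop("read counts must be nonnegative", call. = FALSE)
  denom <- (coverage_locus1 + coverage_locus2) / 2
  af <- ifelse(denom > 0, supporting_reads / denom, NA_real_)
  pmin(1, pmax(0, af))
}

#' Immunohistochemistry H-score
#'
#' `3 x %strong + 2 x %moderate + 1 x %weak`, range 0-300.
#' @param pct_strong,pct_moderate,pct_weak percentages of cells staining at
#'   each intensity; each `>= 0` and their sum `<= 100`
#' @return H-score (vectorized)
#' @export
ihc_h_score <- function(pct_strong, pct_moderate, pct_weak) {
  if (any(c(pct_strong, pct_moderate, pct_weak) < 0))
    stop("percentages must be nonnegative", call. = FALSE)
  if (any(pct_strong + pct_moderate + pct_weak > 100 + 1e-9))
    stop("percentages must sum to at most 100", call. = FALSE)
  3 * pct_strong + 2 * pct_moderate + 1 * pct_weak
}

# residual sum of squares per response column for a fixed design matrix
rss_matrix <- function(X, Y) {
  fit <- stats::lm.fit(X, Y)
  res <- as.matrix(fit$residuals)
  colSums(res^2)
}

#' Per-protein two-way ANOVA on an intensity matrix
#'
#' Fixed-effects two-factor ANOVA with interaction, fitted per protein
#' (row). Sums of squares are computed by model comparison (type II), which
#' coincides with the classical balanced decomposition when the design is
#' balanced; unbalanced designs are accepted with a warning. Raw p-values
#' for each factor and the interaction are Benjamini-Hochberg adjusted
#' across proteins.
#'
#' @param matrix numeric proteins x samples matrix of (log) intensities;
#'   missing values are refused
#' @param genotype factor/character per sample, two levels (e.g. WT / ALT)
#' @param label factor/character per sample, two levels (e.g. OPP+ / OPP-)
#' @return data frame with one row per protein: raw and adjusted p-values
#'   for genotype, label and interaction, plus `effect`, the difference of
#'   cell means (ALT, label2) - (WT, label2) where `label2` is the second
#'   factor level (by convention the OPP+ / signal-carrying condition)
#' @export
two_way_anova_per_feature <- function(matrix, genotype, label) {
  matrix <- as.matrix(matrix)
  if (anyNA(matrix))
    stop("intensity matrix contains missing values; imputation is refused",
         call. = FALSE)
  genotype <- factor(genotype); label <- factor(label)
  if (ncol(matrix) != length(genotype) || ncol(matrix) != length(label))
    stop("factor length must match the number of samples", call. = FALSE)
  if (nlevels(genotype) != 2L || nlevels(label) != 2L)
    stop("each factor must have exactly two levels", call. = FALSE)
  tab <- table(genotype, label)
  if (any(tab < 2L))
    stop("need >= 2 replicates per factor cell", call. = FALSE)
  if (length(unique(as.vector(tab))) > 1L)
    warning("unbalanced design: using type-II sums of squares")
  Y <- t(matrix)
  n <- nrow(Y)
  X_full <- stats::model.matrix(~ genotype * label)
  X_add  <- stats::model.matrix(~ genotype + label)
  X_g    <- stats::model.matrix(~ genotype)
  X_l    <- stats::model.matrix(~ label)
  rss_full <- rss_matrix(X_full, Y)
  rss_add  <- rss_matrix(X_add, Y)
  rss_g    <- rss_matrix(X_g, Y)
  rss_l    <- rss_matrix(X_l, Y)
  df_e <- n - ncol(X_full)
  mse <- rss_full / df_e
  f_p <- function(ss) {
    f <- ss / mse
    p <- stats::pf(f, 1, df_e, lower.tail = FALSE)
    # zero-SS convention: no signal and no residual variance -> p = 1
    degen <- ss <= 1e-12 & mse <= 1e-12
    p[degen] <- 1
    p[!degen & mse <= 1e-12] <- 0
    p
  }
  p_gen <- f_p(pmax(rss_l - rss_add, 0))
  p_lab <- f_p(pmax(rss_g - rss_add, 0))
  p_int <- f_p(pmax(rss_add - rss_full, 0))
  g2 <- levels(genotype)[2]; l2 <- levels(label)[2]
  alt_sig <- genotype == g2 & label == l2
  wt_sig  <- genotype != g2 & label == l2
  effect <- rowMeans(matrix[, alt_sig, drop = FALSE]) -
    rowMeans(matrix[, wt_sig, drop = FALSE])
  data.frame(
    protein = if (!is.null(rownames(matrix))) rownames(matrix)
              else paste0("protein_", seq_len(nrow(matrix))),
    p_genotype = p_gen, p_label = p_lab, p_interaction = p_int,
    padj_genotype = benjamini_hochberg(p_gen),
    padj_label = benjamini_hochberg(p_lab),
    padj_interaction = benjamini_hochberg(p_int),
    effect = effect,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Nascent-proteome shift analysis
#'
#' Selects proteins whose FDR-adjusted genotype p-value from the per-protein
#' two-way ANOVA falls below `alpha`, splits them by effect sign (difference
#' of the (ALT, OPP+) and (WT, OPP+) cell means), and tests the association
#' between tumor-suppressor annotation and downregulation with a two-sided
#' Fisher exact test.
#'
#' @param matrix proteins x samples intensity matrix
#' @param genotype,label per-sample factors, see [two_way_anova_per_feature()]
#' @param annotation optional per-protein annotation, values in
#'   `c("oncoprotein", "TSP", "none")`; `NULL` skips the association test
#' @param alpha adjusted-p cutoff for calling a protein shifted
#' @return list with `up`, `down` (protein ids), `anova` (full table),
#'   `association_p` (Fisher p or `NA` when skipped) and the 2x2
#'   `association_table`
#' @export
proteome_shift_analysis <- function(matrix, genotype, label,
                                    annotation = NULL, alpha = 0.01) {
  res <- two_way_anova_per_feature(matrix, genotype, label)
  sig <- res$padj_genotype < alpha
  up <- res$protein[sig & res$effect > 0]
  down <- res$protein[sig & res$effect < 0]
  association_p <- NA_real_
  association_table <- NULL
  if (is.null(annotation)) {
    message("no protein annotation supplied; association test skipped")
  } else if (length(up) + length(down) == 0L) {
    message("no proteins pass alpha = ", alpha, "; association test skipped")
  } else {
    ann <- annotation[c(down, up)]
    is_tsp <- ann == "TSP"
    is_down <- c(rep(TRUE, length(down)), rep(FALSE, length(up)))
    association_table <- matrix(
      c(sum(is_tsp & is_down), sum(is_tsp & !is_down),
        sum(!is_tsp & is_down), sum(!is_tsp & !is_down)),
      nrow = 2, byrow = TRUE,
      dimnames = list(c("TSP", "non-TSP"), c("down", "up")))
    association_p <- fisher_exact_2x2(association_table, sided = "two")
  }
  list(up = up, down = down, anova = res,
       association_p = association_p, association_table = association_table)
}
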