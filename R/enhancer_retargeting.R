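#' Enumerate TAD-resident gene pairs
#'
#' Any two genes whose promoters (TSS positions) lie within the same TAD
#' form a candidate pair; genes outside every TAD are excluded.
#'
#' @param genes gene annotation (`id`, `chrom`, `tss`)
#' @param tads TAD interval data frame (non-overlapping per chromosome)
#' @return data frame `gene_a`, `gene_b`, `tad_id` of unordered pairs
#' @export
enumerate_tad_gene_pairs <- function(genes, tads) {
  iv_validate(tads, "tads")
  empty <- data.frame(gene_a = character(), gene_b = character(),
                      tad_id = character(), stringsAsFactors = FALSE)
  if (!nrow(genes) || !nrow(tads)) return(empty)
  tad_idx <- iv_locate(genes$chrom, genes$tss, tads)
  tad_id <- ifelse(is.na(tad_idx), NA_character_,
                   paste0(tads$chrom[tad_idx], ":", tads$start[tad_idx],
                          "-", tads$end[tad_idx]))
  keep <- !is.na(tad_idx)
  res <- list()
  for (tid in unique(tad_id[keep])) {
    ids <- sort(genes$id[keep & tad_id == tid & !is.na(tad_id)])
    if (length(ids) < 2L) next
    cmb <- utils::combn(ids, 2L)
    res[[length(res) + 1L]] <- data.frame(
      gene_a = cmb[1, ], gene_b = cmb[2, ], tad_id = tid,
      stringsAsFactors = FALSE)
  }
  if (!length(res)) return(empty)
  out <- do.call(rbind, res)
  out[order(out$tad_id, out$gene_a, out$gene_b), , drop = FALSE]
}

#' Spearman rank correlation
#'
#' Average-rank tie handling; Pearson correlation of the rank vectors.
#'
#' @param x,y numeric vectors of equal length (at least 3)
#' @return correlation in `[-1, 1]`; `NA` when either vector is constant
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values are refused", call. = FALSE)
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) return(NA_real_)
  stats::cor(rx, ry)
}

#' Central-limit rank-aggregation p-values
#'
#' Each item carries one rank per list (`1` = strongest in that list's
#' direction, average ranks on ties). With mean rank `Rbar` over `m` lists
#' of size `n`, the z-score is
#' `z = (Rbar - (n + 1) / 2) / sqrt((n^2 - 1) / (12 m))` and the one-sided
#' p-value is `pnorm(z)`: small p means consistently strong.
#'
#' @param ranks numeric matrix, items x lists; every item must carry a rank
#'   in every list
#' @return data frame `item`, `mean_rank`, `z`, `p`
#' @export
rank_aggregation_pvalue <- function(ranks) {
  ranks <- as.matrix(ranks)
  n <- nrow(ranks); m <- ncol(ranks)
  if (n < 2L || m < 1L)
    stop("need at least 2 items and 1 list", call. = FALSE)
  if (anyNA(ranks))
    stop("every item must be ranked in every list", call. = FALSE)
  rbar <- rowMeans(ranks)
  z <- (rbar - (n + 1) / 2) / sqrt((n^2 - 1) / (12 * m))
  data.frame(item = if (!is.null(rownames(ranks))) rownames(ranks)
             else paste0("item_", seq_len(n)),
             mean_rank = rbar, z = z, p = stats::pnorm(z),
             stringsAsFactors = FALSE, row.names = NULL)
}

# rank a score vector so that rank 1 is strongest in the stated direction
ranks_from_scores <- function(scores, direction = c("desc", "asc")) {
  direction <- match.arg(direction)
  if (direction == "desc") rank(-scores) else rank(scores)
}

#' Flag gene pairs overlapping hypermutated loci
#'
#' A pair is flagged when either gene's promoter window (TSS +/-
#' `promoter_bp`) or gene body overlaps any locus.
#'
#' @param pairs data frame with `gene_a`, `gene_b`
#' @param genes gene annotation (`id`, `chrom`, `tss`, `start`, `end`)
#' @param loci interval data frame of hypermutated loci (e.g. significant
#'   [segment_scan()] segments or a user BED)
#' @param promoter_bp promoter half-width
#' @return `pairs` with a logical `hypermutated` column
#' @export
annotate_hypermutated_pairs <- function(pairs, genes, loci,
                                        promoter_bp = 2000) {
  iv_validate(loci, "loci")
  g <- genes[match(unique(c(pairs$gene_a, pairs$gene_b)), genes$id), ,
             drop = FALSE]
  if (anyNA(g$id)) stop("pair gene missing from annotation", call. = FALSE)
  span <- intervals(g$chrom,
                    pmin(g$start, pmax(0, g$tss - 1 - promoter_bp)),
                    pmax(g$end, g$tss - 1 + promoter_bp + 1))
  hit <- rep(FALSE, nrow(span))
  if (nrow(loci)) {
    h <- iv_overlap_query(span, loci)
    hit[unique(h$query)] <- TRUE
  }
  names(hit) <- g$id
  pairs$hypermutated <- hit[pairs$gene_a] | hit[pairs$gene_b]
  pairs
}

#' Rank enhancer-retargeting candidate gene pairs
#'
#' Builds, over all TAD-resident pairs, three ranked lists -- mean
#' expression of the higher-expressed member (descending), mean expression
#' of the lower-expressed member (descending), and the Spearman correlation
#' between the two (most negative first by default, matching
#' retargeting-style anticorrelation) -- and aggregates them with
#' [rank_aggregation_pvalue()]. Genes absent from the expression matrix or
#' with zero variance are dropped (expressed genes only).
#'
#' @param pairs output of [enumerate_tad_gene_pairs()]
#' @param expression numeric matrix, genes x cell lines (already
#'   normalized); missing values are refused
#' @param genes optional gene annotation, required for hypermutation
#'   annotation
#' @param hypermutated_loci optional interval set; when given, pairs are
#'   flagged and a filtered table of hypermutated pairs is attached
#' @param correlation_rank `"negative"` ranks the most negative correlation
#'   first, `"positive"` the most positive, `"absolute"` the largest
#'   magnitude
#' @param promoter_bp promoter half-width for hypermutation annotation
#' @return `er_candidates` data frame sorted by aggregate p, with columns
#'   `gene_a` (higher-expressed member), `gene_b`, `tad_id`, `mean_a`,
#'   `mean_b`, `rho`, ranks, `z`, `p` and (optionally) `hypermutated`;
#'   attribute `hypermutated_only` holds the filtered table
#' @export
rank_er_candidates <- function(pairs, expression, genes = NULL,
                               hypermutated_loci = NULL,
                               correlation_rank = c("negative", "positive",
                                                    "absolute"),
                               promoter_bp = 2000) {
  correlation_rank <- match.arg(correlation_rank)
  expression <- as.matrix(expression)
  if (anyNA(expression))
    stop("expression matrix contains missing values; imputation is refused",
         call. = FALSE)
  if (ncol(expression) < 3L)
    stop("need at least 3 cell lines for correlation", call. = FALSE)
  vars <- apply(expression, 1, stats::var)
  expressed <- rownames(expression)[vars > 0]
  keep <- pairs$gene_a %in% expressed & pairs$gene_b %in% expressed
  pairs <- pairs[keep, , drop = FALSE]
  if (!nrow(pairs))
    stop("no scorable pairs (genes absent or constant)", call. = FALSE)
  mu <- rowMeans(expression)
  # canonical orientation: gene_a is the higher-expressed member
  swap <- mu[pairs$gene_a] < mu[pairs$gene_b]
  tmp <- pairs$gene_a[swap]
  pairs$gene_a[swap] <- pairs$gene_b[swap]
  pairs$gene_b[swap] <- tmp
  mean_a <- mu[pairs$gene_a]; mean_b <- mu[pairs$gene_b]
  rho <- vapply(seq_len(nrow(pairs)), function(i)
    spearman_rho(expression[pairs$gene_a[i], ], expression[pairs$gene_b[i], ]),
    numeric(1))
  rho_scores <- switch(correlation_rank,
                       negative = rho, positive = -rho, absolute = -abs(rho))
  ranks <- cbind(a = ranks_from_scores(mean_a, "desc"),
                 b = ranks_from_scores(mean_b, "desc"),
                 rho = ranks_from_scores(rho_scores, "asc"))
  agg <- if (nrow(pairs) == 1L) {
    # a single pair carries no ranking information: p = 0.5 by convention
    data.frame(item = "pair_1", mean_rank = 1, z = 0, p = 0.5)
  } else rank_aggregation_pvalue(ranks)
  out <- data.frame(gene_a = pairs$gene_a, gene_b = pairs$gene_b,
                    tad_id = pairs$tad_id,
                    mean_a = unname(mean_a), mean_b = unname(mean_b),
                    rho = rho,
                    rank_a = ranks[, "a"], rank_b = ranks[, "b"],
                    rank_rho = ranks[, "rho"],
                    z = agg$z, p = agg$p,
                    stringsAsFactors = FALSE)
  if (!is.null(hypermutated_loci)) {
    if (is.null(genes))
      stop("gene annotation required to annotate hypermutated pairs",
           call. = FALSE)
    out <- annotate_hypermutated_pairs(out, genes, hypermutated_loci,
                                       promoter_bp)
  }
  out <- out[order(out$p, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  if (!is.null(hypermutated_loci))
    attr(out, "hypermutated_only") <- out[out$hypermutated, , drop = FALSE]
  class(out) <- c("er_candidates", class(out))
  out
}
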