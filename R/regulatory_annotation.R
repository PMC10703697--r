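#' Stitch enhancer peaks into candidate (super-)enhancer regions
#'
#' ROSE-style stitching: peaks whose gap is strictly below `stitch_distance`
#' are merged into one region whose signal is the sum of constituent peak
#' signals. Peaks lying entirely within `tss_exclusion` bp of a TSS are
#' removed before stitching (promoter-proximal signal is excluded from
#' enhancer ranking); set `tss_exclusion = 0` or `genes = NULL` to disable.
#'
#' @param peaks H3K27ac peak intervals; an optional `score` column carries
#'   the aggregate ChIP signal (peak width is used when absent)
#' @param stitch_distance gaps strictly smaller than this merge (bp)
#' @param tss_exclusion half-width of the TSS exclusion zone (bp)
#' @param genes gene annotation with `chrom`, `tss` (1-based); only needed
#'   when `tss_exclusion > 0`
#' @return interval data frame with `signal` (summed) and `n_peaks`
#' @export
stitch_enhancers <- function(peaks, stitch_distance = 12500,
                             tss_exclusion = 2500, genes = NULL) {
  iv_validate(peaks, "peaks")
  if (!"score" %in% names(peaks))
    peaks$score <- peaks$end - peaks$start
  if (tss_exclusion > 0 && !is.null(genes) && nrow(genes)) {
    excl <- intervals(genes$chrom,
                      pmax(0, genes$tss - 1 - tss_exclusion),
                      genes$tss - 1 + tss_exclusion + 1)
    hits <- iv_overlap_query(peaks, excl)
    inside <- unique(hits$query[
      peaks$start[hits$query] >= excl$start[hits$subject] &
      peaks$end[hits$query] <= excl$end[hits$subject]])
    if (length(inside)) peaks <- peaks[-inside, , drop = FALSE]
  }
  # gap < stitch_distance merges, i.e. max joined gap is stitch_distance - 1
  out <- iv_merge(peaks, max_gap = stitch_distance - 1, sum_score = TRUE)
  names(out)[names(out) == "score"] <- "signal"
  names(out)[names(out) == "n"] <- "n_peaks"
  out
}

#' Call super-enhancers from stitched regions (rank-signal elbow)
#'
#' Regions are sorted by ascending signal; rank and signal are min-max
#' rescaled to `[0, 1]` and the discrete tangent is estimated by consecutive
#' secants. The cutoff is the signal at the upper end of the first secant
#' whose slope exceeds 1; every region with signal at or above the cutoff is
#' flagged super. On a perfectly linear curve no secant exceeds slope 1 and
#' no region is flagged.
#'
#' @param stitched output of [stitch_enhancers()] (needs a `signal` column)
#' @return a `superenhancer_set`: the input with `rank` (1 = strongest),
#'   `is_super`, plus attributes `cutoff` and `curve` (the rescaled
#'   rank-signal table)
#' @export
call_superenhancers <- function(stitched) {
  if (!"signal" %in% names(stitched))
    stop("stitched regions need a 'signal' column", call. = FALSE)
  n <- nrow(stitched)
  if (n < 3L)
    stop("need at least 3 stitched regions to place an elbow", call. = FALSE)
  o <- order(stitched$signal)
  s <- stitched$signal[o]
  rng <- s[n] - s[1]
  x <- (seq_len(n) - 1) / (n - 1)
  y <- if (rng > 0) (s - s[1]) / rng else rep(0, n)
  slope <- diff(y) / diff(x)
  k <- which(slope > 1)
  cutoff <- if (length(k)) s[min(k) + 1L] else Inf
  out <- stitched
  out$rank <- rank(-stitched$signal, ties.method = "first")
  out$is_super <- stitched$signal >= cutoff
  attr(out, "cutoff") <- cutoff
  attr(out, "curve") <- data.frame(rank_scaled = x, signal_scaled = y,
                                   signal = s)
  class(out) <- c("superenhancer_set", class(out))
  out
}

#' Partition two histone-mark peak sets into exclusive and shared regions
#'
#' @param k27ac,k4me3 interval data frames
#' @return named list of three disjoint interval sets: `K27ac_only`
#'   (enhancer without promoter mark), `K4me3_only` (promoter outside
#'   enhancers) and `intersection` (promoters embedded in enhancer regions);
#'   their union equals the union of the inputs
#' @export
partition_mark_regions <- function(k27ac, k4me3) {
  list(K27ac_only = iv_subtract(k27ac, k4me3),
       K4me3_only = iv_subtract(k4me3, k27ac),
       intersection = iv_intersect(k27ac, k4me3))
}

#' Base-pair fractions of a feature set per compartment label
#'
#' @param feature interval data frame (e.g. super-enhancers)
#' @param compartments interval data frame with a `label` column (A/B)
#' @return data frame with one row per label: covered `bp` and `fraction`
#'   of labelled feature bases; attribute `uncovered_bp` counts feature
#'   bases outside any compartment
#' @export
compartment_fractions <- function(feature, compartments) {
  if (!"label" %in% names(compartments))
    stop("compartments need a 'label' column", call. = FALSE)
  labs <- sort(unique(compartments$label))
  bp <- vapply(labs, function(l)
    iv_coverage_bp(iv_intersect(feature,
                                compartments[compartments$label == l, ])),
    numeric(1))
  total <- iv_coverage_bp(feature)
  covered <- sum(bp)
  out <- data.frame(label = labs, bp = bp,
                    fraction = if (covered > 0) bp / covered else
                      rep(NA_real_, length(bp)),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "uncovered_bp") <- total - covered
  out
}

#' Signed, strand-aware distance to the nearest TSS
#'
#' Negative values are upstream of the TSS relative to the gene's strand;
#' positive values downstream. Ties on absolute distance resolve to the
#' first gene in `(chrom, tss)` order.
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions
#' @param genes gene annotation with `id`, `chrom`, `tss`, `strand`
#' @param value `"distance"` returns the signed bp distance, `"gene"` the id
#'   of the nearest gene
#' @return numeric (or character) vector; `NA` where the chromosome has no
#'   annotated gene
#' @export
nearest_tss_distance <- function(chrom, pos, genes,
                                 value = c("distance", "gene")) {
  value <- match.arg(value)
  chrom <- rep_len(chrom, length(pos))
  nd <- rep(NA_real_, length(pos))
  ng <- rep(NA_character_, length(pos))
  if (!nrow(genes)) return(if (value == "distance") nd else ng)
  g <- genes[order(genes$chrom, genes$tss), , drop = FALSE]
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    gi <- which(g$chrom == ch)
    if (!length(gi)) next
    tss <- g$tss[gi]
    k <- findInterval(pos[idx], tss)
    lo <- pmax(k, 1L); hi <- pmin(k + 1L, length(tss))
    d_lo <- abs(pos[idx] - tss[lo]); d_hi <- abs(pos[idx] - tss[hi])
    pick <- ifelse(d_lo <= d_hi, lo, hi)
    gene_row <- gi[pick]
    raw <- pos[idx] - g$tss[gene_row]
    nd[idx] <- ifelse(g$strand[gene_row] == "-", -raw, raw)
    ng[idx] <- g$id[gene_row]
  }
  if (value == "distance") nd else ng
}
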