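# Shared core for anchored mutation-density profiles.
#
# dist_fun(chrom, pos) must return the signed bp distance of each mutation
# to its nearest anchor (NA = no anchor on that chromosome). Each sample's
# in-window counts are binned and either normalized to a proportion vector
# (load differences removed, so FL and DHL shapes are comparable) or scaled
# to mutations per Mb per anchor.
anchored_profile <- function(cohort, dist_fun, window, bin,
                             mode = c("proportion", "per_mb"),
                             anchor = "anchor", n_anchors = NA_integer_) {
  mode <- match.arg(mode)
  if (window <= 0 || bin <= 0 || window %% bin != 0)
    stop("window must be a positive multiple of bin", call. = FALSE)
  edges <- seq(-window, window, by = bin)
  mids <- (edges[-1] + edges[-length(edges)]) / 2
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  stages <- vapply(cohort, function(s) s$stage, character(1))
  skipped <- character(0)
  mats <- list(FL = NULL, DHL = NULL)
  for (i in seq_along(cohort)) {
    s <- cohort[[i]]
    v <- s$variants
    d <- if (nrow(v)) dist_fun(v$chrom, v$pos) else numeric(0)
    d <- d[!is.na(d) & d >= -window & d <= window]
    if (!length(d)) {
      warning("sample ", s$sample_id, " has no in-window mutations; skipped")
      skipped <- c(skipped, s$sample_id)
      next
    }
    # right-open bins, except the last bin which includes +window
    k <- pmin(findInterval(d, edges), length(edges) - 1L)
    counts <- tabulate(k, nbins = length(edges) - 1L)
    vec <- switch(mode,
      proportion = counts / sum(counts),
      per_mb = counts / (max(n_anchors, 1L) * bin / 1e6))
    mats[[s$stage]] <- rbind(mats[[s$stage]],
                             stats::setNames(vec, NULL))
    rownames(mats[[s$stage]])[nrow(mats[[s$stage]])] <- s$sample_id
  }
  means <- lapply(mats, function(m)
    if (is.null(m)) rep(NA_real_, length(mids)) else colMeans(m))
  structure(list(anchor = anchor, edges = edges, mid = mids,
                 per_sample = mats, mean = means, mode = mode,
                 skipped = skipped),
            class = "density_profile")
}

#' @export
print.density_profile <- function(x, ...) {
  cat("Density profile around", x$anchor, "(", x$mode, "mode,",
      length(x$mid), "bins )\n")
  for (st in names(x$mean))
    if (!all(is.na(x$mean[[st]])))
      cat(" ", st, ": peak bin at", x$mid[which.max(x$mean[[st]])], "bp\n")
  invisible(x)
}

#' Mutation-density profile around transcription start sites
#'
#' Per sample, every mutation within `window` bp of its nearest TSS is
#' binned by signed, strand-aware distance (upstream negative); each
#' sample's vector is normalized to a proportion and the per-stage profile
#' is the mean over samples.
#'
#' @param cohort list of sample mutation sets
#' @param genes gene annotation (`id`, `chrom`, `tss`, `strand`)
#' @param window half-width of the profile (bp)
#' @param bin bin width (bp); must divide `window`
#' @param mode `"proportion"` (default) or `"per_mb"`
#' @return a `density_profile`
#' @export
tss_density_profile <- function(cohort, genes, window = 5000, bin = 100,
                                mode = "proportion") {
  anchored_profile(cohort,
                   function(chrom, pos) nearest_tss_distance(chrom, pos, genes),
                   window, bin, mode, anchor = "TSS",
                   n_anchors = nrow(genes))
}

#' Mutation-density profile around arbitrary anchor intervals
#'
#' Anchors at interval midpoints (no strand); otherwise as
#' [tss_density_profile()]. Run it per histone mark or per
#' [partition_mark_regions()] class.
#'
#' @param cohort list of sample mutation sets
#' @param anchor_set interval data frame
#' @param window,bin,mode see [tss_density_profile()]
#' @param anchor_name label stored in the profile
#' @return a `density_profile`
#' @export
feature_density_profile <- function(cohort, anchor_set, window = 5000,
                                    bin = 100, mode = "proportion",
                                    anchor_name = "feature") {
  iv_validate(anchor_set, "anchor_set")
  if (!nrow(anchor_set)) stop("anchor set is empty", call. = FALSE)
  mid_df <- data.frame(chrom = anchor_set$chrom,
                       mid = floor((anchor_set$start + anchor_set$end) / 2))
  dist_fun <- function(chrom, pos) {
    out <- rep(NA_real_, length(pos))
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      m <- sort(mid_df$mid[mid_df$chrom == ch])
      if (!length(m)) next
      p0 <- pos[idx] - 1
      k <- findInterval(p0, m)
      lo <- pmax(k, 1L); hi <- pmin(k + 1L, length(m))
      d_lo <- abs(p0 - m[lo]); d_hi <- abs(p0 - m[hi])
      out[idx] <- ifelse(d_lo <= d_hi, p0 - m[lo], p0 - m[hi])
    }
    out
  }
  anchored_profile(cohort, dist_fun, window, bin, mode,
                   anchor = anchor_name, n_anchors = nrow(anchor_set))
}

#' Intermutation distances for a rainfall plot
#'
#' @param sample a sample mutation set
#' @return data frame `chrom`, `pos`, `imd` sorted by position; the first
#'   mutation of each chromosome (undefined IMD) is omitted
#' @export
rainfall <- function(sample) {
  v <- sample$variants
  out <- data.frame(chrom = character(), pos = numeric(), imd = numeric())
  if (!nrow(v)) return(out)
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  res <- lapply(split(v$pos, v$chrom), function(p) {
    if (length(p) < 2L) return(NULL)
    data.frame(pos = p[-1], imd = diff(p))
  })
  res <- res[!vapply(res, is.null, TRUE)]
  if (!length(res)) return(out)
  out <- do.call(rbind, Map(function(ch, df)
    data.frame(chrom = ch, pos = df$pos, imd = df$imd,
               stringsAsFactors = FALSE), names(res), res))
  rownames(out) <- NULL
  out[order(out$chrom, out$pos), , drop = FALSE]
}

#' Detect kataegis clusters
#'
#' Maximal runs of at least `min_cluster` mutations whose consecutive
#' intermutation distances are all at most `max_imd`.
#'
#' @param sample a sample mutation set
#' @param min_cluster minimum number of mutations per cluster
#' @param max_imd maximum intermutation distance within a cluster (bp)
#' @return data frame `chrom`, `start_pos`, `end_pos` (1-based, inclusive),
#'   `n_mutations`
#' @export
detect_kataegis <- function(sample, min_cluster = 6L, max_imd = 1000) {
  v <- sample$variants
  out <- data.frame(chrom = character(), start_pos = numeric(),
                    end_pos = numeric(), n_mutations = integer())
  if (!nrow(v)) return(out)
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  res <- list()
  for (ch in unique(v$chrom)) {
    p <- v$pos[v$chrom == ch]
    if (length(p) < min_cluster) next
    close <- diff(p) <= max_imd
    r <- rle(close)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths >= min_cluster - 1L)) {
      i0 <- starts[k]; i1 <- ends[k] + 1L   # run of gaps -> mutations
      res[[length(res) + 1L]] <- data.frame(
        chrom = ch, start_pos = p[i0], end_pos = p[i1],
        n_mutations = i1 - i0 + 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(out)
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out[order(out$chrom, out$start_pos), , drop = FALSE]
}

# one-sided binomial upper tail: P(X >= x | n, p0)
binom_tail_p <- function(x, n, p0) {
  stats::pbinom(x - 1, n, p0, lower.tail = FALSE)
}

#' Fixed-width differential mutation segment scan
#'
#' Tiles the genome into `segment_size` bp segments, counts FL and DHL
#' mutations per segment, and for every segment with at least `min_total`
#' mutations tests whether the DHL count exceeds the genome-wide DHL
#' proportion (one-sided binomial by default, per-segment Fisher as an
#' alternative). P-values are Benjamini-Hochberg adjusted.
#'
#' When DHL variants carry an `acquired` flag (longitudinal cohorts) and
#' `use_acquired = TRUE`, only transformation-acquired DHL mutations are
#' counted, mirroring a comparison of acquired versus pre-existing burden.
#'
#' @param cohort list of sample mutation sets (both stages required)
#' @param chromosomes data frame `name`, `length` (bp)
#' @param segment_size segment width in bp
#' @param min_total minimum pooled FL+DHL count for a segment to be tested
#' @param alpha BH significance level
#' @param method `"binomial"` or `"fisher"`
#' @param use_acquired restrict DHL counts to acquired mutations when the
#'   flag column is present
#' @param p0 optional override of the genome-wide DHL proportion
#' @param superenhancers,enhancers optional interval sets used to annotate
#'   significant segments
#' @return a `segment_scan_result` data frame of tested segments with
#'   counts, `p`, `padj`, `significant` and overlap flags; attributes
#'   `p0`, `totals` and `n_segments_genome`
#' @export
segment_scan <- function(cohort, chromosomes, segment_size = 3000,
                         min_total = 5L, alpha = 0.05,
                         method = c("binomial", "fisher"),
                         use_acquired = TRUE, p0 = NULL,
                         superenhancers = NULL, enhancers = NULL) {
  method <- match.arg(method)
  stages <- vapply(cohort, function(s) s$stage, character(1))
  if (!all(c("FL", "DHL") %in% stages))
    stop("cohort must contain both FL and DHL samples", call. = FALSE)
  get_pos <- function(s) {
    v <- s$variants
    if (s$stage == "DHL" && use_acquired && "acquired" %in% names(v))
      v <- v[v$acquired, , drop = FALSE]
    v[, c("chrom", "pos"), drop = FALSE]
  }
  fl <- do.call(rbind, lapply(cohort[stages == "FL"], get_pos))
  dhl <- do.call(rbind, lapply(cohort[stages == "DHL"], get_pos))
  count_seg <- function(df, ch, nseg) {
    p <- df$pos[df$chrom == ch]
    tabulate(pmin(floor((p - 1) / segment_size) + 1L, nseg), nbins = nseg)
  }
  rows <- list()
  n_segments_genome <- 0L
  for (i in seq_len(nrow(chromosomes))) {
    ch <- chromosomes$name[i]
    nseg <- ceiling(chromosomes$length[i] / segment_size)
    n_segments_genome <- n_segments_genome + nseg
    cf <- count_seg(fl, ch, nseg)
    cd <- count_seg(dhl, ch, nseg)
    keep <- which(cf + cd >= min_total)
    if (length(keep))
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ch, start = (keep - 1) * segment_size,
        end = pmin(keep * segment_size, chromosomes$length[i]),
        fl = cf[keep], dhl = cd[keep], stringsAsFactors = FALSE)
  }
  tot_fl <- nrow(fl); tot_dhl <- nrow(dhl)
  if (is.null(p0)) {
    if (tot_fl + tot_dhl == 0)
      stop("cohort has no mutations", call. = FALSE)
    p0 <- tot_dhl / (tot_fl + tot_dhl)
  }
  if (!length(rows)) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      fl = integer(), dhl = integer(), p = numeric(),
                      padj = numeric(), significant = logical(),
                      se_overlap = logical(), enhancer_overlap = logical())
  } else {
    out <- do.call(rbind, rows)
    out$p <- if (method == "binomial") {
      binom_tail_p(out$dhl, out$fl + out$dhl, p0)
    } else {
      vapply(seq_len(nrow(out)), function(i)
        fisher_exact_2x2(c(out$dhl[i], tot_dhl - out$dhl[i],
                           out$fl[i], tot_fl - out$fl[i]),
                         sided = "one-greater"), numeric(1))
    }
    out$padj <- benjamini_hochberg(out$p)
    out$significant <- out$padj <= alpha
    seg_iv <- intervals(out$chrom, out$start, out$end)
    flag_overlap <- function(set) {
      if (is.null(set) || !nrow(set)) return(rep(NA, nrow(out)))
      nrow_hits <- iv_overlap_query(seg_iv, set)
      seq_len(nrow(out)) %in% nrow_hits$query
    }
    out$se_overlap <- flag_overlap(superenhancers)
    out$enhancer_overlap <- flag_overlap(enhancers)
    rownames(out) <- NULL
  }
  attr(out, "p0") <- p0
  attr(out, "totals") <- c(FL = tot_fl, DHL = tot_dhl)
  attr(out, "n_segments_genome") <- n_segments_genome
  attr(out, "segment_size") <- segment_size
  class(out) <- c("segment_scan_result", class(out))
  out
}

#' Per-peak mutation overlap percentages by stage
#'
#' For each peak and stage, the percentage of that stage's cohort mutations
#' falling inside the peak, followed by a paired two-sided Wilcoxon
#' signed-rank test over peaks (DHL vs FL percentage; zero differences are
#' discarded, so identical stage sets give p = 1).
#'
#' @param cohort list of sample mutation sets
#' @param peaks interval data frame (peaks kept as individual rows)
#' @param genes optional gene annotation used to label top peaks with their
#'   nearest gene
#' @param top_k number of most-mutated peaks reported
#' @return list with `table` (per-peak counts and percentages), `p.value`,
#'   and `top` (the `top_k` most mutated peaks)
#' @export
per_peak_overlap_comparison <- function(cohort, peaks, genes = NULL,
                                        top_k = 15L) {
  iv_validate(peaks, "peaks")
  stages <- vapply(cohort, function(s) s$stage, character(1))
  pos <- function(st) do.call(rbind, lapply(cohort[stages == st], function(s)
    s$variants[, c("chrom", "pos"), drop = FALSE]))
  fl <- pos("FL"); dhl <- pos("DHL")
  count_in_peaks <- function(df) {
    if (is.null(df) || !nrow(df)) return(integer(nrow(peaks)))
    pts <- intervals(df$chrom, df$pos - 1, df$pos)
    hits <- iv_overlap_query(peaks, pts)
    tabulate(hits$query, nbins = nrow(peaks))
  }
  cf <- count_in_peaks(fl); cd <- count_in_peaks(dhl)
  tf <- if (is.null(fl)) 0L else nrow(fl)
  td <- if (is.null(dhl)) 0L else nrow(dhl)
  tab <- data.frame(chrom = peaks$chrom, start = peaks$start,
                    end = peaks$end, fl = cf, dhl = cd,
                    fl_pct = if (tf) 100 * cf / tf else NA_real_,
                    dhl_pct = if (td) 100 * cd / td else NA_real_,
                    stringsAsFactors = FALSE)
  p <- wilcoxon_signed_rank(tab$dhl_pct, tab$fl_pct, sided = "two")$p.value
  top <- tab[order(-(tab$fl + tab$dhl)), , drop = FALSE]
  top <- utils::head(top, top_k)
  if (!is.null(genes) && nrow(genes) && nrow(top)) {
    mid <- floor((top$start + top$end) / 2) + 1
    top$nearest_gene <- nearest_tss_distance(top$chrom, mid, genes,
                                             value = "gene")
  }
  list(table = tab, p.value = p, top = top)
}

#' Mutation-density profile around TAD boundaries
#'
#' Only boundaries of top-level TADs are used (TADs contained in another TAD
#' are dropped). Each mutation is assigned to its nearest used boundary;
#' the signed distance is negative inside the TAD and positive outside.
#'
#' @param cohort list of sample mutation sets
#' @param tads TAD interval data frame
#' @param window,bin,mode see [tss_density_profile()]
#' @return a `density_profile`
#' @export
tad_boundary_profile <- function(cohort, tads, window = 100000, bin = 5000,
                                 mode = "proportion") {
  iv_validate(tads, "tads")
  if (!nrow(tads)) stop("no TADs supplied", call. = FALSE)
  # drop TADs fully contained in another TAD
  hits <- iv_overlap_query(tads, tads)
  hits <- hits[hits$query != hits$subject, , drop = FALSE]
  contained <- unique(hits$query[
    tads$start[hits$query] >= tads$start[hits$subject] &
    tads$end[hits$query] <= tads$end[hits$subject]])
  top <- if (length(contained)) tads[-contained, , drop = FALSE] else tads
  # boundary table: position plus the direction of the TAD interior
  b <- rbind(data.frame(chrom = top$chrom, at = top$start, inside = +1),
             data.frame(chrom = top$chrom, at = top$end, inside = -1))
  dist_fun <- function(chrom, pos) {
    out <- rep(NA_real_, length(pos))
    for (ch in unique(chrom)) {
      idx <- which(chrom == ch)
      bb <- b[b$chrom == ch, , drop = FALSE]
      if (!nrow(bb)) next
      bb <- bb[order(bb$at), , drop = FALSE]
      p0 <- pos[idx] - 1
      k <- findInterval(p0, bb$at)
      lo <- pmax(k, 1L); hi <- pmin(k + 1L, nrow(bb))
      d_lo <- abs(p0 - bb$at[lo]); d_hi <- abs(p0 - bb$at[hi])
      pick <- ifelse(d_lo <= d_hi, lo, hi)
      raw <- p0 - bb$at[pick]
      # inside = +1 means interior lies to the right of the boundary
      out[idx] <- ifelse(bb$inside[pick] > 0, -raw, raw)
    }
    out
  }
  anchored_profile(cohort, dist_fun, window, bin, mode,
                   anchor = "TAD boundary", n_anchors = nrow(b))
}

#' Per-sample compartment split of super-enhancer mutations
#'
#' Restricts each sample to mutations inside super-enhancer regions, splits
#' them by A/B compartment and tests A versus B fractions with a paired
#' two-sided Wilcoxon signed-rank test per stage.
#'
#' @param cohort list of sample mutation sets
#' @param superenhancers a `superenhancer_set` (only `is_super` rows are
#'   used) or a plain interval data frame
#' @param compartments interval data frame with `label` in `{A, B}`
#' @return list with `per_sample` (fractions per sample), `p` (named vector
#'   of per-stage Wilcoxon p-values) and `excluded` (samples without SE
#'   mutations)
#' @export
compartment_se_mutation_fractions <- function(cohort, superenhancers,
                                              compartments) {
  se <- superenhancers
  if ("is_super" %in% names(se)) se <- se[se$is_super, , drop = FALSE]
  iv_validate(se, "superenhancers")
  if (!"label" %in% names(compartments))
    stop("compartments need a 'label' column", call. = FALSE)
  rows <- list(); excluded <- character(0)
  for (s in cohort) {
    v <- s$variants
    inside <- if (nrow(v))
      points_in_intervals(v$chrom, v$pos, se) else logical(0)
    v <- v[inside, , drop = FALSE]
    if (!nrow(v)) {
      warning("sample ", s$sample_id, " has no SE mutations; excluded")
      excluded <- c(excluded, s$sample_id)
      next
    }
    comp <- iv_locate(v$chrom, v$pos, compartments)
    lab <- compartments$label[comp]
    nA <- sum(lab == "A", na.rm = TRUE); nB <- sum(lab == "B", na.rm = TRUE)
    rows[[length(rows) + 1L]] <- data.frame(
      sample = s$sample_id, stage = s$stage, n_se_mutations = nrow(v),
      frac_A = if (nA + nB > 0) nA / (nA + nB) else NA_real_,
      frac_B = if (nA + nB > 0) nB / (nA + nB) else NA_real_,
      n_unlabelled = sum(is.na(lab)), stringsAsFactors = FALSE)
  }
  per_sample <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), stage = character(),
               n_se_mutations = integer(), frac_A = numeric(),
               frac_B = numeric(), n_unlabelled = integer())
  p <- vapply(c(FL = "FL", DHL = "DHL"), function(st) {
    d <- per_sample[per_sample$stage == st & !is.na(per_sample$frac_A), ]
    if (!nrow(d)) return(NA_real_)
    wilcoxon_signed_rank(d$frac_A, d$frac_B, sided = "two")$p.value
  }, numeric(1))
  list(per_sample = per_sample, p = p, excluded = excluded)
}

#' Micro-indel class summary by stage
#'
#' Classifies variants as micro-insertions / microdeletions (ref/alt length
#' mismatch of at most `max_len` bp) and reports their fraction of all
#' mutations per stage, plus the fraction of each indel class falling in
#' promoter-within-enhancer (K27ac intersect K4me3) regions when supplied.
#'
#' @param cohort list of sample mutation sets
#' @param intersection optional interval set (e.g.
#'   `partition_mark_regions(...)$intersection`)
#' @param max_len maximum indel length still called "micro"
#' @return data frame, one row per stage
#' @export
indel_class_summary <- function(cohort, intersection = NULL, max_len = 20L) {
  stages <- vapply(cohort, function(s) s$stage, character(1))
  one_stage <- function(st) {
    v <- do.call(rbind, lapply(cohort[stages == st], function(s)
      s$variants[, c("chrom", "pos", "ref", "alt"), drop = FALSE]))
    if (is.null(v) || !nrow(v))
      return(data.frame(stage = st, n = 0L, micro_ins_frac = NA_real_,
                        micro_del_frac = NA_real_,
                        ins_in_intersection = NA_real_,
                        del_in_intersection = NA_real_))
    dl <- nchar(v$alt) - nchar(v$ref)
    ins <- dl > 0 & dl <= max_len
    del <- dl < 0 & -dl <= max_len
    in_frac <- function(sel) {
      if (is.null(intersection) || !sum(sel)) return(NA_real_)
      mean(points_in_intervals(v$chrom[sel], v$pos[sel], intersection))
    }
    data.frame(stage = st, n = nrow(v),
               micro_ins_frac = mean(ins), micro_del_frac = mean(del),
               ins_in_intersection = in_frac(ins),
               del_in_intersection = in_frac(del))
  }
  out <- rbind(one_stage("FL"), one_stage("DHL"))
  rownames(out) <- NULL
  out
}
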