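#' Genomic interval sets
#'
#' All interval sets in this package are plain data frames with columns
#' `chrom`, `start`, `end` using BED conventions: 0-based, half-open
#' `[start, end)`. Point positions (variant coordinates, TSSs) are 1-based,
#' so a point `p` overlaps `[start, end)` iff `start <= p - 1 < end`.
#'
#' @param chrom character vector of chromosome names
#' @param start,end 0-based half-open bounds, `start < end`
#' @param ... further columns (e.g. `score`, `label`), recycled as in
#'   [data.frame()]
#' @return a validated interval data frame
#' @export
intervals <- function(chrom = character(), start = numeric(),
                      end = numeric(), ...) {
  iv_validate(data.frame(chrom = as.character(chrom),
                         start = as.numeric(start),
                         end = as.numeric(end), ...,
                         stringsAsFactors = FALSE))
}

#' Validate an interval data frame
#'
#' @param x data frame with columns `chrom`, `start`, `end`
#' @param name label used in error messages
#' @return `x`, invisibly unchanged, or an error
#' @export
iv_validate <- function(x, name = "intervals") {
  if (!is.data.frame(x))
    stop(name, " must be a data frame", call. = FALSE)
  miss <- setdiff(c("chrom", "start", "end"), names(x))
  if (length(miss))
    stop(name, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(x)) {
    if (anyNA(x$start) || anyNA(x$end) || anyNA(x$chrom))
      stop(name, ": NA coordinates are not allowed", call. = FALSE)
    if (any(x$start < 0))
      stop(name, ": negative start (coordinates are 0-based)", call. = FALSE)
    if (any(x$end <= x$start))
      stop(name, ": need start < end (0-based half-open)", call. = FALSE)
  }
  x
}

#' Sort intervals by chromosome, start, end
#' @param x interval data frame
#' @return sorted copy of `x`
#' @export
iv_sort <- function(x) {
  if (!nrow(x)) return(x)
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Total base pairs covered by an interval set
#'
#' Overlapping intervals are merged first, so each base is counted once.
#' @param x interval data frame
#' @return numeric scalar, covered bases
#' @export
iv_coverage_bp <- function(x) {
  m <- iv_merge(x)
  if (!nrow(m)) return(0)
  sum(m$end - m$start)
}

#' Merge overlapping (and optionally nearby) intervals
#'
#' Intervals whose gap is `<= max_gap` are joined; the default 0 joins
#' overlapping and abutting intervals. Extra columns are dropped except an
#' optional `score`, which is summed over merged constituents when
#' `sum_score = TRUE`.
#'
#' @param x interval data frame
#' @param max_gap maximum gap (bp) joined across; `0` merges abutting runs
#' @param sum_score if `TRUE` and `x$score` exists, output carries the
#'   constituent sum in `score` and the constituent count in `n`
#' @return merged, sorted interval data frame
#' @export
iv_merge <- function(x, max_gap = 0, sum_score = FALSE) {
  iv_validate(x)
  keep_score <- sum_score && "score" %in% names(x)
  if (!nrow(x)) {
    out <- x[, c("chrom", "start", "end"), drop = FALSE]
    if (keep_score) { out$score <- numeric(0); out$n <- integer(0) }
    return(out)
  }
  x <- iv_sort(x)
  n <- nrow(x)
  # running maximum of end per chromosome defines merge groups
  run_end <- x$end
  new_chrom <- c(TRUE, x$chrom[-1] != x$chrom[-n])
  grp <- integer(n)
  grp[1] <- 1L
  cur_end <- x$end[1]
  for (i in seq_len(n)[-1]) {
    if (new_chrom[i] || x$start[i] > cur_end + max_gap) {
      grp[i] <- grp[i - 1L] + 1L
      cur_end <- x$end[i]
    } else {
      grp[i] <- grp[i - 1L]
      cur_end <- max(cur_end, x$end[i])
    }
  }
  out <- data.frame(
    chrom = tapply(x$chrom, grp, `[`, 1L),
    start = as.numeric(tapply(x$start, grp, min)),
    end   = as.numeric(tapply(x$end, grp, max)),
    stringsAsFactors = FALSE
  )
  if (keep_score) {
    out$score <- as.numeric(tapply(x$score, grp, sum))
    out$n <- as.integer(tapply(rep(1L, n), grp, sum))
  }
  rownames(out) <- NULL
  iv_sort(out)
}

#' Intersection of two interval sets
#'
#' Set semantics: both inputs are merged internally, the result is the
#' disjoint set of bases present in both.
#' @param x,y interval data frames
#' @return interval data frame of the common bases
#' @export
iv_intersect <- function(x, y) {
  xm <- iv_merge(x); ym <- iv_merge(y)
  if (!nrow(xm) || !nrow(ym))
    return(xm[0, c("chrom", "start", "end"), drop = FALSE])
  res <- list()
  for (ch in intersect(unique(xm$chrom), unique(ym$chrom))) {
    a <- xm[xm$chrom == ch, ]; b <- ym[ym$chrom == ch, ]
    i <- 1L; j <- 1L
    while (i <= nrow(a) && j <= nrow(b)) {
      s <- max(a$start[i], b$start[j]); e <- min(a$end[i], b$end[j])
      if (s < e)
        res[[length(res) + 1L]] <- data.frame(chrom = ch, start = s, end = e,
                                              stringsAsFactors = FALSE)
      if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
    }
  }
  if (!length(res)) return(xm[0, c("chrom", "start", "end"), drop = FALSE])
  iv_sort(do.call(rbind, res))
}

#' Subtract one interval set from another
#'
#' @param x,y interval data frames; returns bases of `x` not covered by `y`
#' @return interval data frame
#' @export
iv_subtract <- function(x, y) {
  xm <- iv_merge(x); ym <- iv_merge(y)
  if (!nrow(xm) || !nrow(ym)) return(xm)
  res <- list()
  for (ch in unique(xm$chrom)) {
    a <- xm[xm$chrom == ch, ]
    b <- ym[ym$chrom == ch, ]
    for (i in seq_len(nrow(a))) {
      s <- a$start[i]; e <- a$end[i]
      hits <- b[b$start < e & b$end > s, , drop = FALSE]
      cur <- s
      if (nrow(hits)) {
        hits <- hits[order(hits$start), , drop = FALSE]
        for (k in seq_len(nrow(hits))) {
          if (hits$start[k] > cur)
            res[[length(res) + 1L]] <- data.frame(
              chrom = ch, start = cur, end = hits$start[k],
              stringsAsFactors = FALSE)
          cur <- max(cur, hits$end[k])
        }
      }
      if (cur < e)
        res[[length(res) + 1L]] <- data.frame(chrom = ch, start = cur, end = e,
                                              stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(xm[0, , drop = FALSE])
  iv_sort(do.call(rbind, res))
}

#' All overlapping pairs between two interval sets
#'
#' @param query,subject interval data frames (not merged; row identities kept)
#' @return data frame with columns `query`, `subject` (row indices)
#' @export
iv_overlap_query <- function(query, subject) {
  iv_validate(query, "query"); iv_validate(subject, "subject")
  hits <- list()
  if (nrow(query) && nrow(subject)) {
    for (ch in intersect(unique(query$chrom), unique(subject$chrom))) {
      qi <- which(query$chrom == ch); si <- which(subject$chrom == ch)
      s <- subject[si, ]
      for (k in seq_along(qi)) {
        i <- qi[k]
        ov <- si[s$start < query$end[i] & s$end > query$start[i]]
        if (length(ov))
          hits[[length(hits) + 1L]] <- data.frame(query = i, subject = ov)
      }
    }
  }
  if (!length(hits)) return(data.frame(query = integer(), subject = integer()))
  out <- do.call(rbind, hits)
  out[order(out$query, out$subject), , drop = FALSE]
}

#' Test whether 1-based points fall inside an interval set
#'
#' @param chrom,pos vectors of chromosome names and 1-based positions
#' @param set interval data frame (merged internally)
#' @return logical vector
#' @export
points_in_intervals <- function(chrom, pos, set) {
  chrom <- rep_len(chrom, length(pos))
  m <- iv_merge(set)
  out <- logical(length(pos))
  if (!nrow(m) || !length(pos)) return(out)
  p0 <- pos - 1
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    s <- m[m$chrom == ch, ]
    if (!nrow(s)) next
    k <- findInterval(p0[idx], s$start)
    out[idx] <- k >= 1L & p0[idx] < s$end[pmax(k, 1L)]
  }
  out
}

#' Locate 1-based points within a disjoint interval set
#'
#' Intervals must be non-overlapping per chromosome (e.g. compartments,
#' TADs); returns the row index of the covering interval or `NA`.
#' @param chrom,pos vectors of chromosome names and 1-based positions
#' @param set disjoint interval data frame
#' @return integer vector of row indices into `set`, `NA` where uncovered
#' @export
iv_locate <- function(chrom, pos, set) {
  iv_validate(set)
  chrom <- rep_len(chrom, length(pos))
  out <- rep(NA_integer_, length(pos))
  if (!nrow(set) || !length(pos)) return(out)
  p0 <- pos - 1
  for (ch in unique(chrom)) {
    idx <- which(chrom == ch)
    si <- which(set$chrom == ch)
    if (!length(si)) next
    s <- set[si, ]
    o <- order(s$start)
    si <- si[o]; s <- s[o, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("iv_locate requires a disjoint interval set", call. = FALSE)
    k <- findInterval(p0[idx], s$start)
    hit <- k >= 1L & p0[idx] < s$end[pmax(k, 1L)]
    out[idx[hit]] <- si[k[hit]]
  }
  out
}
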