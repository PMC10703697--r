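# Independent brute-force oracles. Everything here is deliberately naive
# (per-base-pair sets, full enumerations) and must stay independent of the
# package's own implementations.

# covered 0-based bases of an interval set, per chromosome
oracle_bases <- function(x) {
  if (!nrow(x)) return(list())
  out <- list()
  for (i in seq_len(nrow(x))) {
    ch <- x$chrom[i]
    out[[ch]] <- union(out[[ch]], seq(x$start[i], x$end[i] - 1))
  }
  lapply(out, sort)
}

# rebuild intervals from a per-base set (for comparing against iv_* output)
bases_to_intervals <- function(bases) {
  rows <- list()
  for (ch in sort(names(bases))) {
    b <- sort(bases[[ch]])
    if (!length(b)) next
    brk <- c(0, which(diff(b) > 1), length(b))
    for (k in seq_len(length(brk) - 1)) {
      seg <- b[(brk[k] + 1):brk[k + 1]]
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = min(seg), end = max(seg) + 1,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric()))
  out <- do.call(rbind, rows)
  out[order(out$chrom, out$start), , drop = FALSE]
}

random_interval_set <- function(n, max_coord = 200, chroms = c("c1", "c2")) {
  start <- sample.int(max_coord, n, replace = TRUE) - 1
  width <- sample.int(20, n, replace = TRUE)
  data.frame(chrom = sample(chroms, n, replace = TRUE),
             start = start, end = start + width, stringsAsFactors = FALSE)
}

# all-pairs overlap oracle
oracle_overlaps <- function(q, s) {
  hits <- list()
  for (i in seq_len(nrow(q))) for (j in seq_len(nrow(s)))
    if (q$chrom[i] == s$chrom[j] &&
        q$start[i] < s$end[j] && s$start[j] < q$end[i])
      hits[[length(hits) + 1]] <- data.frame(query = i, subject = j)
  if (!length(hits)) return(data.frame(query = integer(), subject = integer()))
  out <- do.call(rbind, hits)
  out[order(out$query, out$subject), , drop = FALSE]
}

# full-enumeration Fisher oracle built from choose(), no dhyper
oracle_fisher_two_sided <- function(a, b, c_, d) {
  m <- a + c_; n2 <- b + d; k <- a + b; N <- m + n2
  xs <- max(0, k - n2):min(k, m)
  pr <- vapply(xs, function(x)
    choose(m, x) * choose(n2, k - x) / choose(N, k), numeric(1))
  pobs <- pr[xs == a]
  sum(pr[pr <= pobs * (1 + 1e-7)])
}

# exact Wilcoxon signed-rank oracle: enumerate all 2^n sign assignments
oracle_wilcoxon_greater <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(1)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(w_all >= w_obs - 1e-9)
}

# definitional BH oracle
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  sorted <- p[o] * n / seq_len(n)
  for (i in seq_len(n)) adj[i] <- min(1, min(sorted[i:n]))
  out <- numeric(n)
  out[o] <- adj
  out
}

# small default genome/cohort shared across tests (cached per session)
.tiny_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      genome <- build_toy_genome(seed = 11)
      cohort <- simulate_cohort(genome, cohort_config(seed = 12))
      cache <<- list(genome = genome, cohort = cohort)
    }
    cache
  }
})
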