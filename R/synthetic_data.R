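# Seeded generators for a toy genome, paired FL/DHL cohorts, expression and
# proteome matrices with planted effects. All randomness is drawn from a
# locally seeded RNG stream; the caller's RNG state is restored on exit, so
# identical seeds give byte-identical outputs regardless of context.

with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(list = ".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Build a fully annotated toy genome
#'
#' A deterministic stand-in for a reference genome plus its epigenomic
#' tracks: genes with TSS/strand and simple exon/UTR structure, H3K4me3
#' promoter peaks, H3K27ac enhancer clusters stitched around designated
#' "SE genes" (wide promoter peaks embedded in high-signal enhancer
#' clusters), H3K4me1 peaks, non-overlapping TADs and alternating A/B
#' compartments partitioning each chromosome.
#'
#' @param chromosomes named numeric vector of chromosome lengths in bp
#'   (each at least 1 Mb)
#' @param n_genes total genes, allocated to chromosomes by length
#' @param seed integer seed fixing all randomness
#' @param tad_size,tad_gap TAD tiling period and inter-TAD gap (bp)
#' @param compartment_size alternating A/B block size (bp)
#' @param se_gene_fraction fraction of genes designated SE genes
#' @param promoter_peak_bp H3K4me3 peak width at SE-gene promoters; this is
#'   the width of the K27ac-intersect-K4me3 aSHM footprint
#' @param k4me3_tss_fraction fraction of TSSs carrying an H3K4me3 peak
#' @param background_peaks_per_mb scattered low-signal H3K27ac peaks per Mb
#' @return a `genome_model` list: `chromosomes`, `genes`, `features`,
#'   `tracks` (`k27ac`, `k4me3`, `k4me1`, `tads`, `compartments`),
#'   `se_genes`
#' @export
build_toy_genome <- function(chromosomes = c(chr1 = 1e7),
                             n_genes = 60, seed = 1,
                             tad_size = 5e5, tad_gap = 2e4,
                             compartment_size = 1e6,
                             se_gene_fraction = 0.2,
                             promoter_peak_bp = 4000,
                             k4me3_tss_fraction = 0.7,
                             background_peaks_per_mb = 3) {
  if (!length(chromosomes)) stop("need at least one chromosome", call. = FALSE)
  if (any(chromosomes < 1e6))
    stop("chromosomes must be at least 1 Mb", call. = FALSE)
  if (is.null(names(chromosomes)))
    names(chromosomes) <- paste0("chr", seq_along(chromosomes))
  with_local_seed(seed, {
    chrom_df <- data.frame(name = names(chromosomes),
                           length = as.numeric(chromosomes),
                           stringsAsFactors = FALSE)
    margin <- 5e4
    # allocate genes by chromosome length
    alloc <- floor(n_genes * chromosomes / sum(chromosomes))
    rem <- n_genes - sum(alloc)
    if (rem > 0) alloc[seq_len(rem)] <- alloc[seq_len(rem)] + 1L
    genes <- list(); feats <- list()
    gid <- 0L
    for (ci in seq_len(nrow(chrom_df))) {
      ch <- chrom_df$name[ci]; L <- chrom_df$length[ci]
      ng <- alloc[ci]
      if (ng == 0L) next
      slot <- floor((L - 2 * margin) / ng)
      gene_max <- 30000
      if (slot < gene_max + 2e4)
        stop("chromosome ", ch, " too small to host ", ng, " genes",
             call. = FALSE)
      for (k in seq_len(ng)) {
        gid <- gid + 1L
        len <- round(stats::runif(1, 5000, gene_max))
        off <- round(stats::runif(1, 5000, slot - len - 5000))
        start <- margin + (k - 1) * slot + off
        end <- start + len
        strand <- sample(c("+", "-"), 1)
        tss <- if (strand == "+") start + 1 else end
        genes[[gid]] <- data.frame(
          id = sprintf("G%03d", gid), chrom = ch, tss = tss,
          strand = strand, start = start, end = end,
          stringsAsFactors = FALSE)
        # simple gene structure: 200 bp UTRs at the ends, two coding exons
        if (strand == "+") {
          f <- data.frame(feature = c("utr5", "coding_exon", "coding_exon",
                                      "utr3"),
                          start = c(start, start + 400,
                                    end - 1600, end - 200),
                          end = c(start + 200, start + 1400,
                                  end - 600, end))
        } else {
          f <- data.frame(feature = c("utr5", "coding_exon", "coding_exon",
                                      "utr3"),
                          start = c(end - 200, end - 1400,
                                    start + 600, start),
                          end = c(end, end - 400,
                                  start + 1600, start + 200))
          f[, c("start", "end")] <- t(apply(f[, c("start", "end")], 1,
                                            range))
        }
        f$gene_id <- sprintf("G%03d", gid); f$chrom <- ch
        feats[[gid]] <- f
      }
    }
    genes <- if (length(genes)) do.call(rbind, genes) else
      data.frame(id = character(), chrom = character(), tss = numeric(),
                 strand = character(), start = numeric(), end = numeric())
    features <- if (length(feats)) do.call(rbind, feats)[,
      c("gene_id", "feature", "chrom", "start", "end")] else
      data.frame(gene_id = character(), feature = character(),
                 chrom = character(), start = numeric(), end = numeric())
    rownames(features) <- NULL

    # SE genes: designated subset whose promoters sit inside H3K27ac clusters
    n_se <- if (nrow(genes)) max(0L, round(se_gene_fraction * nrow(genes)))
            else 0L
    se_genes <- if (n_se > 0) sort(sample(genes$id, n_se)) else character(0)
    genes$is_se <- genes$id %in% se_genes

    # TADs: regular non-overlapping tiling with small gaps
    tads <- do.call(rbind, lapply(seq_len(nrow(chrom_df)), function(ci) {
      L <- chrom_df$length[ci]
      n <- floor(L / tad_size)
      if (n < 1) return(NULL)
      i <- seq_len(n) - 1
      data.frame(chrom = chrom_df$name[ci],
                 start = i * tad_size + tad_gap / 2,
                 end = (i + 1) * tad_size - tad_gap / 2)
    }))
    # compartments: alternating A/B blocks partitioning each chromosome
    compartments <- do.call(rbind, lapply(seq_len(nrow(chrom_df)),
                                          function(ci) {
      L <- chrom_df$length[ci]
      starts <- seq(0, L - 1, by = compartment_size)
      data.frame(chrom = chrom_df$name[ci], start = starts,
                 end = pmin(starts + compartment_size, L),
                 label = rep(c("A", "B"), length.out = length(starts)))
    }))

    clip <- function(x, L) pmin(pmax(x, 0), L)
    k4me3 <- list(); k27ac <- list(); k4me1 <- list()
    if (nrow(genes)) {
      Lof <- stats::setNames(chrom_df$length, chrom_df$name)
      # H3K4me3 at SE-gene TSSs (wide) and a fraction of other TSSs
      others <- genes$id[!genes$is_se]
      k4_ids <- c(se_genes,
                  sample(others, round(k4me3_tss_fraction * length(others))))
      for (id in k4_ids) {
        g <- genes[genes$id == id, ]
        w <- if (g$is_se) promoter_peak_bp else round(stats::runif(1, 1000,
                                                                   2000))
        t0 <- g$tss - 1
        k4me3[[length(k4me3) + 1L]] <- data.frame(
          chrom = g$chrom, start = clip(t0 - w / 2, Lof[g$chrom]),
          end = clip(t0 + w / 2, Lof[g$chrom]),
          score = stats::runif(1, 5, 15))
      }
      # H3K27ac clusters around SE-gene promoters: one peak covering the
      # promoter plus flanking peaks within stitching distance
      for (id in se_genes) {
        g <- genes[genes$id == id, ]
        t0 <- g$tss - 1; L <- Lof[g$chrom]
        core <- data.frame(chrom = g$chrom,
                           start = clip(t0 - promoter_peak_bp / 2 - 500, L),
                           end = clip(t0 + promoter_peak_bp / 2 + 500, L),
                           score = stats::runif(1, 40, 80))
        nfl <- sample(2:4, 1)
        offs <- sample(c(-1, 1), nfl, replace = TRUE) *
          round(stats::runif(nfl, 4000, 12000))
        wfl <- round(stats::runif(nfl, 1000, 3000))
        flank <- data.frame(chrom = g$chrom,
                            start = clip(t0 + offs - wfl / 2, L),
                            end = clip(t0 + offs + wfl / 2, L),
                            score = stats::runif(nfl, 20, 50))
        k27ac[[length(k27ac) + 1L]] <- rbind(core, flank)
      }
    }
    # scattered low-signal enhancer peaks
    for (ci in seq_len(nrow(chrom_df))) {
      L <- chrom_df$length[ci]
      nbg <- max(1L, round(background_peaks_per_mb * L / 1e6))
      st <- round(stats::runif(nbg, margin, L - margin))
      w <- round(stats::runif(nbg, 500, 2000))
      k27ac[[length(k27ac) + 1L]] <- data.frame(
        chrom = chrom_df$name[ci], start = st, end = pmin(st + w, L),
        score = stats::runif(nbg, 1, 8))
      st1 <- round(stats::runif(nbg, margin, L - margin))
      w1 <- round(stats::runif(nbg, 500, 2000))
      k4me1[[length(k4me1) + 1L]] <- data.frame(
        chrom = chrom_df$name[ci], start = st1, end = pmin(st1 + w1, L),
        score = stats::runif(nbg, 1, 8))
    }
    # H3K4me1 flanks each SE cluster (primed enhancer mark)
    if (length(k27ac)) {
      kc <- do.call(rbind, k27ac)
      k4me1[[length(k4me1) + 1L]] <- data.frame(
        chrom = kc$chrom, start = pmax(0, kc$start - 1000),
        end = kc$end + 1000, score = kc$score / 2)
    }
    bind_track <- function(l) {
      if (!length(l)) return(data.frame(chrom = character(),
                                        start = numeric(), end = numeric(),
                                        score = numeric()))
      out <- iv_sort(do.call(rbind, l))
      rownames(out) <- NULL
      out
    }
    structure(list(chromosomes = chrom_df, genes = genes,
                   features = features,
                   tracks = list(k27ac = bind_track(k27ac),
                                 k4me3 = bind_track(k4me3),
                                 k4me1 = bind_track(k4me1),
                                 tads = iv_sort(tads),
                                 compartments = iv_sort(compartments)),
                   se_genes = se_genes, seed = seed),
              class = "genome_model")
  })
}

#' @export
print.genome_model <- function(x, ...) {
  cat("Toy genome:", nrow(x$chromosomes), "chromosome(s),",
      sum(x$chromosomes$length) / 1e6, "Mb,", nrow(x$genes), "genes (",
      length(x$se_genes), "SE genes )\n")
  invisible(x)
}

#' Cohort simulation configuration
#'
#' The stated world of the simulated paired cohort: per-sample mutation
#' rates are piecewise constant with a genome-wide background and elevated
#' aSHM footprints (H3K4me3-intersect-H3K27ac regions, which are
#' hypermutated in both stages); the DHL-acquired rate inside footprints is
#' additionally multiplied by `se_promoter_enrichment`. DHL samples carry
#' all mutations of the patient's preceding FL sample plus acquired ones.
#'
#' @param n_patients number of patients
#' @param samples_per_patient stage vector per patient, e.g. `c("FL","DHL")`
#'   or `c("FL","FL","DHL")`
#' @param background_rate background mutations per Mb per sample
#' @param hotspot_rate FL-stage mutation rate per Mb inside aSHM footprints
#' @param se_promoter_enrichment fold multiplier on the footprint rate for
#'   DHL-acquired mutations (>= 1)
#' @param kataegis list `n_clusters`, `cluster_size`, `max_imd` (bp)
#' @param kataegis_stages stages receiving planted clusters (default DHL
#'   only)
#' @param af_model per-stage mean/sd of the tumor allele fraction
#' @param gain_probability_dhl probability a DHL sample carries the planted
#'   copy-gain locus
#' @param read_model list `read_length`, `depth_mean`
#' @param violation_fraction fraction of variants per sample deliberately
#'   generated to violate one cascade filter each
#' @param indel_insertion_fraction,indel_deletion_fraction micro-indel mix
#' @param fl_increment_rate rate multiplier for mutations acquired between
#'   two FL samples of the same patient
#' @param patients_without_normal patient indices lacking nontumor DNA
#' @param seed integer seed
#' @return a `cohort_config` list
#' @export
cohort_config <- function(n_patients = 8,
                          samples_per_patient = c("FL", "DHL"),
                          background_rate = 10,
                          hotspot_rate = 300,
                          se_promoter_enrichment = 10,
                          kataegis = list(n_clusters = 2, cluster_size = 8,
                                          max_imd = 500),
                          kataegis_stages = "DHL",
                          af_model = list(FL = c(mean = 0.35, sd = 0.06),
                                          DHL = c(mean = 0.45, sd = 0.08)),
                          gain_probability_dhl = 0.75,
                          read_model = list(read_length = 150,
                                            depth_mean = 60),
                          violation_fraction = 0.10,
                          indel_insertion_fraction = 0.04,
                          indel_deletion_fraction = 0.06,
                          fl_increment_rate = 0.25,
                          patients_without_normal = integer(),
                          seed = 1) {
  stopifnot(n_patients >= 1, background_rate >= 0, hotspot_rate >= 0,
            se_promoter_enrichment >= 1,
            violation_fraction >= 0, violation_fraction < 1,
            gain_probability_dhl >= 0, gain_probability_dhl <= 1,
            all(samples_per_patient %in% c("FL", "DHL")),
            kataegis$max_imd > 0, kataegis$cluster_size >= 2)
  structure(as.list(environment()), class = "cohort_config")
}

# draw n 1-based positions uniformly from an interval set
sample_positions_in <- function(n, set) {
  if (n == 0L || !nrow(set)) return(data.frame(chrom = character(),
                                               pos = numeric()))
  w <- set$end - set$start
  idx <- sample.int(nrow(set), n, replace = TRUE, prob = w)
  pos <- set$start[idx] + floor(stats::runif(n) * w[idx]) + 1
  data.frame(chrom = set$chrom[idx], pos = pos, stringsAsFactors = FALSE)
}

# random SNV / micro-indel alleles
draw_alleles <- function(n, ins_frac, del_frac) {
  bases <- c("A", "C", "G", "T")
  type <- sample(c("snv", "ins", "del"), n, replace = TRUE,
                 prob = c(1 - ins_frac - del_frac, ins_frac, del_frac))
  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(seq_len(n), function(i) {
    if (type[i] == "snv") sample(setdiff(bases, ref[i]), 1)
    else if (type[i] == "ins")
      paste(c(ref[i], sample(bases, sample(1:6, 1), replace = TRUE)),
            collapse = "")
    else ref[i]
  }, character(1))
  ref <- vapply(seq_len(n), function(i) {
    if (type[i] == "del")
      paste(c(ref[i], sample(bases, sample(1:6, 1), replace = TRUE)),
            collapse = "")
    else ref[i]
  }, character(1))
  data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
}

# read-level evidence for one variant; `violate` is NA or the name of the
# single cascade filter this variant must fail first
gen_evidence <- function(stage, violate, config, has_normal) {
  rm_ <- config$read_model
  depth <- max(30L, stats::rpois(1, rm_$depth_mean))
  afm <- config$af_model[[stage]]
  af_t <- min(0.9, max(0.25, stats::rnorm(1, afm["mean"], afm["sd"])))
  t_alt <- min(depth, max(ceiling(0.25 * depth), round(af_t * depth)))
  if (!is.na(violate) && violate == "allele_fraction")
    t_alt <- max(5L, round(stats::runif(1, 0.10, 0.17) * depth))
  af <- t_alt / depth
  hq <- min(t_alt, max(min(5L, t_alt), stats::rbinom(1, t_alt, 0.92)))
  if (!is.na(violate) && violate == "hq_support") hq <- sample(0:4, 1)
  plus <- stats::rbinom(1, t_alt, 0.5)
  if (t_alt >= 5 && max(plus, t_alt - plus) / t_alt >= 0.95)
    plus <- floor(t_alt / 2)
  if (!is.na(violate) && violate == "strand_bias") plus <- t_alt
  ef <- stats::runif(t_alt, 0, 0.5)
  if (all(ef < 0.25)) ef[1] <- stats::runif(1, 0.3, 0.5)
  if (!is.na(violate) && violate == "edge_of_read")
    ef <- stats::runif(t_alt, 0, 0.24)
  post <- 10^stats::runif(1, -12, -6.5)
  if (!is.na(violate) && violate == "posterior")
    post <- 10^stats::runif(1, -5.5, -1)
  if (has_normal) {
    n_depth <- max(20L, stats::rpois(1, rm_$depth_mean))
    if (!is.na(violate) && violate == "normal_depth")
      n_depth <- sample(0:14, 1)
    n_alt <- min(1L, stats::rbinom(1, n_depth, 0.005))
    if (!is.na(violate) && violate == "normal_alt")
      n_alt <- 2L + stats::rpois(1, 1)
  } else {
    n_depth <- NA_real_; n_alt <- NA_real_
  }
  list(t_depth = depth, t_alt = t_alt, t_alt_hq = hq, alt_plus = plus,
       alt_minus = t_alt - plus, edge_fracs = ef, af = af,
       n_depth = n_depth, n_alt = n_alt, posterior_p = post)
}

# assemble a full variant table from positions, with planted violations
build_variant_table <- function(pos_df, stage, acquired, config, has_normal,
                                violation_filters) {
  n <- nrow(pos_df)
  if (n == 0L) {
    v <- data.frame(chrom = character(), pos = numeric(), ref = character(),
                    alt = character(), t_depth = numeric(),
                    t_alt = numeric(), t_alt_hq = numeric(),
                    alt_plus = numeric(), alt_minus = numeric(),
                    af = numeric(), n_depth = numeric(), n_alt = numeric(),
                    posterior_p = numeric(), acquired = logical(),
                    stringsAsFactors = FALSE)
    v$edge_fracs <- list()
    v$planted_violation <- character()
    return(v)
  }
  alle <- draw_alleles(n, config$indel_insertion_fraction,
                       config$indel_deletion_fraction)
  violate <- rep(NA_character_, n)
  nv <- floor(config$violation_fraction * n)
  if (nv > 0 && length(violation_filters)) {
    idx <- sample.int(n, nv)
    violate[idx] <- rep_len(violation_filters, nv)
  }
  ev <- lapply(seq_len(n), function(i)
    gen_evidence(stage, violate[i], config, has_normal))
  pull <- function(f) vapply(ev, `[[`, numeric(1), f)
  v <- data.frame(chrom = pos_df$chrom, pos = pos_df$pos,
                  ref = alle$ref, alt = alle$alt,
                  t_depth = pull("t_depth"), t_alt = pull("t_alt"),
                  t_alt_hq = pull("t_alt_hq"), alt_plus = pull("alt_plus"),
                  alt_minus = pull("alt_minus"),
                  af = pull("af"), n_depth = pull("n_depth"),
                  n_alt = pull("n_alt"), posterior_p = pull("posterior_p"),
                  acquired = acquired, stringsAsFactors = FALSE)
  v$edge_fracs <- lapply(ev, `[[`, "edge_fracs")
  v$planted_violation <- violate
  v <- v[order(v$chrom, v$pos), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Simulate a paired FL/DHL cohort on a toy genome
#'
#' Draws per-sample somatic mutations from the piecewise-constant rate model
#' of [cohort_config()], plants kataegis clusters, copy-gain calls, paired
#' structural-variant allele frequencies and deliberate filter violations,
#' and records all planted effects in a truth ledger for testing.
#'
#' @param genome a `genome_model` from [build_toy_genome()]
#' @param config a [cohort_config()]
#' @return an `ashm_cohort`: list with `samples` (sample mutation sets whose
#'   variant tables carry full evidence plus `acquired` and
#'   `planted_violation` columns), `cnv`, `sv`, `truth` and `chromosomes`
#' @export
simulate_cohort <- function(genome, config = cohort_config()) {
  stopifnot(inherits(genome, "genome_model"),
            inherits(config, "cohort_config"))
  footprints <- iv_intersect(genome$tracks$k4me3, genome$tracks$k27ac)
  if (config$se_promoter_enrichment > 1 && !nrow(footprints))
    stop("enrichment requested but genome has no K4me3-intersect-K27ac ",
         "footprints", call. = FALSE)
  chrom_df <- genome$chromosomes
  whole <- intervals(chrom_df$name, 0, chrom_df$length)
  background_set <- iv_subtract(whole, footprints)
  bp_fp <- iv_coverage_bp(footprints)
  bp_bg <- iv_coverage_bp(background_set)

  with_local_seed(config$seed, {
    samples <- list(); truth_kat <- list(); truth_vio <- list()
    cnv <- list(); sv <- list(); gain_truth <- list()

    # planted copy-gain locus: the TAD containing the first SE gene
    gain_locus <- NULL
    if (nrow(genome$tracks$tads)) {
      if (length(genome$se_genes)) {
        g <- genome$genes[genome$genes$id == genome$se_genes[1], ]
        ti <- iv_locate(g$chrom, g$tss, genome$tracks$tads)
      } else ti <- 1L
      if (is.na(ti)) ti <- 1L
      gain_locus <- genome$tracks$tads[ti, c("chrom", "start", "end")]
    }

    draw_mutations <- function(rate_bg, rate_fp) {
      nb <- stats::rpois(1, rate_bg * bp_bg / 1e6)
      nf <- stats::rpois(1, rate_fp * bp_fp / 1e6)
      rbind(sample_positions_in(nb, background_set),
            sample_positions_in(nf, footprints))
    }
    draw_kataegis <- function() {
      kat <- config$kataegis
      res <- list()
      for (k in seq_len(kat$n_clusters)) {
        ci <- sample.int(nrow(chrom_df), 1, prob = chrom_df$length)
        span_max <- (kat$cluster_size - 1) * kat$max_imd
        start <- round(stats::runif(1, 1e5,
                                    chrom_df$length[ci] - span_max - 1e5))
        gaps <- round(stats::runif(kat$cluster_size - 1, 10, kat$max_imd))
        res[[k]] <- data.frame(chrom = chrom_df$name[ci],
                               pos = start + c(0, cumsum(gaps)))
      }
      res
    }

    for (p in seq_len(config$n_patients)) {
      patient <- sprintf("P%d", p)
      has_normal <- !(p %in% config$patients_without_normal)
      vio_filters <- c("posterior", "hq_support", "strand_bias",
                       "allele_fraction", "edge_of_read",
                       if (has_normal) c("normal_alt", "normal_depth"))
      stages <- config$samples_per_patient
      n_fl_seen <- 0L
      carried <- NULL   # persisted positions (chrom/pos) from previous sample
      for (si in seq_along(stages)) {
        st <- stages[si]
        if (st == "FL") {
          n_fl_seen <- n_fl_seen + 1L
          sid <- if (sum(stages == "FL") > 1)
            sprintf("%s-FL%s", patient, LETTERS[n_fl_seen])
          else paste0(patient, "-FL")
          mult <- if (is.null(carried)) 1 else config$fl_increment_rate
          acq <- draw_mutations(config$background_rate * mult,
                                config$hotspot_rate * mult)
          if (st %in% config$kataegis_stages) {
            kat <- draw_kataegis()
            for (kk in kat)
              truth_kat[[length(truth_kat) + 1L]] <- data.frame(
                sample = sid, chrom = kk$chrom[1], start_pos = min(kk$pos),
                end_pos = max(kk$pos), n_mutations = nrow(kk))
            acq <- rbind(acq, do.call(rbind, kat))
          }
        } else {
          sid <- paste0(patient, "-DHL")
          acq <- draw_mutations(config$background_rate,
                                config$hotspot_rate *
                                  config$se_promoter_enrichment)
          if (st %in% config$kataegis_stages) {
            kat <- draw_kataegis()
            for (kk in kat)
              truth_kat[[length(truth_kat) + 1L]] <- data.frame(
                sample = sid, chrom = kk$chrom[1], start_pos = min(kk$pos),
                end_pos = max(kk$pos), n_mutations = nrow(kk))
            acq <- rbind(acq, do.call(rbind, kat))
          }
        }
        # acquired = new in this sample; persisted = inherited positions
        acq <- acq[!duplicated(paste(acq$chrom, acq$pos)), , drop = FALSE]
        if (!is.null(carried)) {
          key_new <- paste(acq$chrom, acq$pos)
          key_old <- paste(carried$chrom, carried$pos)
          acq <- acq[!key_new %in% key_old, , drop = FALSE]
        }
        v_acq <- build_variant_table(acq, st, TRUE, config, has_normal,
                                     vio_filters)
        v <- v_acq
        if (!is.null(carried)) {
          v_old <- build_variant_table(carried, st, FALSE, config,
                                       has_normal, vio_filters)
          v <- rbind(v_acq, v_old)
          v <- v[order(v$chrom, v$pos), , drop = FALSE]
          rownames(v) <- NULL
        }
        vio <- v[!is.na(v$planted_violation),
                 c("chrom", "pos", "planted_violation"), drop = FALSE]
        if (nrow(vio))
          truth_vio[[length(truth_vio) + 1L]] <- data.frame(
            sample = sid, vio, stringsAsFactors = FALSE)
        samples[[sid]] <- new_sample_mutation_set(patient, st, sid, v,
                                                  has_normal)
        carried <- v[, c("chrom", "pos"), drop = FALSE]

        # planted copy-gain calls: DHL only
        if (st == "DHL" && !is.null(gain_locus)) {
          has_gain <- stats::runif(1) < config$gain_probability_dhl
          gain_truth[[length(gain_truth) + 1L]] <- data.frame(
            patient = patient, sample = sid, gain = has_gain)
          if (has_gain)
            cnv[[length(cnv) + 1L]] <- data.frame(
              patient = patient, sample = sid, stage = st,
              chrom = gain_locus$chrom, start = gain_locus$start,
              end = gain_locus$end, call = "gain",
              stringsAsFactors = FALSE)
        }
      }
      # paired SV allele frequencies: a BCL2-like SV present in both stages
      # with rising AF, a MYC-like SV appearing only in DHL
      dm <- config$read_model$depth_mean
      af_fl <- min(0.6, max(0.02, stats::rnorm(1, 0.20, 0.05)))
      af_dhl <- min(0.95, af_fl + max(0.05, stats::rnorm(1, 0.25, 0.07)))
      for (sid in names(samples)[vapply(samples, function(s)
        s$patient == patient, TRUE)]) {
        s <- samples[[sid]]
        for (svname in c("BCL2", "MYC")) {
          af0 <- if (svname == "BCL2") {
            if (s$stage == "FL") af_fl else af_dhl
          } else {
            if (s$stage == "FL") 0 else
              min(0.9, max(0.05, stats::rnorm(1, 0.35, 0.10)))
          }
          c1 <- stats::rpois(1, dm); c2 <- stats::rpois(1, dm)
          supp <- round(af0 * (c1 + c2) / 2)
          sv[[length(sv) + 1L]] <- data.frame(
            patient = patient, sample = sid, stage = s$stage, sv = svname,
            supporting = supp, cov1 = c1, cov2 = c2,
            af = sv_allele_frequency(supp, c1, c2),
            stringsAsFactors = FALSE)
        }
      }
    }
    bindl <- function(l, proto) if (length(l)) {
      out <- do.call(rbind, l); rownames(out) <- NULL; out
    } else proto
    truth <- list(
      footprints = footprints,
      kataegis = bindl(truth_kat,
                       data.frame(sample = character(), chrom = character(),
                                  start_pos = numeric(), end_pos = numeric(),
                                  n_mutations = integer())),
      violations = bindl(truth_vio,
                         data.frame(sample = character(), chrom = character(),
                                    pos = numeric(),
                                    planted_violation = character())),
      gain = bindl(gain_truth, data.frame(patient = character(),
                                          sample = character(),
                                          gain = logical())),
      gain_locus = gain_locus,
      config = config)
    structure(list(samples = samples,
                   cnv = bindl(cnv, data.frame()),
                   sv = bindl(sv, data.frame()),
                   truth = truth,
                   chromosomes = chrom_df),
              class = "ashm_cohort")
  })
}

#' @export
print.ashm_cohort <- function(x, ...) {
  st <- vapply(x$samples, function(s) s$stage, character(1))
  nv <- vapply(x$samples, function(s) nrow(s$variants), integer(1))
  cat("Synthetic paired cohort:", length(x$samples), "samples (",
      sum(st == "FL"), "FL /", sum(st == "DHL"), "DHL ), median",
      stats::median(nv), "variants per sample\n")
  invisible(x)
}

#' Apply the somatic filter cascade to every sample of a cohort
#'
#' @param cohort an `ashm_cohort` (or any list of sample mutation sets)
#' @param config a [filter_config()]
#' @return the cohort with per-sample variants replaced by the kept set;
#'   per-sample ledgers are attached as `ledgers`
#' @export
filter_cohort <- function(cohort, config = filter_config()) {
  ledgers <- list()
  for (sid in names(cohort$samples)) {
    s <- cohort$samples[[sid]]
    led <- filter_somatic_variants(s$variants, config,
                                   has_matched_normal = s$has_matched_normal,
                                   sample_id = sid)
    ledgers[[sid]] <- led
    cohort$samples[[sid]] <- new_sample_mutation_set(
      s$patient, s$stage, sid, led$kept, s$has_matched_normal)
  }
  cohort$ledgers <- ledgers
  cohort
}

#' Simulate an expression matrix with a planted correlated gene pair
#'
#' Gene expression across cell lines is Gaussian per gene; the planted pair
#' is drawn from a bivariate normal whose Pearson parameter is chosen so the
#' population Spearman correlation equals `rho_target`, and both planted
#' genes receive the highest mean expression in the matrix (top quartile).
#'
#' @param genome a `genome_model`
#' @param n_cell_lines number of cell lines (columns)
#' @param planted_pair character vector of two gene ids sharing a TAD;
#'   `NULL` picks the first TAD containing two SE genes (falling back to any
#'   TAD with two genes)
#' @param rho_target target Spearman correlation in `[-1, 1]`
#' @param seed integer seed
#' @param base_mean,base_sd distribution of per-gene mean log-expression
#' @return list with `matrix` (genes x cell lines), `planted_pair`,
#'   `rho_target`
#' @export
simulate_expression_matrix <- function(genome, n_cell_lines = 11,
                                       planted_pair = NULL,
                                       rho_target = -0.9, seed = 1,
                                       base_mean = 5, base_sd = 1.5) {
  stopifnot(inherits(genome, "genome_model"),
            rho_target >= -1, rho_target <= 1, n_cell_lines >= 3)
  genes <- genome$genes
  if (is.null(planted_pair)) {
    tad_idx <- iv_locate(genes$chrom, genes$tss, genome$tracks$tads)
    for (prefer_se in c(TRUE, FALSE)) {
      pool <- if (prefer_se) genes$is_se else rep(TRUE, nrow(genes))
      tt <- table(tad_idx[pool & !is.na(tad_idx)])
      tt <- tt[tt >= 2]
      if (length(tt)) {
        tid <- as.integer(names(tt)[1])
        planted_pair <- sort(genes$id[pool & !is.na(tad_idx) &
                                        tad_idx == tid])[1:2]
        break
      }
    }
    if (is.null(planted_pair))
      stop("no TAD hosts two genes; cannot plant a pair", call. = FALSE)
  }
  if (!all(planted_pair %in% genes$id))
    stop("planted genes not found in genome", call. = FALSE)
  with_local_seed(seed, {
    n_g <- nrow(genes)
    mu <- stats::rnorm(n_g, base_mean, base_sd)
    names(mu) <- genes$id
    mu[planted_pair] <- max(mu) + c(0.5, 0.4)   # top of the expression range
    # Pearson parameter of the Gaussian copula matching the target Spearman
    r <- 2 * sin(pi * rho_target / 6)
    z1 <- stats::rnorm(n_cell_lines)
    z2 <- r * z1 + sqrt(max(0, 1 - r^2)) * stats::rnorm(n_cell_lines)
    mat <- matrix(stats::rnorm(n_g * n_cell_lines), nrow = n_g) + mu
    rownames(mat) <- genes$id
    colnames(mat) <- sprintf("CL%02d", seq_len(n_cell_lines))
    mat[planted_pair[1], ] <- mu[planted_pair[1]] + z1
    mat[planted_pair[2], ] <- mu[planted_pair[2]] + z2
    list(matrix = mat, planted_pair = planted_pair, rho_target = rho_target)
  })
}

#' Simulate a two-factor nascent-proteome intensity matrix
#'
#' Samples are fully crossed: genotype (WT / ALT) x OPP label (OPP+ / OPP-)
#' with `n_replicates` replicates per cell. Effect proteins shift only in
#' the (ALT, OPP+) cell by their stated signed magnitude; all other proteins
#' are exchangeable across genotype.
#'
#' @param n_proteins number of proteins
#' @param n_replicates replicates per factor cell
#' @param effect_set data frame `protein`, `effect` (signed log-intensity
#'   shift); `NULL` plants 20 downregulated TSPs and 20 upregulated
#'   oncoproteins at magnitude 1.5; use `effect_set = data.frame()` for a
#'   null design
#' @param seed integer seed
#' @param noise_sd residual intensity noise
#' @return list with `matrix` (proteins x samples), `factors`, `annotation`
#'   (named vector over proteins: oncoprotein / TSP / none) and `truth`
#' @export
simulate_proteome <- function(n_proteins = 400, n_replicates = 3,
                              effect_set = NULL, seed = 1, noise_sd = 0.2) {
  stopifnot(n_proteins >= 2, n_replicates >= 2)
  prot <- sprintf("PR%04d", seq_len(n_proteins))
  if (is.null(effect_set)) {
    n_eff <- min(20L, floor(n_proteins / 4))
    effect_set <- data.frame(
      protein = prot[seq_len(2 * n_eff)],
      effect = c(rep(-1.5, n_eff), rep(1.5, n_eff)),
      stringsAsFactors = FALSE)
  }
  if (nrow(effect_set) && !all(effect_set$protein %in% prot))
    stop("effect protein not in matrix", call. = FALSE)
  genotype <- rep(c("WT", "ALT"), each = 2 * n_replicates)
  label <- rep(rep(c("OPP-", "OPP+"), each = n_replicates), 2)
  sample_ids <- sprintf("%s_%s_r%d", genotype, label,
                        rep(seq_len(n_replicates), 4))
  with_local_seed(seed, {
    base <- stats::rnorm(n_proteins, 20, 2)
    opp_gain <- stats::rnorm(n_proteins, 1, 0.3)   # capture signal in OPP+
    mat <- matrix(stats::rnorm(n_proteins * length(sample_ids), 0, noise_sd),
                  nrow = n_proteins,
                  dimnames = list(prot, sample_ids))
    mat <- mat + base
    mat[, label == "OPP+"] <- mat[, label == "OPP+"] + opp_gain
    sig <- genotype == "ALT" & label == "OPP+"
    if (nrow(effect_set)) {
      idx <- match(effect_set$protein, prot)
      mat[idx, sig] <- mat[idx, sig] + effect_set$effect
    }
    annotation <- stats::setNames(rep("none", n_proteins), prot)
    if (nrow(effect_set)) {
      annotation[effect_set$protein[effect_set$effect < 0]] <- "TSP"
      annotation[effect_set$protein[effect_set$effect > 0]] <- "oncoprotein"
    }
    factors <- data.frame(sample = sample_ids,
                          genotype = factor(genotype, c("WT", "ALT")),
                          label = factor(label, c("OPP-", "OPP+")),
                          stringsAsFactors = FALSE)
    list(matrix = mat, factors = factors, annotation = annotation,
         truth = list(effect_set = effect_set))
  })
}

#' Write a genome + cohort fixture bundle to disk
#'
#' Emits, in plain deterministic text: `genome.tsv` and `features.tsv`
#' (gene annotation), `k27ac.bed` / `k4me3.bed` / `k4me1.bed` / `tads.bed`
#' (BED3), `compartments.bed` (BED4), one `variants.<sample>.tsv` per
#' sample, optional `expression.tsv` and `proteome.tsv`, and
#' `planted_truth.json` with the generator's planted-effect ledger.
#'
#' @param genome a `genome_model`
#' @param cohort an `ashm_cohort` (may be `NULL`)
#' @param outdir output directory (created)
#' @param expression optional [simulate_expression_matrix()] result
#' @param proteome optional [simulate_proteome()] result
#' @return invisible character vector of the files written
#' @export
write_fixture_bundle <- function(genome, cohort, outdir,
                                 expression = NULL, proteome = NULL) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  w <- function(fn, writer, ...) {
    path <- file.path(outdir, fn)
    writer(..., path = path)
    files <<- c(files, path)
  }
  w("genome.tsv", write_genome_tsv, genome$genes)
  w("features.tsv", function(x, path)
    utils::write.table(x, path, sep = "\t", quote = FALSE,
                       row.names = FALSE), genome$features)
  w("k27ac.bed", function(x, path)
    write_bed(x[, c("chrom", "start", "end")], path), genome$tracks$k27ac)
  w("k4me3.bed", function(x, path)
    write_bed(x[, c("chrom", "start", "end")], path), genome$tracks$k4me3)
  w("k4me1.bed", function(x, path)
    write_bed(x[, c("chrom", "start", "end")], path), genome$tracks$k4me1)
  w("tads.bed", write_bed, genome$tracks$tads)
  w("compartments.bed", write_bed, genome$tracks$compartments)
  truth <- list()
  if (!is.null(cohort)) {
    for (sid in names(cohort$samples))
      w(sprintf("variants.%s.tsv", sid), write_variants_tsv,
        cohort$samples[[sid]]$variants)
    truth <- cohort$truth
    truth$config <- unclass(truth$config)
  }
  if (!is.null(expression)) {
    w("expression.tsv", write_expression_tsv, expression$matrix)
    truth$expression_planted_pair <- expression$planted_pair
    truth$expression_rho_target <- expression$rho_target
  }
  if (!is.null(proteome)) {
    w("proteome.tsv", function(x, path)
      write_proteome_tsv(x$matrix, x$factors, path), proteome)
    truth$proteome_effects <- proteome$truth$effect_set
  }
  path <- file.path(outdir, "planted_truth.json")
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = 10,
                       dataframe = "columns", null = "null")
  files <- c(files, path)
  invisible(files)
}
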