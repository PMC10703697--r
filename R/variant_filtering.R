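#' Filter-cascade configuration
#'
#' Thresholds for the somatic post-filter cascade applied to candidate
#' variant calls from paired tumor / nontumor sequencing.
#'
#' @param posterior_alpha keep variants with caller posterior `p <` this
#' @param max_normal_alt reject when the nontumor sample shows at least this
#'   many supporting reads
#' @param min_hq_alt minimum high-quality supporting reads in the tumor
#' @param af_min_default minimum tumor allele fraction
#' @param af_min_low_purity AF threshold used for `low_purity_samples`
#' @param low_purity_samples character vector of sample ids genotyped at the
#'   relaxed AF threshold (low tumor purity)
#' @param min_normal_depth minimum total read depth in nontumor DNA
#' @param edge_fraction_cut a variant fails when every supporting read
#'   places it within this fraction of the read length from a read end
#' @param strand_bias_min_alt strand bias is only assessed at this many or
#'   more supporting reads
#' @param strand_bias_fraction fail when at least this fraction of
#'   supporting reads sit on one strand
#' @param low_complexity_mask optional interval data frame (0-based
#'   half-open) of low-complexity regions to exclude
#' @param germline_exclude optional data frame with `chrom`, `pos` (1-based)
#'   of known germline positions (dbSNP/gnomAD/TOPMed style exclusion list)
#' @return a `filter_config` list
#' @export
filter_config <- function(posterior_alpha = 1e-6,
                          max_normal_alt = 2L,
                          min_hq_alt = 5L,
                          af_min_default = 0.20,
                          af_min_low_purity = 0.10,
                          low_purity_samples = character(),
                          min_normal_depth = 15L,
                          edge_fraction_cut = 0.25,
                          strand_bias_min_alt = 5L,
                          strand_bias_fraction = 0.95,
                          low_complexity_mask = NULL,
                          germline_exclude = NULL) {
  stopifnot(posterior_alpha > 0, posterior_alpha <= 1,
            max_normal_alt >= 0, min_hq_alt >= 0,
            af_min_default >= 0, af_min_default <= 1,
            af_min_low_purity >= 0, af_min_low_purity <= 1,
            min_normal_depth >= 0,
            edge_fraction_cut >= 0, edge_fraction_cut <= 0.5,
            strand_bias_min_alt >= 1,
            strand_bias_fraction > 0.5, strand_bias_fraction <= 1)
  if (!is.null(low_complexity_mask)) iv_validate(low_complexity_mask, "mask")
  structure(list(posterior_alpha = posterior_alpha,
                 max_normal_alt = max_normal_alt,
                 min_hq_alt = min_hq_alt,
                 af_min_default = af_min_default,
                 af_min_low_purity = af_min_low_purity,
                 low_purity_samples = low_purity_samples,
                 min_normal_depth = min_normal_depth,
                 edge_fraction_cut = edge_fraction_cut,
                 strand_bias_min_alt = strand_bias_min_alt,
                 strand_bias_fraction = strand_bias_fraction,
                 low_complexity_mask = low_complexity_mask,
                 germline_exclude = germline_exclude),
            class = "filter_config")
}

# the ordered filter names of the cascade
.cascade_filters <- c("posterior", "normal_alt", "germline", "low_complexity",
                      "hq_support", "strand_bias", "allele_fraction",
                      "normal_depth", "edge_of_read")

.require_field <- function(variants, field, filter) {
  if (!field %in% names(variants) ||
      (is.list(variants[[field]]) && any(vapply(variants[[field]], is.null, TRUE))) ||
      (!is.list(variants[[field]]) && anyNA(variants[[field]])))
    stop("active filter '", filter, "' needs evidence field '", field,
         "' for every variant", call. = FALSE)
}

#' Edge-of-read filter
#'
#' A variant fails when the distance from the variant to the nearer read end
#' is below `cut` (as a fraction of the read length) for *every* supporting
#' read; a single interior read rescues the call.
#'
#' @param edge_fractions numeric vector in `[0, 0.5]`, one value per
#'   supporting read
#' @param cut fraction of the read length defining the edge zone
#' @return `TRUE` (pass) or `FALSE` (fail)
#' @export
edge_of_read_filter <- function(edge_fractions, cut = 0.25) {
  if (!length(edge_fractions))
    stop("edge_fractions must be nonempty", call. = FALSE)
  if (any(edge_fractions < 0 | edge_fractions > 0.5))
    stop("edge fractions must lie in [0, 0.5]", call. = FALSE)
  !all(edge_fractions < cut)
}

#' Strand-bias filter
#'
#' Fails when the total supporting-read count reaches `min_alt` and at least
#' `fraction` of the supporting reads map to a single strand.
#'
#' @param alt_plus,alt_minus supporting reads on the plus / minus strand
#' @param min_alt minimum total support for the rule to apply
#' @param fraction one-strand fraction at or above which the call fails
#' @return `TRUE` (pass) or `FALSE` (fail); vectorized
#' @export
strand_bias_filter <- function(alt_plus, alt_minus, min_alt = 5L,
                               fraction = 0.95) {
  total <- alt_plus + alt_minus
  bias <- ifelse(total > 0, pmax(alt_plus, alt_minus) / total, 0)
  !(total >= min_alt & bias >= fraction)
}

#' Apply the somatic post-filter cascade
#'
#' Filters are applied in a fixed order (caller posterior gate; nontumor
#' support; germline exclusion list; low-complexity mask; high-quality read
#' support; strand bias; allele-fraction threshold; nontumor depth;
#' edge-of-read) and the *first* failing filter is recorded per rejected
#' variant. With `has_matched_normal = FALSE` the nontumor-dependent filters
#' (`normal_alt`, `normal_depth`) are skipped.
#'
#' @param variants data frame of candidate variants, sorted by
#'   `(chrom, pos)`, with the evidence columns `chrom`, `pos`, `ref`, `alt`,
#'   `t_depth`, `t_alt`, `t_alt_hq`, `alt_plus`, `alt_minus`, `edge_fracs`
#'   (list column of per-read fractions), `af`, `n_depth`, `n_alt`,
#'   `posterior_p`
#' @param config a [filter_config()]
#' @param has_matched_normal whether a matched nontumor sample exists
#' @param sample_id optional sample id, used to pick the low-purity AF
#'   threshold
#' @return a `filter_ledger`: list with `kept` (data frame), `rejected`
#'   (data frame plus a `filter` column), and `counts` (named integer
#'   vector over filters plus `"kept"`)
#' @export
filter_somatic_variants <- function(variants, config = filter_config(),
                                    has_matched_normal = TRUE,
                                    sample_id = NULL) {
  stopifnot(inherits(config, "filter_config"))
  n <- nrow(variants)
  fail <- rep(NA_character_, n)
  af_min <- if (!is.null(sample_id) &&
                sample_id %in% config$low_purity_samples)
    config$af_min_low_purity else config$af_min_default

  mark <- function(bad, name) {
    idx <- which(is.na(fail) & bad)
    fail[idx] <<- name
  }
  if (n) {
    variants <- variants[order(variants$chrom, variants$pos), , drop = FALSE]

    .require_field(variants, "posterior_p", "posterior")
    mark(variants$posterior_p >= config$posterior_alpha, "posterior")

    if (has_matched_normal) {
      .require_field(variants, "n_alt", "normal_alt")
      mark(variants$n_alt >= config$max_normal_alt, "normal_alt")
    }
    if (!is.null(config$germline_exclude) && nrow(config$germline_exclude)) {
      key <- paste(variants$chrom, variants$pos)
      bad <- key %in% paste(config$germline_exclude$chrom,
                            config$germline_exclude$pos)
      mark(bad, "germline")
    }
    if (!is.null(config$low_complexity_mask) &&
        nrow(config$low_complexity_mask)) {
      mark(points_in_intervals(variants$chrom, variants$pos,
                               config$low_complexity_mask),
           "low_complexity")
    }
    .require_field(variants, "t_alt_hq", "hq_support")
    mark(variants$t_alt_hq < config$min_hq_alt, "hq_support")

    .require_field(variants, "alt_plus", "strand_bias")
    .require_field(variants, "alt_minus", "strand_bias")
    mark(!strand_bias_filter(variants$alt_plus, variants$alt_minus,
                             config$strand_bias_min_alt,
                             config$strand_bias_fraction),
         "strand_bias")

    .require_field(variants, "af", "allele_fraction")
    mark(variants$af < af_min, "allele_fraction")

    if (has_matched_normal) {
      .require_field(variants, "n_depth", "normal_depth")
      mark(variants$n_depth < config$min_normal_depth, "normal_depth")
    }
    .require_field(variants, "edge_fracs", "edge_of_read")
    edge_pass <- vapply(variants$edge_fracs, edge_of_read_filter,
                        logical(1), cut = config$edge_fraction_cut)
    mark(!edge_pass, "edge_of_read")
  }
  kept <- variants[is.na(fail), , drop = FALSE]
  rejected <- variants[!is.na(fail), , drop = FALSE]
  rejected$filter <- fail[!is.na(fail)]
  counts <- c(table(factor(fail, levels = .cascade_filters)),
              kept = nrow(kept))
  structure(list(kept = kept, rejected = rejected, counts = counts),
            class = "filter_ledger")
}

#' @export
print.filter_ledger <- function(x, ...) {
  cat("Somatic filter ledger:", nrow(x$kept), "kept,",
      nrow(x$rejected), "rejected\n")
  print(x$counts[x$counts > 0 | names(x$counts) == "kept"])
  invisible(x)
}

#' Classify variants by genic context
#'
#' Categories, in precedence order: coding exon, 5'/3' UTR, promoter
#' (within `promoter_bp` of a TSS), intron (inside a gene body), intergenic.
#'
#' @param variants data frame with `chrom`, `pos` (1-based)
#' @param genes gene annotation: `id`, `chrom`, `tss` (1-based), `strand`,
#'   `start`, `end` (0-based half-open body)
#' @param features optional data frame of sub-gene features with columns
#'   `gene_id`, `feature` in `c("coding_exon", "utr5", "utr3")`, `chrom`,
#'   `start`, `end` (0-based half-open); without it, no exon/UTR calls are
#'   made and intragenic variants fall to intron
#' @param promoter_bp promoter half-width around the TSS
#' @return factor with levels `coding-exon`, `5'UTR`, `3'UTR`, `promoter`,
#'   `intron`, `intergenic`
#' @export
classify_genic_context <- function(variants, genes, features = NULL,
                                   promoter_bp = 2000) {
  lv <- c("coding-exon", "5'UTR", "3'UTR", "promoter", "intron", "intergenic")
  n <- nrow(variants)
  out <- rep("intergenic", n)
  if (n == 0L) return(factor(out, levels = lv))
  # intron: inside any gene body
  if (nrow(genes)) {
    body <- intervals(genes$chrom, genes$start, genes$end)
    out[points_in_intervals(variants$chrom, variants$pos, body)] <- "intron"
    # promoter: within +/- promoter_bp of any TSS
    prom <- intervals(genes$chrom,
                      pmax(0, genes$tss - 1 - promoter_bp),
                      genes$tss - 1 + promoter_bp + 1)
    out[points_in_intervals(variants$chrom, variants$pos, prom)] <- "promoter"
  }
  if (!is.null(features) && nrow(features)) {
    for (ft in c("utr3", "utr5", "coding_exon")) {  # ascending precedence
      f <- features[features$feature == ft, , drop = FALSE]
      if (!nrow(f)) next
      labs <- c(utr3 = "3'UTR", utr5 = "5'UTR", coding_exon = "coding-exon")
      set <- intervals(f$chrom, f$start, f$end)
      out[points_in_intervals(variants$chrom, variants$pos, set)] <- labs[[ft]]
    }
  }
  factor(out, levels = lv)
}

#' Genic-context burden table by stage
#'
#' Counts filtered variants of each genic-context category per disease
#' stage; the table feeds [chi_squared_contingency()].
#'
#' @param cohort list of sample mutation sets (see
#'   [new_sample_mutation_set()])
#' @param genes,features,promoter_bp passed to [classify_genic_context()]
#' @return integer matrix, stages x categories
#' @export
stage_burden_table <- function(cohort, genes, features = NULL,
                               promoter_bp = 2000) {
  if (!length(cohort)) stop("empty cohort", call. = FALSE)
  stages <- vapply(cohort, function(s) s$stage, character(1))
  rows <- lapply(cohort, function(s)
    table(classify_genic_context(s$variants, genes, features, promoter_bp)))
  cats <- names(rows[[1]])
  out <- matrix(0L, nrow = 2, ncol = length(cats),
                dimnames = list(c("FL", "DHL"), cats))
  for (i in seq_along(rows))
    out[stages[i], ] <- out[stages[i], ] + as.integer(rows[[i]])
  out
}

#' Construct a sample mutation set
#'
#' @param patient patient id
#' @param stage `"FL"` or `"DHL"`
#' @param sample_id sample id
#' @param variants variant data frame (post-filter)
#' @param has_matched_normal whether a matched nontumor sample exists
#' @return a `sample_mutation_set` list
#' @export
new_sample_mutation_set <- function(patient, stage, sample_id, variants,
                                    has_matched_normal = TRUE) {
  stage <- match.arg(stage, c("FL", "DHL"))
  structure(list(patient = patient, stage = stage, sample_id = sample_id,
                 variants = variants, n = nrow(variants),
                 has_matched_normal = has_matched_normal),
            class = "sample_mutation_set")
}
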