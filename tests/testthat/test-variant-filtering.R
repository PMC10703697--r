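# a variant row that passes every filter at default thresholds
clean_variant <- function(chrom = "c1", pos = 1000) {
  v <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                  t_depth = 60, t_alt = 20, t_alt_hq = 18, alt_plus = 10,
                  alt_minus = 10, af = 20 / 60, n_depth = 55, n_alt = 0,
                  posterior_p = 1e-9, stringsAsFactors = FALSE)
  v$edge_fracs <- list(runif(20, 0.05, 0.5))
  v
}

test_that("edge-of-read filter: one interior read rescues", {
  expect_false(edge_of_read_filter(c(0.05, 0.10, 0.20), cut = 0.25))
  expect_true(edge_of_read_filter(c(0.05, 0.30), cut = 0.25))
  expect_error(edge_of_read_filter(numeric(0)), "nonempty")
  set.seed(601)
  for (rep in 1:60) {
    ef <- runif(sample(1:12, 1), 0, 0.5)
    expect_equal(edge_of_read_filter(ef), !all(ef < 0.25))
  }
})

test_that("strand-bias rule over a sweep of splits", {
  expect_false(strand_bias_filter(10, 0))
  expect_true(strand_bias_filter(5, 5))
  for (total in 0:12) for (plus in 0:total) {
    want <- !(total >= 5 && max(plus, total - plus) / total >= 0.95)
    expect_equal(strand_bias_filter(plus, total - plus), want)
  }
})

test_that("cascade rejects by the first failing filter, in order", {
  cases <- list(
    posterior       = function(v) { v$posterior_p <- 1e-3; v },
    normal_alt      = function(v) { v$n_alt <- 2; v },
    hq_support      = function(v) { v$t_alt_hq <- 4; v },
    strand_bias     = function(v) { v$alt_plus <- 20; v$alt_minus <- 0; v },
    allele_fraction = function(v) { v$af <- 0.15; v },
    normal_depth    = function(v) { v$n_depth <- 14; v },
    edge_of_read    = function(v) { v$edge_fracs <- list(rep(0.1, 20)); v }
  )
  for (name in names(cases)) {
    led <- filter_somatic_variants(cases[[name]](clean_variant()))
    expect_equal(nrow(led$kept), 0L)
    expect_equal(led$rejected$filter, name)
  }
  # a variant violating two filters is charged to the earlier one
  v <- cases$normal_depth(cases$posterior(clean_variant()))
  expect_equal(filter_somatic_variants(v)$rejected$filter, "posterior")
  # ledger partition invariant
  vs <- do.call(rbind, c(list(clean_variant(pos = 1)),
                         lapply(seq_along(cases), function(i)
                           cases[[i]](clean_variant(pos = i * 100)))))
  led <- filter_somatic_variants(vs)
  expect_equal(nrow(led$kept) + nrow(led$rejected), nrow(vs))
  expect_equal(sum(led$counts), nrow(vs))
})

test_that("mask, germline list and low-purity AF thresholds apply", {
  v <- clean_variant(pos = 1000)
  cfg <- filter_config(low_complexity_mask = intervals("c1", 990, 1010))
  expect_equal(filter_somatic_variants(v, cfg)$rejected$filter,
               "low_complexity")
  cfg2 <- filter_config(germline_exclude = data.frame(chrom = "c1",
                                                      pos = 1000))
  expect_equal(filter_somatic_variants(v, cfg2)$rejected$filter, "germline")
  # AF 0.15 fails the default 20% gate but passes a low-purity sample
  v$af <- 0.15
  cfg3 <- filter_config(low_purity_samples = "P2-FL")
  expect_equal(nrow(filter_somatic_variants(v, cfg3,
                                            sample_id = "P2-FL")$kept), 1L)
  expect_equal(filter_somatic_variants(v, cfg3,
                                       sample_id = "P1-FL")$rejected$filter,
               "allele_fraction")
})

test_that("skip contract without matched normal", {
  v <- clean_variant()
  v$n_alt <- 5; v$n_depth <- 3   # would fail both normal filters
  led <- filter_somatic_variants(v, has_matched_normal = FALSE)
  expect_equal(nrow(led$kept), 1L)
  # and the normal evidence columns may be entirely absent
  v2 <- clean_variant()
  v2$n_alt <- NA_real_; v2$n_depth <- NA_real_
  expect_equal(nrow(filter_somatic_variants(
    v2, has_matched_normal = FALSE)$kept), 1L)
  expect_error(filter_somatic_variants(v2, has_matched_normal = TRUE),
               "n_alt")
})

test_that("cascade is idempotent and monotone under filter relaxation", {
  w <- .tiny_world()
  v <- w$cohort$samples[["P3-DHL"]]$variants
  led <- filter_somatic_variants(v)
  led2 <- filter_somatic_variants(led$kept)
  expect_equal(nrow(led2$rejected), 0L)
  expect_equal(nrow(led2$kept), nrow(led$kept))
  # disabling any single filter never decreases the kept count
  relaxed <- list(
    filter_config(posterior_alpha = 1),
    filter_config(max_normal_alt = .Machine$integer.max),
    filter_config(min_hq_alt = 0),
    filter_config(strand_bias_fraction = 1, strand_bias_min_alt = 1e9),
    filter_config(af_min_default = 0),
    filter_config(min_normal_depth = 0),
    filter_config(edge_fraction_cut = 0))
  for (cfg in relaxed)
    expect_gte(nrow(filter_somatic_variants(v, cfg)$kept), nrow(led$kept))
})

test_that("ledger counts equal the generator's planted-violation ledger", {
  w <- .tiny_world()
  for (sid in c("P1-FL", "P2-DHL", "P5-DHL")) {
    s <- w$cohort$samples[[sid]]
    led <- filter_somatic_variants(s$variants, has_matched_normal =
                                     s$has_matched_normal, sample_id = sid)
    truth <- w$cohort$truth$violations
    truth <- truth[truth$sample == sid, ]
    got <- led$counts[names(led$counts) != "kept"]
    want <- table(factor(truth$planted_violation, levels = names(got)))
    expect_equal(as.integer(got), as.integer(want))
    expect_equal(nrow(led$rejected), nrow(truth))
  }
})

test_that("genic context classification and precedence", {
  genes <- data.frame(id = "G1", chrom = "c1", tss = 10001, strand = "+",
                      start = 10000, end = 20000, stringsAsFactors = FALSE)
  features <- data.frame(gene_id = "G1",
                         feature = c("utr5", "coding_exon", "utr3"),
                         chrom = "c1",
                         start = c(10000, 10400, 19800),
                         end = c(10200, 11400, 20000))
  cls <- function(pos) as.character(classify_genic_context(
    data.frame(chrom = "c1", pos = pos), genes, features))
  expect_equal(cls(10002), "5'UTR")          # TSS + 1
  expect_equal(cls(8002), "promoter")        # 1999 bp upstream of TSS
  expect_equal(cls(10500), "coding-exon")    # exon beats promoter
  expect_equal(cls(19900), "3'UTR")
  expect_equal(cls(15000), "intron")
  expect_equal(cls(500), "intergenic")
})

test_that("random positions agree with a linear-scan context oracle", {
  w <- .tiny_world()
  genes <- w$genome$genes
  features <- w$genome$features
  set.seed(602)
  pos <- sample.int(1e7, 400)
  got <- as.character(classify_genic_context(
    data.frame(chrom = "chr1", pos = pos), genes, features))
  oracle_one <- function(p) {
    b <- p - 1
    hit <- function(f) any(features$feature == f & features$start <= b &
                             b < features$end)
    if (hit("coding_exon")) return("coding-exon")
    if (hit("utr5")) return("5'UTR")
    if (hit("utr3")) return("3'UTR")
    if (any(abs(p - genes$tss) <= 2000)) return("promoter")
    if (any(genes$start <= b & b < genes$end)) return("intron")
    "intergenic"
  }
  expect_equal(got, vapply(pos, oracle_one, character(1)))
})

test_that("stage burden table counts and errors", {
  genes <- data.frame(id = "G1", chrom = "c1", tss = 10001, strand = "+",
                      start = 10000, end = 20000, stringsAsFactors = FALSE)
  s <- new_sample_mutation_set("P1", "FL", "P1-FL",
                               data.frame(chrom = "c1", pos = 15000))
  tab <- stage_burden_table(list(s), genes)
  expect_equal(sum(tab), 1L)
  expect_equal(tab["FL", "intron"], 1L)
  expect_error(stage_burden_table(list(), genes), "empty cohort")
})

test_that("variant TSV and VCF readers round-trip the evidence dialect", {
  w <- .tiny_world()
  v <- w$cohort$samples[["P1-FL"]]$variants
  f <- tempfile(fileext = ".tsv")
  write_variants_tsv(v, f)
  v2 <- read_variants_tsv(f)
  expect_equal(v2$pos, v$pos)
  expect_equal(v2$t_alt, v$t_alt)
  expect_equal(lengths(v2$edge_fracs), lengths(v$edge_fracs))
  f2 <- tempfile(fileext = ".tsv")
  write_variants_tsv(v2, f2)
  expect_identical(readLines(f), readLines(f2))
  # minimal VCF mapping and loud failure on missing evidence
  vcf <- c("##fileformat=VCFv4.2",
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "T1", sep = "\t"),
           paste("c1", "101", ".", "A", "G", ".", ".", ".",
                 "DP:AD:AF", "60:40,20:0.333", sep = "\t"))
  fv <- tempfile(fileext = ".vcf")
  writeLines(vcf, fv)
  x <- read_vcf_variants(fv)
  expect_equal(x$t_depth, 60)
  expect_equal(x$t_alt, 20)
  expect_error(read_vcf_variants(fv, require_evidence = c("t_alt_hq")),
               "t_alt_hq")
})
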