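test_that("toy genome is deterministic under its seed", {
  g1 <- build_toy_genome(chromosomes = c(chr1 = 1e7), n_genes = 50, seed = 7)
  g2 <- build_toy_genome(chromosomes = c(chr1 = 1e7), n_genes = 50, seed = 7)
  expect_identical(g1, g2)
  g3 <- build_toy_genome(chromosomes = c(chr1 = 1e7), n_genes = 50, seed = 8)
  expect_false(identical(g1$genes, g3$genes))
})

test_that("zero genes yield an empty gene table with valid tracks", {
  g <- build_toy_genome(n_genes = 0, seed = 7)
  expect_equal(nrow(g$genes), 0L)
  expect_gt(nrow(g$tracks$k27ac), 0)
  expect_gt(nrow(g$tracks$tads), 0)
  iv_validate(g$tracks$k27ac)
})

test_that("sizing errors for impossible requests", {
  expect_error(build_toy_genome(chromosomes = c(chr1 = 5e5)), "1 Mb")
  expect_error(build_toy_genome(chromosomes = c(chr1 = 1e6), n_genes = 60),
               "too small")
})

test_that("two-chromosome genome respects all bounds (exhaustive scan)", {
  g <- build_toy_genome(chromosomes = c(chrA = 4e6, chrB = 6e6),
                        n_genes = 40, seed = 9)
  len <- setNames(g$chromosomes$length, g$chromosomes$name)
  check_bounds <- function(df) {
    for (i in seq_len(nrow(df))) {
      expect_gte(df$start[i], 0)
      expect_lte(df$end[i], len[[df$chrom[i]]])
      expect_lt(df$start[i], df$end[i])
    }
  }
  for (tr in g$tracks) check_bounds(tr)
  check_bounds(g$genes[, c("chrom", "start", "end")])
  expect_true(all(g$genes$tss >= 1 & g$genes$tss <= len[g$genes$chrom]))
  # TADs non-overlapping per chromosome
  for (ch in names(len)) {
    t <- g$tracks$tads[g$tracks$tads$chrom == ch, ]
    t <- t[order(t$start), ]
    if (nrow(t) > 1) expect_true(all(t$start[-1] >= t$end[-nrow(t)]))
    # compartments partition the chromosome
    comp <- g$tracks$compartments[g$tracks$compartments$chrom == ch, ]
    comp <- comp[order(comp$start), ]
    expect_equal(comp$start[1], 0)
    expect_equal(comp$end[nrow(comp)], len[[ch]])
    expect_true(all(comp$start[-1] == comp$end[-nrow(comp)]))
    expect_true(all(comp$label %in% c("A", "B")))
  }
})

test_that("cohort simulation is deterministic and structured", {
  g <- build_toy_genome(seed = 7)
  c1 <- simulate_cohort(g, cohort_config(seed = 3))
  c2 <- simulate_cohort(g, cohort_config(seed = 3))
  expect_identical(c1$samples, c2$samples)
  stages <- vapply(c1$samples, function(s) s$stage, character(1))
  expect_equal(sum(stages == "FL"), 8L)
  expect_equal(sum(stages == "DHL"), 8L)
  # DHL is a superset of the patient's FL positions
  for (p in paste0("P", 1:8)) {
    fl <- c1$samples[[paste0(p, "-FL")]]$variants
    dhl <- c1$samples[[paste0(p, "-DHL")]]$variants
    expect_gt(nrow(dhl), nrow(fl))
    expect_true(all(paste(fl$chrom, fl$pos) %in%
                      paste(dhl$chrom, dhl$pos)))
    # acquired flag marks exactly the non-persisted DHL variants
    expect_equal(sum(!dhl$acquired), nrow(fl))
  }
})

test_that("copy-gain calls appear only in DHL samples", {
  g <- build_toy_genome(seed = 7)
  co <- simulate_cohort(g, cohort_config(gain_probability_dhl = 0.75,
                                         n_patients = 8, seed = 3))
  expect_true(all(co$cnv$stage == "DHL"))
  expect_equal(nrow(co$cnv), sum(co$truth$gain$gain))
  # gain truth covers every DHL sample
  expect_equal(nrow(co$truth$gain), 8L)
})

test_that("two FL samples per patient persist sequentially", {
  g <- build_toy_genome(seed = 7)
  co <- simulate_cohort(g, cohort_config(
    n_patients = 2, samples_per_patient = c("FL", "FL", "DHL"), seed = 5))
  expect_setequal(names(co$samples)[1:3],
                  c("P1-FLA", "P1-FLB", "P1-DHL"))
  fla <- co$samples[["P1-FLA"]]$variants
  flb <- co$samples[["P1-FLB"]]$variants
  expect_true(all(paste(fla$chrom, fla$pos) %in% paste(flb$chrom, flb$pos)))
})

test_that("null enrichment keeps footprint and background rate ratios equal", {
  g <- build_toy_genome(seed = 7)
  co <- simulate_cohort(g, cohort_config(se_promoter_enrichment = 1,
                                         seed = 13))
  fp <- co$truth$footprints
  stages <- vapply(co$samples, function(s) s$stage, character(1))
  count_in <- function(st, inside) {
    sum(vapply(co$samples[stages == st], function(s) {
      v <- s$variants
      if (st == "DHL") v <- v[v$acquired, ]
      hits <- points_in_intervals(v$chrom, v$pos, fp)
      sum(if (inside) hits else !hits)
    }, numeric(1)))
  }
  # acquired-DHL / FL ratio inside footprints ~ ratio outside (both ~1)
  r_in <- count_in("DHL", TRUE) / count_in("FL", TRUE)
  r_out <- count_in("DHL", FALSE) / count_in("FL", FALSE)
  expect_lt(abs(r_in - r_out), 0.5)
})

test_that("planted kataegis clusters satisfy their max-IMD constraint", {
  w <- .tiny_world()
  kat <- w$cohort$truth$kataegis
  expect_true(all(kat$sample %in% names(w$cohort$samples)))
  cfg <- w$cohort$truth$config
  expect_true(all(vapply(w$cohort$samples[unique(kat$sample)],
                         function(s) s$stage, character(1)) == "DHL"))
  for (i in seq_len(nrow(kat))) {
    s <- w$cohort$samples[[kat$sample[i]]]
    p <- sort(s$variants$pos[s$variants$chrom == kat$chrom[i] &
                               s$variants$pos >= kat$start_pos[i] &
                               s$variants$pos <= kat$end_pos[i]])
    expect_gte(length(p), cfg$kataegis$cluster_size)
    expect_lte(max(diff(p)), cfg$kataegis$max_imd)
  }
})

test_that("expression simulation hits the planted correlation and quartile", {
  g <- build_toy_genome(seed = 7)
  ex <- simulate_expression_matrix(g, n_cell_lines = 50, rho_target = -0.9,
                                   seed = 15)
  rho <- spearman_rho(ex$matrix[ex$planted_pair[1], ],
                      ex$matrix[ex$planted_pair[2], ])
  expect_true(rho >= -1 && rho <= -0.75)
  ex0 <- simulate_expression_matrix(g, n_cell_lines = 50, rho_target = 0,
                                    seed = 15)
  expect_lt(abs(spearman_rho(ex0$matrix[ex0$planted_pair[1], ],
                             ex0$matrix[ex0$planted_pair[2], ])), 0.3)
  mu <- rowMeans(ex$matrix)
  q3 <- quantile(mu, 0.75)
  expect_true(all(mu[ex$planted_pair] >= q3))
  expect_identical(ex$matrix,
                   simulate_expression_matrix(g, n_cell_lines = 50,
                                              rho_target = -0.9,
                                              seed = 15)$matrix)
  expect_error(simulate_expression_matrix(g, planted_pair = c("nope", "G001")),
               "not found")
})

test_that("proteome simulation: determinism, null and planted recovery", {
  p1 <- simulate_proteome(n_proteins = 100, seed = 5)
  p2 <- simulate_proteome(n_proteins = 100, seed = 5)
  expect_identical(p1$matrix, p2$matrix)
  expect_equal(dim(p1$matrix), c(100L, 12L))
  expect_equal(as.vector(table(p1$factors$genotype, p1$factors$label)),
               rep(3L, 4))
  # effects land only in the (ALT, OPP+) cell
  eff <- p1$truth$effect_set
  a <- two_way_anova_per_feature(p1$matrix, p1$factors$genotype,
                                 p1$factors$label)
  hit <- a$protein[a$padj_genotype < 0.01]
  expect_gt(mean(eff$protein %in% hit), 0.8)
  expect_lt(mean(setdiff(a$protein, eff$protein) %in% hit), 0.05)
  # null design: genotype p-values healthy (no spurious planted signal)
  p0 <- simulate_proteome(n_proteins = 150, effect_set = data.frame(),
                          seed = 6)
  a0 <- two_way_anova_per_feature(p0$matrix, p0$factors$genotype,
                                  p0$factors$label)
  expect_gt(suppressWarnings(ks.test(a0$p_genotype, "punif")$p.value), 1e-3)
})

test_that("fixture bundle round-trips and is checksum-stable under its seed", {
  g <- build_toy_genome(chromosomes = c(chr1 = 2e6), n_genes = 8, seed = 7)
  co <- simulate_cohort(g, cohort_config(n_patients = 2, background_rate = 5,
                                         hotspot_rate = 50, seed = 3))
  ex <- simulate_expression_matrix(g, seed = 4)
  pr <- simulate_proteome(n_proteins = 20, seed = 5)
  d1 <- file.path(tempdir(), "bundle1"); d2 <- file.path(tempdir(), "bundle2")
  f1 <- write_fixture_bundle(g, co, d1, expression = ex, proteome = pr)
  f2 <- write_fixture_bundle(g, co, d2, expression = ex, proteome = pr)
  h1 <- tools::md5sum(sort(f1)); h2 <- tools::md5sum(sort(f2))
  expect_equal(unname(h1), unname(h2))
  # write -> read -> write is byte-identical for every dialect
  bed <- file.path(d1, "tads.bed")
  bed2 <- tempfile()
  write_bed(read_bed(bed), bed2)
  expect_identical(readLines(bed), readLines(bed2))
  comp <- file.path(d1, "compartments.bed")
  comp2 <- tempfile()
  write_bed(read_bed(comp), comp2)
  expect_identical(readLines(comp), readLines(comp2))
  ex2 <- tempfile()
  write_expression_tsv(read_expression_tsv(file.path(d1, "expression.tsv")),
                       ex2)
  expect_identical(readLines(file.path(d1, "expression.tsv")), readLines(ex2))
  prt <- read_proteome_tsv(file.path(d1, "proteome.tsv"))
  pr2 <- tempfile()
  write_proteome_tsv(prt$matrix, prt$factors, pr2)
  expect_identical(readLines(file.path(d1, "proteome.tsv")), readLines(pr2))
  # empty cohort: valid headers only
  d3 <- file.path(tempdir(), "bundle3")
  write_fixture_bundle(g, NULL, d3)
  expect_true(file.exists(file.path(d3, "genome.tsv")))
  expect_equal(nrow(read_genome_tsv(file.path(d3, "genome.tsv"))), 8L)
  # truth ledger readable
  truth <- jsonlite::read_json(file.path(d1, "planted_truth.json"))
  expect_true(all(c("footprints", "kataegis", "violations") %in%
                    names(truth)))
})

test_that("generator guards reject inconsistent configurations", {
  expect_error(cohort_config(se_promoter_enrichment = 0.5))
  expect_error(cohort_config(background_rate = -1))
  g <- build_toy_genome(n_genes = 0, se_gene_fraction = 0, seed = 7)
  # no K4me3 at all -> no footprints -> enrichment impossible
  expect_error(simulate_cohort(g, cohort_config(se_promoter_enrichment = 10)),
               "footprints")
})
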