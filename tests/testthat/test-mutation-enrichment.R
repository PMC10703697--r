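mk_sample <- function(pos, stage = "FL", chrom = "c1", patient = "P1",
                      sample_id = paste0(patient, "-", stage),
                      acquired = NULL) {
  v <- data.frame(chrom = chrom, pos = pos, ref = "A", alt = "G",
                  stringsAsFactors = FALSE)
  if (!is.null(acquired)) v$acquired <- acquired
  new_sample_mutation_set(patient, stage, sample_id, v)
}

test_that("TSS profile puts delta mass in the central bin and conserves counts", {
  genes <- data.frame(id = c("G1", "G2"), chrom = "c1", tss = c(1e4, 5e4),
                      strand = "+", start = c(1e4, 5e4) - 1,
                      end = c(1e4, 5e4) + 5000)
  cohort <- list(mk_sample(c(1e4, 1e4, 5e4), "FL"),
                 mk_sample(c(1e4, 5e4), "DHL", patient = "P2"))
  prof <- tss_density_profile(cohort, genes, window = 1000, bin = 100)
  central <- which(prof$mid == 50)  # bin [0, 100)
  expect_equal(prof$mean$FL[central], 1)
  expect_equal(sum(prof$mean$FL), 1)
  expect_equal(rowSums(prof$per_sample$DHL), 1, ignore_attr = TRUE)
  # sample with no in-window mutations is skipped with a warning
  cohort2 <- c(cohort, list(mk_sample(9.9e6, "FL", patient = "P3")))
  expect_warning(p2 <- tss_density_profile(cohort2, genes, window = 1000,
                                           bin = 100), "skipped")
  expect_equal(p2$skipped, "P3-FL")
})

test_that("profiles are invariant to mutation input order", {
  w <- .tiny_world()
  s <- w$cohort$samples[["P1-DHL"]]
  shuf <- s
  set.seed(801)
  shuf$variants <- s$variants[sample.int(nrow(s$variants)), ]
  genes <- w$genome$genes
  p1 <- tss_density_profile(list(s), genes)
  p2 <- tss_density_profile(list(shuf), genes)
  expect_equal(p1$mean, p2$mean)
})

test_that("feature profile centers on anchor midpoints", {
  anchors <- intervals("c1", 900, 1100)  # midpoint base 1000
  cohort <- list(mk_sample(c(1001, 1001, 1001), "FL"))
  prof <- feature_density_profile(cohort, anchors, window = 500, bin = 100)
  expect_equal(prof$mean$FL[which(prof$mid == 50)], 1)
  # symmetric placement (offsets at bin midpoints) gives a symmetric profile
  cohort2 <- list(mk_sample(c(751, 1251, 851, 1151), "FL"))
  p2 <- feature_density_profile(cohort2, anchors, window = 500, bin = 100)
  expect_equal(p2$mean$FL, rev(p2$mean$FL))
})

test_that("rainfall distances and sort invariance", {
  s <- mk_sample(c(100, 200, 1200))
  rf <- rainfall(s)
  expect_equal(rf$imd, c(100, 1000))
  expect_equal(rf$pos, c(200, 1200))
  expect_equal(nrow(rainfall(mk_sample(42))), 0L)
  s2 <- mk_sample(c(1200, 100, 200))
  expect_equal(rainfall(s2), rf)
})

test_that("kataegis run rule at the threshold", {
  expect_equal(detect_kataegis(mk_sample(seq(1, by = 500,
                                             length.out = 6)))$n_mutations, 6L)
  expect_equal(nrow(detect_kataegis(mk_sample(seq(1, by = 500,
                                                  length.out = 5)))), 0L)
  # a 1,001 bp gap splits the run
  pos <- c(seq(1, by = 500, length.out = 6),
           seq(10000, by = 500, length.out = 7))
  det <- detect_kataegis(mk_sample(pos))
  expect_equal(det$n_mutations, c(6L, 7L))
})

test_that("planted clusters are recovered exactly on a background-free world", {
  genome <- build_toy_genome(seed = 31)
  cfg <- cohort_config(background_rate = 0, hotspot_rate = 0,
                       se_promoter_enrichment = 1, seed = 32)
  co <- simulate_cohort(genome, cfg)
  truth <- co$truth$kataegis
  expect_gt(nrow(truth), 0)
  for (sid in unique(truth$sample)) {
    det <- detect_kataegis(co$samples[[sid]])
    tr <- truth[truth$sample == sid, ]
    tr <- tr[order(tr$chrom, tr$start_pos), ]
    expect_equal(det$start_pos, tr$start_pos)
    expect_equal(det$end_pos, tr$end_pos)
    expect_equal(det$n_mutations, tr$n_mutations)
  }
})

test_that("segment scan closed form and annotation", {
  chroms <- data.frame(name = "c1", length = 12000)
  cohort <- list(mk_sample(c(101, 102, 103, 104, 105), "DHL"),
                 mk_sample(c(3101, 3102, 3103, 3104, 3105), "FL",
                           patient = "P2"))
  res <- segment_scan(cohort, chroms, min_total = 5, alpha = 0.05)
  expect_equal(attr(res, "p0"), 0.5)
  seg1 <- res[res$start == 0, ]
  expect_equal(seg1$p, 0.03125)          # (1/2)^5
  expect_equal(res[res$start == 3000, ]$p, 1)
  # explicit p0 override gives the same closed form
  res2 <- segment_scan(cohort, chroms, p0 = 0.5)
  expect_equal(res2[res2$start == 0, ]$p, 0.03125)
  # SE annotation flags the overlapping segment
  res3 <- segment_scan(cohort, chroms,
                       superenhancers = intervals("c1", 50, 60))
  expect_true(res3[res3$start == 0, ]$se_overlap)
  expect_false(res3[res3$start == 3000, ]$se_overlap)
  # no qualifying segments -> empty result, not an error
  res4 <- segment_scan(cohort, chroms, min_total = 11)
  expect_equal(nrow(res4), 0L)
  expect_error(segment_scan(cohort[1], chroms), "both FL and DHL")
})

test_that("fisher segment mode agrees with the exact test", {
  chroms <- data.frame(name = "c1", length = 9000)
  cohort <- list(mk_sample(c(101, 102, 103, 104, 4001, 4002), "DHL"),
                 mk_sample(c(105, 4003, 4004, 4005), "FL", patient = "P2"))
  res <- segment_scan(cohort, chroms, method = "fisher", min_total = 5)
  i <- which(res$start == 0)
  expect_equal(res$p[i],
               fisher_exact_2x2(c(4, 2, 1, 3), sided = "one-greater"))
})

test_that("acquired flag restricts DHL counts", {
  chroms <- data.frame(name = "c1", length = 6000)
  dhl <- mk_sample(c(101, 102, 103, 104, 105, 106), "DHL",
                   acquired = c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  fl <- mk_sample(c(110, 111, 112), "FL", patient = "P2")
  res <- segment_scan(list(dhl, fl), chroms, min_total = 5)
  expect_equal(res$dhl, 3L)
  res_all <- segment_scan(list(dhl, fl), chroms, min_total = 5,
                          use_acquired = FALSE)
  expect_equal(res_all$dhl, 6L)
})

test_that("per-peak percentages match a direct recount; identical stages give p = 1", {
  peaks <- intervals(c("c1", "c1"), c(0, 1000), c(100, 1100))
  same <- c(50, 60, 1050)
  cohort <- list(mk_sample(same, "FL"), mk_sample(same, "DHL",
                                                  patient = "P2"))
  out <- per_peak_overlap_comparison(cohort, peaks)
  expect_equal(out$p.value, 1)
  expect_equal(out$table$fl_pct, out$table$dhl_pct)
  # single peak holding every DHL mutation tops the ranking
  cohort2 <- list(mk_sample(c(50, 5000), "FL"),
                  mk_sample(c(1050, 1060, 1070), "DHL", patient = "P2"))
  out2 <- per_peak_overlap_comparison(cohort2, peaks, top_k = 1)
  expect_equal(out2$top$start, 1000)
  expect_equal(out2$top$dhl_pct, 100)
  # random cohorts vs recount oracle
  set.seed(802)
  for (rep in 1:10) {
    pk <- random_interval_set(6, chroms = "c1")
    fl_pos <- sample.int(220, 30, replace = TRUE)
    dhl_pos <- sample.int(220, 40, replace = TRUE)
    co <- list(mk_sample(fl_pos, "FL"),
               mk_sample(dhl_pos, "DHL", patient = "P2"))
    got <- per_peak_overlap_comparison(co, pk)$table
    for (i in seq_len(nrow(pk))) {
      expect_equal(got$fl[i], sum(fl_pos - 1 >= pk$start[i] &
                                    fl_pos - 1 < pk$end[i]))
      expect_equal(got$dhl_pct[i], 100 * sum(dhl_pos - 1 >= pk$start[i] &
                                               dhl_pos - 1 < pk$end[i]) / 40)
    }
  }
})

test_that("TAD boundary profile signs distances into the TAD as negative", {
  tads <- intervals("c1", 10000, 50000)
  # 1 kb inside the left boundary, 1 kb outside it, and at the boundary
  cohort <- list(mk_sample(c(11001, 9001, 10001), "FL"))
  prof <- tad_boundary_profile(cohort, tads, window = 5000, bin = 1000)
  expect_equal(prof$mean$FL[prof$mid == -500], 1 / 3)  # 1 kb inside
  expect_equal(prof$mean$FL[prof$mid == 500], 1 / 3)   # at the boundary
  expect_equal(prof$mean$FL[prof$mid == 1500], 1 / 3)  # 1 kb outside
  # nested TADs are dropped: only outer boundaries anchor
  nested <- rbind(tads, intervals("c1", 20000, 30000))
  cohort2 <- list(mk_sample(c(20501), "FL"))
  p2 <- tad_boundary_profile(cohort2, nested, window = 20000, bin = 1000)
  # nearest outer boundary is 10,000 away (inside), not the nested one at 500
  expect_equal(p2$mean$FL[p2$mid == -10500], 1)
})

test_that("SE mutations split by compartment per sample", {
  se <- intervals("c1", 0, 1000)
  comp <- intervals(c("c1", "c1"), c(0, 500), c(500, 1000),
                    label = c("A", "B"))
  cohort <- list(mk_sample(c(100, 200, 300, 600), "FL"),
                 mk_sample(c(100, 2000), "DHL", patient = "P2"))
  out <- compartment_se_mutation_fractions(cohort, se, comp)
  expect_equal(out$per_sample$frac_A, c(0.75, 1))
  expect_equal(out$per_sample$frac_A + out$per_sample$frac_B, c(1, 1))
  # all SEs in A
  compA <- intervals("c1", 0, 1000, label = "A")
  outA <- compartment_se_mutation_fractions(cohort, se, compA)
  expect_equal(outA$per_sample$frac_A, c(1, 1))
  # sample without SE mutations is excluded with a warning
  cohort2 <- c(cohort, list(mk_sample(5000, "FL", patient = "P3")))
  expect_warning(out2 <- compartment_se_mutation_fractions(cohort2, se, comp),
                 "excluded")
  expect_equal(out2$excluded, "P3-FL")
})

test_that("micro-indel fractions by stage", {
  snv <- mk_sample(1:10, "FL")
  expect_equal(indel_class_summary(list(snv))$micro_ins_frac[1], 0)
  v <- snv$variants
  v$alt[1] <- "AGGG"  # one 3 bp insertion among 10
  s <- new_sample_mutation_set("P1", "FL", "P1-FL", v)
  out <- indel_class_summary(list(s))
  expect_equal(out$micro_ins_frac[out$stage == "FL"], 0.1)
  expect_equal(out$micro_del_frac[out$stage == "FL"], 0)
  # long indels are not micro
  v$ref[2] <- paste(rep("A", 30), collapse = "")
  s2 <- new_sample_mutation_set("P1", "FL", "P1-FL", v)
  out2 <- indel_class_summary(list(s2), max_len = 20)
  expect_equal(out2$micro_del_frac[out2$stage == "FL"], 0)
  # intersection overlap fractions recount
  inter <- intervals("c1", 0, 5)
  out3 <- indel_class_summary(list(s), intersection = inter)
  expect_equal(out3$ins_in_intersection[out3$stage == "FL"], 1)
})
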