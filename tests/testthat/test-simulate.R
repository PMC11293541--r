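test_that("the synthetic reference contains exactly the configured CpG sites", {
  cfg <- sim_config(n_regions = 10, cpg_per_region = 100, seed = 1)
  sim <- simulate_reference(cfg)
  expect_equal(nrow(sim$regions), 10L)
  expect_equal(nrow(sim$cpg_sites), 1000L)
  seq <- Biostrings::DNAString(sim$sequence)
  total_cg <- 0L
  for (r in seq_len(nrow(sim$regions))) {
    sub <- seq[(sim$regions$start[r] + 1):(sim$regions$end[r])]
    n_cg <- Biostrings::countPattern("CG", sub)
    expect_equal(n_cg, 100L)  # no accidental CpG in spacers
    total_cg <- total_cg + n_cg
  }
  expect_equal(total_cg, 1000L)
  # recorded CpG positions point at a C followed by a G
  chars <- strsplit(sim$sequence, "")[[1]]
  expect_true(all(chars[sim$cpg_sites$pos + 1L] == "C"))
  expect_true(all(chars[sim$cpg_sites$pos + 2L] == "G"))
  # nothing CpG outside the regions
  expect_equal(Biostrings::countPattern("CG", seq), 1000L)
})

test_that("control regions are appended fully methylated with a WM table", {
  cfg <- sim_config(n_regions = 3, cpg_per_region = 20, n_control = 4,
                    control_wm = 0.95, methylation = 0.2, seed = 2)
  sim <- simulate_reference(cfg)
  ctrl <- sim$regions[sim$regions$kind == "control", ]
  expect_equal(nrow(ctrl), 4L)
  expect_true(all(ctrl$methylation == 1))
  expect_equal(sim$controls$wm, rep(0.95, 4))
  expect_equal(sim$controls$name, ctrl$name)
})

test_that("simulation is deterministic in the seed", {
  cfg <- sim_config(n_regions = 3, cpg_per_region = 30, coverage = 20, seed = 123)
  s1 <- simulate_reference(cfg)
  s2 <- simulate_reference(cfg)
  expect_identical(s1$sequence, s2$sequence)
  expect_identical(s1$cpg_sites, s2$cpg_sites)
  expect_identical(simulate_pileup_counts(s1), simulate_pileup_counts(s2))
  f1 <- withr::local_tempfile(fileext = ".sam")
  f2 <- withr::local_tempfile(fileext = ".sam")
  write_sam(simulate_sam_reads(s1), f1)
  write_sam(simulate_sam_reads(s2), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the observations
  s3 <- simulate_reference(sim_config(n_regions = 3, cpg_per_region = 30,
                                      coverage = 20, seed = 124))
  expect_false(identical(simulate_pileup_counts(s1)$error,
                         simulate_pileup_counts(s3)$error))
})

test_that("degenerate parameter settings behave as stated", {
  # zero methylation everywhere: no methylated site in the truth
  cfg0 <- sim_config(n_regions = 4, cpg_per_region = 50, methylation = 0, seed = 6)
  expect_equal(sum(simulate_reference(cfg0)$cpg_sites$status), 0L)
  # zero deamination and zero background: no transition anywhere
  cfgz <- sim_config(n_regions = 2, cpg_per_region = 50, methylation = 1,
                     deamination_rate = 0, background_rate = 0,
                     coverage = 50, seed = 8)
  simz <- simulate_reference(cfgz)
  expect_equal(sum(simulate_pileup_counts(simz)$error), 0L)
  samz <- simulate_sam_reads(simz)
  sitesz <- count_transitions(samz$records, simz$ref, counting_filters())
  expect_equal(sum(sitesz$error), 0L)
})

test_that("observed transition rates match the configured signal model", {
  # fully methylated, deep coverage: CpG rate ~ d within binomial error
  cfg <- sim_config(n_regions = 1, cpg_per_region = 100, methylation = 1,
                    coverage = 5000, seed = 21)
  sim <- simulate_reference(cfg)
  counts <- simulate_pileup_counts(sim)
  cpg <- counts[counts$context == "CpG", ]
  rate <- sum(cpg$error) / sum(cpg$total)
  se <- sqrt(0.01 * 0.99 / sum(cpg$total))
  expect_lt(abs(rate - (0.01 + 1e-5)), 3 * se)

  # per-region CpG rate tracks e + d * realized methylation (linearity)
  cfg2 <- sim_config(n_regions = 8, cpg_per_region = 100, coverage = 500, seed = 22)
  sim2 <- simulate_reference(cfg2)
  counts2 <- simulate_pileup_counts(sim2)
  agg <- aggregate_regions(counts2, sim2$regions, context = "CpG")
  realized <- as.numeric(tapply(sim2$cpg_sites$status, sim2$cpg_sites$region,
                                mean)[sim2$regions$name])
  pred <- 1e-5 + 0.01 * realized
  se2 <- sqrt(pmax(pred * (1 - pred), 1e-9) / agg$total)
  expect_true(all(abs(agg$rate - pred) < 4 * se2))

  # pooled non-CpG rate ~ background
  non <- counts2[counts2$context != "CpG", ]
  expect_lt(sum(non$error) / sum(non$total), 1e-4)
})

test_that("simulated read pairs are well-formed and overlap as configured", {
  cfg <- sim_config(n_regions = 2, cpg_per_region = 40, coverage = 20,
                    read_length = 100, fragment_length = 160, seed = 33)
  sim <- simulate_reference(cfg)
  sam <- simulate_sam_reads(sim)
  rec <- sam$records
  expect_setequal(unique(rec$flag), c(99L, 147L))
  expect_true(all(nchar(rec$seq) == 100L))
  expect_true(all(nchar(rec$qual) == 100L))
  expect_true(!is.unsorted(rec$pos0))
  # every mate pair overlaps by 2*read_length - fragment_length = 40 bases
  r1 <- rec[rec$flag == 99L, ]
  r2 <- rec[rec$flag == 147L, ]
  m <- match(r1$qname, r2$qname)
  expect_false(anyNA(m))
  expect_true(all(r2$pos0[m] - r1$pos0 == 60L))
})

test_that("planted SNPs create apparent transitions until masked", {
  cfg <- sim_config(n_regions = 2, cpg_per_region = 60, methylation = 0,
                    background_rate = 0, coverage = 60, snp_rate = 0.02,
                    seed = 44)
  sim <- simulate_reference(cfg)
  expect_gt(nrow(sim$snps), 0L)
  sam <- simulate_sam_reads(sim)
  no_mask <- count_transitions(sam$records, sim$ref, counting_filters())
  ct_snps <- sim$snps[sim$snps$ref == "C" & sim$snps$alt == "T", ]
  if (nrow(ct_snps) > 0L) {
    hit <- no_mask[no_mask$pos %in% ct_snps$pos, ]
    expect_true(all(hit$error == hit$total))  # homozygous C>T looks fully converted
  }
  masked <- count_transitions(sam$records, sim$ref,
    counting_filters(snp_mask = snp_mask(sim$snps$chrom, sim$snps$pos)))
  expect_length(intersect(masked$pos, sim$snps$pos), 0L)
  # with methylation 0 and no background, all remaining signal is SNP-driven
  expect_equal(sum(masked$error), 0L)
})

test_that("paired-condition simulation books its truth correctly", {
  cfg <- sim_config(n_regions = 10, cpg_per_region = 50, methylation = 0.2,
                    coverage = 30, seed = 55)
  # no shift: conditions identical in truth
  pc0 <- simulate_paired_conditions(cfg, dmr_fraction = 0, effect = 0.3)
  expect_false(any(pc0$truth$is_dmr))
  expect_equal(pc0$truth$meth_a, pc0$truth$meth_b)
  # full shift: 0.2 + 0.3 = 0.5 everywhere
  pc1 <- simulate_paired_conditions(cfg, dmr_fraction = 1, effect = 0.3)
  expect_true(all(pc1$truth$is_dmr))
  expect_equal(pc1$truth$meth_a, rep(0.5, 10))
  expect_length(pc1$cond_a, 3L)
  expect_length(pc1$cond_b, 3L)
  # labels match the regions actually shifted
  pc2 <- simulate_paired_conditions(cfg, dmr_fraction = 0.4, effect = 0.3)
  expect_equal(sum(pc2$truth$is_dmr), 4L)
  expect_equal(pc2$truth$meth_a != pc2$truth$meth_b, pc2$truth$is_dmr)
  # clipping is warned about and recorded
  cfg_hi <- sim_config(n_regions = 5, cpg_per_region = 50, methylation = 0.9,
                       coverage = 30, seed = 56)
  expect_warning(pc3 <- simulate_paired_conditions(cfg_hi, dmr_fraction = 1,
                                                   effect = 0.3), "clipped")
  expect_true(all(pc3$truth$meth_a == 1))
  expect_true(all(pc3$truth$clipped))
})
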