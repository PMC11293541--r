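# ref: AAACGTTTT -> C at 0-based position 3, CpG context, upstream A;
#      the G of the CpG sits at position 4.
REF1 <- c(chr1 = "AAACGTTTT")

test_that("a single Read1 C-to-T observation is counted with its context", {
  rec <- make_rec(flag = 99L, pos0 = 0L, seq = "AAATGTTTT")  # T over the C, cycle 4/9
  s <- count_base_transitions(rec, REF1, counting_filters(), "C", "T", 1L)
  expect_equal(nrow(s), 1L)
  expect_equal(s$pos, 3L)
  expect_equal(s$strand, "+")
  expect_equal(s$context, "CpG")
  expect_equal(s$upstream, "A")
  expect_equal(s$error, 1L)
  expect_equal(s$total, 1L)

  # matching C increments total only
  rec_c <- make_rec(flag = 99L, pos0 = 0L, seq = "AAACGTTTT")
  s2 <- count_base_transitions(rec_c, REF1, counting_filters(), "C", "T", 1L)
  expect_equal(s2$error, 0L)
  expect_equal(s2$total, 1L)

  # a non-C/non-T read base is not cytosine-informative
  rec_g <- make_rec(flag = 99L, pos0 = 0L, seq = "AAAGGTTTT")
  expect_equal(nrow(count_base_transitions(rec_g, REF1, counting_filters(), "C", "T", 1L)), 0L)
})

test_that("base quality, mapping quality and cycle filters drop observations", {
  rec <- make_rec(flag = 99L, pos0 = 0L, seq = "AAATGTTTT")
  # BQ 20 ('5') at the observed base
  qual <- strrep("F", 9L); substr(qual, 4L, 4L) <- "5"
  rec_bq <- make_rec(flag = 99L, pos0 = 0L, seq = "AAATGTTTT", qual = qual)
  expect_equal(nrow(count_base_transitions(rec_bq, REF1, counting_filters(), "C", "T", 1L)), 0L)
  expect_equal(nrow(count_base_transitions(rec_bq, REF1,
    counting_filters(min_baseq = 20L), "C", "T", 1L)), 1L)

  # MAPQ below threshold
  rec_mq <- make_rec(flag = 99L, pos0 = 0L, mapq = 5L, seq = "AAATGTTTT")
  expect_equal(nrow(count_base_transitions(rec_mq, REF1, counting_filters(), "C", "T", 1L)), 0L)

  # observation on cycle 2 excluded by the head exclusion
  ref <- c(chr1 = "ACGTTTTTT")
  head_only <- counting_filters(exclude_cycles = c(2L, 0L))
  rec_cyc <- make_rec(flag = 99L, pos0 = 0L, seq = "ATGTTTTTT")  # C at qpos 2
  expect_equal(nrow(count_base_transitions(rec_cyc, ref, head_only, "C", "T", 1L)), 0L)
  s <- count_base_transitions(rec_cyc, ref,
    counting_filters(exclude_cycles = c(0L, 0L)), "C", "T", 1L)
  expect_equal(s$error, 1L)

  # for a reverse-strand alignment cycles count from the other end:
  # qpos 2 of a 9-mer is cycle 8, which a head-only exclusion keeps
  rec_rev <- make_rec(flag = 83L, pos0 = 0L, seq = "ATGTTTTTT")
  expect_equal(nrow(count_base_transitions(rec_rev, ref, head_only, "C", "T", 1L)), 1L)
})

test_that("Read2 counts G-to-A as the bottom-strand cytosine with CpG context", {
  rec <- make_rec(flag = 147L, pos0 = 0L, seq = "AAACATTTT")  # A over the G at pos 4
  s <- count_base_transitions(rec, REF1, counting_filters(), "G", "A", 2L)
  expect_equal(s$pos, 4L)
  expect_equal(s$strand, "-")
  expect_equal(s$context, "CpG")  # complement of the C at pos 3
  expect_equal(s$error, 1L)
  # upstream on the bottom strand: complement of the base at pos 5 (T) -> A
  expect_equal(s$upstream, "A")
})

test_that("contexts follow the reference neighbour on the cytosine strand", {
  ref <- c(chr1 = "AACATACTTACCTACNTAA")
  # C at 2 (next A -> CpA), C at 6 (next T -> CpT), C at 10 (next C -> CpC),
  # C at 11 (next T -> CpT), C at 14 (next N -> CpN)
  rec <- make_rec(flag = 99L, pos0 = 0L, seq = ref[[1]])
  s <- count_base_transitions(rec, ref, counting_filters(exclude_cycles = c(0L, 0L)),
                              "C", "T", 1L)
  got <- setNames(s$context, s$pos)
  expect_equal(unname(got[c("2", "6", "10", "11", "14")]),
               c("CpA", "CpT", "CpC", "CpT", "CpN"))
  # CpN sites never enter a CpG aggregate
  agg <- aggregate_regions(s, data.frame(chrom = "chr1", start = 0L, end = 19L,
                                         name = "all"), context = "CpG")
  expect_true(agg$uncovered)
})

test_that("SNP-masked positions are removed from counting, nothing else", {
  ref <- c(chr1 = "AACGAACGAA")  # CpG cytosines at 2 and 6
  rec <- make_rec(flag = 99L, pos0 = 0L, seq = "AATGAATGAA")
  flt_all <- counting_filters(exclude_cycles = c(0L, 0L))
  s_all <- count_base_transitions(rec, ref, flt_all, "C", "T", 1L)
  expect_setequal(s_all$pos, c(2L, 6L))
  flt_mask <- counting_filters(exclude_cycles = c(0L, 0L),
                               snp_mask = snp_mask("chr1", 2L))
  s_masked <- count_base_transitions(rec, ref, flt_mask, "C", "T", 1L)
  expect_equal(s_masked$pos, 6L)
  expect_equal(s_masked$error, s_all$error[s_all$pos == 6L])
})

test_that("bases adjacent to indels are skipped", {
  ref <- c(chr1 = "AAACGTTTT")
  # 4M1I4M: insertion after qpos 4 -> the C observation at qpos 4 is indel-adjacent
  rec <- make_rec(flag = 99L, pos0 = 0L, cigar = "4M1I4M", seq = "AAATGGTTT")
  flt <- counting_filters(exclude_cycles = c(0L, 0L))
  expect_equal(nrow(count_base_transitions(rec, ref, flt, "C", "T", 1L)), 0L)
})

test_that("raising quality thresholds never increases any total", {
  cfg <- sim_config(n_regions = 2, cpg_per_region = 30, coverage = 30, seed = 88)
  sim <- simulate_reference(cfg)
  sam <- simulate_sam_reads(sim, degrade_ends = TRUE)
  loose <- count_transitions(sam$records, sim$ref,
                             counting_filters(min_baseq = 0L, exclude_cycles = c(0L, 0L)))
  strict <- count_transitions(sam$records, sim$ref, counting_filters())
  expect_lt(sum(strict$total), sum(loose$total))
  key_l <- paste(loose$pos, loose$read)
  key_s <- paste(strict$pos, strict$read)
  common <- intersect(key_l, key_s)
  expect_true(all(strict$total[match(common, key_s)] <=
                  loose$total[match(common, key_l)]))
})

test_that("regional aggregation sums sites and conserves counts over partitions", {
  sites <- data.frame(chrom = "chr1", pos = c(10L, 20L, 40L), strand = "+",
                      context = "CpG", upstream = "A", read = 1L,
                      error = c(1L, 2L, 7L), total = c(100L, 100L, 50L),
                      stringsAsFactors = FALSE)
  reg <- data.frame(chrom = "chr1", start = c(0L, 30L), end = c(30L, 60L),
                    name = c("a", "b"), stringsAsFactors = FALSE)
  agg <- aggregate_regions(sites, reg, context = "CpG")
  expect_equal(agg$error, c(3L, 7L))
  expect_equal(agg$total, c(200L, 50L))
  expect_equal(agg$rate, c(0.015, 0.14))
  expect_equal(agg$n_sites, c(2L, 1L))

  # empty region: uncovered flag, undefined rate
  empty <- aggregate_regions(sites, data.frame(chrom = "chr1", start = 500L,
                                               end = 600L, name = "e"))
  expect_true(empty$uncovered)
  expect_true(is.na(empty$rate))

  # whole-chromosome region equals the column sums
  whole <- aggregate_regions(sites, data.frame(chrom = "chr1", start = 0L,
                                               end = 1000L, name = "w"))
  expect_equal(whole$error, sum(sites$error))
  expect_equal(whole$total, sum(sites$total))
  # partition conservation
  expect_equal(sum(agg$error), whole$error)
  expect_equal(sum(agg$total), whole$total)
})

test_that("imbalance isolates the deamination signal from shared error", {
  # identical channels -> zero imbalance everywhere
  tab <- data.frame(chrom = "c", pos = 1:4, strand = "+",
                    context = c("CpG", "CpG", "CpA", "CpT"), upstream = "A",
                    read = 1L, error = c(5L, 3L, 1L, 0L), total = 100L,
                    stringsAsFactors = FALSE)
  tab2 <- tab; tab2$read <- 2L
  imb <- compute_imbalance(tab, tab2, by = "context")
  expect_true(all(imb$imbalance == 0))

  # a cell absent from one channel is reported missing
  imb2 <- compute_imbalance(tab, tab2[tab2$context != "CpA", ], by = "context")
  expect_true(is.na(imb2$imbalance[imb2$context == "CpA"]))

  # simulated: CpG imbalance tracks the deamination rate, other contexts ~0,
  # and an equal background shift in both channels cancels out
  for (e_bg in c(1e-5, 5e-3)) {
    cfg <- sim_config(n_regions = 2, cpg_per_region = 100, methylation = 1,
                      coverage = 2000, background_rate = e_bg, seed = 31)
    sim <- simulate_reference(cfg)
    counts <- simulate_pileup_counts(sim, channels = c("signal", "background"))
    r1 <- counts[counts$read == 1L & counts$strand == "+", ]
    r2 <- counts[counts$read == 2L & counts$strand == "+", ]
    imb <- compute_imbalance(r1, r2, by = "context")
    cpg <- imb$imbalance[imb$context == "CpG"]
    expect_lt(abs(cpg - 0.01), 2e-3)
    expect_true(all(abs(imb$imbalance[imb$context != "CpG"]) < 2e-3))
  }
})
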