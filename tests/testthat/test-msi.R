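# Microsatellite scanner, intraread lengths, KS test, FDR, MSI calling.

test_that("scanner enforces the 7-60 bp tract and 1-4 bp unit bounds", {
  expect_equal(nrow(find_microsatellites(c(s = "AAAAAA"))), 0L)   # 6 bp
  one <- find_microsatellites(c(s = "AAAAAAA"))                   # 7 bp
  expect_equal(nrow(one), 1L)
  expect_equal(one$unit, "A")
  expect_equal(one$tract_length, 7L)
  expect_equal(c(one$start, one$end), c(0L, 7L))
  # 60 bp retained, 61 bp discarded (not truncated)
  expect_equal(find_microsatellites(c(s = strrep("A", 60)))$tract_length, 60L)
  expect_equal(nrow(find_microsatellites(c(s = strrep("A", 61)))), 0L)
  expect_error(find_microsatellites(c(s = "ACGTQ")), "outside")
})

test_that("scanner reports maximal tracts with canonical smallest units", {
  loci <- find_microsatellites(c(s = "GACACACACAT"))
  expect_equal(nrow(loci), 1L)
  expect_equal(loci$unit, "AC")       # minimal rotation of "CA"/"AC"
  expect_equal(loci$start, 1L)
  expect_equal(loci$end, 10L)         # 9 bp tract ACACACACA, partial unit in
  expect_equal(loci$tract_length, 9L)
  # a poly-A run is never also reported at period 2 ("AA")
  polya <- find_microsatellites(c(s = "GGAAAAAAAAGG"))
  expect_equal(polya$unit, "A")
  expect_equal(nrow(polya), 1L)
  # N breaks tracts
  expect_equal(nrow(find_microsatellites(c(s = "AAAANAAAA"))), 0L)
  split <- find_microsatellites(c(s = "AAAAAAAANAAAAAAA"))
  expect_equal(nrow(split), 2L)
})

test_that("scanner agrees with the exhaustive period-scan oracle", {
  set.seed(77)
  for (i in 1:60) {
    sq <- paste(sample(c("A", "C", "G", "T"), 400, replace = TRUE),
                collapse = "")
    imp <- find_microsatellites(c(s = sq))
    ora <- oracle_msat(sq)
    expect_equal(imp$start, ora$start, label = paste("starts, seq", i))
    expect_equal(imp$end, ora$end, label = paste("ends, seq", i))
    expect_equal(imp$unit, ora$unit, label = paste("units, seq", i))
  }
})

test_that("intraread lengths track indels and require spanning reads", {
  ref <- paste0("GGTCG", strrep("CA", 8), "TTGCA")
  loci <- find_microsatellites(setNames(ref, "chr1"))
  expect_equal(loci$tract_length, 16L)
  reads <- rbind(
    make_spanning_read("normal", "CA", 8),            # matches reference
    make_spanning_read("normal", "CA", 8, delta = -2), # two units deleted
    data.frame(sample = "normal", sequence = substr(ref, 1, 12),
               mapped_start = 0L)                      # does not span
  )
  dist <- extract_intraread_lengths(reads, loci, min_flank = 5)
  expect_equal(nrow(dist), 2L)
  expect_setequal(dist$length, c(16L, 12L))
  expect_equal(attr(dist, "skipped"), 1L)
})

test_that("KS statistic is the sup-CDF distance with asymptotic p", {
  same <- ks_two_sample(c(1, 2, 2, 3), c(1, 2, 2, 3))
  expect_equal(same$D, 0)
  expect_equal(same$p, 1)
  disj <- ks_two_sample(c(1, 2, 3), c(4, 5, 6))
  expect_equal(disj$D, 1)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")

  # agreement with the reference implementation on random tied multisets
  set.seed(55)
  for (i in 1:40) {
    x <- sample(10:20, sample(5:40, 1), replace = TRUE)
    y <- sample(10:22, sample(5:40, 1), replace = TRUE)
    ours <- ks_two_sample(x, y)
    ref <- suppressWarnings(stats::ks.test(x, y, exact = FALSE))
    expect_equal(ours$D, unname(ref$statistic), tolerance = 1e-12)
    # the reference truncates the Kolmogorov series at a coarser tolerance
    expect_equal(ours$p, ref$p.value, tolerance = 1e-3)
  }
})

test_that("KS D is symmetric and shift-invariant; tiny-n p is conservative", {
  set.seed(66)
  for (i in 1:20) {
    x <- sample(5:15, 12, replace = TRUE)
    y <- sample(5:15, 9, replace = TRUE)
    expect_equal(ks_two_sample(x, y)$D, ks_two_sample(y, x)$D)
    expect_equal(ks_two_sample(x + 7, y + 7)$D, ks_two_sample(x, y)$D)
  }
  # exact permutation p for D = 1 with |x|=|y|=2 is 2/6
  expect_equal(oracle_ks_perm_p(c(1, 2), c(3, 4)), 1 / 3)
  # the asymptotic p at this tiny n is smaller (anticonservative there),
  # which is why call_msi enforces a minimum read count
  expect_lt(ks_two_sample(c(1, 2), c(3, 4))$p, 1 / 3)
})

test_that("BH step-up matches the hand-computed adjustment", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.5), 0.5)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(88)
  p <- runif(50)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))  # monotone on sorted p
})

test_that("call_msi skips shallow loci and controls the null", {
  sim <- simulate_msi_observations(msi_simulation_config(
    n_null_loci = 150, n_msi_loci = 0, reads_per_locus = 50,
    stutter_prob = 0.1, seed = 41L))
  # thin one locus below min_reads in the normal
  thin <- sim$lengths
  drop <- which(thin$locus_id == "ms0001" & thin$sample == "normal")[1:45]
  thin <- thin[-drop, ]
  calls <- call_msi(thin)
  expect_false("ms0001" %in% calls$locus_id)
  expect_true("ms0001" %in% attr(calls, "skipped_loci"))
  expect_equal(nrow(calls), 149L)
  # global null: no locus reaches q < 0.05 here
  expect_lt(mean(calls$is_msi), 0.05)
})

test_that("call_msi detects shifted loci with high power", {
  sim <- simulate_msi_observations(msi_simulation_config(
    n_null_loci = 100, n_msi_loci = 20, reads_per_locus = 50,
    stutter_prob = 0.1, msi_shift = -3L, seed = 42L))
  calls <- call_msi(sim$lengths)
  truth <- sim$truth$is_msi[match(calls$locus_id, sim$truth$locus_id)]
  expect_gte(mean(calls$is_msi[truth]), 0.8)
  if (sum(calls$is_msi)) expect_lte(mean(!truth[calls$is_msi]), 0.1)
})

test_that("indel reconciliation flags overlaps and conserves counts", {
  loci <- data.frame(locus_id = c("L1", "L2"), seq_id = c("1", "1"),
                     start = c(95L, 400L), end = c(110L, 420L))
  calls <- data.frame(locus_id = c("L1", "L2"), comparison = "carcinoma_vs_normal",
                      n_tumor = 50L, n_normal = 50L, D = c(0.6, 0.5),
                      p = c(1e-6, 1e-5), q = c(2e-6, 1e-5),
                      is_msi = c(TRUE, TRUE), overlaps_indel = NA)
  indels <- make_variants(
    make_variant(chrom = "1", pos = 101L, ref = "CAA", alt = "C"),
    make_variant(chrom = "1", pos = 200L, ref = "CA", alt = "C"),
    make_variant(chrom = "2", pos = 405L, ref = "GT", alt = "G"))
  rec <- reconcile_with_indels(calls, indels, loci)
  expect_equal(rec$overlaps_indel, c(TRUE, FALSE))  # chr2 indel never counts
  retained <- rec[!rec$overlaps_indel, ]
  expect_equal(nrow(retained), nrow(rec) - sum(rec$overlaps_indel))
  expect_lte(nrow(retained), nrow(calls))
})
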