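# Fisher enrichment, truncating recurrence, trunk-branch trees, reports.

test_that("fisher p matches hand-enumerated tables", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2)), 0.1)
  expect_error(fisher_exact_2x2(c(-1, 2, 3, 4)), "non-negative")
})

test_that("fisher p equals the margin-enumeration oracle", {
  # exhaustive over all tables with total n <= 12
  for (n in 0:12) {
    for (a in 0:n) for (b in 0:(n - a)) for (cc in 0:(n - a - b)) {
      d <- n - a - b - cc
      expect_equal(fisher_exact_2x2(c(a, cc, b, d)),
                   oracle_fisher(a, b, cc, d), tolerance = 1e-9,
                   label = sprintf("table (%d,%d;%d,%d)", a, b, cc, d))
    }
  }
  # randomized larger tables with margins <= 30
  set.seed(30)
  for (i in 1:200) {
    repeat {
      t4 <- rpois(4, 6)
      if (max(t4[1] + t4[2], t4[3] + t4[4], t4[1] + t4[3],
              t4[2] + t4[4]) <= 30) break
    }
    expect_equal(fisher_exact_2x2(matrix(t4, 2)),
                 oracle_fisher(t4[1], t4[3], t4[2], t4[4]),
                 tolerance = 1e-9)
  }
})

test_that("class enrichment builds the pooled 2x2 per gene and direction", {
  v <- do.call(rbind, c(
    lapply(1:4, function(i) make_variant(id = sprintf("g%d", i), gene = "APC")),
    lapply(1:10, function(i) make_variant(id = sprintf("bc%d", i),
                                          gene = sprintf("BG%02d", i))),
    lapply(1:30, function(i) make_variant(id = sprintf("bl%d", i),
                                          gene = sprintf("BH%02d", i),
                                          adenoma = c(60L, 0L)))
  ))
  cls <- classify_regional(v)
  res <- class_enrichment(v, cls, min_mutations = 2)
  apc <- res[res$gene == "APC" & res$direction == "clonal", ]
  expect_equal(unlist(apc[c("gene_in", "gene_out", "other_in", "other_out")],
                      use.names = FALSE), c(4L, 0L, 10L, 30L))
  expect_equal(apc$p, fisher_exact_2x2(c(4, 0, 10, 30)))
  expect_equal(res$p[1], min(res$p))  # sorted by p
  # silent mutations are excluded
  v_sil <- v
  v_sil$consequence <- "silent"
  expect_equal(nrow(class_enrichment(v_sil, classify_regional(v_sil))), 0L)
})

test_that("direction swap flips labels but preserves p", {
  v <- do.call(rbind, c(
    lapply(1:4, function(i) make_variant(id = sprintf("g%d", i), gene = "G1")),
    lapply(1:12, function(i) make_variant(id = sprintf("b%d", i),
                                          gene = "BG",
                                          adenoma = c(60L, 0L)))
  ))
  cls <- classify_regional(v)
  # swap lesion roles: adenoma counts <-> carcinoma counts
  v_sw <- v
  v_sw[c("ref_adenoma", "alt_adenoma", "ref_carcinoma", "alt_carcinoma")] <-
    v[c("ref_carcinoma", "alt_carcinoma", "ref_adenoma", "alt_adenoma")]
  cls_sw <- classify_regional(v_sw)
  r <- class_enrichment(v, cls)
  r_sw <- class_enrichment(v_sw, cls_sw)
  g1_clonal <- function(x) x$p[x$gene == "G1" & x$direction == "clonal"]
  expect_equal(g1_clonal(r), g1_clonal(r_sw))
  carc <- r_sw[r_sw$gene == "BG" & r_sw$direction == "carcinoma_specific", ]
  aden <- r[r$gene == "BG" & r$direction == "adenoma_specific", ]
  expect_equal(carc$p, aden$p)
})

test_that("truncating recurrence counts nonsense/frameshift per class", {
  v <- do.call(rbind, c(
    lapply(1:3, function(i) make_variant(id = sprintf("t%d", i),
                                         gene = "ACVR2A",
                                         consequence = "frameshift",
                                         ref = "CA", alt = "C")),
    lapply(1:2, function(i) make_variant(id = sprintf("u%d", i), gene = "MX1",
                                         consequence = "nonsense")),
    lapply(1:5, function(i) make_variant(id = sprintf("m%d", i), gene = "MX1",
                                         consequence = "missense"))
  ))
  cls <- classify_regional(v)
  hits <- truncating_recurrence(v, cls, min_events = 3)
  expect_equal(hits$gene, "ACVR2A")
  expect_equal(hits$class, "clonal")
  expect_equal(hits$n_truncating, 3L)
  # missense never counts; min_events = 1 reports every truncated gene
  all1 <- truncating_recurrence(v, cls, min_events = 1)
  expect_setequal(all1$gene, c("ACVR2A", "MX1"))
  expect_equal(all1$n_truncating[all1$gene == "MX1"], 2L)
})

test_that("trunk-branch tree conserves counts and emits valid Newick", {
  sim <- simulate_lesion_pair(simulation_config("parallel", seed = 51L))
  cls <- classify_regional(sim$variants)
  tree <- build_trunk_branch_tree(sim$variants, cls,
                                  driver_genes = c("GENE001", "GENE002"))
  tab <- summarize_abundance(sim$variants, cls)
  expect_equal(tree$trunk_count, sum(tab["clonal", ]))
  expect_equal(tree$adenoma_branch_count, sum(tab["adenoma_specific", ]))
  expect_equal(tree$carcinoma_branch_count, sum(tab["carcinoma_specific", ]))
  expect_match(tree$newick, "^\\(\\(Adenoma:\\d+,Carcinoma:\\d+\\)LCA:\\d+\\)Normal;$")
  ph <- ape::read.tree(text = tree$newick)
  expect_setequal(ph$tip.label, c("Adenoma", "Carcinoma"))
  expect_equal(sort(ph$edge.length),
               sort(c(tree$trunk_count, tree$adenoma_branch_count,
                      tree$carcinoma_branch_count)))
})

test_that("tree handles zero-length branches and known counts", {
  v <- do.call(rbind, lapply(1:7, function(i)
    make_variant(id = sprintf("c%d", i))))
  tree <- build_trunk_branch_tree(v)
  expect_equal(tree$trunk_count, 7L)
  expect_equal(tree$adenoma_branch_count, 0L)
  expect_equal(tree$newick, "((Adenoma:0,Carcinoma:0)LCA:7)Normal;")
})

test_that("copy-number events land on the matching tree edge", {
  seg <- function(chrom, start, end, call)
    data.frame(chrom = chrom, start = start, end = end, mean_log2 = 0.6,
               n_bins = 10L, call = call)
  aden <- rbind(seg("chr5", 0, 100, "gain"), seg("chr8", 0, 100, "loss"))
  carc <- rbind(seg("chr5", 50, 150, "gain"), seg("chr12", 0, 100, "gain"))
  tree <- build_trunk_branch_tree(make_variant(), "clonal",
                                  segments = list(adenoma = aden,
                                                  carcinoma = carc))
  ev <- tree$segment_events
  expect_equal(ev$branch[grepl("chr5", ev$event)], "clonal")
  expect_equal(ev$branch[grepl("chr8", ev$event)], "adenoma_specific")
  expect_equal(ev$branch[grepl("chr12", ev$event)], "carcinoma_specific")
})

test_that("report bundles the stages and is reproducible", {
  sim <- simulate_lesion_pair(simulation_config("parallel", seed = 61L))
  cls <- classify_regional(sim$variants)
  arch <- clonal_architecture(sim$variants)
  msim <- simulate_msi_observations(msi_simulation_config(
    n_null_loci = 30, n_msi_loci = 5, reads_per_locus = 30, seed = 62L))
  calls <- call_msi(msim$lengths)
  tree <- build_trunk_branch_tree(sim$variants, cls)
  dir <- withr::local_tempdir()
  rep1 <- make_report("case1", variants = sim$variants, classes = cls,
                      architecture = arch, msi_calls = calls, tree = tree,
                      dir = dir)
  expect_equal(rep1$verdict, "parallel")
  expect_equal(rep1$tree$trunk + rep1$tree$adenoma + rep1$tree$carcinoma,
               sum(rep1$abundance[c("clonal", "adenoma_specific",
                                    "carcinoma_specific"), ]))
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "abundance.tsv")))
  # rerun identical apart from the timestamp
  rep2 <- make_report("case1", variants = sim$variants, classes = cls,
                      architecture = arch, msi_calls = calls, tree = tree)
  rep1$timestamp <- rep2$timestamp <- NULL
  expect_equal(rep1, rep2)
  # empty skeleton still valid
  empty <- make_report("empty")
  expect_s3_class(empty, "synclone_report")
  expect_setequal(empty$missing_stages,
                  c("variants", "architecture", "msi", "segments",
                    "enrichment", "tree"))
})
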