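# Class-specific gene enrichment, the truncating-recurrence rule for
# hypermutated genomes, and trunk-branch evolutionary trees.

.NONSILENT <- c("missense", "nonsense", "frameshift", "splice")
.TRUNCATING <- c("nonsense", "frameshift")

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Two-sided p = sum of the hypergeometric probabilities, over all tables
#' with the observed margins, that do not exceed the observed table's
#' probability (within a small relative tolerance). Delegates to
#' [stats::fisher.test()].
#'
#' @param table 2x2 matrix (or length-4 vector, filled by column) of
#'   non-negative integers.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact_2x2(matrix(c(3, 0, 0, 3), 2))  # 0.1
#' @export
fisher_exact_2x2 <- function(table) {
  m <- matrix(as.numeric(table), 2L, 2L)
  if (any(!is.finite(m)) || any(m < 0) || any(m != round(m)))
    stop("the 2x2 table must hold non-negative integers", call. = FALSE)
  fisher.test(matrix(as.integer(m), 2L, 2L))$p.value
}

#' Class-specific gene enrichment by Fisher exact tests
#'
#' For each gene and each regional direction (clonal, adenoma-specific,
#' carcinoma-specific), tests whether the gene's nonsilent mutations
#' (missense, nonsense, frameshift, splice) concentrate in that class:
#' the 2x2 table is (mutations in the gene vs in all other genes) x (in the
#' direction's class vs in the other classes), pooled across cases. P-values
#' are reported raw, without multiple-testing correction.
#'
#' @param variants A variant data frame (variants classified `absent` are
#'   excluded, as are silent/other consequences and empty gene symbols).
#' @param classes Regional classes per variant, as from [classify_regional()].
#' @param min_mutations Genes with fewer nonsilent mutations are skipped
#'   (default 2; a single mutation cannot be enriched).
#' @return Data frame sorted by p: `gene`, `direction`,
#'   `gene_in`, `gene_out`, `other_in`, `other_out`, `p`.
#' @export
class_enrichment <- function(variants, classes = classify_regional(variants),
                             min_mutations = 2L) {
  variants <- suppressWarnings(.validate_variants(variants))
  keep <- variants$consequence %in% .NONSILENT & variants$gene != "" &
    classes != "absent"
  v <- variants[keep, , drop = FALSE]
  cl <- classes[keep]
  if (!nrow(v))
    return(data.frame(gene = character(0), direction = character(0),
                      gene_in = integer(0), gene_out = integer(0),
                      other_in = integer(0), other_out = integer(0),
                      p = numeric(0), stringsAsFactors = FALSE))
  genes <- names(which(table(v$gene) >= min_mutations))
  directions <- c("clonal", "adenoma_specific", "carcinoma_specific")
  rows <- lapply(genes, function(g) {
    in_gene <- v$gene == g
    do.call(rbind, lapply(directions, function(d) {
      a <- sum(in_gene & cl == d)
      b <- sum(in_gene & cl != d)
      cc <- sum(!in_gene & cl == d)
      dd <- sum(!in_gene & cl != d)
      data.frame(gene = g, direction = d, gene_in = a, gene_out = b,
                 other_in = cc, other_out = dd,
                 p = fisher_exact_2x2(c(a, b, cc, dd)),
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, rows)
  res <- res[order(res$p, res$gene, res$direction), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Genes with recurrent truncating events per regional class
#'
#' In hypermutated (microsatellite-unstable) genomes, Fisher tests on raw
#' counts lose power against the mutation flood; instead, genes carrying at
#' least `min_events` truncating events (nonsense or frameshift, including
#' MSI-derived frameshifts) within one regional class are reported.
#'
#' @param variants A variant data frame.
#' @param classes Regional classes per variant.
#' @param min_events Minimum truncating events (default 3).
#' @return Data frame `gene`, `class`, `n_truncating`.
#' @export
truncating_recurrence <- function(variants,
                                  classes = classify_regional(variants),
                                  min_events = 3L) {
  stopifnot(min_events >= 1L)
  variants <- suppressWarnings(.validate_variants(variants))
  keep <- variants$consequence %in% .TRUNCATING & variants$gene != "" &
    classes != "absent"
  v <- variants[keep, , drop = FALSE]
  cl <- classes[keep]
  if (!nrow(v))
    return(data.frame(gene = character(0), class = character(0),
                      n_truncating = integer(0), stringsAsFactors = FALSE))
  tab <- as.data.frame(table(gene = v$gene, class = cl),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq >= min_events, , drop = FALSE]
  res <- data.frame(gene = tab$gene, class = tab$class,
                    n_truncating = as.integer(tab$Freq),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$n_truncating, res$gene), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Pair per-lesion copy-number events: a non-neutral segment called in both
# lesions (overlapping, same call) is a clonal event, otherwise
# lesion-specific.
.segment_events <- function(adenoma, carcinoma) {
  ev <- function(seg) sprintf("%s:%d-%d %s", seg$chrom, seg$start, seg$end,
                              seg$call)
  a <- adenoma[adenoma$call != "neutral", , drop = FALSE]
  c_ <- carcinoma[carcinoma$call != "neutral", , drop = FALSE]
  if (nrow(a)) a$event <- ev(a)
  if (nrow(c_)) c_$event <- ev(c_)
  matched_c <- logical(nrow(c_))
  branch <- character(0)
  event <- character(0)
  for (i in seq_len(nrow(a))) {
    hit <- which(c_$chrom == a$chrom[i] & c_$call == a$call[i] &
                   c_$start < a$end[i] & a$start[i] < c_$end[i])
    if (length(hit)) {
      matched_c[hit[1L]] <- TRUE
      branch <- c(branch, "clonal")
    } else {
      branch <- c(branch, "adenoma_specific")
    }
    event <- c(event, a$event[i])
  }
  if (any(!matched_c)) {
    branch <- c(branch, rep("carcinoma_specific", sum(!matched_c)))
    event <- c(event, c_$event[!matched_c])
  }
  data.frame(event = event, branch = branch, stringsAsFactors = FALSE)
}

#' Trunk-branch evolutionary tree of a lesion pair
#'
#' A two-lesion phylogeny: the trunk carries the clonal mutations, the two
#' branches the adenoma- and carcinoma-specific mutations; edge lengths are
#' the variant counts per class. Nonsilent mutations in `driver_genes` are
#' annotated on their class's edge; per-lesion copy-number events (non-neutral
#' segments) land on the trunk when called in both lesions, else on the
#' lesion's branch.
#'
#' @param variants A variant data frame.
#' @param classes Regional classes per variant.
#' @param driver_genes Optional character vector of genes to annotate.
#' @param segments Optional named list
#'   `list(adenoma = <copy_segments>, carcinoma = <copy_segments>)`.
#' @return Object of class `trunk_branch_tree`: list with `trunk_count`,
#'   `adenoma_branch_count`, `carcinoma_branch_count`, `annotations` (data
#'   frame `gene`, `consequence`, `branch`), `segment_events`, and `newick`
#'   (e.g. `"((Adenoma:40,Carcinoma:60)LCA:120)Normal;"`).
#' @examples
#' sim <- simulate_lesion_pair(simulation_config(seed = 6))
#' tree <- build_trunk_branch_tree(sim$variants)
#' cat(tree$newick, "\n")
#' @export
build_trunk_branch_tree <- function(variants,
                                    classes = classify_regional(variants),
                                    driver_genes = NULL, segments = NULL) {
  variants <- suppressWarnings(.validate_variants(variants))
  counts <- summarize_abundance(variants, classes)
  trunk <- sum(counts["clonal", ])
  aden <- sum(counts["adenoma_specific", ])
  carc <- sum(counts["carcinoma_specific", ])
  ann <- if (!is.null(driver_genes)) {
    keep <- variants$gene %in% driver_genes &
      variants$consequence %in% .NONSILENT & classes != "absent"
    data.frame(gene = variants$gene[keep],
               consequence = variants$consequence[keep],
               branch = classes[keep], stringsAsFactors = FALSE)
  } else {
    data.frame(gene = character(0), consequence = character(0),
               branch = character(0), stringsAsFactors = FALSE)
  }
  seg_ev <- if (!is.null(segments)) {
    .segment_events(segments$adenoma, segments$carcinoma)
  } else {
    data.frame(event = character(0), branch = character(0),
               stringsAsFactors = FALSE)
  }
  structure(list(
    trunk_count = trunk,
    adenoma_branch_count = aden,
    carcinoma_branch_count = carc,
    annotations = ann,
    segment_events = seg_ev,
    newick = sprintf("((Adenoma:%d,Carcinoma:%d)LCA:%d)Normal;",
                     aden, carc, trunk)
  ), class = "trunk_branch_tree")
}

#' @export
print.trunk_branch_tree <- function(x, ...) {
  cat("Trunk-branch tree\n")
  cat(sprintf("  trunk (clonal): %d   adenoma branch: %d   carcinoma branch: %d\n",
              x$trunk_count, x$adenoma_branch_count, x$carcinoma_branch_count))
  cat("  newick:", x$newick, "\n")
  if (nrow(x$annotations)) {
    cat("  driver annotations:\n")
    print(x$annotations, row.names = FALSE)
  }
  if (nrow(x$segment_events)) {
    cat("  copy-number events:\n")
    print(x$segment_events, row.names = FALSE)
  }
  invisible(x)
}

#' Assemble a per-case report bundle
#'
#' Collects whatever stages were run into one structure: regional abundance
#' table, clonal-architecture verdict and clusters, MSI call summary, copy
#' segment table, enrichment tables, and the trunk-branch tree. Missing
#' stages are noted, not fatal. With `dir` set, writes `report.json` plus one
#' TSV per table; reruns on the same inputs are identical apart from the
#' `timestamp` field.
#'
#' @param case_id Case label.
#' @param variants,classes Variant table and regional classes.
#' @param architecture A `clonal_architecture` object.
#' @param msi_calls An `msi_calls` data frame (or a list of them, one per
#'   comparison).
#' @param segments A `copy_segments` data frame.
#' @param enrichment Output of [class_enrichment()].
#' @param tree A `trunk_branch_tree`.
#' @param dir Optional output directory.
#' @return A list of class `synclone_report`.
#' @export
make_report <- function(case_id = "case", variants = NULL, classes = NULL,
                        architecture = NULL, msi_calls = NULL,
                        segments = NULL, enrichment = NULL, tree = NULL,
                        dir = NULL) {
  report <- list(case_id = case_id, timestamp = format(Sys.time(), tz = "UTC"))
  missing_stages <- character(0)

  if (!is.null(variants)) {
    if (is.null(classes)) classes <- classify_regional(variants)
    report$abundance <- summarize_abundance(variants, classes)
  } else missing_stages <- c(missing_stages, "variants")

  if (!is.null(architecture)) {
    report$verdict <- architecture$verdict
    report$purity <- architecture$purity
    report$clusters <- architecture$clusters
    report$n_outliers <- length(architecture$outlier_ids)
  } else missing_stages <- c(missing_stages, "architecture")

  if (!is.null(msi_calls)) {
    if (is.data.frame(msi_calls)) msi_calls <- list(msi_calls)
    report$msi <- do.call(rbind, lapply(msi_calls, function(m) {
      data.frame(comparison = m$comparison[1L], n_tested = nrow(m),
                 n_msi = sum(m$is_msi),
                 n_retained = sum(m$is_msi &
                                    (is.na(m$overlaps_indel) |
                                       !m$overlaps_indel)),
                 stringsAsFactors = FALSE)
    }))
    report$msi_calls <- msi_calls
  } else missing_stages <- c(missing_stages, "msi")

  if (!is.null(segments)) report$segments <- segments
  else missing_stages <- c(missing_stages, "segments")

  if (!is.null(enrichment)) report$enrichment <- enrichment
  else missing_stages <- c(missing_stages, "enrichment")

  if (!is.null(tree)) {
    report$tree <- list(trunk = tree$trunk_count,
                        adenoma = tree$adenoma_branch_count,
                        carcinoma = tree$carcinoma_branch_count,
                        newick = tree$newick)
  } else missing_stages <- c(missing_stages, "tree")

  report$missing_stages <- missing_stages
  class(report) <- "synclone_report"

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    json <- report
    json$abundance <- if (!is.null(report$abundance))
      as.data.frame.table(report$abundance, responseName = "count")
    json$msi_calls <- NULL
    class(json) <- NULL
    jsonlite::write_json(json, file.path(dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    wt <- function(x, name) {
      if (!is.null(x) && nrow(x))
        write.table(x, file.path(dir, name), sep = "\t", quote = FALSE,
                    row.names = FALSE)
    }
    if (!is.null(report$abundance))
      wt(as.data.frame.table(report$abundance, responseName = "count"),
         "abundance.tsv")
    wt(report$clusters, "clusters.tsv")
    if (!is.null(msi_calls))
      wt(do.call(rbind, lapply(msi_calls, as.data.frame)), "msi_calls.tsv")
    wt(report$segments, "segments.tsv")
    wt(report$enrichment, "enrichment.tsv")
    if (!is.null(tree))
      writeLines(tree$newick, file.path(dir, "tree.nwk"))
  }
  report
}

#' @export
print.synclone_report <- function(x, ...) {
  cat(sprintf("Report for %s\n", x$case_id))
  if (!is.null(x$verdict)) cat("  verdict:", x$verdict, "\n")
  if (!is.null(x$abundance)) {
    cat("  abundance:\n")
    print(x$abundance)
  }
  if (!is.null(x$msi)) {
    cat("  MSI:\n")
    print(x$msi, row.names = FALSE)
  }
  if (!is.null(x$tree))
    cat("  tree:", x$tree$newick, "\n")
  if (length(x$missing_stages))
    cat("  stages not provided:", paste(x$missing_stages, collapse = ", "),
        "\n")
  invisible(x)
}
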