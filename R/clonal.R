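# Clonal architecture from paired mutant allele frequencies.
#
# Under copy-neutral heterozygosity, a mutation with cancer-cell fraction c in
# a lesion of purity rho has expected MAF rho * c / 2, so the per-lesion
# clonal reference is m* = rho / 2. Clusters of (MAF adenoma, MAF carcinoma)
# points therefore sit near interpretable anchors: (m*A, m*C) for clonal
# mutations, (m*A, 0) / (0, m*C) for lesion-specific ones, and — the stepwise
# signature — subclonal in the adenoma but clonal in the carcinoma.

#' Select the MAF point set used for clustering
#'
#' Clustering input is restricted to autosomal SNVs (haploid sex chromosomes
#' would halve the expected MAF) and, when a copy-number segmentation is
#' supplied, to variants inside segments called `neutral` (so no copy-number
#' correction of MAF is needed). Without a segmentation all autosomal SNVs are
#' used.
#'
#' @param variants A variant data frame.
#' @param segments Optional segment data frame (`chrom`, `start`, `end`,
#'   `call`) as from [call_segments()]; 0-based half-open coordinates.
#' @return Data frame `variant_id`, `maf_adenoma`, `maf_carcinoma`.
#' @export
select_clustering_input <- function(variants, segments = NULL) {
  variants <- suppressWarnings(.validate_variants(variants))
  keep <- variants$kind == "SNV" & .is_autosome(variants$chrom)
  variants <- variants[keep, , drop = FALSE]
  if (!is.null(segments)) {
    neutral <- segments[segments$call == "neutral", , drop = FALSE]
    pos0 <- variants$pos - 1L  # to 0-based for half-open interval tests
    in_neutral <- vapply(seq_len(nrow(variants)), function(i) {
      any(neutral$chrom == variants$chrom[i] &
            neutral$start <= pos0[i] & pos0[i] < neutral$end)
    }, logical(1L))
    variants <- variants[in_neutral, , drop = FALSE]
  }
  if (!nrow(variants))
    warning("no variants left after clustering-input selection",
            call. = FALSE)
  data.frame(
    variant_id = variants$id,
    maf_adenoma = as.numeric(compute_maf(variants$ref_adenoma,
                                         variants$alt_adenoma)),
    maf_carcinoma = as.numeric(compute_maf(variants$ref_carcinoma,
                                           variants$alt_carcinoma)),
    stringsAsFactors = FALSE
  )
}

.point_matrix <- function(points) {
  if (is.data.frame(points)) {
    stopifnot(all(c("maf_adenoma", "maf_carcinoma") %in% names(points)))
    points <- cbind(points$maf_adenoma, points$maf_carcinoma)
  }
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  points
}

#' DBSCAN clustering of MAF pairs
#'
#' Standard DBSCAN on the unit square with Euclidean distance. A point is a
#' core point when its eps-neighborhood (itself included) holds at least
#' `min_pts` points; clusters are the connected components of the core points
#' under the eps-neighbor relation; a non-core point within eps of a core
#' point is a border point and joins the cluster of its first core neighbor
#' in input order (the declared tie rule); remaining points are outliers.
#' Deterministic for a fixed input order.
#'
#' @param points Data frame with `maf_adenoma`, `maf_carcinoma`, or a
#'   two-column numeric matrix.
#' @param eps Reachability distance (default 0.01 in MAF units, i.e. 1%).
#' @param min_pts Core-point threshold (default 5).
#' @return Integer vector of cluster ids, one per point, `0` for outliers.
#'   Clusters are numbered 1, 2, ... by their earliest core point.
#' @examples
#' pts <- rbind(matrix(rnorm(100, 0.35, 0.002), ncol = 2), c(0.9, 0.1))
#' dbscan_cluster(pts, eps = 0.01, min_pts = 4)
#' @export
dbscan_cluster <- function(points, eps = 0.01, min_pts = 5L) {
  x <- .point_matrix(points)
  stopifnot(eps > 0, min_pts >= 1)
  n <- nrow(x)
  if (n == 0L) return(integer(0))
  adj <- as.matrix(stats::dist(x)) <= eps  # self-distance 0 <= eps: included
  core <- rowSums(adj) >= min_pts
  cluster <- integer(n)
  cid <- 0L
  for (i in seq_len(n)) {
    if (!core[i] || cluster[i] != 0L) next
    cid <- cid + 1L
    frontier <- i
    cluster[i] <- cid
    while (length(frontier)) {     # BFS over density-connected core points
      nb <- which(adj[frontier[1L], ] & core & cluster == 0L)
      cluster[nb] <- cid
      frontier <- c(frontier[-1L], nb)
    }
  }
  border <- which(!core & cluster == 0L)
  for (p in border) {
    core_nb <- which(adj[p, ] & core)
    if (length(core_nb)) cluster[p] <- cluster[min(core_nb)]
  }
  cluster
}

#' Drop clusters holding less than a fraction of all points
#'
#' Clusters containing fewer than `min_frac` of the total number of points
#' (default 1%) are treated as noise: their members move to the outlier set.
#' The boundary is inclusive — a cluster with exactly `min_frac * n` members
#' is retained.
#'
#' @param cluster Integer assignment vector from [dbscan_cluster()].
#' @param min_frac Minimum retained cluster size as a fraction of
#'   `length(cluster)`; in `[0, 1)`.
#' @return The assignment vector with dropped clusters set to 0 and the
#'   remaining clusters renumbered consecutively (original order preserved).
#' @export
filter_small_clusters <- function(cluster, min_frac = 0.01) {
  .stopifnot_fraction(min_frac, "min_frac", open_hi = TRUE)
  n <- length(cluster)
  if (!n) return(cluster)
  sizes <- table(cluster[cluster > 0L])
  drop <- as.integer(names(sizes)[as.integer(sizes) < min_frac * n])
  cluster[cluster %in% drop] <- 0L
  keep <- sort(unique(cluster[cluster > 0L]))
  match(cluster, keep, nomatch = 0L)
}

# Coordinate-wise median centers and sizes of retained clusters.
.cluster_centers <- function(points, cluster) {
  x <- .point_matrix(points)
  ids <- sort(unique(cluster[cluster > 0L]))
  data.frame(
    cluster_id = ids,
    n = vapply(ids, function(k) sum(cluster == k), integer(1L)),
    center_adenoma = vapply(ids, function(k) median(x[cluster == k, 1L]),
                            numeric(1L)),
    center_carcinoma = vapply(ids, function(k) median(x[cluster == k, 2L]),
                              numeric(1L))
  )
}

#' Estimate lesion purity from the clonal cluster
#'
#' Clonal copy-neutral heterozygous mutations sit at expected MAF rho / 2, so
#' the purity estimate per lesion is twice the median MAF of the clonal
#' cluster in that lesion, clipped to `[0, 1]` (with a warning when clipping
#' occurs, since a median MAF above 0.5 is incompatible with the copy-neutral
#' heterozygous model).
#'
#' @param members Data frame of the clonal cluster's member points
#'   (`maf_adenoma`, `maf_carcinoma`).
#' @param label The cluster's label; must be `"clonal"`.
#' @return Named numeric vector `c(adenoma = ..., carcinoma = ...)`.
#' @export
estimate_purity <- function(members, label = "clonal") {
  if (!identical(label, "clonal"))
    stop("purity is estimated from the cluster labeled 'clonal'; got ",
         deparse(label), call. = FALSE)
  x <- .point_matrix(members)
  if (!nrow(x)) stop("empty clonal cluster", call. = FALSE)
  rho <- 2 * apply(x, 2L, median)
  if (any(rho > 1))
    warning("purity estimate(s) clipped to 1 (median clonal MAF > 0.5)",
            call. = FALSE)
  setNames(pmin(1, pmax(0, rho)), c("adenoma", "carcinoma"))
}

#' Label clusters against the expected mutation classes
#'
#' Per lesion, a cluster center is `absent` when below `absent_max`, `clonal`
#' when at least `clonal_min_frac` of the clonal reference m* = rho / 2, and
#' `subclonal` in between. The (adenoma, carcinoma) status pair maps to:
#' (clonal, clonal) -> `clonal`; (clonal or subclonal, absent) ->
#' `adenoma_specific`; (absent, clonal or subclonal) -> `carcinoma_specific`;
#' (subclonal, clonal) -> `stepwise_intermediate` (the stepwise-evolution
#' signature); anything else -> `unlabeled`.
#'
#' @param clusters Cluster data frame with `center_adenoma`,
#'   `center_carcinoma` (as built by [clonal_architecture()]).
#' @param purity_adenoma,purity_carcinoma Lesion purities in `(0, 1]`.
#' @param absent_max MAF below which a lesion is called absent (default 0.05).
#' @param clonal_min_frac Fraction of m* above which a lesion is called
#'   clonal (default 0.6).
#' @return `clusters` with a `label` column added.
#' @export
label_clusters <- function(clusters, purity_adenoma, purity_carcinoma,
                           absent_max = 0.05, clonal_min_frac = 0.6) {
  .stopifnot_fraction(purity_adenoma, "purity_adenoma", open_lo = TRUE)
  .stopifnot_fraction(purity_carcinoma, "purity_carcinoma", open_lo = TRUE)
  status <- function(center, rho) {
    ifelse(center < absent_max, "absent",
           ifelse(center >= clonal_min_frac * rho / 2, "clonal", "subclonal"))
  }
  sa <- status(clusters$center_adenoma, purity_adenoma)
  sc <- status(clusters$center_carcinoma, purity_carcinoma)
  clusters$label <- ifelse(
    sa == "clonal" & sc == "clonal", "clonal",
    ifelse(sa %in% c("clonal", "subclonal") & sc == "absent",
           "adenoma_specific",
    ifelse(sa == "absent" & sc %in% c("clonal", "subclonal"),
           "carcinoma_specific",
    ifelse(sa == "subclonal" & sc == "clonal",
           "stepwise_intermediate", "unlabeled"))))
  clusters
}

#' Evolutionary verdict from labeled clusters
#'
#' `stepwise` when at least one retained cluster carries the
#' `stepwise_intermediate` label (mutations subclonal in the adenoma but
#' clonal in the carcinoma can only arise if the carcinoma descends from an
#' adenoma subclone); `parallel` when a clonal cluster coexists with at least
#' one lesion-specific cluster and no stepwise-intermediate cluster;
#' `indeterminate` otherwise.
#'
#' @param labels Character vector of retained cluster labels.
#' @return `"parallel"`, `"stepwise"`, or `"indeterminate"`.
#' @export
infer_evolution <- function(labels) {
  if (any(labels == "stepwise_intermediate")) return("stepwise")
  if (any(labels == "clonal") &&
      any(labels %in% c("adenoma_specific", "carcinoma_specific")))
    return("parallel")
  "indeterminate"
}

#' Infer the clonal architecture of a synchronous lesion pair
#'
#' The package's core estimator. Selects the MAF point set
#' ([select_clustering_input()]), clusters it with DBSCAN
#' ([dbscan_cluster()]), drops clusters below `min_frac` of the points
#' ([filter_small_clusters()]), estimates lesion purities from the putative
#' clonal cluster (the retained cluster whose smaller center coordinate is
#' largest) unless `purity` is supplied, labels every retained cluster
#' ([label_clusters()]), and calls the evolutionary verdict
#' ([infer_evolution()]). When fewer than `min_points` points survive
#' selection (e.g. microsatellite-stable genomes with few mutations) the
#' verdict is `indeterminate` without clustering.
#'
#' @param variants A variant data frame, or a precomputed MAF point data
#'   frame (`variant_id`, `maf_adenoma`, `maf_carcinoma`).
#' @param segments Optional copy-number segments passed to
#'   [select_clustering_input()].
#' @param eps,min_pts DBSCAN parameters (defaults 0.01, 5).
#' @param min_frac Minimum retained cluster fraction (default 0.01).
#' @param purity Optional known purities, numeric length-2
#'   `(adenoma, carcinoma)`; estimated from the clonal cluster by default.
#' @param absent_max,clonal_min_frac Labeling thresholds, see
#'   [label_clusters()].
#' @param min_points Minimum usable points for a verdict (default 50).
#' @return An object of class `clonal_architecture`: list with `points`
#'   (input points plus `cluster_id`, 0 = outlier), `clusters` (retained
#'   clusters with centers, sizes, labels), `outlier_ids`, `verdict`,
#'   `purity`, `purity_supplied`, and the parameters used.
#' @examples
#' sim <- simulate_lesion_pair(simulation_config("parallel", seed = 3))
#' arch <- clonal_architecture(sim$variants)
#' arch
#' @export
clonal_architecture <- function(variants, segments = NULL,
                                eps = 0.01, min_pts = 5L, min_frac = 0.01,
                                purity = NULL, absent_max = 0.05,
                                clonal_min_frac = 0.6, min_points = 50L) {
  points <- if (is.data.frame(variants) &&
                all(c("maf_adenoma", "maf_carcinoma") %in% names(variants)) &&
                !all(.VARIANT_COLS %in% names(variants))) {
    variants
  } else {
    select_clustering_input(variants, segments)
  }
  if (!"variant_id" %in% names(points))
    points$variant_id <- sprintf("p%05d", seq_len(nrow(points)))

  params <- list(eps = eps, min_pts = min_pts, min_frac = min_frac,
                 absent_max = absent_max, clonal_min_frac = clonal_min_frac,
                 min_points = min_points)

  if (nrow(points) < min_points) {
    points$cluster_id <- rep(0L, nrow(points))
    out <- list(points = points,
                clusters = cbind(.cluster_centers(points, integer(nrow(points))),
                                 label = character(0)),
                outlier_ids = points$variant_id,
                verdict = "indeterminate",
                purity = NULL, purity_supplied = !is.null(purity),
                params = params)
    class(out) <- "clonal_architecture"
    return(out)
  }

  cl <- dbscan_cluster(points, eps = eps, min_pts = min_pts)
  cl <- filter_small_clusters(cl, min_frac = min_frac)
  points$cluster_id <- cl
  clusters <- .cluster_centers(points, cl)

  if (nrow(clusters)) {
    if (is.null(purity)) {
      # The clonal cluster is present in both lesions and maximizes the
      # smaller of its two center coordinates. Small satellite fragments of
      # the main clusters can sit at extreme MAF, so candidates are first
      # restricted to clusters at least half the size of the largest
      # both-lesion cluster.
      cand <- clusters[pmin(clusters$center_adenoma,
                            clusters$center_carcinoma) >= absent_max, ,
                       drop = FALSE]
      if (!nrow(cand)) cand <- clusters
      cand <- cand[cand$n >= 0.5 * max(cand$n), , drop = FALSE]
      clonal_guess <- cand$cluster_id[
        which.max(pmin(cand$center_adenoma, cand$center_carcinoma))]
      rho <- estimate_purity(points[cl == clonal_guess,
                                    c("maf_adenoma", "maf_carcinoma")])
    } else {
      stopifnot(is.numeric(purity), length(purity) == 2L)
      rho <- setNames(as.numeric(purity), c("adenoma", "carcinoma"))
    }
    clusters <- label_clusters(clusters, rho[["adenoma"]], rho[["carcinoma"]],
                               absent_max = absent_max,
                               clonal_min_frac = clonal_min_frac)
    if (is.null(purity) && any(clusters$label == "clonal")) {
      # Refinement pass: DBSCAN at small eps can shave fringe points off the
      # clonal cloud into satellite clusters, so the single-cluster median is
      # noisy. Re-estimate purity from the union of all clusters labeled
      # clonal, then relabel once with the refined value.
      clonal_ids <- clusters$cluster_id[clusters$label == "clonal"]
      rho <- estimate_purity(points[cl %in% clonal_ids,
                                    c("maf_adenoma", "maf_carcinoma")])
      clusters$label <- NULL
      clusters <- label_clusters(clusters, rho[["adenoma"]],
                                 rho[["carcinoma"]],
                                 absent_max = absent_max,
                                 clonal_min_frac = clonal_min_frac)
    }
    verdict <- infer_evolution(clusters$label)
  } else {
    clusters$label <- character(0)
    rho <- NULL
    verdict <- "indeterminate"
  }

  # Partition invariant: retained-cluster members + outliers = all points.
  stopifnot(sum(clusters$n) + sum(cl == 0L) == nrow(points))

  out <- list(points = points, clusters = clusters,
              outlier_ids = points$variant_id[cl == 0L],
              verdict = verdict, purity = rho,
              purity_supplied = !is.null(purity), params = params)
  class(out) <- "clonal_architecture"
  out
}

#' @export
print.clonal_architecture <- function(x, ...) {
  cat("Clonal architecture of a synchronous adenoma-carcinoma pair\n")
  cat(sprintf("  points: %d (%d outliers)  verdict: %s\n",
              nrow(x$points), length(x$outlier_ids), x$verdict))
  if (!is.null(x$purity))
    cat(sprintf("  purity (%s): adenoma %.3f, carcinoma %.3f\n",
                if (x$purity_supplied) "supplied" else "estimated",
                x$purity[["adenoma"]], x$purity[["carcinoma"]]))
  if (nrow(x$clusters)) {
    cat("  clusters:\n")
    print(x$clusters, row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.clonal_architecture <- function(object, ...) {
  structure(list(
    verdict = object$verdict,
    n_points = nrow(object$points),
    n_outliers = length(object$outlier_ids),
    clusters = object$clusters,
    purity = object$purity,
    purity_supplied = object$purity_supplied,
    params = object$params
  ), class = "summary.clonal_architecture")
}

#' @export
print.summary.clonal_architecture <- function(x, ...) {
  cat(sprintf("Verdict: %s (%d points, %d outliers)\n", x$verdict,
              x$n_points, x$n_outliers))
  if (!is.null(x$purity))
    cat(sprintf("Purity: adenoma %.3f, carcinoma %.3f (%s)\n",
                x$purity[["adenoma"]], x$purity[["carcinoma"]],
                if (x$purity_supplied) "supplied" else "estimated"))
  if (nrow(x$clusters)) print(x$clusters, row.names = FALSE)
  cat(sprintf("DBSCAN eps = %g, min_pts = %d; min cluster fraction %g\n",
              x$params$eps, x$params$min_pts, x$params$min_frac))
  invisible(x)
}

.LABEL_COLORS <- c(clonal = "black", adenoma_specific = "forestgreen",
                   carcinoma_specific = "red2",
                   stepwise_intermediate = "darkorange",
                   unlabeled = "steelblue", outlier = "grey60")

#' Scatter plot of the clustered MAF pairs
#'
#' Adenoma MAF on the x-axis, carcinoma MAF on the y-axis, points colored by
#' cluster label (black clonal, green adenoma-specific, red
#' carcinoma-specific, orange stepwise-intermediate, grey outliers).
#'
#' @param x A `clonal_architecture` object.
#' @param ... Further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.clonal_architecture <- function(x, ...) {
  lab <- rep("outlier", nrow(x$points))
  if (nrow(x$clusters)) {
    m <- match(x$points$cluster_id, x$clusters$cluster_id)
    lab[!is.na(m)] <- x$clusters$label[m[!is.na(m)]]
  }
  plot(x$points$maf_adenoma, x$points$maf_carcinoma,
       col = .LABEL_COLORS[lab], pch = 16, cex = 0.6,
       xlim = c(0, 1), ylim = c(0, 1),
       xlab = "MAF adenoma", ylab = "MAF carcinoma",
       main = sprintf("Clonal architecture (%s)", x$verdict), ...)
  used <- intersect(names(.LABEL_COLORS), unique(lab))
  legend("topright", legend = used, col = .LABEL_COLORS[used], pch = 16,
         bty = "n", cex = 0.8)
  invisible(x)
}

#' Write the cluster assignment and architecture summary
#'
#' Emits a TSV of per-variant assignments (`variant_id`, `cluster_id`,
#' `label`) and a JSON summary (clusters, centers, verdict, purities).
#'
#' @param arch A `clonal_architecture` object.
#' @param tsv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, a list with the paths written.
#' @export
write_architecture <- function(arch, tsv_path = NULL, json_path = NULL) {
  stopifnot(inherits(arch, "clonal_architecture"))
  if (!is.null(tsv_path)) {
    lab <- rep("outlier", nrow(arch$points))
    m <- match(arch$points$cluster_id, arch$clusters$cluster_id)
    lab[!is.na(m)] <- arch$clusters$label[m[!is.na(m)]]
    write.table(data.frame(variant_id = arch$points$variant_id,
                           cluster_id = arch$points$cluster_id,
                           label = lab),
                tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(list(verdict = arch$verdict,
                              purity = as.list(arch$purity),
                              clusters = arch$clusters,
                              n_outliers = length(arch$outlier_ids)),
                         json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(list(tsv = tsv_path, json = json_path))
}
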