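# Copy number from binned tumor/normal read depths: GC correction,
# library-size-normalized log2 ratios, circular binary segmentation (CBS)
# with permutation significance, and threshold gain/loss calls.

#' GC-bias correction of binned read depths
#'
#' Per sample, bins are stratified into GC windows of width `stratum_width`
#' (default 2% GC); each depth is divided by (stratum median / global
#' median), so the sample's global median depth is preserved. Strata holding
#' fewer than `min_stratum` bins inherit the correction factor of the nearest
#' populated stratum.
#'
#' @param bins Depth-bin data frame (`chrom`, `start`, `end`, `gc`,
#'   `depth_tumor`, `depth_normal`).
#' @param stratum_width GC stratum width (default 0.02).
#' @param min_stratum Minimum bins per stratum (default 20).
#' @return `bins` with corrected `depth_tumor` and `depth_normal`.
#' @export
gc_correct <- function(bins, stratum_width = 0.02, min_stratum = 20L) {
  stopifnot(all(bins$gc >= 0 & bins$gc <= 1))
  stratum <- floor(bins$gc / stratum_width)
  for (col in c("depth_tumor", "depth_normal")) {
    depth <- bins[[col]]
    global_med <- median(depth)
    tab <- table(stratum)
    sizes <- setNames(as.integer(tab), names(tab))
    meds <- vapply(names(sizes), function(s)
      median(depth[stratum == as.integer(s)]), numeric(1L))
    populated <- names(sizes)[sizes >= min_stratum]
    if (!length(populated)) populated <- names(sizes)
    # sparse strata inherit the nearest populated stratum's median
    use <- vapply(names(sizes), function(s) {
      if (s %in% populated) return(s)
      populated[which.min(abs(as.integer(populated) - as.integer(s)))]
    }, "")
    factor_by_stratum <- meds[use] / global_med
    names(factor_by_stratum) <- names(sizes)
    f <- factor_by_stratum[as.character(stratum)]
    f[!is.finite(f) | f <= 0] <- 1
    bins[[col]] <- depth / f
  }
  bins
}

#' Library-size-normalized log2 tumor/normal depth ratio
#'
#' Bins with normal depth below `min_normal_depth` are masked (`log2ratio`
#' `NA`). Tumor depths are rescaled so the unmasked tumor total equals the
#' unmasked normal total (removing the library-size difference), then
#' `log2ratio = log2((tumor + 0.5) / (normal + 0.5))` with a 0.5 pseudocount.
#'
#' @param bins Depth-bin data frame (GC-correct first with [gc_correct()]).
#' @param min_normal_depth Masking floor on the normal depth (default 10).
#' @param normalize Set `FALSE` to skip the library-size rescaling.
#' @return `bins` with `log2ratio` and logical `masked` columns. Chromosomes
#'   whose bins are all masked are reported with a warning.
#' @export
normalize_and_ratio <- function(bins, min_normal_depth = 10, normalize = TRUE) {
  masked <- bins$depth_normal < min_normal_depth
  tum <- bins$depth_tumor
  if (normalize) {
    scale <- sum(bins$depth_normal[!masked]) / sum(tum[!masked])
    tum <- tum * scale
  }
  bins$log2ratio <- ifelse(masked, NA_real_,
                           log2((tum + 0.5) / (bins$depth_normal + 0.5)))
  bins$masked <- masked
  all_masked <- tapply(masked, bins$chrom, all)
  if (any(all_masked))
    warning("all bins masked on chromosome(s): ",
            paste(names(all_masked)[all_masked], collapse = ", "),
            call. = FALSE)
  bins
}

# Permutation p-value for one candidate split with early stopping: once the
# exceedance count guarantees p > alpha the remaining permutations cannot
# change the decision.
.cbs_perm_p <- function(x, observed, min_width, alpha, n_perm) {
  stop_at <- floor(alpha * n_perm)  # count > stop_at  =>  not significant
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    stat <- .cbs_max_stat_only(x[sample.int(length(x))], min_width)
    if (stat >= observed) {
      exceed <- exceed + 1L
      if (exceed > stop_at) return(exceed / b)
    }
  }
  exceed / n_perm
}

.cbs_recurse <- function(x, offset, alpha, n_perm, min_width) {
  n <- length(x)
  if (n < 2L * min_width || sd(x) == 0) return(integer(0))
  cand <- .cbs_max_stat(x, min_width)
  if (cand$stat <= 0) return(integer(0))
  p <- .cbs_perm_p(x, cand$stat, min_width, alpha, n_perm)
  if (p > alpha) return(integer(0))
  i <- cand$i
  j <- cand$j
  bps <- setdiff(c(i, j), c(0L, n))
  edges <- sort(unique(c(0L, bps, n)))
  kids <- unlist(lapply(seq_len(length(edges) - 1L), function(s) {
    lo <- edges[s]
    hi <- edges[s + 1L]
    .cbs_recurse(x[(lo + 1L):hi], offset + lo, alpha, n_perm, min_width)
  }))
  sort(c(offset + bps, kids))
}

#' Circular binary segmentation of one chromosome's values
#'
#' Recursive CBS: over the circularized sequence, find the arc maximizing the
#' absolute standardized mean difference between arc and complement; assess
#' it by permutation (values shuffled, same statistic; p = fraction of
#' permuted maxima at or above the observed one); accept the split when
#' `p <= alpha` and both resulting arcs have at least `min_width` values;
#' recurse into the resulting pieces. Deterministic under `seed`. A constant
#' input yields no breakpoints (one segment).
#'
#' @param values Numeric vector (e.g. one chromosome's `log2ratio`), no `NA`.
#' @param alpha Split significance level (default 0.01).
#' @param n_perm Permutations per candidate split (default 1000).
#' @param min_width Minimum arc width in bins (default 3).
#' @param seed Integer seed for the permutations.
#' @return Sorted integer breakpoints: a breakpoint `b` separates positions
#'   `1..b` from `b+1..n`. `integer(0)` means a single segment.
#' @examples
#' cbs_segment(c(rep(0, 50), rep(1, 50)), n_perm = 200, seed = 1)
#' @export
cbs_segment <- function(values, alpha = 0.01, n_perm = 1000L,
                        min_width = 3L, seed = 1L) {
  if (anyNA(values)) stop("'values' must not contain NA", call. = FALSE)
  .stopifnot_fraction(alpha, "alpha", open_lo = TRUE, open_hi = TRUE)
  min_width <- .stopifnot_count(min_width, "min_width", min = 1L)
  n_perm <- .stopifnot_count(n_perm, "n_perm", min = 1L)
  .with_seed(seed, .cbs_recurse(as.numeric(values), 0L, alpha, n_perm,
                                min_width))
}

#' Call gains and losses on segments
#'
#' @param segments Segment data frame with `mean_log2`.
#' @param gain_threshold,loss_threshold Calls are `gain` when `mean_log2 >=
#'   gain_threshold`, `loss` when `<= loss_threshold`, else `neutral`
#'   (defaults +0.25 / -0.25; one extra copy at purity 1 gives log2(3/2) =
#'   0.58).
#' @return `segments` with a `call` column.
#' @export
call_segments <- function(segments, gain_threshold = 0.25,
                          loss_threshold = -0.25) {
  stopifnot(gain_threshold > 0, loss_threshold < 0)
  segments$call <- ifelse(segments$mean_log2 >= gain_threshold, "gain",
                          ifelse(segments$mean_log2 <= loss_threshold,
                                 "loss", "neutral"))
  segments
}

#' Segment a depth-bin table into copy-number calls
#'
#' The full copy-number stage: GC correction, masking and log2 ratio
#' formation, per-chromosome CBS over the unmasked bins, then gain/loss
#' calls. Segment coordinates span from the first to the last unmasked bin of
#' the segment; `n_bins` counts unmasked bins, so segments tile each
#' chromosome's unmasked extent exactly.
#'
#' @param bins Depth-bin data frame.
#' @param gc Apply [gc_correct()] first? (default TRUE)
#' @param min_normal_depth,alpha,n_perm,min_width,seed,gain_threshold,loss_threshold
#'   Passed to the component stages.
#' @return Data frame of class `copy_segments`: `chrom`, `start`, `end`,
#'   `mean_log2`, `n_bins`, `call`.
#' @examples
#' bins <- simulate_depth_profile(200, 100, c(0, 1), noise_sd = 2, seed = 5)
#' segment_depth_bins(bins, n_perm = 200)
#' @export
segment_depth_bins <- function(bins, gc = TRUE, min_normal_depth = 10,
                               alpha = 0.01, n_perm = 1000L, min_width = 3L,
                               seed = 1L, gain_threshold = 0.25,
                               loss_threshold = -0.25) {
  if (gc) bins <- gc_correct(bins)
  bins <- normalize_and_ratio(bins, min_normal_depth = min_normal_depth)
  chroms <- unique(bins$chrom)
  segs <- lapply(seq_along(chroms), function(ci) {
    cb <- bins[bins$chrom == chroms[ci] & !bins$masked, , drop = FALSE]
    if (!nrow(cb)) return(NULL)
    v <- cb$log2ratio
    bps <- cbs_segment(v, alpha = alpha, n_perm = n_perm,
                       min_width = min_width, seed = seed + ci)
    edges <- c(0L, bps, length(v))
    data.frame(
      chrom = chroms[ci],
      start = cb$start[edges[-length(edges)] + 1L],
      end = cb$end[edges[-1L]],
      mean_log2 = vapply(seq_len(length(edges) - 1L), function(s)
        mean(v[(edges[s] + 1L):edges[s + 1L]]), numeric(1L)),
      n_bins = diff(edges),
      stringsAsFactors = FALSE
    )
  })
  segments <- do.call(rbind, segs)
  if (is.null(segments))
    segments <- data.frame(chrom = character(0), start = integer(0),
                           end = integer(0), mean_log2 = numeric(0),
                           n_bins = integer(0), stringsAsFactors = FALSE)
  segments <- call_segments(segments, gain_threshold, loss_threshold)
  rownames(segments) <- NULL
  class(segments) <- c("copy_segments", "data.frame")
  segments
}

#' @export
print.copy_segments <- function(x, ...) {
  cat(sprintf("Copy-number segments: %d segment(s) on %d chromosome(s)\n",
              nrow(x), length(unique(x$chrom))))
  NextMethod()
}

#' Write segments as TSV and BED
#'
#' @param segments `copy_segments` data frame.
#' @param tsv_path,bed_path Output paths (either may be `NULL`).
#' @return Invisibly, the paths written.
#' @export
write_segments <- function(segments, tsv_path = NULL, bed_path = NULL) {
  if (!is.null(tsv_path))
    write.table(segments, tsv_path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  if (!is.null(bed_path))
    writeLines(paste(segments$chrom, segments$start, segments$end,
                     segments$call, round(segments$mean_log2, 4), ".",
                     sep = "\t"), bed_path)
  invisible(list(tsv = tsv_path, bed = bed_path))
}
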