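# Microsatellite instability from intraread repeat-length distributions.
#
# Loci are perfect tandem tracts of a 1-4 bp unit, 7-60 bp total, found in the
# reference; each spanning read contributes one observed tract length; tumor
# and normal length distributions are compared per locus by a two-sample
# Kolmogorov-Smirnov test, with Benjamini-Hochberg FDR control across loci
# within one comparison family (one tumor lesion vs the matched normal).

# Lexicographically minimal rotation of a repeat unit ("CA" -> "AC").
.canonical_unit <- function(unit) {
  vapply(unit, function(u) {
    n <- nchar(u)
    rot <- vapply(seq_len(n), function(i)
      paste0(substr(u, i, n), substr(u, 1, i - 1L)), "")
    min(rot)
  }, "", USE.NAMES = FALSE)
}

# TRUE when the unit is a whole-number repetition of a shorter string, i.e.
# its tract is already captured at a smaller period.
.unit_is_periodic <- function(unit) {
  p <- nchar(unit)
  if (p == 1L) return(FALSE)
  for (q in seq_len(p - 1L)) {
    if (p %% q == 0L &&
        unit == strrep(substr(unit, 1L, q), p %/% q)) return(TRUE)
  }
  FALSE
}

# Maximal tandem tracts of period p in character vector s (one char per
# element). Returns data frame with 1-based start/end inclusive.
.period_runs <- function(s, p) {
  n <- length(s)
  if (n <= p) return(data.frame(start = integer(0), end = integer(0)))
  eq <- s[seq_len(n - p)] == s[seq_len(n - p) + p] &
    s[seq_len(n - p)] != "N" & s[seq_len(n - p) + p] != "N"
  r <- rle(eq)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep] + p)
}

# Greedy overlap resolution: smallest unit first, then longest tract, then
# leftmost start; a candidate is kept only if it overlaps no kept call.
.resolve_overlaps <- function(cand) {
  if (nrow(cand) <= 1L) return(cand)
  ord <- order(nchar(cand$unit_raw), -cand$tract_length, cand$start)
  cand <- cand[ord, , drop = FALSE]
  kept <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (j in which(kept)) {
      if (cand$start[i] < cand$end[j] && cand$start[j] < cand$end[i]) {
        ok <- FALSE
        break
      }
    }
    kept[i] <- ok
  }
  cand <- cand[kept, , drop = FALSE]
  cand[order(cand$start), , drop = FALSE]
}

#' Find microsatellite repeat tracts in a reference sequence
#'
#' Scans for maximal perfect tandem tracts of a 1-4 bp unit with total tract
#' length 7-60 bp (a partial trailing unit counts toward the length). Tracts
#' whose unit is itself a repetition of a shorter unit are reported at the
#' smallest period only (a poly-A run is never also reported as an "AA"
#' repeat); overlapping candidates of different periods are resolved to the
#' smallest-unit, longest-tract call. `N` breaks tracts. Coordinates are
#' 0-based half-open; the unit is reported as its lexicographically minimal
#' rotation.
#'
#' @param sequence Named character vector of sequences over `A,C,G,T,N`
#'   (names become `seq_id`; a single unnamed sequence gets `seq1`).
#' @param min_tract,max_tract Tract length bounds in bp (defaults 7 and 60;
#'   tracts longer than `max_tract` are discarded, not truncated).
#' @param max_unit Largest repeat unit length (default 4).
#' @return Data frame of loci: `locus_id`, `seq_id`, `start`, `end`, `unit`,
#'   `tract_length`.
#' @examples
#' find_microsatellites(c(chrT = "GACACACACAT"))
#' @export
find_microsatellites <- function(sequence, min_tract = 7L, max_tract = 60L,
                                 max_unit = 4L) {
  if (is.null(names(sequence)))
    names(sequence) <- paste0("seq", seq_along(sequence))
  out <- lapply(names(sequence), function(sid) {
    seq <- toupper(sequence[[sid]])
    s <- strsplit(seq, "", fixed = TRUE)[[1L]]
    if (length(s) && any(!s %in% c("A", "C", "G", "T", "N")))
      stop("sequence '", sid, "' contains symbols outside A,C,G,T,N",
           call. = FALSE)
    cand <- do.call(rbind, lapply(seq_len(max_unit), function(p) {
      runs <- .period_runs(s, p)
      if (!nrow(runs)) return(NULL)
      runs$unit_raw <- substr(rep(seq, nrow(runs)), runs$start,
                              runs$start + p - 1L)
      runs$tract_length <- runs$end - runs$start + 1L
      runs <- runs[runs$tract_length >= min_tract &
                     runs$tract_length <= max_tract, , drop = FALSE]
      if (!nrow(runs)) return(NULL)
      tract_seq <- substr(rep(seq, nrow(runs)), runs$start, runs$end)
      runs <- runs[!grepl("N", tract_seq, fixed = TRUE), , drop = FALSE]
      if (!nrow(runs)) return(NULL)
      runs[!vapply(runs$unit_raw, .unit_is_periodic, logical(1L)), ,
           drop = FALSE]
    }))
    if (is.null(cand) || !nrow(cand)) return(NULL)
    # switch to 0-based half-open before overlap resolution
    cand$start <- cand$start - 1L
    cand <- .resolve_overlaps(cand)
    data.frame(seq_id = sid, start = cand$start, end = cand$end,
               unit = .canonical_unit(cand$unit_raw),
               tract_length = cand$tract_length,
               stringsAsFactors = FALSE)
  })
  loci <- do.call(rbind, out)
  if (is.null(loci))
    loci <- data.frame(seq_id = character(0), start = integer(0),
                       end = integer(0), unit = character(0),
                       tract_length = integer(0), stringsAsFactors = FALSE)
  loci <- cbind(locus_id = sprintf("%s:%d-%d", loci$seq_id, loci$start,
                                   loci$end),
                loci)
  loci$locus_id <- as.character(loci$locus_id)
  rownames(loci) <- NULL
  loci
}

#' Observed repeat-tract lengths from spanning reads
#'
#' A read contributes one observation when its mapping spans the locus plus
#' `min_flank` anchor bases on each side. The contributed length is the
#' maximal tandem tract of the locus unit found in the read at the expected
#' offset, so insertions or deletions inside the tract change the observed
#' length. Reads that do not span are skipped and counted in the `skipped`
#' attribute.
#'
#' @param reads Data frame of read records: `sample`, `sequence`,
#'   `mapped_start` (0-based position of the read's first base on the
#'   reference); see [read_spanning_reads()].
#' @param locus One locus (single row of [find_microsatellites()] output, or
#'   a list with `locus_id`, `start`, `end`, `unit`).
#' @param min_flank Anchor bases required on each side (default 5).
#' @return Data frame `locus_id`, `sample`, `length` (one row per
#'   contributing read), with attribute `skipped` = number of non-spanning
#'   reads.
#' @export
extract_intraread_lengths <- function(reads, locus, min_flank = 5L) {
  stopifnot(min_flank >= 1L)
  if (is.data.frame(locus)) locus <- as.list(locus[1L, ])
  p <- nchar(locus$unit)
  unit_canon <- .canonical_unit(locus$unit)
  span_lo <- locus$start - min_flank
  span_hi <- locus$end + min_flank
  read_end <- reads$mapped_start + nchar(reads$sequence)
  spans <- reads$mapped_start <= span_lo & read_end >= span_hi
  res <- lapply(which(spans), function(i) {
    s <- strsplit(toupper(reads$sequence[i]), "", fixed = TRUE)[[1L]]
    runs <- .period_runs(s, p)
    if (!nrow(runs)) return(NULL)
    # expected 1-based local start of the tract within the read
    o <- locus$start - reads$mapped_start[i] + 1L
    units <- substr(rep(paste(s, collapse = ""), nrow(runs)), runs$start,
                    runs$start + p - 1L)
    ok <- .canonical_unit(units) == unit_canon &
      runs$start <= o + p & runs$end >= o  # at the expected offset
    if (!any(ok)) return(NULL)
    runs <- runs[ok, , drop = FALSE]
    max(runs$end - runs$start + 1L)
  })
  lens <- unlist(res)
  contributed <- !vapply(res, is.null, logical(1L))
  out <- data.frame(
    locus_id = rep(locus$locus_id, length(lens)),
    sample = reads$sample[which(spans)[contributed]],
    length = if (length(lens)) as.integer(lens) else integer(0),
    stringsAsFactors = FALSE
  )
  attr(out, "skipped") <- sum(!spans)
  out
}

#' Two-sample Kolmogorov-Smirnov test on repeat-length multisets
#'
#' D is the supremum over all observed values of the absolute difference of
#' the two empirical CDFs (ties are handled by evaluating at every observed
#' value). The p-value comes from the asymptotic Kolmogorov distribution at
#' `sqrt(ne) * D` with effective size `ne = nx * ny / (nx + ny)`, clipped to
#' `[0, 1]`. Discrete data make this p conservative, which suits its use for
#' FDR-controlled event calling.
#'
#' @param x,y Numeric vectors (multisets of observed tract lengths); both
#'   non-empty.
#' @return List with elements `D` and `p`.
#' @examples
#' ks_two_sample(c(1, 2, 3), c(4, 5, 6))  # disjoint supports: D = 1
#' @export
ks_two_sample <- function(x, y) {
  if (!length(x) || !length(y))
    stop("both samples must be non-empty", call. = FALSE)
  v <- sort(unique(c(x, y)))
  Fx <- vapply(v, function(t) mean(x <= t), numeric(1L))
  Fy <- vapply(v, function(t) mean(y <= t), numeric(1L))
  D <- max(abs(Fx - Fy))
  ne <- length(x) * length(y) / (length(x) + length(y))
  lambda <- sqrt(ne) * D
  if (lambda == 0) {
    p <- 1
  } else {
    k <- 1:100
    p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda^2))
  }
  list(D = D, p = min(1, max(0, p)))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q(i) = min over j >= i of min(1, p(j) * m / j)` on the sorted p-values,
#' returned in the original order (delegates to [stats::p.adjust()]).
#'
#' @param pvalues Numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values in `[0, 1]`, same order as the input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(!is.finite(pvalues) | pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(pvalues, method = "BH")
}

#' Call MSI events from paired repeat-length distributions
#'
#' One comparison family (one tumor lesion vs the matched normal): loci with
#' fewer than `min_reads` observations in either sample are skipped (recorded
#' in the `skipped_loci` attribute); the remaining loci get a KS test and a
#' single BH correction across the family; `is_msi = q < alpha`.
#'
#' @param lengths Long data frame of observations: `locus_id`, `sample`,
#'   `length` (as from [simulate_msi_observations()] or repeated
#'   [extract_intraread_lengths()] calls).
#' @param tumor_sample,normal_sample Values of the `sample` column to compare
#'   (defaults `"tumor"` and `"normal"`).
#' @param comparison Label stored in the output, e.g.
#'   `"carcinoma_vs_normal"`.
#' @param alpha FDR threshold (default 0.05).
#' @param min_reads Minimum observations per sample per locus (default 10).
#' @return Data frame of class `msi_calls`: `locus_id`, `comparison`,
#'   `n_tumor`, `n_normal`, `D`, `p`, `q`, `is_msi`, `overlaps_indel`
#'   (`NA` until [reconcile_with_indels()]).
#' @examples
#' sim <- simulate_msi_observations(msi_simulation_config(seed = 4))
#' calls <- call_msi(sim$lengths)
#' sum(calls$is_msi)
#' @export
call_msi <- function(lengths, tumor_sample = "tumor",
                     normal_sample = "normal",
                     comparison = "carcinoma_vs_normal",
                     alpha = 0.05, min_reads = 10L) {
  stopifnot(all(c("locus_id", "sample", "length") %in% names(lengths)))
  .stopifnot_fraction(alpha, "alpha", open_lo = TRUE, open_hi = TRUE)
  tum <- split(lengths$length[lengths$sample == tumor_sample],
               lengths$locus_id[lengths$sample == tumor_sample])
  nor <- split(lengths$length[lengths$sample == normal_sample],
               lengths$locus_id[lengths$sample == normal_sample])
  loci <- union(names(tum), names(nor))
  n_t <- vapply(loci, function(l) length(tum[[l]]), integer(1L))
  n_n <- vapply(loci, function(l) length(nor[[l]]), integer(1L))
  ok <- n_t >= min_reads & n_n >= min_reads
  tested <- loci[ok]
  ks <- lapply(tested, function(l) ks_two_sample(tum[[l]], nor[[l]]))
  p <- vapply(ks, `[[`, numeric(1L), "p")
  calls <- data.frame(
    locus_id = tested,
    comparison = comparison,
    n_tumor = n_t[ok],
    n_normal = n_n[ok],
    D = vapply(ks, `[[`, numeric(1L), "D"),
    p = p,
    q = if (length(p)) bh_fdr(p) else numeric(0),
    stringsAsFactors = FALSE
  )
  calls$is_msi <- calls$q < alpha
  calls$overlaps_indel <- NA
  rownames(calls) <- NULL
  attr(calls, "skipped_loci") <- loci[!ok]
  class(calls) <- c("msi_calls", "data.frame")
  calls
}

#' @export
print.msi_calls <- function(x, ...) {
  cat(sprintf("MSI calls (%s): %d loci tested, %d skipped, %d significant\n",
              x$comparison[1L], nrow(x), length(attr(x, "skipped_loci")),
              sum(x$is_msi)))
  NextMethod()
}

#' Reconcile MSI calls with indel calls
#'
#' An MSI call regionally coinciding with an indel call likely represents a
#' clonally fixed event already counted among the indels, so it is flagged:
#' `overlaps_indel` is `TRUE` when an indel's reference span (1-based
#' position plus its ref-allele length, converted to 0-based half-open)
#' intersects the locus interval. The retained event list is
#' `calls[!calls$overlaps_indel, ]`; reconciliation never increases the call
#' count.
#'
#' @param calls `msi_calls` data frame.
#' @param indel_variants Variant data frame (only rows with
#'   `kind == "indel"` are used).
#' @param loci Locus data frame giving `locus_id`, `seq_id`, `start`, `end`
#'   (0-based half-open).
#' @return `calls` with `overlaps_indel` filled in.
#' @export
reconcile_with_indels <- function(calls, indel_variants, loci) {
  idx <- match(calls$locus_id, loci$locus_id)
  if (anyNA(idx))
    stop("calls refer to loci missing from 'loci': ",
         paste(head(calls$locus_id[is.na(idx)], 5L), collapse = ", "),
         call. = FALSE)
  ind <- indel_variants[indel_variants$kind == "indel", , drop = FALSE]
  i_start <- ind$pos - 1L                 # 1-based -> 0-based
  i_end <- i_start + nchar(ind$ref)       # half-open ref span
  calls$overlaps_indel <- vapply(seq_len(nrow(calls)), function(k) {
    l <- idx[k]
    any(ind$chrom == loci$seq_id[l] &
          i_start < loci$end[l] & loci$start[l] < i_end)
  }, logical(1L))
  calls
}
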