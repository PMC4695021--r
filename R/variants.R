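# Somatic variant tables and regional mutation classes.
#
# The canonical in-memory representation of a set of somatic variants is a
# data frame with one row per variant and columns:
#   id, chrom, pos (1-based), ref, alt, kind ("SNV"/"indel"), gene,
#   consequence (missense/nonsense/frameshift/silent/splice/other),
#   ref_adenoma, alt_adenoma, ref_carcinoma, alt_carcinoma,
#   ref_normal, alt_normal  (non-negative read counts).

.VARIANT_COLS <- c("id", "chrom", "pos", "ref", "alt", "kind", "gene",
                   "consequence",
                   "ref_adenoma", "alt_adenoma",
                   "ref_carcinoma", "alt_carcinoma",
                   "ref_normal", "alt_normal")

.COUNT_COLS <- c("ref_adenoma", "alt_adenoma", "ref_carcinoma",
                 "alt_carcinoma", "ref_normal", "alt_normal")

.REGIONAL_CLASSES <- c("clonal", "adenoma_specific", "carcinoma_specific",
                       "absent")

# Validate a variant data frame; returns it invisibly (counts coerced to
# integer). Somatic calls are expected to have ~0 alt reads in the normal;
# that is flagged with a warning, not enforced.
.validate_variants <- function(variants) {
  if (!is.data.frame(variants))
    stop("'variants' must be a data frame", call. = FALSE)
  missing_cols <- setdiff(.VARIANT_COLS, names(variants))
  if (length(missing_cols))
    stop("variant table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(variants)) {
    if (any(variants$pos < 1))
      stop("variant positions must be >= 1 (1-based)", call. = FALSE)
    for (col in .COUNT_COLS) {
      if (any(!is.finite(variants[[col]]) | variants[[col]] < 0))
        stop("negative or missing read counts in '", col, "'", call. = FALSE)
      variants[[col]] <- as.integer(variants[[col]])
    }
    is_snv <- nchar(variants$ref) == 1L & nchar(variants$alt) == 1L
    mislabeled <- xor(is_snv, variants$kind == "SNV")
    if (any(mislabeled))
      stop("'kind' disagrees with allele lengths for variant(s): ",
           paste(head(variants$id[mislabeled], 5L), collapse = ", "),
           call. = FALSE)
    if (anyDuplicated(variants$id))
      stop("duplicated variant ids", call. = FALSE)
    n_alt_normal <- sum(variants$alt_normal > 0)
    if (n_alt_normal > 0)
      warning(sprintf("%d variant(s) have alt reads in the normal sample",
                      n_alt_normal), call. = FALSE)
  }
  invisible(variants)
}

#' Mutant allele frequency from read counts
#'
#' MAF = alt / (ref + alt), the fraction of reads carrying the mutant allele.
#' Sites with zero total coverage get MAF 0 and are flagged in the
#' `no_coverage` attribute.
#'
#' @param ref_count,alt_count Non-negative integer vectors (recycled).
#' @return Numeric vector of MAFs in `[0, 1]`, with a logical attribute
#'   `no_coverage` marking entries where both counts were zero.
#' @examples
#' compute_maf(70, 30)          # 0.3
#' compute_maf(c(50, 0), c(0, 0))
#' @export
compute_maf <- function(ref_count, alt_count) {
  if (any(ref_count < 0) || any(alt_count < 0))
    stop("read counts must be non-negative", call. = FALSE)
  tot <- ref_count + alt_count
  no_cov <- tot == 0
  maf <- ifelse(no_cov, 0, alt_count / ifelse(no_cov, 1, tot))
  attr(maf, "no_coverage") <- no_cov
  maf
}

#' Classify variants by regional presence across the lesion pair
#'
#' A variant is present in a lesion when its alt read count is at least
#' `min_alt_reads` and its MAF at least `min_maf` there. Present in both
#' lesions gives `clonal` (acquired before the lesions diverged), present in
#' only one gives `adenoma_specific` or `carcinoma_specific`, present in
#' neither gives `absent`. These thresholds operationalize "commonly observed
#' in both lesions"; they are deliberately permissive so that subclonal but
#' real mutations still count as present.
#'
#' @param variants A variant data frame (see [read_variants()]).
#' @param min_alt_reads Minimum alt reads for presence (default 4).
#' @param min_maf Minimum MAF for presence (default 0.05).
#' @return Character vector of regional classes, one per variant.
#' @examples
#' sim <- simulate_lesion_pair(simulation_config("parallel", seed = 1))
#' table(classify_regional(sim$variants))
#' @export
classify_regional <- function(variants, min_alt_reads = 4L, min_maf = 0.05) {
  variants <- .validate_variants(variants)
  stopifnot(min_alt_reads >= 0, min_maf >= 0)
  present_a <- variants$alt_adenoma >= min_alt_reads &
    compute_maf(variants$ref_adenoma, variants$alt_adenoma) >= min_maf
  present_c <- variants$alt_carcinoma >= min_alt_reads &
    compute_maf(variants$ref_carcinoma, variants$alt_carcinoma) >= min_maf
  ifelse(present_a & present_c, "clonal",
         ifelse(present_a, "adenoma_specific",
                ifelse(present_c, "carcinoma_specific", "absent")))
}

#' Keep only high-confidence indels
#'
#' Indel calls from exome data are noisy; an indel is retained when its MAF
#' exceeds 0.40 in a lesion where it is observed, or when the site is covered
#' by more than 50 reads in a tumor lesion (so that even a modest MAF is
#' supported by many reads). SNVs pass through untouched.
#'
#' @param variants A variant data frame.
#' @param min_maf MAF disjunct threshold (default 0.40, exclusive).
#' @param min_depth Coverage disjunct threshold (default 50 reads, exclusive).
#' @return The subset of `variants` passing the filter.
#' @export
filter_high_confidence_indels <- function(variants, min_maf = 0.40,
                                          min_depth = 50L) {
  variants <- .validate_variants(variants)
  if (!nrow(variants)) return(variants)
  is_indel <- variants$kind == "indel"
  maf_a <- compute_maf(variants$ref_adenoma, variants$alt_adenoma)
  maf_c <- compute_maf(variants$ref_carcinoma, variants$alt_carcinoma)
  maf_present <- pmax(ifelse(variants$alt_adenoma > 0, maf_a, 0),
                      ifelse(variants$alt_carcinoma > 0, maf_c, 0))
  depth <- pmax(variants$ref_adenoma + variants$alt_adenoma,
                variants$ref_carcinoma + variants$alt_carcinoma)
  keep <- !is_indel | maf_present > min_maf | depth > min_depth
  variants[keep, , drop = FALSE]
}

#' Tabulate mutation abundance by regional class and variant kind
#'
#' @param variants A variant data frame.
#' @param classes Regional class per variant, as from [classify_regional()];
#'   every variant must be classified (no `NA`).
#' @return An integer matrix, rows = regional classes, columns = kinds
#'   (`SNV`, `indel`); entries sum to `nrow(variants)`.
#' @export
summarize_abundance <- function(variants,
                                classes = classify_regional(variants)) {
  variants <- .validate_variants(variants)
  if (length(classes) != nrow(variants))
    stop("'classes' must have one entry per variant", call. = FALSE)
  if (anyNA(classes) || !all(classes %in% .REGIONAL_CLASSES))
    stop("every variant must carry a valid regional class", call. = FALSE)
  tab <- table(factor(classes, levels = .REGIONAL_CLASSES),
               factor(variants$kind, levels = c("SNV", "indel")))
  m <- matrix(as.integer(tab), nrow = length(.REGIONAL_CLASSES),
              dimnames = list(class = .REGIONAL_CLASSES,
                              kind = c("SNV", "indel")))
  stopifnot(sum(m) == nrow(variants))
  m
}

.SPECTRUM_CATEGORIES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Six-category substitution spectrum of SNVs
#'
#' Counts single-base substitutions in the six pyrimidine-reference
#' categories; substitutions with a purine reference (A or G) are collapsed
#' onto the reverse-complement category (e.g. G>A is counted as C>T), the
#' standard strand-symmetric convention.
#'
#' @param variants A variant data frame containing only SNVs.
#' @return Named integer vector over `C>A, C>G, C>T, T>A, T>C, T>G`.
#' @examples
#' v <- simulate_lesion_pair(simulation_config(seed = 2))$variants
#' mutation_spectrum(v)
#' @export
mutation_spectrum <- function(variants) {
  variants <- .validate_variants(variants)
  if (nrow(variants) && any(variants$kind != "SNV"))
    stop("mutation_spectrum() accepts SNVs only", call. = FALSE)
  ref <- variants$ref
  alt <- variants$alt
  flip <- ref %in% c("A", "G")
  ref[flip] <- .COMPLEMENT[ref[flip]]
  alt[flip] <- .COMPLEMENT[alt[flip]]
  cat6 <- paste0(ref, ">", alt)
  bad <- !cat6 %in% .SPECTRUM_CATEGORIES
  if (any(bad))
    stop("non-ACGT substitution(s): ", paste(unique(cat6[bad]),
                                             collapse = ", "), call. = FALSE)
  counts <- table(factor(cat6, levels = .SPECTRUM_CATEGORIES))
  setNames(as.integer(counts), .SPECTRUM_CATEGORIES)
}
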