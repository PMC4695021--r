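# Synthetic paired-lesion data with recoverable ground truth. The MAF model:
# for a copy-neutral heterozygous variant with cancer-cell fraction c in a
# lesion of purity rho, the expected mutant allele frequency is rho * c / 2.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Configuration for a paired-lesion clone-model simulation
#'
#' Defines the ground-truth clone model for one synchronous adenoma-carcinoma
#' pair. Under the `parallel` model both lesions descend independently from a
#' last common ancestor: variants are clonal (in both), adenoma-specific, or
#' carcinoma-specific. Under the `stepwise` model the carcinoma arises from a
#' subclone of the adenoma: the variants private to the carcinoma lineage were
#' acquired while that clone was still an adenoma subclone, so they appear at
#' cancer-cell fraction `stepwise_subclone_fraction` in the adenoma and are
#' clonal in the carcinoma (class `stepwise_intermediate`).
#'
#' @param model `"parallel"` or `"stepwise"`.
#' @param purity_adenoma,purity_carcinoma Tumor cell content of each
#'   microdissected lesion, in `[0, 1]`. Defaults 0.75, typical of careful
#'   needle microdissection.
#' @param n_clonal,n_adenoma_specific,n_carcinoma_specific Variant counts per
#'   class. Under `model = "stepwise"` the `n_carcinoma_specific` variants are
#'   emitted as class `stepwise_intermediate` (see Details).
#' @param stepwise_subclone_fraction Cancer-cell fraction, within the adenoma,
#'   of the carcinoma-fated subclone; in `(0, 1)`. Used only when
#'   `model = "stepwise"`.
#' @param mean_depth Mean sequencing depth; per-lesion depths are
#'   Poisson(`mean_depth`) per variant, typical of whole-exome data.
#' @param outlier_fraction Fraction (of the configured class total) of extra
#'   outlier variants whose true MAF pair is uniform on the unit square,
#'   emulating artifactual calls; in `[0, 1)`.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_lesion_pair()]
#' @export
simulation_config <- function(model = c("parallel", "stepwise"),
                              purity_adenoma = 0.75,
                              purity_carcinoma = 0.75,
                              n_clonal = 400L,
                              n_adenoma_specific = 200L,
                              n_carcinoma_specific = 200L,
                              stepwise_subclone_fraction = 0.3,
                              mean_depth = 120,
                              outlier_fraction = 0.02,
                              seed = 1L) {
  model <- match.arg(model)
  .stopifnot_fraction(purity_adenoma, "purity_adenoma")
  .stopifnot_fraction(purity_carcinoma, "purity_carcinoma")
  n_clonal <- .stopifnot_count(n_clonal, "n_clonal")
  n_adenoma_specific <- .stopifnot_count(n_adenoma_specific,
                                         "n_adenoma_specific")
  n_carcinoma_specific <- .stopifnot_count(n_carcinoma_specific,
                                           "n_carcinoma_specific")
  if (model == "stepwise") {
    .stopifnot_fraction(stepwise_subclone_fraction,
                        "stepwise_subclone_fraction",
                        open_lo = TRUE, open_hi = TRUE)
  }
  if (!is.numeric(mean_depth) || length(mean_depth) != 1L || mean_depth <= 0)
    stop("'mean_depth' must be a single positive number", call. = FALSE)
  .stopifnot_fraction(outlier_fraction, "outlier_fraction", open_hi = TRUE)
  seed <- .stopifnot_count(seed, "seed", min = -2147483647L)
  structure(list(model = model,
                 purity_adenoma = purity_adenoma,
                 purity_carcinoma = purity_carcinoma,
                 n_clonal = n_clonal,
                 n_adenoma_specific = n_adenoma_specific,
                 n_carcinoma_specific = n_carcinoma_specific,
                 stepwise_subclone_fraction = stepwise_subclone_fraction,
                 mean_depth = mean_depth,
                 outlier_fraction = outlier_fraction,
                 seed = seed),
            class = "simulation_config")
}

.SIM_BASES <- c("A", "C", "G", "T")

#' Simulate a paired adenoma-carcinoma somatic variant table
#'
#' Draws somatic variants under the clone model in `config` and emits read
#' counts per lesion: per-lesion depth is Poisson(`mean_depth`) and the alt
#' count is Binomial(depth, rho * c / 2) where rho is the lesion purity and c
#' the class's cancer-cell fraction in that lesion — clonal (1, 1),
#' adenoma-specific (1, 0), carcinoma-specific (0, 1), and (stepwise model
#' only) stepwise-intermediate (f, 1). Outlier variants get a true MAF pair
#' uniform on the unit square. All simulated variants are autosomal,
#' copy-neutral, heterozygous SNVs; the matched normal has alt count 0.
#'
#' @param config A [simulation_config()].
#' @return A list of class `lesion_pair_simulation` with elements
#'   `variants` (a variant data frame as returned by [read_variants()]),
#'   `truth` (data frame `variant_id`, `true_class`), and `config`.
#' @examples
#' sim <- simulate_lesion_pair(simulation_config("parallel", seed = 7))
#' head(sim$variants)
#' table(sim$truth$true_class)
#' @export
simulate_lesion_pair <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n_core <- config$n_clonal + config$n_adenoma_specific +
    config$n_carcinoma_specific
  n_out <- round(config$outlier_fraction * n_core)
  carcinoma_class <- if (config$model == "stepwise")
    "stepwise_intermediate" else "carcinoma_specific"
  classes <- c(rep("clonal", config$n_clonal),
               rep("adenoma_specific", config$n_adenoma_specific),
               rep(carcinoma_class, config$n_carcinoma_specific),
               rep("outlier", n_out))
  n <- length(classes)
  f <- config$stepwise_subclone_fraction
  ccf <- rbind(clonal = c(1, 1),
               adenoma_specific = c(1, 0),
               carcinoma_specific = c(0, 1),
               stepwise_intermediate = c(f, 1))

  is_out <- classes == "outlier"
  ccf_idx <- match(classes, rownames(ccf))
  ccf_idx[is_out] <- 1L  # placeholder; outlier MAFs are drawn uniformly below
  .with_seed(config$seed, {
    p_a <- ifelse(is_out, runif(n),
                  config$purity_adenoma * ccf[ccf_idx, 1] / 2)
    p_c <- ifelse(is_out, runif(n),
                  config$purity_carcinoma * ccf[ccf_idx, 2] / 2)
    dep_a <- rpois(n, config$mean_depth)
    dep_c <- rpois(n, config$mean_depth)
    dep_n <- rpois(n, config$mean_depth)
    alt_a <- rbinom(n, dep_a, p_a)
    alt_c <- rbinom(n, dep_c, p_c)
    chrom <- sample(as.character(1:22), n, replace = TRUE)
    pos <- sample.int(5e7, n, replace = TRUE)
    ref <- sample(.SIM_BASES, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(.SIM_BASES, b), 1L), "")
    gene <- sprintf("GENE%03d", sample.int(300L, n, replace = TRUE))
    consequence <- sample(c("missense", "silent", "nonsense", "splice",
                            "other"),
                          n, replace = TRUE,
                          prob = c(0.50, 0.25, 0.07, 0.03, 0.15))
  })

  id <- sprintf("var%05d", seq_len(n))
  variants <- data.frame(
    id = id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    kind = "SNV", gene = gene, consequence = consequence,
    ref_adenoma = dep_a - alt_a, alt_adenoma = alt_a,
    ref_carcinoma = dep_c - alt_c, alt_carcinoma = alt_c,
    ref_normal = dep_n, alt_normal = 0L,
    stringsAsFactors = FALSE
  )
  structure(list(variants = variants,
                 truth = data.frame(variant_id = id, true_class = classes,
                                    stringsAsFactors = FALSE),
                 config = config),
            class = "lesion_pair_simulation")
}

#' @export
print.lesion_pair_simulation <- function(x, ...) {
  cat(sprintf("Paired-lesion simulation (%s model, seed %d)\n",
              x$config$model, x$config$seed))
  cat(sprintf("  purities: adenoma %.2f, carcinoma %.2f; mean depth %g\n",
              x$config$purity_adenoma, x$config$purity_carcinoma,
              x$config$mean_depth))
  print(table(x$truth$true_class))
  invisible(x)
}

#' Configuration for microsatellite read-length simulation
#'
#' @param n_null_loci,n_msi_loci Numbers of microsatellite-stable and
#'   MSI-positive loci.
#' @param reads_per_locus Spanning reads per locus per sample.
#' @param stutter_prob Per-unit PCR/sequencing slippage probability of the
#'   symmetric geometric stutter noise model: an observed tract length is the
#'   true length plus d, with P(|d| = k) proportional to `stutter_prob^k`,
#'   truncated at |d| <= 3. In `[0, 1)`.
#' @param msi_shift Integer mode shift (bp) of the tumor distribution at MSI
#'   loci, typically negative (deletion slippage dominates in mismatch-repair
#'   deficient tumors).
#' @param seed Integer seed.
#' @return An object of class `msi_simulation_config`.
#' @seealso [simulate_msi_observations()]
#' @export
msi_simulation_config <- function(n_null_loci = 200L, n_msi_loci = 20L,
                                  reads_per_locus = 50L, stutter_prob = 0.1,
                                  msi_shift = -3L, seed = 1L) {
  n_null_loci <- .stopifnot_count(n_null_loci, "n_null_loci", min = 1L)
  n_msi_loci <- .stopifnot_count(n_msi_loci, "n_msi_loci", min = 0L)
  reads_per_locus <- .stopifnot_count(reads_per_locus, "reads_per_locus",
                                      min = 1L)
  .stopifnot_fraction(stutter_prob, "stutter_prob", open_hi = TRUE)
  msi_shift <- .stopifnot_count(msi_shift, "msi_shift", min = -60L)
  seed <- .stopifnot_count(seed, "seed", min = -2147483647L)
  structure(list(n_null_loci = n_null_loci, n_msi_loci = n_msi_loci,
                 reads_per_locus = reads_per_locus,
                 stutter_prob = stutter_prob, msi_shift = msi_shift,
                 seed = seed),
            class = "msi_simulation_config")
}

# Symmetric truncated-geometric stutter draws: P(d = 0) prop. 1,
# P(d = +/-k) prop. stutter_prob^k / 2 for k = 1..3.
.rstutter <- function(n, stutter_prob) {
  if (stutter_prob == 0) return(integer(n))
  d <- -3:3
  w <- ifelse(d == 0, 1, stutter_prob^abs(d) / 2)
  sample(d, n, replace = TRUE, prob = w / sum(w))
}

#' Simulate microsatellite repeat-length observations
#'
#' For each locus with true tract length L, normal-sample observations are
#' L + d with d drawn from the symmetric truncated-geometric stutter model.
#' At MSI-true loci the tumor observations are additionally shifted by
#' `msi_shift` with probability 0.5 per read (a 50/50 mixture of the wild-type
#' and the slipped allele, as expected for a heterozygous somatic event);
#' tumor reads at null loci follow the normal model. Observed lengths are
#' floored at 1 bp.
#'
#' @param config An [msi_simulation_config()].
#' @return A list of class `msi_simulation` with elements `loci` (data frame
#'   `locus_id`, `unit`, `tract_length`), `lengths` (long data frame
#'   `locus_id`, `sample` in normal/tumor, `length`, one row per spanning
#'   read), and `truth` (data frame `locus_id`, `is_msi`).
#' @export
simulate_msi_observations <- function(config) {
  stopifnot(inherits(config, "msi_simulation_config"))
  n_loci <- config$n_null_loci + config$n_msi_loci
  r <- config$reads_per_locus
  .with_seed(config$seed, {
    tract <- sample(10:30, n_loci, replace = TRUE)
    unit <- sample(c("A", "C", "AC", "AG", "AAT"), n_loci, replace = TRUE)
    is_msi <- c(rep(FALSE, config$n_null_loci), rep(TRUE, config$n_msi_loci))
    norm_len <- rep(tract, each = r) + .rstutter(n_loci * r,
                                                 config$stutter_prob)
    shift <- ifelse(rep(is_msi, each = r) & runif(n_loci * r) < 0.5,
                    config$msi_shift, 0L)
    tum_len <- rep(tract, each = r) + shift +
      .rstutter(n_loci * r, config$stutter_prob)
  })
  locus_id <- sprintf("ms%04d", seq_len(n_loci))
  per_read_id <- rep(locus_id, each = r)
  lengths <- rbind(
    data.frame(locus_id = per_read_id, sample = "normal",
               length = pmax(1L, as.integer(norm_len)),
               stringsAsFactors = FALSE),
    data.frame(locus_id = per_read_id, sample = "tumor",
               length = pmax(1L, as.integer(tum_len)),
               stringsAsFactors = FALSE)
  )
  structure(list(
    loci = data.frame(locus_id = locus_id, unit = unit, tract_length = tract,
                      stringsAsFactors = FALSE),
    lengths = lengths,
    truth = data.frame(locus_id = locus_id, is_msi = is_msi,
                       stringsAsFactors = FALSE),
    config = config
  ), class = "msi_simulation")
}

#' Simulate a binned read-depth profile with known segments
#'
#' Generates a tumor/normal depth table over `n_bins` fixed-width bins with a
#' piecewise-constant true copy signal: the normal depth is a constant
#' baseline plus Gaussian noise, the tumor depth is baseline times
#' `2^segment_log2` plus noise. Each bin gets a GC fraction drawn uniformly
#' in `[0.35, 0.55]`; with `gc_effect = TRUE` a smooth multiplicative GC bias
#' (`2^(2 * (gc - 0.45))`) is applied identically to both samples, so it
#' cancels in a perfect correction but distorts raw depths.
#'
#' @param n_bins Number of bins.
#' @param breakpoints Integer positions strictly increasing within
#'   `(0, n_bins)`; bin i belongs to segment j when
#'   `breakpoints[j-1] < i <= breakpoints[j]`.
#' @param segment_log2 True log2 tumor/normal ratio per segment; length
#'   `length(breakpoints) + 1`.
#' @param noise_sd Additive depth noise standard deviation, in read-depth
#'   units.
#' @param gc_effect Apply the shared GC bias?
#' @param seed Integer seed.
#' @param base_depth Baseline normal depth (default 100 reads).
#' @param bin_width Bin width in bp for the emitted coordinates (default 1e4).
#' @return A data frame of bins (`chrom`, `start`, `end`, `gc`,
#'   `depth_tumor`, `depth_normal`) with the truth recorded in attributes
#'   `breakpoints`, `segment_log2` and `gc_bias`.
#' @export
simulate_depth_profile <- function(n_bins, breakpoints, segment_log2,
                                   noise_sd = 5, gc_effect = FALSE,
                                   seed = 1L, base_depth = 100,
                                   bin_width = 1e4) {
  n_bins <- .stopifnot_count(n_bins, "n_bins", min = 1L)
  breakpoints <- as.integer(breakpoints)
  if (length(breakpoints) &&
      (any(diff(breakpoints) <= 0) || any(breakpoints <= 0) ||
       any(breakpoints >= n_bins)))
    stop("'breakpoints' must be strictly increasing within (0, n_bins)",
         call. = FALSE)
  if (length(segment_log2) != length(breakpoints) + 1L)
    stop("'segment_log2' must have length(breakpoints) + 1 values",
         call. = FALSE)
  seed <- .stopifnot_count(seed, "seed", min = -2147483647L)

  seg_id <- findInterval(seq_len(n_bins), breakpoints + 1L) + 1L
  l2 <- segment_log2[seg_id]
  .with_seed(seed, {
    gc <- runif(n_bins, 0.35, 0.55)  # per-bin GC, independent of position
    bias <- if (gc_effect) 2^(2 * (gc - 0.45)) else rep(1, n_bins)
    depth_normal <- pmax(0, base_depth * bias + rnorm(n_bins, 0, noise_sd))
    depth_tumor <- pmax(0, base_depth * 2^l2 * bias +
                          rnorm(n_bins, 0, noise_sd))
  })
  bins <- data.frame(
    chrom = "chr1",
    start = (seq_len(n_bins) - 1L) * bin_width,
    end = seq_len(n_bins) * bin_width,
    gc = gc,
    depth_tumor = depth_tumor,
    depth_normal = depth_normal,
    stringsAsFactors = FALSE
  )
  attr(bins, "breakpoints") <- breakpoints
  attr(bins, "segment_log2") <- segment_log2
  attr(bins, "gc_bias") <- bias
  bins
}
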