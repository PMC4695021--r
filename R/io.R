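# File formats. VCF is 1-based; BED output is 0-based half-open. Microsatellite
# loci are kept 0-based half-open internally, matching their BED serialization;
# conversion from 1-based variant positions happens in one place
# (reconcile_with_indels).

.SAMPLE_NAMES <- c(adenoma = "ADENOMA", carcinoma = "CARCINOMA",
                   normal = "NORMAL")

#' Read somatic variants from VCF or TSV
#'
#' Two dialects are supported. **VCF v4.2** (as written by [write_variants()]):
#' per-sample `AD` FORMAT field holding `ref,alt` depths for the three samples,
#' gene and consequence in the `GENE=`/`CONS=` INFO keys. **TSV**: a header
#' plus the canonical columns `id, chrom, pos, ref, alt, kind, gene,
#' consequence, ref_adenoma, alt_adenoma, ref_carcinoma, alt_carcinoma,
#' ref_normal, alt_normal`. Round-trips losslessly with [write_variants()] in
#' either dialect.
#'
#' @param path File path.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by file extension).
#' @param sample_names Named character vector mapping the roles
#'   `adenoma`, `carcinoma`, `normal` to the VCF sample column names.
#' @return A variant data frame (see [classify_regional()] for the contract).
#' @export
read_variants <- function(path, format = c("auto", "vcf", "tsv"),
                          sample_names = .SAMPLE_NAMES) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (format == "auto") {
    format <- if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE))
      "vcf" else "tsv"
  }
  if (format == "vcf") .read_variants_vcf(path, sample_names)
  else .read_variants_tsv(path)
}

.parse_ad <- function(ad, sample, path) {
  bad <- !grepl("^[0-9]+,[0-9]+$", ad)
  if (any(bad))
    stop(sprintf("%s: malformed AD for sample %s at record(s) %s",
                 path, sample,
                 paste(head(which(bad), 5L), collapse = ", ")),
         call. = FALSE)
  parts <- matrix(as.integer(unlist(strsplit(ad, ",", fixed = TRUE))),
                  ncol = 2L, byrow = TRUE)
  parts
}

.empty_variants <- function() {
  data.frame(id = character(), chrom = character(),
             pos = integer(), ref = character(),
             alt = character(), kind = character(),
             gene = character(), consequence = character(),
             ref_adenoma = integer(), alt_adenoma = integer(),
             ref_carcinoma = integer(), alt_carcinoma = integer(),
             ref_normal = integer(), alt_normal = integer(),
             stringsAsFactors = FALSE)
}

.read_variants_vcf <- function(path, sample_names) {
  # a header-only VCF is a valid empty variant set
  first_chars <- substr(readLines(path, warn = FALSE), 1L, 1L)
  if (!any(first_chars != "#" & first_chars != "")) return(.empty_variants())
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix  # full fixed region including INFO
  n <- nrow(fix)
  if (n == 0L) return(.empty_variants())
  info_get <- function(info, key) {
    hit <- regmatches(info, regexpr(paste0("(^|;)", key, "=[^;]*"), info))
    out <- character(length(info))
    found <- grepl(paste0("(^|;)", key, "="), info)
    out[found] <- sub(paste0("^;?", key, "="), "", hit)
    out
  }
  ad <- vcfR::extract.gt(vcf, element = "AD")
  missing_samples <- setdiff(unname(sample_names), colnames(ad))
  if (length(missing_samples))
    stop(path, ": missing required sample column(s): ",
         paste(missing_samples, collapse = ", "), call. = FALSE)
  info <- unname(fix[, "INFO"])
  info[is.na(info)] <- ""
  ref <- unname(fix[, "REF"])
  alt <- unname(fix[, "ALT"])
  ad_a <- .parse_ad(ad[, sample_names[["adenoma"]]], "adenoma", path)
  ad_c <- .parse_ad(ad[, sample_names[["carcinoma"]]], "carcinoma", path)
  ad_n <- .parse_ad(ad[, sample_names[["normal"]]], "normal", path)
  variants <- data.frame(
    id = unname(fix[, "ID"]),
    chrom = unname(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = ref, alt = alt,
    kind = ifelse(nchar(ref) == 1L & nchar(alt) == 1L, "SNV", "indel"),
    gene = info_get(info, "GENE"),
    consequence = info_get(info, "CONS"),
    ref_adenoma = ad_a[, 1L], alt_adenoma = ad_a[, 2L],
    ref_carcinoma = ad_c[, 1L], alt_carcinoma = ad_c[, 2L],
    ref_normal = ad_n[, 1L], alt_normal = ad_n[, 2L],
    stringsAsFactors = FALSE
  )
  .validate_variants(variants)
  variants
}

.read_variants_tsv <- function(path) {
  variants <- read.delim(path, stringsAsFactors = FALSE,
                         colClasses = c(chrom = "character"))
  missing_cols <- setdiff(.VARIANT_COLS, names(variants))
  if (length(missing_cols))
    stop(path, ": missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (col in .COUNT_COLS) {
    bad <- which(!is.finite(variants[[col]]) | variants[[col]] < 0)
    if (length(bad))
      stop(sprintf("%s: bad count in '%s' at data line(s) %s", path, col,
                   paste(head(bad, 5L), collapse = ", ")), call. = FALSE)
  }
  variants[c("gene", "consequence")] <-
    lapply(variants[c("gene", "consequence")],
           function(x) ifelse(is.na(x), "", as.character(x)))
  .validate_variants(variants)
  variants[.VARIANT_COLS]
}

#' Write somatic variants to VCF or TSV
#'
#' The VCF output is minimal v4.2: `CHROM POS ID REF ALT QUAL FILTER INFO
#' FORMAT` plus the three sample columns, depths in the `AD` FORMAT key and
#' gene/consequence in `GENE=`/`CONS=` INFO keys.
#'
#' @param variants A variant data frame.
#' @param path Output path.
#' @param format `"vcf"`, `"tsv"`, or `"auto"` (by extension).
#' @param sample_names As in [read_variants()].
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path, format = c("auto", "vcf", "tsv"),
                           sample_names = .SAMPLE_NAMES) {
  variants <- .validate_variants(variants)
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.vcf$", path, ignore.case = TRUE)) "vcf" else "tsv"
  }
  if (format == "tsv") {
    write.table(variants[.VARIANT_COLS], path, sep = "\t", quote = FALSE,
                row.names = FALSE)
    return(invisible(path))
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=CONS,Number=1,Type=String,Description=\"Functional consequence\">",
    paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
           "Description=\"Allelic depths (ref,alt)\">"),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names[["adenoma"]], sample_names[["carcinoma"]],
            sample_names[["normal"]]), collapse = "\t")
  )
  info <- ifelse(variants$gene == "" & variants$consequence == "", ".",
                 paste0(ifelse(variants$gene == "", "",
                               paste0("GENE=", variants$gene)),
                        ifelse(variants$gene == "" |
                                 variants$consequence == "", "", ";"),
                        ifelse(variants$consequence == "", "",
                               paste0("CONS=", variants$consequence))))
  if (nrow(variants) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  body <- paste(variants$chrom, variants$pos, variants$id, variants$ref,
                variants$alt, ".", "PASS", info, "AD",
                paste0(variants$ref_adenoma, ",", variants$alt_adenoma),
                paste0(variants$ref_carcinoma, ",", variants$alt_carcinoma),
                paste0(variants$ref_normal, ",", variants$alt_normal),
                sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read / write binned depth tables
#'
#' Plain TSV with header `chrom start end gc depth_tumor depth_normal`
#' (0-based half-open bins), the contract consumed by [gc_correct()] and
#' [normalize_and_ratio()].
#'
#' @param path File path.
#' @return `read_depth_bins()`: the bin data frame; `write_depth_bins()`:
#'   `path` invisibly.
#' @export
read_depth_bins <- function(path) {
  bins <- read.delim(path, stringsAsFactors = FALSE,
                     colClasses = c(chrom = "character"))
  need <- c("chrom", "start", "end", "gc", "depth_tumor", "depth_normal")
  missing_cols <- setdiff(need, names(bins))
  if (length(missing_cols))
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  bins
}

#' @rdname read_depth_bins
#' @param bins A depth-bin data frame.
#' @export
write_depth_bins <- function(bins, path) {
  write.table(bins, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write microsatellite loci as BED
#'
#' 0-based half-open intervals; name column is `locus_id|unit`, score the
#' tract length.
#'
#' @param loci Locus data frame from [find_microsatellites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  lines <- paste(loci$seq_id, loci$start, loci$end,
                 paste0(loci$locus_id, "|", loci$unit),
                 loci$tract_length, ".", sep = "\t")
  writeLines(lines, path)
  invisible(path)
}

#' Read spanning-read records for MSI calling
#'
#' Plain TSV with header `sample sequence mapped_start`; `mapped_start` is the
#' 0-based reference position of the read's first base (the contract of
#' [extract_intraread_lengths()]).
#'
#' @param path File path.
#' @return Data frame of read records.
#' @export
read_spanning_reads <- function(path) {
  reads <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample", "sequence", "mapped_start")
  missing_cols <- setdiff(need, names(reads))
  if (length(missing_cols))
    stop(path, ": missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  reads
}

#' Read a reference sequence from FASTA
#'
#' Thin wrapper returning plain uppercase character strings keyed by record
#' name (first whitespace-delimited token), suitable for
#' [find_microsatellites()]. Uses Biostrings when available, else a minimal
#' parser.
#'
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_reference_fasta <- function(path) {
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    seqs <- Biostrings::readDNAStringSet(path)
    out <- toupper(as.character(seqs))
    names(out) <- sub("\\s.*$", "", names(seqs))
    return(out)
  }
  lines <- readLines(path)
  hdr <- grepl("^>", lines)
  if (!any(hdr)) stop(path, ": not a FASTA file", call. = FALSE)
  idx <- cumsum(hdr)
  out <- vapply(split(lines[!hdr], idx[!hdr]),
                function(x) toupper(paste(x, collapse = "")), "")
  names(out) <- sub("^>", "", sub("\\s.*$", "", lines[hdr]))
  out
}
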