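# In-code fixture builders shared across test files.

# One variant row with sensible defaults, overridable per field.
make_variant <- function(id = "v1", chrom = "1", pos = 1000L, ref = "C",
                         alt = "T", kind = NULL, gene = "GENE1",
                         consequence = "missense",
                         adenoma = c(60L, 20L), carcinoma = c(60L, 20L),
                         normal = c(80L, 0L)) {
  if (is.null(kind))
    kind <- if (nchar(ref) == 1L && nchar(alt) == 1L) "SNV" else "indel"
  data.frame(id = id, chrom = chrom, pos = pos, ref = ref, alt = alt,
             kind = kind, gene = gene, consequence = consequence,
             ref_adenoma = adenoma[1L], alt_adenoma = adenoma[2L],
             ref_carcinoma = carcinoma[1L], alt_carcinoma = carcinoma[2L],
             ref_normal = normal[1L], alt_normal = normal[2L],
             stringsAsFactors = FALSE)
}

make_variants <- function(...) {
  rows <- list(...)
  for (i in seq_along(rows)) {
    if (rows[[i]]$id == "v1") rows[[i]]$id <- sprintf("v%03d", i)
  }
  do.call(rbind, rows)
}

# Reads spanning a locus: reference tract of `units` copies of `unit`,
# flanked by fixed anchors, optionally with `delta` repeat units added or
# removed in the read. The right flank is generous so that deletion reads
# still span the reference locus interval.
make_spanning_read <- function(sample, unit, units, delta = 0L,
                               left = "GGTCG", right = "TTGCATTGCA",
                               locus_start = 5L) {
  seq <- paste0(left, strrep(unit, units + delta), right)
  data.frame(sample = sample, sequence = seq,
             mapped_start = locus_start - nchar(left),
             stringsAsFactors = FALSE)
}
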