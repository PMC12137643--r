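# Shared builders for small in-code fixtures.

# snp_data from a plain dosage matrix (samples x variants), evenly spaced
# positions on one chromosome unless positions are given.
make_snp <- function(D, chrom = "Chr1", pos = NULL, ref = "A", alt = "C",
                     qual = 500, dp = NULL, gq = NULL, phased = NULL) {
  m <- ncol(D)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  v <- data.frame(chrom = rep(chrom, length.out = m), pos = pos,
                  ref = rep(ref, length.out = m),
                  alt = rep(alt, length.out = m),
                  qual = rep(qual, length.out = m),
                  stringsAsFactors = FALSE)
  snp_data(v, D, dp = dp, gq = gq, phased = phased)
}

# phased snp_data from a haplotype matrix (2 rows per sample)
make_phased <- function(H, samples = NULL, chrom = "Chr1", pos = NULL) {
  n <- nrow(H) / 2
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  D <- H[seq(1, 2 * n, 2), , drop = FALSE] + H[seq(2, 2 * n, 2), , drop = FALSE]
  rownames(D) <- samples
  rownames(H) <- paste0(rep(samples, each = 2), c("_h1", "_h2"))
  make_snp(D, chrom = chrom, pos = pos, phased = H)
}

write_lines_tmp <- function(lines, ext) {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# minimal VCF text fixture
vcf_fixture <- function(records, samples = c("S1", "S2", "S3")) {
  c("##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", samples), collapse = "\t"),
    records)
}

simple_pedigree <- function() {
  validate_pedigree(data.frame(
    individual = c("A", "B", "C"),
    sire = c(NA, NA, "A"),
    dam = c(NA, NA, "B"),
    relation_type = "cross", stringsAsFactors = FALSE))
}
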