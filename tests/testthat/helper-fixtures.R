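# in-code fixtures shared across the suite

write_test_vcf <- function(path, rows) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"Gene symbol\">",
    "##INFO=<ID=IMPACT,Number=1,Type=String,Description=\"Functional impact\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "TUMOR", sep = "\t"))
  writeLines(c(header, rows), path)
  path
}

vcf_row <- function(chrom, pos, ref, alt, ad, gene = "TP53", impact = 1) {
  paste(chrom, pos, ".", ref, alt, ".", "PASS",
        sprintf("GENE=%s;IMPACT=%s", gene, impact), "GT:AD",
        paste0("0/1:", ad), sep = "\t")
}

# two-sided Fisher p by explicit hypergeometric tail enumeration: sum the
# probabilities of all tables with the observed margins that are no more
# likely than the observed one
fisher_oracle <- function(a, b, c, d) {
  m <- a + b        # row 1 margin
  n <- c + d        # row 2 margin
  k <- a + c        # col 1 margin
  lo <- max(0L, k - n)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small deterministic segment table (0-based half-open)
make_segments <- function(sample_id = "S1") {
  data.frame(sample_id = sample_id,
             chrom = c("chr1", "chr1", "chr2"),
             start = c(0, 5e6, 2e6),
             end = c(2e6, 9e6, 6e6),
             log2_ratio = c(0.6, -1.0, 0.0),
             total_cn = c(3L, 1L, 2L),
             call = c(1L, -1L, 0L),
             stringsAsFactors = FALSE)
}
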