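# Brute-force oracles and small fixture builders shared across tests.
# The oracles are deliberately naive per-site loops, independent of the
# vectorized implementations they check.

brute_pair_counts <- function(ci, cj) {
  n_AaAa <- n_AAaa <- n_Aa_i <- n_Aa_j <- n_obs <- 0L
  for (k in seq_along(ci)) {
    a <- ci[k]
    b <- cj[k]
    if (is.na(a) || is.na(b)) next
    n_obs <- n_obs + 1L
    if (a == 1L && b == 1L) n_AaAa <- n_AaAa + 1L
    if ((a == 0L && b == 2L) || (a == 2L && b == 0L)) n_AAaa <- n_AAaa + 1L
    if (a == 1L) n_Aa_i <- n_Aa_i + 1L
    if (b == 1L) n_Aa_j <- n_Aa_j + 1L
  }
  list(n_AaAa = n_AaAa, n_AAaa = n_AAaa, n_Aa_i = n_Aa_i, n_Aa_j = n_Aa_j,
       n_obs = n_obs)
}

brute_phi <- function(ci, cj) {
  cnt <- brute_pair_counts(ci, cj)
  den <- cnt$n_Aa_i + cnt$n_Aa_j
  if (den == 0) NA_real_ else (cnt$n_AaAa - 2 * cnt$n_AAaa) / den
}

rand_code_matrix <- function(n_sites, n_samples, miss = 0.1) {
  matrix(
    sample(c(0L, 1L, 2L, NA_integer_), n_sites * n_samples, replace = TRUE,
           prob = c((1 - miss) / 3, (1 - miss) / 3, (1 - miss) / 3, miss)),
    n_sites, n_samples
  )
}

# geno_matrix from a bare code matrix (chrX non-PAR positions by default).
make_gm <- function(codes, contig = "chrX", pos = NULL,
                    samples = paste0("S", seq_len(ncol(codes))),
                    ad = NULL, dp = NULL, gq = NULL, af = NULL,
                    ref = "A", alt = "T") {
  n <- nrow(codes)
  if (is.null(pos)) pos <- 3000000L + seq_len(n)
  sites <- data.frame(contig = rep_len(contig, n), pos = pos,
                      ref = rep_len(ref, n), alt = rep_len(alt, n),
                      stringsAsFactors = FALSE)
  geno_matrix(sites, samples, codes = codes, ad = ad, dp = dp, gq = gq, af = af)
}

vcf_text <- function(body, samples = "S1",
                     format_defs = c("GT", "AD", "DP", "GQ")) {
  defs <- c(
    GT = "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    AD = "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    DP = "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    GQ = "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">"
  )
  c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrX>",
    "##contig=<ID=chr1>",
    unname(defs[format_defs]),
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    body
  )
}

write_temp_vcf <- function(lines) {
  p <- tempfile(fileext = ".vcf")
  writeLines(lines, p)
  p
}

toy_vcf <- function() system.file("extdata", "toy12.vcf", package = "xhetkin")

write_temp_bed <- function(lines) {
  p <- tempfile(fileext = ".bed")
  writeLines(lines, p)
  p
}
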