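# The core Xhet statistic: per-sample heterozygosity proportion on non-PAR
# chromosome X under parametric per-call filters. The denominator is
# het + hom-alt only: the method restricts to 0/1 and 1/1 genotypes before
# taking the proportion, so hom-ref calls never enter either count.

#' Count qualifying het and hom-alt genotypes on an interval
#'
#' Counts, for one sample, the sites inside the (inclusive) interval whose
#' call passes the per-call filters and classifies as het or hom-alt.
#' Hom-ref and missing calls are never counted. Haploid alt calls (`"1"`)
#' count as hom-alt.
#'
#' @param gm A [geno_matrix()].
#' @param sample Sample id present in `gm`.
#' @param region An [interval()]; default the shared non-PAR X interval.
#' @param params A [filter_params()].
#' @return Named integer vector `c(n_het = ..., n_homalt = ...)`.
#' @export
count_x_genotypes <- function(gm, sample, region = nonpar_x_interval(),
                              params = filter_params()) {
  stopifnot(inherits(gm, "geno_matrix"))
  j <- match(sample, gm$samples)
  if (is.na(j)) stop("sample not present in genotype matrix: ", sample, call. = FALSE)
  keep <- in_region(gm$sites$contig, gm$sites$pos, region)
  codes <- gm$codes[keep, j]
  af <- if (is.null(gm$af)) rep(NA_real_, sum(keep)) else gm$af[keep, j]
  dp <- if (is.null(gm$dp)) rep(NA_real_, sum(keep)) else gm$dp[keep, j]
  gq <- if (is.null(gm$gq)) rep(NA_real_, sum(keep)) else gm$gq[keep, j]
  ok <- call_filter_mask(af, dp, gq, params, codes = codes)
  c(
    n_het = sum(codes == 1L & ok, na.rm = TRUE),
    n_homalt = sum(codes == 2L & ok, na.rm = TRUE)
  )
}

#' The Xhet ratio
#'
#' `n_het / (n_het + n_homalt)`: the proportion of heterozygous genotypes
#' among the retained (het + hom-alt) genotypes. Near 0 for XY samples
#' (hemizygous non-PAR X), substantially positive for XX samples. With a
#' zero denominator the ratio is undefined and `NA` is returned (never 0 -
#' an undefined value must not silently cluster with the XY group).
#'
#' @param n_het,n_homalt Non-negative counts.
#' @return Numeric ratio in `[0, 1]`, or `NA` when undefined.
#' @examples
#' compute_xhet(5, 5)   # 0.5
#' compute_xhet(0, 100) # 0: the hemizygous-male pattern
#' @export
compute_xhet <- function(n_het, n_homalt) {
  stopifnot(n_het >= 0, n_homalt >= 0)
  tot <- n_het + n_homalt
  ifelse(tot > 0, n_het / tot, NA_real_)
}

#' Per-sample Xhet over a cohort
#'
#' Computes [count_x_genotypes()] and [compute_xhet()] for every sample,
#' returning one row per sample in sample-id order with the filter
#' parameters recorded for provenance.
#'
#' @param x A [geno_matrix()], a list of them (merged first), or a character
#'   vector of VCF paths.
#' @param region An [interval()]; default the shared non-PAR X interval.
#' @param params A [filter_params()].
#' @return data.frame with columns `sample`, `n_het`, `n_homalt`, `xhet`,
#'   `af_min`, `dp_min`, `gq_min`.
#' @export
xhet_batch <- function(x, region = nonpar_x_interval(), params = filter_params()) {
  gm <- if (is.character(x)) merge_samples(lapply(x, read_vcf)) else merge_samples(x)
  if (length(gm$samples) < 1L) stop("no samples in input", call. = FALSE)
  ord <- order(gm$samples)
  rows <- lapply(gm$samples[ord], function(s) {
    cnt <- count_x_genotypes(gm, s, region = region, params = params)
    data.frame(
      sample = s, n_het = unname(cnt["n_het"]), n_homalt = unname(cnt["n_homalt"]),
      xhet = compute_xhet(cnt["n_het"], cnt["n_homalt"]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$af_min <- params$af_min
  out$dp_min <- params$dp_min
  out$gq_min <- if (is.null(params$gq_min)) NA_real_ else params$gq_min
  out
}
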