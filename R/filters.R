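# Parametric genotype/variant filters shared by the relatedness and Xhet
# branches. Inequality directions follow the method exactly: strict > for
# allele fraction, depth and missingness; inclusive bounds for VAF windows;
# >= for the optional genotype-quality threshold.

#' Construct filter parameters
#'
#' @param af_min Allele-fraction threshold; calls pass when AF `> af_min`
#'   (strict). Default 0.25.
#' @param dp_min Depth threshold; calls pass when DP `> dp_min` (strict).
#'   Default 20.
#' @param gq_min Optional genotype-quality threshold; calls pass when GQ
#'   `>= gq_min`. Default `NULL` (no GQ filter).
#' @param miss_max Maximum missing-genotype fraction per site; sites with a
#'   missing fraction strictly greater are excluded. Default 0.2.
#' @param vaf_window Optional inclusive `(low, high)` VAF bounds in percent,
#'   e.g. `c(25, 75)`.
#' @param strict If `TRUE`, calls lacking AD/AF or DP fail the respective
#'   filter; by default they pass (treated as unfiltered), because not all
#'   callers emit those fields.
#' @return An object of class `filter_params`.
#' @examples
#' filter_params()            # the standard setting: AF > 0.25, DP > 20
#' filter_params(gq_min = 20)
#' @export
filter_params <- function(af_min = 0.25, dp_min = 20, gq_min = NULL,
                          miss_max = 0.2, vaf_window = NULL, strict = FALSE) {
  stopifnot(af_min >= 0, af_min <= 1, dp_min >= 0, miss_max >= 0, miss_max <= 1)
  if (!is.null(gq_min)) stopifnot(gq_min >= 0)
  if (!is.null(vaf_window)) {
    stopifnot(length(vaf_window) == 2L, vaf_window[1] <= vaf_window[2],
              vaf_window[1] >= 0, vaf_window[2] <= 100)
  }
  structure(
    list(af_min = af_min, dp_min = dp_min, gq_min = gq_min,
         miss_max = miss_max, vaf_window = vaf_window, strict = isTRUE(strict)),
    class = "filter_params"
  )
}

#' @export
print.filter_params <- function(x, ...) {
  cat(sprintf(
    "<filter_params> AF > %s, DP > %s, GQ >= %s, site missingness <= %s%s%s\n",
    x$af_min, x$dp_min, if (is.null(x$gq_min)) "(off)" else x$gq_min, x$miss_max,
    if (is.null(x$vaf_window)) "" else
      sprintf(", VAF in [%s, %s]%%", x$vaf_window[1], x$vaf_window[2]),
    if (x$strict) " [strict]" else ""
  ))
  invisible(x)
}

# Vectorized per-call filter mask from AF/DP/GQ values (NA = absent).
# The AF rule judges the credibility of a variant call, so hom-ref calls
# (codes == 0) are exempt from it: their allele fraction measures the
# absence of the variant, and a near-zero value is the expected signal,
# not a quality defect. (Variant-only caller output never contains hom-ref
# records, so there the exemption is vacuous.) DP/GQ apply to every call.
call_filter_mask <- function(af, dp, gq, params, codes = NULL) {
  pass_af <- if (params$strict) !is.na(af) & af > params$af_min else
    is.na(af) | af > params$af_min
  if (!is.null(codes)) pass_af <- pass_af | (!is.na(codes) & codes == 0L)
  pass_dp <- if (params$strict) !is.na(dp) & dp > params$dp_min else
    is.na(dp) | dp > params$dp_min
  pass_gq <- if (is.null(params$gq_min)) rep(TRUE, length(af)) else
    is.na(gq) | gq >= params$gq_min
  pass_af & pass_dp & pass_gq
}

#' Test whether a call passes the per-call filters
#'
#' A call passes iff its allele fraction is strictly above `af_min`, its
#' depth strictly above `dp_min`, and (when a GQ threshold is set) its
#' quality at least `gq_min`. Calls lacking a value pass that component
#' unless `strict` mode is set (GQ is always permissive when absent).
#' Hom-ref calls are exempt from the AF rule: their allele fraction is
#' expected to be near zero, so a low value carries no quality signal
#' (variant-only caller output never contains hom-ref records, making the
#' exemption vacuous there); DP and GQ apply to every call.
#'
#' @param call A [genotype_call()].
#' @param params A [filter_params()].
#' @return `TRUE` or `FALSE`.
#' @examples
#' passes_call_filters(genotype_call("0/1", ad = c(15, 5), dp = 21),
#'                     filter_params()) # AF = 0.25 exactly: fails strict >
#' @export
passes_call_filters <- function(call, params = filter_params()) {
  stopifnot(inherits(call, "genotype_call"), inherits(params, "filter_params"))
  af <- allele_fraction(call)
  gq <- if (length(call$gq)) call$gq else NA_real_
  as.logical(call_filter_mask(af, call$dp, gq, params,
                              codes = genotype_code(call$gt)))
}

#' Apply per-call filters to a genotype matrix
#'
#' Calls failing [passes_call_filters()] become missing genotypes: a
#' variant filtered out of one sample's VCF is, after merging, exactly a
#' missing genotype for that sample (and so feeds the missingness filter).
#'
#' @param gm A [geno_matrix()].
#' @param params A [filter_params()].
#' @return The filtered [geno_matrix()] (same sites, same samples).
#' @export
apply_call_filters <- function(gm, params = filter_params()) {
  stopifnot(inherits(gm, "geno_matrix"))
  af <- if (is.null(gm$af)) matrix(NA_real_, nrow(gm$codes), ncol(gm$codes)) else gm$af
  dp <- if (is.null(gm$dp)) matrix(NA_real_, nrow(gm$codes), ncol(gm$codes)) else gm$dp
  gq <- if (is.null(gm$gq)) matrix(NA_real_, nrow(gm$codes), ncol(gm$codes)) else gm$gq
  fail <- !call_filter_mask(af, dp, gq, params, codes = gm$codes)
  dim(fail) <- dim(gm$codes)
  gm$codes[fail] <- NA_integer_
  gm$gt[fail] <- "./."
  gm
}

#' Drop sites with too many missing genotypes
#'
#' Excludes sites whose fraction of missing genotypes is strictly greater
#' than `miss_max` (a site with exactly `miss_max` missing is retained).
#' The sample set and all retained genotype codes are unchanged.
#'
#' @param gm A [geno_matrix()].
#' @param miss_max Maximum missing fraction, default from `params`;
#'   0.2 reproduces the standard "more than 20% missing" exclusion.
#' @return A [geno_matrix()] with offending sites removed.
#' @export
missingness_filter <- function(gm, miss_max = 0.2) {
  stopifnot(inherits(gm, "geno_matrix"), nrow(gm$codes) >= 0)
  frac <- rowMeans(is.na(gm$codes))
  subset_sites(gm, frac <= miss_max)
}

#' Test whether a call's allele fraction lies in a VAF window
#'
#' @param call A [genotype_call()] or numeric allele fraction(s) in `[0,1]`.
#' @param window Inclusive `(low, high)` bounds in percent.
#' @return Logical; `FALSE` where the fraction is undefined.
#' @examples
#' in_vaf_window(0.25, c(25, 75)) # inclusive lower bound
#' @export
in_vaf_window <- function(call, window) {
  stopifnot(length(window) == 2L, window[1] <= window[2])
  af <- if (inherits(call, "genotype_call")) allele_fraction(call) else as.numeric(call)
  !is.na(af) & af >= window[1] / 100 & af <= window[2] / 100
}
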