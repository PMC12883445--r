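# KING-robust pairwise kinship from genotype codes, with degree
# classification. The estimator is computed over pairwise-complete sites
# only: phi = (N_Aa,Aa - 2 * N_AA,aa) / (N_Aa(i) + N_Aa(j)), the symmetric
# form with both samples' heterozygote counts in the denominator.

#' Pairwise genotype-sharing counts
#'
#' Accumulates, over positions where both samples are non-missing, the
#' counts the KING-robust estimator needs: both-heterozygous sites,
#' opposite-homozygote sites, and each sample's heterozygote count over the
#' jointly observed sites.
#'
#' @param codes_i,codes_j Aligned integer vectors of genotype codes
#'   (0 hom-ref, 1 het, 2 hom-alt, NA missing), equal length.
#' @return Named list: `n_AaAa`, `n_AAaa`, `n_Aa_i`, `n_Aa_j`, `n_obs`.
#' @examples
#' pair_counts(c(1, 1, 2, 0), c(1, 0, 2, 2))
#' @export
pair_counts <- function(codes_i, codes_j) {
  if (length(codes_i) != length(codes_j)) {
    stop("genotype code vectors differ in length", call. = FALSE)
  }
  both <- !is.na(codes_i) & !is.na(codes_j)
  ci <- codes_i[both]
  cj <- codes_j[both]
  list(
    n_AaAa = sum(ci == 1L & cj == 1L),
    n_AAaa = sum((ci == 0L & cj == 2L) | (ci == 2L & cj == 0L)),
    n_Aa_i = sum(ci == 1L),
    n_Aa_j = sum(cj == 1L),
    n_obs = sum(both)
  )
}

#' KING-robust kinship coefficient from pair counts
#'
#' `phi = (n_AaAa - 2 * n_AAaa) / (n_Aa_i + n_Aa_j)`. With a zero
#' denominator (neither sample has a heterozygote over the jointly observed
#' sites) the estimate is undefined and `NA` is returned rather than a
#' coerced 0 - a distinguishable failure mode.
#'
#' @param counts A list as returned by [pair_counts()].
#' @return Numeric phi (at most 0.5), or `NA` when undefined.
#' @export
king_phi <- function(counts) {
  den <- counts$n_Aa_i + counts$n_Aa_j
  if (den == 0) return(NA_real_)
  (counts$n_AaAa - 2 * counts$n_AAaa) / den
}

#' Classify a kinship coefficient into a relationship degree
#'
#' Standard powers-of-two bins: phi > 0.354 duplicate/MZ; (0.177, 0.354]
#' first degree; (0.0884, 0.177] second; (0.0442, 0.0884] third;
#' <= 0.0442 unrelated; `NA` stays `"undefined"`.
#'
#' @param phi Numeric vector of kinship coefficients.
#' @return Character vector of degree labels.
#' @examples
#' classify_degree(c(0.5, 0.26, 0.01, NA))
#' @export
classify_degree <- function(phi) {
  out <- rep("undefined", length(phi))
  ok <- !is.na(phi)
  out[ok & phi > 0.354] <- "duplicate/MZ"
  out[ok & phi > 0.177 & phi <= 0.354] <- "first"
  out[ok & phi > 0.0884 & phi <= 0.177] <- "second"
  out[ok & phi > 0.0442 & phi <= 0.0884] <- "third"
  out[ok & phi <= 0.0442] <- "unrelated"
  out
}

#' Pairwise kinship over a genotype matrix
#'
#' Computes [pair_counts()] and [king_phi()] for every unordered sample
#' pair, including the diagonal (self-kinship, 0.5 whenever the sample has
#' at least one het), in deterministic sample-id order.
#'
#' @param gm A [geno_matrix()] (usually already passed through the per-call
#'   and missingness filters).
#' @param autosomes_only If `TRUE`, restrict to autosomal contigs (drop
#'   X/Y/MT). Default `FALSE`: all contigs surviving the pre-filters enter.
#' @return data.frame with one row per unordered pair: `sample_i`,
#'   `sample_j`, `n_obs`, `n_AaAa`, `n_AAaa`, `n_Aa_i`, `n_Aa_j`, `phi`,
#'   `degree`.
#' @export
kinship_matrix <- function(gm, autosomes_only = FALSE) {
  stopifnot(inherits(gm, "geno_matrix"))
  if (length(gm$samples) < 2L) stop("kinship needs at least 2 samples", call. = FALSE)
  if (autosomes_only) gm <- subset_sites(gm, is_autosome(gm$sites$contig))
  ids <- sort(gm$samples)
  codes <- gm$codes[, ids, drop = FALSE]
  pairs <- list()
  k <- 0L
  for (a in seq_along(ids)) {
    for (b in a:length(ids)) {
      cnt <- pair_counts(codes[, a], codes[, b])
      phi <- king_phi(cnt)
      k <- k + 1L
      pairs[[k]] <- data.frame(
        sample_i = ids[a], sample_j = ids[b],
        n_obs = cnt$n_obs, n_AaAa = cnt$n_AaAa, n_AAaa = cnt$n_AAaa,
        n_Aa_i = cnt$n_Aa_i, n_Aa_j = cnt$n_Aa_j,
        phi = phi, degree = classify_degree(phi),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, pairs)
  rownames(out) <- NULL
  out
}

#' Square kinship matrix from the long pair table
#'
#' @param pairs Output of [kinship_matrix()].
#' @return Symmetric numeric matrix of phi with sample ids as dimnames.
#' @export
kinship_square <- function(pairs) {
  ids <- sort(unique(c(pairs$sample_i, pairs$sample_j)))
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(pairs))) {
    m[pairs$sample_i[r], pairs$sample_j[r]] <- pairs$phi[r]
    m[pairs$sample_j[r], pairs$sample_i[r]] <- pairs$phi[r]
  }
  m
}
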