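# Synthetic-cohort generator: pedigrees with sex-aware chromosome
# transmission under Hardy-Weinberg founders, a Poisson/Binomial read-depth
# model, and QC-failure injectors (sample swaps, duplicates, contamination,
# pseudo-heterozygosity in labeled trap intervals, X-homozygosity runs).
# Emits a genotype matrix (writable as VCF) plus a ground-truth record.

PAR1_LO <- 10001L
NONPAR_LO <- 2781479L
NONPAR_HI <- 153925834L

#' Default two-trio pedigree
#'
#' Two independent trios of mother (XX), father (XY) and son (XY) - the
#' benchmark-trio regime the method was designed around.
#' @return Pedigree data.frame (`id`, `father`, `mother`, `sex`).
#' @export
default_pedigree <- function() {
  data.frame(
    id = c("mother1", "father1", "son1", "mother2", "father2", "son2"),
    father = c(NA, NA, "father1", NA, NA, "father2"),
    mother = c(NA, NA, "mother1", NA, NA, "mother2"),
    sex = c("XX", "XY", "XY", "XX", "XY", "XY"),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration
#'
#' @param pedigree data.frame with columns `id`, `father`, `mother`
#'   (`NA` for founders), `sex` (`"XX"`/`"XY"`); founders must precede
#'   their descendants.
#' @param n_sites_autosome,n_sites_x Site counts for the autosomal panel
#'   (chr1) and chromosome X.
#' @param af_range Allele-frequency range for `runif` site AFs, default
#'   `c(0.05, 0.5)`.
#' @param par_fraction Fraction of X sites placed inside PAR1 coordinates
#'   (diploid in everyone), default 0.1.
#' @param depth_mean Expected read depth (Poisson mean), default 40.
#' @param genotype_error Per-call probability that the emitted genotype is
#'   replaced by a uniformly drawn different class, default 0.001.
#' @param pseudo_het_rate Per-site probability that a male non-PAR X call
#'   is rendered heterozygous (mis-mapping artifact), outside traps;
#'   default 0.005.
#' @param trap_intervals Optional [region_set()] of labeled chrX intervals
#'   where pseudo-heterozygosity concentrates.
#' @param trap_rate Pseudo-het rate inside trap intervals, default 0.35.
#' @param duplicates Named character vector `c(new_id = source_id)`:
#'   genotype-identical duplicate columns appended after transmission
#'   (depths drawn independently).
#' @param swap_pairs List of length-2 character vectors: sample columns to
#'   exchange after generation (header names unchanged).
#' @param contamination data.frame `target`, `source`, `fraction`: each
#'   target call is replaced by the source's call with probability
#'   `fraction`.
#' @param roh data.frame `sample`, `fraction`: renders a contiguous run
#'   covering `fraction` of the sample's non-PAR X sites homozygous
#'   (autozygosity-like), XX samples only.
#' @param diploid_male_x If `TRUE`, emit male non-PAR X calls as `"1/1"`
#'   style diploid genotypes (as many callers do) instead of haploid `"1"`.
#' @param seed Integer seed; all randomness derives from it.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(pedigree = default_pedigree(),
                       n_sites_autosome = 10000L, n_sites_x = 2000L,
                       af_range = c(0.05, 0.5), par_fraction = 0.1,
                       depth_mean = 40, genotype_error = 0.001,
                       pseudo_het_rate = 0.005, trap_intervals = NULL,
                       trap_rate = 0.35, duplicates = NULL,
                       swap_pairs = NULL, contamination = NULL, roh = NULL,
                       diploid_male_x = FALSE, seed = 1L) {
  stopifnot(
    all(c("id", "father", "mother", "sex") %in% names(pedigree)),
    all(pedigree$sex %in% c("XX", "XY")),
    !anyDuplicated(pedigree$id),
    n_sites_autosome >= 0, n_sites_x >= 0,
    length(af_range) == 2L, af_range[1] > 0, af_range[2] < 1,
    par_fraction >= 0, par_fraction <= 1,
    depth_mean > 0, genotype_error >= 0, genotype_error <= 1,
    pseudo_het_rate >= 0, pseudo_het_rate <= 1, trap_rate >= 0, trap_rate <= 1
  )
  for (r in seq_len(nrow(pedigree))) {
    for (p in c("father", "mother")) {
      pid <- pedigree[[p]][r]
      if (!is.na(pid)) {
        at <- match(pid, pedigree$id)
        if (is.na(at)) stop("pedigree references unknown parent: ", pid, call. = FALSE)
        if (at >= r) stop("founders must precede descendants: ", pid, call. = FALSE)
        want <- if (p == "father") "XY" else "XX"
        if (pedigree$sex[at] != want) {
          stop(sprintf("%s of %s must be %s", p, pedigree$id[r], want), call. = FALSE)
        }
      }
    }
  }
  structure(
    list(
      pedigree = pedigree, n_sites_autosome = as.integer(n_sites_autosome),
      n_sites_x = as.integer(n_sites_x), af_range = af_range,
      par_fraction = par_fraction, depth_mean = depth_mean,
      genotype_error = genotype_error, pseudo_het_rate = pseudo_het_rate,
      trap_intervals = trap_intervals, trap_rate = trap_rate,
      duplicates = duplicates, swap_pairs = swap_pairs,
      contamination = contamination, roh = roh,
      diploid_male_x = isTRUE(diploid_male_x), seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' Expected Xhet of an XX sample under Hardy-Weinberg
#'
#' Closed-form expectation with hom-ref excluded from the denominator:
#' `sum(2 p (1-p)) / sum(2 p (1-p) + p^2)` over the site allele
#' frequencies. Serves as the analytic oracle for simulated XX samples.
#'
#' @param af Numeric vector of site allele frequencies in (0, 1].
#' @return Scalar expectation.
#' @examples
#' expected_xhet(rep(0.5, 100)) # 2/3
#' @export
expected_xhet <- function(af) {
  stopifnot(length(af) >= 1L, all(af > 0), all(af <= 1))
  het <- 2 * af * (1 - af)
  sum(het) / sum(het + af^2)
}

#' Simulate a cohort with ground truth
#'
#' Founders are drawn under Hardy-Weinberg from per-site allele
#' frequencies; offspring by Mendelian transmission. Autosomes and PAR
#' sites are diploid in everyone; on non-PAR X, mothers transmit one
#' allele, fathers transmit their single allele to XX offspring only (XY
#' offspring receive the maternal allele alone). Male non-PAR X calls are
#' emitted haploid unless `diploid_male_x` is set. Depth is
#' Poisson(`depth_mean`), allele depths Binomial given the true dosage,
#' after which the error model and the configured injectors apply. The
#' whole procedure is reproducible from `seed`.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_cohort`: `gm` (a [geno_matrix()]), `truth`
#'   (sexes, pedigree, injections, per-call pseudo-het record, traps),
#'   and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed, .simulate_cohort(config))
}

.simulate_cohort <- function(cfg) {
  ped <- cfg$pedigree
  ids <- ped$id
  sex <- stats::setNames(ped$sex, ids)
  n_auto <- cfg$n_sites_autosome
  n_x <- cfg$n_sites_x
  n_par <- round(cfg$par_fraction * n_x)
  n_xnp <- n_x - n_par

  pos_auto <- if (n_auto) sort(sample.int(2.4e8, n_auto)) else integer()
  pos_par <- if (n_par) sort(sample(PAR1_LO:(NONPAR_LO - 1L), n_par)) else integer()
  pos_xnp <- if (n_xnp) sort(sample(NONPAR_LO:NONPAR_HI, n_xnp)) else integer()

  bases <- c("A", "C", "G", "T")
  n <- n_auto + n_par + n_xnp
  sites <- data.frame(
    contig = c(rep("chr1", n_auto), rep("chrX", n_par + n_xnp)),
    pos = c(pos_auto, pos_par, pos_xnp),
    ref = sample(bases, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
  sites$alt <- vapply(sites$ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  af <- stats::runif(n, cfg$af_range[1], cfg$af_range[2])
  diploid_row <- seq_len(n) <= n_auto + n_par # autosome + PAR rows
  xnp_row <- !diploid_row

  # allele matrices: a1 = transmitted/first allele, a2 = second (NA where
  # the sample is haploid, i.e. male non-PAR X)
  m <- length(ids)
  a1 <- matrix(NA_integer_, n, m, dimnames = list(NULL, ids))
  a2 <- matrix(NA_integer_, n, m, dimnames = list(NULL, ids))
  pick <- function(x, y) ifelse(stats::runif(length(x)) < 0.5, x, y)
  for (r in seq_len(nrow(ped))) {
    id <- ped$id[r]
    fa <- ped$father[r]
    mo <- ped$mother[r]
    founder <- is.na(fa) && is.na(mo)
    if (founder) {
      a1[, id] <- stats::rbinom(n, 1L, af)
      a2[, id] <- stats::rbinom(n, 1L, af)
      if (sex[id] == "XY") a2[xnp_row, id] <- NA_integer_
    } else {
      # diploid compartment: one allele from each parent
      a1[diploid_row, id] <- pick(a1[diploid_row, fa], a2[diploid_row, fa])
      a2[diploid_row, id] <- pick(a1[diploid_row, mo], a2[diploid_row, mo])
      # non-PAR X: maternal allele always; paternal X only to XX offspring
      mat_x <- pick(a1[xnp_row, mo], a2[xnp_row, mo])
      a1[xnp_row, id] <- mat_x
      if (sex[id] == "XX") a2[xnp_row, id] <- a1[xnp_row, fa]
    }
  }

  # genotype-identical duplicates (independent depths below)
  if (!is.null(cfg$duplicates)) {
    for (new in names(cfg$duplicates)) {
      src <- cfg$duplicates[[new]]
      stopifnot(src %in% ids, !new %in% ids)
      a1 <- cbind(a1, a1[, src])
      colnames(a1)[ncol(a1)] <- new
      a2 <- cbind(a2, a2[, src])
      colnames(a2)[ncol(a2)] <- new
      ids <- c(ids, new)
      sex[new] <- sex[src]
    }
    m <- length(ids)
  }

  # X-homozygosity runs (consanguinity-like): contiguous non-PAR X run made
  # homozygous by copying the first allele over the second
  roh_truth <- NULL
  if (!is.null(cfg$roh) && nrow(cfg$roh)) {
    xnp_idx <- which(xnp_row)
    for (r in seq_len(nrow(cfg$roh))) {
      s <- cfg$roh$sample[r]
      stopifnot(s %in% ids, sex[s] == "XX")
      k <- round(cfg$roh$fraction[r] * length(xnp_idx))
      if (k < 1L) next
      start <- sample.int(length(xnp_idx) - k + 1L, 1L)
      run <- xnp_idx[start:(start + k - 1L)]
      a2[run, s] <- a1[run, s]
      roh_truth <- rbind(roh_truth, data.frame(
        sample = s, start_pos = sites$pos[run[1]],
        end_pos = sites$pos[run[length(run)]], n_sites = k,
        stringsAsFactors = FALSE
      ))
    }
  }

  # genotype codes from alleles
  codes <- matrix(NA_integer_, n, m, dimnames = list(NULL, ids))
  hap <- is.na(a2) & !is.na(a1)
  dipl <- !is.na(a1) & !is.na(a2)
  codes[hap] <- 2L * a1[hap]
  codes[dipl] <- a1[dipl] + a2[dipl]

  # per-call genotype error: replace by a uniformly drawn different class
  if (cfg$genotype_error > 0) {
    flip <- which(stats::runif(n * m) < cfg$genotype_error & !is.na(codes))
    for (k in flip) {
      old <- codes[k]
      codes[k] <- if (hap[k]) 2L - old else sample(setdiff(c(0L, 1L, 2L), old), 1L)
    }
  }

  # pseudo-heterozygosity on male non-PAR X: per-site rate, elevated inside
  # trap intervals; the call becomes diploid-looking het with VAF near 0.5
  rate_x <- rep(0, n)
  rate_x[xnp_row] <- cfg$pseudo_het_rate
  if (!is.null(cfg$trap_intervals) && nrow(cfg$trap_intervals)) {
    in_trap <- IRanges::overlapsAny(
      sites_granges(sites$contig, sites$pos),
      regions_granges(cfg$trap_intervals)
    )
    rate_x[xnp_row & in_trap] <- cfg$trap_rate
  }
  pseudo <- matrix(FALSE, n, m, dimnames = list(NULL, ids))
  males <- ids[sex[ids] == "XY"]
  for (s in males) {
    hit <- xnp_row & stats::runif(n) < rate_x
    pseudo[hit, s] <- TRUE
    codes[hit, s] <- 1L
  }

  # emission: genotype strings, depth, allele depths, quality
  gt <- matrix("./.", n, m, dimnames = list(NULL, ids))
  gstr <- c("0/0", "0/1", "1/1")
  for (s in ids) {
    cc <- codes[, s]
    g <- gstr[cc + 1L]
    hap_s <- hap[, s] & !pseudo[, s]
    if (any(hap_s)) {
      g[hap_s] <- if (cfg$diploid_male_x) c("0/0", NA, "1/1")[cc[hap_s] + 1L] else
        as.character(cc[hap_s] / 2L)
    }
    g[is.na(cc)] <- "./."
    gt[, s] <- g
  }

  dp <- matrix(stats::rpois(n * m, cfg$depth_mean), n, m, dimnames = list(NULL, ids))
  target_f <- matrix(c(0.005, 0.5, 0.995)[codes + 1L], n, m)
  if (any(pseudo)) {
    # truncated Normal(0.5, 0.08) on (0,1): VAF mass inside the scan windows
    k <- sum(pseudo)
    f <- stats::rnorm(k, 0.5, 0.08)
    while (any(bad <- f <= 0 | f >= 1)) f[bad] <- stats::rnorm(sum(bad), 0.5, 0.08)
    target_f[pseudo] <- f
  }
  target_f[is.na(target_f)] <- 0.005
  altd <- matrix(stats::rbinom(n * m, as.vector(dp), as.vector(target_f)), n, m)
  ad <- matrix(paste0(dp - altd, ",", altd), n, m, dimnames = list(NULL, ids))
  ad[gt == "./."] <- NA_character_
  gq <- matrix(pmin(99L, stats::rpois(n * m, 60)), n, m, dimnames = list(NULL, ids))
  gq[gt == "./."] <- NA_real_
  dp_m <- matrix(as.numeric(dp), n, m, dimnames = list(NULL, ids))
  dp_m[gt == "./."] <- NA_real_

  # contamination injector: target call replaced by source call
  contam_truth <- NULL
  if (!is.null(cfg$contamination) && nrow(cfg$contamination)) {
    for (r in seq_len(nrow(cfg$contamination))) {
      tg <- cfg$contamination$target[r]
      sr <- cfg$contamination$source[r]
      fr <- cfg$contamination$fraction[r]
      stopifnot(tg %in% ids, sr %in% ids, fr >= 0, fr <= 1)
      hit <- stats::runif(n) < fr
      gt[hit, tg] <- gt[hit, sr]
      codes[hit, tg] <- codes[hit, sr]
      ad[hit, tg] <- ad[hit, sr]
      dp_m[hit, tg] <- dp_m[hit, sr]
      gq[hit, tg] <- gq[hit, sr]
      contam_truth <- rbind(contam_truth, data.frame(
        target = tg, source = sr, fraction = fr, n_sites = sum(hit),
        stringsAsFactors = FALSE
      ))
    }
  }

  gm <- geno_matrix(sites, ids, gt = gt, codes = codes, ad = ad,
                    dp = dp_m, gq = gq)

  # sample swaps: exchange genotype columns, header names unchanged
  swap_truth <- NULL
  if (!is.null(cfg$swap_pairs)) {
    for (p in cfg$swap_pairs) {
      gm <- inject_swap(gm, p)
      swap_truth <- rbind(swap_truth, data.frame(
        sample_a = p[1], sample_b = p[2], stringsAsFactors = FALSE
      ))
    }
  }

  pseudo_idx <- which(pseudo, arr.ind = TRUE)
  truth <- list(
    sex = sex[ids],
    pedigree = cfg$pedigree,
    duplicates = cfg$duplicates,
    swaps = swap_truth,
    contamination = contam_truth,
    roh = roh_truth,
    traps = cfg$trap_intervals,
    site_af = af,
    pseudo_het = data.frame(
      site = rownames(gm$codes)[pseudo_idx[, 1]],
      sample = ids[pseudo_idx[, 2]],
      stringsAsFactors = FALSE
    )
  )
  structure(list(gm = gm, truth = truth, config = cfg), class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf(
    "<sim_cohort> %d samples (%d XX / %d XY), %d sites, seed %d\n",
    length(x$gm$samples), sum(x$truth$sex == "XX"), sum(x$truth$sex == "XY"),
    nrow(x$gm$sites), x$config$seed
  ))
  invisible(x)
}

#' Swap two samples' genotype columns
#'
#' Exchanges the full per-call content (genotypes, depths, qualities)
#' between two sample columns while leaving the header sample names in
#' place - the classic sample mix-up. Swapping a sample with itself, or
#' applying the same swap twice, is the identity.
#'
#' @param gm A [geno_matrix()].
#' @param pair Length-2 character vector of sample ids.
#' @return The modified [geno_matrix()].
#' @export
inject_swap <- function(gm, pair) {
  stopifnot(inherits(gm, "geno_matrix"), length(pair) == 2L,
            all(pair %in% gm$samples))
  i <- match(pair[1], gm$samples)
  j <- match(pair[2], gm$samples)
  for (f in c("gt", "codes", "ad", "dp", "gq", "af")) {
    if (!is.null(gm[[f]])) gm[[f]][, c(i, j)] <- gm[[f]][, c(j, i)]
  }
  gm
}

#' Write a simulated cohort to disk
#'
#' Emits the multi-sample VCF, the ground-truth tables (sexes, pedigree,
#' injections) as TSV, and the trap-interval BED when configured.
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(vcf = file.path(dir, "cohort.vcf"))
  write_vcf(sim$gm, paths["vcf"])
  tsv <- function(df, name) {
    p <- file.path(dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  paths["sexes"] <- tsv(
    data.frame(sample = names(sim$truth$sex), sex = unname(sim$truth$sex)),
    "truth_sexes.tsv"
  )
  paths["pedigree"] <- tsv(sim$truth$pedigree, "truth_pedigree.tsv")
  if (!is.null(sim$truth$swaps)) paths["swaps"] <- tsv(sim$truth$swaps, "truth_swaps.tsv")
  if (nrow(sim$truth$pseudo_het)) {
    paths["pseudo_het"] <- tsv(sim$truth$pseudo_het, "truth_pseudo_het.tsv")
  }
  if (!is.null(sim$truth$traps)) {
    p <- file.path(dir, "trap_intervals.bed")
    tr <- sim$truth$traps
    writeLines(
      paste(tr$contig, tr$start - 1L, tr$end, tr$label, sep = "\t"), p
    )
    paths["traps"] <- p
  }
  invisible(paths)
}
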