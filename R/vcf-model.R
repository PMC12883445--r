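# Data model for variant sites and genotype calls: VCF reading (via vcfR),
# genotype classification, allele fractions, multi-sample merging, and a
# deterministic plain-text VCF writer for round-tripping.

GT_MISSING <- NA_integer_

# Fast-path lookup for the overwhelmingly common genotype strings; anything
# else falls through to the general split-and-inspect path.
.gt_lookup <- c(
  "0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "0|1" = 1L, "1/0" = 1L, "1|0" = 1L,
  "1/1" = 2L, "1|1" = 2L, "0" = 0L, "1" = 2L
)

# Vectorized genotype coding: 0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing.
# `samples`/`sites` only provide error context.
genotype_code <- function(gt, samples = NULL, sites = NULL) {
  gt <- as.character(gt)
  out <- rep(NA_integer_, length(gt))
  known <- match(gt, names(.gt_lookup))
  hit <- !is.na(known)
  out[hit] <- unname(.gt_lookup)[known[hit]]
  todo <- which(!hit & !is.na(gt))
  for (k in todo) {
    g <- gt[k]
    if (g == "." || g == "./." || g == ".|.") next
    alleles <- strsplit(g, "[/|]")[[1]]
    if (length(alleles) < 1L || length(alleles) > 2L ||
        any(!grepl("^([0-9]+|\\.)$", alleles))) {
      where <- character(0)
      if (!is.null(samples)) where <- c(where, paste0("sample ", samples[k]))
      if (!is.null(sites)) where <- c(where, paste0("site ", sites[k]))
      stop(
        sprintf(
          "malformed genotype '%s'%s", g,
          if (length(where)) paste0(" (", paste(where, collapse = ", "), ")") else ""
        ),
        call. = FALSE
      )
    }
    if (any(alleles == ".")) next # half-calls classify as missing
    a <- as.integer(alleles)
    out[k] <- if (length(a) == 1L) {
      if (a == 0L) 0L else 2L # haploid: ref -> hom-ref, alt -> hom-alt
    } else if (a[1] != a[2]) {
      1L # any two distinct alleles are het (multiallelic included)
    } else if (a[1] == 0L) 0L else 2L
  }
  out
}

#' Construct a single genotype call
#'
#' A light container for one sample's call at one site, carrying the raw
#' genotype string plus the depth/allele-depth/quality FORMAT values used by
#' the parametric filters.
#'
#' @param gt Genotype string, e.g. `"0/1"`, `"1|2"`, `"1"` (haploid), `"./."`.
#' @param ad Integer vector of per-allele read depths (REF first), or `NULL`.
#' @param dp Total read depth, or `NA`.
#' @param gq Genotype quality, or `NA`.
#' @return An object of class `genotype_call`.
#' @export
genotype_call <- function(gt, ad = NULL, dp = NA_real_, gq = NA_real_) {
  structure(
    list(gt = as.character(gt), ad = if (is.null(ad)) NULL else as.numeric(ad),
         dp = as.numeric(dp), gq = as.numeric(gq)),
    class = "genotype_call"
  )
}

#' Classify a genotype call
#'
#' Classification rules: any missing allele (including half-calls like
#' `"./1"`) is `"missing"`; haploid calls map ref to `"hom-ref"` and any alt
#' to `"hom-alt"`; diploid calls with two distinct allele indices are
#' `"het"` (multiallelic included), with two identical indices `"hom-ref"`
#' if 0 else `"hom-alt"`. The phasing separator (`/` vs `|`) and allele
#' order are irrelevant.
#'
#' @param call A [genotype_call()] or a character vector of genotype strings.
#' @return Character vector in `{"hom-ref","het","hom-alt","missing"}`.
#' @examples
#' classify_genotype(c("0/1", "1/1", "1|2", "./1", "1"))
#' @export
classify_genotype <- function(call) {
  gt <- if (inherits(call, "genotype_call")) call$gt else call
  code <- genotype_code(gt)
  out <- c("hom-ref", "het", "hom-alt")[code + 1L]
  out[is.na(code)] <- "missing"
  out
}

#' Allele fraction of a call
#'
#' The fraction of reads supporting any non-reference allele:
#' `sum(AD[-1]) / sum(AD)`. Defined only when AD has at least two entries
#' and a positive total; otherwise `NA` (undefined is a value, not an
#' error). Note `sum(AD) <= DP` is not required - callers disagree, and
#' both fields are stored as read.
#'
#' @param call A [genotype_call()], a numeric AD vector for one call, or a
#'   character vector of comma-joined AD strings (vectorized).
#' @return Numeric vector of fractions in `[0, 1]`, `NA` where undefined.
#' @examples
#' allele_fraction(c(10, 10))
#' allele_fraction("15,3,2")
#' @export
allele_fraction <- function(call) {
  if (inherits(call, "genotype_call")) call <- call$ad
  if (is.null(call)) return(NA_real_)
  if (is.numeric(call)) {
    if (length(call) < 2L || anyNA(call)) return(NA_real_)
    tot <- sum(call)
    return(if (tot <= 0) NA_real_ else sum(call[-1]) / tot)
  }
  parts <- strsplit(as.character(call), ",", fixed = TRUE)
  vapply(parts, function(p) {
    x <- suppressWarnings(as.numeric(p))
    if (length(x) < 2L || anyNA(x)) return(NA_real_)
    tot <- sum(x)
    if (tot <= 0) NA_real_ else sum(x[-1]) / tot
  }, numeric(1))
}

#' Construct a genotype matrix
#'
#' The substrate for kinship and missingness filtering: sites x samples
#' genotype codes (0 = hom-ref, 1 = het, 2 = hom-alt, NA = missing) plus
#' the per-call FORMAT values the parametric filters consume. All matrices
#' are sites x samples; `sites` rows are parallel to matrix rows.
#'
#' @param sites data.frame with columns `contig`, `pos`, `ref`, `alt`
#'   (alt comma-joined for multiallelic sites).
#' @param samples Character vector of sample ids.
#' @param gt Character matrix of genotype strings (`NULL` to derive from
#'   `codes`).
#' @param codes Integer matrix of genotype codes (`NULL` to derive from `gt`).
#' @param ad Character matrix of comma-joined AD strings, or `NULL`.
#' @param dp,gq Numeric matrices, or `NULL`.
#' @param af Numeric matrix of allele fractions (`NULL` to derive from `ad`).
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(sites, samples, gt = NULL, codes = NULL,
                        ad = NULL, dp = NULL, gq = NULL, af = NULL) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  stopifnot(all(c("contig", "pos", "ref", "alt") %in% names(sites)))
  samples <- as.character(samples)
  if (anyDuplicated(samples)) stop("duplicate sample ids", call. = FALSE)
  n <- nrow(sites)
  m <- length(samples)
  dn <- list(site_key(sites$contig, sites$pos, sites$ref, sites$alt), samples)
  shape <- function(x, fill) {
    if (is.null(x)) x <- matrix(fill, n, m)
    x <- as.matrix(x)
    stopifnot(nrow(x) == n, ncol(x) == m)
    dimnames(x) <- dn
    x
  }
  if (is.null(gt) && is.null(codes)) stop("need gt or codes", call. = FALSE)
  if (is.null(codes)) {
    codes <- matrix(NA_integer_, n, m, dimnames = dn)
    for (j in seq_len(m)) {
      codes[, j] <- genotype_code(gt[, j], samples = rep(samples[j], n), sites = dn[[1]])
    }
  } else {
    codes <- shape(codes, NA_integer_)
    stopifnot(all(codes %in% c(0L, 1L, 2L, NA)))
  }
  if (is.null(gt)) {
    gt <- matrix(c("0/0", "0/1", "1/1")[codes + 1L], n, m)
    gt[is.na(codes)] <- "./."
  }
  gt <- shape(gt, "./.")
  codes <- shape(codes, NA_integer_)
  if (is.null(af) && !is.null(ad)) {
    af <- matrix(allele_fraction(ad), n, m)
  }
  structure(
    list(
      sites = sites, samples = samples, gt = gt,
      codes = codes,
      ad = if (is.null(ad)) NULL else shape(ad, NA_character_),
      dp = if (is.null(dp)) NULL else shape(dp, NA_real_),
      gq = if (is.null(gq)) NULL else shape(gq, NA_real_),
      af = if (is.null(af)) NULL else shape(af, NA_real_)
    ),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d sites x %d samples (%s)\n",
    nrow(x$sites), length(x$samples),
    paste(utils::head(x$samples, 5), collapse = ", ")
  ))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) c(nrow(x$sites), length(x$samples))

# Row-subset every parallel component of a geno_matrix.
subset_sites <- function(gm, idx) {
  gm$sites <- gm$sites[idx, , drop = FALSE]
  rownames(gm$sites) <- NULL
  for (f in c("gt", "codes", "ad", "dp", "gq", "af")) {
    if (!is.null(gm[[f]])) gm[[f]] <- gm[[f]][idx, , drop = FALSE]
  }
  gm
}

#' Read a VCF into a genotype matrix
#'
#' Reads plain or gzipped VCF v4.1+ through vcfR, parsing the GT, AD, DP and
#' GQ FORMAT fields when present (absent fields become missing values).
#' When AD is absent for a call, a caller-supplied `VAF` or `AF` FORMAT
#' field is used as allele-fraction fallback; when neither exists the
#' fraction is undefined.
#'
#' @param path Path to a VCF file.
#' @param region Optional [interval()] or `"contig:start-end"` string;
#'   sites outside the (inclusive) region are dropped.
#' @return A [geno_matrix()]. Sites retain file order.
#' @export
read_vcf <- function(path, region = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: ", path, call. = FALSE)
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  if (ncol(v@gt) < 2L) stop("VCF has no sample columns: ", path, call. = FALSE)
  if (nrow(v@fix) > 0L && !all(grepl("(^|:)GT(:|$)", v@gt[, "FORMAT"]))) {
    stop("VCF records lack the GT FORMAT field: ", path, call. = FALSE)
  }
  samples <- colnames(v@gt)[-1]
  fix <- v@fix
  sites <- data.frame(
    contig = as.character(fix[, "CHROM"]),
    pos = as.integer(fix[, "POS"]),
    ref = as.character(fix[, "REF"]),
    alt = ifelse(is.na(fix[, "ALT"]), ".", as.character(fix[, "ALT"])),
    stringsAsFactors = FALSE
  )
  grab <- function(el, num = FALSE) {
    if (nrow(fix) == 0L) return(NULL)
    m <- tryCatch(
      vcfR::extract.gt(v, element = el, as.numeric = num),
      error = function(e) NULL
    )
    if (is.null(m) || all(is.na(m))) return(NULL)
    m
  }
  gt <- if (nrow(fix)) vcfR::extract.gt(v, element = "GT") else
    matrix(character(), 0, length(samples))
  ad <- grab("AD")
  dp <- grab("DP", num = TRUE)
  gq <- grab("GQ", num = TRUE)
  af <- if (!is.null(ad)) matrix(allele_fraction(ad), nrow(sites), length(samples)) else NULL
  vaf <- grab("VAF", num = TRUE)
  if (is.null(vaf)) vaf <- grab("AF", num = TRUE)
  if (!is.null(vaf)) {
    if (is.null(af)) af <- matrix(NA_real_, nrow(sites), length(samples))
    af[is.na(af)] <- vaf[is.na(af)]
  }
  gm <- geno_matrix(sites, samples, gt = gt, ad = ad, dp = dp, gq = gq, af = af)
  if (!is.null(region)) {
    if (is.character(region)) region <- parse_region(region)
    keep <- in_region(gm$sites$contig, gm$sites$pos, region)
    gm <- subset_sites(gm, keep)
  }
  gm
}

# "contig:start-end" -> interval
parse_region <- function(x) {
  m <- regmatches(x, regexec("^([^:]+):([0-9,]+)-([0-9,]+)$", x))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", x, call. = FALSE)
  interval(m[2], as.integer(gsub(",", "", m[3])), as.integer(gsub(",", "", m[4])))
}

#' Merge per-sample genotype matrices
#'
#' Builds the union of site keys across inputs, in (contig, position) order.
#' A sample without a record at a site gets a missing genotype (mirroring
#' standard VCF-merge semantics, and feeding the missingness filter);
#' multiallelic sites are keyed by their full alt set.
#'
#' @param x A list of [geno_matrix()] objects (or a single one, returned
#'   unchanged).
#' @return A combined [geno_matrix()].
#' @export
merge_samples <- function(x) {
  if (inherits(x, "geno_matrix")) return(x)
  stopifnot(is.list(x), length(x) >= 1L, all(vapply(x, inherits, logical(1), "geno_matrix")))
  if (length(x) == 1L) return(x[[1]])
  samples <- unlist(lapply(x, `[[`, "samples"))
  if (anyDuplicated(samples)) {
    stop("duplicate sample id across inputs: ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "), call. = FALSE)
  }
  allsites <- unique(do.call(rbind, lapply(x, `[[`, "sites")))
  keys <- site_key(allsites$contig, allsites$pos, allsites$ref, allsites$alt)
  if (anyDuplicated(keys)) stop("inconsistent duplicate site keys", call. = FALSE)
  ord <- order(norm_contig(allsites$contig), allsites$pos, allsites$ref, allsites$alt)
  allsites <- allsites[ord, , drop = FALSE]
  keys <- keys[ord]
  rownames(allsites) <- NULL
  n <- nrow(allsites)
  m <- length(samples)
  init <- function(fill) matrix(fill, n, m, dimnames = list(keys, samples))
  gt <- init("./.")
  codes <- init(NA_integer_)
  ad <- init(NA_character_)
  dp <- init(NA_real_)
  gq <- init(NA_real_)
  af <- init(NA_real_)
  any_fmt <- list(ad = FALSE, dp = FALSE, gq = FALSE, af = FALSE)
  for (g in x) {
    rk <- site_key(g$sites$contig, g$sites$pos, g$sites$ref, g$sites$alt)
    ri <- match(rk, keys)
    ci <- match(g$samples, samples)
    gt[ri, ci] <- g$gt
    codes[ri, ci] <- g$codes
    for (f in c("ad", "dp", "gq", "af")) {
      if (!is.null(g[[f]])) {
        tgt <- get(f)
        tgt[ri, ci] <- g[[f]]
        assign(f, tgt)
        any_fmt[[f]] <- TRUE
      }
    }
  }
  geno_matrix(
    allsites, samples, gt = gt, codes = codes,
    ad = if (any_fmt$ad) ad else NULL,
    dp = if (any_fmt$dp) dp else NULL,
    gq = if (any_fmt$gq) gq else NULL,
    af = if (any_fmt$af) af else NULL
  )
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Deterministic VCF v4.2 writer: identical input always yields identical
#' bytes. FORMAT is `GT` plus `AD`/`DP`/`GQ` when the matrix carries them;
#' missing values are written as `.`. Re-reading the file with [read_vcf()]
#' reproduces the genotype codes exactly.
#'
#' @param gm A [geno_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  stopifnot(inherits(gm, "geno_matrix"))
  fmt_fields <- c("GT", if (!is.null(gm$ad)) "AD", if (!is.null(gm$dp)) "DP",
                  if (!is.null(gm$gq)) "GQ")
  header <- c(
    "##fileformat=VCFv4.2",
    paste0("##source=xhetkin-", xhetkin_version()),
    paste0("##contig=<ID=", unique(gm$sites$contig), ">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    if (!is.null(gm$ad)) "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    if (!is.null(gm$dp)) "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    if (!is.null(gm$gq)) "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
            gm$samples), collapse = "\t")
  )
  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  cols <- gm$gt
  if (!is.null(gm$ad)) cols <- matrix(paste(cols, dot(gm$ad), sep = ":"), nrow(cols))
  if (!is.null(gm$dp)) cols <- matrix(paste(cols, dot(gm$dp), sep = ":"), nrow(cols))
  if (!is.null(gm$gq)) cols <- matrix(paste(cols, dot(gm$gq), sep = ":"), nrow(cols))
  body <- if (nrow(gm$sites)) {
    paste(
      gm$sites$contig, gm$sites$pos, ".", gm$sites$ref, gm$sites$alt,
      ".", "PASS", ".", paste(fmt_fields, collapse = ":"),
      apply(cols, 1L, paste, collapse = "\t"),
      sep = "\t"
    )
  } else character()
  writeLines(c(header, body), path)
  invisible(path)
}
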