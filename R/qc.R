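# Composite QC driver: Xhet -> sex inference -> kinship on the same inputs,
# with per-stage TSVs, a combined per-sample summary, advisory flags, a
# machine-readable run manifest, and MultiQC custom-content tables. Flags
# never rename or drop samples - the tool reports, the analyst decides.

#' Run the full genotype QC pipeline
#'
#' Executes the Xhet branch (per-sample heterozygosity on the non-PAR X
#' interval), unsupervised sex-group classification, and the relatedness
#' branch (per-call filters, missingness exclusion, KING-robust kinship)
#' on one multi-sample VCF or several single-sample VCFs (auto-merged).
#' Writes per-stage TSVs, a combined sample summary, a JSON run manifest
#' recording every parameter, and MultiQC custom-content tables. Any stage
#' failure leaves partial outputs plus a `FAILED` marker naming the stage.
#'
#' Inconsistency flags are advisory: `SEX_MISMATCH` when an inferred label
#' contradicts provided sex metadata; `PEDIGREE_MISMATCH` when a declared
#' parent-offspring pair is not first-degree by kinship; `DUPLICATE` when a
#' non-declared pair reaches duplicate-range phi; `AMBIGUOUS_SEX` /
#' `UNDEFINED_XHET` from the classifier. Note that same-sex first-degree
#' pairs (mother-daughter, father-son) are indistinguishable here by
#' design: degree and inferred sex group are identical within such pairs.
#'
#' @param vcf Character vector of VCF paths, or a [geno_matrix()].
#' @param outdir Output directory (created).
#' @param params A [filter_params()] applied to both branches.
#' @param region Non-PAR X [interval()] for the Xhet branch.
#' @param sex_metadata Optional data.frame `sample`, `sex` (`"XX"`/`"XY"`)
#'   for sex-vs-metadata flags.
#' @param pedigree Optional data.frame `id`, `father`, `mother` for
#'   pedigree-vs-kinship flags.
#' @param autosomes_only Restrict the relatedness branch to autosomes.
#' @return List of class `qc_result`: `xhet`, `sex`, `kinship`, `summary`,
#'   `flags`, `paths`; invisibly.
#' @export
run_qc <- function(vcf, outdir, params = filter_params(),
                   region = nonpar_x_interval(), sex_metadata = NULL,
                   pedigree = NULL, autosomes_only = FALSE) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- "read"
  on_fail <- function(e, stage) {
    writeLines(
      sprintf("FAILED at stage '%s': %s", stage, conditionMessage(e)),
      file.path(outdir, "FAILED")
    )
    stop(e)
  }
  tryCatch({
    gm <- if (inherits(vcf, "geno_matrix")) vcf else {
      inputs <- as.character(vcf)
      merge_samples(lapply(inputs, read_vcf))
    }
    if (nrow(gm$sites) == 0L) {
      stop("empty VCF input: ",
           if (is.character(vcf)) paste(vcf, collapse = ", ") else "genotype matrix",
           call. = FALSE)
    }

    stage <- "xhet"
    xh <- xhet_batch(gm, region = region, params = params)

    stage <- "sexinfer"
    sex_calls <- tryCatch({
      cutoff <- unsupervised_threshold(xh$xhet)
      classify_sex(xh$xhet, cutoff, sample_id = xh$sample)
    }, error = function(e) {
      data.frame(
        sample_id = xh$sample, xhet = xh$xhet, label = "undefined",
        method = "threshold", score = NA_real_, threshold_used = NA_real_,
        stringsAsFactors = FALSE
      )
    })

    stage <- "kinship"
    kin <- NULL
    if (length(gm$samples) >= 2L) {
      gmk <- apply_call_filters(gm, params)
      gmk <- missingness_filter(gmk, params$miss_max)
      kin <- kinship_matrix(gmk, autosomes_only = autosomes_only)
    }

    stage <- "flags"
    flags <- qc_flags(sex_calls, kin, sex_metadata, pedigree)

    stage <- "report"
    smry <- qc_summary(xh, sex_calls, kin, flags)
    paths <- c(
      xhet = write_tsv(xh, file.path(outdir, "xhet.tsv"), params),
      sex = write_tsv(sex_calls, file.path(outdir, "sex_calls.tsv"), params),
      summary = write_tsv(smry, file.path(outdir, "sample_summary.tsv"), params)
    )
    if (!is.null(kin)) {
      paths["kinship"] <- write_tsv(kin, file.path(outdir, "kinship.tsv"), params)
    }
    paths <- c(paths, emit_multiqc(xh, kin, outdir))
    manifest <- list(
      tool = "xhetkin", version = xhetkin_version(),
      inputs = if (is.character(vcf)) vcf else "in-memory genotype matrix",
      samples = gm$samples,
      n_sites = nrow(gm$sites),
      params = list(
        af_min = params$af_min, dp_min = params$dp_min,
        gq_min = params$gq_min, miss_max = params$miss_max,
        strict = params$strict
      ),
      region = sprintf("%s:%d-%d", region$contig, region$start, region$end),
      autosomes_only = autosomes_only
    )
    jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null")
    paths["manifest"] <- file.path(outdir, "manifest.json")
    invisible(structure(
      list(xhet = xh, sex = sex_calls, kinship = kin, summary = smry,
           flags = flags, paths = paths),
      class = "qc_result"
    ))
  }, error = function(e) on_fail(e, stage))
}

# TSV with a provenance header: every threshold that shapes the numbers.
write_tsv <- function(df, path, params = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(params)) {
    writeLines(sprintf(
      "# xhetkin %s | af_min=%s dp_min=%s gq_min=%s miss_max=%s strict=%s",
      xhetkin_version(), params$af_min, params$dp_min,
      if (is.null(params$gq_min)) "off" else params$gq_min,
      params$miss_max, params$strict
    ), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

qc_flags <- function(sex_calls, kin, sex_metadata = NULL, pedigree = NULL) {
  flags <- data.frame(sample = character(), flag = character(),
                      detail = character(), stringsAsFactors = FALSE)
  add <- function(sample, flag, detail) {
    rbind(flags, data.frame(sample = sample, flag = flag, detail = detail,
                            stringsAsFactors = FALSE))
  }
  amb <- sex_calls$sample_id[sex_calls$label == "ambiguous"]
  for (s in amb) flags <- add(s, "AMBIGUOUS_SEX", "Xhet within margin of cutoff")
  und <- sex_calls$sample_id[sex_calls$label == "undefined"]
  for (s in und) flags <- add(s, "UNDEFINED_XHET", "no qualifying non-PAR X genotypes")
  if (!is.null(sex_metadata)) {
    expected <- ifelse(sex_metadata$sex == "XX", "xx-like", "xy-like")
    names(expected) <- sex_metadata$sample
    for (r in seq_len(nrow(sex_calls))) {
      s <- sex_calls$sample_id[r]
      if (s %in% names(expected) &&
          sex_calls$label[r] %in% c("xx-like", "xy-like") &&
          sex_calls$label[r] != expected[s]) {
        flags <- add(s, "SEX_MISMATCH",
                     sprintf("metadata %s but inferred %s",
                             expected[s], sex_calls$label[r]))
      }
    }
  }
  if (!is.null(pedigree) && !is.null(kin)) {
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    phi_of <- stats::setNames(kin$phi, key(kin$sample_i, kin$sample_j))
    declared <- character()
    for (r in seq_len(nrow(pedigree))) {
      child <- pedigree$id[r]
      for (p in c(pedigree$father[r], pedigree$mother[r])) {
        if (is.na(p)) next
        k <- key(child, p)
        declared <- c(declared, k)
        phi <- phi_of[k]
        if (!is.na(phi) && classify_degree(phi) != "first") {
          flags <- add(child, "PEDIGREE_MISMATCH",
                       sprintf("declared parent %s has phi=%.3f (%s)",
                               p, phi, classify_degree(phi)))
        }
      }
    }
    off_diag <- kin[kin$sample_i != kin$sample_j, , drop = FALSE]
    dup <- off_diag[!is.na(off_diag$phi) & off_diag$phi > 0.354 &
                      !key(off_diag$sample_i, off_diag$sample_j) %in% declared, ,
                    drop = FALSE]
    for (r in seq_len(nrow(dup))) {
      flags <- add(dup$sample_i[r], "DUPLICATE",
                   sprintf("phi=%.3f with %s", dup$phi[r], dup$sample_j[r]))
    }
  }
  flags
}

qc_summary <- function(xh, sex_calls, kin, flags) {
  top_partner <- function(s) {
    if (is.null(kin)) return(NA_character_)
    rows <- kin[(kin$sample_i == s | kin$sample_j == s) &
                  kin$sample_i != kin$sample_j, , drop = FALSE]
    rows <- rows[!is.na(rows$phi), , drop = FALSE]
    if (!nrow(rows)) return(NA_character_)
    best <- rows[which.max(rows$phi), ]
    other <- ifelse(best$sample_i == s, best$sample_j, best$sample_i)
    sprintf("%s (phi=%.3f, %s)", other, best$phi, best$degree)
  }
  data.frame(
    sample = xh$sample,
    xhet = xh$xhet,
    n_het = xh$n_het,
    n_homalt = xh$n_homalt,
    sex_label = sex_calls$label[match(xh$sample, sex_calls$sample_id)],
    top_kinship = vapply(xh$sample, top_partner, character(1)),
    flags = vapply(xh$sample, function(s) {
      f <- flags$flag[flags$sample == s]
      if (length(f)) paste(unique(f), collapse = ";") else ""
    }, character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Emit MultiQC custom-content tables
#'
#' Writes two files the MultiQC custom-content loader picks up: a square
#' pairwise-relatedness matrix rendered as a heatmap, and a per-sample
#' Xhet table rendered as a bar graph. Undefined Xhet is emitted as an
#' empty cell, never 0.
#'
#' @param xh Output of [xhet_batch()].
#' @param kin Output of [kinship_matrix()], or `NULL` to skip the heatmap.
#' @param outdir Output directory.
#' @return Named character vector of written paths.
#' @export
emit_multiqc <- function(xh, kin, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  xp <- file.path(outdir, "xhet_mqc.tsv")
  con <- file(xp, "w")
  writeLines(c(
    "# id: xhet",
    "# section_name: X heterozygosity",
    "# description: Proportion of heterozygous genotypes among het + hom-alt calls on non-PAR chromosome X. Near 0 indicates a hemizygous (XY-like) X.",
    "# plot_type: bargraph",
    "Sample\txhet"
  ), con)
  writeLines(
    paste(xh$sample, ifelse(is.na(xh$xhet), "", format(xh$xhet, digits = 6)),
          sep = "\t"),
    con
  )
  close(con)
  paths["multiqc_xhet"] <- xp
  if (!is.null(kin)) {
    kp <- file.path(outdir, "relatedness_mqc.tsv")
    sq <- kinship_square(kin)
    con <- file(kp, "w")
    writeLines(c(
      "# id: relatedness",
      "# section_name: Pairwise relatedness",
      "# description: KING-robust kinship coefficients (0.5 duplicate, ~0.25 first degree, ~0 unrelated).",
      "# plot_type: heatmap",
      paste(c("Sample", colnames(sq)), collapse = "\t")
    ), con)
    for (r in seq_len(nrow(sq))) {
      vals <- ifelse(is.na(sq[r, ]), "", format(sq[r, ], digits = 6))
      writeLines(paste(c(rownames(sq)[r], vals), collapse = "\t"), con)
    }
    close(con)
    paths["multiqc_relatedness"] <- kp
  }
  paths
}
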