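# Pseudo-heterozygosity scan over hemizygous-expected samples: tallies
# exonic SNV heterozygous calls whose allele fraction lies inside inclusive
# VAF windows, then aggregates per position, per gene, and per annotated
# region (with per-Mb densities). On truly hemizygous sequence every such
# call is an artifact, typically mis-mapping from paralogs or pseudogenes.

#' Scan hemizygous-expected samples for heterozygous calls
#'
#' A call contributes iff its site is an SNV, overlaps an exon interval,
#' classifies as het, and its AD-derived allele fraction lies inside the
#' VAF window (both bounds inclusive). One table is produced per window.
#'
#' @param gm A [geno_matrix()]; must carry AD-derived allele fractions (the
#'   VAF window is meaningless without a fraction).
#' @param male_samples Character vector: the putatively hemizygous samples
#'   to scan.
#' @param exons A [region_set()] of exon intervals (non-empty).
#' @param windows List of inclusive `(low, high)` percent windows; default
#'   the three standard windows `(25,75)`, `(33,66)`, `(45,55)`.
#' @return Named list (one element per window, named `"low-high"`) of
#'   `het_scan_table` objects with fields `window`,
#'   `unique_het_positions` (distinct sites with >= 1 qualifying het call),
#'   `n_calls` (sample-summed qualifying het genotype calls),
#'   `per_position` (data.frame site/contig/pos/n_samples), and `calls`
#'   (one row per qualifying sample-site call).
#' @export
het_scan <- function(gm, male_samples, exons,
                     windows = list(c(25, 75), c(33, 66), c(45, 55))) {
  stopifnot(inherits(gm, "geno_matrix"), inherits(exons, "region_set"))
  if (nrow(exons) == 0L) stop("exon region set is empty", call. = FALSE)
  if (is.null(gm$af) || all(is.na(gm$af))) {
    stop("hetscan requires AD-derived allele fractions (AD FORMAT absent)",
         call. = FALSE)
  }
  missing_s <- setdiff(male_samples, gm$samples)
  if (length(missing_s)) {
    stop("samples not in matrix: ", paste(missing_s, collapse = ", "), call. = FALSE)
  }
  snv <- is_snv(gm$sites$ref, gm$sites$alt)
  exonic <- IRanges::overlapsAny(
    sites_granges(gm$sites$contig, gm$sites$pos), regions_granges(exons)
  )
  eligible_sites <- which(snv & exonic)
  cols <- match(sort(male_samples), gm$samples)
  out <- lapply(windows, function(w) {
    calls <- list()
    for (j in cols) {
      het <- gm$codes[eligible_sites, j] == 1L
      inwin <- in_vaf_window(gm$af[eligible_sites, j], w)
      hits <- eligible_sites[which(het & inwin)]
      if (length(hits)) {
        calls[[length(calls) + 1L]] <- data.frame(
          site = rownames(gm$codes)[hits],
          contig = gm$sites$contig[hits],
          pos = gm$sites$pos[hits],
          sample = gm$samples[j],
          stringsAsFactors = FALSE
        )
      }
    }
    calls <- if (length(calls)) do.call(rbind, calls) else
      data.frame(site = character(), contig = character(), pos = integer(),
                 sample = character(), stringsAsFactors = FALSE)
    tab <- table(calls$site)
    per_position <- data.frame(
      site = names(tab),
      n_samples = as.integer(tab),
      stringsAsFactors = FALSE
    )
    idx <- match(per_position$site, calls$site)
    per_position$contig <- calls$contig[idx]
    per_position$pos <- calls$pos[idx]
    per_position <- per_position[order(norm_contig(per_position$contig),
                                       per_position$pos), , drop = FALSE]
    rownames(per_position) <- NULL
    structure(
      list(
        window = w,
        unique_het_positions = nrow(per_position),
        n_calls = nrow(calls),
        per_position = per_position,
        calls = calls
      ),
      class = "het_scan_table"
    )
  })
  names(out) <- vapply(windows, function(w) paste(w, collapse = "-"), character(1))
  out
}

#' @export
print.het_scan_table <- function(x, ...) {
  cat(sprintf(
    "<het_scan_table> VAF window [%s, %s]%%: %d unique het positions, %d het calls\n",
    x$window[1], x$window[2], x$unique_het_positions, x$n_calls
  ))
  invisible(x)
}

#' Rank genes by recurrent heterozygous calls
#'
#' Assigns every qualifying het call to every gene interval it overlaps (a
#' call inside two overlapping genes counts in both, so overlapping gene
#' pairs each carry the shared calls), then ranks genes by descending call
#' count with ties broken lexicographically by label.
#'
#' @param table A `het_scan_table` from [het_scan()].
#' @param genes A labeled [region_set()] of gene intervals.
#' @param n Number of top genes to keep; default 20.
#' @return data.frame `gene`, `count`, sorted.
#' @export
top_genes <- function(table, genes, n = 20) {
  stopifnot(inherits(table, "het_scan_table"), inherits(genes, "region_set"))
  if (nrow(table$calls) == 0L || nrow(genes) == 0L) {
    return(data.frame(gene = character(), count = integer(), stringsAsFactors = FALSE))
  }
  hits <- GenomicRanges::findOverlaps(
    sites_granges(table$calls$contig, table$calls$pos),
    regions_granges(genes)
  )
  lab <- genes$label[S4Vectors::subjectHits(hits)]
  if (!length(lab)) {
    return(data.frame(gene = character(), count = integer(), stringsAsFactors = FALSE))
  }
  tab <- base::table(lab)
  out <- data.frame(gene = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, n)
}

#' Heterozygous-call density per annotated region
#'
#' For every region label, counts the qualifying het calls overlapping any
#' of its intervals and divides by the label's total span in Mb. Nested or
#' overlapping regions tally independently (a call may contribute to
#' several labels).
#'
#' @param table A `het_scan_table` from [het_scan()].
#' @param regions A labeled [region_set()] with positive spans.
#' @return data.frame `region`, `n_calls`, `span_mb`, `density_per_mb`.
#' @export
region_density <- function(table, regions) {
  stopifnot(inherits(table, "het_scan_table"), inherits(regions, "region_set"))
  labels <- unique(regions$label)
  span_bp <- vapply(labels, function(l) {
    r <- regions[regions$label == l, , drop = FALSE]
    sum(r$end - r$start + 1)
  }, numeric(1))
  counts <- integer(length(labels))
  if (nrow(table$calls)) {
    gr_calls <- sites_granges(table$calls$contig, table$calls$pos)
    for (k in seq_along(labels)) {
      r <- regions[regions$label == labels[k], , drop = FALSE]
      counts[k] <- sum(IRanges::overlapsAny(gr_calls, regions_granges(r)))
    }
  }
  data.frame(
    region = labels,
    n_calls = counts,
    span_mb = span_bp / 1e6,
    density_per_mb = counts / (span_bp / 1e6),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}
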