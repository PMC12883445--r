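# Chromosome-X region model: the shared non-PAR interval, inclusive-bounds
# membership tests, and BED-backed annotation region sets.

#' Construct a 1-based inclusive genomic interval
#'
#' @param contig Chromosome name.
#' @param start,end 1-based inclusive bounds, `start <= end`.
#' @return An object of class `xk_interval`.
#' @export
interval <- function(contig, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L) {
    stop("interval bounds must be integers >= 1", call. = FALSE)
  }
  if (start > end) stop("interval start must be <= end", call. = FALSE)
  structure(
    list(contig = as.character(contig), start = start, end = end),
    class = "xk_interval"
  )
}

#' @export
print.xk_interval <- function(x, ...) {
  cat(sprintf("<interval> %s:%d-%d (1-based inclusive)\n", x$contig, x$start, x$end))
  invisible(x)
}

#' Non-pseudoautosomal chromosome X interval
#'
#' Returns the smallest chromosome X region excluding PAR1 and PAR2 that is
#' shared among the GRCh37/hg19, GRCh38/hg38 and T2T assemblies:
#' chrX:2,781,479-153,925,834, with both bounds inclusive. Because the
#' interval is the assembly-shared intersection, every supported assembly
#' label returns the same coordinates.
#'
#' @param assembly Assembly label; one of `"default"`, `"GRCh37"`, `"hg19"`,
#'   `"GRCh38"`, `"hg38"`, `"T2T"`, `"CHM13"`.
#' @return An [interval()].
#' @examples
#' nonpar_x_interval()
#' @export
nonpar_x_interval <- function(assembly = "default") {
  supported <- c("default", "GRCh37", "hg19", "GRCh38", "hg38", "T2T", "CHM13")
  if (!is.character(assembly) || length(assembly) != 1L || !assembly %in% supported) {
    stop(
      "unknown assembly label; supported: ",
      paste(supported, collapse = ", "),
      call. = FALSE
    )
  }
  interval("chrX", 2781479L, 153925834L)
}

#' Inclusive interval membership
#'
#' @param contig Contig name(s) of the position(s).
#' @param position 1-based position(s), `>= 1`.
#' @param region An [interval()].
#' @return Logical vector: `TRUE` where the contig matches (after aliasing)
#'   and `start <= position <= end`.
#' @export
in_region <- function(contig, position, region) {
  stopifnot(inherits(region, "xk_interval"))
  position <- as.numeric(position)
  if (any(position < 1, na.rm = TRUE)) stop("positions must be >= 1", call. = FALSE)
  contig_match(contig, region$contig) &
    position >= region$start & position <= region$end
}

#' Construct a labeled region set
#'
#' A region set is a collection of labeled 1-based inclusive intervals, e.g.
#' exons, genes, or the evolutionary strata / ampliconic segments of
#' chromosome X. Labels may repeat (a label's span is the sum of its
#' intervals).
#'
#' @param contig,start,end Parallel vectors of 1-based inclusive intervals.
#' @param label Parallel vector of non-empty labels.
#' @param name Name for the set.
#' @return A `region_set`: a data.frame with columns contig/start/end/label.
#' @export
region_set <- function(contig = character(), start = integer(), end = integer(),
                       label = character(), name = "regions") {
  df <- data.frame(
    contig = as.character(contig),
    start = as.integer(start),
    end = as.integer(end),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  if (nrow(df)) {
    if (any(is.na(df$start) | is.na(df$end) | df$start < 1L | df$start > df$end)) {
      stop("invalid interval in region set (need 1 <= start <= end)", call. = FALSE)
    }
    if (any(is.na(df$label) | df$label == "")) {
      stop("region labels must be non-empty", call. = FALSE)
    }
  }
  attr(df, "name") <- name
  class(df) <- c("region_set", "data.frame")
  df
}

#' Read a BED file into a region set
#'
#' Accepts 3-6 column BED. Half-open 0-based BED records are converted to
#' 1-based inclusive intervals (`start + 1`, `end`), preserving length.
#' Records without a name column are labeled `region_<k>`. Lines starting
#' with `#`, `track` or `browser` are ignored.
#'
#' @param path Path to a BED file.
#' @param name Name for the resulting set (defaults to the file name).
#' @return A [region_set()].
#' @export
load_bed <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("cannot read BED file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- seq_along(lines)[keep]
  if (!length(body)) return(region_set(name = name))
  # pre-validate so errors can carry the offending line number
  fields <- strsplit(body, "[ \t]+")
  for (k in seq_along(fields)) {
    f <- fields[[k]]
    if (length(f) < 3L) {
      stop(sprintf("%s line %d: fewer than 3 BED columns", path, lineno[k]), call. = FALSE)
    }
    s <- suppressWarnings(as.numeric(f[2]))
    e <- suppressWarnings(as.numeric(f[3]))
    if (is.na(s) || is.na(e) || s < 0) {
      stop(sprintf("%s line %d: malformed BED coordinates", path, lineno[k]), call. = FALSE)
    }
    if (e < s + 1) {
      stop(sprintf("%s line %d: zero-length or inverted interval (end <= start)", path, lineno[k]),
           call. = FALSE)
    }
  }
  gr <- rtracklayer::import(
    con = textConnection(paste(body, collapse = "\n")),
    format = "bed"
  )
  labels <- if (!is.null(gr$name) && !all(is.na(gr$name))) {
    lab <- as.character(gr$name)
    lab[is.na(lab) | lab == ""] <- paste0("region_", which(is.na(gr$name) | gr$name == ""))
    lab
  } else {
    paste0("region_", seq_along(gr))
  }
  region_set(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    label = labels,
    name = name
  )
}

# Convert a region_set to GRanges on normalized contig names.
regions_granges <- function(rs) {
  GenomicRanges::GRanges(
    seqnames = norm_contig(rs$contig),
    ranges = IRanges::IRanges(start = rs$start, end = rs$end)
  )
}

# GRanges for variant site coordinates (width-1), normalized contigs.
sites_granges <- function(contig, pos) {
  GenomicRanges::GRanges(
    seqnames = norm_contig(contig),
    ranges = IRanges::IRanges(start = pos, width = 1L)
  )
}
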