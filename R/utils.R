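# Internal helpers shared across modules.

#' Normalize contig names
#'
#' Strips a leading `"chr"` prefix and applies an optional alias map so that
#' e.g. `"X"` and `"chrX"` compare equal. The alias map takes precedence over
#' prefix stripping and maps raw names to normalized names.
#'
#' @param x Character vector of contig names.
#' @param aliases Optional named character vector, `c(raw = normalized, ...)`.
#'   Defaults to the option `xhetkin.contig_aliases` when set.
#' @return Character vector of normalized names.
#' @examples
#' norm_contig(c("chrX", "X", "chr1"))
#' @export
norm_contig <- function(x, aliases = getOption("xhetkin.contig_aliases", NULL)) {
  x <- as.character(x)
  out <- sub("^chr", "", x)
  if (!is.null(aliases)) {
    hit <- x %in% names(aliases)
    out[hit] <- unname(aliases[x[hit]])
  }
  out
}

#' Test contig equality under aliasing
#' @param a,b Contig names (recycled to common length).
#' @param aliases See [norm_contig()].
#' @return Logical vector.
#' @export
contig_match <- function(a, b, aliases = getOption("xhetkin.contig_aliases", NULL)) {
  norm_contig(a, aliases) == norm_contig(b, aliases)
}

# Site keys identify a variant by (contig, position, ref, alt-set); the alt
# string is kept verbatim so multiallelic sites are keyed by their full set.
site_key <- function(contig, pos, ref, alt) {
  paste(contig, pos, ref, alt, sep = ":")
}

is_autosome <- function(contig) {
  !(norm_contig(contig) %in% c("X", "Y", "M", "MT"))
}

# Per-site SNV test: ref and every alt are single bases ("." alt = no alt).
is_snv <- function(ref, alt) {
  alts <- strsplit(as.character(alt), ",", fixed = TRUE)
  nchar(ref) == 1L & vapply(
    alts,
    function(a) length(a) > 0L && all(a != ".") && all(nchar(a) == 1L),
    logical(1)
  )
}

xhetkin_version <- function() {
  as.character(utils::packageVersion("xhetkin"))
}
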