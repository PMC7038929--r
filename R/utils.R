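# Small shared helpers. Coordinates are 1-based inclusive throughout the
# package, matching the Bioconductor convention; external formats keep their
# native dialects and are converted at the I/O boundary.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse-complement a nucleotide string
#'
#' Plain-character reverse complement (ACGTN alphabet, case-insensitive input,
#' uppercase output). Used wherever minus-strand sequence context is needed.
#'
#' @param x character vector of nucleotide strings.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    s <- toupper(s)
    comp <- chartr("ACGTN", "TGCAN", s)
    paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

## Canonical key of a unique chimera: gene pair + exact breakpoints.
chimera_key <- function(gene5, gene3, chrom5, pos5, strand5,
                        chrom3, pos3, strand3) {
  paste(gene5, gene3, chrom5, pos5, strand5, chrom3, pos3, strand3, sep = "|")
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && !is.na(x)

## Round-half-even percentage at one decimal (reproducible printed summaries).
pct1 <- function(num, den) {
  if (den == 0) return(NA_real_)
  round(100 * num / den, 1)
}
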