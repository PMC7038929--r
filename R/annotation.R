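# Gene-model container and queries: exon-boundary roles at fusion
# breakpoints, transcript <-> genomic coordinate conversion, CDS phase,
# 3'UTR lengths and exon ordinals. All coordinates are 1-based inclusive
# genomic positions; "transcript orientation" means 5' to 3' along the mRNA,
# i.e. genomically descending on the minus strand.

#' Build a gene annotation from a feature table
#'
#' @param features data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `feature` (`"exon"` or `"CDS"`), `gene_id`, `gene_name`,
#'   `transcript_id`. Coordinates 1-based inclusive.
#' @return an object of class `chim_annotation`: a list of gene models, each
#'   holding its transcripts with exons (and CDS intervals, if any) ordered
#'   5' to 3' in transcript orientation, plus a symbol/id lookup index.
#' @export
build_annotation <- function(features) {
  stopifnot(is.data.frame(features))
  need <- c("chrom", "start", "end", "strand", "feature", "gene_id",
            "gene_name", "transcript_id")
  if (!all(need %in% names(features)))
    stopf("feature table must have columns: %s", paste(need, collapse = ", "))

  genes <- list()
  if (nrow(features) > 0) {
    for (gid in unique(features$gene_id)) {
      gf <- features[features$gene_id == gid, , drop = FALSE]
      strand <- gf$strand[1]
      chrom <- gf$chrom[1]
      if (!all(gf$strand == strand) || !all(gf$chrom == chrom))
        stopf("gene %s has features on multiple strands/chromosomes", gid)
      txs <- list()
      for (tid in unique(gf$transcript_id)) {
        tf <- gf[gf$transcript_id == tid, , drop = FALSE]
        ex <- tf[tf$feature == "exon", c("start", "end"), drop = FALSE]
        cds <- tf[tf$feature == "CDS", c("start", "end"), drop = FALSE]
        ord <- if (strand == "+") order(ex$start) else order(-ex$start)
        ex <- ex[ord, , drop = FALSE]
        rownames(ex) <- NULL
        if (nrow(ex) > 1) {
          gaps_ok <- if (strand == "+") all(diff(ex$start) > 0) && all(ex$end[-nrow(ex)] < ex$start[-1])
                     else all(diff(ex$start) < 0) && all(ex$end[-1] < ex$start[-nrow(ex)])
          if (!gaps_ok) stopf("transcript %s has overlapping/unordered exons", tid)
        }
        if (nrow(cds) > 0) {
          ordc <- if (strand == "+") order(cds$start) else order(-cds$start)
          cds <- cds[ordc, , drop = FALSE]
          rownames(cds) <- NULL
        } else cds <- NULL
        txs[[tid]] <- list(
          transcript_id = tid, chrom = chrom, strand = strand,
          exons = ex, cds = cds, coding = !is.null(cds)
        )
      }
      genes[[gid]] <- list(
        gene_id = gid, symbol = gf$gene_name[1], chrom = chrom,
        strand = strand, start = min(gf$start), end = max(gf$end),
        transcripts = txs
      )
    }
  }
  index <- if (length(genes) == 0) character(0) else {
    symbols <- vapply(genes, `[[`, character(1), "symbol")
    c(stats::setNames(names(genes), names(genes)),
      stats::setNames(names(genes), symbols))
  }
  structure(list(genes = genes, index = index), class = "chim_annotation")
}

#' @export
print.chim_annotation <- function(x, ...) {
  ntx <- sum(vapply(x$genes, function(g) length(g$transcripts), integer(1)))
  cat(sprintf("chim_annotation: %d gene(s), %d transcript(s)\n",
              length(x$genes), ntx))
  invisible(x)
}

#' Look up a gene model by id or symbol
#'
#' @param annotation a `chim_annotation`.
#' @param name gene id or gene symbol.
#' @return the gene model, or `NULL` if absent.
#' @export
get_gene <- function(annotation, name) {
  gid <- annotation$index[name]
  if (is.na(gid)) return(NULL)
  annotation$genes[[gid]]
}

## Spliced (mRNA) length of a transcript.
spliced_length <- function(tx) sum(tx$exons$end - tx$exons$start + 1L)

#' Classify a genomic position against a gene's exon boundaries
#'
#' On the donor side, a breakpoint is `exon_end` iff it equals the
#' transcript-orientation 3'-most base of some exon of some transcript of the
#' gene (exon end on plus-strand genes, exon start on minus-strand genes);
#' on the acceptor side, iff it equals the 5'-most base of some exon.
#' Otherwise `exon_middle` if the position lies strictly inside some exon,
#' else `outside`. Any transcript qualifying as an end dominates middle.
#'
#' @param gene a gene model from [get_gene()].
#' @param genomic_pos 1-based genomic position on the gene's chromosome.
#' @param side `"donor"` (5' gene) or `"acceptor"` (3' gene).
#' @param tolerance exact matching by default; a positive value accepts ends
#'   within that many bases.
#' @return `"exon_end"`, `"exon_middle"` or `"outside"`.
#' @export
boundary_role <- function(gene, genomic_pos, side = c("donor", "acceptor"),
                          tolerance = 0L) {
  side <- match.arg(side)
  is_end <- FALSE
  is_mid <- FALSE
  for (tx in gene$transcripts) {
    ex <- tx$exons
    ends <- if (side == "donor") {
      if (gene$strand == "+") ex$end else ex$start
    } else {
      if (gene$strand == "+") ex$start else ex$end
    }
    if (any(abs(ends - genomic_pos) <= tolerance)) is_end <- TRUE
    if (any(ex$start < genomic_pos & genomic_pos < ex$end)) is_mid <- TRUE
  }
  if (is_end) "exon_end" else if (is_mid) "exon_middle" else "outside"
}

#' Convert an mRNA position to a genomic coordinate
#'
#' Walks the transcript's exons in transcript orientation and returns the
#' 1-based genomic coordinate of the `mrna_pos`-th spliced base.
#'
#' @param tx a transcript model.
#' @param mrna_pos 1-based position within the spliced mRNA.
#' @return 1-based genomic position.
#' @export
mrna_to_genomic <- function(tx, mrna_pos) {
  if (!is_scalar_number(mrna_pos) || mrna_pos < 1 || mrna_pos != floor(mrna_pos))
    stopf("mrna_pos must be a positive integer")
  total <- spliced_length(tx)
  if (mrna_pos > total)
    stopf("mrna_pos %d exceeds spliced length %d of %s",
          mrna_pos, total, tx$transcript_id)
  offset <- mrna_pos
  for (i in seq_len(nrow(tx$exons))) {
    len <- tx$exons$end[i] - tx$exons$start[i] + 1L
    if (offset <= len) {
      return(if (tx$strand == "+") tx$exons$start[i] + offset - 1L
             else tx$exons$end[i] - offset + 1L)
    }
    offset <- offset - len
  }
  stopf("internal error: exon walk exhausted") # nocov
}

#' Convert a genomic coordinate to an mRNA position
#'
#' Inverse of [mrna_to_genomic()] over exonic positions.
#'
#' @param tx a transcript model.
#' @param genomic_pos 1-based genomic position; must be exonic.
#' @return 1-based position within the spliced mRNA.
#' @export
genomic_to_mrna <- function(tx, genomic_pos) {
  walked <- 0L
  for (i in seq_len(nrow(tx$exons))) {
    s <- tx$exons$start[i]; e <- tx$exons$end[i]
    if (genomic_pos >= s && genomic_pos <= e) {
      inside <- if (tx$strand == "+") genomic_pos - s + 1L else e - genomic_pos + 1L
      return(walked + inside)
    }
    walked <- walked + (e - s + 1L)
  }
  stopf("position %d is not exonic in %s", genomic_pos, tx$transcript_id)
}

## mRNA coordinates (1-based, transcript orientation) of the CDS start/end.
cds_mrna_span <- function(tx) {
  if (!tx$coding) return(NULL)
  first <- tx$cds[1, ]
  last <- tx$cds[nrow(tx$cds), ]
  start_g <- if (tx$strand == "+") first$start else first$end
  end_g <- if (tx$strand == "+") last$end else last$start
  c(start = genomic_to_mrna(tx, start_g), end = genomic_to_mrna(tx, end_g))
}

#' CDS phase of a genomic position
#'
#' Phase is the 0-based offset of the base within the coding sequence modulo
#' 3 (0 = first base of a codon). Positions in UTRs or introns of a coding
#' transcript, or anywhere in a noncoding transcript, return `"noncoding"`;
#' positions outside the transcript span are an error.
#'
#' @param tx a transcript model.
#' @param genomic_pos 1-based genomic position.
#' @return integer 0, 1 or 2, or the string `"noncoding"`.
#' @export
cds_phase <- function(tx, genomic_pos) {
  span_lo <- min(tx$exons$start); span_hi <- max(tx$exons$end)
  if (genomic_pos < span_lo || genomic_pos > span_hi)
    stopf("position %d outside transcript %s", genomic_pos, tx$transcript_id)
  if (!tx$coding) return("noncoding")
  in_cds <- any(tx$cds$start <= genomic_pos & genomic_pos <= tx$cds$end)
  if (!in_cds) return("noncoding")
  exonic <- any(tx$exons$start <= genomic_pos & genomic_pos <= tx$exons$end)
  if (!exonic) return("noncoding")
  mpos <- genomic_to_mrna(tx, genomic_pos)
  cs <- cds_mrna_span(tx)
  as.integer(unname((mpos - cs[["start"]]) %% 3L))
}

#' Spliced 3'UTR length of a transcript
#'
#' Number of spliced bases strictly downstream of the last CDS base. Returns
#' `NA` for noncoding transcripts (excluded from summary statistics).
#'
#' @param tx a transcript model.
#' @return integer length in nucleotides, or `NA` if noncoding.
#' @export
utr3_length <- function(tx) {
  if (!tx$coding) return(NA_integer_)
  cs <- cds_mrna_span(tx)
  as.integer(spliced_length(tx) - cs["end"])
}

#' Gene-level 3'UTR length
#'
#' Maximum [utr3_length()] over the gene's coding transcripts; `NA` if the
#' gene has none. The maximum is stable under annotation subsetting.
#'
#' @param gene a gene model.
#' @return integer or `NA`.
#' @export
gene_utr3_length <- function(gene) {
  vals <- vapply(gene$transcripts, utr3_length, integer(1))
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) NA_integer_ else max(vals)
}

#' Exon ordinal of a genomic position
#'
#' 1-based exon index in transcript orientation (exon 1 is the 5'-most exon
#' of the mRNA), used for e<N>e<M> isoform naming. Intronic positions are an
#' error.
#'
#' @param tx a transcript model.
#' @param genomic_pos 1-based genomic position.
#' @return integer exon ordinal.
#' @export
exon_index_of <- function(tx, genomic_pos) {
  hit <- which(tx$exons$start <= genomic_pos & genomic_pos <= tx$exons$end)
  if (length(hit) == 0)
    stopf("position %d is not exonic in %s", genomic_pos, tx$transcript_id)
  hit[1]
}

#' Spliced transcript sequence from a genome store
#'
#' Concatenates exon sequences in transcript orientation,
#' reverse-complementing on the minus strand.
#'
#' @param tx a transcript model.
#' @param genome named character vector of chromosome sequences.
#' @return character scalar mRNA sequence.
#' @export
transcript_seq <- function(tx, genome) {
  chr <- genome[[tx$chrom]]
  if (is.null(chr)) stopf("chromosome %s absent from genome", tx$chrom)
  pieces <- vapply(seq_len(nrow(tx$exons)), function(i) {
    s <- substr(chr, tx$exons$start[i], tx$exons$end[i])
    if (tx$strand == "-") revcomp(s) else s
  }, character(1))
  paste(pieces, collapse = "")
}
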