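# Per-chimera classifiers: junction class (E/E, E/M, M/E, M/M) from exon
# boundary roles, gene-pair class (read-through / intra-others /
# inter-chromosomal), reading-frame class, canonical splice-motif flags and
# e<N>e<M> isoform naming.

#' Pair-class configuration
#'
#' Controls the read-through (cis-SAGe) proximity rule: two genes form a
#' read-through pair when they sit on the same chromosome and strand, the 5'
#' gene lies strictly upstream of the 3' gene in transcription direction, and
#' the intergenic gap does not exceed `readthrough_max_gap`.
#'
#' @param readthrough_max_gap maximum intergenic gap in bp (default 100000,
#'   wide enough for known cis-SAGe pairs while excluding distal events).
#' @param require_no_intervening_same_strand_gene if `TRUE`, additionally
#'   require that no same-strand gene lies wholly between the pair.
#' @return a `pair_class_config` list.
#' @export
pair_class_config <- function(readthrough_max_gap = 100000L,
                              require_no_intervening_same_strand_gene = FALSE) {
  stopifnot(readthrough_max_gap >= 0)
  structure(list(
    readthrough_max_gap = as.integer(readthrough_max_gap),
    require_no_intervening_same_strand_gene =
      isTRUE(require_no_intervening_same_strand_gene)
  ), class = "pair_class_config")
}

#' Junction class of one chimera
#'
#' Combines the donor-side boundary role of the 5' breakpoint with the
#' acceptor-side role of the 3' breakpoint: end+end = `EE`, end+middle =
#' `EM`, middle+end = `ME`, middle+middle = `MM`. A breakpoint outside any
#' exon of its gene maps to the `M` role (most conservative; the four-class
#' scheme has no fifth category).
#'
#' @param call one-row data.frame (or list) with semantic call fields.
#' @param annotation a `chim_annotation`.
#' @param tolerance exon-end matching tolerance in bp (default exact).
#' @return `"EE"`, `"EM"`, `"ME"` or `"MM"`.
#' @export
classify_junction <- function(call, annotation, tolerance = 0L) {
  g5 <- get_gene(annotation, call$gene5)
  g3 <- get_gene(annotation, call$gene3)
  if (is.null(g5) || is.null(g3))
    stopf("gene symbol absent from annotation: %s",
          if (is.null(g5)) call$gene5 else call$gene3)
  r5 <- boundary_role(g5, call$pos5, "donor", tolerance)
  r3 <- boundary_role(g3, call$pos3, "acceptor", tolerance)
  code <- function(r) if (r == "exon_end") "E" else "M"
  paste0(code(r5), code(r3))
}

#' Gene-pair class of one chimera
#'
#' `inter_chromosomal` when the parental genes lie on different chromosomes;
#' `read_through` when they satisfy the proximity rule of
#' [pair_class_config()]; `intra_other` otherwise (including overlapping
#' gene spans, which trigger a warning).
#'
#' @param call one-row call record.
#' @param annotation a `chim_annotation`.
#' @param cfg a [pair_class_config()].
#' @return `"read_through"`, `"intra_other"` or `"inter_chromosomal"`.
#' @export
classify_pair <- function(call, annotation, cfg = pair_class_config()) {
  g5 <- get_gene(annotation, call$gene5)
  g3 <- get_gene(annotation, call$gene3)
  if (is.null(g5) || is.null(g3))
    stopf("gene symbol absent from annotation: %s",
          if (is.null(g5)) call$gene5 else call$gene3)
  if (g5$chrom != g3$chrom) return("inter_chromosomal")
  if (g5$strand != g3$strand) return("intra_other")
  overlap <- g5$start <= g3$end && g3$start <= g5$end
  if (overlap) {
    warnf("overlapping gene spans for pair %s-%s; classified intra_other",
          g5$symbol, g3$symbol)
    return("intra_other")
  }
  upstream <- if (g5$strand == "+") g5$end < g3$start else g3$end < g5$start
  if (!upstream) return("intra_other")
  gap <- if (g5$strand == "+") g3$start - g5$end - 1L else g5$start - g3$end - 1L
  if (gap > cfg$readthrough_max_gap) return("intra_other")
  if (cfg$require_no_intervening_same_strand_gene) {
    lo <- if (g5$strand == "+") g5$end else g3$end
    hi <- if (g5$strand == "+") g3$start else g5$start
    for (g in annotation$genes) {
      if (g$gene_id %in% c(g5$gene_id, g3$gene_id)) next
      if (g$chrom == g5$chrom && g$strand == g5$strand &&
          g$start > lo && g$end < hi)
        return("intra_other")
    }
  }
  "read_through"
}

#' Reading-frame class of one chimera
#'
#' `in_frame` iff some pair of coding transcripts (one per parental gene)
#' places both breakpoints inside the CDS with a continuing codon walk:
#' `(phase(last 5' base) + 1) mod 3 == phase(first 3' base)`. If no pair is
#' compatible but at least one pair has both breakpoints in coding sequence,
#' `frame_shift`; otherwise (UTR, intron or noncoding on either side) `na`.
#'
#' @param call one-row call record.
#' @param annotation a `chim_annotation`.
#' @return `"in_frame"`, `"frame_shift"` or `"na"`.
#' @export
predict_frame <- function(call, annotation) {
  g5 <- get_gene(annotation, call$gene5)
  g3 <- get_gene(annotation, call$gene3)
  if (is.null(g5) || is.null(g3))
    stopf("gene symbol absent from annotation: %s",
          if (is.null(g5)) call$gene5 else call$gene3)
  phases <- function(gene, pos) {
    out <- integer(0)
    for (tx in gene$transcripts) {
      if (!tx$coding) next
      if (pos < min(tx$exons$start) || pos > max(tx$exons$end)) next
      ph <- cds_phase(tx, pos)
      if (!identical(ph, "noncoding")) out <- c(out, ph)
    }
    unique(out)
  }
  p5 <- phases(g5, call$pos5)
  p3 <- phases(g3, call$pos3)
  if (length(p5) == 0 || length(p3) == 0) return("na")
  compatible <- outer((p5 + 1L) %% 3L, p3, `==`)
  if (any(compatible)) "in_frame" else "frame_shift"
}

#' Canonical splice-motif flags at the junction
#'
#' Donor flag: the two bases ending at the 5' breakpoint, read on the 5'
#' gene's strand, are `AG` and the two bases immediately after are `GT`
#' (the canonical AG/GT donor context). Acceptor flag: the two bases
#' immediately before the 3' breakpoint are `AG` and the breakpoint base is
#' `G` (AG/G context). Minus-strand genes are evaluated on the reverse
#' complement. Breakpoints within two bases of a contig edge return `NA`
#' flags (excluded from percentage denominators).
#'
#' @param call one-row call record.
#' @param genome named character vector of chromosome sequences.
#' @return list with logical `donor_motif` and `acceptor_motif` (or `NA`).
#' @export
splice_motifs <- function(call, genome) {
  ctx <- function(chrom, pos, strand, before, after) {
    chr <- genome[[chrom]]
    if (is.null(chr)) stopf("chromosome %s absent from genome", chrom)
    n <- nchar(chr)
    if (strand == "+") {
      lo <- pos - before + 1L; hi <- pos + after
      if (lo < 1 || hi > n) return(NA_character_)
      substr(chr, lo, hi)
    } else {
      lo <- pos - after; hi <- pos + before - 1L
      if (lo < 1 || hi > n) return(NA_character_)
      revcomp(substr(chr, lo, hi))
    }
  }
  don <- ctx(call$chrom5, call$pos5, call$strand5, 2L, 2L)
  acc <- ctx(call$chrom3, call$pos3, call$strand3, 3L, 0L)
  donor <- if (is.na(don)) NA else substr(don, 1, 2) == "AG" && substr(don, 3, 4) == "GT"
  acceptor <- if (is.na(acc)) NA else substr(acc, 1, 2) == "AG" && substr(acc, 3, 3) == "G"
  list(donor_motif = donor, acceptor_motif = acceptor)
}

#' e<N>e<M> isoform name of a chimera
#'
#' Names a fusion isoform by the exon ordinal of the 5' breakpoint and of
#' the 3' breakpoint. Per gene, the transcript whose exon boundary matches
#' the breakpoint is used (falling back to any transcript containing the
#' position in an exon); ties are broken toward the longest spliced
#' transcript, deterministically. Intronic breakpoints yield `NA` (unnamed).
#'
#' @param call one-row call record.
#' @param annotation a `chim_annotation`.
#' @return string such as `"e14e2"`, or `NA_character_`.
#' @export
isoform_name <- function(call, annotation) {
  g5 <- get_gene(annotation, call$gene5)
  g3 <- get_gene(annotation, call$gene3)
  if (is.null(g5) || is.null(g3)) return(NA_character_)
  pick <- function(gene, pos, side) {
    cand <- list(); cand_match <- logical(0); cand_len <- integer(0)
    for (tx in gene$transcripts) {
      hit <- any(tx$exons$start <= pos & pos <= tx$exons$end)
      if (!hit) next
      ends <- if (side == "donor") {
        if (gene$strand == "+") tx$exons$end else tx$exons$start
      } else {
        if (gene$strand == "+") tx$exons$start else tx$exons$end
      }
      cand[[length(cand) + 1L]] <- tx
      cand_match <- c(cand_match, pos %in% ends)
      cand_len <- c(cand_len, spliced_length(tx))
    }
    if (length(cand) == 0) return(NULL)
    pool <- if (any(cand_match)) which(cand_match) else seq_along(cand)
    ids <- vapply(cand, `[[`, character(1), "transcript_id")
    best <- pool[order(-cand_len[pool], ids[pool])][1]
    cand[[best]]
  }
  tx5 <- pick(g5, call$pos5, "donor")
  tx3 <- pick(g3, call$pos3, "acceptor")
  if (is.null(tx5) || is.null(tx3)) return(NA_character_)
  sprintf("e%de%d", exon_index_of(tx5, call$pos5), exon_index_of(tx3, call$pos3))
}

#' Classify every call in a table
#'
#' Applies [classify_junction()], [classify_pair()], [predict_frame()],
#' [splice_motifs()] and [isoform_name()] to each call with breakpoints.
#' Calls whose gene symbols are absent from the annotation receive `NA`
#' labels and a `classification_error` flag; they are excluded from
#' class-dependent stages downstream.
#'
#' @param calls data.frame of calls (semantic columns).
#' @param annotation a `chim_annotation`.
#' @param genome named character vector of chromosome sequences (optional;
#'   motif flags are `NA` when absent).
#' @param cfg a [pair_class_config()].
#' @param tolerance exon-end matching tolerance in bp.
#' @return `calls` with columns `junction_class`, `pair_class`,
#'   `frame_class`, `donor_motif`, `acceptor_motif`, `isoform`,
#'   `classification_error` appended.
#' @export
classify_calls <- function(calls, annotation, genome = NULL,
                           cfg = pair_class_config(), tolerance = 0L) {
  n <- nrow(calls)
  jc <- pc <- fc <- iso <- rep(NA_character_, n)
  dm <- am <- rep(NA, n)
  err <- rep(FALSE, n)
  for (i in seq_len(n)) {
    row <- calls[i, ]
    if (isTRUE(row$missing_breakpoint)) { err[i] <- TRUE; next }
    known <- !is.null(get_gene(annotation, row$gene5)) &&
             !is.null(get_gene(annotation, row$gene3))
    if (!known) { err[i] <- TRUE; next }
    jc[i] <- classify_junction(row, annotation, tolerance)
    pc[i] <- classify_pair(row, annotation, cfg)
    fc[i] <- predict_frame(row, annotation)
    iso[i] <- isoform_name(row, annotation)
    if (!is.null(genome)) {
      m <- splice_motifs(row, genome)
      dm[i] <- m$donor_motif
      am[i] <- m$acceptor_motif
    }
  }
  calls$junction_class <- jc
  calls$pair_class <- pc
  calls$frame_class <- fc
  calls$donor_motif <- dm
  calls$acceptor_motif <- am
  calls$isoform <- iso
  calls$classification_error <- err
  calls
}
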