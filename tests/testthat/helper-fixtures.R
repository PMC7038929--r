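# Shared fixtures and independent oracles. Fixtures are built in code; the
# oracles deliberately re-derive expected values from first principles
# (raw exon lists, regex digestion, string slicing) rather than calling the
# implementation under test.

rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## A minimal feature table for one gene with explicit exons (1-based,
## genomic) and optional CDS intervals.
gene_features <- function(gene_id, chrom, strand, exons, cds = NULL,
                          transcript_id = paste0("TX_", gene_id)) {
  f <- data.frame(chrom = chrom, start = exons$start, end = exons$end,
                  strand = strand, feature = "exon", gene_id = gene_id,
                  gene_name = gene_id, transcript_id = transcript_id,
                  stringsAsFactors = FALSE)
  if (!is.null(cds))
    f <- rbind(f, data.frame(chrom = chrom, start = cds$start, end = cds$end,
                             strand = strand, feature = "CDS",
                             gene_id = gene_id, gene_name = gene_id,
                             transcript_id = transcript_id,
                             stringsAsFactors = FALSE))
  f
}

iv <- function(start, end) data.frame(start = start, end = end)

## One-row call record with sensible defaults.
make_call <- function(gene5, gene3, chrom5, pos5, strand5, chrom3, pos3,
                      strand3, sample_id = "S1", tissue = "liver",
                      junction_seq = NA_character_, score = 0.9,
                      chimera_expr = 10, gene5_expr = 40, gene3_expr = 40,
                      missing_breakpoint = FALSE) {
  data.frame(sample_id = sample_id, tissue = tissue, gene5 = gene5,
             gene3 = gene3, chrom5 = chrom5, pos5 = pos5, strand5 = strand5,
             chrom3 = chrom3, pos3 = pos3, strand3 = strand3,
             junction_seq = junction_seq, score = score,
             chimera_expr = chimera_expr, gene5_expr = gene5_expr,
             gene3_expr = gene3_expr,
             missing_breakpoint = missing_breakpoint,
             stringsAsFactors = FALSE)
}

## Brute-force boundary-role oracle working directly on raw exon interval
## lists: donor end = transcript-orientation 3'-most base of an exon,
## acceptor end = 5'-most; middle = strictly inside; outside otherwise.
oracle_boundary_role <- function(exon_list, strand, pos, side) {
  is_end <- FALSE
  is_mid <- FALSE
  for (ex in exon_list) {
    for (i in seq_len(nrow(ex))) {
      s <- ex$start[i]; e <- ex$end[i]
      endpos <- if (side == "donor") {
        if (strand == "+") e else s
      } else {
        if (strand == "+") s else e
      }
      if (pos == endpos) is_end <- TRUE
      if (pos > s && pos < e) is_mid <- TRUE
    }
  }
  if (is_end) "exon_end" else if (is_mid) "exon_middle" else "outside"
}

## Brute-force spliced coordinate map: enumerate every mRNA position of a
## transcript as (mrna_pos, genomic_pos) pairs.
oracle_splice_map <- function(exons, strand) {
  ord <- if (strand == "+") order(exons$start) else order(-exons$start)
  gpos <- unlist(lapply(ord, function(i) {
    if (strand == "+") exons$start[i]:exons$end[i]
    else exons$end[i]:exons$start[i]
  }))
  data.frame(mrna = seq_along(gpos), genomic = gpos)
}

## Independent tryptic digestion via regex split (cleave after K/R unless
## followed by P).
oracle_digest <- function(pep) {
  if (nchar(pep) == 0) return(character(0))
  strsplit(pep, "(?<=[KR])(?!P)", perl = TRUE)[[1]]
}

## Independent full enumeration of junction-spanning tryptic peptides:
## translate each frame with Biostrings, split segments at stops, digest
## with the regex oracle, and keep fragments with >= min_side residues whose
## codons lie fully on each side of the junction boundary.
oracle_junction_peptides <- function(seq, junction_offset, min_side = 2) {
  out <- list()
  jpos <- junction_offset + 1
  for (f in 0:2) {
    sub <- substr(seq, f + 1, nchar(seq))
    n_cod <- nchar(sub) %/% 3
    if (n_cod == 0) next
    aa <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(sub, 1, 3 * n_cod)),
      if.fuzzy.codon = "X", no.init.codon = TRUE))
    ## global residue index i covers bases [f + 3i - 2, f + 3i]
    res_start <- f + 3 * seq_len(n_cod) - 2
    res_end <- f + 3 * seq_len(n_cod)
    aav <- strsplit(aa, "", fixed = TRUE)[[1]]
    seg_id <- cumsum(aav == "*")
    for (seg in unique(seg_id)) {
      idx <- which(seg_id == seg & aav != "*")
      if (length(idx) == 0) next
      frags <- oracle_digest(paste(aav[idx], collapse = ""))
      pos <- 0
      for (fr in frags) {
        ids <- idx[(pos + 1):(pos + nchar(fr))]
        pos <- pos + nchar(fr)
        left <- sum(res_end[ids] <= junction_offset)
        right <- sum(res_start[ids] >= jpos)
        spans <- any(res_start[ids] <= jpos & res_end[ids] >= jpos) ||
          (left > 0 && right > 0)
        if (spans && left >= min_side && right >= min_side)
          out[[length(out) + 1]] <- data.frame(
            frame = f, sequence = fr, left_len = left, right_len = right,
            stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(frame = integer(0), sequence = character(0),
                      left_len = integer(0), right_len = integer(0)))
  do.call(rbind, out)
}

## Cached small simulation shared across test files (built once per run).
.sim_cache <- new.env(parent = emptyenv())
get_small_sim <- function(seed = 42) {
  key <- paste0("sim_", seed)
  if (is.null(.sim_cache[[key]])) {
    cfg <- sim_preset("small", seed = seed)
    u <- make_universe(cfg)
    .sim_cache[[key]] <- list(cfg = cfg, sim = simulate_calls(cfg, u))
  }
  .sim_cache[[key]]
}
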