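# Chimeric peptide prediction: junction flank assembly, three-frame
# translation, in-silico tryptic digestion, retention of junction-spanning
# fragments, search-database export, PSM filtering and reference-proteome
# side screening.

#' Assemble the nucleotide sequence around a chimeric junction
#'
#' Joins `flank` bases ending at the 5' breakpoint (in the 5' gene's
#' transcript orientation) to `flank` bases starting at the 3' breakpoint
#' (in the 3' gene's orientation). In `"genomic"` mode the flanks are
#' unspliced genomic windows; in `"spliced"` mode they walk the exons of a
#' transcript containing the breakpoint (longest such transcript). Windows
#' are truncated, never padded, at contig or transcript edges.
#'
#' @param call one-row call record.
#' @param genome named character vector of chromosome sequences.
#' @param annotation `chim_annotation`; required for `"spliced"` mode.
#' @param flank flank width in bp (default 200).
#' @param mode `"genomic"` or `"spliced"`.
#' @return list with `key`, `sequence`, `junction_offset` (number of
#'   upstream bases, i.e. 0-based index of the first 3'-segment base) and
#'   `truncated` flag.
#' @export
build_junction_sequence <- function(call, genome, annotation = NULL,
                                    flank = 200L, mode = c("genomic", "spliced")) {
  mode <- match.arg(mode)
  key <- chimera_key(call$gene5, call$gene3, call$chrom5, call$pos5,
                     call$strand5, call$chrom3, call$pos3, call$strand3)
  if (mode == "genomic") {
    side_seq <- function(chrom, pos, strand, upstream) {
      chr <- genome[[chrom]]
      if (is.null(chr)) stopf("chromosome %s absent from genome", chrom)
      n <- nchar(chr)
      if (pos < 1 || pos > n)
        stopf("breakpoint %d off contig %s (length %d)", pos, chrom, n)
      ## upstream: window ends at pos in transcript orientation;
      ## downstream: window starts at pos.
      left_window <- (strand == "+") == upstream
      if (left_window) {
        lo <- max(1L, pos - flank + 1L); s <- substr(chr, lo, pos)
      } else {
        hi <- min(n, pos + flank - 1L); s <- substr(chr, pos, hi)
      }
      if (strand == "-") s <- revcomp(s)
      s
    }
    up <- side_seq(call$chrom5, call$pos5, call$strand5, upstream = TRUE)
    down <- side_seq(call$chrom3, call$pos3, call$strand3, upstream = FALSE)
  } else {
    if (is.null(annotation)) stopf("spliced mode requires an annotation")
    pick_tx <- function(gname, pos) {
      gene <- get_gene(annotation, gname)
      if (is.null(gene)) stopf("gene %s absent from annotation", gname)
      cand <- Filter(function(tx) any(tx$exons$start <= pos & pos <= tx$exons$end),
                     gene$transcripts)
      if (length(cand) == 0)
        stopf("breakpoint %d not exonic in gene %s", pos, gname)
      lens <- vapply(cand, spliced_length, numeric(1))
      ids <- vapply(cand, `[[`, character(1), "transcript_id")
      cand[[order(-lens, ids)[1]]]
    }
    tx5 <- pick_tx(call$gene5, call$pos5)
    tx3 <- pick_tx(call$gene3, call$pos3)
    m5 <- genomic_to_mrna(tx5, call$pos5)
    m3 <- genomic_to_mrna(tx3, call$pos3)
    s5 <- transcript_seq(tx5, genome)
    s3 <- transcript_seq(tx3, genome)
    up <- substr(s5, max(1L, m5 - flank + 1L), m5)
    down <- substr(s3, m3, min(nchar(s3), m3 + flank - 1L))
  }
  list(key = key, sequence = paste0(up, down),
       junction_offset = nchar(up),
       truncated = nchar(up) < flank || nchar(down) < flank)
}

## Codon table lookup; N-containing codons -> X, stops -> "*".
.translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa) & grepl("N", codons)] <- "X"
  if (anyNA(aa))
    stopf("non-ACGTN character in codon '%s'", codons[which(is.na(aa))[1]])
  aa
}

#' Three-frame translation with junction tracking
#'
#' Translates the junction sequence in reading frames 0, 1 and 2 with the
#' standard genetic code. Stop codons are emitted as `*` (segment
#' separators). The residue whose codon overlaps the first 3'-segment base
#' is reported as the junction residue for each frame.
#'
#' @param js a junction sequence from [build_junction_sequence()].
#' @return list of three frames, each with `frame` (0/1/2), `aa` (string
#'   including `*`), and `junction_residue` (1-based index, or `NA` when no
#'   codon covers the junction base in that frame).
#' @export
three_frame_translate <- function(js) {
  seq <- toupper(js$sequence)
  if (nchar(seq) < 3L) stopf("junction sequence shorter than one codon")
  if (grepl("[^ACGTN]", seq)) stopf("non-ACGTN character in junction sequence")
  jpos <- js$junction_offset + 1L      # first 3'-segment base, 1-based
  lapply(0:2, function(f) {
    n_cod <- (nchar(seq) - f) %/% 3L
    if (n_cod == 0L)
      return(list(frame = f, aa = "", junction_residue = NA_integer_))
    starts <- f + 1L + 3L * (seq_len(n_cod) - 1L)
    codons <- substring(seq, starts, starts + 2L)
    aa <- .translate_codons(codons)
    jres <- if (jpos <= f) NA_integer_ else as.integer(ceiling((jpos - f) / 3))
    if (!is.na(jres) && jres > n_cod) jres <- NA_integer_
    list(frame = f, aa = paste(aa, collapse = ""), junction_residue = jres)
  })
}

#' In-silico tryptic digestion
#'
#' Cleaves C-terminal to lysine (K) or arginine (R), suppressed when the
#' next residue is proline (P). Zero missed cleavages by default; up to two
#' may be allowed, in which case fragments spanning that many internal
#' cleavage sites are also returned.
#'
#' @param peptide amino-acid string without stop symbols.
#' @param missed_cleavages integer 0-2.
#' @param proline_rule disable to cleave K/R-P bonds as well.
#' @return data.frame with `start`, `end` (1-based residue coordinates) and
#'   `fragment`; zero rows for empty input.
#' @export
tryptic_digest <- function(peptide, missed_cleavages = 0L, proline_rule = TRUE) {
  stopifnot(missed_cleavages %in% 0:2)
  n <- nchar(peptide)
  if (n == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      fragment = character(0), stringsAsFactors = FALSE))
  if (grepl("\\*", peptide)) stopf("stop symbol inside digestion input")
  res <- strsplit(peptide, "", fixed = TRUE)[[1]]
  cut_after <- which(res %in% c("K", "R"))
  cut_after <- cut_after[cut_after < n]
  if (proline_rule && length(cut_after) > 0)
    cut_after <- cut_after[res[cut_after + 1L] != "P"]
  bounds <- c(0L, cut_after, n)
  base <- data.frame(start = bounds[-length(bounds)] + 1L, end = bounds[-1])
  out <- base
  if (missed_cleavages > 0) {
    for (mc in seq_len(missed_cleavages)) {
      if (nrow(base) <= mc) break
      i <- seq_len(nrow(base) - mc)
      out <- rbind(out, data.frame(start = base$start[i], end = base$end[i + mc]))
    }
    out <- out[order(out$start, out$end), , drop = FALSE]
  }
  out$fragment <- substring(peptide, out$start, out$end)
  rownames(out) <- NULL
  out
}

## Residue-side arithmetic: counts of fragment residues whose codons lie
## entirely 5' / entirely 3' of the junction boundary, in frame f.
.side_lengths <- function(s, e, f, jpos) {
  i5max <- floor((jpos - 1L - f) / 3)       # last fully-5' residue index
  i3min <- ceiling((jpos + 2L - f) / 3)     # first fully-3' residue index
  left <- max(0L, min(e, i5max) - s + 1L)
  right <- max(0L, e - max(s, i3min) + 1L)
  c(left = as.integer(left), right = as.integer(right))
}

#' Junction-spanning tryptic peptides of a chimera
#'
#' For each reading frame: translate the assembled junction sequence, locate
#' the stop-free segment containing the junction residue, digest it with
#' trypsin, and retain the fragment that spans the junction with at least
#' `min_side` residues strictly on each side of the boundary (residues whose
#' codons lie entirely within one parental segment). A frame whose junction
#' codon is a stop, or whose spanning fragment fails the side minimum,
#' yields nothing — so a chimera produces at most three peptides.
#'
#' @param call one-row call record.
#' @param genome named character vector of chromosome sequences.
#' @param annotation optional `chim_annotation` (for spliced flank mode).
#' @param flank flank width in bp (default 200).
#' @param min_side minimum residues on each side of the junction (default 2).
#' @param mode flank assembly mode, see [build_junction_sequence()].
#' @param missed_cleavages passed to [tryptic_digest()].
#' @return data.frame with `key`, `frame`, `sequence`, `left_len`,
#'   `right_len`; zero rows when no frame qualifies.
#' @export
junction_peptides <- function(call, genome, annotation = NULL, flank = 200L,
                              min_side = 2L, mode = "genomic",
                              missed_cleavages = 0L) {
  js <- build_junction_sequence(call, genome, annotation, flank, mode)
  peptides_from_junction(js, min_side, missed_cleavages)
}

#' @rdname junction_peptides
#' @param js a junction sequence from [build_junction_sequence()]; this
#'   variant skips flank assembly (used by tests and the generator).
#' @export
peptides_from_junction <- function(js, min_side = 2L, missed_cleavages = 0L) {
  frames <- three_frame_translate(js)
  jpos <- js$junction_offset + 1L
  out <- list()
  for (fr in frames) {
    if (is.na(fr$junction_residue) || nchar(fr$aa) == 0L) next
    aa <- strsplit(fr$aa, "", fixed = TRUE)[[1]]
    jres <- fr$junction_residue
    if (aa[jres] == "*") next
    stops <- which(aa == "*")
    seg_start <- max(c(0L, stops[stops < jres])) + 1L
    seg_end <- min(c(length(aa) + 1L, stops[stops > jres])) - 1L
    segment <- paste(aa[seg_start:seg_end], collapse = "")
    frags <- tryptic_digest(segment, missed_cleavages)
    if (nrow(frags) == 0) next
    for (i in seq_len(nrow(frags))) {
      s <- frags$start[i] + seg_start - 1L     # global residue coordinates
      e <- frags$end[i] + seg_start - 1L
      sides <- .side_lengths(s, e, fr$frame, jpos)
      if (sides[["left"]] >= min_side && sides[["right"]] >= min_side) {
        out[[length(out) + 1L]] <- data.frame(
          key = js$key, frame = fr$frame, sequence = frags$fragment[i],
          left_len = sides[["left"]], right_len = sides[["right"]],
          stringsAsFactors = FALSE
        )
        break    # fragments partition the segment: at most one spans
      }
    }
  }
  if (length(out) == 0)
    return(data.frame(key = character(0), frame = integer(0),
                      sequence = character(0), left_len = integer(0),
                      right_len = integer(0), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Write the chimeric-peptide search database
#'
#' FASTA with one record per chimeric peptide, headers carrying the chimera
#' key, frame and side lengths (`chim|<key>|frame=<f>|left=<n>|right=<m>`),
#' followed by the reference protein records. Record order is deterministic
#' (peptides sorted by key then frame; reference proteins by id).
#'
#' @param peptides data.frame from [junction_peptides()].
#' @param reference_proteins named character vector of protein sequences.
#' @param path output FASTA path.
#' @export
write_peptide_db <- function(peptides, reference_proteins, path) {
  if (nrow(peptides) == 0)
    warnf("no chimeric peptides; writing reference-only database")
  ord <- order(peptides$key, peptides$frame)
  pep <- peptides[ord, , drop = FALSE]
  ids <- sprintf("chim|%s|frame=%d|left=%d|right=%d",
                 pep$key, pep$frame, pep$left_len, pep$right_len)
  seqs <- c(stats::setNames(pep$sequence, ids),
            reference_proteins[order(names(reference_proteins))])
  write_fasta(seqs, path)
  invisible(path)
}

#' Parse a chimeric-peptide FASTA header
#'
#' @param id header string written by [write_peptide_db()].
#' @return list with `key`, `frame`, `left_len`, `right_len`, or `NULL` for
#'   non-chimeric (reference) records.
#' @export
parse_peptide_header <- function(id) {
  if (!startsWith(id, "chim|")) return(NULL)
  m <- regmatches(id, regexec(
    "^chim\\|(.+)\\|frame=(\\d+)\\|left=(\\d+)\\|right=(\\d+)$", id))[[1]]
  if (length(m) != 5) stopf("malformed chimeric peptide header: %s", id)
  list(key = m[2], frame = as.integer(m[3]),
       left_len = as.integer(m[4]), right_len = as.integer(m[5]))
}

#' Filter PSMs against the chimeric-peptide database
#'
#' Accepts peptide spectrum matches with `q_value` strictly below `q_max`
#' whose peptide sequence is a chimeric database entry with both side
#' lengths at least `min_side`. PSMs whose peptide is absent from the
#' chimeric entries count as non-chimeric and are excluded.
#'
#' @param psms data.frame of PSM records (see [read_psm_table()]).
#' @param peptide_db data.frame of chimeric peptides
#'   ([junction_peptides()] output).
#' @param q_max q-value cutoff (strict `<`; default 0.05).
#' @param min_side minimum residues on each side of the junction.
#' @return list with `accepted` (PSM rows), `peptides` (unique accepted
#'   peptide sequences), `n_psms` and `n_peptides`.
#' @export
filter_psms <- function(psms, peptide_db, q_max = 0.05, min_side = 2L) {
  ok_db <- peptide_db[peptide_db$left_len >= min_side &
                      peptide_db$right_len >= min_side, , drop = FALSE]
  accept <- psms$q_value < q_max & psms$peptide %in% ok_db$sequence
  accepted <- psms[accept, , drop = FALSE]
  rownames(accepted) <- NULL
  peptides <- sort(unique(accepted$peptide))
  list(accepted = accepted, peptides = peptides,
       n_psms = nrow(accepted), n_peptides = length(peptides))
}

#' Screen peptide halves against a reference proteome
#'
#' Splits each chimeric peptide at the junction boundary (the fully-5'
#' residues versus the fully-3' residues) and searches each half as an exact
#' substring of the reference proteins. Labels: `both_sides` when both
#' halves hit, `one_side` when exactly one does, `no_hit` otherwise.
#'
#' @param peptides data.frame from [junction_peptides()].
#' @param reference_proteome named character vector of protein sequences.
#' @return `peptides` with a `ref_match` column appended.
#' @export
side_match_screen <- function(peptides, reference_proteome) {
  prot <- unname(reference_proteome)
  hit <- function(x) {
    if (is.na(x) || nchar(x) == 0) return(FALSE)
    any(vapply(prot, function(p) grepl(x, p, fixed = TRUE), logical(1)))
  }
  labels <- character(nrow(peptides))
  for (i in seq_len(nrow(peptides))) {
    left <- substr(peptides$sequence[i], 1L, peptides$left_len[i])
    nres <- nchar(peptides$sequence[i])
    right <- substr(peptides$sequence[i], nres - peptides$right_len[i] + 1L, nres)
    n_hit <- hit(left) + hit(right)
    labels[i] <- c("no_hit", "one_side", "both_sides")[n_hit + 1L]
  }
  peptides$ref_match <- labels
  peptides
}
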