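# Readers and writers for the external file formats: fusion call tables
# (configurable TSV dialect), GTF annotation, FASTA sequence stores, sample
# metadata, FPKM expression matrices, cancer fusion-database tables and PSM
# tables. Every writer/reader pair round-trips field-for-field.

.SEMANTIC_FIELDS <- c(
  "sample_id", "gene5", "gene3", "chrom5", "pos5", "strand5",
  "chrom3", "pos3", "strand3", "junction_seq", "score",
  "chimera_expr", "gene5_expr", "gene3_expr"
)

#' Call-table dialect
#'
#' Maps the semantic fields of a fusion call table onto the column names of a
#' concrete TSV flavour. The default corresponds to an EricScript-style table
#' (`Sample`, `GeneName1`, `GeneName2`, `chr1`, `Breakpoint1`, `strand1`, ...,
#' `EricScore`, `JunctionSequence`, `GeneExpr1`, `GeneExpr2`,
#' `GeneExpr_Fused`). Breakpoints are 1-based: `pos5` is the genomic
#' coordinate of the last base of the 5' segment and `pos3` the first base of
#' the 3' segment, each on its parental gene's strand.
#'
#' @param column_map named character vector mapping semantic fields to source
#'   column names; defaults cover all fourteen required fields.
#' @param has_header logical; whether the file carries a header row.
#' @return an object of class `call_table_dialect`.
#' @export
call_table_dialect <- function(column_map = NULL, has_header = TRUE) {
  default <- c(
    sample_id = "Sample", gene5 = "GeneName1", gene3 = "GeneName2",
    chrom5 = "chr1", pos5 = "Breakpoint1", strand5 = "strand1",
    chrom3 = "chr2", pos3 = "Breakpoint2", strand3 = "strand2",
    junction_seq = "JunctionSequence", score = "EricScore",
    chimera_expr = "GeneExpr_Fused", gene5_expr = "GeneExpr1",
    gene3_expr = "GeneExpr2"
  )
  map <- default
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), .SEMANTIC_FIELDS)
    if (length(unknown) > 0)
      stopf("unknown semantic fields in column_map: %s",
            paste(unknown, collapse = ", "))
    map[names(column_map)] <- column_map
  }
  missing <- setdiff(.SEMANTIC_FIELDS, names(map))
  if (length(missing) > 0)
    stopf("dialect is missing semantic fields: %s",
          paste(missing, collapse = ", "))
  if (anyDuplicated(map))
    stopf("dialect maps two semantic fields to the same source column")
  structure(list(column_map = map, has_header = isTRUE(has_header)),
            class = "call_table_dialect")
}

#' Read a fusion call table
#'
#' One row per predicted chimera per sample. Rows whose breakpoint fields are
#' empty or `NA` are returned with `missing_breakpoint = TRUE` rather than
#' dropped, so that the score filter can discard them with an auditable
#' reason. Breakpoint values that are present but not positive integers raise
#' a row-level parse error naming the offending line.
#'
#' @param path TSV file path.
#' @param dialect a [call_table_dialect()].
#' @return a data.frame of calls with semantic column names plus
#'   `missing_breakpoint`.
#' @export
read_call_table <- function(path, dialect = call_table_dialect()) {
  if (!file.exists(path)) stopf("call table not found: %s", path)
  stopifnot(inherits(dialect, "call_table_dialect"))
  raw <- utils::read.delim(path, header = dialect$has_header,
                           colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (!dialect$has_header) names(raw) <- dialect$column_map
  map <- dialect$column_map
  absent <- setdiff(unname(map), names(raw))
  if (length(absent) > 0)
    stopf("call table lacks mapped column(s): %s", paste(absent, collapse = ", "))
  calls <- as.data.frame(lapply(map, function(col) raw[[col]]),
                         stringsAsFactors = FALSE)
  names(calls) <- names(map)

  parse_pos <- function(x, field) {
    blank <- is.na(x) | trimws(x) == "" | toupper(trimws(x)) == "NA"
    out <- rep(NA_integer_, length(x))
    if (any(!blank)) {
      v <- suppressWarnings(as.numeric(x[!blank]))
      bad <- is.na(v) | v != floor(v) | v < 1
      if (any(bad)) {
        line <- which(!blank)[which(bad)[1]] + as.integer(dialect$has_header)
        stopf("non-integer %s at line %d: '%s'", field, line,
              x[!blank][which(bad)[1]])
      }
      out[!blank] <- as.integer(v)
    }
    list(value = out, blank = blank)
  }
  p5 <- parse_pos(calls$pos5, "pos5")
  p3 <- parse_pos(calls$pos3, "pos3")
  calls$pos5 <- p5$value
  calls$pos3 <- p3$value
  calls$missing_breakpoint <- p5$blank | p3$blank
  for (fld in c("score", "chimera_expr", "gene5_expr", "gene3_expr")) {
    v <- suppressWarnings(as.numeric(calls[[fld]]))
    bad <- which(is.na(v) & !is.na(calls[[fld]]) & trimws(calls[[fld]]) != "")
    if (length(bad) > 0)
      stopf("malformed numeric field %s at line %d", fld,
            bad[1] + as.integer(dialect$has_header))
    calls[[fld]] <- v
  }
  bad_strand <- !(calls$strand5 %in% c("+", "-")) | !(calls$strand3 %in% c("+", "-"))
  if (any(bad_strand))
    stopf("invalid strand at line %d", which(bad_strand)[1] + as.integer(dialect$has_header))
  rownames(calls) <- NULL
  calls
}

#' Write a fusion call table
#'
#' Inverse of [read_call_table()]: writes semantic columns back out under the
#' dialect's source column names. `read_call_table(write_call_table(x))`
#' reproduces `x` field-for-field.
#'
#' @param calls data.frame of calls (semantic column names).
#' @param path output TSV path.
#' @param dialect a [call_table_dialect()].
#' @export
write_call_table <- function(calls, path, dialect = call_table_dialect()) {
  map <- dialect$column_map
  out <- calls[, names(map), drop = FALSE]
  names(out) <- unname(map)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = dialect$has_header)
  invisible(path)
}

#' Read a GTF gene annotation
#'
#' Parses an Ensembl-dialect GTF into a gene -> transcript -> exon/CDS model.
#' Exons are stored in transcript order (5' to 3' in transcript orientation);
#' coordinates stay 1-based inclusive. Duplicate exon lines are collapsed
#' with a warning; exon features without a `transcript_id` are an error.
#'
#' @param path GTF file path.
#' @return a `chim_annotation` object (see [build_annotation()]).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF not found: %s", path)
  lines <- readLines(path)
  if (!any(nzchar(lines) & !grepl("^#", lines))) {
    return(build_annotation(data.frame(
      chrom = character(), start = integer(), end = integer(),
      strand = character(), feature = character(), gene_id = character(),
      gene_name = character(), transcript_id = character()
    )))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = as.character(gr$type),
    gene_id = as.character(gr$gene_id),
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  df$gene_name <- if ("gene_name" %in% names(mc)) as.character(gr$gene_name) else df$gene_id
  df$transcript_id <- if ("transcript_id" %in% names(mc)) as.character(gr$transcript_id) else NA_character_
  df <- df[df$feature %in% c("exon", "CDS"), , drop = FALSE]
  if (any(df$feature == "exon" & (is.na(df$transcript_id) | df$transcript_id == "")))
    stopf("GTF exon feature without transcript_id")
  key <- paste(df$feature, df$transcript_id, df$chrom, df$start, df$end)
  dup <- duplicated(key)
  if (any(dup)) {
    warnf("GTF: %d duplicate exon/CDS line(s) collapsed", sum(dup))
    df <- df[!dup, , drop = FALSE]
  }
  build_annotation(df)
}

#' Read a FASTA file into a sequence store
#'
#' @param path FASTA file path.
#' @return named character vector, ids truncated at first whitespace,
#'   sequences uppercased. Duplicate ids are an error.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("FASTA not found: %s", path)
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stopf("duplicate FASTA id: %s", ids[duplicated(ids)][1])
  seqs <- toupper(as.character(set))
  names(seqs) <- ids
  seqs
}

#' Write a sequence store to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read sample metadata
#'
#' TSV with columns `sample_id`, `tissue`, `donor_id`. Sample ids must be
#' unique and every tissue has at least one sample by construction.
#'
#' @param path TSV path.
#' @return data.frame with the three columns.
#' @export
read_metadata <- function(path) {
  md <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "tissue", "donor_id")
  if (!all(need %in% names(md)))
    stopf("metadata must have columns: %s", paste(need, collapse = ", "))
  if (anyDuplicated(md$sample_id))
    stopf("duplicate sample_id in metadata: %s",
          md$sample_id[duplicated(md$sample_id)][1])
  md[, need]
}

#' @rdname read_metadata
#' @param metadata data.frame to write.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cancer fusion-database table
#'
#' TSV with columns `gene5`, `gene3` and optionally `transcript5`,
#' `transcript3`, `mrna_pos5`, `mrna_pos3` (1-based positions within the
#' parental mRNA). `has_breakpoint` is true iff both transcripts and both
#' mRNA positions are present, mirroring the difference between databases
#' that store mRNA breakpoints and those that list gene pairs only.
#'
#' @param path TSV path.
#' @param source one of `"cosmic"`, `"mitelman"`, `"ticdb"`, `"generic"`.
#' @return data.frame of records with a `has_breakpoint` column.
#' @export
read_fusion_db <- function(path, source = c("generic", "cosmic", "mitelman", "ticdb")) {
  source <- match.arg(source)
  db <- utils::read.delim(path, colClasses = "character",
                          stringsAsFactors = FALSE)
  if (!all(c("gene5", "gene3") %in% names(db)))
    stopf("fusion database must have gene5 and gene3 columns")
  for (col in c("transcript5", "transcript3", "mrna_pos5", "mrna_pos3"))
    if (!col %in% names(db)) db[[col]] <- NA_character_
  blank <- function(x) is.na(x) | trimws(x) == ""
  for (col in c("mrna_pos5", "mrna_pos3")) {
    x <- db[[col]]
    v <- rep(NA_integer_, length(x))
    ok <- !blank(x)
    if (any(ok)) {
      num <- suppressWarnings(as.numeric(x[ok]))
      bad <- is.na(num) | num != floor(num) | num < 1
      if (any(bad))
        stopf("malformed %s at row %d: '%s'", col, which(ok)[which(bad)[1]],
              x[ok][which(bad)[1]])
      v[ok] <- as.integer(num)
    }
    db[[col]] <- v
  }
  db$transcript5[blank(db$transcript5)] <- NA_character_
  db$transcript3[blank(db$transcript3)] <- NA_character_
  db$source <- source
  db$has_breakpoint <- !is.na(db$transcript5) & !is.na(db$transcript3) &
    !is.na(db$mrna_pos5) & !is.na(db$mrna_pos3)
  db[, c("source", "gene5", "gene3", "transcript5", "transcript3",
         "mrna_pos5", "mrna_pos3", "has_breakpoint")]
}

#' @rdname read_fusion_db
#' @param db data.frame of fusion records to write.
#' @export
write_fusion_db <- function(db, path) {
  out <- db[, c("gene5", "gene3", "transcript5", "transcript3",
                "mrna_pos5", "mrna_pos3")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a gene x sample FPKM expression table
#'
#' TSV whose first column (`gene_id`) names genes and remaining columns are
#' samples.
#'
#' @param path TSV path.
#' @return numeric matrix, genes as rownames, samples as colnames.
#' @export
read_expression <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "gene_id")
    stopf("expression table must start with a gene_id column")
  m <- as.matrix(tab[, -1, drop = FALSE])
  if (!is.numeric(m)) stopf("malformed numeric field in expression table")
  rownames(m) <- tab$gene_id
  m
}

#' @rdname read_expression
#' @param expr numeric matrix to write (genes x samples).
#' @export
write_expression <- function(expr, path) {
  tab <- data.frame(gene_id = rownames(expr), expr, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PSM (peptide spectrum match) table
#'
#' TSV with columns `peptide`, `q_value`, `spectrum_id`, `sample_id`.
#'
#' @param path TSV path.
#' @return data.frame of PSM records; q-values validated to lie in \[0, 1\].
#' @export
read_psm_table <- function(path) {
  psm <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = c(q_value = "character"))
  need <- c("peptide", "q_value", "spectrum_id", "sample_id")
  if (!all(need %in% names(psm)))
    stopf("PSM table must have columns: %s", paste(need, collapse = ", "))
  q <- suppressWarnings(as.numeric(psm$q_value))
  bad <- which(is.na(q) | q < 0 | q > 1)
  if (length(bad) > 0)
    stopf("malformed q_value at row %d: '%s'", bad[1], psm$q_value[bad[1]])
  psm$q_value <- q
  psm[, need]
}

#' @rdname read_psm_table
#' @param psms data.frame of PSM records to write.
#' @export
write_psm_table <- function(psms, path) {
  utils::write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic TSV
#'
#' @param x data.frame.
#' @param path output path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
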