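# Matching chimera sets against cancer fusion databases (gene-pair and
# exact-breakpoint resolution) and normal-baseline filtering of cancer call
# sets with eliminated-fraction reporting.

## Normalize gene symbols: uppercase plus optional user alias table
## (named character vector alias -> canonical). No live lookups.
normalize_symbols <- function(x, aliases = NULL) {
  x <- toupper(x)
  if (!is.null(aliases)) {
    names(aliases) <- toupper(names(aliases))
    hit <- x %in% names(aliases)
    x[hit] <- toupper(aliases[x[hit]])
  }
  x
}

#' Match gene pairs against a fusion database
#'
#' Ordered matching by default: a query pair matches a database record iff
#' the 5' genes agree and the 3' genes agree (orientation matters for
#' fusions). Unordered matching — either orientation — is available for
#' databases whose pair conventions vary.
#'
#' @param query data.frame with `gene5`, `gene3` columns (or a character
#'   vector of `"A|B"` pairs).
#' @param db fusion database data.frame (see [read_fusion_db()]).
#' @param ordered logical; orientation-sensitive matching (default `TRUE`).
#' @param aliases optional named character vector of symbol aliases.
#' @return data.frame of matched query pairs with a `mode` column recording
#'   which matching mode fired.
#' @export
match_gene_pairs <- function(query, db, ordered = TRUE, aliases = NULL) {
  if (is.character(query)) {
    parts <- strsplit(query, "|", fixed = TRUE)
    query <- data.frame(gene5 = vapply(parts, `[`, "", 1),
                        gene3 = vapply(parts, `[`, "", 2),
                        stringsAsFactors = FALSE)
  }
  q5 <- normalize_symbols(query$gene5, aliases)
  q3 <- normalize_symbols(query$gene3, aliases)
  d5 <- normalize_symbols(db$gene5, aliases)
  d3 <- normalize_symbols(db$gene3, aliases)
  fwd <- paste(q5, q3) %in% paste(d5, d3)
  if (ordered) {
    hit <- fwd
    mode <- ifelse(fwd, "ordered", NA_character_)
  } else {
    rev <- paste(q3, q5) %in% paste(d5, d3)
    hit <- fwd | rev
    mode <- ifelse(fwd, "ordered", ifelse(rev, "reversed", NA_character_))
  }
  out <- unique(data.frame(gene5 = q5[hit], gene3 = q3[hit],
                           mode = mode[hit], stringsAsFactors = FALSE))
  out <- out[order(out$gene5, out$gene3), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match exact breakpoints against database mRNA coordinates
#'
#' Database records that store breakpoints as positions within the parental
#' mRNA are mapped to genomic coordinates via the annotated transcript
#' ([mrna_to_genomic()]); a query chimera matches iff both mapped genomic
#' positions equal the query's breakpoints exactly (same isoform). Records
#' whose transcript is absent from the annotation are skipped and counted.
#'
#' @param uniques a `unique_chimeras` object.
#' @param db fusion database data.frame with breakpoint records.
#' @param annotation a `chim_annotation` providing the transcripts.
#' @param aliases optional symbol alias table.
#' @return list with `matches` (data.frame of exact matches: query key and
#'   database row), `gene_pair_matches` (keys matching at gene-pair level
#'   among breakpoint records) and `skipped_records`.
#' @export
match_breakpoints <- function(uniques, db, annotation, aliases = NULL) {
  bp <- db[db$has_breakpoint, , drop = FALSE]
  tab <- uniques$table
  t5 <- normalize_symbols(tab$gene5, aliases)
  t3 <- normalize_symbols(tab$gene3, aliases)
  skipped <- 0L
  exact <- list()
  pair_keys <- character(0)
  find_tx <- function(tid) {
    for (g in annotation$genes)
      if (tid %in% names(g$transcripts)) return(g$transcripts[[tid]])
    NULL
  }
  for (i in seq_len(nrow(bp))) {
    g5 <- normalize_symbols(bp$gene5[i], aliases)
    g3 <- normalize_symbols(bp$gene3[i], aliases)
    cand <- which(t5 == g5 & t3 == g3)
    if (length(cand) == 0) next
    pair_keys <- c(pair_keys, tab$key[cand])
    tx5 <- find_tx(bp$transcript5[i])
    tx3 <- find_tx(bp$transcript3[i])
    if (is.null(tx5) || is.null(tx3)) { skipped <- skipped + 1L; next }
    if (bp$mrna_pos5[i] > spliced_length(tx5) ||
        bp$mrna_pos3[i] > spliced_length(tx3)) { skipped <- skipped + 1L; next }
    gpos5 <- mrna_to_genomic(tx5, bp$mrna_pos5[i])
    gpos3 <- mrna_to_genomic(tx3, bp$mrna_pos3[i])
    hit <- cand[tab$pos5[cand] == gpos5 & tab$pos3[cand] == gpos3]
    for (h in hit)
      exact[[length(exact) + 1L]] <- data.frame(
        key = tab$key[h], db_row = i, gene5 = g5, gene3 = g3,
        genomic_pos5 = gpos5, genomic_pos3 = gpos3, stringsAsFactors = FALSE)
  }
  matches <- if (length(exact) == 0) {
    data.frame(key = character(0), db_row = integer(0), gene5 = character(0),
               gene3 = character(0), genomic_pos5 = integer(0),
               genomic_pos3 = integer(0), stringsAsFactors = FALSE)
  } else unique(do.call(rbind, exact))
  list(matches = matches,
       gene_pair_matches = sort(unique(pair_keys)),
       skipped_records = skipped)
}

#' Normal-baseline filter of a cancer call set
#'
#' Eliminates from a cancer set the entries also present in a control set
#' drawn from normal tissue (matched normal or a normal-cohort baseline),
#' both at the same resolution (gene pairs by default). Percentages are
#' reported at one decimal, round-half-even.
#'
#' @param cancer_pairs character vector (or set) of cancer entries.
#' @param control_pairs character vector of control entries.
#' @return list with `retained`, `eliminated` (sorted character vectors) and
#'   `report` (counts plus `eliminated_pct`).
#' @export
normal_filter <- function(cancer_pairs, control_pairs) {
  cancer <- unique(cancer_pairs)
  if (length(cancer) == 0) stopf("empty cancer set")
  control <- unique(control_pairs)
  eliminated <- sort(intersect(cancer, control))
  retained <- sort(setdiff(cancer, control))
  report <- list(
    input = length(cancer),
    retained = length(retained),
    eliminated = length(eliminated),
    eliminated_pct = pct1(length(eliminated), length(cancer))
  )
  stopifnot(report$retained + report$eliminated == report$input)
  list(retained = retained, eliminated = eliminated, report = report)
}

#' Three-way partition of a cancer set against two controls
#'
#' Partitions the cancer entries by membership in a matched-normal control
#' and a normal-cohort baseline: cancer-only, in both controls, in matched
#' normal only, in baseline only. Percentages are relative to the cancer
#' set size (one decimal).
#'
#' @param cancer,matched_normal,baseline character vectors at the same
#'   resolution (gene pairs).
#' @return list of counts and percentages; counts sum to `length(cancer)`.
#' @export
three_way_partition <- function(cancer, matched_normal, baseline) {
  cancer <- unique(cancer)
  mn <- unique(matched_normal)
  bl <- unique(baseline)
  in_mn <- cancer %in% mn
  in_bl <- cancer %in% bl
  counts <- c(
    cancer_only = sum(!in_mn & !in_bl),
    matched_and_baseline = sum(in_mn & in_bl),
    matched_only = sum(in_mn & !in_bl),
    baseline_only = sum(!in_mn & in_bl)
  )
  stopifnot(sum(counts) == length(cancer))
  pcts <- vapply(counts, pct1, numeric(1), den = length(cancer))
  list(counts = counts, percentages = pcts, n_cancer = length(cancer))
}
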