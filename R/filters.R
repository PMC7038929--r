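# The staged false-positive filtering ladder: prediction-score cutoff,
# junction-sequence identity against the reference transcriptome, relative
# expression ratio, deduplication to unique chimeras, M/M removal, and
# global / tissue-aware recurrence.

#' Construct a filter report
#'
#' Bookkeeping record for one ladder stage. `kept + removed == input` is
#' enforced; any one of the three counts may be omitted and is derived from
#' the other two.
#'
#' @param stage stage name.
#' @param input,kept,removed stage counts (two of three suffice).
#' @param reasons optional named integer vector histogram of removal reasons.
#' @return an object of class `filter_report`.
#' @export
filter_report <- function(stage, input = NULL, kept = NULL, removed = NULL,
                          reasons = integer(0)) {
  if (is.null(input)) input <- kept + removed
  if (is.null(kept)) kept <- input - removed
  if (is.null(removed)) removed <- input - kept
  if (kept + removed != input)
    stopf("inconsistent filter report for stage %s: %d kept + %d removed != %d input",
          stage, kept, removed, input)
  if (kept < 0 || removed < 0)
    stopf("negative count in filter report for stage %s", stage)
  structure(list(stage = stage, input = as.numeric(input),
                 kept = as.numeric(kept), removed = as.numeric(removed),
                 reasons = reasons),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("[%s] input %s -> kept %s, removed %s\n", x$stage,
              format(x$input, big.mark = ","), format(x$kept, big.mark = ","),
              format(x$removed, big.mark = ",")))
  if (length(x$reasons) > 0)
    cat("  reasons:", paste(sprintf("%s=%d", names(x$reasons), x$reasons),
                            collapse = ", "), "\n")
  invisible(x)
}

#' Prediction-score filter
#'
#' Discards calls with score below `min_score` (strict: a score exactly at
#' the cutoff is kept) or without predicted breakpoint positions.
#'
#' @param calls data.frame of calls.
#' @param min_score minimum retained prediction score (default 0.6).
#' @return list with `kept`, `removed` (data.frames) and `report`.
#' @export
score_filter <- function(calls, min_score = 0.6) {
  missing_bp <- calls$missing_breakpoint | is.na(calls$score)
  low <- !missing_bp & calls$score < min_score
  drop <- missing_bp | low
  list(
    kept = calls[!drop, , drop = FALSE],
    removed = calls[drop, , drop = FALSE],
    report = filter_report("score", input = nrow(calls),
                           removed = sum(drop),
                           reasons = c(low_score = sum(low),
                                       missing_breakpoint = sum(missing_bp)))
  )
}

## k-mer seed index over a sequence store (named character vector).
## Returns a hashed environment mapping kmer -> integer vector of sequence
## indices containing it.
build_kmer_index <- function(seqs, k = 11L) {
  kl <- vector("list", length(seqs))
  il <- vector("list", length(seqs))
  for (si in seq_along(seqs)) {
    s <- seqs[[si]]
    n <- nchar(s)
    if (n < k) next
    starts <- seq_len(n - k + 1L)
    kmers <- substring(s, starts, starts + k - 1L)
    keep <- !grepl("[^ACGT]", kmers)
    km <- unique(kmers[keep])
    kl[[si]] <- km
    il[[si]] <- rep.int(si, length(km))
  }
  list2env(split(unlist(il), unlist(kl)),
           new.env(parent = emptyenv(), hash = TRUE))
}

.align_cache <- new.env(parent = emptyenv())

## Best local alignment statistics of one or more patterns vs one subject
## under +1/-1 match/mismatch, linear gap -2 (vectorized over patterns).
## Identity is matches over alignment columns; a non-positive score marks
## the absence of any local alignment.
local_align_stats <- function(pattern, subject) {
  if (is.null(.align_cache$submat))
    .align_cache$submat <- Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -1, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    pattern = pattern, subject = subject, type = "local",
    substitutionMatrix = .align_cache$submat, gapOpening = 0, gapExtension = 2
  )
  nm <- Biostrings::nmatch(aln)
  nmm <- Biostrings::nmismatch(aln)
  ind <- Biostrings::nindel(aln)
  cols <- nm + nmm + Biostrings::insertion(ind)[, "WidthSum"] +
    Biostrings::deletion(ind)[, "WidthSum"]
  data.frame(
    score = Biostrings::score(aln),
    identity = nm / pmax(cols, 1L),
    p_start = Biostrings::start(Biostrings::pattern(aln)),
    p_end = Biostrings::end(Biostrings::pattern(aln))
  )
}

## Core removal criterion shared by identity_filter and the synthetic-data
## generator: is each junction sequence explainable by a single reference
## transcript (spanning local alignment at >= min_identity)? Candidate
## (sequence, transcript) pairs come from exact k-mer seeding; alignments
## are batched per transcript.
reference_explainable <- function(seqs, reference, min_identity = 0.90,
                                  min_flank = 10L, k = 11L) {
  idx <- build_kmer_index(reference, k)
  n_seq <- length(seqs)
  eligible <- !is.na(seqs) & nchar(seqs) >= 2L * min_flank
  cand_map <- vector("list", n_seq)
  for (i in which(eligible)) {
    js <- seqs[i]
    starts <- seq_len(max(nchar(js) - k + 1L, 0L))
    kmers <- unique(substring(js, starts, starts + k - 1L))
    cand_map[[i]] <- unique(unlist(lapply(kmers, function(km) idx[[km]])))
  }
  removable <- rep(FALSE, n_seq)
  pairs_seq <- rep(seq_len(n_seq), lengths(cand_map))
  pairs_tx <- unlist(cand_map)
  if (length(pairs_tx) == 0) return(removable)
  for (si in unique(pairs_tx)) {
    qs <- pairs_seq[pairs_tx == si]
    qs <- qs[!removable[qs]]
    if (length(qs) == 0) next
    st <- local_align_stats(seqs[qs], reference[[si]])
    mid <- nchar(seqs[qs]) %/% 2L         # junction between mid and mid+1
    hit <- st$score > 0 &
      (mid - st$p_start + 1L) >= min_flank &
      (st$p_end - mid) >= min_flank &
      st$identity >= min_identity
    removable[qs[hit]] <- TRUE
  }
  removable
}

#' Junction-sequence identity filter
#'
#' Removes calls whose junction sequence is explainable by a single
#' annotated reference transcript: some transcript carries a local alignment
#' to the junction sequence with identity at or above `min_identity` that
#' spans the junction midpoint with at least `min_flank` aligned bases on
#' each side. Candidate transcripts are found by exact k-mer seeding
#' (`k = 11`); alignment uses match +1 / mismatch -1 / gap -2 scoring, with
#' identity computed as matches over alignment columns.
#'
#' @param calls data.frame of calls with `junction_seq` (junction at the
#'   sequence midpoint).
#' @param reference_transcriptome named character vector of transcript
#'   sequences.
#' @param min_identity minimum identity for removal (default 0.90).
#' @param min_flank minimum aligned bases on each side of the midpoint
#'   (default 10).
#' @param k seed length.
#' @return list with `kept`, `removed` and `report`.
#' @export
identity_filter <- function(calls, reference_transcriptome,
                            min_identity = 0.90, min_flank = 10L, k = 11L) {
  if (length(reference_transcriptome) == 0)
    stopf("empty reference transcriptome")
  seqs <- toupper(calls$junction_seq)
  uniq <- unique(seqs)
  removable <- reference_explainable(uniq, reference_transcriptome,
                                     min_identity, min_flank, k)
  drop <- removable[match(seqs, uniq)]
  drop[is.na(drop)] <- FALSE
  list(
    kept = calls[!drop, , drop = FALSE],
    removed = calls[drop, , drop = FALSE],
    report = filter_report("identity", input = nrow(calls),
                           removed = sum(drop),
                           reasons = c(reference_match = sum(drop)))
  )
}

#' Relative-expression ratio filter
#'
#' Computes the ratio of chimera expression to each parental gene's
#' expression and removes calls where the ratio exceeds 1 (strict). A ratio
#' with a zero-expressed parent is infinite when the chimera is expressed
#' and 0 when both are 0.
#'
#' @param calls data.frame of calls with expression columns.
#' @param mode which parent must exceed the bound to remove the call:
#'   `"either"` (default), `"both"`, `"five_prime"` or `"three_prime"`.
#' @return list with `kept`, `removed` and `report`.
#' @export
ratio_filter <- function(calls, mode = c("either", "both", "five_prime", "three_prime")) {
  mode <- match.arg(mode)
  if (any(calls$chimera_expr < 0 | calls$gene5_expr < 0 | calls$gene3_expr < 0,
          na.rm = TRUE))
    stopf("negative expression value")
  ratio <- function(chim, parent) {
    ifelse(parent > 0, chim / parent, ifelse(chim > 0, Inf, 0))
  }
  r5 <- ratio(calls$chimera_expr, calls$gene5_expr)
  r3 <- ratio(calls$chimera_expr, calls$gene3_expr)
  drop <- switch(mode,
    either = r5 > 1 | r3 > 1,
    both = r5 > 1 & r3 > 1,
    five_prime = r5 > 1,
    three_prime = r3 > 1
  )
  drop[is.na(drop)] <- FALSE
  list(
    kept = calls[!drop, , drop = FALSE],
    removed = calls[drop, , drop = FALSE],
    report = filter_report("ratio", input = nrow(calls), removed = sum(drop),
                           reasons = c(ratio_exceeds_1 = sum(drop)))
  )
}

#' Deduplicate calls into unique chimeras
#'
#' Groups calls by the full chimera key (gene pair, chromosomes, exact
#' breakpoints and strands). Frequency counts distinct supporting samples
#' (not reads, not donors). Classification labels, being key-determined,
#' must agree within a group. Tissue membership is accumulated when the
#' calls carry a `tissue` column.
#'
#' @param calls data.frame of (typically classified) calls.
#' @return an object of class `unique_chimeras`: list with `table` (one row
#'   per unique chimera: key, key fields, labels, `frequency`), `samples`
#'   (key x sample map) and `tissue_counts` (distinct-sample counts per key
#'   and tissue).
#' @export
dedupe <- function(calls) {
  key <- chimera_key(calls$gene5, calls$gene3, calls$chrom5, calls$pos5,
                     calls$strand5, calls$chrom3, calls$pos3, calls$strand3)
  label_cols <- intersect(
    c("junction_class", "pair_class", "frame_class", "donor_motif",
      "acceptor_motif", "isoform", "classification_error"),
    names(calls)
  )
  for (col in label_cols) {
    nlab <- tapply(calls[[col]], key, function(v) length(unique(v)))
    if (any(nlab > 1))
      stopf("conflicting %s labels within chimera key %s", col,
            names(nlab)[nlab > 1][1])
  }
  pairs <- unique(data.frame(key = key, sample_id = calls$sample_id,
                             stringsAsFactors = FALSE))
  freq <- table(pairs$key)

  first <- !duplicated(key)
  tab <- calls[first, c("gene5", "gene3", "chrom5", "pos5", "strand5",
                        "chrom3", "pos3", "strand3", label_cols),
               drop = FALSE]
  tab$key <- key[first]
  tab$frequency <- as.integer(freq[tab$key])
  tab <- tab[order(tab$key), , drop = FALSE]
  rownames(tab) <- NULL

  tissue_counts <- NULL
  if ("tissue" %in% names(calls)) {
    tp <- unique(data.frame(key = key, tissue = calls$tissue,
                            sample_id = calls$sample_id,
                            stringsAsFactors = FALSE))
    agg <- stats::aggregate(sample_id ~ key + tissue, data = tp,
                            FUN = function(v) length(unique(v)))
    names(agg)[3] <- "n_samples"
    tissue_counts <- agg[order(agg$key, agg$tissue), , drop = FALSE]
    rownames(tissue_counts) <- NULL
  }
  structure(list(table = tab, samples = pairs[order(pairs$key, pairs$sample_id), ],
                 tissue_counts = tissue_counts),
            class = "unique_chimeras")
}

#' @export
print.unique_chimeras <- function(x, ...) {
  cat(sprintf("unique_chimeras: %d chimera(s), %d (key, sample) pair(s)\n",
              nrow(x$table), nrow(x$samples)))
  invisible(x)
}

## Subset a unique_chimeras object to a set of keys, keeping all components
## in sync.
subset_uniques <- function(uniques, keys) {
  out <- uniques
  out$table <- uniques$table[uniques$table$key %in% keys, , drop = FALSE]
  out$samples <- uniques$samples[uniques$samples$key %in% keys, , drop = FALSE]
  if (!is.null(uniques$tissue_counts))
    out$tissue_counts <-
      uniques$tissue_counts[uniques$tissue_counts$key %in% keys, , drop = FALSE]
  rownames(out$table) <- rownames(out$samples) <- NULL
  out
}

#' Remove M/M chimeras
#'
#' Drops unique chimeras whose junction class is `MM` (both breakpoints
#' mid-exon), the class with the lowest experimental validation rate.
#'
#' @param uniques a `unique_chimeras` object with junction classes.
#' @return list with `kept`, `removed` (both `unique_chimeras`) and `report`.
#' @export
remove_mm <- function(uniques) {
  is_mm <- uniques$table$junction_class == "MM" |
    is.na(uniques$table$junction_class)
  kept_keys <- uniques$table$key[!is_mm]
  removed_keys <- uniques$table$key[is_mm]
  list(
    kept = subset_uniques(uniques, kept_keys),
    removed = subset_uniques(uniques, removed_keys),
    report = filter_report("non_mm", input = nrow(uniques$table),
                           removed = length(removed_keys),
                           reasons = c(mm_junction = length(removed_keys)))
  )
}

#' Global recurrence filter
#'
#' Keeps unique chimeras detected in at least `min_frequency` distinct
#' samples across the whole cohort.
#'
#' @param uniques a `unique_chimeras` object.
#' @param min_frequency minimum distinct-sample count (default 5, i.e.
#'   frequency > 4).
#' @return list with `kept`, `removed` and `report`.
#' @export
global_recurrence <- function(uniques, min_frequency = 5L) {
  keep <- uniques$table$frequency >= min_frequency
  list(
    kept = subset_uniques(uniques, uniques$table$key[keep]),
    removed = subset_uniques(uniques, uniques$table$key[!keep]),
    report = filter_report("recurrent", input = nrow(uniques$table),
                           removed = sum(!keep),
                           reasons = c(low_frequency = sum(!keep)))
  )
}

#' Per-tissue recurrence threshold
#'
#' At least 2 supporting samples in tissues of 100 or fewer samples, at
#' least 3 in tissues of 300 or fewer, at least 5 in larger tissues.
#'
#' @param n_samples tissue sample count(s).
#' @return integer threshold(s).
#' @export
tissue_threshold <- function(n_samples) {
  ifelse(n_samples <= 100L, 2L, ifelse(n_samples <= 300L, 3L, 5L))
}

#' Tissue-aware recurrence
#'
#' A chimera is recurrent in a tissue iff its distinct-sample count within
#' that tissue reaches the tissue's threshold (see [tissue_threshold()]),
#' which depends on how many samples the tissue contributes to the cohort.
#'
#' @param uniques a `unique_chimeras` object carrying tissue counts.
#' @param metadata sample metadata data.frame (see [read_metadata()]).
#' @return data.frame with columns `tissue`, `key` listing, per tissue, the
#'   chimeras recurrent in it.
#' @export
tissue_recurrent <- function(uniques, metadata) {
  if (is.null(uniques$tissue_counts))
    stopf("unique chimeras carry no tissue information")
  sizes <- table(metadata$tissue)
  tc <- uniques$tissue_counts
  unknown <- setdiff(unique(tc$tissue), names(sizes))
  if (length(unknown) > 0)
    stopf("tissue absent from metadata: %s", unknown[1])
  thr <- tissue_threshold(as.integer(sizes[tc$tissue]))
  rec <- tc[tc$n_samples >= thr, c("tissue", "key"), drop = FALSE]
  rec <- rec[order(rec$tissue, rec$key), , drop = FALSE]
  rownames(rec) <- NULL
  rec
}
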