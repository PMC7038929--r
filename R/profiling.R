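# Binary presence/absence profiling: samples x chimera and samples x gene
# matrices, simple-matching-coefficient similarity to parental-gene
# profiles, cohort-common and tissue-specific chimera sets, and
# embedding-ready matrix export.

#' Samples x chimera presence matrix
#'
#' Binary matrix with one row per sample and one column per unique chimera;
#' a cell is 1 iff the chimera was called in the sample. Rows and columns
#' are sorted lexicographically so the matrix is reproducible byte-for-byte.
#'
#' @param uniques a `unique_chimeras` object (the features).
#' @param samples character vector of sample ids (the rows).
#' @return integer 0/1 matrix with dimnames.
#' @export
chimera_matrix <- function(uniques, samples) {
  feats <- sort(uniques$table$key)
  samples <- sort(unique(samples))
  m <- matrix(0L, nrow = length(samples), ncol = length(feats),
              dimnames = list(samples, feats))
  sm <- uniques$samples[uniques$samples$sample_id %in% samples, , drop = FALSE]
  if (nrow(sm) > 0)
    m[cbind(match(sm$sample_id, samples), match(sm$key, feats))] <- 1L
  m
}

#' Samples x gene presence matrix from FPKM
#'
#' Binarizes a gene expression matrix at `cutoff` (1 iff FPKM >= cutoff).
#' The default cutoff, 0.04, is the convention of treating a parental gene
#' as expressed whenever it reaches the lowest expression seen among the
#' chimeras themselves.
#'
#' @param expression gene x sample numeric matrix (see [read_expression()]).
#' @param genes genes to include (error if any is absent).
#' @param cutoff FPKM threshold (default 0.04; `>=` is expressed).
#' @return integer 0/1 matrix, samples x genes, sorted dimnames.
#' @export
gene_matrix <- function(expression, genes, cutoff = 0.04) {
  genes <- unique(genes)
  absent <- setdiff(genes, rownames(expression))
  if (length(absent) > 0)
    stopf("gene(s) absent from expression table: %s",
          paste(absent, collapse = ", "))
  sub <- expression[genes, , drop = FALSE]
  m <- t((sub >= cutoff) * 1L)
  m <- m[order(rownames(m)), order(colnames(m)), drop = FALSE]
  storage.mode(m) <- "integer"
  m
}

#' Simple matching coefficient
#'
#' Fraction of positions at which two equal-length binary vectors agree:
#' 1 means identical, 0 means complementary. Equals 1 minus the normalized
#' Hamming distance.
#'
#' @param a,b binary vectors of equal positive length.
#' @return similarity in \[0, 1\].
#' @export
smc <- function(a, b) {
  if (length(a) != length(b)) stopf("smc: length mismatch (%d vs %d)",
                                    length(a), length(b))
  if (length(a) == 0) stopf("smc: empty vectors")
  sum(a == b) / length(a)
}

#' Per-chimera SMC against parental profiles
#'
#' For each chimera column, computes the SMC between its presence profile
#' and the binary expression profile of its 5' and of its 3' parental gene,
#' plus a binned histogram of all scores. Chimeras whose parent gene is
#' absent from the gene matrices are skipped with a warning.
#'
#' @param chim_mat samples x chimera presence matrix ([chimera_matrix()]).
#' @param gene5_mat,gene3_mat samples x gene presence matrices for 5' and 3'
#'   parents ([gene_matrix()]); rows must match `chim_mat`.
#' @param uniques the `unique_chimeras` object giving each chimera's parents.
#' @param breaks histogram bin edges over \[0, 1\] (defaults mirror the
#'   dissimilar / intermediate / high-similarity bands 0-0.25, 0.25-0.6,
#'   0.6-1).
#' @return list with `scores` (data.frame key, smc5, smc3) and `histogram`
#'   (bin x side counts).
#' @export
smc_summary <- function(chim_mat, gene5_mat, gene3_mat, uniques,
                        breaks = c(0, 0.25, 0.6, 1)) {
  if (!identical(rownames(chim_mat), rownames(gene5_mat)) ||
      !identical(rownames(chim_mat), rownames(gene3_mat)))
    stopf("matrices must share identical sample rows")
  tab <- uniques$table[match(colnames(chim_mat), uniques$table$key), ]
  smc5 <- smc3 <- rep(NA_real_, ncol(chim_mat))
  skipped <- 0L
  for (j in seq_len(ncol(chim_mat))) {
    g5 <- tab$gene5[j]; g3 <- tab$gene3[j]
    if (!(g5 %in% colnames(gene5_mat)) || !(g3 %in% colnames(gene3_mat))) {
      skipped <- skipped + 1L
      next
    }
    smc5[j] <- smc(chim_mat[, j], gene5_mat[, g5])
    smc3[j] <- smc(chim_mat[, j], gene3_mat[, g3])
  }
  if (skipped > 0)
    warnf("smc_summary: %d chimera(s) skipped (parent gene not in matrix)", skipped)
  scores <- data.frame(key = colnames(chim_mat), smc5 = smc5, smc3 = smc3,
                       stringsAsFactors = FALSE)
  ## right-open bins, except the last which is closed so SMC == 1 is counted
  bin <- function(v) {
    v <- v[!is.na(v)]
    table(cut(v, breaks = breaks, include.lowest = TRUE, right = FALSE))
  }
  hist5 <- bin(smc5); hist3 <- bin(smc3)
  list(scores = scores,
       histogram = rbind(smc5 = as.integer(hist5), smc3 = as.integer(hist3)) |>
         `colnames<-`(names(hist5)))
}

#' Chimeras common to all tissues
#'
#' @param uniques a `unique_chimeras` object with tissue counts.
#' @param metadata sample metadata.
#' @return character vector of chimera keys detected in every tissue listed
#'   in the metadata.
#' @export
common_chimeras <- function(uniques, metadata) {
  if (is.null(uniques$tissue_counts)) return(character(0))
  all_tissues <- sort(unique(metadata$tissue))
  per_key <- tapply(uniques$tissue_counts$tissue, uniques$tissue_counts$key,
                    function(t) length(unique(t)))
  sort(names(per_key)[per_key == length(all_tissues)])
}

#' Tissue-specific recurrent chimeras
#'
#' A chimera is specific to tissue T iff it is recurrent in T (per-tissue
#' thresholds, [tissue_recurrent()]) and detected in zero samples of any
#' other tissue (strict definition). The relaxed alternative — recurrent in
#' exactly one tissue regardless of stray single-sample detections — is
#' available via `strict = FALSE`.
#'
#' @param uniques a `unique_chimeras` object with tissue counts.
#' @param metadata sample metadata.
#' @param strict logical; see above.
#' @return data.frame with columns `tissue`, `key`.
#' @export
tissue_specific <- function(uniques, metadata, strict = TRUE) {
  rec <- tissue_recurrent(uniques, metadata)
  tc <- uniques$tissue_counts
  n_tissues <- tapply(tc$tissue, tc$key, function(t) length(unique(t)))
  if (strict) {
    only_one <- names(n_tissues)[n_tissues == 1L]
    out <- rec[rec$key %in% only_one, , drop = FALSE]
  } else {
    rec_n <- table(rec$key)
    out <- rec[rec$key %in% names(rec_n)[rec_n == 1L], , drop = FALSE]
  }
  out <- out[order(out$tissue, out$key), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export a presence matrix for embedding tools
#'
#' Writes the matrix as TSV with an `id` column and lexicographically
#' ordered feature columns; re-export is byte-identical. The export summary
#' notes duplicate-row counts (identical binary profiles), which matter to
#' neighbour-embedding tools, without drawing further conclusions.
#'
#' @param matrix binary matrix with dimnames.
#' @param path output TSV path.
#' @return invisibly, a list with `path` and `duplicate_rows`.
#' @export
export_embedding_matrix <- function(matrix, path) {
  m <- matrix[order(rownames(matrix)), order(colnames(matrix)), drop = FALSE]
  tab <- data.frame(id = rownames(m), m, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(path = path, duplicate_rows = sum(duplicated(m))))
}
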