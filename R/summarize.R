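# Descriptive statistics over the filtered call sets: class distributions
# across ladder stages, splice-motif percentages per junction class,
# frequency histogram, relative-expression CDF, 3'UTR length comparison,
# chromosome-distribution correlation and junction flank-window export.

#' Class distributions across filtering stages
#'
#' Normalized proportions of junction, pair and frame classes for each
#' stage of the ladder (all unique chimeras, after M/M removal, after the
#' recurrence filter).
#'
#' @param all,non_mm,recurrent `unique_chimeras` objects for the three
#'   stages.
#' @return list of per-stage lists with `junction_class`, `pair_class`,
#'   `frame_class` proportion vectors (each summing to 1).
#' @export
stage_distributions <- function(all, non_mm, recurrent) {
  stages <- list(all = all, non_mm = non_mm, non_mm_recurrent = recurrent)
  lapply(stages, function(u) {
    tab <- u$table
    if (nrow(tab) == 0) stopf("empty stage in stage_distributions")
    prop <- function(col) {
      v <- tab[[col]]
      v <- v[!is.na(v)]
      p <- table(v) / length(v)
      stats::setNames(as.numeric(p), names(p))
    }
    list(junction_class = prop("junction_class"),
         pair_class = prop("pair_class"),
         frame_class = prop("frame_class"),
         n = nrow(tab))
  })
}

#' Splice-motif percentages per junction class
#'
#' Percentage of chimeras carrying the canonical donor (AG/GT) and acceptor
#' (AG/G) contexts, per junction class. Chimeras with undefined motif flags
#' (contig-edge breakpoints) are excluded from denominators; classes with
#' no members are reported as absent rather than 0%.
#'
#' @param uniques a `unique_chimeras` object with motif flags.
#' @return data.frame with `junction_class`, `donor_pct`, `acceptor_pct`,
#'   `n_donor`, `n_acceptor`.
#' @export
splice_motif_summary <- function(uniques) {
  tab <- uniques$table
  classes <- sort(unique(tab$junction_class[!is.na(tab$junction_class)]))
  rows <- lapply(classes, function(cl) {
    sub <- tab[tab$junction_class == cl & !is.na(tab$junction_class), ]
    don <- sub$donor_motif[!is.na(sub$donor_motif)]
    acc <- sub$acceptor_motif[!is.na(sub$acceptor_motif)]
    data.frame(junction_class = cl,
               donor_pct = pct1(sum(don), length(don)),
               acceptor_pct = pct1(sum(acc), length(acc)),
               n_donor = length(don), n_acceptor = length(acc),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Frequency histogram of unique chimeras
#'
#' @param uniques a `unique_chimeras` object.
#' @return named integer vector: count of chimeras per frequency value.
#' @export
frequency_histogram <- function(uniques) {
  if (nrow(uniques$table) == 0) return(stats::setNames(integer(0), character(0)))
  h <- table(uniques$table$frequency)
  stats::setNames(as.integer(h), names(h))
}

#' Relative-expression cumulative distribution
#'
#' Per unique chimera, the ratio of chimeric to parental expression is
#' aggregated across supporting calls (`max` by default) for the 5' and 3'
#' parent separately, and the empirical CDF is evaluated on a fixed grid
#' over \[0, 1\].
#'
#' @param calls data.frame of calls with expression columns.
#' @param grid evaluation grid (default 0 to 1 by 0.05).
#' @param aggregate `"max"` (default), `"mean"` or `"median"` across the
#'   calls supporting one unique chimera.
#' @return list with `ratios` (data.frame key, ratio5, ratio3) and `cdf`
#'   (data.frame grid, cdf5, cdf3), where `cdf*(x)` is the fraction of
#'   chimeras with ratio <= x.
#' @export
relative_expression_cdf <- function(calls, grid = seq(0, 1, by = 0.05),
                                    aggregate = c("max", "mean", "median")) {
  aggregate <- match.arg(aggregate)
  fun <- switch(aggregate, max = max, mean = mean, median = stats::median)
  ratio <- function(chim, parent)
    ifelse(parent > 0, chim / parent, ifelse(chim > 0, Inf, 0))
  key <- chimera_key(calls$gene5, calls$gene3, calls$chrom5, calls$pos5,
                     calls$strand5, calls$chrom3, calls$pos3, calls$strand3)
  r5 <- tapply(ratio(calls$chimera_expr, calls$gene5_expr), key, fun)
  r3 <- tapply(ratio(calls$chimera_expr, calls$gene3_expr), key, fun)
  ratios <- data.frame(key = names(r5), ratio5 = as.numeric(r5),
                       ratio3 = as.numeric(r3[names(r5)]),
                       stringsAsFactors = FALSE)
  cdf <- data.frame(
    grid = grid,
    cdf5 = vapply(grid, function(x) mean(ratios$ratio5 <= x), numeric(1)),
    cdf3 = vapply(grid, function(x) mean(ratios$ratio3 <= x), numeric(1))
  )
  list(ratios = ratios, cdf = cdf)
}

#' Two-sample rank-sum test
#'
#' Wilcoxon rank-sum (Mann-Whitney U) through the standard implementation:
#' normal approximation with continuity and tie corrections, switching to
#' the exact distribution for small untied samples (combined n below 20).
#'
#' @param x,y numeric samples.
#' @return list with `statistic` (U for the first sample) and `p_value`
#'   (two-sided).
#' @export
rank_sum_test <- function(x, y) {
  if (length(x) < 2 || length(y) < 2)
    stopf("rank-sum test needs at least 2 values per group")
  use_exact <- (length(x) + length(y)) < 20 &&
    !any(duplicated(c(x, y)))
  wt <- stats::wilcox.test(x, y, exact = use_exact, correct = TRUE)
  list(statistic = unname(wt$statistic), p_value = wt$p.value)
}

#' 3'UTR length comparison of parental genes
#'
#' Gene-level 3'UTR lengths (maximum over coding transcripts) for the 5'
#' parental genes, the 3' parental genes and all annotated genes, with
#' two-sided rank-sum tests for parental-vs-all and 5'-vs-3' parental.
#' Noncoding genes are excluded.
#'
#' @param parental5_genes,parental3_genes character vectors of gene symbols
#'   or ids.
#' @param annotation a `chim_annotation`.
#' @return list with the three length vectors and `p_parental_vs_all`,
#'   `p_5p_vs_3p`.
#' @export
utr3_comparison <- function(parental5_genes, parental3_genes, annotation) {
  lengths_of <- function(names) {
    v <- vapply(unique(names), function(nm) {
      g <- get_gene(annotation, nm)
      if (is.null(g)) return(NA_integer_)
      gene_utr3_length(g)
    }, integer(1))
    as.numeric(v[!is.na(v)])
  }
  l5 <- lengths_of(parental5_genes)
  l3 <- lengths_of(parental3_genes)
  lall <- lengths_of(vapply(annotation$genes, `[[`, character(1), "symbol"))
  if (length(l5) < 2 || length(l3) < 2 || length(lall) < 2)
    stopf("fewer than 2 UTR lengths in a comparison group")
  parental <- c(l5, l3)
  list(
    utr3_5p = l5, utr3_3p = l3, utr3_all = lall,
    p_parental_vs_all = rank_sum_test(parental, lall)$p_value,
    p_5p_vs_3p = rank_sum_test(l5, l3)$p_value
  )
}

#' Chromosome distribution of chimera-forming genes
#'
#' Per chromosome, counts annotated genes and distinct chimera-forming
#' parental genes, and reports the Pearson correlation between the two.
#' A degenerate input (constant gene counts) yields `NA` with a flag.
#'
#' @param uniques a `unique_chimeras` object.
#' @param annotation a `chim_annotation`.
#' @return list with `counts` (data.frame chrom, n_genes, n_parent_genes)
#'   and `correlation` (Pearson r, or `NA` if degenerate).
#' @export
chromosome_correlation <- function(uniques, annotation) {
  gene_chrom <- vapply(annotation$genes, `[[`, character(1), "chrom")
  gene_symbol <- vapply(annotation$genes, `[[`, character(1), "symbol")
  chroms <- sort(unique(gene_chrom))
  if (length(chroms) < 3) stopf("need at least 3 chromosomes")
  parents <- unique(c(uniques$table$gene5, uniques$table$gene3))
  parent_chrom <- gene_chrom[match(parents, gene_symbol)]
  counts <- data.frame(
    chrom = chroms,
    n_genes = as.integer(table(factor(gene_chrom, levels = chroms))),
    n_parent_genes = as.integer(table(factor(parent_chrom, levels = chroms))),
    stringsAsFactors = FALSE
  )
  degenerate <- stats::sd(counts$n_genes) == 0 || stats::sd(counts$n_parent_genes) == 0
  r <- if (degenerate) NA_real_ else stats::cor(counts$n_genes, counts$n_parent_genes)
  list(counts = counts, correlation = r, degenerate = degenerate)
}

#' Junction flank windows for motif discovery
#'
#' Extracts, per unique chimera, the `width`-bp windows upstream and
#' downstream of each breakpoint on the parental gene's strand (four
#' windows per chimera), truncated at contig edges. Intended as input to
#' external motif-discovery tools.
#'
#' @param uniques a `unique_chimeras` object.
#' @param genome named character vector of chromosome sequences.
#' @param width window width in bp (default 200).
#' @param dir optional output directory; when given, four FASTA files
#'   (`flank_5p_upstream.fa`, `flank_5p_downstream.fa`,
#'   `flank_3p_upstream.fa`, `flank_3p_downstream.fa`) are written.
#' @return named list of four sequence stores (ids `<key>|<role>`).
#' @export
flank_windows <- function(uniques, genome, width = 200L, dir = NULL) {
  tab <- uniques$table
  slice <- function(chrom, pos, strand, upstream) {
    chr <- genome[[chrom]]
    if (is.null(chr)) stopf("chromosome %s absent from genome", chrom)
    n <- nchar(chr)
    left_window <- (strand == "+") == upstream
    s <- if (left_window) substr(chr, max(1L, pos - width + 1L), pos)
         else substr(chr, pos, min(n, pos + width - 1L))
    if (strand == "-") revcomp(s) else s
  }
  roles <- list(
    flank_5p_upstream = function(r) slice(r$chrom5, r$pos5, r$strand5, TRUE),
    flank_5p_downstream = function(r) slice(r$chrom5, r$pos5, r$strand5, FALSE),
    flank_3p_upstream = function(r) slice(r$chrom3, r$pos3, r$strand3, TRUE),
    flank_3p_downstream = function(r) slice(r$chrom3, r$pos3, r$strand3, FALSE)
  )
  out <- lapply(names(roles), function(role) {
    seqs <- vapply(seq_len(nrow(tab)), function(i) roles[[role]](tab[i, ]),
                   character(1))
    stats::setNames(seqs, paste0(tab$key, "|", role))
  })
  names(out) <- names(roles)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    for (role in names(out))
      write_fasta(out[[role]], file.path(dir, paste0(role, ".fa")))
  }
  out
}
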