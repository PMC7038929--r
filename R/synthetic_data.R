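# Self-contained synthetic universe with planted ground truth: a random
# genome with multi-exon genes (UTRs and CDS), adjacent same-strand gene
# pairs reserved for read-throughs, and a fusion call table whose junction
# classes, pair classes, frame classes, splice-motif flags, reference-copy
# decoys, expression ratios and per-tissue recurrence structure are all
# constructed to be unambiguous, so every pipeline stage can be checked
# against a truth table.

#' Simulation configuration
#'
#' Defaults define the reference study conditions: four tissues with sample
#' counts (50, 150, 350, 20) exercising every per-tissue recurrence
#' threshold branch; per-class splice-motif rates of the magnitude seen in
#' large normal-tissue cohorts (donor/acceptor: EE 0.42/0.425, EM
#' 0.155/0.10, ME 0.06/0.348, MM 0.017/0.094); 10% of planted chimeras
#' drawn below the 0.6 score cutoff, 10% with missing breakpoints and 10%
#' violating the expression-ratio bound.
#'
#' @param seed integer seed fixing every downstream draw.
#' @param n_chromosomes,genes_per_chromosome universe layout.
#' @param exons_per_gene integer range (min, max); at least 5.
#' @param samples_per_tissue named integer vector of tissue sizes.
#' @param n_true_chimeras planted genuine chimeras.
#' @param n_decoys reference-copy false positives.
#' @param junction_mix,pair_mix,frame_mix target class proportions.
#' @param motif_rates 4x2 matrix (rows EE, EM, ME, MM; columns donor,
#'   acceptor) of motif-planting probabilities.
#' @param frac_low_score,frac_missing_breakpoint,frac_ratio_violation
#'   planted early-stage removal fractions.
#' @param parent_profile parental-gene FPKM profile relative to chimera
#'   presence: `"random"`, `"matched"` or `"anti"`.
#' @return a `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 4L,
                       genes_per_chromosome = 30L,
                       exons_per_gene = c(5L, 7L),
                       samples_per_tissue = c(adipose = 50L, lung = 150L,
                                              muscle = 350L, bladder = 20L),
                       n_true_chimeras = 300L,
                       n_decoys = 40L,
                       junction_mix = c(EE = 0.10, EM = 0.16, ME = 0.16, MM = 0.58),
                       pair_mix = c(read_through = 0.08, intra_other = 0.17,
                                    inter_chromosomal = 0.75),
                       frame_mix = c(in_frame = 0.25, frame_shift = 0.35, na = 0.40),
                       motif_rates = rbind(EE = c(0.42, 0.425),
                                           EM = c(0.155, 0.10),
                                           ME = c(0.06, 0.348),
                                           MM = c(0.017, 0.094)),
                       frac_low_score = 0.10,
                       frac_missing_breakpoint = 0.10,
                       frac_ratio_violation = 0.10,
                       parent_profile = c("random", "matched", "anti")) {
  stopifnot(abs(sum(junction_mix) - 1) < 1e-9, abs(sum(pair_mix) - 1) < 1e-9,
            abs(sum(frame_mix) - 1) < 1e-9, exons_per_gene[1] >= 5,
            n_chromosomes >= 2, genes_per_chromosome >= 10,
            all(samples_per_tissue >= 1))
  colnames(motif_rates) <- c("donor", "acceptor")
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    exons_per_gene = as.integer(exons_per_gene),
    samples_per_tissue = samples_per_tissue,
    n_true_chimeras = as.integer(n_true_chimeras),
    n_decoys = as.integer(n_decoys),
    junction_mix = junction_mix, pair_mix = pair_mix, frame_mix = frame_mix,
    motif_rates = motif_rates,
    frac_low_score = frac_low_score,
    frac_missing_breakpoint = frac_missing_breakpoint,
    frac_ratio_violation = frac_ratio_violation,
    parent_profile = match.arg(parent_profile)
  ), class = "sim_config")
}

#' Preset configurations
#'
#' `"paper-shaped"` is the full reference preset ([sim_config()] defaults);
#' `"small"` keeps the same tissue structure but plants fewer chimeras for
#' fast tests.
#'
#' @param preset `"small"` or `"paper-shaped"`.
#' @param seed integer seed.
#' @return a `sim_config`.
#' @export
sim_preset <- function(preset = c("small", "paper-shaped"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "paper-shaped") sim_config(seed = seed)
  else sim_config(seed = seed, n_true_chimeras = 60L, n_decoys = 10L,
                  genes_per_chromosome = 15L)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

## Map a transcript-order mRNA position to a genomic coordinate for a
## generator gene record (exons_tx: data.frame in transcript order).
.gene_m2g <- function(gene, m) {
  off <- m
  for (i in seq_len(nrow(gene$exons_tx))) {
    len <- gene$exons_tx$end[i] - gene$exons_tx$start[i] + 1L
    if (off <= len)
      return(if (gene$strand == "+") gene$exons_tx$start[i] + off - 1L
             else gene$exons_tx$end[i] - off + 1L)
    off <- off - len
  }
  stopf("mRNA position %d beyond gene %s", m, gene$gene_id)
}

## Map an mRNA interval [lo, hi] to genomic intervals (one per overlapped
## exon), ascending genomic order.
.gene_mrange2g <- function(gene, lo, hi) {
  out <- list()
  walked <- 0L
  for (i in seq_len(nrow(gene$exons_tx))) {
    s <- gene$exons_tx$start[i]; e <- gene$exons_tx$end[i]
    len <- e - s + 1L
    a <- walked + 1L; b <- walked + len
    ov_lo <- max(a, lo); ov_hi <- min(b, hi)
    if (ov_lo <= ov_hi) {
      if (gene$strand == "+")
        out[[length(out) + 1L]] <- c(s + (ov_lo - a), s + (ov_hi - a))
      else
        out[[length(out) + 1L]] <- c(e - (ov_hi - a), e - (ov_lo - a))
    }
    walked <- walked + len
  }
  df <- do.call(rbind, out)
  df <- data.frame(start = df[, 1], end = df[, 2])
  df[order(df$start), , drop = FALSE]
}

#' Build the synthetic universe
#'
#' Lays out `n_chromosomes` random-sequence chromosomes carrying multi-exon
#' genes with 5'UTR, CDS and 3'UTR structure (CDS from inside the second
#' exon to inside the second-to-last exon, length divisible by 3). On each
#' chromosome the first ten genes form five adjacent same-strand pairs with
#' short intergenic gaps, reserved as read-through candidates; all other
#' neighbours are separated so that proximity never classifies them as
#' read-throughs by accident. Deterministic under `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return list with `genome` (named character), `genes` (generator gene
#'   records), `features` (GTF-style feature table), `annotation`
#'   (`chim_annotation`), `transcriptome`, `proteome` (named character),
#'   and `readthrough_pairs` (data.frame of reserved 5'/3' gene ids).
#' @export
make_universe <- function(cfg) {
  set.seed(cfg$seed)
  genes <- list()
  genome <- character(0)
  rt_pairs <- list()
  for (ci in seq_len(cfg$n_chromosomes)) {
    chrom <- paste0("chr", ci)
    cursor <- 1001L
    chrom_genes <- list()
    for (gi in seq_len(cfg$genes_per_chromosome)) {
      n_ex <- sample(seq(cfg$exons_per_gene[1], cfg$exons_per_gene[2]), 1L)
      L <- sample(120:240, n_ex, replace = TRUE)
      introns <- sample(300:800, n_ex - 1L, replace = TRUE)
      reserved <- gi <= 10L
      strand <- if (reserved) "+" else sample(c("+", "-"), 1L)
      ## reserved neighbours sit close (read-through range); all others far
      gap_before <- if (reserved && gi %% 2L == 0L) sample(3000:8000, 1L)
                    else 110000L + sample(0:20000, 1L)
      if (gi > 1L) cursor <- cursor + gap_before
      starts <- integer(n_ex)
      pos <- cursor
      for (k in seq_len(n_ex)) {
        starts[k] <- pos
        pos <- pos + L[k] + (if (k < n_ex) introns[k] else 0L)
      }
      exons_g <- data.frame(start = starts, end = starts + L - 1L)
      gene_id <- sprintf("G%d_%02d", ci, gi)
      tx_idx <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      exons_tx <- exons_g[tx_idx, , drop = FALSE]
      rownames(exons_tx) <- NULL
      Lt <- exons_tx$end - exons_tx$start + 1L
      cum <- cumsum(Lt)
      c0 <- Lt[1] + 61L                           # CDS start (mRNA coords)
      ce0 <- cum[n_ex - 2L] + 60L                 # into second-to-last exon
      ce <- ce0 + ((c0 + 2L - ce0) %% 3L)         # CDS length divisible by 3
      gene <- list(
        gene_id = gene_id, chrom = chrom, strand = strand,
        exons_g = exons_g, exons_tx = exons_tx, L = Lt, cum = cum,
        n_ex = n_ex, c0 = c0, ce = ce,
        span = c(exons_g$start[1], exons_g$end[n_ex]),
        reserved = reserved
      )
      chrom_genes[[gi]] <- gene
      cursor <- exons_g$end[n_ex]
      if (reserved && gi %% 2L == 0L)
        rt_pairs[[length(rt_pairs) + 1L]] <-
          data.frame(gene5 = chrom_genes[[gi - 1L]]$gene_id, gene3 = gene_id,
                     stringsAsFactors = FALSE)
    }
    genome[chrom] <- random_dna(cursor + 1000L)
    genes <- c(genes, chrom_genes)
  }
  names(genes) <- vapply(genes, `[[`, character(1), "gene_id")
  universe <- list(genome = genome, genes = genes,
                   readthrough_pairs = do.call(rbind, rt_pairs))
  universe <- refresh_universe(universe)
  universe
}

## Rebuild features/annotation/transcriptome/proteome from the (possibly
## edited) genome. Called by make_universe and again after motif planting.
refresh_universe <- function(universe) {
  feat <- list()
  for (gene in universe$genes) {
    n_ex <- gene$n_ex
    tid <- paste0("TX_", gene$gene_id)
    feat[[length(feat) + 1L]] <- data.frame(
      chrom = gene$chrom, start = gene$exons_g$start, end = gene$exons_g$end,
      strand = gene$strand, feature = "exon", gene_id = gene$gene_id,
      gene_name = gene$gene_id, transcript_id = tid, stringsAsFactors = FALSE
    )
    cds_g <- .gene_mrange2g(gene, gene$c0, gene$ce)
    feat[[length(feat) + 1L]] <- data.frame(
      chrom = gene$chrom, start = cds_g$start, end = cds_g$end,
      strand = gene$strand, feature = "CDS", gene_id = gene$gene_id,
      gene_name = gene$gene_id, transcript_id = tid, stringsAsFactors = FALSE
    )
  }
  universe$features <- do.call(rbind, feat)
  universe$annotation <- build_annotation(universe$features)
  tx_seqs <- character(0)
  prot_seqs <- character(0)
  for (gene in universe$genes) {
    tid <- paste0("TX_", gene$gene_id)
    tx <- universe$annotation$genes[[gene$gene_id]]$transcripts[[tid]]
    s <- transcript_seq(tx, universe$genome)
    tx_seqs[tid] <- s
    cds_seq <- substr(s, gene$c0, gene$ce)
    codons <- substring(cds_seq, seq(1, nchar(cds_seq) - 2, 3),
                        seq(3, nchar(cds_seq), 3))
    aa <- .translate_codons(codons)
    prot_seqs[paste0("PROT_", gene$gene_id)] <-
      paste(aa[aa != "*"], collapse = "")  # synthetic proteome: stops dropped
  }
  universe$transcriptome <- tx_seqs
  universe$proteome <- prot_seqs
  universe
}

#' Write the universe files
#'
#' @param universe from [make_universe()].
#' @param dir output directory (`genome.fa`, `annotation.gtf`,
#'   `transcriptome.fa`, `proteome.fa`).
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(universe$genome, file.path(dir, "genome.fa"))
  write_fasta(universe$transcriptome, file.path(dir, "transcriptome.fa"))
  write_fasta(universe$proteome, file.path(dir, "proteome.fa"))
  f <- universe$features
  attrs <- sprintf('gene_id "%s"; transcript_id "%s"; gene_name "%s";',
                   f$gene_id, f$transcript_id, f$gene_name)
  lines <- paste(f$chrom, "chimerascope_sim", f$feature, f$start, f$end,
                 ".", f$strand, ".", attrs, sep = "\t")
  writeLines(lines, file.path(dir, "annotation.gtf"))
  invisible(dir)
}

## --- breakpoint candidate machinery -------------------------------------

## mRNA position of the transcript-orientation 3'-most base of exon j.
.exon_end_m <- function(gene, j) gene$cum[j]
## mRNA position of the 5'-most base of exon j.
.exon_start_m <- function(gene, j) if (j == 1L) 1L else gene$cum[j - 1L] + 1L

.phase_at <- function(gene, m) as.integer((m - gene$c0) %% 3L)

## Candidate mRNA positions for one side of a junction.
## side: donor/acceptor; role: E/M; region: cds/na; want_phase: NULL or 0:2.
.candidates <- function(gene, side, role, region, want_phase = NULL) {
  n <- gene$n_ex
  if (role == "E") {
    if (side == "donor") {
      js <- if (region == "cds") 2:(n - 2L) else 1L
      ms <- vapply(js, function(j) .exon_end_m(gene, j), integer(1))
    } else {
      js <- if (region == "cds") 3:(n - 1L) else c(2L, n)
      ms <- vapply(js, function(j) .exon_start_m(gene, j), integer(1))
    }
    if (region == "cds")
      ms <- ms[ms >= gene$c0 & ms <= gene$ce]
    else
      ms <- ms[ms < gene$c0 | ms > gene$ce]
  } else {
    margin <- 6L
    interior <- function(j) {
      a <- .exon_start_m(gene, j) + margin
      b <- .exon_end_m(gene, j) - margin
      if (a > b) integer(0) else seq(a, b)
    }
    js <- if (region == "cds") 3:(n - 2L) else c(1L, n)
    ms <- unlist(lapply(js, interior))
    ms <- if (region == "cds") ms[ms > gene$c0 + 3L & ms < gene$ce - 3L]
          else ms[ms < gene$c0 - 3L | ms > gene$ce + 3L]
  }
  if (!is.null(want_phase) && length(ms) > 0)
    ms <- ms[.phase_at(gene, ms) == want_phase]
  ms
}

## Plant (or deny) a splice motif at a breakpoint by editing the genome.
## Returns list(genome, edited_range) or NULL if the window collides with a
## previous edit.
.plant_motif <- function(genome, registry, chrom, pos, strand, side, flag) {
  if (side == "donor") {
    ## transcript-strand window: [pos-1, pos] = AG, [pos+1, pos+2] = GT
    if (strand == "+") { lo <- pos - 1L; bases <- if (flag) "AGGT" else "CCCC" }
    else { lo <- pos - 2L; bases <- if (flag) revcomp("AGGT") else "CCCC" }
  } else {
    ## transcript-strand window: [pos-2, pos-1] = AG, [pos] = G
    if (strand == "+") { lo <- pos - 2L; bases <- if (flag) "AGG" else "CCC" }
    else { lo <- pos; bases <- if (flag) revcomp("AGG") else "CCC" }
  }
  hi <- lo + nchar(bases) - 1L
  reg <- registry[[chrom]]
  if (!is.null(reg) && any(reg$lo <= hi & lo <= reg$hi)) return(NULL)
  chr <- genome[[chrom]]
  if (lo < 1L || hi > nchar(chr)) return(NULL)
  substr(chr, lo, hi) <- bases
  genome[[chrom]] <- chr
  registry[[chrom]] <- rbind(reg, data.frame(lo = lo, hi = hi))
  list(genome = genome, registry = registry)
}

## --- call simulation -----------------------------------------------------

#' Simulate the fusion call set with planted truth
#'
#' Draws `n_true_chimeras` chimeras realizing the configured junction /
#' pair / frame class mix, plants splice motifs at the configured per-class
#' rates by editing the genome around each breakpoint, adds
#' reference-transcript-copy decoys, assigns prediction scores, expression
#' ratios and per-tissue sample support realizing the planted filter fates,
#' and rebuilds the transcriptome from the edited genome.
#'
#' @param cfg a [sim_config()].
#' @param universe from [make_universe()] with the same config.
#' @return list with `calls` (one row per chimera per sample, semantic
#'   columns plus `tissue`), `metadata`, `expression` (parental-gene FPKM
#'   matrix), `truth` (one row per planted chimera: classes, motif flags,
#'   decoy flag and expected filter fate), `truth_tissue` (planted
#'   per-tissue sample counts) and `universe` (genome edited with motif
#'   plants; annotation/transcriptome refreshed).
#' @export
simulate_calls <- function(cfg, universe) {
  force(universe)   # evaluate before seeding: building it consumes the RNG
  set.seed(cfg$seed + 1L)
  genes <- universe$genes
  gene_ids <- names(genes)
  gene_chrom <- vapply(genes, `[[`, character(1), "chrom")
  gene_strand <- vapply(genes, `[[`, character(1), "strand")
  rt <- universe$readthrough_pairs

  n <- cfg$n_true_chimeras
  jclass <- sample(names(cfg$junction_mix), n, TRUE, cfg$junction_mix)
  pclass <- sample(names(cfg$pair_mix), n, TRUE, cfg$pair_mix)
  fclass <- sample(names(cfg$frame_mix), n, TRUE, cfg$frame_mix)

  registry <- list()
  genome <- universe$genome
  used_keys <- character(0)
  truth_rows <- list()

  pick_pair <- function(pc) {
    if (pc == "read_through") {
      i <- sample(nrow(rt), 1L)
      c(rt$gene5[i], rt$gene3[i])
    } else if (pc == "inter_chromosomal") {
      repeat {
        g <- sample(gene_ids, 2L)
        if (gene_chrom[g[1]] != gene_chrom[g[2]]) return(g)
      }
    } else {
      ## intra_other: same chromosome, but opposite strand or with the 5'
      ## gene downstream, so proximity never makes it a read-through
      repeat {
        chrom <- sample(unique(gene_chrom), 1L)
        pool <- gene_ids[gene_chrom == chrom]
        g <- sample(pool, 2L)
        a <- genes[[g[1]]]; b <- genes[[g[2]]]
        if (a$strand != b$strand) return(g)
        ## same strand: order so gene5 is DOWNSTREAM of gene3
        upstream_first <- if (a$strand == "+") a$span[1] < b$span[1]
                          else a$span[1] > b$span[1]
        return(if (upstream_first) c(g[2], g[1]) else g)
      }
    }
  }

  place_one <- function(jc, pc, fc) {
    for (attempt in 1:200) {
      pair <- pick_pair(pc)
      g5 <- genes[[pair[1]]]; g3 <- genes[[pair[2]]]
      role5 <- substr(jc, 1, 1)
      role3 <- substr(jc, 2, 2)
      if (fc == "na") {
        ## noncoding on the 5' side forces the NA frame call
        m5 <- .candidates(g5, "donor", role5, "na")
        m3 <- c(.candidates(g3, "acceptor", role3, "cds"),
                .candidates(g3, "acceptor", role3, "na"))
        if (length(m5) == 0 || length(m3) == 0) next
        m5 <- if (length(m5) == 1L) m5 else sample(m5, 1L)
        m3 <- if (length(m3) == 1L) m3 else sample(m3, 1L)
      } else {
        m5c <- .candidates(g5, "donor", role5, "cds")
        if (length(m5c) == 0) next
        m5 <- m5c[sample.int(length(m5c), 1L)]
        p5 <- .phase_at(g5, m5)
        want <- if (fc == "in_frame") (p5 + 1L) %% 3L
                else sample(setdiff(0:2, (p5 + 1L) %% 3L), 1L)
        m3c <- .candidates(g3, "acceptor", role3, "cds", want_phase = want)
        if (length(m3c) == 0) next
        m3 <- m3c[sample.int(length(m3c), 1L)]
      }
      pos5 <- .gene_m2g(g5, m5)
      pos3 <- .gene_m2g(g3, m3)
      key <- chimera_key(g5$gene_id, g3$gene_id, g5$chrom, pos5, g5$strand,
                         g3$chrom, pos3, g3$strand)
      if (key %in% used_keys) next
      rates <- cfg$motif_rates[jc, ]
      dflag <- stats::runif(1) < rates[["donor"]]
      aflag <- stats::runif(1) < rates[["acceptor"]]
      e1 <- .plant_motif(genome, registry, g5$chrom, pos5, g5$strand,
                         "donor", dflag)
      if (is.null(e1)) next
      e2 <- .plant_motif(e1$genome, e1$registry, g3$chrom, pos3, g3$strand,
                         "acceptor", aflag)
      if (is.null(e2)) next
      genome <<- e2$genome; registry <<- e2$registry
      used_keys <<- c(used_keys, key)
      return(data.frame(
        key = key, gene5 = g5$gene_id, gene3 = g3$gene_id,
        chrom5 = g5$chrom, pos5 = pos5, strand5 = g5$strand,
        chrom3 = g3$chrom, pos3 = pos3, strand3 = g3$strand,
        junction_class = jc, pair_class = pc, frame_class = fc,
        donor_motif = dflag, acceptor_motif = aflag,
        decoy = FALSE, stringsAsFactors = FALSE
      ))
    }
    NULL
  }

  for (i in seq_len(n)) {
    truth_rows[[i]] <- place_one(jclass[i], pclass[i], fclass[i])
    if (is.null(truth_rows[[i]]))
      stopf("could not place chimera %d (class %s/%s/%s); universe too small",
            i, jclass[i], pclass[i], fclass[i])
  }

  ## Re-place any planted chimera whose junction context is, by chance,
  ## explainable by a single reference transcript under the identity
  ## criterion, so that planted identity-stage fates are unambiguous (the
  ## exact flank around a genomic breakpoint can extend across the junction
  ## by luck of the draw; such placements are rejected, not relabelled).
  truth <- NULL
  for (round in 1:20) {
    universe$genome <- genome
    universe <- refresh_universe(universe)
    truth <- do.call(rbind, truth_rows)
    truth$junction_seq <- vapply(seq_len(nrow(truth)), function(i) {
      build_junction_sequence(truth[i, ], universe$genome, flank = 50L)$sequence
    }, character(1))
    bad <- which(reference_explainable(truth$junction_seq,
                                       universe$transcriptome))
    if (length(bad) == 0) break
    if (round == 20L)
      stopf("could not construct unambiguous junction contexts")
    for (b in bad) {
      replaced <- place_one(truth$junction_class[b], truth$pair_class[b],
                            truth$frame_class[b])
      if (is.null(replaced))
        stopf("could not re-place chimera %d; universe too small", b)
      truth_rows[[b]] <- replaced
    }
  }

  ## decoys: junction sequences copied verbatim from reference transcripts
  if (cfg$n_decoys > 0) {
    decoy_rows <- list()
    for (d in seq_len(cfg$n_decoys)) {
      repeat {
        g5 <- genes[[sample(gene_ids, 1L)]]
        g3 <- genes[[sample(gene_ids, 1L)]]
        if (g5$gene_id == g3$gene_id) next
        m5 <- .candidates(g5, "donor", "M", "cds")
        m3 <- .candidates(g3, "acceptor", "M", "cds")
        if (length(m5) == 0 || length(m3) == 0) next
        pos5 <- .gene_m2g(g5, m5[sample.int(length(m5), 1L)])
        pos3 <- .gene_m2g(g3, m3[sample.int(length(m3), 1L)])
        key <- chimera_key(g5$gene_id, g3$gene_id, g5$chrom, pos5, g5$strand,
                           g3$chrom, pos3, g3$strand)
        if (key %in% used_keys) next
        used_keys <- c(used_keys, key)
        src <- sample(names(universe$transcriptome), 1L)
        slen <- nchar(universe$transcriptome[[src]])
        start <- sample(seq_len(slen - 99L), 1L)
        js <- substr(universe$transcriptome[[src]], start, start + 99L)
        decoy_rows[[d]] <- data.frame(
          key = key, gene5 = g5$gene_id, gene3 = g3$gene_id,
          chrom5 = g5$chrom, pos5 = pos5, strand5 = g5$strand,
          chrom3 = g3$chrom, pos3 = pos3, strand3 = g3$strand,
          junction_class = NA_character_, pair_class = NA_character_,
          frame_class = NA_character_, donor_motif = NA, acceptor_motif = NA,
          decoy = TRUE, junction_seq = js, stringsAsFactors = FALSE
        )
        break
      }
    }
    decoys <- do.call(rbind, decoy_rows)
  } else decoys <- NULL

  truth <- rbind(truth, decoys)

  ## planted filter fates
  nT <- nrow(truth)
  fate <- rep("pass", nT)
  is_true <- !truth$decoy
  idx_true <- which(is_true)
  n_low <- round(cfg$frac_low_score * length(idx_true))
  n_miss <- round(cfg$frac_missing_breakpoint * length(idx_true))
  early <- sample(idx_true, n_low + n_miss)
  fate[early[seq_len(n_low)]] <- "low_score"
  if (n_miss > 0) fate[early[n_low + seq_len(n_miss)]] <- "missing_breakpoint"
  fate[truth$decoy] <- "identity_removed"
  survivors <- which(fate == "pass")
  n_ratio <- round(cfg$frac_ratio_violation * length(survivors))
  if (n_ratio > 0) fate[sample(survivors, n_ratio)] <- "ratio_removed"
  truth$fate <- fate

  ## scores and expression
  truth$score <- round(ifelse(truth$fate == "low_score",
                              stats::runif(nT, 0.15, 0.595),
                              stats::runif(nT, 0.62, 0.99)), 3)
  truth$chimera_expr <- round(stats::runif(nT, 2, 30), 2)
  ratio_target <- ifelse(truth$fate == "ratio_removed",
                         stats::runif(nT, 1.1, 2.5),      # ratio > 1: removed
                         stats::runif(nT, 0.05, 0.95))
  truth$gene5_expr <- round(truth$chimera_expr / ratio_target, 2)
  truth$gene3_expr <- round(truth$chimera_expr /
                              stats::runif(nT, 0.05, 0.95), 2)
  ## guard against rounding pushing a planted ratio across the bound
  bad5 <- truth$fate != "ratio_removed" &
    truth$chimera_expr / truth$gene5_expr > 1
  truth$gene5_expr[bad5] <- truth$chimera_expr[bad5] + 1
  bad3 <- truth$chimera_expr / truth$gene3_expr > 1
  truth$gene3_expr[bad3] <- truth$chimera_expr[bad3] + 1

  ## tissue membership realizing the recurrence plan
  tissues <- names(cfg$samples_per_tissue)
  sizes <- cfg$samples_per_tissue
  metadata <- do.call(rbind, lapply(tissues, function(t) {
    data.frame(sample_id = sprintf("S_%s_%03d", t, seq_len(sizes[[t]])),
               tissue = t,
               donor_id = sprintf("D_%s_%03d", t, ceiling(seq_len(sizes[[t]]) / 2)),
               stringsAsFactors = FALSE)
  }))

  late <- which(truth$fate %in% c("pass"))
  enriched <- is_true & (truth$junction_class == "EE" |
                           truth$pair_class == "read_through")
  plan <- vector("list", nT)
  for (i in seq_len(nT)) {
    if (!(i %in% late)) {
      t1 <- sample(tissues, 1L)
      plan[[i]] <- stats::setNames(1L, t1)
      next
    }
    slot <- match(i, late)
    if (slot <= 5L) {
      ## housekeeping plant: present in every tissue
      counts <- pmin(sizes, sample(2:4, length(tissues), TRUE))
      plan[[i]] <- stats::setNames(as.integer(counts), tissues)
    } else if (slot <= 13L) {
      ## tissue-specific plant: exactly one tissue, at threshold
      t1 <- tissues[(slot - 6L) %% length(tissues) + 1L]
      plan[[i]] <- stats::setNames(tissue_threshold(sizes[[t1]]), t1)
    } else if (isTRUE(enriched[i])) {
      k <- sample(2:length(tissues), 1L)
      ts <- sample(tissues, k)
      plan[[i]] <- stats::setNames(pmin(sizes[ts], sample(2:6, k, TRUE)), ts)
    } else {
      k <- sample(1:2, 1L)
      ts <- sample(tissues, k)
      plan[[i]] <- stats::setNames(pmin(sizes[ts], sample(1:3, k, TRUE)), ts)
    }
  }
  truth$frequency_planted <- vapply(plan, function(p) sum(as.integer(p)), integer(1))

  truth_tissue <- do.call(rbind, lapply(seq_len(nT), function(i) {
    p <- plan[[i]]
    data.frame(key = truth$key[i], tissue = names(p),
               n_samples = as.integer(p), stringsAsFactors = FALSE)
  }))

  ## expand to per-sample call rows
  call_rows <- lapply(seq_len(nT), function(i) {
    p <- plan[[i]]
    samples <- unlist(lapply(names(p), function(t) {
      pool <- metadata$sample_id[metadata$tissue == t]
      sample(pool, p[[t]])
    }), use.names = FALSE)
    data.frame(
      sample_id = samples,
      tissue = metadata$tissue[match(samples, metadata$sample_id)],
      gene5 = truth$gene5[i], gene3 = truth$gene3[i],
      chrom5 = truth$chrom5[i],
      pos5 = if (truth$fate[i] == "missing_breakpoint") NA_integer_ else truth$pos5[i],
      strand5 = truth$strand5[i],
      chrom3 = truth$chrom3[i],
      pos3 = if (truth$fate[i] == "missing_breakpoint") NA_integer_ else truth$pos3[i],
      strand3 = truth$strand3[i],
      junction_seq = truth$junction_seq[i], score = truth$score[i],
      chimera_expr = truth$chimera_expr[i], gene5_expr = truth$gene5_expr[i],
      gene3_expr = truth$gene3_expr[i],
      missing_breakpoint = truth$fate[i] == "missing_breakpoint",
      stringsAsFactors = FALSE
    )
  })
  calls <- do.call(rbind, call_rows)
  rownames(calls) <- NULL

  ## parental-gene FPKM matrix
  parents <- sort(unique(c(truth$gene5[is_true], truth$gene3[is_true])))
  expr <- matrix(0, nrow = length(parents), ncol = nrow(metadata),
                 dimnames = list(parents, metadata$sample_id))
  if (cfg$parent_profile == "random") {
    ## parental genes are broadly expressed across samples (0.9 prevalence),
    ## independent of where the chimera was called
    expr[] <- ifelse(stats::runif(length(expr)) < 0.9,
                     round(stats::runif(length(expr), 0.05, 50), 3),
                     round(stats::runif(length(expr), 0, 0.039), 3))
  } else {
    present <- matrix(FALSE, length(parents), nrow(metadata),
                      dimnames = dimnames(expr))
    for (i in which(is_true)) {
      rows <- call_rows[[i]]
      for (g in unique(c(truth$gene5[i], truth$gene3[i])))
        present[g, rows$sample_id] <- TRUE
    }
    on_val <- round(stats::runif(length(expr), 0.05, 50), 3)
    off_val <- round(stats::runif(length(expr), 0, 0.039), 3)
    sel <- if (cfg$parent_profile == "matched") present else !present
    expr[] <- ifelse(sel, on_val, off_val)
  }

  list(calls = calls, metadata = metadata, expression = expr,
       truth = truth, truth_tissue = truth_tissue, universe = universe)
}

#' Write the simulated call set
#'
#' @param sim result of [simulate_calls()].
#' @param dir output directory (`calls.tsv`, `metadata.tsv`,
#'   `expression.tsv`, `truth.tsv`, `truth_tissue.tsv`).
#' @param dialect call-table dialect for `calls.tsv`.
#' @export
write_simulation <- function(sim, dir, dialect = call_table_dialect()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_call_table(sim$calls, file.path(dir, "calls.tsv"), dialect)
  write_metadata(sim$metadata, file.path(dir, "metadata.tsv"))
  write_expression(sim$expression, file.path(dir, "expression.tsv"))
  write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  write_tsv(sim$truth_tissue, file.path(dir, "truth_tissue.tsv"))
  invisible(dir)
}

#' Simulate a PSM table against a chimeric-peptide database
#'
#' Plants `n_true_psms` passing matches (q drawn below the cutoff) over
#' `n_true_peptides` distinct chimeric peptides (so the PSM count exceeds
#' the unique-peptide count), plus borderline matches at or above the
#' cutoff and non-chimeric spectra. Deterministic under `cfg$seed`.
#'
#' @param peptide_db data.frame of chimeric peptides
#'   ([junction_peptides()] output).
#' @param cfg a [sim_config()].
#' @param n_true_psms,n_true_peptides,n_borderline,n_nonchimeric plant sizes.
#' @return data.frame PSM table (see [read_psm_table()]).
#' @export
simulate_psms <- function(peptide_db, cfg, n_true_psms = 25L,
                          n_true_peptides = 15L, n_borderline = 5L,
                          n_nonchimeric = 10L) {
  force(peptide_db)
  set.seed(cfg$seed + 2L)
  avail <- unique(peptide_db$sequence)
  if (length(avail) < n_true_peptides)
    stopf("peptide database has only %d unique peptides (need %d)",
          length(avail), n_true_peptides)
  chosen <- sample(avail, n_true_peptides)
  ## every chosen peptide at least once; remaining PSMs spread over them
  extra <- sample(chosen, n_true_psms - n_true_peptides, replace = TRUE)
  true_pep <- c(chosen, extra)
  border_pep <- sample(avail, n_borderline, replace = TRUE)
  fake_pep <- vapply(seq_len(n_nonchimeric), function(i)
    paste(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")),
                 12, replace = TRUE), collapse = ""), character(1))
  tab <- data.frame(
    peptide = c(true_pep, border_pep, fake_pep),
    q_value = c(round(stats::runif(length(true_pep), 0.0005, 0.045), 4),
                round(stats::runif(n_borderline, 0.05, 0.4), 4),
                round(stats::runif(n_nonchimeric, 0.0005, 0.045), 4)),
    stringsAsFactors = FALSE
  )
  tab$spectrum_id <- sprintf("spec_%04d", seq_len(nrow(tab)))
  tab$sample_id <- sprintf("MS_%02d", sample(1:30, nrow(tab), replace = TRUE))
  tab
}
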