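# Orchestration of the full ladder: score -> identity -> ratio ->
# classify/dedupe -> M/M removal -> recurrence, followed by profiling and
# summaries, with per-stage reports and a reproducibility manifest.

#' Run the full post-detection pipeline
#'
#' Applies the staged filtering ladder to a call set, classifying unique
#' chimera keys once (labels are key-determined) and propagating the labels
#' to all supporting calls before deduplication. Each stage emits a
#' [filter_report()]; the manifest records every parameter and stage count,
#' which suffices to reproduce the run.
#'
#' @param calls data.frame of calls (semantic columns; a `tissue` column is
#'   joined from `metadata` if absent).
#' @param annotation a `chim_annotation`.
#' @param genome named character vector of chromosome sequences (optional;
#'   motif flags are skipped when absent).
#' @param transcriptome named character vector of reference transcript
#'   sequences (optional; identity stage is skipped when absent).
#' @param metadata sample metadata data.frame.
#' @param min_score,min_identity,min_flank,ratio_mode,min_frequency stage
#'   parameters (defaults: 0.6, 0.90, 10, `"either"`, 5).
#' @param pair_cfg a [pair_class_config()].
#' @param out_dir optional directory for per-stage TSV outputs and the JSON
#'   manifest.
#' @return list with `stages` (kept call/chimera sets per stage), `reports`
#'   (named list of `filter_report`s), `uniques` (classified, deduplicated),
#'   `non_mm`, `recurrent`, `tissue_recurrent`, `manifest`.
#' @export
run_pipeline <- function(calls, annotation, genome = NULL,
                         transcriptome = NULL, metadata = NULL,
                         min_score = 0.6, min_identity = 0.90,
                         min_flank = 10L, ratio_mode = "either",
                         min_frequency = 5L,
                         pair_cfg = pair_class_config(), out_dir = NULL) {
  if (!"tissue" %in% names(calls) && !is.null(metadata))
    calls$tissue <- metadata$tissue[match(calls$sample_id, metadata$sample_id)]
  reports <- list()

  st <- score_filter(calls, min_score)
  reports$score <- st$report
  kept <- st$kept

  if (!is.null(transcriptome)) {
    st <- identity_filter(kept, transcriptome, min_identity, min_flank)
    reports$identity <- st$report
    kept <- st$kept
  }

  st <- ratio_filter(kept, ratio_mode)
  reports$ratio <- st$report
  kept <- st$kept

  ## classify once per unique key, then label every supporting call
  key <- chimera_key(kept$gene5, kept$gene3, kept$chrom5, kept$pos5,
                     kept$strand5, kept$chrom3, kept$pos3, kept$strand3)
  reps <- kept[!duplicated(key), , drop = FALSE]
  reps <- classify_calls(reps, annotation, genome, pair_cfg)
  rep_key <- chimera_key(reps$gene5, reps$gene3, reps$chrom5, reps$pos5,
                         reps$strand5, reps$chrom3, reps$pos3, reps$strand3)
  idx <- match(key, rep_key)
  for (col in c("junction_class", "pair_class", "frame_class",
                "donor_motif", "acceptor_motif", "isoform",
                "classification_error"))
    kept[[col]] <- reps[[col]][idx]

  uniques <- dedupe(kept)

  mm <- remove_mm(uniques)
  reports$non_mm <- mm$report

  rec <- global_recurrence(mm$kept, min_frequency)
  reports$recurrent <- rec$report

  trec <- if (!is.null(metadata)) tissue_recurrent(mm$kept, metadata) else NULL

  manifest <- list(
    parameters = list(min_score = min_score, min_identity = min_identity,
                      min_flank = min_flank, ratio_mode = ratio_mode,
                      min_frequency = min_frequency,
                      readthrough_max_gap = pair_cfg$readthrough_max_gap),
    stage_order = names(reports),
    stage_counts = lapply(reports, function(r)
      list(input = r$input, kept = r$kept, removed = r$removed))
  )

  for (r in reports)
    if (r$kept + r$removed != r$input)
      stopf("stage %s violates kept + removed == input", r$stage)  # nocov

  out <- list(stages = list(post_filter_calls = kept), reports = reports,
              uniques = uniques, non_mm = mm$kept, recurrent = rec$kept,
              tissue_recurrent = trec, manifest = manifest)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(kept, file.path(out_dir, "calls_filtered.tsv"))
    write_tsv(uniques$table, file.path(out_dir, "unique_chimeras.tsv"))
    write_tsv(mm$kept$table, file.path(out_dir, "non_mm.tsv"))
    write_tsv(rec$kept$table, file.path(out_dir, "non_mm_recurrent.tsv"))
    if (!is.null(trec)) write_tsv(trec, file.path(out_dir, "tissue_recurrent.tsv"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  }
  out
}
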