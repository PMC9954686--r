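# End-to-end experiment driver:
# synth -> decompose -> split -> train (x repetitions) -> predict ->
# evaluate (slice + subject) -> aggregate -> attention panels.

#' Experiment configuration
#'
#' @param modality `"fmri"` or `"smri"`.
#' @param variant model variant (see [canonical_config()]); any
#'   [vit_config()] can be supplied via `model_config`.
#' @param scheme experiment scheme name (see [experiment_scheme()]).
#' @param seeds one seed per repetition (default 3 repetitions, matching
#'   the published protocol of three random data splits).
#' @param cohort a [cohort_spec()] for synthetic data, or `NULL` when
#'   `cohort_dir` points at an existing cohort.
#' @param cohort_dir directory holding (or receiving) the NIfTI cohort.
#' @param model_config optional explicit [vit_config()] overriding
#'   `variant`.
#' @param train a [train_config()].
#' @param decompose a [decompose_params()].
#' @param noise list(n_to_ad, n_to_mci) for the healthy-control noise
#'   challenge, or NULL.
#' @param fractions train/val/test fractions (default the published
#'   80/10/10; desk-scale smoke runs on tiny cohorts need coarser ones,
#'   e.g. equal thirds, for every split to be nonempty under the
#'   floor-based convention).
#' @return object of class `experiment_config`.
#' @export
experiment_config <- function(modality = c("fmri", "smri"),
                              variant = "ovitad",
                              scheme = "AD_HC_MCI",
                              seeds = c(1L, 2L, 3L),
                              cohort = NULL, cohort_dir = NULL,
                              model_config = NULL,
                              train = train_config(),
                              decompose = decompose_params(),
                              noise = NULL,
                              fractions = c(0.8, 0.1, 0.1)) {
  modality <- match.arg(modality)
  structure(list(modality = modality, variant = variant, scheme = scheme,
                 seeds = as.integer(seeds), cohort = cohort,
                 cohort_dir = cohort_dir, model_config = model_config,
                 train = train, decompose = decompose, noise = noise,
                 fractions = fractions),
            class = "experiment_config")
}

pipeline_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stopf("pipeline stage '%s' failed: %s", name, conditionMessage(e))
  })
}

#' Run the full pipeline
#'
#' Executes every stage and writes a self-describing run directory:
#' cohort manifest, slice manifest, split tables, per-repetition
#' histories, slice- and subject-level reports, the repetition summary,
#' normalized confusion matrices and an attention panel, plus a JSON run
#' log with all configurations and seeds.
#'
#' @param config an [experiment_config()].
#' @param out_dir run directory (created).
#' @param verbose print stage progress.
#' @return `out_dir`, invisibly; key results are also returned as the
#'   attribute `results` (list with per-repetition reports and the
#'   summaries).
#' @export
run_pipeline <- function(config, out_dir, verbose = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))

  cohort <- pipeline_stage("synth", {
    if (!is.null(config$cohort)) {
      say("[synth] generating synthetic cohort")
      co <- generate_cohort(config$cohort)
      if (!is.null(config$cohort_dir)) write_cohort(co, config$cohort_dir)
      co
    } else if (!is.null(config$cohort_dir)) {
      say("[synth] loading cohort from %s", config$cohort_dir)
      read_cohort(config$cohort_dir)
    } else stopf("no cohort spec and no cohort directory given")
  })

  records <- pipeline_stage("decompose", {
    say("[decompose] %d subjects", length(cohort))
    decompose_cohort(cohort, config$decompose, out_dir = file.path(out_dir, "slices"))
  })
  utils::write.csv(records, file.path(out_dir, "slice_records.csv"), row.names = FALSE)

  subjects <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    label = vapply(cohort, `[[`, character(1), "label"),
    stringsAsFactors = FALSE)
  mcfg <- config$model_config %||% canonical_config(config$variant)

  slice_reports <- list(); subject_reports <- list()
  histories <- list(); best_paths <- character()
  for (r in seq_along(config$seeds)) {
    seed <- config$seeds[r]
    say("[split] repetition %d (seed %d)", r, seed)
    split <- pipeline_stage("split", {
      sp <- stratified_split(subjects, fractions = config$fractions, seed = seed,
                             min_class_size = min(3L, min(table(subjects$label))))
      if (!is.null(config$noise)) {
        sp <- insert_hc_noise(sp, config$noise$n_to_ad %||% 0L,
                              config$noise$n_to_mci %||% 0L, seed = seed)
      }
      sp
    })
    utils::write.csv(split, file.path(out_dir, sprintf("split_rep%d.csv", r)),
                     row.names = FALSE)
    manifest <- pipeline_stage("manifest", {
      m <- build_manifest(records, split)
      if (!is.null(split$train_label)) {
        m$train_label <- split$train_label[match(m$subject_id, split$subject_id)]
      }
      apply_scheme(m, config$scheme)
    })
    n_classes <- length(unique(manifest_labels(manifest)))
    mcfg_r <- mcfg; mcfg_r$num_classes <- n_classes
    model <- build_model(mcfg_r, seed = seed)
    tc <- config$train; tc$seed <- seed
    say("[train] repetition %d: %d train / %d val slices",
        r, sum(manifest$split == "train"), sum(manifest$split == "val"))
    fit <- pipeline_stage("train", {
      train_model(model, manifest, tc,
                  checkpoint_dir = file.path(out_dir, sprintf("ckpt_rep%d", r)))
    })
    histories[[r]] <- fit$history
    utils::write.csv(fit$history, file.path(out_dir, sprintf("history_rep%d.csv", r)),
                     row.names = FALSE)
    best <- select_best_checkpoint(fit$history, fit$checkpoints)
    best_paths[r] <- best
    test_rows <- manifest[manifest$split == "test", , drop = FALSE]
    say("[predict] repetition %d: %d test slices", r, nrow(test_rows))
    preds <- pipeline_stage("predict", predict_slices(best, test_rows))
    utils::write.csv(preds, file.path(out_dir, sprintf("slice_predictions_rep%d.csv", r)),
                     row.names = FALSE)
    slice_reports[[r]] <- classification_report(preds$predicted_label,
                                                preds$true_label, level = "slice")
    subj <- vote_majority(preds)
    subject_reports[[r]] <- classification_report(subj$predicted_label,
                                                  subj$true_label, level = "subject")
    cm <- normalized_confusion(subj$predicted_label, subj$true_label)
    utils::write.csv(cm, file.path(out_dir, sprintf("confusion_subject_rep%d.csv", r)))
  }

  summary_slice <- aggregate_repetitions(slice_reports)
  summary_subject <- aggregate_repetitions(subject_reports)
  utils::write.csv(summary_slice, file.path(out_dir, "summary_slice.csv"), row.names = FALSE)
  utils::write.csv(summary_subject, file.path(out_dir, "summary_subject.csv"), row.names = FALSE)

  pipeline_stage("attention", {
    ck <- load_checkpoint(best_paths[1])
    first <- records[1, ]
    img_raw <- png_read_gray(first$path)
    img <- img_raw / max(1, max(img_raw))
    stack <- extract_attention_maps(ck$model, img)
    write_attention_panel(stack, file.path(out_dir, "attention_panel.png"))
    fc <- extract_fc_vector(ck$model, img)
    g <- global_attention_feature_map(img_raw, fc, ck$model$config$image_size)
    write_gafm_png(g, file.path(out_dir, "gafm_first_slice.png"))
  })

  run_log <- list(
    modality = config$modality, variant = config$variant, scheme = config$scheme,
    seeds = config$seeds, repetitions = length(config$seeds),
    model_config = unclass(mcfg), train_config = unclass(config$train),
    decompose_params = unclass(config$decompose),
    cohort_spec = if (!is.null(config$cohort)) unclass(config$cohort) else NULL,
    noise = config$noise,
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("vitad")))
  jsonlite::write_json(run_log, file.path(out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")

  structure(invisible(out_dir),
            results = list(slice_reports = slice_reports,
                           subject_reports = subject_reports,
                           summary_slice = summary_slice,
                           summary_subject = summary_subject,
                           histories = histories, best_checkpoints = best_paths))
}
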