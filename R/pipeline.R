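#' Run the full SFI pipeline
#'
#' simulate (or load) cohorts -> fit the per-laterality reference model
#' -> score pointwise SFI -> SFI Hemifield Test -> ROC evaluation.
#' All artifacts are written under `out_dir`; the seed and package
#' version are recorded in the evaluation report, and a rerun with the
#' same configuration reproduces identical outputs.
#'
#' @param config a list, or path to a YAML file, with elements:
#'   \describe{
#'     \item{seed}{integer, mandatory.}
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{n_reference, n_suspect, n_glaucoma}{cohort sizes for
#'       simulation (defaults 500/300/300); ignored for any group whose
#'       `*_cohort` path is given.}
#'     \item{reference_cohort, test_cohort}{optional paths to cohort
#'       files written by [write_cohort()]; `test_cohort` must contain
#'       suspect and glaucoma eyes.}
#'     \item{laterality}{single laterality for the run (default
#'       `"right"`).}
#'     \item{map_sd}{insertion-angle SD, degrees (default 15).}
#'   }
#' @return Invisibly, a list with the fitted `model`, `ht` summaries,
#'   `evaluation` metrics and output `paths`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("pipeline config not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$seed)) stop("config$seed is mandatory", call. = FALSE)
  seed <- as.integer(config$seed)
  lat <- check_laterality(config$laterality %||% "right")
  out_dir <- config$out_dir %||% "sfi_run"
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  map_sd <- config$map_sd %||% 15
  lat_mix <- if (lat == "right") c(right = 1, left = 0) else c(right = 0, left = 1)

  get_cohort <- function(path_field, group, n_default, seed_offset) {
    path <- config[[path_field]]
    if (!is.null(path)) {
      if (!file.exists(path))
        stop("stage load-cohort: file not found: ", path, call. = FALSE)
      return(read_cohort(path))
    }
    n <- config[[paste0("n_", group)]] %||% n_default
    simulate_cohort(cohort_config(n, group, seed + seed_offset,
                                  laterality_mix = lat_mix,
                                  map_sd = map_sd))$records
  }
  ref <- get_cohort("reference_cohort", "reference", 500, 1)
  if (is.null(config$test_cohort)) {
    test <- c(
      simulate_cohort(cohort_config(config$n_suspect %||% 300, "suspect",
                                    seed + 2, laterality_mix = lat_mix,
                                    map_sd = map_sd))$records,
      simulate_cohort(cohort_config(config$n_glaucoma %||% 300, "glaucoma",
                                    seed + 3, laterality_mix = lat_mix,
                                    map_sd = map_sd))$records)
  } else {
    if (!file.exists(config$test_cohort))
      stop("stage load-cohort: file not found: ", config$test_cohort,
           call. = FALSE)
    test <- read_cohort(config$test_cohort)
  }
  ref <- Filter(function(r) r$laterality == lat, ref)
  test <- Filter(function(r) r$laterality == lat, test)

  model <- fit_reference_model(ref, lat)
  linkage <- build_linkage(default_map(lat, sd_angle = map_sd))
  ref_scores <- score_cohort(ref, model, linkage)
  model <- fit_ht_reference(model, ref_scores)

  scores <- score_cohort(test, model, linkage)
  ht <- lapply(scores, ht_summary, model = model)
  labels <- vapply(test, `[[`, "", "group")
  summary_vals <- vapply(ht, `[[`, 0, "summary")
  md_vals <- vapply(test, `[[`, 0, "md")
  psd_vals <- vapply(test, `[[`, 0, "psd")
  rim_vals <- vapply(test, function(r) sum(rim_area_difference(r)), 0)

  roc_ht <- roc(summary_vals, labels)
  roc_md <- roc(md_vals, labels, direction = "<")
  roc_psd <- roc(psd_vals, labels)
  roc_rim <- roc(rim_vals, labels, direction = "<")
  opt <- optimal_point(roc_ht)

  paths <- list(
    model = file.path(out_dir, "reference_model.json"),
    reference_cohort = file.path(out_dir, "reference_cohort.csv"),
    test_cohort = file.path(out_dir, "test_cohort.csv"),
    scores = file.path(out_dir, "sfi_scores.csv"),
    ht = file.path(out_dir, "sfi_ht.csv"),
    evaluation = file.path(out_dir, "evaluation.json"))
  save_model(model, paths$model)
  write_cohort(ref, paths$reference_cohort)
  write_cohort(test, paths$test_cohort)
  score_rows <- do.call(rbind, lapply(scores, function(s)
    cbind(subject_id = attr(s, "subject_id"), as.data.frame(s),
          mean_sfi = mean_sfi(s))))
  utils::write.csv(score_rows, paths$scores, row.names = FALSE)
  ht_rows <- do.call(rbind, lapply(seq_along(ht), function(i) {
    probs <- ht[[i]]$abnormality_probs
    names(probs) <- paste0("p_", names(probs))
    data.frame(subject_id = test[[i]]$subject_id, group = labels[i],
               t(ht[[i]]$region_scores), t(ht[[i]]$diffs),
               total = ht[[i]]$total, t(probs),
               summary = ht[[i]]$summary,
               most_abnormal = ht[[i]]$most_abnormal,
               check.names = FALSE)
  }))
  utils::write.csv(ht_rows, paths$ht, row.names = FALSE)
  evaluation <- list(
    seed = seed, laterality = lat,
    package_version = as.character(utils::packageVersion("sfindex")),
    n_suspect = sum(labels == "suspect"),
    n_glaucoma = sum(labels == "glaucoma"),
    auc = list(sfi_ht = roc_ht$auc, md = roc_md$auc, psd = roc_psd$auc,
               rim_area = roc_rim$auc),
    auc_se = list(sfi_ht = roc_ht$auc_se, md = roc_md$auc_se,
                  psd = roc_psd$auc_se, rim_area = roc_rim$auc_se),
    optimal_point = opt)
  jsonlite::write_json(evaluation, paths$evaluation, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(model = model, ht = ht, evaluation = evaluation,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
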