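#' Fit a per-laterality reference model
#'
#' Builds the empirical CPFs that define "normal": one per scored 24-2
#' location, fitted on the reference cohort's total-deviation values
#' (total deviation is used because it already embeds the age
#' correction), and one per disc sector, fitted on the measured-minus-
#' Moorfields-predicted rim-area differences. Right- and left-eye models
#' are kept separate; data are never mirrored between eyes.
#'
#' @param records list of [eye_record()] objects, all with
#'   `group == "reference"` and matching `laterality`.
#' @param laterality `"right"` or `"left"`.
#' @param min_n minimum reference sample size per CPF (default 20).
#' @return An object of class `sfi_reference_model`: list with
#'   `laterality`, `n`, `field_cpfs` (52, named by grid key),
#'   `sector_cpfs` (6, named by sector), `ht_reference` (NULL until
#'   [fit_ht_reference()] is run), `version`.
#' @export
fit_reference_model <- function(records, laterality, min_n = 20) {
  laterality <- check_laterality(laterality)
  if (!length(records)) stop("no reference records", call. = FALSE)
  ok <- vapply(records, function(r)
    inherits(r, "eye_record") && r$laterality == laterality &&
      r$group == "reference", TRUE)
  if (!all(ok))
    stop("all records must be reference-group eye_records of laterality ",
         laterality, call. = FALSE)
  if (length(records) < min_n)
    stop("need at least ", min_n, " reference eyes (got ",
         length(records), ")", call. = FALSE)
  grid <- grid_24_2(laterality)
  td_mat <- vapply(records, function(r) r$td[grid$key], numeric(nrow(grid)))
  field_cpfs <- lapply(seq_len(nrow(grid)), function(i)
    fit_cpf(td_mat[i, ], min_n = min_n, label = grid$key[i]))
  names(field_cpfs) <- grid$key
  sec <- disc_sector_names()
  rd_mat <- vapply(records, function(r) rim_area_difference(r)[sec],
                   numeric(length(sec)))
  sector_cpfs <- lapply(seq_along(sec), function(i)
    fit_cpf(rd_mat[i, ], min_n = min_n, label = sec[i]))
  names(sector_cpfs) <- sec
  structure(list(laterality = laterality, n = length(records),
                 field_cpfs = field_cpfs, sector_cpfs = sector_cpfs,
                 ht_reference = NULL, version = model_format_version()),
            class = "sfi_reference_model")
}

model_format_version <- function() "1"

#' @export
print.sfi_reference_model <- function(x, ...) {
  cat(sprintf("<sfi_reference_model> %s eyes, n = %d; %d field CPFs, %d sector CPFs; SFI-HT reference %s\n",
              x$laterality, x$n, length(x$field_cpfs), length(x$sector_cpfs),
              if (is.null(x$ht_reference)) "not fitted" else "fitted"))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Serialization: JSON, reference samples written at full double precision
# (hex "%a" encoding) so reload reproduces evaluation bit for bit.

cpf_to_list <- function(cpf) {
  list(sample = sprintf("%a", cpf$sample), n = cpf$n,
       label = if (is.null(cpf$label)) NA else cpf$label)
}

cpf_from_list <- function(lst) {
  vals <- unname(vapply(unlist(lst$sample), as.double, 0))
  fit_cpf(vals, min_n = 1, label = if (is.na(lst$label)) NULL else lst$label)
}

#' Save / load a fitted reference model
#'
#' JSON archive with an embedded schema version. Reference samples are
#' written in hexadecimal floating-point notation so a save/load round
#' trip is lossless and re-evaluated CPFs are bitwise identical.
#'
#' @param model an [fit_reference_model()] object.
#' @param path file path.
#' @return `save_model`: the path, invisibly. `load_model`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "sfi_reference_model"))
  payload <- list(
    format = "sfindex_reference_model",
    version = model$version,
    laterality = model$laterality,
    n = model$n,
    field_cpfs = lapply(model$field_cpfs, cpf_to_list),
    sector_cpfs = lapply(model$sector_cpfs, cpf_to_list),
    ht_reference = if (is.null(model$ht_reference)) NULL
                   else lapply(model$ht_reference, cpf_to_list)
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                      error = function(e)
                        stop("cannot parse model file: ", conditionMessage(e),
                             call. = FALSE))
  if (!identical(payload$format, "sfindex_reference_model"))
    stop("not a reference model file", call. = FALSE)
  if (!identical(payload$version, model_format_version()))
    stop("model format version mismatch: file has ", payload$version,
         ", expected ", model_format_version(), call. = FALSE)
  model <- structure(list(
    laterality = check_laterality(payload$laterality),
    n = payload$n,
    field_cpfs = lapply(payload$field_cpfs, cpf_from_list),
    sector_cpfs = lapply(payload$sector_cpfs, cpf_from_list),
    ht_reference = if (is.null(payload$ht_reference)) NULL
                   else lapply(payload$ht_reference, cpf_from_list),
    version = payload$version
  ), class = "sfi_reference_model")
  expected_keys <- grid_24_2(model$laterality)$key
  if (!setequal(names(model$field_cpfs), expected_keys) ||
      !setequal(names(model$sector_cpfs), disc_sector_names()))
    stop("model file is incomplete", call. = FALSE)
  model
}
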