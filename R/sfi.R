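#' Pointwise Structure Function Index
#'
#' The SFI at one visual-field location is the probability of a joint
#' structure-function abnormality there:
#' `SFI = p_field * sum_s p_sector[s] * p_anatomy[s]`,
#' where `p_field` is the probability the field point is abnormal,
#' `p_sector[s]` the probability disc sector `s` is abnormal, and
#' `p_anatomy[s]` the probability the point is anatomically linked to
#' sector `s`. Because the anatomy vector sums to 1, the result lies in
#' [0, 1] and cannot exceed `p_field * max(p_sector)`: field and disc
#' defects only reinforce each other where the anatomy links them.
#'
#' @param p_field_abn probability the field point is abnormal, in [0, 1].
#' @param p_sector_abn 6-vector of sector abnormality probabilities.
#' @param p_anatomy 6-vector of sector linkage probabilities; must sum
#'   to 1 (tolerance 1e-6).
#' @return A probability in [0, 1].
#' @export
sfi_point <- function(p_field_abn, p_sector_abn, p_anatomy) {
  stopifnot(length(p_field_abn) == 1L,
            length(p_sector_abn) == length(p_anatomy))
  if (p_field_abn < 0 || p_field_abn > 1 ||
      any(p_sector_abn < 0) || any(p_sector_abn > 1) || any(p_anatomy < 0))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (abs(sum(p_anatomy) - 1) > 1e-6)
    stop("anatomy probabilities must sum to 1", call. = FALSE)
  # sectors carrying essentially no anatomical mass add only zero terms
  use <- p_anatomy >= 1e-6
  p_field_abn * sum(p_sector_abn[use] * p_anatomy[use])
}

#' Score one eye: 52 pointwise SFI values
#'
#' For each scored 24-2 location: the probability of field abnormality is
#' one minus the CPF of the point's total deviation; the six sector
#' abnormality probabilities are one minus the CPFs of the sector
#' rim-area differences; these are fused with the point's anatomical
#' linkage vector by [sfi_point()].
#'
#' @param record an [eye_record()].
#' @param model a [fit_reference_model()] of the same laterality.
#' @param linkage a [build_linkage()] of the same laterality.
#' @return An object of class `sfi_result`: data frame with columns `x`,
#'   `y`, `key`, `td`, `p_field_abn`, `sfi`, plus attributes
#'   `p_sector_abn` (named 6-vector), `subject_id`, `laterality`.
#' @export
score_eye <- function(record, model, linkage) {
  stopifnot(inherits(record, "eye_record"),
            inherits(model, "sfi_reference_model"),
            inherits(linkage, "sector_linkage"))
  if (!identical(record$laterality, model$laterality) ||
      !identical(record$laterality, attr(linkage, "laterality")))
    stop("record, model and linkage lateralities must match", call. = FALSE)
  grid <- grid_24_2(record$laterality)
  missing_cpf <- setdiff(grid$key, names(model$field_cpfs))
  if (length(missing_cpf))
    stop("reference model lacks CPFs for: ",
         paste(missing_cpf, collapse = ", "), call. = FALSE)
  rd <- rim_area_difference(record)
  sec <- disc_sector_names()
  p_sector_abn <- vapply(sec, function(s)
    1 - cpf_eval(model$sector_cpfs[[s]], rd[[s]]), 0)
  p_field_abn <- vapply(grid$key, function(k)
    1 - cpf_eval(model$field_cpfs[[k]], record$td[[k]]), 0)
  sfi <- vapply(grid$key, function(k)
    sfi_point(p_field_abn[[k]], p_sector_abn, linkage[k, ]), 0)
  out <- data.frame(x = grid$x, y = grid$y, key = grid$key,
                    td = unname(record$td[grid$key]),
                    p_field_abn = unname(p_field_abn),
                    sfi = unname(sfi))
  structure(out, p_sector_abn = p_sector_abn,
            subject_id = record$subject_id,
            laterality = record$laterality,
            class = c("sfi_result", "data.frame"))
}

#' Mean SFI over the 52 points of an eye
#'
#' @param result an [score_eye()] result.
#' @return Arithmetic mean of the 52 pointwise SFI values.
#' @export
mean_sfi <- function(result) {
  stopifnot(inherits(result, "sfi_result"))
  mean(result$sfi)
}

#' Score a whole cohort
#'
#' @param records list of [eye_record()] objects, all of one laterality.
#' @param model,linkage as for [score_eye()].
#' @return List of `sfi_result` objects.
#' @export
score_cohort <- function(records, model, linkage) {
  lapply(records, score_eye, model = model, linkage = linkage)
}
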