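#' Per-point hemifield score
#'
#' The SFI Hemifield Test region score accumulates `1 / (10 (1 - SFI))`
#' over a cluster's points; as SFI approaches 1 the term diverges, so the
#' per-point contribution is capped at 100 (reached at SFI = 99.9%). An
#' SFI of 0 contributes the floor value 0.1.
#'
#' @param sfi numeric vector of SFI values in [0, 1].
#' @param cap per-point maximum (default 100).
#' @return Numeric vector of per-point scores in [0.1, cap].
#' @export
point_score <- function(sfi, cap = 100) {
  if (any(sfi < 0 | sfi > 1)) stop("sfi must lie in [0, 1]", call. = FALSE)
  pmin(1 / (10 * (1 - sfi)), cap)
}

#' Score one hemifield cluster
#'
#' Sum of [point_score()] over the cluster's points; ranges from
#' 0.1 per point to 100 per point, so a 3-point region tops out at 300
#' and a 6-point region at 600.
#'
#' @param result an [score_eye()] result.
#' @param keys grid keys of the cluster's points.
#' @param cap per-point cap, see [point_score()].
#' @return Scalar region score.
#' @export
region_score <- function(result, keys, cap = 100) {
  stopifnot(inherits(result, "sfi_result"))
  m <- match(keys, result$key)
  if (anyNA(m)) stop("region points missing from the SFI result", call. = FALSE)
  sum(point_score(result$sfi[m], cap = cap))
}

#' All ten region scores of an eye
#'
#' @param result an [score_eye()] result.
#' @param regions cluster table from [ght_regions()] for the eye's
#'   laterality (defaults to the packaged table).
#' @param cap per-point cap, see [point_score()].
#' @return Named numeric vector `s1..s5, i1..i5` (superior then inferior
#'   regions 1-5).
#' @export
region_scores <- function(result, regions = NULL, cap = 100) {
  stopifnot(inherits(result, "sfi_result"))
  if (is.null(regions)) regions <- ght_regions(attr(result, "laterality"))
  out <- numeric(0)
  for (h in c("superior", "inferior")) {
    for (r in 1:5) {
      keys <- regions$key[regions$hemifield == h & regions$region == r]
      out[paste0(substr(h, 1, 1), r)] <- region_score(result, keys, cap = cap)
    }
  }
  out
}

#' Paired hemifield differences and diffuse-loss sum
#'
#' The five signed differences score(superior k) - score(inferior k)
#' localise hemifield-asymmetric damage; the sum of all ten region
#' scores captures loss too diffuse to produce an asymmetry.
#'
#' @inheritParams region_scores
#' @return List with `diffs` (named numeric, `d1..d5`), `total` (scalar)
#'   and `region_scores` (the 10-vector).
#' @export
ht_statistics <- function(result, regions = NULL, cap = 100) {
  rs <- region_scores(result, regions = regions, cap = cap)
  diffs <- rs[paste0("s", 1:5)] - rs[paste0("i", 1:5)]
  names(diffs) <- paste0("d", 1:5)
  list(diffs = diffs, total = sum(rs), region_scores = rs)
}

#' Fit the SFI-HT reference distributions
#'
#' Computes the five paired differences and the region-score total for
#' every eye of a scored reference cohort and stores their empirical
#' distributions (as CPFs) into the reference model. These are the
#' distributions against which [ht_summary()] measures abnormality.
#'
#' @param model a [fit_reference_model()].
#' @param results list of `sfi_result` objects for the reference cohort,
#'   scored with this model and its linkage.
#' @param regions,cap as for [region_scores()].
#' @param min_n minimum reference size (default 20).
#' @return The model with `ht_reference` populated (list of six
#'   `sfi_cpf` objects named `d1..d5`, `total`).
#' @export
fit_ht_reference <- function(model, results, regions = NULL, cap = 100,
                             min_n = 20) {
  stopifnot(inherits(model, "sfi_reference_model"))
  stats_all <- lapply(results, ht_statistics, regions = regions, cap = cap)
  samples <- c(
    lapply(1:5, function(k)
      vapply(stats_all, function(s) s$diffs[[paste0("d", k)]], 0)),
    list(vapply(stats_all, function(s) s$total, 0))
  )
  names(samples) <- c(paste0("d", 1:5), "total")
  model$ht_reference <- lapply(names(samples), function(nm)
    fit_cpf(samples[[nm]], min_n = min_n, label = paste0("ht_", nm)))
  names(model$ht_reference) <- names(samples)
  model
}

#' Summarise an eye with the SFI Hemifield Test
#'
#' Each of the five paired differences is compared two-sided to its
#' reference distribution (either hemifield may be the damaged one):
#' abnormality probability `2 * max(F(d), 1 - F(d)) - 1`, the empirical
#' extremity of the observed difference. The total is compared one-sided
#' (high totals are abnormal): abnormality probability `F(total)`.
#' Because the reference CPFs are clamped, probabilities never reach 1.
#' The eye's summary is the single largest of the six abnormality
#' probabilities, together with which statistic attained it.
#'
#' @param result an `sfi_result`, or a precomputed [ht_statistics()]
#'   list.
#' @param model a reference model with `ht_reference` fitted.
#' @param regions,cap as for [region_scores()] (ignored when `result` is
#'   already an `ht_statistics` list).
#' @return An object of class `sfi_ht_result`: list with
#'   `region_scores`, `diffs`, `total`, `abnormality_probs` (named
#'   6-vector), `summary` (max), `most_abnormal` (name of the argmax).
#' @export
ht_summary <- function(result, model, regions = NULL, cap = 100) {
  stopifnot(inherits(model, "sfi_reference_model"))
  if (is.null(model$ht_reference))
    stop("model has no fitted SFI-HT reference; run fit_ht_reference()",
         call. = FALSE)
  st <- if (inherits(result, "sfi_result"))
    ht_statistics(result, regions = regions, cap = cap) else result
  probs <- c(
    vapply(1:5, function(k) {
      f <- cpf_eval(model$ht_reference[[paste0("d", k)]], st$diffs[[paste0("d", k)]])
      2 * max(f, 1 - f) - 1
    }, 0),
    cpf_eval(model$ht_reference$total, st$total)
  )
  names(probs) <- c(paste0("d", 1:5), "total")
  structure(list(region_scores = st$region_scores,
                 diffs = st$diffs, total = st$total,
                 abnormality_probs = probs,
                 summary = max(probs),
                 most_abnormal = names(probs)[which.max(probs)]),
            class = "sfi_ht_result")
}

#' @export
print.sfi_ht_result <- function(x, ...) {
  cat(sprintf("<sfi_ht_result> summary %.4f (most abnormal: %s)\n",
              x$summary, x$most_abnormal))
  invisible(x)
}
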