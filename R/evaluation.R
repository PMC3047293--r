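#' Receiver operating characteristic analysis
#'
#' Builds the ROC curve of a continuous score against a binary diagnosis,
#' with the caller declaring the orientation (by default higher scores
#' mean more diseased). The AUC is computed by the trapezoidal rule over
#' the full curve, which with half-credit tie handling is exactly the
#' rank (Mann-Whitney) statistic
#' `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param scores numeric vector, one per eye.
#' @param labels vector of class labels aligned with `scores`.
#' @param positive the label counted as diseased (default `"glaucoma"`).
#' @param direction `">"` if higher scores indicate disease (default),
#'   `"<"` otherwise (scores are negated internally).
#' @return An object of class `sfi_roc`: list with `thresholds`
#'   (ascending), `sensitivity`, `specificity` (per threshold, score >=
#'   threshold called positive), `auc`, `auc_se` (Hanley-McNeil),
#'   `n_pos`, `n_neg`.
#' @export
roc <- function(scores, labels, positive = "glaucoma", direction = ">") {
  stopifnot(length(scores) == length(labels), direction %in% c(">", "<"))
  keep <- is.finite(scores) & !is.na(labels)
  scores <- scores[keep]; labels <- labels[keep]
  if (direction == "<") scores <- -scores
  pos <- labels == positive
  n_pos <- sum(pos); n_neg <- sum(!pos)
  if (n_pos == 0 || n_neg == 0)
    stop("both classes must be non-empty", call. = FALSE)
  thr <- sort(unique(scores))
  sens <- vapply(thr, function(t) mean(scores[pos] >= t), 0)
  spec <- vapply(thr, function(t) mean(scores[!pos] < t), 0)
  # trapezoid over (FPR, TPR), endpoints (0,0) and (1,1) included
  fpr <- c(1, 1 - spec, 0); tpr <- c(1, sens, 0)
  auc <- sum((fpr[-length(fpr)] - fpr[-1]) *
             (tpr[-length(tpr)] + tpr[-1]) / 2)
  out <- structure(list(thresholds = thr, sensitivity = sens,
                        specificity = spec, auc = auc,
                        n_pos = n_pos, n_neg = n_neg,
                        positive = positive, direction = direction),
                   class = "sfi_roc")
  out$auc_se <- auc_se(out)
  out
}

#' @export
print.sfi_roc <- function(x, ...) {
  cat(sprintf("<sfi_roc> AUC = %.4f (SE %.4f), %d positives / %d negatives\n",
              x$auc, x$auc_se, x$n_pos, x$n_neg))
  invisible(x)
}

#' Hanley-McNeil standard error of an AUC
#'
#' The 1982 Hanley-McNeil variance:
#' `SE^2 = (A(1-A) + (n_pos-1)(Q1-A^2) + (n_neg-1)(Q2-A^2)) / (n_pos n_neg)`
#' with `Q1 = A/(2-A)` and `Q2 = 2A^2/(1+A)`.
#'
#' @param roc an [roc()] object.
#' @return The standard error; 0 (with a warning) for degenerate
#'   AUC of exactly 0 or 1.
#' @export
auc_se <- function(roc) {
  stopifnot(inherits(roc, "sfi_roc"))
  a <- roc$auc
  if (a %in% c(0, 1)) {
    warning("degenerate AUC of ", a, "; SE reported as 0", call. = FALSE)
    return(0)
  }
  q1 <- a / (2 - a)
  q2 <- 2 * a^2 / (1 + a)
  sqrt((a * (1 - a) + (roc$n_pos - 1) * (q1 - a^2) +
          (roc$n_neg - 1) * (q2 - a^2)) / (roc$n_pos * roc$n_neg))
}

#' Compare two areas under ROC curves
#'
#' Hanley-McNeil z-test `z = (A1 - A2) / sqrt(SE1^2 + SE2^2 - 2 r SE1 SE2)`.
#' For paired designs (both scores measured on the same eyes) the
#' correlation `r` between the two areas is approximated by the average
#' of the two class-conditional Spearman rank correlations between the
#' score vectors, the quantity the published correlated-AUC table is
#' indexed by. With `paired = FALSE`, `r = 0` and the test reduces to
#' the independent two-SE z-test.
#'
#' @param roc_a,roc_b [roc()] objects.
#' @param scores_a,scores_b the score vectors (required when
#'   `paired = TRUE`; must be aligned eye for eye).
#' @param labels class labels aligned with the scores (paired mode).
#' @param paired logical.
#' @return List with `z`, `p` (two-sided), `r`, `diff` (A1 - A2).
#' @export
compare_auc <- function(roc_a, roc_b, scores_a = NULL, scores_b = NULL,
                        labels = NULL, paired = TRUE) {
  stopifnot(inherits(roc_a, "sfi_roc"), inherits(roc_b, "sfi_roc"))
  if (paired) {
    if (is.null(scores_a) || is.null(scores_b) || is.null(labels))
      stop("paired comparison needs scores_a, scores_b and labels",
           call. = FALSE)
    if (length(scores_a) != length(scores_b) ||
        length(scores_a) != length(labels))
      stop("paired comparison needs aligned subject sets", call. = FALSE)
    if (roc_a$n_pos != roc_b$n_pos || roc_a$n_neg != roc_b$n_neg)
      stop("paired ROC objects disagree on class sizes", call. = FALSE)
    pos <- labels == roc_a$positive
    r_pos <- suppressWarnings(
      stats::cor(scores_a[pos], scores_b[pos], method = "spearman"))
    r_neg <- suppressWarnings(
      stats::cor(scores_a[!pos], scores_b[!pos], method = "spearman"))
    r <- mean(c(r_pos, r_neg), na.rm = TRUE)
    if (!is.finite(r)) r <- 0
  } else {
    r <- 0
  }
  se1 <- roc_a$auc_se; se2 <- roc_b$auc_se
  d <- roc_a$auc - roc_b$auc
  denom <- sqrt(max(se1^2 + se2^2 - 2 * r * se1 * se2, 0))
  z <- if (d == 0) 0 else d / denom
  list(z = z, p = 2 * stats::pnorm(-abs(z)), r = r, diff = d)
}

#' Sensitivity and specificity of a categorical test
#'
#' Counts against the clinical diagnosis and exact Clopper-Pearson 95%
#' confidence intervals for both proportions.
#'
#' @param predicted logical (or `"positive"`/`"negative"`) test calls.
#' @param labels class labels.
#' @param positive diseased label (default `"glaucoma"`).
#' @param conf_level confidence level (default 0.95).
#' @return List with `tp`, `fp`, `tn`, `fn`, `sensitivity`,
#'   `specificity`, and `sensitivity_ci` / `specificity_ci`
#'   (2-vectors); `ci_method = "clopper-pearson"`.
#' @export
binary_performance <- function(predicted, labels, positive = "glaucoma",
                               conf_level = 0.95) {
  if (is.character(predicted)) predicted <- predicted == "positive"
  stopifnot(is.logical(predicted), length(predicted) == length(labels))
  pos <- labels == positive
  tp <- sum(predicted & pos); fn <- sum(!predicted & pos)
  fp <- sum(predicted & !pos); tn <- sum(!predicted & !pos)
  cp_ci <- function(x, n) {
    a <- (1 - conf_level) / 2
    lo <- if (x == 0) 0 else stats::qbeta(a, x, n - x + 1)
    hi <- if (x == n) 1 else stats::qbeta(1 - a, x + 1, n - x)
    c(lo, hi)
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       sensitivity_ci = cp_ci(tp, tp + fn),
       specificity_ci = cp_ci(tn, tn + fp),
       ci_method = "clopper-pearson", conf_level = conf_level)
}

#' Optimal ROC operating point
#'
#' The threshold whose (sensitivity, specificity) is closest, in
#' Euclidean distance, to the ideal (1, 1); ties resolved to the lower
#' threshold.
#'
#' @param roc an [roc()] object.
#' @return List with `threshold`, `sensitivity`, `specificity`,
#'   `distance`.
#' @export
optimal_point <- function(roc) {
  stopifnot(inherits(roc, "sfi_roc"))
  d <- sqrt((1 - roc$sensitivity)^2 + (1 - roc$specificity)^2)
  i <- which(d == min(d))[1]  # thresholds ascending: first hit = lowest
  list(threshold = roc$thresholds[i], sensitivity = roc$sensitivity[i],
       specificity = roc$specificity[i], distance = d[i])
}

#' Cross-test concordance table
#'
#' Counts eyes by their pattern of positivity across k binary tests
#' (the tabulation behind a Venn diagram of test agreement), optionally
#' within an MD stratum (e.g. mild disease, MD > -5 dB, or severe,
#' MD < -10 dB).
#'
#' @param outcomes named list of aligned logical vectors, one per test.
#' @param md optional numeric vector of MD values for stratification.
#' @param md_range optional `c(lo, hi)`: keep eyes with
#'   `lo < md < hi` (use `-Inf`/`Inf` for one-sided strata).
#' @return Data frame with one row per observed positivity pattern:
#'   one logical column per test plus `count`. Counts sum to the number
#'   of (retained) eyes.
#' @export
concordance_table <- function(outcomes, md = NULL, md_range = NULL) {
  stopifnot(is.list(outcomes), length(outcomes) >= 1)
  n <- unique(vapply(outcomes, length, 0L))
  if (length(n) != 1) stop("test outcome vectors must be aligned", call. = FALSE)
  keep <- rep(TRUE, n)
  if (!is.null(md_range)) {
    if (is.null(md) || length(md) != n)
      stop("md values required (and aligned) for stratification", call. = FALSE)
    keep <- md > md_range[1] & md < md_range[2]
  }
  df <- as.data.frame(lapply(outcomes, function(v) as.logical(v)[keep]))
  agg <- stats::aggregate(list(count = rep(1L, nrow(df))),
                          by = df, FUN = sum)
  agg[do.call(order, agg[names(outcomes)]), , drop = FALSE]
}
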