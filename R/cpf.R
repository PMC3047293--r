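#' Fit an empirical cumulative probability function (CPF)
#'
#' The CPF maps an observed value to its probability of normality:
#' the empirical cumulative probability of the value in a reference
#' sample. Hazen plotting positions ((i - 0.5)/n) are assigned to the
#' order statistics and evaluation interpolates linearly between them,
#' giving a continuous, strictly bounded curve: values below the sample
#' minimum evaluate to 1/(2n) and values above the maximum to
#' 1 - 1/(2n), so a probability of abnormality (1 - CPF) never reaches
#' exactly 0 or 1.
#'
#' @param values numeric reference sample (dB for field points, mm^2 for
#'   sector rim-area differences). Non-finite values are an error.
#' @param min_n minimum sample size accepted (default 20).
#' @param label optional label (point or sector name) used in error
#'   messages and stored for provenance.
#' @return An object of class `sfi_cpf` with elements `sample` (sorted),
#'   `n`, `clamp_lo`, `clamp_hi`, `label`.
#' @export
fit_cpf <- function(values, min_n = 20, label = NULL) {
  if (any(!is.finite(values)))
    stop("non-finite reference value(s)",
         if (!is.null(label)) paste0(" for ", label), call. = FALSE)
  n <- length(values)
  if (n < min_n)
    stop("need at least ", min_n, " reference values",
         if (!is.null(label)) paste0(" for ", label), " (got ", n, ")",
         call. = FALSE)
  structure(list(sample = sort(unname(values)), n = n,
                 clamp_lo = 1 / (2 * n), clamp_hi = 1 - 1 / (2 * n),
                 label = label),
            class = "sfi_cpf")
}

#' Evaluate a CPF: probability of normality
#'
#' Linear interpolation of the Hazen plotting positions; clamped to
#' `[1/(2n), 1 - 1/(2n)]` outside the sample range. Non-decreasing in
#' `x`. The probability of abnormality is `1 - cpf_eval(cpf, x)`.
#'
#' @param cpf an [fit_cpf()] object.
#' @param x numeric vector of values to evaluate; must be finite.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
cpf_eval <- function(cpf, x) {
  stopifnot(inherits(cpf, "sfi_cpf"))
  if (any(!is.finite(x))) stop("x must be finite", call. = FALSE)
  n <- cpf$n
  pp <- (seq_len(n) - 0.5) / n
  if (cpf$sample[1] == cpf$sample[n]) {  # degenerate: constant sample
    out <- ifelse(x < cpf$sample[1], cpf$clamp_lo, cpf$clamp_hi)
    return(out)
  }
  # ties = max: at a tied sample value the CPF takes the highest
  # plotting position, i.e. (#{sample <= x} - 0.5)/n
  out <- stats::approx(cpf$sample, pp, xout = x, rule = 2,
                       ties = list("ordered", max))$y
  pmin(pmax(out, cpf$clamp_lo), cpf$clamp_hi)
}

#' @export
print.sfi_cpf <- function(x, ...) {
  cat(sprintf("<sfi_cpf> n = %d%s, range [%g, %g], clamp [%g, %g]\n",
              x$n, if (is.null(x$label)) "" else paste0(" (", x$label, ")"),
              min(x$sample), max(x$sample), x$clamp_lo, x$clamp_hi))
  invisible(x)
}
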