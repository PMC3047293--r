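# Fixtures are generated in code; nothing is read from disk.

# a minimal valid eye with constant TD and rim == predicted
make_flat_eye <- function(td_value = 0, laterality = "right",
                          subject_id = "s1", group = "reference") {
  grid <- grid_24_2(laterality)
  td <- stats::setNames(rep(td_value, nrow(grid)), grid$key)
  sec <- disc_sector_names()
  rim <- stats::setNames(rep(0.25, 6), sec)
  eye_record(subject_id, laterality, td, md = td_value, psd = 0.1,
             rim = rim, mra = rim, group = group)
}

# simulated single-laterality cohorts
sim_records <- function(n, group, seed, laterality = "right", ...) {
  mix <- if (laterality == "right") c(right = 1, left = 0) else c(right = 0, left = 1)
  simulate_cohort(cohort_config(n, group, seed, laterality_mix = mix, ...))$records
}

# reference model + linkage fitted on a small simulated cohort
make_fitted_model <- function(n = 60, seed = 42, laterality = "right",
                              with_ht = FALSE) {
  ref <- sim_records(n, "reference", seed, laterality)
  model <- fit_reference_model(ref, laterality)
  linkage <- build_linkage(default_map(laterality))
  if (with_ht)
    model <- fit_ht_reference(model, score_cohort(ref, model, linkage))
  list(model = model, linkage = linkage, records = ref)
}

# independent brute-force plotting-position ECDF: Hazen positions on the
# sorted sample ((#{<= v} - 0.5)/n at each distinct value), linear
# interpolation between distinct values, clamped to [1/(2n), 1 - 1/(2n)]
brute_cpf <- function(sample, x) {
  s <- sort(sample)
  n <- length(s)
  v <- unique(s)
  pp <- vapply(v, function(vi) (sum(s <= vi) - 0.5) / n, 0)
  lo <- 1 / (2 * n); hi <- 1 - 1 / (2 * n)
  vapply(x, function(xi) {
    if (xi <= v[1]) return(max(lo, min(pp[1], hi)))
    if (xi >= v[length(v)]) return(min(hi, max(pp[length(v)], lo)))
    j <- findInterval(xi, v)
    if (xi == v[j]) p <- pp[j]
    else p <- pp[j] + (pp[j + 1] - pp[j]) * (xi - v[j]) / (v[j + 1] - v[j])
    min(max(p, lo), hi)
  }, 0)
}

# exhaustive pairwise Mann-Whitney statistic with half credit for ties
brute_auc <- function(scores, labels, positive = "glaucoma") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
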