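#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the published cohort moments: suspect (and reference)
#' eyes have mean MD -0.46 dB with between-eye global noise of SD 1.7 dB
#' and per-point local noise of SD 2.0 dB; glaucoma eyes are calibrated
#' so the cohort mean MD is -6.3 dB. Glaucomatous damage is a focal arc
#' defect on the disc circumference: each field point is depressed by
#' the defect depth times the overlap of its insertion-angle
#' distribution with the arc, and each disc sector loses rim area in
#' proportion to the fraction of the arc it contains -- so structure and
#' function are depressed jointly, through the same anatomy, which is
#' the premise the SFI tests. Arc centers favour the inferotemporal and
#' superotemporal poles, where glaucomatous damage concentrates.
#'
#' @param n_eyes number of eyes (>= 0).
#' @param group `"reference"`, `"suspect"` or `"glaucoma"`.
#' @param seed integer seed; every draw is reproducible from it.
#' @param laterality_mix named probabilities for `right`/`left`.
#' @param md_mean baseline mean total deviation (dB).
#' @param sigma_global SD (dB) of the per-eye global sensitivity shift.
#' @param sigma_local SD (dB) of independent per-point noise.
#' @param sigma_rim SD (mm^2) of per-sector rim-area difference noise.
#' @param target_md glaucoma-cohort target mean MD (dB); the mean defect
#'   depth is derived from it analytically (see [expected_mean_overlap()]).
#' @param defect_prob probability a glaucoma eye carries a defect.
#' @param arc_width defect arc width, degrees.
#' @param arc_center_mean,arc_center_sd,arc_center_weight mixture of
#'   wrapped-normal arc-center components (degrees; defaults put 60% of
#'   mass at the inferotemporal pole, 40% superotemporal).
#' @param depth_mean mean defect depth (dB at full overlap); `NULL`
#'   (default) derives it from `target_md`.
#' @param rim_coef rim loss per dB of defect depth (mm^2/dB).
#' @param discordant if `TRUE`, rim loss is placed in the arc 180
#'   degrees away from the field defect (breaking the anatomical link
#'   while preserving both marginal severities).
#' @param map_sd insertion-angle SD (degrees) of the map used to spread
#'   defects over field points.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_eyes, group, seed,
                          laterality_mix = c(right = 0.5, left = 0.5),
                          md_mean = -0.46, sigma_global = 1.7,
                          sigma_local = 2.0, sigma_rim = 0.12,
                          target_md = -6.3, defect_prob = 0.9,
                          arc_width = 60,
                          arc_center_mean = c(292.5, 67.5),
                          arc_center_sd = c(25, 25),
                          arc_center_weight = c(0.6, 0.4),
                          depth_mean = NULL, rim_coef = 0.015,
                          discordant = FALSE, map_sd = 15) {
  stopifnot(n_eyes >= 0, group %in% c("reference", "suspect", "glaucoma"),
            is.numeric(seed), length(seed) == 1,
            sigma_global >= 0, sigma_local >= 0, sigma_rim >= 0,
            defect_prob >= 0, defect_prob <= 1, arc_width > 0,
            all(arc_center_weight >= 0), sum(arc_center_weight) > 0,
            rim_coef >= 0, map_sd > 0)
  structure(list(n_eyes = as.integer(n_eyes), group = group,
                 seed = as.integer(seed), laterality_mix = laterality_mix,
                 md_mean = md_mean, sigma_global = sigma_global,
                 sigma_local = sigma_local, sigma_rim = sigma_rim,
                 target_md = target_md, defect_prob = defect_prob,
                 arc_width = arc_width, arc_center_mean = arc_center_mean,
                 arc_center_sd = arc_center_sd,
                 arc_center_weight = arc_center_weight / sum(arc_center_weight),
                 depth_mean = depth_mean, rim_coef = rim_coef,
                 discordant = isTRUE(discordant), map_sd = map_sd),
            class = "cohort_config")
}

# typical Moorfields-predicted sector rim areas (mm^2): nasal sectors
# carry more rim; total ~1.6 mm^2
predicted_rim_means <- function() {
  c(temporal = 0.30, superotemporal = 0.20, superonasal = 0.20,
    nasal = 0.45, inferonasal = 0.22, inferotemporal = 0.22)
}

#' Expected mean anatomical overlap of a random defect arc
#'
#' The mean, over the arc-center distribution of a config and over the
#' 52 field points, of the probability that a point's insertion-angle
#' distribution falls inside the defect arc. Used to calibrate the mean
#' defect depth: a defect of depth D lowers MD by D times this quantity
#' on average, so `depth_mean = (md_mean - target_md) / (defect_prob * overlap)`.
#'
#' @param config a [cohort_config()].
#' @param map insertion map (defaults to the packaged right-eye map at
#'   the config's `map_sd`; by mirror symmetry the value is the same for
#'   both eyes).
#' @return Scalar in (0, 1).
#' @export
expected_mean_overlap <- function(config, map = NULL) {
  if (is.null(map)) map <- default_map("right", sd_angle = config$map_sd)
  centers <- seq(0, 358, by = 2)
  dens <- rep(0, length(centers))
  for (j in seq_along(config$arc_center_mean)) {
    k <- -2:2
    dens <- dens + config$arc_center_weight[j] *
      rowSums(outer(centers, 360 * k, function(c, off)
        stats::dnorm(c + off, config$arc_center_mean[j], config$arc_center_sd[j])))
  }
  dens <- dens / sum(dens)
  ov <- vapply(centers, function(cc)
    mean(point_arc_overlap(map, cc, config$arc_width)), 0)
  sum(dens * ov)
}

# per-point overlap of the insertion-angle distribution with an arc
point_arc_overlap <- function(map, center, width) {
  start <- (center - width / 2) %% 360
  end <- (center + width / 2) %% 360
  vapply(seq_len(nrow(map)), function(i)
    wrapped_normal_arc_mass(map$mean_angle[i], map$sd_angle[i], start, end), 0)
}

# geometric fraction of the arc lying in each disc sector
arc_sector_fractions <- function(center, width, sectors = disc_sectors()) {
  a0 <- (center - width / 2) %% 360
  a1 <- a0 + width
  frac <- vapply(seq_len(nrow(sectors)), function(i) {
    s0 <- sectors$start[i]
    s1 <- s0 + (sectors$end[i] - sectors$start[i]) %% 360
    tot <- 0
    for (k in -1:1) {  # sector replicated over adjacent periods
      lo <- max(a0, s0 + 360 * k); hi <- min(a1, s1 + 360 * k)
      if (hi > lo) tot <- tot + (hi - lo)
    }
    tot / width
  }, 0)
  stats::setNames(frac, sectors$sector)
}

#' Inject a focal arc defect into an eye record
#'
#' Depresses each field point by `depth` times the overlap of the
#' point's insertion-angle distribution with the arc, and reduces each
#' sector's measured rim area by `rim_coef * depth` times the fraction
#' of the arc inside the sector (floored at zero rim). MD and PSD are
#' recomputed as the mean and SD of the modified total deviations. In
#' discordant mode the rim loss is placed 180 degrees away, severing the
#' anatomical link while keeping both marginal severities.
#'
#' @param record an [eye_record()].
#' @param arc_center,arc_width defect arc, degrees.
#' @param depth defect depth at full overlap, dB (>= 0).
#' @param map insertion map of the record's laterality.
#' @param rim_coef rim loss per dB of depth (mm^2/dB).
#' @param discordant logical, see above.
#' @return List with `record` (modified), `field_delta` (named, <= 0)
#'   and `rim_delta` (named, <= 0).
#' @export
inject_defect <- function(record, arc_center, arc_width, depth, map,
                          rim_coef = 0.015, discordant = FALSE) {
  stopifnot(inherits(record, "eye_record"), inherits(map, "insertion_map"),
            depth >= 0)
  if (!identical(attr(map, "laterality"), record$laterality))
    stop("map laterality must match the record", call. = FALSE)
  overlap <- point_arc_overlap(map, arc_center, arc_width)
  field_delta <- stats::setNames(-depth * overlap, map$key)
  rim_center <- if (discordant) (arc_center + 180) %% 360 else arc_center
  rim_delta <- -rim_coef * depth * arc_sector_fractions(rim_center, arc_width)
  td <- record$td + field_delta[names(record$td)]
  rim <- pmax(record$rim + rim_delta[names(record$rim)], 0)
  rec <- eye_record(record$subject_id, record$laterality, td,
                    md = mean(td), psd = stats::sd(td),
                    rim = rim, mra = record$mra, group = record$group,
                    reliable = record$reliable,
                    quality_acceptable = record$quality_acceptable,
                    ght_category = record$ght_category,
                    mfc_category = record$mfc_category)
  list(record = rec, field_delta = field_delta, rim_delta = rim_delta)
}

#' Simulate a cohort of paired field + disc eye records
#'
#' Reference and suspect eyes: per-point total deviation
#' `md_mean + g + eps` with a shared global shift `g` and independent
#' local noise, and per-sector rim differences drawn around zero.
#' Glaucoma eyes additionally receive, with probability `defect_prob`, a
#' focal arc defect (see [inject_defect()]) whose mean depth is
#' calibrated so the cohort mean MD matches `target_md`; depths are
#' exponentially distributed, giving the long left MD tail seen in
#' glaucoma populations. MD and PSD are the mean and SD of the simulated
#' total deviations (an explicit simplification of the device formulas).
#'
#' @param config a [cohort_config()].
#' @return List with `records` (list of [eye_record()]) and `truth`
#'   (list: `eyes` data frame of per-eye defect parameters,
#'   `field_delta` and `rim_delta` lists of per-eye injected deltas).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sec <- disc_sector_names()
  maps <- list(right = default_map("right", sd_angle = config$map_sd),
               left = default_map("left", sd_angle = config$map_sd))
  depth_mean <- config$depth_mean
  if (config$group == "glaucoma" && is.null(depth_mean)) {
    ov <- expected_mean_overlap(config, maps$right)
    depth_mean <- (config$md_mean - config$target_md) /
      (config$defect_prob * ov)
  }
  records <- vector("list", config$n_eyes)
  n <- config$n_eyes
  truth_eyes <- data.frame(subject_id = character(n),
                           laterality = character(n),
                           defect = logical(n),
                           arc_center = rep(NA_real_, n),
                           arc_width = rep(NA_real_, n),
                           depth = rep(NA_real_, n))
  field_delta <- vector("list", config$n_eyes)
  rim_delta <- vector("list", config$n_eyes)
  p_right <- config$laterality_mix[["right"]] /
    sum(unlist(config$laterality_mix))
  rim_mu <- predicted_rim_means()
  for (i in seq_len(config$n_eyes)) {
    lat <- if (stats::runif(1) < p_right) "right" else "left"
    grid <- grid_24_2(lat)
    id <- sprintf("%s%05d", substr(config$group, 1, 3), i)
    g <- stats::rnorm(1, 0, config$sigma_global)
    td <- stats::setNames(
      config$md_mean + g + stats::rnorm(nrow(grid), 0, config$sigma_local),
      grid$key)
    mra <- pmax(0.05, stats::rnorm(length(sec), rim_mu, 0.04))
    names(mra) <- sec
    rim <- pmax(0, mra + stats::rnorm(length(sec), 0, config$sigma_rim))
    names(rim) <- sec
    rec <- eye_record(id, lat, td, md = mean(td), psd = stats::sd(td),
                      rim = rim, mra = mra, group = config$group)
    fd <- stats::setNames(rep(0, nrow(grid)), grid$key)
    rd <- stats::setNames(rep(0, length(sec)), sec)
    has_defect <- FALSE; center <- NA_real_; depth <- NA_real_
    if (config$group == "glaucoma" &&
        stats::runif(1) < config$defect_prob) {
      has_defect <- TRUE
      comp <- sample.int(length(config$arc_center_weight), 1,
                         prob = config$arc_center_weight)
      center <- stats::rnorm(1, config$arc_center_mean[comp],
                             config$arc_center_sd[comp]) %% 360
      depth <- stats::rexp(1, rate = 1 / depth_mean)
      inj <- inject_defect(rec, center, config$arc_width, depth,
                           maps[[lat]], rim_coef = config$rim_coef,
                           discordant = config$discordant)
      rec <- inj$record
      fd <- inj$field_delta
      rd <- inj$rim_delta
    }
    records[[i]] <- rec
    truth_eyes$subject_id[i] <- id
    truth_eyes$laterality[i] <- lat
    truth_eyes$defect[i] <- has_defect
    truth_eyes$arc_center[i] <- center
    truth_eyes$arc_width[i] <- if (has_defect) config$arc_width else NA_real_
    truth_eyes$depth[i] <- depth
    field_delta[[i]] <- fd
    rim_delta[[i]] <- rd
  }
  list(records = records,
       truth = list(eyes = truth_eyes, field_delta = field_delta,
                    rim_delta = rim_delta))
}
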