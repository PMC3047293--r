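#' The six HRT sector arcs on the disc circumference
#'
#' Angles are in a per-eye convention: 0 degrees at the temporal pole of
#' the disc, increasing through superior (90), nasal (180) and inferior
#' (270). With this convention the arcs are identical for right and left
#' eyes and the left-eye insertion map is the horizontal mirror of the
#' right-eye map. The arcs partition [0, 360).
#'
#' @param arcs optional override: data frame with columns `sector`,
#'   `start`, `end` (degrees; `end` may be numerically below `start` for
#'   the arc wrapping 0, as for the temporal sector).
#' @return Data frame with columns `sector`, `start`, `end`.
#' @export
disc_sectors <- function(arcs = NULL) {
  if (is.null(arcs)) {
    arcs <- data.frame(
      sector = disc_sector_names(),
      start  = c(315, 45, 90, 135, 225, 270),
      end    = c(45, 90, 135, 225, 270, 315)
    )
  }
  stopifnot(is.data.frame(arcs), all(c("sector", "start", "end") %in% names(arcs)))
  widths <- (arcs$end - arcs$start) %% 360
  if (abs(sum(widths) - 360) > 1e-9)
    stop("sector arcs must partition the circle", call. = FALSE)
  arcs
}

#' Default insertion-angle map for the 24-2 grid
#'
#' For every scored 24-2 location, the mean and standard deviation of the
#' angle on the disc circumference at which that location's nerve fiber
#' bundle inserts. Means come from a smooth geometric model of fiber
#' courses fit to the known retinotopy (disc 15.5 degrees nasal and 1.5
#' degrees superior on the retina; straight-line entry for retina nasal
#' of the disc; arcuate paths, with entry pushed toward the vertical
#' poles, for retina temporal of the disc), calibrated so that the point
#' 3 degrees right / 15 degrees up in a right eye splits its linkage
#' roughly 74%/26% between the inferotemporal and inferonasal sectors.
#' The per-point SD defaults to a uniform 15 degrees; per-point values
#' are not published, so both means and SDs can be overridden.
#'
#' @inheritParams grid_24_2
#' @param sd_angle uniform insertion-angle SD in degrees (> 0).
#' @param override optional data frame with columns `x`, `y`,
#'   `mean_angle` and optionally `sd_angle`, replacing packaged values
#'   for the listed points (coordinates in this laterality's field
#'   space).
#' @return An object of class `insertion_map`: data frame with columns
#'   `x`, `y`, `key`, `mean_angle` (degrees in [0, 360)), `sd_angle`
#'   (degrees > 0), plus attribute `laterality`.
#' @export
default_map <- function(laterality, sd_angle = 15, override = NULL) {
  laterality <- check_laterality(laterality)
  stopifnot(sd_angle > 0)
  grid <- grid_24_2(laterality)
  # evaluate the right-eye model at mirrored x for a left eye
  xr <- if (laterality == "right") grid$x else -grid$x
  mean_angle <- vapply(seq_len(nrow(grid)),
                       function(i) insertion_angle_right(xr[i], grid$y[i]), 0)
  map <- data.frame(x = grid$x, y = grid$y, key = grid$key,
                    mean_angle = mean_angle %% 360, sd_angle = sd_angle)
  if (!is.null(override)) {
    stopifnot(is.data.frame(override),
              all(c("x", "y", "mean_angle") %in% names(override)))
    m <- match(paste(override$x, override$y), paste(map$x, map$y))
    if (anyNA(m)) stop("override lists points not on the grid", call. = FALSE)
    map$mean_angle[m] <- override$mean_angle %% 360
    if ("sd_angle" %in% names(override)) map$sd_angle[m] <- override$sd_angle
  }
  if (any(map$sd_angle <= 0)) stop("sd_angle must be > 0", call. = FALSE)
  structure(map, laterality = laterality, class = c("insertion_map", "data.frame"))
}

# Geometric fiber-course heuristic, right-eye field coordinates.
# Retina: n = x (nasal+), v = -y (field superior -> retina inferior);
# disc center at (15.5, 1.5). Returns degrees, 0 = temporal pole,
# 90 = superior, wrapped to [0, 360).
insertion_angle_right <- function(x, y) {
  dn <- x - 15.5
  dv <- -y - 1.5
  if (dn >= 0) {                      # retina nasal of the disc: direct entry
    theta <- atan2(dv, -dn) * 180 / pi
  } else {                            # temporal: arcuate course
    beta <- atan2(dv, -dn) * 180 / pi # straight-line entry angle
    d <- sqrt(dn^2 + dv^2)
    warp <- 67 * (1 - exp(-max(0, d - 13) / 15))
    theta <- sign(beta) * min(abs(beta) + warp, 88)
    if (beta == 0) theta <- 0         # on the papillomacular axis
  }
  theta %% 360
}

#' Linkage probabilities of one field point over the disc sectors
#'
#' The nerve-fiber insertion angle of a field point is modelled as a
#' normal distribution on the disc circumference; the probability that
#' the point is linked to a sector is the mass of that (wrapped)
#' distribution falling in the sector's arc. The wrap is evaluated by
#' summing the plain normal CDF over +/-2 extra circle periods, exact to
#' well below 1e-12 for SDs up to 60 degrees.
#'
#' @param mean_angle mean insertion angle, degrees.
#' @param sd_angle SD of the insertion angle, degrees (> 0).
#' @param sectors sector arc table from [disc_sectors()].
#' @return Named probability 6-vector summing to 1.
#' @export
sector_probabilities <- function(mean_angle, sd_angle, sectors = disc_sectors()) {
  if (sd_angle <= 0) stop("sd_angle must be > 0", call. = FALSE)
  p <- vapply(seq_len(nrow(sectors)), function(i)
    wrapped_normal_arc_mass(mean_angle, sd_angle,
                            sectors$start[i], sectors$end[i]), 0)
  p <- pmax(p, 0)
  stats::setNames(p / sum(p), sectors$sector)
}

# P(N(mean, sd) mod 360 falls in the arc [start, end)), arcs may wrap 0;
# wrap handled by summing the plain CDF over +/-2 extra periods
wrapped_normal_arc_mass <- function(mean_angle, sd_angle, start, end) {
  mass_below <- function(a) {  # P(wrapped angle < a), a in [0, 360]
    k <- -2:2
    sum(stats::pnorm(a + 360 * k, mean_angle, sd_angle) -
        stats::pnorm(360 * k, mean_angle, sd_angle))
  }
  start <- start %% 360
  end_w <- end %% 360
  if (end == 360) end_w <- 360
  if (end_w > start) mass_below(end_w) - mass_below(start)
  else (mass_below(360) - mass_below(start)) + mass_below(end_w)
}

#' Build the full 52-point sector-linkage table
#'
#' @param map an [default_map()] insertion map.
#' @param sectors sector arc table from [disc_sectors()].
#' @return An object of class `sector_linkage`: 52 x 6 matrix of
#'   probabilities (rows sum to 1), rownames the grid keys, with
#'   attributes `laterality` and `map`.
#' @export
build_linkage <- function(map, sectors = disc_sectors()) {
  stopifnot(inherits(map, "insertion_map"))
  L <- t(vapply(seq_len(nrow(map)), function(i)
    sector_probabilities(map$mean_angle[i], map$sd_angle[i], sectors),
    numeric(nrow(sectors))))
  rownames(L) <- map$key
  structure(L, laterality = attr(map, "laterality"), map = map,
            class = c("sector_linkage", "matrix", "array"))
}

#' @export
print.sector_linkage <- function(x, ...) {
  cat(sprintf("<sector_linkage> %s eye, %d points x %d sectors\n",
              attr(x, "laterality"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read an insertion-map override file
#'
#' Plain CSV with columns `x`, `y`, `mean_angle` and optionally
#' `sd_angle`, suitable for the `override` argument of [default_map()].
#'
#' @param path CSV file path.
#' @return Data frame.
#' @export
read_map_override <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("x", "y", "mean_angle")
  if (!all(need %in% names(df)))
    stop("map override needs columns x, y, mean_angle", call. = FALSE)
  df
}
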