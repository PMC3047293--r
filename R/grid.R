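#' The standard 24-2 test-point lattice
#'
#' Enumerates the Humphrey 24-2 test locations in field coordinates
#' (x positive rightward, y positive superior, degrees of eccentricity,
#' for both eyes -- laterality is handled by per-laterality reference
#' models, never by mirroring stored data). The lattice has 54 locations;
#' the two at the physiologic blind spot (temporal 15 degree column,
#' y = +/-3) are excluded from scoring.
#'
#' @param laterality `"right"` or `"left"`.
#' @param include_blind_spot if `TRUE`, return the full 54-point lattice.
#' @return A data frame with columns `x`, `y` (degrees) and `key` (the
#'   `td_x_y` column key used by the cohort file format), 52 rows
#'   (54 with `include_blind_spot = TRUE`), ordered row-major from the
#'   superior row downwards, nasal extension included.
#' @examples
#' nrow(grid_24_2("right"))  # 52
#' @export
grid_24_2 <- function(laterality, include_blind_spot = FALSE) {
  laterality <- check_laterality(laterality)
  rows <- list(
    `21` = seq(-9, 9, by = 6),
    `15` = seq(-15, 15, by = 6),
    `9`  = seq(-21, 21, by = 6),
    `3`  = seq(-21, 21, by = 6)
  )
  # nasal horizontal rows extend to 27 degrees; nasal is away from the
  # blind spot, so negative x for a right eye, positive for a left eye
  nasal_x <- if (laterality == "right") -27 else 27
  pts <- do.call(rbind, lapply(c(21, 15, 9, 3), function(ay) {
    x <- rows[[as.character(ay)]]
    if (ay == 3) x <- sort(c(x, nasal_x))
    rbind(data.frame(x = x, y = ay), data.frame(x = x, y = -ay))
  }))
  # row-major, superior to inferior, left to right
  pts <- pts[order(-pts$y, pts$x), , drop = FALSE]
  if (!include_blind_spot) {
    bs <- blind_spot_24_2(laterality)
    keep <- !(paste(pts$x, pts$y) %in% paste(bs$x, bs$y))
    pts <- pts[keep, , drop = FALSE]
  }
  rownames(pts) <- NULL
  pts$key <- point_key(pts$x, pts$y)
  pts
}

#' Blind-spot locations of the 24-2 lattice
#'
#' @inheritParams grid_24_2
#' @return Data frame with the two unscored locations (temporal 15 degree
#'   column at y = +/-3).
#' @export
blind_spot_24_2 <- function(laterality) {
  laterality <- check_laterality(laterality)
  bx <- if (laterality == "right") 15 else -15
  data.frame(x = c(bx, bx), y = c(3, -3), key = point_key(c(bx, bx), c(3, -3)))
}

#' @noRd
point_key <- function(x, y) paste0("td_", x, "_", y)

#' @noRd
check_laterality <- function(laterality) {
  if (length(laterality) != 1L || !laterality %in% c("right", "left"))
    stop("laterality must be \"right\" or \"left\"", call. = FALSE)
  laterality
}

# ---------------------------------------------------------------------------
# GHT-style hemifield clusters

#' GHT-style hemifield clusters for the SFI Hemifield Test
#'
#' Partitions the 52 scored locations into 10 clusters: 5 in the superior
#' hemifield (regions 1-5, nasal to temporal) mirrored across the
#' horizontal meridian into 5 inferior partners. Cluster sizes follow the
#' Glaucoma Hemifield Test layout (3 to 6 points; region 1 is the 3-point
#' nasal-step cluster, region 4 the 6-point superior arcuate), so region
#' scores range up to 300 for region 1 and 600 for region 4. The default
#' table can be replaced by any partition with the same structure.
#'
#' @inheritParams grid_24_2
#' @param regions optional override: a data frame with columns
#'   `x`, `y`, `region` (1-5) covering all 26 superior points of the
#'   right-eye grid; it is mirrored vertically and, for a left eye,
#'   horizontally.
#' @return A data frame with columns `x`, `y`, `key`, `region` (1-5) and
#'   `hemifield` (`"superior"`/`"inferior"`), one row per scored location.
#' @export
ght_regions <- function(laterality, regions = NULL) {
  laterality <- check_laterality(laterality)
  sup <- if (is.null(regions)) default_ght_superior() else validate_ght_override(regions)
  inf <- transform(sup, y = -y)
  both <- rbind(cbind(sup, hemifield = "superior"),
                cbind(inf, hemifield = "inferior"))
  if (laterality == "left") both$x <- -both$x
  grid <- grid_24_2(laterality)
  m <- match(paste(grid$x, grid$y), paste(both$x, both$y))
  if (anyNA(m)) stop("region table does not cover the 24-2 grid", call. = FALSE)
  out <- cbind(grid, region = both$region[m], hemifield = both$hemifield[m])
  rownames(out) <- NULL
  out
}

# Superior-hemifield cluster membership, right-eye field coordinates.
# Nasal (negative x) to temporal; sizes 3, 6, 6, 6, 5.
default_ght_superior <- function() {
  reg <- list(
    `1` = list(c(-27, 3), c(-21, 3), c(-21, 9)),
    `2` = list(c(-15, 3), c(-9, 3), c(-15, 9), c(-9, 9), c(-15, 15), c(-9, 15)),
    `3` = list(c(-3, 3), c(3, 3), c(-3, 9), c(3, 9), c(-3, 15), c(3, 15)),
    `4` = list(c(-9, 21), c(-3, 21), c(3, 21), c(9, 21), c(9, 15), c(9, 9)),
    `5` = list(c(9, 3), c(21, 3), c(15, 9), c(21, 9), c(15, 15))
  )
  do.call(rbind, lapply(names(reg), function(r) {
    xy <- do.call(rbind, reg[[r]])
    data.frame(x = xy[, 1], y = xy[, 2], region = as.integer(r))
  }))
}

validate_ght_override <- function(regions) {
  stopifnot(is.data.frame(regions), all(c("x", "y", "region") %in% names(regions)))
  grid <- grid_24_2("right")
  sup <- grid[grid$y > 0, ]
  if (nrow(regions) != nrow(sup) ||
      !setequal(paste(regions$x, regions$y), paste(sup$x, sup$y)))
    stop("region override must cover exactly the 26 superior right-eye points",
         call. = FALSE)
  sizes <- table(regions$region)
  if (!setequal(names(sizes), as.character(1:5)) ||
      any(sizes < 3) || any(sizes > 6))
    stop("regions must be numbered 1-5 with 3 to 6 points each", call. = FALSE)
  regions[, c("x", "y", "region")]
}
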