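#' Optic-disc sector names
#'
#' The six sectors reported by the Heidelberg Retina Tomograph, in the
#' canonical order used throughout the package.
#' @return Character vector of length 6.
#' @export
disc_sector_names <- function() {
  c("temporal", "superotemporal", "superonasal",
    "nasal", "inferonasal", "inferotemporal")
}

#' Construct a validated per-eye record
#'
#' An `eye_record` bundles one eye's same-day visual field and optic disc
#' scan: 52 total-deviation values on the 24-2 grid, the global field
#' indices, and measured plus Moorfields-predicted rim area for the six
#' HRT sectors. The Moorfields prediction is an input (it already
#' normalises for disc area and age); this package never computes it.
#'
#' @param subject_id opaque subject identifier (character scalar).
#' @param laterality `"right"` or `"left"`.
#' @param td named numeric vector of total deviation (dB), one entry per
#'   scored 24-2 location, names as produced by [grid_24_2()] (`td_x_y`).
#' @param md,psd mean deviation and pattern standard deviation (dB).
#' @param rim,mra named numeric vectors (mm^2) over [disc_sector_names()]:
#'   measured rim area and Moorfields-predicted rim area.
#' @param group one of `"reference"`, `"suspect"`, `"glaucoma"`.
#' @param reliable,quality_acceptable logical flags (field reliability,
#'   HRT image quality).
#' @param ght_category,mfc_category optional device categorical outputs
#'   (`"within_normal_limits"`, `"borderline"`, `"outside_normal_limits"`,
#'   `"other"`), or `NA`.
#' @return An object of class `eye_record`.
#' @export
eye_record <- function(subject_id, laterality, td, md, psd, rim, mra,
                       group = "suspect",
                       reliable = TRUE, quality_acceptable = TRUE,
                       ght_category = NA_character_,
                       mfc_category = NA_character_) {
  laterality <- check_laterality(laterality)
  grid <- grid_24_2(laterality)
  if (is.null(names(td)) || !setequal(names(td), grid$key))
    stop("td must be named with the 52 grid keys for this laterality",
         call. = FALSE)
  td <- td[grid$key]
  if (any(!is.finite(td)))
    stop("all 52 total-deviation values must be finite", call. = FALSE)
  if (!is.finite(md) || !is.finite(psd))
    stop("md and psd must be finite", call. = FALSE)
  sec <- disc_sector_names()
  for (nm in c("rim", "mra")) {
    v <- get(nm)
    if (is.null(names(v)) || !setequal(names(v), sec))
      stop(nm, " must be named with the six disc sectors", call. = FALSE)
    if (any(!is.finite(v)) || any(v < 0))
      stop(nm, " areas must be finite and non-negative", call. = FALSE)
  }
  if (!group %in% c("reference", "suspect", "glaucoma"))
    stop("group must be reference, suspect or glaucoma", call. = FALSE)
  structure(list(
    subject_id = as.character(subject_id),
    laterality = laterality,
    td = td, md = md, psd = psd,
    rim = rim[sec], mra = mra[sec],
    group = group,
    reliable = isTRUE(reliable),
    quality_acceptable = isTRUE(quality_acceptable),
    ght_category = as.character(ght_category),
    mfc_category = as.character(mfc_category)
  ), class = "eye_record")
}

#' @export
print.eye_record <- function(x, ...) {
  cat(sprintf("<eye_record> subject %s, %s eye, group %s\n",
              x$subject_id, x$laterality, x$group))
  cat(sprintf("  MD %.2f dB, PSD %.2f dB; rim-MRA range [%.3f, %.3f] mm^2\n",
              x$md, x$psd, min(x$rim - x$mra), max(x$rim - x$mra)))
  invisible(x)
}

#' Per-sector rim-area difference
#'
#' Measured rim area minus the Moorfields-predicted rim area, per sector.
#' Negative values indicate less rim than predicted for the eye's disc
#' area and age, i.e. the structural abnormality signal.
#'
#' @param record an [eye_record()].
#' @return Named numeric vector (mm^2) over [disc_sector_names()].
#' @export
rim_area_difference <- function(record) {
  stopifnot(inherits(record, "eye_record"))
  record$rim - record$mra
}

# ---------------------------------------------------------------------------
# Cohort files: one row per eye, comma-delimited.

cohort_fixed_cols <- function() {
  c("subject_id", "laterality", "group", "md", "psd",
    "reliable", "quality_acceptable", "ght_category", "mfc_category")
}

#' Write a cohort to a delimited text file
#'
#' One row per eye. Fixed columns (`subject_id`, `laterality`, `group`,
#' `md`, `psd`, flags, device categories) are followed by the 52 `td_x_y`
#' total-deviation columns and `rim_<sector>` / `mra_<sector>` columns.
#' Numeric values are serialized at full double precision so that a
#' read/write round trip is exact.
#'
#' @param records list of [eye_record()] objects.
#' @param path output file path.
#' @return Invisibly, the path.
#' @export
write_cohort <- function(records, path) {
  sec <- disc_sector_names()
  # union of keys across lateralities so mixed cohorts share one header
  keys <- union(grid_24_2("right")$key, grid_24_2("left")$key)
  header <- c(cohort_fixed_cols(), keys, paste0("rim_", sec), paste0("mra_", sec))
  fmt <- function(x) {
    if (is.numeric(x)) vapply(x, function(v) sprintf("%.17g", v), "") else as.character(x)
  }
  rows <- vapply(records, function(r) {
    td_all <- stats::setNames(rep(NA_real_, length(keys)), keys)
    td_all[names(r$td)] <- r$td
    vals <- c(r$subject_id, r$laterality, r$group,
              fmt(r$md), fmt(r$psd),
              as.character(r$reliable), as.character(r$quality_acceptable),
              r$ght_category, r$mfc_category,
              fmt(unname(td_all)), fmt(unname(r$rim)), fmt(unname(r$mra)))
    paste(vals, collapse = ",")
  }, "")
  writeLines(c(paste(header, collapse = ","), rows), path)
  invisible(path)
}

#' Read a cohort file
#'
#' Reads the delimited format written by [write_cohort()]. Every returned
#' record satisfies the `eye_record` invariants; rows that fail validation
#' (missing sector, non-finite total deviation, bad laterality, ...) are
#' dropped and reported via a warning carrying the row number and reason.
#' A missing mandatory column is an error.
#'
#' @param path input file path.
#' @return List of [eye_record()] objects (possibly empty), with an
#'   attribute `rejected`: data frame of row numbers and reasons.
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        colClasses = "character")
  missing_cols <- setdiff(cohort_fixed_cols(), names(df))
  if (length(missing_cols))
    stop("cohort file missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sec <- disc_sector_names()
  records <- list()
  rejected <- data.frame(row = integer(), reason = character())
  num <- function(x) suppressWarnings(as.numeric(x))
  for (i in seq_len(nrow(df))) {
    row <- df[i, ]
    rec <- tryCatch({
      lat <- check_laterality(row$laterality)
      keys <- grid_24_2(lat)$key
      missing_td <- setdiff(keys, names(df))
      if (length(missing_td))
        stop("missing TD column(s): ", paste(missing_td, collapse = ", "))
      td <- stats::setNames(num(unlist(row[keys])), keys)
      rim <- stats::setNames(num(unlist(row[paste0("rim_", sec)])), sec)
      mra <- stats::setNames(num(unlist(row[paste0("mra_", sec)])), sec)
      eye_record(row$subject_id, lat, td,
                 md = num(row$md), psd = num(row$psd),
                 rim = rim, mra = mra, group = row$group,
                 reliable = identical(row$reliable, "TRUE"),
                 quality_acceptable = identical(row$quality_acceptable, "TRUE"),
                 ght_category = row$ght_category,
                 mfc_category = row$mfc_category)
    }, error = function(e) conditionMessage(e))
    if (inherits(rec, "eye_record")) {
      records[[length(records) + 1L]] <- rec
    } else {
      rejected <- rbind(rejected, data.frame(row = i, reason = rec))
    }
  }
  if (nrow(rejected))
    warning(sprintf("%d row(s) rejected; see attr(, \"rejected\")", nrow(rejected)),
            call. = FALSE)
  attr(records, "rejected") <- rejected
  records
}

#' Keep one eye per subject: the worse mean deviation
#'
#' For subjects contributing both eyes, retains the eye with the lower
#' (more negative) MD; single-eye subjects pass through. An exact MD tie
#' keeps the right eye (documented deterministic tie-break). Duplicate
#' (subject, laterality) pairs are an error.
#'
#' @param records list of [eye_record()] objects.
#' @return List of records, at most one per subject, in order of first
#'   appearance of each subject.
#' @export
select_worse_eye <- function(records) {
  ids <- vapply(records, `[[`, "", "subject_id")
  lats <- vapply(records, `[[`, "", "laterality")
  if (anyDuplicated(paste(ids, lats)))
    stop("duplicate (subject, laterality) pairs in cohort", call. = FALSE)
  out <- list()
  for (id in unique(ids)) {
    eyes <- records[ids == id]
    if (length(eyes) == 1L) { out[[length(out) + 1L]] <- eyes[[1L]]; next }
    md <- vapply(eyes, `[[`, 0, "md")
    if (any(!is.finite(md))) stop("non-finite MD for subject ", id, call. = FALSE)
    worst <- which(md == min(md))
    if (length(worst) > 1L)  # tie: keep the right eye
      worst <- worst[match("right", vapply(eyes[worst], `[[`, "", "laterality"))]
    out[[length(out) + 1L]] <- eyes[[worst]]
  }
  out
}
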