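# Annotation data model for small-bowel capsule endoscopy (SBCE) readings.
#
# The canonical container is a long "annotation table": one row per annotation
# (lesion or stenosis), with study-level fields repeated on every row. A study
# with no findings is represented by a single row with record_type "none".
# Any extra columns are treated as study-level covariates (e.g. cdai, crp)
# and carried through scoring unchanged.

.lesion_grades <- c(
  normal                              = 0L,
  edema_redness                       = 1L,
  erosion                             = 2L,
  irregular_circular_ulcer            = 3L,
  longitudinal_large_ulcer_cobblestone = 4L
)

.annotation_cols <- c(
  "study_id", "capsule_model", "sb_duration_s", "reached_colon",
  "record_type", "timestamp_s", "lesion_type", "traversed"
)

#' Lesion type vocabulary and inflammation grades
#'
#' The five mucosal inflammation grades used to score each small-bowel
#' quartile: 0 normal mucosa, 1 edematous/reddish, 2 erosion (<0.5 cm),
#' 3 irregular/circular ulcer (0.5--2 cm), 4 longitudinal/large ulcer or
#' cobblestone appearance.
#'
#' @return A named integer vector mapping lesion type to grade 0--4.
#' @export
#' @examples
#' lesion_types()
lesion_types <- function() .lesion_grades

#' Grade of a lesion type
#'
#' Maps each categorical lesion type onto its 0--4 inflammation grade.
#'
#' @param lesion_type Character vector of lesion types; see [lesion_types()].
#' @return Integer vector of grades, same length as the input.
#' @export
#' @examples
#' lesion_grade(c("normal", "erosion", "longitudinal_large_ulcer_cobblestone"))
lesion_grade <- function(lesion_type) {
  g <- .lesion_grades[as.character(lesion_type)]
  if (anyNA(g)) {
    bad <- unique(lesion_type[is.na(g)])
    stop("unknown lesion_type: ", paste(bad, collapse = ", "),
         " (valid: ", paste(names(.lesion_grades), collapse = ", "), ")",
         call. = FALSE)
  }
  unname(g)
}

#' Assign a timestamp to a small-bowel quartile
#'
#' Small-bowel transit (entry to exit, or entry to last image when the capsule
#' does not reach the colon) is divided into four equal quartiles. Quartiles
#' are half-open intervals: a timestamp at exactly 25/50/75% of transit belongs
#' to the later quartile, and the terminal timestamp is clamped into
#' quartile 4.
#'
#' @param timestamp Seconds since small-bowel entry (vectorised).
#' @param sb_duration Small-bowel transit duration in seconds (scalar or
#'   vector recycled against `timestamp`).
#' @return Integer vector of quartile indices in 1..4.
#' @export
#' @examples
#' assign_quartile(c(0, 250, 999, 1000), 1000)
assign_quartile <- function(timestamp, sb_duration) {
  stopifnot(is.numeric(timestamp), is.numeric(sb_duration))
  if (any(sb_duration <= 0)) {
    stop("sb_duration must be > 0", call. = FALSE)
  }
  bad <- timestamp < 0 | timestamp > sb_duration
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    stop("timestamp outside [0, sb_duration]: ",
         paste(utils::head(timestamp[is.na(bad) | bad], 5), collapse = ", "),
         call. = FALSE)
  }
  as.integer(pmin(floor(4 * timestamp / sb_duration) + 1, 4))
}

#' Assign a timestamp to a small-bowel tertile
#'
#' Tertile analogue of [assign_quartile()], used by the Lewis Score, with the
#' same half-open boundary convention and terminal clamp.
#'
#' @inheritParams assign_quartile
#' @return Integer vector of tertile indices in 1..3.
#' @export
#' @examples
#' tertile_of(c(0, 300, 900), 900)
tertile_of <- function(timestamp, sb_duration) {
  stopifnot(is.numeric(timestamp), is.numeric(sb_duration))
  if (any(sb_duration <= 0)) stop("sb_duration must be > 0", call. = FALSE)
  bad <- timestamp < 0 | timestamp > sb_duration
  if (any(bad, na.rm = TRUE) || anyNA(bad)) {
    stop("timestamp outside [0, sb_duration]: ",
         paste(utils::head(timestamp[is.na(bad) | bad], 5), collapse = ", "),
         call. = FALSE)
  }
  as.integer(pmin(floor(3 * timestamp / sb_duration) + 1, 3))
}

#' Build the annotation rows for one SBCE study
#'
#' Convenience constructor assembling the long annotation table for a single
#' capsule session from its lesion and stenosis annotations.
#'
#' @param study_id Study identifier (string).
#' @param sb_duration_s Small-bowel transit duration in seconds (> 0). For an
#'   incomplete study this is entry to last image.
#' @param lesions Data frame with columns `timestamp_s` and `lesion_type`, or
#'   `NULL` for a lesion-free study.
#' @param stenoses Data frame with columns `timestamp_s` and `traversed`
#'   (logical), or `NULL`.
#' @param reached_colon Did the capsule reach the colon? Default `TRUE`.
#' @param capsule_model `"SB2"` or `"SB3"`; metadata only, never alters
#'   scoring.
#' @param covariates Optional named list of study-level covariates (e.g.
#'   `list(cdai = 150)`) added as extra columns.
#' @return A validated annotation tibble (one row per annotation; a single
#'   `record_type = "none"` row if the study has no findings).
#' @export
#' @examples
#' sbce_study("s1", 14400,
#'   lesions = data.frame(timestamp_s = c(600, 4000), lesion_type = "erosion"))
sbce_study <- function(study_id, sb_duration_s, lesions = NULL,
                       stenoses = NULL, reached_colon = TRUE,
                       capsule_model = "SB3", covariates = NULL) {
  rows <- list()
  if (!is.null(lesions) && nrow(lesions) > 0) {
    rows$lesion <- tibble::tibble(
      record_type = "lesion",
      timestamp_s = as.numeric(lesions$timestamp_s),
      lesion_type = as.character(lesions$lesion_type),
      traversed   = NA
    )
  }
  if (!is.null(stenoses) && nrow(stenoses) > 0) {
    rows$stenosis <- tibble::tibble(
      record_type = "stenosis",
      timestamp_s = as.numeric(stenoses$timestamp_s),
      lesion_type = NA_character_,
      traversed   = as.logical(stenoses$traversed)
    )
  }
  ann <- if (length(rows) == 0) {
    tibble::tibble(record_type = "none", timestamp_s = NA_real_,
                   lesion_type = NA_character_, traversed = NA)
  } else {
    dplyr::bind_rows(rows)
  }
  out <- dplyr::mutate(
    ann,
    study_id      = as.character(study_id),
    capsule_model = as.character(capsule_model),
    sb_duration_s = as.numeric(sb_duration_s),
    reached_colon = as.logical(reached_colon),
    .before = 1
  )
  for (nm in names(covariates)) out[[nm]] <- covariates[[nm]]
  validate_annotations(out)
}

#' Validate an annotation table
#'
#' Checks the schema and invariants of the long annotation table: required
#' columns, positive small-bowel duration, timestamps within
#' `[0, sb_duration_s]`, known lesion types, consistent study-level fields,
#' logical `traversed` for stenoses.
#'
#' @param annotations An annotation tibble as produced by [sbce_study()],
#'   [read_annotations()] or [simulate_cohort()].
#' @return The validated annotations, invisibly coerced to a tibble.
#' @export
validate_annotations <- function(annotations) {
  x <- tibble::as_tibble(annotations)
  missing_cols <- setdiff(.annotation_cols, names(x))
  if (length(missing_cols) > 0) {
    stop("annotation table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(x) == 0) stop("annotation table has no rows", call. = FALSE)
  bad_row <- function(cond, msg) {
    if (any(cond, na.rm = TRUE)) {
      stop(msg, " (rows ",
           paste(utils::head(which(cond), 10), collapse = ", "), ")",
           call. = FALSE)
    }
  }
  bad_row(!x$record_type %in% c("lesion", "stenosis", "none"),
          "record_type must be lesion, stenosis or none")
  bad_row(is.na(x$study_id) | x$study_id == "", "study_id must be non-empty")
  bad_row(is.na(x$sb_duration_s) | x$sb_duration_s <= 0,
          "sb_duration_s must be > 0")
  bad_row(is.na(x$reached_colon), "reached_colon must be TRUE/FALSE")
  ann <- x$record_type != "none"
  bad_row(ann & (is.na(x$timestamp_s) | x$timestamp_s < 0 |
                   x$timestamp_s > x$sb_duration_s),
          "timestamp_s must lie in [0, sb_duration_s]")
  les <- x$record_type == "lesion"
  bad_row(les & !(x$lesion_type %in% names(.lesion_grades)),
          "unknown lesion_type")
  ste <- x$record_type == "stenosis"
  bad_row(ste & is.na(x$traversed), "traversed must be TRUE/FALSE for stenoses")
  # study-level fields must be constant within a study
  meta <- dplyr::distinct(x, .data$study_id, .data$sb_duration_s,
                          .data$reached_colon, .data$capsule_model)
  if (anyDuplicated(meta$study_id)) {
    dup <- meta$study_id[duplicated(meta$study_id)]
    stop("inconsistent study-level fields for study: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  x
}

#' Per-quartile inflammation profile of each study
#'
#' Collapses the lesion annotations of each study onto its four small-bowel
#' quartiles. A quartile is characterised by its worst finding: the grade is
#' the maximum lesion grade among lesions assigned to it (0 when none), not a
#' lesion count.
#'
#' @inheritParams validate_annotations
#' @return A tibble with one row per study: `study_id`, study metadata,
#'   covariate columns, and quartile grades `q1`..`q4` (integers 0--4).
#' @export
#' @examples
#' s <- sbce_study("s1", 1000,
#'   lesions = data.frame(timestamp_s = 100, lesion_type = "erosion"))
#' quartile_profile(s)
quartile_profile <- function(annotations) {
  x <- validate_annotations(annotations)
  meta <- dplyr::distinct(
    x, dplyr::across(dplyr::all_of(setdiff(
      names(x), c("record_type", "timestamp_s", "lesion_type", "traversed"))))
  )
  les <- dplyr::filter(x, .data$record_type == "lesion")
  grades <- if (nrow(les) > 0) {
    les |>
      dplyr::mutate(
        quartile = assign_quartile(.data$timestamp_s, .data$sb_duration_s),
        grade = lesion_grade(.data$lesion_type)
      ) |>
      dplyr::group_by(.data$study_id, .data$quartile) |>
      dplyr::summarise(grade = max(.data$grade), .groups = "drop") |>
      tidyr::pivot_wider(names_from = "quartile", values_from = "grade",
                         names_prefix = "q", values_fill = 0L)
  } else {
    tibble::tibble(study_id = character())
  }
  out <- dplyr::left_join(meta, grades, by = "study_id")
  for (q in paste0("q", 1:4)) {
    if (!q %in% names(out)) out[[q]] <- 0L
    out[[q]] <- as.integer(dplyr::coalesce(out[[q]], 0L))
  }
  dplyr::relocate(out, dplyr::all_of(paste0("q", 1:4)),
                  .after = dplyr::last_col())
}
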