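# Comparator scores: the Lewis Score (tertile-based villous edema + ulcer
# subscores, worst tertile, plus an independent stenosis term) and the CECDAI
# (two-segment inflammation x extent + stricture, summed). Both accept their
# native findings tables; approximate adapters from the annotation model are
# provided for cross-score analyses on the same cohort.

.pkg_env <- new.env(parent = emptyenv())

#' Lewis Score descriptor point table
#'
#' The closed descriptor vocabularies of the Lewis system with their point
#' values, shipped as a plain-text data file so the transcription from the
#' original publication is auditable. Class `none` (0 points) is the
#' empty-finding placeholder for extent/descriptor/size columns.
#'
#' @return A tibble with columns `parameter`, `class`, `points`.
#' @export
lewis_points <- function() {
  if (is.null(.pkg_env$lewis_points)) {
    path <- system.file("extdata", "lewis_score_points.csv", package = "cdace",
                        mustWork = TRUE)
    .pkg_env$lewis_points <- readr::read_csv(
      path, col_types = readr::cols(parameter = "c", class = "c", points = "i"))
  }
  .pkg_env$lewis_points
}

.lewis_lookup <- function(parameter, class) {
  tab <- lewis_points()
  tab <- tab[tab$parameter == parameter, ]
  pts <- tab$points[match(as.character(class), tab$class)]
  if (anyNA(pts)) {
    bad <- unique(class[is.na(pts)])
    stop("unknown Lewis ", parameter, " class: ",
         paste(bad, collapse = ", "), " (valid: ",
         paste(tab$class, collapse = ", "), ")", call. = FALSE)
  }
  pts
}

#' Lewis Score
#'
#' Per tertile, the villous-edema subscore is the product of its number,
#' longitudinal-extent and descriptor points, and the ulcer subscore the
#' product of its number, extent and size points; the tertile score is their
#' sum. The Lewis Score is the worst (maximum) tertile score plus an
#' independent whole-study stenosis term (product of stenosis number,
#' ulcerated and traversed points).
#'
#' @param tertiles Data frame of tertile findings with columns `tertile`
#'   (1..3), `villous_number`, `villous_extent`, `villous_descriptor`,
#'   `ulcer_number`, `ulcer_extent`, `ulcer_size` (classes per
#'   [lewis_points()]), and optionally `study_id` for a multi-study table.
#' @param stenosis Data frame with columns `stenosis_number`,
#'   `stenosis_ulcerated`, `stenosis_traversed` (one row per study, with
#'   `study_id` when `tertiles` has it).
#' @return A tibble with `study_id` (if supplied) and `lewis`.
#' @export
#' @examples
#' t3 <- data.frame(tertile = 1:3,
#'   villous_number = "normal", villous_extent = "none",
#'   villous_descriptor = "none", ulcer_number = c("single", "none", "none"),
#'   ulcer_extent = c("short_segment", "none", "none"),
#'   ulcer_size = c("lt_quarter", "none", "none"))
#' st <- data.frame(stenosis_number = "none", stenosis_ulcerated = "none",
#'   stenosis_traversed = "none")
#' lewis_score(t3, st)   # 3 * 5 * 9 = 135
lewis_score <- function(tertiles, stenosis) {
  tertiles <- tibble::as_tibble(tertiles)
  stenosis <- tibble::as_tibble(stenosis)
  has_id <- "study_id" %in% names(tertiles)
  if (!has_id) {
    tertiles$study_id <- "study"
    stenosis$study_id <- "study"
  }
  cnt <- dplyr::count(tertiles, .data$study_id)
  if (any(cnt$n != 3)) {
    stop("exactly 3 tertile findings are required per study (study ",
         cnt$study_id[cnt$n != 3][1], " has ", cnt$n[cnt$n != 3][1], ")",
         call. = FALSE)
  }
  tert <- tertiles |>
    dplyr::mutate(
      villous = .lewis_lookup("villous_number", .data$villous_number) *
        .lewis_lookup("villous_extent", .data$villous_extent) *
        .lewis_lookup("villous_descriptor", .data$villous_descriptor),
      ulcer = .lewis_lookup("ulcer_number", .data$ulcer_number) *
        .lewis_lookup("ulcer_extent", .data$ulcer_extent) *
        .lewis_lookup("ulcer_size", .data$ulcer_size)
    ) |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(worst_tertile = max(.data$villous + .data$ulcer),
                     .groups = "drop")
  sten <- stenosis |>
    dplyr::mutate(stenosis_term =
      .lewis_lookup("stenosis_number", .data$stenosis_number) *
      .lewis_lookup("stenosis_ulcerated", .data$stenosis_ulcerated) *
      .lewis_lookup("stenosis_traversed", .data$stenosis_traversed)) |>
    dplyr::select("study_id", "stenosis_term")
  out <- tert |>
    dplyr::left_join(sten, by = "study_id") |>
    dplyr::mutate(
      stenosis_term = dplyr::coalesce(.data$stenosis_term, 0L),
      lewis = as.integer(.data$worst_tertile + .data$stenosis_term)) |>
    dplyr::select("study_id", "lewis")
  if (!has_id) out$study_id <- NULL
  out
}

#' CECDAI score
#'
#' The small bowel is divided into proximal and distal segments by transit
#' time. Per segment the subscore is inflammation (A, 0--5) times extent
#' (B, 0--3) plus stricture (C, 0--3); the CECDAI is the sum of the two
#' segment subscores, range 0--36.
#'
#' @param segments Data frame with columns `segment`
#'   (`"proximal"`/`"distal"`), `inflammation` (0--5), `extent` (0--3),
#'   `stricture` (0--3), and optionally `study_id`.
#' @return A tibble with `study_id` (if supplied) and `cecdai`.
#' @export
#' @examples
#' seg <- data.frame(segment = c("proximal", "distal"),
#'   inflammation = c(2, 0), extent = c(1, 0), stricture = c(0, 0))
#' cecdai_score(seg)   # 2
cecdai_score <- function(segments) {
  x <- tibble::as_tibble(segments)
  has_id <- "study_id" %in% names(x)
  if (!has_id) x$study_id <- "study"
  if (!all(x$segment %in% c("proximal", "distal"))) {
    stop("segment must be 'proximal' or 'distal'", call. = FALSE)
  }
  chk <- function(v, lo, hi, nm) {
    if (any(is.na(v) | v < lo | v > hi | v != round(v))) {
      stop(nm, " must be an integer in ", lo, "..", hi, call. = FALSE)
    }
  }
  chk(x$inflammation, 0, 5, "inflammation (A)")
  chk(x$extent, 0, 3, "extent (B)")
  chk(x$stricture, 0, 3, "stricture (C)")
  cnt <- dplyr::count(x, .data$study_id)
  if (any(cnt$n != 2)) {
    stop("exactly one proximal and one distal findings row per study",
         call. = FALSE)
  }
  out <- x |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(
      cecdai = as.integer(sum(.data$inflammation * .data$extent +
                                .data$stricture)),
      .groups = "drop")
  if (!has_id) out$study_id <- NULL
  out
}

# Monotone map from the 0-4 quartile inflammation grade onto the CECDAI
# inflammation scale A (0-5): edema -> 1, erosion -> 3 (aphthae/erosion),
# 0.5-2 cm ulcer -> 4 (moderate ulcer), longitudinal/cobblestone -> 5.
.grade_to_cecdai_a <- c(`0` = 0L, `1` = 1L, `2` = 3L, `3` = 4L, `4` = 5L)

#' Approximate Lewis findings from CDACE-style annotations
#'
#' Maps the annotation model onto native Lewis findings. The mapping is
#' approximate and deliberately conservative: the annotation model records a
#' single categorical grade per lesion and carries no villous-edema extent or
#' ulcer longitudinal extent, so fixed conventions are used (grade-1 lesions
#' become short-segment edema, single vs patchy by count; grade >= 2 lesions
#' become ulcers, number class by count, size class by grade). Use native
#' findings tables when they are available.
#'
#' @inheritParams validate_annotations
#' @return A list with elements `tertiles` and `stenosis`, ready for
#'   [lewis_score()].
#' @export
as_lewis_findings <- function(annotations) {
  x <- validate_annotations(annotations)
  ids <- unique(x$study_id)
  les <- x |>
    dplyr::filter(.data$record_type == "lesion") |>
    dplyr::mutate(tertile = tertile_of(.data$timestamp_s, .data$sb_duration_s),
                  grade = lesion_grade(.data$lesion_type))
  base <- tidyr::expand_grid(study_id = ids, tertile = 1:3)
  tert <- les |>
    dplyr::group_by(.data$study_id, .data$tertile) |>
    dplyr::summarise(
      n_edema = sum(.data$grade == 1),
      n_ulcer = sum(.data$grade >= 2),
      max_grade = max(c(0L, .data$grade[.data$grade >= 2])),
      .groups = "drop") |>
    dplyr::right_join(base, by = c("study_id", "tertile")) |>
    dplyr::mutate(
      n_edema = dplyr::coalesce(.data$n_edema, 0L),
      n_ulcer = dplyr::coalesce(.data$n_ulcer, 0L),
      max_grade = dplyr::coalesce(.data$max_grade, 0L),
      villous_number = ifelse(.data$n_edema > 0, "edematous", "normal"),
      villous_extent = ifelse(.data$n_edema > 0, "short_segment", "none"),
      villous_descriptor = dplyr::case_when(
        .data$n_edema == 0 ~ "none",
        .data$n_edema == 1 ~ "single",
        .default = "patchy"),
      ulcer_number = dplyr::case_when(
        .data$n_ulcer == 0 ~ "none",
        .data$n_ulcer == 1 ~ "single",
        .data$n_ulcer <= 3 ~ "few",
        .default = "multiple"),
      ulcer_extent = ifelse(.data$n_ulcer > 0, "short_segment", "none"),
      ulcer_size = dplyr::case_when(
        .data$n_ulcer == 0 ~ "none",
        .data$max_grade == 2 ~ "lt_quarter",
        .data$max_grade == 3 ~ "quarter_to_half",
        .default = "gt_half")
    ) |>
    dplyr::select("study_id", "tertile", dplyr::starts_with("villous_"),
                  dplyr::starts_with("ulcer_")) |>
    dplyr::arrange(.data$study_id, .data$tertile)
  any_ulcer <- les |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(ulcerated = any(.data$grade >= 2), .groups = "drop")
  sten <- x |>
    dplyr::filter(.data$record_type == "stenosis") |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(n_sten = dplyr::n(),
                     all_traversed = all(.data$traversed), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(study_id = ids), by = "study_id") |>
    dplyr::left_join(any_ulcer, by = "study_id") |>
    dplyr::mutate(
      n_sten = dplyr::coalesce(.data$n_sten, 0L),
      ulcerated = dplyr::coalesce(.data$ulcerated, FALSE),
      stenosis_number = dplyr::case_when(
        .data$n_sten == 0 ~ "none",
        .data$n_sten == 1 ~ "single",
        .default = "multiple"),
      stenosis_ulcerated = dplyr::case_when(
        .data$n_sten == 0 ~ "none",
        .data$ulcerated ~ "ulcerated",
        .default = "nonulcerated"),
      stenosis_traversed = dplyr::case_when(
        .data$n_sten == 0 ~ "none",
        .data$all_traversed ~ "traversed",
        .default = "not_traversed")
    ) |>
    dplyr::select("study_id", dplyr::starts_with("stenosis_"))
  list(tertiles = tert, stenosis = sten)
}

#' Approximate CECDAI findings from CDACE-style annotations
#'
#' Maps the annotation model onto native CECDAI segment findings. Proximal =
#' first half of small-bowel transit, distal = second half. Inflammation (A)
#' is a fixed monotone map of the worst lesion grade in the segment; extent
#' (B) counts the inflamed quartiles within the segment (0--2, saturating at
#' 3 for many lesions); stricture (C) is 1 for a single traversed stenosis,
#' 2 for multiple traversed, 3 for any non-traversed. Approximate; use native
#' findings when available.
#'
#' @inheritParams validate_annotations
#' @return A segments tibble ready for [cecdai_score()].
#' @export
as_cecdai_findings <- function(annotations) {
  x <- validate_annotations(annotations)
  ids <- unique(x$study_id)
  base <- tidyr::expand_grid(study_id = ids,
                             segment = c("proximal", "distal"))
  les <- x |>
    dplyr::filter(.data$record_type == "lesion") |>
    dplyr::mutate(
      quartile = assign_quartile(.data$timestamp_s, .data$sb_duration_s),
      segment = dplyr::if_else(.data$quartile <= 2, "proximal", "distal"),
      grade = lesion_grade(.data$lesion_type)) |>
    dplyr::group_by(.data$study_id, .data$segment) |>
    dplyr::summarise(
      max_grade = max(c(0L, .data$grade)),
      n_quart = dplyr::n_distinct(.data$quartile[.data$grade > 0]),
      n_lesions = sum(.data$grade > 0),
      .groups = "drop")
  sten <- x |>
    dplyr::filter(.data$record_type == "stenosis") |>
    dplyr::mutate(
      quartile = assign_quartile(.data$timestamp_s, .data$sb_duration_s),
      segment = dplyr::if_else(.data$quartile <= 2, "proximal", "distal")) |>
    dplyr::group_by(.data$study_id, .data$segment) |>
    dplyr::summarise(n_sten = dplyr::n(),
                     all_traversed = all(.data$traversed), .groups = "drop")
  base |>
    dplyr::left_join(les, by = c("study_id", "segment")) |>
    dplyr::left_join(sten, by = c("study_id", "segment")) |>
    dplyr::mutate(
      max_grade = dplyr::coalesce(.data$max_grade, 0L),
      n_quart = dplyr::coalesce(.data$n_quart, 0L),
      n_lesions = dplyr::coalesce(.data$n_lesions, 0L),
      n_sten = dplyr::coalesce(.data$n_sten, 0L),
      all_traversed = dplyr::coalesce(.data$all_traversed, TRUE),
      inflammation = unname(.grade_to_cecdai_a[as.character(.data$max_grade)]),
      extent = pmin(.data$n_quart + as.integer(.data$n_lesions > 4), 3L),
      stricture = dplyr::case_when(
        .data$n_sten == 0 ~ 0L,
        !.data$all_traversed ~ 3L,
        .data$n_sten >= 2 ~ 2L,
        .default = 1L)
    ) |>
    dplyr::select("study_id", "segment", "inflammation", "extent",
                  "stricture") |>
    dplyr::arrange(.data$study_id, dplyr::desc(.data$segment))
}
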