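# The CDACE composite score: Li (location inflammation), R (range),
# S (stenosis), the positional composite Li*100 + R*10 + S, and its decoding.

.as_grade_matrix <- function(grades) {
  if (is.data.frame(grades)) {
    qcols <- paste0("q", 1:4)
    if (!all(qcols %in% names(grades))) {
      stop("data-frame input must have columns q1..q4", call. = FALSE)
    }
    grades <- as.matrix(grades[qcols])
  } else if (is.null(dim(grades))) {
    if (length(grades) != 4) {
      stop("a quartile profile has exactly 4 grades", call. = FALSE)
    }
    grades <- matrix(grades, nrow = 1)
  }
  if (ncol(grades) != 4) {
    stop("a quartile profile has exactly 4 grades", call. = FALSE)
  }
  if (any(is.na(grades)) || any(grades != round(grades)) ||
      any(grades < 0) || any(grades > 4)) {
    stop("quartile grades must be integers in 0..4", call. = FALSE)
  }
  grades
}

#' Location inflammation (Li) score
#'
#' Sum of the four per-quartile inflammation grades, range 0--16.
#'
#' @param grades A quartile profile: numeric vector of length 4, an n-by-4
#'   matrix, or a data frame with columns `q1`..`q4` (e.g. from
#'   [quartile_profile()]).
#' @return Integer vector of Li scores.
#' @export
#' @examples
#' li_score(c(3, 3, 0, 0))
li_score <- function(grades) {
  as.integer(rowSums(.as_grade_matrix(grades)))
}

#' Range (R) score
#'
#' Number of small-bowel quartiles containing inflammatory lesions
#' (grade > 0), range 0--4.
#'
#' @inheritParams li_score
#' @return Integer vector of R scores.
#' @export
#' @examples
#' r_score(c(3, 3, 0, 0))
r_score <- function(grades) {
  as.integer(rowSums(.as_grade_matrix(grades) > 0))
}

#' Stenosis (S) score
#'
#' Grades the stenosis status of the whole small intestine for one study:
#' 0 no stenosis, 1 single passage, 2 multiple passages, 3 no passage. A
#' stenosis the capsule did not traverse, or an incomplete study in the
#' presence of any stenosis, scores 3.
#'
#' @param traversed Logical vector with one entry per stenosis annotation
#'   (`TRUE` if the capsule passed through); `logical(0)` when the study has
#'   no stenosis.
#' @param reached_colon Did the capsule reach the colon? Default `TRUE`.
#' @return Integer S score in 0..3.
#' @export
#' @examples
#' s_score(logical(0))          # 0: no stenosis
#' s_score(TRUE)                # 1: single passage
#' s_score(c(TRUE, TRUE))       # 2: multiple passages
#' s_score(c(TRUE, FALSE))      # 3: no passage
s_score <- function(traversed, reached_colon = TRUE) {
  stopifnot(is.logical(traversed), !anyNA(traversed),
            is.logical(reached_colon), length(reached_colon) == 1)
  n <- length(traversed)
  if (n == 0) return(0L)
  if (any(!traversed) || !reached_colon) return(3L)
  if (n >= 2) 2L else 1L
}

.check_triple <- function(li, r, s, where = "") {
  ok_range <- li >= 0 & li <= 16 & r >= 0 & r <= 4 & s >= 0 & s <= 3 &
    li == round(li) & r == round(r) & s == round(s)
  if (any(!ok_range)) {
    stop("component out of range", where, ": (li, r, s) = (",
         li[!ok_range][1], ", ", r[!ok_range][1], ", ", s[!ok_range][1], ")",
         call. = FALSE)
  }
  # r = 0 iff li = 0, and with r > 0 quartile grades 1..4 force r <= li <= 4r
  ok_cons <- ifelse(r == 0, li == 0, li >= r & li <= 4 * r)
  if (any(!ok_cons)) {
    stop("inconsistent (li, r) pair", where, ": li = ", li[!ok_cons][1],
         ", r = ", r[!ok_cons][1],
         " (requires r = 0 iff li = 0, and r <= li <= 4r)", call. = FALSE)
  }
  invisible(TRUE)
}

#' Compose the CDACE score from its components
#'
#' `CDACE = Li * 100 + R * 10 + S`, range 0--1643. The decimal digits of the
#' composite are readable: the first two digits are Li, the third R and the
#' fourth S.
#'
#' @param li Li score(s), 0--16.
#' @param r R score(s), 0--4.
#' @param s S score(s), 0--3.
#' @return Integer composite score(s) in 0..1643.
#' @export
#' @examples
#' compose_cdace(6, 2, 0)    # 620
#' compose_cdace(16, 4, 3)   # 1643, the maximum
compose_cdace <- function(li, r, s) {
  .check_triple(li, r, s)
  as.integer(li * 100 + r * 10 + s)
}

#' Decode a CDACE composite into (Li, R, S)
#'
#' Positional-digit interpretation: first two digits Li, third digit R,
#' fourth digit S. Only composites producible by [compose_cdace()] from a
#' consistent triple are accepted; the codomain is sparse in 0..1643, so e.g.
#' 1253 (R digit 5) is rejected.
#'
#' @param composite Integer vector of composite scores.
#' @return A tibble with columns `composite`, `li`, `r`, `s`, `severity` and
#'   `display`.
#' @export
#' @examples
#' decode_cdace(c(620, 1643))
decode_cdace <- function(composite) {
  stopifnot(is.numeric(composite), !anyNA(composite))
  if (any(composite != round(composite) | composite < 0 | composite > 1643)) {
    stop("composite must be an integer in 0..1643", call. = FALSE)
  }
  composite <- as.integer(composite)
  li <- composite %/% 100L
  r <- (composite %% 100L) %/% 10L
  s <- composite %% 10L
  for (i in seq_along(composite)) {
    .check_triple(li[i], r[i], s[i],
                  where = paste0(" decoding composite ", composite[i]))
  }
  tibble::tibble(
    composite = composite, li = li, r = r, s = s,
    severity = severity_index(li, r),
    display = format_cdace(composite)
  )
}

#' Severity-of-inflammation index
#'
#' Li divided by R: the mean inflammation grade of the inflamed quartiles
#' (the first two digits of the composite divided by the third). Defined as 0
#' for a lesion-free study (Li = R = 0).
#'
#' @param li Li score(s), 0--16.
#' @param r R score(s), 0--4.
#' @return Numeric severity index in \[0, 4\].
#' @export
#' @examples
#' severity_index(6, 2)   # 3
severity_index <- function(li, r) {
  .check_triple(li, r, s = 0)
  ifelse(r == 0, 0, li / r)
}

#' Zero-padded display form of a CDACE score
#'
#' @param composite Integer composite score(s) in 0..1643.
#' @return Character vector of 4-character zero-padded strings.
#' @export
#' @examples
#' format_cdace(620)   # "0620"
format_cdace <- function(composite) {
  stopifnot(is.numeric(composite), !anyNA(composite),
            all(composite >= 0), all(composite <= 1643),
            all(composite == round(composite)))
  sprintf("%04d", as.integer(composite))
}

#' Enumerate all consistent (Li, R, S) triples
#'
#' The full codomain of [compose_cdace()]: every triple with Li in 0..16,
#' R in 0..4, S in 0..3 satisfying R = 0 iff Li = 0 and R <= Li <= 4R.
#'
#' @return A tibble with columns `li`, `r`, `s`, `composite`, sorted by
#'   composite.
#' @export
cdace_triples <- function() {
  g <- tidyr::expand_grid(li = 0:16, r = 0:4, s = 0:3)
  g <- dplyr::filter(
    g, ifelse(.data$r == 0, .data$li == 0,
              .data$li >= .data$r & .data$li <= 4 * .data$r))
  g$composite <- as.integer(g$li * 100 + g$r * 10 + g$s)
  dplyr::arrange(g, .data$composite)
}

#' Score a cohort of SBCE studies with CDACE
#'
#' Full pipeline from annotations to the composite: quartile profile, Li, R
#' and S components, composite, display string and severity index, one row
#' per study.
#'
#' An incomplete study (capsule did not reach the colon) with at least one
#' stenosis annotation scores S = 3 (no passage). An incomplete study with no
#' stenosis annotation (e.g. battery exhaustion) is not silently inflated:
#' S keeps its annotation-derived value and the study is flagged
#' `incomplete_no_stenosis`, with a warning.
#'
#' @inheritParams validate_annotations
#' @return A tibble of class `cdace_scores`, one row per study: metadata and
#'   covariates, `q1`..`q4`, `li`, `r`, `s`, `cdace`, `display`, `severity`,
#'   `flags`.
#' @export
#' @examples
#' s <- sbce_study("s1", 1000, lesions = data.frame(
#'   timestamp_s = c(100, 300), lesion_type = "irregular_circular_ulcer"))
#' score_cdace(s)
score_cdace <- function(annotations) {
  x <- validate_annotations(annotations)
  prof <- quartile_profile(x)
  sten <- x |>
    dplyr::filter(.data$record_type == "stenosis") |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(traversed = list(.data$traversed), .groups = "drop")
  out <- prof |>
    dplyr::left_join(sten, by = "study_id") |>
    dplyr::mutate(
      traversed = purrr::map(.data$traversed, \(tr) tr %||% logical(0)),
      li = li_score(dplyr::pick(dplyr::all_of(paste0("q", 1:4)))),
      r  = r_score(dplyr::pick(dplyr::all_of(paste0("q", 1:4)))),
      s  = purrr::map2_int(.data$traversed, .data$reached_colon, s_score),
      cdace = compose_cdace(.data$li, .data$r, .data$s),
      display = format_cdace(.data$cdace),
      severity = severity_index(.data$li, .data$r),
      flags = ifelse(!.data$reached_colon & lengths(.data$traversed) == 0,
                     "incomplete_no_stenosis", "")
    ) |>
    dplyr::select(-"traversed")
  if (any(out$flags == "incomplete_no_stenosis")) {
    warning("incomplete study without stenosis annotation (S not forced ",
            "to 3): ",
            paste(out$study_id[out$flags == "incomplete_no_stenosis"],
                  collapse = ", "), call. = FALSE)
  }
  class(out) <- c("cdace_scores", class(out))
  out
}
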