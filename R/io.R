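# Readers and writers for the annotation table (CSV and JSON dialects, both
# lossless round-trips) and the deterministic cohort report.

.csv_col_types <- function() {
  readr::cols(
    study_id = readr::col_character(),
    capsule_model = readr::col_character(),
    sb_duration_s = readr::col_double(),
    reached_colon = readr::col_logical(),
    record_type = readr::col_character(),
    timestamp_s = readr::col_double(),
    lesion_type = readr::col_character(),
    traversed = readr::col_logical(),
    .default = readr::col_guess()
  )
}

.guess_format <- function(path, format) {
  if (format != "auto") return(format)
  if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
}

#' Read SBCE annotations from CSV or JSON
#'
#' CSV dialect: one row per annotation with columns `study_id`,
#' `capsule_model`, `sb_duration_s`, `reached_colon`, `record_type`
#' (`lesion`/`stenosis`/`none`), `timestamp_s`, `lesion_type`, `traversed`;
#' extra columns are carried as study-level covariates. JSON dialect: an
#' array of study objects with nested `lesions` and `stenoses` arrays. Both
#' encode the same data model and round-trip losslessly.
#'
#' @param path Path to the annotation file.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return A validated annotation tibble.
#' @export
read_annotations <- function(path, format = c("auto", "csv", "json")) {
  format <- .guess_format(path, match.arg(format))
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  x <- if (format == "csv") {
    out <- readr::read_csv(path, col_types = .csv_col_types(),
                           progress = FALSE)
    prob <- readr::problems(out)
    if (nrow(prob) > 0) {
      stop("malformed annotation CSV at row(s) ",
           paste(utils::head(unique(prob$row), 10), collapse = ", "),
           call. = FALSE)
    }
    out
  } else {
    studies <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
    if (length(studies) == 0) stop("empty input: no studies in ", path,
                                   call. = FALSE)
    purrr::map(studies, function(st) {
      sbce_study(
        study_id = st$study_id,
        sb_duration_s = st$sb_duration_s,
        lesions = if (length(st$lesions) > 0) dplyr::bind_rows(st$lesions),
        stenoses = if (length(st$stenoses) > 0) dplyr::bind_rows(st$stenoses),
        reached_colon = st$reached_colon %||% TRUE,
        capsule_model = st$capsule_model %||% NA_character_,
        covariates = st$covariates
      )
    }) |>
      dplyr::bind_rows()
  }
  if (nrow(x) == 0) stop("empty input: no annotation rows in ", path,
                         call. = FALSE)
  validate_annotations(x)
}

#' Write SBCE annotations to CSV or JSON
#'
#' @inheritParams validate_annotations
#' @param path Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path,
                              format = c("auto", "csv", "json")) {
  x <- validate_annotations(annotations)
  format <- .guess_format(path, match.arg(format))
  if (format == "csv") {
    readr::write_csv(x, path, progress = FALSE)
  } else {
    covar_cols <- setdiff(names(x), .annotation_cols)
    studies <- x |>
      dplyr::group_by(.data$study_id) |>
      dplyr::group_map(function(g, key) {
        st <- list(
          study_id = key$study_id,
          capsule_model = g$capsule_model[1],
          sb_duration_s = g$sb_duration_s[1],
          reached_colon = g$reached_colon[1],
          lesions = g |>
            dplyr::filter(.data$record_type == "lesion") |>
            dplyr::select("timestamp_s", "lesion_type"),
          stenoses = g |>
            dplyr::filter(.data$record_type == "stenosis") |>
            dplyr::select("timestamp_s", "traversed")
        )
        if (length(covar_cols) > 0) {
          st$covariates <- as.list(g[1, covar_cols, drop = FALSE])
        }
        st
      })
    jsonlite::write_json(studies, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  }
  invisible(path)
}

.fmt3 <- function(x) formatC(x, digits = 3, format = "f")

#' Write a deterministic cohort report
#'
#' Renders a scored cohort (and optional comparator scores and reader
#' matrix) into a Markdown report plus a machine-readable JSON companion,
#' mirroring the usual validation layout: cohort summary, score
#' distribution, cross-score correlations, multilevel-lesion cutoff
#' diagnostics, inter-rater reliability. Output is deterministic: studies
#' sorted by id, floats at 3 decimals.
#'
#' @param scores A `cdace_scores` tibble from [score_cdace()] (may have zero
#'   rows).
#' @param path Output path for the Markdown report; the JSON companion
#'   replaces the extension with `.json`.
#' @param lewis Optional tibble `study_id`, `lewis` (e.g. from
#'   [lewis_score()] on [as_lewis_findings()]).
#' @param cecdai Optional tibble `study_id`, `cecdai`.
#' @param reader_matrix Optional subjects-by-readers matrix for ICC(2,1).
#' @return Invisibly, a list with the report paths and the JSON payload.
#' @export
write_report <- function(scores, path, lewis = NULL, cecdai = NULL,
                         reader_matrix = NULL) {
  json_path <- sub("\\.[A-Za-z]+$", "", path)
  json_path <- paste0(json_path, ".json")
  md <- c("# SBCE cohort report", "")
  payload <- list()
  if (nrow(scores) == 0) {
    md <- c(md, "## Cohort summary", "", "No studies in cohort.", "")
    payload$n_studies <- 0
    payload$studies <- list()
  } else {
    scores <- dplyr::arrange(tibble::as_tibble(scores), .data$study_id)
    md <- c(
      md, "## Cohort summary", "",
      paste0("- Studies: ", nrow(scores)),
      paste0("- CDACE mean (SD): ", .fmt3(mean(scores$cdace)), " (",
             .fmt3(stats::sd(scores$cdace)), "), range ",
             min(scores$cdace), "-", max(scores$cdace)),
      paste0("- Li mean ", .fmt3(mean(scores$li)),
             "; R mean ", .fmt3(mean(scores$r)),
             "; S > 0 in ", sum(scores$s > 0), " studies"),
      paste0("- Flagged incomplete without stenosis: ",
             sum(scores$flags == "incomplete_no_stenosis")),
      "", "## Studies", "",
      "| study_id | display | li | r | s | severity | flags |",
      "|---|---|---|---|---|---|---|",
      sprintf("| %s | %s | %d | %d | %d | %s | %s |",
              scores$study_id, scores$display, scores$li, scores$r,
              scores$s, .fmt3(scores$severity), scores$flags),
      "")
    payload$n_studies <- nrow(scores)
    payload$studies <- scores |>
      dplyr::select("study_id", "li", "r", "s", composite = "cdace",
                    "display", "severity", "flags")
  }
  if (!is.null(lewis) && nrow(scores) > 0) {
    j <- dplyr::inner_join(scores, lewis, by = "study_id")
    ct <- spearman_rho(j$cdace, j$lewis)
    md <- c(md, "## Correlation with Lewis Score", "",
            paste0("- Spearman rho = ", .fmt3(ct$rho), " (p = ",
                   .fmt3(ct$p_value), ", n = ", ct$n, ")"), "")
    payload$lewis_correlation <- as.list(ct)
  }
  if (!is.null(cecdai) && nrow(scores) > 0) {
    j <- dplyr::inner_join(scores, cecdai, by = "study_id")
    ct <- spearman_rho(j$cdace, j$cecdai)
    md <- c(md, "## Correlation with CECDAI", "",
            paste0("- Spearman rho = ", .fmt3(ct$rho), " (p = ",
                   .fmt3(ct$p_value), ", n = ", ct$n, ")"), "")
    payload$cecdai_correlation <- as.list(ct)
  }
  if (nrow(scores) > 0) {
    truth <- multilevel_lesion(
      as.matrix(scores[paste0("q", 1:4)]) > 0, "CDACE")
    if (length(unique(truth)) == 2) {
      perf <- roc_cutoff(as.numeric(scores$cdace), truth)
      md <- c(md, "## Multilevel-lesion cutoff (CDACE)", "",
              paste0("- AUC ", .fmt3(perf$auc), ", cutoff ",
                     .fmt3(perf$cutoff)),
              paste0("- Sensitivity ", .fmt3(perf$sensitivity),
                     ", specificity ", .fmt3(perf$specificity),
                     ", PPV ", .fmt3(perf$ppv), ", NPV ", .fmt3(perf$npv)),
              "")
      payload$multilevel_cutoff <- as.list(generics::glance(perf))
    }
  }
  if (!is.null(reader_matrix)) {
    icc <- icc_2_1(reader_matrix)
    md <- c(md, "## Inter-rater reliability", "",
            paste0("- ICC(2,1) = ", .fmt3(icc$icc), " (95% CI ",
                   .fmt3(icc$ci_low), "-", .fmt3(icc$ci_high), "), n = ",
                   icc$n, ", k = ", icc$k), "")
    payload$icc <- as.list(generics::glance(icc))
  }
  writeLines(md, path)
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = 10,
                       dataframe = "rows")
  invisible(list(markdown = path, json = json_path, payload = payload))
}
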