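# broom-style tidiers for the fitted result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @rdname roc_cutoff
#' @param x A `cdace_roc` or `cdace_icc` object.
#' @param ... Unused.
#' @export
tidy.cdace_roc <- function(x, ...) {
  x$curve
}

#' @rdname roc_cutoff
#' @export
glance.cdace_roc <- function(x, ...) {
  tibble::tibble(
    cutoff = x$cutoff, auc = x$auc, sensitivity = x$sensitivity,
    specificity = x$specificity, ppv = x$ppv, npv = x$npv,
    youden = x$youden, n_pos = x$n_pos, n_neg = x$n_neg
  )
}

#' @rdname icc_2_1
#' @param x A `cdace_icc` object.
#' @param ... Unused.
#' @export
tidy.cdace_icc <- function(x, ...) {
  tibble::tibble(
    term = c("subject", "reader", "error"),
    mean_square = c(x$ms_subject, x$ms_reader, x$ms_error)
  )
}

#' @rdname icc_2_1
#' @export
glance.cdace_icc <- function(x, ...) {
  tibble::tibble(
    icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
    n_subjects = x$n, k_readers = x$k, conf_level = x$conf_level
  )
}
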