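#' Flow-deficit percentage over a region
#'
#' CCFD% is the proportion of the evaluable area lacking detectable flow
#' signal: `100 * |deficit & roi & !exclusion| / |roi & !exclusion|`. An
#' empty evaluable area is an error, never a silent zero.
#'
#' @param deficit Binary deficit [region_mask] (label `deficit_binary` or
#'   `truth_deficit`).
#' @param exclusion Optional `vessel_exclusion` [region_mask]; `NULL` means
#'   nothing excluded.
#' @param roi Optional [region_mask] restricting evaluation; `NULL` means
#'   the whole image.
#' @return An `fd_result` list: `ccfd_percent`, `evaluable_px`,
#'   `excluded_px` (ROI pixels removed by the exclusion mask).
#' @export
fd_percent <- function(deficit, exclusion = NULL, roi = NULL) {
  stopifnot(inherits(deficit, "region_mask"))
  dpx <- deficit$pixels
  rpx <- if (is.null(roi)) {
    matrix(TRUE, nrow(dpx), ncol(dpx))
  } else {
    check_same_geometry(deficit, roi)
    roi$pixels
  }
  epx <- if (is.null(exclusion)) {
    matrix(FALSE, nrow(dpx), ncol(dpx))
  } else {
    check_same_geometry(deficit, exclusion)
    exclusion$pixels
  }
  evaluable <- rpx & !epx
  n_eval <- sum(evaluable)
  if (n_eval == 0) {
    stop("evaluable area is empty (ROI entirely excluded); ",
         "flow-deficit percentage is undefined", call. = FALSE)
  }
  structure(
    list(ccfd_percent = 100 * sum(dpx & evaluable) / n_eval,
         evaluable_px = n_eval,
         excluded_px = sum(rpx & epx)),
    class = "fd_result"
  )
}

#' @exportS3Method base::print
print.fd_result <- function(x, ...) {
  cat(sprintf("<fd_result> CCFD %.3f%% over %d evaluable px (%d excluded)\n",
              x$ccfd_percent, x$evaluable_px, x$excluded_px))
  invisible(x)
}
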