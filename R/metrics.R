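#' Count-error metrics
#'
#' Standard object-counting evaluation over a set of per-image count
#' records: mean absolute error (accuracy), root mean squared error
#' (robustness), mean absolute percentage error, and signed bias (positive
#' means overestimation). Predicted counts enter as real numbers — the
#' density-map integral — without rounding; round before calling if integer
#' reporting is wanted.
#'
#' @param records a data frame with numeric columns `c_pred` (estimated
#'   count) and `c_gt` (ground-truth count), one row per test image, and
#'   optionally `stage` (growth-stage label) and `image_id`.
#' @return `mae`, `rmse`, `mape`, `bias`: a scalar. `count_metrics`: a
#'   one-row tibble `n, mae, rmse, mape, bias`.
#' @examples
#' r <- tibble::tibble(c_pred = c(10, 20), c_gt = c(12, 16))
#' mae(r)   # 3
#' rmse(r)  # sqrt(10)
#' mape(r)  # 20.833 (%)
#' bias(r)  # 1
#' @name count-metrics
NULL

check_records <- function(records, need_positive_gt = FALSE) {
  if (!all(c("c_pred", "c_gt") %in% names(records))) {
    abort("`records` needs columns `c_pred` and `c_gt`.")
  }
  if (nrow(records) < 1) abort("`records` must contain at least one row.")
  if (any(records$c_gt < 0)) abort("Ground-truth counts must be >= 0.")
  if (need_positive_gt && any(records$c_gt == 0)) {
    abort("MAPE is undefined when any ground-truth count is 0.")
  }
  invisible(records)
}

#' @rdname count-metrics
#' @export
mae <- function(records) {
  check_records(records)
  mean(abs(records$c_pred - records$c_gt))
}

#' @rdname count-metrics
#' @export
rmse <- function(records) {
  check_records(records)
  sqrt(mean((records$c_pred - records$c_gt)^2))
}

#' @rdname count-metrics
#' @export
mape <- function(records) {
  check_records(records, need_positive_gt = TRUE)
  mean(abs(records$c_gt - records$c_pred) / records$c_gt) * 100
}

#' @rdname count-metrics
#' @export
bias <- function(records) {
  check_records(records)
  mean(records$c_pred - records$c_gt)
}

#' @rdname count-metrics
#' @export
count_metrics <- function(records) {
  check_records(records)
  tibble(n = nrow(records), mae = mae(records), rmse = rmse(records),
         mape = if (all(records$c_gt > 0)) mape(records) else NA_real_,
         bias = bias(records))
}

#' Stage-stratified evaluation
#'
#' One metrics row per growth-stage label present in the records (missing
#' labels are pooled as `"unknown"`), plus an `"overall"` row over all
#' records. Pooled MAE and bias equal the group-size-weighted means of the
#' per-group values; pooled RMSE pools through the weighted mean of squared
#' errors.
#'
#' @inheritParams count-metrics
#' @return a tibble with columns `stage, n, mae, rmse, mape, bias`.
#' @export
evaluate_by_stage <- function(records) {
  check_records(records)
  records <- as_tibble(records)
  if (!"stage" %in% names(records)) records$stage <- "unknown"
  records$stage <- dplyr::coalesce(as.character(records$stage), "unknown")
  per_stage <- records |>
    dplyr::group_by(stage) |>
    dplyr::group_modify(function(g, key) count_metrics(g)) |>
    dplyr::ungroup()
  dplyr::bind_rows(per_stage,
                   dplyr::mutate(count_metrics(records), stage = "overall",
                                 .before = 1))
}
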