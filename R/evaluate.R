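# Detection evaluation: per-image MAE over the four box coordinates,
# intersection-over-union, the Successful / Acceptable / Failed binning
# (IoU > 0.8 / 0.6 < IoU <= 0.8 / IoU <= 0.6), and the per-class +
# overall summary tables.

EVAL_BINS <- c("Successful", "Acceptable", "Failed")

#' Mean absolute error between two bounding boxes
#'
#' Mean of the four absolute coordinate differences
#' `(|dx_min| + |dy_min| + |dx_max| + |dy_max|) / 4`, in pixels.
#'
#' @param gt,pred [bbox()] objects (ground truth and prediction).
#' @return Non-negative numeric scalar.
#' @export
mae <- function(gt, pred) {
  stopifnot(inherits(gt, "bbox"), inherits(pred, "bbox"))
  mean(abs(as.numeric(gt) - as.numeric(pred)))
}

#' Intersection over union of two bounding boxes
#'
#' @param a,b [bbox()] objects.
#' @return Numeric in `[0, 1]`; 0 for disjoint boxes, 1 iff identical.
#' @export
iou <- function(a, b) {
  inter <- bbox_intersection(a, b)
  ai <- if (is.null(inter)) 0 else bbox_area(inter)
  ai / (bbox_area(a) + bbox_area(b) - ai)
}

#' Classify an IoU value into a quality bin
#'
#' `Successful` for IoU > 0.8, `Acceptable` for 0.6 < IoU <= 0.8 (the 0.8
#' boundary belongs to Acceptable), `Failed` for IoU <= 0.6.
#'
#' @param v IoU value in `[0, 1]`.
#' @return One of `"Successful"`, `"Acceptable"`, `"Failed"`.
#' @export
classify_iou <- function(v) {
  if (!is.finite(v) || v < 0 || v > 1) stop("IoU must lie in [0, 1]")
  if (v > 0.8) "Successful" else if (v > 0.6) "Acceptable" else "Failed"
}

#' Score one prediction against ground truth
#'
#' A missing prediction (`NULL`) counts as Failed with IoU 0 and an
#' undefined (NA) MAE.
#'
#' @param id Image identifier.
#' @param gt Ground-truth [bbox()].
#' @param pred Predicted [bbox()] or `NULL` for a missed detection.
#' @return A one-row data.frame: `id`, `mae`, `iou`, `bin`, `detected`.
#' @export
eval_record <- function(id, gt, pred) {
  if (is.null(pred)) {
    return(data.frame(id = id, mae = NA_real_, iou = 0,
                      bin = "Failed", detected = FALSE,
                      stringsAsFactors = FALSE))
  }
  v <- iou(gt, pred)
  data.frame(id = id, mae = mae(gt, pred), iou = v, bin = classify_iou(v),
             detected = TRUE, stringsAsFactors = FALSE)
}

#' Summarize evaluation records into class-wise and overall tables
#'
#' Produces the per-bin absolute and relative frequencies with per-bin mean
#' MAE and IoU, plus the overall mean and sample (n-1) standard deviation
#' of both metrics. Missed detections contribute to bin frequencies (as
#' Failed) and to the IoU statistics, but are excluded from MAE averages,
#' which are undefined without a predicted box.
#'
#' @param records A data.frame of [eval_record()] rows.
#' @return A list of class `eval_summary` with `per_class` (data.frame:
#'   `bin`, `n`, `rel_freq_pct`, `mean_mae`, `mean_iou`), `overall`
#'   (data.frame: `metric`, `mean`, `sd`), `n_records` and `n_missed`.
#' @export
summarize_eval <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1L)
  per <- do.call(rbind, lapply(EVAL_BINS, function(b) {
    sel <- records$bin == b
    data.frame(bin = b, n = sum(sel),
               rel_freq_pct = round(100 * sum(sel) / nrow(records), 2),
               mean_mae = if (any(sel & records$detected))
                 mean(records$mae[sel & records$detected]) else NA_real_,
               mean_iou = if (any(sel)) mean(records$iou[sel]) else NA_real_,
               stringsAsFactors = FALSE)
  }))
  det <- records$detected
  overall <- data.frame(
    metric = c("MAE", "IoU"),
    mean = c(if (any(det)) mean(records$mae[det]) else NA_real_,
             mean(records$iou)),
    sd = c(if (sum(det) > 1) stats::sd(records$mae[det]) else NA_real_,
           if (nrow(records) > 1) stats::sd(records$iou) else NA_real_),
    stringsAsFactors = FALSE)
  structure(list(per_class = per, overall = overall,
                 n_records = nrow(records), n_missed = sum(!det)),
            class = "eval_summary")
}

#' @export
print.eval_summary <- function(x, ...) {
  cat(sprintf("Evaluation over %d images (%d missed detections)\n",
              x$n_records, x$n_missed))
  print(x$per_class, row.names = FALSE)
  cat("Overall:\n")
  print(x$overall, row.names = FALSE)
  invisible(x)
}
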