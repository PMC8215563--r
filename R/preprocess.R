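# Smoothing of raw plate-weight curves and per-meal summaries.

#' Running-minimum smoothing of a food-removal curve
#'
#' Raw plate-scale recordings contain transient upward spikes (cutlery or a
#' hand resting on the plate). Since food can only leave the plate, weight is
#' only allowed to decrease: whenever a snapshot exceeds the previous smoothed
#' value, it is replaced by that previous value. The result is the running
#' minimum of the series — non-increasing, pointwise no larger than the
#' input, idempotent, and leaving the first snapshot unchanged.
#'
#' @param x a numeric vector of weights (grams) for one meal, or a long data
#'   frame with columns `participant_id`, `meal_id`, `time_s`, `weight_g`
#'   (smoothed per meal).
#' @return An object of the same shape with smoothed weights.
#' @examples
#' smooth_monotone(c(300, 295, 297, 290))   # 300 295 295 290
#' @export
smooth_monotone <- function(x) UseMethod("smooth_monotone")

#' @export
smooth_monotone.numeric <- function(x) {
  if (length(x) < 1L) stop("curve must have at least one snapshot")
  cummin(x)
}

#' @export
smooth_monotone.data.frame <- function(x) {
  .check_curves(x)
  key <- paste(x$participant_id, x$meal_id, sep = "\r")
  x <- x[order(key, x$time_s), , drop = FALSE]
  key <- paste(x$participant_id, x$meal_id, sep = "\r")
  x$weight_g <- ave(x$weight_g, key, FUN = cummin)
  rownames(x) <- NULL
  x
}

.check_curves <- function(x) {
  need <- c("participant_id", "meal_id", "time_s", "weight_g")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("curve data frame lacks column(s): ", paste(miss, collapse = ", "))
  if (nrow(x) == 0L) stop("curve data frame is empty")
  invisible(x)
}

#' Trim leading zero-weight snapshots
#'
#' Snapshots recorded before the plate is loaded (weight 0 at the start of the
#' recording) carry no information about the meal; they are removed and time
#' is re-zeroed so that time 0 corresponds to the full starting portion.
#'
#' @param curves long curve data frame (see [smooth_monotone()]).
#' @return The trimmed data frame.
#' @export
trim_leading_zeros <- function(curves) {
  .check_curves(curves)
  key <- paste(curves$participant_id, curves$meal_id, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(curves)), key), function(idx) {
    idx <- idx[order(curves$time_s[idx])]
    w <- curves$weight_g[idx]
    first <- which(w > 0)
    if (length(first) == 0L) return(integer())
    idx[first[1L]:length(idx)]
  }), use.names = FALSE)
  out <- curves[sort(keep), , drop = FALSE]
  key <- paste(out$participant_id, out$meal_id, sep = "\r")
  out$time_s <- out$time_s - ave(out$time_s, key, FUN = min)
  rownames(out) <- NULL
  out
}

#' Per-meal summary statistics
#'
#' For each meal of a (smoothed) long curve data frame, computes the starting
#' weight (snapshot at time 0), final weight, duration, mean eating speed
#' `(start - end) / duration` in g/s, and the number of snapshots.
#'
#' @param curves long curve data frame, ideally after [smooth_monotone()].
#' @return data frame with one row per meal: `participant_id`, `meal_id`,
#'   `start_weight`, `end_weight`, `duration`, `mean_speed`, `n_snapshots`.
#' @examples
#' crv <- data.frame(participant_id = "P1", meal_id = "M1",
#'                   time_s = 0:300, weight_g = seq(300, 0, by = -1))
#' summarize_meals(crv)   # mean_speed 1 g/s
#' @export
summarize_meals <- function(curves) {
  .check_curves(curves)
  key <- paste(curves$participant_id, curves$meal_id, sep = "\r")
  rows <- lapply(split(seq_len(nrow(curves)), key), function(idx) {
    idx <- idx[order(curves$time_s[idx])]
    tt <- curves$time_s[idx]
    w <- curves$weight_g[idx]
    dur <- tt[length(tt)] - tt[1L]
    if (dur <= 0) stop("meal ", curves$participant_id[idx[1L]], "/",
                       curves$meal_id[idx[1L]], " has zero duration")
    data.frame(participant_id = curves$participant_id[idx[1L]],
               meal_id = curves$meal_id[idx[1L]],
               start_weight = w[1L], end_weight = w[length(w)],
               duration = dur,
               mean_speed = (w[1L] - w[length(w)]) / dur,
               n_snapshots = length(idx), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$participant_id, out$meal_id), , drop = FALSE]
}
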