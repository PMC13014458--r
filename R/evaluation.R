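# Metrics, hit evaluation, uncertainty binning and report generation.

#' Prediction-error metrics
#'
#' For errors `e_i = predicted_i - observed_i`: MSE = mean(e^2),
#' RMSE = sqrt(MSE), bias = mean(e) (signed), and SDEP (standard deviation of
#' the error of prediction) in the population convention (divide by n), so
#' that the decomposition `rmse^2 = bias^2 + sdep^2` holds exactly.
#' Pearson R is the sample correlation of predicted and observed; it is
#' reported as `NA` ("missing") when either vector is constant, rather than
#' 0 or an error.
#'
#' @param predicted,observed equal-length finite numeric vectors.
#' @return a list of class `MetricsReport` with fields `mse`, `rmse`, `bias`,
#'   `sdep`, `pearson_r`, `n`.
#' @export
#' @examples
#' computeMetrics(c(0, 2), c(0, 0))  # bias 1, sdep 1, rmse sqrt(2)
computeMetrics <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    stop("predicted and observed must have equal length")
  if (!length(predicted)) stop("cannot compute metrics on empty vectors")
  if (any(!is.finite(predicted)) || any(!is.finite(observed)))
    stop("computeMetrics requires finite values")
  e <- predicted - observed
  mse <- mean(e^2)
  bias <- mean(e)
  sdep <- sqrt(mean((e - bias)^2))
  r <- if (length(e) >= 2 && sd(predicted) > 0 && sd(observed) > 0)
    cor(predicted, observed) else NA_real_
  structure(list(mse = mse, rmse = sqrt(mse), bias = bias, sdep = sdep,
                 pearson_r = r, n = length(e)),
            class = "MetricsReport")
}

#' @export
print.MetricsReport <- function(x, ...) {
  cat(sprintf(
    "MetricsReport (n = %d): RMSE %.4f, bias %+.4f, SDEP %.4f, Pearson R %s\n",
    x$n, x$rmse, x$bias, x$sdep,
    if (is.na(x$pearson_r)) "NA" else sprintf("%.4f", x$pearson_r)))
  invisible(x)
}

#' Hit overlap of the predicted top k
#'
#' Ranks predictions by predicted docking score (most negative first, ties by
#' id) and counts how many of the best `topK` lie in the retrospective hit
#' set.
#'
#' @param predictions data.frame/DataFrame with columns `id` and `yMean`.
#' @param hitSet character vector of hit ids (see [defineHitSet()]).
#' @param topK number of top-ranked predictions considered (default 50).
#' @return list with `count` and `rate_percent` (= 100 * count / topK).
#' @export
hitOverlap <- function(predictions, hitSet, topK = 50L) {
  if (!length(hitSet)) stop("hit set is empty")
  ids <- as.character(predictions$id)
  if (length(ids) < topK)
    stop("topK (", topK, ") exceeds the number of predictions (",
         length(ids), ")")
  ord <- order(predictions$yMean, ids, method = "radix")
  top <- ids[ord[seq_len(topK)]]
  count <- sum(top %in% hitSet)
  list(count = as.integer(count), rate_percent = 100 * count / topK)
}

.UNCERTAINTY_LABELS <- c("very_certain", "moderately_certain", "certain",
                         "quite_uncertain", "very_uncertain")

#' Bin predictions by ensemble uncertainty
#'
#' Assigns each prediction to a left-open, right-closed uncertainty bin
#' (defaults `(0, 0.2], (0.2, 0.4], (0.4, 0.6], (0.6, 0.8], (0.8, Inf)`,
#' labelled very_certain ... very_uncertain) and reports the per-bin count
#' and RMSE against the observed values. `sigma = 0` falls in the lowest
#' bin. Empty bins are reported with `n = 0` and missing RMSE.
#'
#' @param predicted,observed numeric vectors of predictions and truths.
#' @param sigma non-negative ensemble uncertainties, one per prediction.
#' @param edges increasing interior bin edges.
#' @return data.frame with columns `bin`, `n`, `rmse`.
#' @export
binUncertainty <- function(predicted, observed, sigma,
                           edges = c(0.2, 0.4, 0.6, 0.8)) {
  stopifnot(length(predicted) == length(observed),
            length(sigma) == length(predicted))
  if (any(sigma < 0)) stop("sigma must be non-negative")
  labels <- if (length(edges) == 4) .UNCERTAINTY_LABELS
            else paste0("bin", seq_len(length(edges) + 1))
  # left.open makes the intervals (lo, hi], matching the bin convention
  idx <- findInterval(sigma, edges, left.open = TRUE) + 1L
  out <- data.frame(bin = labels, n = 0L, rmse = NA_real_)
  for (b in seq_along(labels)) {
    inBin <- idx == b
    out$n[b] <- sum(inBin)
    if (out$n[b] > 0)
      out$rmse[b] <- sqrt(mean((predicted[inBin] - observed[inBin])^2))
  }
  out
}

#' Mean uncertainty by predicted-score bin
#'
#' Groups pool predictions into predicted-docking-score bins (left-open,
#' right-closed) and reports the mean ensemble uncertainty per bin -- the
#' summary used to ask whether the most favourably predicted molecules are
#' also the most uncertain ones. By default three equal-width bins span the
#' observed prediction range.
#'
#' @param yMean predicted scores.
#' @param sigma ensemble uncertainties.
#' @param breaks full break vector (length nBins + 1) or `NULL` for
#'   equal-width bins over the range.
#' @param nBins number of equal-width bins when `breaks` is `NULL`.
#' @return data.frame with columns `bin_lo`, `bin_hi`, `n`, `mean_sigma`.
#' @export
meanUncertaintyByPrediction <- function(yMean, sigma, breaks = NULL,
                                        nBins = 3L) {
  stopifnot(length(yMean) == length(sigma))
  if (is.null(breaks)) breaks <- seq(min(yMean), max(yMean),
                                     length.out = nBins + 1L)
  idx <- cut(yMean, breaks, include.lowest = TRUE, labels = FALSE)
  out <- data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                    n = 0L, mean_sigma = NA_real_)
  for (b in seq_len(nrow(out))) {
    inBin <- !is.na(idx) & idx == b
    out$n[b] <- sum(inBin)
    if (out$n[b] > 0) out$mean_sigma[b] <- mean(sigma[inBin])
  }
  out
}

# Long-format rows for one trajectory.
.trajectoryRows <- function(traj) {
  strategy <- traj@config$strategy %||% NA_character_
  rec <- traj@records
  scalarCols <- setdiff(names(rec),
                        c("iteration", "cumulative_added"))
  recRows <- do.call(rbind, lapply(scalarCols, function(col)
    data.frame(strategy = strategy, seed = traj@seed,
               iteration = rec$iteration,
               cumulative_added = rec$cumulative_added,
               metric = col, set = "trajectory",
               value = as.numeric(rec[[col]]))))
  met <- traj@metrics
  metRows <- data.frame(strategy = strategy, seed = traj@seed,
                        iteration = met$iteration,
                        cumulative_added = rec$cumulative_added[
                          match(met$iteration, rec$iteration)],
                        metric = met$metric, set = met$set,
                        value = met$value)
  out <- rbind(recRows, metRows)
  out[order(out$iteration, out$set, out$metric, method = "radix"), ]
}

#' Write a tidy trajectory report
#'
#' Flattens one or more [DmtaTrajectory-class] objects into a single
#' long-format table with columns `strategy, seed, iteration,
#' cumulative_added, metric, set, value` (deterministic row and column
#' order), optionally writing it to CSV. Re-running on the same input
#' produces byte-identical output.
#'
#' @param trajectories a [DmtaTrajectory-class] or list of them.
#' @param path optional CSV output path.
#' @return the long-format data.frame, invisibly when `path` is given.
#' @export
writeReport <- function(trajectories, path = NULL) {
  if (is(trajectories, "DmtaTrajectory")) trajectories <- list(trajectories)
  stopifnot(length(trajectories) >= 1)
  out <- do.call(rbind, lapply(trajectories, .trajectoryRows))
  rownames(out) <- NULL
  if (!is.null(path)) {
    write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
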