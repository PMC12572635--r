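# Benchmarking protocol: TP/FP/FN matching with radius clustering, PR
# curves with AUC, MAD location-accuracy statistics, and the per-metal
# selectivity panel.

.pred_frame <- function(predictions) {
  if (is.data.frame(predictions)) return(predictions)
  predictions_table(predictions)
}

#' Match predictions against ground-truth ion sites
#'
#' A truth site is a true positive iff at least one prediction of the same
#' structure lies within `radius`; every prediction within `radius` of some
#' truth counts toward `n_pred_within` but the truth counts once.
#' Predictions matching no truth are clustered greedily (seeded on the
#' best-scoring, i.e. highest-probability, prediction; a cluster absorbs
#' everything within `radius`) and each cluster counts one false positive.
#'
#' @param predictions Prediction list or data frame (needs structure_id,
#'   zinc_x/y/z, p).
#' @param truths Data frame: structure_id, x, y, z (optionally metal).
#' @param radius Match radius (Angstrom): 2 or 5 in the standard protocol.
#' @return `MatchResult` list: `radius`, `tp`, `fp`, `fn`, `n_pred_within`,
#'   `tp_distances` (prediction-to-nearest-truth, for truth-matching
#'   predictions).
#' @export
match_predictions <- function(predictions, truths, radius = 2) {
  pf <- .pred_frame(predictions)
  tp <- 0L; fn <- 0L; n_within <- 0L; fp <- 0L
  tp_dist <- numeric()
  all_sids <- union(unique(pf$structure_id), unique(truths$structure_id))
  for (sid in all_sids) {
    p <- pf[pf$structure_id == sid, , drop = FALSE]
    tr <- truths[truths$structure_id == sid, , drop = FALSE]
    if (nrow(p) > 0L && nrow(tr) > 0L) {
      pm <- as.matrix(p[, c("zinc_x", "zinc_y", "zinc_z")])
      tm <- as.matrix(tr[, c("x", "y", "z")])
      D <- outer(seq_len(nrow(pm)), seq_len(nrow(tm)),
                 Vectorize(function(i, j) sqrt(sum((pm[i, ] - tm[j, ])^2))))
      near_truth <- apply(D, 1, min) <= radius
      matched_truth <- apply(D, 2, min) <= radius
      tp <- tp + sum(matched_truth)
      fn <- fn + sum(!matched_truth)
      n_within <- n_within + sum(near_truth)
      tp_dist <- c(tp_dist, apply(D, 1, min)[near_truth])
      unmatched <- which(!near_truth)
    } else {
      fn <- fn + nrow(tr)
      unmatched <- seq_len(nrow(p))
    }
    # greedy FP clustering, best score (highest p) first
    if (length(unmatched) > 0L) {
      um <- p[unmatched, , drop = FALSE]
      um <- um[order(-um$p), , drop = FALSE]
      pm <- as.matrix(um[, c("zinc_x", "zinc_y", "zinc_z")])
      alive <- rep(TRUE, nrow(um))
      for (i in seq_len(nrow(um))) {
        if (!alive[i]) next
        fp <- fp + 1L
        d <- sqrt(colSums((t(pm) - pm[i, ])^2))
        alive[d <= radius] <- FALSE
      }
    }
  }
  list(radius = radius, tp = tp, fp = fp, fn = fn,
       n_pred_within = n_within, tp_distances = tp_dist)
}

#' Precision-recall curve over probability thresholds
#'
#' Sweeps the distinct prediction probabilities as thresholds; at each,
#' precision = TP / (TP + FP) and recall = TP / n_truths under
#' [match_predictions()] semantics.  AUC by trapezoid over unique recall
#' points (0 for an empty prediction set).
#'
#' @param predictions Prediction list or data frame.
#' @param truths Truth data frame.
#' @param radius Match radius (Angstrom).
#' @return `PRCurve` list: `points` (threshold, precision, recall, tp, fp,
#'   fn), `auc`.
#' @export
pr_curve <- function(predictions, truths, radius = 2) {
  if (nrow(truths) == 0L) stop("PR curve undefined with zero truth sites")
  pf <- .pred_frame(predictions)
  if (nrow(pf) == 0L) {
    return(list(points = data.frame(threshold = double(),
                                    precision = double(), recall = double(),
                                    tp = integer(), fp = integer(),
                                    fn = integer()),
                auc = 0))
  }
  thresholds <- sort(unique(pf$p), decreasing = TRUE)
  rows <- lapply(thresholds, function(th) {
    m <- match_predictions(pf[pf$p >= th, , drop = FALSE], truths, radius)
    prec <- if (m$tp + m$fp == 0) 1 else m$tp / (m$tp + m$fp)
    data.frame(threshold = th, precision = prec,
               recall = m$tp / (m$tp + m$fn), tp = m$tp, fp = m$fp,
               fn = m$fn)
  })
  pts <- do.call(rbind, rows)
  # trapezoid over unique recall values (take best precision per recall)
  agg <- stats::aggregate(precision ~ recall, data = pts, FUN = max)
  agg <- agg[order(agg$recall), , drop = FALSE]
  r <- c(0, agg$recall)
  p <- c(if (nrow(agg)) agg$precision[1] else 1, agg$precision)
  auc <- sum(diff(r) * (utils::head(p, -1) + utils::tail(p, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Location-accuracy statistics of true-positive distances
#'
#' @param tp_distances Distances between truth-matching predictions and
#'   their nearest truth ion (Angstrom).
#' @return List: `mean`, `sd` (sample sd; 0 for a single value), `median`,
#'   `iqr` (25th and 75th percentiles, linear interpolation), `n`.
#' @export
mad_stats <- function(tp_distances) {
  if (length(tp_distances) == 0L) stop("no true-positive distances")
  q <- stats::quantile(tp_distances, c(0.25, 0.75), type = 7, names = FALSE)
  s <- if (length(tp_distances) > 1L) stats::sd(tp_distances) else 0
  list(mean = mean(tp_distances), sd = s,
       median = stats::median(tp_distances), iqr = q,
       n = length(tp_distances))
}

#' Per-metal selectivity panel
#'
#' Applies [match_predictions()] separately against the truth sites of each
#' metal species, at a fixed probability threshold.
#'
#' @param predictions Prediction list or data frame.
#' @param truths Truth data frame with a `metal` column.
#' @param radius Match radius (Angstrom).
#' @param min_p Probability threshold applied to predictions.
#' @return Data frame: metal, n_truth, tp, fp, fn, precision, recall.
#'   Metals with zero truth sites are omitted.
#' @export
selectivity_panel <- function(predictions, truths, radius = 2,
                              min_p = 0.75) {
  pf <- .pred_frame(predictions)
  pf <- pf[pf$p >= min_p, , drop = FALSE]
  metals <- unique(truths$metal)
  rows <- lapply(metals, function(mm) {
    tr <- truths[truths$metal == mm, , drop = FALSE]
    if (nrow(tr) == 0L) return(NULL)
    m <- match_predictions(pf, tr, radius)
    data.frame(metal = mm, n_truth = m$tp + m$fn, tp = m$tp, fp = m$fp,
               fn = m$fn,
               precision = if (m$tp + m$fp == 0) NA_real_ else
                 m$tp / (m$tp + m$fp),
               recall = m$tp / (m$tp + m$fn), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Write / read the ground-truth CSV schema
#'
#' Columns: structure_id, metal, x, y, z.
#'
#' @param truths Data frame.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_truth_csv <- function(truths, path) {
  utils::write.csv(truths[, c("structure_id", "metal", "x", "y", "z")],
                   path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' @rdname write_truth_csv
#' @export
read_truth_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
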