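#' Confusion matrix from binary label sequences
#'
#' @param pred_labels,true_labels equal-length binary (0/1 or logical)
#'   vectors.
#' @return a `confusion_matrix`: list with integer counts `TP, FP, FN, TN`.
#' @export
confusion <- function(pred_labels, true_labels) {
  if (length(pred_labels) != length(true_labels))
    stop("prediction and truth sequences differ in length")
  p <- as.integer(pred_labels); t <- as.integer(true_labels)
  if (!all(p %in% c(0L, 1L)) || !all(t %in% c(0L, 1L)))
    stop("labels must be binary (0/1)")
  structure(list(TP = sum(p == 1L & t == 1L),
                 FP = sum(p == 1L & t == 0L),
                 FN = sum(p == 0L & t == 1L),
                 TN = sum(p == 0L & t == 0L)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TN, x$FP, x$FN, x$TP), 2, 2, byrow = TRUE,
              dimnames = list(c("actual neg", "actual pos"),
                              c("pred neg", "pred pos")))
  m[1, ] <- c(x$TN, x$FP); m[2, ] <- c(x$FN, x$TP)
  print(m)
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Recall (sensitivity) `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, accuracy `(TP+TN)/total`, and F1 (harmonic mean of precision
#' and recall). A metric whose denominator is zero is returned as `NA` and
#' named in the `undefined` field rather than silently zero-filled.
#'
#' @param cm a `confusion_matrix` from [confusion()], or a list with fields
#'   `TP, FP, FN, TN`.
#' @return a `metrics_report`: list with the five metrics and a character
#'   vector `undefined`.
#' @export
metrics <- function(cm) {
  TP <- cm$TP; FP <- cm$FP; FN <- cm$FN; TN <- cm$TN
  if (any(c(TP, FP, FN, TN) < 0)) stop("negative counts")
  total <- TP + FP + FN + TN
  if (total == 0) stop("empty confusion matrix")
  undef <- character(0)
  safe <- function(num, den, name) {
    if (den == 0) { undef <<- c(undef, name); return(NA_real_) }
    num / den
  }
  recall <- safe(TP, TP + FN, "recall")
  specificity <- safe(TN, TN + FP, "specificity")
  precision <- safe(TP, TP + FP, "precision")
  accuracy <- (TP + TN) / total
  f1 <- if (is.na(precision) || is.na(recall)) {
    undef <- c(undef, "f1"); NA_real_
  } else if (precision + recall == 0) {
    undef <- c(undef, "f1"); 0
  } else 2 * precision * recall / (precision + recall)
  structure(list(recall = recall, specificity = specificity,
                 precision = precision, accuracy = accuracy, f1 = f1,
                 undefined = undef),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, digits = 4, ...) {
  for (nm in c("recall", "specificity", "precision", "accuracy", "f1"))
    cat(sprintf("%-12s %s\n", nm,
                if (is.na(x[[nm]])) "undefined" else
                  formatC(x[[nm]], digits = digits, format = "f")))
  invisible(x)
}

#' ROC curve and AUC
#'
#' Sweeps thresholds over the unique scores to build the (FPR, TPR) curve and
#' computes the AUC by the rank (Mann-Whitney) statistic, which averages over
#' tied scores -- equal to the trapezoidal area under the tie-aware curve.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (0/1), both classes present.
#' @return list with `curve` (data.frame `threshold, fpr, tpr`, descending
#'   thresholds) and `auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.integer(labels)
  stopifnot(length(scores) == length(labels))
  npos <- sum(labels == 1L); nneg <- sum(labels == 0L)
  if (npos == 0L || nneg == 0L)
    stop("both classes must be present to compute a ROC curve")
  r <- rank(scores)  # rank-averaged over ties
  auc <- (sum(r[labels == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(scores >= t & labels == 0L) / nneg,
                 numeric(1)),
    tpr = vapply(thr, function(t) sum(scores >= t & labels == 1L) / npos,
                 numeric(1)))
  list(curve = curve, auc = auc)
}

#' Score localization against phantom ground truth
#'
#' Greedy one-to-one matching of candidate centroids to true deposit centers
#' by ascending distance, accepting matches within `match_radius_px`. Spot
#' recall is matched/total spots; candidate precision is matched/total
#' candidates. Empty inputs yield 0 or `NA` (flagged) rather than errors.
#'
#' @param candidates a `region_candidates` data.frame (columns `row`, `col`).
#' @param truth a `phantom_truth` (or any list with a `spots` data.frame).
#' @param match_radius_px maximum center distance for a match; default is the
#'   largest planted spot radius + 2 px.
#' @return list with `spot_recall`, `candidate_precision`, `matches`
#'   (data.frame `spot, candidate, distance`), and `undefined` flags.
#' @export
localization_score <- function(candidates, truth, match_radius_px = NULL) {
  spots <- truth$spots
  n_spots <- if (is.null(spots)) 0L else nrow(spots)
  n_cand <- if (is.null(candidates)) 0L else nrow(candidates)
  if (is.null(match_radius_px)) {
    match_radius_px <- if (n_spots > 0)
      max(spots$diameter_px) / 2 + 2 else 2
  }
  if (match_radius_px <= 0) stop("match_radius_px must be positive")
  matches <- data.frame(spot = integer(0), candidate = integer(0),
                        distance = numeric(0))
  if (n_spots > 0L && n_cand > 0L) {
    d <- outer(seq_len(n_spots), seq_len(n_cand), function(i, j) {
      sqrt((spots$row[i] - candidates$row[j])^2 +
           (spots$col[i] - candidates$col[j])^2)
    })
    repeat {
      best <- which.min(d)
      if (!length(best) || d[best] > match_radius_px || !is.finite(d[best]))
        break
      i <- (best - 1L) %% n_spots + 1L
      j <- (best - 1L) %/% n_spots + 1L
      matches <- rbind(matches,
                       data.frame(spot = i, candidate = j, distance = d[best]))
      d[i, ] <- Inf; d[, j] <- Inf
    }
  }
  undef <- character(0)
  recall <- if (n_spots > 0) nrow(matches) / n_spots else {
    undef <- c(undef, "spot_recall"); NA_real_
  }
  precision <- if (n_cand > 0) nrow(matches) / n_cand else {
    undef <- c(undef, "candidate_precision"); NA_real_
  }
  list(spot_recall = recall, candidate_precision = precision,
       matches = matches, undefined = undef)
}

#' Partition predicted probabilities by outcome
#'
#' Splits per-sample probabilities into the four confusion outcomes (TP, FP,
#' TN, FN) for distributional inspection, optionally writing a long-format
#' CSV (`outcome,probability`).
#'
#' @param results data.frame with columns `probability`, `label` (predicted
#'   0/1), and `truth` (0/1).
#' @param path optional CSV output path.
#' @return named list of four numeric vectors `TP, FP, TN, FN`.
#' @export
probability_distribution_export <- function(results, path = NULL) {
  stopifnot(all(c("probability", "label", "truth") %in% names(results)))
  p <- as.integer(results$label); t <- as.integer(results$truth)
  out <- list(TP = results$probability[p == 1L & t == 1L],
              FP = results$probability[p == 1L & t == 0L],
              TN = results$probability[p == 0L & t == 0L],
              FN = results$probability[p == 0L & t == 1L])
  if (!is.null(path)) {
    long <- data.frame(
      outcome = rep(names(out), vapply(out, length, integer(1))),
      probability = unlist(out, use.names = FALSE))
    utils::write.csv(long, path, row.names = FALSE)
  }
  out
}
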