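## Evaluation of alignments against ground-truth peak correspondences.
##
## With s true pairs and u matched pairs among an m-reference,
## n-target comparison:
##   TP = matched pairs that are true, FP = u - TP, FN = s - TP,
##   TN = m*n - s - FP,
##   TPR = TP/s, FPR = (u - TP)/(m*n - s), PPV = TP/u,
##   F1 = 2*TP/(s + u)  (the harmonic mean of TPR and PPV).

#' Count alignment outcomes against ground truth
#'
#' @param result An `alignment_result`.
#' @param truth A [true_pair_set()].
#' @param m,n Reference and target peak counts; default to those recorded
#'   in `result`.
#' @return A list of class `outcome_counts` with `TP`, `FP`, `FN`, `TN`,
#'   `s`, `u`, `m`, `n`.
#' @export
count_outcomes <- function(result, truth, m = result$m, n = result$n) {
  stopifnot(inherits(result, "alignment_result"),
            inherits(truth, "true_pair_set"))
  s <- nrow(truth); u <- nrow(result$matches)
  if (u > 0L) {
    if (any(result$matches$ref > m) || any(result$matches$target > n)) {
      stop("match index out of range for the stated m/n", call. = FALSE)
    }
  }
  if (s > 0L && (any(truth$ref > m) || any(truth$target > n))) {
    stop("truth index out of range for the stated m/n", call. = FALSE)
  }
  key_match <- paste(result$matches$ref, result$matches$target)
  key_truth <- paste(truth$ref, truth$target)
  TP <- sum(key_match %in% key_truth)
  FP <- u - TP
  FN <- s - TP
  TN <- m * n - s - FP
  structure(list(TP = TP, FP = FP, FN = FN, TN = TN,
                 s = s, u = u, m = m, n = n),
            class = "outcome_counts")
}

#' Compute alignment performance metrics from outcome counts
#'
#' @param counts An `outcome_counts` object (or a list with `TP`, `s`,
#'   `u`, `m`, `n`).
#' @return A list of class `evaluation_report` with the counts plus
#'   `TPR`, `FPR`, `PPV`, `F1`. With `u = 0`, `PPV` and `F1` are `NA`
#'   while `TPR` and `FPR` are still computed.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; s <- counts$s; u <- counts$u
  m <- counts$m; n <- counts$n
  if (s <= 0L) stop("metrics need s > 0 true pairs", call. = FALSE)
  TPR <- TP / s
  FPR <- (u - TP) / (m * n - s)
  PPV <- if (u > 0L) TP / u else NA_real_
  F1 <- if (u > 0L) 2 * TP / (s + u) else NA_real_
  structure(c(unclass(count_like(counts)),
              list(TPR = TPR, FPR = FPR, PPV = PPV, F1 = F1)),
            class = "evaluation_report")
}

count_like <- function(counts) {
  list(TP = counts$TP, FP = counts$u - counts$TP, FN = counts$s - counts$TP,
       TN = counts$m * counts$n - counts$s - (counts$u - counts$TP),
       s = counts$s, u = counts$u, m = counts$m, n = counts$n)
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "<evaluation_report> TP=%d FP=%d FN=%d TN=%d | TPR=%.4f FPR=%.4f PPV=%s F1=%s\n",
    x$TP, x$FP, x$FN, x$TN, x$TPR, x$FPR,
    ifelse(is.na(x$PPV), "NA", sprintf("%.4f", x$PPV)),
    ifelse(is.na(x$F1), "NA", sprintf("%.4f", x$F1))))
  invisible(x)
}

#' Evaluate an alignment against ground truth
#'
#' Convenience wrapper: [count_outcomes()] then [compute_metrics()].
#'
#' @inheritParams count_outcomes
#' @return An `evaluation_report`.
#' @export
evaluate_alignment <- function(result, truth, m = result$m, n = result$n) {
  compute_metrics(count_outcomes(result, truth, m, n))
}

#' Empirical ROC curve from scores and labels
#'
#' For each cut-off `c` (default: the descending unique observed scores)
#' the pairs with score `>= c` are called positive; TPR is the fraction
#' of truly-positive pairs called, FPR the fraction of truly-negative
#' pairs called. Boundary points (0,0) and (1,1) are appended and the AUC
#' is the trapezoidal integral over the FPR-sorted points. On ties-free
#' scores this AUC equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`.
#'
#' @param scores Numeric scores (higher = more likely a true pair).
#' @param labels Logical (or 0/1) vector: `TRUE` for true pairs.
#' @param cutoffs Optional descending cut-off sequence; defaults to the
#'   sorted unique scores.
#' @return An object of class `roc_curve` with fields `cutoffs`, `points`
#'   (data frame `FPR`, `TPR`) and `auc`.
#' @export
roc_curve <- function(scores, labels, cutoffs = NULL) {
  labels <- as.logical(labels)
  ok <- !is.na(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0L || n_neg == 0L) {
    stop("roc_curve needs at least one true and one false pair score",
         call. = FALSE)
  }
  if (is.null(cutoffs)) cutoffs <- sort(unique(scores), decreasing = TRUE)
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  TPR <- vapply(cutoffs, function(c) sum(scores[labels] >= c) / n_pos,
                numeric(1))
  FPR <- vapply(cutoffs, function(c) sum(scores[!labels] >= c) / n_neg,
                numeric(1))
  pts <- data.frame(FPR = c(0, FPR, 1), TPR = c(0, TPR, 1))
  pts <- pts[order(pts$FPR, pts$TPR), ]
  auc <- .trapezoid_auc(pts$FPR, pts$TPR)
  structure(list(cutoffs = cutoffs,
                 points = data.frame(cutoff = c(Inf, cutoffs, -Inf),
                                     FPR = c(0, FPR, 1), TPR = c(0, TPR, 1)),
                 auc = auc),
            class = "roc_curve")
}

.trapezoid_auc <- function(fpr, tpr) {
  sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d cutoffs, AUC = %.4f\n",
              length(x$cutoffs), x$auc))
  invisible(x)
}

#' ROC curve of an alignment by thresholding its match scores
#'
#' Re-derives the alignment at every cut-off by keeping only the matches
#' whose selection score is at least the cut-off, then recomputes TPR and
#' FPR from the confusion counts. When no matches survive a high cut-off,
#' TPR = FPR = 0. Boundary anchors (0,0) and (1,1) close the curve for
#' the trapezoidal AUC.
#'
#' @param result An `alignment_result`.
#' @param truth A [true_pair_set()].
#' @param m,n Reference and target peak counts.
#' @param cutoffs Optional descending cut-offs; defaults to the unique
#'   match scores.
#' @return A `roc_curve` object.
#' @export
alignment_roc <- function(result, truth, m = result$m, n = result$n,
                          cutoffs = NULL) {
  stopifnot(inherits(result, "alignment_result"),
            inherits(truth, "true_pair_set"))
  sc <- result$matches$score
  if (length(sc) == 0L) stop("alignment has no matches", call. = FALSE)
  if (is.null(cutoffs)) cutoffs <- sort(unique(sc), decreasing = TRUE)
  cutoffs <- sort(cutoffs, decreasing = TRUE)
  s <- nrow(truth)
  key_truth <- paste(truth$ref, truth$target)
  key_match <- paste(result$matches$ref, result$matches$target)
  is_true <- key_match %in% key_truth
  TPR <- numeric(length(cutoffs)); FPR <- numeric(length(cutoffs))
  for (a in seq_along(cutoffs)) {
    keep <- sc >= cutoffs[a]
    u <- sum(keep)
    TP <- sum(keep & is_true)
    TPR[a] <- if (s > 0) TP / s else 0
    FPR[a] <- if (m * n - s > 0) (u - TP) / (m * n - s) else 0
  }
  pts <- data.frame(cutoff = c(Inf, cutoffs, -Inf),
                    FPR = c(0, FPR, 1), TPR = c(0, TPR, 1))
  o <- order(pts$FPR, pts$TPR)
  auc <- .trapezoid_auc(pts$FPR[o], pts$TPR[o])
  structure(list(cutoffs = cutoffs, points = pts, auc = auc),
            class = "roc_curve")
}

#' Same-peak versus different-peak similarity score distributions
#'
#' Splits the pairwise similarity matrix between a reference and a target
#' list into the scores over true peak pairs ("same peaks") and over all
#' remaining cross pairs ("different peaks"). In the ideal noise-free
#' case the same-peak scores sit at 1 for every correlation measure; the
#' separation between the two distributions is what makes a measure
#' useful for alignment.
#'
#' @param reference,target Harmonized `peak_list`s.
#' @param truth A [true_pair_set()].
#' @param spec A [similarity_spec()].
#' @return A list with numeric vectors `same` (length `s`) and
#'   `different` (length `m*n - s`).
#' @export
score_distributions <- function(reference, target, truth, spec) {
  stopifnot(inherits(truth, "true_pair_set"))
  S <- unclass(similarity_matrix(target, reference, spec))
  idx_same <- cbind(truth$target, truth$ref)
  same <- S[idx_same]
  mask <- matrix(TRUE, nrow(S), ncol(S))
  mask[idx_same] <- FALSE
  list(same = same, different = S[mask])
}

#' Overlap coefficient between two score distributions
#'
#' A simple separation statistic for [score_distributions()]: the
#' overlapping area of the two kernel density estimates on a common
#' support (0 = perfectly separated, 1 = identical). `NA` scores are
#' dropped.
#'
#' @param a,b Numeric score vectors.
#' @param n_grid Grid size for the density evaluation.
#' @return A number in \[0, 1\].
#' @export
overlap_coefficient <- function(a, b, n_grid = 512) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2L || length(b) < 2L) {
    stop("need at least two finite scores on each side", call. = FALSE)
  }
  lo <- min(a, b); hi <- max(a, b)
  if (lo == hi) return(1)
  da <- stats::density(a, from = lo, to = hi, n = n_grid)
  db <- stats::density(b, from = lo, to = hi, n = n_grid)
  dx <- da$x[2L] - da$x[1L]
  sum(pmin(da$y, db$y)) * dx
}
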