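#' Multilabel ranking metrics
#'
#' The evaluation suite for multilabel syndrome differentiation: precision at
#' k, Hamming loss, average precision, and label ranking loss. Scores are real
#' valued (higher = more confident); truths are 0/1 matrices of the same
#' shape. All four metrics are rank statistics except Hamming loss, which
#' binarizes scores at a threshold first.
#'
#' @name metrics
NULL

check_batch <- function(scores, truths) {
  scores <- as.matrix(scores)
  truths <- as.matrix(truths)
  if (!all(dim(scores) == dim(truths)))
    stop("scores and truths must have identical dimensions")
  if (!all(truths %in% c(0, 1)))
    stop("truths must be strictly 0/1")
  list(scores = scores, truths = truths)
}

#' Precision at k
#'
#' Fraction of the k top-scoring labels that are true, averaged over samples.
#' Ties in scores are broken by the (stable) label index so the result is
#' deterministic.
#'
#' @param scores Numeric matrix (samples x labels) or a single row vector.
#' @param truths Binary matrix of the same shape.
#' @param k Number of top labels to inspect, `1 <= k <= n_labels`.
#' @return Mean precision at k over samples, in \[0, 1\].
#' @export
#' @examples
#' precision_at_k(c(0.9, 0.1, 0.8), c(1, 0, 0), k = 3)  # 1/3
precision_at_k <- function(scores, truths, k) {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, nrow = 1)
    truths <- matrix(truths, nrow = 1)
  }
  b <- check_batch(scores, truths)
  n_labels <- ncol(b$scores)
  if (k < 1 || k > n_labels)
    stop(sprintf("k must be in [1, %d], got %s", n_labels, k))
  per_sample <- vapply(seq_len(nrow(b$scores)), function(i) {
    ord <- order_desc_stable(b$scores[i, ])
    mean(b$truths[i, ord[seq_len(k)]])
  }, numeric(1))
  mean(per_sample)
}

#' Hamming loss
#'
#' Proportion of wrongly predicted labels after binarizing scores. By default
#' scores are treated as logits: a label is predicted positive when
#' `sigmoid(score) >= threshold`, i.e. `score >= logit(threshold)`.
#'
#' @param scores Numeric matrix (samples x labels).
#' @param truths Binary matrix of the same shape.
#' @param threshold Probability cut for the positive call (default 0.5).
#' @param scores_are_prob Set `TRUE` when scores already live in \[0, 1\].
#' @return Mean 0/1 disagreement over all sample-label cells.
#' @export
hamming_loss <- function(scores, truths, threshold = 0.5,
                         scores_are_prob = FALSE) {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, nrow = 1)
    truths <- matrix(truths, nrow = 1)
  }
  b <- check_batch(scores, truths)
  p <- if (scores_are_prob) b$scores else sigmoid(b$scores)
  pred <- (p >= threshold) * 1
  mean(pred != b$truths)
}

ap_row <- function(s, y) {
  ord <- order_desc_stable(s)
  y <- y[ord]
  n_pos <- sum(y)
  hits <- cumsum(y)
  prec <- hits / seq_along(y)
  rec <- hits / n_pos
  drec <- diff(c(0, rec))
  sum(drec * prec)
}

#' Average precision
#'
#' Per-sample area under the precision-recall curve computed over descending
#' score thresholds (sum of precision weighted by recall increments), averaged
#' over samples. Rows with no positive label carry no ranking information and
#' are excluded; the number excluded is attached as the `"n_excluded"`
#' attribute.
#'
#' @inheritParams hamming_loss
#' @return Mean average precision with attribute `n_excluded`.
#' @export
average_precision <- function(scores, truths) {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, nrow = 1)
    truths <- matrix(truths, nrow = 1)
  }
  b <- check_batch(scores, truths)
  pos <- rowSums(b$truths) > 0
  if (!any(pos)) stop("no row has a positive label; average precision undefined")
  vals <- vapply(which(pos), function(i) ap_row(b$scores[i, ], b$truths[i, ]),
                 numeric(1))
  out <- mean(vals)
  attr(out, "n_excluded") <- sum(!pos)
  out
}

rloss_row <- function(s, y) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  # ties between a positive and a negative count as violations (pessimistic)
  viol <- sum(outer(pos, neg, FUN = "<="))
  viol / (length(pos) * length(neg))
}

#' Label ranking loss
#'
#' Per-sample fraction of (positive, negative) label pairs that are ordered
#' incorrectly -- the negative label scoring at least as high as the positive
#' -- normalized by the number of such pairs, then averaged over samples.
#' Rows with no positive or no negative label are excluded (count in the
#' `"n_excluded"` attribute).
#'
#' @inheritParams hamming_loss
#' @return Mean ranking loss with attribute `n_excluded`.
#' @export
label_ranking_loss <- function(scores, truths) {
  if (is.null(dim(scores))) {
    scores <- matrix(scores, nrow = 1)
    truths <- matrix(truths, nrow = 1)
  }
  b <- check_batch(scores, truths)
  ok <- rowSums(b$truths) > 0 & rowSums(b$truths) < ncol(b$truths)
  if (!any(ok)) stop("no row has both a positive and a negative label")
  vals <- vapply(which(ok), function(i) rloss_row(b$scores[i, ], b$truths[i, ]),
                 numeric(1))
  out <- mean(vals)
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Full metric report for a score/truth batch
#'
#' Computes the complete evaluation suite used for the multilabel
#' differentiation task: P@k for each requested k, Hamming loss, average
#' precision, and label ranking loss.
#'
#' @inheritParams hamming_loss
#' @param ks Integer vector of k values for precision at k.
#' @return A list of class `"metrics_report"`.
#' @export
evaluate_batch <- function(scores, truths, ks = c(1, 3, 5), threshold = 0.5) {
  b <- check_batch(scores, truths)
  ks <- ks[ks <= ncol(b$scores)]
  p_at_k <- vapply(ks, function(k) precision_at_k(b$scores, b$truths, k),
                   numeric(1))
  names(p_at_k) <- paste0("p_at_", ks)
  rep <- list(
    p_at_k = p_at_k,
    hamming_loss = as.numeric(hamming_loss(b$scores, b$truths, threshold)),
    average_precision = as.numeric(average_precision(b$scores, b$truths)),
    label_ranking_loss = as.numeric(label_ranking_loss(b$scores, b$truths)),
    n_samples = nrow(b$scores),
    n_labels = ncol(b$scores)
  )
  class(rep) <- "metrics_report"
  rep
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Multilabel metrics (", x$n_samples, " samples, ", x$n_labels,
      " labels)\n", sep = "")
  for (nm in names(x$p_at_k))
    cat(sprintf("  %-20s %.4f\n", gsub("_", "@", sub("p_at_", "P@", nm)),
                x$p_at_k[[nm]]))
  cat(sprintf("  %-20s %.4f\n", "average precision", x$average_precision))
  cat(sprintf("  %-20s %.4f\n", "hamming loss", x$hamming_loss))
  cat(sprintf("  %-20s %.4f\n", "label ranking loss", x$label_ranking_loss))
  invisible(x)
}
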