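#' Confusion matrix of a binary prediction against a reference
#'
#' @param predicted,reference Logical vectors of equal length (`TRUE` =
#'   dysfunction / positive).
#' @return A `confusion_matrix` with integer fields `tp`, `fp`, `tn`, `fn`.
#' @examples
#' confusion(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))
#' @export
confusion <- function(predicted, reference) {
  if (length(predicted) != length(reference) || length(predicted) < 1) {
    abort("`predicted` and `reference` must be non-empty and of equal length.")
  }
  predicted <- as.logical(predicted)
  reference <- as.logical(reference)
  if (anyNA(predicted) || anyNA(reference)) abort("Missing values are not allowed.")
  confusion_matrix(tp = sum(predicted & reference),
                   fp = sum(predicted & !reference),
                   tn = sum(!predicted & !reference),
                   fn = sum(!predicted & reference))
}

#' @rdname confusion
#' @param tp,fp,tn,fn Non-negative integer cell counts.
#' @export
confusion_matrix <- function(tp, fp, tn, fn) {
  for (nm in c("tp", "fp", "tn", "fn")) {
    v <- get(nm)
    check_number(v, nm, min = 0)
    if (v != round(v)) abort(sprintf("`%s` must be an integer count.", nm))
  }
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 tn = as.integer(tn), fn = as.integer(fn)),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat("Confusion matrix (reference in columns)\n")
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(predicted = c("positive", "negative"),
                              reference = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Diagnostic metrics of a confusion matrix
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, positive and
#' negative predictive values, and accuracy. A metric whose denominator
#' is zero is undefined and reported as `NA`, never as 0.
#'
#' @param cm A [confusion_matrix()].
#' @return One-row tibble of the five metrics.
#' @examples
#' diagnostic_metrics(confusion_matrix(10, 6, 46, 9))
#' @export
diagnostic_metrics <- function(cm) {
  if (!inherits(cm, "confusion_matrix")) abort("`cm` must be a confusion_matrix.")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  tibble::tibble(
    sensitivity = ratio(cm$tp, cm$tp + cm$fn),
    specificity = ratio(cm$tn, cm$tn + cm$fp),
    ppv = ratio(cm$tp, cm$tp + cm$fp),
    npv = ratio(cm$tn, cm$tn + cm$fn),
    accuracy = ratio(cm$tp + cm$tn, cm$tp + cm$fp + cm$tn + cm$fn)
  )
}

#' @export
tidy.confusion_matrix <- function(x, ...) {
  tibble::tibble(cell = c("tp", "fp", "tn", "fn"),
                 count = c(x$tp, x$fp, x$tn, x$fn))
}

#' @export
glance.confusion_matrix <- function(x, ...) diagnostic_metrics(x)

#' Reconstruct a confusion matrix from published rounded metrics
#'
#' Publications report diagnostic performance as metrics rounded to two
#' decimals, not as raw counts. Given the class sizes, this exhaustively
#' enumerates every integer matrix (`tp` in `0..n_pos`, `tn` in
#' `0..n_neg`) and returns the one whose anchored metrics round
#' (half-up, two decimals, the printing convention of clinical tables)
#' to the supplied values. If several matrices qualify, the one with the
#' smallest summed squared deviation from the anchors is returned and
#' marked non-unique; if none qualifies, the error names the nearest
#' candidate.
#'
#' @param n_pos,n_neg Number of reference-positive / -negative subjects.
#' @param anchors Named numeric vector (1-4 entries, names among
#'   `sensitivity`, `specificity`, `ppv`, `npv`, `accuracy`), values as
#'   printed at 2 decimals.
#' @return A [confusion_matrix()] with attributes `unique` (logical) and
#'   `anchors`.
#' @examples
#' reconstruct_confusion(19, 52, c(sensitivity = 0.53, specificity = 0.77))
#' @export
reconstruct_confusion <- function(n_pos, n_neg, anchors) {
  check_number(n_pos, "n_pos", min = 1)
  check_number(n_neg, "n_neg", min = 1)
  if (length(anchors) < 1 || length(anchors) > 4) {
    abort("Between 1 and 4 anchors are required.")
  }
  known <- c("sensitivity", "specificity", "ppv", "npv", "accuracy")
  if (is.null(names(anchors)) || !all(names(anchors) %in% known)) {
    abort(paste0("Anchor names must be among: ", paste(known, collapse = ", "), "."))
  }
  if (any(anchors < 0) || any(anchors > 1)) {
    abort("Anchor values must be proportions in [0, 1]; an impossible anchor cannot be attained by any matrix.")
  }

  grid <- tidyr::expand_grid(tp = 0:n_pos, tn = 0:n_neg)
  ratio <- function(num, den) {
    out <- num / den
    out[rep_len(den == 0, length(out))] <- NA_real_
    out
  }
  m <- dplyr::mutate(
    grid,
    fp = n_neg - .data$tn, fn = n_pos - .data$tp,
    sensitivity = ratio(.data$tp, n_pos),
    specificity = ratio(.data$tn, n_neg),
    ppv = ratio(.data$tp, .data$tp + .data$fp),
    npv = ratio(.data$tn, .data$tn + .data$fn),
    accuracy = (.data$tp + .data$tn) / (n_pos + n_neg)
  )
  exact <- as.matrix(m[names(anchors)])
  dev <- sweep(exact, 2, anchors)
  dev[is.na(dev)] <- Inf
  sumsq <- rowSums(dev^2)
  hit <- rep(TRUE, nrow(m))
  for (j in seq_along(anchors)) {
    r <- round_half_up(exact[, j], 2)
    hit <- hit & !is.na(r) & r == round_half_up(anchors[j], 2)
  }

  if (!any(hit)) {
    best <- m[which.min(sumsq), ]
    abort(sprintf(
      paste0("No integer matrix with %d positives / %d negatives rounds to the ",
             "anchors; nearest candidate is tp=%d, tn=%d (%s)."),
      n_pos, n_neg, best$tp, best$tn,
      paste(sprintf("%s=%.3f", names(anchors), as.numeric(best[names(anchors)])),
            collapse = ", ")))
  }
  cand <- which(hit)
  pick <- cand[which.min(sumsq[cand])]
  if (length(cand) > 1) {
    warn(sprintf("%d matrices round to the anchors; returning the closest (tp=%d, tn=%d).",
                 length(cand), m$tp[pick], m$tn[pick]))
  }
  out <- confusion_matrix(tp = m$tp[pick], fp = m$fp[pick],
                          tn = m$tn[pick], fn = m$fn[pick])
  attr(out, "unique") <- length(cand) == 1
  attr(out, "anchors") <- anchors
  out
}

#' Compare a confusion matrix against printed metric values
#'
#' For each supplied printed value, reports the exact metric, its
#' half-up 2-decimal rounding, and whether that rounding agrees with the
#' print. Published tables occasionally disagree with every integer
#' matrix (e.g. through double rounding at the source); this report
#' surfaces such discrepancies instead of hiding them.
#'
#' @param cm A [confusion_matrix()].
#' @param printed Named numeric vector of printed 2-decimal values.
#' @return Tibble with columns `metric`, `computed`, `rounded`,
#'   `printed`, `agrees`.
#' @examples
#' cm <- reconstruct_confusion(19, 52, c(sensitivity = 0.53, accuracy = 0.79))
#' printed_metric_report(cm, c(ppv = 0.63, npv = 0.84, specificity = 0.89))
#' @export
printed_metric_report <- function(cm, printed) {
  met <- diagnostic_metrics(cm)
  if (is.null(names(printed)) || !all(names(printed) %in% names(met))) {
    abort("`printed` must be named with metric names.")
  }
  computed <- as.numeric(met[names(printed)])
  tibble::tibble(
    metric = names(printed),
    computed = computed,
    rounded = round_half_up(computed, 2),
    printed = as.numeric(printed),
    agrees = round_half_up(computed, 2) == round_half_up(as.numeric(printed), 2)
  )
}

#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney concordance probability (equivalent to
#' trapezoidal integration of the empirical ROC curve): the probability
#' that a random positive case receives a more positive-leaning score
#' than a random negative case, ties counting one half. The orientation
#' must be stated explicitly: for function scores such as erLF or PDR,
#' *lower* values indicate dysfunction, and forgetting to flip the sign
#' would silently report `1 - AUC`.
#'
#' @param scores Numeric scores.
#' @param reference Logical vector (`TRUE` = positive); both classes must
#'   be present.
#' @param orientation `"lower_is_positive"` or `"higher_is_positive"`.
#' @return AUC in `[0, 1]`.
#' @examples
#' roc_auc(c(5, 8, 12, 20), c(TRUE, TRUE, FALSE, FALSE), "lower_is_positive")
#' @export
roc_auc <- function(scores, reference,
                    orientation = c("lower_is_positive", "higher_is_positive")) {
  orientation <- match.arg(orientation)
  reference <- as.logical(reference)
  if (length(scores) != length(reference)) {
    abort("`scores` and `reference` must have equal length.")
  }
  if (!is.numeric(scores) || anyNA(scores) || anyNA(reference)) {
    abort("`scores` and `reference` must be complete.")
  }
  n1 <- sum(reference); n0 <- sum(!reference)
  if (n1 == 0 || n0 == 0) {
    abort("Both classes must be present to compute an AUC.")
  }
  s <- if (orientation == "lower_is_positive") -scores else scores
  r <- rank(s)  # midranks for ties
  (sum(r[reference]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent groups with midranks for ties.
#' The U statistic counts pairs `(a, b)` with `a > b` (ties half). For
#' combined sample sizes up to 12 the two-sided p-value is exact, by
#' enumeration of all group assignments of the pooled ranks (valid under
#' ties, unlike the classical null tables); larger samples use the
#' normal approximation with tie and continuity corrections.
#'
#' @param group_a,group_b Numeric vectors, non-empty.
#' @param exact_limit Combined size at or below which enumeration is used.
#' @return One-row tibble with `u_statistic`, `p_value`, `method`.
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # exact p = 1/3
#' @export
mann_whitney <- function(group_a, group_b, exact_limit = 12) {
  if (length(group_a) < 1 || length(group_b) < 1) {
    abort("Both groups must be non-empty.")
  }
  if (anyNA(group_a) || anyNA(group_b)) abort("Missing values are not allowed.")
  n1 <- length(group_a); n2 <- length(group_b); n <- n1 + n2
  pooled_ranks <- rank(c(group_a, group_b))
  u <- sum(pooled_ranks[seq_len(n1)]) - n1 * (n1 + 1) / 2

  if (n <= exact_limit) {
    picks <- combn(n, n1)
    u_all <- colSums(matrix(pooled_ranks[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= u + eps), mean(u_all >= u - eps)))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    ties <- table(pooled_ranks)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal-approximation"
  }
  tibble::tibble(u_statistic = u, p_value = p, method = method)
}
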