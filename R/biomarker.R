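#' Relative expression by the 2^-ddCt method
#'
#' Per subject, dCt = target Ct - reference (U6) Ct.  The group ddCt is
#' the patient-group dCt statistic minus the control-group statistic
#' (arithmetic mean by default, median via `stat`), and the group fold
#' change is `2^-ddCt`.  Per-subject relative expression
#' (`2^-(dCt - control statistic)`) is returned for downstream ROC
#' analysis.  Subjects missing either Ct are dropped with a warning.
#'
#' @param ct a Ct table: data.frame with `subject`, `group`, `ct_target`,
#'   `ct_reference` (see [simulate_ct_table()]).
#' @param patient,control group labels.
#' @param stat group statistic: `"mean"` (default) or `"median"`.
#' @return a list with `ddct`, `fold_change`, `dct` (per-subject, with
#'   `rel_expr`), and the group dCt statistics.
#' @export
ddct <- function(ct, patient = "patient", control = "control",
                 stat = c("mean", "median")) {
  stat <- match.arg(stat)
  need <- c("subject", "group", "ct_target", "ct_reference")
  if (!all(need %in% names(ct)))
    stop("Ct table needs columns: ", paste(need, collapse = ", "))
  bad <- !is.finite(ct$ct_target) | !is.finite(ct$ct_reference)
  if (any(bad)) {
    warning(sum(bad), " subject(s) dropped for missing Ct values")
    ct <- ct[!bad, , drop = FALSE]
  }
  if (any(ct$ct_target <= 0) || any(ct$ct_reference <= 0))
    stop("Ct values must be positive")
  for (g in c(patient, control))
    if (!any(ct$group == g)) stop("no subjects in group '", g, "'")
  sfun <- if (stat == "mean") mean else stats::median
  dct <- ct$ct_target - ct$ct_reference
  dct_p <- sfun(dct[ct$group == patient])
  dct_c <- sfun(dct[ct$group == control])
  dd <- dct_p - dct_c
  per <- data.frame(subject = ct$subject, group = ct$group, dct = dct,
                    rel_expr = 2^-(dct - dct_c), stringsAsFactors = FALSE)
  list(ddct = dd, fold_change = 2^-dd, dct = per,
       dct_patient = dct_p, dct_control = dct_c, stat = stat)
}

#' Empirical ROC curve with rank-estimator AUC
#'
#' The AUC is the Mann-Whitney rank estimator (ties contribute 1/2), so
#' `auc == U / (n1 * n2)` holds exactly against [mann_whitney()] of the
#' same data.  The 95% CI uses the Hanley-McNeil variance with a normal
#' approximation, truncated to [0, 1].  For markers down-regulated in
#' patients set `direction = "down"`: lower scores then indicate the
#' positive (patient) class.
#'
#' @param score numeric marker values.
#' @param label class labels.
#' @param positive label of the positive class (default "patient").
#' @param direction `"up"` if high scores indicate the positive class,
#'   `"down"` (default) if low scores do.
#' @return an object of class `roc_curve`: `points` (FPR/TPR, cutoff),
#'   `auc`, `ci95`, `n_pos`, `n_neg`, `youden` (the Youden-optimal
#'   operating point), plus the inputs.
#' @export
roc_curve <- function(score, label, positive = "patient",
                      direction = c("down", "up")) {
  direction <- match.arg(direction)
  pos <- label == positive
  if (!any(pos) || all(pos)) stop("both classes must be present")
  s <- if (direction == "down") -score else score
  n1 <- sum(pos); n2 <- sum(!pos)
  r <- rank(s)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n2)

  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  v <- (auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
          (n2 - 1) * (q2 - auc^2)) / (n1 * n2)
  se <- sqrt(max(v, 0))
  ci <- pmin(1, pmax(0, auc + c(-1, 1) * qnorm(0.975) * se))

  # threshold sweep in the oriented space: predict positive when s >= t
  ths <- c(Inf, sort(unique(s), decreasing = TRUE), -Inf)
  tpr <- vapply(ths, function(t) mean(s[pos] >= t), numeric(1))
  fpr <- vapply(ths, function(t) mean(s[!pos] >= t), numeric(1))
  cutoff <- if (direction == "down") -ths else ths
  points <- data.frame(cutoff = cutoff, fpr = fpr, tpr = tpr)
  j <- tpr - fpr
  best <- which.max(j)
  obj <- structure(list(points = points, auc = auc, ci95 = ci,
                        n_pos = n1, n_neg = n2,
                        score = score, label = label, positive = positive,
                        direction = direction),
                   class = "roc_curve")
  obj$youden <- data.frame(cutoff = points$cutoff[best],
                           sensitivity = tpr[best],
                           specificity = 1 - fpr[best],
                           youden_j = j[best])
  obj
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: %d positives vs %d negatives (direction: %s)\n",
              x$n_pos, x$n_neg, x$direction))
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f)\n", x$auc, x$ci95[1], x$ci95[2]))
  cat(sprintf("Youden cutoff %.3g: sensitivity %.1f%%, specificity %.1f%%\n",
              x$youden$cutoff, 100 * x$youden$sensitivity,
              100 * x$youden$specificity))
  invisible(x)
}

#' Sensitivity and specificity at a cutoff
#'
#' With `direction = "down"` (a marker reduced in patients) a subject is
#' called positive when the score is strictly below the cutoff; scores at
#' or above the cutoff are called control-like.  With `direction = "up"`
#' the calls invert (positive iff score >= cutoff).
#'
#' @param roc a `roc_curve`.
#' @param cutoff cutoff on the original score scale.
#' @return a one-row data.frame: `cutoff`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
operating_point <- function(roc, cutoff) {
  stopifnot(inherits(roc, "roc_curve"))
  pos <- roc$label == roc$positive
  call_pos <- if (roc$direction == "down") roc$score < cutoff else
    roc$score >= cutoff
  sens <- mean(call_pos[pos])
  spec <- mean(!call_pos[!pos])
  data.frame(cutoff = cutoff, sensitivity = sens, specificity = spec,
             youden_j = sens + spec - 1)
}
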