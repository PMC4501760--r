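#' Discriminant classification of diagnostic group from the score
#'
#' Linear discriminant analysis (via [MASS::lda()]) of the binary group
#' label on the single consonants-in-noise score, with observed class
#' frequencies as priors by default. Reports the resubstitution confusion
#' matrix and percent correctly classified, Wilks lambda
#' (SS_within / SS_total), the associated chi-square
#' `-(n - 1 - (p + g)/2) log(lambda)` with `p (g - 1)` degrees of freedom,
#' and the one-way F test on group means.
#'
#' @param scores Numeric score vector.
#' @param labels Group labels (two levels, e.g. "LD"/"control").
#' @param priors `"observed"` (class frequencies) or `"equal"`.
#' @return An object of class `dfa_result`: `confusion`, `percent_correct`,
#'   `wilks_lambda`, `chi_sq` (statistic, df, p), `f_test` (statistic, df,
#'   p), `cut` (the equal-prior pooled midpoint, for the single-variable
#'   threshold interpretation), `priors`, `n`, and `degenerate`.
#' @export
discriminant_classify <- function(scores, labels, priors = c("observed", "equal")) {
  priors <- match.arg(priors)
  ok <- complete.cases(cbind(scores, labels))
  s <- as.numeric(scores)[ok]
  g <- factor(labels[ok])
  if (nlevels(g) != 2) stop("labels must have exactly two levels")
  if (any(table(g) < 2)) stop("need at least two children per group")
  n <- length(s)
  means <- tapply(s, g, mean)
  ss_total <- sum((s - mean(s))^2)
  ss_within <- sum(tapply(s, g, function(v) sum((v - mean(v))^2)))
  degenerate <- ss_total == 0
  lambda <- if (degenerate) 1 else ss_within / ss_total
  p_vars <- 1; ng <- 2
  chi_stat <- -(n - 1 - (p_vars + ng) / 2) * log(max(lambda, .FISHER_EPS))
  chi_df <- p_vars * (ng - 1)
  chi_p <- pchisq(chi_stat, chi_df, lower.tail = FALSE)
  f_stat <- if (degenerate) NA_real_ else
    ((ss_total - ss_within) / (ng - 1)) / (ss_within / (n - ng))
  f_p <- if (degenerate) NA_real_ else
    pf(f_stat, ng - 1, n - ng, lower.tail = FALSE)

  pr <- if (priors == "observed") as.numeric(table(g)) / n else c(0.5, 0.5)
  fit <- MASS::lda(matrix(s, ncol = 1), grouping = g, prior = pr)
  pred <- predict(fit, matrix(s, ncol = 1))$class
  confusion <- table(actual = g, predicted = pred)
  structure(list(
    confusion = confusion,
    percent_correct = 100 * mean(pred == g),
    wilks_lambda = lambda,
    chi_sq = list(statistic = chi_stat, df = chi_df, p = chi_p),
    f_test = list(statistic = f_stat, df = c(ng - 1, n - ng), p = f_p),
    group_means = means,
    cut = mean(means),
    priors = setNames(pr, levels(g)),
    n = n, degenerate = degenerate
  ), class = "dfa_result")
}

#' @export
print.dfa_result <- function(x, ...) {
  cat(sprintf(
    "<dfa_result> %.1f%% correctly classified (n = %d), lambda = %.3f, chi-sq(%d) = %.3f, p = %.4g\n",
    x$percent_correct, x$n, x$wilks_lambda, x$chi_sq$df,
    x$chi_sq$statistic, x$chi_sq$p))
  invisible(x)
}

# Hanley-McNeil standard error of an empirical AUC.
#' @noRd
.auc_se_hanley <- function(auc, n_pos, n_neg) {
  q1 <- auc / (2 - auc)
  q2 <- 2 * auc^2 / (1 + auc)
  sqrt((auc * (1 - auc) + (n_pos - 1) * (q1 - auc^2) +
          (n_neg - 1) * (q2 - auc^2)) / (n_pos * n_neg))
}

#' ROC analysis of group membership from the score
#'
#' Empirical ROC over all observed score thresholds, with higher scores
#' taken as evidence for the positive class (default `"control"`: the model
#' is used to "clear" children as unlikely to be reading impaired). The AUC
#' equals the Mann-Whitney U statistic scaled by `n_pos * n_neg`; the 95%
#' confidence interval uses the Hanley-McNeil standard error, and the
#' p-value tests AUC = 0.5 with a two-sided z test on that standard error.
#'
#' @param scores Numeric score vector.
#' @param labels Group labels (two levels).
#' @param positive The positive-class label.
#' @return An object of class `roc_result`: `points` (tibble with
#'   threshold, sensitivity, specificity), `auc`, `ci` (95%), `se`, `p`,
#'   `positive`, `n_pos`, `n_neg`, `degenerate`.
#' @export
roc_analysis <- function(scores, labels, positive = "control") {
  ok <- complete.cases(cbind(scores, labels))
  s <- as.numeric(scores)[ok]
  lab <- as.character(labels[ok])
  if (!positive %in% lab) stop("positive class not present in labels")
  neg <- setdiff(unique(lab), positive)
  if (length(neg) != 1) stop("labels must have exactly two levels")
  n_pos <- sum(lab == positive); n_neg <- sum(lab == neg)
  if (length(unique(s)) == 1) {
    return(structure(list(
      points = tibble::tibble(threshold = c(Inf, -Inf),
                              sensitivity = c(0, 1), specificity = c(1, 0)),
      auc = 0.5, ci = c(NA_real_, NA_real_), se = NA_real_, p = NA_real_,
      positive = positive, n_pos = n_pos, n_neg = n_neg, degenerate = TRUE
    ), class = "roc_result"))
  }
  r <- pROC::roc(response = factor(lab, levels = c(neg, positive)),
                 predictor = s, direction = "<", quiet = TRUE)
  auc <- as.numeric(pROC::auc(r))
  se <- .auc_se_hanley(auc, n_pos, n_neg)
  ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * se, 0), 1)
  p <- 2 * pnorm(-abs((auc - 0.5) / se))
  structure(list(
    points = tibble::tibble(threshold = r$thresholds,
                            sensitivity = r$sensitivities,
                            specificity = r$specificities),
    auc = auc, ci = ci, se = se, p = p,
    positive = positive, n_pos = n_pos, n_neg = n_neg, degenerate = FALSE
  ), class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> AUC = %.3f (95%% CI %.3f-%.3f), p = %.4g; positive = %s (n = %d vs %d)\n",
    x$auc, x$ci[1], x$ci[2], x$p, x$positive, x$n_pos, x$n_neg))
  invisible(x)
}
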