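#' Fit the two-block hierarchical regression
#'
#' Step 1 regresses the outcome on demographic factors (sex, age, non-verbal
#' IQ); Step 2 adds the nine neural-coding predictors. The increment in
#' explained variance (delta R^2) quantifies what neural coding accounts for
#' over and above demographics. Rows with any missing value among the used
#' columns are dropped (listwise deletion, logged). Also reports
#' standardized coefficients (from z-scored columns of the fitting sample),
#' the F-change test for the second block, and per-predictor collinearity
#' tolerances (1 - R^2 of each predictor regressed on the others).
#'
#' @param data Data frame with the outcome and predictor columns.
#' @param outcome Name of the outcome column.
#' @param block1 Names of the demographic (step 1) columns.
#' @param block2 Names of the neural (step 2) columns.
#' @return An object of class `hier_fit`: raw coefficients (`coefficients`,
#'   named, with `(Intercept)`), standardized betas for both steps
#'   (`beta_std_step1`, `beta_std`), `r2_block1`, `r2_total`, `delta_r2`,
#'   `f_change` (statistic, df, p), `f_total`, `tolerance`, `n`,
#'   `n_dropped`, the column roles, and a provenance hash.
#' @export
fit_hierarchical <- function(data,
                             outcome = "phono_awareness",
                             block1 = c("sex", "age", "nonverbal_iq"),
                             block2 = neural_predictors()) {
  used <- c(outcome, block1, block2)
  miss <- setdiff(used, names(data))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- as.data.frame(data)[used]
  cc <- complete.cases(d)
  n_dropped <- sum(!cc)
  d <- d[cc, , drop = FALSE]
  n <- nrow(d)
  k1 <- length(block1); k2 <- length(block2)
  if (n <= k1 + k2 + 1)
    stop("too few complete cases for the design")
  X <- as.matrix(d[c(block1, block2)])
  qrX <- qr(cbind("(Intercept)" = 1, X))
  if (qrX$rank < ncol(X) + 1) {
    cn <- c("(Intercept)", colnames(X))
    bad <- cn[qrX$pivot[(qrX$rank + 1):length(cn)]]
    stop("rank-deficient design; collinear column(s): ",
         paste(bad, collapse = ", "))
  }

  f1 <- stats::as.formula(paste(outcome, "~", paste(block1, collapse = "+")))
  f2 <- stats::as.formula(paste(outcome, "~",
                                paste(c(block1, block2), collapse = "+")))
  m1 <- lm(f1, data = d)
  m2 <- lm(f2, data = d)
  r2_1 <- summary(m1)$r.squared
  r2_t <- summary(m2)$r.squared
  dr2 <- r2_t - r2_1
  df2 <- n - k1 - k2 - 1
  f_change <- (dr2 / k2) / ((1 - r2_t) / df2)
  p_change <- pf(f_change, k2, df2, lower.tail = FALSE)
  f_total <- (r2_t / (k1 + k2)) / ((1 - r2_t) / df2)
  p_total <- pf(f_total, k1 + k2, df2, lower.tail = FALSE)

  zd <- as.data.frame(lapply(d, function(x) (x - mean(x)) / sd(x)))
  b_std1 <- coef(lm(f1, data = zd))[-1]
  b_std2 <- coef(lm(f2, data = zd))[-1]

  preds <- c(block1, block2)
  tolerance <- vapply(preds, function(p) {
    others <- setdiff(preds, p)
    fr <- stats::as.formula(paste(p, "~", paste(others, collapse = "+")))
    1 - summary(lm(fr, data = d))$r.squared
  }, numeric(1))

  structure(list(
    coefficients = coef(m2),
    beta_std_step1 = b_std1, beta_std = b_std2,
    r2_block1 = r2_1, r2_total = r2_t, delta_r2 = dr2,
    f_change = list(statistic = f_change, df1 = k2, df2 = df2, p = p_change),
    f_total = list(statistic = f_total, df1 = k1 + k2, df2 = df2,
                   p = p_total),
    tolerance = tolerance, n = n, n_dropped = n_dropped,
    outcome = outcome, block1 = block1, block2 = block2,
    hash = NA_character_
  ), class = "hier_fit") -> fit
  fit$hash <- .hash(fit[c("coefficients", "outcome", "block1", "block2")])
  fit
}

#' @export
print.hier_fit <- function(x, ...) {
  cat(sprintf(
    "<hier_fit> n = %d (%d dropped)\n  Step 1 R2 = %.3f; Step 2 dR2 = %.3f, F(%d,%d) = %.3f, p = %.4g\n  total R2 = %.3f; tolerance %.3f-%.3f\n",
    x$n, x$n_dropped, x$r2_block1, x$delta_r2, x$f_change$df1,
    x$f_change$df2, x$f_change$statistic, x$f_change$p, x$r2_total,
    min(x$tolerance), max(x$tolerance)
  ))
  invisible(x)
}

#' Apply a frozen fit to a cohort: the consonants-in-noise score
#'
#' Computes `intercept + sum(coefficient * column)` with the raw-scale
#' coefficients of a frozen [fit_hierarchical()] fit. The model is never
#' refit during transfer; a child with any missing predictor receives `NA`
#' and is flagged.
#'
#' @param fit A `hier_fit`.
#' @param newdata Data frame holding all predictor columns of the fit (the
#'   outcome is not required).
#' @return Numeric score vector with attributes `refit_flag` (always
#'   FALSE), `fit_hash`, and `flagged` (row indices with missing
#'   predictors).
#' @export
predict_scores <- function(fit, newdata) {
  stopifnot(inherits(fit, "hier_fit"))
  preds <- c(fit$block1, fit$block2)
  miss <- setdiff(preds, names(newdata))
  if (length(miss))
    stop("newdata lacks predictor column(s): ", paste(miss, collapse = ", "))
  X <- as.matrix(as.data.frame(newdata)[preds])
  scores <- as.numeric(fit$coefficients["(Intercept)"] +
                         X %*% fit$coefficients[preds])
  flagged <- which(!complete.cases(X))
  scores[flagged] <- NA_real_
  attr(scores, "refit_flag") <- FALSE
  attr(scores, "fit_hash") <- fit$hash
  attr(scores, "flagged") <- flagged
  scores
}

#' Correlate scores with a behavioral outcome
#'
#' Pearson correlation with a two-tailed p-value; if the outcome's
#' test-retest reliability is supplied, also reports the disattenuated
#' correlation `r / sqrt(reliability)` (correcting for outcome
#' unreliability only), capped at 1.
#'
#' @param scores Numeric score vector.
#' @param outcome Numeric behavioral outcome, same length.
#' @param reliability Optional reliability in (0, 1].
#' @return List with `r`, `n`, `p`, and `r_adjusted` (NULL if no
#'   reliability given).
#' @export
correlate_scores <- function(scores, outcome, reliability = NULL) {
  ok <- complete.cases(cbind(scores, outcome))
  s <- as.numeric(scores)[ok]; y <- outcome[ok]
  if (sd(s) == 0 || sd(y) == 0) stop("zero variance: correlation undefined")
  ct <- cor.test(s, y, alternative = "two.sided", method = "pearson")
  r_adj <- NULL
  if (!is.null(reliability)) {
    if (reliability <= 0 || reliability > 1)
      stop("reliability must be in (0, 1]")
    r_adj <- sign(ct$estimate) * min(abs(ct$estimate) / sqrt(reliability), 1)
    r_adj <- unname(r_adj)
  }
  list(r = unname(ct$estimate), n = sum(ok), p = ct$p.value,
       r_adjusted = r_adj)
}

#' Prediction-error summary
#'
#' Absolute differences between actual and model-predicted scores, as used
#' to summarise how close individual predictions fall to observed test
#' scores.
#'
#' @param actual,predicted Paired numeric vectors.
#' @return List with `median`, `range`, and the vector of absolute errors.
#' @export
prediction_error_summary <- function(actual, predicted) {
  ok <- complete.cases(cbind(actual, predicted))
  e <- abs(actual[ok] - predicted[ok])
  list(median = median(e), range = range(e), abs_error = e)
}

#' Cross-validate the hierarchical model
#'
#' Refits the model on a random subset of `n_train` children and transfers
#' the frozen fit to the remaining children, reporting the holdout Pearson
#' correlation between frozen-model scores and the observed outcome.
#'
#' @param data Data frame with outcome and predictors.
#' @param n_train Training-set size (default 20, leaving 17 of a 37-child
#'   cohort for holdout).
#' @param seed RNG seed for the random split.
#' @param outcome,block1,block2 Column roles, as in [fit_hierarchical()].
#' @return List with `train_fit`, `holdout_r` (a [correlate_scores()]
#'   result), `train_idx`, and `holdout_idx`.
#' @export
cross_validate <- function(data, n_train = 20, seed = NULL,
                           outcome = "phono_awareness",
                           block1 = c("sex", "age", "nonverbal_iq"),
                           block2 = neural_predictors()) {
  n <- nrow(data)
  if (n_train >= n) stop("n_train must leave at least one holdout child")
  if (n_train <= length(block1) + length(block2) + 1)
    stop("n_train too small for the design")
  .with_seed(seed, {
    tr <- sort(sample.int(n, n_train))
    ho <- setdiff(seq_len(n), tr)
    fit <- fit_hierarchical(data[tr, , drop = FALSE], outcome, block1, block2)
    sc <- predict_scores(fit, data[ho, , drop = FALSE])
    r <- correlate_scores(sc, data[[outcome]][ho])
    list(train_fit = fit, holdout_r = r, train_idx = tr, holdout_idx = ho)
  })
}

#' Serialize a fitted model to JSON
#' @param fit A `hier_fit`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  stopifnot(inherits(fit, "hier_fit"))
  x <- unclass(fit)
  for (f in c("coefficients", "beta_std", "beta_std_step1", "tolerance"))
    x[[f]] <- as.list(x[[f]])  # keep names in the JSON object
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a fitted model from JSON
#' @param path Path written by [write_fit()].
#' @return A `hier_fit`.
#' @export
read_fit <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$coefficients <- unlist(x$coefficients)
  x$beta_std <- unlist(x$beta_std)
  x$beta_std_step1 <- unlist(x$beta_std_step1)
  x$tolerance <- unlist(x$tolerance)
  structure(x, class = "hier_fit")
}
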