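# Shared fixtures, all built in code.

# A minimal trial_set around given sample rows (uV), for direct stage tests.
make_trial_set <- function(rows, sample_rate = 8000, t0 = -40,
                           epoch_window = c(-40, 210)) {
  if (is.null(dim(rows))) rows <- matrix(rows, nrow = 1)
  structure(list(
    trials = rows,
    polarity = rep(c("condensation", "rarefaction"),
                   length.out = nrow(rows)),
    sample_rate = sample_rate, t0 = t0, epoch_window = epoch_window
  ), class = "trial_set")
}

# Matrix of identical rows.
rep_rows <- function(x, n) matrix(rep(x, each = n), nrow = n)

# Planted two-block linear design with independent standard-normal
# predictors; noise_sd chosen so the population R^2 equals r2_target.
# Returns the data plus the implied standardized coefficients.
planted_design <- function(n, seed, r2_target = 0.68,
                           beta = c(sex = -0.5, age = 0.4,
                                    nonverbal_iq = 0.3,
                                    stats::setNames(seq(0.4, -0.4,
                                                        length.out = 9),
                                                    neural_predictors()))) {
  withr::with_seed(seed, {
    cols <- names(beta)
    d <- as.data.frame(matrix(rnorm(n * length(cols)), n,
                              dimnames = list(NULL, cols)))
    var_lp <- sum(beta^2)
    noise_sd <- sqrt(var_lp * (1 - r2_target) / r2_target)
    d$phono_awareness <- 25 + as.matrix(d) %*% beta + rnorm(n, 0, noise_sd)
    d$phono_awareness <- as.numeric(d$phono_awareness)
    sd_y <- sqrt(var_lp + noise_sd^2)
    list(data = d, beta = beta, beta_std_true = beta / sd_y,
         r2_true = r2_target)
  })
}

# Two-group Gaussian scores for classification tests.
two_group_scores <- function(n_control = 29, n_ld = 26, d = 1, seed = 1) {
  withr::with_seed(seed, {
    list(scores = c(rnorm(n_control, d), rnorm(n_ld, 0)),
         labels = rep(c("control", "LD"), c(n_control, n_ld)))
  })
}

# Exhaustive pairwise Mann-Whitney AUC oracle.
auc_pairwise <- function(scores, labels, positive = "control") {
  sp <- scores[labels == positive]
  sn <- scores[labels != positive]
  mean(outer(sp, sn, ">") + 0.5 * outer(sp, sn, "=="))
}
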