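#' Random-intercept linear mixed-effects model for modality comparisons
#'
#' Fits `accuracy ~ modality + (1 | participant)` by restricted maximum
#' likelihood: sensing modality is the categorical fixed effect and the
#' participant random intercept absorbs the repeated-measures structure.
#' Estimated marginal means (EMMs) per modality and their standard errors
#' are computed from the generalized-least-squares fixed-effect solution;
#' under the balanced design used here they coincide with the raw level
#' means.
#'
#' @param records Accuracy records (one scheme), e.g. a subset of
#'   [run_evaluation()] output.
#' @param response,level_col,subject_col Column names of the response, the
#'   fixed-effect factor and the grouping factor.
#' @param transform `"identity"` fits the accuracies as-is; `"rank"`
#'   rank-transforms the response first (a robust option for schemes whose
#'   accuracy distributions are skewed).
#' @return An `lme_fit` with `levels`, `emm` (level, estimate, se),
#'   `sigma_u` (random-intercept SD), `sigma_e` (residual SD), `beta`,
#'   `vcov_beta`, `n_subjects`, `n_obs` and the underlying `lme4` fit.
#' @export
fit_modality_lme <- function(records, response = "accuracy_pct",
                             level_col = "modality",
                             subject_col = "participant_id",
                             transform = c("identity", "rank")) {
  transform <- match.arg(transform)
  df <- data.frame(
    y = records[[response]],
    level = factor(records[[level_col]]),
    subject = factor(records[[subject_col]])
  )
  if (anyNA(df)) stop("records contain missing values", call. = FALSE)
  if (nlevels(df$level) < 2L) {
    stop("need at least 2 factor levels, got ", nlevels(df$level),
         call. = FALSE)
  }
  if (nlevels(df$subject) < 3L) {
    stop("need at least 3 subjects, got ", nlevels(df$subject),
         call. = FALSE)
  }
  cells <- table(df$subject, df$level)
  if (any(cells == 0L)) {
    stop("unbalanced design: some subject x level cells are empty",
         call. = FALSE)
  }
  if (transform == "rank") df$y <- rank(df$y)
  fit <- lme4::lmer(y ~ level + (1 | subject), data = df, REML = TRUE)
  beta <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  sigma_u <- vc$sdcor[vc$grp == "subject"]
  sigma_e <- vc$sdcor[vc$grp == "Residual"]
  v_beta <- as.matrix(stats::vcov(fit))
  # EMM of level j: L_j beta with treatment contrasts
  lev <- levels(df$level)
  L <- cbind(1, rbind(0, diag(length(lev) - 1L)))
  emm <- data.frame(
    level = lev,
    estimate = as.vector(L %*% beta),
    se = sqrt(diag(L %*% v_beta %*% t(L)))
  )
  structure(
    list(levels = lev, emm = emm, sigma_u = sigma_u, sigma_e = sigma_e,
         beta = beta, vcov_beta = v_beta, contrast_matrix = L,
         n_subjects = nlevels(df$subject), n_obs = nrow(df),
         transform = transform, model = fit),
    class = "lme_fit"
  )
}

#' Pairwise contrasts of estimated marginal means
#'
#' All level pairs of the fitted fixed effect, with standard errors from
#' the GLS covariance of the fixed effects, two-sided p-values from the
#' normal reference distribution, and Benjamini-Hochberg adjustment across
#' the pairs of the model.
#'
#' @param fit An `lme_fit`.
#' @param alpha Significance level for the `significant` flag (applied to
#'   the adjusted p-values).
#' @return Data.frame with one row per pair: `level_1`, `level_2`,
#'   `estimate` (EMM difference), `se`, `z`, `p_value`, `p_adjusted`,
#'   `significant`.
#' @export
pairwise_emm_contrasts <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lme_fit"))
  lev <- fit$levels
  if (length(lev) < 2L) stop("need at least 2 levels", call. = FALSE)
  pairs <- utils::combn(seq_along(lev), 2)
  L <- fit$contrast_matrix
  est <- se <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    cj <- L[pairs[1, j], ] - L[pairs[2, j], ]
    est[j] <- sum(cj * fit$beta)
    se[j] <- sqrt(as.numeric(t(cj) %*% fit$vcov_beta %*% cj))
  }
  z <- est / se
  p <- 2 * stats::pnorm(-abs(z))
  p_adj <- bh_fdr(p)
  data.frame(
    level_1 = lev[pairs[1, ]], level_2 = lev[pairs[2, ]],
    estimate = est, se = se, z = z, p_value = p, p_adjusted = p_adj,
    significant = p_adj < alpha,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values `min_{j: rank(j) >= rank(i)} m * p_(j) / j`,
#' capped at 1, in the input order.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_fdr <- function(pvalues) {
  if (!is.numeric(pvalues) || anyNA(pvalues) ||
      any(pvalues < 0 | pvalues > 1)) {
    stop("p-values must be numbers in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' @export
print.lme_fit <- function(x, ...) {
  cat(sprintf(
    "<lme_fit> %d levels, %d subjects, %d obs; sigma_u = %.3f, sigma_e = %.3f%s\n",
    length(x$levels), x$n_subjects, x$n_obs, x$sigma_u, x$sigma_e,
    if (x$transform == "rank") " (rank-transformed response)" else ""
  ))
  print(x$emm, row.names = FALSE)
  invisible(x)
}
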