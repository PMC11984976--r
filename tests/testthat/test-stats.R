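# Balanced accuracy-style records: n_sub subjects x levels, y = mu_level +
# u_subject + e.
make_records <- function(n_sub = 12, levels = c("emg", "fmg", "emg_fmg"),
                         mu = c(80, 75, 90), sigma_u = 5, sigma_e = 3,
                         seed = 1) {
  set.seed(seed)
  u <- rnorm(n_sub, 0, sigma_u)
  out <- expand.grid(participant_id = sprintf("P%02d", seq_len(n_sub)),
                     modality = levels, stringsAsFactors = FALSE)
  out$accuracy_pct <- mu[match(out$modality, levels)] +
    u[match(out$participant_id, sprintf("P%02d", seq_len(n_sub)))] +
    rnorm(nrow(out), 0, sigma_e)
  out
}

test_that("with independent errors the fixed estimates match OLS", {
  recs <- make_records(sigma_u = 0, sigma_e = 4, seed = 5)
  fit <- fit_modality_lme(recs)
  ols <- lm(accuracy_pct ~ factor(modality), data = recs)
  # balanced design: GLS fixed effects coincide with OLS
  expect_equal(unname(fit$beta), unname(coef(ols)), tolerance = 1e-6)
})

test_that("EMMs equal the raw level means under the balanced design", {
  recs <- make_records(seed = 2)
  fit <- fit_modality_lme(recs)
  raw <- tapply(recs$accuracy_pct, recs$modality, mean)
  expect_equal(fit$emm$estimate, as.numeric(raw[fit$emm$level]),
               tolerance = 1e-8)
})

test_that("EMMs agree with the emmeans reference implementation", {
  skip_if_not_installed("emmeans")
  recs <- make_records(seed = 8)
  fit <- fit_modality_lme(recs)
  ref <- as.data.frame(emmeans::emmeans(fit$model, "level"))
  expect_equal(fit$emm$estimate, ref$emmean[match(fit$emm$level, ref$level)],
               tolerance = 1e-6)
  expect_equal(fit$emm$se, ref$SE[match(fit$emm$level, ref$level)],
               tolerance = 1e-6)
})

test_that("adding a constant shifts the intercept and nothing else", {
  recs <- make_records(seed = 3)
  fit1 <- fit_modality_lme(recs)
  recs2 <- recs
  recs2$accuracy_pct <- recs2$accuracy_pct + 7
  fit2 <- fit_modality_lme(recs2)
  expect_equal(fit2$beta[1], fit1$beta[1] + 7, tolerance = 1e-6,
               ignore_attr = TRUE)
  expect_equal(fit2$beta[-1], fit1$beta[-1], tolerance = 1e-6)
  expect_equal(fit2$sigma_u, fit1$sigma_u, tolerance = 1e-6)
  expect_equal(fit2$sigma_e, fit1$sigma_e, tolerance = 1e-6)
})

test_that("the REML variance ratio matches a grid-search oracle", {
  # tiny fixture: 5 subjects x 2 levels; profile the REML criterion over
  # the variance ratio phi = sigma_u^2 / sigma_e^2 by brute force
  recs <- make_records(n_sub = 5, levels = c("emg", "fmg"), mu = c(80, 70),
                       sigma_u = 4, sigma_e = 2, seed = 9)
  fit <- fit_modality_lme(recs)
  y <- recs$accuracy_pct
  X <- model.matrix(~ factor(recs$modality))
  Z <- model.matrix(~ 0 + factor(recs$participant_id))
  n <- length(y)
  p <- ncol(X)
  reml_crit <- function(phi) {
    V <- diag(n) + phi * tcrossprod(Z)
    Vi <- solve(V)
    XtViX <- t(X) %*% Vi %*% X
    beta <- solve(XtViX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - p)
    -0.5 * (determinant(V)$modulus + determinant(XtViX)$modulus +
              (n - p) * log(s2))
  }
  grid <- seq(0.01, 30, by = 0.001)
  phi_hat <- grid[which.max(vapply(grid, reml_crit, 0))]
  expect_equal(fit$sigma_u^2 / fit$sigma_e^2, phi_hat, tolerance = 2e-3)
})

test_that("pairwise contrasts enumerate all level pairs with BH adjustment", {
  recs <- make_records(n_sub = 10, seed = 4)
  fit <- fit_modality_lme(recs)
  ct <- pairwise_emm_contrasts(fit)
  expect_equal(nrow(ct), 3L)              # K(K-1)/2 with K = 3
  expect_true(all(ct$p_adjusted >= ct$p_value))
  expect_true(all(ct$p_adjusted <= 1))
  expect_equal(ct$significant, ct$p_adjusted < 0.05)
  # contrast estimates are EMM differences
  emm <- fit$emm
  for (j in seq_len(nrow(ct))) {
    expect_equal(ct$estimate[j],
                 emm$estimate[emm$level == ct$level_1[j]] -
                   emm$estimate[emm$level == ct$level_2[j]],
                 tolerance = 1e-10)
  }
})

test_that("a 10-sigma shifted level is flagged in both its contrasts", {
  recs <- make_records(n_sub = 10, mu = c(80, 80, 80 + 30), sigma_u = 2,
                       sigma_e = 3, seed = 6)
  ct <- pairwise_emm_contrasts(fit_modality_lme(recs))
  hit <- ct$level_1 == "emg_fmg" | ct$level_2 == "emg_fmg"
  expect_true(all(ct$significant[hit]))
  expect_false(any(ct$significant[!hit]))
})

test_that("rank transformation is exposed and preserves the level order", {
  recs <- make_records(n_sub = 8, mu = c(70, 60, 90), sigma_u = 1,
                       sigma_e = 1, seed = 7)
  fit <- fit_modality_lme(recs, transform = "rank")
  expect_equal(fit$transform, "rank")
  emm <- fit$emm
  expect_gt(emm$estimate[emm$level == "emg_fmg"],
            emm$estimate[emm$level == "emg"])
  expect_gt(emm$estimate[emm$level == "emg"],
            emm$estimate[emm$level == "fmg"])
})

test_that("degenerate inputs are rejected with labelled errors", {
  recs <- make_records()
  expect_error(fit_modality_lme(recs[recs$modality == "emg", ]), "2 factor")
  expect_error(fit_modality_lme(recs[recs$participant_id %in%
                                       c("P01", "P02"), ]), "3 subjects")
  expect_error(fit_modality_lme(recs[-1, ]), "unbalanced")
})

test_that("Benjamini-Hochberg adjustment matches the step-up rule", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205)
  adj <- bh_fdr(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= -1e-12))   # monotone on sorted input
  # hand application of min_j { m p_(j) / j } for the first entries
  expect_equal(adj[1], 0.008)   # min(8*0.001/1, 8*0.008/2, ...) = 0.008
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  # never flags more discoveries than unadjusted testing
  expect_lte(sum(adj < 0.05), sum(p < 0.05))
})
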