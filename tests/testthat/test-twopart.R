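two_cell_trial <- function(n = 600, seed = 1, sigma_c = 0.25, k = 1.2) {
  d <- build_design(6, 8, seed = seed)
  p <- make_test_params(
    arm_totals = c(usual = as.integer(n / 2), revealed = as.integer(n / 2)),
    cells = c("gt100:normal", "lt12:preeclampsia"),
    p = 0.55, mu = 3.5, k = k,
    sigma_c = sigma_c, beta_t = 0,
    arm_logit_shift = -0.5, arm_log_shift = -0.25)
  simulate_trial(d, p, seed = seed)
}

test_that("two-part fit reports a coherent likelihood and AIC identity", {
  tr <- two_cell_trial(800, seed = 2)
  fit <- fit_two_part(tr, "outpatient")
  expect_s3_class(fit, "two_part_fit")
  expect_true(fit$converged)
  # AIC identity, recomputed independently from the parts
  ll <- as.numeric(logLik(fit$part1)) + as.numeric(logLik(fit$part2))
  df <- attr(logLik(fit$part1), "df") + attr(logLik(fit$part2), "df")
  expect_equal(fit$logLik, ll)
  expect_equal(fit$df, df)
  expect_equal(fit$AIC, 2 * df - 2 * ll)
  expect_equal(AIC(fit), fit$AIC) # via the logLik method
  expect_gt(fit$k, 0)
})

test_that("with no between-centre variance the mixed fit collapses to the plain fit", {
  tr <- two_cell_trial(6000, seed = 3, sigma_c = 0)
  fit <- fit_two_part(tr, "antenatal_ward")
  expect_lt(fit$sigma_c[["part1"]], 0.05)
  # fixed effects match a no-random-effect logistic fit
  mf <- plgfcea:::prepare_model_frame(tr, "antenatal_ward")
  keep <- mf$cellarm %in% fit$combos$estimable
  sub <- droplevels(mf[keep, ])
  plain <- glm(use ~ cellarm + time_c, data = sub, family = binomial())
  b_mixed <- plgfcea:::fe_parts(fit$part1)$beta
  b_plain <- coef(plain)
  expect_equal(unname(b_mixed[names(b_plain)]), unname(b_plain),
               tolerance = 1e-3)
})

test_that("single-cluster fit matches direct maximum likelihood of the hurdle model", {
  # one cluster, one step, one subgroup: intercept-only two-part model
  d <- build_design(1, 2, seed = 1)
  p <- make_test_params(arm_totals = c(usual = 500L, revealed = 500L),
                        p = 0.6, mu = 4, k = 1.5)
  tr <- simulate_trial(d, p, seed = 4)
  tr <- tr[tr$step == 0, ] # usual arm only: no covariates at all
  fit <- fit_two_part(tr, "outpatient")
  b <- coef(fit)

  # independent oracle: direct optimisation of the factorised likelihood
  y <- tr$outpatient
  use <- as.integer(y > 0)
  nll <- function(par) {
    -sum(dbinom(use, 1, plogis(par[1]), log = TRUE)) -
      sum(dtnb_log(y[y > 0], exp(par[2]), exp(par[3])))
  }
  opt <- optim(c(0, 1, 0), nll, method = "BFGS")
  expect_lt(abs(b$part1[["(Intercept)"]] - opt$par[1]), 1e-2)
  expect_lt(abs(b$part2[["(Intercept)"]] - opt$par[2]), 1e-2)
  expect_lt(abs(log(fit$k) - opt$par[3]), 5e-2)
})

test_that("adjusted means equal the hurdle identity p * E[Y | Y > 0] from the coefficients", {
  tr <- two_cell_trial(800, seed = 5)
  fit <- fit_two_part(tr, "outpatient")
  am <- suppressWarnings(adjusted_means(fit))
  expect_identical(nrow(am), 18L)
  b <- coef(fit)
  ref <- fit$combos$estimable[1]
  for (cb in fit$combos$estimable) {
    eta1 <- b$part1[["(Intercept)"]] +
      if (cb == ref) 0 else b$part1[[paste0("cellarm", cb)]]
    eta2 <- b$part2[["(Intercept)"]] +
      if (cb == ref) 0 else b$part2[[paste0("cellarm", cb)]]
    expected <- plogis(eta1) * plgfcea:::tnb_cond_mean(exp(eta2), fit$k)
    parts <- strsplit(cb, "[:/]")[[1]]
    got <- am$mean[am$plgf == parts[1] & am$diagnosis == parts[2] &
                     am$arm == parts[3]]
    expect_equal(got, expected, tolerance = 1e-8)
  }
  # cells without data are emitted as fixed zeros, never dropped
  empty <- am[!(paste0(am$plgf, ":", am$diagnosis) %in%
                  c("gt100:normal", "lt12:preeclampsia")), ]
  expect_true(all(empty$mean == 0 & empty$se == 0 & empty$dist == "fixed"))
})

test_that("shifting the positive part upward increases every predicted mean", {
  tr <- two_cell_trial(800, seed = 6)
  fit1 <- fit_two_part(tr, "outpatient")
  tr2 <- tr
  tr2$outpatient <- ifelse(tr$outpatient > 0, tr$outpatient + 2L, 0L)
  fit2 <- fit_two_part(tr2, "outpatient")
  am1 <- suppressWarnings(adjusted_means(fit1))
  am2 <- suppressWarnings(adjusted_means(fit2))
  est <- am1$dist != "fixed"
  expect_true(all(am2$mean[est] > am1$mean[est]))
})

test_that("predict() maps records to their subgroup-arm adjusted means", {
  tr <- two_cell_trial(600, seed = 7)
  fit <- fit_two_part(tr, "outpatient")
  am <- suppressWarnings(adjusted_means(fit))
  pr <- suppressWarnings(predict(fit, tr[1:20, ]))
  key <- paste(am$plgf, am$diagnosis, am$arm)
  expect_equal(pr, am$mean[match(paste(tr$plgf, tr$diagnosis, tr$arm)[1:20],
                                 key)])
  expect_error(suppressWarnings(predict(fit, data.frame(plgf = "x",
    diagnosis = "y", arm = "usual"))), "unknown")
})
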