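test_that("truncated-NB parent-mean inversion and sampler agree with closed forms", {
  for (k in c(0.5, 1.5, 10, Inf)) {
    for (m in c(1.3, 2, 4.7, 9)) {
      parent <- plgfcea:::tnb_parent_mean(m, k)
      expect_equal(plgfcea:::tnb_cond_mean(parent, k), m, tolerance = 1e-9)
    }
  }
  # 1e6-draw simulation against the closed-form conditional mean
  set.seed(1)
  draws <- plgfcea:::rtrunc_nbinom(1e6, mu = 2.5, size = 1.2)
  expect_true(all(draws >= 1))
  m_true <- plgfcea:::tnb_cond_mean(2.5, 1.2)
  expect_lt(abs(mean(draws) - m_true), 3 * sd(draws) / sqrt(1e6))
})

test_that("sampled women reproduce arm totals, subgroup closure and PlGF marginals", {
  d <- build_design(11, 12, seed = 1)
  params <- default_generator_params()
  w <- sample_women(d, params, seed = 1)
  expect_identical(as.integer(table(w$arm)[c("usual", "revealed")]),
                   c(434L, 571L))
  cell <- paste(w$plgf, w$diagnosis, sep = ":")
  expect_true(all(cell %in% cell_levels()))
  expect_identical(sum(table(cell)), nrow(w))

  # marginal PlGF proportions at large n: 38.2 / 38.3 / 23.5 percent
  big <- params
  big$arm_totals <- c(usual = 50000L, revealed = 50000L)
  wb <- sample_women(d, big, seed = 2)
  props <- prop.table(table(factor(wb$plgf, plgf_levels())))
  target <- c(gt100 = 0.382, "12to100" = 0.383, lt12 = 0.235)
  for (b in names(target)) {
    se <- sqrt(target[[b]] * (1 - target[[b]]) / nrow(wb))
    expect_lt(abs(props[[b]] - target[[b]]), 3 * se)
  }
})

test_that("a point-mass subgroup distribution puts every woman in that cell", {
  d <- build_design(3, 5, seed = 1)
  p <- make_test_params(cells = "lt12:preeclampsia")
  w <- sample_women(d, p, seed = 1)
  expect_true(all(w$plgf == "lt12" & w$diagnosis == "preeclampsia"))
})

test_that("identical parameters and seed give a byte-identical dataset", {
  d <- build_design(5, 7, seed = 3)
  p <- make_test_params(sigma_c = 0.3, beta_t = 0.01)
  t1 <- simulate_trial(d, p, seed = 11)
  t2 <- simulate_trial(d, p, seed = 11)
  expect_identical(t1, t2)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_trial_csv(t1, f1); write_trial_csv(t2, f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  t3 <- simulate_trial(d, p, seed = 12)
  expect_false(identical(t1[names(t1) != "id"], t3[names(t3) != "id"]))
})

test_that("zero hurdle probability gives all-zero resource use", {
  d <- build_design(2, 4, seed = 1)
  p <- make_test_params(p = 0)
  tr <- simulate_trial(d, p, seed = 1)
  expect_true(all(tr[resource_categories()$category] == 0))
  expect_true(all(!tr$infant_icu_hdu_admit))
})

test_that("empirical hurdle means converge to p * mu_pos without centre or time effects", {
  d <- build_design(2, 4, seed = 1)
  p <- make_test_params(arm_totals = c(usual = 50000L, revealed = 50000L),
                        p = 0.4, mu = 3.5, k = 1.2,
                        sigma_c = 0, beta_t = 0)
  tr <- simulate_trial(d, p, seed = 5)
  for (cat in c("outpatient", "infant_scbu")) {
    y <- tr[[cat]]
    expect_lt(abs(mean(y) - 0.4 * 3.5), 3 * sd(y) / sqrt(length(y)))
    # admission days positive iff flagged
    if (cat == "infant_icu_hdu") {
      expect_identical(y > 0, tr$infant_icu_hdu_admit)
    }
  }
  # strong overdispersion: positives have variance above their mean
  pos <- tr$outpatient[tr$outpatient > 0]
  expect_gt(var(pos), mean(pos))
})

test_that("centre effects and secular trend shift use rates in the expected direction", {
  d <- build_design(2, 12, seed = 1)
  p <- make_test_params(arm_totals = c(usual = 20000L, revealed = 20000L),
                        p = 0.3, mu = 3, beta_t = 0.2)
  tr <- simulate_trial(d, p, seed = 7)
  early <- tr$outpatient[tr$step <= 3] > 0
  late <- tr$outpatient[tr$step >= 8] > 0
  expect_gt(mean(late), mean(early))
})

test_that("adverse-event flags follow the per-arm rates", {
  d <- build_design(2, 4, seed = 1)
  p <- make_test_params(arm_totals = c(usual = 50000L, revealed = 50000L))

  p$adverse <- list(events_usual = 0L, n_usual = 100L,
                    events_plgf = 100L, n_plgf = 100L)
  tr <- simulate_trial(d, p, seed = 1)
  expect_true(all(!tr$adverse_event[tr$arm == "usual"]))
  expect_true(all(tr$adverse_event[tr$arm == "revealed"]))

  p$adverse <- list(events_usual = 24L, n_usual = 447L,
                    events_plgf = 22L, n_plgf = 573L)
  tr <- simulate_trial(d, p, seed = 2)
  rates <- tapply(tr$adverse_event, tr$arm, mean)
  for (arm in c("usual", "revealed")) {
    r0 <- if (arm == "usual") 24 / 447 else 22 / 573
    se <- sqrt(r0 * (1 - r0) / 50000)
    expect_lt(abs(rates[[arm]] - r0), 3 * se)
  }
})

test_that("trial CSV round-trips through the documented schema", {
  d <- build_design(3, 5, seed = 2)
  tr <- simulate_trial(d, make_test_params(), seed = 3)
  f <- tempfile(fileext = ".csv")
  write_trial_csv(tr, f)
  back <- read_trial_csv(f)
  expect_equal(back, as.data.frame(tr)[plgfcea:::trial_columns()],
               ignore_attr = TRUE)
  # schema violations are rejected by name
  bad <- tr; bad$plgf[1] <- "unknown_band"
  fb <- tempfile(fileext = ".csv"); write_trial_csv(bad, fb)
  expect_error(read_trial_csv(fb), "unknown_band")
  expect_error(write_trial_csv(tr[, -3], f), "step")
})
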