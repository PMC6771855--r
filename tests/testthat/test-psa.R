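uc_flat <- function() {
  # unit costs of 1 GBP make quantity differences equal cost differences
  plgfcea:::new_unit_cost_table(
    setNames(rep(1, 7), resource_categories()$category),
    setNames(rep(1000, 4), delivery_modes()), 70, "test GBP")
}

test_that("degenerate standard errors make every iteration the point estimate", {
  am <- make_am_grid(function(c, l, a) if (a == "revealed") 1 else 2,
                     function(c, l, a) 0)
  res <- run_psa(am, uc_flat(), weights = equal_weights(),
                 n_iterations = 50, seed = 1)
  # every category difference is -1 per cell, 7 categories
  expect_true(all(abs(res$totals$weighted[res$totals$group == "combined"] -
                        (-7)) < 1e-9))
  expect_true(all(res$totals$pct_saving == 100))
  expect_true(all(res$prob_without_test == 1))
  # all-saving cells: probability 1 everywhere
  expect_true(all(res$cell_stats$pct_saving == 100))
})

test_that("equal arms give zero difference and truncation keeps quantities nonnegative", {
  am <- make_am_grid(function(c, l, a) 2, function(c, l, a) 0)
  res <- run_psa(am, uc_flat(), weights = equal_weights(),
                 n_iterations = 20, seed = 1)
  expect_true(all(abs(res$totals$actual) < 1e-9))
  expect_true(all(abs(res$totals$weighted) < 1e-9))

  x <- plgfcea:::rtruncnorm0(5000, mean = 0.5, sd = 2)
  expect_true(all(x >= 0))
  set.seed(1)
  big <- plgfcea:::rtruncnorm0(20000, mean = 30, sd = 1)
  expect_lt(abs(mean(big) - 30), 3 * 1 / sqrt(20000))
})

test_that("Monte Carlo draw means converge to the adjusted means", {
  am <- make_am_grid(function(c, l, a) 20 + c, function(c, l, a) 2)
  res <- run_psa(am, uc_flat(), weights = equal_weights(),
                 n_iterations = 5000, seed = 2)
  # each cell difference has mean 0 and sd sqrt(8); MC SE = sqrt(8/5000);
  # 4-sigma bands because 63 cells are checked simultaneously
  cells <- res$cell_stats[res$cell_stats$group %in%
                            resource_categories()$category, ]
  expect_true(all(abs(cells$actual) < 4 * sqrt(8 / 5000)))
})

test_that("per-iteration accounting identities hold to 1e-9 GBP", {
  am <- make_am_grid(function(c, l, a) 3 + c / 2 + l / 3 +
                       (a == "revealed") * -0.4,
                     function(c, l, a) 0.5 + c / 10)
  w <- cell_weights(default_pipeline()$trial)
  res <- run_psa(am, default_unit_costs(), weights = w,
                 n_iterations = 500, seed = 3)
  wd <- res$weighted_draws
  expect_lt(max(abs(wd$combined - (wd$maternal + wd$infant))), 1e-9)
  # weighted draws equal the weight-sum of stored per-cell differences
  rc <- resource_categories()
  recomputed <- Reduce(`+`, lapply(rc$category[rc$group == "maternal"],
                                   function(cat)
                                     drop(res$cell_diff_draws[[cat]] %*% w)))
  expect_lt(max(abs(recomputed - wd$maternal)), 1e-9)
  expect_equal(sum(w), 1, tolerance = 1e-12)
})

test_that("weight_costs validates and applies subgroup weights", {
  expect_error(weight_costs(1:9, rep(0.1, 9)), "sum to 1")
  expect_error(weight_costs(1:9, c(-0.1, rep(1.1 / 8, 8))), "nonnegative")
  w <- rep(0, 9); w[4] <- 1
  expect_equal(weight_costs(11:19, w), 14)
  # zero weight means zero contribution
  w2 <- c(0.5, 0.5, rep(0, 7))
  expect_equal(weight_costs(c(10, 20, rep(1e6, 7)), w2), 15)
  # a cell observed at -647 GBP with weight 0.127 contributes about -82 GBP
  expect_equal(round(-647 * 0.127), -82)
  m <- matrix(1:18, nrow = 2, byrow = TRUE)
  expect_equal(weight_costs(m, w), c(4, 13))
})

test_that("cost-saving probability matches a brute-force recount", {
  expect_equal(prob_cost_saving(c(-1, -2, 3, -4)), 0.75)
  expect_equal(prob_cost_saving(c(1, 2)), 0)
  expect_equal(prob_cost_saving(c(0, -1)), 0.5) # zero is not a saving
  set.seed(4)
  x <- rnorm(997)
  expect_equal(prob_cost_saving(x), sum(x < 0) / length(x))
})

test_that("beta adverse-event draws have the closed-form means", {
  d <- adverse_event_draws(24, 447, 22, 573, n_iter = 20000, seed = 5)
  se0 <- sd(d$p_usual) / sqrt(20000)
  se1 <- sd(d$p_plgf) / sqrt(20000)
  expect_lt(abs(mean(d$p_usual) - 24 / 447), 3 * se0)
  expect_lt(abs(mean(d$p_plgf) - 22 / 573), 3 * se1)
  expect_equal(d$events_avoided_per_1000,
               1000 * (d$p_usual - d$p_plgf))
  # identical arms: difference centred on zero
  same <- adverse_event_draws(24, 447, 24, 447, n_iter = 20000, seed = 6)
  expect_lt(abs(same$mean_events_avoided_per_1000),
            3 * sd(same$events_avoided_per_1000) / sqrt(20000))
  # boundary rule engages with a note
  expect_message(z <- adverse_event_draws(0, 100, 1, 100, n_iter = 100,
                                          seed = 7), "Beta")
  expect_true(all(z$p_usual > 0 & z$p_usual < 1))
})

test_that("the CEAC reduces to the cost-saving probability at lambda 0 and is monotone", {
  set.seed(8)
  cost <- rnorm(4000, 100, 400)
  effect <- runif(4000, 5, 25) # strictly positive effects
  grid <- seq(0, 50000, by = 1000)
  cc <- compute_ceac(cost, effect, grid)
  expect_identical(nrow(cc), length(grid))
  expect_equal(cc$probability[cc$lambda == 0], mean(cost < 0))
  expect_true(all(diff(cc$probability) >= 0))
  # zero cost and positive effects: certain cost-effectiveness for lambda > 0
  cc0 <- compute_ceac(rep(0, 10), rep(3, 10), c(0, 1000))
  expect_equal(cc0$probability, c(0, 1))
  expect_error(compute_ceac(1:3, 1:4), "equal iteration")
})

test_that("test-price sweep is monotone and matches a recount", {
  am <- make_am_grid(function(c, l, a) 3 + (a == "revealed") * -0.1,
                     function(c, l, a) 0.6)
  res <- run_psa(am, default_unit_costs(), weights = equal_weights(),
                 n_iterations = 2000, seed = 9)
  sw <- res$price_sweep
  expect_identical(sw$test_cost, c(50, 100, 150, 200))
  for (col in c("maternal", "infant", "combined")) {
    expect_true(all(diff(sw[[col]]) <= 0))
  }
  # price zero equals the no-test probabilities
  sw0 <- test_price_sweep(res, 0)
  expect_equal(sw0$combined / 100, res$prob_without_test[["combined"]])
  # brute-force recount at one price
  expect_equal(sw$combined[2] / 100,
               mean(res$weighted_draws$combined + 100 < 0))
  expect_error(test_price_sweep(res, -5), "nonnegative")
})

test_that("the probabilistic model is reproducible from its seed", {
  am <- make_am_grid(function(c, l, a) 2 + (a == "revealed") * -0.2,
                     function(c, l, a) 0.4)
  r1 <- run_psa(am, default_unit_costs(), weights = equal_weights(),
                n_iterations = 300, seed = 42)
  r2 <- run_psa(am, default_unit_costs(), weights = equal_weights(),
                n_iterations = 300, seed = 42)
  expect_equal(r1$totals, r2$totals)
  expect_identical(r1$weighted_draws, r2$weighted_draws)
  expect_identical(r1$ceac, r2$ceac)
  r3 <- run_psa(am, default_unit_costs(), weights = equal_weights(),
                n_iterations = 300, seed = 43)
  expect_false(identical(r1$weighted_draws, r3$weighted_draws))
})

test_that("cost-saving probabilities are stable across seeds at 5000 iterations", {
  am <- make_am_grid(function(c, l, a) 3 + (a == "revealed") * -0.05,
                     function(c, l, a) 0.5)
  probs <- vapply(1:10, function(s) {
    r <- run_psa(am, default_unit_costs(), weights = equal_weights(),
                 n_iterations = 5000, seed = s)
    r$prob_with_test[["combined"]]
  }, numeric(1))
  expect_lt(max(abs(probs - mean(probs))), 0.02)
})

test_that("per-arm weighting mode is accepted and matches pooled under equal weights", {
  am <- make_am_grid(function(c, l, a) 2 + (a == "revealed") * -0.3,
                     function(c, l, a) 0.2)
  w <- equal_weights()
  wm <- cbind(usual = w, revealed = w)
  r_pool <- run_psa(am, default_unit_costs(), weights = w,
                    n_iterations = 200, seed = 10)
  r_arm <- run_psa(am, default_unit_costs(), weights = wm,
                   n_iterations = 200, seed = 10)
  expect_equal(r_pool$totals, r_arm$totals)
  expect_identical(r_arm$weights_mode, "per_arm")
})

test_that("incomplete or invalid mean grids are rejected", {
  am <- make_am_grid()
  expect_error(run_psa(am[-1, ], uc_flat(), weights = equal_weights(),
                       n_iterations = 10, seed = 1), "incomplete")
  am_bad <- am; am_bad$mean[1] <- -1
  expect_error(run_psa(am_bad, uc_flat(), weights = equal_weights(),
                       n_iterations = 10, seed = 1), "nonnegative")
  expect_error(run_psa(am, uc_flat(), weights = rep(0.2, 9),
                       n_iterations = 10, seed = 1), "named|sum to 1")
  expect_error(run_psa(am, uc_flat(), weights = equal_weights(),
                       n_iterations = 10, seed = 1, test_cost = -1),
               "nonnegative")
})

test_that("dominance is declared when testing saves money and prevents events", {
  am <- make_am_grid(function(c, l, a) if (a == "revealed") 1 else 3,
                     function(c, l, a) 0)
  res <- run_psa(am, default_unit_costs(), weights = equal_weights(),
                 n_iterations = 500, seed = 11)
  expect_true(res$dominant)
  am_worse <- make_am_grid(function(c, l, a) if (a == "revealed") 3 else 1,
                           function(c, l, a) 0)
  res2 <- run_psa(am_worse, default_unit_costs(), weights = equal_weights(),
                  n_iterations = 500, seed = 11)
  expect_false(res2$dominant)
})
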