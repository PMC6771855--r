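#' Proportion of Monte Carlo iterations that are cost-saving
#'
#' Strictly negative incremental cost counts as cost-saving; zero does not.
#'
#' @param x numeric vector of per-iteration incremental costs (GBP,
#'   intervention minus comparator).
#' @return fraction in `[0, 1]`.
#' @export
prob_cost_saving <- function(x) {
  stopifnot(length(x) >= 1)
  mean(x < 0)
}

#' Weight per-cell values to a per-woman value
#'
#' @param values numeric vector (or matrix with one column per cell) of
#'   per-cell quantities.
#' @param weights nonnegative weights summing to 1 within `1e-9`.
#' @return weighted sum (vector rows if `values` is a matrix).
#' @export
weight_costs <- function(values, weights) {
  if (any(weights < 0)) stop("subgroup weights must be nonnegative")
  if (abs(sum(weights) - 1) > 1e-9) {
    stop("subgroup weights must sum to 1 (got ", format(sum(weights)), ")")
  }
  if (is.matrix(values)) {
    stopifnot(ncol(values) == length(weights))
    drop(values %*% weights)
  } else {
    stopifnot(length(values) == length(weights))
    sum(values * weights)
  }
}

#' Observed subgroup weights from trial records
#'
#' @param data trial records.
#' @param mode `"pooled"` (both arms together, default) or `"per_arm"`.
#' @return named 9-vector of cell proportions (pooled) or a 9 x 2 matrix
#'   with one column per arm.
#' @export
cell_weights <- function(data, mode = c("pooled", "per_arm")) {
  mode <- match.arg(mode)
  cell <- factor(paste(data$plgf, data$diagnosis, sep = ":"),
                 levels = cell_levels())
  if (mode == "pooled") {
    w <- table(cell) / nrow(data)
    setNames(as.numeric(w), cell_levels())
  } else {
    arm <- factor(data$arm, levels = arm_levels())
    tab <- table(cell, arm)
    sweep(unclass(tab), 2, colSums(tab), "/")
  }
}

#' Beta-distributed adverse-event draws and events avoided per 1000
#'
#' Per-arm event probabilities are drawn from `Beta(r, n - r)`, whose mean is
#' the observed proportion `r / n` (mean-preserving rule).  If an arm has
#' zero events the rule degenerates, and `Beta(r + 1/2, n - r + 1/2)` is
#' used instead with a note.  Events avoided per 1000 women =
#' `1000 * (p_usual - p_plgf)`.
#'
#' @param events_usual,n_usual events / denominator, usual-care arm.
#' @param events_plgf,n_plgf events / denominator, revealed-testing arm.
#' @param n_iter number of Monte Carlo iterations.
#' @param seed optional integer seed.
#' @return list with vectors `p_usual`, `p_plgf`, `events_avoided_per_1000`
#'   and scalars `mean_events_avoided_per_1000`,
#'   `events_avoided_per_1000_rounded`.
#' @examples
#' d <- adverse_event_draws(24, 447, 22, 573, n_iter = 5000, seed = 1)
#' d$events_avoided_per_1000_rounded # 15
#' @export
adverse_event_draws <- function(events_usual, n_usual, events_plgf, n_plgf,
                                n_iter = 5000, seed = NULL) {
  stopifnot(events_usual >= 0, events_usual <= n_usual,
            events_plgf >= 0, events_plgf <= n_plgf, n_iter >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw_arm <- function(r, n) {
    if (r == 0 || r == n) {
      message("boundary event count (", r, "/", n,
              "): using Beta(r + 1/2, n - r + 1/2)")
      rbeta(n_iter, r + 0.5, n - r + 0.5)
    } else {
      rbeta(n_iter, r, n - r)
    }
  }
  p0 <- draw_arm(events_usual, n_usual)
  p1 <- draw_arm(events_plgf, n_plgf)
  avoided <- 1000 * (p0 - p1)
  list(p_usual = p0, p_plgf = p1,
       events_avoided_per_1000 = avoided,
       mean_events_avoided_per_1000 = mean(avoided),
       events_avoided_per_1000_rounded = round(mean(avoided)))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay `lambda` (GBP per adverse event avoided), the
#' probability that net monetary benefit per 1000 women is positive:
#' `lambda * events_avoided_per_1000 - cost_per_1000 > 0`.
#'
#' @param cost_per_1000 per-iteration incremental cost per 1000 women,
#'   including the test cost.
#' @param events_avoided_per_1000 per-iteration adverse events avoided per
#'   1000 women.
#' @param wtp_grid willingness-to-pay values (GBP).
#' @return data.frame `lambda`, `probability`.
#' @export
compute_ceac <- function(cost_per_1000, events_avoided_per_1000,
                         wtp_grid = seq(0, 50000, by = 1000)) {
  if (length(cost_per_1000) != length(events_avoided_per_1000)) {
    stop("cost and effect draws must have equal iteration counts")
  }
  prob <- vapply(wtp_grid, function(l)
    mean(l * events_avoided_per_1000 - cost_per_1000 > 0), numeric(1))
  data.frame(lambda = wtp_grid, probability = prob)
}

# Sample one Monte Carlo matrix of quantities for every row of the
# adjusted-means table: n_iter x nrow(am), each column drawn from the row's
# tagged sampling distribution.
draw_quantities <- function(am, n_iter) {
  draws <- matrix(0, nrow = n_iter, ncol = nrow(am))
  for (j in seq_len(nrow(am))) {
    draws[, j] <- switch(
      am$dist[j],
      fixed = rep(am$mean[j], n_iter),
      normal_truncated0 = rtruncnorm0(n_iter, am$mean[j], am$se[j]),
      beta = {
        m <- am$mean[j]; s <- am$se[j]
        if (s <= 0) rep(m, n_iter) else {
          v <- s^2
          if (v >= m * (1 - m)) stop("beta tag needs se^2 < mean(1-mean)")
          a <- m * (m * (1 - m) / v - 1)
          rbeta(n_iter, a, a * (1 - m) / m)
        }
      },
      stop("unknown distribution tag: ", am$dist[j]))
  }
  draws
}

#' Run the probabilistic Monte Carlo cost model
#'
#' The within-trial probabilistic sensitivity analysis: for each iteration,
#' every adjusted mean (per resource category, subgroup and arm) is sampled
#' from its tagged distribution (normal truncated at zero by default; fixed
#' cells pass through), converted to cost via the unit-cost table, and the
#' per-cell cost difference (revealed PlGF minus usual care; saving is
#' negative) is formed.  Cell differences are weighted by the subgroup
#' proportions to a per-woman difference; maternal, infant and combined
#' totals, cost-saving probabilities with and without the PlGF test cost,
#' beta-distributed adverse-event draws, the CEAC and the test-price
#' sensitivity sweep are derived from the stored iteration vectors.
#'
#' @param adjusted_means data.frame from [fit_all_resources()] /
#'   [read_adjusted_means_csv()]: complete 9 x 2 grid per category.
#' @param unit_costs a `unit_cost_table`.
#' @param adverse list with `events_usual`, `n_usual`, `events_plgf`,
#'   `n_plgf` (defaults to the trial counts 24/447 and 22/573).
#' @param weights subgroup weights: named 9-vector (pooled) or 9 x 2 matrix
#'   (per-arm mode, columns `usual`, `revealed`).
#' @param n_iterations Monte Carlo iterations (default 5000).
#' @param seed integer seed; the whole result is reproducible from it.
#' @param test_cost PlGF test price in GBP (default: the table's, GBP 70).
#' @param test_cost_sweep prices for the sensitivity table.
#' @param wtp_grid willingness-to-pay grid for the CEAC.
#' @return object of class `psa_result`; see [summary.psa_result()].
#' @export
run_psa <- function(adjusted_means, unit_costs,
                    adverse = list(events_usual = 24, n_usual = 447,
                                   events_plgf = 22, n_plgf = 573),
                    weights,
                    n_iterations = 5000, seed = 1,
                    test_cost = NULL,
                    test_cost_sweep = c(50, 100, 150, 200),
                    wtp_grid = seq(0, 50000, by = 1000)) {
  am <- adjusted_means
  rc <- resource_categories()
  stopifnot(inherits(unit_costs, "unit_cost_table"))
  test_cost <- test_cost %||% unit_costs$plgf_test_cost
  if (test_cost < 0) stop("test cost must be nonnegative")
  if (n_iterations < 1) stop("n_iterations must be >= 1")

  # validate the mean/se grid: every category x cell x arm exactly once
  key <- paste(am$category, am$plgf, am$diagnosis, am$arm)
  if (anyDuplicated(key)) stop("duplicated adjusted-mean cells")
  want <- expand.grid(category = rc$category, cell = cell_levels(),
                      arm = arm_levels(), stringsAsFactors = FALSE)
  want_key <- paste(want$category,
                    sub(":", " ", want$cell, fixed = TRUE), want$arm)
  have_key <- paste(am$category, am$plgf, am$diagnosis, am$arm)
  miss <- setdiff(want_key, have_key)
  if (length(miss)) {
    stop("adjusted-means grid incomplete; missing ", length(miss),
         " cells, e.g. ", miss[1])
  }
  if (any(am$mean < 0) || any(am$se < 0)) {
    stop("adjusted means and standard errors must be nonnegative")
  }

  per_arm <- is.matrix(weights)
  wmat <- if (per_arm) {
    stopifnot(all(colnames(weights) %in% arm_levels()))
    apply(weights[cell_levels(), arm_levels()], 2, function(w) {
      if (abs(sum(w) - 1) > 1e-9) stop("per-arm weights must sum to 1")
      w
    })
  } else {
    w <- weights[cell_levels()]
    if (anyNA(w)) stop("weights must be named by the nine subgroup cells")
    if (abs(sum(w) - 1) > 1e-9) stop("subgroup weights must sum to 1")
    cbind(usual = w, revealed = w)
  }

  set.seed(seed)
  draws <- draw_quantities(am, n_iterations)

  # per-category: n_iter x 9 matrices of cell cost differences and weighted
  # per-arm cost contributions
  cellcols <- function(cat, a) {
    vapply(cell_levels(), function(cl) {
      pd <- strsplit(cl, ":", fixed = TRUE)[[1]]
      which(am$category == cat & am$plgf == pd[1] &
              am$diagnosis == pd[2] & am$arm == a)
    }, integer(1))
  }
  cell_diff <- list()      # actual per-patient-in-cell difference
  cell_wdiff <- list()     # weighted contribution per cell
  for (cat in rc$category) {
    uc <- unit_costs$category_costs[[cat]]
    q0 <- draws[, cellcols(cat, "usual"), drop = FALSE]
    q1 <- draws[, cellcols(cat, "revealed"), drop = FALSE]
    cell_diff[[cat]] <- (q1 - q0) * uc
    cell_wdiff[[cat]] <- sweep(q1 * uc, 2, wmat[, "revealed"], "*") -
      sweep(q0 * uc, 2, wmat[, "usual"], "*")
  }
  mat_cats <- rc$category[rc$group == "maternal"]
  inf_cats <- rc$category[rc$group == "infant"]
  sum_mats <- function(cats, lst) Reduce(`+`, lst[cats])
  cell_diff$maternal <- sum_mats(mat_cats, cell_diff)
  cell_diff$infant <- sum_mats(inf_cats, cell_diff)
  cell_diff$combined <- cell_diff$maternal + cell_diff$infant
  cell_wdiff$maternal <- sum_mats(mat_cats, cell_wdiff)
  cell_wdiff$infant <- sum_mats(inf_cats, cell_wdiff)
  cell_wdiff$combined <- cell_wdiff$maternal + cell_wdiff$infant

  weighted_draws <- lapply(cell_wdiff, rowSums)

  ae <- adverse_event_draws(adverse$events_usual, adverse$n_usual,
                            adverse$events_plgf, adverse$n_plgf,
                            n_iter = n_iterations, seed = NULL)

  groups <- c(rc$category, "maternal", "infant", "combined")
  cell_stats <- do.call(rbind, lapply(groups, function(g) {
    d <- cell_diff[[g]]
    wd <- cell_wdiff[[g]]
    data.frame(group = g,
               cell = cell_levels(),
               actual = colMeans(d),
               weighted = colMeans(wd),
               pct_saving = 100 * colMeans(d < 0),
               row.names = NULL)
  }))
  totals <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group = g,
               actual = sum(colMeans(cell_diff[[g]])),
               weighted = mean(weighted_draws[[g]]),
               pct_saving = 100 * prob_cost_saving(weighted_draws[[g]]),
               row.names = NULL)
  }))

  prob_with_test <- vapply(c(maternal = "maternal", infant = "infant",
                             combined = "combined"), function(g)
    prob_cost_saving(weighted_draws[[g]] + test_cost), numeric(1))
  prob_without_test <- vapply(c(maternal = "maternal", infant = "infant",
                                combined = "combined"), function(g)
    prob_cost_saving(weighted_draws[[g]]), numeric(1))

  ceac <- compute_ceac(1000 * (weighted_draws$combined + test_cost),
                       ae$events_avoided_per_1000, wtp_grid)

  result <- structure(
    list(n_iterations = n_iterations,
         seed = seed,
         test_cost = test_cost,
         weights = wmat,
         weights_mode = if (per_arm) "per_arm" else "pooled",
         currency_year = unit_costs$currency_year,
         cell_stats = cell_stats,
         totals = totals,
         prob_with_test = prob_with_test,
         prob_without_test = prob_without_test,
         weighted_draws = weighted_draws,
         cell_diff_draws = cell_diff[rc$category],
         adverse = ae,
         adverse_counts = adverse,
         ceac = ceac,
         dominant = NA),
    class = "psa_result")
  result$price_sweep <- test_price_sweep(result, test_cost_sweep)
  result$dominant <- (mean(weighted_draws$combined) + test_cost) < 0 &&
    ae$mean_events_avoided_per_1000 > 0
  result
}

#' Sensitivity of cost-saving probabilities to the PlGF test price
#'
#' Recomputes the maternal-only, infant-only and combined cost-saving
#' probabilities from the stored iteration vectors with the test price added
#' to each total.  Probabilities are non-increasing in price.
#'
#' @param result a `psa_result`.
#' @param prices nonnegative test prices (GBP).
#' @return data.frame `test_cost`, `maternal`, `infant`, `combined`
#'   (probabilities in percent).
#' @export
test_price_sweep <- function(result, prices = c(50, 100, 150, 200)) {
  stopifnot(inherits(result, "psa_result"))
  if (any(prices < 0)) stop("test prices must be nonnegative")
  wd <- result$weighted_draws
  do.call(rbind, lapply(prices, function(pr) {
    data.frame(test_cost = pr,
               maternal = 100 * prob_cost_saving(wd$maternal + pr),
               infant = 100 * prob_cost_saving(wd$infant + pr),
               combined = 100 * prob_cost_saving(wd$combined + pr))
  }))
}

#' Net per-woman saving after the test price
#'
#' @param pre_test_saving_gbp weighted per-woman saving before the test
#'   price (positive = saving).
#' @param test_cost_gbp test price.
#' @return net saving in GBP.
#' @export
net_saving_per_woman <- function(pre_test_saving_gbp, test_cost_gbp) {
  pre_test_saving_gbp - test_cost_gbp
}

#' @export
print.psa_result <- function(x, ...) {
  t <- x$totals
  g <- function(gr, col) t[t$group == gr, col]
  cat("Probabilistic cost model:", x$n_iterations, "iterations, seed",
      x$seed, paste0("(", x$currency_year, ")"), "\n")
  cat(sprintf("  Weighted per-woman cost difference (PlGF - usual), before test:\n"))
  cat(sprintf("    maternal %8.0f GBP  (%.1f%% of iterations cost-saving)\n",
              g("maternal", "weighted"), g("maternal", "pct_saving")))
  cat(sprintf("    infant   %8.0f GBP  (%.1f%% cost-saving)\n",
              g("infant", "weighted"), g("infant", "pct_saving")))
  cat(sprintf("    combined %8.0f GBP  (%.1f%% cost-saving)\n",
              g("combined", "weighted"), g("combined", "pct_saving")))
  cat(sprintf("  Including PlGF test at %.0f GBP: combined %8.0f GBP (%.1f%% cost-saving)\n",
              x$test_cost, g("combined", "weighted") + x$test_cost,
              100 * x$prob_with_test[["combined"]]))
  cat(sprintf("  Maternal adverse events avoided per 1000 women: %.1f (reported %d)\n",
              x$adverse$mean_events_avoided_per_1000,
              x$adverse$events_avoided_per_1000_rounded))
  cat("  Dominant (cheaper and more effective):", x$dominant, "\n")
  invisible(x)
}

#' Summarise a probabilistic cost model run
#'
#' @param object a `psa_result`.
#' @param ... unused.
#' @return list of data.frames: `totals`, `cell_stats`, `price_sweep`,
#'   `ceac`, plus adverse-event and configuration scalars.
#' @export
summary.psa_result <- function(object, ...) {
  out <- list(totals = object$totals,
              cell_stats = object$cell_stats,
              price_sweep = object$price_sweep,
              ceac = object$ceac,
              events_avoided_per_1000 =
                object$adverse$mean_events_avoided_per_1000,
              dominant = object$dominant,
              test_cost = object$test_cost,
              n_iterations = object$n_iterations,
              seed = object$seed)
  class(out) <- "summary.psa_result"
  out
}

#' @export
print.summary.psa_result <- function(x, ...) {
  cat("Totals (GBP per woman):\n")
  print(transform(x$totals, actual = round(actual), weighted = round(weighted),
                  pct_saving = round(pct_saving, 1)))
  cat("\nTest-price sensitivity (% of iterations cost-saving):\n")
  print(transform(x$price_sweep, maternal = round(maternal, 1),
                  infant = round(infant, 1), combined = round(combined, 1)))
  cat(sprintf("\nEvents avoided per 1000: %.1f; dominant: %s\n",
              x$events_avoided_per_1000, x$dominant))
  invisible(x)
}

#' Plot the cost-effectiveness acceptability curve
#'
#' @param x a `psa_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.psa_result <- function(x, ...) {
  graphics::plot(x$ceac$lambda, x$ceac$probability, type = "l", lwd = 2,
                 xlab = "Willingness to pay per adverse event avoided (GBP)",
                 ylab = "Probability cost-effective", ylim = c(0, 1), ...)
  graphics::abline(h = c(0.5, 0.72), lty = 3, col = "grey60")
  invisible(x)
}
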