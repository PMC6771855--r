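#' Default synthetic-trial generator parameters
#'
#' Returns the parameter set used to generate synthetic stepped-wedge trial
#' data with the structure the economic analysis assumes.  Quantities the
#' trial reports are used directly: enrolment of 434 usual-care and 571
#' revealed-testing women, marginal PlGF band proportions 38.2% / 38.3% /
#' 23.5% (>100, 12-100, <12 pg/ml), severe maternal adverse-event counts
#' 24/447 (usual) and 22/573 (revealed), and arm-level mean delivery costs of
#' GBP 3,318 / 3,372.  Everything the trial does not report per subgroup --
#' the diagnosis split within each PlGF band and the per-category hurdle
#' probabilities, positive-part means and dispersions -- is synthetic, chosen
#' to give realistic zero-inflated, over-dispersed resource use (see the
#' methods vignette).
#'
#' @param sigma_c SD of the shared normal centre (cluster) random intercept,
#'   entering both hurdle parts on the link scale. Default 0.3.
#' @param beta_t linear secular-trend coefficient per 6-week step, on the
#'   link scale of both parts. Default 0.005.
#' @return An object of class `generator_params`: a list with elements
#'   `arm_totals`, `subgroup_probs` (9 x 2 matrix of cell probabilities per
#'   arm, columns summing to 1), `resource` (data.frame with one row per
#'   category x cell x arm holding hurdle probability `p`, conditional
#'   positive mean `mu_pos` (> 1) and dispersion `k`), `sigma_c`, `beta_t`,
#'   `adverse` (per-arm event counts r/n), and `delivery_mode_probs`
#'   (4 x 2 matrix).
#' @export
default_generator_params <- function(sigma_c = 0.3, beta_t = 0.005) {
  plgf <- plgf_levels()
  diag <- diagnosis_levels()

  # marginal PlGF band proportions as printed; diagnosis split within band is
  # synthetic (normal outcomes dominate when PlGF is normal, pre-eclampsia
  # dominates when PlGF is very low)
  band_marg <- c(gt100 = 0.382, "12to100" = 0.383, lt12 = 0.235)
  diag_given_band <- rbind(
    gt100     = c(0.70, 0.22, 0.08),
    "12to100" = c(0.40, 0.35, 0.25),
    lt12      = c(0.10, 0.25, 0.65)
  )
  colnames(diag_given_band) <- diag
  cellp <- as.vector(t(band_marg * diag_given_band)) # cell_levels() order
  cellp <- cellp / sum(cellp)
  subgroup_probs <- cbind(usual = cellp, revealed = cellp)
  rownames(subgroup_probs) <- cell_levels()

  grid <- expand.grid(category = resource_categories()$category,
                      plgf = plgf, diagnosis = diag, arm = arm_levels(),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  sev <- match(grid$diagnosis, diag)          # 1 normal .. 3 pre-eclampsia
  band <- match(grid$plgf, plgf)              # 1 gt100 .. 3 lt12
  rev <- grid$arm == "revealed"

  p <- numeric(nrow(grid))
  mu <- numeric(nrow(grid))
  k <- numeric(nrow(grid))
  for (cat in unique(grid$category)) {
    i <- grid$category == cat
    switch(cat,
      outpatient = {
        p[i] <- 0.90
        mu[i] <- 3.0 + 1.2 * (sev[i] - 1) + 0.8 * (band[i] - 1)
        # revealed testing reduces outpatient surveillance in every subgroup
        mu[i][rev[i]] <- mu[i][rev[i]] * 0.78
        k[i] <- 1.2
      },
      antenatal_ward = {
        p[i] <- 0.20 + 0.16 * (sev[i] - 1) + 0.10 * (band[i] - 1)
        # more appropriate admission of high-risk (low PlGF) women
        p[i][rev[i]] <- pmin(0.95, p[i][rev[i]] * (1 + 0.10 * (band[i][rev[i]] - 1)))
        mu[i] <- 2.2 + 1.0 * (sev[i] - 1) + 0.7 * (band[i] - 1)
        k[i] <- 1.0
      },
      labour_ward = {
        p[i] <- 0.85
        mu[i] <- 1.6 + 0.3 * (sev[i] - 1)
        k[i] <- 2.0
      },
      maternal_postnatal = {
        p[i] <- 0.88
        mu[i] <- 2.1 + 0.8 * (sev[i] - 1) + 0.4 * (band[i] - 1)
        mu[i][rev[i]] <- mu[i][rev[i]] * 0.95
        k[i] <- 1.5
      },
      maternal_icu_hdu = {
        p[i] <- 0.10 + 0.10 * (sev[i] - 1) + 0.08 * (band[i] - 1)
        p[i][rev[i]] <- p[i][rev[i]] * 0.9
        mu[i] <- 2.5 + 0.5 * (sev[i] - 1)
        k[i] <- 1.0
      },
      infant_icu_hdu = {
        p[i] <- 0.04 + 0.05 * (sev[i] - 1) + 0.06 * (band[i] - 1)
        mu[i] <- 4.0 + 3.0 * (band[i] - 1) + 1.5 * (sev[i] - 1)
        mu[i][rev[i]] <- mu[i][rev[i]] * 0.9
        k[i] <- 0.8
        # no neonatal intensive-care use among normal-outcome very-low-PlGF
        # women (structural zero, as in the reported cost tables)
        p[i][grid$plgf[i] == "lt12" & grid$diagnosis[i] == "normal"] <- 0
      },
      infant_scbu = {
        p[i] <- 0.08 + 0.10 * (sev[i] - 1) + 0.12 * (band[i] - 1)
        mu[i] <- 3.0 + 2.0 * (band[i] - 1) + 1.0 * (sev[i] - 1)
        mu[i][rev[i]] <- mu[i][rev[i]] * 0.9
        k[i] <- 0.8
      }
    )
  }
  grid$p <- p
  grid$mu_pos <- mu
  grid$k <- k

  # delivery-mode mixes solved so the mixture means under the default unit
  # costs equal the reported arm-level delivery costs (3318 usual, 3372 PlGF)
  delivery_mode_probs <- cbind(
    usual    = c(0.41034, 0.12, 0.18, 0.28966),
    revealed = c(0.39172, 0.12, 0.18, 0.30828)
  )
  rownames(delivery_mode_probs) <- delivery_modes()

  params <- structure(
    list(arm_totals = c(usual = 434L, revealed = 571L),
         subgroup_probs = subgroup_probs,
         resource = grid,
         sigma_c = sigma_c,
         beta_t = beta_t,
         adverse = list(events_usual = 24L, n_usual = 447L,
                        events_plgf = 22L, n_plgf = 573L),
         delivery_mode_probs = delivery_mode_probs),
    class = "generator_params"
  )
  validate_params(params)
  params
}

#' Validate generator parameters
#'
#' @param params a `generator_params` list.
#' @return `params`, invisibly, or an error naming the violated constraint.
#' @export
validate_params <- function(params) {
  stopifnot(is.list(params))
  sp <- params$subgroup_probs
  if (!all(abs(colSums(sp) - 1) < 1e-9)) {
    stop("subgroup probabilities must sum to 1 within each arm")
  }
  if (any(sp < 0)) stop("subgroup probabilities must be non-negative")
  r <- params$resource
  if (any(r$p < 0 | r$p > 1)) stop("hurdle probabilities p must lie in [0, 1]")
  if (any(r$p > 0 & r$mu_pos <= 1)) {
    stop("positive-part conditional means mu_pos must exceed 1 wherever p > 0")
  }
  if (any(r$k <= 0)) stop("dispersion k must be positive (Inf allowed for Poisson)")
  with(params$adverse, {
    stopifnot(events_usual >= 0, events_usual <= n_usual,
              events_plgf >= 0, events_plgf <= n_plgf)
  })
  dm <- params$delivery_mode_probs
  if (!all(abs(colSums(dm) - 1) < 1e-9) || any(dm < 0)) {
    stop("delivery-mode probabilities must be a distribution within each arm")
  }
  if (!is.finite(params$sigma_c) || params$sigma_c < 0) {
    stop("sigma_c must be a finite non-negative number")
  }
  if (!is.finite(params$beta_t)) stop("beta_t must be finite")
  invisible(params)
}

#' @export
print.generator_params <- function(x, ...) {
  cat("Synthetic stepped-wedge trial generator parameters\n")
  cat("  arm totals:", paste(names(x$arm_totals), x$arm_totals,
                             sep = "=", collapse = ", "), "\n")
  cat("  centre random-effect SD:", x$sigma_c,
      " secular trend/step:", x$beta_t, "\n")
  cat("  adverse events:", x$adverse$events_usual, "/", x$adverse$n_usual,
      "(usual) vs", x$adverse$events_plgf, "/", x$adverse$n_plgf, "(revealed)\n")
  cat("  resource grid:", nrow(x$resource), "category x cell x arm rows\n")
  invisible(x)
}
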