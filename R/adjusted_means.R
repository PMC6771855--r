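# Response-scale prediction for one cell x arm combination with a
# delta-method variance, curvature-corrected to second order:
# Var[g(eta_hat)] ~ g'(eta)^2 v + g''(eta)^2 v^2 / 2 for eta_hat ~ N(eta, v).
# The first-order term alone visibly understates the spread of convex
# transforms (exp, truncated-count means) at realistic cell sizes.
# `tvals` is the set of centred time values to standardise over: 0 for the
# conditional prediction (time fixed at its sample mean), the observed
# values for marginal standardisation.  inv/dinv/d2inv are the inverse link
# and its first two derivatives with respect to the linear predictor.
combo_response <- function(fp, combo, ref_level, tvals, inv, dinv,
                           d2inv = NULL) {
  x0 <- setNames(numeric(length(fp$beta)), names(fp$beta))
  if ("(Intercept)" %in% names(x0)) x0[["(Intercept)"]] <- 1
  nm <- paste0("cellarm", combo)
  if (nm %in% names(x0)) {
    x0[[nm]] <- 1
  } else if (!identical(combo, ref_level)) {
    stop("no coefficient for combination ", combo)
  }
  has_t <- "time_c" %in% names(x0)
  X <- matrix(rep(x0, each = length(tvals)), nrow = length(tvals),
              dimnames = list(NULL, names(x0)))
  if (has_t) X[, "time_c"] <- tvals
  eta <- drop(X %*% fp$beta)
  val <- mean(inv(eta))
  grad <- colMeans(dinv(eta) * X)
  v1 <- max(as.numeric(t(grad) %*% fp$V %*% grad), 0)
  v2 <- if (is.null(d2inv)) 0 else {
    v_eta <- mean(vapply(seq_along(eta), function(i)
      as.numeric(t(X[i, ]) %*% fp$V %*% X[i, ]), numeric(1)))
    0.5 * mean(d2inv(eta))^2 * v_eta^2
  }
  list(value = val, var = v1 + v2, eta = mean(eta))
}

am_row <- function(category, combo, mean, se, dist) {
  cl <- strsplit(combo, "/", fixed = TRUE)[[1]]
  pd <- strsplit(cl[1], ":", fixed = TRUE)[[1]]
  data.frame(category = category, plgf = pd[1], diagnosis = pd[2],
             arm = cl[2], mean = mean, se = se, dist = dist,
             stringsAsFactors = FALSE)
}

#' Adjusted mean resource use per subgroup and arm
#'
#' Model-predicted per-woman mean quantity (with delta-method standard error)
#' for each of the nine PlGF x diagnosis subgroups in each trial arm, at the
#' centre random effect's centre (0).  With
#' `standardise = "conditional"` (default) the time covariate is fixed at its
#' sample mean; `"marginal"` averages predictions over the observed secular
#' times.  All 9 x 2 cells are always emitted: cells that were held out as
#' degenerate zeros (or absent from the data, with a warning) come back with
#' `mean = 0`, `se = 0` and distribution tag `"fixed"`.
#'
#' @param fit a fitted resource-use model (`two_part_fit`,
#'   `glmm_count_fit` or `fallback_fit`).
#' @param standardise `"conditional"` or `"marginal"`.
#' @param ... unused.
#' @return data.frame with columns `category`, `plgf`, `diagnosis`, `arm`,
#'   `mean`, `se`, `dist` (18 rows), the input schema of [run_psa()].
#' @export
adjusted_means <- function(fit, standardise = c("conditional", "marginal"), ...) {
  UseMethod("adjusted_means")
}

am_tvals <- function(fit, standardise) {
  if (standardise == "marginal" && !is.null(fit$time_values)) {
    fit$time_values
  } else {
    0
  }
}

#' @rdname adjusted_means
#' @export
adjusted_means.two_part_fit <- function(fit,
                                        standardise = c("conditional",
                                                        "marginal"), ...) {
  standardise <- match.arg(standardise)
  tv <- am_tvals(fit, standardise)
  combos <- fit$combos
  if (length(combos$absent)) {
    warning("no trial records for: ", paste(combos$absent, collapse = ", "),
            "; emitting fixed zeros", call. = FALSE)
  }
  fp1 <- if (!is.null(fit$part1) && !inherits(fit$part1, "try-error"))
    fe_parts(fit$part1)
  fp2 <- if (!is.null(fit$part2) && !inherits(fit$part2, "try-error"))
    fe_parts(fit$part2)
  # reference level of each part is the first retained factor level
  ref1 <- combos$estimable[1]
  lv2 <- c(combos$estimable, combos$deg1)
  ref2 <- intersect(combo_levels(), lv2)[1]
  k <- fit$k

  cond_fun <- function(mu) tnb_cond_mean(mu, k)
  dcond_deta <- function(eta) {
    mu <- exp(eta)
    tnb_cond_mean_dmu(mu, k) * mu
  }
  d2cond_deta <- function(eta) {
    mu <- exp(eta)
    (tnb_cond_mean_d2mu(mu, k) * mu + tnb_cond_mean_dmu(mu, k)) * mu
  }

  rows <- lapply(combo_levels(), function(cb) {
    if (cb %in% c(combos$deg0, combos$absent)) {
      return(am_row(fit$category, cb, 0, 0, "fixed"))
    }
    # part 1: use probability
    if (cb %in% combos$deg1) {
      p <- 1; vp <- 0
    } else {
      if (is.null(fp1)) return(am_row(fit$category, cb, 0, 0, "fixed"))
      r1 <- combo_response(fp1, cb, ref1, tv, plogis, dlogis_eta, d2logis_eta)
      p <- r1$value; vp <- r1$var
    }
    if (is.null(fp2)) return(am_row(fit$category, cb, 0, 0, "fixed"))
    r2 <- combo_response(fp2, cb, ref2, tv, function(e) cond_fun(exp(e)),
                         dcond_deta, d2cond_deta)
    m <- p * r2$value
    # independent parts: exact product variance from the per-part moments
    v <- r2$value^2 * vp + p^2 * r2$var + vp * r2$var
    am_row(fit$category, cb, m, sqrt(v), "normal_truncated0")
  })
  do.call(rbind, rows)
}

dlogis_eta <- function(e) plogis(e) * (1 - plogis(e))
d2logis_eta <- function(e) {
  p <- plogis(e)
  p * (1 - p) * (1 - 2 * p)
}

#' @rdname adjusted_means
#' @export
adjusted_means.glmm_count_fit <- function(fit,
                                          standardise = c("conditional",
                                                          "marginal"), ...) {
  standardise <- match.arg(standardise)
  tv <- am_tvals(fit, standardise)
  combos <- fit$combos
  if (length(combos$absent)) {
    warning("no trial records for: ", paste(combos$absent, collapse = ", "),
            "; emitting fixed zeros", call. = FALSE)
  }
  fp <- if (!is.null(fit$fit) && !inherits(fit$fit, "try-error"))
    fe_parts(fit$fit)
  keep <- c(combos$estimable, combos$deg1)
  ref <- intersect(combo_levels(), keep)[1]
  rows <- lapply(combo_levels(), function(cb) {
    if (!(cb %in% keep) || is.null(fp)) {
      return(am_row(fit$category, cb, 0, 0, "fixed"))
    }
    r <- combo_response(fp, cb, ref, tv, exp, exp, exp)
    am_row(fit$category, cb, r$value, sqrt(r$var), "normal_truncated0")
  })
  do.call(rbind, rows)
}

#' Standard errors of adjusted means by coefficient resampling
#'
#' Independent cross-check of the delta-method standard errors: draws `B`
#' coefficient vectors from the asymptotic normal distribution of each
#' part's fixed effects, recomputes the cell mean for each draw, and returns
#' the empirical SD per cell.  Used as a test oracle.
#'
#' @param fit a `two_part_fit`.
#' @param B number of coefficient draws.
#' @param seed integer seed.
#' @return data.frame like [adjusted_means()] but with column `se_boot`.
#' @export
bootstrap_adjusted_se <- function(fit, B = 500, seed = 1) {
  stopifnot(inherits(fit, "two_part_fit"))
  set.seed(seed)
  fp1 <- fe_parts(fit$part1)
  fp2 <- fe_parts(fit$part2)
  b1 <- MASS::mvrnorm(B, fp1$beta, fp1$V)
  b2 <- MASS::mvrnorm(B, fp2$beta, fp2$V)
  combos <- fit$combos
  ref1 <- combos$estimable[1]
  lv2 <- c(combos$estimable, combos$deg1)
  ref2 <- intersect(combo_levels(), lv2)[1]
  k <- fit$k
  xvec <- function(fp, cb, ref) {
    x <- setNames(numeric(length(fp$beta)), names(fp$beta))
    if ("(Intercept)" %in% names(x)) x[["(Intercept)"]] <- 1
    nm <- paste0("cellarm", cb)
    if (nm %in% names(x)) x[[nm]] <- 1
    x
  }
  rows <- lapply(combo_levels(), function(cb) {
    if (cb %in% c(combos$deg0, combos$absent)) {
      return(cbind(am_row(fit$category, cb, 0, 0, "fixed"), se_boot = 0))
    }
    p_draw <- if (cb %in% combos$deg1) rep(1, B) else
      plogis(drop(b1 %*% xvec(fp1, cb, ref1)))
    mu_draw <- exp(drop(b2 %*% xvec(fp2, cb, ref2)))
    m_draw <- p_draw * tnb_cond_mean(mu_draw, k)
    cbind(am_row(fit$category, cb, mean(m_draw), sd(m_draw),
                 "normal_truncated0"),
          se_boot = sd(m_draw))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
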