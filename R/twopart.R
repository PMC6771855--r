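# Shared model-frame preparation for all resource-use models.  The covariate
# set is fixed across candidate families: one indicator per subgroup x arm
# combination (so every cell has its own adjusted mean in each arm, reference
# gt100:normal/usual), the step index centred at its sample mean, and a
# centre random intercept.
prepare_model_frame <- function(data, category) {
  need <- c("centre", "step", "arm", "plgf", "diagnosis", category)
  missing <- setdiff(need, names(data))
  if (length(missing)) {
    stop("data lacks columns: ", paste(missing, collapse = ", "))
  }
  cell <- factor(paste(data$plgf, data$diagnosis, sep = ":"),
                 levels = cell_levels())
  if (anyNA(cell)) stop("unrecognised plgf/diagnosis labels in data")
  cellarm <- factor(paste(cell, data$arm, sep = "/"),
                    levels = as.vector(outer(cell_levels(), arm_levels(),
                                             function(cl, a) paste(cl, a, sep = "/"))))
  y <- data[[category]]
  if (any(y < 0)) stop("negative quantities in category ", category)
  data.frame(y = y,
             use = as.integer(y > 0),
             cellarm = cellarm,
             centre = factor(data$centre),
             time_c = data$step - mean(data$step),
             stringsAsFactors = FALSE)
}

combo_levels <- function() {
  as.vector(outer(cell_levels(), arm_levels(),
                  function(cl, a) paste(cl, a, sep = "/")))
}

# Classify cell x arm combinations whose hurdle indicator carries no
# information: absent from the data, all-zero (fixed zero cells) or all-one
# (use probability pinned at 1).  These rows are excluded from estimation so
# that complete separation cannot destroy the fit.
classify_combos <- function(mf) {
  n_by <- table(mf$cellarm)
  users <- tapply(mf$use, mf$cellarm, sum)
  users[is.na(users)] <- 0
  lv <- levels(mf$cellarm)
  list(absent = lv[n_by == 0],
       deg0 = lv[n_by > 0 & users == 0],
       deg1 = lv[n_by > 0 & users == n_by],
       estimable = lv[n_by > 0 & users > 0 & users < n_by])
}

has_mixed_structure <- function(mf) nlevels(droplevels(mf$centre)) >= 2

build_formula <- function(response, mf, random = TRUE) {
  rhs <- c(if (nlevels(droplevels(mf$cellarm)) > 1) "cellarm",
           if (length(unique(mf$time_c)) > 1) "time_c")
  if (!length(rhs)) rhs <- "1"
  if (random && has_mixed_structure(mf)) rhs <- c(rhs, "(1 | centre)")
  as.formula(paste(response, "~", paste(rhs, collapse = " + ")))
}

# Fixed-effect estimates, their covariance and the random-intercept SD,
# uniformly across the engines used (glm, lme4, glmmTMB).
fe_parts <- function(fit) {
  if (inherits(fit, "glmmTMB")) {
    beta <- glmmTMB::fixef(fit)$cond
    V <- as.matrix(vcov(fit)$cond)
    vc <- glmmTMB::VarCorr(fit)$cond
    sdc <- if (!is.null(vc$centre)) attr(vc$centre, "stddev")[[1]] else 0
  } else if (inherits(fit, "glmerMod")) {
    beta <- lme4::fixef(fit)
    V <- as.matrix(vcov(fit))
    vc <- as.data.frame(lme4::VarCorr(fit))
    sdc <- vc$sdcor[vc$grp == "centre"][1]
  } else { # glm / lm
    beta <- coef(fit)
    V <- as.matrix(vcov(fit))
    sdc <- 0
  }
  ok <- is.finite(beta) & is.finite(diag(V))
  list(beta = beta, V = V, sigma_c = sdc, se = sqrt(pmax(diag(V), 0)), ok = all(ok))
}

# A fit counts as converged when it produced a usable curvature: finite
# coefficients, finite standard errors below a link-scale sanity bound, and
# (for glmmTMB) a positive-definite Hessian.  Effectively-unidentified
# parameters from near-empty cells show up as enormous SEs and are treated
# as non-convergence, which routes the category to the fallback model.
fit_usable <- function(fit, se_cap = 10) {
  if (is.null(fit)) return(FALSE)
  if (inherits(fit, "try-error")) return(FALSE)
  if (inherits(fit, "glmmTMB")) {
    if (!isTRUE(fit$sdr$pdHess)) return(FALSE)
    if (!is.null(fit$fit$convergence) && fit$fit$convergence != 0) return(FALSE)
  }
  fp <- try(fe_parts(fit), silent = TRUE)
  if (inherits(fp, "try-error")) return(FALSE)
  fp$ok && all(fp$se < se_cap)
}

# Link-scale prediction (value and variance) for one cell x arm combination
# at time_c = 0 and random effect 0, built from the named coefficient vector
# so it is robust to levels dropped from the estimation subset.
linkpred_combo <- function(fp, combo, ref_level) {
  x <- setNames(numeric(length(fp$beta)), names(fp$beta))
  if ("(Intercept)" %in% names(x)) x[["(Intercept)"]] <- 1
  nm <- paste0("cellarm", combo)
  if (nm %in% names(x)) {
    x[[nm]] <- 1
  } else if (!identical(combo, ref_level)) {
    stop("no coefficient for combination ", combo)
  }
  eta <- sum(x * fp$beta)
  v <- as.numeric(t(x) %*% fp$V %*% x)
  c(eta = eta, var = max(v, 0))
}

#' Fit a two-part (hurdle) mixed model for one resource category
#'
#' Part 1 models the probability that a woman uses the service at all
#' (binomial GLMM, logit link, centre random intercept integrated by adaptive
#' Gauss-Hermite quadrature).  Part 2 models the positive quantity among
#' users with a zero-truncated negative binomial (or Poisson) GLMM on the log
#' scale (Laplace approximation).  The two likelihoods factorise, so the
#' total log-likelihood and AIC are the sums over parts.  Cell x arm
#' combinations with all-zero or all-one use are held out as degenerate
#' (probability 0 or 1, zero variance) rather than fed to the optimiser.
#'
#' @param data trial records (schema of [simulate_trial()]).
#' @param category one of `resource_categories()$category`.
#' @param positive_family `"truncated_nbinom"` (default) or
#'   `"truncated_poisson"`.
#' @param nAGQ number of adaptive Gauss-Hermite quadrature points for the
#'   binomial part (default 7).
#' @return An object of class `two_part_fit` with parts, dispersion `k`,
#'   per-part centre SDs `sigma_c`, `logLik`, `df`, `AIC` (`= 2 df - 2
#'   logLik`), `converged`, and the degenerate-combination bookkeeping.
#' @export
fit_two_part <- function(data, category,
                         positive_family = c("truncated_nbinom",
                                             "truncated_poisson"),
                         nAGQ = 7, .part1 = NULL) {
  positive_family <- match.arg(positive_family)
  mf <- prepare_model_frame(data, category)
  combos <- classify_combos(mf)

  part1 <- NULL
  warn1 <- character(0)
  sub1 <- droplevels(mf[mf$cellarm %in% combos$estimable, , drop = FALSE])
  if (!is.null(.part1)) {
    # the binomial part does not depend on the positive-part family, so a
    # prefitted part can be shared between the two two-part candidates
    part1 <- .part1
  } else if (nrow(sub1) > 0L) {
    f1 <- build_formula("use", sub1, random = TRUE)
    part1 <- withCallingHandlers(
      try(suppressMessages(if (has_mixed_structure(sub1)) {
        lme4::glmer(f1, data = sub1, family = binomial(), nAGQ = nAGQ)
      } else {
        glm(f1, data = sub1, family = binomial())
      }), silent = TRUE),
      warning = function(w) {
        warn1 <<- c(warn1, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }

  sub2 <- droplevels(mf[mf$y > 0, , drop = FALSE])
  part2 <- NULL
  if (nrow(sub2) > 0L) {
    f2 <- build_formula("y", sub2, random = TRUE)
    fam <- if (positive_family == "truncated_nbinom") {
      glmmTMB::truncated_nbinom2()
    } else {
      glmmTMB::truncated_poisson()
    }
    part2 <- suppressWarnings(
      try(glmmTMB::glmmTMB(f2, data = sub2, family = fam), silent = TRUE))
  }

  ll <- 0
  df <- 0
  for (m in list(part1, part2)) {
    if (!is.null(m) && !inherits(m, "try-error")) {
      l <- logLik(m)
      ll <- ll + as.numeric(l)
      df <- df + attr(l, "df")
    }
  }
  converged <-
    (is.null(part1) || fit_usable(part1)) &&
    (is.null(part2) || fit_usable(part2)) &&
    !(nrow(sub1) > 0L && (is.null(part1) || inherits(part1, "try-error"))) &&
    !(nrow(sub2) > 0L && (is.null(part2) || inherits(part2, "try-error")))

  k <- if (!is.null(part2) && !inherits(part2, "try-error") &&
           positive_family == "truncated_nbinom") {
    suppressWarnings(glmmTMB::sigma(part2))
  } else {
    Inf
  }
  sig <- c(
    part1 = if (!is.null(part1) && !inherits(part1, "try-error"))
      fe_parts(part1)$sigma_c else 0,
    part2 = if (!is.null(part2) && !inherits(part2, "try-error"))
      fe_parts(part2)$sigma_c else 0)

  structure(
    list(category = category,
         family = if (positive_family == "truncated_nbinom")
           "two_part_truncNB" else "two_part_truncPoisson",
         part1 = part1, part2 = part2,
         combos = combos,
         k = k, sigma_c = sig,
         logLik = ll, df = df, AIC = 2 * df - 2 * ll,
         converged = isTRUE(converged),
         nAGQ = nAGQ,
         n = nrow(mf), n_users = sum(mf$use),
         time_center = mean(data$step),
         time_values = mf$time_c,
         messages = warn1),
    class = "two_part_fit")
}

#' Fit a single-part count GLMM (negative binomial or Poisson)
#'
#' Candidate families without a hurdle, on the same covariate set.  All-zero
#' cell x arm combinations are held out as fixed zeros (they are perfectly
#' predicted and would otherwise separate on the log scale).
#'
#' @inheritParams fit_two_part
#' @param family `"negative_binomial"` or `"poisson"`.
#' @return Object of class `glmm_count_fit`.
#' @export
fit_count_glmm <- function(data, category,
                           family = c("negative_binomial", "poisson")) {
  family <- match.arg(family)
  mf <- prepare_model_frame(data, category)
  combos <- classify_combos(mf)
  keep <- c(combos$estimable, combos$deg1)
  sub <- droplevels(mf[mf$cellarm %in% keep, , drop = FALSE])
  fit <- NULL
  if (nrow(sub) > 0L) {
    f <- build_formula("y", sub, random = TRUE)
    fam <- if (family == "negative_binomial") glmmTMB::nbinom2() else stats::poisson()
    fit <- suppressWarnings(
      try(glmmTMB::glmmTMB(f, data = sub, family = fam), silent = TRUE))
  }
  ok <- !is.null(fit) && !inherits(fit, "try-error")
  l <- if (ok) logLik(fit) else structure(0, df = 0)
  structure(
    list(category = category, family = family,
         fit = fit, combos = combos,
         k = if (ok && family == "negative_binomial")
           suppressWarnings(glmmTMB::sigma(fit)) else Inf,
         sigma_c = if (ok) fe_parts(fit)$sigma_c else 0,
         logLik = as.numeric(l), df = attr(l, "df"),
         AIC = 2 * attr(l, "df") - 2 * as.numeric(l),
         converged = ok && fit_usable(fit),
         n = nrow(mf),
         time_center = mean(data$step),
         time_values = mf$time_c),
    class = "glmm_count_fit")
}

#' @export
print.two_part_fit <- function(x, ...) {
  cat("Two-part", if (x$family == "two_part_truncNB") "truncated-NB"
      else "truncated-Poisson", "mixed model:", x$category, "\n")
  cat(sprintf("  n = %d (%d users); logLik = %.2f, df = %d, AIC = %.2f\n",
              x$n, x$n_users, x$logLik, x$df, x$AIC))
  cat(sprintf("  dispersion k = %.3g; centre SD part1 = %.3f, part2 = %.3f\n",
              x$k, x$sigma_c[["part1"]], x$sigma_c[["part2"]]))
  cat("  converged:", x$converged, "\n")
  if (length(c(x$combos$deg0, x$combos$absent))) {
    cat("  fixed-zero cells:",
        paste(c(x$combos$deg0, x$combos$absent), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
coef.two_part_fit <- function(object, ...) {
  list(part1 = if (!is.null(object$part1) &&
                   !inherits(object$part1, "try-error"))
         fe_parts(object$part1)$beta,
       part2 = if (!is.null(object$part2) &&
                   !inherits(object$part2, "try-error"))
         fe_parts(object$part2)$beta)
}

#' @export
logLik.two_part_fit <- function(object, ...) {
  structure(object$logLik, df = object$df, class = "logLik")
}

#' @export
summary.two_part_fit <- function(object, ...) {
  fmt <- function(m) {
    if (is.null(m) || inherits(m, "try-error")) return(NULL)
    fp <- fe_parts(m)
    data.frame(estimate = fp$beta, se = fp$se,
               z = fp$beta / fp$se, row.names = names(fp$beta))
  }
  out <- list(category = object$category, family = object$family,
              part1 = fmt(object$part1), part2 = fmt(object$part2),
              k = object$k, sigma_c = object$sigma_c,
              AIC = object$AIC, converged = object$converged)
  class(out) <- "summary.two_part_fit"
  out
}

#' @export
print.summary.two_part_fit <- function(x, ...) {
  cat("Two-part model (", x$family, ") for ", x$category, "\n", sep = "")
  cat("Use-probability part (logit scale):\n")
  print(round(x$part1, 4))
  cat("Positive part (log scale):\n")
  print(round(x$part2, 4))
  cat(sprintf("k = %.3g; sigma_c = (%.3f, %.3f); AIC = %.2f; converged = %s\n",
              x$k, x$sigma_c[["part1"]], x$sigma_c[["part2"]],
              x$AIC, x$converged))
  invisible(x)
}

#' Predicted per-woman mean resource use for new records
#'
#' Hurdle mean `p * E[Y | Y > 0]` per row, at the random effect's centre
#' (0) and the fitted time centring.
#'
#' @param object a `two_part_fit`.
#' @param newdata data.frame with `plgf`, `diagnosis`, `arm` (and optionally
#'   `step`) columns.
#' @param ... unused.
#' @return numeric vector of expected quantities.
#' @export
predict.two_part_fit <- function(object, newdata, ...) {
  am <- adjusted_means(object)
  key <- paste(am$plgf, am$diagnosis, am$arm)
  out <- am$mean[match(paste(newdata$plgf, newdata$diagnosis, newdata$arm), key)]
  if (anyNA(out)) stop("newdata contains unknown subgroup/arm labels")
  out
}
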