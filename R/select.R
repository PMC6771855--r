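#' Fit one candidate resource-use model family
#'
#' Dispatcher over the candidate families compared by AIC: the two two-part
#' (hurdle) mixed models and the single-part negative binomial and Poisson
#' GLMMs.  The covariate set (subgroup x arm indicators, centred linear time,
#' centre random intercept) is identical across families.
#'
#' @inheritParams fit_two_part
#' @param family one of `"two_part_truncNB"`, `"two_part_truncPoisson"`,
#'   `"negative_binomial"`, `"poisson"`.
#' @return a fitted model object (`two_part_fit` or `glmm_count_fit`).
#' @export
fit_resource_model <- function(data, category,
                               family = c("two_part_truncNB",
                                          "two_part_truncPoisson",
                                          "negative_binomial", "poisson"),
                               nAGQ = 7) {
  family <- match.arg(family)
  switch(family,
    two_part_truncNB = fit_two_part(data, category, "truncated_nbinom", nAGQ),
    two_part_truncPoisson = fit_two_part(data, category, "truncated_poisson",
                                         nAGQ),
    negative_binomial = fit_count_glmm(data, category, "negative_binomial"),
    poisson = fit_count_glmm(data, category, "poisson"))
}

#' Select the best-fitting model family for a resource category
#'
#' Fits every candidate family and returns the converged candidate with the
#' smallest AIC; exact ties are broken toward the model with fewer free
#' parameters.  If no candidate converges, the category is escalated to the
#' logistic + linear fallback ([fit_fallback()]), mirroring the analysis
#' rule used when the complex GLMM for neonatal intensive/high-dependency
#' care would not converge.
#'
#' @inheritParams fit_two_part
#' @param candidates character vector of family names (see
#'   [fit_resource_model()]).
#' @return the winning fit, with an `aic_table` attribute (data.frame:
#'   family, df, AIC, converged) and a `selected` attribute naming the
#'   family (`"fallback_logistic_linear"` if escalated).
#' @export
select_resource_model <- function(data, category,
                                  candidates = c("two_part_truncNB",
                                                 "two_part_truncPoisson",
                                                 "negative_binomial",
                                                 "poisson"),
                                  nAGQ = 7) {
  fits <- list()
  for (f in candidates) {
    fits[[f]] <- if (f == "two_part_truncPoisson" &&
                     "two_part_truncNB" %in% names(fits)) {
      fit_two_part(data, category, "truncated_poisson", nAGQ,
                   .part1 = fits[["two_part_truncNB"]]$part1)
    } else {
      fit_resource_model(data, category, f, nAGQ)
    }
  }
  fits <- fits[candidates]
  tab <- data.frame(
    family = candidates,
    df = vapply(fits, function(f) as.numeric(f$df), numeric(1)),
    AIC = vapply(fits, function(f) as.numeric(f$AIC), numeric(1)),
    converged = vapply(fits, function(f) isTRUE(f$converged), logical(1)),
    row.names = NULL)
  best <- pick_best(tab)
  if (is.na(best)) {
    out <- fit_fallback(data, category)
    attr(out, "aic_table") <- tab
    attr(out, "selected") <- "fallback_logistic_linear"
    return(out)
  }
  out <- fits[[best]]
  attr(out, "aic_table") <- tab
  attr(out, "selected") <- tab$family[best]
  out
}

# Minimal-AIC converged candidate; exact ties go to the model with fewer
# free parameters.  NA when nothing converged (fallback path).
pick_best <- function(tab) {
  ok <- which(tab$converged)
  if (!length(ok)) return(NA_integer_)
  ok[order(tab$AIC[ok], tab$df[ok])][1]
}

#' Logistic + linear fallback for admission-type categories
#'
#' When the two-part mixed model cannot be estimated (the analysis rule for
#' neonatal ICU/HDU), admission is modelled by plain logistic regression and
#' length of stay among admitted infants by linear regression, on the same
#' fixed covariates (no random effect).  The combined adjusted mean is
#' `P(admitted) x mean days | admitted`.  Subgroups with no admissions are
#' emitted as fixed zeros.
#'
#' @inheritParams fit_two_part
#' @return object of class `fallback_fit`.
#' @export
fit_fallback <- function(data, category) {
  mf <- prepare_model_frame(data, category)
  combos <- classify_combos(mf)
  sub1 <- droplevels(mf[mf$cellarm %in% combos$estimable, , drop = FALSE])
  logit <- if (nrow(sub1) > 0L) {
    glm(build_formula("use", sub1, random = FALSE), data = sub1,
        family = binomial())
  }
  sub2 <- droplevels(mf[mf$y > 0, , drop = FALSE])
  linear <- if (nrow(sub2) > 0L) {
    lm(build_formula("y", sub2, random = FALSE), data = sub2)
  }
  structure(
    list(category = category, family = "fallback_logistic_linear",
         logit = logit, linear = linear, combos = combos,
         converged = TRUE,
         n = nrow(mf),
         time_center = mean(data$step),
         time_values = mf$time_c),
    class = "fallback_fit")
}

#' @rdname adjusted_means
#' @export
adjusted_means.fallback_fit <- function(fit,
                                        standardise = c("conditional",
                                                        "marginal"), ...) {
  standardise <- match.arg(standardise)
  tv <- am_tvals(fit, standardise)
  combos <- fit$combos
  if (length(combos$absent)) {
    warning("no trial records for: ", paste(combos$absent, collapse = ", "),
            "; emitting fixed zeros", call. = FALSE)
  }
  fp1 <- if (!is.null(fit$logit)) fe_parts(fit$logit)
  fp2 <- if (!is.null(fit$linear)) fe_parts(fit$linear)
  ref1 <- combos$estimable[1]
  lv2 <- c(combos$estimable, combos$deg1)
  ref2 <- intersect(combo_levels(), lv2)[1]
  rows <- lapply(combo_levels(), function(cb) {
    if (cb %in% c(combos$deg0, combos$absent)) {
      return(am_row(fit$category, cb, 0, 0, "fixed"))
    }
    if (cb %in% combos$deg1) {
      p <- 1; vp <- 0
    } else {
      if (is.null(fp1)) return(am_row(fit$category, cb, 0, 0, "fixed"))
      r1 <- combo_response(fp1, cb, ref1, tv, plogis, dlogis_eta, d2logis_eta)
      p <- r1$value; vp <- r1$var
    }
    if (is.null(fp2)) return(am_row(fit$category, cb, 0, 0, "fixed"))
    r2 <- combo_response(fp2, cb, ref2, tv, identity,
                         function(e) rep(1, length(e)))
    days <- max(r2$value, 0)
    m <- p * days
    v <- days^2 * vp + p^2 * r2$var + vp * r2$var
    am_row(fit$category, cb, m, sqrt(v), "normal_truncated0")
  })
  do.call(rbind, rows)
}

#' @export
print.fallback_fit <- function(x, ...) {
  cat("Fallback logistic + linear model:", x$category, "\n")
  cat("  admissions:", sum(!is.null(x$logit)), "model;",
      length(x$combos$deg0), "fixed-zero cells\n")
  invisible(x)
}

#' Fit all resource categories and assemble the adjusted-means table
#'
#' Runs [select_resource_model()] for every resource category and binds the
#' per-category [adjusted_means()] into the 9 x 2 grid per category that the
#' probabilistic model consumes.
#'
#' @inheritParams fit_two_part
#' @param categories categories to fit (default: all seven).
#' @param standardise passed to [adjusted_means()].
#' @return list with `fits` (named list of fitted models), `selected`
#'   (named character of selected families) and `adjusted_means`
#'   (row-bound data.frame).
#' @export
fit_all_resources <- function(data, categories = resource_categories()$category,
                              nAGQ = 7,
                              standardise = c("conditional", "marginal")) {
  standardise <- match.arg(standardise)
  fits <- lapply(categories, function(cat)
    select_resource_model(data, cat, nAGQ = nAGQ))
  names(fits) <- categories
  am <- do.call(rbind, lapply(fits, adjusted_means, standardise = standardise))
  rownames(am) <- NULL
  list(fits = fits,
       selected = vapply(fits, function(f)
         attr(f, "selected") %||% f$family, character(1)),
       adjusted_means = am)
}

#' Read/write the adjusted-means table as CSV
#'
#' Columns: `category`, `plgf`, `diagnosis`, `arm`, `mean`, `se`, `dist` --
#' the exact input schema of [run_psa()].
#'
#' @param am adjusted-means data.frame.
#' @param path file path.
#' @export
write_adjusted_means_csv <- function(am, path) {
  stopifnot(all(c("category", "plgf", "diagnosis", "arm", "mean", "se",
                  "dist") %in% names(am)))
  write.csv(am, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_adjusted_means_csv
#' @export
read_adjusted_means_csv <- function(path) {
  am <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("category", "plgf", "diagnosis", "arm", "mean", "se", "dist")
  missing <- setdiff(need, names(am))
  if (length(missing)) {
    stop("adjusted-means CSV lacks columns: ", paste(missing, collapse = ", "))
  }
  am
}
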