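#' @importFrom stats dnbinom pnbinom qnbinom rbinom runif uniroot plogis qlogis
#'   pnorm qnorm rnorm rbeta quantile sd setNames vcov coef logLik predict
#'   model.matrix terms glm lm binomial Gamma as.formula aggregate
#' @importFrom utils read.csv write.csv packageVersion modifyList
NULL

# P(Y = 0) for NB(mean mu, dispersion size), computed on the log scale so that
# 1 - p0 stays accurate for tiny mu.  size = Inf gives the Poisson limit.
# Recycles mu and size against each other.
nb_log_p0 <- function(mu, size) {
  n <- max(length(mu), length(size))
  mu <- rep_len(mu, n)
  size <- rep_len(size, n)
  out <- -size * log1p(mu / size)
  pois <- is.infinite(size)
  out[pois] <- -mu[pois]
  out
}

# Conditional mean E[Y | Y > 0] of a zero-truncated NB with parent mean mu.
tnb_cond_mean <- function(mu, size) {
  mu / (-expm1(nb_log_p0(mu, size)))
}

# First and second derivatives of the conditional mean with respect to the
# parent mean mu; needed for (curvature-corrected) delta-method standard
# errors of hurdle-model predictions.
tnb_cond_mean_dmu <- function(mu, size) {
  p0 <- exp(nb_log_p0(mu, size))
  q <- -expm1(nb_log_p0(mu, size)) # 1 - p0
  dp0 <- if (is.infinite(size)) -p0 else -p0 * size / (size + mu)
  (q + mu * dp0) / q^2
}

tnb_cond_mean_d2mu <- function(mu, size) {
  p0 <- exp(nb_log_p0(mu, size))
  q <- -expm1(nb_log_p0(mu, size))
  if (is.infinite(size)) {
    dp0 <- -p0
    d2p0 <- p0
  } else {
    dp0 <- -p0 * size / (size + mu)
    d2p0 <- p0 * size * (size + 1) / (size + mu)^2
  }
  2 * dp0 / q^2 + mu * d2p0 / q^2 + 2 * mu * dp0^2 / q^3
}

# Invert the conditional-mean map: find the parent NB mean whose zero-truncated
# conditional mean equals m (> 1).  Monotone in mu, so uniroot is safe.
tnb_parent_mean <- function(m, size) {
  size <- rep_len(size, length(m))
  vapply(seq_along(m), function(i) {
    mi <- m[i]
    if (!is.finite(mi) || mi <= 1) {
      stop("conditional mean of a zero-truncated count must be finite and > 1 (got ",
           mi, ")")
    }
    uniroot(function(mu) tnb_cond_mean(mu, size[i]) - mi,
            interval = c(mi * 1e-12, mi), tol = 1e-12)$root
  }, numeric(1))
}

# Zero-truncated NB sampler by inverse CDF conditioned on Y >= 1.
# Vectorised over mu and size; size may be Inf (truncated Poisson).
rtrunc_nbinom <- function(n, mu, size) {
  mu <- rep_len(mu, n)
  size <- rep_len(size, n)
  p0 <- exp(nb_log_p0(mu, size))
  u <- runif(n, min = p0, max = 1)
  out <- integer(n)
  pois <- is.infinite(size)
  if (any(pois)) out[pois] <- stats::qpois(u[pois], lambda = mu[pois])
  if (any(!pois)) out[!pois] <- qnbinom(u[!pois], size = size[!pois], mu = mu[!pois])
  pmax(out, 1L)
}

# Normal truncated below at zero, by inverse CDF.  se = 0 degenerates to the
# point estimate, which is what deterministic ("fixed") PSA cells rely on.
rtruncnorm0 <- function(n, mean, sd) {
  if (length(mean) == 1L) mean <- rep_len(mean, n)
  if (length(sd) == 1L) sd <- rep_len(sd, n)
  out <- mean
  pos <- sd > 0
  if (any(pos)) {
    lo <- pnorm(0, mean[pos], sd[pos])
    out[pos] <- qnorm(runif(sum(pos), lo, 1), mean[pos], sd[pos])
  }
  pmax(out, 0)
}

#' PlGF category, final-diagnosis and subgroup labels
#'
#' The trial stratifies women by PlGF band (normal `gt100`, low `12to100`,
#' very low `lt12` pg/ml) and final diagnosis (`normal`,
#' `GH_CHT_SGA` = gestational/chronic hypertension or small-for-gestational-age,
#' `preeclampsia`), giving nine analysis subgroups.
#'
#' @return Character vectors of level labels. `cell_levels()` returns the nine
#'   `plgf:diagnosis` combinations with `gt100:normal` first (the reference
#'   cell in all models).
#' @export
plgf_levels <- function() c("gt100", "12to100", "lt12")

#' @rdname plgf_levels
#' @export
diagnosis_levels <- function() c("normal", "GH_CHT_SGA", "preeclampsia")

#' @rdname plgf_levels
#' @export
cell_levels <- function() {
  as.vector(t(outer(plgf_levels(), diagnosis_levels(),
                    function(p, d) paste(p, d, sep = ":"))))
}

#' @rdname plgf_levels
#' @export
arm_levels <- function() c("usual", "revealed")

#' @rdname plgf_levels
#' @export
delivery_modes <- function() {
  c("spontaneous", "assisted", "planned_CS", "emergency_CS")
}

#' Resource-use categories costed in the evaluation
#'
#' Five maternal categories (outpatient attendances and four inpatient bed-day
#' categories) and two infant neonatal-unit categories.  `infant_icu_hdu`
#' carries an admission flag: days are positive only for admitted infants, so
#' its hurdle probability is the admission probability.
#'
#' @return A data.frame with columns `category`, `unit` (attendance/bed_day),
#'   `group` (maternal/infant) and `admission_flag`.
#' @export
resource_categories <- function() {
  data.frame(
    category = c("outpatient", "antenatal_ward", "labour_ward",
                 "maternal_postnatal", "maternal_icu_hdu",
                 "infant_icu_hdu", "infant_scbu"),
    unit = c("attendance", rep("bed_day", 6L)),
    group = c(rep("maternal", 5L), "infant", "infant"),
    admission_flag = c(rep(FALSE, 5L), TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Format a proportion the way trial reports print it
#'
#' @param events numerator count
#' @param n denominator count
#' @param digits decimal places (default 1, e.g. 24/447 -> 5.4)
#' @return Percentage rounded to `digits`.
#' @export
event_rate_pct <- function(events, n, digits = 1) {
  stopifnot(n > 0, events >= 0, events <= n)
  round(100 * events / n, digits)
}
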