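#' Sample women onto a stepped-wedge design
#'
#' Allocates the configured number of women per arm to (cluster, step) cells
#' of the design, with cluster membership proportional to enrolment weights
#' and uniform spread over steps, then draws each woman's PlGF band and final
#' diagnosis from her arm's nine-cell multinomial, and a delivery mode from
#' the arm's mode mix.
#'
#' @param design an `sw_design` from [build_design()].
#' @param params a `generator_params` list (see [default_generator_params()]).
#' @param seed optional integer seed.
#' @return data.frame with one row per woman: `id`, `centre`, `step`, `arm`,
#'   `plgf`, `diagnosis`, `delivery_mode`.
#' @export
sample_women <- function(design, params, seed = NULL) {
  stopifnot(inherits(design, "sw_design"))
  validate_params(params)
  if (!is.null(seed)) set.seed(seed)

  cells <- expand.grid(centre = seq_len(design$n_clusters),
                       step = 0:(design$n_steps - 1),
                       KEEP.OUT.ATTRS = FALSE)
  cells$arm <- arm_at(design, cells$centre, cells$step)
  cells$w <- design$cluster_weights[cells$centre]

  rows <- lapply(arm_levels(), function(a) {
    n_a <- params$arm_totals[[a]]
    sub <- cells[cells$arm == a, , drop = FALSE]
    if (nrow(sub) == 0L && n_a > 0L) {
      stop("design has no (cluster, step) cells in arm ", a)
    }
    pick <- sub[sample.int(nrow(sub), n_a, replace = TRUE,
                           prob = sub$w), c("centre", "step")]
    cell <- sample(cell_levels(), n_a, replace = TRUE,
                   prob = params$subgroup_probs[, a])
    parts <- strsplit(cell, ":", fixed = TRUE)
    data.frame(centre = pick$centre,
               step = pick$step,
               arm = a,
               plgf = vapply(parts, `[`, "", 1L),
               diagnosis = vapply(parts, `[`, "", 2L),
               delivery_mode = sample(delivery_modes(), n_a, replace = TRUE,
                                      prob = params$delivery_mode_probs[, a]),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$centre, out$step), , drop = FALSE]
  out <- cbind(id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Draw resource-use quantities for sampled women
#'
#' For every resource category, each woman uses the service with probability
#' `plogis(qlogis(p) + u_c + beta_t * step)`; given use, the quantity is a
#' zero-truncated negative binomial whose baseline conditional mean is
#' `mu_pos` (dispersion `k`; `k = Inf` gives the truncated Poisson).  The
#' shared centre effect `u_c` and the secular trend also shift the positive
#' part, on the log scale of the parent (untruncated) mean.
#'
#' @param women data.frame from [sample_women()].
#' @param params a `generator_params` list.
#' @param cluster_effects named numeric vector of centre random intercepts
#'   (names = centre ids).  `NULL` means all zero.
#' @return `women` with one nonnegative integer column per resource category
#'   plus the logical `infant_icu_hdu_admit` flag (days > 0 iff admitted).
#' @export
draw_resource_use <- function(women, params, cluster_effects = NULL) {
  validate_params(params)
  n <- nrow(women)
  if (is.null(cluster_effects)) {
    cluster_effects <- setNames(rep(0, length(unique(women$centre))),
                                unique(women$centre))
  }
  if (any(!is.finite(cluster_effects))) {
    stop("cluster random effects must be finite")
  }
  u <- cluster_effects[as.character(women$centre)]
  trend <- params$beta_t * women$step
  if (any(!is.finite(trend))) stop("non-finite linear predictor (secular trend)")

  res <- params$resource
  res_key <- paste(res$category, res$plgf, res$diagnosis, res$arm)
  # parent means solved once per parameter row (uniroot), then shifted
  res$parent <- NA_real_
  need <- res$p > 0
  res$parent[need] <- tnb_parent_mean(res$mu_pos[need], res$k[need])

  for (cat in resource_categories()$category) {
    idx <- match(paste(cat, women$plgf, women$diagnosis, women$arm), res_key)
    if (anyNA(idx)) stop("generator parameters missing for category ", cat)
    eta1 <- qlogis(res$p[idx]) + u + trend
    if (any(is.nan(eta1))) stop("non-finite linear predictor for ", cat)
    use <- rbinom(n, 1L, plogis(eta1))
    y <- integer(n)
    pos <- which(use == 1L)
    if (length(pos)) {
      mu_i <- res$parent[idx[pos]] * exp(u[pos] + trend[pos])
      y[pos] <- rtrunc_nbinom(length(pos), mu_i, res$k[idx[pos]])
    }
    women[[cat]] <- y
  }
  women$infant_icu_hdu_admit <- women$infant_icu_hdu > 0L
  women
}

#' Draw severe maternal adverse-event flags
#'
#' Bernoulli per woman at her arm's configured event rate (r/n).
#'
#' @inheritParams draw_resource_use
#' @return `women` with a logical `adverse_event` column.
#' @export
draw_adverse_event <- function(women, params) {
  a <- params$adverse
  rate <- c(usual = a$events_usual / a$n_usual,
            plgf = a$events_plgf / a$n_plgf)
  p <- ifelse(women$arm == "usual", rate[["usual"]], rate[["plgf"]])
  women$adverse_event <- rbinom(nrow(women), 1L, p) == 1L
  women
}

#' Generate a complete synthetic stepped-wedge trial dataset
#'
#' One call to the full generator: samples women onto the design, draws one
#' shared centre random intercept per cluster (`N(0, sigma_c^2)`), then
#' resource use and adverse-event flags.  All randomness flows from the
#' single root seed, so identical `(design, params, seed)` give a
#' byte-identical dataset.
#'
#' @inheritParams sample_women
#' @param seed integer root seed.
#' @return data.frame, one row per woman (see [write_trial_csv()] for the
#'   column contract).
#' @examples
#' d <- build_design(11, 12, seed = 1)
#' trial <- simulate_trial(d, default_generator_params(), seed = 1)
#' table(trial$arm)
#' @export
simulate_trial <- function(design, params, seed) {
  set.seed(seed)
  women <- sample_women(design, params, seed = NULL)
  u <- setNames(rnorm(design$n_clusters, 0, params$sigma_c),
                as.character(seq_len(design$n_clusters)))
  women <- draw_resource_use(women, params, cluster_effects = u)
  women <- draw_adverse_event(women, params)
  attr(women, "seed") <- seed
  women
}

trial_columns <- function() {
  c("id", "centre", "step", "arm", "plgf", "diagnosis", "delivery_mode",
    resource_categories()$category, "infant_icu_hdu_admit", "adverse_event")
}

#' Read/write trial records as delimited text
#'
#' The fixed column contract is: `id`, `centre`, `step` (0-based 6-week
#' step), `arm` (`usual`/`revealed`), `plgf` (`gt100`/`12to100`/`lt12`),
#' `diagnosis` (`normal`/`GH_CHT_SGA`/`preeclampsia`), `delivery_mode`
#' (`spontaneous`/`assisted`/`planned_CS`/`emergency_CS`), one nonnegative
#' integer column per resource category, `infant_icu_hdu_admit` and
#' `adverse_event` (TRUE/FALSE).
#'
#' @param trial data.frame of trial records.
#' @param path file path.
#' @return `read_trial_csv()` returns the validated data.frame;
#'   `write_trial_csv()` returns `path` invisibly.
#' @export
write_trial_csv <- function(trial, path) {
  cols <- trial_columns()
  missing <- setdiff(cols, names(trial))
  if (length(missing)) {
    stop("trial data is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  write.csv(trial[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(trial_columns(), names(x))
  if (length(missing)) {
    stop("trial CSV is missing required columns: ",
         paste(missing, collapse = ", "))
  }
  bad_plgf <- setdiff(unique(x$plgf), plgf_levels())
  if (length(bad_plgf)) stop("unknown plgf categories: ",
                             paste(bad_plgf, collapse = ", "))
  bad_diag <- setdiff(unique(x$diagnosis), diagnosis_levels())
  if (length(bad_diag)) stop("unknown diagnosis categories: ",
                             paste(bad_diag, collapse = ", "))
  cats <- resource_categories()$category
  if (any(vapply(x[cats], function(v) any(v < 0), logical(1)))) {
    stop("resource-use quantities must be nonnegative")
  }
  x$infant_icu_hdu_admit <- as.logical(x$infant_icu_hdu_admit)
  x$adverse_event <- as.logical(x$adverse_event)
  x
}
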