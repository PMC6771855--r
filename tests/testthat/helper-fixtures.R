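# Shared fixtures.  Everything is generated in code; nothing is read from
# disk except files the tests themselves write to tempdir().

# Generator parameters with a simplified subgroup structure: probability mass
# on `cells` only, one common (p, mu, k) for every category (revealed-arm
# shifts applied on the link scales).  Keeps model matrices small so fits in
# tests stay fast.
make_test_params <- function(arm_totals = c(usual = 300L, revealed = 300L),
                             cells = "gt100:normal",
                             cell_probs = NULL,
                             p = 0.6, mu = 4, k = 1.5,
                             sigma_c = 0, beta_t = 0,
                             arm_logit_shift = 0, arm_log_shift = 0) {
  base <- default_generator_params(sigma_c = sigma_c, beta_t = beta_t)
  base$arm_totals <- arm_totals
  probs <- stats::setNames(rep(0, 9), cell_levels())
  if (is.null(cell_probs)) cell_probs <- rep(1 / length(cells), length(cells))
  probs[cells] <- cell_probs
  base$subgroup_probs <- cbind(usual = probs, revealed = probs)
  r <- base$resource
  r$p <- p
  r$mu_pos <- mu
  r$k <- k
  rev <- r$arm == "revealed"
  r$p[rev] <- stats::plogis(stats::qlogis(p) + arm_logit_shift)
  r$mu_pos[rev] <- mu * exp(arm_log_shift)
  base$resource <- r
  validate_params(base)
}

# A complete 7-category x 9-cell x 2-arm adjusted-means grid built from
# functions of (category index, cell index, arm).
make_am_grid <- function(mean_fun = function(cat, cell, arm) 2,
                         se_fun = function(cat, cell, arm) 0,
                         dist = "normal_truncated0") {
  cats <- resource_categories()$category
  g <- expand.grid(category = cats, cell = cell_levels(),
                   arm = arm_levels(), stringsAsFactors = FALSE)
  pd <- strsplit(g$cell, ":", fixed = TRUE)
  ci <- match(g$category, cats)
  li <- match(g$cell, cell_levels())
  data.frame(category = g$category,
             plgf = vapply(pd, `[`, "", 1L),
             diagnosis = vapply(pd, `[`, "", 2L),
             arm = g$arm,
             mean = mapply(mean_fun, ci, li, g$arm),
             se = mapply(se_fun, ci, li, g$arm),
             dist = dist,
             stringsAsFactors = FALSE)
}

equal_weights <- function() {
  stats::setNames(rep(1 / 9, 9), cell_levels())
}

# The paper-default synthetic pipeline is expensive (~40 s); run it once per
# session and share across test files.
.pipeline_cache <- new.env(parent = emptyenv())

default_pipeline <- function() {
  if (is.null(.pipeline_cache$pipe)) {
    cfg <- default_config()
    cfg$n_iterations <- 2000
    .pipeline_cache$pipe <- suppressWarnings(run_pipeline(cfg, seed = 1))
  }
  .pipeline_cache$pipe
}

# Independent zero-truncated NB log-density for oracle fits in tests.
dtnb_log <- function(y, mu, size) {
  stats::dnbinom(y, size = size, mu = mu, log = TRUE) -
    log1p(-stats::dnbinom(0, size = size, mu = mu))
}
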