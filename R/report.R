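# Table-1/2 shape: rows = resource categories (+ totals) x three statistic
# rows, columns = the nine subgroup cells + a total column.  Values stay as
# raw floats; rounding to whole GBP is a presentation concern.
psa_table_frame <- function(result, groups) {
  cs <- result$cell_stats
  tt <- result$totals
  out <- do.call(rbind, lapply(groups, function(g) {
    sub <- cs[cs$group == g, ]
    m <- rbind(actual = sub$actual, weighted = sub$weighted,
               pct_saving = sub$pct_saving)
    colnames(m) <- sub$cell
    tot <- c(tt$actual[tt$group == g], tt$weighted[tt$group == g],
             tt$pct_saving[tt$group == g])
    data.frame(resource_use = g, statistic = rownames(m), m, total = tot,
               check.names = FALSE, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Write publication-shaped outputs for a probabilistic model run
#'
#' Writes, under `dir`:
#' * `maternal_costs.csv` -- maternal resource categories plus the maternal
#'   total, one row per statistic (actual / weighted / percent cost-saving),
#'   nine subgroup columns plus a total column;
#' * `infant_combined_costs.csv` -- the infant categories, infant total and
#'   the combined maternal+infant total, same shape;
#' * `price_sweep.csv` -- cost-saving probabilities across test prices;
#' * `ceac.csv` -- the acceptability curve (`lambda`, `probability`);
#' * `scaling.csv` -- national extrapolation (when `scaling` is supplied);
#' * `run_metadata.json` -- seed, iterations, test cost, weights mode,
#'   currency year and package version.
#'
#' Writing is idempotent: a fixed `psa_result` produces byte-identical files.
#'
#' @param result a `psa_result`.
#' @param dir output directory (created if needed).
#' @param scaling optional result of [scale_to_population()].
#' @return invisible character vector of the files written.
#' @export
render_outputs <- function(result, dir, scaling = NULL) {
  stopifnot(inherits(result, "psa_result"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(dir)) stop("cannot create output directory ", dir)
  }
  rc <- resource_categories()
  paths <- character(0)
  wr <- function(df, name) {
    p <- file.path(dir, name)
    write.csv(df, p, row.names = FALSE, quote = FALSE)
    paths <<- c(paths, p)
  }
  wr(psa_table_frame(result, c(rc$category[rc$group == "maternal"],
                               "maternal")),
     "maternal_costs.csv")
  wr(psa_table_frame(result, c(rc$category[rc$group == "infant"],
                               "infant", "combined")),
     "infant_combined_costs.csv")
  wr(result$price_sweep, "price_sweep.csv")
  wr(result$ceac, "ceac.csv")
  if (!is.null(scaling)) {
    wr(data.frame(eligible_women = scaling$eligible_women,
                  annual_saving_gbp = scaling$annual_saving_gbp),
       "scaling.csv")
  }
  meta <- list(seed = result$seed,
               n_iterations = result$n_iterations,
               test_cost = result$test_cost,
               weights_mode = result$weights_mode,
               currency_year = result$currency_year,
               events_avoided_per_1000 =
                 result$adverse$mean_events_avoided_per_1000,
               dominant = result$dominant,
               package_version = as.character(packageVersion("plgfcea")))
  mp <- file.path(dir, "run_metadata.json")
  jsonlite::write_json(meta, mp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  paths <- c(paths, mp)
  invisible(paths)
}
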