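#' Build a stepped-wedge crossover design
#'
#' Constructs the cluster-level design of a stepped-wedge cluster-randomised
#' trial: all clusters start under usual care, and at each successive 6-week
#' step one randomly chosen cluster crosses over to the intervention
#' (revealed PlGF testing).  Steps are indexed `0 .. n_steps - 1`; the k-th
#' cluster in the seeded random crossover order crosses at step `k`, so step 0
#' is all-usual-care and the final step is all-intervention.
#'
#' @param n_clusters number of maternity units (clusters).
#' @param n_steps number of 6-week periods; must be at least
#'   `n_clusters + 1` so that every cluster crosses over before the end.
#' @param seed optional integer seed for the crossover permutation.
#' @param cluster_weights optional positive enrolment weights, one per
#'   cluster.  Defaults to a linear ramp emulating units of 3000-9000
#'   deliveries per year.
#' @return An object of class `sw_design`: list with `n_clusters`, `n_steps`,
#'   `crossover_order` (a permutation of cluster ids), `step_of_crossover`
#'   (named integer vector, cluster -> step index) and normalised
#'   `cluster_weights`.
#' @examples
#' d <- build_design(11, 12, seed = 1)
#' table(arm_at(d, cluster = 1, step = 0:11))
#' @export
build_design <- function(n_clusters, n_steps, seed = NULL,
                         cluster_weights = NULL) {
  stopifnot(n_clusters >= 1, n_steps >= 2)
  if (n_steps < n_clusters + 1) {
    stop("n_steps must be >= n_clusters + 1 (", n_clusters + 1,
         ") so that every cluster crosses over before the trial ends; got ",
         n_steps)
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(cluster_weights)) {
    cluster_weights <- seq(3000, 9000, length.out = n_clusters)
  }
  stopifnot(length(cluster_weights) == n_clusters, all(cluster_weights > 0))
  order <- sample.int(n_clusters)
  step_of <- integer(n_clusters)
  step_of[order] <- seq_len(n_clusters)
  names(step_of) <- as.character(seq_len(n_clusters))
  structure(
    list(n_clusters = n_clusters,
         n_steps = n_steps,
         crossover_order = order,
         step_of_crossover = step_of,
         cluster_weights = cluster_weights / sum(cluster_weights)),
    class = "sw_design"
  )
}

#' Trial arm of a cluster at a given step
#'
#' @param design an `sw_design`.
#' @param cluster cluster id (1-based).
#' @param step step index (0-based); vectorised over `cluster` and `step`.
#' @return `"usual"` or `"revealed"`; the intervention indicator is monotone
#'   non-decreasing in step for every cluster.
#' @export
arm_at <- function(design, cluster, step) {
  stopifnot(inherits(design, "sw_design"))
  ifelse(step >= design$step_of_crossover[as.character(cluster)],
         "revealed", "usual")
}

#' @export
print.sw_design <- function(x, ...) {
  cat("Stepped-wedge design:", x$n_clusters, "clusters,",
      x$n_steps, "six-week steps\n")
  cat("Crossover order:", paste(x$crossover_order, collapse = " "), "\n")
  n_int <- vapply(0:(x$n_steps - 1), function(s)
    sum(arm_at(x, seq_len(x$n_clusters), s) == "revealed"), numeric(1))
  cat("Clusters on intervention by step:",
      paste(n_int, collapse = " "), "\n")
  invisible(x)
}
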