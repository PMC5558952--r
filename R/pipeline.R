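#' Run the full ring-to-carbon analysis pipeline
#'
#' Orchestrates the complete retrospective analysis for a cohort of trees:
#' cross-dating coherence check, mean ring series per tree, diameter
#' reconstruction, allometric carbon trajectory, lifetime-quartile shares,
#' species-level summary tables, per-tree trend and change-point tests,
#' and growth-pattern classification.  The Cox-Stuart trend test is run on
#' both the annual carbon accumulation series and the cumulative carbon
#' curve of every tree (the two natural readings of "growth trend"), and
#' the archetype classifier is applied both to the mean ring-width series
#' (`pattern_width`, comparable to the synthetic generator's ground truth)
#' and to the annual carbon series (`pattern_carbon`, the carbon-space
#' reading; the allometry's convexity makes the two differ for slow-growth
#' plateaus).
#'
#' @param trees List of [tree_record()] objects (each with >= 2 radii),
#'   e.g. `simulate_cohort(config)$trees` or records assembled from
#'   [read_rwl()] / [read_series_table()] input.
#' @param alpha Significance level for the trend tests (default 0.05).
#' @param classifier A [classifier_config()].
#' @param out_dir Optional directory; when given, every result table is
#'   written there as a tab-separated file (byte-identical across runs
#'   with the same input).
#' @param crossdate_threshold Correlation threshold below which radius
#'   pairs are flagged (default 0.3).
#' @return A list of class `run_report` with elements `summary` (the
#'   [cohort_summary()] tables), `trajectories` (named list of
#'   `carbon_trajectory`), `quartiles` (one data frame, 4 rows per tree),
#'   `tests` (one row per tree: trend/change-point/label results), and
#'   `crossdating` (flagged-pair report).
#' @export
run_pipeline <- function(trees, alpha = 0.05,
                         classifier = classifier_config(alpha = alpha),
                         out_dir = NULL, crossdate_threshold = 0.3) {
  if (length(trees) == 0) stop("run_pipeline: no trees supplied")
  stopifnot(all(vapply(trees, inherits, logical(1), "tree_record")))
  ids <- vapply(trees, `[[`, character(1), "tree_id")

  stage <- function(what, id, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed for tree %s: %s",
                   what, id, conditionMessage(e)), call. = FALSE))
  }

  nradii <- vapply(trees, function(tr) length(tr$radii), integer(1))
  if (any(nradii < 2L))
    stop(sprintf(
      "pipeline stage 'mean_tree_series' failed for tree %s: need at least 2 radii",
      ids[which(nradii < 2L)[1]]), call. = FALSE)

  crossdating <- do.call(rbind, lapply(trees, function(tr) {
    cd <- stage("crossdate_check", tr$tree_id,
                crossdate_check(tr$radii, threshold = crossdate_threshold))
    cbind(tree_id = tr$tree_id, cd, stringsAsFactors = FALSE)
  }))

  mean_series <- lapply(trees, function(tr)
    stage("mean_tree_series", tr$tree_id, mean_tree_series(tr$radii)))
  trajectories <- lapply(seq_along(trees), function(i) {
    tr <- trees[[i]]
    dtraj <- stage("reconstruct_diameter", tr$tree_id,
                   reconstruct_diameter(mean_series[[i]]))
    stage("carbon_trajectory", tr$tree_id,
          carbon_trajectory(dtraj, rho = tr$wood_density, E = tr$stress_E,
                            carbon_fraction = tr$carbon_fraction))
  })
  names(trajectories) <- ids

  quart_list <- lapply(seq_along(trees), function(i)
    stage("quartile_shares", ids[i], quartile_shares(trajectories[[i]])))
  quartiles <- do.call(rbind, c(quart_list, list(make.row.names = FALSE)))

  species <- vapply(trees, `[[`, character(1), "species")
  summary_tables <- cohort_summary(trajectories, species,
                                   quartiles = quart_list)

  tests <- do.call(rbind, lapply(seq_along(trees), function(i) {
    id <- ids[i]
    ann <- trajectories[[i]]$annual_c_kg
    cum <- cumulative_curve(trajectories[[i]])
    cs_ann <- stage("cox_stuart(annual)", id, cox_stuart(ann))
    cs_cum <- stage("cox_stuart(cumulative)", id, cox_stuart(cum))
    pt <- stage("pettitt", id, pettitt(ann))
    lab_c <- stage("classify(annual carbon)", id,
                   classify_pattern(ann, classifier, tree_id = id))
    lab_w <- stage("classify(ring width)", id,
                   classify_pattern(mean_series[[i]]$widths, classifier,
                                    tree_id = id))
    data.frame(
      tree_id = id, species = species[i],
      age = nrow(trajectories[[i]]),
      final_diameter_cm = trajectories[[i]]$diameter_cm[nrow(trajectories[[i]])],
      final_carbon_kg = trajectories[[i]]$carbon_kg[nrow(trajectories[[i]])],
      trend_annual_p = cs_ann$p_value,
      trend_annual_direction = cs_ann$direction,
      trend_cumulative_p = cs_cum$p_value,
      trend_cumulative_direction = cs_cum$direction,
      pettitt_K = pt$K, pettitt_tau = pt$tau, pettitt_p = pt$p_approx,
      pattern_carbon = lab_c$label,
      pattern_width = lab_w$label,
      stringsAsFactors = FALSE)
  }))

  report <- structure(
    list(summary = summary_tables, trajectories = trajectories,
         quartiles = quartiles, tests = tests, crossdating = crossdating,
         alpha = alpha),
    class = "run_report")

  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d trees, %d species; alpha = %g\n",
              nrow(x$tests), nrow(x$summary$stock), x$alpha))
  cat(sprintf("  significant increasing cumulative-carbon trend: %d of %d trees\n",
              sum(x$tests$trend_cumulative_p <= x$alpha &
                    x$tests$trend_cumulative_direction == "increasing"),
              nrow(x$tests)))
  invisible(x)
}

#' Write all pipeline result tables to a directory
#'
#' Writes the summary, per-tree trajectory, quartile, test and
#' cross-dating tables of a [run_pipeline()] report as tab-separated text
#' files.  Output is deterministic: identical reports produce
#' byte-identical files.
#'
#' @param report A `run_report`.
#' @param out_dir Directory (created if absent).
#' @return Invisibly, the vector of files written.
#' @export
write_report <- function(report, out_dir) {
  stopifnot(inherits(report, "run_report"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
    path
  }
  traj <- do.call(rbind, c(report$trajectories, list(make.row.names = FALSE)))
  files <- c(
    wt(report$summary$stock, "summary_stock.tsv"),
    wt(report$summary$annual, "summary_annual.tsv"),
    wt(report$summary$quartiles, "summary_quartiles.tsv"),
    wt(traj, "trajectories.tsv"),
    wt(report$quartiles, "quartile_shares.tsv"),
    wt(report$tests, "tree_tests.tsv"),
    wt(report$crossdating, "crossdating.tsv"))
  invisible(files)
}

#' Assemble tree records from ring series and species parameters
#'
#' Groups a flat list of [ring_series()] by `tree_id` and attaches species
#' parameters (wood density, stress factor, carbon fraction) to build
#' [tree_record()]s ready for [run_pipeline()].
#'
#' @param series List of [ring_series()].
#' @param species_params Optional data frame with columns `species`,
#'   `wood_density` and optionally `carbon_fraction`; unknown species fall
#'   back to [default_wood_density()].
#' @param stress_E Site stress factor applied to all trees.
#' @param carbon_fraction Default carbon fraction.
#' @return Named list of [tree_record()].
#' @export
collect_trees <- function(series, species_params = NULL, stress_E = 0,
                          carbon_fraction = 0.471) {
  stopifnot(all(vapply(series, inherits, logical(1), "ring_series")))
  by_tree <- split(series, vapply(series, `[[`, character(1), "tree_id"))
  lapply(by_tree, function(radii) {
    sp <- radii[[1]]$species
    rho <- NULL; cf <- carbon_fraction
    if (!is.null(species_params) && sp %in% species_params$species) {
      row <- species_params[species_params$species == sp, ][1, ]
      rho <- row$wood_density
      if ("carbon_fraction" %in% names(row) && !is.na(row$carbon_fraction))
        cf <- row$carbon_fraction
    }
    tree_record(tree_id = radii[[1]]$tree_id, species = sp, radii = radii,
                wood_density = rho, stress_E = stress_E,
                carbon_fraction = cf)
  })
}
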