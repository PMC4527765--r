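#' Run the full observation-table analysis pipeline
#'
#' Orchestrates the table-level stages in dependency order on one
#' configuration: (optionally) simulate an observation table, apply the
#' parsing rules, fit the speed to Dynamic Cell Area line and derive CMD,
#' measure the net-area and speed-persistence couplings, classify
#' feature archetypes against both processes, and run the two-step feature
#' selection. Identical configuration and seed give an identical report.
#'
#' @param config List with either `table` (an observation table with
#'   feature columns) or `table_spec` (a [table_sim_spec()] to simulate
#'   from); optional entries `features` (feature column names; default:
#'   columns matching `^F[0-9]`), `alpha` (0.001), `wilcoxon_family`,
#'   `kw_family`, `pixel_size_um` (0.21), `max_lag` (12), `standardize`
#'   (TRUE), `apply_parsing` (FALSE for already-parsed tables).
#' @return List of class `run_report` with the fit parameters, coupling
#'   correlations, archetype Venn counts per process, selection class
#'   counts, per-stage parameter echo, and (for simulated tables) the
#'   ground-truth plan.
#' @export
run_pipeline <- function(config) {
  stopifnot(is.list(config))
  if (is.null(config[["table"]]) && is.null(config[["table_spec"]])) {
    stop("config needs either a table or a table_spec")
  }
  truth <- NULL
  if (is.null(config[["table"]])) {
    sim <- generate_feature_table(config[["table_spec"]])
    tab <- sim$table
    truth <- sim$truth
  } else {
    tab <- config[["table"]]
  }
  features <- config[["features"]] %||% grep("^F[0-9]", names(tab), value = TRUE)
  if (length(features) == 0) stop("no feature columns found")
  alpha <- config[["alpha"]] %||% 0.001
  px <- config[["pixel_size_um"]] %||% 0.21
  if (isTRUE(config[["apply_parsing"]])) tab <- parse_validity(tab)
  use <- if ("valid" %in% names(tab)) tab$valid else rep(TRUE, nrow(tab))

  fit <- fit_cmd(tab$cell_speed[use], tab$dynamic_cell_area[use])
  tab <- compute_cmd(tab, fit)

  coupling <- delta_area_coupling(tab[use, , drop = FALSE], px)
  autoc <- suppressWarnings(
    speed_autocorrelation(tab, max_lag = config[["max_lag"]] %||% 12))

  arch_speed <- archetype_classify(tab, "speed", features, alpha = alpha,
                                   family = config[["wilcoxon_family"]])
  arch_cmd <- archetype_classify(tab, "cmd", features, alpha = alpha,
                                 family = config[["wilcoxon_family"]])
  sel <- select_features(tab, features, alpha = alpha,
                         family = config[["kw_family"]],
                         standardize = config[["standardize"]] %||% TRUE)

  confusion <- NULL
  if (!is.null(truth)) {
    truth_class <- ifelse(truth$process == "none", "neither",
                   ifelse(truth$process == "speed", "speed_only",
                   ifelse(truth$process == "cmd", "cmd_only", "both")))
    confusion <- table(truth = truth_class, recovered = sel$results$class)
  }

  structure(
    list(
      schema_version = 1L,
      n_observations = nrow(tab), n_valid = sum(use),
      n_features = length(features),
      fit = list(k = fit$k, m = fit$m, r = fit$r, n = fit$n),
      cmd_checks = list(mean_cmd = mean(tab$cmd[use]),
                        cor_cmd_speed = stats::cor(tab$cmd[use],
                                                   tab$cell_speed[use])),
      delta_area = coupling[c("r", "slope", "p")],
      autocorrelation = list(r = autoc$r, p = autoc$p,
                             n_cells = if (is.null(autoc$cells)) 0L
                                       else nrow(autoc$cells)),
      archetypes = list(speed = list(venn = arch_speed$venn,
                                     n_related = arch_speed$n_related),
                        cmd = list(venn = arch_cmd$venn,
                                   n_related = arch_cmd$n_related)),
      selection = list(counts = sel$counts),
      confusion = confusion,
      parameters = list(alpha = alpha, pixel_size_um = px,
                        wilcoxon_family = arch_speed$family,
                        kw_family = sel$family,
                        max_lag = config[["max_lag"]] %||% 12),
      truth = truth,
      table = tab,
      details = list(archetype_speed = arch_speed, archetype_cmd = arch_cmd,
                     selection = sel)
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %d observations (%d valid), %d features\n",
              x$n_observations, x$n_valid, x$n_features))
  cat(sprintf("  DCA = %.2f * speed + %.2f  (r = %.3f)\n",
              x$fit$k, x$fit$m, x$fit$r))
  cat(sprintf("  delta-area~speed r = %.3f; autocorr~speed r = %.3f\n",
              x$delta_area$r, x$autocorrelation$r))
  cat(sprintf("  related features: speed %d, cmd %d\n",
              x$archetypes$speed$n_related, x$archetypes$cmd$n_related))
  cat("  selection: ", paste(names(x$selection$counts),
                             x$selection$counts, sep = "=",
                             collapse = " "), "\n")
  invisible(x)
}

#' Write a machine-readable run report
#'
#' Serializes the summary sections of a [run_pipeline()] report (fit,
#' couplings, archetype Venn counts, selection counts, parameters,
#' confusion table if present) as JSON. The table and model objects are
#' not serialized.
#'
#' @param report A `run_report`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_run_report <- function(report, path) {
  stopifnot(inherits(report, "run_report"))
  out <- report[c("schema_version", "n_observations", "n_valid",
                  "n_features", "fit", "cmd_checks", "delta_area",
                  "autocorrelation", "archetypes", "selection",
                  "parameters")]
  out$archetypes$speed$venn <- as.list(report$archetypes$speed$venn)
  out$archetypes$cmd$venn <- as.list(report$archetypes$cmd$venn)
  out$selection$counts <- as.list(report$selection$counts)
  if (!is.null(report$confusion)) {
    cf <- as.data.frame(report$confusion)
    out$confusion <- cf
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
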