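#' Read an observation table from a CSV triplet
#'
#' Reads the three-sheet observation layout (features / processes / index)
#' from CSV files and merges them row-wise. The three files must have
#' identical row counts and carry the observations in the same order; rows
#' are merged positionally, never joined by key.
#'
#' @param dir Directory containing `features.csv`, `processes.csv` and
#'   `index.csv`, or `NULL` when the three paths are given explicitly.
#' @param features,processes,index Explicit file paths (override `dir`).
#' @return A data.frame: index columns, then process columns, then feature
#'   columns, with a `valid` column added (all `TRUE`) if absent.
#' @export
read_observation_table <- function(dir = NULL, features = NULL,
                                   processes = NULL, index = NULL) {
  if (!is.null(dir)) {
    features <- features %||% file.path(dir, "features.csv")
    processes <- processes %||% file.path(dir, "processes.csv")
    index <- index %||% file.path(dir, "index.csv")
  }
  for (p in c(features, processes, index)) {
    if (!file.exists(p)) stop("missing input file: ", p)
  }
  fe <- utils::read.csv(features, check.names = FALSE)
  pr <- utils::read.csv(processes, check.names = FALSE)
  ix <- utils::read.csv(index, check.names = FALSE)
  if (nrow(fe) != nrow(pr) || nrow(fe) != nrow(ix)) {
    stop(sprintf("sheet row counts differ: features=%d processes=%d index=%d",
                 nrow(fe), nrow(pr), nrow(ix)))
  }
  need <- c("cell_speed", "dynamic_cell_area")
  miss <- setdiff(need, names(pr))
  if (length(miss)) stop("processes sheet lacks columns: ",
                         paste(miss, collapse = ", "))
  tab <- cbind(ix, pr, fe)
  if (!"valid" %in% names(tab)) tab$valid <- TRUE
  key <- paste(tab$cell_trace_id, tab$frame_number)
  if (anyDuplicated(key)) stop("duplicated (cell_trace_id, frame_number)")
  tab
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write an observation table as a CSV triplet
#'
#' Inverse of [read_observation_table()]: splits the table into index,
#' process and feature sheets written as three CSVs, preserving row order.
#'
#' @param table Observation table (as produced by
#'   [generate_feature_table()] or [read_observation_table()]).
#' @param dir Output directory (created if needed).
#' @param feature_cols Character vector naming the feature columns; by
#'   default every column not recognized as index or process.
#' @return `dir`, invisibly.
#' @export
write_observation_table <- function(table, dir, feature_cols = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  index_cols <- intersect(
    c("experiment_id", "cell_trace_id", "frame_number",
      "position_x", "position_y", "valid"), names(table))
  process_cols <- intersect(
    c("cell_speed", "protrusion_pixels", "retraction_pixels",
      "short_lived_pixels", "dynamic_cell_area", "cmd"), names(table))
  feature_cols <- feature_cols %||%
    setdiff(names(table), c(index_cols, process_cols))
  utils::write.csv(table[index_cols], file.path(dir, "index.csv"),
                   row.names = FALSE)
  utils::write.csv(table[process_cols], file.path(dir, "processes.csv"),
                   row.names = FALSE)
  utils::write.csv(table[feature_cols], file.path(dir, "features.csv"),
                   row.names = FALSE)
  invisible(dir)
}

#' Flag observations unusable for dynamic measures
#'
#' Applies the parsing rules for per-frame membrane measures to a table of
#' tracked observations: the first and last frame of every cell trace are
#' flagged invalid (protrusions are undefined without a previous frame,
#' retractions without a next one), as is any frame adjacent to a gap in
#' the trace's frame numbering.
#'
#' @param table Observation table with `cell_trace_id` and `frame_number`.
#' @return The table with its `valid` column set accordingly.
#' @export
parse_validity <- function(table) {
  stopifnot(all(c("cell_trace_id", "frame_number") %in% names(table)))
  valid <- rep(TRUE, nrow(table))
  for (id in unique(table$cell_trace_id)) {
    rows <- which(table$cell_trace_id == id)
    fr <- table$frame_number[rows]
    present <- function(f) f %in% fr
    ok <- vapply(fr, function(f) present(f - 1) && present(f + 1), logical(1))
    valid[rows] <- ok
  }
  table$valid <- valid
  table
}

#' Standardize CMAC intensities to the smallest-object reference
#'
#' Per experiment and per intensity channel, computes the median intensity
#' of the reference set of smallest objects (the smallest `percentile_cut`
#' area-percentiles, by default 3, corresponding to adhesions of roughly
#' 0.15-0.2 um^2) and divides every intensity in that experiment and
#' channel by it. Makes intensity-derived features comparable across
#' experimental repeats with different illumination or expression levels.
#'
#' @param cmacs Data frame of per-object records.
#' @param intensity_cols Character vector of intensity column names.
#' @param area_col Name of the object area column (um^2).
#' @param experiment_col Name of the experiment identifier column.
#' @param percentile_cut Size of the reference set in area percentiles.
#' @return `cmacs` with the intensity columns divided by the per-experiment
#'   reference medians; experiments with an empty reference set are dropped
#'   with a warning.
#' @export
standardize_intensities <- function(cmacs, intensity_cols,
                                    area_col = "area_um2",
                                    experiment_col = "experiment_id",
                                    percentile_cut = 3) {
  stopifnot(all(c(intensity_cols, area_col, experiment_col) %in% names(cmacs)))
  keep <- rep(TRUE, nrow(cmacs))
  for (e in unique(cmacs[[experiment_col]])) {
    rows <- which(cmacs[[experiment_col]] == e)
    areas <- cmacs[[area_col]][rows]
    n_ref <- max(1L, ceiling(length(rows) * percentile_cut / 100))
    ref <- rows[order(areas)[seq_len(n_ref)]]
    for (col in intensity_cols) {
      med <- stats::median(cmacs[[col]][ref])
      if (!is.finite(med) || med == 0) {
        warning("experiment ", e, " has no usable reference for ", col,
                "; excluded")
        keep[rows] <- FALSE
        next
      }
      cmacs[[col]][rows] <- cmacs[[col]][rows] / med
    }
  }
  cmacs[keep, , drop = FALSE]
}

#' Quartile-based cohort descriptors of one feature distribution
#'
#' Summarizes the distribution of a per-object feature within one cohort
#' (the set of adhesion objects of one cell at one time point): quartiles,
#' quartile dispersion `QD = (q3 - q1) / 2` (the semi-interquartile range),
#' Bowley-type quartile skewness `QS = (q2 - (q1 + q3)/2) / QD`, and the
#' quartile coefficient of variation `CoV = QD / q2`. `QS` is undefined
#' (NA, flagged) when `QD = 0`, and `CoV` when `q2 = 0`.
#'
#' @param values Numeric vector of the cohort's feature values (non-empty).
#' @param type Quantile interpolation rule, passed to [stats::quantile()]
#'   (default 7, linear interpolation between order statistics).
#' @param literal If `TRUE`, use the alternative operator placements
#'   `QD = 2*(q3 - q1)` and `QS = q2 - (q3 - q1) / (2*QD)` for sensitivity
#'   analysis.
#' @return One-row data.frame: `q1`, `q2`, `q3`, `qd`, `qs`, `cov`, `n`,
#'   plus logical flags `qs_defined`, `cov_defined`.
#' @export
cohort_descriptors <- function(values, type = 7, literal = FALSE) {
  values <- values[is.finite(values)]
  if (length(values) == 0) stop("empty cohort")
  q <- unname(stats::quantile(values, c(0.25, 0.5, 0.75), type = type))
  qd <- if (literal) 2 * (q[3] - q[1]) else (q[3] - q[1]) / 2
  qs <- if (qd == 0) NA_real_ else if (literal) {
    q[2] - (q[3] - q[1]) / (2 * qd)
  } else {
    (q[2] - (q[1] + q[3]) / 2) / qd
  }
  cv <- if (q[2] == 0) NA_real_ else qd / q[2]
  data.frame(q1 = q[1], q2 = q[2], q3 = q[3], qd = qd, qs = qs, cov = cv,
             n = length(values), qs_defined = qd != 0, cov_defined = q[2] != 0)
}

#' Cohort summaries per cell and frame
#'
#' Groups per-object records into cohorts (cell x frame) and computes, for
#' each requested feature column, the quartile descriptors of
#' [cohort_descriptors()], plus cohort sums (e.g. total adhesion area,
#' total marker content) and the mean lifetime.
#'
#' @param cmacs Data frame of per-object records with `cell_trace_id` and
#'   `frame_number`.
#' @param feature_cols Columns summarized by quartile descriptors.
#' @param sum_cols Columns summed over the cohort.
#' @param lifetime_col Column averaged over the cohort (or `NULL`).
#' @inheritParams cohort_descriptors
#' @return Data.frame, one row per cohort, descriptor columns named
#'   `<stat>_<feature>`.
#' @export
summarize_cohorts <- function(cmacs, feature_cols, sum_cols = character(),
                              lifetime_col = NULL, type = 7,
                              literal = FALSE) {
  stopifnot(all(c("cell_trace_id", "frame_number", feature_cols, sum_cols,
                  lifetime_col) %in% names(cmacs)))
  key <- interaction(cmacs$cell_trace_id, cmacs$frame_number, drop = TRUE)
  groups <- split(seq_len(nrow(cmacs)), key)
  rows <- lapply(groups, function(idx) {
    out <- data.frame(cell_trace_id = cmacs$cell_trace_id[idx[1]],
                      frame_number = cmacs$frame_number[idx[1]],
                      n_cmacs = length(idx))
    for (col in feature_cols) {
      d <- cohort_descriptors(cmacs[[col]][idx], type = type,
                              literal = literal)
      names(d) <- paste0(names(d), "_", col)
      out <- cbind(out, d[c(1:6)])
    }
    for (col in sum_cols) out[[paste0("sum_", col)]] <- sum(cmacs[[col]][idx])
    if (!is.null(lifetime_col)) {
      out[[paste0("mean_", lifetime_col)]] <- mean(cmacs[[lifetime_col]][idx])
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[order(res$cell_trace_id, res$frame_number), , drop = FALSE]
}
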