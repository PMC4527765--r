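#' Fit the linear Cell Speed to Dynamic Cell Area relationship
#'
#' Ordinary least squares of Dynamic Cell Area on Cell Speed, pooled over
#' all valid observations: `DCA = k * speed + m`. The residuals define
#' Corrected Membrane Dynamics (CMD), a speed-independent measure of
#' membrane activity: by the OLS normal equations CMD has exactly zero mean
#' and zero correlation with speed.
#'
#' @param speed,dca Paired numeric vectors (um/min, um^2); pairs with
#'   non-finite entries are dropped.
#' @return An object of class `cmd_fit`: `k` (slope), `m` (intercept), `n`,
#'   `r` (Pearson correlation of the fit), `k_se` (slope standard error)
#'   and `cmd` (residuals in input order, `NA` where a pair was dropped).
#' @export
fit_cmd <- function(speed, dca) {
  stopifnot(length(speed) == length(dca))
  ok <- is.finite(speed) & is.finite(dca)
  if (sum(ok) < 3) stop("need at least 3 valid paired observations")
  if (stats::var(speed[ok]) == 0) stop("zero variance in speed: fit undefined")
  fit <- stats::lm(dca[ok] ~ speed[ok])
  cmd <- rep(NA_real_, length(speed))
  res <- stats::residuals(fit)
  cmd[ok] <- res
  n <- sum(ok)
  k_se <- sqrt(sum(res^2) / (n - 2) /
                 sum((speed[ok] - mean(speed[ok]))^2))
  structure(
    list(k = unname(stats::coef(fit)[2]), m = unname(stats::coef(fit)[1]),
         n = n, r = stats::cor(speed[ok], dca[ok]),
         k_se = k_se,
         cmd = cmd),
    class = "cmd_fit"
  )
}

#' @export
print.cmd_fit <- function(x, ...) {
  cat(sprintf("<cmd_fit> DCA = %.3f * speed + %.3f  (n = %d, r = %.3f)\n",
              x$k, x$m, x$n, x$r))
  invisible(x)
}

#' Add the Corrected Membrane Dynamics column to an observation table
#'
#' `cmd = dynamic_cell_area - k * cell_speed - m` per row, using the slope
#' and intercept of a fit obtained on the same population.
#'
#' @param table Observation table with `cell_speed` and `dynamic_cell_area`.
#' @param fit A `cmd_fit`; by default refitted on the table's valid rows.
#' @return The table with a `cmd` column (`NA` where speed or area is
#'   missing).
#' @export
compute_cmd <- function(table, fit = NULL) {
  stopifnot(all(c("cell_speed", "dynamic_cell_area") %in% names(table)))
  if (is.null(fit)) {
    use <- if ("valid" %in% names(table)) table$valid else TRUE
    fit <- fit_cmd(table$cell_speed[use], table$dynamic_cell_area[use])
  }
  stopifnot(inherits(fit, "cmd_fit"))
  table$cmd <- table$dynamic_cell_area - fit$k * table$cell_speed - fit$m
  table
}

#' Net area change versus speed coupling
#'
#' Net per-frame area change is the protrusion minus retraction area.
#' Returns its Pearson correlation and OLS slope against cell speed —
#' negative when slow cells tend to grow and fast cells to shrink.
#'
#' @param table Observation table with `protrusion_pixels`,
#'   `retraction_pixels` and `cell_speed`.
#' @param pixel_size_um Pixel size used to convert counts to um^2.
#' @return List with `r`, `p` (two-sided, t approximation), `slope` and `n`.
#' @export
delta_area_coupling <- function(table, pixel_size_um = 0.21) {
  stopifnot(all(c("protrusion_pixels", "retraction_pixels", "cell_speed")
                %in% names(table)))
  delta <- (table$protrusion_pixels - table$retraction_pixels) *
    pixel_size_um^2
  ok <- is.finite(delta) & is.finite(table$cell_speed)
  if (stats::sd(delta[ok]) == 0 || stats::sd(table$cell_speed[ok]) == 0) {
    # e.g. rigid translation: net area change identically zero
    return(list(r = NA_real_, p = NA_real_, slope = 0, n = sum(ok)))
  }
  ct <- stats::cor.test(table$cell_speed[ok], delta[ok])
  slope <- unname(stats::coef(stats::lm(delta[ok] ~ table$cell_speed[ok]))[2])
  list(r = unname(ct$estimate), p = ct$p.value, slope = slope, n = sum(ok))
}

# Zero-lag-normalized autocovariance coefficients at lags 1..max_lag
# (biased estimator: sums are not rescaled by the per-lag term count, so
# the denominator is the lag-0 sum of squares).
autocov_coeff <- function(x, max_lag, unbiased = FALSE) {
  x <- x - mean(x)
  n <- length(x)
  denom <- sum(x^2)
  vapply(seq_len(max_lag), function(l) {
    s <- sum(x[1:(n - l)] * x[(l + 1):n])
    if (unbiased) s / (n - l) / (denom / n) else s / denom
  }, numeric(1))
}

#' Per-trajectory autocorrelation of cell speed
#'
#' For each cell trajectory: missing speed values are replaced by the
#' trajectory mean, the series is mean-centred, and autocovariance
#' coefficients normalized by the zero-lag value are computed at lags 1 to
#' `max_lag` (12 frames = 1 h at 5 min/frame). The mean coefficient over
#' those lags summarizes the cell's speed persistence; its population-level
#' Pearson correlation with the cell's mean speed tests whether fast cells
#' sustain their speed.
#'
#' @param table Observation table with `cell_trace_id`, `frame_number`,
#'   `cell_speed`.
#' @param max_lag Maximum lag in frames (default 12).
#' @param min_length Minimum trajectory length; shorter trajectories are
#'   excluded with a warning (default `max_lag + 1`).
#' @param unbiased Use the per-lag term-count corrected estimator instead
#'   of the biased default.
#' @return List of class `autocorr_result`: `cells` (data.frame with
#'   `cell_trace_id`, `mean_speed`, `mean_autocorr`), `coefficients`
#'   (matrix cells x lags), `r` and `p` of the mean_autocorr ~ mean_speed
#'   correlation.
#' @export
speed_autocorrelation <- function(table, max_lag = 12,
                                  min_length = max_lag + 1,
                                  unbiased = FALSE) {
  stopifnot(all(c("cell_trace_id", "frame_number", "cell_speed")
                %in% names(table)))
  ids <- unique(table$cell_trace_id)
  rows <- list(); coefs <- list(); dropped <- 0L
  for (id in ids) {
    sub <- table[table$cell_trace_id == id, ]
    x <- sub$cell_speed[order(sub$frame_number)]
    if (all(is.na(x))) { dropped <- dropped + 1L; next }
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    if (length(x) < min_length) { dropped <- dropped + 1L; next }
    if (stats::var(x) == 0) { dropped <- dropped + 1L; next }
    cf <- autocov_coeff(x, max_lag, unbiased)
    rows[[id]] <- data.frame(cell_trace_id = id, mean_speed = mean(x),
                             mean_autocorr = mean(cf))
    coefs[[id]] <- cf
  }
  if (dropped > 0) {
    warning(dropped, " trajectories excluded (too short, all-missing, or ",
            "zero variance)")
  }
  cells <- do.call(rbind, rows)
  rownames(cells) <- NULL
  cm <- do.call(rbind, coefs)
  if (is.null(cells) || nrow(cells) < 3) {
    return(structure(list(cells = cells, coefficients = cm,
                          r = NA_real_, p = NA_real_),
                     class = "autocorr_result"))
  }
  ct <- stats::cor.test(cells$mean_autocorr, cells$mean_speed)
  structure(list(cells = cells, coefficients = cm,
                 r = unname(ct$estimate), p = ct$p.value),
            class = "autocorr_result")
}

#' Conditional density matrix for scatter displays
#'
#' Bivariate histogram of `y` given `x` where each `x`-bin's counts are
#' normalized to sum to 1, then log10-transformed — the colour scale used
#' to display observation density conditioned on the horizontal axis.
#'
#' @param x,y Paired numeric vectors.
#' @param x_bins,y_bins Either a single bin count or a vector of break
#'   points.
#' @return List: `density` (matrix, rows = y bins, columns = x bins, `NA`
#'   for empty cells and `NaN`-free: empty columns are all-`NA`),
#'   `x_breaks`, `y_breaks`.
#' @export
conditional_density <- function(x, y, x_bins = 50, y_bins = 50) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  xb <- if (length(x_bins) == 1) {
    seq(min(x), max(x), length.out = x_bins + 1)
  } else x_bins
  yb <- if (length(y_bins) == 1) {
    seq(min(y), max(y), length.out = y_bins + 1)
  } else y_bins
  xi <- cut(x, xb, include.lowest = TRUE, labels = FALSE)
  yi <- cut(y, yb, include.lowest = TRUE, labels = FALSE)
  counts <- matrix(0, length(yb) - 1, length(xb) - 1)
  keep <- !is.na(xi) & !is.na(yi)
  for (i in which(keep)) counts[yi[i], xi[i]] <- counts[yi[i], xi[i]] + 1
  colsum <- colSums(counts)
  dens <- sweep(counts, 2, ifelse(colsum == 0, NA, colsum), "/")
  dens <- log10(dens)
  dens[is.infinite(dens)] <- NA  # empty cells within occupied columns
  list(density = dens, x_breaks = xb, y_breaks = yb)
}
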