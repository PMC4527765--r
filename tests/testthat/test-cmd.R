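test_that("an exact linear relationship is fitted perfectly", {
  speed <- seq(0.05, 1, length.out = 50)
  fit <- fit_cmd(speed, 2 * speed + 1)
  expect_equal(fit$k, 2)
  expect_equal(fit$m, 1)
  expect_equal(fit$cmd, rep(0, 50), tolerance = 1e-10)
  expect_equal(fit$r, 1)
  expect_error(fit_cmd(rep(0.3, 10), rnorm(10)), "zero variance")
  expect_error(fit_cmd(1:2, 1:2), "at least 3")
})

test_that("CMD residuals have zero mean and zero speed correlation always", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 500
    speed <- rlnorm(n, -1.5, 0.6)
    dca <- 300 * speed + 100 + rnorm(n, 0, 40)
    tab <- data.frame(cell_speed = speed, dynamic_cell_area = dca)
    tab <- compute_cmd(tab)
    expect_lt(abs(mean(tab$cmd)), 1e-10 * sd(dca))
    expect_lt(abs(cor(tab$cmd, speed)), 1e-10)
  }
})

test_that("randomly paired speed and area show no spurious fit correlation", {
  set.seed(21)
  n <- 2000
  speed <- rlnorm(n, -1.5, 0.6)
  dca <- sample(300 * speed + 100 + rnorm(n, 0, 40))
  expect_lt(abs(fit_cmd(speed, dca)$r), 3 / sqrt(n))
})

test_that("rows with missing measurements get NA CMD, others the formula", {
  tab <- data.frame(cell_speed = c(0.1, 0.2, NA, 0.4),
                    dynamic_cell_area = c(150, 180, 200, 250))
  fit <- structure(list(k = 400, m = 100), class = "cmd_fit")
  out <- compute_cmd(tab, fit)
  expect_equal(out$cmd, tab$dynamic_cell_area - 400 * tab$cell_speed - 100)
  expect_true(is.na(out$cmd[3]))
})

test_that("net area change is identically zero under rigid translation", {
  seq_ <- generate_mask_sequence(
    mask_sim_spec(n_frames = 8, grid_size = 80, speed_px_per_frame = 3, seed = 6))
  d <- sequence_dynamics(seq_)
  expect_true(all(abs(d$delta_cell_area[d$valid]) <= 1 * 0.21^2))
  tab <- data.frame(cell_speed = d$speed, protrusion_pixels = d$protrusion_pixels,
                    retraction_pixels = d$retraction_pixels)[d$valid, ]
  cp <- delta_area_coupling(tab)
  expect_true(is.na(cp$r))
  expect_equal(cp$slope, 0)
})

test_that("a planted protrusion-retraction imbalance yields negative coupling", {
  sim <- generate_feature_table(
    table_sim_spec(n_cells = 60, frames_per_cell = 40, seed = 13))
  cp <- delta_area_coupling(sim$table)
  expect_lt(cp$r, -0.1)
  expect_lt(cp$p, 0.001)
})

test_that("autocorrelation coefficients follow the closed forms", {
  # alternating series: lag-1 coefficient is -(n-1)/n
  n <- 12
  tab <- data.frame(cell_trace_id = "c1", frame_number = 1:n,
                    cell_speed = rep(c(1, -1), n / 2))
  res <- speed_autocorrelation(tab, max_lag = 2, min_length = 3)
  expect_equal(unname(res$coefficients[1, 1]), -(n - 1) / n)
  expect_equal(unname(res$coefficients[1, 2]), (n - 2) / n)
  # missing values are filled with the trajectory mean before centring
  tab2 <- data.frame(cell_trace_id = "c2", frame_number = 1:3,
                     cell_speed = c(2, NA, 4))
  res2 <- speed_autocorrelation(tab2, max_lag = 1, min_length = 3)
  expect_equal(res2$cells$mean_speed, 3)   # filled value is the mean, 3
  expect_equal(unname(res2$coefficients[1, 1]), 0) # centred [-1, 0, 1]: zero lag-1 sum
})

test_that("coefficients are bounded and short or flat traces are excluded", {
  set.seed(5)
  tab <- data.frame(
    cell_trace_id = rep(c("a", "b", "c"), times = c(30, 5, 30)),
    frame_number = c(1:30, 1:5, 1:30),
    cell_speed = c(rlnorm(30), rlnorm(5), rep(2, 30)))
  expect_warning(res <- speed_autocorrelation(tab, max_lag = 12), "excluded")
  expect_equal(res$cells$cell_trace_id, "a")
  expect_true(all(res$coefficients >= -1 & res$coefficients <= 1))
})

test_that("white-noise speeds have near-zero mean autocorrelation", {
  set.seed(31)
  n_cells <- 100; len <- 40
  tab <- data.frame(
    cell_trace_id = rep(sprintf("c%03d", 1:n_cells), each = len),
    frame_number = rep(1:len, n_cells),
    cell_speed = rlnorm(n_cells * len))
  res <- speed_autocorrelation(tab, max_lag = 12)
  # biased estimator: small negative O(1/n) bias, mean within 3 sd of it
  m <- mean(res$cells$mean_autocorr)
  expect_lt(abs(m), 0.05 + 3 * sd(res$cells$mean_autocorr) / sqrt(n_cells))
  expect_gt(res$p, 1e-4)
})

test_that("persistence declines with speed in the planted generator", {
  sim <- generate_feature_table(
    table_sim_spec(n_cells = 80, frames_per_cell = 50, seed = 17))
  res <- speed_autocorrelation(sim$table)
  expect_lt(res$r, 0)
})

test_that("conditional density columns are normalized before the log", {
  d <- conditional_density(c(1, 1), c(0.2, 0.8), x_bins = c(0, 2),
                           y_bins = c(0, 0.5, 1))
  expect_equal(d$density[, 1], log10(c(0.5, 0.5)))
  d2 <- conditional_density(rep(1, 4), c(0.1, 0.4, 0.6, 0.9),
                            x_bins = c(0, 2), y_bins = seq(0, 1, 0.25))
  expect_equal(d2$density[, 1], rep(log10(0.25), 4))
  set.seed(3)
  d3 <- conditional_density(runif(500), rnorm(500), 8, 6)
  sums <- colSums(10^d3$density, na.rm = TRUE)
  expect_equal(sums, rep(1, 8), tolerance = 1e-12)
  # one x bin, y counts 1 and 3
  d4 <- conditional_density(rep(1, 4), c(0.1, 0.6, 0.7, 0.8),
                            x_bins = c(0, 2), y_bins = c(0, 0.5, 1))
  expect_equal(d4$density[, 1], log10(c(0.25, 0.75)))
})

test_that("CMD quintiles show no monotone trend in median speed", {
  sim <- generate_feature_table(
    table_sim_spec(n_cells = 120, frames_per_cell = 50, seed = 23))
  tab <- compute_cmd(sim$table)
  q <- assign_quintiles(tab$cmd)
  # per-observation rank association between CMD stratum and speed
  expect_lt(abs(cor(q, tab$cell_speed, method = "spearman")), 0.05)
  # and the quintile median speeds span a negligible range
  med <- tapply(tab$cell_speed, q, median)
  expect_lt(diff(range(med)) / median(tab$cell_speed), 0.1)
})
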