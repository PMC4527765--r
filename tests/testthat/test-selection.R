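test_that("Kruskal-Wallis matches the closed-form rank statistic", {
  ks <- kruskal_screen(c(1:3, 4:6, 7:9), rep(1:3, each = 3))
  expect_equal(ks$H, 7.2)
  expect_equal(ks$H, oracle_kw_H(list(1:3, 4:6, 7:9)))
  flat <- kruskal_screen(rep(c(1, 2, 3), 3), rep(1:3, each = 3))
  expect_equal(flat$H, 0)
  expect_equal(flat$p, 1)
  # random tie-free small samples against the oracle
  set.seed(41)
  for (i in 1:20) {
    sizes <- sample(3:8, 3, replace = TRUE)
    x <- sample(1:60, sum(sizes))
    g <- rep(1:3, times = sizes)
    expect_equal(kruskal_screen(x, g)$H,
                 oracle_kw_H(split(x, g)))
  }
})

test_that("Bonferroni adjustment caps at one and gates significance", {
  ks <- kruskal_screen(rnorm(30), rep(1:3, each = 10), family = 150)
  expect_lte(ks$p_adj, 1)
  expect_equal(ks$p_adj, min(1, ks$p * 150))
})

make_group_data <- function(n_per, p, shift_feature = 1, shift = 1,
                            seed = 1) {
  set.seed(seed)
  g <- rep(1:3, each = n_per)
  x <- matrix(rnorm(3 * n_per * p), ncol = p)
  x[, shift_feature] <- x[, shift_feature] + (g - 2) * shift
  list(x = x, g = g)
}

test_that("canonical vectors isolate the separating feature", {
  d <- make_group_data(1000, 2, shift_feature = 1, shift = 1.5, seed = 2)
  model <- fit_cva(d$x, d$g)
  v1 <- model$loads[, 1]
  expect_lt(abs(v1[2] / v1[1]), 0.05)
  expect_gt(model$eigenvalues[1], 10 * model$eigenvalues[2])
})

test_that("identical group means give vanishing eigenvalues", {
  set.seed(3)
  x <- matrix(rnorm(900 * 4), ncol = 4)
  model <- fit_cva(x, rep(1:3, each = 300))
  expect_true(all(model$eigenvalues < 0.05))
})

test_that("canonical variates have unit pooled within-group variance", {
  d <- make_group_data(300, 5, shift = 1, seed = 4)
  model <- fit_cva(d$x, d$g)
  for (j in seq_len(ncol(model$scores))) {
    s <- model$scores[, j]
    within <- sum(tapply(s, d$g, function(v) sum((v - mean(v))^2))) /
      (length(s) - 3)
    expect_equal(within, 1, tolerance = 1e-10)
  }
})

test_that("canonical vectors solve the generalized eigenproblem", {
  d <- make_group_data(400, 6, shift = 1.2, seed = 5)
  model <- fit_cva(d$x, d$g, standardize = TRUE)
  # rebuild scatter matrices from scratch on the standardized data
  xs <- scale(d$x)
  ms <- rowsum(xs, d$g) / as.vector(table(d$g))
  grand <- colMeans(xs)
  B <- matrix(0, 6, 6)
  for (k in 1:3) {
    dd <- ms[k, ] - grand
    B <- B + sum(d$g == k) * tcrossprod(dd)
  }
  W <- crossprod(xs - ms[d$g, ])
  WinvB <- solve(W, B)
  for (j in 1:2) {
    v <- model$loads[, j]
    res <- WinvB %*% v - model$eigenvalues[j] * v
    expect_lt(sqrt(sum(res^2)) / sqrt(sum(v^2)), 1e-8)
  }
})

test_that("canonical vectors agree with an independent discriminant fit", {
  skip_if_not_installed("MASS")
  d <- make_group_data(500, 8, shift = 1, seed = 6)
  model <- fit_cva(d$x, d$g, standardize = FALSE)
  ld <- MASS::lda(d$x, grouping = d$g)
  for (j in 1:2) {
    a <- model$loads[, j] / sqrt(sum(model$loads[, j]^2))
    b <- ld$scaling[, j] / sqrt(sum(ld$scaling[, j]^2))
    expect_equal(abs(sum(a * b)), 1, tolerance = 1e-6)
  }
})

test_that("load scores rank a dominant feature first, ties inclusive", {
  d <- make_group_data(1000, 10, shift_feature = 3, shift = 2, seed = 7)
  model <- fit_cva(d$x, d$g)
  sc <- cva_load_scores(model)
  expect_equal(which.max(sc$score), 3)
  expect_equal(sc$rank[3], 1)
  expect_equal(sum(sc$top_half), 5)
  # a tie straddling the boundary keeps both features
  fake <- model
  fake$loads <- matrix(c(4, 3, 2, 2, 1, 0.5), ncol = 1)
  rownames(fake$loads) <- sprintf("F%d", 1:6)
  sc2 <- cva_load_scores(fake)
  expect_equal(sum(sc2$top_half), 4)
  expect_true(all(sc2$top_half[3:4]))
})

test_that("all-null features show no persistently selected feature", {
  n_seeds <- 10
  tops <- matrix(FALSE, n_seeds, 20)
  for (seed in seq_len(n_seeds)) {
    set.seed(400 + seed)
    x <- matrix(rnorm(600 * 20), ncol = 20)
    g <- rep(1:3, each = 200)
    tops[seed, ] <- cva_load_scores(fit_cva(x, g))$top_half
  }
  # top-half membership is exchangeable: no feature selected in every seed
  expect_lt(max(colSums(tops)), n_seeds)
  expect_equal(mean(colSums(tops)), n_seeds / 2)
})

test_that("two-step selection classifies by the pass pattern", {
  plan <- default_archetype_plan(40, 3, 3, 3, effect = 5)
  sim <- generate_feature_table(
    table_sim_spec(n_cells = 70, frames_per_cell = 45, archetype_plan = plan,
                   seed = 43))
  tab <- compute_cmd(sim$table)
  sel <- select_features(tab, plan$feature)
  expect_equal(unname(sel$counts[c("speed_only", "cmd_only", "both")]),
               c(3L, 3L, 3L))
  r <- sel$results
  expect_identical(r$class == "speed_only",
                   r$kw_sig_speed & r$top_half_speed &
                     !(r$kw_sig_cmd & r$top_half_cmd))
  expect_equal(sum(sel$counts), length(plan$feature))
})

test_that("selection is monotone in planted effect size", {
  selected <- logical(0)
  for (eff in c(0.5, 1.5, 3, 5, 8)) {
    plan <- default_archetype_plan(20, 1, 0, 0, effect = eff)
    sim <- generate_feature_table(
      table_sim_spec(n_cells = 50, frames_per_cell = 30,
                     archetype_plan = plan, seed = 47))
    tab <- compute_cmd(sim$table)
    sel <- select_features(tab, plan$feature)
    selected <- c(selected, sel$results$class[1] == "speed_only")
  }
  # once selected at some effect, stays selected at every larger effect
  expect_true(all(diff(as.integer(selected)) >= 0))
  expect_true(selected[length(selected)])
})

test_that("ill-conditioned within-group scatter falls back to a ridge", {
  set.seed(9)
  # more features than observations: within-group scatter is singular
  x <- matrix(rnorm(12 * 15), nrow = 12)
  expect_warning(model <- fit_cva(x, rep(1:3, each = 4)), "ridge")
  expect_true(all(is.finite(model$loads)))
})
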