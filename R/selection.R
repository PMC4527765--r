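#' Kruskal-Wallis screen of one feature across three process groups
#'
#' Kruskal-Wallis rank test (with tie correction, chi-square approximation,
#' df = 2) of a feature between the groups defined by quintiles 1, 3 and 5
#' of a process, Bonferroni-adjusted for the family of one test per
#' feature.
#'
#' @param feature Numeric vector of feature values.
#' @param groups Group labels (three distinct values), same length.
#' @param family Bonferroni family size (default 150).
#' @param alpha Significance threshold on the adjusted p (default 0.001).
#' @return List: `H` statistic, `p` raw, `p_adj`, `significant`.
#' @export
kruskal_screen <- function(feature, groups, family = 150, alpha = 0.001) {
  ok <- is.finite(feature) & !is.na(groups)
  kt <- stats::kruskal.test(feature[ok], factor(groups[ok]))
  p_adj <- min(1, kt$p.value * family)
  list(H = unname(kt$statistic), p = kt$p.value, p_adj = p_adj,
       significant = p_adj < alpha)
}

#' Canonical variate analysis of grouped observations
#'
#' Multi-group discriminant decomposition: finds the canonical vectors
#' maximizing the ratio of between-group to within-group variance, i.e.
#' solves the generalized eigenproblem `B v = lambda W v` with `B` the
#' between-group scatter of group means (weighted by group size) and `W`
#' the pooled within-group scatter. At most `n_groups - 1` vectors carry
#' between-group structure. Features are centred and scaled to unit
#' variance beforehand by default, so that loads (the per-feature
#' coefficients of the canonical vectors) are comparable across features
#' with different units. Canonical variates are normalized to unit pooled
#' within-group variance. A small ridge (`1e-8 x mean diagonal`) stabilizes
#' `W` when it is ill-conditioned, with a warning.
#'
#' @param x Numeric matrix or data.frame (observations x features); rows
#'   with missing values are dropped listwise.
#' @param groups Group labels, same length as `nrow(x)`.
#' @param standardize Centre and unit-scale features first (default TRUE).
#' @param ridge Relative ridge added to `W` when inversion fails.
#' @return List of class `cva_model`: `loads` (features x vectors),
#'   `eigenvalues` (of `W^-1 B`, decreasing), `scores` (canonical variates
#'   of the retained rows), `groups`, `center`, `scale`, `n`.
#' @export
fit_cva <- function(x, groups, standardize = TRUE, ridge = 1e-8) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (is.null(colnames(x))) colnames(x) <- sprintf("V%d", seq_len(ncol(x)))
  keep <- stats::complete.cases(x) & !is.na(groups)
  x <- x[keep, , drop = FALSE]
  g <- factor(groups[keep])
  n <- nrow(x); p <- ncol(x); ng <- nlevels(g)
  stopifnot(ng >= 2, n > ng)

  ctr <- colMeans(x)
  scl <- if (standardize) apply(x, 2, stats::sd) else rep(1, p)
  if (any(scl == 0)) {
    scl[scl == 0] <- 1  # constant feature: leave centred at zero
  }
  xs <- sweep(sweep(x, 2, ctr), 2, scl, "/")

  gi <- as.integer(g)
  ngk <- tabulate(gi, ng)
  means <- rowsum(xs, gi) / ngk
  grand <- colMeans(xs)
  B <- matrix(0, p, p)
  for (k in seq_len(ng)) {
    d <- means[k, ] - grand
    B <- B + ngk[k] * tcrossprod(d)
  }
  resid <- xs - means[gi, , drop = FALSE]
  W <- crossprod(resid)

  R <- tryCatch(chol(W), error = function(e) NULL)
  if (is.null(R)) {
    warning("within-group scatter ill-conditioned; ridge regularization applied")
    W <- W + diag(ridge * mean(diag(W)), p)
    R <- chol(W)
  }
  # W = R'R; eigen of R'^-1 B R^-1 gives lambda of W^-1 B, v = R^-1 u
  M <- backsolve(R, t(backsolve(R, B, transpose = TRUE)), transpose = TRUE)
  M <- (M + t(M)) / 2
  e <- eigen(M, symmetric = TRUE)
  d <- min(ng - 1, p)
  lambda <- pmax(e$values[seq_len(d)], 0)
  V <- backsolve(R, e$vectors[, seq_len(d), drop = FALSE])
  # unit pooled within-group variance of each canonical variate:
  # v' (W / (n - ng)) v = 1
  V <- V * sqrt(n - ng)
  scores <- xs %*% V
  rownames(V) <- colnames(x)
  structure(
    list(loads = V, eigenvalues = lambda, scores = scores, groups = g,
         center = ctr, scale = scl, n = n, standardize = standardize),
    class = "cva_model"
  )
}

#' Per-feature CVA load scores and top-half membership
#'
#' Sums the squared load of each feature over all canonical vectors, sorts
#' features by this score, and flags the top half (the top
#' `ceiling(p / 2)` features, inclusive at ties on the boundary score) —
#' the features that dominate the multivariate group separation.
#'
#' @param model A [fit_cva()] model.
#' @return Data.frame per feature: `feature`, `score`, `rank`, `top_half`.
#' @export
cva_load_scores <- function(model) {
  stopifnot(inherits(model, "cva_model"))
  score <- rowSums(model$loads^2)
  p <- length(score)
  ord <- order(score, decreasing = TRUE)
  thresh <- score[ord][ceiling(p / 2)]
  data.frame(feature = rownames(model$loads), score = score,
             rank = rank(-score, ties.method = "min"),
             top_half = score >= thresh,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Two-step selection of Cell Speed- and CMD-related features
#'
#' Disentangles features by process specificity with the stringent
#' two-step criterion, applied independently to Cell Speed and CMD. For
#' each process: observations in quintiles 1, 3 and 5 are selected; step 1
#' is a Kruskal-Wallis test per feature between those three groups
#' (Bonferroni family = number of features, significant at adjusted
#' P < `alpha`); step 2 is a canonical variate analysis of the same groups
#' over all features, keeping the features in the top half of the
#' sum-of-squared-loads ranking. A feature is related to a process when it
#' passes both steps, and is classified `speed_only`, `cmd_only`, `both`
#' or `neither` by the pass pattern.
#'
#' @param table Observation table with `cell_speed` and `cmd` columns
#'   (rows with `valid == FALSE` are excluded).
#' @param features Character vector of feature column names.
#' @param alpha Adjusted-p threshold (default 0.001).
#' @param family Kruskal-Wallis Bonferroni family per process (default
#'   `length(features)`; pass `2 * length(features)` for a joint family).
#' @param standardize,ridge Passed to [fit_cva()].
#' @return List of class `selection_result`: `results` (per feature:
#'   KW p-values, CVA scores, flags, `class`), `counts` (named vector
#'   speed_only / cmd_only / both / neither), `cva` (the two models).
#' @export
select_features <- function(table, features, alpha = 0.001, family = NULL,
                            standardize = TRUE, ridge = 1e-8) {
  stopifnot(all(c("cell_speed", "cmd") %in% names(table)),
            all(features %in% names(table)))
  if ("valid" %in% names(table)) table <- table[table$valid, , drop = FALSE]
  family <- family %||% length(features)

  step <- function(col) {
    q <- assign_quintiles(table[[col]])
    sub <- table[q %in% c(1L, 3L, 5L), , drop = FALSE]
    grp <- q[q %in% c(1L, 3L, 5L)]
    kw <- lapply(features, function(f)
      kruskal_screen(sub[[f]], grp, family = family, alpha = alpha))
    model <- fit_cva(sub[features], grp, standardize = standardize,
                     ridge = ridge)
    scores <- cva_load_scores(model)
    list(kw_p = vapply(kw, `[[`, numeric(1), "p"),
         kw_p_adj = vapply(kw, `[[`, numeric(1), "p_adj"),
         kw_sig = vapply(kw, `[[`, logical(1), "significant"),
         scores = scores, model = model)
  }
  sp <- step("cell_speed")
  cm <- step("cmd")

  pass_speed <- sp$kw_sig & sp$scores$top_half
  pass_cmd <- cm$kw_sig & cm$scores$top_half
  cls <- ifelse(pass_speed & pass_cmd, "both",
         ifelse(pass_speed, "speed_only",
         ifelse(pass_cmd, "cmd_only", "neither")))
  results <- data.frame(
    feature = features,
    kw_p_speed = sp$kw_p, kw_p_adj_speed = sp$kw_p_adj,
    kw_sig_speed = sp$kw_sig,
    cva_score_speed = sp$scores$score, top_half_speed = sp$scores$top_half,
    kw_p_cmd = cm$kw_p, kw_p_adj_cmd = cm$kw_p_adj, kw_sig_cmd = cm$kw_sig,
    cva_score_cmd = cm$scores$score, top_half_cmd = cm$scores$top_half,
    class = cls, stringsAsFactors = FALSE
  )
  counts <- vapply(c("speed_only", "cmd_only", "both", "neither"),
                   function(k) sum(cls == k), integer(1))
  structure(
    list(results = results, counts = counts,
         cva = list(speed = sp$model, cmd = cm$model),
         alpha = alpha, family = family),
    class = "selection_result"
  )
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> class counts:\n")
  print(x$counts)
  invisible(x)
}
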