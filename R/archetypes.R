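#' Assign observations to quintiles of a process variable
#'
#' Rank-based assignment into five equal-count groups: quintile 1 holds the
#' lowest 20% of values, quintile 5 the highest 20%. Ties are broken by
#' stable original order, so group sizes differ by at most one.
#'
#' @param values Numeric vector (length >= 5, not all identical; `NA`s are
#'   not allowed — subset to valid observations first).
#' @return Integer vector of quintile labels in 1..5.
#' @export
assign_quintiles <- function(values) {
  if (anyNA(values)) stop("values contain NA; subset to valid observations")
  n <- length(values)
  if (n < 5) stop("need at least 5 observations")
  if (length(unique(values)) == 1) stop("all values identical: quintiles undefined")
  r <- rank(values, ties.method = "first")
  as.integer(floor((r - 1) * 5 / n) + 1L)
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Wrapper around [stats::wilcox.test()]: exact enumeration for small
#' tie-free samples (both groups at most `exact_max`), otherwise the normal
#' approximation with tie correction and continuity correction.
#'
#' @param a,b Numeric samples, both non-empty.
#' @param exact_max Largest per-group size for the exact method (default 10).
#' @return Two-sided p-value.
#' @export
wilcoxon_ranksum <- function(a, b, exact_max = 10) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  stopifnot(length(a) > 0, length(b) > 0)
  has_ties <- anyDuplicated(c(a, b)) > 0
  use_exact <- !has_ties && length(a) <= exact_max && length(b) <= exact_max
  suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value
  )
}

# Map a significance triple (1v3, 3v5, 1v5) to a named archetype category.
archetype_category <- function(s13, s35, s15) {
  code <- paste0(as.integer(s13), as.integer(s35), as.integer(s15))
  switch(code,
    "111" = "all_pairs_distinct",
    "101" = "plateau_early",
    "011" = "plateau_late",
    "001" = "extremes_only",
    "100" = "early_only",
    "010" = "late_only",
    "110" = "nonmonotone",
    "000" = "none")
}

#' Archetype categories in display order
#' @return Character vector of the seven category names plus `"none"`.
#' @export
archetype_categories <- function() {
  c("all_pairs_distinct", "plateau_early", "plateau_late", "extremes_only",
    "early_only", "late_only", "nonmonotone", "none")
}

#' Classify feature-process relationship structures (archetypes)
#'
#' Stratifies valid observations into quintiles of one process (Cell Speed
#' or CMD), then for each feature runs two-sided Wilcoxon rank-sum tests
#' between quintiles 1 vs 3, 3 vs 5 and 1 vs 5, Bonferroni-adjusts the
#' p-values for the family of 3 x (number of features) comparisons, and
#' maps each feature's significance triple at adjusted P < `alpha` to one
#' of seven archetype categories (or `"none"`). Direction signs (sign of
#' the median difference per pair) are reported separately, since an
#' archetype describes only where differences arise, not their sign.
#'
#' @param table Observation table (rows with `valid == FALSE` are excluded).
#' @param process `"speed"` or `"cmd"` — selects the stratifying column
#'   (`cell_speed` or `cmd`).
#' @param features Character vector of feature column names.
#' @param alpha Significance threshold on adjusted p-values (default 0.001).
#' @param family Bonferroni family size; default `3 * length(features)`
#'   (per-process family; pass `6 * length(features)` for a joint family
#'   across both processes).
#' @return List of class `archetype_result`: `results` (data.frame per
#'   feature: raw and adjusted p-values, significance triple, direction
#'   signs, `category`), `venn` (named counts over the seven segments),
#'   `n_related` (features with at least one significant pair), `process`,
#'   `family`, `alpha`.
#' @export
archetype_classify <- function(table, process = c("speed", "cmd"),
                               features, alpha = 0.001, family = NULL) {
  process <- match.arg(process)
  col <- if (process == "speed") "cell_speed" else "cmd"
  stopifnot(col %in% names(table), all(features %in% names(table)))
  if ("valid" %in% names(table)) table <- table[table$valid, , drop = FALSE]
  family <- family %||% (3L * length(features))

  q <- assign_quintiles(table[[col]])
  pairs <- list(c(1L, 3L), c(3L, 5L), c(1L, 5L))
  res <- lapply(features, function(f) {
    v <- table[[f]]
    out <- numeric(3); dir <- integer(3)
    for (i in seq_along(pairs)) {
      a <- v[q == pairs[[i]][1]]; b <- v[q == pairs[[i]][2]]
      a <- a[is.finite(a)]; b <- b[is.finite(b)]
      out[i] <- wilcoxon_ranksum(a, b)
      dir[i] <- sign(stats::median(b) - stats::median(a))
    }
    adj <- pmin(1, out * family)
    sig <- adj < alpha
    data.frame(feature = f,
               p13 = out[1], p35 = out[2], p15 = out[3],
               p13_adj = adj[1], p35_adj = adj[2], p15_adj = adj[3],
               sig13 = sig[1], sig35 = sig[2], sig15 = sig[3],
               dir13 = dir[1], dir35 = dir[2], dir15 = dir[3],
               category = archetype_category(sig[1], sig[2], sig[3]),
               stringsAsFactors = FALSE)
  })
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  venn <- table(factor(results$category, levels = archetype_categories()))
  structure(
    list(results = results, venn = c(venn),
         n_related = sum(results$category != "none"),
         process = process, family = family, alpha = alpha),
    class = "archetype_result"
  )
}

#' @export
print.archetype_result <- function(x, ...) {
  cat(sprintf("<archetype_result> process = %s: %d/%d features related\n",
              x$process, x$n_related, nrow(x$results)))
  print(x$venn)
  invisible(x)
}
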