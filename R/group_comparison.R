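#' Kruskal–Wallis omnibus test
#'
#' Rank-based H with tie correction and a chi-square reference with k - 1
#' degrees of freedom (delegating to [stats::kruskal.test()]).  When every
#' pooled value is identical the tie correction divides by zero and the
#' statistic is undefined; that case raises an error rather than returning
#' NaN.
#'
#' @param groups List of (>= 2) numeric vectors, each non-empty, total
#'   n >= 3.
#' @return List with `h`, `df`, `p`.
#' @export
#' @examples
#' kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))  # H = 27/7
kruskal_wallis <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) {
    nn_stop("groups must be a list of at least two numeric vectors")
  }
  sizes <- lengths(groups)
  if (any(sizes < 1L)) nn_stop("every group needs at least one observation")
  pooled <- unlist(groups, use.names = FALSE)
  if (length(pooled) < 3L) nn_stop("total sample size must be at least 3")
  if (anyNA(pooled)) nn_stop("missing values in groups")
  if (length(unique(pooled)) == 1L) {
    nn_stop_numeric("undefined statistic: all pooled values are identical")
  }
  g <- factor(rep(seq_along(groups), sizes))
  kt <- kruskal.test(pooled, g)
  list(h = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Benjamini–Hochberg FDR adjustment
#'
#' Step-up adjusted p-values (monotone in rank, capped at 1), delegating to
#' [stats::p.adjust()] after range validation.
#'
#' @param pvalues Numeric vector of raw p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
bh_fdr <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1)) {
    nn_stop("p-values must lie in [0, 1]")
  }
  p.adjust(pvalues, method = "BH")
}

#' Cliff's delta with confidence interval
#'
#' Dominance effect size `delta = (#\{x_i > y_j\} - #\{x_i < y_j\}) /
#' (n_x * n_y)` in \[-1, 1\].  The confidence interval uses Cliff's
#' unbiased variance estimate (floored at the consistency bound
#' `(1 - delta^2) / (n_x * n_y - 1)`) with a normal approximation,
#' truncated to \[-1, 1\].  The effect is conventionally called
#' significant when the interval excludes zero.
#'
#' @param x,y Non-empty numeric vectors.
#' @param conf.level Confidence level (default 0.95).
#' @return List with `delta`, `ci_low`, `ci_high`, `variance`,
#'   `significant`.
#' @export
#' @examples
#' cliffs_delta(c(1, 2, 3), c(2, 3, 4))$delta  # -5/9
cliffs_delta <- function(x, y, conf.level = 0.95) {
  if (length(x) == 0L || length(y) == 0L) {
    nn_stop("both groups must be non-empty")
  }
  if (anyNA(x) || anyNA(y)) nn_stop("missing values in inputs")
  nx <- length(x)
  ny <- length(y)
  sgn <- sign(outer(x, y, "-"))
  d <- mean(sgn)
  floor_var <- (1 - d^2) / (nx * ny - 1)
  v <- if (nx > 1L && ny > 1L) {
    di <- rowMeans(sgn)
    dj <- colMeans(sgn)
    raw <- (ny^2 * sum((di - d)^2) + nx^2 * sum((dj - d)^2) -
              sum((sgn - d)^2)) / (nx * ny * (nx - 1) * (ny - 1))
    max(raw, floor_var)
  } else {
    floor_var
  }
  if (abs(d) == 1) v <- 0  # complete dominance: degenerate interval
  zcrit <- qnorm(1 - (1 - conf.level) / 2)
  ci <- d + c(-1, 1) * zcrit * sqrt(v)
  ci <- pmin(pmax(ci, -1), 1)
  list(delta = d, ci_low = ci[1], ci_high = ci[2], variance = v,
       significant = ci[1] > 0 || ci[2] < 0)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Tie-aware rank correlation (Pearson correlation of average ranks) with
#' a two-sided p-value from the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom.
#' Used to relate robust z-scores to CSF analyte levels.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return List with `rho`, `p`, `n`.
#' @export
spearman_correlation <- function(x, y) {
  n <- length(x)
  if (length(y) != n) nn_stop("x and y must be paired (equal length)")
  if (n < 3L) nn_stop("rank correlation needs at least 3 pairs")
  if (anyNA(x) || anyNA(y)) nn_stop("missing values in inputs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    nn_stop_numeric("undefined correlation: constant input")
  }
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) {
    0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Compare z-scores across groups with FDR-gated follow-up
#'
#' Per metric-by-ROI cell: a Kruskal–Wallis omnibus test across all group
#' levels, BH-FDR adjusted within the configured family (default: the six
#' ROIs within each metric-by-tissue-class block); for cells passing the
#' omnibus gate at `alpha`, pairwise two-group Kruskal–Wallis follow-ups
#' and Cliff's delta (oriented as first-level-minus-second in the supplied
#' level order) for every level pair.  Cells never receive a pairwise
#' record unless their omnibus `p_fdr < alpha`.
#'
#' @param ztable Z-score table from [compute_zscores()].
#' @param groups Named character vector mapping `participant_id` to a group
#'   level; participants absent from it are ignored.  Levels with zero
#'   members are dropped with a warning.
#' @param alpha Omnibus gate applied to the FDR-adjusted p-value.
#' @param family FDR family: `"metric_tissue"` (default), `"metric"`, or
#'   `"all"` cells jointly.
#' @param method Multiplicity adjustment applied within each family:
#'   `"BH"` (default) or any method accepted by [stats::p.adjust()].
#' @param level_order Optional explicit ordering of group levels (controls
#'   the sign of Cliff's delta).
#' @return Data frame of comparison records (`type` is `"omnibus"` or
#'   `"pairwise"`).
#' @export
compare_groups <- function(ztable, groups, alpha = 0.05,
                           family = c("metric_tissue", "metric", "all"),
                           method = "BH", level_order = NULL) {
  family <- match.arg(family)
  if (is.null(names(groups))) {
    nn_stop("groups must be a named vector (participant_id -> level)")
  }
  zt <- ztable[ztable$participant_id %in% names(groups), , drop = FALSE]
  zt$group <- unname(groups[zt$participant_id])
  levels_all <- if (is.null(level_order)) unique(unname(groups)) else level_order
  present <- levels_all[levels_all %in% unique(zt$group)]
  dropped <- setdiff(levels_all, present)
  if (length(dropped) > 0) {
    warning(sprintf("group level(s) with no z-score rows skipped: %s",
                    paste(dropped, collapse = ", ")), call. = FALSE)
  }
  if (length(present) < 2L) nn_stop("need at least two non-empty group levels")
  cells <- unique(zt[, c("roi_name", "metric", "tissue_class")])
  omni <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- zt[zt$roi_name == cells$roi_name[i] &
                zt$metric == cells$metric[i] &
                zt$tissue_class == cells$tissue_class[i], ]
    by_group <- lapply(present, function(lv) sub$z[sub$group == lv])
    kw <- kruskal_wallis(by_group)
    data.frame(
      roi_name = cells$roi_name[i], metric = cells$metric[i],
      tissue_class = cells$tissue_class[i], type = "omnibus",
      contrast = paste(present, collapse = " vs "),
      n_per_group = paste(lengths(by_group), collapse = "/"),
      h_statistic = kw$h, df = kw$df, p_raw = kw$p, p_fdr = NA_real_,
      cliffs_delta = NA_real_, delta_ci_low = NA_real_,
      delta_ci_high = NA_real_, stringsAsFactors = FALSE
    )
  })
  omni <- do.call(rbind, omni)
  fam_key <- switch(family,
    metric_tissue = paste(omni$metric, omni$tissue_class),
    metric = omni$metric,
    all = rep("all", nrow(omni))
  )
  for (k in unique(fam_key)) {
    sel <- fam_key == k
    omni$p_fdr[sel] <- if (method == "BH") {
      bh_fdr(omni$p_raw[sel])
    } else {
      p.adjust(omni$p_raw[sel], method = method)
    }
  }
  pairs <- utils::combn(present, 2L, simplify = FALSE)
  pw <- list()
  for (i in which(omni$p_fdr < alpha)) {
    sub <- zt[zt$roi_name == omni$roi_name[i] &
                zt$metric == omni$metric[i] &
                zt$tissue_class == omni$tissue_class[i], ]
    for (pr in pairs) {
      za <- sub$z[sub$group == pr[1]]
      zb <- sub$z[sub$group == pr[2]]
      kw <- kruskal_wallis(list(za, zb))
      cd <- cliffs_delta(za, zb)
      pw[[length(pw) + 1L]] <- data.frame(
        roi_name = omni$roi_name[i], metric = omni$metric[i],
        tissue_class = omni$tissue_class[i], type = "pairwise",
        contrast = paste(pr[1], "vs", pr[2]),
        n_per_group = paste(length(za), length(zb), sep = "/"),
        h_statistic = kw$h, df = kw$df, p_raw = kw$p, p_fdr = NA_real_,
        cliffs_delta = cd$delta, delta_ci_low = cd$ci_low,
        delta_ci_high = cd$ci_high, stringsAsFactors = FALSE
      )
    }
  }
  out <- rbind(omni, if (length(pw) > 0) do.call(rbind, pw))
  rownames(out) <- NULL
  out
}
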