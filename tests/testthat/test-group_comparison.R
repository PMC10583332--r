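test_that("Kruskal-Wallis H matches hand rank arithmetic and is rank-invariant", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  # rank sums 6 and 15: H = 12/(6*7) * (36/3 + 225/3) - 3*7 = 27/7
  expect_equal(kw$h, 27 / 7, tolerance = 1e-12)
  expect_equal(kw$df, 1)
  # identical multisets give H = 0
  expect_equal(kruskal_wallis(list(c(1, 2, 3), c(3, 1, 2)))$h, 0)
  # invariance under strictly monotone transforms
  set.seed(4)
  for (i in 1:20) {
    g <- list(rnorm(8), rnorm(12), rnorm(5))
    h1 <- kruskal_wallis(g)$h
    h2 <- kruskal_wallis(lapply(g, function(v) exp(3 * v) + 1))$h
    expect_equal(h2, h1, tolerance = 1e-10)
  }
  expect_error(kruskal_wallis(list(c(1, 1), c(1, 1))), "identical")
  expect_error(kruskal_wallis(list(1:3)), "at least two")
  expect_error(kruskal_wallis(list(1, 2)), "at least 3")
})

test_that("two-group KW equals the tie-corrected Mann-Whitney z-squared", {
  set.seed(5)
  for (i in 1:30) {
    x <- sample(round(rnorm(9), 1))   # rounding forces ties
    y <- sample(round(rnorm(13), 1))
    if (length(unique(c(x, y))) == 1L) next
    h <- kruskal_wallis(list(x, y))$h
    # brute-force U by pair enumeration (ties count one half)
    u <- sum(outer(x, y, function(a, b) (a > b) + 0.5 * (a == b)))
    n1 <- length(x); n2 <- length(y); n <- n1 + n2
    ties <- table(c(x, y))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    expect_equal(h, (u - n1 * n2 / 2)^2 / sigma2, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches the literal step-up definition", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  set.seed(6)
  for (i in 1:50) {
    p <- runif(sample(1:20, 1))
    adj <- bh_fdr(p)
    expect_equal(adj, brute_bh(p), tolerance = 1e-12)
    # monotone in raw-p rank order
    expect_true(all(diff(adj[order(p)]) >= -1e-12))
  }
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Cliff's delta equals brute-force pair enumeration", {
  cd <- cliffs_delta(c(1, 2, 3), c(2, 3, 4))
  expect_equal(cd$delta, -5 / 9, tolerance = 1e-12)
  expect_equal(cliffs_delta(c(1, 2), c(2, 1))$delta, 0)
  expect_equal(cliffs_delta(c(5, 6), c(1, 2))$delta, 1)
  set.seed(7)
  for (i in 1:60) {
    x <- round(rnorm(sample(2:20, 1)), 1)
    y <- round(rnorm(sample(2:20, 1)), 1)
    cd <- cliffs_delta(x, y)
    expect_equal(cd$delta, brute_cliffs_delta(x, y), tolerance = 1e-12)
    # antisymmetry, CI containment, bounds
    expect_equal(cliffs_delta(y, x)$delta, -cd$delta, tolerance = 1e-12)
    expect_gte(cd$delta, cd$ci_low)
    expect_lte(cd$delta, cd$ci_high)
    expect_gte(cd$ci_low, -1)
    expect_lte(cd$ci_high, 1)
  }
})

test_that("Cliff's delta CI flags a planted shift but not a null", {
  set.seed(8)
  cd_null <- cliffs_delta(rnorm(80), rnorm(80))
  expect_false(cd_null$significant)
  cd_shift <- cliffs_delta(rnorm(80) + 1.5, rnorm(80))
  expect_true(cd_shift$significant)
})

test_that("Spearman correlation matches Pearson-on-ranks with t p-value", {
  expect_equal(spearman_correlation(1:6, (1:6)^3)$rho, 1)
  r <- spearman_correlation(c(1, 2, 3, 4), c(10, 8, 9, 7))
  expect_equal(r$rho, cor(rank(c(1, 2, 3, 4)), rank(c(10, 8, 9, 7))))
  set.seed(9)
  for (i in 1:20) {
    x <- round(rnorm(15), 1)
    y <- round(rnorm(15), 1)
    if (length(unique(x)) == 1L || length(unique(y)) == 1L) next
    s <- spearman_correlation(x, y)
    expect_equal(s$rho, unname(cor(x, y, method = "spearman")),
                 tolerance = 1e-12)
    # independent oracle for the t approximation: Pearson test on ranks
    ref <- cor.test(rank(x), rank(y), method = "pearson")
    expect_equal(s$p, ref$p.value, tolerance = 1e-10)
    expect_equal(spearman_correlation(x, -y)$rho, -s$rho, tolerance = 1e-12)
  }
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
})

make_ztable <- function(values_by_group, rois = c("r1", "r2")) {
  # one GM metric, |groups| levels, identical values across ROIs except as given
  rows <- list()
  ids <- character(0)
  for (g in names(values_by_group)) {
    v <- values_by_group[[g]]
    gid <- paste0(g, "_", seq_along(v))
    ids <- c(ids, gid)
    for (r in rois) {
      rows[[length(rows) + 1L]] <- data.frame(
        participant_id = gid, roi_name = r, metric = "NDI",
        tissue_class = "GM", z = v, stringsAsFactors = FALSE
      )
    }
  }
  list(ztable = do.call(rbind, rows),
       groups = setNames(rep(names(values_by_group),
                             lengths(values_by_group)), ids))
}

test_that("pairwise records exist only behind a passing omnibus gate", {
  set.seed(10)
  fx <- make_ztable(list(a = rnorm(40), b = rnorm(40) - 2, c = rnorm(40)))
  out <- compare_groups(fx$ztable, fx$groups, alpha = 0.05)
  omni <- out[out$type == "omnibus", ]
  pw <- out[out$type == "pairwise", ]
  expect_equal(nrow(omni), 2L)
  gated <- paste(omni$roi_name[omni$p_fdr < 0.05])
  expect_setequal(unique(pw$roi_name), gated)
  # null fixture: no pairwise rows at all when nothing passes
  fx0 <- make_ztable(list(a = rnorm(10), b = rnorm(10) + 0.01))
  out0 <- compare_groups(fx0$ztable, fx0$groups, alpha = 1e-6)
  expect_equal(sum(out0$type == "pairwise"), 0L)
})

test_that("two-level grouping gives identical omnibus and pairwise H", {
  set.seed(11)
  fx <- make_ztable(list(a = rnorm(30), b = rnorm(30) - 3), rois = "r1")
  out <- compare_groups(fx$ztable, fx$groups, alpha = 0.05)
  h <- out$h_statistic
  expect_equal(h[out$type == "pairwise"], h[out$type == "omnibus"],
               tolerance = 1e-12)
})

test_that("empty group levels are skipped with a warning", {
  set.seed(12)
  fx <- make_ztable(list(a = rnorm(20), b = rnorm(20) - 2))
  expect_warning(
    compare_groups(fx$ztable, fx$groups, level_order = c("a", "b", "ghost")),
    "ghost"
  )
})
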