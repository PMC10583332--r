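test_that("exact linear data recovers coefficients to machine precision", {
  set.seed(1)
  n <- 60
  age <- runif(n, 50, 85)
  sex <- rbinom(n, 1, 0.6)
  center <- 65
  vals <- 0.55 - 0.002 * (age - center) + 0.01 * sex
  f <- fit_metric_regression(vals, age, sex, center)
  expect_equal(f$b0, 0.55, tolerance = 1e-12)
  expect_equal(f$b_age, -0.002, tolerance = 1e-12)
  expect_equal(f$b_sex, 0.01, tolerance = 1e-12)
  expect_lt(f$rmse, 1e-10)
})

test_that("noisy regression recovers generator truth within 3 SE", {
  set.seed(2)
  n <- 200
  age <- runif(n, 50, 85)
  sex <- rbinom(n, 1, 0.5)
  vals <- 0.55 - 0.002 * (age - 65) + 0.01 * sex + rnorm(n, 0, 0.05)
  f <- fit_metric_regression(vals, age, sex, 65)
  ref <- summary(lm(vals ~ I(age - 65) + sex))
  expect_lt(abs(f$b_age + 0.002), 3 * ref$coefficients[2, "Std. Error"])
  expect_lt(abs(f$b_sex - 0.01), 3 * ref$coefficients[3, "Std. Error"])
  # n-3 RMSE denominator coincides with lm's residual standard error
  expect_equal(f$rmse, ref$sigma, tolerance = 1e-12)
})

test_that("degenerate and invalid regression inputs are rejected or flat", {
  set.seed(3)
  age <- runif(20, 50, 80)
  sex <- rep(c(0, 1), 10)
  f <- fit_metric_regression(rep(0.5, 20), age, sex, 65)
  expect_equal(f$b0, 0.5)
  expect_equal(f$b_age, 0)
  expect_equal(f$rmse, 0)
  expect_error(fit_metric_regression(runif(20), age, rep(1, 20), 65),
               "unidentifiable")
  expect_error(fit_metric_regression(runif(5), age[1:5], sex[1:5], 65),
               "at least 10")
})

test_that("z-scores substitute the frozen model directly", {
  model <- structure(list(
    coefficients = data.frame(
      roi_name = "hippocampus", metric = "NDI", tissue_class = "GM",
      b0 = 0.5, b_age = -0.002, b_sex = 0.01, rmse = 0.05, n_fit = 100,
      stringsAsFactors = FALSE
    ),
    age_center = 65
  ), class = "normative_model")
  pt <- data.frame(participant_id = c("A", "B", "C"),
                   age = c(75, 65, 65), sex = c(1, 0, 0),
                   stringsAsFactors = FALSE)
  roi <- data.frame(participant_id = c("A", "B", "C"),
                    roi_name = "hippocampus", metric = "NDI",
                    tissue_class = "GM",
                    value = c(0.44, 0.5, 0.55), stringsAsFactors = FALSE)
  z <- compute_zscores(model, roi, pt)
  # predicted for A: 0.5 - 0.002*10 + 0.01 = 0.49 -> z = -1
  expect_equal(z$z, c(-1, 0, 1), tolerance = 1e-12)
})

test_that("z-scoring validates model and demographics", {
  model <- structure(list(
    coefficients = data.frame(
      roi_name = "hippocampus", metric = "NDI", tissue_class = "GM",
      b0 = 0.5, b_age = 0, b_sex = 0, rmse = 0, n_fit = 10,
      stringsAsFactors = FALSE
    ),
    age_center = 65
  ), class = "normative_model")
  pt <- data.frame(participant_id = "A", age = 70, sex = 1,
                   stringsAsFactors = FALSE)
  roi <- data.frame(participant_id = "A", roi_name = "hippocampus",
                    metric = "NDI", tissue_class = "GM", value = 0.5,
                    stringsAsFactors = FALSE)
  expect_error(compute_zscores(model, roi, pt), "rmse")
  model$coefficients$rmse <- 0.05
  pt$age <- NA
  expect_error(compute_zscores(model, roi, pt), "missing age/sex")
  pt$age <- 70
  roi$roi_name <- "amygdala"
  expect_error(compute_zscores(model, roi, pt), "no normative fit")
})

test_that("the flag rule is one-sided and inclusive at the threshold", {
  zt <- data.frame(
    participant_id = c("A", "B", "C"),
    roi_name = "hippocampus", metric = "NDI", tissue_class = "GM",
    z = c(-1.5, -1.49, 2.5), stringsAsFactors = FALSE
  )
  fl <- flag_outliers(zt, 1.5)
  expect_identical(fl$flagged_ids, "A")
  # -1.49 in all 24 cells still not flagged
  cells <- noddi_cells()
  zt24 <- data.frame(participant_id = "B", roi_name = cells$roi_name,
                     metric = cells$metric,
                     tissue_class = cells$tissue_class, z = -1.49,
                     stringsAsFactors = FALSE)
  expect_length(flag_outliers(zt24, 1.5)$flagged_ids, 0)
})

test_that("an infinite threshold reduces to the single-pass fit", {
  co <- generate_cohort(normative_only_config(120, seed = 17L))
  robust <- build_norms(co$roi_values, co$participants,
                        norms_config(exclusion_threshold = Inf))
  expect_equal(length(robust$model$normative_ids_final), 120L)
  expect_equal(nrow(robust$model$excluded), 0L)
  # equals a direct single fit of the full set
  direct <- fit_metric_regression(
    co$roi_values$value[co$roi_values$roi_name == "hippocampus" &
                          co$roi_values$metric == "NDI"],
    co$participants$age, co$participants$sex,
    mean(co$participants$age)
  )
  row <- robust$model$coefficients
  row <- row[row$roi_name == "hippocampus" & row$metric == "NDI", ]
  expect_equal(row$b_age, direct$b_age, tolerance = 1e-12)
  expect_equal(row$rmse, direct$rmse, tolerance = 1e-12)
})

test_that("z-scores on the final normative set have mean 0 and unit-ish SD", {
  co <- generate_cohort(normative_only_config(240, seed = 19L))
  robust <- build_norms(co$roi_values, co$participants)
  zfin <- robust$zscores[
    robust$zscores$participant_id %in% robust$model$normative_ids_final, ]
  agg <- aggregate(z ~ roi_name + metric, zfin,
                   function(v) c(m = mean(v), s = sd(v)))
  expect_lt(max(abs(agg$z[, "m"])), 1e-10)
  n_fin <- length(robust$model$normative_ids_final)
  expect_true(all(agg$z[, "s"] > 0.9 & agg$z[, "s"] < 1.1))
  # with the n-3 RMSE denominator the SD is exactly sqrt((n-3)/(n-1))
  expect_equal(unname(agg$z[1, "s"]), sqrt((n_fin - 3) / (n_fin - 1)),
               tolerance = 1e-10)
})

test_that("frozen norms are independent of non-normative participants", {
  cfg <- small_mixed_config(seed = 23L)
  co <- generate_cohort(cfg)
  nc <- norms_config(min_n = 10L)
  robust <- build_norms(co$roi_values, co$participants, nc)
  # drop one MCI participant and rebuild: everyone else's z unchanged
  mci <- co$participants$participant_id[co$participants$diagnosis == "MCI"][1]
  pt2 <- co$participants[co$participants$participant_id != mci, ]
  roi2 <- co$roi_values[co$roi_values$participant_id != mci, ]
  robust2 <- build_norms(roi2, pt2, nc)
  z1 <- robust$zscores[robust$zscores$participant_id != mci, ]
  expect_equal(robust2$zscores$z, z1$z, tolerance = 1e-12)
})

test_that("z is strictly monotone in the observed value", {
  co <- generate_cohort(normative_only_config(60, seed = 29L))
  robust <- build_norms(co$roi_values, co$participants,
                        norms_config(min_n = 10L))
  roi2 <- co$roi_values
  pick <- 5L
  roi2$value[pick] <- roi2$value[pick] - 0.01
  z2 <- compute_zscores(robust$model, roi2, co$participants)
  expect_lt(z2$z[pick], robust$zscores$z[pick])
  expect_equal(z2$z[-pick], robust$zscores$z[-pick])
})

test_that("norms JSON round-trip reproduces z-scores exactly", {
  co <- generate_cohort(normative_only_config(80, seed = 37L))
  robust <- build_norms(co$roi_values, co$participants,
                        norms_config(min_n = 10L))
  path <- withr::local_tempfile(fileext = ".json")
  write_norms(robust$model, path)
  model2 <- read_norms(path)
  z2 <- compute_zscores(model2, co$roi_values, co$participants)
  expect_equal(z2$z, robust$zscores$z, tolerance = 1e-12)
})

test_that("a too-small reduced normative set aborts with advice", {
  co <- generate_cohort(normative_only_config(30, seed = 41L))
  expect_error(
    build_norms(co$roi_values, co$participants,
                norms_config(exclusion_threshold = 0.5, min_n = 25L)),
    "larger normative sample"
  )
})
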