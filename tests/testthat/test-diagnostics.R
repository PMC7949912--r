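# independent closed-form oracles for the two t-tests
oracle_paired <- function(x, y) {
  d <- x - y
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}
oracle_pooled <- function(x, y) {
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  list(t = t, df = nx + ny - 2, p = 2 * pt(-abs(t), nx + ny - 2))
}

test_that("paired t matches its closed form on the worked example", {
  x <- c(20, 30, 40)
  y <- c(21, 33, 41)
  r <- paired_t(x, y)
  # differences (-1, -3, -1): mean -5/3, sd 2/sqrt(3), t = -2.5
  expect_equal(r$t, -2.5, tolerance = 1e-12)
  expect_equal(abs(r$t), 2.5, tolerance = 1e-12)
  expect_equal(r$df, 2)
  expect_identical(r$test_type, "dependent")

  # swapping arguments negates t, p unchanged
  r2 <- paired_t(y, x)
  expect_equal(r2$t, -r$t, tolerance = 1e-12)
  expect_equal(r2$p, r$p, tolerance = 1e-12)

  expect_error(paired_t(x, x), "zero-variance")
  expect_error(paired_t(x, y[1:2]), "equal length")
})

test_that("unpaired t matches the pooled-variance closed form", {
  x <- c(1, 2, 3)
  y <- c(4, 5, 6)
  r <- unpaired_t(x, y)
  o <- oracle_pooled(x, y)
  expect_equal(r$t, o$t, tolerance = 1e-12)
  expect_equal(r$df, 4)
  expect_equal(r$p, o$p, tolerance = 1e-12)

  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # p invariant under a common affine transform
  r2 <- unpaired_t(10 + 2 * x, 10 + 2 * y)
  expect_equal(r2$p, r$p, tolerance = 1e-12)

  expect_error(unpaired_t(1, y), "n >= 2")
})

test_that("both tests agree with the oracles on random datasets", {
  set.seed(20)
  for (i in 1:200) {
    n <- sample(3:40, 1)
    x <- rnorm(n, 50, 10)
    y <- x + rnorm(n, sample(c(0, 2), 1), 3)
    rp <- paired_t(x, y)
    op <- oracle_paired(x, y)
    expect_equal(rp$t, op$t, tolerance = 1e-10)
    expect_equal(rp$p, op$p, tolerance = 1e-10)

    m <- sample(3:40, 1)
    z <- rnorm(m, 52, 8)
    ru <- unpaired_t(x, z)
    ou <- oracle_pooled(x, z)
    expect_equal(ru$t, ou$t, tolerance = 1e-10)
    expect_equal(ru$p, ou$p, tolerance = 1e-10)
  }
})

make_site_preds <- function(records, bias_site = NULL, bias = 0, noise_sd = 1,
                            views = c("axial", "coronal", "sagittal")) {
  purrr::map_dfr(views, function(v) {
    tibble::tibble(
      participant_id = records$participant_id,
      view = v,
      predicted_age = records$age +
        ifelse(records$site %in% bias_site, bias, 0) +
        rnorm(nrow(records), 0, noise_sd)
    )
  })
}

test_that("site report flags an injected single-site bias and only that site", {
  set.seed(30)
  records <- tibble::tibble(
    participant_id = sprintf("s%03d", 1:80),
    age = runif(80, 20, 80),
    sex = rep(c("F", "M"), 40),
    site = rep(1:4, each = 20)
  )
  # site 3 predictions biased by +5 years (with noise), all others exact
  preds <- make_site_preds(records, noise_sd = 0)
  biased <- preds$participant_id %in% records$participant_id[records$site == 3]
  preds$predicted_age[biased] <- preds$predicted_age[biased] + 5 +
    rnorm(sum(biased), 0, 1)
  rep_tbl <- site_effect_report(preds, records, alpha = 0.03)
  expect_equal(nrow(rep_tbl), 12) # 4 sites x 3 views
  flagged <- unique(rep_tbl$grouping[rep_tbl$significant])
  expect_identical(flagged, "3")

  # exact predictions: zero sites flagged, reported as no-effect rows
  exact <- make_site_preds(records, noise_sd = 0)
  rep0 <- site_effect_report(exact, records, alpha = 0.03)
  expect_false(any(rep0$significant))
  expect_true(all(rep0$p == 1))

  # flags invariant to site relabeling
  rec2 <- records
  rec2$site <- c(10, 20, 99, 40)[records$site]
  rep2 <- site_effect_report(preds, rec2, alpha = 0.03)
  expect_identical(unique(rep2$grouping[rep2$significant]), "99")

  # singleton sites are skipped with a warning
  rec3 <- records
  rec3$site[1] <- 7
  expect_warning(
    rep3 <- site_effect_report(preds[preds$view == "axial", ], rec3),
    "single subject"
  )
  expect_true(any(!is.na(rep3$note) & grepl("singleton", rep3$note)))
})

test_that("sex report has exactly the four standard tests (I, I, D, D)", {
  set.seed(40)
  records <- tibble::tibble(
    participant_id = sprintf("s%03d", 1:200),
    age = runif(200, 20, 80),
    sex = rep(c("F", "M"), each = 100),
    site = 1L
  )
  preds <- tibble::tibble(
    participant_id = records$participant_id,
    predicted_age = records$age
  )
  rep0 <- sex_effect_report(preds, records)
  expect_equal(nrow(rep0), 4)
  expect_identical(rep0$test_type, c("independent", "independent", "dependent", "dependent"))
  expect_false(any(rep0$significant))

  # +3-year bias applied to one sex only is detected by the paired test
  biased <- preds
  biased$predicted_age <- records$age +
    ifelse(records$sex == "M", 3, 0) + rnorm(200, 0, 1)
  repb <- sex_effect_report(biased, records)
  expect_true(repb$significant[repb$grouping == "M: age vs prediction"])
  expect_false(repb$significant[repb$grouping == "F: age vs prediction"])

  expect_error(
    sex_effect_report(preds, dplyr::mutate(records, sex = "F")),
    "both sexes"
  )
})

test_that("null site reports flag about alpha of sites", {
  set.seed(50)
  n_rep <- 400
  flags <- replicate(n_rep, {
    age <- runif(20, 20, 80)
    pred <- age + rnorm(20, 0, 2)
    paired_t(age, pred, alpha = 0.03)$significant
  })
  expect_lt(abs(mean(flags) - 0.03), 3 * sqrt(0.03 * 0.97 / n_rep))
})

test_that("injected biases of one pooled SD are detected with high power", {
  set.seed(60)
  hits <- replicate(200, {
    age <- runif(100, 20, 80)
    pred <- age + 2 + rnorm(100, 0, 2) # bias = 1 residual SD
    paired_t(age, pred, alpha = 0.03)$significant
  })
  expect_gt(mean(hits), 0.9)
})

test_that("age-bias fit recovers the gap regression line", {
  ages <- seq(20, 80, by = 2)
  fit0 <- age_bias_fit(ages, ages)
  expect_equal(fit0$slope, 0, tolerance = 1e-12)
  expect_equal(fit0$intercept, 0, tolerance = 1e-12)

  fit <- age_bias_fit(0.5 * ages + 18, ages)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 18, tolerance = 1e-12)
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "age"], -0.5, tolerance = 1e-12)

  expect_error(age_bias_fit(c(1, 2, 3), rep(5, 3)), "constant ages")
  expect_error(age_bias_fit(1:2, 1:2), "n >= 3")
})
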