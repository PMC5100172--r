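test_that("total_scores computes the summed endpoints", {
  r1 <- make_record(1)                         # everything 5
  r2 <- make_record(2, base_L = rep(0, 5), base_R = rep(0, 5))
  ts <- total_scores(make_cohort(r1, r2))
  expect_equal(ts$y_star_2, c(50, 50))
  expect_equal(ts$y_star_1, c(50, 0))
  expect_equal(ts$y_double_star, c(0, 50))

  # three-participant fixture against a spreadsheet-style recount
  trial <- simulate_trial(default_pop(), 3, 0, seed = 21)
  ts3 <- total_scores(trial)
  for (i in 1:3) {
    b <- sum(unlist(trial[i, muscle_cols_pub("base")]))
    f <- sum(unlist(trial[i, muscle_cols_pub("fu")]))
    expect_equal(ts3$y_star_1[i], b)
    expect_equal(ts3$y_star_2[i], f)
    expect_equal(ts3$y_double_star[i], f - b)
  }
})

test_that("t-test matches the closed-form Welch computation", {
  # identical outcomes in both arms: statistic 0, p 1
  recs <- make_cohort(make_record(1, arm = 0), make_record(2, arm = 1),
                      make_record(3, arm = 0), make_record(4, arm = 1))
  res <- t_test_total(recs)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  # two arms of three with hand-computable moments
  trial <- simulate_trial(default_pop(), 6, 0, seed = 22)
  trial$arm <- c(1, 1, 1, 0, 0, 0)
  ts <- total_scores(trial)
  yt <- ts$y_star_2[1:3]; yc <- ts$y_star_2[4:6]
  skip_if(var(yt) == 0 && var(yc) == 0)
  se2 <- var(yt) / 3 + var(yc) / 3
  tstat <- (mean(yt) - mean(yc)) / sqrt(se2)
  df <- se2^2 / ((var(yt) / 3)^2 / 2 + (var(yc) / 3)^2 / 2)
  res2 <- t_test_total(trial)
  expect_equal(res2$statistic, tstat, tolerance = 1e-12)
  expect_equal(res2$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  expect_equal(res2$detail$df, df, tolerance = 1e-12)

  # delta variant uses the change score
  resd <- t_test_total(trial, use_delta = TRUE)
  yd <- ts$y_double_star
  expect_equal(resd$estimate, mean(yd[1:3]) - mean(yd[4:6]))
})

test_that("ANCOVA matches the normal-equations solution", {
  trial <- simulate_trial(default_pop(), 8, 0, seed = 23)
  ts <- total_scores(trial)
  X <- cbind(1, ts$arm, ts$y_star_1)
  bhat <- solve(crossprod(X), crossprod(X, ts$y_star_2))
  resid <- ts$y_star_2 - X %*% bhat
  s2 <- sum(resid^2) / (8 - 3)
  se <- sqrt(s2 * solve(crossprod(X))[2, 2])
  tstat <- bhat[2] / se
  res <- ancova_total(trial)
  expect_equal(res$estimate, bhat[2], tolerance = 1e-10)
  expect_equal(res$statistic, tstat, tolerance = 1e-10)
  expect_equal(res$p_value, 2 * pt(-abs(tstat), 5), tolerance = 1e-10)

  # y2 == y1 with balanced arms: arm coefficient is exactly 0
  same <- trial
  for (s in segments_uems()) for (sd in c("L", "R")) {
    same[[paste0("fu_", sd, "_", s)]] <- same[[paste0("base_", sd, "_", s)]]
  }
  expect_equal(suppressWarnings(ancova_total(same))$estimate, 0,
               tolerance = 1e-10)

  # constant baseline falls back to the t-test, flagged in detail
  const <- make_cohort(make_record(1, arm = 0, fu_L = c(5, 4, 3, 2, 1)),
                       make_record(2, arm = 1), make_record(3, arm = 0),
                       make_record(4, arm = 1, fu_R = c(5, 5, 4, 4, 3)))
  resf <- ancova_total(const)
  expect_equal(resf$detail$fallback, "t_test")
  expect_equal(resf$method, "ancova")
})

test_that("i-test matches exhaustive permutation enumeration (single stratum)", {
  trial <- simulate_trial(
    make_synthetic_population(list(constellation_weights = c("C6/C6" = 1)),
                              seed = 1),
    6, 0, seed = 24)
  trial$arm <- c(1, 0, 1, 0, 1, 0)
  ts <- total_scores(trial)
  y <- ts$y_star_2
  skip_if(var(y) == 0)

  combos <- combn(6, 3)
  Tperm <- apply(combos, 2, function(idx) sum(y[idx]))
  Tobs <- sum(y[trial$arm == 1])
  Zoracle <- (Tobs - mean(Tperm)) / sqrt(mean((Tperm - mean(Tperm))^2))
  res <- stratified_independence_test(trial)
  expect_equal(res$statistic, Zoracle, tolerance = 1e-10)

  p_exact <- mean(abs(Tperm - mean(Tperm)) >= abs(Tobs - mean(Tperm)) - 1e-12)
  mc <- with_seed_pub(7, stratified_independence_test(trial, mode = "montecarlo",
                                                      B = 4999))
  expect_lt(abs(mc$p_value - p_exact), 0.05)

  # identical outcome vectors in the two arms: Z = 0, p = 1
  dup <- trial
  dup$arm <- c(1, 1, 1, 0, 0, 0)
  for (cn in c(muscle_cols_pub("base"), muscle_cols_pub("fu")))
    dup[[cn]] <- rep(dup[[cn]][1:3], 2)
  resd <- stratified_independence_test(dup)
  expect_equal(resd$statistic, 0, tolerance = 1e-12)
  expect_equal(resd$p_value, 1)
})

test_that("single-arm strata are inert and a fully degenerate layout is flagged", {
  trial <- simulate_trial(default_pop(), 10, 0, seed = 25)
  trial$arm <- rep(1, 10)                   # everyone treated
  res <- stratified_independence_test(trial)
  expect_true(isTRUE(res$detail$flagged))
  expect_equal(res$p_value, 1)
})

test_that("transitional permutation test: symmetric doubling gives p near 1", {
  trial <- simulate_trial(default_pop(), 20, log(1.4), seed = 26)
  flip <- trial
  flip$arm <- 1 - flip$arm
  flip$id <- flip$id + 1000
  doubled <- rbind(trial, flip)
  res <- with_seed_pub(8, transitional_permutation_test(doubled, B = 99))
  expect_lt(abs(res$estimate), 1e-4)
  expect_gt(res$p_value, 0.9)
})

test_that("transitional test flags a single-arm trial instead of erroring", {
  trial <- simulate_trial(default_pop(), 10, 0, seed = 27)
  trial$arm <- 0
  res <- transitional_permutation_test(trial, B = 19)
  expect_true(isTRUE(res$detail$flagged))
  expect_true(is.na(res$p_value))
})

test_that("run_battery returns six labelled results, reproducibly", {
  trial <- simulate_trial(default_pop(), 30, 0, seed = 28)
  cfg <- list(permutations = 49)
  r1 <- with_seed_pub(9, run_battery(trial, cfg))
  r2 <- with_seed_pub(9, run_battery(trial, cfg))
  expect_named(r1, c("t_test", "t_test_delta", "i_test", "i_test_delta",
                     "ancova", "transitional"))
  p1 <- vapply(r1, `[[`, 0, "p_value")
  p2 <- vapply(r2, `[[`, 0, "p_value")
  expect_identical(p1, p2)
  expect_true(all(p1 >= 0 & p1 <= 1))

  df <- as.data.frame(r1)
  expect_equal(df$method, names(r1))

  f <- tempfile(fileext = ".json")
  write_battery_json(r1, f)
  expect_length(jsonlite::read_json(f), 6)
})

test_that("analyze_trial long path reports the six-entry battery", {
  trial <- simulate_trial(default_pop(), 40, log(1.3), seed = 29)
  rows <- build_transitional_rows(trial)
  f <- tempfile(fileext = ".csv")
  write_rows_long_csv(rows, f)
  res <- with_seed_pub(10, analyze_trial(f, format = "long",
                                         config = list(permutations = 49)))
  expect_named(res, c("t_test", "t_test_delta", "i_test", "i_test_delta",
                      "ancova", "transitional"))
  expect_match(res$t_test$detail$totals_scope, "below-level")
  # the transitional result must agree with the wide-path fit estimate
  wide <- fit_proportional_odds(rows, include_treatment = TRUE)
  expect_equal(res$transitional$estimate, wide$coefficients$beta_trt,
               tolerance = 1e-6)
})
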