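test_that("lev_code maps (motor level, segment) to the ten codes", {
  expect_equal(lev_code("C5", "C6"), "C5.-1")
  expect_equal(lev_code("C5", "T1"), "C5.-4")
  expect_equal(lev_code("C8", "T1"), "C8.-1")

  segs <- segments_uems()
  codes <- character(0)
  for (ml in segs[1:4]) {
    for (sg in segs[seq_index_of(ml) + seq_len(5 - seq_index_of(ml))])
      codes <- c(codes, lev_code(ml, sg))
  }
  expect_length(unique(codes), 10)
  expect_setequal(codes, lev_levels())

  expect_error(lev_code("C6", "C5"), "not below")
  expect_error(lev_code("C6", "C6"), "not below")
  expect_error(lev_code("T1", "T1"), "no muscles below")
})

test_that("build_transitional_rows produces one row per below-level muscle", {
  # left ML C5, right ML T1: only the left side contributes (4 rows)
  r1 <- make_record(1, left_ml = "C5", right_ml = "T1",
                    base_L = c(4, 3, 2, 1, 0), base_R = c(5, 5, 5, 5, 4),
                    fu_L = c(5, 4, 3, 2, 1), fu_R = c(5, 5, 5, 5, 5))
  rows <- build_transitional_rows(r1)
  expect_equal(nrow(rows), 4)
  expect_equal(rows$lev, paste0("C5.-", 1:4))
  # autoregressive chaining: d=-1 sees the at-level follow-up, deeper
  # rows see the previous below-level follow-up
  expect_equal(rows$y_auto, c(5, 4, 3, 2))
  expect_equal(rows$y_out, c(4, 3, 2, 1))
  expect_equal(rows$y_base, c(3, 2, 1, 0))

  # both MLs at C8: two rows, both (C8,-1)
  r2 <- make_record(2, left_ml = "C8", right_ml = "C8")
  rows2 <- build_transitional_rows(r2)
  expect_equal(nrow(rows2), 2)
  expect_true(all(rows2$lev == "C8.-1"))

  expect_error(build_transitional_rows(make_record(3, base_L = c(7, 5, 5, 5, 5))),
               "0..5")
})

test_that("row counts match a brute-force enumeration on a 50-participant cohort", {
  trial <- simulate_trial(default_pop(), 50, 0, seed = 99)
  rows <- build_transitional_rows(trial)
  # independent counter: per side, 5 - rank(ML) muscles below the level
  expected <- 0L
  for (i in seq_len(nrow(trial))) {
    for (ml in c(trial$left_ml[i], trial$right_ml[i]))
      expected <- expected + 5L - match(ml, segments_uems())
  }
  expect_equal(nrow(rows), expected)
})

test_that("encode_design emits the documented columns and drops absent levels", {
  rows <- fixture_rows(100, seed = 5)
  stopifnot(length(unique(rows$lev)) == 10,
            length(unique(rows$y_base)) == 6,
            length(unique(rows$y_auto)) == 6)
  des <- encode_design(rows, include_treatment = TRUE)
  expect_equal(ncol(des$X), 9 + 5 + 5 + 1)
  expect_equal(sum(startsWith(des$col_labels, "lev:")), 9)
  expect_false("lev:C5.-1" %in% des$col_labels)

  # constant baseline: that factor vanishes
  rows0 <- rows
  rows0$y_base <- 0L
  des0 <- encode_design(rows0)
  expect_false(any(startsWith(des0$col_labels, "base:")))
  expect_equal(des0$dropped_levels$y_base, 1:5)

  # single observed lev level becomes the (column-free) reference
  rc8 <- make_cohort(make_record(1, left_ml = "C8", right_ml = "C8",
                                 fu_L = c(5, 5, 5, 5, 3), fu_R = c(5, 5, 5, 5, 1)))
  desc8 <- encode_design(build_transitional_rows(rc8))
  expect_false(any(startsWith(desc8$col_labels, "lev:")))
  expect_equal(desc8$dropped_levels$lev_reference, "C8.-1")

  rows1 <- rows[1, ]
  expect_error(encode_design(rows1), "degenerate")
})

test_that("neg_log_likelihood matches an independent per-row recomputation", {
  cs <- coefficient_set(qlogis((1:5) / 6))
  one <- fixture_rows(10, seed = 2)[1, ]
  expect_equal(neg_log_likelihood(cs, one), -log(1 / 6), tolerance = 1e-12)

  # 20-row fixture, non-trivial coefficients, straight-line oracle
  rows <- fixture_rows(20, seed = 8)[1:20, ]
  cs2 <- default_pop()$coefficients
  cs2$beta_trt <- log(1.3)
  oracle <- 0
  for (i in 1:20) {
    eta <- cs2$beta_lev[[rows$lev[i]]] +
      cs2$beta_base[[as.character(rows$y_base[i])]] +
      cs2$beta_auto[[as.character(rows$y_auto[i])]] +
      cs2$beta_trt * rows$arm[i]
    cum <- c(plogis(cs2$cutpoints - eta), 1)
    pk <- cum - c(0, cum[-6])
    oracle <- oracle - log(pk[rows$y_out[i] + 1])
  }
  expect_equal(neg_log_likelihood(cs2, rows), oracle, tolerance = 1e-10)

  expect_error(coefficient_set(c(0, 0, 1, 2, 3)), "increasing")
})

test_that("intercept-only fit reproduces the closed-form MLE", {
  rows <- fixture_rows(60, seed = 12)
  rows$lev <- "C5.-1"; rows$y_base <- 0L; rows$y_auto <- 0L; rows$arm <- 0
  fit <- fit_proportional_odds(rows)
  lv <- sort(unique(rows$y_out))
  f <- as.numeric(table(factor(rows$y_out, levels = lv))) / nrow(rows)
  expect_equal(fit$coefficients$cutpoints,
               qlogis(cumsum(f)[-length(f)]), tolerance = 1e-5)
  expect_equal(fit$log_likelihood, sum(table(rows$y_out) * log(f)),
               tolerance = 1e-8)
})

test_that("MLE matches a dense zooming grid search on a 3-parameter fixture", {
  set.seed(31)
  x <- rep(0:1, each = 15)
  eta <- 0.8 * x
  u <- runif(30)
  cum1 <- plogis(-0.3 - eta); cum2 <- plogis(0.9 - eta)
  y <- ifelse(u < cum1, 1L, ifelse(u < cum2, 2L, 3L))
  stopifnot(length(unique(y)) == 3)

  oracle <- grid_oracle_nll(x, y)
  fit <- ordtrial:::fit_po_xy(matrix(x, ncol = 1,
                                     dimnames = list(NULL, "trt")), y, 3L)
  expect_true(fit$converged)
  expect_equal(-fit$logLik, oracle$nll, tolerance = 1e-6)
  expect_lte(-fit$logLik, oracle$nll + 1e-6)
})

test_that("fit agrees with MASS::polr on a realistic trial", {
  skip_if_not_installed("MASS")
  rows <- fixture_rows(120, beta_trt = log(1.3), seed = 17)
  fit <- fit_proportional_odds(rows, include_treatment = TRUE)
  d <- rows
  d$y_out <- factor(d$y_out, levels = 0:5, ordered = TRUE)
  d$lev <- factor(d$lev, levels = lev_levels())
  d$y_base <- factor(d$y_base, levels = 0:5)
  d$y_auto <- factor(d$y_auto, levels = 0:5)
  pf <- MASS::polr(y_out ~ lev + y_base + y_auto + arm, data = d,
                   method = "logistic")
  expect_equal(fit$log_likelihood, as.numeric(logLik(pf)), tolerance = 1e-6)
  expect_equal(fit$coefficients$beta_trt, unname(coef(pf)["arm"]),
               tolerance = 1e-3)
})

test_that("analytic gradient matches central finite differences", {
  rows <- fixture_rows(30, seed = 23)
  des <- encode_design(rows, include_treatment = TRUE)
  K <- length(des$outcome_levels)
  set.seed(5)
  for (rep in 1:3) {
    theta <- c(sort(rnorm(K - 1, sd = 0.8)), rnorm(ncol(des$X), sd = 0.3))
    an <- ordtrial:::po_nll_grad(des$X, des$y, K, theta)
    fd <- vapply(seq_along(theta), function(j) {
      h <- 1e-6 * max(1, abs(theta[j]))
      tp <- theta; tp[j] <- tp[j] + h
      tm <- theta; tm[j] <- tm[j] - h
      (ordtrial:::po_nll_grad(des$X, des$y, K, tp)$nll -
         ordtrial:::po_nll_grad(des$X, des$y, K, tm)$nll) / (2 * h)
    }, numeric(1))
    expect_equal(an$grad, fd, tolerance = 1e-6)
  }
})

test_that("maximized likelihood is invariant to full-rank factor recoding", {
  rows <- fixture_rows(60, seed = 3)
  des <- encode_design(rows, include_treatment = TRUE)
  K <- length(des$outcome_levels)
  f1 <- ordtrial:::fit_po_xy(des$X, des$y, K)

  # recode the baseline block by an arbitrary invertible matrix
  bidx <- which(startsWith(colnames(des$X), "base:"))
  set.seed(77)
  M <- diag(length(bidx)) + matrix(rnorm(length(bidx)^2, sd = 0.2),
                                   length(bidx))
  X2 <- des$X
  X2[, bidx] <- des$X[, bidx] %*% M
  f2 <- ordtrial:::fit_po_xy(X2, des$y, K)
  expect_equal(f1$logLik, f2$logLik, tolerance = 1e-8)
})

test_that("predicted probabilities obey the proportional-odds structure", {
  cs <- default_pop()$coefficients
  cs$beta_trt <- log(1.3)

  # sum to one, monotone cumulative, for a spread of settings
  for (lv in c("C5.-1", "C5.-3", "C7.-2", "C8.-1")) {
    for (arm in 0:1) {
      p <- predict_category_probabilities(cs, lv, 1, 3, arm)[1, ]
      expect_equal(sum(p), 1, tolerance = 1e-12)
      expect_true(all(diff(cumsum(p)) >= -1e-12))
    }
  }

  # cumulative log-odds differ by exactly beta_trt at every k
  pc <- predict_category_probabilities(cs, "C5.-3", 1, 3, 0)[1, ]
  pt <- predict_category_probabilities(cs, "C5.-3", 1, 3, 1)[1, ]
  dlo <- qlogis(cumsum(pc)[1:5]) - qlogis(cumsum(pt)[1:5])
  expect_equal(unname(dlo), rep(log(1.3), 5), tolerance = 1e-10)

  # positive effect shifts mass up: treatment cumulative strictly smaller
  expect_true(all(cumsum(pt)[1:5] < cumsum(pc)[1:5]))

  # uniform special case
  cu <- coefficient_set(qlogis((1:5) / 6))
  expect_equal(unname(predict_category_probabilities(cu, "C5.-1", 0, 0, 0)[1, ]),
               rep(1 / 6, 6), tolerance = 1e-12)
})

test_that("sample_score is reproducible and matches its distribution", {
  cs <- default_pop()$coefficients
  s1 <- with_seed_pub(11, sample_score(cs, rep("C5.-2", 100), 1, 3, 0))
  s2 <- with_seed_pub(11, sample_score(cs, rep("C5.-2", 100), 1, 3, 0))
  expect_identical(s1, s2)

  # strong concentration at the top category
  hot <- cs; hot$beta_trt <- 50
  expect_true(all(with_seed_pub(1, sample_score(hot, rep("C5.-1", 50), 5, 5, 1)) == 5))

  # law of large numbers at one covariate setting
  pr <- predict_category_probabilities(cs, "C6.-2", 2, 3, 0)[1, ]
  draws <- with_seed_pub(13, sample_score(cs, rep("C6.-2", 1e5), 2, 3, 0))
  emp <- tabulate(draws + 1L, 6L) / 1e5
  expect_lt(max(abs(emp - pr)), 0.01)
})

test_that("coefficient JSON round-trips exactly", {
  cs <- default_pop()$coefficients
  cs$beta_trt <- log(1.2)
  f <- tempfile(fileext = ".json")
  write_coefficients_json(cs, f)
  cs2 <- read_coefficients_json(f)
  expect_equal(cs2$cutpoints, cs$cutpoints)
  expect_equal(cs2$beta_lev, cs$beta_lev)
  expect_equal(cs2$beta_auto, cs$beta_auto)
  expect_equal(cs2$beta_trt, cs$beta_trt)
})
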