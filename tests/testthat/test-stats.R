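test_that("Yates-corrected chi-squared and p agree with chisq.test on random tables", {
  set.seed(41)
  for (i in 1:50) {
    cells <- sample(1:2000, 4, replace = TRUE)
    res <- or_ci_chi2(cells[1], cells[2], cells[3], cells[4])
    ref <- suppressWarnings(
      stats::chisq.test(matrix(cells, 2, byrow = TRUE), correct = TRUE))
    expect_equal(res$chi2, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("identical case and control rows give OR 1 and p 1", {
  res <- or_ci_chi2(10, 90, 10, 90)
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)
  expect_lt(res$ci_low, 1)
  expect_gt(res$ci_high, 1)
})

test_that("odds ratio is reciprocal and chi-squared invariant under row swap", {
  set.seed(42)
  for (i in 1:25) {
    cells <- sample(1:500, 4, replace = TRUE)
    r1 <- or_ci_chi2(cells[1], cells[2], cells[3], cells[4])
    r2 <- or_ci_chi2(cells[3], cells[4], cells[1], cells[2])
    expect_equal(r2$odds_ratio, 1 / r1$odds_ratio, tolerance = 1e-12)
    expect_equal(r2$ci_low, 1 / r1$ci_high, tolerance = 1e-12)
    expect_equal(r2$chi2, r1$chi2, tolerance = 1e-12)
    expect_equal(r2$p, r1$p, tolerance = 1e-12)
  }
})

test_that("Woolf 95% interval covers a known true odds ratio at the nominal rate", {
  set.seed(7)
  true_or <- 2
  p0 <- 0.1
  p1 <- true_or * (p0 / (1 - p0)) / (1 + true_or * p0 / (1 - p0))
  n_case <- 4000; n_ctrl <- 4000
  covered <- replicate(2000, {
    a <- rbinom(1, n_case, p1); c_ <- rbinom(1, n_ctrl, p0)
    r <- or_ci_chi2(a, n_case - a, c_, n_ctrl - c_)
    r$ci_low <= true_or && true_or <= r$ci_high
  })
  expect_gt(mean(covered), 0.93)
  expect_lt(mean(covered), 0.97)
})

test_that("zero cells trigger the Haldane-Anscombe correction, zero margins raise", {
  r <- or_ci_chi2(0, 100, 5, 95)
  expect_true(r$haldane)
  expect_true(is.finite(r$ci_low) && is.finite(r$ci_high))
  expect_equal(r$odds_ratio, (0.5 * 95.5) / (100.5 * 5.5))
  expect_error(or_ci_chi2(0, 0, 5, 95), class = "cnv_config_error")
})

test_that("numeric memory and pairs matching binarise at the documented cutoffs", {
  expect_equal(preprocess_outcome("numeric_memory", c(2, 6, 7, 9))$values,
               c(0L, 0L, 1L, 1L))
  expect_equal(preprocess_outcome("pairs_matching", c(0, 3, 1, 0))$values,
               c(0L, 1L, 1L, 0L))
})

test_that("fecundity preprocessing applies sex caps and the 5-SD rule", {
  vals <- c(2, 9, 1, 8, 0, 8)
  sex <- c("male", "male", "female", "female", "male", "male")
  pp <- preprocess_outcome("fecundity", vals, sex = sex)
  # male 9 > 8 removed; female 8 > 7 removed; male 8 kept
  expect_equal(pp$kept, c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  expect_setequal(pp$removed$rule, "sex_cap")
})

test_that("the 5-SD outlier rule is applied once, not iteratively", {
  x <- c(rep(0, 50), 30, 6)
  pp <- preprocess_outcome("reaction_time", x)
  mu <- mean(x); s <- sd(x)
  expect_false(pp$kept[51])                      # 30 is beyond 5 SD
  expect_gt(5 * s, abs(6 - mu))
  expect_true(pp$kept[52])                       # 6 survives the single pass
  # a second pass over the kept values would have removed it
  kept <- x[pp$kept]
  expect_gt(abs(6 - mean(kept)), 5 * sd(kept))
})

test_that("a constant Poisson outcome recovers intercept log k and null effects", {
  set.seed(1)
  d <- data.frame(outcome = rep(3, 400),
                  carrier = rep(c(0, 1), 200),
                  age = runif(400, 40, 70),
                  sex = sample(c("male", "female"), 400, TRUE))
  f <- fit_adjusted_model("fluid_intelligence", d)
  est <- coef(f)
  expect_equal(unname(est["(Intercept)"]), log(3), tolerance = 1e-6)
  expect_equal(unname(est["carrier"]), 0, tolerance = 1e-6)
})

test_that("logistic model recovers a simulated carrier log-odds effect", {
  set.seed(11)
  n <- 20000
  carrier <- rbinom(n, 1, 0.5)
  age <- runif(n, 40, 70)
  sex <- sample(c("male", "female"), n, TRUE)
  eta <- -0.5 + 0.6 * carrier + 0.01 * (age - 55) + 0.1 * (sex == "male")
  y <- rbinom(n, 1, plogis(eta))
  f <- fit_adjusted_model("numeric_memory", data.frame(
    outcome = y, carrier = carrier, age = age, sex = sex),
    family = "logistic")
  tr <- f$coefficients[f$coefficients$term == "carrier", ]
  expect_lt(abs(tr$estimate - 0.6), 3 * tr$se)
})

test_that("multinomial qualifications model uses 'other' as baseline and recovers odds", {
  set.seed(12)
  n <- 30000
  carrier <- rbinom(n, 1, 0.3)
  pn <- c(degree = 0.33, alevels = 0.11, other = 0.56)
  pc <- c(degree = 0.23, alevels = 0.10, other = 0.67)
  qual <- ifelse(carrier == 1,
                 sample(names(pc), n, TRUE, prob = pc),
                 sample(names(pn), n, TRUE, prob = pn))
  f <- fit_adjusted_model("qualifications", data.frame(
    outcome = qual, carrier = carrier, age = runif(n, 40, 70),
    sex = sample(c("male", "female"), n, TRUE)))
  cf <- f$coefficients
  truth_degree <- log(pc["degree"] / pc["other"]) - log(pn["degree"] / pn["other"])
  row <- cf[cf$category == "degree" & cf$term == "carrier", ]
  expect_lt(abs(row$estimate - truth_degree), 3 * row$se)
})

test_that("fecundity analysis handles single-sex input and reports interaction", {
  set.seed(13)
  n <- 4000
  carrier <- rbinom(n, 1, 0.1)
  sex <- rep(c("male", "female"), n / 2)
  y <- rpois(n, ifelse(sex == "male", exp(log(1.8) - 0.1 * carrier), 1.8))
  fa <- fecundity_analysis(data.frame(outcome = y, carrier = carrier, sex = sex))
  expect_s3_class(fa$male, "outcome_fit")
  expect_s3_class(fa$female, "outcome_fit")
  expect_true(fa$interaction_p > 0 && fa$interaction_p <= 1)

  males <- data.frame(outcome = y, carrier = carrier, sex = sex)
  males <- males[males$sex == "male", ]
  fm <- fecundity_analysis(males)
  expect_null(fm$female)
  expect_true(is.na(fm$interaction_p))
})

test_that("degenerate fecundity input is reported as a fit failure", {
  d <- data.frame(outcome = rep(0, 100), carrier = rep(c(0, 1), 50),
                  sex = rep("male", 100))
  expect_error(fecundity_analysis(d), class = "cnv_fit_error")
})

test_that("raw attainment odds fall inside the published adjusted intervals", {
  f <- rbind(noncarrier = c(degree = 157988, alevels = 54077, other = 268962),
             carrier = c(degree = 414, alevels = 185, other = 1209))
  raw_or <- function(cat) (f["carrier", cat] / f["carrier", "other"]) /
    (f["noncarrier", cat] / f["noncarrier", "other"])
  expect_gt(raw_or("degree"), 0.51)
  expect_lt(raw_or("degree"), 0.64)
  expect_gt(raw_or("alevels"), 0.65)
  expect_lt(raw_or("alevels"), 0.88)
})

test_that("attainment proportions divide within groups at 1 dp", {
  m <- rbind(noncarrier = c(degree = 157988, alevels = 54077, other = 268962),
             carrier = c(degree = 414, alevels = 185, other = 1209))
  pc <- attainment_proportions(m)
  expect_equal(unname(pc["noncarrier", "degree"]), 32.8)
  expect_equal(unname(pc["carrier", "degree"]), 22.9)
  expect_equal(unname(attainment_proportions(rbind(g = c(0, 0, 10)))[1, ]),
               c(0, 0, 100))
  expect_error(attainment_proportions(rbind(g = c(0, 0, 0))),
               class = "cnv_config_error")
})
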