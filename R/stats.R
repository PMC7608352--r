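#' Odds ratio, Woolf confidence interval and Yates-corrected chi-squared
#' for a 2x2 deletion-by-phenotype table
#'
#' Cells follow the case-control layout: `a` deletion carriers among
#' cases, `b` non-carriers among cases, `c` carriers among controls, `d`
#' non-carriers among controls. The odds ratio is `(a*d)/(b*c)` with the
#' Woolf log-scale 95% interval `exp(log(OR) +/- 1.96*sqrt(1/a+1/b+1/c+1/d))`.
#' The chi-squared statistic applies the Yates continuity correction,
#' `N*(max(|ad-bc| - N/2, 0))^2 / ((a+b)(c+d)(a+c)(b+d))`, referred to a
#' chi-squared distribution on 1 df. If any single cell is zero (with both
#' case and control margins positive) the Haldane-Anscombe correction adds
#' 0.5 to every cell for the odds-ratio and interval computation (flagged
#' in the result); the chi-squared statistic always uses the original
#' counts.
#'
#' @param a,b,c_,d non-negative integer cell counts (carriers/non-carriers
#'   among cases, then among controls).
#' @param conf_level confidence level of the Woolf interval (default 0.95).
#' @return An object of class `assoc2x2`: list with `odds_ratio`,
#'   `ci_low`, `ci_high`, `chi2`, `p`, `prevalence_cases`,
#'   `prevalence_controls` (percent), the input `counts` and a `haldane`
#'   flag.
#' @export
#' @examples
#' or_ci_chi2(18, 2774, 1769, 470611)
or_ci_chi2 <- function(a, b, c_, d, conf_level = 0.95) {
  counts <- as.numeric(c(a = a, b = b, c = c_, d = d))
  names(counts) <- c("a", "b", "c", "d")
  a <- counts[["a"]]; b <- counts[["b"]]; c_ <- counts[["c"]]; d <- counts[["d"]]
  if (any(is.na(counts)) || any(counts < 0))
    config_error("all four cell counts must be non-negative numbers",
                 field = "contingency_table")
  if (a + b == 0 || c_ + d == 0)
    config_error("a zero case or control margin leaves the odds ratio undefined",
                 field = "contingency_table")
  haldane <- any(counts == 0)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  k <- if (haldane) counts + 0.5 else counts
  or <- (k["a"] * k["d"]) / (k["b"] * k["c"])
  se <- sqrt(sum(1 / k))
  ci <- exp(log(or) + c(-1, 1) * z * se)

  N <- sum(counts)
  num <- max(abs(a * d - b * c_) - N / 2, 0)
  denom <- (a + b) * (c_ + d) * (a + c_) * (b + d)
  chi2 <- if (denom > 0) N * num^2 / denom else NA_real_
  p <- if (is.na(chi2)) NA_real_ else stats::pchisq(chi2, 1, lower.tail = FALSE)

  structure(list(
    odds_ratio = unname(or), ci_low = unname(ci[1]), ci_high = unname(ci[2]),
    se_log_or = unname(se), chi2 = unname(chi2), p = unname(p),
    prevalence_cases = 100 * a / (a + b),
    prevalence_controls = 100 * c_ / (c_ + d),
    conf_level = conf_level, counts = counts, haldane = haldane
  ), class = "assoc2x2")
}

#' @export
print.assoc2x2 <- function(x, digits = 2, ...) {
  cat(sprintf("2x2 association (a=%.5g carriers / %.7g cases vs c=%.5g / %.7g controls)\n",
              x$counts["a"], x$counts["a"] + x$counts["b"],
              x$counts["c"], x$counts["c"] + x$counts["d"]))
  cat(sprintf("  prevalence: cases %.2f%%, controls %.2f%%\n",
              x$prevalence_cases, x$prevalence_controls))
  cat(sprintf("  OR = %.*f [%d%% CI %.*f-%.*f]%s\n", digits, x$odds_ratio,
              round(100 * x$conf_level), digits, x$ci_low, digits, x$ci_high,
              if (x$haldane) " (Haldane-Anscombe corrected)" else ""))
  cat(sprintf("  Yates chi-squared = %.3f, p = %.3g\n", x$chi2, x$p))
  invisible(x)
}

#' Outcome-specific preprocessing for the cognitive and fecundity analyses
#'
#' Rules by outcome name: `reaction_time` and `fecundity` drop values more
#' than five standard deviations from the mean (mean and SD computed once
#' on the full input, with no re-iteration); `fecundity` additionally
#' applies sex-specific integer caps (males reporting more than 8 children
#' fathered and females more than 7 live births are removed);
#' `pairs_matching` is binarised as 0 -> 0, >0 -> 1; `numeric_memory` as
#' <=6 -> 0, >6 -> 1; `fluid_intelligence` and `qualifications` pass
#' through unchanged.
#'
#' @param name outcome name, one of `reaction_time`, `fluid_intelligence`,
#'   `numeric_memory`, `pairs_matching`, `qualifications`, `fecundity`.
#' @param values numeric vector (character allowed for `qualifications`).
#' @param sex factor/character vector (`"male"`/`"female"`), required for
#'   `fecundity`.
#' @param male_cap,female_cap fecundity caps (defaults 8 and 7).
#' @return List with `values` (transformed values for kept rows), `kept`
#'   (logical over the input) and `removed` (data frame logging index,
#'   value and rule for each removal).
#' @export
#' @examples
#' preprocess_outcome("numeric_memory", c(2, 6, 7, 9))$values
preprocess_outcome <- function(name, values, sex = NULL,
                               male_cap = 8, female_cap = 7) {
  name <- match.arg(name, c("reaction_time", "fluid_intelligence",
                            "numeric_memory", "pairs_matching",
                            "qualifications", "fecundity"))
  n <- length(values)
  kept <- rep(TRUE, n)
  rule <- rep(NA_character_, n)
  if (name != "qualifications") {
    num <- suppressWarnings(as.numeric(values))
    bad <- which(!is.na(values) & is.na(num))
    if (length(bad))
      config_error(sprintf("non-numeric value at row %d", bad[1]),
                   field = name)
    values <- num
    kept[is.na(values)] <- FALSE
    rule[is.na(values)] <- "missing"
  }
  if (name %in% c("reaction_time", "fecundity")) {
    mu <- mean(values, na.rm = TRUE)
    sdv <- stats::sd(values, na.rm = TRUE)
    out5 <- kept & !is.na(values) & abs(values - mu) > 5 * sdv
    kept[out5] <- FALSE
    rule[out5] <- "outlier_5sd"
  }
  if (name == "fecundity") {
    if (is.null(sex) || length(sex) != n)
      config_error("fecundity preprocessing requires a sex vector of the same length",
                   field = "fecundity")
    capped <- kept & ((sex == "male" & values > male_cap) |
                        (sex == "female" & values > female_cap))
    kept[capped] <- FALSE
    rule[capped] <- "sex_cap"
  }
  out_values <- values[kept]
  if (name == "pairs_matching") out_values <- as.integer(out_values > 0)
  if (name == "numeric_memory") out_values <- as.integer(out_values > 6)
  removed_idx <- which(!kept)
  list(values = out_values, kept = kept,
       removed = data.frame(index = removed_idx,
                            value = if (length(removed_idx)) values[removed_idx] else numeric(),
                            rule = rule[removed_idx],
                            stringsAsFactors = FALSE))
}

outcome_family <- function(name) {
  switch(name,
         reaction_time = "linear",
         fluid_intelligence = "poisson",
         numeric_memory = "logistic",
         pairs_matching = "logistic",
         qualifications = "multinomial",
         fecundity = "poisson",
         config_error(sprintf("unknown outcome '%s'", name), field = "outcome"))
}

wald_table <- function(fit) {
  s <- summary(fit)$coefficients
  data.frame(term = rownames(s), estimate = s[, 1], se = s[, 2],
             p = s[, ncol(s)], row.names = NULL, stringsAsFactors = FALSE)
}

#' Fit the covariate-adjusted association model for one outcome
#'
#' Fits the generalized linear family the outcome's distribution calls
#' for — linear (identity link) for reaction time, Poisson (log link) for
#' fluid intelligence and fecundity counts, logistic for the binarised
#' numeric-memory and pairs-matching tests, multinomial log-linear for
#' highest qualification — with deletion carrier status coded 0/1 and
#' age (years) and sex (0 = female, 1 = male) as covariates. The
#' multinomial model treats the combined `other` category as baseline and
#' reports per-category effects for degree and A/AS-level attainment.
#' Preprocessing ([preprocess_outcome()]) is assumed already applied.
#'
#' @param name outcome name (see [preprocess_outcome()]).
#' @param data data frame with columns `outcome`, `carrier` (logical or
#'   0/1), `age`, `sex` (`"male"`/`"female"` or 0/1).
#' @param family override the outcome's default family
#'   (`linear`/`poisson`/`logistic`/`multinomial`).
#' @return An object of class `outcome_fit`: list with `name`, `family`,
#'   `coefficients` (term, estimate, se, p), `n_used` and the underlying
#'   `fit`.
#' @export
fit_adjusted_model <- function(name, data, family = NULL) {
  family <- family %||% outcome_family(name)
  need <- c("outcome", "carrier", "age", "sex")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols))
    config_error(sprintf("model data missing column(s): %s",
                         paste(missing_cols, collapse = ", ")), field = name)
  df <- data.frame(
    outcome = data$outcome,
    carrier = as.integer(as.logical(data$carrier)),
    age = as.numeric(data$age),
    sex = if (is.numeric(data$sex)) as.integer(data$sex)
          else as.integer(data$sex == "male")
  )
  df <- df[stats::complete.cases(df), , drop = FALSE]
  if (length(unique(df$carrier)) < 2L)
    fit_error("need at least one carrier and one non-carrier to fit",
              diagnostics = table(df$carrier))

  fit <- switch(
    family,
    linear = stats::lm(outcome ~ carrier + age + sex, data = df),
    poisson = stats::glm(outcome ~ carrier + age + sex, data = df,
                         family = stats::poisson()),
    logistic = stats::glm(outcome ~ carrier + age + sex, data = df,
                          family = stats::binomial()),
    multinomial = {
      df$outcome <- stats::relevel(factor(df$outcome), ref = "other")
      nnet::multinom(outcome ~ carrier + age + sex, data = df, trace = FALSE)
    },
    config_error(sprintf("unknown family '%s'", family), field = name)
  )

  if (family %in% c("poisson", "logistic") && !fit$converged)
    fit_error(sprintf("%s fit did not converge", family),
              diagnostics = fit)

  if (family == "multinomial") {
    s <- summary(fit)
    z <- s$coefficients / s$standard.errors
    p <- 2 * stats::pnorm(-abs(z))
    coefs <- do.call(rbind, lapply(rownames(s$coefficients), function(cat) {
      data.frame(category = cat, term = colnames(s$coefficients),
                 estimate = s$coefficients[cat, ], se = s$standard.errors[cat, ],
                 p = p[cat, ], row.names = NULL, stringsAsFactors = FALSE)
    }))
  } else {
    coefs <- wald_table(fit)
  }

  structure(list(name = name, family = family, coefficients = coefs,
                 n_used = nrow(df), fit = fit),
            class = "outcome_fit")
}

#' @export
print.outcome_fit <- function(x, ...) {
  cat(sprintf("%s (%s regression, n = %d)\n", x$name, x$family, x$n_used))
  print(x$coefficients, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.outcome_fit <- function(object, ...) {
  stats::setNames(object$coefficients$estimate,
                  if ("category" %in% names(object$coefficients))
                    paste(object$coefficients$category,
                          object$coefficients$term, sep = ":")
                  else object$coefficients$term)
}

# carrier-term row of an outcome_fit (non-multinomial)
carrier_term <- function(fit) {
  fit$coefficients[fit$coefficients$term == "carrier", , drop = FALSE]
}

#' Sex-stratified fecundity analysis with interaction test
#'
#' Poisson regressions of offspring count on deletion carrier status,
#' fitted separately in males (children fathered) and females (live
#' births), plus a pooled Poisson model with deletion, sex and a
#' deletion-by-sex interaction term; the interaction p-value is the Wald
#' test of that coefficient. Preprocessing (5-SD rule and the sex-specific
#' caps) should already have been applied via
#' `preprocess_outcome("fecundity", ...)`.
#'
#' @param data data frame with columns `outcome` (offspring count),
#'   `carrier`, `sex` (`"male"`/`"female"`).
#' @return List with `male` and `female` (class `outcome_fit`, or `NULL`
#'   when that sex is absent), `pooled` (the interaction fit) and
#'   `interaction_p` (`NA` when only one sex is present).
#' @export
fecundity_analysis <- function(data) {
  sexes <- intersect(c("male", "female"), unique(as.character(data$sex)))
  if (!length(sexes))
    config_error("no male or female rows present", field = "fecundity")
  fit_sex <- function(s) {
    df <- data[data$sex == s, , drop = FALSE]
    df$carrier <- as.integer(as.logical(df$carrier))
    if (length(unique(df$carrier)) < 2L || all(df$outcome == 0))
      fit_error(sprintf("degenerate fecundity data for %s", s),
                diagnostics = table(df$carrier))
    fit <- stats::glm(outcome ~ carrier, data = df, family = stats::poisson())
    structure(list(name = paste0("fecundity_", s), family = "poisson",
                   coefficients = wald_table(fit), n_used = nrow(df),
                   fit = fit), class = "outcome_fit")
  }
  male <- if ("male" %in% sexes) fit_sex("male") else NULL
  female <- if ("female" %in% sexes) fit_sex("female") else NULL
  pooled <- NULL
  interaction_p <- NA_real_
  if (length(sexes) == 2L) {
    df <- data
    df$carrier <- as.integer(as.logical(df$carrier))
    df$male <- as.integer(df$sex == "male")
    pfit <- stats::glm(outcome ~ carrier + male + carrier:male, data = df,
                       family = stats::poisson())
    tab <- wald_table(pfit)
    pooled <- structure(list(name = "fecundity_pooled", family = "poisson",
                             coefficients = tab, n_used = nrow(df),
                             fit = pfit), class = "outcome_fit")
    interaction_p <- tab$p[tab$term == "carrier:male"]
  }
  list(male = male, female = female, pooled = pooled,
       interaction_p = interaction_p)
}

#' Per-group attainment category percentages
#'
#' @param freq numeric matrix (or data frame) of counts with one row per
#'   group (e.g. carrier / non-carrier) and one column per qualification
#'   category; percentages are computed within rows and rounded to 1 dp.
#' @return Matrix of percentages with the same dimnames.
#' @export
#' @examples
#' attainment_proportions(rbind(noncarrier = c(degree = 157988,
#'   alevels = 54077, other = 268962)))
attainment_proportions <- function(freq) {
  m <- as.matrix(freq)
  if (any(m < 0) || any(m != round(m)))
    config_error("frequencies must be non-negative integers",
                 field = "qualifications")
  totals <- rowSums(m)
  if (any(totals == 0))
    config_error("a group with zero total has undefined proportions",
                 field = "qualifications")
  round(100 * sweep(m, 1, totals, "/"), 1)
}
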