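# independent enumeration oracle: two-sided Fisher p by summing
# hypergeometric probabilities not exceeding the observed table's
fisher_enum <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  pr <- stats::dhyper(xs, m, n, k)
  sum(pr[pr <= stats::dhyper(a, m, n, k) * (1 + 1e-7)])
}

test_that("risk ratios and Wald intervals behave on boundary cases", {
  eq <- risk_ratio(10, 10, 20, 20)
  expect_equal(eq$rr, 1)
  expect_lte(eq$ci_low, 1)
  expect_gte(eq$ci_high, 1)
  r <- risk_ratio(7, 25, 25, 26)
  expect_equal(round(c(r$rr, r$ci_low, r$ci_high), 2), c(0.45, 0.22, 0.91))
  expect_error(risk_ratio(0, 10, 5, 5), class = "undefined_estimate")
  expect_error(risk_ratio(3, -1, 5, 5), class = "invalid_input")
})

test_that("Fisher exact matches exhaustive hypergeometric enumeration", {
  tabs <- list(c(7, 25, 25, 26), c(10, 0, 0, 10), c(3, 7, 6, 4), c(1, 1, 1, 1),
               c(12, 2, 3, 9))
  for (tb in tabs) {
    got <- fisher_exact(tb[1], tb[2], tb[3], tb[4])$p
    expect_equal(got, fisher_enum(tb[1], tb[2], tb[3], tb[4]), tolerance = 1e-8,
                 info = paste(tb, collapse = ","))
    # invariant to transposition
    expect_equal(got, fisher_exact(tb[1], tb[3], tb[2], tb[4])$p, tolerance = 1e-12)
  }
  # identical margins, symmetric table
  expect_equal(fisher_exact(5, 5, 5, 5)$p, 1)
})

test_that("the product-limit estimator matches hand computation", {
  # complete data: empirical survival, median = 3
  km <- km_fit(1:5, rep(1, 5))
  expect_equal(km$median, 3)
  expect_equal(km$curve$surv, 1 - (1:5) / 5)

  # all censored: median not reached, follow-up reported instead
  km2 <- km_fit(c(4, 8, 12), c(0, 0, 0))
  expect_false(km2$reached)
  expect_true(is.na(km2$median))
  expect_equal(km2$median_followup, 8)

  # mixed eight-patient set, risk sets worked out by hand
  times <- c(1, 2, 3, 4, 4, 5, 6, 7)
  events <- c(1, 0, 1, 1, 0, 1, 1, 0)
  km3 <- km_fit(times, events)
  ev <- km3$curve[km3$curve$time %in% c(1, 3, 4, 5, 6), ]
  expect_equal(ev$surv, c(7 / 8, 7 / 8 * 5 / 6, 7 / 8 * 5 / 6 * 4 / 5,
                          7 / 8 * 5 / 6 * 4 / 5 * 2 / 3,
                          7 / 8 * 5 / 6 * 4 / 5 * 2 / 3 * 1 / 2),
               tolerance = 1e-12)
  expect_equal(km3$median, 5)
  expect_error(km_fit(numeric(0), integer(0)), class = "empty_input")

  # no censoring: KM is the empirical survival function (property)
  set.seed(71)
  t <- round(stats::rexp(40, 0.2), 3)
  kme <- km_fit(t, rep(1, 40))
  ecdf_surv <- vapply(kme$curve$time, function(u) mean(t > u), numeric(1))
  expect_equal(kme$curve$surv, ecdf_surv, tolerance = 1e-12)
})

# explicit risk-set log-rank for two groups
manual_logrank <- function(t1, e1, t2, e2) {
  times <- sort(unique(c(t1[e1 == 1], t2[e2 == 1])))
  O <- E <- V <- 0
  for (tt in times) {
    n1 <- sum(t1 >= tt); n2 <- sum(t2 >= tt); n <- n1 + n2
    d1 <- sum(t1 == tt & e1 == 1); d <- d1 + sum(t2 == tt & e2 == 1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (n2 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

test_that("the log-rank statistic matches an explicit risk-set computation", {
  t1 <- c(2, 4, 5, 7, 9, 12, 13)
  e1 <- c(1, 1, 0, 1, 1, 0, 1)
  t2 <- c(1, 3, 3, 6, 8, 10)
  e2 <- c(1, 1, 1, 0, 1, 1)
  lr <- log_rank(c(t1, t2), c(e1, e2), rep(c("a", "b"), c(7, 6)))
  expect_equal(lr$chisq, manual_logrank(t1, e1, t2, e2), tolerance = 1e-10)
  expect_equal(lr$p, stats::pchisq(lr$chisq, 1, lower.tail = FALSE))

  # two identical groups: statistic 0, p = 1
  lr0 <- log_rank(rep(1:4, 2), rep(1, 8), rep(c("a", "b"), each = 4))
  expect_equal(lr0$chisq, 0, tolerance = 1e-12)
  expect_equal(lr0$p, 1)

  # four-group comparison supported
  set.seed(72)
  tt <- stats::rexp(80); gg <- rep(letters[1:4], each = 20)
  lr4 <- log_rank(tt, rep(1, 80), gg)
  expect_identical(lr4$df, 3L)
  expect_error(log_rank(1:5, rep(1, 5), rep("a", 5)), class = "arity_error")
})

test_that("Cox regression is sane, stratification-consistent, and guarded", {
  # identical groups: hazard ratio 1
  dat <- data.frame(time = rep(c(1, 2, 3, 4, 6, 9), 2), event = 1,
                    g = rep(c(0, 1), each = 6))
  cx <- cox_ph(dat$time, dat$event, data.frame(g = dat$g))
  expect_equal(cx$coefficients$hr, 1, tolerance = 1e-6)

  # a single stratum leaves the model unchanged
  set.seed(73)
  n <- 120
  x <- stats::rbinom(n, 1, 0.5)
  tm <- stats::rexp(n, 0.1 * exp(-0.7 * x))
  ev <- as.integer(tm < 15); tm <- pmin(tm, 15)
  un <- cox_ph(tm, ev, data.frame(x = x))
  st <- cox_ph(tm, ev, data.frame(x = x), strata = rep("s1", n))
  expect_equal(un$coefficients$coef, st$coefficients$coef, tolerance = 1e-10)

  # HR direction agrees with the log-rank comparison
  lr <- log_rank(tm, ev, x)
  expect_true((un$coefficients$hr < 1) == (lr$hr < 1))
  expect_error(cox_ph(1:5, rep(0, 5), data.frame(x = 1:5)),
               class = "degenerate_model")
})

test_that("AUROC equals exhaustive pair counting, with midrank ties", {
  auc_pairs <- function(s, l) {
    pos <- s[l]; neg <- s[!l]
    mean(outer(pos, neg, function(p, n) (p > n) + 0.5 * (p == n)))
  }
  expect_equal(auroc(c(1, 2, 3, 4), c(FALSE, FALSE, TRUE, TRUE)), 1)
  toy_s <- c(0.1, 0.4, 0.4, 0.8)
  toy_l <- c(FALSE, TRUE, FALSE, TRUE)
  expect_equal(auroc(toy_s, toy_l), auc_pairs(toy_s, toy_l))
  set.seed(74)
  for (i in 1:25) {
    s <- sample(1:5, 12, replace = TRUE)
    l <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(auroc(s, l), auc_pairs(s, l), tolerance = 1e-12)
  }
  # labels independent of scores: near 1/2 at large n
  set.seed(75)
  expect_equal(auroc(stats::rnorm(4000), stats::rbinom(4000, 1, 0.5)), 0.5,
               tolerance = 0.05)
  expect_error(auroc(1:5, rep(TRUE, 5)), class = "undefined_estimate")
})

test_that("Spearman correlation uses midranks and flags degenerate input", {
  expect_equal(spearman_cor(1:10, (1:10)^2)$rho, 1)
  expect_equal(spearman_cor(1:10, -(1:10))$rho, -1)
  x <- c(1, 2, 2, 3, 5)
  y <- c(2, 1, 4, 4, 6)
  expect_equal(spearman_cor(x, y)$rho,
               stats::cor(rank(x), rank(y)), tolerance = 1e-12)
  expect_error(spearman_cor(rep(1, 5), 1:5), class = "undefined_estimate")
})

test_that("Mann-Whitney matches exhaustive permutation for small samples", {
  ident <- mann_whitney(c(1, 2, 3), c(1, 2, 3))
  expect_gte(ident$p, 0.99)
  sep <- mann_whitney(c(10, 11, 12), c(1, 2, 3))
  expect_true(sep$U %in% c(0, 9))
  # exact two-sided p by enumeration of all rank assignments
  x <- c(10, 11, 12); y <- c(1, 2, 3)
  pooled <- c(x, y)
  u_obs <- sum(outer(x, y, ">"))
  combos <- utils::combn(6, 3)
  us <- apply(combos, 2, function(ix) {
    sum(outer(pooled[ix], pooled[-ix], ">"))
  })
  p_enum <- mean(abs(us - 4.5) >= abs(u_obs - 4.5))
  expect_equal(sep$p, p_enum, tolerance = 1e-12)
})

test_that("backward AIC elimination keeps signal, drops noise, honors forcing", {
  set.seed(76)
  n <- 400
  x_inf <- stats::rnorm(n)
  x_noise <- stats::rnorm(n)
  y <- stats::rbinom(n, 1, stats::plogis(-0.2 + 1.2 * x_inf))
  dat <- data.frame(y = y, x_inf = x_inf, x_noise = x_noise)
  sel <- backward_aic_logistic(dat, "y", c("x_inf", "x_noise"))
  expect_identical(sel$retained, "x_inf")

  # greedy result attains the exhaustive-subset AIC minimum here
  subsets <- list(character(0), "x_inf", "x_noise", c("x_inf", "x_noise"))
  aics <- vapply(subsets, function(tm) {
    stats::AIC(stats::glm(stats::reformulate(if (length(tm)) tm else "1", "y"),
                          stats::binomial(), data = dat))
  }, numeric(1))
  expect_equal(min(sel$trace$aic), min(aics), tolerance = 1e-9)

  # fixed point: removing either informative term raises AIC
  x2 <- stats::rnorm(n)
  dat2 <- data.frame(y = stats::rbinom(n, 1, stats::plogis(x_inf + x2)),
                     x_inf = x_inf, x2 = x2)
  sel2 <- backward_aic_logistic(dat2, "y", c("x_inf", "x2"))
  expect_setequal(sel2$retained, c("x_inf", "x2"))

  # empty candidate set: intercept-only model
  sel3 <- backward_aic_logistic(dat, "y", character(0), forced = "x_inf")
  expect_identical(sel3$retained, character(0))
  expect_identical(sel3$trace$action, c("start", "add_forced"))
  expect_named(sel3$auroc, c("selected", "+x_inf"))
  expect_gt(sel3$auroc[["+x_inf"]], 0.5)
})

test_that("a joint TMB + PHBR model is at least as discriminative as either alone", {
  set.seed(77)
  n <- 600
  tmb <- stats::rlnorm(n, 2.3, 1.4)
  phbr <- stats::rlnorm(n, -0.3, 1)
  lin <- -1 + 0.05 * tmb - 0.6 * log(phbr)
  y <- stats::rbinom(n, 1, stats::plogis(lin))
  dat <- data.frame(y = y, tmb = tmb, phbr = phbr)
  auc_of <- function(terms) {
    fit <- suppressWarnings(
      stats::glm(stats::reformulate(terms, "y"), stats::binomial(), dat))
    auroc(stats::predict(fit, type = "response"), y)
  }
  both <- auc_of(c("tmb", "phbr"))
  expect_gte(both + 1e-6, auc_of("tmb"))
  expect_gte(both + 1e-6, auc_of("phbr"))
})
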