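test_that("Kruskal-Wallis and post-hoc behave on closed-form toys", {
  rt <- rank_tests(c(1, 2, 3, 4, 5, 6, 7, 8, 9),
                   rep(c("a", "b", "c"), each = 3), "c")
  expect_equal(rt$kw_h, 7.2)
  # all values identical: H defined as 0, p = 1
  rt0 <- rank_tests(rep(5, 9), rep(c("a", "b", "c"), each = 3), "c")
  expect_equal(rt0$kw_h, 0)
  expect_equal(rt0$kw_p, 1)
  # a group with < 2 values skips the site
  rts <- rank_tests(c(1, 2, 3), c("a", "a", "b"), "b")
  expect_true(rts$skipped)
  # with two groups KW equals the two-sided MW normal approximation
  set.seed(8)
  x <- c(rnorm(50), rnorm(50, 0.3))
  g <- rep(c("a", "b"), each = 50)
  kw <- rank_tests(x, g, "b")
  mw <- mw_test(x[g == "b"], x[g == "a"])
  expect_equal(kw$kw_p, mw$p, tolerance = 1e-6)
})

test_that("covariate screens handle nulls and degenerate covariates", {
  set.seed(9)
  n <- 200
  subj <- data.frame(sex = rep(c("F", "M"), n / 2),
                     age = sample(20:45, n, TRUE),
                     smoking = sample(c("yes", "no", "unknown"), n, TRUE))
  m <- runif(n)
  cs <- covariate_screen(m, subj)
  expect_lt(abs(cs$age_rho), 2 / sqrt(n) + 0.05)  # null correlation
  expect_gt(cs$smoking_p, 0.001)
  # methylation identical across sexes -> p = 1 under tie handling
  cs2 <- covariate_screen(rep(0.5, n), subj)
  expect_equal(cs2$sex_p, 1)
  # constant age: Spearman undefined, screen skipped
  subj3 <- subj; subj3$age <- 30
  expect_true(is.na(covariate_screen(m, subj3)$age_p))
})

test_that("per-site logistic regression matches a direct ML oracle", {
  set.seed(10)
  n <- 40
  subj <- data.frame(group = rep(c("case", "control"), each = n / 2),
                     age = sample(20:45, n, TRUE),
                     sex = sample(c("F", "M"), n, TRUE),
                     hap1 = sample(c("H1", "H2"), n, TRUE),
                     hap2 = sample(c("H1", "H2"), n, TRUE))
  m <- runif(n)
  fit <- logistic_per_site(m, subj, reference_haplotype = "H1")
  X <- cbind(1, m, subj$age, subj$sex == "M",
             (subj$hap1 == "H2") + (subj$hap2 == "H2"))
  y <- as.integer(subj$group == "case")
  b <- oracle_logistic(X, y)
  expect_equal(fit$beta_m, b[2], tolerance = 1e-6)
  # intercept-only structure: balanced case:control gives logit ~ 0
  m0 <- rep(0.5, n)
  d0 <- subj; d0$age <- 30; d0$sex <- "F"; d0$hap1 <- "H1"; d0$hap2 <- "H1"
  f0 <- suppressWarnings(stats::glm(y ~ 1, family = stats::binomial()))
  expect_equal(unname(coef(f0)[1]), 0, tolerance = 1e-8)
  # perfect separation is flagged, no p emitted
  msep <- c(rep(0.1, n / 2), rep(0.9, n / 2))
  fsep <- logistic_per_site(msep, subj, reference_haplotype = "H1")
  expect_true(is.na(fsep$logistic_p))
  expect_equal(fsep$flag, "separation_or_nonconvergence")
})

test_that("matched pairs: genotype-exact, coverage-greedy, random order", {
  subj <- function(ids, h1, h2, cov)
    data.frame(subject_id = ids, hap1 = h1, hap2 = h2,
               mean_coverage = cov)
  # 1 case / 1 control with same genotype pair regardless of coverage
  set.seed(2)
  p1 <- match_pairs(subj("C1", "A", "B", 30), subj("K1", "B", "A", 5))
  expect_equal(nrow(p1), 1L)
  # case genotype absent among controls -> unmatched
  p2 <- match_pairs(subj("C1", "A", "A", 10), subj("K1", "A", "B", 10))
  expect_equal(nrow(p2), 0L)
  # each control used at most once
  cases <- subj(c("C1", "C2"), "A", "B", c(10, 11))
  ctrls <- subj(c("K1", "K2"), "A", "B", c(10, 30))
  p3 <- match_pairs(cases, ctrls)
  expect_equal(anyDuplicated(p3$control_id), 0L)
  expect_equal(nrow(p3), 2L)
})

test_that("matched-pairs Wilcoxon handles ties and missingness", {
  expect_equal(matched_pair_test(c(1, 2, 3), c(1, 2, 3))$p, 1)
  r <- matched_pair_test(c(1, 2, NA, 4), c(2, 1, 5, NA))
  expect_equal(r$n_pairs, 2L)
})

test_that("cognition models recover a built-in diagnosis effect and match OLS", {
  set.seed(12)
  n <- 300
  subj <- data.frame(group = rep(c("case", "control"), each = n / 2),
                     age = sample(20:45, n, TRUE),
                     sex = sample(c("F", "M"), n, TRUE),
                     hap1 = sample(c("H1", "H2"), n, TRUE, c(0.6, 0.4)),
                     hap2 = sample(c("H1", "H2"), n, TRUE, c(0.6, 0.4)))
  subj$cognitive_t <- ifelse(subj$group == "case",
                             rnorm(n, 38.66, 6.53), rnorm(n, 49.63, 5.04))
  cg <- cognition_glm(subj, predictor = "genotype", coding = "risk_dosage",
                      risk_haplotype = "H2")
  dx_coef <- cg$coef[["dxcontrol"]]
  expect_lt(abs(dx_coef - 10.97), 2.5)    # ~3 se at n = 300
  # coefficients equal the normal-equations oracle
  m <- runif(n)
  cs <- cognition_glm(subj, predictor = m)
  X <- cbind(1, m, subj$age, subj$sex == "M", subj$group == "control")
  beta <- solve(t(X) %*% X, t(X) %*% subj$cognitive_t)
  expect_equal(unname(cs$coef), as.numeric(beta), tolerance = 1e-8)
  # null genotype effect: dosage p roughly uniform
  set.seed(13)
  ps <- replicate(300, {
    s2 <- subj
    s2$cognitive_t <- rnorm(n, 45, 6)
    cognition_glm(s2, "genotype", "risk_dosage", "H2")$p
  })
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  # constant predictor flagged
  s3 <- subj; s3$hap1 <- "H1"; s3$hap2 <- "H1"
  expect_true(is.na(cognition_glm(s3, "genotype", "risk_dosage",
                                  "H2")$p))
})

test_that("BH q-values: worked example, single p, monotonicity", {
  b <- bh_fdr(c(0.01, 0.02, 0.03))
  expect_equal(b$q, c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.04)$q, 0.04)
  set.seed(14)
  for (i in 1:20) {
    p <- runif(sample(3:40, 1))
    q <- bh_fdr(p)$q
    expect_true(all(q >= p - 1e-12))
    o <- order(p)
    expect_true(all(diff(q[o]) >= -1e-12))
  }
})

test_that("pooled t from summaries matches raw-data t and the printed |t|", {
  r <- pooled_t_from_summary(38.66, 6.53, 77, 49.63, 5.04, 70)
  expect_lt(abs(abs(r$t) - 11.31), 0.02)
  expect_equal(pooled_t_from_summary(5, 1, 10, 5, 2, 12)$t, 0)
  set.seed(15)
  x <- rnorm(25, 1); y <- rnorm(30, 0.5)
  r2 <- pooled_t_from_summary(mean(x), sd(x), 25, mean(y), sd(y), 30)
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(r2$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-10)
})
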