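## The statistical battery: rank-based ASM tests, covariate screens,
## per-site logistic regression, coverage-matched pairs, cognition general
## linear models, BH-FDR, and a summary-statistic pooled t.

#' Two-sided Mann-Whitney U test (normal approximation, tie-corrected)
#'
#' One shared routine used for post-hoc haplotype contrasts, sex and
#' smoking screens, and MS-HRM genotype comparisons.  Degenerate inputs
#' (all values tied) give p = 1.
#'
#' @param x,y numeric samples.
#' @return list `statistic` (U for `x`), `p`.
#' @export
mw_test <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 1 || length(y) < 1)
    return(list(statistic = NA_real_, p = NA_real_))
  if (length(unique(c(x, y))) == 1L)
    return(list(statistic = length(x) * length(y) / 2, p = 1))
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                            correct = FALSE))
  list(statistic = unname(wt$statistic), p = wt$p.value)
}

#' Kruskal-Wallis ASM test with risk-haplotype post-hoc
#'
#' Ties-corrected Kruskal-Wallis across haplotype groups, then a two-sided
#' Mann-Whitney post-hoc of the risk haplotype against the pooled others.
#' Groups with fewer than 2 observations cause the site to be skipped.
#'
#' @param m methylation values.
#' @param haplotype parallel haplotype labels.
#' @param risk_haplotype name of the risk haplotype.
#' @return list `kw_h`, `kw_p`, `posthoc_p`, `skipped`, `reason`.
#' @export
rank_tests <- function(m, haplotype, risk_haplotype) {
  ok <- !is.na(m) & !is.na(haplotype)
  m <- m[ok]; haplotype <- as.character(haplotype)[ok]
  counts <- table(haplotype)
  if (length(counts) < 2 || any(counts < 2))
    return(list(kw_h = NA_real_, kw_p = NA_real_, posthoc_p = NA_real_,
                skipped = TRUE, reason = "group_too_small"))
  if (length(unique(m)) == 1L) {
    kw_h <- 0; kw_p <- 1   # tie-correction degenerate: H defined as 0
  } else {
    kt <- stats::kruskal.test(m, factor(haplotype))
    kw_h <- unname(kt$statistic); kw_p <- kt$p.value
  }
  ph <- if (risk_haplotype %in% haplotype) {
    mw_test(m[haplotype == risk_haplotype],
            m[haplotype != risk_haplotype])$p
  } else NA_real_
  list(kw_h = kw_h, kw_p = kw_p, posthoc_p = ph,
       skipped = FALSE, reason = NA_character_)
}

#' Covariate screens: sex, age, smoking
#'
#' Sex and smoking by two-sided Mann-Whitney (subjects with unknown smoking
#' status are dropped from the smoking screen only); age by Spearman rank
#' correlation with the t-approximation p-value.
#'
#' @param m methylation values (one site).
#' @param subjects data.frame with `sex`, `age`, `smoking` aligned with `m`.
#' @return list `sex_p`, `age_rho`, `age_p`, `smoking_p` (NA when a screen
#'   is not computable, e.g. constant covariate).
#' @export
covariate_screen <- function(m, subjects) {
  stopifnot(nrow(subjects) == length(m))
  ok <- !is.na(m)
  m <- m[ok]; subjects <- subjects[ok, , drop = FALSE]
  sex_p <- if (length(unique(subjects$sex)) == 2)
    mw_test(m[subjects$sex == "F"], m[subjects$sex == "M"])$p
  else NA_real_
  if (length(m) >= 3 && length(unique(subjects$age)) > 1 &&
      length(unique(m)) > 1) {
    ct <- suppressWarnings(
      stats::cor.test(subjects$age, m, method = "spearman", exact = FALSE))
    age_rho <- unname(ct$estimate); age_p <- ct$p.value
  } else { age_rho <- NA_real_; age_p <- NA_real_ }
  sm <- subjects$smoking
  known <- sm %in% c("yes", "no")
  smoking_p <- if (length(unique(sm[known])) == 2)
    mw_test(m[known & sm == "yes"], m[known & sm == "no"])$p
  else NA_real_
  list(sex_p = sex_p, age_rho = age_rho, age_p = age_p,
       smoking_p = smoking_p)
}

#' Per-site logistic regression of diagnosis on methylation
#'
#' One model per methylated cytosine (analysis set 1% < mean M < 99%):
#' `diagnosis ~ M + age + sex + haplotype dosages`, fitted by IRLS; Wald p
#' for the M coefficient.  Haplotype adjustment enters as counts (0/1/2) of
#' each non-reference haplotype in the subject's genotype.  Non-convergence
#' or separation flags the site untestable (no p emitted).
#'
#' @param m allele-averaged methylation values (one site).
#' @param subjects data.frame with `group` (`case`/`control`), `age`,
#'   `sex`, `hap1`, `hap2` aligned with `m`.
#' @param reference_haplotype dosage reference (dropped from adjustment).
#' @return list `beta_m`, `logistic_p`, `converged`, `flag`.
#' @export
logistic_per_site <- function(m, subjects, reference_haplotype = NULL) {
  ok <- stats::complete.cases(m, subjects$age, subjects$sex)
  d <- data.frame(y = as.integer(subjects$group[ok] == "case"),
                  m = m[ok], age = subjects$age[ok],
                  sex = factor(subjects$sex[ok]))
  haps <- sort(unique(c(subjects$hap1, subjects$hap2)))
  if (is.null(reference_haplotype)) reference_haplotype <- haps[1]
  for (h in setdiff(haps, reference_haplotype))
    d[[paste0("dos_", h)]] <- (subjects$hap1[ok] == h) +
                              (subjects$hap2[ok] == h)
  if (length(unique(d$y)) < 2 || nrow(d) < 8)
    return(list(beta_m = NA_real_, logistic_p = NA_real_,
                converged = FALSE, flag = "degenerate_outcome"))
  fit <- suppressWarnings(stats::glm(y ~ ., data = d, family = stats::binomial()))
  sep <- any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE) ||
         any(fit$fitted.values > 1 - 1e-8) || any(fit$fitted.values < 1e-8)
  if (!fit$converged || sep)
    return(list(beta_m = NA_real_, logistic_p = NA_real_,
                converged = fit$converged, flag = "separation_or_nonconvergence"))
  sm <- summary(fit)$coefficients
  list(beta_m = sm["m", "Estimate"], logistic_p = sm["m", "Pr(>|z|)"],
       converged = TRUE, flag = NA_character_)
}

#' Greedy coverage-matched case-control pairing
#'
#' Cases are processed in a random order (seeded by the caller's RNG);
#' each is matched to the unused control with the identical genotype that
#' minimizes the absolute coverage difference (ties broken by the smallest
#' control id).  Unmatched cases are excluded.
#'
#' @param cases,controls data.frames with `subject_id`, `hap1`, `hap2`,
#'   `mean_coverage`.
#' @return data.frame `case_id`, `control_id`, `genotype`, `coverage_diff`.
#' @export
match_pairs <- function(cases, controls) {
  geno <- function(d) paste(pmin(d$hap1, d$hap2), pmax(d$hap1, d$hap2))
  cg <- geno(cases); kg <- geno(controls)
  used <- rep(FALSE, nrow(controls))
  ord <- sample.int(nrow(cases))
  out <- list()
  for (i in ord) {
    cand <- which(!used & kg == cg[i])
    if (!length(cand)) next
    dd <- abs(controls$mean_coverage[cand] - cases$mean_coverage[i])
    best <- cand[order(dd, controls$subject_id[cand])][1]
    used[best] <- TRUE
    out[[length(out) + 1L]] <- data.frame(
      case_id = cases$subject_id[i],
      control_id = controls$subject_id[best],
      genotype = cg[i],
      coverage_diff = abs(controls$mean_coverage[best] -
                            cases$mean_coverage[i]))
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(case_id = character(), control_id = character(),
                      genotype = character(), coverage_diff = numeric())
  rownames(res) <- NULL
  res
}

#' Wilcoxon matched-pairs test on paired methylation values
#'
#' @param case_m,control_m paired methylation values (pairs with a missing
#'   member are dropped).
#' @return list `p`, `n_pairs`.
#' @export
matched_pair_test <- function(case_m, control_m) {
  ok <- !is.na(case_m) & !is.na(control_m)
  x <- case_m[ok]; y <- control_m[ok]
  if (length(x) < 2) return(list(p = NA_real_, n_pairs = length(x)))
  if (all(x == y)) return(list(p = 1, n_pairs = length(x)))
  wt <- suppressWarnings(stats::wilcox.test(x, y, paired = TRUE,
                                            exact = FALSE, correct = FALSE))
  list(p = wt$p.value, n_pairs = length(x))
}

#' Cognition general linear models
#'
#' Ordinary least squares of the cognitive T-score on a predictor plus age,
#' sex and diagnosis.  The haplotype predictor comes in two codings: the
#' full genotype as a factor of all haplotype combinations, or the risk
#' dosage (number of risk-haplotype alleles, 0/1/2).  Alternatively the
#' predictor is a site's allele-averaged methylation.  The p-value is the
#' F test (factor) / Wald t (numeric) for the predictor term.
#'
#' @param subjects data.frame with `cognitive_t`, `age`, `sex`, `group`,
#'   `hap1`, `hap2`.
#' @param predictor `"genotype"` or numeric vector of site methylation.
#' @param coding `"full_genotype"` or `"risk_dosage"` (genotype predictor).
#' @param risk_haplotype needed for `risk_dosage`.
#' @return list `p`, `coef` (fitted coefficients), `flag`.
#' @export
cognition_glm <- function(subjects, predictor = "genotype",
                          coding = c("full_genotype", "risk_dosage"),
                          risk_haplotype = NULL) {
  coding <- match.arg(coding)
  d <- data.frame(t = subjects$cognitive_t, age = subjects$age,
                  sex = factor(subjects$sex),
                  dx = factor(subjects$group))
  if (identical(predictor, "genotype")) {
    if (coding == "risk_dosage") {
      stopifnot(!is.null(risk_haplotype))
      d$pred <- (subjects$hap1 == risk_haplotype) +
                (subjects$hap2 == risk_haplotype)
    } else {
      d$pred <- factor(paste(pmin(subjects$hap1, subjects$hap2),
                             pmax(subjects$hap1, subjects$hap2)))
    }
  } else {
    d$pred <- as.numeric(predictor)
  }
  d <- d[stats::complete.cases(d), ]
  if (is.factor(d$pred)) d$pred <- droplevels(d$pred)
  if ((is.factor(d$pred) && nlevels(d$pred) < 2) ||
      (!is.factor(d$pred) && length(unique(d$pred)) < 2))
    return(list(p = NA_real_, coef = NULL, flag = "constant_predictor"))
  fit <- stats::lm(t ~ pred + age + sex + dx, data = d)
  if (any(is.na(stats::coef(fit))))
    return(list(p = NA_real_, coef = stats::coef(fit),
                flag = "rank_deficient"))
  if (is.factor(d$pred)) {
    av <- stats::anova(fit)
    p <- av["pred", "Pr(>F)"]
  } else {
    p <- summary(fit)$coefficients["pred", "Pr(>|t|)"]
  }
  list(p = p, coef = stats::coef(fit), flag = NA_character_)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param pvalues numeric vector in (0, 1] (NAs passed through).
#' @param alpha FDR threshold for the significance flags.
#' @return list `q`, `significant`.
#' @export
bh_fdr <- function(pvalues, alpha = 0.05) {
  if (length(pvalues) == 0)
    return(list(q = numeric(0), significant = logical(0)))
  q <- stats::p.adjust(pvalues, method = "BH")
  list(q = q, significant = !is.na(q) & q <= alpha)
}

#' Pooled two-sample t from summary statistics
#'
#' Classical pooled-variance t-test computed from group means, sds and
#' sizes; used for report tables and to validate simulated cohorts against
#' printed phenotype summaries.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 group summaries (`n >= 2`, `sd > 0`).
#' @return list `t`, `df`, `p` (two-sided).
#' @export
pooled_t_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  stopifnot(n1 >= 2, n2 >= 2, sd1 > 0, sd2 > 0)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}
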