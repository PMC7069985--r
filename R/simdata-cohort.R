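## Synthetic case/control cohorts with haplotype genotypes under
## Hardy-Weinberg equilibrium and group-specific cognitive T-scores.

#' Default phenotype parameters for simulated cohorts
#'
#' Cognitive composite scores are T-scores (population mean 50, sd 10);
#' the defaults reproduce a case group with a marked cognitive deficit
#' (38.66 +/- 6.53) against controls near the population mean
#' (49.63 +/- 5.04).  Age and sex distributions are shared by the two
#' groups (balanced by design).
#'
#' @return named list of phenotype-generator parameters.
#' @export
pheno_params <- function() {
  list(case_t_mean = 38.66, case_t_sd = 6.53,
       control_t_mean = 49.63, control_t_sd = 5.04,
       age_min = 18, age_max = 45, age_mean = 27, age_sd = 6.8,
       smoking_probs = c(yes = 0.30, no = 0.60, unknown = 0.10))
}

#' Simulate a case/control cohort
#'
#' Genotypes are unordered haplotype pairs drawn under Hardy-Weinberg
#' equilibrium from `haplotype_freqs`; cognitive T-scores are Normal with
#' group-specific means/sds; age and sex are balanced across groups.
#' Uses R's global RNG (seed with [set.seed()]).
#'
#' @param n_cases,n_controls group sizes (>= 0, at least one positive).
#' @param haplotype_freqs named numeric vector of haplotype frequencies
#'   summing to 1.
#' @param pheno list as returned by [pheno_params()].
#' @return data.frame of subjects: `subject_id`, `group`, `age`, `sex`,
#'   `cognitive_t`, `smoking`, `hap1`, `hap2`.
#' @export
make_cohort <- function(n_cases, n_controls,
                        haplotype_freqs = c(AGAGGCD = 0.40, AGAGGCI = 0.30,
                                            TAGAATI = 0.30),
                        pheno = pheno_params()) {
  if (n_cases < 0 || n_controls < 0 || n_cases + n_controls <= 0)
    stop("cohort sizes must be non-negative and total > 0")
  if (abs(sum(haplotype_freqs) - 1) > 1e-8)
    stop("haplotype frequencies must sum to 1")
  n <- n_cases + n_controls
  group <- c(rep("case", n_cases), rep("control", n_controls))
  hnames <- names(haplotype_freqs)
  hap1 <- sample(hnames, n, replace = TRUE, prob = haplotype_freqs)
  hap2 <- sample(hnames, n, replace = TRUE, prob = haplotype_freqs)
  age <- round(pmin(pheno$age_max, pmax(pheno$age_min,
           stats::rnorm(n, pheno$age_mean, pheno$age_sd))))
  sex <- sample(c("F", "M"), n, replace = TRUE)
  tmean <- ifelse(group == "case", pheno$case_t_mean, pheno$control_t_mean)
  tsd <- ifelse(group == "case", pheno$case_t_sd, pheno$control_t_sd)
  cognitive_t <- stats::rnorm(n, tmean, tsd)
  smoking <- sample(names(pheno$smoking_probs), n, replace = TRUE,
                    prob = pheno$smoking_probs)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             group = group, age = age, sex = sex,
             cognitive_t = cognitive_t, smoking = smoking,
             hap1 = hap1, hap2 = hap2)
}
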