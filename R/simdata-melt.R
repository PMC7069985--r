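## Two-state melt-curve simulator for MS-HRM experiments.  Methylation
## survives bisulfite conversion as C (higher GC content after PCR), so the
## melting temperature of the amplicon rises with the fraction of
## methylation-retained CpGs; a melt curve is a logistic decay of
## fluorescence around Tm.

#' Simulate an MS-HRM melt curve
#'
#' Fluorescence follows a two-state model
#' `F(T) = 1 / (1 + exp((T - Tm) / s)) + noise` with
#' `Tm = tm0 + delta_tm * meth_fraction`.  A heterozygote between a
#' high-methylation and a low-methylation allele is an equal mixture of two
#' logistic components.  The fully methylated standard (`meth_fraction = 1`)
#' has the highest Tm.
#'
#' @param meth_fraction fraction(s) of methylation-retained CpGs of the
#'   contributing allele(s); a vector gives an equal-weight mixture (e.g.
#'   `c(1, 0)` for a heterozygote of fully/un-methylated alleles).
#' @param temperatures ascending grid in degrees Celsius within \[60, 95\].
#' @param tm0 melting temperature of the fully unmethylated template (C).
#' @param delta_tm Tm shift from no to full methylation (C).
#' @param slope logistic slope parameter s (C).
#' @param noise_sd additive Gaussian noise sd (fluorescence units).
#' @param sample_id,genotype,role curve annotations carried through to the
#'   output (roles: `sample`, `unmethylated_standard`,
#'   `methylated_standard`).
#' @return data.frame: `sample_id`, `genotype`, `role`, `temperature`,
#'   `fluorescence`.
#' @export
simulate_melt <- function(meth_fraction,
                          temperatures = seq(60, 95, by = 0.25),
                          tm0 = 75, delta_tm = 5, slope = 1.5,
                          noise_sd = 0, sample_id = "sim",
                          genotype = NA_character_, role = "sample") {
  if (any(temperatures < 60 | temperatures > 95))
    stop("temperature grid must lie within [60, 95] degrees C")
  if (is.unsorted(temperatures, strictly = TRUE))
    stop("temperature grid must be strictly ascending")
  if (any(meth_fraction < 0 | meth_fraction > 1))
    stop("meth_fraction must lie in [0, 1]")
  tms <- tm0 + delta_tm * meth_fraction
  comp <- vapply(tms, function(tm)
    1 / (1 + exp((temperatures - tm) / slope)), numeric(length(temperatures)))
  f <- rowMeans(comp)
  if (noise_sd > 0) f <- f + stats::rnorm(length(f), 0, noise_sd)
  data.frame(sample_id = sample_id, genotype = genotype, role = role,
             temperature = temperatures, fluorescence = f)
}
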