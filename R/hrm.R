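## MS-HRM difference-curve analysis: two-point normalization of melt
## curves, difference data against the unmethylated standard, the point of
## maximum separation between the standards, and genotype-group
## comparisons.

#' Normalize a melt curve by two-point (pre/post) windows
#'
#' Linear normalization mapping the mean fluorescence in the pre-melt
#' window to 1 and in the post-melt window to 0; invariant to any affine
#' rescaling of the raw curve.
#'
#' @param curve data.frame with `temperature`, `fluorescence` (one curve).
#' @param pre_window,post_window c(lo, hi) temperature windows; defaults
#'   are the first and last 2 degrees C of the grid.
#' @return the curve with `fluorescence` normalized.
#' @export
normalize_melt <- function(curve, pre_window = NULL, post_window = NULL) {
  tg <- curve$temperature
  if (is.unsorted(tg, strictly = TRUE))
    stop("temperature grid must be strictly ascending")
  if (is.null(pre_window)) pre_window <- c(min(tg), min(tg) + 2)
  if (is.null(post_window)) post_window <- c(max(tg) - 2, max(tg))
  if (pre_window[2] >= post_window[1])
    stop("pre window must precede post window")
  hi <- mean(curve$fluorescence[tg >= pre_window[1] & tg <= pre_window[2]])
  lo <- mean(curve$fluorescence[tg >= post_window[1] & tg <= post_window[2]])
  if (!is.finite(hi) || !is.finite(lo) || abs(hi - lo) < 1e-12)
    stop("zero dynamic range between normalization windows")
  curve$fluorescence <- (curve$fluorescence - lo) / (hi - lo)
  curve
}

## average replicate wells (same sample_id) on a shared grid; genotype may
## be NA (standards), which formula aggregation would silently drop
.average_replicates <- function(curves) {
  ag <- stats::aggregate(
    list(fluorescence = curves$fluorescence),
    by = list(sample_id = curves$sample_id,
              genotype = addNA(factor(curves$genotype)),
              role = curves$role, temperature = curves$temperature),
    FUN = mean)
  ag$genotype <- as.character(ag$genotype)
  ag[order(ag$sample_id, ag$temperature), ]
}

#' Difference analysis against the melt standards
#'
#' `t_star` is the grid temperature maximizing the absolute difference
#' between the unmethylated and fully methylated standards (ties -> lowest
#' temperature).  Each sample's statistic is its difference from the
#' unmethylated standard at `t_star`.  Replicate wells are averaged first.
#'
#' @param curves long data.frame: `sample_id`, `genotype`, `role`
#'   (`sample` / `unmethylated_standard` / `methylated_standard`),
#'   `temperature`, `fluorescence`; curves must be normalized to a shared
#'   grid (see [normalize_melt()]).
#' @return list of class `hrm_difference`: `t_star`, `values` (data.frame
#'   `sample_id`, `genotype`, `difference`), `standard_gap`.
#' @export
difference_analysis <- function(curves) {
  curves <- .average_replicates(curves)
  um <- curves[curves$role == "unmethylated_standard", ]
  mm <- curves[curves$role == "methylated_standard", ]
  if (nrow(um) == 0 || nrow(mm) == 0)
    stop("both melt standards are required")
  grid <- sort(unique(curves$temperature))
  u <- um$fluorescence[match(grid, um$temperature)]
  m <- mm$fluorescence[match(grid, mm$temperature)]
  if (anyNA(u) || anyNA(m))
    stop("standards do not cover the shared temperature grid")
  dd <- abs(u - m)
  t_star <- grid[which.max(dd)]   # which.max takes the first (lowest T) tie
  samp <- curves[curves$role == "sample", ]
  us <- u[match(t_star, grid)]
  vals <- do.call(rbind, lapply(split(samp, samp$sample_id), function(d) {
    f <- d$fluorescence[match(t_star, d$temperature)]
    data.frame(sample_id = d$sample_id[1], genotype = d$genotype[1],
               difference = f - us)
  }))
  rownames(vals) <- NULL
  structure(list(t_star = t_star, values = vals,
                 standard_gap = max(dd)),
            class = "hrm_difference")
}

#' Pairwise genotype comparisons of HRM difference values
#'
#' Two-sided Mann-Whitney U on the per-sample difference values between
#' every pair of genotype groups (the same routine as the ASM post-hoc
#' tests); groups with fewer than 2 samples are skipped.
#'
#' @param values data.frame `sample_id`, `genotype`, `difference`
#'   (from [difference_analysis()]).
#' @return data.frame `group1`, `group2`, `n1`, `n2`, `p`.
#' @export
hrm_genotype_test <- function(values) {
  gs <- sort(unique(values$genotype))
  out <- list()
  for (i in seq_along(gs)) for (j in seq_along(gs)) {
    if (j <= i) next
    x <- values$difference[values$genotype == gs[i]]
    y <- values$difference[values$genotype == gs[j]]
    if (length(x) < 2 || length(y) < 2) next
    out[[length(out) + 1L]] <- data.frame(
      group1 = gs[i], group2 = gs[j], n1 = length(x), n2 = length(y),
      p = mw_test(x, y)$p)
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(group1 = character(), group2 = character(),
                      n1 = integer(), n2 = integer(), p = numeric())
  res
}
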