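## Aggregation of per-read conversion states into subject x haplotype x
## site methylation levels, CpG-SNP masking, depth filtering, site
## classification, and subject-level matrices.

#' Aggregate per-read states into methylation records
#'
#' Counts are pooled per (subject, haplotype, site); the methylation level
#' is `M = n_unconverted / n_total`.  Records are emitted only when
#' `n_total >= min_depth`; (haplotype, site) pairs whose cytosine is absent
#' on that haplotype, or whose only informative strand is conversion-
#' confounded by an overlapping variant (`maskable`), are masked: the
#' record is absent, not zero, so downstream tests cannot silently include
#' it.  `mismatch` states (sequencing errors) are excluded from both
#' counts.
#'
#' @param site_calls data.frame `read_id`, `site_id`, `state`.
#' @param read_haps data.frame `read_id`, `subject_id`, `assigned`
#'   (haplotype; unassigned reads are dropped).
#' @param amplicon amplicon bundle (for masking).
#' @param min_depth minimum reads per (subject, haplotype, site).
#' @return data.frame `subject_id`, `haplotype`, `site_id`,
#'   `n_unconverted`, `n_total`, `m`.
#' @export
aggregate_methylation <- function(site_calls, read_haps, amplicon,
                                  min_depth = 5L) {
  rh <- read_haps[!is.na(read_haps$assigned),
                  c("read_id", "subject_id", "assigned")]
  d <- merge(site_calls, rh, by = "read_id")
  d <- d[d$state %in% c("converted", "unconverted"), ]
  if (nrow(d) == 0)
    return(data.frame(subject_id = character(), haplotype = character(),
                      site_id = character(), n_unconverted = integer(),
                      n_total = integer(), m = numeric()))
  key <- paste(d$subject_id, d$assigned, d$site_id, sep = "\r")
  n_total <- tapply(d$state, key, length)
  n_unc <- tapply(d$state == "unconverted", key, sum)
  parts <- do.call(rbind, strsplit(names(n_total), "\r", fixed = TRUE))
  rec <- data.frame(subject_id = parts[, 1], haplotype = parts[, 2],
                    site_id = parts[, 3],
                    n_unconverted = as.integer(n_unc),
                    n_total = as.integer(n_total))
  rec$m <- rec$n_unconverted / rec$n_total
  ## masking: absent context or conversion-confounded informative strand
  sh <- amplicon$site_haplotypes
  bad <- sh$context == "absent" | sh$maskable
  mask_key <- paste(sh$haplotype[bad], sh$site_id[bad])
  rec <- rec[!(paste(rec$haplotype, rec$site_id) %in% mask_key), ]
  rec <- rec[rec$n_total >= min_depth, ]
  rec <- rec[order(rec$subject_id, rec$haplotype, rec$site_id), ]
  rownames(rec) <- NULL
  rec
}

#' Classify sites by mean methylation across analysable subjects
#'
#' Classes follow strict thresholds: `unmethylated` iff mean M <= 0.01,
#' `intermediate` iff 0.20 < mean M < 0.80, `hypermethylated` iff mean M >
#' 0.80, otherwise `low`.  The analysis set for association testing is the
#' sites with 0.01 < mean M < 0.99.
#'
#' @param records methylation records from [aggregate_methylation()].
#' @return data.frame `site_id`, `mean_m`, `class`, `in_analysis_set`.
#' @export
classify_sites <- function(records) {
  mm <- tapply(records$m, records$site_id, mean)
  cls <- ifelse(mm <= 0.01, "unmethylated",
         ifelse(mm > 0.80, "hypermethylated",
         ifelse(mm > 0.20 & mm < 0.80, "intermediate", "low")))
  data.frame(site_id = names(mm), mean_m = as.numeric(mm),
             class = as.character(cls),
             in_analysis_set = as.numeric(mm) > 0.01 & as.numeric(mm) < 0.99,
             row.names = NULL)
}

#' Subject x site methylation matrix
#'
#' `per_haplotype` mode returns one row per (subject, haplotype);
#' `allele_averaged` one row per subject with M averaged over the two
#' haplotype records in heterozygotes (the single haplotype's M in
#' homozygotes; missing when either allele record is masked/absent).
#'
#' @param records methylation records.
#' @param genotypes data.frame `subject_id`, `hap1`, `hap2` (called
#'   genotypes; required for `allele_averaged`).
#' @param mode `"per_haplotype"` or `"allele_averaged"`.
#' @return data.frame; first column(s) identify the row, remaining columns
#'   are site M values (NA = missing/masked).
#' @export
subject_site_matrix <- function(records, genotypes = NULL,
                                mode = c("per_haplotype",
                                         "allele_averaged")) {
  mode <- match.arg(mode)
  sites <- sort(unique(records$site_id))
  if (mode == "per_haplotype") {
    rows <- unique(records[, c("subject_id", "haplotype")])
    rows <- rows[order(rows$subject_id, rows$haplotype), ]
    mat <- matrix(NA_real_, nrow(rows), length(sites),
                  dimnames = list(NULL, sites))
    ri <- match(paste(records$subject_id, records$haplotype),
                paste(rows$subject_id, rows$haplotype))
    mat[cbind(ri, match(records$site_id, sites))] <- records$m
    out <- cbind(rows, as.data.frame(mat, check.names = FALSE))
    rownames(out) <- NULL
    return(out)
  }
  if (is.null(genotypes)) stop("allele_averaged mode requires genotypes")
  subs <- genotypes$subject_id
  mat <- matrix(NA_real_, length(subs), length(sites),
                dimnames = list(NULL, sites))
  key <- paste(records$subject_id, records$haplotype)
  for (i in seq_along(subs)) {
    h <- c(genotypes$hap1[i], genotypes$hap2[i])
    r1 <- records[key == paste(subs[i], h[1]), ]
    m1 <- stats::setNames(r1$m, r1$site_id)
    if (h[1] == h[2]) {
      mat[i, names(m1)] <- m1
    } else {
      r2 <- records[key == paste(subs[i], h[2]), ]
      m2 <- stats::setNames(r2$m, r2$site_id)
      common <- intersect(names(m1), names(m2))
      mat[i, common] <- (m1[common] + m2[common]) / 2
    }
  }
  out <- cbind(data.frame(subject_id = subs),
               as.data.frame(mat, check.names = FALSE))
  rownames(out) <- NULL
  out
}

#' Per-subject mean coverage
#'
#' Mean `n_total` over a subject's records; used for coverage-matched
#' pairing of cases and controls.
#'
#' @param records methylation records.
#' @return data.frame `subject_id`, `mean_coverage`.
#' @export
subject_coverage <- function(records) {
  mc <- tapply(records$n_total, records$subject_id, mean)
  data.frame(subject_id = names(mc), mean_coverage = as.numeric(mc),
             row.names = NULL)
}
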