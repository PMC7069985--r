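.toy_amp <- function() {
  # small amplicon frame for masking tests built from the default bundle
  default_amplicon()
}

.mkcalls <- function(read_states, site_id) {
  # read_states: named vector read_id -> state at one site
  data.frame(read_id = names(read_states), site_id = site_id,
             state = unname(read_states))
}

test_that("methylation level is the unconverted fraction at >= min depth", {
  amp <- .toy_amp()
  sid <- "CpG7_60054"
  states <- c(rep("unconverted", 9), rep("converted", 1))
  names(states) <- sprintf("r%02d", 1:10)
  calls <- .mkcalls(states, sid)
  rh <- data.frame(read_id = names(states), subject_id = "S1",
                   assigned = "AGAGGCD")
  rec <- aggregate_methylation(calls, rh, amp, min_depth = 5)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$m, 0.9)
  expect_equal(rec$n_total, 10L)
  # four reads at min depth 5 -> no record at all
  rec2 <- aggregate_methylation(calls[1:4, ], rh[1:4, ], amp, min_depth = 5)
  expect_equal(nrow(rec2), 0L)
  # mismatch states count toward neither numerator nor denominator
  states2 <- c(rep("unconverted", 5), rep("mismatch", 3))
  names(states2) <- sprintf("q%02d", 1:8)
  rh2 <- data.frame(read_id = names(states2), subject_id = "S1",
                    assigned = "AGAGGCD")
  rec3 <- aggregate_methylation(.mkcalls(states2, sid), rh2, amp, 5)
  expect_equal(rec3$n_total, 5L)
  expect_equal(rec3$m, 1)
})

test_that("absent and conversion-confounded (haplotype, site) pairs are masked", {
  amp <- .toy_amp()
  s <- amp$sites
  sid_absent <- s$site_id[s$coord == 104060440 & s$strand == "+"]
  states <- rep("unconverted", 8)
  names(states) <- sprintf("r%02d", 1:8)
  rh_risk <- data.frame(read_id = names(states), subject_id = "S1",
                        assigned = "TAGAATI")
  rec <- aggregate_methylation(.mkcalls(states, sid_absent), rh_risk, amp, 5)
  expect_equal(nrow(rec), 0L)   # CpG destroyed by the risk allele: masked
  # the same site is conversion-confounded (C/T at the cytosine) on the
  # haplotypes that keep the C -> masked there too
  rh_ref <- data.frame(read_id = names(states), subject_id = "S1",
                       assigned = "AGAGGCD")
  rec2 <- aggregate_methylation(.mkcalls(states, sid_absent), rh_ref, amp, 5)
  expect_equal(nrow(rec2), 0L)
  # a regular site is not masked
  rec3 <- aggregate_methylation(.mkcalls(states, "CpG7_60054"), rh_ref,
                                amp, 5)
  expect_equal(nrow(rec3), 1L)
})

test_that("site classes use the exact strict boundaries", {
  rec <- data.frame(subject_id = "S1", haplotype = "H",
                    site_id = sprintf("s%d", 1:6),
                    n_unconverted = 1L, n_total = 10L,
                    m = c(0.005, 0.01, 0.20, 0.50, 0.80, 0.95))
  cl <- classify_sites(rec)
  got <- cl$class[match(sprintf("s%d", 1:6), cl$site_id)]
  expect_equal(got, c("unmethylated", "unmethylated", "low",
                      "intermediate", "low", "hypermethylated"))
  inset <- cl$in_analysis_set[match(sprintf("s%d", 1:6), cl$site_id)]
  expect_equal(inset, c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE))
})

test_that("allele averaging over heterozygote records", {
  rec <- data.frame(
    subject_id = c("S1", "S1", "S2", "S1"),
    haplotype = c("H1", "H2", "H1", "H1"),
    site_id = c("sA", "sA", "sA", "sB"),
    n_unconverted = c(2L, 8L, 5L, 5L), n_total = 10L,
    m = c(0.2, 0.8, 0.5, 0.5))
  gt <- data.frame(subject_id = c("S1", "S2"),
                   hap1 = c("H1", "H1"), hap2 = c("H2", "H1"),
                   analysable = TRUE, homozygous = c(FALSE, TRUE))
  av <- subject_site_matrix(rec, gt, "allele_averaged")
  expect_equal(av$sA[av$subject_id == "S1"], 0.5)
  # homozygote: the single haplotype's value
  expect_equal(av$sA[av$subject_id == "S2"], 0.5)
  # one allele masked/absent -> missing, never half-informed
  expect_true(is.na(av$sB[av$subject_id == "S1"]))
  ph <- subject_site_matrix(rec, mode = "per_haplotype")
  expect_equal(nrow(ph), 3L)
  expect_error(subject_site_matrix(rec, gt, "bogus"))
})

test_that("pipeline recovery: estimated M tracks simulator truth closely", {
  amp <- default_amplicon()
  tr <- default_truth(amp)
  set.seed(303)
  subj <- make_cohort(6, 6)
  p <- sim_params(conversion_efficiency = 1, molecule_failure_rate = 0,
                  sequencing_error_rate = 0, duplication_rate = 0,
                  reads_per_subject = 60, rng_seed = 404)
  sim <- simulate_reads(subj, amp, tr, p)
  ins <- substr(sim$reads$sequence, 9L, nchar(sim$reads$sequence) - 8L)
  calls <- align_bin(data.frame(read_id = sim$reads$read_id,
                                sequence = ins), amp,
                     align_params(band = 15L))
  hc <- haplotype_calls(calls$marker_calls, amp$catalog)
  hc$subject_id <- sim$molecules$subject_id[match(hc$read_id,
                                                  sim$molecules$read_id)]
  rec <- aggregate_methylation(calls$site_calls,
                               hc[, c("read_id", "subject_id", "assigned")],
                               amp, min_depth = 5)
  # pooled per-haplotype estimate vs truth at every unmasked site with
  # decent pooled depth
  agg_n <- tapply(rec$n_total, list(rec$haplotype, rec$site_id), sum)
  agg_u <- tapply(rec$n_unconverted, list(rec$haplotype, rec$site_id), sum)
  checked <- 0L
  for (h in rownames(agg_n)) for (sid in colnames(agg_n)) {
    n <- agg_n[h, sid]
    if (is.na(n) || n < 150) next
    m_true <- tr$true_m[tr$haplotype == h & tr$site_id == sid]
    if (!length(m_true)) next
    m_hat <- agg_u[h, sid] / n
    expect_lt(abs(m_hat - m_true),
              3 * sqrt(m_true * (1 - m_true) / n) + 0.01)
    checked <- checked + 1L
  }
  expect_gt(checked, 100)
})
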