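test_that("conversion-aware scoring picks the right strand on toy reads", {
  ref <- "ACGTACGT"
  p <- align_params(min_read_length = 4)
  # fully converted OT read: C>T at both CpGs, no mismatches
  a <- align_read("ATGTATGT", ref, p)
  expect_equal(a$bs_strand, "OT")
  expect_equal(a$identity, 1)
  expect_equal(a$score, 8 * 2)
  # untouched read aligns as OT with both cytosines retained
  b <- align_read("ACGTACGT", ref, p)
  expect_equal(b$bs_strand, "OT")
  expect_equal(b$score, 16)
  # G>A converted read is OB
  d <- align_read("ACATACAT", ref, p)
  expect_equal(d$bs_strand, "OB")
  expect_equal(d$identity, 1)
})

test_that("alignment states and under-conversion on toy reads", {
  ref <- "ACGTACGT"
  amp <- list(reference = list(amplicon_id = "toy", chrom = "chrT",
                               start_coord = 1L, sequence = ref))
  amp$reference$end_coord <- 8L
  amp$sites <- derive_sites(ref, 1L)
  amp$markers <- data.frame(marker_id = character(), coord = integer(),
                            ref_allele = character(),
                            alt_allele = character(),
                            creates_cpg = logical())
  p <- align_params(min_read_length = 4)
  a <- align_read("ATGTATGT", ref, p)
  a <- extract_states(a, "ATGTATGT", amp)
  plus <- amp$sites$site_id[amp$sites$strand == "+"]
  expect_true(all(a$site_state[plus] == "converted"))
  # minus-strand sites are unobservable from an OT read
  expect_false(any(names(a$site_state) %in%
                     amp$sites$site_id[amp$sites$strand == "-"] &
                     a$site_state != "missing"))
  b <- align_read("ACGTACGT", ref, p)
  b <- extract_states(b, "ACGTACGT", amp)
  expect_true(all(b$site_state[plus] == "unconverted"))
})

test_that("reads below the length or identity floor are rejected", {
  ref <- default_amplicon()$reference$sequence
  p <- align_params()
  r1 <- align_read(strrep("A", 20), ref, p)
  expect_true(r1$rejected)
  expect_equal(r1$reason, "read_too_short")
  set.seed(5)
  junk <- paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")
  r2 <- align_read(junk, ref, p)
  expect_true(r2$rejected)
  expect_equal(r2$reason, "low_alignment_identity")
})

test_that("the under-conversion filter applies a strict 5% threshold", {
  fake <- function(frac, covered = 40) {
    list(unconverted_cph_fraction = frac, covered_cph = covered)
  }
  expect_false(underconversion_filter(fake(2 / 40))$keep)  # 5.0% exactly
  expect_true(underconversion_filter(fake(1 / 40))$keep)   # 2.5%
  nocph <- underconversion_filter(list(unconverted_cph_fraction = NA_real_))
  expect_true(nocph$keep)
  expect_equal(nocph$flag, "no_cph_covered")
})

test_that("conversion-failure molecules are caught at the simulated rate", {
  amp <- default_amplicon()
  tr <- default_truth(amp)
  subj <- data.frame(subject_id = "S001", group = "case", age = 30,
                     sex = "F", cognitive_t = 40, smoking = "no",
                     hap1 = "AGAGGCD", hap2 = "TAGAATI")
  p <- sim_params(molecule_failure_rate = 0.05, duplication_rate = 0,
                  reads_per_subject = 300, rng_seed = 13)
  sim <- simulate_reads(subj, amp, tr, p)
  ins <- substr(sim$reads$sequence, 9L, nchar(sim$reads$sequence) - 8L)
  reads <- data.frame(read_id = sim$reads$read_id, sequence = ins)
  calls <- align_bin(reads, amp, align_params(band = 15L))
  discarded <- !calls$read_info$kept
  truthf <- sim$molecules$conversion_failed
  # every conversion failure is caught; false discards are rare events
  # (a clean molecule needs ~8 retained CpHs to cross 5%)
  expect_true(all(discarded[truthf]))
  expect_lt(mean(discarded & !truthf), 0.02)
  frac <- mean(discarded)
  expect_lt(abs(frac - 0.05), 1.96 * sqrt(0.05 * 0.95 / 300) + 0.02)
})

test_that("per-site states reproduce simulator truth on error-free reads", {
  amp <- default_amplicon()
  tr <- default_truth(amp)
  subj <- data.frame(subject_id = "S001", group = "case", age = 30,
                     sex = "F", cognitive_t = 40, smoking = "no",
                     hap1 = "AGAGGCI", hap2 = "TAGAATI")
  p <- sim_params(conversion_efficiency = 1, molecule_failure_rate = 0,
                  sequencing_error_rate = 0, duplication_rate = 0,
                  reads_per_subject = 60, rng_seed = 17)
  sim <- simulate_reads(subj, amp, tr, p)
  ins <- substr(sim$reads$sequence, 9L, nchar(sim$reads$sequence) - 8L)
  sites <- amp$sites
  nwrong <- 0L; nchecked <- 0L
  for (k in seq_len(nrow(sim$reads))) {
    al <- align_read(ins[k], amp, align_params(band = 15L),
                     read_id = sim$reads$read_id[k])
    expect_false(isTRUE(al$rejected))
    # strand inference is exact on error-free reads
    expect_equal(al$bs_strand, sim$molecules$bs_strand[k])
    al <- extract_states(al, ins[k], amp)
    truth_states <- strsplit(sim$molecules$states[k], "")[[1]]
    hap <- sim$molecules$haplotype[k]
    sh <- amp$site_haplotypes
    for (j in which(truth_states != ".")) {
      sid <- sites$site_id[j]
      got <- al$site_state[[sid]]
      if (is.null(got) || got %in% c("missing", "mismatch")) next
      nchecked <- nchecked + 1L
      want <- if (truth_states[j] == "1") "unconverted" else "converted"
      if (got != want) nwrong <- nwrong + 1L
    }
  }
  expect_gt(nchecked, 5000)
  expect_equal(nwrong, 0L)
})

test_that("lowering the under-conversion threshold never keeps more reads", {
  amp <- default_amplicon()
  tr <- default_truth(amp)
  subj <- data.frame(subject_id = "S001", group = "case", age = 30,
                     sex = "F", cognitive_t = 40, smoking = "no",
                     hap1 = "AGAGGCD", hap2 = "TAGAATI")
  p <- sim_params(molecule_failure_rate = 0.2, reads_per_subject = 80,
                  rng_seed = 23)
  sim <- simulate_reads(subj, amp, tr, p)
  ins <- substr(sim$reads$sequence, 9L, nchar(sim$reads$sequence) - 8L)
  kept <- vapply(c(0.10, 0.05, 0.02, 0.005), function(thr) {
    calls <- align_bin(data.frame(read_id = sim$reads$read_id,
                                  sequence = ins), amp,
                       align_params(band = 15L), thr)
    sum(calls$read_info$kept)
  }, 0)
  expect_true(all(diff(kept) <= 0))
})

test_that("banded alignment equals the full dynamic program on sim reads", {
  amp <- default_amplicon()
  tr <- default_truth(amp)
  subj <- data.frame(subject_id = "S001", group = "case", age = 30,
                     sex = "F", cognitive_t = 40, smoking = "no",
                     hap1 = "AGAGGCI", hap2 = "TAGAATI")
  p <- sim_params(reads_per_subject = 12, rng_seed = 41)
  sim <- simulate_reads(subj, amp, tr, p)
  ins <- substr(sim$reads$sequence, 9L, nchar(sim$reads$sequence) - 8L)
  for (k in seq_len(length(ins))) {
    full <- align_read(ins[k], amp, align_params())
    band <- align_read(ins[k], amp, align_params(band = 15L))
    expect_equal(band$score, full$score)
    expect_equal(band$bs_strand, full$bs_strand)
  }
})
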