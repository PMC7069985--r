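test_that("marker resolution follows the conversion truth table", {
  ct <- data.frame(marker_id = "x", coord = 10L, ref_allele = "C",
                   alt_allele = "T", creates_cpg = FALSE)
  # C/T on OT: observed T is either a T allele or a converted C
  expect_equal(resolve_marker("T", ct, "OT"), "ambiguous")
  expect_equal(resolve_marker("C", ct, "OT"), "ref")
  # the same marker on OB resolves cleanly (template G/A unaffected):
  # reads are in plus orientation, so the alleles still read C vs T
  expect_equal(resolve_marker("T", ct, "OB"), "alt")
  expect_equal(resolve_marker("C", ct, "OB"), "ref")
  ga <- data.frame(marker_id = "y", coord = 20L, ref_allele = "G",
                   alt_allele = "A", creates_cpg = FALSE)
  expect_equal(resolve_marker("A", ga, "OB"), "ambiguous")
  expect_equal(resolve_marker("G", ga, "OB"), "ref")
  expect_equal(resolve_marker("A", ga, "OT"), "alt")
  # an A/T variant is informative on both strands
  at <- data.frame(marker_id = "z", coord = 30L, ref_allele = "A",
                   alt_allele = "T", creates_cpg = FALSE)
  expect_equal(resolve_marker("T", at, "OT"), "alt")
  expect_equal(resolve_marker("T", at, "OB"), "alt")
  # conversion can masquerade: C/G marker, OT, observed T = converted C
  cg <- data.frame(marker_id = "w", coord = 40L, ref_allele = "C",
                   alt_allele = "G", creates_cpg = FALSE)
  expect_equal(resolve_marker("T", cg, "OT"), "ref")
  expect_equal(resolve_marker("G", cg, "OT"), "alt")
  # indel gap patterns resolve on either strand
  ins <- data.frame(marker_id = "v", coord = 50L, ref_allele = "C",
                    alt_allele = "CCG", creates_cpg = TRUE)
  expect_equal(resolve_marker("alt", ins, "OT"), "alt")
  expect_equal(resolve_marker("alt", ins, "OB"), "alt")
  expect_equal(resolve_marker("missing", ins, "OT"), "missing")
  expect_error(resolve_marker("A", ct[0, ], "OT"))
})

test_that("read assignment requires a unique fully compatible haplotype", {
  cat_ <- toy_catalog()
  mk <- cat_$markers
  # all-alt observation on OB (G/A markers are OB-ambiguous; emulate an OT
  # read where every marker resolves)
  obs_alt <- list(t1 = "T", t2 = "alt", t3 = "G", t4 = "A", t5 = "C",
                  t6 = "A", t7 = "alt")
  a <- assign_haplotype(obs_alt, cat_, "OT")
  expect_equal(a$assigned, "hapAA")
  expect_equal(a$reason, "ok")
  # the two non-risk haplotypes differ only at the indel: with the indel
  # missing the read is multi-compatible, hence unassigned
  obs_rr <- list(t1 = "A", t2 = "ref", t3 = "A", t4 = "G", t5 = "A",
                 t6 = "G", t7 = "missing")
  b <- assign_haplotype(obs_rr, cat_, "OT")
  expect_true(is.na(b$assigned))
  expect_equal(b$reason, "multi_compatible")
  # alleles matching no catalog row
  obs_x <- list(t1 = "T", t2 = "ref", t3 = "A", t4 = "G", t5 = "A",
                t6 = "G", t7 = "ref")
  d <- assign_haplotype(obs_x, cat_, "OT")
  expect_equal(d$reason, "conflict")
  # below the informative-marker floor
  obs_few <- list(t1 = "A", t2 = "missing", t3 = "missing", t4 = "missing",
                  t5 = "missing", t6 = "missing", t7 = "missing")
  e <- assign_haplotype(obs_few, cat_, "OT")
  expect_equal(e$reason, "insufficient_markers")
  expect_error(assign_haplotype(obs_alt,
                                structure(list(markers = mk,
                                               haplotypes = list(),
                                               risk_haplotype = "x"),
                                          class = "haplotype_catalog"),
                                "OT"),
               "empty")
})

test_that("genotype calls enforce the per-haplotype depth rule", {
  cat_ <- toy_catalog()
  mkcalls <- function(counts, strands = NULL) {
    hap <- rep(names(counts), counts)
    if (is.null(strands))
      strands <- rep(c("OT", "OB"), length.out = length(hap))
    data.frame(read_id = sprintf("r%03d", seq_along(hap)),
               subject_id = "S1", bs_strand = strands, assigned = hap,
               reason = "ok", informative_marker_count = 7L)
  }
  g <- call_genotype(mkcalls(c(hapAA = 12, hapRI = 9)), cat_)
  expect_true(g$analysable)
  expect_setequal(g$genotype, c("hapAA", "hapRI"))
  g2 <- call_genotype(mkcalls(c(hapAA = 12, hapRI = 4)), cat_)
  expect_false(g2$analysable)   # 4 < minimum depth 5
  # per-strand depth rule is stricter
  g3 <- call_genotype(mkcalls(c(hapAA = 12, hapRI = 9),
                              strands = c(rep("OT", 12), rep("OB", 9))),
                      cat_, per_strand = TRUE)
  expect_false(g3$analysable)
  # zero assigned reads -> uncalled
  empty <- mkcalls(c(hapAA = 1))[0, ]
  g4 <- call_genotype(empty, cat_)
  expect_false(g4$analysable)
  expect_equal(g4$reason, "no_assigned_reads")
  # invariant to read order
  x <- mkcalls(c(hapAA = 7, hapRR = 6))
  g5 <- call_genotype(x[sample(nrow(x)), ], cat_)
  expect_setequal(g5$genotype, c("hapAA", "hapRR"))
})

test_that("error-free reads are assigned perfectly and split ~50/50", {
  amp <- default_amplicon()
  tr <- default_truth(amp)
  subj <- data.frame(subject_id = "S001", group = "case", age = 30,
                     sex = "F", cognitive_t = 40, smoking = "no",
                     hap1 = "AGAGGCI", hap2 = "TAGAATI")
  p <- sim_params(conversion_efficiency = 1, molecule_failure_rate = 0,
                  sequencing_error_rate = 0, duplication_rate = 0,
                  reads_per_subject = 120, rng_seed = 19)
  sim <- simulate_reads(subj, amp, tr, p)
  ins <- substr(sim$reads$sequence, 9L, nchar(sim$reads$sequence) - 8L)
  calls <- align_bin(data.frame(read_id = sim$reads$read_id,
                                sequence = ins), amp,
                     align_params(band = 15L))
  hc <- haplotype_calls(calls$marker_calls, amp$catalog)
  truth_hap <- sim$molecules$haplotype[match(hc$read_id,
                                             sim$molecules$read_id)]
  assigned <- !is.na(hc$assigned)
  expect_equal(mean(assigned), 1)           # 100% assignment
  expect_true(all(hc$assigned == truth_hap))  # 100% accuracy
  frac <- mean(hc$assigned == "TAGAATI")
  expect_lt(abs(frac - 0.5), 1.96 * sqrt(0.25 / nrow(hc)) + 0.02)
  # no double counting: support totals equal assigned reads
  hc$subject_id <- "S001"
  g <- call_genotype(hc, amp$catalog)
  expect_equal(sum(g$support), sum(assigned))
})
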