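## End-to-end orchestration: synthetic run -> read preparation ->
## conversion-aware alignment -> haplotyping -> methylation calling ->
## statistics (-> factor/network structure), with TSV artifacts, a
## publication-style per-site report, and a manifest of output hashes.

#' Default pipeline configuration
#'
#' A single nested list drives every stage; unknown keys are rejected by
#' [run_pipeline()].  All randomness flows from the root `seed`.
#'
#' @param seed root RNG seed.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    simdata = list(
      enabled = TRUE, n_cases = 48L, n_controls = 48L,
      haplotype_frequencies = c(AGAGGCD = 0.40, AGAGGCI = 0.30,
                                TAGAATI = 0.30),
      conversion_efficiency = 0.995, molecule_failure_rate = 0.01,
      sequencing_error_rate = 0.002, duplication_rate = 0.1,
      reads_per_subject = 40L, low_quality_fraction = 0),
    readprep = list(min_read_quality = 30),
    bsalign = list(min_identity = 0.9, band = 15L,
                   underconversion_threshold = 0.05),
    haplo = list(min_informative = 2L, min_depth = 5L, per_strand = FALSE),
    methcall = list(min_depth = 5L),
    asmstats = list(fdr_alpha = 0.05, heterozygotes_only = TRUE),
    structure = list(enabled = FALSE, gamma = 0.5, n_lambdas = 30L,
                     min_overlap = 20L))
}

.validate_config <- function(config) {
  ref <- default_config()
  bad <- setdiff(names(config), names(ref))
  if (length(bad)) stop("unknown config key: ", paste(bad, collapse = ", "))
  for (sec in intersect(names(config), setdiff(names(ref), "seed"))) {
    bads <- setdiff(names(config[[sec]]), names(ref[[sec]]))
    if (length(bads))
      stop("unknown config key: ", sec, "$",
           paste(bads, collapse = paste0(", ", sec, "$")))
  }
  cfg <- ref
  for (sec in names(config)) {
    if (is.list(config[[sec]])) {
      for (k in names(config[[sec]])) cfg[[sec]][[k]] <- config[[sec]][[k]]
    } else cfg[[sec]] <- config[[sec]]
  }
  cfg
}

#' Per-site ASM and association statistics
#'
#' For every site in the analysis set: per-haplotype mean +/- sd of M
#' across analysable heterozygous subjects, Kruskal-Wallis ASM p, risk-vs-
#' others Mann-Whitney post-hoc, sex/age/smoking screens, per-site logistic
#' diagnosis p, matched-pairs Wilcoxon p, and per-site cognition model p,
#' with BH q-values per test family (family = this fragment x test type).
#'
#' @param records methylation records (see [aggregate_methylation()]).
#' @param classes site classes (see [classify_sites()]).
#' @param subjects cohort phenotype table.
#' @param genotypes called genotypes ([genotype_table()]).
#' @param catalog haplotype catalog.
#' @param coverage per-subject mean coverage ([subject_coverage()]).
#' @param fdr_alpha FDR threshold.
#' @param heterozygotes_only restrict per-haplotype ASM contrasts to
#'   heterozygous subjects (the default mirrors a heterozygote-only design).
#' @return list: `site_stats` (data.frame), `pairs` (matched pairs),
#'   `cognition_genotype` (fragment-level genotype models).
#' @export
site_stats_table <- function(records, classes, subjects, genotypes,
                             catalog, coverage, fdr_alpha = 0.05,
                             heterozygotes_only = TRUE) {
  risk <- catalog$risk_haplotype
  gt <- genotypes[genotypes$analysable, , drop = FALSE]
  an_subj <- merge(gt, subjects, by = "subject_id",
                   suffixes = c("", ".sim"))
  het <- an_subj[an_subj$hap1 != an_subj$hap2, , drop = FALSE]
  asm_subj <- if (heterozygotes_only) het else an_subj
  rec_an <- records[records$subject_id %in% an_subj$subject_id, ]
  mat_avg <- subject_site_matrix(rec_an, an_subj, "allele_averaged")
  msub <- an_subj[match(mat_avg$subject_id, an_subj$subject_id), ]
  cov <- coverage
  cs <- merge(an_subj, cov, by = "subject_id")
  pairs <- match_pairs(cs[cs$group == "case", ],
                       cs[cs$group == "control", ])
  sites <- classes$site_id[classes$in_analysis_set]
  rec_asm <- rec_an[rec_an$subject_id %in% asm_subj$subject_id, ]
  rows <- list()
  for (sid in sites) {
    r <- rec_asm[rec_asm$site_id == sid, ]
    rt <- rank_tests(r$m, r$haplotype, risk)
    hap_stats <- lapply(names(catalog$haplotypes), function(h) {
      v <- r$m[r$haplotype == h]
      c(mean = mean(v), sd = stats::sd(v), n = length(v))
    })
    names(hap_stats) <- names(catalog$haplotypes)
    mcol <- mat_avg[[sid]]
    if (is.null(mcol)) mcol <- rep(NA_real_, nrow(mat_avg))
    cvs <- covariate_screen(mcol, msub)
    lg <- logistic_per_site(mcol, msub)
    pm_case <- mcol[match(pairs$case_id, mat_avg$subject_id)]
    pm_ctrl <- mcol[match(pairs$control_id, mat_avg$subject_id)]
    mp <- matched_pair_test(pm_case, pm_ctrl)
    cg <- cognition_glm(msub, predictor = mcol)
    row <- data.frame(site_id = sid, kw_p = rt$kw_p,
                      posthoc_p = rt$posthoc_p,
                      sex_p = cvs$sex_p, age_rho = cvs$age_rho,
                      age_p = cvs$age_p, smoking_p = cvs$smoking_p,
                      logistic_p = lg$logistic_p,
                      wilcoxon_matched_p = mp$p, cognition_p = cg$p)
    for (h in names(hap_stats)) {
      row[[paste0("mean_", h)]] <- hap_stats[[h]][["mean"]]
      row[[paste0("sd_", h)]] <- hap_stats[[h]][["sd"]]
      row[[paste0("n_", h)]] <- hap_stats[[h]][["n"]]
    }
    rows[[sid]] <- row
  }
  st <- do.call(rbind, rows)
  rownames(st) <- NULL
  if (!is.null(st)) {
    for (fam in c("kw_p", "posthoc_p", "logistic_p", "wilcoxon_matched_p",
                  "cognition_p")) {
      fq <- bh_fdr(st[[fam]], fdr_alpha)
      st[[sub("_p$", "_q", fam)]] <- fq$q
    }
    st <- merge(st, classes, by = "site_id")
  }
  cg_full <- cognition_glm(an_subj, predictor = "genotype",
                           coding = "full_genotype")
  cg_dose <- cognition_glm(an_subj, predictor = "genotype",
                           coding = "risk_dosage", risk_haplotype = risk)
  list(site_stats = st, pairs = pairs,
       cognition_genotype = list(full_genotype_p = cg_full$p,
                                 risk_dosage_p = cg_dose$p))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate -> demultiplex/trim/
#' filter/deduplicate -> align -> haplotype -> aggregate -> test
#' [-> structure]), writes every artifact as TSV/FASTQ/FASTA under
#' `out_dir` together with a JSON manifest (seed, resolved config, md5 of
#' every output), and returns the in-memory results.
#'
#' @param config configuration list (see [default_config()]); partial
#'   configs are completed with defaults, unknown keys rejected.
#' @param out_dir output directory (created); NULL for no file output.
#' @return list with `amplicon`, `truth`, `subjects`, `qc`, `calls`,
#'   `haplotype_calls`, `genotypes`, `records`, `classes`, `stats`,
#'   `structure`, `manifest` (invisible).
#' @export
run_pipeline <- function(config = list(), out_dir = NULL) {
  cfg <- .validate_config(config)
  set.seed(cfg$seed)
  outputs <- character(0)
  emit <- function(obj, name, writer = write_tsv) {
    if (is.null(out_dir)) return(invisible(NULL))
    p <- file.path(out_dir, name)
    writer(obj, p)
    outputs <<- c(outputs, p)
  }
  if (!is.null(out_dir))
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!isTRUE(cfg$simdata$enabled))
    stop("only synthetic runs are supported without external inputs; ",
         "enable the simdata stage or call the stage functions directly")
  ## --- simdata ---
  amplicon <- default_amplicon()
  truth <- default_truth(amplicon)
  sd <- cfg$simdata
  subjects <- make_cohort(sd$n_cases, sd$n_controls,
                          sd$haplotype_frequencies)
  params <- sim_params(conversion_efficiency = sd$conversion_efficiency,
                       molecule_failure_rate = sd$molecule_failure_rate,
                       sequencing_error_rate = sd$sequencing_error_rate,
                       duplication_rate = sd$duplication_rate,
                       reads_per_subject = sd$reads_per_subject,
                       low_quality_fraction = sd$low_quality_fraction)
  sim <- simulate_reads(subjects, amplicon, truth, params)
  emit(amplicon, "amplicon.fasta", write_amplicon_fasta)
  emit(sim$reads, "reads.fastq", write_fastq)
  emit(subjects, "subjects.tsv")
  emit(sim$sample_sheet, "sample_sheet.tsv")
  emit(truth, "truth.tsv")
  emit(amplicon$sites, "sites.tsv")
  emit(amplicon$markers, "markers.tsv")
  ## --- readprep ---
  bars <- default_barcodes()
  dm <- demultiplex(sim$reads, bars$forward, bars$reverse,
                    sim$sample_sheet)
  prepped <- list(); qc_rows <- list()
  for (sid in names(dm$bins)) {
    bin <- dm$bins[[sid]]
    sh <- sim$sample_sheet[sim$sample_sheet$sample_id == sid, ]
    tf <- trim_and_filter(bin, list(fwd = sh$fwd_barcode,
                                    rev = sh$rev_barcode),
                          cfg$readprep$min_read_quality)
    dd <- deduplicate(tf$kept)
    u <- dd$unique
    if (nrow(u)) u$subject_id <- sid
    prepped[[sid]] <- u
    qc_rows[[sid]] <- data.frame(sample_id = sid, assigned = nrow(bin),
      q30_failed = sum(tf$rejected$reason == "below_min_read_quality",
                       na.rm = TRUE),
      duplicates_removed = dd$removed, retained = nrow(u))
  }
  qc <- do.call(rbind, qc_rows)
  rownames(qc) <- NULL
  qc_total <- c(input = unname(dm$counters["input"]),
                unassigned = unname(dm$counters["unassigned"]))
  emit(qc, "readprep_qc.tsv")
  reads_prepped <- do.call(rbind, prepped)
  ## --- bsalign ---
  ap <- align_params(min_identity = cfg$bsalign$min_identity,
                     band = cfg$bsalign$band)
  calls <- align_bin(reads_prepped, amplicon, ap,
                     cfg$bsalign$underconversion_threshold)
  read_subject <- stats::setNames(reads_prepped$subject_id,
                                  reads_prepped$read_id)
  emit(calls$read_info, "alignment_info.tsv")
  ## --- haplo ---
  hc <- haplotype_calls(calls$marker_calls, amplicon$catalog,
                        cfg$haplo$min_informative)
  hc$subject_id <- unname(read_subject[hc$read_id])
  genotypes <- genotype_table(hc, amplicon$catalog,
                              cfg$haplo$min_depth, cfg$haplo$per_strand)
  emit(hc, "haplotype_calls.tsv")
  emit(genotypes, "genotypes.tsv")
  ## --- methcall ---
  rh <- hc[, c("read_id", "subject_id", "assigned")]
  records <- aggregate_methylation(calls$site_calls, rh, amplicon,
                                   cfg$methcall$min_depth)
  classes <- classify_sites(records)
  coverage <- subject_coverage(records)
  emit(records, "methylation_records.tsv")
  emit(classes, "site_classes.tsv")
  ## --- asmstats ---
  stats_res <- site_stats_table(records, classes, subjects, genotypes,
                                amplicon$catalog, coverage,
                                cfg$asmstats$fdr_alpha,
                                cfg$asmstats$heterozygotes_only)
  emit(stats_res$site_stats, "site_stats.tsv")
  emit(stats_res$pairs, "matched_pairs.tsv")
  ## --- structure (optional) ---
  struct <- NULL
  if (isTRUE(cfg$structure$enabled) && !is.null(stats_res$site_stats)) {
    gt <- genotypes[genotypes$analysable, ]
    mat <- subject_site_matrix(
      records[records$subject_id %in% gt$subject_id, ], gt,
      "allele_averaged")
    asm_sites <- stats_res$site_stats$site_id[
      !is.na(stats_res$site_stats$kw_q) &
        stats_res$site_stats$kw_q <= cfg$asmstats$fdr_alpha]
    m <- as.matrix(mat[, intersect(asm_sites, colnames(mat)), drop = FALSE])
    if (ncol(m) >= 3) {
      z <- nonparanormal_transform(m)
      net <- ebicglasso(z, gamma = cfg$structure$gamma,
                        n_lambdas = cfg$structure$n_lambdas,
                        min_overlap = cfg$structure$min_overlap)
      nf <- tryCatch(parallel_analysis(z, n_sims = 200),
                     error = function(e) NA_integer_)
      efa <- if (!is.na(nf) && nf >= 1 && nf < ncol(z))
        tryCatch(efa_promax(z, nf), error = function(e) NULL) else NULL
      struct <- list(network = net, n_factors = nf, efa = efa)
      emit(network_edges(net), "network_edges.tsv")
      if (!is.null(efa))
        emit(cbind(site_id = rownames(efa$loadings),
                   as.data.frame(efa$loadings)), "factor_loadings.tsv")
    }
  }
  ## --- report + manifest ---
  res <- list(amplicon = amplicon, truth = truth, subjects = subjects,
              sim = sim, qc = qc, qc_total = qc_total, calls = calls,
              haplotype_calls = hc, genotypes = genotypes,
              records = records, classes = classes, coverage = coverage,
              stats = stats_res, structure = struct)
  if (!is.null(out_dir)) {
    write_report(stats_res, classes, amplicon$catalog, out_dir)
    outputs <- c(outputs, file.path(out_dir, c("report.tsv", "report.txt")))
    manifest <- list(seed = cfg$seed, config = cfg,
                     files = lapply(stats::setNames(outputs,
                                                    basename(outputs)),
                                    function(p)
                                      unname(tools::md5sum(p))))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    res$manifest <- manifest
  }
  invisible(res)
}

#' Write the publication-style per-site report
#'
#' Machine-readable TSV plus a short human-readable text rendering of the
#' per-haplotype means, ASM tests and q-values for every analysable site.
#'
#' @param stats result of [site_stats_table()].
#' @param classes site classes.
#' @param catalog haplotype catalog.
#' @param out_dir destination directory.
#' @return paths, invisibly.
#' @export
write_report <- function(stats, classes, catalog, out_dir) {
  st <- stats$site_stats
  tsv <- file.path(out_dir, "report.tsv")
  txt <- file.path(out_dir, "report.txt")
  if (is.null(st) || nrow(st) == 0) {
    write_tsv(data.frame(), tsv)
    writeLines(c("per-site ASM report", "",
                 "analysis set empty: no site passed the 1% < mean M < 99% filter"),
               txt)
    return(invisible(c(tsv, txt)))
  }
  write_tsv(st, tsv)
  haps <- names(catalog$haplotypes)
  lines <- c("per-site ASM report (analysable sites)",
             sprintf("risk haplotype: %s", catalog$risk_haplotype), "")
  hdr <- sprintf("%-14s %-16s %s %10s %10s %8s", "site", "class",
                 paste(sprintf("%-13s", haps), collapse = " "),
                 "KW p", "posthoc p", "KW q")
  lines <- c(lines, hdr)
  for (i in seq_len(nrow(st))) {
    ms <- vapply(haps, function(h)
      sprintf("%4.2f±%4.2f", st[[paste0("mean_", h)]][i],
              st[[paste0("sd_", h)]][i]), "")
    lines <- c(lines, sprintf("%-14s %-16s %s %10.2g %10.2g %8.2g",
                              st$site_id[i], st$class[i],
                              paste(sprintf("%-13s", ms), collapse = " "),
                              st$kw_p[i], st$posthoc_p[i], st$kw_q[i]))
  }
  writeLines(lines, txt)
  invisible(c(tsv, txt))
}
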