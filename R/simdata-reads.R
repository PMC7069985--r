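## Barcoded bisulfite read simulation: per-molecule haplotype and strand,
## Bernoulli methylation states from the truth table, conversion with
## per-molecule failure, substitution sequencing errors, PCR duplicates and
## dual barcodes.

#' Simulation parameters
#'
#' @param conversion_efficiency probability that an unmethylated cytosine is
#'   converted (read as T / complementary A).
#' @param molecule_failure_rate probability that a molecule escaped
#'   conversion entirely (all cytosines retained) -- these molecules are the
#'   target of the under-conversion filter.
#' @param sequencing_error_rate per-base substitution error probability.
#' @param duplication_rate probability that a read is a PCR duplicate
#'   (byte-identical copy) of an earlier molecule of the same sample.
#' @param reads_per_subject reads generated per subject.
#' @param low_quality_fraction fraction of reads emitted at `low_quality`
#'   instead of `base_quality` (to exercise the Q30 filter).
#' @param base_quality,low_quality constant Phred scores for read bases.
#' @param rng_seed optional integer; when non-NULL [simulate_reads()] seeds
#'   the RNG so identical parameters give byte-identical output.
#' @return list of class `sim_params`.
#' @export
sim_params <- function(conversion_efficiency = 0.995,
                       molecule_failure_rate = 0.01,
                       sequencing_error_rate = 0.002,
                       duplication_rate = 0.1,
                       reads_per_subject = 40,
                       low_quality_fraction = 0,
                       base_quality = 40L,
                       low_quality = 20L,
                       rng_seed = NULL) {
  p <- list(conversion_efficiency = conversion_efficiency,
            molecule_failure_rate = molecule_failure_rate,
            sequencing_error_rate = sequencing_error_rate,
            duplication_rate = duplication_rate,
            reads_per_subject = reads_per_subject,
            low_quality_fraction = low_quality_fraction,
            base_quality = as.integer(base_quality),
            low_quality = as.integer(low_quality),
            rng_seed = rng_seed)
  rates <- unlist(p[c("conversion_efficiency", "molecule_failure_rate",
                      "sequencing_error_rate", "duplication_rate",
                      "low_quality_fraction")])
  if (any(rates < 0 | rates > 1)) stop("all rates must lie in [0, 1]")
  structure(p, class = "sim_params")
}

#' Default dual-barcode catalog
#'
#' Eight forward and twelve reverse 8-mer barcodes (96 combinations), fixed
#' sequences over the {A, G, T} alphabet so conversion state cannot be
#' confused with barcode content.
#'
#' @return list with `forward` and `reverse` named character vectors.
#' @export
default_barcodes <- function() {
  fwd <- c("AGATAGGT", "TTAGGAGA", "GATTAGTG", "AGGTTAGA",
           "TAGAGTTG", "GGTATAGT", "ATTGAGGA", "TGAGATTG")
  rev <- c("AGTTGATG", "TGATAGGA", "GATAGTTA", "TTGGATAG",
           "AGAGTGTA", "GTTAGAGT", "TAGGTGAT", "ATGATTGG",
           "GGAGATAT", "TATTGGAG", "AAGGTAGT", "GTGTAATG")
  names(fwd) <- sprintf("F%02d", seq_along(fwd))
  names(rev) <- sprintf("R%02d", seq_along(rev))
  list(forward = fwd, reverse = rev)
}

## assign one (forward, reverse) pair per subject; at most 96 per run
.assign_barcodes <- function(subject_ids, barcodes) {
  nf <- length(barcodes$forward); nr <- length(barcodes$reverse)
  if (length(subject_ids) > nf * nr)
    stop("at most ", nf * nr, " subjects per sequencing run ",
         "(barcode combination space)")
  i <- seq_along(subject_ids) - 1L
  data.frame(subject_id = subject_ids,
             fwd_name = names(barcodes$forward)[i %% nf + 1L],
             fwd = unname(barcodes$forward[i %% nf + 1L]),
             rev_name = names(barcodes$reverse)[i %/% nf + 1L],
             rev = unname(barcodes$reverse[i %/% nf + 1L]))
}

.ERR_SUB <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
                 G = c("A", "C", "T"), T = c("A", "C", "G"))

#' Simulate barcoded bisulfite reads with ground truth
#'
#' Per molecule: a haplotype is drawn uniformly from the subject's two, the
#' bisulfite strand (OT/OB) with probability 1/2 each, and every cytosine on
#' the template strand is methylated by a Bernoulli draw from the truth
#' table.  Unmethylated cytosines convert with `conversion_efficiency`
#' unless the molecule is a conversion failure (all cytosines retained).
#' Reads are emitted in plus orientation: OT conversion appears as C>T, OB
#' conversion as G>A relative to the plus reference.  Substitution
#' sequencing errors are i.i.d. per base; duplicates copy an existing
#' molecule's read; dual barcodes flank the insert per subject.
#'
#' @param subjects cohort data.frame from [make_cohort()].
#' @param amplicon amplicon bundle.
#' @param truth truth table from [build_truth()]/[default_truth()].
#' @param params [sim_params()].
#' @param barcodes barcode catalog, see [default_barcodes()].
#' @return list: `reads` (read_id, sequence, quality), `molecules` (per-read
#'   truth: subject, haplotype, strand, conversion_failed, duplicate_of,
#'   low_quality, methylation-state string over `state_sites`),
#'   `state_sites` (site_id order of the state strings), `sample_sheet`
#'   (subject_id, fwd_barcode, rev_barcode).
#' @export
simulate_reads <- function(subjects, amplicon, truth,
                           params = sim_params(),
                           barcodes = default_barcodes()) {
  if (!is.null(params$rng_seed)) set.seed(params$rng_seed)
  haps <- names(amplicon$catalog$haplotypes)
  used <- unique(c(subjects$hap1, subjects$hap2))
  if (!all(used %in% unique(truth$haplotype)))
    stop("haplotype absent from truth table: ",
         paste(setdiff(used, unique(truth$haplotype)), collapse = ", "))
  sheet <- .assign_barcodes(subjects$subject_id, barcodes)
  sites <- amplicon$sites
  nsite <- nrow(sites)
  ## per-haplotype template cache and per-site template index / truth
  tpl <- lapply(stats::setNames(haps, haps),
                function(h) apply_haplotype(amplicon, h))
  hinfo <- lapply(stats::setNames(haps, haps), function(h) {
    t <- tpl[[h]]
    ti <- match(sites$coord, t$coord)            # template index per site
    chv <- strsplit(t$sequence, "")[[1]]
    need <- ifelse(sites$strand == "+", "C", "G")
    ok <- !is.na(ti) & chv[pmax(ti, 1L)] == need
    ti[!ok] <- NA_integer_
    tm <- rep(NA_real_, nsite)
    tr <- truth[truth$haplotype == h, ]
    tm[match(tr$site_id, sites$site_id)] <- tr$true_m
    list(chars = chv, site_tpl_idx = ti, true_m = tm,
         is_c = chv == "C", is_g = chv == "G")
  })
  reads <- vector("list", nrow(subjects) * params$reads_per_subject)
  mols <- vector("list", length(reads))
  ridx <- 0L
  for (s in seq_len(nrow(subjects))) {
    sub_haps <- c(subjects$hap1[s], subjects$hap2[s])
    sub_reads <- list()   # molecule records of this subject (for duplication)
    for (r in seq_len(params$reads_per_subject)) {
      ridx <- ridx + 1L
      read_id <- sprintf("mol%06d", ridx)
      if (length(sub_reads) > 0 &&
          stats::runif(1) < params$duplication_rate) {
        src <- sub_reads[[sample.int(length(sub_reads), 1)]]
        rec <- src
        rec$read_id <- read_id
        rec$duplicate_of <- src$read_id
      } else {
        h <- sub_haps[sample.int(2L, 1L)]
        st <- if (stats::runif(1) < 0.5) "OT" else "OB"
        hi <- hinfo[[h]]
        failed <- stats::runif(1) < params$molecule_failure_rate
        chv <- hi$chars
        on_strand <- sites$strand == (if (st == "OT") "+" else "-") &
                     !is.na(hi$site_tpl_idx)
        meth <- rep(NA, nsite)
        meth[on_strand] <- stats::runif(sum(on_strand)) < hi$true_m[on_strand]
        ## conversion: template-strand cytosines
        if (st == "OT") {
          conv_pos <- which(hi$is_c)
        } else {
          conv_pos <- which(hi$is_g)
        }
        tracked <- hi$site_tpl_idx[on_strand]
        meth_pos <- tracked[meth[on_strand] %in% TRUE]
        out <- chv
        if (!failed) {
          unmeth <- setdiff(conv_pos, meth_pos)
          doconv <- unmeth[stats::runif(length(unmeth)) <
                             params$conversion_efficiency]
          out[doconv] <- if (st == "OT") "T" else "A"
        }
        ## sequencing errors (substitutions only)
        nerr <- stats::rbinom(1, length(out), params$sequencing_error_rate)
        if (nerr > 0) {
          pos <- sample.int(length(out), nerr)
          out[pos] <- vapply(out[pos],
                             function(b) sample(.ERR_SUB[[b]], 1L), "")
        }
        state <- rep(".", nsite)
        state[on_strand] <- ifelse(meth[on_strand], "1", "0")
        rec <- list(read_id = read_id, subject_id = subjects$subject_id[s],
                    haplotype = h, bs_strand = st,
                    conversion_failed = failed,
                    duplicate_of = NA_character_,
                    insert = paste(out, collapse = ""),
                    states = paste(state, collapse = ""))
      }
      rec$low_quality <- stats::runif(1) < params$low_quality_fraction
      q <- if (rec$low_quality) params$low_quality else params$base_quality
      seqfull <- paste0(sheet$fwd[s], rec$insert, sheet$rev[s])
      reads[[ridx]] <- list(read_id = read_id, sequence = seqfull,
        quality = strrep(rawToChar(as.raw(q + 33L)), nchar(seqfull)))
      sub_reads[[length(sub_reads) + 1L]] <- rec
      mols[[ridx]] <- rec
    }
  }
  reads_df <- do.call(rbind, lapply(reads, function(x)
    data.frame(read_id = x$read_id, sequence = x$sequence,
               quality = x$quality)))
  mol_df <- do.call(rbind, lapply(mols, function(x)
    data.frame(read_id = x$read_id, subject_id = x$subject_id,
               haplotype = x$haplotype, bs_strand = x$bs_strand,
               conversion_failed = x$conversion_failed,
               duplicate_of = x$duplicate_of,
               low_quality = x$low_quality, states = x$states)))
  list(reads = reads_df, molecules = mol_df,
       state_sites = sites$site_id,
       sample_sheet = data.frame(sample_id = sheet$subject_id,
                                 fwd_barcode = sheet$fwd,
                                 rev_barcode = sheet$rev))
}
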