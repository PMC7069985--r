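## The packaged default amplicon: a deterministic synthetic ~1 kb fragment
## emulating an intronic enhancer in the fourth intron of KLC1 -- a CpG-SNP
## rich region where a risk haplotype both facilitates methylation at a
## cluster of CpGs near a tag SNP and creates/destroys CpGs outright.  The
## companion truth profile (inst/extdata) carries the per-haplotype true
## methylation means used by the read simulator.

.DEFAULT_START <- 104060000L
.DEFAULT_LEN <- 953L

.default_marker_table <- function() {
  data.frame(
    marker_id  = c("m1_60150", "m2_60368", "m3_60379", "m4_60385",
                   "m5_60392", "m7_60421", "m6_60440"),
    coord      = 104060000L + c(150L, 368L, 379L, 385L, 392L, 421L, 440L),
    ref_allele = c("A", "G", "A", "G", "G", "C",  "C"),
    alt_allele = c("T", "A", "G", "A", "A", "CG", "T"),
    creates_cpg = c(FALSE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE))
}

#' The packaged default synthetic amplicon
#'
#' A deterministic 953 bp amplicon (chr14-like frame, start 104,060,000)
#' with seven markers forming three haplotypes: `AGAGGCD` and `AGAGGCI`
#' (non-risk, differing only at the terminal indel) and the risk haplotype
#' `TAGAATI` carrying every alternative allele.  The risk haplotype shows a
#' "facilitated" methylation increase at five CpGs near the first marker,
#' destroys three CpGs (G>A at the CpG guanine), creates one CpG from a CpH
#' (A>G), gains one CpG through a single-base insertion, and removes the
#' cytosine of one CpG via a C>T allele (that site is conversion-confounded
#' and maskable).  The layout mirrors the allele-specific methylation
#' architecture reported for CpG-SNP rich schizophrenia-risk regions.
#'
#' @return amplicon bundle (see [make_amplicon()]).
#' @export
default_amplicon <- function() {
  n <- .DEFAULT_LEN
  ch <- .lcg_bases(n, seed = 987654321)
  idx <- function(coord) coord - .DEFAULT_START + 1L
  assign_at <- list()  # 1-based position -> base
  put <- function(a, pos, base) { a[[as.character(pos)]] <- base; a }
  tp <- read_truth_profile()
  cg_coords <- c(104060054, 104060087, 104060156, 104060164, 104060226,
                 104060367, 104060384, 104060391, 104060427, 104060464,
                 104060678, 104060845, 104060440)
  cph_coords <- c(104060373, 104060378, 104060380, 104060381, 104060386,
                  104060389, 104060390, 104060421)
  for (co in cg_coords) {
    assign_at <- put(assign_at, idx(co), "C")
    assign_at <- put(assign_at, idx(co) + 1L, "G")
  }
  for (co in cph_coords) assign_at <- put(assign_at, idx(co), "C")
  for (co in cph_coords) {  # following base non-G unless already pinned
    p <- idx(co) + 1L
    if (is.null(assign_at[[as.character(p)]]))
      assign_at <- put(assign_at, p, "A")
  }
  mk <- .default_marker_table()
  for (i in seq_len(nrow(mk))) {  # pin marker reference alleles
    p <- idx(mk$coord[i])
    ref1 <- substr(mk$ref_allele[i], 1, 1)
    prev <- assign_at[[as.character(p)]]
    if (!is.null(prev) && prev != ref1)
      stop("internal: marker ", mk$marker_id[i], " collides with site layout")
    assign_at <- put(assign_at, p, ref1)
  }
  for (p in names(assign_at)) ch[as.integer(p)] <- assign_at[[p]]
  ## scrub stray CpGs/CpHs that would perturb the pinned layout: make sure
  ## no unpinned C directly precedes a pinned position in a confusing way is
  ## unnecessary -- context derivation reads the final sequence.
  mk <- mk[order(mk$coord), ]
  rownames(mk) <- NULL
  haps <- list(
    AGAGGCD = c("A", "G", "A", "G", "G", "C",  "C"),
    AGAGGCI = c("A", "G", "A", "G", "G", "CG", "C"),
    TAGAATI = c("T", "A", "G", "A", "A", "CG", "T"))
  ## align allele vectors with the coord-sorted marker order
  perm <- match(mk$marker_id,
                c("m1_60150", "m2_60368", "m3_60379", "m4_60385",
                  "m5_60392", "m7_60421", "m6_60440"))
  haps <- lapply(haps, function(a) a[perm])
  catalog <- haplotype_catalog(mk, haps, risk_haplotype = "TAGAATI")
  reference <- list(amplicon_id = "KLC1_enhancer_sim", chrom = "chr14",
                    start_coord = .DEFAULT_START,
                    sequence = paste(ch, collapse = ""))
  amp <- .new_amplicon(reference, mk, catalog)
  ## sanity: truth-profile coordinates must be plus-strand sites
  stopifnot(all(tp$coord %in% amp$sites$coord[amp$sites$strand == "+"]))
  amp
}

read_truth_profile <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata",
                        "truth_profile_klc1_enhancer_synthetic.tsv",
                        package = "haplometh")
  utils::read.delim(path, comment.char = "#", check.names = FALSE)
}

#' Build the simulator truth table of per-(haplotype, site) methylation
#'
#' Combines an amplicon bundle with a truth profile: listed (coord, strand)
#' rows take the profile's per-haplotype means, all other sites default by
#' their haplotype-resolved context (`cpg_default` for CpGs, `cph_default`
#' for CpHs -- most non-CpG cytosines are essentially unmethylated).  Sites
#' absent on a haplotype get no truth row.  CpH (and CpG) truth is kept
#' strand-specific: each strand's cytosine has its own row.
#'
#' @param amplicon amplicon bundle.
#' @param profile data.frame with `coord`, `strand` and one column per
#'   haplotype, or NULL for defaults only.  The packaged profile is used by
#'   [default_truth()].
#' @param cpg_default,cph_default default true methylation probabilities.
#' @return data.frame `haplotype`, `site_id`, `coord`, `strand`, `true_m`.
#' @export
build_truth <- function(amplicon, profile = NULL,
                        cpg_default = 0.90, cph_default = 0.004) {
  sh <- amplicon$site_haplotypes
  sites <- amplicon$sites
  out <- merge(sh, sites, by = "site_id")
  out <- out[out$context.x != "absent", ]
  out$true_m <- ifelse(out$context.x == "CpG", cpg_default, cph_default)
  if (!is.null(profile)) {
    for (r in seq_len(nrow(profile))) {
      hit <- out$coord == profile$coord[r] & out$strand == profile$strand[r]
      for (h in intersect(names(profile), names(amplicon$catalog$haplotypes)))
        out$true_m[hit & out$haplotype == h] <- profile[[h]][r]
    }
  }
  if (any(out$true_m < 0 | out$true_m > 1))
    stop("truth probabilities must lie in [0, 1]")
  res <- out[order(out$haplotype, out$coord, out$strand),
             c("haplotype", "site_id", "coord", "strand", "true_m")]
  rownames(res) <- NULL
  res
}

#' @rdname build_truth
#' @export
default_truth <- function(amplicon = default_amplicon()) {
  build_truth(amplicon, read_truth_profile())
}
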