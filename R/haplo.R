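## Conversion-aware per-read haplotype assignment and per-subject genotype
## calling, directly from the bisulfite reads.
##
## The crux is the conversion truth table: a C/T substitution cannot be read
## on the OT strand (an observed T may be a converted unmethylated C), and a
## G/A substitution cannot be read on the OB strand.  Observed alleles that
## are conversion-confounded are `ambiguous` and never used as evidence.

#' Resolve a marker observation under the bisulfite conversion truth table
#'
#' On the OT strand an allele X is observed as X, or as T when X is C (an
#' unmethylated C converts); on the OB strand as X, or as A when X is G.
#' The observation resolves to the unique compatible allele; if both
#' alleles are compatible the call is `ambiguous`; if neither, `missing`.
#' Indel observations (`"ref"`/`"alt"` from the gap pattern) resolve on
#' both strands.
#'
#' @param observation observed read base (substitution markers), or
#'   `"ref"`/`"alt"`/`"missing"` (indel markers).
#' @param marker one row of the marker table.
#' @param bs_strand `"OT"` or `"OB"`.
#' @return one of `"ref"`, `"alt"`, `"ambiguous"`, `"missing"`.
#' @export
resolve_marker <- function(observation, marker, bs_strand) {
  if (is.na(observation) || observation == "missing") return("missing")
  if (nchar(marker$ref_allele) != nchar(marker$alt_allele)) {
    ## indel: gap pattern already names the allele
    if (observation %in% c("ref", "alt")) return(observation)
    return("missing")
  }
  compat <- function(allele) {
    if (observation == allele) return(TRUE)
    if (bs_strand == "OT") allele == "C" && observation == "T"
    else allele == "G" && observation == "A"
  }
  r <- compat(marker$ref_allele); a <- compat(marker$alt_allele)
  if (r && a) "ambiguous" else if (r) "ref" else if (a) "alt" else "missing"
}

#' Assign a read to a catalog haplotype
#'
#' Resolved (non-ambiguous, non-missing) alleles are compared with every
#' catalog haplotype; the read is assigned iff exactly one haplotype is
#' fully compatible and at least `min_informative` markers were resolved.
#'
#' @param marker_obs named character vector of raw observations (bases /
#'   indel codes) as produced by [extract_states()].
#' @param catalog `haplotype_catalog`.
#' @param bs_strand the read's bisulfite strand.
#' @param min_informative minimum resolved marker count (default 2).
#' @return list: `assigned` (haplotype name or NA), `reason` (`ok`,
#'   `conflict`, `insufficient_markers`, `multi_compatible`),
#'   `informative_marker_count`, `resolved` (per-marker calls).
#' @export
assign_haplotype <- function(marker_obs, catalog, bs_strand,
                             min_informative = 2L) {
  mk <- catalog$markers
  if (length(catalog$haplotypes) == 0) stop("empty haplotype catalog")
  res <- vapply(seq_len(nrow(mk)), function(i)
    resolve_marker(marker_obs[[mk$marker_id[i]]], mk[i, ], bs_strand), "")
  names(res) <- mk$marker_id
  informative <- res %in% c("ref", "alt")
  n_inf <- sum(informative)
  if (n_inf < min_informative)
    return(list(assigned = NA_character_, reason = "insufficient_markers",
                informative_marker_count = n_inf, resolved = res))
  compat <- vapply(names(catalog$haplotypes), function(h) {
    al <- catalog$haplotypes[[h]]
    hap_code <- ifelse(al == mk$ref_allele, "ref", "alt")
    all(res[informative] == hap_code[informative])
  }, NA)
  hits <- names(compat)[compat]
  if (length(hits) == 1L)
    list(assigned = hits, reason = "ok",
         informative_marker_count = n_inf, resolved = res)
  else if (length(hits) == 0L)
    list(assigned = NA_character_, reason = "conflict",
         informative_marker_count = n_inf, resolved = res)
  else
    list(assigned = NA_character_, reason = "multi_compatible",
         informative_marker_count = n_inf, resolved = res)
}

#' Per-read haplotype calls for a table of marker observations
#'
#' @param marker_calls data.frame `read_id`, `marker_id`, `obs`,
#'   `bs_strand` from [align_bin()].
#' @param catalog `haplotype_catalog`.
#' @param min_informative see [assign_haplotype()].
#' @return data.frame `read_id`, `bs_strand`, `assigned`, `reason`,
#'   `informative_marker_count`.
#' @export
haplotype_calls <- function(marker_calls, catalog, min_informative = 2L) {
  out <- lapply(split(marker_calls, marker_calls$read_id), function(d) {
    obs <- stats::setNames(as.list(d$obs), d$marker_id)
    hc <- assign_haplotype(obs, catalog, d$bs_strand[1], min_informative)
    data.frame(read_id = d$read_id[1], bs_strand = d$bs_strand[1],
               assigned = hc$assigned, reason = hc$reason,
               informative_marker_count = hc$informative_marker_count)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Call a subject's genotype from haplotype-assigned reads
#'
#' The two most-supported haplotypes form the genotype (one, duplicated,
#' for apparent homozygotes).  The subject is analysable iff every carried
#' haplotype has at least `min_depth` assigned reads -- per bisulfite
#' strand when `per_strand = TRUE`.
#'
#' @param calls data.frame of one subject's haplotype calls
#'   (see [haplotype_calls()]).
#' @param catalog `haplotype_catalog`.
#' @param min_depth minimum supporting reads per haplotype (default 5).
#' @param per_strand require `min_depth` on each strand separately.
#' @param min_fraction haplotypes supported by fewer than this fraction of
#'   assigned reads are treated as noise, not as a second allele.
#' @return list: `genotype` (character(2) or NA), `analysable`,
#'   `homozygous`, `support` (per-haplotype read counts, total & by strand).
#' @export
call_genotype <- function(calls, catalog, min_depth = 5L,
                          per_strand = FALSE, min_fraction = 0.1) {
  ok <- calls[!is.na(calls$assigned), , drop = FALSE]
  haps <- names(catalog$haplotypes)
  support <- table(factor(ok$assigned, levels = haps))
  by_strand <- table(factor(ok$assigned, levels = haps),
                     factor(ok$bs_strand, levels = c("OT", "OB")))
  if (nrow(ok) == 0)
    return(list(genotype = c(NA_character_, NA_character_),
                analysable = FALSE, homozygous = NA,
                support = support, support_by_strand = by_strand,
                reason = "no_assigned_reads"))
  ord <- names(sort(support, decreasing = TRUE))
  top2 <- ord[seq_len(min(2L, sum(support > 0)))]
  ## drop a trace-level second haplotype (mis-assignment noise)
  if (length(top2) == 2L &&
      support[[top2[2]]] < min_fraction * nrow(ok)) top2 <- top2[1]
  genotype <- sort(c(top2, top2)[1:2])
  depth_ok <- if (per_strand) {
    all(by_strand[unique(genotype), , drop = FALSE] >= min_depth)
  } else {
    all(support[unique(genotype)] >= min_depth)
  }
  list(genotype = genotype, analysable = depth_ok,
       homozygous = genotype[1] == genotype[2],
       support = support, support_by_strand = by_strand,
       reason = if (depth_ok) "ok" else "insufficient_depth")
}

#' Genotype every subject in a run
#'
#' @param calls haplotype calls joined with `subject_id`.
#' @param catalog `haplotype_catalog`.
#' @inheritParams call_genotype
#' @return data.frame: `subject_id`, `hap1`, `hap2`, `analysable`,
#'   `homozygous`, plus per-haplotype support counts.
#' @export
genotype_table <- function(calls, catalog, min_depth = 5L,
                           per_strand = FALSE) {
  out <- lapply(split(calls, calls$subject_id), function(d) {
    g <- call_genotype(d, catalog, min_depth, per_strand)
    data.frame(subject_id = d$subject_id[1],
               hap1 = g$genotype[1], hap2 = g$genotype[2],
               analysable = g$analysable, homozygous = g$homozygous)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
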