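## Conversion-aware alignment of bisulfite reads against amplicon
## references, per-site conversion-state and per-marker allele extraction,
## and the under-conversion filter.
##
## Alignment is global with affine gaps (Gotoh), scored twice: once
## OT-aware (reference C matched by read C or T at full match score) and
## once OB-aware (reference G matched by read G or A); the higher-scoring
## strand is the inferred bisulfite strand.  The amplicon is a known ~1 kb
## reference, so global alignment replaces genome mapping.

#' Alignment scoring parameters
#'
#' Defaults: match +2, mismatch -3, gap open -6, gap extend -1 (a gap of
#' length k costs `gap_open + k * gap_ext`), conversion-consistent pair +2.
#' `band` restricts the dynamic program to a corridor around the diagonal
#' (half-width in bp); `band = NULL` computes the full matrix.
#'
#' @param match,mismatch,gap_open,gap_ext,conv scores.
#' @param min_identity reject alignments below this identity (conversion-
#'   consistent pairs count as matches; denominator = alignment columns).
#' @param min_read_length reject shorter reads outright.
#' @param band optional DP band half-width (NULL = full matrix).
#' @return list of class `align_params`.
#' @export
align_params <- function(match = 2, mismatch = -3, gap_open = -6,
                         gap_ext = -1, conv = 2, min_identity = 0.9,
                         min_read_length = 50L, band = NULL) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, conv = conv,
                 min_identity = min_identity,
                 min_read_length = as.integer(min_read_length),
                 band = if (is.null(band)) -1L else as.integer(band)),
            class = "align_params")
}

#' Align one bisulfite read to an amplicon reference
#'
#' @param sequence read sequence (plus orientation, barcodes trimmed).
#' @param amplicon amplicon bundle (or a plain reference sequence string).
#' @param params [align_params()].
#' @param read_id identifier carried through to the result.
#' @return an `aligned_molecule` list (`read_id`, `bs_strand`, `score`,
#'   `ref_offset`/`read_offset` 0-based aligned pairs with -1 for gaps,
#'   `identity`), or a rejection record (`rejected = TRUE`, `reason`).
#' @export
align_read <- function(sequence, amplicon, params = align_params(),
                       read_id = "read") {
  ref <- if (is.character(amplicon)) amplicon
         else amplicon$reference$sequence
  if (nchar(sequence) < params$min_read_length)
    return(list(read_id = read_id, rejected = TRUE,
                reason = "read_too_short"))
  sc <- vapply(c("OT", "OB"), function(st)
    .gotoh_align(ref, sequence, st, params$match, params$mismatch,
                 params$gap_open, params$gap_ext, params$conv,
                 params$band, TRUE)$score, 0)
  strand <- if (sc[["OT"]] >= sc[["OB"]]) "OT" else "OB"
  al <- .gotoh_align(ref, sequence, strand, params$match, params$mismatch,
                     params$gap_open, params$gap_ext, params$conv,
                     params$band, FALSE)
  identity <- al$n_match / al$n_cols
  if (identity < params$min_identity)
    return(list(read_id = read_id, rejected = TRUE,
                reason = "low_alignment_identity", identity = identity,
                bs_strand = strand))
  structure(list(read_id = read_id, rejected = FALSE, bs_strand = strand,
                 score = al$score, ref_offset = al$ref_offset,
                 read_offset = al$read_offset, identity = identity),
            class = "aligned_molecule")
}

## map reference offset (0-based) -> read offset (0-based; NA if gap or
## uncovered) and insertion counts after each reference offset
.alignment_maps <- function(aligned, ref_len) {
  m <- rep(NA_integer_, ref_len)
  cov <- aligned$ref_offset >= 0 & aligned$read_offset >= 0
  m[aligned$ref_offset[cov] + 1L] <- aligned$read_offset[cov]
  ins <- integer(ref_len + 1L)  # insertions occurring before ref offset i
  gap <- which(aligned$ref_offset < 0)
  if (length(gap)) {
    ro <- aligned$ref_offset
    for (g in gap) {
      nxt <- g
      while (nxt <= length(ro) && ro[nxt] < 0) nxt <- nxt + 1L
      at <- if (nxt <= length(ro)) ro[nxt] + 1L else ref_len + 1L
      ins[at] <- ins[at] + 1L
    }
  }
  list(map = m, ins = ins)
}

#' Extract per-site conversion states and per-marker observations
#'
#' For each cytosine site covered on the read's informative strand (plus
#' strand for OT, minus for OB): read base C -> `unconverted`, T ->
#' `converted` on OT (G/A symmetrically on OB), anything else ->
#' `mismatch`.  Sites on the other strand are not observable from this read
#' and are omitted.  Substitution markers yield the observed read base;
#' indel markers are resolved by the gap pattern within a small window of the
#' marker (net length difference matching the alt allele -> `alt`, zero ->
#' `ref`, otherwise `missing`).  The under-conversion statistic
#' (`unconverted_cph_fraction`) is computed over all covered CpH sites of
#' the informative strand, using reference context.
#'
#' @param aligned `aligned_molecule` from [align_read()].
#' @param sequence the read sequence that was aligned.
#' @param amplicon amplicon bundle.
#' @return the molecule with `site_state` (named character vector),
#'   `marker_obs` (named character vector), `unconverted_cph_fraction`,
#'   `covered_cph` fields added.
#' @export
extract_states <- function(aligned, sequence, amplicon) {
  stopifnot(!isTRUE(aligned$rejected))
  sites <- amplicon$sites
  markers <- amplicon$markers
  start <- amplicon$reference$start_coord
  ref_len <- nchar(amplicon$reference$sequence)
  if (any(sites$coord < start | sites$coord > start + ref_len - 1L))
    stop("site outside amplicon")
  if (any(markers$coord < start | markers$coord > start + ref_len - 1L))
    stop("marker outside amplicon")
  mp <- .alignment_maps(aligned, ref_len)
  rch <- strsplit(sequence, "")[[1]]
  inf_strand <- if (aligned$bs_strand == "OT") "+" else "-"
  on <- sites$strand == inf_strand
  off <- sites$coord[on] - start
  rb <- rch[mp$map[off + 1L] + 1L]
  if (aligned$bs_strand == "OT") {
    st <- ifelse(is.na(rb), "missing",
          ifelse(rb == "C", "unconverted",
          ifelse(rb == "T", "converted", "mismatch")))
  } else {
    st <- ifelse(is.na(rb), "missing",
          ifelse(rb == "G", "unconverted",
          ifelse(rb == "A", "converted", "mismatch")))
  }
  names(st) <- sites$site_id[on]
  covered <- st != "missing"
  cph <- sites$context[on] == "CpH" & covered
  n_cph <- sum(cph)
  ucf <- if (n_cph > 0) sum(st[cph] == "unconverted") / n_cph else NA_real_
  ## markers
  obs <- character(nrow(markers))
  for (i in seq_len(nrow(markers))) {
    o <- markers$coord[i] - start
    L <- nchar(markers$ref_allele[i]); La <- nchar(markers$alt_allele[i])
    if (L == 1L && La == 1L) {
      b <- rch[mp$map[o + 1L] + 1L]
      obs[i] <- if (is.na(b)) "missing" else b
    } else {
      span <- (o + 1L):(o + L)
      covered_span <- !is.na(mp$map[span])
      if (!any(covered_span)) { obs[i] <- "missing"; next }
      n_read <- sum(covered_span)
      ## window of +/- several bases: a conversion-altered inserted base can
      ## merge into an adjacent match run and the affine aligner then floats
      ## the gap to the end of that run
      ins_near <- sum(mp$ins[pmax(1L, o - 5L):min(ref_len + 1L, o + L + 6L)])
      delta <- (n_read + ins_near) - L
      obs[i] <- if (delta == (La - L)) "alt"
                else if (delta == 0L) "ref" else "missing"
    }
  }
  names(obs) <- markers$marker_id
  aligned$site_state <- st
  aligned$marker_obs <- obs
  aligned$unconverted_cph_fraction <- ucf
  aligned$covered_cph <- n_cph
  aligned
}

#' Under-conversion filter
#'
#' A molecule is kept iff its unconverted CpH fraction is strictly below
#' the threshold (default 5%): genuinely methylated CpHs are rare, so a
#' high retained-CpH fraction marks a molecule that escaped conversion.
#' Molecules covering no CpH site are kept with a warning flag.
#'
#' @param aligned molecule with states extracted.
#' @param threshold maximum tolerated unconverted CpH fraction.
#' @return list `keep` (logical) and `flag` (`"no_cph_covered"` or NA).
#' @export
underconversion_filter <- function(aligned, threshold = 0.05) {
  if (is.na(aligned$unconverted_cph_fraction))
    return(list(keep = TRUE, flag = "no_cph_covered"))
  list(keep = aligned$unconverted_cph_fraction < threshold, flag = NA_character_)
}

#' Align and call a whole bin of reads
#'
#' Convenience driver: aligns every read, extracts states, applies the
#' under-conversion filter, and returns long-format call tables.
#'
#' @param reads data.frame `read_id`, `sequence` (trimmed inserts).
#' @param amplicon amplicon bundle.
#' @param params [align_params()].
#' @param underconversion_threshold see [underconversion_filter()].
#' @return list: `site_calls` (read_id, site_id, state), `marker_calls`
#'   (read_id, marker_id, obs), `read_info` (read_id, bs_strand, identity,
#'   unconverted_cph_fraction, kept, reason).
#' @export
align_bin <- function(reads, amplicon, params = align_params(),
                      underconversion_threshold = 0.05) {
  site_l <- list(); marker_l <- list(); info_l <- list()
  for (i in seq_len(nrow(reads))) {
    rid <- reads$read_id[i]
    al <- align_read(reads$sequence[i], amplicon, params, read_id = rid)
    if (isTRUE(al$rejected)) {
      info_l[[i]] <- data.frame(read_id = rid, bs_strand = NA_character_,
        identity = if (is.null(al$identity)) NA_real_ else al$identity,
        unconverted_cph_fraction = NA_real_, kept = FALSE,
        reason = al$reason)
      next
    }
    al <- extract_states(al, reads$sequence[i], amplicon)
    uc <- underconversion_filter(al, underconversion_threshold)
    info_l[[i]] <- data.frame(read_id = rid, bs_strand = al$bs_strand,
      identity = al$identity,
      unconverted_cph_fraction = al$unconverted_cph_fraction,
      kept = uc$keep,
      reason = if (uc$keep) NA_character_ else "under_conversion")
    if (uc$keep) {
      keep_sites <- al$site_state != "missing"
      site_l[[i]] <- data.frame(read_id = rid,
        site_id = names(al$site_state)[keep_sites],
        state = unname(al$site_state[keep_sites]))
      marker_l[[i]] <- data.frame(read_id = rid,
        marker_id = names(al$marker_obs),
        obs = unname(al$marker_obs),
        bs_strand = al$bs_strand)
    }
  }
  list(site_calls = do.call(rbind, site_l),
       marker_calls = do.call(rbind, marker_l),
       read_info = do.call(rbind, info_l))
}
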