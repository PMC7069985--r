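## Read preparation: exact dual-barcode demultiplexing, flank trimming, the
## Q30 read-quality filter, and within-sample deduplication.

.phred_vec <- function(quality) utf8ToInt(quality) - 33L

#' Read-level quality score
#'
#' The mean per-base error probability converted back to the Phred scale:
#' `-10 log10(mean(10^(-q/10)))`.  This is the natural read-level analog of
#' a circular-consensus read quality.
#'
#' @param quality Phred+33 quality string.
#' @return numeric scalar (Phred units).
#' @export
read_quality <- function(quality) {
  q <- .phred_vec(quality)
  -10 * log10(mean(10^(-q / 10)))
}

#' Demultiplex reads by exact dual-barcode match
#'
#' A read is assigned iff its forward barcode (read prefix) and reverse
#' barcode (read suffix) both match a catalog entry exactly -- no errors in
#' barcode sequences are allowed -- and the pair appears in the sample
#' sheet.  The combination space is `length(forward) x length(reverse)`.
#'
#' @param reads data.frame with `read_id`, `sequence`, `quality`.
#' @param forward_barcodes,reverse_barcodes character vectors of barcode
#'   sequences (pairwise distinct within each set).
#' @param sample_sheet data.frame `sample_id`, `fwd_barcode`, `rev_barcode`.
#' @return list with `bins` (named list: sample_id -> reads data.frame with
#'   barcodes trimmed off recorded separately), `unassigned` (reads with
#'   `reason`), and `counters`.
#' @export
demultiplex <- function(reads, forward_barcodes, reverse_barcodes,
                        sample_sheet) {
  if (anyDuplicated(forward_barcodes) || anyDuplicated(reverse_barcodes))
    stop("duplicate barcode within a set")
  if (length(unique(nchar(forward_barcodes))) > 1 ||
      length(unique(nchar(reverse_barcodes))) > 1)
    stop("barcodes within a set must share one length")
  key <- paste(sample_sheet$fwd_barcode, sample_sheet$rev_barcode)
  if (anyDuplicated(key)) stop("duplicate barcode pair in sample sheet")
  bins <- stats::setNames(vector("list", nrow(sample_sheet)),
                          sample_sheet$sample_id)
  n <- nrow(reads)
  if (n == 0) {
    empty <- reads
    bins[] <- list(empty)
    return(list(bins = bins,
                unassigned = cbind(reads, reason = character(0)),
                counters = c(input = 0L, assigned = 0L, unassigned = 0L)))
  }
  fl <- nchar(forward_barcodes[1]); rl <- nchar(reverse_barcodes[1])
  fwd_obs <- substr(reads$sequence, 1L, fl)
  len <- nchar(reads$sequence)
  rev_obs <- substr(reads$sequence, len - rl + 1L, len)
  f_ok <- fwd_obs %in% forward_barcodes
  r_ok <- rev_obs %in% reverse_barcodes
  pair <- paste(fwd_obs, rev_obs)
  samp <- sample_sheet$sample_id[match(pair, key)]
  assigned <- f_ok & r_ok & !is.na(samp) & len > fl + rl
  reason <- rep(NA_character_, n)
  reason[!f_ok] <- "forward_barcode_mismatch"
  reason[f_ok & !r_ok] <- "reverse_barcode_mismatch"
  reason[f_ok & r_ok & is.na(samp)] <- "pair_not_in_sample_sheet"
  reason[f_ok & r_ok & !is.na(samp) & len <= fl + rl] <- "read_too_short"
  for (sid in sample_sheet$sample_id) {
    sel <- assigned & samp == sid
    bins[[sid]] <- reads[which(sel), , drop = FALSE]
    rownames(bins[[sid]]) <- NULL
  }
  unassigned <- reads[!assigned, , drop = FALSE]
  unassigned$reason <- reason[!assigned]
  rownames(unassigned) <- NULL
  list(bins = bins, unassigned = unassigned,
       counters = c(input = n, assigned = sum(assigned),
                    unassigned = sum(!assigned)))
}

#' Trim flanking sequences and apply the read-quality filter
#'
#' Flanks (barcodes/adapters) found exactly at the read ends are removed;
#' the read is then rejected iff its read-level quality (see
#' [read_quality()]) is below `min_read_quality`.  A read of quality exactly
#' Q30 is kept ("no less than Q30").
#'
#' @param reads data.frame `read_id`, `sequence`, `quality`.
#' @param adapter_spec list with `fwd` and `rev` flanking sequences to
#'   remove (either may be "" for none).
#' @param min_read_quality Phred threshold (default 30).
#' @return list with `kept` (trimmed reads + `read_q`) and `rejected`
#'   (reads + `reason`).
#' @export
trim_and_filter <- function(reads, adapter_spec = list(fwd = "", rev = ""),
                            min_read_quality = 30) {
  n <- nrow(reads)
  fl <- nchar(adapter_spec$fwd); rl <- nchar(adapter_spec$rev)
  len <- nchar(reads$sequence)
  reason <- rep(NA_character_, n)
  too_short <- len <= fl + rl
  reason[too_short] <- "adapter_longer_than_read"
  seqs <- reads$sequence; quals <- reads$quality
  trim <- !too_short
  if (fl > 0) {
    has_f <- substr(seqs, 1, fl) == adapter_spec$fwd & trim
    seqs[has_f] <- substr(seqs[has_f], fl + 1L, len[has_f])
    quals[has_f] <- substr(quals[has_f], fl + 1L, len[has_f])
  }
  len2 <- nchar(seqs)
  if (rl > 0) {
    has_r <- trim & substr(seqs, len2 - rl + 1L, len2) == adapter_spec$rev
    seqs[has_r] <- substr(seqs[has_r], 1L, len2[has_r] - rl)
    quals[has_r] <- substr(quals[has_r], 1L, len2[has_r] - rl)
  }
  rq <- vapply(quals, read_quality, 0, USE.NAMES = FALSE)
  lowq <- !too_short & rq < min_read_quality
  reason[lowq] <- "below_min_read_quality"
  keep <- !too_short & !lowq
  kept <- reads[keep, , drop = FALSE]
  kept$sequence <- seqs[keep]
  kept$quality <- quals[keep]
  kept$read_q <- rq[keep]
  rejected <- reads[!keep, , drop = FALSE]
  rejected$reason <- reason[!keep]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Deduplicate a sample bin by exact insert sequence
#'
#' Within one sample, reads with byte-identical insert sequences collapse to
#' one representative: the highest read-level quality, ties broken by the
#' lexicographically smallest read id.  For fixed amplicons the insert
#' sequence is the natural duplicate key (there are no alignment
#' coordinates to distinguish molecules).
#'
#' @param bin data.frame of trimmed reads (`read_id`, `sequence`,
#'   `quality`, optionally `read_q`).
#' @return list with `unique` (surviving reads) and `removed` (count).
#' @export
deduplicate <- function(bin) {
  if (nrow(bin) == 0) return(list(unique = bin, removed = 0L))
  if (is.null(bin$read_q))
    bin$read_q <- vapply(bin$quality, read_quality, 0, USE.NAMES = FALSE)
  ord <- order(bin$sequence, -bin$read_q, bin$read_id)
  b <- bin[ord, , drop = FALSE]
  keep <- !duplicated(b$sequence)
  out <- b[keep, , drop = FALSE]
  out <- out[order(out$read_id), , drop = FALSE]
  rownames(out) <- NULL
  list(unique = out, removed = as.integer(sum(!keep)))
}
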