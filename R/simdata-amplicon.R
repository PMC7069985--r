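## Synthetic amplicon references, cytosine site catalogs, marker/haplotype
## catalogs.  An "amplicon bundle" is the genomic frame every read is
## interpreted against: reference sequence, per-strand cytosine sites with
## haplotype-resolved context, markers, and the haplotype catalog.

BASES <- c("A", "C", "G", "T")

## deterministic base stream independent of R's global RNG (used only for
## the packaged default amplicon, which must be bit-stable)
.lcg_bases <- function(n, seed) {
  m <- 2147483647; a <- 48271
  x <- as.numeric(seed %% m)
  u <- numeric(n)
  for (i in seq_len(n)) {
    x <- (a * x) %% m
    u[i] <- x / m
  }
  BASES[findInterval(u, c(0, 0.30, 0.50, 0.70, 1.0))]
}

comp_base <- function(b) chartr("ACGT", "TGCA", b)

revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}

#' Strand ambiguity of a marker under bisulfite conversion
#'
#' A substitution whose two alleles differ only by C vs T cannot be read on
#' the original-top (OT) strand: an observed T may be either the T allele or
#' a converted unmethylated C.  Symmetrically, alleles differing only by
#' G vs A are confounded on the original-bottom (OB) strand.
#'
#' @param ref_allele,alt_allele allele strings.
#' @return named logical vector `c(OT = , OB = )`.
#' @export
marker_strand_ambiguity <- function(ref_allele, alt_allele) {
  r <- strsplit(ref_allele, "")[[1]]
  a <- strsplit(alt_allele, "")[[1]]
  if (length(r) != length(a)) return(c(OT = FALSE, OB = FALSE))  # indel
  d <- which(r != a)
  pair <- function(x, y) paste(sort(c(x, y)), collapse = "")
  pairs <- vapply(d, function(i) pair(r[i], a[i]), "")
  c(OT = length(d) > 0 && all(pairs == "CT"),
    OB = length(d) > 0 && all(pairs == "AG"))
}

## context of the cytosine at 0-based offset `off` on `strand` in `seq_chars`
## (character vector); returns "CpG", "CpH", or "absent"
.site_context <- function(seq_chars, off, strand) {
  n <- length(seq_chars)
  if (strand == "+") {
    if (off < 0 || off >= n || seq_chars[off + 1] != "C") return("absent")
    nxt <- if (off + 2 <= n) seq_chars[off + 2] else ""
    if (identical(nxt, "G")) "CpG" else "CpH"
  } else {
    if (off < 0 || off >= n || seq_chars[off + 1] != "G") return("absent")
    prv <- if (off >= 1) seq_chars[off] else ""
    if (identical(prv, "C")) "CpG" else "CpH"
  }
}

#' Derive the cytosine site catalog of an amplicon reference
#'
#' Scans both strands: every C on the plus strand and every C on the minus
#' strand (a G in the plus-strand sequence) becomes a site.  Context is CpG
#' when the cytosine is followed by G on its own strand, CpH otherwise.
#' Site ids follow the `<context><serial>_<last5>` convention, e.g.
#' `CpG59_29024`: serial number within context along the amplicon plus the
#' last five digits of the genomic coordinate.
#'
#' @param sequence plus-strand reference sequence (A/C/G/T).
#' @param start_coord 1-based genomic coordinate of the first base.
#' @return data.frame with `site_id`, `coord`, `strand`, `context`.
#' @export
derive_sites <- function(sequence, start_coord) {
  ch <- strsplit(sequence, "")[[1]]
  rows <- list()
  for (off in seq_along(ch) - 1L) {
    if (ch[off + 1] == "C") {
      rows[[length(rows) + 1L]] <- list(coord = start_coord + off,
        strand = "+", context = .site_context(ch, off, "+"))
    } else if (ch[off + 1] == "G") {
      rows[[length(rows) + 1L]] <- list(coord = start_coord + off,
        strand = "-", context = .site_context(ch, off, "-"))
    }
  }
  df <- do.call(rbind, lapply(rows, as.data.frame))
  if (is.null(df)) {
    return(data.frame(site_id = character(), coord = integer(),
                      strand = character(), context = character()))
  }
  serial <- stats::ave(seq_len(nrow(df)), df$context, FUN = seq_along)
  df$site_id <- sprintf("%s%d_%05d", df$context, serial, df$coord %% 100000L)
  df[, c("site_id", "coord", "strand", "context")]
}

#' Build a haplotype catalog
#'
#' @param markers marker data.frame (`marker_id`, `coord`, `ref_allele`,
#'   `alt_allele`, `creates_cpg`).
#' @param haplotypes named list: haplotype name -> character vector of
#'   alleles, one per marker, each the marker's ref or alt allele.
#' @param risk_haplotype name of the risk haplotype.
#' @return object of class `haplotype_catalog`.
#' @export
haplotype_catalog <- function(markers, haplotypes, risk_haplotype) {
  stopifnot(is.data.frame(markers), nrow(markers) >= 1)
  if (anyDuplicated(names(haplotypes)))
    stop("haplotype names must be pairwise distinct")
  for (h in names(haplotypes)) {
    al <- haplotypes[[h]]
    if (length(al) != nrow(markers))
      stop("allele vector of ", h, " does not match marker count")
    ok <- al == markers$ref_allele | al == markers$alt_allele
    if (!all(ok))
      stop("haplotype ", h, " carries an allele that is neither ref nor alt",
           " at marker ", markers$marker_id[which(!ok)[1]])
  }
  if (!risk_haplotype %in% names(haplotypes))
    stop("risk haplotype not in catalog")
  structure(list(markers = markers, haplotypes = haplotypes,
                 risk_haplotype = risk_haplotype),
            class = "haplotype_catalog")
}

#' @export
print.haplotype_catalog <- function(x, ...) {
  cat("haplotype catalog:", length(x$haplotypes), "haplotypes over",
      nrow(x$markers), "markers; risk =", x$risk_haplotype, "\n")
  for (h in names(x$haplotypes))
    cat(" ", h, ":", paste(x$haplotypes[[h]], collapse = " "), "\n")
  invisible(x)
}

#' Apply a haplotype's alleles to the reference sequence
#'
#' Returns the haplotype template (plus-strand orientation) and a coordinate
#' map giving, for each template base, its 1-based genomic coordinate (NA
#' for inserted bases).
#'
#' @param amplicon amplicon bundle (see [make_amplicon()]).
#' @param haplotype haplotype name in the bundle's catalog.
#' @return list with `sequence` and `coord` (integer vector, NA = inserted).
#' @export
apply_haplotype <- function(amplicon, haplotype) {
  cat_ <- amplicon$catalog
  if (!haplotype %in% names(cat_$haplotypes))
    stop("unknown haplotype: ", haplotype)
  alleles <- cat_$haplotypes[[haplotype]]
  mk <- cat_$markers
  ord <- order(mk$coord)
  ref_ch <- strsplit(amplicon$reference$sequence, "")[[1]]
  coords <- seq.int(amplicon$reference$start_coord,
                    length.out = length(ref_ch))
  out_ch <- character(0); out_co <- integer(0)
  pos <- 1L  # 1-based index into ref_ch
  for (k in ord) {
    start <- mk$coord[k] - amplicon$reference$start_coord + 1L
    ref_a <- strsplit(mk$ref_allele[k], "")[[1]]
    if (start < pos) stop("overlapping markers at coord ", mk$coord[k])
    if (!identical(ref_ch[start:(start + length(ref_a) - 1L)], ref_a))
      stop("reference does not carry ref allele of ", mk$marker_id[k])
    if (start > pos) {
      out_ch <- c(out_ch, ref_ch[pos:(start - 1L)])
      out_co <- c(out_co, coords[pos:(start - 1L)])
    }
    al <- strsplit(alleles[k], "")[[1]]
    ref_len <- length(ref_a)
    ## map allele bases onto ref coordinates where they align from the left
    co <- rep(NA_integer_, length(al))
    nshare <- min(length(al), ref_len)
    co[seq_len(nshare)] <- coords[start:(start + nshare - 1L)]
    out_ch <- c(out_ch, al); out_co <- c(out_co, co)
    pos <- start + ref_len
  }
  if (pos <= length(ref_ch)) {
    out_ch <- c(out_ch, ref_ch[pos:length(ref_ch)])
    out_co <- c(out_co, coords[pos:length(ref_ch)])
  }
  list(sequence = paste(out_ch, collapse = ""), coord = out_co)
}

## per-haplotype context/maskability for every reference-derived site
.site_haplotype_table <- function(reference, sites, markers, catalog) {
  haps <- names(catalog$haplotypes)
  res <- list()
  for (h in haps) {
    tpl <- apply_haplotype(list(reference = reference, catalog = catalog), h)
    ch <- strsplit(tpl$sequence, "")[[1]]
    ctx <- character(nrow(sites)); mask <- logical(nrow(sites))
    for (i in seq_len(nrow(sites))) {
      ti <- match(sites$coord[i], tpl$coord)
      if (is.na(ti)) { ctx[i] <- "absent"; mask[i] <- TRUE; next }
      base_needed <- if (sites$strand[i] == "+") "C" else "G"
      if (ch[ti] != base_needed) { ctx[i] <- "absent"; mask[i] <- TRUE; next }
      ctx[i] <- if (sites$strand[i] == "+") {
        if (ti < length(ch) && ch[ti + 1] == "G") "CpG" else "CpH"
      } else {
        if (ti > 1 && ch[ti - 1] == "C") "CpG" else "CpH"
      }
      ## conversion-confounded marker sitting on the cytosine itself: the
      ## only informative strand cannot distinguish allele from conversion
      ov <- which(markers$coord == sites$coord[i] &
                  nchar(markers$ref_allele) == 1 &
                  nchar(markers$alt_allele) == 1)
      if (length(ov)) {
        amb <- marker_strand_ambiguity(markers$ref_allele[ov[1]],
                                       markers$alt_allele[ov[1]])
        mask[i] <- (sites$strand[i] == "+" && amb[["OT"]]) ||
                   (sites$strand[i] == "-" && amb[["OB"]])
      }
    }
    res[[h]] <- data.frame(site_id = sites$site_id, haplotype = h,
                           context = ctx, maskable = mask)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

.new_amplicon <- function(reference, markers, catalog) {
  stopifnot(nchar(reference$sequence) > 0,
            grepl("^[ACGT]+$", reference$sequence))
  reference$end_coord <- reference$start_coord +
    nchar(reference$sequence) - 1L
  if (anyDuplicated(markers$coord) > 0)
    stop("marker positions collide at coord ",
         markers$coord[anyDuplicated(markers$coord)])
  amb <- t(vapply(seq_len(nrow(markers)), function(i)
    marker_strand_ambiguity(markers$ref_allele[i], markers$alt_allele[i]),
    c(OT = FALSE, OB = FALSE)))
  markers$ot_ambiguous <- amb[, "OT"]
  markers$ob_ambiguous <- amb[, "OB"]
  sites <- derive_sites(reference$sequence, reference$start_coord)
  site_hap <- .site_haplotype_table(reference, sites, markers, catalog)
  structure(list(reference = reference, sites = sites, markers = markers,
                 catalog = catalog, site_haplotypes = site_hap),
            class = "haplometh_amplicon")
}

#' @export
print.haplometh_amplicon <- function(x, ...) {
  cat("amplicon", x$reference$amplicon_id, ":",
      sprintf("%s:%d-%d (%d bp),", x$reference$chrom,
              x$reference$start_coord, x$reference$end_coord,
              nchar(x$reference$sequence)),
      nrow(x$sites), "cytosine sites",
      sprintf("(%d CpG),", sum(x$sites$context == "CpG")),
      nrow(x$markers), "markers,",
      length(x$catalog$haplotypes), "haplotypes\n")
  invisible(x)
}

#' Generate a random synthetic amplicon with embedded markers
#'
#' Builds a random reference sequence of the requested length and CpG
#' density, embeds the requested markers (plain SNPs, indels, CpG-SNPs that
#' create or destroy a CpG), and derives a catalog of three haplotypes (all
#' reference alleles; a mixed haplotype; and a designated risk haplotype
#' carrying every alternative allele).  Uses R's global RNG; seed with
#' [set.seed()] for reproducibility.
#'
#' @param length amplicon length in bp (>= 200).
#' @param cpg_density target fraction of positions starting a CpG
#'   dinucleotide (approximate; default 0.03).
#' @param marker_plan named integer vector with any of `SNP`, `indel`,
#'   `CpG_SNP` giving marker counts; or a data.frame with columns `type`
#'   and optional `coord` for explicit placement.
#' @param amplicon_id,chrom,start_coord reference labels/frame.
#' @return amplicon bundle: list with `reference`, `sites`, `markers`,
#'   `catalog`, `site_haplotypes`.
#' @export
make_amplicon <- function(length, cpg_density = 0.03,
                          marker_plan = c(SNP = 2, indel = 1, CpG_SNP = 4),
                          amplicon_id = "sim_amplicon", chrom = "chr14",
                          start_coord = 104060000L) {
  if (length < 200) stop("length must be >= 200")
  if (is.data.frame(marker_plan)) {
    types <- marker_plan$type
    want_coord <- if ("coord" %in% names(marker_plan)) marker_plan$coord
                  else rep(NA_integer_, nrow(marker_plan))
  } else {
    types <- rep(names(marker_plan), marker_plan)
    want_coord <- rep(NA_integer_, length(types))
  }
  if (anyDuplicated(stats::na.omit(want_coord)) > 0)
    stop("marker positions collide at coord ",
         want_coord[anyDuplicated(want_coord)])
  ch <- sample(BASES, length, replace = TRUE, prob = c(.3, .2, .2, .3))
  ## plant CpGs to reach target density
  n_cpg <- max(0L, round(cpg_density * length))
  cand <- sample(seq_len(length - 1L))
  planted <- 0L
  for (p in cand) {
    if (planted >= n_cpg) break
    ch[p] <- "C"; ch[p + 1L] <- "G"; planted <- planted + 1L
  }
  ## spaced marker positions (keep 10 bp apart, away from the ends)
  n_mk <- length(types)
  pos <- want_coord - start_coord + 1L
  taken <- stats::na.omit(pos)
  for (i in seq_len(n_mk)) {
    if (!is.na(pos[i])) next
    repeat {
      p <- sample(seq(20L, length - 20L), 1L)
      if (!any(abs(p - taken) < 10)) { pos[i] <- p; taken <- c(taken, p); break }
    }
  }
  ref_a <- alt_a <- character(n_mk); creates <- logical(n_mk)
  for (i in seq_len(n_mk)) {
    p <- pos[i]
    if (types[i] %in% c("CpG_SNP", "CpG-SNP")) {
      ## alternate creating vs destroying CpGs
      if (i %% 2 == 0) {           # destroy: ref CpG, alt abolishes the G
        ch[p] <- "C"; ch[p + 1L] <- "G"
        pos[i] <- p + 1L; ref_a[i] <- "G"; alt_a[i] <- "A"
      } else {                     # create: ref CpH, alt G completes a CpG
        ch[p] <- "C"; ch[p + 1L] <- "A"
        pos[i] <- p + 1L; ref_a[i] <- "A"; alt_a[i] <- "G"
      }
      creates[i] <- ref_a[i] == "A"
    } else if (types[i] == "indel") {
      ref_a[i] <- ch[p]
      alt_a[i] <- paste0(ch[p], paste(sample(BASES, 2, TRUE), collapse = ""))
    } else {
      ref_a[i] <- ch[p]
      alt_a[i] <- sample(setdiff(BASES, ch[p]), 1L)
    }
  }
  ord <- order(pos)
  coords <- start_coord + pos[ord] - 1L
  markers <- data.frame(
    marker_id = sprintf("m%d_%05d", seq_len(n_mk), coords %% 100000L),
    coord = coords, ref_allele = ref_a[ord], alt_allele = alt_a[ord],
    creates_cpg = creates[ord])
  hap_ref <- markers$ref_allele
  hap_alt <- markers$alt_allele
  mixed <- hap_ref
  flip <- seq_len(max(1L, n_mk %/% 2L))
  mixed[flip] <- hap_alt[flip]
  allele_letter <- function(a, m) {
    ifelse(nchar(m$ref_allele) != nchar(m$alt_allele),
           ifelse(nchar(a) == pmin(nchar(m$ref_allele), nchar(m$alt_allele)),
                  "D", "I"),
           substr(a, 1, 1))
  }
  haps <- list(hap_ref, mixed, hap_alt)
  names(haps) <- vapply(haps, function(a)
    paste(allele_letter(a, markers), collapse = ""), "")
  if (anyDuplicated(names(haps)))  # mixed collapsed onto ref/alt: keep 2
    haps <- haps[!duplicated(names(haps))]
  catalog <- haplotype_catalog(markers, haps,
                               risk_haplotype = names(haps)[length(haps)])
  reference <- list(amplicon_id = amplicon_id, chrom = chrom,
                    start_coord = as.integer(start_coord),
                    sequence = paste(ch, collapse = ""))
  .new_amplicon(reference, markers, catalog)
}
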