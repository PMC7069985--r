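#' Genomic coordinate utilities
#'
#' Amplicon references carry 1-based inclusive genomic coordinates (the
#' convention of genome browsers and region strings such as
#' `"chr14:104,060,285-104,060,422"`), while internal amplicon offsets are
#' 0-based half-open. These helpers convert between the two and compute
#' inclusive span lengths.
#'
#' @param start,end 1-based inclusive genomic positions, `end >= start`.
#' @return `region_length()` returns the inclusive length in bp.
#' @examples
#' region_length(104060285, 104060422)  # 138
#' @export
region_length <- function(start, end) {
  stopifnot(is.numeric(start), is.numeric(end))
  if (any(end < start)) stop("end must be >= start")
  as.integer(end - start + 1L)
}

#' Parse a genome-browser style region string
#'
#' Accepts `"chr14:104,060,285-104,060,422"` with optional thousands
#' separators; the dash may be an ASCII hyphen or an en dash.
#'
#' @param x region string.
#' @return list with `chrom`, `start`, `end`, `length` (inclusive bp).
#' @export
parse_region <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x2 <- gsub(",", "", x, fixed = TRUE)
  x2 <- gsub("–", "-", x2)  # en dash
  m <- regmatches(x2, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x2))[[1]]
  if (length(m) != 4L) stop("cannot parse region string: ", x)
  start <- as.integer(m[3]); end <- as.integer(m[4])
  list(chrom = m[2], start = start, end = end,
       length = region_length(start, end))
}

#' @rdname region_length
#' @param genomic 1-based genomic position(s).
#' @param amp_start 1-based genomic position of the amplicon's first base.
#' @return `genomic_to_offset()` returns 0-based amplicon offsets;
#'   `offset_to_genomic()` the inverse.
#' @export
genomic_to_offset <- function(genomic, amp_start) {
  as.integer(genomic - amp_start)
}

#' @rdname region_length
#' @param offset 0-based amplicon offset(s).
#' @export
offset_to_genomic <- function(offset, amp_start) {
  as.integer(offset + amp_start)
}
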