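# Parsing and formatting of promoter identifiers in the FANTOM5 coordinate
# dialect "chr:start..end,strand". Coordinates are treated as 1-based
# inclusive and stored verbatim: the IDs are opaque keys and only round-trip
# fidelity matters.

#' Parse promoter identifiers
#'
#' Parses IDs of the form `"<chrom>:<start>..<end>,<strand>"` (e.g.
#' `"chr2:106015491..106015518,-"`) into their genomic components.
#'
#' @param ids character vector of promoter ID strings.
#' @return A data frame with columns `chrom` (character), `start`, `end`
#'   (integer, 1-based inclusive) and `strand` (`"+"` or `"-"`), one row per
#'   input, of class `genomic_promoter`.
#' @examples
#' parse_promoter_id("chr2:106015491..106015518,-")
#' @export
parse_promoter_id <- function(ids) {
  ids <- as.character(ids)
  if (length(ids) == 0L) stop("no promoter IDs supplied")
  m <- regexec("^([^:,[:space:]]+):([0-9]+)\\.\\.([0-9]+),(.+)$", ids)
  parts <- regmatches(ids, m)
  bad <- lengths(parts) != 5L
  if (any(bad))
    stop("malformed promoter ID (expected \"chrom:start..end,strand\"): '",
         ids[which(bad)[1L]], "'")
  chrom <- vapply(parts, `[`, "", 2L)
  start <- vapply(parts, `[`, "", 3L)
  end <- vapply(parts, `[`, "", 4L)
  strand <- vapply(parts, `[`, "", 5L)
  bad_strand <- !strand %in% c("+", "-")
  if (any(bad_strand))
    stop("invalid strand '", strand[which(bad_strand)[1L]], "' in promoter ID '",
         ids[which(bad_strand)[1L]], "'")
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start < 1))
    stop("start coordinate below 1 in promoter ID '",
         ids[which(start < 1)[1L]], "'")
  if (any(start > end))
    stop("start exceeds end in promoter ID '", ids[which(start > end)[1L]], "'")
  structure(
    data.frame(chrom = chrom, start = start, end = end, strand = strand,
               stringsAsFactors = FALSE),
    class = c("genomic_promoter", "data.frame")
  )
}

#' Format promoter components back into ID strings
#'
#' Inverse of [parse_promoter_id()]: `format_promoter_id(parse_promoter_id(s))`
#' reproduces `s` for any well-formed ID.
#'
#' @param x data frame with columns `chrom`, `start`, `end`, `strand`.
#' @return character vector of promoter IDs.
#' @export
format_promoter_id <- function(x) {
  stopifnot(all(c("chrom", "start", "end", "strand") %in% names(x)))
  sprintf("%s:%d..%d,%s", x$chrom, as.integer(x$start), as.integer(x$end),
          x$strand)
}
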