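#' @importFrom data.table data.table as.data.table setkey setkeyv setorder
#'   setorderv rbindlist copy fread fwrite shift setnames setDT := fifelse
#'   tstrsplit uniqueN setattr .I .N .SD
#' @importFrom stats median runif rbinom rbeta rlnorm setNames
#' @importFrom utils head tail packageVersion
NULL

# Internal coordinate convention: 0-based half-open ([start, end)), BED-style.
# GTF I/O converts from/to 1-based closed at the boundary. Strand is "+"/"-".

#' Construct a table of genomic intervals
#'
#' The coordinate atom used throughout the package for exons, Alu elements
#' and polyA sites. Coordinates are 0-based half-open; `start < end` and
#' strand must be `"+"` or `"-"`.
#'
#' @param chrom Character vector of sequence names.
#' @param start,end Integer vectors, 0-based half-open.
#' @param strand Character vector of `"+"`/`"-"`.
#' @param name Optional labels (e.g. Alu element names); recycled.
#'
#' @return A `data.table` with columns `chrom`, `start`, `end`, `strand`,
#'   `name`, one row per interval.
#' @export
#' @examples
#' genomic_intervals("chr1", 100, 200, "-", name = "AluSx")
genomic_intervals <- function(chrom, start, end, strand, name = NA_character_) {
  gi <- data.table(
    chrom = as.character(chrom),
    start = as.integer(start),
    end = as.integer(end),
    strand = as.character(strand),
    name = as.character(name)
  )
  validate_intervals(gi)
  gi
}

validate_intervals <- function(gi, what = "interval") {
  bad_coord <- which(!(gi$start >= 0L & gi$start < gi$end))
  if (length(bad_coord)) {
    stop(sprintf("invalid %s: need 0 <= start < end at row(s) %s",
                 what, paste(head(bad_coord, 5L), collapse = ", ")))
  }
  bad_strand <- which(!gi$strand %in% c("+", "-"))
  if (length(bad_strand)) {
    stop(sprintf("invalid %s strand (must be '+' or '-') at row(s) %s",
                 what, paste(head(bad_strand, 5L), collapse = ", ")))
  }
  invisible(gi)
}

#' Do two genomic intervals overlap?
#'
#' Vectorised over both arguments (standard recycling). Under the half-open
#' convention, intervals sharing only a boundary do not overlap.
#'
#' @param a,b Interval tables as returned by [genomic_intervals()].
#' @param require_same_strand If `TRUE`, intervals on opposite strands never
#'   overlap.
#'
#' @return Logical vector.
#' @export
overlaps <- function(a, b, require_same_strand = FALSE) {
  ok <- a$chrom == b$chrom &
    pmax(a$start, b$start) < pmin(a$end, b$end)
  if (require_same_strand) ok <- ok & a$strand == b$strand
  ok
}

#' Is a position downstream of a reference, in transcription direction?
#'
#' On the plus strand downstream means a larger genomic coordinate; on the
#' minus strand a smaller one. Equality is never downstream.
#'
#' @param point,reference Genomic positions (same chromosome assumed).
#' @param strand `"+"` or `"-"` (of the transcription unit).
#'
#' @return Logical vector.
#' @export
is_downstream <- function(point, reference, strand) {
  n <- max(length(point), length(reference), length(strand))
  plus <- rep_len(strand == "+", n)
  point <- rep_len(point, n)
  reference <- rep_len(reference, n)
  out <- logical(n)
  out[plus] <- point[plus] > reference[plus]
  out[!plus] <- point[!plus] < reference[!plus]
  out
}

#' Distance along the direction of transcription
#'
#' Absolute genomic separation in bp between a reference position (typically
#' the last genuine polyA cleavage position) and a downstream position
#' (typically the gene-proximal boundary of an intergenic Alu exon).
#' Errors if `to` is not strictly downstream of `from`.
#'
#' @param from,to Genomic positions; `to` must be downstream of `from`.
#' @param strand `"+"` or `"-"`.
#'
#' @return Non-negative integer vector of distances in bp.
#' @export
#' @examples
#' transcription_distance(5000, 8200, "+") # 3200
#' transcription_distance(5000, 4959, "-") # 41
transcription_distance <- function(from, to, strand) {
  down <- is_downstream(to, from, strand)
  if (!all(down)) {
    stop("transcription_distance: 'to' is not downstream of 'from' (strand ",
         paste(unique(strand[!down]), collapse = ","), ")")
  }
  as.integer(abs(to - from))
}

# Vectorised strand-wise selection (recycles all three arguments; unlike
# ifelse(), a scalar strand does not collapse vector values).
strand_select <- function(plus_val, minus_val, strand) {
  n <- max(length(plus_val), length(minus_val), length(strand))
  plus <- rep_len(strand == "+", n)
  plus_val <- rep_len(plus_val, n)
  minus_val <- rep_len(minus_val, n)
  out <- plus_val
  out[!plus] <- minus_val[!plus]
  out
}

# Strand-wise boundary helpers for an exon [start, end).
# The acceptor (3' splice site) boundary is the coordinate at which an
# intron gap abuts the first exonic base: `start` on "+", `end` on "-".
# The donor (5' splice site) boundary is the opposite edge.
acceptor_boundary <- function(start, end, strand) {
  strand_select(start, end, strand)
}

donor_boundary <- function(start, end, strand) {
  strand_select(end, start, strand)
}

# Position of the first exonic base of an exon (transcription direction);
# used when asking whether a splice site lies inside an Alu element.
acceptor_base <- function(start, end, strand) {
  strand_select(start, end - 1L, strand)
}

donor_base <- function(start, end, strand) {
  strand_select(end - 1L, start, strand)
}

# Strand-wise 3'-most base of an interval [start, end): the cleavage
# position used for polyA sites given as wider intervals.
three_prime_base <- function(start, end, strand) {
  as.integer(strand_select(end - 1L, start, strand))
}

point_in_intervals <- function(chrom, pos, ivs, strand = NULL,
                               antisense_to = NULL) {
  # returns index of first containing interval in `ivs`, NA if none
  vapply(seq_along(pos), function(i) {
    hit <- ivs$chrom == chrom[i] & ivs$start <= pos[i] & ivs$end > pos[i]
    if (!is.null(strand)) hit <- hit & ivs$strand == strand[i]
    if (!is.null(antisense_to)) hit <- hit & ivs$strand != antisense_to[i]
    w <- which(hit)
    if (length(w)) w[1L] else NA_integer_
  }, integer(1L))
}
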