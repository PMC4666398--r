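#' Aggregate splice junctions from aligned reads
#'
#' Each gap between consecutive blocks of a read is one junction
#' observation; junctions are keyed by their exact genomic gap
#' (chromosome, 0-based gap start, exclusive gap end) and counted across
#' reads. Read strand is not part of the key: junction assignment to genes
#' is done in genomic coordinates, so unstranded libraries are supported.
#'
#' @param reads An `aligned_reads` object.
#'
#' @return A `data.table` with columns `chrom`, `start`, `end` (the
#'   intronic gap, half-open) and `read_count`.
#' @export
aggregate_junctions <- function(reads) {
  blk <- reads$blocks
  if (!nrow(blk)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), read_count = integer()))
  }
  blk <- blk[order(read_id, start)]
  same <- blk$read_id == shift(blk$read_id, type = "lead")
  same[is.na(same)] <- FALSE
  gaps <- data.table(chrom = blk$chrom[same],
                     start = blk$end[same],
                     end = shift(blk$start, type = "lead")[same])
  if (!nrow(gaps)) {
    return(data.table(chrom = character(), start = integer(),
                      end = integer(), read_count = integer()))
  }
  jx <- gaps[, .(read_count = .N), by = .(chrom, start, end)]
  setorder(jx, chrom, start, end)
  jx[]
}

# per-read gap table (junction observations with read identity), used
# where individual junction-spanning reads must be counted once
read_gaps <- function(blocks) {
  blk <- blocks[order(read_id, start)]
  same <- blk$read_id == shift(blk$read_id, type = "lead")
  same[is.na(same)] <- FALSE
  data.table(read_id = blk$read_id[same], chrom = blk$chrom[same],
             start = blk$end[same],
             end = shift(blk$start, type = "lead")[same])
}

#' Call candidate Alu exons from predicted exons
#'
#' A predicted exon becomes a candidate Alu exon when (i) its 3' splice
#' site (acceptor) or 5' splice site (donor) lies inside an Alu element
#' annotated antisense to the exon strand, (ii) that splice site coincides
#' exactly with a junction boundary carrying at least `min_junction_reads`
#' junction-spanning reads, and (iii) no other predicted exon overlaps it
#' on the same strand (predicted exons with identical coordinates are
#' collapsed first, so duplicates do not make a candidate ambiguous).
#' Failing exons are retained with the failing criterion recorded.
#'
#' @param predicted_exons Interval table (e.g. from
#'   [read_bed()]`(kind = "exon")`).
#' @param alu_elements Alu interval table with strand (RepeatMasker-style).
#' @param junctions Junction table from [aggregate_junctions()].
#' @param min_junction_reads Minimum junction read support for a splice
#'   site; default 1.
#' @param fuzz Matching window (bp) between splice site and junction
#'   boundary; default 0 (exact coordinate equality).
#'
#' @return A `data.table` of candidates, one row per collapsed predicted
#'   exon, with columns `chrom`, `start`, `end`, `strand`, `alu_element`,
#'   `alu_start`, `alu_end`, `acceptor_in_alu`, `donor_in_alu`,
#'   `acceptor_reads`, `donor_reads`, `ambiguous`, `pass`, `fail_reason`.
#' @export
call_alu_exons <- function(predicted_exons, alu_elements, junctions,
                           min_junction_reads = 1L, fuzz = 0L) {
  pe <- unique(as.data.table(predicted_exons)[, .(chrom, start, end, strand)])
  setorder(pe, chrom, start, end, strand)
  if (!nrow(pe)) return(empty_candidates())
  alu <- as.data.table(alu_elements)
  jx <- as.data.table(junctions)

  acc_base <- acceptor_base(pe$start, pe$end, pe$strand)
  don_base <- donor_base(pe$start, pe$end, pe$strand)
  acc_alu <- point_in_intervals(pe$chrom, acc_base, alu,
                                antisense_to = pe$strand)
  don_alu <- point_in_intervals(pe$chrom, don_base, alu,
                                antisense_to = pe$strand)
  acc_b <- acceptor_boundary(pe$start, pe$end, pe$strand)
  don_b <- donor_boundary(pe$start, pe$end, pe$strand)
  acc_reads <- junction_support(jx, pe$chrom, acc_b, pe$strand,
                                side = "acceptor", fuzz = fuzz)
  don_reads <- junction_support(jx, pe$chrom, don_b, pe$strand,
                                side = "donor", fuzz = fuzz)
  ambiguous <- vapply(seq_len(nrow(pe)), function(i) {
    any(pe$chrom == pe$chrom[i] & pe$strand == pe$strand[i] &
          pmax(pe$start, pe$start[i]) < pmin(pe$end, pe$end[i]) &
          !(pe$start == pe$start[i] & pe$end == pe$end[i]))
  }, logical(1L))

  cand <- data.table(
    chrom = pe$chrom, start = pe$start, end = pe$end, strand = pe$strand,
    alu_element = ifelse(!is.na(acc_alu), alu$name[acc_alu],
                         ifelse(!is.na(don_alu), alu$name[don_alu],
                                NA_character_)),
    alu_start = ifelse(!is.na(acc_alu), alu$start[acc_alu],
                       ifelse(!is.na(don_alu), alu$start[don_alu],
                              NA_integer_)),
    alu_end = ifelse(!is.na(acc_alu), alu$end[acc_alu],
                     ifelse(!is.na(don_alu), alu$end[don_alu], NA_integer_)),
    acceptor_in_alu = !is.na(acc_alu) & acc_reads >= min_junction_reads,
    donor_in_alu = !is.na(don_alu) & don_reads >= min_junction_reads,
    acceptor_reads = acc_reads, donor_reads = don_reads,
    ambiguous = ambiguous)
  cand[, pass := (acceptor_in_alu | donor_in_alu) & !ambiguous]
  cand[, fail_reason := fifelse(
    pass, NA_character_,
    fifelse(ambiguous, "overlapping_predicted_exon",
            fifelse(is.na(alu_element), "no_splice_site_in_alu",
                    "no_junction_support")))]
  cand[]
}

empty_candidates <- function() {
  data.table(chrom = character(), start = integer(), end = integer(),
             strand = character(), alu_element = character(),
             alu_start = integer(), alu_end = integer(),
             acceptor_in_alu = logical(), donor_in_alu = logical(),
             acceptor_reads = integer(), donor_reads = integer(),
             ambiguous = logical(), pass = logical(),
             fail_reason = character())
}

# Junction read support at an exon boundary. An acceptor boundary is
# matched by junction gaps *ending* at it ("+" strand exons) or *starting*
# at it ("-" strand exons); donors are the mirror image.
junction_support <- function(jx, chrom, boundary, strand,
                             side = c("acceptor", "donor"), fuzz = 0L) {
  side <- match.arg(side)
  if (!nrow(jx)) return(rep(0L, length(boundary)))
  vapply(seq_along(boundary), function(i) {
    edge <- if ((side == "acceptor") == (strand[i] == "+")) jx$end else
      jx$start
    hit <- jx$chrom == chrom[i] & abs(edge - boundary[i]) <= fuzz
    if (any(hit)) sum(jx$read_count[hit]) else 0L
  }, integer(1L))
}
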