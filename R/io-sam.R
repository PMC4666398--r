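# SAM subset reader. The analysis only needs block geometry and strand of
# single-end split alignments, so the dialect is deliberately narrow:
# M runs become aligned blocks, N runs become splice-junction gaps, S runs
# are trimmed (they consume read bases only), and any other CIGAR operation
# rejects the record with a warning. FLAG bit 0x4 skips the record
# (unmapped); bit 0x10 sets the minus strand. Mate and quality fields are
# ignored.

#' Read split alignments from a SAM file
#'
#' Parses mapped single-end records into an `aligned_reads` container:
#' a table with one row per aligned block, where gaps between consecutive
#' blocks of one read are splice junctions. Records with CIGAR operations
#' other than M/N/S are rejected with a warning; the whole file errors only
#' if more than half of its records fail.
#'
#' @param path Path to a SAM file (header optional).
#'
#' @return An `aligned_reads` object: a list with element `blocks`, a
#'   `data.table` with columns `read_id`, `chrom`, `strand`, `start`, `end`
#'   (0-based half-open), `bidx` (block index within read), and `n_reads`.
#' @export
read_sam <- function(path) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines)) return(aligned_reads(empty_blocks()))
  fld <- data.table::tstrsplit(lines, "\t", fixed = TRUE, keep = 1:6)
  rec <- data.table(
    qname = fld[[1]], flag = suppressWarnings(as.integer(fld[[2]])),
    chrom = fld[[3]], pos = suppressWarnings(as.integer(fld[[4]])),
    cigar = fld[[6]]
  )
  n_total <- nrow(rec)
  malformed <- is.na(rec$flag) | is.na(rec$pos) | rec$pos < 1L |
    is.na(rec$cigar) | !grepl("^([0-9]+[MIDNSHP=X])+$|^\\*$", rec$cigar)
  if (any(malformed)) {
    warning(sum(malformed), " malformed SAM record(s) skipped")
  }
  rec <- rec[!malformed]
  # unmapped records are silently skipped; non-M/N/S ops reject the record
  rec <- rec[bitwAnd(rec$flag, 4L) == 0L & rec$cigar != "*"]
  unsupported <- grepl("[IDHP=X]", rec$cigar)
  if (any(unsupported)) {
    warning(sum(unsupported),
            " SAM record(s) with unsupported CIGAR operations rejected")
  }
  rec <- rec[!unsupported]
  if (n_total > 0L && (sum(malformed) + sum(unsupported)) > n_total / 2) {
    stop("more than 50% of SAM records failed to parse: ", path)
  }
  if (!nrow(rec)) return(aligned_reads(empty_blocks()))
  rec[, read_id := .I]
  rec[, strand := ifelse(bitwAnd(flag, 16L) != 0L, "-", "+")]

  ops_m <- gregexpr("[0-9]+[MNS]", rec$cigar)
  ops <- regmatches(rec$cigar, ops_m)
  n_ops <- lengths(ops)
  op_dt <- data.table(
    read_id = rep(rec$read_id, n_ops),
    tok = unlist(ops, use.names = FALSE)
  )
  op_dt[, op := substring(tok, nchar(tok), nchar(tok))]
  op_dt[, len := as.integer(substring(tok, 1L, nchar(tok) - 1L))]
  op_dt[, reflen := ifelse(op == "S", 0L, len)]
  op_dt[, ref_off := cumsum(reflen) - reflen, by = read_id]
  blk <- op_dt[op == "M"]
  blk <- merge(blk, rec[, .(read_id, chrom, strand, pos)], by = "read_id")
  blk[, start := pos - 1L + ref_off]
  blk[, end := start + len]
  setorder(blk, read_id, start)
  blk[, bidx := seq_len(.N), by = read_id]
  aligned_reads(blk[, .(read_id, chrom, strand, start, end, bidx)])
}

empty_blocks <- function() {
  data.table(read_id = integer(), chrom = character(), strand = character(),
             start = integer(), end = integer(), bidx = integer())
}

#' Aligned-read container
#'
#' Wraps a per-block table into an `aligned_reads` object. Blocks of one
#' read must share chromosome and strand, be sorted by genomic start, and
#' consecutive blocks must be separated by a gap of at least 1 bp (the
#' splice junction).
#'
#' @param blocks A `data.table` with columns `read_id`, `chrom`, `strand`,
#'   `start`, `end`, `bidx`.
#'
#' @return An object of class `aligned_reads`.
#' @export
aligned_reads <- function(blocks) {
  blocks <- as.data.table(blocks)
  if (nrow(blocks)) {
    validate_intervals(blocks, what = "read block")
    setorder(blocks, read_id, start)
    blocks[, bidx := seq_len(.N), by = read_id]
    same <- blocks$read_id == shift(blocks$read_id)
    if (any(same & shift(blocks$end) >= blocks$start, na.rm = TRUE)) {
      stop("read blocks overlap or abut without a gap")
    }
  }
  structure(list(blocks = blocks,
                 n_reads = data.table::uniqueN(blocks$read_id)),
            class = "aligned_reads")
}

#' @export
print.aligned_reads <- function(x, ...) {
  cat("aligned_reads:", x$n_reads, "reads,", nrow(x$blocks), "blocks\n")
  invisible(x)
}

#' Write aligned reads as SAM
#'
#' Emits a minimal single-end SAM file: `@SQ` header lines for every
#' chromosome, `@CO` metadata comments, and one record per read with a
#' CIGAR built from its blocks (M runs separated by N gaps). Sequence and
#' quality fields are written as `*`; the strand sets FLAG bit 0x10.
#'
#' @param reads An `aligned_reads` object.
#' @param path Output path.
#' @param seq_lengths Optional named vector of chromosome lengths for the
#'   `@SQ` header; inferred from block extents when missing.
#' @param comments Character vector of metadata strings written as `@CO`
#'   header lines.
#'
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, seq_lengths = NULL, comments = character()) {
  blk <- copy(reads$blocks)
  if (is.null(seq_lengths)) {
    sl <- blk[, .(len = max(end) + 1000L), by = chrom]
    seq_lengths <- setNames(sl$len, sl$chrom)
  }
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seq_lengths),
                   as.integer(seq_lengths)),
           if (length(comments)) paste0("@CO\t", comments))
  if (!nrow(blk)) {
    writeLines(hdr, path)
    return(invisible(path))
  }
  setorder(blk, read_id, start)
  # vectorised CIGAR assembly: per-block "lenM[gapN]" tokens pasted
  # column-wise over the (small) maximum block count
  blk[, nxt_gap := shift(start, type = "lead") - end]
  blk[, last_in_read := bidx == max(bidx), by = read_id]
  blk[, tok := paste0(end - start, "M",
                      fifelse(last_in_read, "", paste0(nxt_gap, "N")))]
  wide <- data.table::dcast(blk, read_id ~ bidx, value.var = "tok",
                            fill = "")
  tok_cols <- setdiff(names(wide), "read_id")
  cigar <- do.call(paste0, wide[, tok_cols, with = FALSE])
  seg <- blk[bidx == 1L, .(read_id, chrom, strand, pos = start + 1L)]
  setorder(seg, read_id)
  seg[, cigar := cigar[match(read_id, wide$read_id)]]
  recs <- sprintf("r%06d\t%d\t%s\t%d\t255\t%s\t*\t0\t0\t*\t*",
                  seg$read_id, ifelse(seg$strand == "-", 16L, 0L),
                  seg$chrom, seg$pos, seg$cigar)
  writeLines(c(hdr, recs), path)
  invisible(path)
}
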