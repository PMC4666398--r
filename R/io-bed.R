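#' Read a BED6 file of genomic intervals
#'
#' Strict BED6 reader for the repeat-element, polyA-site and predicted-exon
#' tracks. Lines starting with `#`, `track` or `browser` are skipped.
#' Coordinate or strand violations are reported with their line number.
#'
#' @param path Path to a BED6 file.
#' @param kind One of `"alu"`, `"polya"`, `"exon"`; sets the label
#'   namespace recorded in the result (attribute `kind`).
#'
#' @return A `data.table` of validated intervals with columns `chrom`,
#'   `start`, `end`, `name`, `score`, `strand`. PolyA intervals wider than
#'   1 bp are kept as given; their cleavage position is resolved strand-wise
#'   downstream (see [classify_locus()]).
#' @export
read_bed <- function(path, kind = c("exon", "alu", "polya")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  keep <- !(startsWith(lines, "#") | startsWith(lines, "track") |
              startsWith(lines, "browser") | lines == "")
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.table(chrom = character(), start = integer(),
                      end = integer(), name = character(),
                      score = numeric(), strand = character())
  if (!length(lines)) {
    data.table::setattr(empty, "kind", kind)
    return(empty)
  }
  fld <- data.table::tstrsplit(lines, "\t", fixed = TRUE)
  if (length(fld) < 6L) stop("BED6 requires 6 columns: ", path)
  bed <- data.table(
    chrom = fld[[1]],
    start = suppressWarnings(as.integer(fld[[2]])),
    end = suppressWarnings(as.integer(fld[[3]])),
    name = fld[[4]],
    score = suppressWarnings(as.numeric(fld[[5]])),
    strand = fld[[6]]
  )
  bad <- which(is.na(bed$start) | is.na(bed$end) | bed$start < 0L |
                 bed$start >= bed$end | !bed$strand %in% c("+", "-"))
  if (length(bad)) {
    stop(sprintf("invalid BED record(s) in %s at line(s): %s", path,
                 paste(head(lineno[bad], 5L), collapse = ", ")))
  }
  data.table::setattr(bed, "kind", kind)
  bed
}

#' Write intervals as BED6
#'
#' @param x Table with columns `chrom`, `start`, `end`, `name`, `strand`
#'   (and optionally `score`, default 0).
#' @param path Output path.
#' @param comments Character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path, comments = character()) {
  x <- as.data.table(x)
  score <- if ("score" %in% names(x)) x$score else 0
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s", x$chrom, as.integer(x$start),
                   as.integer(x$end), as.character(x$name), score, x$strand)
  writeLines(c(if (length(comments)) paste0("# ", comments), lines), path)
  invisible(path)
}
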