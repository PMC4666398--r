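CALL_COLUMNS <- c(
  "call_id", "gene_id", "chrom", "start", "end", "strand", "alu_element",
  "locus_class", "scenario", "distance_bp", "splicing_contribution",
  "junction_reads", "continuous_reads", "downstream_cryptic_exons",
  "link_hops", "cryptic_donor")

#' Write finalized Alu exon calls as TSV and BED
#'
#' One TSV row per call in a stable, documented column order (the fixed
#' columns above, then any `inclusion_*` columns in alphabetical order),
#' plus a BED6 file of the Alu exon intervals. Rows are ordered by
#' chromosome, start and call id, so re-running on identical input yields
#' byte-identical files.
#'
#' @param calls Call table from [classify_calls()].
#' @param path Output TSV path; the BED is written next to it with
#'   extension `.bed`.
#' @param comments Character vector written as leading `#` lines in both
#'   files.
#'
#' @return Named character vector of the two paths, invisibly.
#' @export
write_calls <- function(calls, path, comments = character()) {
  calls <- as.data.table(calls)
  inc_cols <- sort(grep("^inclusion_", names(calls), value = TRUE))
  cols <- c(CALL_COLUMNS, inc_cols)
  for (cn in setdiff(cols, names(calls))) calls[[cn]] <- NA
  out <- calls[, cols, with = FALSE]
  if (nrow(out)) setorder(out, chrom, start, call_id)
  con <- file(path, "w")
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(cols, collapse = "\t"), con)
  if (nrow(out)) {
    body <- do.call(paste, c(lapply(out, format_tsv_field), sep = "\t"))
    writeLines(body, con)
  }
  close(con)
  bed_path <- sub("\\.tsv$", ".bed", path)
  if (bed_path == path) bed_path <- paste0(path, ".bed")
  bed <- if (nrow(out)) {
    out[, .(chrom, start, end, name = call_id, score = 0, strand)]
  } else {
    data.table(chrom = character(), start = integer(), end = integer(),
               name = character(), score = numeric(), strand = character())
  }
  write_bed(bed, bed_path, comments = comments)
  invisible(c(tsv = path, bed = bed_path))
}

format_tsv_field <- function(x) {
  if (is.double(x)) {
    ifelse(is.na(x), "NA", formatC(x, digits = 6, format = "g"))
  } else {
    ifelse(is.na(x), "NA", as.character(x))
  }
}

#' Read a calls TSV written by [write_calls()]
#' @param path Path to the TSV.
#' @return A `data.table`.
#' @export
read_calls <- function(path) {
  lines <- readLines(path)
  skip <- sum(cumprod(startsWith(lines, "# ")))
  fread(path, sep = "\t", skip = skip, header = TRUE, na.strings = "NA")
}
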