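# Tissue-wise relative abundance of Alu-exon-containing isoforms from
# per-isoform FPKM tables (Cufflinks-style output, one column per tissue).

#' Build an isoform abundance matrix
#'
#' @param x `data.frame`/`data.table` with columns `gene_id`, `isoform_id`,
#'   `contains_alu_exon` (logical) and one numeric FPKM column per tissue.
#'
#' @return An `isoform_abundance` object (validated `data.table` plus the
#'   tissue column names as attribute `tissues`).
#' @export
isoform_abundance <- function(x) {
  x <- as.data.table(x)
  req <- c("gene_id", "isoform_id", "contains_alu_exon")
  if (!all(req %in% names(x))) {
    stop("missing required column(s): ",
         paste(setdiff(req, names(x)), collapse = ", "))
  }
  tissues <- setdiff(names(x), req)
  if (!length(tissues)) stop("no tissue columns")
  for (tc in tissues) {
    v <- x[[tc]]
    if (!is.numeric(v) || anyNA(v) || any(v < 0)) {
      stop("FPKM column '", tc, "' must be non-negative numeric")
    }
  }
  if (anyNA(x$contains_alu_exon)) {
    stop("contains_alu_exon must be defined for every isoform")
  }
  x$contains_alu_exon <- as.logical(x$contains_alu_exon)
  data.table::setattr(x, "tissues", tissues)
  data.table::setattr(x, "class", c("isoform_abundance", class(x)))
  x
}

#' Read an FPKM table
#' @param path TSV with columns `gene_id`, `isoform_id`,
#'   `contains_alu_exon`, one column per tissue. Leading `#` lines are
#'   skipped.
#' @return An `isoform_abundance` object.
#' @export
read_fpkm <- function(path) {
  lines <- readLines(path, n = 50L)
  skip <- sum(cumprod(startsWith(lines, "# ")))
  isoform_abundance(fread(path, sep = "\t", skip = skip, header = TRUE))
}

#' Relative abundance of the Alu-exon-containing isoforms of a gene
#'
#' Sum of FPKM over the `contains_alu_exon` isoforms divided by the sum
#' over all isoforms of the gene in the given tissue; `NA` when the gene is
#' silent there (denominator 0).
#'
#' @param mat An [isoform_abundance()] object.
#' @param gene_id,tissue Gene and tissue to query (errors if unknown).
#'
#' @return A fraction in \[0, 1\], or `NA_real_`.
#' @export
relative_abundance <- function(mat, gene_id, tissue) {
  sel <- which(mat$gene_id == gene_id)  # plain vector scan, no NSE capture
  g <- mat[sel]
  if (!nrow(g)) stop("unknown gene: ", gene_id)
  if (!tissue %in% attr(mat, "tissues")) stop("unknown tissue: ", tissue)
  total <- sum(g[[tissue]])
  if (total == 0) return(NA_real_)
  sum(g[[tissue]][g$contains_alu_exon]) / total
}

#' log2 expression with a pseudocount of 1
#'
#' @param fpkm Non-negative FPKM values.
#' @return `log2(fpkm + 1)`.
#' @export
log_expression <- function(fpkm) {
  if (any(fpkm < 0, na.rm = TRUE)) stop("FPKM must be non-negative")
  log2(fpkm + 1)
}

#' Two-group isoform summary per tissue
#'
#' Groups a gene's isoforms into Alu-exon-containing versus all others and
#' reports each group's fraction of total FPKM per tissue. Fractions sum
#' to 1 wherever the gene is expressed; silent tissues are `NA`. A
#' tissue-specificity flag is set when the spread (max minus min) of the
#' Alu-group fraction across defined tissues exceeds `spread_threshold`.
#'
#' @param mat An [isoform_abundance()] object.
#' @param gene_id Gene to summarise (errors if unknown).
#' @param spread_threshold Relative-abundance spread above which the gene
#'   is flagged tissue-specific; default 0.10.
#'
#' @return List with `by_tissue` (`data.table`: `tissue`, `alu_fraction`,
#'   `other_fraction`) and `tissue_specific` (logical; `NA` if fewer than
#'   two defined tissues).
#' @export
group_isoforms <- function(mat, gene_id, spread_threshold = 0.10) {
  sel <- which(mat$gene_id == gene_id)
  g <- mat[sel]
  if (!nrow(g)) stop("unknown gene: ", gene_id)
  tissues <- attr(mat, "tissues")
  alu_fraction <- vapply(tissues, function(tc) {
    total <- sum(g[[tc]])
    if (total == 0) NA_real_ else sum(g[[tc]][g$contains_alu_exon]) / total
  }, numeric(1L))
  by_tissue <- data.table(tissue = tissues, alu_fraction = alu_fraction,
                          other_fraction = 1 - alu_fraction)
  def <- alu_fraction[!is.na(alu_fraction)]
  tissue_specific <- if (length(def) < 2L) NA else
    (max(def) - min(def)) > spread_threshold
  list(by_tissue = by_tissue, tissue_specific = tissue_specific)
}

#' Relative-abundance report for every gene
#'
#' @param mat An [isoform_abundance()] object.
#' @param spread_threshold Passed to [group_isoforms()].
#' @return Long-format `data.table`: `gene_id`, `tissue`, `alu_fraction`,
#'   `other_fraction`, `tissue_specific`.
#' @export
abundance_report <- function(mat, spread_threshold = 0.10) {
  rbindlist(lapply(unique(mat$gene_id), function(g) {
    gs <- group_isoforms(mat, g, spread_threshold)
    cbind(data.table(gene_id = g), gs$by_tissue,
          tissue_specific = gs$tissue_specific)
  }))
}
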