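# Gene/transcript models. A gene_models object keeps a flat exon table
# (internal 0-based half-open coordinates) plus a per-gene summary, and —
# once assign_polya() has run — the genuine polyA cleavage positions of
# each gene. "Terminal exon" always means the strand-wise last exon.

#' Build a gene-model container from an exon table
#'
#' @param exons `data.table` with columns `gene_id`, `transcript_id`,
#'   `chrom`, `strand`, `start`, `end` (0-based half-open). Exons are
#'   sorted into transcription order per transcript.
#'
#' @return A `gene_models` object: list with `exons` (plus `exon_rank`),
#'   `genes` (gene spans) and `polya` (empty until [assign_polya()]).
#' @export
gene_models <- function(exons) {
  exons <- as.data.table(exons)
  if (nrow(exons)) {
    validate_intervals(exons, what = "exon")
    setorder(exons, gene_id, transcript_id, start)
    exons[, exon_rank := if (strand[1L] == "+") seq_len(.N) else rev(seq_len(.N)),
          by = transcript_id]
    setorder(exons, gene_id, transcript_id, exon_rank)
  } else {
    exons[, exon_rank := integer()]
  }
  genes <- exons[, .(chrom = chrom[1L], strand = strand[1L],
                     span_start = min(start), span_end = max(end)),
                 by = gene_id]
  structure(list(exons = exons, genes = genes,
                 polya = data.table(gene_id = character(), pos = integer())),
            class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("gene_models:", nrow(x$genes), "genes,",
      data.table::uniqueN(x$exons$transcript_id), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read gene models from a GTF file
#'
#' Imports `exon` features (via \pkg{rtracklayer}), requiring `gene_id` and
#' `transcript_id` attributes, and converts 1-based closed GTF coordinates
#' to the internal 0-based half-open convention.
#'
#' @param path Path to a GTF file.
#' @return A `gene_models` object.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) return(gene_models(data.table(
    gene_id = character(), transcript_id = character(), chrom = character(),
    strand = character(), start = integer(), end = integer())))
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid)) {
    stop("GTF exon feature(s) without transcript_id: ", path)
  }
  exons <- data.table(
    gene_id = as.character(gr$gene_id),
    transcript_id = as.character(tid),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr)
  )
  if (any(!exons$strand %in% c("+", "-"))) {
    stop("GTF exon(s) without '+'/'-' strand: ", path)
  }
  gene_models(exons)
}

#' Write gene models as GTF
#'
#' Emits one `exon` feature per exon row, converting back to 1-based closed
#' coordinates, so that a read/write round trip preserves coordinates
#' exactly.
#'
#' @param gm A `gene_models` object.
#' @param path Output path.
#' @param source Value for the GTF source column.
#' @param comments Character vector written as leading `#` lines.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(gm, path, source = "aluexon", comments = character()) {
  ex <- copy(gm$exons)
  setorder(ex, chrom, start, end, transcript_id)
  lines <- sprintf(
    '%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    ex$chrom, source, ex$start + 1L, ex$end, ex$strand, ex$gene_id,
    ex$transcript_id)
  writeLines(c(if (length(comments)) paste0("#", comments), lines), path)
  invisible(path)
}

#' Assign genuine polyA sites to genes
#'
#' A polyA "site" is a single cleavage position; for track intervals wider
#' than 1 bp the strand-wise 3'-most base is used. Sites are assigned to a
#' gene by the BED name column when it matches a gene id, else to the
#' nearest gene on the matching strand whose span lies within `window` bp.
#' Unassignable sites are dropped with a warning.
#'
#' @param gm A `gene_models` object.
#' @param polya_bed PolyA track as returned by [read_bed()].
#' @param window Maximum distance (bp) for nearest-gene assignment when the
#'   name column does not identify a gene. Default 10000.
#'
#' @return `gm` with its `polya` table populated (`gene_id`, `pos`).
#' @export
assign_polya <- function(gm, polya_bed, window = 10000L) {
  if (!nrow(polya_bed)) return(gm)
  pa <- as.data.table(polya_bed)
  pa[, pos := three_prime_base(start, end, strand)]
  known <- pa$name %in% gm$genes$gene_id
  assigned <- pa[known, .(gene_id = name, pos)]
  rest <- pa[!known]
  if (nrow(rest)) {
    extra <- lapply(seq_len(nrow(rest)), function(i) {
      g <- gm$genes[chrom == rest$chrom[i] & strand == rest$strand[i]]
      if (!nrow(g)) return(NULL)
      d <- pmax(g$span_start - rest$pos[i], rest$pos[i] - (g$span_end - 1L), 0L)
      j <- which.min(d)
      if (d[j] > window) return(NULL)
      data.table(gene_id = g$gene_id[j], pos = rest$pos[i])
    })
    dropped <- sum(vapply(extra, is.null, logical(1L)))
    if (dropped) {
      warning(dropped, " polyA site(s) not assignable to any gene within ",
              window, " bp; dropped")
    }
    assigned <- rbindlist(c(list(assigned), extra))
  }
  gm$polya <- unique(assigned[, .(gene_id, pos = as.integer(pos))])
  setorder(gm$polya, gene_id, pos)
  gm
}

# Terminal exon of each transcript (strand-wise last exon), and per gene
# the terminal exon of the transcript whose 3' end reaches furthest
# downstream.
terminal_exons <- function(gm) {
  te <- gm$exons[, .SD[exon_rank == max(exon_rank)], by = transcript_id]
  te[, tx_end3 := donor_boundary(start, end, strand)]
  te
}

gene_terminal_exon <- function(gm, gid) {
  te <- terminal_exons(gm)[gene_id == gid]
  if (!nrow(te)) return(NULL)
  if (te$strand[1L] == "+") te[which.max(tx_end3)] else te[which.min(tx_end3)]
}

# Last genuine polyA cleavage position of a gene: strand-wise most
# downstream annotated site; falls back to the gene 3' end with a warning.
last_polya <- function(gm, gid) {
  sites <- gm$polya[gene_id == gid, pos]
  g <- gm$genes[gene_id == gid]
  if (!nrow(g)) stop("unknown gene: ", gid)
  if (!length(sites)) {
    warning("gene ", gid, " has no annotated polyA site; using gene 3' end")
    return(if (g$strand == "+") g$span_end - 1L else g$span_start)
  }
  if (g$strand == "+") max(sites) else min(sites)
}
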