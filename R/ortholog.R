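# Human/mouse ortholog filter: identifies human genes whose annotation
# carries an Alu-derived 3' extension absent from the mouse orthologue.
# Exon correspondence between the species is an input (annotation-level
# matching, e.g. from an orthology resource), not computed here.

#' Construct an ortholog pair
#'
#' @param human_gene_id,mouse_gene_id Gene identifiers.
#' @param human_exons `data.table` with columns `chrom`, `start`, `end`,
#'   `strand`, `transcript_id`, `is_alu_exon` (logical) — all annotated
#'   exons of the human gene.
#' @param exon_correspondence `data.table` with columns `human_start`,
#'   `human_end` identifying the human exons that have a one-to-one mouse
#'   counterpart.
#' @param mouse_terminal_in_human `c(start, end)` of the human exon
#'   corresponding to the mouse terminal exon; must be among the
#'   correspondence rows.
#'
#' @return An `ortholog_pair` object.
#' @export
ortholog_pair <- function(human_gene_id, mouse_gene_id, human_exons,
                          exon_correspondence, mouse_terminal_in_human) {
  human_exons <- as.data.table(human_exons)
  validate_intervals(human_exons, what = "human exon")
  exon_correspondence <- as.data.table(exon_correspondence)
  if (anyDuplicated(exon_correspondence[, .(human_start, human_end)])) {
    stop("exon correspondence is not one-to-one over human exons")
  }
  if (is.null(mouse_terminal_in_human) ||
      !nrow(exon_correspondence[human_start == mouse_terminal_in_human[1L] &
                                  human_end == mouse_terminal_in_human[2L]])) {
    stop("mouse terminal exon has no human counterpart in the correspondence")
  }
  structure(list(human_gene_id = human_gene_id,
                 mouse_gene_id = mouse_gene_id,
                 human_exons = human_exons,
                 exon_correspondence = exon_correspondence,
                 mouse_terminal_in_human = as.integer(mouse_terminal_in_human)),
            class = "ortholog_pair")
}

#' Apply the three-criterion Alu 3'-extension filter to an ortholog pair
#'
#' Criterion (i): some human transcript's strand-wise 3' end lies
#' downstream of the 3' boundary of the human exon corresponding to the
#' mouse terminal exon ("the human copy extends beyond the mouse one").
#' Criterion (ii): at least one human exon flagged as Alu exon lies
#' entirely downstream of that boundary. Criterion (iii): there exists
#' such an Alu exon with no corresponded (conserved) human exon downstream
#' of it. The pair passes iff all three hold.
#'
#' @param pair An [ortholog_pair()] object.
#'
#' @return `list(pass, criteria = c(extends, alu_downstream,
#'   no_conserved_after))`.
#' @export
filter_pair <- function(pair) {
  ex <- pair$human_exons
  s <- ex$strand[1L]
  mt <- pair$mouse_terminal_in_human
  mt3 <- donor_boundary(mt[1L], mt[2L], s)  # 3' boundary of conserved TE

  tx3 <- ex[, .(end3 = if (strand[1L] == "+") max(end) else min(start)),
            by = transcript_id]$end3
  crit1 <- any(is_downstream(tx3, mt3, s))

  alu <- ex[is_alu_exon == TRUE]
  alu_prox <- acceptor_boundary(alu$start, alu$end, s)  # gene-proximal edge
  alu_down <- alu[is_downstream(alu_prox, mt3, s) &
                    is_downstream(donor_boundary(alu$start, alu$end, s),
                                  mt3, s)]
  crit2 <- nrow(alu_down) > 0L

  crit3 <- FALSE
  if (crit2) {
    corr <- pair$exon_correspondence
    conserved3 <- donor_boundary(corr$human_start, corr$human_end, s)
    crit3 <- any(vapply(seq_len(nrow(alu_down)), function(i) {
      a3 <- donor_boundary(alu_down$start[i], alu_down$end[i], s)
      !any(is_downstream(conserved3, a3, s))
    }, logical(1L)))
  }
  list(pass = crit1 && crit2 && crit3,
       criteria = c(extends = crit1, alu_downstream = crit2,
                    no_conserved_after = crit3))
}

#' Summarize the ortholog filter over many pairs
#'
#' @param pairs List of [ortholog_pair()] objects.
#' @return List with `counts` (`data.table`: `n_pairs`, `n_extends`,
#'   `n_alu_downstream`, `n_no_conserved_after`, `n_pass`) and
#'   `passing` (sorted human gene ids).
#' @export
summarize_filter <- function(pairs) {
  if (!length(pairs)) {
    return(list(counts = data.table(n_pairs = 0L, n_extends = 0L,
                                    n_alu_downstream = 0L,
                                    n_no_conserved_after = 0L, n_pass = 0L),
                passing = character()))
  }
  res <- lapply(pairs, filter_pair)
  crit <- t(vapply(res, `[[`, logical(3L), "criteria"))
  pass <- vapply(res, `[[`, logical(1L), "pass")
  list(counts = data.table(n_pairs = length(pairs),
                           n_extends = sum(crit[, 1L]),
                           n_alu_downstream = sum(crit[, 2L]),
                           n_no_conserved_after = sum(crit[, 3L]),
                           n_pass = sum(pass)),
       passing = sort(vapply(pairs, `[[`, character(1L),
                             "human_gene_id")[pass]))
}

#' Build a toy ortholog pair from a feature triple
#'
#' Constructs a minimal human annotation with a conserved two-exon core
#' and optional features: a transcript extension beyond the conserved
#' terminal exon, an Alu exon downstream of it, and a conserved
#' (corresponded) exon after the Alu exon. Enumerating the 8 presence/
#' absence combinations exercises the full truth table of
#' [filter_pair()]; only (extension, Alu exon, no conserved exon after)
#' passes.
#'
#' @param extension,alu_exon,conserved_after Logical feature switches.
#' @param strand `"+"` or `"-"`.
#' @param origin Genomic offset of the gene.
#'
#' @return An [ortholog_pair()] object.
#' @export
toy_ortholog_pair <- function(extension, alu_exon, conserved_after,
                              strand = "+", origin = 10000L) {
  # transcription-axis layout: exon1 [0,200), conserved terminal
  # [1000,1600), alu [2400,2520), post-alu conserved [3200,3400)
  ivs <- list(e1 = c(0L, 200L), te = c(1000L, 1600L),
              alu = c(2400L, 2520L), post = c(3200L, 3400L))
  ext <- 4500L
  mp <- function(iv) map_axis(iv[1L], iv[2L], origin, ext, strand)
  rows <- list(data.table(tid = "t1", a = mp(ivs$e1), alu = FALSE),
               data.table(tid = "t1", a = mp(ivs$te), alu = FALSE))
  corr <- list(mp(ivs$e1), mp(ivs$te))
  if (extension) {
    # extended transcript reuses exon 1 and splices on downstream features
    rows <- c(rows, list(data.table(tid = "t2", a = mp(ivs$e1), alu = FALSE)))
    if (alu_exon) {
      rows <- c(rows, list(data.table(tid = "t2", a = mp(ivs$alu),
                                      alu = TRUE)))
    } else {
      # plain (non-Alu) downstream extension exon
      rows <- c(rows, list(data.table(tid = "t2", a = mp(c(2400L, 2600L)),
                                      alu = FALSE)))
    }
    if (conserved_after) {
      rows <- c(rows, list(data.table(tid = "t2", a = mp(ivs$post),
                                      alu = FALSE)))
      corr <- c(corr, list(mp(ivs$post)))
    }
  } else if (alu_exon) {
    # an Alu exon annotated inside the conserved span (not downstream of
    # the mouse terminal exon): crit2 must fail
    rows <- c(rows, list(data.table(tid = "t1", a = mp(c(400L, 520L)),
                                    alu = TRUE)))
    if (conserved_after) corr <- c(corr, list(mp(c(400L, 520L))))
  }
  ex <- rbindlist(lapply(rows, function(r) {
    data.table(chrom = "chrT", start = r$a[1L], end = r$a[2L],
               strand = strand, transcript_id = r$tid, is_alu_exon = r$alu)
  }))
  corr_dt <- unique(rbindlist(lapply(corr, function(a) {
    data.table(human_start = a[1L], human_end = a[2L])
  })))
  ortholog_pair("HGENE", "MGENE", ex, corr_dt,
                mouse_terminal_in_human = mp(ivs$te))
}

#' Build ortholog pairs from annotations and a correspondence table
#'
#' @param human_gm,mouse_gm `gene_models` for the two species.
#' @param correspondence `data.table`/TSV path with columns `human_gene`,
#'   `mouse_gene`, `human_start`, `human_end`, `mouse_start`, `mouse_end`
#'   (one row per matched exon pair).
#' @param alu_exons Interval table of Alu exon calls (`chrom`, `start`,
#'   `end`, `strand`); human exons with identical coordinates are flagged
#'   `is_alu_exon`.
#'
#' @return List of [ortholog_pair()] objects, one per `human_gene`/
#'   `mouse_gene` combination in the correspondence.
#' @export
read_ortholog_pairs <- function(human_gm, mouse_gm, correspondence,
                                alu_exons = NULL) {
  if (is.character(correspondence)) {
    correspondence <- fread(correspondence, sep = "\t")
  }
  corr <- as.data.table(correspondence)
  alu <- if (is.null(alu_exons)) NULL else as.data.table(alu_exons)
  keys <- unique(corr[, .(human_gene, mouse_gene)])
  lapply(seq_len(nrow(keys)), function(i) {
    hg <- keys$human_gene[i]
    mg <- keys$mouse_gene[i]
    cr <- corr[human_gene == hg & mouse_gene == mg]
    hex <- human_gm$exons[human_gm$exons$gene_id == hg,
                          .(chrom, start, end, strand, transcript_id)]
    if (!nrow(hex)) stop("human gene not annotated: ", hg)
    hex <- unique(hex)
    hex[, is_alu_exon := FALSE]
    if (!is.null(alu) && nrow(alu)) {
      hex[alu, is_alu_exon := TRUE,
          on = c("chrom", "start", "end", "strand")]
    }
    mte <- gene_terminal_exon(mouse_gm, mg)
    if (is.null(mte)) stop("mouse gene not annotated: ", mg)
    hit <- cr[mouse_start == mte$start & mouse_end == mte$end]
    if (!nrow(hit)) {
      stop("mouse terminal exon of ", mg, " missing from correspondence")
    }
    ortholog_pair(hg, mg, hex,
                  cr[, .(human_start, human_end)],
                  mouse_terminal_in_human = c(hit$human_start[1L],
                                              hit$human_end[1L]))
  })
}
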