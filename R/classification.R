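# Classification of candidate Alu exons: gene linkage through the
# splice-junction graph, intergenic/intronic status relative to the last
# genuine polyA site, mechanism scenario, splicing contribution at the
# 3' splice site, downstream cryptic exons, and per-condition inclusion.

#' Link a candidate Alu exon to a gene through the junction graph
#'
#' Breadth-first traversal starting from the candidate's acceptor and donor
#' boundaries. One hop follows a junction from one of the frontier
#' positions to its opposite boundary; between hops the frontier is closed
#' over predicted exons (a junction landing on one boundary of an exon also
#' exposes the exon's other boundary). The candidate links to the gene
#' whose annotated span (on the candidate strand) is reached within
#' `max_hops` hops; among genes reached at the same hop count, the gene
#' whose span is nearest upstream of the candidate wins.
#'
#' @param candidate One-row candidate table (from [call_alu_exons()]).
#' @param genes A `gene_models` object.
#' @param junctions Junction table from [aggregate_junctions()].
#' @param predicted_exons Interval table used to close the frontier over
#'   exon bodies.
#' @param max_hops Maximum junction hops; default 3.
#'
#' @return `list(gene_id = <id or NA>, hops = <int or NA>)`.
#' @export
link_gene <- function(candidate, genes, junctions, predicted_exons = NULL,
                      max_hops = 3L) {
  jx <- as.data.table(junctions)[chrom == candidate$chrom]
  gsp <- genes$genes[chrom == candidate$chrom & strand == candidate$strand]
  if (!nrow(jx) || !nrow(gsp)) {
    return(list(gene_id = NA_character_, hops = NA_integer_))
  }
  pe <- if (is.null(predicted_exons)) NULL else
    as.data.table(predicted_exons)[chrom == candidate$chrom &
                                     strand == candidate$strand]
  frontier <- unique(c(candidate$start, candidate$end))
  visited <- frontier
  for (hop in seq_len(max_hops)) {
    hit_a <- jx[start %in% frontier, end]
    hit_b <- jx[end %in% frontier, start]
    reached <- setdiff(unique(c(hit_a, hit_b)), visited)
    if (!length(reached)) break
    in_gene <- gsp[, any(reached >= span_start & reached <= span_end),
                   by = gene_id][V1 == TRUE, gene_id]
    if (length(in_gene)) {
      if (length(in_gene) > 1L) {
        # tie-break: gene span nearest upstream of the candidate
        g <- gsp[gene_id %in% in_gene]
        up <- if (candidate$strand == "+") candidate$start - g$span_end
              else g$span_start - candidate$end
        in_gene <- g$gene_id[order(up < 0, abs(up))][1L]
      }
      return(list(gene_id = in_gene[1L], hops = hop))
    }
    visited <- c(visited, reached)
    # close over predicted exon bodies: expose the opposite boundary
    if (!is.null(pe) && nrow(pe)) {
      mates <- unique(c(pe[start %in% reached, end],
                        pe[end %in% reached, start]))
      reached <- unique(c(reached, setdiff(mates, visited)))
      visited <- unique(c(visited, reached))
    }
    frontier <- reached
  }
  list(gene_id = NA_character_, hops = NA_integer_)
}

#' Classify a linked Alu exon as intergenic or intronic
#'
#' The "last" genuine polyA site is the strand-wise most downstream
#' annotated site across all transcripts of the gene. The exon is
#' intergenic when it lies entirely downstream of that position, with
#' `distance_bp` measured from the polyA cleavage position to the
#' gene-proximal exon boundary; otherwise it is intronic. Genes without an
#' annotated polyA site fall back to the gene 3' end (with a warning from
#' [last_polya()]).
#'
#' @param candidate One-row candidate table.
#' @param genes A `gene_models` object with polyA sites assigned.
#' @param gene_id Linked gene.
#' @param distance_to One of `"exon"` (default: the gene-proximal boundary
#'   of the Alu exon) or `"alu_element"` (the gene-proximal boundary of the
#'   Alu element itself).
#'
#' @return `list(locus_class = "intergenic"|"intronic",
#'   distance_bp = <int or NA>, last_polya = <pos>)`.
#' @export
classify_locus <- function(candidate, genes, gene_id,
                           distance_to = c("exon", "alu_element")) {
  distance_to <- match.arg(distance_to)
  s <- genes$genes$strand[genes$genes$gene_id == gene_id]
  pa <- last_polya(genes, gene_id)
  prox <- if (distance_to == "exon") {
    if (s == "+") candidate$start else candidate$end
  } else {
    if (s == "+") candidate$alu_start else candidate$alu_end
  }
  distal <- if (s == "+") candidate$end else candidate$start
  if (is_downstream(prox, pa, s) && is_downstream(distal, pa, s)) {
    list(locus_class = "intergenic",
         distance_bp = transcription_distance(pa, prox, s), last_polya = pa)
  } else {
    list(locus_class = "intronic", distance_bp = NA_integer_,
         last_polya = pa)
  }
}

#' Assign the exonisation mechanism scenario
#'
#' Compares junction evidence at the Alu exon acceptor: junctions arriving
#' from an annotated donor upstream of the terminal exon support
#' terminal-exon skipping; junctions whose donor lies strictly inside the
#' terminal exon body support cryptic 5' splice-site activation. Both
#' classes reaching `min_reads` yields `"both"`; neither yields
#' `"not_applicable"` (the call survives).
#'
#' @param candidate One-row candidate table.
#' @param genes A `gene_models` object.
#' @param gene_id Linked gene.
#' @param junctions Junction table.
#' @param min_reads Minimum junction reads per class; default 1.
#'
#' @return `list(scenario, skip_reads, cryptic_reads,
#'   cryptic_donor = <boundary or NA>)`.
#' @export
classify_scenario <- function(candidate, genes, gene_id, junctions,
                              min_reads = 1L) {
  te <- gene_terminal_exon(genes, gene_id)
  s <- te$strand
  acc_b <- acceptor_boundary(candidate$start, candidate$end, s)
  jx <- as.data.table(junctions)[chrom == candidate$chrom]
  into_acc <- if (s == "+") jx[end == acc_b] else jx[start == acc_b]
  donor_of <- function(j) if (s == "+") j$start else j$end
  don <- donor_of(into_acc)
  # donors of annotated exons strictly upstream (transcription) of the
  # terminal exon
  ex <- genes$exons[which(genes$exons$gene_id == gene_id)]
  before_te <- if (s == "+") ex$end <= te$start else ex$start >= te$end
  upstream_don <- unique(donor_boundary(ex$start, ex$end, ex$strand)[before_te])
  skip_reads <- sum(into_acc$read_count[don %in% upstream_don])
  inside_te <- don > te$start & don < te$end
  cryp_reads <- sum(into_acc$read_count[inside_te])
  cd <- if (any(inside_te)) {
    don[inside_te][which.max(into_acc$read_count[inside_te])]
  } else NA_integer_
  scenario <- if (skip_reads >= min_reads && cryp_reads >= min_reads) "both"
  else if (skip_reads >= min_reads) "terminal_exon_skipping"
  else if (cryp_reads >= min_reads) "cryptic_5ss"
  else "not_applicable"
  if (scenario == "not_applicable") {
    warning("candidate at ", candidate$chrom, ":", candidate$start, "-",
            candidate$end, " has no scenario-informative junctions")
  }
  list(scenario = scenario, skip_reads = as.integer(skip_reads),
       cryptic_reads = as.integer(cryp_reads), cryptic_donor = cd)
}

#' Splicing contribution at the Alu exon 3' splice site
#'
#' Classifies every read overlapping the acceptor: junction-spanning if it
#' contains the exact intron gap ending at the acceptor, continuous if one
#' of its blocks covers at least `flank` nt on each side of the splice
#' site. The contribution is junction / (junction + continuous); when no
#' read qualifies the value is `NA` (flagged absent).
#'
#' @param candidate One-row candidate table (uses its acceptor boundary).
#' @param reads An `aligned_reads` object.
#' @param strand Strand of the transcription unit (defaults to the
#'   candidate's strand).
#' @param flank Minimum aligned nt on each side for a continuous read;
#'   default 10.
#'
#' @return `list(contribution, junction_reads, continuous_reads)`.
#' @export
splicing_contribution <- function(candidate, reads,
                                  strand = candidate$strand, flank = 10L,
                                  junctions = NULL) {
  b <- acceptor_boundary(candidate$start, candidate$end, strand)
  blk <- reads$blocks[chrom == candidate$chrom]
  cont <- blk[start <= b - flank & end >= b + flank, data.table::uniqueN(read_id)]
  jx <- if (is.null(junctions)) aggregate_junctions(list(blocks = blk)) else
    as.data.table(junctions)[chrom == candidate$chrom]
  jr <- if (strand == "+") jx[end == b, sum(read_count)] else
    jx[start == b, sum(read_count)]
  jr <- as.integer(jr)
  if (jr + cont == 0L) {
    return(list(contribution = NA_real_, junction_reads = 0L,
                continuous_reads = 0L))
  }
  list(contribution = jr / (jr + cont), junction_reads = jr,
       continuous_reads = as.integer(cont))
}

#' Count cryptic exons downstream of an Alu exon
#'
#' Walks the junction chain leaving the Alu exon donor: each junction must
#' land on the acceptor boundary of a predicted exon strictly downstream
#' (transcription direction) of the Alu exon on the same strand; the walk
#' continues from that exon's donor. Returns the number of distinct exons
#' reached (and their coordinates).
#'
#' @param candidate One-row candidate table.
#' @param predicted_exons Interval table.
#' @param junctions Junction table.
#'
#' @return `list(count, exons = data.table(start, end))`.
#' @export
downstream_cryptic_exons <- function(candidate, predicted_exons, junctions) {
  s <- candidate$strand
  jx <- as.data.table(junctions)[chrom == candidate$chrom]
  pe <- unique(as.data.table(predicted_exons)[
    chrom == candidate$chrom & strand == s, .(start, end, strand)])
  found <- data.table(start = integer(), end = integer())
  cur_donor <- donor_boundary(candidate$start, candidate$end, s)
  alu_don <- cur_donor
  repeat {
    nxt_acc <- if (s == "+") jx[start == cur_donor, end] else
      jx[end == cur_donor, start]
    if (!length(nxt_acc)) break
    hit <- pe[acceptor_boundary(start, end, strand) %in% nxt_acc &
                is_downstream(acceptor_boundary(start, end, strand),
                              alu_don, s)]
    hit <- hit[!found, on = c("start", "end")]
    if (!nrow(hit)) break
    # follow the nearest downstream exon (transcription order)
    if (s == "+") setorder(hit, start) else setorder(hit, -end)
    hit <- hit[1L]
    found <- rbind(found, hit[, .(start, end)])
    cur_donor <- donor_boundary(hit$start, hit$end, s)
  }
  list(count = nrow(found), exons = found)
}

#' Estimate per-condition Alu exon inclusion from read counts
#'
#' Counts isoform-discriminating reads: junction reads into the Alu exon
#' acceptor support the Alu isoform; for terminal-exon skipping, junction
#' reads into the terminal-exon acceptor support the canonical isoform;
#' for cryptic 5'ss activation (and "both"), canonical support comes from
#' reads overlapping the polyA-proximal terminal-exon body beyond the
#' cryptic donor, which only the canonical isoform retains. Raw counts are
#' normalised by each class's read-start capture window computed from the
#' isoform structures (effective-length correction), making the estimate
#' comparable to a molar inclusion fraction.
#'
#' @param call One-row classified call (needs scenario, cryptic donor,
#'   downstream cryptic exon coordinates; see [classify_calls()]).
#' @param reads An `aligned_reads` object for one condition.
#' @param genes A `gene_models` object.
#' @param read_length Read length in bp (taken from the data's most common
#'   block-sum when `NULL`).
#' @param both_mix Assumed mixing weight of the skipping structure inside
#'   "both" genes; default 0.5.
#'
#' @return `list(inclusion, n_alu_reads, n_canonical_reads)`; `inclusion`
#'   is `NA` when no discriminating read exists or the scenario is
#'   `not_applicable`.
#' @export
estimate_inclusion <- function(call, reads, genes, read_length = NULL,
                               both_mix = 0.5, junctions = NULL) {
  if (is.na(call$scenario) || call$scenario == "not_applicable") {
    return(list(inclusion = NA_real_, n_alu_reads = 0L,
                n_canonical_reads = 0L))
  }
  s <- call$strand
  blk <- reads$blocks[chrom == call$chrom]
  if (is.null(read_length)) {
    rl <- blk[, .(L = sum(end - start)), by = read_id]$L
    read_length <- if (length(rl)) as.integer(median(rl)) else 75L
  }
  jx <- if (is.null(junctions)) aggregate_junctions(list(blocks = blk)) else
    as.data.table(junctions)[chrom == call$chrom]
  acc_b <- acceptor_boundary(call$start, call$end, s)
  A <- if (s == "+") jx[end == acc_b, sum(read_count)] else
    jx[start == acc_b, sum(read_count)]
  A <- as.integer(A)

  te <- gene_terminal_exon(genes, call$gene_id)
  str <- reconstruct_structures(call, genes)
  p_A <- capture_p_junction(str$alu, acc_b, s, read_length, both_mix)
  if (call$scenario == "terminal_exon_skipping") {
    te_acc <- acceptor_boundary(te$start, te$end, s)
    K <- if (s == "+") jx[end == te_acc, sum(read_count)] else
      jx[start == te_acc, sum(read_count)]
    K <- as.integer(K)
    p_K <- capture_p_junction(list(str$canonical), te_acc, s, read_length, 1)
  } else {
    # polyA-proximal terminal-exon body beyond the cryptic donor
    cd <- call$cryptic_donor
    region <- if (s == "+") c(cd, te$end) else c(te$start, cd)
    K <- blk[start < region[2L] & end > region[1L],
             data.table::uniqueN(read_id)]
    p_K <- capture_p_region(str$canonical, region, s, read_length)
  }
  if (A + K == 0L || is.na(p_A) || is.na(p_K) || p_A <= 0 || p_K <= 0) {
    return(list(inclusion = NA_real_, n_alu_reads = A,
                n_canonical_reads = as.integer(K)))
  }
  a_norm <- A / p_A
  k_norm <- K / p_K
  list(inclusion = max(0, min(1, a_norm / (a_norm + k_norm))),
       n_alu_reads = A, n_canonical_reads = as.integer(K))
}

# Rebuild the isoform exon structures implied by a classified call:
# canonical from the annotation; Alu isoform(s) from the upstream exons,
# the (possibly truncated) terminal exon, the Alu exon and the downstream
# cryptic exon chain.
reconstruct_structures <- function(call, genes) {
  ex <- genes$exons[genes$exons$gene_id == call$gene_id]
  tid <- terminal_exons(genes)[gene_id == call$gene_id]
  tid <- if (call$strand == "+") tid[which.max(tx_end3), transcript_id] else
    tid[which.min(tx_end3), transcript_id]
  ex <- ex[transcript_id == tid][order(exon_rank)]
  canon <- ex[, .(start, end)]
  term <- canon[nrow(canon)]
  upstream <- canon[-nrow(canon)]
  alu_exon <- data.table(start = call$start, end = call$end)
  cryp <- if (!is.null(call$cryptic_exons) && nrow(call$cryptic_exons)) {
    cr <- copy(call$cryptic_exons)
    if (call$strand == "+") setorder(cr, start) else setorder(cr, -start)
    cr[, .(start, end)]
  } else data.table(start = integer(), end = integer())
  alu <- list()
  if (call$scenario %in% c("terminal_exon_skipping", "both")) {
    alu$skip <- rbind(upstream, alu_exon, cryp)
  }
  if (call$scenario %in% c("cryptic_5ss", "both")) {
    cd <- call$cryptic_donor
    trunc <- if (call$strand == "+") {
      data.table(start = term$start, end = cd)
    } else data.table(start = cd, end = term$end)
    alu$cryptic <- rbind(upstream, trunc, alu_exon, cryp)
  }
  list(canonical = canon, alu = alu)
}

# Transcript coordinates: cumulative position of a genomic boundary along
# an isoform given in genomic order; exons must be non-overlapping.
transcript_pos_of_boundary <- function(iso, boundary, strand) {
  iso <- as.data.table(iso)
  if (strand == "-") iso <- iso[order(-start)] else iso <- iso[order(start)]
  lens <- iso$end - iso$start
  cs <- cumsum(c(0L, lens))
  for (k in seq_len(nrow(iso))) {
    hit <- if (strand == "+") iso$start[k] == boundary || iso$end[k] == boundary
           else iso$end[k] == boundary || iso$start[k] == boundary
    if (strand == "+" && iso$end[k] == boundary) return(cs[k] + lens[k])
    if (strand == "+" && iso$start[k] == boundary) return(cs[k])
    if (strand == "-" && iso$start[k] == boundary) return(cs[k] + lens[k])
    if (strand == "-" && iso$end[k] == boundary) return(cs[k])
  }
  NA_integer_
}

# Probability that a uniformly placed read of length L on an isoform
# contains the junction at transcript position t (>=1 base on each side).
junction_window <- function(t, M, L) {
  if (is.na(t) || t <= 0L || t >= M) return(NA_real_)
  lo <- max(0L, t - L + 1L)
  hi <- min(t - 1L, M - L)
  w <- hi - lo + 1L
  if (w <= 0L) return(0)
  w / (M - L + 1L)
}

capture_p_junction <- function(alu_structs, acc_b, strand, L, both_mix) {
  if (!length(alu_structs)) return(NA_real_)
  ps <- vapply(alu_structs, function(iso) {
    M <- sum(iso$end - iso$start)
    t <- transcript_pos_of_boundary(iso, acc_b, strand)
    junction_window(t, M, L)
  }, numeric(1L))
  if (length(ps) == 2L) both_mix * ps[["skip"]] + (1 - both_mix) * ps[["cryptic"]]
  else ps[[1L]]
}

# Probability that a read overlaps (>=1 nt) a genomic sub-region of one
# exon of the canonical isoform.
capture_p_region <- function(canon, region, strand, L) {
  iso <- as.data.table(canon)
  if (strand == "-") iso <- iso[order(-start)] else iso <- iso[order(start)]
  lens <- iso$end - iso$start
  cs <- cumsum(c(0L, lens))
  M <- sum(lens)
  k <- which(iso$start <= region[1L] & iso$end >= region[2L])
  if (!length(k)) return(NA_real_)
  k <- k[1L]
  off1 <- if (strand == "+") region[1L] - iso$start[k] else
    iso$end[k] - region[2L]
  t1 <- cs[k] + off1
  t2 <- t1 + (region[2L] - region[1L])
  lo <- max(0L, t1 - L + 1L)
  hi <- min(t2 - 1L, M - L)
  w <- hi - lo + 1L
  if (w <= 0) return(0)
  w / (M - L + 1L)
}

#' Classify all passing candidates into final Alu exon calls
#'
#' Runs gene linkage, locus classification, scenario assignment, splicing
#' contribution, downstream-cryptic-exon counting and per-condition
#' inclusion estimation over the passing candidates of
#' [call_alu_exons()].
#'
#' @param candidates Candidate table from [call_alu_exons()].
#' @param genes A `gene_models` object with polyA sites assigned.
#' @param reads_by_condition Named list of `aligned_reads` (e.g.
#'   `list(control = ..., kd = ...)`); junction evidence for detection-side
#'   statistics comes from `detect_condition`.
#' @param predicted_exons Interval table of predicted exons.
#' @param detect_condition Which condition drives junction-based
#'   classification; default `"kd"` (falls back to the first element).
#' @param max_hops,min_reads,flank,distance_to,both_mix See the individual
#'   operations.
#'
#' @return A `data.table` with one row per passing candidate: coordinates,
#'   `gene_id`, `locus_class` (`intergenic`/`intronic`/`unlinked`),
#'   `scenario`, `distance_bp`, `splicing_contribution`,
#'   `junction_reads`, `continuous_reads`, `downstream_cryptic_exons`, and
#'   one `inclusion_<condition>` column per read set.
#' @export
classify_calls <- function(candidates, genes, reads_by_condition,
                           predicted_exons, detect_condition = "kd",
                           max_hops = 3L, min_reads = 1L, flank = 10L,
                           distance_to = "exon", both_mix = 0.5) {
  cand <- as.data.table(candidates)[pass == TRUE]
  conds <- names(reads_by_condition)
  if (!detect_condition %in% conds) detect_condition <- conds[1L]
  jx_by_cond <- lapply(reads_by_condition, aggregate_junctions)
  rl_by_cond <- lapply(reads_by_condition, function(r) {
    if (!nrow(r$blocks)) return(75L)
    as.integer(median(r$blocks[, .(L = sum(end - start)), by = read_id]$L))
  })
  jx <- jx_by_cond[[detect_condition]]
  rows <- vector("list", nrow(cand))
  for (i in seq_len(nrow(cand))) {
    cc <- cand[i]
    lk <- link_gene(cc, genes, jx, predicted_exons, max_hops = max_hops)
    row <- data.table(
      call_id = NA_character_, gene_id = lk$gene_id, chrom = cc$chrom,
      start = cc$start, end = cc$end, strand = cc$strand,
      alu_element = cc$alu_element, locus_class = "unlinked",
      scenario = "not_applicable", distance_bp = NA_integer_,
      splicing_contribution = NA_real_, junction_reads = NA_integer_,
      continuous_reads = NA_integer_,
      downstream_cryptic_exons = NA_integer_, link_hops = lk$hops)
    if (!is.na(lk$gene_id)) {
      loc <- classify_locus(cc, genes, lk$gene_id, distance_to = distance_to)
      row$locus_class <- loc$locus_class
      row$distance_bp <- loc$distance_bp
      sc <- splicing_contribution(
        cc, reads_by_condition[[detect_condition]], strand = cc$strand,
        flank = flank, junctions = jx)
      row$splicing_contribution <- sc$contribution
      row$junction_reads <- sc$junction_reads
      row$continuous_reads <- sc$continuous_reads
      cryptic_donor <- NA_integer_
      if (loc$locus_class == "intergenic") {
        scn <- classify_scenario(cc, genes, lk$gene_id, jx,
                                 min_reads = min_reads)
        row$scenario <- scn$scenario
        cryptic_donor <- scn$cryptic_donor
        dce <- downstream_cryptic_exons(cc, predicted_exons, jx)
        row$downstream_cryptic_exons <- dce$count
        callobj <- c(as.list(row), list(cryptic_donor = cryptic_donor,
                                        cryptic_exons = dce$exons))
        for (cond in conds) {
          inc <- estimate_inclusion(callobj, reads_by_condition[[cond]],
                                    genes, read_length = rl_by_cond[[cond]],
                                    both_mix = both_mix,
                                    junctions = jx_by_cond[[cond]])
          row[[paste0("inclusion_", cond)]] <- inc$inclusion
          row[[paste0("inclusion_", cond, "_n")]] <-
            inc$n_alu_reads + inc$n_canonical_reads
        }
      } else {
        for (cond in conds) {
          row[[paste0("inclusion_", cond)]] <- NA_real_
          row[[paste0("inclusion_", cond, "_n")]] <- NA_integer_
        }
      }
      row$cryptic_donor <- cryptic_donor
    } else {
      row$cryptic_donor <- NA_integer_
      for (cond in conds) {
        row[[paste0("inclusion_", cond)]] <- NA_real_
        row[[paste0("inclusion_", cond, "_n")]] <- NA_integer_
      }
    }
    rows[[i]] <- row
  }
  calls <- rbindlist(rows, fill = TRUE)
  if (nrow(calls)) {
    setorder(calls, chrom, start, end)
    calls[, call_id := sprintf("AEX%04d", seq_len(.N))]
  }
  calls[]
}
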