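# Synthetic-data generator: annotation bundles and read sets with planted
# intergenic Alu exonisation events plus a ground-truth table. Geometry is
# constructive (genes laid out sequentially with per-gene margins), so
# planted intervals never collide. Coordinates are built on a per-gene
# transcription axis and reflected for minus-strand genes, which makes the
# generator strand-symmetric by construction.

#' Simulation configuration
#'
#' Defaults encode the study conditions the detector is meant to face:
#' polyA-to-Alu distances log-uniform over 41 bp to 21.4 kb, Alu exon
#' inclusion near-silent under control conditions (uniform 0 to 0.15) and
#' derepressed after knockdown (uniform 0.1 to 0.8), and a scenario mix
#' favouring terminal-exon skipping over cryptic 5' splice-site activation
#' with a minority of genes showing both.
#'
#' @param n_genes Number of genes.
#' @param fraction_with_events Fraction of genes with a planted intergenic
#'   Alu exonisation event.
#' @param scenario_mix Probabilities for (terminal_exon_skipping,
#'   cryptic_5ss, both); must sum to 1.
#' @param distance_range Log-uniform sampling bounds (bp) for the gap
#'   between the last genuine polyA site and the Alu exon.
#' @param read_depth Reads per gene and condition.
#' @param read_length Read length in bp.
#' @param inclusion_control,inclusion_kd Uniform sampling bounds for the
#'   Alu-isoform inclusion fraction in each condition.
#' @param p_downstream_cryptic Probability that an event gene carries
#'   cryptic exons beyond the Alu exon (1 or 2, weighted 0.7/0.3).
#' @param p_extra_polya Probability of an additional genuine polyA site
#'   upstream of the last one.
#' @param both_mix Weight of the terminal-exon-skipping isoform structure
#'   within "both" genes.
#' @param fpkm_concentration Beta concentration of per-tissue relative
#'   abundance around the base inclusion level.
#' @param n_tissues Number of tissues in the FPKM matrix.
#' @param seed Integer seed; recorded in all output metadata.
#'
#' @return A `sim_config` list.
#' @export
simulation_config <- function(n_genes = 50L,
                              fraction_with_events = 0.5,
                              scenario_mix = c(0.45, 0.37, 0.18),
                              distance_range = c(41L, 21400L),
                              read_depth = 500L,
                              read_length = 75L,
                              inclusion_control = c(0, 0.15),
                              inclusion_kd = c(0.1, 0.8),
                              p_downstream_cryptic = 0.26,
                              p_extra_polya = 0.3,
                              both_mix = 0.5,
                              fpkm_concentration = 30,
                              n_tissues = 16L,
                              seed = 1L) {
  stopifnot(length(scenario_mix) == 3L, all(scenario_mix >= 0),
            abs(sum(scenario_mix) - 1) < 1e-8,
            fraction_with_events >= 0, fraction_with_events <= 1,
            distance_range[1L] >= 1L, distance_range[1L] < distance_range[2L])
  structure(list(
    n_genes = as.integer(n_genes),
    fraction_with_events = fraction_with_events,
    scenario_mix = scenario_mix,
    distance_range = as.integer(distance_range),
    read_depth = as.integer(read_depth),
    read_length = as.integer(read_length),
    inclusion_control = inclusion_control,
    inclusion_kd = inclusion_kd,
    p_downstream_cryptic = p_downstream_cryptic,
    p_extra_polya = p_extra_polya,
    both_mix = both_mix,
    fpkm_concentration = fpkm_concentration,
    n_tissues = as.integer(n_tissues),
    seed = as.integer(seed)
  ), class = "sim_config")
}

SCENARIOS <- c("terminal_exon_skipping", "cryptic_5ss", "both")

# Fixed per-gene geometry on the transcription axis (bp). Constitutive
# exons of 150 bp, introns of 800 bp, a 800-bp terminal exon whose 3' end
# carries the genuine polyA site, a 120-bp Alu exon inside a ~300-bp
# antisense Alu element, a cryptic donor 500 bp into the terminal exon,
# and 100-bp downstream cryptic exons spaced 400 bp apart.
GEOM <- list(exon_len = 150L, intron_len = 800L, n_const = 3L,
             term_len = 800L, alu_exon_len = 120L, alu_pad5 = 100L,
             alu_pad3 = 80L, cryptic_donor_offset = 500L,
             cryp_exon_len = 100L, cryp_gap = 400L, margin = 1000L)

# Map an interval [a, b) on the transcription axis of a gene with genomic
# origin `o`, axis extent `ext` and strand `s` into genomic coordinates.
map_axis <- function(a, b, o, ext, s) {
  if (s == "+") c(o + a, o + b) else c(o + ext - b, o + ext - a)
}

#' Generate an annotation bundle with planted events
#'
#' Lays out `n_genes` genes (alternating strands) on one chromosome, each
#' with three constitutive exons and a terminal exon ending at its genuine
#' polyA site. Event genes additionally receive an antisense Alu element in
#' the downstream intergenic region at a log-uniformly sampled distance,
#' with a 3' and 5' splice site inside the element, optional downstream
#' cryptic exons, a cryptic donor inside the terminal exon for cryptic-5'ss
#' genes, and a new polyA position after the last planted exon. The
#' predicted-exon track contains the canonical exons plus, for event genes,
#' the Alu exon and any downstream cryptic exons.
#'
#' @param config A [simulation_config()].
#'
#' @return A list with elements `bundle` (annotation: `genes` as
#'   [gene_models()] with polyA sites assigned, `alu`, `polya`,
#'   `predicted_exons` interval tables, `seq_lengths`) and `events` (the
#'   planted-truth table, one row per gene).
#' @export
generate_annotation <- function(config) {
  set.seed(config$seed)
  g <- GEOM
  n <- config$n_genes
  n_event <- round(n * config$fraction_with_events)
  event_gene <- sort(sample.int(n, n_event))
  scen <- rep("none", n)
  if (n_event > 0L) {
    scen[event_gene] <- sample(SCENARIOS, n_event, replace = TRUE,
                               prob = config$scenario_mix)
  }
  dist_bp <- as.integer(round(exp(runif(
    n, log(config$distance_range[1L]), log(config$distance_range[2L])))))
  incl_c <- runif(n, config$inclusion_control[1L], config$inclusion_control[2L])
  incl_k <- runif(n, config$inclusion_kd[1L], config$inclusion_kd[2L])
  n_cryp <- ifelse(runif(n) < config$p_downstream_cryptic,
                   ifelse(runif(n) < 0.7, 1L, 2L), 0L)
  extra_pa <- runif(n) < config$p_extra_polya
  strand <- rep(c("+", "-"), length.out = n)

  exon_rows <- vector("list", n)
  alu_rows <- vector("list", n)
  pa_rows <- vector("list", n)
  pred_rows <- vector("list", n)
  ev_rows <- vector("list", n)
  offset <- 0L
  for (i in seq_len(n)) {
    gid <- sprintf("gene%03d", i)
    s <- strand[i]
    is_event <- scen[i] != "none"
    d <- dist_bp[i]
    # transcription-axis layout
    const <- lapply(seq_len(g$n_const), function(k) {
      a <- (k - 1L) * (g$exon_len + g$intron_len)
      c(a, a + g$exon_len)
    })
    te_a <- g$n_const * (g$exon_len + g$intron_len)
    term <- c(te_a, te_a + g$term_len)
    pa_base <- term[2L] - 1L            # genuine polyA cleavage base
    # distance is measured from the cleavage base to the gene-proximal
    # exon *boundary*; under the half-open convention the minus-strand
    # boundary sits one base beyond the first exonic base, so shift by 1
    # to plant the same measured distance on both strands
    alu_off <- pa_base + d + (s == "-")
    alu_exon <- c(alu_off, alu_off + g$alu_exon_len)
    alu_elem <- c(alu_exon[1L] - g$alu_pad5, alu_exon[2L] + g$alu_pad3)
    cryp <- if (is_event && n_cryp[i] > 0L) {
      lapply(seq_len(n_cryp[i]), function(k) {
        a <- alu_exon[2L] + k * g$cryp_gap + (k - 1L) * g$cryp_exon_len
        c(a, a + g$cryp_exon_len)
      })
    } else list()
    last_end <- if (length(cryp)) cryp[[length(cryp)]][2L] else alu_exon[2L]
    # the decoy Alu element of event-free genes also lives inside the slot
    ext <- alu_elem[2L] + ifelse(is_event, last_end - alu_exon[2L], 0L) +
      g$margin
    mp <- function(iv) map_axis(iv[1L], iv[2L], offset, ext, s)
    mbase <- function(p) mp(c(p, p + 1L))[1L]  # genomic base of an axis base

    canon <- lapply(c(const, list(term)), mp)
    canon_dt <- data.table(
      gene_id = gid, transcript_id = paste0(gid, ".t1"), chrom = "chr1",
      strand = s,
      start = vapply(canon, `[`, numeric(1L), 1L),
      end = vapply(canon, `[`, numeric(1L), 2L))
    exon_rows[[i]] <- canon_dt
    pa_pos <- mbase(pa_base)
    pa_i <- data.table(chrom = "chr1", start = pa_pos, end = pa_pos + 1L,
                       name = gid, score = 0, strand = s)
    if (extra_pa[i]) {
      p2 <- mbase(pa_base - 249L)       # additional upstream genuine site
      pa_i <- rbind(pa_i, data.table(chrom = "chr1", start = p2,
                                     end = p2 + 1L, name = gid, score = 0,
                                     strand = s))
    }
    pa_rows[[i]] <- pa_i
    pred <- canon_dt[, .(chrom, start, end, strand)]
    if (is_event) {
      ae <- mp(alu_exon)
      el <- mp(alu_elem)
      anti <- if (s == "+") "-" else "+"
      alu_rows[[i]] <- data.table(chrom = "chr1", start = el[1L],
                                  end = el[2L],
                                  name = sprintf("AluSx_%03d", i), score = 0,
                                  strand = anti)
      pred <- rbind(pred, data.table(chrom = "chr1", start = ae[1L],
                                     end = ae[2L], strand = s))
      for (cv in cryp) {
        cg <- mp(cv)
        pred <- rbind(pred, data.table(chrom = "chr1", start = cg[1L],
                                       end = cg[2L], strand = s))
      }
      cd_boundary <- if (scen[i] %in% c("cryptic_5ss", "both")) {
        mp(c(te_a, te_a + g$cryptic_donor_offset))[if (s == "+") 2L else 1L]
      } else NA_integer_
      new_pa <- mbase(last_end - 1L)
      ev_rows[[i]] <- data.table(
        gene_id = gid, scenario = scen[i], chrom = "chr1", strand = s,
        alu_start = el[1L], alu_end = el[2L],
        exon_start = ae[1L], exon_end = ae[2L],
        distance_bp = d, inclusion_control = incl_c[i],
        inclusion_kd = incl_k[i], n_downstream_cryptic = n_cryp[i],
        cryptic_donor = cd_boundary, new_polya = new_pa)
    } else {
      # decoy antisense Alu element downstream, never exonised
      el <- mp(c(pa_base + d - g$alu_pad5,
                 pa_base + d + g$alu_exon_len + g$alu_pad3))
      alu_rows[[i]] <- data.table(chrom = "chr1", start = el[1L],
                                  end = el[2L],
                                  name = sprintf("AluJb_%03d", i), score = 0,
                                  strand = if (s == "+") "-" else "+")
      ev_rows[[i]] <- data.table(
        gene_id = gid, scenario = "none", chrom = "chr1", strand = s,
        alu_start = el[1L], alu_end = el[2L],
        exon_start = NA_integer_, exon_end = NA_integer_,
        distance_bp = NA_integer_, inclusion_control = 0,
        inclusion_kd = 0, n_downstream_cryptic = 0L,
        cryptic_donor = NA_integer_, new_polya = NA_integer_)
    }
    pred[, name := sprintf("pe_%03d_%d", i, seq_len(.N))]
    pred[, score := 0]
    pred_rows[[i]] <- pred[, .(chrom, start, end, name, score, strand)]
    offset <- offset + as.integer(ext) + g$margin
  }
  exons <- rbindlist(exon_rows)
  exons[, `:=`(start = as.integer(start), end = as.integer(end))]
  gm <- gene_models(exons)
  polya <- rbindlist(pa_rows)
  gm <- assign_polya(gm, polya)
  events <- rbindlist(ev_rows)
  bundle <- list(genes = gm, alu = rbindlist(alu_rows), polya = polya,
                 predicted_exons = rbindlist(pred_rows),
                 seq_lengths = c(chr1 = offset + 1000L), config = config)
  list(bundle = bundle, events = events)
}

# Exon structures (transcription order, genomic coords) of the isoforms a
# gene can express. Returns a list of data.tables with columns start/end.
isoform_structures <- function(bundle, ev) {
  gm <- bundle$genes
  ex <- gm$exons[gene_id == ev$gene_id][order(exon_rank)]
  canon <- ex[, .(start, end)]
  out <- list(canonical = canon)
  if (ev$scenario == "none") return(out)
  s <- ev$strand
  alu_exon <- data.table(start = ev$exon_start, end = ev$exon_end)
  cryp <- cryptic_exon_table(bundle, ev)
  upstream <- canon[-nrow(canon)]               # constitutive exons only
  term <- canon[nrow(canon)]
  if (ev$scenario %in% c("terminal_exon_skipping", "both")) {
    out$alu_skip <- rbind(upstream, alu_exon, cryp)
  }
  if (ev$scenario %in% c("cryptic_5ss", "both")) {
    trunc <- if (s == "+") data.table(start = term$start, end = ev$cryptic_donor)
             else data.table(start = ev$cryptic_donor, end = term$end)
    out$alu_cryptic <- rbind(upstream, trunc, alu_exon, cryp)
  }
  out
}

cryptic_exon_table <- function(bundle, ev) {
  if (ev$n_downstream_cryptic == 0L) {
    return(data.table(start = integer(), end = integer()))
  }
  pe <- bundle$predicted_exons
  down <- pe[chrom == ev$chrom & strand == ev$strand &
               is_downstream(acceptor_boundary(start, end, strand),
                             donor_boundary(ev$exon_start, ev$exon_end,
                                            ev$strand), strand)]
  # transcription order
  if (ev$strand == "+") setorder(down, start) else setorder(down, -end)
  down[seq_len(ev$n_downstream_cryptic), .(start, end)]
}

# Simulate reads from one isoform: `n` coverage-uniform start positions
# (a deterministic stratified grid along the transcript) of length L,
# mapped through the exon structure into genomic blocks.
reads_from_isoform <- function(iso, n, L, strand, id0) {
  # `iso` rows must already be in transcription order (5' to 3')
  if (n <= 0L) return(empty_blocks())
  lens <- as.integer(iso$end - iso$start)
  M <- sum(lens)
  L <- min(L, M)
  cs <- cumsum(c(0L, lens))  # cumulative transcript starts, length nrow+1
  starts <- if (n == 1L) as.integer((M - L) %/% 2L) else
    as.integer(round(seq(0L, M - L, length.out = n)))
  f <- findInterval(starts, cs, rightmost.closed = TRUE)
  l <- findInterval(starts + L - 1L, cs, rightmost.closed = TRUE)
  nblk <- l - f + 1L
  rid <- rep(seq_len(n), nblk)
  eidx <- sequence(nblk, from = f)
  t1 <- pmax(rep(starts, nblk), cs[eidx])
  t2 <- pmin(rep(starts + L, nblk), cs[eidx + 1L])
  o1 <- t1 - cs[eidx]
  o2 <- t2 - cs[eidx]
  if (strand == "+") {
    bs <- iso$start[eidx] + o1
    be <- iso$start[eidx] + o2
  } else {
    bs <- iso$end[eidx] - o2
    be <- iso$end[eidx] - o1
  }
  data.table(read_id = id0 + rid, chrom = NA_character_, strand = strand,
             start = as.integer(bs), end = as.integer(be), bidx = 0L)
}

#' Simulate reads for one condition
#'
#' For each gene, reads are drawn from the Alu-derived isoform with the
#' planted per-condition inclusion probability (binomial per read) and from
#' the canonical isoform otherwise; within a "both" gene the two Alu
#' isoform structures are mixed with weight `both_mix`. Read start
#' positions are coverage-uniform along the chosen isoform, so every splice
#' junction of an isoform receiving enough reads is guaranteed to be
#' spanned.
#'
#' @param bundle,events Output of [generate_annotation()].
#' @param config The [simulation_config()] used.
#' @param condition `"control"` or `"kd"`.
#'
#' @return An `aligned_reads` object.
#' @export
simulate_reads <- function(bundle, events, config,
                           condition = c("control", "kd")) {
  condition <- match.arg(condition)
  set.seed(config$seed + if (condition == "control") 1L else 2L)
  L <- config$read_length
  depth <- config$read_depth
  out <- vector("list", nrow(events))
  id0 <- 0L
  for (i in seq_len(nrow(events))) {
    ev <- events[i]
    iso <- isoform_structures(bundle, ev)
    incl <- if (condition == "control") ev$inclusion_control else
      ev$inclusion_kd
    n_alu <- rbinom(1L, depth, incl)
    n_can <- depth - n_alu
    counts <- c(canonical = n_can)
    if (ev$scenario == "both") {
      n_skip <- rbinom(1L, n_alu, config$both_mix)
      counts <- c(counts, alu_skip = n_skip, alu_cryptic = n_alu - n_skip)
    } else if (ev$scenario == "terminal_exon_skipping") {
      counts <- c(counts, alu_skip = n_alu)
    } else if (ev$scenario == "cryptic_5ss") {
      counts <- c(counts, alu_cryptic = n_alu)
    }
    for (nm in names(counts)) {
      blk <- reads_from_isoform(iso[[nm]], counts[[nm]], L, ev$strand, id0)
      if (nrow(blk)) {
        blk[, chrom := ev$chrom]
        id0 <- max(blk$read_id)
        out[[length(out) + 1L]] <- blk
      }
    }
  }
  aligned_reads(rbindlist(out))
}

#' Generate a per-isoform, per-tissue FPKM matrix with planted truth
#'
#' Event genes receive a canonical and an Alu-exon-containing isoform;
#' event-free genes only the canonical one. Per tissue, total gene
#' expression is log-normal and the relative abundance of the Alu isoform
#' is Beta-distributed around the gene's knockdown inclusion level
#' (concentration `fpkm_concentration`); a small fraction of gene/tissue
#' pairs is silenced to exercise the undefined-denominator path.
#'
#' @param events Planted-event table from [generate_annotation()].
#' @param config The [simulation_config()] used (`n_tissues` tissues).
#'
#' @return List with `matrix` (a `data.table`: `gene_id`, `isoform_id`,
#'   `contains_alu_exon`, one numeric column per tissue) and `truth`
#'   (long-format planted relative abundance per gene and tissue; `NA`
#'   where total FPKM is 0).
#' @export
generate_fpkm_matrix <- function(events, config) {
  set.seed(config$seed + 3L)
  tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
  rows <- list()
  truth <- list()
  for (i in seq_len(nrow(events))) {
    ev <- events[i]
    has_alu <- ev$scenario != "none"
    total <- rlnorm(config$n_tissues, log(10), 1)
    total[runif(config$n_tissues) < 0.05] <- 0
    base <- ev$inclusion_kd
    a <- if (has_alu) {
      rbeta(config$n_tissues, config$fpkm_concentration * base,
            config$fpkm_concentration * (1 - base))
    } else rep(0, config$n_tissues)
    fpkm_alu <- round(a * total, 4L)
    fpkm_can <- round((1 - a) * total, 4L)
    can <- c(list(gene_id = ev$gene_id,
                  isoform_id = paste0(ev$gene_id, ".t1"),
                  contains_alu_exon = FALSE),
             as.list(setNames(fpkm_can, tissues)))
    rows[[length(rows) + 1L]] <- as.data.table(can)
    denom <- fpkm_can
    ra <- rep(NA_real_, config$n_tissues)
    if (has_alu) {
      alu <- c(list(gene_id = ev$gene_id,
                    isoform_id = paste0(ev$gene_id, ".alu"),
                    contains_alu_exon = TRUE),
               as.list(setNames(fpkm_alu, tissues)))
      rows[[length(rows) + 1L]] <- as.data.table(alu)
      denom <- fpkm_alu + fpkm_can
      ra[denom > 0] <- fpkm_alu[denom > 0] / denom[denom > 0]
    } else {
      ra[denom > 0] <- 0
    }
    truth[[length(truth) + 1L]] <- data.table(
      gene_id = ev$gene_id, tissue = tissues, relative_abundance = ra)
  }
  list(matrix = rbindlist(rows), truth = rbindlist(truth))
}
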