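# a minimal annotated gene for boundary-arithmetic tests:
# exons [1000,1200), [2000,2200), terminal [3000,3800) on +, polyA at 3799
toy_gene <- function(strand = "+") {
  if (strand == "+") {
    ex <- data.table::data.table(
      gene_id = "g1", transcript_id = "g1.t", chrom = "chr1", strand = "+",
      start = c(1000L, 2000L, 3000L), end = c(1200L, 2200L, 3800L))
    pa <- 3799L
  } else {
    ex <- data.table::data.table(
      gene_id = "g1", transcript_id = "g1.t", chrom = "chr1", strand = "-",
      start = c(8800L, 7800L, 6200L), end = c(9000L, 8000L, 7000L))
    pa <- 6200L
  }
  gm <- gene_models(ex)
  gm$polya <- data.table::data.table(gene_id = "g1", pos = pa)
  gm
}

cand_row <- function(start, end, strand = "+", alu_start = start - 80L,
                     alu_end = end + 80L) {
  data.table::data.table(chrom = "chr1", start = start, end = end,
                         strand = strand, alu_element = "AluY",
                         alu_start = alu_start, alu_end = alu_end,
                         pass = TRUE)
}

test_that("gene linkage follows junctions and reports unlinked candidates", {
  gm <- toy_gene()
  jx <- data.table::data.table(chrom = "chr1", start = 2200L, end = 8200L,
                               read_count = 4L)
  lk <- link_gene(cand_row(8200L, 8320L), gm, jx)
  expect_equal(lk$gene_id, "g1")
  expect_equal(lk$hops, 1L)
  lk2 <- link_gene(cand_row(50000L, 50100L), gm, jx)
  expect_true(is.na(lk2$gene_id))
})

test_that("multi-hop linkage closes over predicted exon bodies", {
  gm <- toy_gene()
  # candidate -> intermediate exon -> gene, two junction hops
  pe <- data.table::data.table(chrom = "chr1", start = c(8200L, 9000L),
                               end = c(8320L, 9100L), strand = "+")
  jx <- data.table::data.table(chrom = "chr1",
                               start = c(2200L, 8320L),
                               end = c(8200L, 9000L),
                               read_count = 2L)
  lk <- link_gene(cand_row(9000L, 9100L), gm, jx, predicted_exons = pe)
  expect_equal(lk$gene_id, "g1")
  expect_equal(lk$hops, 2L)
  # a 1-hop cap cannot reach it
  lk2 <- link_gene(cand_row(9000L, 9100L), gm, jx, predicted_exons = pe,
                   max_hops = 1L)
  expect_true(is.na(lk2$gene_id))
})

test_that("ties between equally distant genes pick the upstream one", {
  ex <- data.table::data.table(
    gene_id = c("up", "down"), transcript_id = c("up.t", "down.t"),
    chrom = "chr1", strand = "+",
    start = c(1000L, 20000L), end = c(2000L, 21000L))
  gm <- gene_models(ex)
  jx <- data.table::data.table(chrom = "chr1",
                               start = c(2000L, 10120L),
                               end = c(10000L, 20000L),
                               read_count = 1L)
  lk <- link_gene(cand_row(10000L, 10120L), gm, jx)
  expect_equal(lk$gene_id, "up")
})

test_that("locus classification measures strand-aware polyA distance", {
  gm <- toy_gene("+")
  gm$polya <- data.table::data.table(gene_id = "g1", pos = 5000L)
  loc <- classify_locus(cand_row(8200L, 8400L), gm, "g1")
  expect_equal(loc$locus_class, "intergenic")
  expect_equal(loc$distance_bp, 3200L)

  gmm <- toy_gene("-")
  gmm$polya <- data.table::data.table(gene_id = "g1", pos = 5000L)
  locm <- classify_locus(cand_row(4800L, 4959L, "-"), gmm, "g1")
  expect_equal(locm$locus_class, "intergenic")
  expect_equal(locm$distance_bp, 41L)

  # exon upstream of the last polyA site is intronic
  loc2 <- classify_locus(cand_row(4000L, 4200L), gm, "g1")
  expect_equal(loc2$locus_class, "intronic")
  expect_true(is.na(loc2$distance_bp))

  # the last polyA site is the strand-wise most downstream of the gene
  gm$polya <- data.table::data.table(gene_id = "g1", pos = c(3799L, 5000L))
  expect_equal(classify_locus(cand_row(4000L, 4200L), gm, "g1")$locus_class,
               "intronic")

  # distance can alternatively be measured to the Alu element boundary
  loc3 <- classify_locus(cand_row(8200L, 8400L), gm, "g1",
                         distance_to = "alu_element")
  expect_equal(loc3$distance_bp, 3120L)
})

test_that("genes without polyA sites fall back to the gene 3' end", {
  gm <- toy_gene()
  gm$polya <- gm$polya[0]
  expect_warning(loc <- classify_locus(cand_row(8200L, 8400L), gm, "g1"),
                 "polyA")
  expect_equal(loc$locus_class, "intergenic")
  expect_equal(loc$distance_bp, 8200L - 3799L)
})

test_that("scenario assignment separates skipping from cryptic donors", {
  gm <- toy_gene()
  acc <- 8200L
  j_skip <- data.table::data.table(chrom = "chr1", start = 2200L, end = acc,
                                   read_count = 3L)
  j_cryp <- data.table::data.table(chrom = "chr1", start = 3400L, end = acc,
                                   read_count = 2L)
  cc <- cand_row(8200L, 8320L)
  expect_equal(classify_scenario(cc, gm, "g1", j_skip)$scenario,
               "terminal_exon_skipping")
  sc <- classify_scenario(cc, gm, "g1", j_cryp)
  expect_equal(sc$scenario, "cryptic_5ss")
  expect_equal(sc$cryptic_donor, 3400L)
  expect_equal(classify_scenario(cc, gm, "g1", rbind(j_skip, j_cryp))$scenario,
               "both")
  expect_warning(
    sc_na <- classify_scenario(cc, gm, "g1", j_skip[0]),
    "no scenario-informative")
  expect_equal(sc_na$scenario, "not_applicable")
  # threshold: a single read of each class is enough for "both"
  one_each <- rbind(j_skip, j_cryp)[, read_count := 1L]
  expect_equal(classify_scenario(cc, gm, "g1", one_each)$scenario, "both")
})

test_that("splicing contribution counts junction vs continuous reads", {
  acc <- 500L
  rd <- make_reads(
    list(chrom = "chr1", strand = "+", blocks = list(c(400, 450), c(500, 550))),
    list(chrom = "chr1", strand = "+", blocks = list(c(420, 460), c(500, 560))),
    list(chrom = "chr1", strand = "+", blocks = list(c(430, 470), c(500, 570))),
    list(chrom = "chr1", strand = "+", blocks = list(c(480, 540))))
  cc <- cand_row(500L, 620L)
  sc <- splicing_contribution(cc, rd)
  expect_equal(sc$contribution, 0.75)
  expect_equal(sc$junction_reads, 3L)
  expect_equal(sc$continuous_reads, 1L)

  # all continuous
  rd0 <- make_reads(
    list(chrom = "chr1", strand = "+", blocks = list(c(480, 540))),
    list(chrom = "chr1", strand = "+", blocks = list(c(470, 530))))
  expect_equal(splicing_contribution(cc, rd0)$contribution, 0)
  # all junction
  rd1 <- make_reads(
    list(chrom = "chr1", strand = "+", blocks = list(c(400, 450), c(500, 550))))
  expect_equal(splicing_contribution(cc, rd1)$contribution, 1)
  # a one-sided read is neither: flagged absent
  rd2 <- make_reads(
    list(chrom = "chr1", strand = "+", blocks = list(c(495, 560))))
  expect_true(is.na(splicing_contribution(cc, rd2)$contribution))
})

test_that("splicing contribution equals the per-read brute-force oracle", {
  fx <- sim_fixture(n_genes = 16L, seed = 47L, read_depth = 150L)
  cand <- call_alu_exons(fx$bundle$predicted_exons, fx$bundle$alu, fx$jx)
  for (i in which(cand$pass)) {
    cc <- cand[i]
    got <- splicing_contribution(cc, fx$kd)$contribution
    b <- if (cc$strand == "+") cc$start else cc$end
    want <- oracle_splicing_contribution(fx$kd, cc$chrom, b, cc$strand)
    expect_identical(got, want)
  }
})

test_that("downstream cryptic exon chains are counted by reachability", {
  pe <- data.table::data.table(
    chrom = "chr1", start = c(500L, 900L, 1400L),
    end = c(620L, 1000L, 1500L), strand = "+")
  cc <- cand_row(500L, 620L)
  jx0 <- data.table::data.table(chrom = "chr1", start = integer(),
                                end = integer(), read_count = integer())
  expect_equal(downstream_cryptic_exons(cc, pe, jx0)$count, 0L)
  jx1 <- data.table::data.table(chrom = "chr1", start = 620L, end = 900L,
                                read_count = 2L)
  expect_equal(downstream_cryptic_exons(cc, pe, jx1)$count, 1L)
  jx2 <- rbind(jx1, data.table::data.table(chrom = "chr1", start = 1000L,
                                           end = 1400L, read_count = 1L))
  got <- downstream_cryptic_exons(cc, pe, jx2)
  expect_equal(got$count, 2L)
  want <- oracle_downstream_count(as.data.frame(pe[-1]), as.data.frame(jx2),
                                  500L, 620L, "+")
  expect_equal(got$count, want)
})

test_that("classification recovers planted truth and partitions scenarios", {
  fx <- sim_fixture(n_genes = 24L, seed = 91L, read_depth = 500L)
  cand <- call_alu_exons(fx$bundle$predicted_exons, fx$bundle$alu, fx$jx)
  calls <- classify_calls(cand, fx$bundle$genes,
                          list(control = fx$control, kd = fx$kd),
                          fx$bundle$predicted_exons)
  ev <- fx$events[scenario != "none"]
  m <- merge(calls, ev, by = "gene_id", suffixes = c("", ".true"))
  expect_equal(nrow(m), nrow(ev))
  expect_true(all(m$locus_class == "intergenic"))
  expect_identical(m$scenario, m$scenario.true)
  expect_identical(m$distance_bp, m$distance_bp.true)
  expect_identical(m$downstream_cryptic_exons, m$n_downstream_cryptic)
  # scenario counts partition the intergenic calls
  inter <- calls[locus_class == "intergenic"]
  expect_equal(
    sum(inter$scenario %in% c("terminal_exon_skipping", "cryptic_5ss",
                              "both", "not_applicable")),
    nrow(inter))
  # inclusion estimates approach planted values within binomial noise
  expect_true(all(abs(m$inclusion_kd - m$inclusion_kd.true) <=
                    3 * sqrt(pmax(m$inclusion_kd.true *
                                    (1 - m$inclusion_kd.true), 0.05) /
                               m$inclusion_kd_n) + 1e-9))
})

test_that("classification output is invariant to read-order shuffling", {
  fx <- sim_fixture(n_genes = 10L, seed = 37L, read_depth = 200L)
  cand <- call_alu_exons(fx$bundle$predicted_exons, fx$bundle$alu, fx$jx)
  set.seed(4)
  shuf <- data.table::copy(fx$kd$blocks)[sample(.N)]
  relabel <- data.table::data.table(read_id = unique(shuf$read_id))
  relabel[, new_id := sample(.N)]
  shuf <- merge(shuf, relabel, by = "read_id")[, read_id := new_id]
  kd2 <- aligned_reads(shuf[, .(read_id, chrom, strand, start, end, bidx)])
  a <- classify_calls(cand, fx$bundle$genes,
                      list(control = fx$control, kd = fx$kd),
                      fx$bundle$predicted_exons)
  b <- classify_calls(cand, fx$bundle$genes,
                      list(control = fx$control, kd = kd2),
                      fx$bundle$predicted_exons)
  expect_equal(a, b)
})
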