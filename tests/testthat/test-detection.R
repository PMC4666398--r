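test_that("junctions aggregate identical gaps across reads", {
  rd <- make_reads(
    list(chrom = "chr1", strand = "+", blocks = list(c(100, 120), c(220, 250))),
    list(chrom = "chr1", strand = "+", blocks = list(c(90, 120), c(220, 260))),
    list(chrom = "chr1", strand = "+",
         blocks = list(c(10, 40), c(100, 120), c(220, 240))))
  jx <- aggregate_junctions(rd)
  expect_equal(nrow(jx), 2L)
  expect_equal(jx[start == 120 & end == 220, read_count], 3L)
  expect_equal(jx[start == 40 & end == 100, read_count], 1L)

  expect_equal(nrow(aggregate_junctions(make_reads(
    list(chrom = "chr1", strand = "+", blocks = list(c(5, 80)))))), 0L)
})

# a hand-built locus: gene exons at [100,200) and [300,400) on +, an
# antisense Alu element [490,800) holding an Alu exon [500,620)
toy_locus <- function() {
  list(
    predicted = data.table::data.table(
      chrom = "chr1", start = c(100L, 300L, 500L),
      end = c(200L, 400L, 620L), name = c("e1", "e2", "alu"),
      score = 0, strand = "+"),
    alu = data.table::data.table(chrom = "chr1", start = 490L, end = 800L,
                                 name = "AluY", score = 0, strand = "-"),
    jx = data.table::data.table(chrom = "chr1", start = c(200L, 400L),
                                end = c(300L, 500L),
                                read_count = c(8L, 5L)))
}

test_that("candidates require an Alu splice site with junction support", {
  tl <- toy_locus()
  cand <- call_alu_exons(tl$predicted, tl$alu, tl$jx)
  alu_row <- cand[start == 500]
  expect_true(alu_row$pass)
  expect_true(alu_row$acceptor_in_alu)
  expect_false(alu_row$donor_in_alu)
  expect_equal(alu_row$acceptor_reads, 5L)
  expect_equal(alu_row$alu_element, "AluY")
  # ordinary gene exons fail criterion (i)
  expect_true(all(!cand[start != 500]$pass))
  expect_equal(cand[start == 100]$fail_reason, "no_splice_site_in_alu")
})

test_that("junction support threshold and strand-sense are enforced", {
  tl <- toy_locus()
  # not enough reads
  cand <- call_alu_exons(tl$predicted, tl$alu, tl$jx, min_junction_reads = 6L)
  expect_false(cand[start == 500]$pass)
  expect_equal(cand[start == 500]$fail_reason, "no_junction_support")
  # sense Alu element does not qualify (must be antisense to the exon)
  alu_sense <- data.table::copy(tl$alu)[, strand := "+"]
  cand2 <- call_alu_exons(tl$predicted, alu_sense, tl$jx)
  expect_false(cand2[start == 500]$pass)
  expect_equal(cand2[start == 500]$fail_reason, "no_splice_site_in_alu")
  # no junction at all at the acceptor
  cand3 <- call_alu_exons(tl$predicted, tl$alu, tl$jx[start != 400])
  expect_false(cand3[start == 500]$pass)
})

test_that("overlapping predicted exons make a candidate ambiguous", {
  tl <- toy_locus()
  overlapping <- rbind(tl$predicted,
                       data.table::data.table(chrom = "chr1", start = 619L,
                                              end = 700L, name = "x",
                                              score = 0, strand = "+"))
  cand <- call_alu_exons(overlapping, tl$alu, tl$jx)
  expect_false(cand[start == 500]$pass)
  expect_equal(cand[start == 500]$fail_reason, "overlapping_predicted_exon")
  # identical duplicates collapse and do not count as overlap
  dup <- rbind(tl$predicted, tl$predicted[3])
  cand2 <- call_alu_exons(dup, tl$alu, tl$jx)
  expect_true(cand2[start == 500]$pass)
  expect_equal(nrow(cand2), 3L)
})

test_that("detection output is independent of input row order", {
  fx <- sim_fixture(n_genes = 12L, seed = 61L, read_depth = 200L)
  set.seed(1)
  pe_shuf <- fx$bundle$predicted_exons[sample(.N)]
  jx_shuf <- fx$jx[sample(.N)]
  alu_shuf <- fx$bundle$alu[sample(.N)]
  a <- call_alu_exons(fx$bundle$predicted_exons, fx$bundle$alu, fx$jx)
  b <- call_alu_exons(pe_shuf, alu_shuf, jx_shuf)
  expect_equal(a, b)
})

test_that("planted events are detected and event-free genes stay silent", {
  fx <- sim_fixture(n_genes = 20L, seed = 83L, read_depth = 400L)
  cand <- call_alu_exons(fx$bundle$predicted_exons, fx$bundle$alu, fx$jx)
  ev <- fx$events[scenario != "none"]
  for (i in seq_len(nrow(ev))) {
    hit <- cand[start == ev$exon_start[i] & end == ev$exon_end[i]]
    expect_true(hit$pass, label = ev$gene_id[i])
  }
  # no passing candidate outside planted Alu exons
  extra <- cand[pass == TRUE][!ev[, .(start = exon_start, end = exon_end)],
                              on = c("start", "end")]
  expect_equal(nrow(extra), 0L)
})
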