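test_that("only extension with downstream Alu and no conserved tail passes", {
  grid <- expand.grid(extension = c(FALSE, TRUE),
                      alu_exon = c(FALSE, TRUE),
                      conserved_after = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    pair <- toy_ortholog_pair(g$extension, g$alu_exon, g$conserved_after)
    res <- filter_pair(pair)
    should_pass <- g$extension && g$alu_exon && !g$conserved_after
    expect_identical(res$pass, should_pass,
                     label = paste0("(", g$extension, ",", g$alu_exon, ",",
                                    g$conserved_after, ")"))
    # logical consistency: pass implies every criterion flag
    if (res$pass) expect_true(all(res$criteria))
  }
})

test_that("the filter verdict is strand-reflection invariant", {
  grid <- expand.grid(extension = c(FALSE, TRUE),
                      alu_exon = c(FALSE, TRUE),
                      conserved_after = c(FALSE, TRUE))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    plus <- filter_pair(toy_ortholog_pair(g$extension, g$alu_exon,
                                          g$conserved_after, strand = "+"))
    minus <- filter_pair(toy_ortholog_pair(g$extension, g$alu_exon,
                                           g$conserved_after, strand = "-"))
    expect_identical(plus$pass, minus$pass)
    expect_identical(plus$criteria, minus$criteria)
  }
})

test_that("filter summaries tally criteria deterministically", {
  pairs <- c(lapply(1:3, function(i) toy_ortholog_pair(TRUE, TRUE, FALSE)),
             list(toy_ortholog_pair(TRUE, TRUE, TRUE),
                  toy_ortholog_pair(FALSE, FALSE, FALSE)))
  sm <- summarize_filter(pairs)
  expect_equal(sm$counts$n_pairs, 5L)
  expect_equal(sm$counts$n_pass, 3L)
  expect_equal(sm$passing, rep("HGENE", 3))
  expect_identical(sm, summarize_filter(pairs))  # idempotent
  empty <- summarize_filter(list())
  expect_equal(empty$counts$n_pass, 0L)
  expect_equal(length(empty$passing), 0L)
})

test_that("a pair without the mouse terminal exon mapping errors", {
  pair <- toy_ortholog_pair(TRUE, TRUE, FALSE)
  expect_error(
    ortholog_pair("h", "m", pair$human_exons,
                  pair$exon_correspondence[-2],
                  pair$mouse_terminal_in_human),
    "mouse terminal exon")
  expect_error(
    ortholog_pair("h", "m", pair$human_exons,
                  rbind(pair$exon_correspondence,
                        pair$exon_correspondence[1]),
                  pair$mouse_terminal_in_human),
    "one-to-one")
})

test_that("pairs assemble from annotations plus a correspondence table", {
  # human gene: conserved exons at [100,200) and [500,800), an Alu-derived
  # extension exon [1200,1320) on transcript t2
  hex <- data.table::data.table(
    gene_id = "HG", transcript_id = c("t1", "t1", "t2", "t2", "t2"),
    chrom = "chr1", strand = "+",
    start = c(100L, 500L, 100L, 500L, 1200L),
    end = c(200L, 800L, 200L, 800L, 1320L))
  mex <- data.table::data.table(
    gene_id = "MG", transcript_id = "mt1", chrom = "chr5", strand = "+",
    start = c(1000L, 1400L), end = c(1100L, 1700L))
  corr <- data.table::data.table(
    human_gene = "HG", mouse_gene = "MG",
    human_start = c(100L, 500L), human_end = c(200L, 800L),
    mouse_start = c(1000L, 1400L), mouse_end = c(1100L, 1700L))
  alu <- data.table::data.table(chrom = "chr1", start = 1200L, end = 1320L,
                                strand = "+")
  pairs <- read_ortholog_pairs(gene_models(hex), gene_models(mex), corr,
                               alu_exons = alu)
  expect_length(pairs, 1L)
  res <- filter_pair(pairs[[1L]])
  expect_true(res$pass)
  # without the Alu flag the same pair fails criterion (ii)
  pairs2 <- read_ortholog_pairs(gene_models(hex), gene_models(mex), corr)
  expect_false(filter_pair(pairs2[[1L]])$pass)
})
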