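test_that("annotation generation honours event fraction and scenario mix", {
  cfg0 <- simulation_config(n_genes = 1L, fraction_with_events = 0, seed = 2L)
  ann0 <- generate_annotation(cfg0)
  expect_equal(nrow(ann0$bundle$genes$genes), 1L)
  expect_true(all(ann0$events$scenario == "none"))

  cfg1 <- simulation_config(n_genes = 10L, fraction_with_events = 1,
                            scenario_mix = c(1, 0, 0), seed = 3L)
  ann1 <- generate_annotation(cfg1)
  expect_true(all(ann1$events$scenario == "terminal_exon_skipping"))
  expect_equal(nrow(ann1$events), 10L)
})

test_that("planted geometry satisfies its own invariants", {
  fx <- sim_fixture(n_genes = 30L, seed = 19L, read_depth = 10L)
  ev <- fx$events[scenario != "none"]
  gm <- fx$bundle$genes
  # antisense Alu elements, distances in the configured envelope
  alu <- fx$bundle$alu
  m <- merge(ev, alu, by.x = c("alu_start", "alu_end"),
             by.y = c("start", "end"))
  expect_true(all(m$strand.x != m$strand.y))
  expect_true(all(ev$distance_bp >= 41 & ev$distance_bp <= 21400))
  # every gene has >= 2 constitutive exons plus a terminal exon and a polyA
  n_ex <- gm$exons[, .N, by = transcript_id]$N
  expect_true(all(n_ex >= 3L))
  expect_true(all(gm$genes$gene_id %in% gm$polya$gene_id))
  # the planted Alu exon lies downstream of the gene's last polyA site
  for (i in seq_len(nrow(ev))) {
    pa <- aluexon:::last_polya(gm, ev$gene_id[i])
    prox <- if (ev$strand[i] == "+") ev$exon_start[i] else ev$exon_end[i]
    expect_true(is_downstream(prox, pa, ev$strand[i]))
    expect_equal(transcription_distance(pa, prox, ev$strand[i]),
                 ev$distance_bp[i])
  }
})

test_that("identical config and seed give byte-identical fixtures", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  for (d in c(d1, d2)) {
    cfg <- run_config(out_dir = d, stages = "simulate",
                      sim = simulation_config(n_genes = 8L, seed = 55L,
                                              read_depth = 60L),
                      log_level = "quiet")
    run_pipeline(cfg)
  }
  for (f in c("genome.gtf", "alu.bed", "polya.bed", "predicted_exons.bed",
              "control.sam", "kd.sam", "fpkm.tsv", "truth.tsv")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
})

test_that("zero inclusion yields no junction reads into the Alu exon", {
  cfg <- simulation_config(n_genes = 6L, fraction_with_events = 1,
                           inclusion_control = c(0, 0),
                           inclusion_kd = c(0, 0), seed = 21L)
  ann <- generate_annotation(cfg)
  ann$events[, `:=`(inclusion_control = 0, inclusion_kd = 0)]
  rd <- simulate_reads(ann$bundle, ann$events, cfg, "kd")
  jx <- aggregate_junctions(rd)
  for (i in seq_len(nrow(ann$events))) {
    ev <- ann$events[i]
    acc <- if (ev$strand == "+") ev$exon_start else ev$exon_end
    hit <- if (ev$strand == "+") jx[end == acc] else jx[start == acc]
    expect_equal(nrow(hit), 0L)
  }
})

test_that("full inclusion under skipping leaves no terminal-exon junctions", {
  cfg <- simulation_config(n_genes = 4L, fraction_with_events = 1,
                           scenario_mix = c(1, 0, 0), seed = 23L)
  ann <- generate_annotation(cfg)
  ann$events[, inclusion_kd := 1]
  rd <- simulate_reads(ann$bundle, ann$events, cfg, "kd")
  jx <- aggregate_junctions(rd)
  for (gid in ann$events$gene_id) {
    te <- aluexon:::gene_terminal_exon(ann$bundle$genes, gid)
    acc <- if (te$strand == "+") te$start else te$end
    hit <- if (te$strand == "+") jx[end == acc] else jx[start == acc]
    expect_equal(sum(hit$read_count), 0L)
  }
})

test_that("read counts per isoform follow the binomial inclusion draw", {
  # only Alu-isoform reads can overlap the Alu exon body; with coverage-
  # uniform read starts, the overlapping fraction of those reads is the
  # overlap window over the isoform's start positions, which lets the
  # drawn isoform count be recovered and compared to the binomial draw
  cfg <- simulation_config(n_genes = 1L, fraction_with_events = 1,
                           scenario_mix = c(1, 0, 0), read_depth = 1000L,
                           inclusion_kd = c(0.3, 0.3),
                           p_downstream_cryptic = 0, seed = 29L)
  ann <- generate_annotation(cfg)
  rd <- simulate_reads(ann$bundle, ann$events, cfg, "kd")
  ev <- ann$events[1L]
  L <- cfg$read_length
  alu_len <- ev$exon_end - ev$exon_start
  m_alu <- 3L * 150L + alu_len             # constitutive exons + Alu exon
  n_overlap <- rd$blocks[start < ev$exon_end & end > ev$exon_start,
                         data.table::uniqueN(read_id)]
  # the Alu exon is the isoform 3' terminus: starts in the trailing
  # (alu_len + L - 1, clipped) window overlap it
  w <- (m_alu - L) - (m_alu - alu_len - L + 1L) + 1L
  n_alu_hat <- n_overlap * (m_alu - L + 1L) / w
  sd3 <- 3 * sqrt(0.3 * 0.7 / 1000)
  expect_lt(abs(n_alu_hat / 1000 - 0.3), sd3 + 0.02)
})

test_that("FPKM matrices encode the planted relative abundance", {
  cfg <- simulation_config(n_genes = 12L, seed = 41L, n_tissues = 6L)
  ann <- generate_annotation(cfg)
  fp <- generate_fpkm_matrix(ann$events, cfg)
  mat <- isoform_abundance(fp$matrix)
  for (i in seq_len(nrow(fp$truth))) {
    tr <- fp$truth[i]
    got <- relative_abundance(mat, tr$gene_id, tr$tissue)
    if (is.na(tr$relative_abundance)) expect_true(is.na(got))
    else expect_identical(got, tr$relative_abundance)
  }
  # reproducibility under the same seed
  fp2 <- generate_fpkm_matrix(ann$events, cfg)
  expect_identical(fp$matrix, fp2$matrix)
})
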