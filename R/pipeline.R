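# End-to-end orchestration: simulate -> detect -> classify -> abundance ->
# orthologs, with a run configuration, structured per-stage logging, and a
# key-value summary report. Every output file carries a header naming the
# package version, configuration hash and seed.

#' Run configuration for the pipeline
#'
#' @param stages Character vector of stages to run, in order, from
#'   `c("simulate", "detect", "classify", "abundance")`.
#' @param out_dir Output directory (created if missing).
#' @param sim [simulation_config()] driving the simulate stage.
#' @param min_junction_reads,min_reads,flank,max_hops,distance_to,
#'   both_mix,spread_threshold,polya_window Analysis thresholds; see the
#'   stage functions for semantics and defaults.
#' @param detect_condition Condition whose junctions drive detection and
#'   classification; default `"kd"`.
#' @param paths Named list of input paths for stages run without the
#'   simulate stage (`gtf`, `alu_bed`, `polya_bed`, `predicted_bed`,
#'   `sam_control`, `sam_kd`, `fpkm`).
#' @param log_level `"info"` or `"quiet"`.
#'
#' @return A `run_config` list with a stable configuration hash.
#' @export
run_config <- function(stages = c("simulate", "detect", "classify",
                                  "abundance"),
                       out_dir = tempfile("aluexon_run_"),
                       sim = simulation_config(),
                       min_junction_reads = 1L, min_reads = 1L,
                       flank = 10L, max_hops = 3L, distance_to = "exon",
                       both_mix = 0.5, spread_threshold = 0.10,
                       polya_window = 10000L,
                       detect_condition = "kd",
                       paths = list(), log_level = "info") {
  cfg <- list(stages = stages, out_dir = out_dir, sim = sim,
              min_junction_reads = as.integer(min_junction_reads),
              min_reads = as.integer(min_reads), flank = as.integer(flank),
              max_hops = as.integer(max_hops), distance_to = distance_to,
              both_mix = both_mix, spread_threshold = spread_threshold,
              polya_window = as.integer(polya_window),
              detect_condition = detect_condition, paths = paths,
              log_level = log_level)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

# hash over the effective parameters only (not output paths or verbosity)
config_hash <- function(cfg) {
  eff <- cfg[c("stages", "sim", "min_junction_reads", "min_reads", "flank",
               "max_hops", "distance_to", "both_mix", "spread_threshold",
               "polya_window", "detect_condition")]
  rlang::hash(eff)
}

log_msg <- function(cfg, ...) {
  if (identical(cfg$log_level, "quiet")) return(invisible())
  message(sprintf("[aluexon %s] ", format(Sys.time(), "%H:%M:%S")), ...)
}

meta_comments <- function(cfg) {
  c(sprintf("aluexon %s", as.character(packageVersion("aluexon"))),
    sprintf("config_hash=%s seed=%d", cfg$hash, cfg$sim$seed))
}

#' Run the Alu exonisation pipeline
#'
#' Executes the enabled stages in order. The simulate stage writes
#' `genome.gtf`, `alu.bed`, `polya.bed`, `predicted_exons.bed`,
#' `control.sam`, `kd.sam`, `fpkm.tsv` and `truth.tsv` into `out_dir`;
#' detect writes `candidates.tsv`; classify writes `calls.tsv`,
#' `calls.bed` and `summary.tsv`; abundance writes `relabund.tsv`. Stages
#' run from files, so detect/classify/abundance can also consume external
#' inputs via `config$paths`. A stage failure raises a condition of class
#' `aluexon_stage_error` naming the stage.
#'
#' @param config A [run_config()].
#'
#' @return Invisibly, a list with the produced `artifacts` (paths), the
#'   final `calls` table (if classify ran) and the `summary` table.
#' @export
run_pipeline <- function(config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- list()
  p <- function(f) file.path(config$out_dir, f)
  cmt <- meta_comments(config)
  calls <- NULL
  summary_dt <- NULL

  in_path <- function(key, default) {
    if (!is.null(config$paths[[key]])) config$paths[[key]] else default
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) {
      stop(rlang::error_cnd(class = "aluexon_stage_error",
                            message = sprintf("stage '%s' failed: %s",
                                              stage, conditionMessage(e))))
    })
  }

  if ("simulate" %in% config$stages) {
    log_msg(config, "simulate: ", config$sim$n_genes, " genes, seed ",
            config$sim$seed)
    run_stage("simulate", {
      ann <- generate_annotation(config$sim)
      write_gtf(ann$bundle$genes, p("genome.gtf"), comments = cmt)
      write_bed(ann$bundle$alu, p("alu.bed"), comments = cmt)
      write_bed(ann$bundle$polya, p("polya.bed"), comments = cmt)
      write_bed(ann$bundle$predicted_exons, p("predicted_exons.bed"),
                comments = cmt)
      for (cond in c("control", "kd")) {
        rd <- simulate_reads(ann$bundle, ann$events, config$sim, cond)
        write_sam(rd, p(paste0(cond, ".sam")),
                  seq_lengths = ann$bundle$seq_lengths, comments = cmt)
      }
      fp <- generate_fpkm_matrix(ann$events, config$sim)
      write_tsv_with_header(fp$matrix, p("fpkm.tsv"), cmt)
      write_tsv_with_header(ann$events, p("truth.tsv"), cmt)
      write_tsv_with_header(fp$truth, p("fpkm_truth.tsv"), cmt)
      art[c("gtf", "alu_bed", "polya_bed", "predicted_bed", "sam_control",
            "sam_kd", "fpkm", "truth")] <- list(
        p("genome.gtf"), p("alu.bed"), p("polya.bed"),
        p("predicted_exons.bed"), p("control.sam"), p("kd.sam"),
        p("fpkm.tsv"), p("truth.tsv"))
    })
  }

  needs_reads <- any(c("detect", "classify") %in% config$stages)
  if (needs_reads) {
    reads <- run_stage("input", list(
      control = read_sam(in_path("sam_control", p("control.sam"))),
      kd = read_sam(in_path("sam_kd", p("kd.sam")))))
    predicted <- run_stage("input", read_bed(
      in_path("predicted_bed", p("predicted_exons.bed")), kind = "exon"))
    alu <- run_stage("input", read_bed(in_path("alu_bed", p("alu.bed")),
                                       kind = "alu"))
  }

  if ("detect" %in% config$stages) {
    log_msg(config, "detect: ", nrow(predicted), " predicted exons")
    run_stage("detect", {
      jx <- aggregate_junctions(reads[[config$detect_condition]])
      cand <- call_alu_exons(predicted, alu, jx,
                             min_junction_reads = config$min_junction_reads)
      write_tsv_with_header(cand, p("candidates.tsv"), cmt)
      art$candidates <- p("candidates.tsv")
      log_msg(config, "detect: ", sum(cand$pass), " passing candidates")
    })
  }

  if ("classify" %in% config$stages) {
    run_stage("classify", {
      cand <- fread(p("candidates.tsv"), skip = length(cmt))
      genes <- read_gtf(in_path("gtf", p("genome.gtf")))
      polya <- read_bed(in_path("polya_bed", p("polya.bed")), kind = "polya")
      genes <- assign_polya(genes, polya, window = config$polya_window)
      calls <- classify_calls(
        cand, genes, reads, predicted,
        detect_condition = config$detect_condition,
        max_hops = config$max_hops, min_reads = config$min_reads,
        flank = config$flank, distance_to = config$distance_to,
        both_mix = config$both_mix)
      paths <- write_calls(calls, p("calls.tsv"), comments = cmt)
      summary_dt <- summarize_calls(calls)
      write_tsv_with_header(summary_dt, p("summary.tsv"), cmt)
      art[c("calls", "calls_bed", "summary")] <-
        list(paths[["tsv"]], paths[["bed"]], p("summary.tsv"))
      log_msg(config, "classify: ", nrow(calls), " calls (",
              sum(calls$locus_class == "intergenic"), " intergenic)")
    })
  }

  if ("abundance" %in% config$stages) {
    run_stage("abundance", {
      mat <- read_fpkm(in_path("fpkm", p("fpkm.tsv")))
      rep_dt <- abundance_report(mat, config$spread_threshold)
      write_tsv_with_header(rep_dt, p("relabund.tsv"), cmt)
      art$relabund <- p("relabund.tsv")
    })
  }

  invisible(list(artifacts = art, calls = calls, summary = summary_dt,
                 config = config))
}

write_tsv_with_header <- function(x, path, comments = character()) {
  con <- file(path, "w")
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(names(x), collapse = "\t"), con)
  if (nrow(x)) {
    writeLines(do.call(paste, c(lapply(x, format_tsv_field), sep = "\t")),
               con)
  }
  close(con)
  invisible(path)
}

#' Summarize a call table
#'
#' Key-value summary: total Alu exons, locus-class and scenario
#' breakdowns, distance minimum/median/maximum, the fraction of intergenic
#' calls followed by downstream cryptic exons, and a ten-bin histogram of
#' the splicing contribution on \[0, 1\].
#'
#' @param calls Call table from [classify_calls()].
#' @return A two-column `data.table` (`key`, `value`).
#' @export
summarize_calls <- function(calls) {
  calls <- as.data.table(calls)
  inter <- calls[locus_class == "intergenic"]
  kv <- list(
    total_alu_exons = nrow(calls),
    intergenic = nrow(inter),
    intronic = sum(calls$locus_class == "intronic"),
    unlinked = sum(calls$locus_class == "unlinked"),
    scenario_terminal_exon_skipping =
      sum(inter$scenario == "terminal_exon_skipping"),
    scenario_cryptic_5ss = sum(inter$scenario == "cryptic_5ss"),
    scenario_both = sum(inter$scenario == "both"),
    scenario_not_applicable = sum(inter$scenario == "not_applicable"),
    distance_min_bp = if (nrow(inter)) min(inter$distance_bp) else NA,
    distance_median_bp = if (nrow(inter)) median(inter$distance_bp) else NA,
    distance_max_bp = if (nrow(inter)) max(inter$distance_bp) else NA,
    downstream_cryptic_fraction = downstream_cryptic_fraction(inter)
  )
  hist_counts <- contribution_histogram(calls$splicing_contribution)
  for (i in seq_along(hist_counts)) {
    kv[[paste0("contribution_bin_", names(hist_counts)[i])]] <-
      hist_counts[[i]]
  }
  out <- data.table(k = names(kv),
                    value = vapply(kv,
                                   function(v) format_tsv_field(as.numeric(v)),
                                   character(1L)))
  setnames(out, "k", "key")
  out
}

#' Fraction of intergenic calls followed by downstream cryptic exons
#'
#' @param calls Call table (intergenic rows are selected internally).
#' @return Fraction in \[0, 1\] (`NA` when there are no intergenic calls).
#' @export
downstream_cryptic_fraction <- function(calls) {
  calls <- as.data.table(calls)
  inter <- if ("locus_class" %in% names(calls)) {
    calls[locus_class == "intergenic"]
  } else calls
  if (!nrow(inter)) return(NA_real_)
  sum(inter$downstream_cryptic_exons > 0, na.rm = TRUE) / nrow(inter)
}

# ten equal bins on [0,1]; right-closed, first bin includes 0
contribution_histogram <- function(x) {
  x <- x[!is.na(x)]
  br <- seq(0, 1, by = 0.1)
  counts <- table(cut(x, breaks = br, include.lowest = TRUE))
  setNames(as.integer(counts),
           sprintf("%02d_%02d", 0:9, seq_len(10L)))
}

#' Fraction of exons with appreciable inclusion in at least one tissue
#'
#' Screening convention for tissue panels: an exon counts as
#' tissue-included when its inclusion exceeds `threshold` in at least one
#' tissue column.
#'
#' @param inclusion Matrix or data.frame of inclusion fractions (rows =
#'   exons, columns = tissues).
#' @param threshold Minimum inclusion; default 0.10.
#' @return Fraction of rows with any tissue above threshold.
#' @export
tissue_inclusion_fraction <- function(inclusion, threshold = 0.10) {
  m <- as.matrix(inclusion)
  if (!nrow(m)) return(NA_real_)
  mean(apply(m, 1L, function(r) any(r > threshold, na.rm = TRUE)))
}

#' Compare pipeline calls against the planted truth
#'
#' Joins intergenic calls to the planted-event table by gene and reports
#' per-event agreement of locus class, scenario, distance and downstream
#' cryptic exon count, plus aggregate sensitivity (fraction of planted
#' events recovered with all four fields exact) and specificity (fraction
#' of event-free genes with no call).
#'
#' @param calls Call table (or path to a `calls.tsv`).
#' @param truth Planted-event table from [generate_annotation()] (or path
#'   to a `truth.tsv`).
#'
#' @return List with `per_event` (`data.table`), `sensitivity`,
#'   `specificity` (`NA` when vacuous) and `n_false_calls`.
#' @export
compare_to_truth <- function(calls, truth) {
  if (is.character(calls)) calls <- read_calls(calls)
  if (is.character(truth)) {
    lines <- readLines(truth, n = 10L)
    truth <- fread(truth, skip = sum(cumprod(startsWith(lines, "# "))))
  }
  calls <- as.data.table(calls)
  truth <- as.data.table(truth)
  if (nrow(calls) && !all(calls$gene_id %in% c(truth$gene_id, NA))) {
    stop("calls reference gene ids absent from the truth table")
  }
  ev <- truth[scenario != "none"]
  none <- truth[scenario == "none"]
  per_event <- ev[, .(gene_id, scenario_true = scenario,
                      distance_true = distance_bp,
                      cryptic_true = n_downstream_cryptic)]
  cc <- calls[, .(gene_id, locus_class, scenario_called = scenario,
                  distance_called = distance_bp,
                  cryptic_called = downstream_cryptic_exons)]
  per_event <- merge(per_event, cc, by = "gene_id", all.x = TRUE)
  per_event[, matched := !is.na(locus_class) & locus_class == "intergenic" &
              scenario_called == scenario_true &
              distance_called == distance_true &
              cryptic_called == cryptic_true]
  sens <- if (nrow(per_event)) mean(per_event$matched) else NA_real_
  false_calls <- calls[gene_id %in% none$gene_id |
                         (is.na(gene_id) & nrow(calls) > 0)]
  spec <- if (nrow(none)) {
    1 - data.table::uniqueN(false_calls$gene_id[!is.na(false_calls$gene_id)]) /
      nrow(none)
  } else NA_real_
  list(per_event = per_event[], sensitivity = sens, specificity = spec,
       n_false_calls = nrow(false_calls))
}
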