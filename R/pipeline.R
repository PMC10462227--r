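#' Load a cohort directory written by [write_cohort()]
#'
#' Reads both modality triplets, the gene model, peaks, metadata and the
#' fixture tables back into a `synth_cohort`-shaped list (ground-truth
#' tables are attached when present).
#'
#' @param dir cohort directory.
#' @return list with the same core elements as [generate_cohort()].
#' @export
load_cohort <- function(dir) {
  rna <- read_10x(file.path(dir, "rna"))
  atac <- read_10x(file.path(dir, "atac"))
  gene_model <- read_gene_model(file.path(dir, "gene_model.tsv"))
  pk_raw <- utils::read.table(file.path(dir, "peaks.bed"), sep = "\t",
                              header = FALSE, stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = pk_raw[[1]], start = pk_raw[[2]], end = pk_raw[[3]],
                      peak = if (ncol(pk_raw) >= 4) pk_raw[[4]] else
                        sprintf("PK%05d", seq_len(nrow(pk_raw))),
                      stringsAsFactors = FALSE)
  md_cells <- read_tsv(file.path(dir, "metadata.tsv"))
  md_pat <- read_tsv(file.path(dir, "patients.tsv"))
  fixtures <- list()
  if (file.exists(file.path(dir, "tf_map.tsv"))) {
    fixtures$tf_map <- read_tf_map(file.path(dir, "tf_map.tsv"))
  }
  if (file.exists(file.path(dir, "chip_peaks.bed"))) {
    chip <- read_bed(file.path(dir, "chip_peaks.bed"))
    chip$peak <- sprintf("CH%04d", seq_len(nrow(chip)))
    fixtures$chip_peaks <- chip
  }
  if (file.exists(file.path(dir, "kd_table.tsv"))) {
    fixtures$kd_table <- read_tsv(file.path(dir, "kd_table.tsv"))
  }
  truth <- NULL
  if (file.exists(file.path(dir, "truth_cells.tsv"))) {
    truth <- list(cells = read_tsv(file.path(dir, "truth_cells.tsv")))
    if (file.exists(file.path(dir, "truth_events.tsv"))) {
      truth$events <- read_tsv(file.path(dir, "truth_events.tsv"))
    }
    if (file.exists(file.path(dir, "truth_de_genes.tsv"))) {
      truth$de_genes <- read_tsv(file.path(dir, "truth_de_genes.tsv"))$gene
    }
  }
  list(rna = rna, atac = atac, gene_model = gene_model, peaks = peaks,
       metadata = list(cells = md_cells, patients = md_pat),
       fixtures = fixtures, truth = truth)
}

resolve_gene <- function(g, gene_model) {
  if (g %in% gene_model$gene) return(g)
  if (!is.null(gene_model$name) && g %in% gene_model$name) {
    return(gene_model$gene[match(g, gene_model$name)])
  }
  stop(sprintf("gene '%s' not found in gene model", g), call. = FALSE)
}

canonical_translocation_markers <- c("NSD2", "FGFR3", "CCND1", "CCND3",
                                     "MAF", "MAFB", "ITGB7", "CCND2", "MYC")

#' Run the full analysis pipeline
#'
#' Orchestrates the seven analysis stages over a simulated or loaded
#' multiome cohort: per-cell QC, iterative marker-percentile contaminant
#' removal, joint RNA+ATAC clustering, CNV inference with clone assignment
#' and genomic-event imputation, cluster-proportion association with
#' disease stage, differential expression/accessibility with signature
#' intersection, and TF promoter-peak analysis. Per-stage TSV outputs and a
#' summary are written under `out_dir`; stage timings and retained cell
#' counts are logged to stderr and `run.log`. Reruns with the same
#' configuration and seed produce byte-identical TSV outputs.
#'
#' @param config YAML config path or equivalent nested list; unknown keys
#'   raise a configuration error before any stage runs.
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @return list of class `pipeline_report`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  cfg <- read_config(config)
  seed <- cfg$seed %||% 1L
  out_dir <- out_dir %||% cfg$out_dir %||% tempfile("plasmapipe_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat(sprintf("run_pipeline seed=%d\n", as.integer(seed)), file = log_path)
  logf <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    cat(format(Sys.time(), "[%H:%M:%S] "), msg, "\n", sep = "", file = log_path,
        append = TRUE)
    message(msg)
  }
  stage_rows <- list()
  run_stage <- function(name, cells_in, fn) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(fn(), error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    logf("stage %-8s done in %.1fs", name, proc.time()[["elapsed"]] - t0)
    stage_rows[[length(stage_rows) + 1L]] <<- data.frame(
      stage = name, cells_in = cells_in, cells_out = res$n_cells,
      stringsAsFactors = FALSE)
    res
  }

  # ---- input -------------------------------------------------------------
  if (!is.null(cfg$input_dir)) {
    cohort <- load_cohort(cfg$input_dir)
  } else {
    sim <- cfg$simulate %||% list()
    if (is.null(sim$seed)) sim$seed <- seed
    cohort <- generate_cohort(do.call(synth_config, sim))
  }
  gm <- cohort$gene_model
  logf("input: %d cells, %d genes, %d peaks", nrow(cohort$rna), ncol(cohort$rna),
       ncol(cohort$atac))

  ccl <- cfg$cluster %||% list()
  k <- ccl$k %||% 20
  resolution <- ccl$resolution %||% 1.0
  n_comp <- ccl$n_components %||% 20
  n_feat <- ccl$n_features %||% 2000
  fusion <- ccl$fusion %||% "equal"
  cluster_counts <- function(counts) {
    norm <- normalize_log_cp10k(counts)
    feats <- select_variable_features(norm, n_feat)
    emb <- reduce(norm[, feats, drop = FALSE],
                  min(n_comp, length(feats) - 1, nrow(norm) - 1))
    snn_cluster(emb, k_neighbors = k, resolution = resolution, seed = seed)
  }

  # ---- stage 1: qc -------------------------------------------------------
  qcc <- cfg$qc %||% list()
  th <- qc_thresholds(min_counts = qcc$min_counts %||% 500,
                      min_features = qcc$min_features %||% 100,
                      max_features = qcc$max_features %||% 6000,
                      max_mito = qcc$max_mito %||% 1,
                      mito_prefix = qcc$mito_prefix %||% "MT-")
  qc_res <- run_stage("qc", nrow(cohort$rna), function() {
    r <- qc_filter_cells(cohort$rna, th)
    list(res = r, n_cells = r$n_kept)
  })
  kept <- qc_res$res$kept
  rna <- cohort$rna[kept, , drop = FALSE]
  atac <- cohort$atac[kept, , drop = FALSE]
  write_tsv(qc_res$res$report, file.path(out_dir, "qc_report.tsv"))

  # ---- stage 2: contaminant removal --------------------------------------
  marker <- resolve_gene(qcc$marker %||% "SDC1", gm)
  schedule <- qcc$schedule %||% c(0.90, 0.75)
  ip <- run_stage("contam", nrow(rna), function() {
    r <- iterative_plasma_selection(rna, cluster_counts, marker, schedule)
    list(res = r, n_cells = length(r$kept))
  })
  kept <- ip$res$kept
  rna <- rna[kept, , drop = FALSE]
  atac <- atac[kept, , drop = FALSE]
  writeLines(kept, file.path(out_dir, "kept_barcodes.tsv"))

  cells_md <- cohort$metadata$cells
  cells_md <- cells_md[match(kept, cells_md$barcode), ]
  patients_md <- cohort$metadata$patients

  # ---- stage 3: joint clustering -----------------------------------------
  cl <- run_stage("cluster", nrow(rna), function() {
    norm_rna <- normalize_log_cp10k(rna)
    norm_atac <- normalize_log_cp10k(atac)
    feats <- select_variable_features(norm_rna, n_feat)
    emb_rna <- reduce(norm_rna[, feats, drop = FALSE],
                      min(n_comp, length(feats) - 1, nrow(rna) - 1), "RNA")
    pfeats <- select_variable_features(norm_atac, n_feat)
    emb_atac <- reduce(norm_atac[, pfeats, drop = FALSE],
                       min(n_comp, length(pfeats) - 1, nrow(atac) - 1), "ATAC")
    fused <- fuse_modalities(emb_rna, emb_atac, mode = fusion, k_neighbors = k)
    labels <- joint_cluster(fused, resolution = resolution, seed = seed)
    list(norm_rna = norm_rna, norm_atac = norm_atac, labels = labels,
         weights = fused$weights, n_cells = length(labels))
  })
  labels <- cl$labels
  write_tsv(data.frame(barcode = names(labels), cluster = as.integer(labels),
                       stringsAsFactors = FALSE),
            file.path(out_dir, "clusters.tsv"))
  write_tsv(cl$weights, file.path(out_dir, "modality_weights.tsv"))

  # ---- stage 4: cnv ------------------------------------------------------
  cnvc <- cfg$cnv %||% list()
  window <- cnvc$window %||% 51
  t_loss <- cnvc$t_loss %||% -0.15
  t_gain <- cnvc$t_gain %||% 0.15
  t_amp <- cnvc$t_amp %||% 0.45
  cnv <- run_stage("cnv", nrow(rna), function() {
    ref_cluster <- cnvc$reference_cluster
    if (is.null(ref_cluster)) {
      prof0 <- infer_cnv_profile(cl$norm_rna, gm, rownames(rna), window)
      arm0 <- call_arm_events(prof0, t_loss, t_gain, t_amp)
      score <- tapply(rowMeans(abs(arm0$mean)), labels, mean)
      ref_cluster <- names(score)[which.min(score)]
    }
    ref_cells <- names(labels)[as.character(labels) == as.character(ref_cluster)]
    profile <- infer_cnv_profile(cl$norm_rna, gm, ref_cells, window)
    arm <- call_arm_events(profile, t_loss, t_gain, t_amp)
    clones <- assign_clones(profile, "from_labels", labels = labels,
                            t_loss = t_loss, t_gain = t_gain, t_amp = t_amp)
    pat_calls <- patient_arm_calls(arm, cells_md$patient)
    hrd <- impute_hyperdiploidy(pat_calls,
                                cnvc$trisomy_arms %||% c("chr1p", "chr3p", "chr3q"),
                                cnvc$min_trisomy_gains %||% 2)
    markers <- intersect(canonical_translocation_markers, gm$name)
    transloc <- if (length(markers) >= 1) {
      ids <- gm$gene[match(markers, gm$name)]
      tl <- impute_translocation(cl$norm_rna, cells_md$patient,
                                 stats::setNames(ids, markers),
                                 cnvc$z_threshold %||% 2)
      tl$call_name <- markers[match(tl$call, ids)]
      tl
    } else NULL
    list(reference_cluster = ref_cluster, profile = profile, arm = arm,
         clones = clones, patient_calls = pat_calls, hyperdiploid = hrd,
         translocation = transloc, n_cells = nrow(profile$mat))
  })
  write_tsv(data.frame(patient = rownames(cnv$patient_calls),
                       cnv$patient_calls,
                       hyperdiploid = unname(cnv$hyperdiploid[rownames(cnv$patient_calls)]),
                       stringsAsFactors = FALSE, check.names = FALSE),
            file.path(out_dir, "patient_arm_calls.tsv"))
  if (!is.null(cnv$translocation)) {
    write_tsv(cnv$translocation, file.path(out_dir, "translocation_imputation.tsv"))
  }
  write_tsv(data.frame(barcode = names(cnv$clones$clone),
                       clone = unname(cnv$clones$clone), stringsAsFactors = FALSE),
            file.path(out_dir, "clones.tsv"))

  # ---- stage 5: association ----------------------------------------------
  assoc <- run_stage("assoc", nrow(rna), function() {
    prop <- cluster_proportions(labels, cells_md$patient)
    pm <- patients_md[match(rownames(prop), patients_md$patient), ]
    stage_cov <- stats::setNames(factor(pm$stage,
                                        levels = c("SMM", "NDMM", "RRMM")),
                                 pm$patient)
    stage_cov <- droplevels(stage_cov)
    res <- group_test(prop, stage_cov)
    res$covariate <- "stage"
    all_tests <- list(res)
    # genomic covariates: arm event carrier status, amp-vs-gain among
    # carriers, and mutation flag, tested on the same proportion matrix
    add_cov <- function(values, name, rows = rownames(prop)) {
      cov <- stats::setNames(as.character(values), rownames(prop))[rows]
      if (length(unique(cov)) < 2) return()
      t <- group_test(prop[rows, , drop = FALSE], cov)
      t$covariate <- name
      all_tests[[length(all_tests) + 1L]] <<- t
    }
    if (!is.null(pm$arm_event)) {
      add_cov(ifelse(pm$arm_event == "none", "normal", "event"), "arm_1q")
      carriers <- rownames(prop)[pm$arm_event %in% c("gain", "amp")]
      if (length(carriers) >= 2) {
        add_cov(pm$arm_event, "amp_vs_gain", carriers)
      }
    }
    if (!is.null(pm$tp53)) add_cov(ifelse(pm$tp53, "mut", "wt"), "tp53")
    tests <- do.call(rbind, all_tests)
    # one BH family across every (cluster x covariate x contrast) test
    tested <- !tests$skipped & !is.na(tests$p_val)
    tests$fdr <- NA_real_
    tests$fdr[tested] <- bh_adjust(tests$p_val[tested])
    tests <- tests[order(tests$fdr), ]
    lv <- levels(stage_cov)
    extreme <- paste(lv[1], "vs", lv[length(lv)])
    cand <- tests[tests$covariate == "stage" & tests$contrast == extreme &
                    !tests$skipped, ]
    top <- cand$cluster[which.min(cand$p_val)]
    alt <- (pm$arm_event != "none") + pm$tp53
    names(alt) <- pm$patient
    corr <- alteration_count_correlation(prop[, top], alt)
    list(proportions = prop, tests = tests, top_cluster = top,
         alteration_correlation = corr, n_cells = nrow(rna))
  })
  write_tsv(data.frame(patient = rownames(assoc$proportions),
                       assoc$proportions, stringsAsFactors = FALSE,
                       check.names = FALSE),
            file.path(out_dir, "cluster_proportions.tsv"))
  write_tsv(assoc$tests, file.path(out_dir, "stage_association.tsv"))

  # ---- stage 6: differential ---------------------------------------------
  dcfg <- cfg$diff %||% list()
  dif <- run_stage("diff", nrow(rna), function() {
    in_cells <- names(labels)[labels == assoc$top_cluster]
    out_cells <- setdiff(names(labels), in_cells)
    deg <- differential_features(cl$norm_rna, in_cells, out_cells, "RNA",
                                 lfc_cutoff = dcfg$cutoff_rna,
                                 fdr = dcfg$fdr %||% 0.05,
                                 min_cells = dcfg$min_cells %||% 3)
    act <- gene_activity(atac, cohort$peaks, gm, dcfg$upstream %||% 2000)
    dac <- differential_features(normalize_log_cp10k(act + 0), in_cells,
                                 out_cells, "ATAC",
                                 lfc_cutoff = dcfg$cutoff_atac,
                                 fdr = dcfg$fdr %||% 0.05,
                                 min_cells = dcfg$min_cells %||% 3)
    sigs <- list()
    if (!is.null(cohort$fixtures$kd_table)) {
      kd_path <- file.path(out_dir, "kd_table.tsv")
      write_tsv(cohort$fixtures$kd_table, kd_path)
      sigs <- list(load_signature(kd_path, fc = dcfg$signature_fc %||% 2,
                                  p = dcfg$signature_p %||% 0.05, name = "kd"))
    }
    inter <- intersect_signatures(deg, dac, sigs)
    overlap <- NULL
    if (length(sigs)) {
      kd_down <- sigs[[1]]$genes[sigs[[1]]$direction < 0]
      overlap <- set_overlap_fisher(inter$consistent_up, kd_down, deg$feature)
    }
    list(deg = deg, dac = dac, intersections = inter, overlap = overlap,
         n_cells = nrow(rna))
  })
  write_tsv(dif$deg, file.path(out_dir, "deg.tsv"))
  write_tsv(dif$dac, file.path(out_dir, "dac.tsv"))

  # ---- stage 7: tf -------------------------------------------------------
  tcfg <- cfg$tf %||% list()
  tfres <- run_stage("tf", nrow(rna), function() {
    if (is.null(cohort$fixtures$tf_map) || is.null(cohort$fixtures$chip_peaks)) {
      return(list(skipped = TRUE, n_cells = nrow(rna)))
    }
    target <- resolve_gene(tcfg$gene %||% cohort$truth$target_gene %||% "PHF19L", gm)
    region <- tcfg$region %||% "chr1q"
    hits <- tfs_targeting(target, cohort$fixtures$tf_map)
    regional <- filter_tfs_by_region(hits$union, gm, region)
    chip <- cohort$fixtures$chip_peaks
    prom <- promoter_peaks(chip, target, gm, tcfg$distance %||% 5000)
    ranks <- if (nrow(prom)) {
      peak_percentile(stats::setNames(chip$score, chip$peak), prom$peak)
    } else NULL
    list(skipped = FALSE, target = target, tfs = hits, regional_tfs = regional,
         promoter_peaks = prom, ranks = ranks, n_cells = nrow(rna))
  })
  if (!tfres$skipped) {
    write_tsv(data.frame(tf = tfres$tfs$union,
                         on_region = tfres$tfs$union %in% tfres$regional_tfs,
                         stringsAsFactors = FALSE),
              file.path(out_dir, "tf_candidates.tsv"))
    if (!is.null(tfres$ranks)) {
      write_tsv(tfres$ranks, file.path(out_dir, "promoter_peak_ranks.tsv"))
    }
  }

  stages <- do.call(rbind, stage_rows)
  write_tsv(stages, file.path(out_dir, "report.tsv"))
  logf("pipeline complete: %d/%d stages", nrow(stages), 7L)

  structure(list(stages = stages, out_dir = out_dir, seed = seed,
                 qc = qc_res$res, plasma = ip$res, labels = labels,
                 cnv = cnv[setdiff(names(cnv), "profile")],
                 assoc = assoc, diff = dif, tf = tfres,
                 reference_cluster = cnv$reference_cluster),
            class = "pipeline_report")
}

#' @exportS3Method base::print
print.pipeline_report <- function(x, ...) {
  cat("plasmapipe run (seed", x$seed, ")\n")
  print(x$stages, row.names = FALSE)
  cat("top stage-associated cluster:", x$assoc$top_cluster, "\n")
  invisible(x)
}
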