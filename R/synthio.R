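#' Configuration for a synthetic multiome cohort
#'
#' Builds and validates the parameter set driving [generate_cohort()]. The
#' defaults emulate the statistical structure of a plasma-cell disorder
#' cohort profiled by single-cell multiome (RNA + ATAC): three disease-stage
#' groups (smoldering, newly diagnosed, relapsed/refractory), a marker-silent
#' contaminant (non-plasma) population in every sample, a rare malignant
#' cluster whose per-patient proportion rises across stages (means
#' 0.01/0.03/0.08), clonal arm-level gains/amplifications expressed as dosage
#' shifts in both modalities, translocation-marker overexpression in carrier
#' patients, and a TF/target co-expression effect confined to the rare
#' cluster.
#'
#' Counts are negative binomial with per-gene baseline means drawn
#' LogNormal(`base_mean_meanlog`, `base_mean_sdlog`) and a per-cell log-normal
#' library-size factor. The pseudo-genome has `n_chromosomes` chromosomes of
#' two arms each, with genes laid out on a deterministic grid.
#'
#' @param n_patients integer vector of length 3: patients per stage group.
#' @param cells_per_patient cells simulated per patient (>= 50).
#' @param n_genes,n_chromosomes,n_peaks pseudo-genome size.
#' @param contaminant_fraction expected fraction of marker-silent
#'   contaminant cells per patient.
#' @param normal_fraction expected fraction of normal plasma cells among
#'   non-contaminant cells.
#' @param rare_mean length-3 vector: mean rare-cluster proportion per stage
#'   group (among non-contaminant cells).
#' @param rare_concentration Beta concentration for the per-patient draws of
#'   rare and normal fractions.
#' @param base_mean_meanlog,base_mean_sdlog log-normal parameters of per-gene
#'   baseline NB means (counts).
#' @param dispersion NB size parameter (shared).
#' @param libsize_sdlog sd(log) of the per-cell library-size factor.
#' @param gain_multiplier,amp_multiplier dosage multipliers for arm gain /
#'   amplification.
#' @param gain_arm arm label carrying the planted high-risk gain/amp.
#' @param n_gain_carriers,n_amp_carriers carriers of gain / amp on `gain_arm`,
#'   assigned deterministically among stage-2/3 patients.
#' @param subclone_fraction fraction of a carrier's malignant cells in the
#'   altered clone (1 = clonal event).
#' @param n_hyperdiploid_carriers patients with gains on `trisomy_arms`.
#' @param trisomy_arms arm set whose joint gain defines hyperdiploidy.
#' @param n_translocation_carriers patients overexpressing a translocation
#'   marker gene in all malignant cells.
#' @param translocation_markers marker gene names cycled over carriers.
#' @param translocation_multiplier marker overexpression factor.
#' @param n_tp53_carriers patients flagged with a TP53-analog mutation
#'   (annotation only; no expression effect).
#' @param marker_gene name given to the plasma-marker (SDC1-analog) gene;
#'   contaminant cells have its mean forced to zero.
#' @param marker_mean baseline NB mean of the plasma-marker gene.
#' @param contaminant_program_size,contaminant_program_multiplier size and
#'   fold-change of the gene program that separates contaminants.
#' @param n_de_genes,de_multiplier planted differential genes for the rare
#'   cluster and their fold-change.
#' @param de_min_base_mean,de_max_base_mean planted-effect genes are drawn
#'   among genes with baseline mean inside this band: an effect on a
#'   near-silent gene is undetectable under the pseudocount fold-change
#'   convention, while planting on the brightest genes inflates the
#'   in-group library and compositionally deflates every fold.
#' @param tf_gene_name,target_gene_name names of the planted transcription
#'   factor (resident on `gain_arm`) and its target gene.
#' @param tf_effect fold-change of TF and target in rare-cluster cells.
#' @param peak_mean_meanlog,peak_mean_sdlog log-normal parameters of per-peak
#'   baseline ATAC means.
#' @param dac_multiplier accessibility fold-change, in rare-cluster cells, of
#'   the promoter peaks of planted genes (mirrors the DE direction).
#' @param chip_n_peaks,chip_promoter_rank size of the synthetic ChIP peak
#'   fixture and the rank (1 = strongest) planted for the peak at the target
#'   gene's promoter.
#' @param seed global seed; per-patient substreams are derived from it.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_patients = c(8L, 8L, 8L),
                         cells_per_patient = 400L,
                         n_genes = 500L,
                         n_chromosomes = 4L,
                         n_peaks = 1000L,
                         contaminant_fraction = 0.10,
                         normal_fraction = 0.20,
                         rare_mean = c(0.01, 0.03, 0.08),
                         rare_concentration = 50,
                         base_mean_meanlog = log(3),
                         base_mean_sdlog = 0.6,
                         dispersion = 2,
                         libsize_sdlog = 0.3,
                         gain_multiplier = 1.5,
                         amp_multiplier = 2.0,
                         gain_arm = "chr1q",
                         n_gain_carriers = 2L,
                         n_amp_carriers = 2L,
                         subclone_fraction = 1.0,
                         n_hyperdiploid_carriers = 1L,
                         trisomy_arms = c("chr1p", "chr3p", "chr3q"),
                         n_translocation_carriers = 1L,
                         translocation_markers = c("CCND1", "NSD2"),
                         translocation_multiplier = 8,
                         n_tp53_carriers = 2L,
                         marker_gene = "SDC1",
                         marker_mean = 8,
                         contaminant_program_size = 40L,
                         contaminant_program_multiplier = 6,
                         n_de_genes = 30L,
                         de_multiplier = 4,
                         de_min_base_mean = 3,
                         de_max_base_mean = 6,
                         tf_gene_name = "PBX1L",
                         target_gene_name = "PHF19L",
                         tf_effect = 6,
                         peak_mean_meanlog = log(0.8),
                         peak_mean_sdlog = 0.5,
                         dac_multiplier = 4,
                         chip_n_peaks = 200L,
                         chip_promoter_rank = 8L,
                         seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "synth_config"
  validate_synth_config(cfg)
  cfg
}

validate_synth_config <- function(cfg) {
  frac_fields <- c("contaminant_fraction", "normal_fraction", "subclone_fraction")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      stop_config(f, "must be a fraction in [0, 1]")
    }
  }
  if (!is.numeric(cfg$rare_mean) || length(cfg$rare_mean) != 3 ||
      any(cfg$rare_mean < 0) || any(cfg$rare_mean > 1)) {
    stop_config("rare_mean", "must be three fractions in [0, 1]")
  }
  mult_fields <- c("gain_multiplier", "amp_multiplier", "translocation_multiplier",
                   "contaminant_program_multiplier", "de_multiplier", "tf_effect",
                   "dac_multiplier")
  for (f in mult_fields) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || cfg[[f]] <= 0) {
      stop_config(f, "must be a positive multiplier")
    }
  }
  if (cfg$cells_per_patient < 50) stop_config("cells_per_patient", "must be >= 50")
  if (length(cfg$n_patients) != 3 || any(cfg$n_patients < 1)) {
    stop_config("n_patients", "must give a patient count for each of 3 stage groups")
  }
  if (cfg$normal_fraction + max(cfg$rare_mean) >= 1) {
    stop_config("normal_fraction", "plus max(rare_mean) must stay below 1 (invalid mixture)")
  }
  if (cfg$n_peaks < cfg$n_genes) {
    stop_config("n_peaks", "must be >= n_genes (one promoter peak per gene)")
  }
  if (cfg$n_genes < 8 * cfg$n_chromosomes) {
    stop_config("n_genes", "must allow at least 4 genes per arm")
  }
  if (cfg$chip_promoter_rank < 1 || cfg$chip_promoter_rank > cfg$chip_n_peaks) {
    stop_config("chip_promoter_rank", "must lie in 1..chip_n_peaks")
  }
  if (cfg$dispersion <= 0) stop_config("dispersion", "must be positive")
  if (cfg$de_min_base_mean >= cfg$de_max_base_mean) {
    stop_config("de_min_base_mean", "must be below de_max_base_mean")
  }
  if (cfg$n_chromosomes < 2) stop_config("n_chromosomes", "must be >= 2")
  invisible(cfg)
}

#' Deterministic pseudo-genome gene model
#'
#' Genes are placed on a regular grid: per chromosome, gene k occupies the
#' 0-based half-open interval `[1000 + 2000 (k-1), 2000 + 2000 (k-1))`, with
#' alternating strand. The first half of each chromosome is arm "p", the
#' second arm "q".
#'
#' @param n_genes total genes.
#' @param n_chromosomes chromosomes (two arms each).
#' @return data.frame with columns gene, chrom, start, end, strand, arm.
#' @export
make_gene_model <- function(n_genes = 500L, n_chromosomes = 4L) {
  per_chrom <- diff(floor(seq(0, n_genes, length.out = n_chromosomes + 1)))
  rows <- vector("list", n_chromosomes)
  idx0 <- 0L
  for (c in seq_len(n_chromosomes)) {
    nc <- per_chrom[c]
    k <- seq_len(nc)
    start <- 1000L + 2000L * (k - 1L)
    rows[[c]] <- data.frame(
      gene = sprintf("G%04d", idx0 + k),
      chrom = paste0("chr", c),
      start = start,
      end = start + 1000L,
      strand = ifelse(k %% 2L == 1L, "+", "-"),
      arm = paste0("chr", c, ifelse(k <= ceiling(nc / 2), "p", "q")),
      stringsAsFactors = FALSE
    )
    idx0 <- idx0 + nc
  }
  do.call(rbind, rows)
}

# chromosome lengths implied by the grid layout
chrom_lengths <- function(gene_model) {
  vapply(split(gene_model$end, gene_model$chrom),
         function(e) max(e) + 1000L, numeric(1))
}

# draw per-patient population composition; RNG must already be set.
# Returns probabilities over (contaminant, normal, bulk, rare).
draw_composition <- function(cfg, stage_idx) {
  phi <- cfg$rare_concentration
  rmu <- cfg$rare_mean[stage_idx]
  rare <- if (rmu <= 0) 0 else stats::rbeta(1, rmu * phi, (1 - rmu) * phi)
  nmu <- cfg$normal_fraction
  normal <- if (nmu <= 0) 0 else stats::rbeta(1, nmu * phi, (1 - nmu) * phi)
  bulk <- max(0, 1 - normal - rare)
  p <- c(normal = normal, bulk = bulk, rare = rare)
  p / sum(p)
}

# assign carrier roles deterministically among stage-2/3 patients
assign_carriers <- function(cfg, patients, stages) {
  eligible <- patients[stages != 1L]
  need <- cfg$n_gain_carriers + cfg$n_amp_carriers +
    cfg$n_hyperdiploid_carriers + cfg$n_translocation_carriers
  if (length(eligible) < need) {
    stop_config("n_patients", sprintf(
      "must provide >= %d stage-2/3 patients to host the configured carriers", need))
  }
  i <- 0L
  take <- function(n) {
    out <- eligible[i + seq_len(n)]
    i <<- i + n
    out
  }
  gain <- take(cfg$n_gain_carriers)
  amp <- take(cfg$n_amp_carriers)
  hrd <- take(cfg$n_hyperdiploid_carriers)
  tl <- take(cfg$n_translocation_carriers)
  tp53 <- rev(eligible)[seq_len(min(cfg$n_tp53_carriers, length(eligible)))]
  list(gain = gain, amp = amp, hyperdiploid = hrd, translocation = tl, tp53 = tp53)
}

# per-clone dosage vector over genes (or peaks) for a patient's event table
dosage_vector <- function(arms, events, cfg) {
  d <- rep(1, length(arms))
  if (nrow(events) == 0) return(d)
  for (r in seq_len(nrow(events))) {
    mult <- if (events$class[r] == "amp") cfg$amp_multiplier else cfg$gain_multiplier
    d[arms == events$arm[r]] <- d[arms == events$arm[r]] * mult
  }
  d
}

# peak arm assignment by midpoint against the gene grid's arm boundary
peak_arms <- function(peaks, gene_model) {
  out <- rep(NA_character_, nrow(peaks))
  for (ch in unique(gene_model$chrom)) {
    gm <- gene_model[gene_model$chrom == ch, ]
    qstart <- min(gm$start[gm$arm == paste0(ch, "q")])
    sel <- peaks$chrom == ch
    mid <- (peaks$start[sel] + peaks$end[sel]) / 2
    out[sel] <- paste0(ch, ifelse(mid < qstart, "p", "q"))
  }
  out
}

nb_block <- function(n_cells, mu_gene, libsize, dispersion) {
  # cells x features block of NB counts with per-cell library factors
  mu <- outer(libsize, mu_gene)
  matrix(stats::rnbinom(length(mu), mu = as.vector(mu), size = dispersion),
         nrow = n_cells)
}

#' Generate a synthetic multiome cohort with ground truth
#'
#' Draws the full cohort described by a [synth_config()]: an RNA cells x
#' genes and an ATAC cells x peaks count matrix, the gene model and peak set,
#' per-cell/per-patient metadata (the genomic annotation table), fixture
#' tables for the TF analysis (TF-target maps, a scored ChIP peak set with a
#' planted promoter peak, and a knockdown differential-expression table), and
#' the ground truth of every planted effect. The same seed yields identical
#' output; per-patient random substreams are derived from the global seed so
#' existing patients are unchanged when the patient count grows.
#'
#' @param config a `synth_config`.
#' @return list of class `synth_cohort` with elements rna, atac, gene_model,
#'   peaks, metadata (cells, patients), truth, fixtures, config.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_synth_config(config)
  stages <- c("SMM", "NDMM", "RRMM")
  n_pat <- sum(cfg$n_patients)
  patients <- sprintf("P%02d", seq_len(n_pat))
  stage_idx <- rep(1:3, times = cfg$n_patients)

  gene_model <- make_gene_model(cfg$n_genes, cfg$n_chromosomes)
  genes <- gene_model$gene
  gene_names <- genes

  # deterministic special-gene placement
  chr2 <- which(gene_model$chrom == "chr2")
  last_chr <- which(gene_model$chrom == paste0("chr", cfg$n_chromosomes))
  marker_idx <- chr2[1]
  tmk_idx <- last_chr[1 + seq_along(cfg$translocation_markers)]
  arm_of <- gene_model$arm
  gain_arm_genes <- which(arm_of == cfg$gain_arm)
  tf_idx <- gain_arm_genes[ceiling(length(gain_arm_genes) / 2)]
  chr2q <- which(arm_of == "chr2q")
  target_idx <- chr2q[ceiling(length(chr2q) / 2)]
  gene_names[marker_idx] <- cfg$marker_gene
  gene_names[tmk_idx] <- cfg$translocation_markers
  gene_names[tf_idx] <- cfg$tf_gene_name
  gene_names[target_idx] <- cfg$target_gene_name

  globals <- with_seed(derive_seed(cfg$seed, 0L), {
    base_mean <- stats::rlnorm(cfg$n_genes, cfg$base_mean_meanlog, cfg$base_mean_sdlog)
    base_mean[marker_idx] <- cfg$marker_mean
    base_mean[tmk_idx] <- pmax(base_mean[tmk_idx], 5)
    base_mean[c(tf_idx, target_idx)] <- pmax(base_mean[c(tf_idx, target_idx)], 5)

    special <- c(marker_idx, tmk_idx, tf_idx, target_idx)
    de_pool <- setdiff(which(base_mean >= cfg$de_min_base_mean &
                               base_mean <= cfg$de_max_base_mean), special)
    de_idx <- sort(sample(de_pool, min(cfg$n_de_genes, length(de_pool))))
    cont_pool <- setdiff(seq_len(cfg$n_genes), c(special, de_idx))
    cont_idx <- sort(sample(cont_pool, min(cfg$contaminant_program_size, length(cont_pool))))

    # peaks: one promoter peak per gene plus uniform background
    prom_start <- ifelse(gene_model$strand == "+",
                         pmax(0L, gene_model$start - 800L), gene_model$end + 300L)
    prom <- data.frame(chrom = gene_model$chrom, start = prom_start,
                       end = prom_start + 500L, stringsAsFactors = FALSE)
    lens <- chrom_lengths(gene_model)
    n_bg <- cfg$n_peaks - cfg$n_genes
    bg_chrom <- sample(names(lens), n_bg, replace = TRUE)
    bg_start <- floor(stats::runif(n_bg, 0, lens[bg_chrom] - 500))
    bg <- data.frame(chrom = bg_chrom, start = as.integer(bg_start),
                     end = as.integer(bg_start) + 500L, stringsAsFactors = FALSE)
    peaks <- rbind(prom, bg)
    ord <- order(match(peaks$chrom, names(lens)), peaks$start, peaks$end)
    prom_of_gene <- match(seq_len(cfg$n_genes), ord)  # row of gene's promoter peak
    peaks <- peaks[ord, ]
    peaks$peak <- sprintf("PK%05d", seq_len(nrow(peaks)))
    rownames(peaks) <- NULL
    peak_mean <- stats::rlnorm(nrow(peaks), cfg$peak_mean_meanlog, cfg$peak_mean_sdlog)

    list(base_mean = base_mean, de_idx = de_idx, cont_idx = cont_idx,
         peaks = peaks, peak_mean = peak_mean, prom_of_gene = prom_of_gene)
  })

  carriers <- assign_carriers(cfg, patients, stage_idx)
  events <- list()
  for (p in carriers$gain) events[[length(events) + 1L]] <-
    data.frame(patient = p, arm = cfg$gain_arm, class = "gain",
               dosage = cfg$gain_multiplier, stringsAsFactors = FALSE)
  for (p in carriers$amp) events[[length(events) + 1L]] <-
    data.frame(patient = p, arm = cfg$gain_arm, class = "amp",
               dosage = cfg$amp_multiplier, stringsAsFactors = FALSE)
  for (p in carriers$hyperdiploid) events[[length(events) + 1L]] <-
    data.frame(patient = p, arm = cfg$trisomy_arms, class = "gain",
               dosage = cfg$gain_multiplier, stringsAsFactors = FALSE)
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(patient = character(), arm = character(), class = character(),
               dosage = numeric(), stringsAsFactors = FALSE)

  transloc <- stats::setNames(rep(NA_character_, n_pat), patients)
  if (length(carriers$translocation)) {
    transloc[carriers$translocation] <-
      rep(cfg$translocation_markers, length.out = length(carriers$translocation))
  }

  # accessibility mirrors the DE direction across each planted gene's locus:
  # every peak overlapping the gene body plus 2000 bp strand-aware upstream
  # (the gene-activity window) is boosted in rare cells
  planted_idx <- c(globals$de_idx, tf_idx, target_idx)
  dac_peak_rows <- sort(unique(unlist(lapply(planted_idx, function(g) {
    ws <- if (gene_model$strand[g] == "+") gene_model$start[g] - 2000L else gene_model$start[g]
    we <- if (gene_model$strand[g] == "+") gene_model$end[g] else gene_model$end[g] + 2000L
    which(globals$peaks$chrom == gene_model$chrom[g] &
            globals$peaks$start < we & globals$peaks$end > ws)
  }))))
  dac_peaks <- globals$peaks$peak[dac_peak_rows]
  parm <- peak_arms(globals$peaks, gene_model)

  rna_list <- vector("list", n_pat)
  atac_list <- vector("list", n_pat)
  cell_rows <- vector("list", n_pat)

  for (i in seq_len(n_pat)) {
    pat <- patients[i]
    pev <- events[events$patient == pat, , drop = FALSE]
    res <- with_seed(derive_seed(cfg$seed, i), {
      n <- cfg$cells_per_patient
      comp <- draw_composition(cfg, stage_idx[i])
      contam <- stats::runif(n) < cfg$contaminant_fraction
      pop <- rep("contaminant", n)
      pop[!contam] <- sample(c("normal", "bulk", "rare"), sum(!contam),
                             replace = TRUE, prob = comp)
      clone <- integer(n)
      malignant <- pop %in% c("bulk", "rare")
      if (nrow(pev) > 0) {
        altered <- malignant & (stats::runif(n) < cfg$subclone_fraction)
        clone[malignant] <- 1L
        clone[altered] <- 2L
      } else {
        clone[malignant] <- 1L
      }

      # group-wise expression multipliers
      mult_for <- function(popk, clk) {
        m <- rep(1, cfg$n_genes)
        if (popk == "contaminant") {
          m[marker_idx] <- 0
          m[globals$cont_idx] <- cfg$contaminant_program_multiplier
          return(m)
        }
        if (popk %in% c("bulk", "rare")) {
          if (!is.na(transloc[pat])) {
            m[tmk_idx[match(transloc[pat], cfg$translocation_markers)]] <-
              cfg$translocation_multiplier
          }
          if (clk == 2L) m <- m * dosage_vector(arm_of, pev, cfg)
          if (popk == "rare") {
            m[globals$de_idx] <- m[globals$de_idx] * cfg$de_multiplier
            m[c(tf_idx, target_idx)] <- m[c(tf_idx, target_idx)] * cfg$tf_effect
          }
        }
        m
      }
      mult_peak_for <- function(popk, clk) {
        m <- rep(1, nrow(globals$peaks))
        if (popk == "contaminant") return(m)
        if (clk == 2L) m <- m * dosage_vector(parm, pev, cfg)
        if (popk == "rare") {
          m[dac_peak_rows] <- m[dac_peak_rows] * cfg$dac_multiplier
        }
        m
      }

      lib_rna <- stats::rlnorm(n, 0, cfg$libsize_sdlog)
      lib_atac <- stats::rlnorm(n, 0, cfg$libsize_sdlog)
      rna <- matrix(0, n, cfg$n_genes)
      atac <- matrix(0, n, nrow(globals$peaks))
      grp <- interaction(pop, clone, drop = TRUE)
      for (g in levels(grp)) {
        sel <- which(grp == g)
        popk <- pop[sel[1]]
        clk <- clone[sel[1]]
        rna[sel, ] <- nb_block(length(sel), globals$base_mean * mult_for(popk, clk),
                               lib_rna[sel], cfg$dispersion)
        atac[sel, ] <- nb_block(length(sel), globals$peak_mean * mult_peak_for(popk, clk),
                                lib_atac[sel], cfg$dispersion)
      }
      list(pop = pop, clone = clone, rna = rna, atac = atac)
    })
    bc <- sprintf("%s_C%04d", pat, seq_len(cfg$cells_per_patient))
    rownames(res$rna) <- bc
    rownames(res$atac) <- bc
    rna_list[[i]] <- methods::as(res$rna, "CsparseMatrix")
    atac_list[[i]] <- methods::as(res$atac, "CsparseMatrix")
    cell_rows[[i]] <- data.frame(barcode = bc, patient = pat,
                                 stage = stages[stage_idx[i]],
                                 population = res$pop, clone = res$clone,
                                 stringsAsFactors = FALSE)
  }

  rna <- do.call(rbind, rna_list)
  atac <- do.call(rbind, atac_list)
  colnames(rna) <- genes
  colnames(atac) <- globals$peaks$peak
  cells <- do.call(rbind, cell_rows)
  rownames(cells) <- NULL

  patients_df <- data.frame(
    patient = patients,
    stage = stages[stage_idx],
    translocation = unname(transloc),
    arm_event = vapply(patients, function(p) {
      e <- events[events$patient == p & events$arm == cfg$gain_arm, ]
      if (nrow(e)) e$class[1] else "none"
    }, character(1)),
    hyperdiploid = patients %in% carriers$hyperdiploid,
    tp53 = patients %in% carriers$tp53,
    stringsAsFactors = FALSE
  )

  fixtures <- with_seed(derive_seed(cfg$seed, 0L, salt = 1L), {
    make_fixtures(cfg, gene_model, gene_names, globals, tf_idx, target_idx)
  })

  structure(list(
    rna = rna, atac = atac,
    gene_model = transform(gene_model, name = gene_names),
    peaks = globals$peaks[, c("chrom", "start", "end", "peak")],
    metadata = list(cells = cells[, c("barcode", "patient", "stage")],
                    patients = patients_df),
    truth = list(cells = cells,
                 events = events,
                 de_genes = genes[globals$de_idx],
                 contaminant_genes = genes[globals$cont_idx],
                 dac_peaks = dac_peaks,
                 tf_gene = genes[tf_idx],
                 target_gene = genes[target_idx],
                 marker_gene = genes[marker_idx]),
    fixtures = fixtures,
    config = cfg
  ), class = "synth_cohort")
}

# TF-target maps, scored ChIP peaks with a planted promoter peak, and a
# knockdown DE table; RNG must already be set.
make_fixtures <- function(cfg, gene_model, gene_names, globals, tf_idx, target_idx) {
  target <- gene_model$gene[target_idx]
  tf <- gene_model$gene[tf_idx]
  off_arm <- which(gene_model$arm != cfg$gain_arm)
  decoys <- gene_model$gene[off_arm[round(seq(3, length(off_arm) - 2, length.out = 4))]]
  decoys <- setdiff(decoys, c(tf, target))
  tf_map <- rbind(
    data.frame(tf = tf, target = target, source = "db1", stringsAsFactors = FALSE),
    data.frame(tf = tf, target = target, source = "db2", stringsAsFactors = FALSE),
    data.frame(tf = decoys[1:2], target = target, source = "db1", stringsAsFactors = FALSE),
    data.frame(tf = decoys[3:4], target = target, source = "db2", stringsAsFactors = FALSE),
    data.frame(tf = tf, target = decoys[1], source = "db1", stringsAsFactors = FALSE)
  )

  # ChIP peaks: background scores plus one peak in the target's promoter whose
  # score lands at the configured rank (rank 1 = strongest).
  lens <- chrom_lengths(gene_model)
  n_bg <- cfg$chip_n_peaks - 1L
  bg_chrom <- sample(names(lens), n_bg, replace = TRUE)
  bg_start <- as.integer(floor(stats::runif(n_bg, 0, lens[bg_chrom] - 400)))
  bg_score <- round(stats::rlnorm(n_bg, log(20), 0.8), 3)
  srt <- sort(bg_score, decreasing = TRUE)
  r <- cfg$chip_promoter_rank
  planted_score <- if (r == 1) srt[1] + 1 else round((srt[r - 1] + srt[r]) / 2, 3)
  tgt <- gene_model[target_idx, ]
  prom_start <- if (tgt$strand == "+") tgt$start - 700L else tgt$end + 200L
  chip <- data.frame(
    chrom = c(bg_chrom, tgt$chrom),
    start = c(bg_start, prom_start),
    end = c(bg_start + 400L, prom_start + 400L),
    score = c(bg_score, planted_score),
    stringsAsFactors = FALSE
  )
  ord <- order(match(chip$chrom, names(lens)), chip$start)
  chip <- chip[ord, ]
  chip$peak <- sprintf("CH%04d", seq_len(nrow(chip)))
  rownames(chip) <- NULL

  # knockdown DE table: knocking down the TF lowers its activated genes, so
  # the planted rare-cluster "up" genes appear with negative log2FC.
  kd_genes <- globals$de_idx[seq_len(min(20L, length(globals$de_idx)))]
  non_de <- setdiff(seq_len(cfg$n_genes), c(globals$de_idx, tf_idx, target_idx))
  kd_decoys <- non_de[round(seq(1, length(non_de), length.out = 30))]
  null_rows <- non_de[round(seq(2, length(non_de) - 1, length.out = 50))]
  kd_table <- data.frame(
    gene = gene_model$gene[c(kd_genes, target_idx, kd_decoys, null_rows)],
    log2FC = c(rep(-2, length(kd_genes)), -2.5, rep(-1.8, length(kd_decoys)),
               rep(0.1, length(null_rows))),
    p_val = c(rep(1e-4, length(kd_genes)), 1e-5, rep(1e-3, length(kd_decoys)),
              rep(0.5, length(null_rows))),
    stringsAsFactors = FALSE
  )
  kd_table$p_adj <- bh_adjust(kd_table$p_val)
  kd_table <- kd_table[!duplicated(kd_table$gene), ]

  list(tf_map = tf_map, chip_peaks = chip, kd_table = kd_table)
}

#' Simulate per-patient population proportions only
#'
#' Runs just the compositional layer of the cohort generator (the same
#' per-patient substreams and Beta/multinomial draws as [generate_cohort()]),
#' returning the realized per-patient proportions of the non-contaminant
#' populations. Used for association power and calibration studies where
#' count matrices are not needed.
#'
#' @param config a `synth_config`.
#' @return list with `proportions` (patients x populations matrix, rows
#'   summing to 1) and `stage` (named stage vector).
#' @export
simulate_proportions <- function(config) {
  cfg <- validate_synth_config(config)
  stages <- c("SMM", "NDMM", "RRMM")
  n_pat <- sum(cfg$n_patients)
  patients <- sprintf("P%02d", seq_len(n_pat))
  stage_idx <- rep(1:3, times = cfg$n_patients)
  pops <- c("normal", "bulk", "rare")
  prop <- matrix(0, n_pat, 3, dimnames = list(patients, pops))
  for (i in seq_len(n_pat)) {
    prop[i, ] <- with_seed(derive_seed(cfg$seed, i), {
      n <- cfg$cells_per_patient
      comp <- draw_composition(cfg, stage_idx[i])
      contam <- stats::runif(n) < cfg$contaminant_fraction
      pop <- sample(pops, sum(!contam), replace = TRUE, prob = comp)
      tab <- table(factor(pop, levels = pops))
      as.numeric(tab) / sum(tab)
    })
  }
  list(proportions = prop,
       stage = stats::setNames(stages[stage_idx], patients))
}

#' Simulate an expression matrix with planted clone dosages
#'
#' Negative-binomial counts for a set of cells partitioned into clones, where
#' each clone multiplies the baseline mean of all genes on selected arms by a
#' dosage factor. A focused generator for benchmarking copy-number inference
#' and clone assignment.
#'
#' @param gene_model gene model as from [make_gene_model()].
#' @param cell_clones character/integer vector: clone id per cell.
#' @param clone_dosage named list: clone id -> named numeric vector of
#'   arm -> dosage multiplier (arms absent keep dosage 1).
#' @param base_means optional per-gene baseline NB means; drawn
#'   LogNormal(log 3, 0.6) when NULL.
#' @param dispersion NB size parameter.
#' @param libsize_sdlog sd(log) of per-cell library factors.
#' @param seed integer seed.
#' @return sparse cells x genes count matrix with barcode rownames.
#' @export
simulate_clone_matrix <- function(gene_model, cell_clones, clone_dosage,
                                  base_means = NULL, dispersion = 2,
                                  libsize_sdlog = 0.3, seed = 1L) {
  n <- length(cell_clones)
  g <- nrow(gene_model)
  with_seed(seed, {
    if (is.null(base_means)) base_means <- stats::rlnorm(g, log(3), 0.6)
    lib <- stats::rlnorm(n, 0, libsize_sdlog)
    out <- matrix(0, n, g)
    for (cl in unique(cell_clones)) {
      sel <- which(cell_clones == cl)
      d <- rep(1, g)
      dos <- clone_dosage[[as.character(cl)]]
      if (!is.null(dos)) {
        for (a in names(dos)) d[gene_model$arm == a] <- dos[[a]]
      }
      out[sel, ] <- nb_block(length(sel), base_means * d, lib[sel], dispersion)
    }
    dimnames(out) <- list(sprintf("CELL%05d", seq_len(n)), gene_model$gene)
    methods::as(out, "CsparseMatrix")
  })
}

#' Simulate a two-group expression matrix with planted differential genes
#'
#' Negative-binomial counts for two cell groups where a planted gene subset
#' is multiplied by `multiplier` in the first group. Planted genes are drawn
#' among genes with baseline mean at or above `de_min_base_mean` (an effect
#' on a near-silent gene is undetectable by construction). A focused
#' generator for benchmarking the differential-testing stage.
#'
#' @param n_in,n_out cells per group.
#' @param n_genes genes.
#' @param n_de planted differential genes.
#' @param multiplier fold change planted in the first group.
#' @param base_mean_meanlog,base_mean_sdlog log-normal baseline means.
#' @param dispersion NB size.
#' @param libsize_sdlog per-cell library-size spread.
#' @param de_min_base_mean,de_max_base_mean selection band for planted genes.
#' @param seed integer seed.
#' @return list: `counts` (sparse cells x genes), `in_cells`, `out_cells`,
#'   `de_genes`.
#' @export
simulate_de_matrix <- function(n_in = 300L, n_out = 300L, n_genes = 2000L,
                               n_de = 100L, multiplier = 4,
                               base_mean_meanlog = log(3),
                               base_mean_sdlog = 0.6, dispersion = 4,
                               libsize_sdlog = 0.3, de_min_base_mean = 3,
                               de_max_base_mean = 6, seed = 1L) {
  with_seed(seed, {
    genes <- sprintf("G%04d", seq_len(n_genes))
    base <- stats::rlnorm(n_genes, base_mean_meanlog, base_mean_sdlog)
    pool <- which(base >= de_min_base_mean & base <= de_max_base_mean)
    de_idx <- sort(sample(pool, min(n_de, length(pool))))
    lib <- stats::rlnorm(n_in + n_out, 0, libsize_sdlog)
    mult <- rep(1, n_genes)
    mult[de_idx] <- multiplier
    counts <- rbind(
      nb_block(n_in, base * mult, lib[seq_len(n_in)], dispersion),
      nb_block(n_out, base, lib[n_in + seq_len(n_out)], dispersion)
    )
    dimnames(counts) <- list(sprintf("CELL%05d", seq_len(n_in + n_out)), genes)
    list(counts = methods::as(counts, "CsparseMatrix"),
         in_cells = rownames(counts)[seq_len(n_in)],
         out_cells = rownames(counts)[n_in + seq_len(n_out)],
         de_genes = genes[de_idx])
  })
}

#' Write a synthetic cohort to disk in plain-text formats
#'
#' Emits one 10x-style triplet directory per modality (`rna/`, `atac/` with
#' `matrix.mtx`, `barcodes.tsv`, `features.tsv`; matrix rows are cells),
#' TSV metadata/annotation/ground-truth tables, the gene model, a BED peak
#' file, and the TF-analysis fixtures. [read_10x()] on the written
#' directories reproduces the count matrices exactly.
#'
#' @param cohort a `synth_cohort`.
#' @param dir output directory (created if missing).
#' @return named character vector of written paths, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synth_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop(sprintf("cannot create output directory '%s'", dir), call. = FALSE)
  paths <- c()
  feat_names <- cohort$gene_model$name
  paths["rna"] <- write_10x(cohort$rna, file.path(dir, "rna"), "RNA", feat_names)
  pk <- cohort$peaks
  paths["atac"] <- write_10x(cohort$atac, file.path(dir, "atac"), "ATAC",
                             sprintf("%s:%d-%d", pk$chrom, pk$start, pk$end))
  paths["metadata"] <- write_tsv(cohort$metadata$cells, file.path(dir, "metadata.tsv"))
  paths["patients"] <- write_tsv(cohort$metadata$patients, file.path(dir, "patients.tsv"))
  paths["truth_cells"] <- write_tsv(cohort$truth$cells, file.path(dir, "truth_cells.tsv"))
  paths["truth_events"] <- write_tsv(cohort$truth$events, file.path(dir, "truth_events.tsv"))
  paths["gene_model"] <- write_tsv(cohort$gene_model, file.path(dir, "gene_model.tsv"))
  paths["peaks"] <- write_bed(cohort$peaks, file.path(dir, "peaks.bed"))
  paths["tf_map"] <- write_tsv(cohort$fixtures$tf_map, file.path(dir, "tf_map.tsv"))
  chip <- cohort$fixtures$chip_peaks[, c("chrom", "start", "end", "score")]
  paths["chip_peaks"] <- write_bed(chip, file.path(dir, "chip_peaks.bed"))
  paths["kd_table"] <- write_tsv(cohort$fixtures$kd_table, file.path(dir, "kd_table.tsv"))
  de <- data.frame(gene = cohort$truth$de_genes, stringsAsFactors = FALSE)
  paths["truth_de_genes"] <- write_tsv(de, file.path(dir, "truth_de_genes.tsv"))
  invisible(paths)
}

#' @exportS3Method base::print
print.synth_cohort <- function(x, ...) {
  cat(sprintf("synthetic multiome cohort: %d cells, %d genes, %d peaks, %d patients\n",
              nrow(x$rna), ncol(x$rna), ncol(x$atac), nrow(x$metadata$patients)))
  cat(sprintf("stages: %s\n",
              paste(sprintf("%s=%d", names(table(x$metadata$patients$stage)),
                            table(x$metadata$patients$stage)), collapse = " ")))
  invisible(x)
}
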