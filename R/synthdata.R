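#' Configuration for the synthetic acetylation/expression time-course generator
#'
#' Describes the layout and statistical structure of a simulated promoter
#' ChIP-chip acetylation study with matched expression data: probe tiling
#' around the TSS, replicate structure, the differentiation time course,
#' class fractions, and the day-by-day coupling between acetylation change
#' and expression change.
#'
#' @param n_genes Number of genes to simulate.
#' @param n_control_probes Number of un-acetylated control probes (the
#'   background null) per array.
#' @param probes_per_gene_mean Mean number of probes per gene.
#' @param probe_spacing_bp Grid spacing of probe positions in base pairs.
#' @param tss_window_bp Half-width of the promoter window around the TSS;
#'   probes live in `[-tss_window_bp, +tss_window_bp]`.
#' @param days Ordered vector of measurement days; day 0 is the anchor state.
#' @param chip_replicates Number of ChIP-chip replicates per day.
#' @param expr_replicates Number of expression replicates per day.
#' @param frac_up,frac_down Fractions of transcriptionally up-/down-regulated
#'   genes (defaults total ~5% differential).
#' @param frac_esc Fraction of "ESC-like" genes carrying elevated baseline
#'   acetylation and a strong monotone loss over the time course.
#' @param coupling_by_day Per-day coupling coefficient (one per entry of
#'   `days`) between standardized mean acetylation change and expression
#'   change; the default increases over the course.
#' @param noise_sd_acet,noise_sd_expr Replicate-level Gaussian noise standard
#'   deviations of log-scale acetylation signal and expression.
#' @param island_frac Expected fraction of a gene's probe positions inside its
#'   acetylation island.
#' @param island_height Above-background log-signal of island probes at day 0.
#' @param esc_baseline Extra baseline signal added everywhere for ESC-like
#'   genes.
#' @param effect_up Day-5 gain of up-regulated genes, applied only within
#'   1.5 kb of the TSS (narrow gain).
#' @param effect_down Day-5 loss of down-regulated genes, applied across the
#'   whole window (broad loss).
#' @param effect_esc Day-5 loss of ESC-like genes, applied across the whole
#'   window.
#' @param effect_cv Log-normal sdlog of the per-gene effect-size multiplier:
#'   differential and ESC-like genes differ in how strongly they respond,
#'   so some carry weak, barely detectable changes.
#' @param gene_day_sd Standard deviation of a per-(gene, day) random
#'   intercept shared by every probe of the gene on that day, emulating
#'   array- and biology-level variation that replicate averaging cannot
#'   remove.
#' @param seed Integer seed; all draws come from one stream seeded with it.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 2000,
                       n_control_probes = 5000,
                       probes_per_gene_mean = 28,
                       probe_spacing_bp = 248,
                       tss_window_bp = 3500,
                       days = c(0, 1, 3, 5),
                       chip_replicates = 2,
                       expr_replicates = 3,
                       frac_up = 0.025,
                       frac_down = 0.025,
                       frac_esc = 0.05,
                       coupling_by_day = c(0, 0.1, 0.3, 0.35),
                       noise_sd_acet = 0.5,
                       noise_sd_expr = 0.3,
                       island_frac = 0.6,
                       island_height = 2,
                       esc_baseline = 1.5,
                       effect_up = 0.6,
                       effect_down = 1.5,
                       effect_esc = 2,
                       effect_cv = 0.6,
                       gene_day_sd = 0.15,
                       seed = 1L) {
  cfg <- list(n_genes = n_genes, n_control_probes = n_control_probes,
              probes_per_gene_mean = probes_per_gene_mean,
              probe_spacing_bp = probe_spacing_bp,
              tss_window_bp = tss_window_bp, days = days,
              chip_replicates = chip_replicates,
              expr_replicates = expr_replicates,
              frac_up = frac_up, frac_down = frac_down, frac_esc = frac_esc,
              coupling_by_day = coupling_by_day,
              noise_sd_acet = noise_sd_acet, noise_sd_expr = noise_sd_expr,
              island_frac = island_frac, island_height = island_height,
              esc_baseline = esc_baseline, effect_up = effect_up,
              effect_down = effect_down, effect_esc = effect_esc,
              effect_cv = effect_cv, gene_day_sd = gene_day_sd,
              seed = as.integer(seed))
  counts <- c("n_genes", "n_control_probes", "probes_per_gene_mean",
              "chip_replicates", "expr_replicates")
  for (nm in counts) {
    if (!is.numeric(cfg[[nm]]) || cfg[[nm]] < 1) {
      stop(sprintf("'%s' must be a positive count", nm), call. = FALSE)
    }
  }
  if (frac_up < 0 || frac_down < 0 || frac_up + frac_down > 1) {
    stop("frac_up + frac_down must lie in [0, 1]", call. = FALSE)
  }
  if (frac_esc < 0 || frac_esc > 1) stop("frac_esc must lie in [0, 1]", call. = FALSE)
  if (any(diff(days) <= 0)) stop("days must be strictly increasing", call. = FALSE)
  if (length(coupling_by_day) != length(days)) {
    stop("coupling_by_day must have one entry per day", call. = FALSE)
  }
  if (any(abs(coupling_by_day) > 1)) {
    stop("coupling values must lie in [-1, 1]", call. = FALSE)
  }
  if (noise_sd_acet < 0 || noise_sd_expr < 0 || gene_day_sd < 0 ||
      effect_cv < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (island_frac <= 0 || island_frac > 1) {
    stop("island_frac must lie in (0, 1]", call. = FALSE)
  }
  if (probes_per_gene_mean * probe_spacing_bp > 2 * tss_window_bp) {
    stop("cannot place probes: probes_per_gene_mean * probe_spacing_bp ",
         "exceeds the TSS window", call. = FALSE)
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a probe-level acetylation and expression time course
#'
#' Generates a dataset with the structure a promoter acetylation study
#' assumes: each gene carries a fixed contiguous acetylation island whose
#' location never changes across days; down-regulated genes lose signal over
#' the whole promoter window while up-regulated genes gain signal only within
#' 1.5 kb of the TSS; ESC-like genes carry elevated baseline acetylation
#' everywhere and a strong monotone loss. Control probes are drawn from the
#' zero-mean background null. Per-gene expression change from day 0 is
#' `coupling_by_day[t]` times the standardized mean acetylation change driven
#' by the gene's regulation class, plus Gaussian noise, then replicated; the
#' ESC-specific de-acetylation is deliberately left out of the coupling input
#' so that the strong chromatin loss of ESC-like genes is not mirrored by a
#' concordant expression change.
#'
#' @param config A [sim_config()] object.
#' @return An object of class `sim_dataset`: a list with elements
#'   `probe_table` (long probe-level data.frame: `probe_id`, `gene_id`
#'   (`NA` for controls), `offset_bp`, `day`, `replicate`, `signal`),
#'   `expr_table` (`gene_id`, `day`, `replicate`, `expression`),
#'   `truth` (data.frame `gene_id`, `label` in up/down/stable),
#'   `esc_genes` (character vector), `gene_sets` (named list of gene-id
#'   vectors emulating five overlapping descriptions of ESC genes),
#'   `island_truth` (per-probe data.frame with the generating island
#'   membership, constant across days by construction), and
#'   `coupling_by_day`.
#' @examples
#' d <- simulate_dataset(sim_config(n_genes = 50, n_control_probes = 200))
#' table(d$truth$label)
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)

  n <- cfg$n_genes
  genes <- sprintf("g%05d", seq_len(n))
  W <- cfg$tss_window_bp
  sp <- cfg$probe_spacing_bp
  n_slots <- floor(2 * W / sp) + 1L
  grid <- seq(-W, by = sp, length.out = n_slots)
  keep_p <- min(1, cfg$probes_per_gene_mean / n_slots)

  # class labels with deterministic counts, randomly assigned
  n_up <- round(cfg$frac_up * n)
  n_down <- round(cfg$frac_down * n)
  label <- rep("stable", n)
  idx <- sample.int(n, n_up + n_down)
  label[idx[seq_len(n_up)]] <- "up"
  if (n_down > 0) label[idx[n_up + seq_len(n_down)]] <- "down"
  esc <- sample(genes, round(cfg$frac_esc * n))
  is_esc <- genes %in% esc

  # probe layout: jittered grid, variable per-gene counts
  keep <- matrix(stats::runif(n * n_slots) < keep_p, nrow = n)
  jitter <- matrix(stats::runif(n * n_slots, -sp / 2, sp / 2), nrow = n)
  offset <- pmin(pmax(sweep(jitter, 2, grid, `+`), -W), W)

  # fixed contiguous island per gene (location constant across days)
  island_len <- max(1L, round(cfg$island_frac * n_slots))
  island_start <- sample.int(n_slots - island_len + 1L, n, replace = TRUE)
  slot_idx <- matrix(rep(seq_len(n_slots), each = n), nrow = n)
  in_island <- slot_idx >= island_start & slot_idx < island_start + island_len

  days <- cfg$days
  dayfrac <- if (max(days) > 0) days / max(days) else rep(0, length(days))
  base <- in_island * cfg$island_height + is_esc * cfg$esc_baseline
  near_tss <- abs(offset) <= 1500

  # per-gene effect-size heterogeneity: responding genes differ in strength
  eff_mult <- stats::rlnorm(n, 0, cfg$effect_cv)
  # per-(gene, day) random intercept shared by all probes and replicates
  gd_shift <- matrix(stats::rnorm(n * length(days), 0, cfg$gene_day_sd), n)

  # per-day true mean signal components; the label component drives coupling
  label_eff <- function(t) {
    eff_mult * ((label == "up") * cfg$effect_up * dayfrac[t] * near_tss -
                  (label == "down") * cfg$effect_down * dayfrac[t])
  }
  esc_eff <- function(t) -is_esc * eff_mult * cfg$effect_esc * dayfrac[t]

  n_rep <- cfg$chip_replicates
  probe_id <- matrix(sprintf("%s_p%02d", rep(genes, n_slots),
                             rep(seq_len(n_slots), each = n)), nrow = n)
  kept <- which(keep)
  rows_per_day <- length(kept)

  probe_chunks <- vector("list", length(days) * n_rep)
  k <- 0L
  mean_change_label <- matrix(0, n, length(days))  # coupling input
  for (t in seq_along(days)) {
    true_t <- base + label_eff(t) + esc_eff(t) + gd_shift[, t]
    # per-gene mean change of the label-driven component over kept probes
    lbl_t <- label_eff(t)
    lbl_t[!keep] <- NA
    mean_change_label[, t] <- rowMeans(lbl_t, na.rm = TRUE)
    for (r in seq_len(n_rep)) {
      k <- k + 1L
      probe_chunks[[k]] <- data.frame(
        probe_id = probe_id[kept],
        gene_id = rep(genes, n_slots)[kept],
        offset_bp = round(offset[kept]),
        day = days[t],
        replicate = r,
        signal = true_t[kept] + stats::rnorm(rows_per_day, 0, cfg$noise_sd_acet),
        stringsAsFactors = FALSE)
    }
  }
  mean_change_label[is.na(mean_change_label)] <- 0

  # control probes: i.i.d. zero-mean background, exchangeable across days
  nc <- cfg$n_control_probes
  ctrl_chunks <- vector("list", length(days) * n_rep)
  k <- 0L
  for (t in seq_along(days)) {
    for (r in seq_len(n_rep)) {
      k <- k + 1L
      ctrl_chunks[[k]] <- data.frame(
        probe_id = sprintf("ctrl%05d", seq_len(nc)),
        gene_id = NA_character_,
        offset_bp = NA_integer_,
        day = days[t],
        replicate = r,
        signal = stats::rnorm(nc, 0, cfg$noise_sd_acet),
        stringsAsFactors = FALSE)
    }
  }
  probe_table <- do.call(rbind, c(probe_chunks, ctrl_chunks))
  rownames(probe_table) <- NULL

  # expression: coupling_by_day[t] * z(mean label-driven acetylation change)
  sdv <- apply(mean_change_label, 2, stats::sd)
  z <- sweep(mean_change_label, 2, colMeans(mean_change_label), `-`)
  z <- sweep(z, 2, ifelse(sdv > 0, sdv, 1), `/`)
  expr_change <- sweep(z, 2, cfg$coupling_by_day, `*`) +
    matrix(stats::rnorm(n * length(days), 0, cfg$noise_sd_expr), n)
  expr_change[, days == 0] <- 0
  baseline_expr <- stats::rnorm(n, 8, 1)
  n_er <- cfg$expr_replicates
  expr_chunks <- vector("list", length(days) * n_er)
  k <- 0L
  for (t in seq_along(days)) {
    for (r in seq_len(n_er)) {
      k <- k + 1L
      expr_chunks[[k]] <- data.frame(
        gene_id = genes,
        day = days[t],
        replicate = r,
        expression = baseline_expr + expr_change[, t] +
          stats::rnorm(n, 0, cfg$noise_sd_expr),
        stringsAsFactors = FALSE)
    }
  }
  expr_table <- do.call(rbind, expr_chunks)
  rownames(expr_table) <- NULL

  # five overlapping ESC-like gene sets (GMT-compatible)
  gene_sets <- list()
  if (length(esc) >= 5) {
    sizes <- pmax(2L, round(length(esc) * c(0.6, 0.5, 0.3, 0.4, 0.15)))
    names(sizes) <- c("plurinet_like", "rnai_screen_like", "go_stemcell_like",
                      "ppi_network_like", "tf_regulators_like")
    gene_sets <- lapply(sizes, function(s) {
      core <- sample(esc, s)
      extra <- sample(setdiff(genes, core), max(1L, round(s * 0.1)))
      c(core, extra)
    })
    attr(gene_sets, "descriptions") <-
      stats::setNames(paste("synthetic ESC-like set:", names(sizes)),
                      names(sizes))
  }

  island_truth <- data.frame(
    probe_id = probe_id[kept],
    gene_id = rep(genes, n_slots)[kept],
    offset_bp = round(offset[kept]),
    in_island = in_island[kept],
    stringsAsFactors = FALSE)

  structure(list(probe_table = probe_table,
                 expr_table = expr_table,
                 truth = data.frame(gene_id = genes, label = label,
                                    stringsAsFactors = FALSE),
                 esc_genes = esc,
                 gene_sets = gene_sets,
                 island_truth = island_truth,
                 coupling_by_day = cfg$coupling_by_day,
                 config = cfg),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("sim_dataset: %d genes, %d probe rows, %d expression rows\n",
              nrow(x$truth), nrow(x$probe_table), nrow(x$expr_table)))
  cat("labels:", paste(sprintf("%s=%d", names(table(x$truth$label)),
                               table(x$truth$label)), collapse = " "), "\n")
  invisible(x)
}
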