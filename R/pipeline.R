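#' Pipeline configuration
#'
#' Collects every stage parameter of the end-to-end analysis together with
#' input paths (optional: omitted inputs are simulated), output directory and
#' the global seed. Every stochastic stage receives a sub-seed derived from
#' the global seed via [derive_seed()], so toggling one stage never changes
#' another stage's random stream.
#'
#' @param probe_table_path,expr_table_path,gene_sets_path Optional input
#'   files (TSV / TSV / GMT). When `NULL`, a dataset is simulated from
#'   `sim`.
#' @param sim A [sim_config()] used when no input files are given.
#' @param min_probes,window_bp Gene filter parameters.
#' @param fdr Island-call FDR cutoff.
#' @param min_state_count Transition-summary discard threshold.
#' @param coverage Peak coverage fraction.
#' @param n_perm_corr,n_perm_gsea Permutation counts.
#' @param edge_cutoff BH q cutoff for partial-correlation edges.
#' @param n_resamples,folds Balanced-CV parameters.
#' @param problems Classification problems to run.
#' @param classifiers Names of registry entries to benchmark (`NULL` = all).
#' @param stages Character vector of stages to run, a subset of
#'   `c("islands", "profiles", "assoc", "classify", "enrich")`.
#' @param seed Global seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(probe_table_path = NULL, expr_table_path = NULL,
                            gene_sets_path = NULL,
                            sim = sim_config(),
                            min_probes = 10, window_bp = 3500,
                            fdr = 0.10, min_state_count = 3,
                            coverage = 0.30,
                            n_perm_corr = 1000, n_perm_gsea = 1000,
                            edge_cutoff = 0.05,
                            n_resamples = 20, folds = 10,
                            problems = c("i", "ii", "iii", "iv"),
                            classifiers = NULL,
                            stages = c("islands", "profiles", "assoc",
                                       "classify", "enrich"),
                            seed = 1L) {
  structure(as.list(environment()), class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = ".", fileEncoding = "UTF-8")
  path
}

#' Run the full analysis pipeline
#'
#' Executes the stages in order (islands, profiles, assoc, classify, enrich)
#' on either supplied input files or a freshly simulated dataset, writes all
#' stage outputs as TSV under `out_dir`, and records a JSON manifest with
#' package version, seeds, parameters, input hashes and per-stage output
#' paths. Re-running with the same configuration reproduces identical
#' output files.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  stopifnot(inherits(config, "pipeline_config"))
  paths <- c(config$probe_table_path, config$expr_table_path,
             config$gene_sets_path)
  missing <- paths[!vapply(paths, file.exists, TRUE)]
  if (length(missing) > 0L) {
    stop(sprintf("input path does not exist: %s", missing[1]), call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    package = "acetr",
    version = as.character(utils::packageVersion("acetr")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    parameters = config[setdiff(names(config), "sim")],
    inputs = list(),
    stages = list())
  log_stage <- function(name, outputs, t0) {
    manifest$stages[[name]] <<- list(
      name = name, outputs = outputs,
      elapsed_s = round(as.numeric(Sys.time()) - t0, 3))
    message(sprintf("[%s] done (%.1fs): %s", name,
                    manifest$stages[[name]]$elapsed_s,
                    paste(basename(outputs), collapse = ", ")))
  }

  truth <- NULL
  if (is.null(config$probe_table_path)) {
    sim <- config$sim
    sim$seed <- derive_seed(config$seed, "simulate")
    ds <- simulate_dataset(sim)
    probe_table <- ds$probe_table
    expr_table <- ds$expr_table
    gene_sets <- ds$gene_sets
    truth <- ds$truth
    manifest$inputs$simulated <- TRUE
  } else {
    probe_table <- read_probe_table(config$probe_table_path)
    expr_table <- read_expr_table(config$expr_table_path)
    gene_sets <- if (!is.null(config$gene_sets_path)) {
      read_gmt(config$gene_sets_path)
    } else {
      list()
    }
    manifest$inputs <- lapply(
      stats::setNames(paths, basename(paths)),
      function(p) unname(tools::md5sum(p)))
  }

  probe_table <- filter_genes(probe_table, config$min_probes, config$window_bp)
  null_model <- fit_null(probe_table)

  states <- NULL
  if ("islands" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    states <- call_states(probe_table, null_model, fdr = config$fdr)
    trans <- pooled_transition_summary(states, config$min_state_count)
    outs <- c(write_tsv(states, file.path(out_dir, "states.tsv")),
              write_tsv(trans, file.path(out_dir, "transitions.tsv")))
    log_stage("islands", outs, t0)
  }

  binned <- bin_profiles(probe_table, null_model, window_bp = config$window_bp)
  changes <- build_changes(binned, expr_table)
  if ("profiles" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    days <- sort(unique(binned$day))
    peak_rows <- list()
    for (d in days) {
      m <- profile_matrix(binned, d)
      for (g in rownames(m)) {
        pk <- find_peak(m[g, ], coverage = config$coverage)
        peak_rows[[length(peak_rows) + 1L]] <- data.frame(
          gene_id = g, day = d, lo = pk$lo, hi = pk$hi,
          covered_fraction = pk$covered_fraction, stringsAsFactors = FALSE)
      }
    }
    peaks <- do.call(rbind, peak_rows)
    outs <- c(write_tsv(binned, file.path(out_dir, "binned_profiles.tsv")),
              write_tsv(peaks, file.path(out_dir, "peaks.tsv")))
    log_stage("profiles", outs, t0)
  }

  if ("assoc" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    rep_perm <- permutation_significance(
      changes, "pearson", n_perm = config$n_perm_corr,
      seed = derive_seed(config$seed, "assoc"))
    corr_df <- data.frame(
      acet_day = rep(rownames(rep_perm$r), ncol(rep_perm$r)),
      expr_day = rep(colnames(rep_perm$r), each = nrow(rep_perm$r)),
      r = as.vector(rep_perm$r), p_analytic = as.vector(rep_perm$p),
      p_perm = as.vector(rep_perm$p_perm), stringsAsFactors = FALSE)
    pc <- shrinkage_pcor(stack_profiles(binned))
    edges <- pcor_edges(pc, cutoff = config$edge_cutoff)
    outs <- c(write_tsv(corr_df, file.path(out_dir, "correlations.tsv")),
              write_tsv(edges, file.path(out_dir, "pcor_edges.tsv")))
    log_stage("assoc", outs, t0)
  }

  if ("classify" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    labels <- if (!is.null(truth)) {
      stats::setNames(truth$label, truth$gene_id)
    } else {
      dd <- call_differential(expr_table, max(changes$days))
      stats::setNames(dd$label, dd$gene_id)
    }
    Xd <- changes$profiles[[paste0("day", max(changes$days))]]
    y <- labels[rownames(Xd)]
    reg <- classifier_registry()
    if (!is.null(config$classifiers)) reg <- reg[config$classifiers]
    report <- full_benchmark(Xd, y, problems = config$problems,
                             registry = reg,
                             n_resamples = config$n_resamples,
                             folds = config$folds,
                             seed = derive_seed(config$seed, "classify"))
    outs <- c(write_tsv(report, file.path(out_dir, "cv_report.tsv")),
              write_tsv(summary(report), file.path(out_dir, "cv_summary.tsv")))
    log_stage("classify", outs, t0)
  }

  if ("enrich" %in% config$stages && length(gene_sets) > 0) {
    t0 <- as.numeric(Sys.time())
    scores <- phenotype_scores(binned, changes)
    panel <- enrichment_panel(scores, gene_sets,
                              n_perm = config$n_perm_gsea,
                              seed = derive_seed(config$seed, "enrich"))
    outs <- write_tsv(panel, file.path(out_dir, "enrichment.tsv"))
    log_stage("enrich", outs, t0)
  }

  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(manifest)
}
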