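# End-to-end orchestration: simulate/load -> qc -> genotype -> cluster -> order

#' Assemble a pipeline run configuration
#'
#' Every stage parameter with its module default; either a patient preset
#' name or paths to a panel and depth file must be supplied.
#'
#' @param preset Patient preset name (see [patient_preset()]), or `NULL`.
#' @param panel_path,depths_path Input files, used when `preset` is `NULL`.
#' @param n_progenitors Progenitor cells to simulate (presets only;
#'   `NA` = the preset's default).
#' @param min_reads,minor_frac,max_combined QC parameters.
#' @param min_total,min_alt,min_vaf Genotype-calling parameters.
#' @param linkage,min_k,max_k Clustering parameters.
#' @param alpha,beta,top_k,merge_similarity Order-inference parameters.
#' @param seed Integer seed for all randomness in the run.
#' @return A `run_config`.
#' @export
run_config <- function(preset = NULL, panel_path = NULL, depths_path = NULL,
                       n_progenitors = NA, min_reads = 4, minor_frac = 0.10,
                       max_combined = 1 / 3, min_total = 10, min_alt = 2,
                       min_vaf = 0.10, linkage = "average", min_k = 2,
                       max_k = 8, alpha = 0.01, beta = 0.15, top_k = 100,
                       merge_similarity = 0.95, seed = 1L) {
  if (is.null(preset) && (is.null(panel_path) || is.null(depths_path)))
    stop_fmt("run_config needs either a preset or panel_path + depths_path")
  structure(as.list(environment()), class = "run_config")
}

#' Run the full pipeline
#'
#' Executes the stages in order — simulate (or load), QC filter, genotype
#' calling, clonal clustering, event grouping, order enumeration — writing
#' each stage's outputs to `out_dir` before the next starts, plus a
#' machine-readable `summary.tsv`, the verbatim configuration and a log.
#' A stage failure aborts with the stage name; outputs of completed stages
#' are retained.
#'
#' @param config A `run_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with `qc`, `clones`, `order_report`,
#'   `sensitivity` and `summary`.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  writeLines(sprintf("%s=%s", names(unclass(config)),
                     vapply(unclass(config), function(x)
                       paste(format(x), collapse = ","), "")),
             file.path(out_dir, "config.txt"))
  log <- file.path(out_dir, "run.log")
  note <- function(...) cat(sprintf(...), "\n", sep = "", file = log, append = TRUE)
  cat(sprintf("clonetrace %s | R %s | seed %d\n",
              as.character(utils::packageVersion("clonetrace")),
              getRversion(), config$seed), file = log)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_fmt("pipeline stage '%s' failed: %s", name, conditionMessage(e)))
  }

  mat <- stage("input", {
    if (!is.null(config$preset)) {
      ps <- patient_preset(config$preset)
      np <- if (is.na(config$n_progenitors)) ps$n_progenitors else config$n_progenitors
      sim <- simulate_cells(ps$model, noise_config(seed = config$seed),
                            ps$n_cells, n_progenitors = np)
      utils::write.table(sim$truth, file.path(out_dir, "truth.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      sim$matrix
    } else {
      panel <- read_panel(config$panel_path)
      read_depth_matrix(config$depths_path, panel)
    }
  })
  note("input: %d cells x %d loci", nrow(mat$ref), ncol(mat$ref))

  flt <- stage("qc", filter_cells(mat, config$min_reads, config$minor_frac,
                                  config$max_combined))
  utils::write.table(flt$qc, file.path(out_dir, "cell_qc.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(flt$matrix))
    write_depth_matrix(flt$matrix, file.path(out_dir, "retained_depths.tsv"))
  note("qc: %d/%d cells retained", sum(flt$qc$passed), nrow(flt$qc))
  if (is.null(flt$matrix) || nrow(flt$matrix$ref) < 2)
    stop_fmt("pipeline stage 'cluster' failed: fewer than 2 cells after QC")

  g <- stage("genotype", call_genotypes(flt$matrix, config$min_total,
                                        config$min_alt, config$min_vaf))
  write_genotype_matrix(g, file.path(out_dir, "genotypes.tsv"))

  clones <- stage("cluster", cluster_cells(
    g, linkage = config$linkage, min_k = config$min_k, max_k = config$max_k))
  utils::write.table(
    data.frame(cell_id = names(clones$assignments),
               cluster_id = unname(clones$assignments)),
    file.path(out_dir, "clusters.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(clones$clusters, file.path(out_dir, "clone_frequencies.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  cons_df <- data.frame(cluster_id = rownames(clones$consensus),
                        apply(clones$consensus, 2, gt_to_token),
                        check.names = FALSE)
  utils::write.table(cons_df, file.path(out_dir, "consensus_genotypes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  note("cluster: %d clusters", nrow(clones$clusters))

  groups <- stage("order", group_events(g, config$merge_similarity,
                                        clusters = clones))
  report <- stage("order", enumerate_and_rank(g, groups, config$alpha,
                                              config$beta, config$top_k))
  utils::write.table(report$ranked, file.path(out_dir, "ranked_orders.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  steps <- consensus_order(report)
  utils::write.table(steps, file.path(out_dir, "consensus_steps.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sens <- compartment_sensitivity(g, config$alpha, config$beta,
                                  config$top_k, config$merge_similarity)
  note("order: rank-1 %s", report$ranked$order[1])

  summary_df <- data.frame(
    n_cells_in = nrow(mat$ref),
    n_cells_retained = sum(flt$qc$passed),
    n_clusters = nrow(clones$clusters),
    clone_frequencies = paste(sprintf("%s=%.4f", clones$clusters$cluster_id,
                                      clones$clusters$frequency), collapse = ";"),
    rank1_order = report$ranked$order[1],
    progenitor_robust = if (isTRUE(sens$applicable)) sens$consistent else NA,
    seed = config$seed
  )
  utils::write.table(summary_df, file.path(out_dir, "summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(qc = flt$qc, clones = clones, order_report = report,
                 sensitivity = sens, summary = summary_df))
}
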