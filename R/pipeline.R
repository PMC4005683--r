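default_config <- function() {
  list(
    normalization = list(target = 500, trim = 0.02, r_min = 0.7,
                         min_keep = 3L),
    gene_expression = list(threshold = 500, fc_min = 1.5, alpha = 0.05,
                           welch = FALSE),
    splicing = list(alpha_ps = 0.01, on_si = TRUE)
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

log_line <- function(con, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                 paste0(...))
  message(msg)
  if (!is.null(con)) writeLines(msg, con)
}

#' Run the full junction-array pipeline
#'
#' Orchestrates simulate (optional) -> normalize -> gene expression ->
#' splicing caller -> report. The configuration is a YAML file (or a list)
#' with blocks \code{simulation} (generator parameters; alternative to
#' real inputs), \code{inputs} (\code{design}, \code{intensities},
#' \code{conditions} file paths), \code{normalization},
#' \code{gene_expression} and \code{splicing} (thresholds; defaults are
#' 500 expressed cutoff, fold change 1.5, gene alpha 0.05, probeset alpha
#' 0.01, trim 0.02, r_min 0.7). The resolved configuration, stage timings
#' and scaling factors are echoed to \code{run.log}, and all result tables
#' are written to \code{out_dir}.
#'
#' @param config path to a YAML config file, or an equivalent named list.
#' @param out_dir output directory.
#' @return Invisibly, a list with all stage results (\code{design},
#'   \code{truth} when simulated, \code{pre}, \code{genes}, \code{splice},
#'   \code{summary}).
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- merge_config(default_config(), config)
  has_sim <- !is.null(cfg$simulation)
  has_inputs <- !is.null(cfg$inputs$design) &&
    !is.null(cfg$inputs$intensities) && !is.null(cfg$inputs$conditions)
  if (!has_sim && !has_inputs)
    stop("config must provide either a 'simulation' block or 'inputs' ",
         "(design, intensities, conditions)")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  logf <- file(file.path(out_dir, "run.log"), open = "wt")
  on.exit(close(logf), add = TRUE)

  truth <- NULL
  t0 <- Sys.time()
  if (has_sim) {
    params <- do.call(sim_params, cfg$simulation)
    log_line(logf, "simulate: seed=", params$seed, " n_genes=",
             params$n_genes)
    design <- generate_design(params)
    sim <- simulate_experiment(design, params)
    raw <- sim$intensities
    truth <- sim$truth
    write_design(design, file.path(out_dir, "design.tsv"))
    write_intensities(raw, file.path(out_dir, "intensities.tsv"))
    utils::write.table(truth$events, file.path(out_dir, "truth_events.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth$genes, file.path(out_dir, "truth_genes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    log_line(logf, "load: ", cfg$inputs$design)
    design <- read_design(cfg$inputs$design)
    cond_tab <- utils::read.delim(cfg$inputs$conditions, sep = "\t",
                                  stringsAsFactors = FALSE)
    conditions <- stats::setNames(cond_tab$condition, cond_tab$sample_id)
    raw <- read_intensities(cfg$inputs$intensities, design, conditions)
  }
  log_line(logf, "design: ", nrow(design$genes), " genes, ",
           nrow(design$events), " events, ", nrow(design$probes), " probes")

  ncfg <- cfg$normalization
  pre <- preprocess(raw, design, target = ncfg$target, trim = ncfg$trim,
                    r_min = ncfg$r_min, min_keep = ncfg$min_keep)
  log_line(logf, "normalize: scaling factors ",
           paste(sprintf("%s=%.3f", names(pre$scaling_factors),
                         pre$scaling_factors), collapse = " "))
  log_line(logf, "normalize: ", sum(!pre$mask), " probes dropped by selection")

  gcfg <- cfg$gene_expression
  genes <- call_regulated_genes(pre$index, raw$conditions,
                                threshold = gcfg$threshold,
                                fc_min = gcfg$fc_min, alpha = gcfg$alpha,
                                welch = isTRUE(gcfg$welch))
  log_line(logf, "expression: ", sum(genes$regulated), " regulated genes")

  scfg <- cfg$splicing
  splice <- call_splicing(pre$corrected, pre$index, design,
                          alpha_ps = scfg$alpha_ps,
                          on_si = isTRUE(scfg$on_si))
  log_line(logf, "splicing: ", splice$summary$total, " called events (",
           splice$summary$cassette, " cassette, ",
           splice$summary$mutually_exclusive, " mutually exclusive, ",
           splice$summary$alt_ss, " alt 5'/3')")

  write_results(genes, splice$calls, splice$probeset_stats, design, out_dir)
  yaml::write_yaml(cfg, file.path(out_dir, "config_resolved.yaml"))
  log_line(logf, "done in ",
           sprintf("%.1f", as.numeric(difftime(Sys.time(), t0, units = "secs"))),
           " s")
  invisible(list(design = design, truth = truth, pre = pre, genes = genes,
                 splice = splice, summary = splice$summary))
}

#' Human-readable report of a pipeline run
#'
#' Summarizes a result directory in the style of the headline array
#' figures: the regulated-gene count and called events by category. When a
#' simulated ground truth (\code{truth_events.tsv}) is present, a
#' confusion section with TP/FP/FN counts, sensitivity and direction
#' accuracy among true positives is appended.
#'
#' @param out_dir a directory written by \code{\link{run_pipeline}}.
#' @return Character vector of report lines (also printed); invisibly the
#'   underlying numbers as a list.
#' @export
report_run <- function(out_dir) {
  f_sum <- file.path(out_dir, "summary.tsv")
  f_ev <- file.path(out_dir, "events.tsv")
  missing <- c(f_sum, f_ev)[!file.exists(c(f_sum, f_ev))]
  if (length(missing))
    stop("missing result file(s): ", paste(missing, collapse = ", "))
  summ <- utils::read.delim(f_sum, stringsAsFactors = FALSE)
  calls <- utils::read.delim(f_ev, stringsAsFactors = FALSE)
  lines <- c(
    "Junction-array analysis report",
    "==============================",
    sprintf("Regulated genes: %d", summ$regulated_genes),
    sprintf("Called splicing events: %d (%d cassette, %d mutually exclusive, %d alt 5'/3')",
            summ$total, summ$cassette, summ$mutually_exclusive, summ$alt_ss))
  stats_out <- list(summary = summ)
  f_truth <- file.path(out_dir, "truth_events.tsv")
  if (file.exists(f_truth)) {
    truth <- utils::read.delim(f_truth, stringsAsFactors = FALSE)
    m <- merge(calls, truth, by = "event_id", suffixes = c("", ".truth"))
    tp <- sum(m$called & m$regulated)
    fp <- sum(m$called & !m$regulated)
    fn <- sum(!m$called & m$regulated)
    sens <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    dir_ok <- if (tp > 0)
      mean(m$direction[m$called & m$regulated] ==
             m$direction.truth[m$called & m$regulated])
    else NA_real_
    lines <- c(lines, "",
               "Recovery against simulated truth",
               sprintf("  TP=%d FP=%d FN=%d", tp, fp, fn),
               sprintf("  Sensitivity: %.3f", sens),
               sprintf("  Direction accuracy among TP: %.3f", dir_ok))
    stats_out$confusion <- list(tp = tp, fp = fp, fn = fn,
                                sensitivity = sens,
                                direction_accuracy = dir_ok)
  }
  cat(lines, sep = "\n")
  invisible(stats_out)
}
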