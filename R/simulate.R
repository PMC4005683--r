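# Event-type mix of the HJAY array content used as the generator default:
# 13150 cassette, 6517 alt 5'/3' (split evenly), 1145 mutually exclusive,
# out of 20812 alternative events.
HJAY_EVENT_MIX <- c(cassette = 13150 / 20812,
                    alt5 = 6517 / 20812 / 2,
                    alt3 = 6517 / 20812 / 2,
                    mutually_exclusive = 1145 / 20812)

#' Simulation parameters for the synthetic junction-array generator
#'
#' Collects every knob of the generator: array scale, the two-isoform
#' signal model, noise levels and the injected effects, with defaults that
#' describe a small HJAY-like experiment with 3 replicates per condition.
#'
#' The signal model is multiplicative on the linear scale: an
#' inclusion-group probe has mean \code{2^affinity * PSI * E}, an
#' exclusion-group probe \code{2^affinity * (1 - PSI) * E} and a
#' constitutive probe \code{2^affinity * E}, where \code{E} is the gene's
#' transcript abundance (fluorescence units) and PSI the fraction of
#' transcripts containing the alternative exon. Replicate noise is
#' log-normal (\code{2^N(0, sd_noise)}) and a 1-unit intensity floor keeps
#' logs finite.
#'
#' @param seed integer seed; every draw is governed by it (the design stage
#'   uses \code{seed}, the experiment stage \code{seed + 1}).
#' @param n_genes number of genes on the synthetic array.
#' @param events_per_gene mean of the Poisson number of alternative events
#'   per gene.
#' @param n_replicates arrays per condition (>= 2).
#' @param mu_expr,sd_expr mean/sd of baseline log2 gene abundance.
#' @param sd_affinity sd of per-probe log2 affinity.
#' @param sd_noise sd of log2 replicate noise.
#' @param psi_min,psi_max range of the uniform baseline PSI.
#' @param fraction_regulated_splicing fraction of events whose PSI is
#'   shifted in the treated condition.
#' @param delta_psi magnitude of the injected PSI shift (sign drawn at
#'   random per event; PSI clipped to [0, 1]).
#' @param fraction_regulated_expression fraction of genes whose abundance
#'   changes in the treated condition.
#' @param expr_log2fc log2 fold change injected into regulated genes (sign
#'   drawn at random per gene).
#' @param fraction_unexpressed fraction of genes drawn near optical
#'   background instead of the expressed abundance distribution.
#' @param mu_background mean log2 abundance of unexpressed genes
#'   (default 7, i.e. 128 fluorescence units, below the 500 expressed
#'   threshold).
#' @param n_constitutive_probesets constitutive probesets per gene.
#' @return A list of class \code{SimulationParams}.
#' @export
sim_params <- function(seed = 1L,
                       n_genes = 200L,
                       events_per_gene = 1,
                       n_replicates = 3L,
                       mu_expr = 10, sd_expr = 1.5,
                       sd_affinity = 0.5,
                       sd_noise = 0.25,
                       psi_min = 0.2, psi_max = 0.8,
                       fraction_regulated_splicing = 0.1,
                       delta_psi = 0.3,
                       fraction_regulated_expression = 0.1,
                       expr_log2fc = 1,
                       fraction_unexpressed = 0.1,
                       mu_background = 7,
                       n_constitutive_probesets = 4L) {
  p <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
            events_per_gene = events_per_gene,
            n_replicates = as.integer(n_replicates),
            mu_expr = mu_expr, sd_expr = sd_expr,
            sd_affinity = sd_affinity, sd_noise = sd_noise,
            psi_min = psi_min, psi_max = psi_max,
            fraction_regulated_splicing = fraction_regulated_splicing,
            delta_psi = delta_psi,
            fraction_regulated_expression = fraction_regulated_expression,
            expr_log2fc = expr_log2fc,
            fraction_unexpressed = fraction_unexpressed,
            mu_background = mu_background,
            n_constitutive_probesets = as.integer(n_constitutive_probesets))
  if (p$n_genes <= 0L) stop("n_genes must be positive")
  if (p$n_replicates < 2L) stop("n_replicates must be >= 2")
  if (p$events_per_gene < 0) stop("events_per_gene must be >= 0")
  fracs <- c(p$fraction_regulated_splicing, p$fraction_regulated_expression,
             p$fraction_unexpressed)
  if (any(fracs < 0 | fracs > 1)) stop("fractions must lie in [0, 1]")
  if (p$psi_min < 0 || p$psi_max > 1 || p$psi_min > p$psi_max)
    stop("PSI range must satisfy 0 <= psi_min <= psi_max <= 1")
  if (p$sd_noise < 0 || p$sd_affinity < 0) stop("sds must be >= 0")
  if (p$n_constitutive_probesets < 2L)
    stop("need >= 2 constitutive probesets per gene")
  class(p) <- "SimulationParams"
  p
}

# probesets of one event; returns a data.frame of (group, role) rows
event_probeset_layout <- function(event_type) {
  switch(event_type,
    cassette = data.frame(
      group = c("exclusion", "inclusion", "inclusion", "inclusion"),
      role  = c("junction", "exon_body", "junction", "junction"),
      stringsAsFactors = FALSE),
    alt5 = ,
    alt3 = data.frame(
      group = c("inclusion", "exclusion"),
      role  = c("junction", "junction"),
      stringsAsFactors = FALSE),
    mutually_exclusive = data.frame(
      group = c("inclusion", "inclusion", "exclusion", "exclusion"),
      role  = c("exon_body", "junction", "exon_body", "junction"),
      stringsAsFactors = FALSE),
    stop("unknown event type: ", event_type))
}

#' Generate a synthetic HJAY-like array design
#'
#' Draws a design whose event-type mix follows the HJAY array content
#' (about 63\% cassette, 31\% alternative 5'/3', 6\% mutually exclusive).
#' Cassette events get 1 exclusion junction plus up to 3 inclusion
#' probesets (exon body + 2 inclusion junctions); alternative 5'/3' events
#' get a distal (inclusion) and proximal (exclusion) junction probeset;
#' mutually exclusive events get an exon-body + junction probeset pair per
#' exon, with exon A labelled inclusion and exon B exclusion. Every gene
#' receives constitutive probesets, and every probeset 3--4 probes.
#'
#' @param params a \code{\link{sim_params}} object.
#' @return A validated \code{\link{ArrayDesign}}; identical for identical
#'   seeds.
#' @export
generate_design <- function(params = sim_params()) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(params$seed)
  n_genes <- params$n_genes
  gene_ids <- sprintf("G%05d", seq_len(n_genes))
  n_events_per_gene <- stats::rpois(n_genes, params$events_per_gene)
  strands <- sample(c("+", "-"), n_genes, replace = TRUE)

  rows <- vector("list", n_genes)
  gene_start <- 1L
  ev_counter <- 0L
  for (gi in seq_len(n_genes)) {
    gid <- gene_ids[gi]
    chrom <- "chrS"
    n_ev <- n_events_per_gene[gi]
    n_ps_const <- params$n_constitutive_probesets
    # lay the gene out as consecutive 200-bp blocks: constitutive
    # probesets first, then one 3-block region per event
    blocks <- n_ps_const + 3L * max(n_ev, 0L)
    g_start <- gene_start
    g_rows <- list()
    # constitutive probesets
    for (k in seq_len(n_ps_const)) {
      psid <- sprintf("%s_const%02d", gid, k)
      n_probes <- sample(3:4, 1L)
      s <- g_start + (k - 1L) * 200L
      g_rows[[length(g_rows) + 1L]] <- data.frame(
        probe_id = sprintf("%s_p%d", psid, seq_len(n_probes)),
        probeset_id = psid, group = "constitutive", role = "exon_body",
        event_id = ".", event_type = ".", gene_id = gid, chrom = chrom,
        start = s, end = s + 199L, strand = strands[gi],
        stringsAsFactors = FALSE)
    }
    # alternative events
    if (n_ev > 0L) {
      types <- sample(names(HJAY_EVENT_MIX), n_ev, replace = TRUE,
                      prob = HJAY_EVENT_MIX)
      for (k in seq_len(n_ev)) {
        ev_counter <- ev_counter + 1L
        eid <- sprintf("E%05d", ev_counter)
        s <- g_start + (n_ps_const + 3L * (k - 1L)) * 200L
        e <- s + 599L
        layout <- event_probeset_layout(types[k])
        for (j in seq_len(nrow(layout))) {
          psid <- sprintf("%s_%s%d", eid, substr(layout$group[j], 1L, 4L), j)
          n_probes <- sample(3:4, 1L)
          g_rows[[length(g_rows) + 1L]] <- data.frame(
            probe_id = sprintf("%s_p%d", psid, seq_len(n_probes)),
            probeset_id = psid, group = layout$group[j], role = layout$role[j],
            event_id = eid, event_type = types[k], gene_id = gid,
            chrom = chrom, start = s, end = e, strand = strands[gi],
            stringsAsFactors = FALSE)
        }
      }
    }
    rows[[gi]] <- do.call(rbind, g_rows)
    gene_start <- g_start + blocks * 200L + 1000L
  }
  ArrayDesign(do.call(rbind, rows))
}

#' Simulate a two-condition junction-array experiment
#'
#' Applies the two-isoform mixture signal model to a design: per-gene
#' abundance and per-event PSI are drawn, effects are injected into a
#' random subset of genes (expression) and events (splicing), probe
#' affinities and log-normal replicate noise are applied, and intensities
#' are floored at 1 fluorescence unit.
#'
#' @param design an \code{\link{ArrayDesign}}, typically from
#'   \code{\link{generate_design}}.
#' @param params a \code{\link{sim_params}} object (same seed conventions).
#' @return A list with \code{intensities} (an \code{\link{IntensityMatrix}},
#'   state \code{"raw"}) and \code{truth} (class \code{TruthTable}: a list
#'   of per-gene and per-event data.frames recording the injected ground
#'   truth).
#' @export
simulate_experiment <- function(design, params = sim_params()) {
  stopifnot(inherits(design, "ArrayDesign"),
            inherits(params, "SimulationParams"))
  set.seed(params$seed + 1L)
  n_rep <- params$n_replicates
  sample_ids <- c(sprintf("ctrl_%d", seq_len(n_rep)),
                  sprintf("trt_%d", seq_len(n_rep)))
  conditions <- stats::setNames(rep(c("control", "treated"), each = n_rep),
                                sample_ids)

  genes <- design$genes$gene_id
  n_genes <- length(genes)
  unexpressed <- stats::runif(n_genes) < params$fraction_unexpressed
  log2_e <- ifelse(unexpressed,
                   stats::rnorm(n_genes, params$mu_background, 0.5),
                   stats::rnorm(n_genes, params$mu_expr, params$sd_expr))
  reg_expr <- stats::runif(n_genes) < params$fraction_regulated_expression
  expr_sign <- sample(c(-1, 1), n_genes, replace = TRUE)
  log2_e_ctrl <- log2_e
  log2_e_trt <- log2_e + ifelse(reg_expr, expr_sign * params$expr_log2fc, 0)

  events <- design$events$event_id
  n_events <- length(events)
  psi_ctrl <- stats::runif(n_events, params$psi_min, params$psi_max)
  reg_spl <- stats::runif(n_events) < params$fraction_regulated_splicing
  spl_sign <- sample(c(-1, 1), n_events, replace = TRUE)
  psi_trt <- pmin(1, pmax(0, psi_ctrl + ifelse(reg_spl,
                                               spl_sign * params$delta_psi, 0)))

  tab <- design$table
  n_probes <- nrow(tab)
  affinity <- stats::rnorm(n_probes, 0, params$sd_affinity)

  gene_idx <- match(tab$gene_id, genes)
  ev_idx <- match(tab$event_id, events)  # NA for constitutive probes
  # per-probe isoform fraction in each condition
  frac_for <- function(psi) {
    f <- rep(1, n_probes)
    inc <- tab$group == "inclusion"
    exc <- tab$group == "exclusion"
    f[inc] <- psi[ev_idx[inc]]
    f[exc] <- 1 - psi[ev_idx[exc]]
    f
  }
  mean_ctrl <- 2^(affinity + log2_e_ctrl[gene_idx]) * frac_for(psi_ctrl)
  mean_trt  <- 2^(affinity + log2_e_trt[gene_idx]) * frac_for(psi_trt)

  noise <- matrix(2^stats::rnorm(n_probes * 2L * n_rep, 0, params$sd_noise),
                  nrow = n_probes)
  vals <- cbind(matrix(mean_ctrl, n_probes, n_rep),
                matrix(mean_trt, n_probes, n_rep)) * noise
  vals <- pmax(vals, 1)  # intensity floor: scanner data are positive
  dimnames(vals) <- list(tab$probe_id, sample_ids)

  truth <- structure(list(
    genes = data.frame(gene_id = genes,
                       true_expr_control = 2^log2_e_ctrl,
                       true_expr_treated = 2^log2_e_trt,
                       regulated = reg_expr,
                       direction = ifelse(reg_expr, expr_sign, 0L),
                       stringsAsFactors = FALSE),
    events = data.frame(event_id = events,
                        event_type = design$events$event_type,
                        psi_control = psi_ctrl,
                        psi_treated = psi_trt,
                        regulated = reg_spl,
                        direction = ifelse(reg_spl, spl_sign, 0L),
                        stringsAsFactors = FALSE)),
    class = "TruthTable")

  list(intensities = IntensityMatrix(vals, conditions, state = "raw"),
       truth = truth)
}

#' Simulate a full dataset and write it to disk
#'
#' Convenience wrapper: generates a design, simulates the experiment and
#' writes \code{design.tsv}, \code{intensities.tsv}, \code{conditions.tsv}
#' and \code{truth_genes.tsv}/\code{truth_events.tsv} under \code{out_dir}.
#'
#' @param params a \code{\link{sim_params}} object.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with \code{design}, \code{intensities} and
#'   \code{truth}.
#' @export
simulate_dataset <- function(params = sim_params(), out_dir) {
  design <- generate_design(params)
  sim <- simulate_experiment(design, params)
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_design(design, file.path(out_dir, "design.tsv"))
  write_intensities(sim$intensities, file.path(out_dir, "intensities.tsv"))
  utils::write.table(
    data.frame(sample_id = sim$intensities$sample_ids,
               condition = unname(sim$intensities$conditions)),
    file.path(out_dir, "conditions.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$genes, file.path(out_dir, "truth_genes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$events, file.path(out_dir, "truth_events.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(design = design, intensities = sim$intensities,
                 truth = sim$truth))
}
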