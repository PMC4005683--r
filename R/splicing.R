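#' Per-probe splicing index
#'
#' For every probe and sample, the splicing index is the log2 ratio of the
#' probe's intensity to its gene's expression index in that sample:
#' \code{si(p, s) = log2(intensity(p, s) / index(gene(p), s))}. Dividing by
#' the gene index removes transcription-level changes, so a condition
#' contrast in si isolates splicing. The per-probe contrast
#' \code{delta_si} is the mean si over treated samples minus the mean over
#' control samples.
#'
#' @param corrected background-corrected \code{\link{IntensityMatrix}}.
#' @param index gene x sample expression-index matrix.
#' @param design the matching \code{\link{ArrayDesign}}.
#' @return List of class \code{SplicingIndexMatrix}: \code{si} (probe x
#'   sample), \code{delta_si} (per probe), \code{conditions}.
#' @export
splicing_index <- function(corrected, index, design) {
  stopifnot(inherits(corrected, "IntensityMatrix"),
            inherits(design, "ArrayDesign"))
  tab <- design$table
  gene_rows <- index[tab$gene_id, colnames(corrected$values), drop = FALSE]
  si <- log2(pmax(corrected$values, 1)) - log2(pmax(gene_rows, 1))
  rownames(si) <- tab$probe_id
  cond <- corrected$conditions
  delta <- rowMeans(si[, cond == "treated", drop = FALSE]) -
    rowMeans(si[, cond == "control", drop = FALSE])
  structure(list(si = si, delta_si = delta, conditions = cond),
            class = "SplicingIndexMatrix")
}

#' Per-probe t-tests on the splicing index
#'
#' Two-sided pooled-variance t-test per probe comparing its splicing-index
#' values between conditions (same routine as the gene-level test). With
#' \code{on_si = FALSE} the tests run on log2 raw probe intensities
#' instead, in which case gene-level expression changes also register.
#'
#' @param si a \code{SplicingIndexMatrix} from \code{\link{splicing_index}}.
#' @param corrected the background-corrected \code{\link{IntensityMatrix}}
#'   (only used when \code{on_si = FALSE}).
#' @param on_si test gene-normalized splicing indices (default) or raw
#'   log2 probe intensities.
#' @return Named numeric vector of per-probe two-sided p-values.
#' @export
probe_si_ttest <- function(si, corrected = NULL, on_si = TRUE) {
  stopifnot(inherits(si, "SplicingIndexMatrix"))
  ctrl <- which(si$conditions == "control")
  trt  <- which(si$conditions == "treated")
  if (length(ctrl) < 2L || length(trt) < 2L)
    stop("t-tests need at least 2 samples per condition")
  x <- if (on_si) si$si else log2(pmax(corrected$values, 1))
  stats::setNames(row_pooled_ttest(x, ctrl, trt)$p, rownames(x))
}

#' Combine p-values with Fisher's method
#'
#' \code{X = -2 * sum(log(p_i))} follows a chi-square distribution with
#' \code{2k} degrees of freedom under the joint null; the combined p-value
#' is the upper-tail probability at X. Inputs are clipped to
#' \code{[1e-300, 1]} so the log is finite. For \code{k = 1} the transform
#' inverts exactly and the input p is returned.
#'
#' @param p_values numeric vector of k >= 1 p-values.
#' @return Combined p-value in [0, 1].
#' @export
fisher_combine <- function(p_values) {
  if (length(p_values) == 0L) stop("no p-values to combine")
  p <- pmin(pmax(as.numeric(p_values), 1e-300), 1)
  x <- -2 * sum(log(p))
  stats::pchisq(x, df = 2 * length(p), lower.tail = FALSE)
}

#' Per-probeset statistics
#'
#' Summarizes probe-level evidence at the probeset level: the member
#' probes' p-values are combined with Fisher's method, the probeset
#' splicing-index contrast is the mean of the member probes'
#' \code{delta_si}, direction is its sign, and the probeset is significant
#' when the combined p is at or below \code{alpha_ps}.
#'
#' @param si a \code{SplicingIndexMatrix}.
#' @param probe_p named per-probe p-values from \code{\link{probe_si_ttest}}.
#' @param design the matching \code{\link{ArrayDesign}}.
#' @param alpha_ps probeset significance cutoff (default 0.01).
#' @return data.frame (one row per probeset): \code{probeset_id},
#'   \code{event_id}, \code{group}, \code{gene_id}, \code{n_probes},
#'   \code{fisher_p}, \code{delta_si}, \code{direction}, \code{significant}.
#' @export
probeset_stats <- function(si, probe_p, design, alpha_ps = 0.01) {
  stopifnot(inherits(si, "SplicingIndexMatrix"),
            inherits(design, "ArrayDesign"))
  tab <- design$table
  probe_p <- probe_p[tab$probe_id]
  ps <- design$probesets
  idx_by_ps <- split(seq_len(nrow(tab)), tab$probeset_id)[ps$probeset_id]
  fisher_p <- vapply(idx_by_ps, function(i) fisher_combine(probe_p[i]),
                     numeric(1))
  delta <- vapply(idx_by_ps, function(i) mean(si$delta_si[i]), numeric(1))
  data.frame(probeset_id = ps$probeset_id,
             event_id = ps$event_id,
             group = ps$group,
             gene_id = ps$gene_id,
             n_probes = lengths(idx_by_ps),
             fisher_p = unname(fisher_p),
             delta_si = unname(delta),
             direction = sign(unname(delta)),
             significant = unname(fisher_p) <= alpha_ps,
             row.names = NULL, stringsAsFactors = FALSE)
}

# one-third rule: minimum significant probesets out of n
min_one_third <- function(n) as.integer(ceiling(n / 3))

#' Call alternative-splicing events
#'
#' Applies the combinatorial event rule to the probeset statistics of each
#' event. An event is called when: at least one-third (ceiling) of its
#' exclusion probesets are significant; at least one-third of its
#' inclusion probesets are significant; and every significant inclusion
#' probeset's splicing-index direction is opposite to the consensus
#' direction of the significant exclusion probesets (the sign of their
#' summed \code{delta_si}). For a cassette exon (1 exclusion junction, up
#' to 3 inclusion probesets) this reduces to: the exclusion junction plus
#' at least one of the three inclusion probesets significant, with
#' opposite regulation. A zero exclusion consensus leaves the event
#' uncalled (indeterminate).
#'
#' @param ps_stats probeset statistics from \code{\link{probeset_stats}}.
#' @param design the matching \code{\link{ArrayDesign}}.
#' @return data.frame (one row per event): \code{event_id},
#'   \code{event_type}, \code{gene_id}, \code{n_incl}, \code{n_excl},
#'   \code{n_sig_incl}, \code{n_sig_excl}, \code{called},
#'   \code{direction} (+1 inclusion up in treated, -1 inclusion down,
#'   0 not called/indeterminate).
#' @export
call_events <- function(ps_stats, design) {
  stopifnot(inherits(design, "ArrayDesign"))
  ev <- design$events
  n_ev <- nrow(ev)
  out <- data.frame(event_id = ev$event_id,
                    event_type = ev$event_type,
                    gene_id = ev$gene_id,
                    n_incl = integer(n_ev), n_excl = integer(n_ev),
                    n_sig_incl = integer(n_ev), n_sig_excl = integer(n_ev),
                    called = logical(n_ev),
                    direction = integer(n_ev),
                    stringsAsFactors = FALSE)
  if (n_ev == 0L) return(out)
  st_by_ev <- split(ps_stats[ps_stats$event_id != ".", , drop = FALSE],
                    ps_stats$event_id[ps_stats$event_id != "."])
  for (i in seq_len(nrow(ev))) {
    st <- st_by_ev[[ev$event_id[i]]]
    inc <- st[st$group == "inclusion", , drop = FALSE]
    exc <- st[st$group == "exclusion", , drop = FALSE]
    out$n_incl[i] <- nrow(inc)
    out$n_excl[i] <- nrow(exc)
    sig_inc <- inc[inc$significant, , drop = FALSE]
    sig_exc <- exc[exc$significant, , drop = FALSE]
    out$n_sig_incl[i] <- nrow(sig_inc)
    out$n_sig_excl[i] <- nrow(sig_exc)
    if (nrow(sig_exc) < min_one_third(nrow(exc)) ||
        nrow(sig_inc) < min_one_third(nrow(inc))) next
    consensus <- sign(sum(sig_exc$delta_si))
    if (consensus == 0) next                      # indeterminate
    if (all(sig_inc$direction == -consensus)) {
      out$called[i] <- TRUE
      out$direction[i] <- -consensus              # inclusion-side direction
    }
  }
  out
}

#' Summarize called events by type
#'
#' Counts called events per category: cassette exons, mutually exclusive
#' exons, and alternative 5'/3' splice sites (pooled), plus their total.
#'
#' @param calls event calls from \code{\link{call_events}}.
#' @return data.frame with one row: \code{cassette},
#'   \code{mutually_exclusive}, \code{alt_ss}, \code{total}.
#' @export
summarize_events <- function(calls) {
  called <- calls[calls$called, , drop = FALSE]
  n_cas <- sum(called$event_type == "cassette")
  n_me  <- sum(called$event_type == "mutually_exclusive")
  n_alt <- sum(called$event_type %in% c("alt5", "alt3"))
  data.frame(cassette = n_cas, mutually_exclusive = n_me, alt_ss = n_alt,
             total = n_cas + n_me + n_alt)
}

#' Run the full splicing-caller stage
#'
#' Chains \code{\link{splicing_index}}, \code{\link{probe_si_ttest}},
#' \code{\link{probeset_stats}} and \code{\link{call_events}}.
#'
#' @param corrected background-corrected \code{\link{IntensityMatrix}}.
#' @param index gene x sample expression-index matrix.
#' @param design the matching \code{\link{ArrayDesign}}.
#' @param alpha_ps probeset significance cutoff (default 0.01).
#' @param on_si run probe t-tests on gene-normalized splicing indices
#'   (default) or raw log2 intensities.
#' @return List with \code{si}, \code{probe_p}, \code{probeset_stats},
#'   \code{calls} and \code{summary}.
#' @export
call_splicing <- function(corrected, index, design, alpha_ps = 0.01,
                          on_si = TRUE) {
  si <- splicing_index(corrected, index, design)
  probe_p <- probe_si_ttest(si, corrected, on_si = on_si)
  ps <- probeset_stats(si, probe_p, design, alpha_ps = alpha_ps)
  calls <- call_events(ps, design)
  list(si = si, probe_p = probe_p, probeset_stats = ps, calls = calls,
       summary = summarize_events(calls))
}
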