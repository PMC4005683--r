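# Fixtures are built in code: a minimal 1-gene design carrying one cassette
# event (constitutive probeset + exclusion junction + inclusion exon body +
# inclusion junction; 2 probes each = 4 probesets, 8 probes).
tiny_design_table <- function() {
  row <- function(probe, ps, group, role, ev, type, start, end)
    data.frame(probe_id = probe, probeset_id = ps, group = group, role = role,
               event_id = ev, event_type = type, gene_id = "G1",
               chrom = "chr1", start = start, end = end, strand = "+",
               stringsAsFactors = FALSE)
  rbind(
    row("c1", "ps_const", "constitutive", "exon_body", ".", ".", 1, 200),
    row("c2", "ps_const", "constitutive", "exon_body", ".", ".", 1, 200),
    row("x1", "ps_excl", "exclusion", "junction", "E1", "cassette", 301, 900),
    row("x2", "ps_excl", "exclusion", "junction", "E1", "cassette", 301, 900),
    row("b1", "ps_body", "inclusion", "exon_body", "E1", "cassette", 301, 900),
    row("b2", "ps_body", "inclusion", "exon_body", "E1", "cassette", 301, 900),
    row("i1", "ps_incj", "inclusion", "junction", "E1", "cassette", 301, 900),
    row("i2", "ps_incj", "inclusion", "junction", "E1", "cassette", 301, 900))
}

tiny_design <- function() ArrayDesign(tiny_design_table())

# intensity matrix over a design with 3+3 samples and given per-probe values
tiny_matrix <- function(design, values, state = "raw", n_rep = 3L) {
  n <- nrow(design$table)
  samples <- c(sprintf("c%d", seq_len(n_rep)), sprintf("t%d", seq_len(n_rep)))
  if (is.null(dim(values)))
    values <- matrix(values, nrow = n, ncol = length(samples))
  dimnames(values) <- list(design$table$probe_id, samples)
  cond <- stats::setNames(rep(c("control", "treated"), each = n_rep), samples)
  IntensityMatrix(values, cond, state = state)
}

# hand-built probeset-stats row for caller tests
ps_row <- function(id, event, group, p, dsi, alpha = 0.01) {
  data.frame(probeset_id = id, event_id = event, group = group,
             gene_id = "G1", n_probes = 2L, fisher_p = p, delta_si = dsi,
             direction = sign(dsi), significant = p <= alpha,
             stringsAsFactors = FALSE)
}

# event-call rows with given types/called flags, for summary tests
call_rows <- function(types, called = TRUE) {
  n <- length(types)
  data.frame(event_id = sprintf("E%d", seq_len(n)), event_type = types,
             gene_id = rep("G1", n), n_incl = rep(1L, n),
             n_excl = rep(1L, n), n_sig_incl = rep(1L, n),
             n_sig_excl = rep(1L, n), called = rep_len(called, n),
             direction = rep(1L, n), stringsAsFactors = FALSE)
}
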