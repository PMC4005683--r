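#' Write pipeline result tables
#'
#' Writes \code{genes.tsv} (one row per gene with the regulated-gene
#' statistics), \code{events.tsv} (one row per event with the call,
#' direction and per-probeset evidence), \code{summary.tsv} (regulated
#' gene count plus called events split by cassette / mutually exclusive /
#' alternative 5'/3'), and \code{events.bed} (BED6 of called events;
#' design coordinates are 1-based inclusive and are converted to BED's
#' 0-based half-open, i.e. start - 1, end unchanged).
#'
#' @param genes regulated-gene table from \code{\link{call_regulated_genes}}.
#' @param calls event calls from \code{\link{call_events}}.
#' @param ps_stats probeset statistics from \code{\link{probeset_stats}}.
#' @param design the matching \code{\link{ArrayDesign}}.
#' @param out_dir output directory (created if needed).
#' @return Invisibly, the vector of files written.
#' @export
write_results <- function(genes, calls, ps_stats, design, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(out_dir))
      stop("cannot create output directory '", out_dir, "'")
  }
  f_genes <- file.path(out_dir, "genes.tsv")
  utils::write.table(genes, f_genes, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # per-event probeset evidence collapsed into two summary columns
  ev_stats <- ps_stats[ps_stats$event_id != ".", , drop = FALSE]
  fmt <- function(eid, col, digits = 4) {
    st <- ev_stats[ev_stats$event_id == eid, , drop = FALSE]
    paste(sprintf("%s=%s", st$probeset_id, signif(st[[col]], digits)),
          collapse = ",")
  }
  ev_out <- calls
  ev_out$probeset_p <- vapply(calls$event_id, fmt, character(1),
                              col = "fisher_p")
  ev_out$probeset_delta_si <- vapply(calls$event_id, fmt, character(1),
                                     col = "delta_si")
  f_events <- file.path(out_dir, "events.tsv")
  utils::write.table(ev_out, f_events, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  summ <- summarize_events(calls)
  summ <- cbind(data.frame(regulated_genes = sum(genes$regulated)), summ)
  f_summary <- file.path(out_dir, "summary.tsv")
  utils::write.table(summ, f_summary, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  called <- calls[calls$called, , drop = FALSE]
  ev_annot <- design$events[match(called$event_id, design$events$event_id), ,
                            drop = FALSE]
  bed <- data.frame(chrom = ev_annot$chrom,
                    start = ev_annot$start - 1L,   # 0-based half-open
                    end = ev_annot$end,
                    name = called$event_id,
                    score = called$direction,
                    strand = ev_annot$strand)
  f_bed <- file.path(out_dir, "events.bed")
  utils::write.table(bed, f_bed, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  if (nrow(bed) == 0L) file.create(f_bed)
  invisible(c(f_genes, f_events, f_summary, f_bed))
}
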