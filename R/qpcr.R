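#' ChIP-qPCR relative enrichment from Ct values
#'
#' Relative enrichment of immunoprecipitated chromatin over input DNA:
#' \code{2^(ct_reference - ct_sample)}, where the reference Ct is measured
#' on input DNA and the sample Ct on the IP'd chromatin. Only the Ct
#' difference matters; no amplification-efficiency correction is applied.
#'
#' @param ct_reference,ct_sample finite positive Ct values (cycles);
#'   vectors are handled elementwise.
#' @return Enrichment ratio(s), \code{2^(ct_reference - ct_sample)}.
#' @export
relative_expression <- function(ct_reference, ct_sample) {
  ct_reference <- as.numeric(ct_reference)
  ct_sample <- as.numeric(ct_sample)
  if (any(!is.finite(ct_reference)) || any(!is.finite(ct_sample)))
    stop("Ct values must be finite")
  if (any(ct_reference <= 0) || any(ct_sample <= 0))
    stop("Ct values must be positive")
  2^(ct_reference - ct_sample)
}

#' Aggregate qPCR replicate enrichments
#'
#' Mean and sample standard deviation of per-replicate enrichment ratios
#' for one target/antibody. Fewer than 3 replicates (the usual minimum for
#' ChIP experiments) triggers a warning; a single replicate reports sd 0.
#'
#' @param ratios numeric vector of per-replicate enrichment ratios from
#'   \code{\link{relative_expression}}.
#' @return List with \code{mean}, \code{sd} and \code{n}.
#' @export
aggregate_replicates <- function(ratios) {
  ratios <- as.numeric(ratios)
  if (length(ratios) == 0L) stop("no replicates to aggregate")
  n <- length(ratios)
  if (n < 3L)
    warning("only ", n, " replicate(s); at least 3 immunoprecipitations ",
            "are recommended")
  s <- if (n >= 2L) stats::sd(ratios) else 0
  list(mean = mean(ratios), sd = s, n = n)
}

#' Analyze a table of ChIP-qPCR Ct measurements
#'
#' Reads (or accepts) a table with columns \code{target_id},
#' \code{condition} (optional), \code{replicate_id}, \code{ct_reference},
#' \code{ct_sample}; computes per-replicate enrichments and aggregates
#' them per target (and condition, when present). When both conditions are
#' present for a target, the treated/control ratio of mean enrichments is
#' reported with its propagated standard deviation.
#'
#' @param cts a data.frame or a path to a tab-delimited file.
#' @return data.frame with one row per target (x condition):
#'   \code{target_id}, \code{condition}, \code{mean_enrichment},
#'   \code{sd_enrichment}, \code{n}, and (when both conditions exist)
#'   \code{ratio_treated_control}, \code{ratio_sd}.
#' @export
analyze_qpcr <- function(cts) {
  if (is.character(cts))
    cts <- utils::read.delim(cts, header = TRUE, sep = "\t",
                             comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("target_id", "replicate_id", "ct_reference", "ct_sample")
                %in% names(cts)))
  if (is.null(cts$condition)) cts$condition <- "sample"
  cts$enrichment <- relative_expression(cts$ct_reference, cts$ct_sample)
  key <- interaction(cts$target_id, cts$condition, drop = TRUE)
  agg <- lapply(split(cts, key), function(d) {
    a <- aggregate_replicates(d$enrichment)
    data.frame(target_id = d$target_id[1L], condition = d$condition[1L],
               mean_enrichment = a$mean, sd_enrichment = a$sd, n = a$n,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, agg)
  rownames(out) <- NULL
  # treated/control ratio per target, with first-order error propagation
  out$ratio_treated_control <- NA_real_
  out$ratio_sd <- NA_real_
  for (tg in unique(out$target_id)) {
    i_t <- which(out$target_id == tg & out$condition == "treated")
    i_c <- which(out$target_id == tg & out$condition == "control")
    if (length(i_t) == 1L && length(i_c) == 1L) {
      r <- out$mean_enrichment[i_t] / out$mean_enrichment[i_c]
      rel2 <- (out$sd_enrichment[i_t] / out$mean_enrichment[i_t])^2 +
        (out$sd_enrichment[i_c] / out$mean_enrichment[i_c])^2
      out$ratio_treated_control[c(i_t, i_c)] <- r
      out$ratio_sd[c(i_t, i_c)] <- r * sqrt(rel2)
    }
  }
  out
}
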