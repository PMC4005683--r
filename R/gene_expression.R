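#' Call expressed genes per condition
#'
#' A gene is expressed in a condition when its mean expression index over
#' that condition's samples is at or above \code{threshold} (inclusive).
#'
#' @param index gene x sample expression-index matrix (linear scale), as
#'   from \code{\link{gene_expression_index}}.
#' @param conditions named character vector, sample ->
#'   \code{"control"}/\code{"treated"}.
#' @param threshold expressed cutoff in fluorescence units (default 500).
#' @return data.frame with \code{gene_id}, \code{mean_control},
#'   \code{mean_treated}, \code{expressed_control}, \code{expressed_treated}.
#' @export
call_expressed <- function(index, conditions, threshold = 500) {
  conditions <- conditions[colnames(index)]
  m_ctrl <- rowMeans(index[, conditions == "control", drop = FALSE])
  m_trt  <- rowMeans(index[, conditions == "treated", drop = FALSE])
  data.frame(gene_id = rownames(index),
             mean_control = m_ctrl,
             mean_treated = m_trt,
             expressed_control = m_ctrl >= threshold,
             expressed_treated = m_trt >= threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Call regulated genes
#'
#' Applies the three-clause regulated-gene rule: a gene is regulated when
#' (i) it is expressed in at least one condition, (ii) its symmetric fold
#' change on linear condition means is >= \code{fc_min}, and (iii) the
#' two-sided unpaired t-test on its log2 expression indices between
#' conditions gives p <= \code{alpha}. No multiple-testing correction is
#' applied; the thresholds are used raw.
#'
#' @param index gene x sample expression-index matrix (linear scale).
#' @param conditions named character vector, sample ->
#'   \code{"control"}/\code{"treated"} (>= 2 samples each).
#' @param threshold expressed cutoff (default 500).
#' @param fc_min minimum fold change (default 1.5).
#' @param alpha t-test significance cutoff (default 0.05).
#' @param welch use the Welch t-test instead of the pooled form.
#' @return data.frame (one row per gene): \code{gene_id},
#'   \code{mean_control}, \code{mean_treated}, \code{expressed_control},
#'   \code{expressed_treated}, \code{fold_change} (>= 1),
#'   \code{direction} (sign of treated minus control), \code{t}, \code{p},
#'   \code{regulated}.
#' @export
call_regulated_genes <- function(index, conditions, threshold = 500,
                                 fc_min = 1.5, alpha = 0.05, welch = FALSE) {
  conditions <- conditions[colnames(index)]
  ctrl <- which(conditions == "control")
  trt  <- which(conditions == "treated")
  if (length(ctrl) < 2L || length(trt) < 2L)
    stop("t-tests need at least 2 samples per condition")
  expr <- call_expressed(index, conditions, threshold)
  fc <- pmax(expr$mean_treated / expr$mean_control,
             expr$mean_control / expr$mean_treated)
  direction <- sign(expr$mean_treated - expr$mean_control)
  logv <- log2(pmax(index, 1))
  if (welch) {
    tp <- t(apply(logv, 1L, function(x) {
      r <- unpaired_ttest(x[trt], x[ctrl], welch = TRUE)
      c(r$t, r$p)
    }))
    t_stat <- tp[, 1L]; p <- tp[, 2L]
  } else {
    r <- row_pooled_ttest(logv, ctrl, trt)
    t_stat <- r$t; p <- r$p
  }
  expr$fold_change <- fc
  expr$direction <- direction
  expr$t <- t_stat
  expr$p <- p
  expr$regulated <- (expr$expressed_control | expr$expressed_treated) &
    fc >= fc_min & p <= alpha
  expr
}
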