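#' Probe-by-sample intensity matrix
#'
#' Container for raw or normalized fluorescence intensities (linear scale)
#' with the sample-to-condition map. Rows are probes in the order of the
#' array design; columns are samples.
#'
#' @param values numeric matrix, probes x samples, all values >= 0.
#' @param conditions named character vector mapping every sample (column
#'   name) to \code{"control"} or \code{"treated"}.
#' @param state processing state, one of \code{"raw"}, \code{"scaled"},
#'   \code{"background_corrected"}.
#' @return An object of class \code{IntensityMatrix}.
#' @export
IntensityMatrix <- function(values, conditions,
                            state = c("raw", "scaled", "background_corrected")) {
  state <- match.arg(state)
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("intensity matrix needs probe rownames and sample colnames")
  if (any(!is.finite(values)))
    stop("non-finite intensity values")
  neg <- which(values < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative intensity at probe '%s', sample '%s'",
                 rownames(values)[neg[1L, 1L]], colnames(values)[neg[1L, 2L]]))
  conditions <- conditions[colnames(values)]
  if (any(is.na(conditions)))
    stop("conditions missing for samples: ",
         paste(colnames(values)[is.na(conditions)], collapse = ", "))
  bad <- setdiff(unique(conditions), c("control", "treated"))
  if (length(bad))
    stop("conditions must be 'control' or 'treated', got: ",
         paste(bad, collapse = ", "))
  n_per <- table(factor(conditions, levels = c("control", "treated")))
  if (any(n_per < 2L))
    warning("condition(s) with fewer than 2 samples: ",
            paste(names(n_per)[n_per < 2L], collapse = ", "),
            "; t-tests will refuse")
  structure(list(values = values,
                 sample_ids = colnames(values),
                 conditions = conditions,
                 state = state),
            class = "IntensityMatrix")
}

#' Read a probe-by-sample intensity table
#'
#' Reads a tab-delimited table whose first column is \code{probe_id} and
#' remaining columns are per-sample intensities, checks it against the
#' array design (same probe set, no negatives), and reorders rows to the
#' design's probe order.
#'
#' @param path intensity TSV path.
#' @param design an \code{\link{ArrayDesign}}; the probe set must match
#'   exactly.
#' @param conditions named character vector, sample id ->
#'   \code{"control"}/\code{"treated"}.
#' @return An \code{\link{IntensityMatrix}} in state \code{"raw"}.
#' @export
read_intensities <- function(path, design, conditions) {
  stopifnot(inherits(design, "ArrayDesign"))
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  if (names(tab)[1L] != "probe_id")
    stop("first column of intensity file must be 'probe_id'")
  probes <- as.character(tab$probe_id)
  extra <- setdiff(probes, design$probes$probe_id)
  if (length(extra))
    stop("probe not in design: ", paste(extra, collapse = ", "))
  missing <- setdiff(design$probes$probe_id, probes)
  if (length(missing))
    stop("missing probe row(s): ", paste(missing, collapse = ", "))
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  if (!is.numeric(vals)) stop("non-numeric intensity values")
  rownames(vals) <- probes
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stop(sprintf("negative intensity at row %d (probe '%s'), column '%s'",
                 neg[1L, 1L], probes[neg[1L, 1L]], colnames(vals)[neg[1L, 2L]]))
  vals <- vals[design$probes$probe_id, , drop = FALSE]
  IntensityMatrix(vals, conditions, state = "raw")
}

#' Write an intensity table
#'
#' @param mat an \code{\link{IntensityMatrix}}.
#' @param path output TSV path.
#' @export
write_intensities <- function(mat, path) {
  stopifnot(inherits(mat, "IntensityMatrix"))
  out <- data.frame(probe_id = rownames(mat$values), mat$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @export
print.IntensityMatrix <- function(x, ...) {
  cat("IntensityMatrix:", nrow(x$values), "probes x", ncol(x$values),
      "samples, state =", x$state, "\n")
  print(table(x$conditions))
  invisible(x)
}

# column indices per condition; refuses when a condition has < 2 samples
condition_index <- function(mat, require_two = TRUE) {
  ctrl <- which(mat$conditions == "control")
  trt  <- which(mat$conditions == "treated")
  if (require_two && (length(ctrl) < 2L || length(trt) < 2L))
    stop("t-tests need at least 2 samples per condition")
  list(control = ctrl, treated = trt)
}
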