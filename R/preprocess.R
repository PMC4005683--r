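#' Probe scaling: per-array trimmed-mean normalization
#'
#' Rescales every sample (array) by a single multiplicative factor so that
#' its trimmed mean equals \code{target}. This removes per-array intensity
#' differences (labelling, scanning) under the assumption that most probes
#' do not change.
#'
#' @param raw an \code{\link{IntensityMatrix}} in state \code{"raw"}.
#' @param target trimmed-mean intensity after scaling (default 500
#'   fluorescence units, aligning the array-wide level with the
#'   expressed-gene threshold).
#' @param trim fraction trimmed from each tail before averaging
#'   (default 0.02).
#' @return A scaled \code{\link{IntensityMatrix}} (state \code{"scaled"})
#'   with the per-sample factors in attribute \code{"scaling_factors"}.
#' @export
scale_arrays <- function(raw, target = 500, trim = 0.02) {
  stopifnot(inherits(raw, "IntensityMatrix"))
  if (raw$state != "raw")
    stop("scale_arrays expects a raw matrix, got state '", raw$state, "'")
  tm <- apply(raw$values, 2L, mean, trim = trim)
  if (any(tm <= 0))
    stop("cannot scale sample(s) with non-positive trimmed mean: ",
         paste(colnames(raw$values)[tm <= 0], collapse = ", "))
  factors <- target / tm
  out <- sweep(raw$values, 2L, factors, `*`)
  res <- IntensityMatrix(out, raw$conditions, state = "scaled")
  attr(res, "scaling_factors") <- stats::setNames(factors, colnames(out))
  res
}

# Per-probe log2 affinity: median across samples of the probe's log2
# residual versus the gene's per-sample median constitutive probe signal.
# The reference uses constitutive probes only: junction/exon probes carry
# isoform-fraction signal that must not contaminate the gene reference.
probe_affinities <- function(mat, design) {
  logv <- log2(pmax(mat$values, 1))
  tab <- design$table
  aff <- numeric(nrow(logv))
  for (idx in split(seq_len(nrow(tab)), tab$gene_id)) {
    if (length(idx) == 1L) { aff[idx] <- 0; next }
    ref_idx <- idx[tab$group[idx] == "constitutive"]
    med <- apply(logv[ref_idx, , drop = FALSE], 2L, stats::median)
    sub <- logv[idx, , drop = FALSE]
    aff[idx] <- apply(sweep(sub, 2L, med), 1L, stats::median)
  }
  stats::setNames(aff, rownames(mat$values))
}

#' Probe-affinity (background) correction
#'
#' Estimates each probe's affinity as the median, across samples, of its
#' log2 residual against the gene's per-sample median constitutive probe
#' signal, and subtracts it in log2 space. Probes that systematically read high or low
#' relative to their gene (sequence-dependent affinity, background) are
#' brought onto the gene's common scale; a gene with a single probe gets
#' affinity 0.
#'
#' @param scaled an \code{\link{IntensityMatrix}} in state \code{"scaled"}.
#' @param design the matching \code{\link{ArrayDesign}}.
#' @return An \code{\link{IntensityMatrix}} in state
#'   \code{"background_corrected"}, with per-probe affinities in attribute
#'   \code{"affinities"}.
#' @export
correct_probe_effects <- function(scaled, design) {
  stopifnot(inherits(scaled, "IntensityMatrix"),
            inherits(design, "ArrayDesign"))
  if (scaled$state != "scaled")
    stop("correct_probe_effects expects a scaled matrix, got state '",
         scaled$state, "'")
  if (!identical(rownames(scaled$values), design$table$probe_id))
    stop("probe rows do not match design")
  aff <- probe_affinities(scaled, design)
  out <- scaled$values / 2^aff
  res <- IntensityMatrix(out, scaled$conditions,
                         state = "background_corrected")
  attr(res, "affinities") <- aff
  res
}

#' Select constitutive probes for the gene expression index
#'
#' Per gene, keeps the constitutive probes whose cross-sample log2 profile
#' has Pearson correlation >= \code{r_min} with the gene's median
#' constitutive profile; badly behaved probes (cross-hybridization,
#' saturation) track the gene poorly and are dropped. If fewer than
#' \code{min_keep} constitutive probes survive, all constitutive probes of
#' that gene are kept. Event (inclusion/exclusion) probes carry the
#' splicing signal and are never subject to selection: they are always
#' marked \code{TRUE} in the returned mask but are not used by the index.
#'
#' The Pearson correlation between a probe profile and the gene median
#' profile is only meaningful when the gene actually varies across
#' samples: on a gene whose expression is identical in every sample the
#' profiles are pure replicate noise, the population correlation is
#' undefined, and filtering on the sample correlation just discards a
#' random, mutually noise-correlated subset of good probes — inflating
#' the index noise. The filter is therefore gated on detectable
#' cross-sample signal: it is applied only when the variance of the
#' median profile exceeds \code{signal_gate} times its expectation under
#' pure replicate noise (estimated per gene from the pooled
#' within-condition probe variances).
#'
#' @param corrected background-corrected \code{\link{IntensityMatrix}}.
#' @param design the matching \code{\link{ArrayDesign}}.
#' @param r_min minimum Pearson correlation with the gene median profile
#'   (default 0.7). A zero-variance probe profile gets correlation 0.
#' @param min_keep minimum surviving constitutive probes per gene before
#'   the keep-all fallback triggers (default 3).
#' @param signal_gate multiple of the noise-only median-profile variance
#'   that the observed median-profile variance must exceed before the
#'   correlation filter is applied (default 3).
#' @return Named logical vector over probes (design order).
#' @export
select_probes <- function(corrected, design, r_min = 0.7, min_keep = 3L,
                          signal_gate = 3) {
  stopifnot(inherits(corrected, "IntensityMatrix"),
            inherits(design, "ArrayDesign"))
  if (corrected$state != "background_corrected")
    stop("select_probes expects a background-corrected matrix")
  tab <- design$table
  logv <- log2(pmax(corrected$values, 1))
  cond <- corrected$conditions
  cond_f <- factor(cond)
  n_s <- ncol(logv)
  df_within <- n_s - nlevels(cond_f)
  keep <- rep(TRUE, nrow(tab))
  const_idx <- which(tab$group == "constitutive")
  for (idx in split(const_idx, tab$gene_id[const_idx])) {
    if (length(idx) < 2L) next
    sub <- logv[idx, , drop = FALSE]
    med <- apply(sub, 2L, stats::median)
    if (df_within > 0L) {
      # per-probe replicate noise variance, pooled within conditions
      cm <- t(apply(sub, 1L, function(x) tapply(x, cond_f, mean)))
      resid <- sub - cm[, as.integer(cond_f), drop = FALSE]
      s2 <- stats::median(rowSums(resid^2) / df_within)
      # variance of the median of n iid normals ~ pi/2 * s2 / n
      null_med_var <- s2 * pi / (2 * length(idx))
      if (stats::var(med) <= signal_gate * null_med_var) next
    }
    r <- apply(sub, 1L, function(x) {
      if (stats::sd(x) == 0 || stats::sd(med) == 0) return(0)
      stats::cor(x, med)
    })
    ok <- r >= r_min
    if (sum(ok) >= min_keep) keep[idx] <- ok
    # else: fallback, keep all constitutive probes of this gene
  }
  stats::setNames(keep, tab$probe_id)
}

#' Gene expression index
#'
#' Per gene and sample, the arithmetic mean of the linear-scale intensities
#' of the gene's selected constitutive probes. This is the per-sample
#' expression summary that the expressed/regulated calls and the splicing
#' index are computed against.
#'
#' @param corrected background-corrected \code{\link{IntensityMatrix}}.
#' @param mask logical probe mask from \code{\link{select_probes}}.
#' @param design the matching \code{\link{ArrayDesign}}.
#' @return Numeric matrix, genes x samples (linear scale).
#' @export
gene_expression_index <- function(corrected, mask, design) {
  stopifnot(inherits(corrected, "IntensityMatrix"),
            inherits(design, "ArrayDesign"),
            length(mask) == nrow(design$table))
  tab <- design$table
  use <- tab$group == "constitutive" & mask
  grp <- tab$gene_id[use]
  sums <- rowsum(corrected$values[use, , drop = FALSE], grp)
  counts <- table(grp)
  idx <- sums / as.vector(counts[rownames(sums)])
  idx[design$genes$gene_id, , drop = FALSE]
}

#' Run the full normalization stage
#'
#' Chains \code{\link{scale_arrays}}, \code{\link{correct_probe_effects}},
#' \code{\link{select_probes}} and \code{\link{gene_expression_index}}.
#'
#' @param raw raw \code{\link{IntensityMatrix}}.
#' @param design the matching \code{\link{ArrayDesign}}.
#' @param target,trim,r_min,min_keep stage parameters, see the individual
#'   functions.
#' @return List with \code{corrected} (IntensityMatrix), \code{mask}
#'   (logical), \code{index} (gene x sample matrix) and
#'   \code{scaling_factors}.
#' @export
preprocess <- function(raw, design, target = 500, trim = 0.02,
                       r_min = 0.7, min_keep = 3L, signal_gate = 3) {
  scaled <- scale_arrays(raw, target = target, trim = trim)
  corrected <- correct_probe_effects(scaled, design)
  mask <- select_probes(corrected, design, r_min = r_min, min_keep = min_keep,
                        signal_gate = signal_gate)
  index <- gene_expression_index(corrected, mask, design)
  list(corrected = corrected, mask = mask, index = index,
       scaling_factors = attr(scaled, "scaling_factors"))
}
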