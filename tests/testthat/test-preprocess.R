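test_that("probe scaling brings each trimmed column mean to the target", {
  d <- tiny_design()
  col <- c(10, 20, 30, 40, 50, 10, 20, 30)
  m <- tiny_matrix(d, matrix(rep(col, 6), nrow = 8))
  s <- scale_arrays(m, target = 100, trim = 0)
  # column [10..50,...] has mean 26.25, factor 100/26.25
  expect_equal(unname(s$values[1:5, 1]),
               c(10, 20, 30, 40, 50) * 100 / 26.25)
  expect_equal(unname(colMeans(s$values)), rep(100, 6))
  expect_equal(s$state, "scaled")

  # column already at the target is unchanged
  m2 <- tiny_matrix(d, matrix(100, nrow = 8, ncol = 6))
  s2 <- scale_arrays(m2, target = 100, trim = 0)
  expect_equal(s2$values, m2$values)
})

test_that("scaling absorbs any per-sample multiplicative distortion", {
  d <- tiny_design()
  set.seed(1)
  base <- matrix(runif(48, 50, 900), nrow = 8)
  m <- tiny_matrix(d, base)
  warped <- base
  warped[, 2] <- warped[, 2] * 7.3   # one array scanned brighter
  mw <- tiny_matrix(d, warped)
  expect_equal(scale_arrays(m)$values, scale_arrays(mw)$values)
})

test_that("probe-effect correction subtracts the median log2 residual", {
  d <- tiny_design()
  set.seed(2)
  base <- matrix(2^runif(48, 5, 10), nrow = 8)
  # probe 3 reads exactly 2x the gene constitutive reference everywhere
  base[3, ] <- 2 * 2^colMeans(log2(base[1:2, ]))
  m <- tiny_matrix(d, base, state = "scaled")
  corr <- correct_probe_effects(m, d)
  aff <- attr(corr, "affinities")
  expect_equal(unname(aff["x1"]), 1)
  expect_equal(unname(corr$values[3, ]),
               unname(2^colMeans(log2(base[1:2, ]))))
  expect_equal(corr$state, "background_corrected")

  # brute-force oracle on a random fixture: per-probe median residual
  # against the gene's constitutive (probes 1-2) median log2 profile
  set.seed(3)
  rnd <- matrix(2^runif(48, 4, 12), nrow = 8)
  mr <- tiny_matrix(d, rnd, state = "scaled")
  got <- correct_probe_effects(mr, d)$values
  med <- apply(log2(rnd[1:2, ]), 2, stats::median)
  exp_vals <- rnd
  for (i in 1:8) {
    a <- stats::median(log2(rnd[i, ]) - med)
    exp_vals[i, ] <- rnd[i, ] / 2^a
  }
  expect_equal(unname(got), unname(exp_vals))

  # all probes identical within the gene -> unchanged
  flat <- tiny_matrix(d, matrix(rep(c(300, 400, 500, 600, 700, 800),
                                    each = 8), nrow = 8), state = "scaled")
  expect_equal(correct_probe_effects(flat, d)$values, flat$values)
})

test_that("probe selection keeps proportional probes and drops anticorrelated ones", {
  # gene with 6 constitutive probes and strong cross-sample signal
  tab <- do.call(rbind, lapply(1:6, function(k)
    data.frame(probe_id = paste0("p", k), probeset_id = paste0("ps", k),
               group = "constitutive", role = "exon_body", event_id = ".",
               event_type = ".", gene_id = "G1", chrom = "chr1",
               start = 1, end = 100, strand = "+",
               stringsAsFactors = FALSE)))
  d <- ArrayDesign(tab)
  profile <- 2^c(6, 9, 7, 10, 8, 11)   # strong cross-sample variation
  vals <- t(sapply(c(1, 2, 0.5, 1.5, 4, 1), function(a) a * profile))
  m <- tiny_matrix(d, vals, state = "background_corrected")
  mask <- select_probes(m, d)
  expect_true(all(mask))   # all proportional -> r = 1 -> all kept

  # one probe exactly anticorrelated
  vals2 <- vals
  vals2[6, ] <- 2^(17 - log2(profile))
  m2 <- tiny_matrix(d, vals2, state = "background_corrected")
  mask2 <- select_probes(m2, d)
  expect_false(mask2[["p6"]])
  expect_true(all(mask2[1:5]))
})

test_that("selection falls back to keep-all below min_keep and never touches event probes", {
  d <- tiny_design()   # 2 constitutive probes < min_keep = 3
  set.seed(4)
  m <- tiny_matrix(d, matrix(2^runif(48, 4, 12), nrow = 8),
                   state = "background_corrected")
  mask <- select_probes(m, d)
  expect_true(all(mask))   # fallback keeps both constitutive probes

  # event probes are always retained in the mask regardless of behaviour
  expect_true(all(mask[d$table$group != "constitutive"]))
})

test_that("selection leaves replicate-homogeneous genes intact", {
  # no cross-sample signal: profiles are pure noise and the correlation
  # criterion carries no information, so no probe may be dropped
  tab <- do.call(rbind, lapply(1:10, function(k)
    data.frame(probe_id = paste0("p", k), probeset_id = paste0("ps", k),
               group = "constitutive", role = "exon_body", event_id = ".",
               event_type = ".", gene_id = "G1", chrom = "chr1",
               start = 1, end = 100, strand = "+",
               stringsAsFactors = FALSE)))
  d <- ArrayDesign(tab)
  set.seed(5)
  kept <- replicate(20, {
    vals <- 500 * 2^matrix(rnorm(60, 0, 0.25), nrow = 10)
    m <- tiny_matrix(d, vals, state = "background_corrected")
    mean(select_probes(m, d))
  })
  expect_equal(mean(kept), 1)
})

test_that("gene expression index is the mean of selected constitutive probes", {
  d <- tiny_design()
  vals <- matrix(1000, nrow = 8, ncol = 6)
  vals[1, ] <- 400
  vals[2, ] <- 600
  m <- tiny_matrix(d, vals, state = "background_corrected")
  mask <- stats::setNames(rep(TRUE, 8), d$table$probe_id)
  idx <- gene_expression_index(m, mask, d)
  expect_equal(unname(idx["G1", ]), rep(500, 6))  # mean(400, 600)

  # single selected probe -> index equals that probe
  mask1 <- mask; mask1["c2"] <- FALSE
  expect_equal(unname(gene_expression_index(m, mask1, d)["G1", ]),
               rep(400, 6))

  # brute-force oracle on a random fixture
  set.seed(6)
  rnd <- matrix(runif(48, 10, 2000), nrow = 8)
  mr <- tiny_matrix(d, rnd, state = "background_corrected")
  expect_equal(unname(gene_expression_index(mr, mask, d)["G1", ]),
               unname(colMeans(rnd[1:2, ])))
})

test_that("noise-free pipeline recovers the true expression index", {
  p <- sim_params(seed = 8, n_genes = 30, sd_noise = 0, sd_affinity = 0,
                  fraction_unexpressed = 0,
                  fraction_regulated_expression = 0,
                  fraction_regulated_splicing = 0)
  d <- generate_design(p)
  sim <- simulate_experiment(d, p)
  pre <- preprocess(sim$intensities, d)
  # scaling multiplies all samples by a common factor (identical arrays)
  f <- attr(scale_arrays(sim$intensities), "scaling_factors")[1]
  truth <- sim$truth$genes
  expect_equal(unname(pre$index[truth$gene_id, 1]),
               truth$true_expr_control * f, tolerance = 1e-10)
})

test_that("state transitions are enforced", {
  d <- tiny_design()
  m <- tiny_matrix(d, 100)
  expect_error(correct_probe_effects(m, d), "scaled")
  expect_error(select_probes(m, d), "background")
  s <- scale_arrays(m)
  expect_error(scale_arrays(s), "raw")
})
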