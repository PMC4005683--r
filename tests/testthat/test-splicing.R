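test_that("splicing index is the log2 probe/gene-index ratio", {
  d <- tiny_design()
  vals <- matrix(1000, nrow = 8, ncol = 6)
  m <- tiny_matrix(d, vals, state = "background_corrected")
  idx <- matrix(1000, nrow = 1, ncol = 6,
                dimnames = list("G1", colnames(m$values)))
  si <- splicing_index(m, idx, d)
  expect_true(all(si$si == 0))
  expect_true(all(si$delta_si == 0))

  # probe/gene ratio doubling in every treated sample -> delta_si = +1
  vals2 <- vals
  vals2[3, 4:6] <- 2000
  m2 <- tiny_matrix(d, vals2, state = "background_corrected")
  si2 <- splicing_index(m2, idx, d)
  expect_equal(unname(si2$delta_si["x1"]), 1)

  # brute-force oracle on a random fixture
  set.seed(20)
  rnd <- matrix(2^runif(48, 4, 12), nrow = 8)
  idxr <- matrix(2^runif(6, 8, 10), nrow = 1,
                 dimnames = list("G1", colnames(m$values)))
  mr <- tiny_matrix(d, rnd, state = "background_corrected")
  sir <- splicing_index(mr, idxr, d)
  for (i in 1:8) for (s in 1:6)
    expect_equal(unname(sir$si[i, s]), log2(rnd[i, s] / idxr[1, s]))
})

test_that("Fisher's method matches its closed forms", {
  # k = 1 identity over a log-spaced grid (chi-square 2 df inverts -2 log p)
  grid <- 10^seq(-12, 0, length.out = 60)
  for (p in grid) expect_equal(fisher_combine(p), p, tolerance = 1e-12)

  expect_equal(fisher_combine(c(1, 1)), 1)

  # frozen closed form e^(-x/2)(1 + x/2), x = -2 log(0.0025)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.01747866136777,
               tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.02, 0.03, 0.9)), 0.0198875458721925,
               tolerance = 1e-12)
  expect_error(fisher_combine(numeric(0)), "no p-values")
  # extreme values are clipped, never NaN
  expect_gte(fisher_combine(c(1e-320, 1)), 0)
})

test_that("probe t-tests on splicing indices behave at the extremes", {
  d <- tiny_design()
  vals <- matrix(1000, nrow = 8, ncol = 6)
  m <- tiny_matrix(d, vals, state = "background_corrected")
  idx <- matrix(1000, nrow = 1, ncol = 6,
                dimnames = list("G1", colnames(m$values)))
  si <- splicing_index(m, idx, d)
  p <- probe_si_ttest(si)
  expect_true(all(p == 1))   # identical si vectors

  # [0,0,0] vs [1,1,1] with tiny jitter is overwhelmingly significant
  set.seed(21)
  vals2 <- vals * 2^matrix(rnorm(48, 0, 0.005), nrow = 8)
  vals2[3, 4:6] <- vals2[3, 4:6] * 2
  m2 <- tiny_matrix(d, vals2, state = "background_corrected")
  si2 <- splicing_index(m2, idx, d)
  expect_lt(probe_si_ttest(si2)[["x1"]], 0.01)
})

test_that("null probe si p-values are uniform", {
  p <- sim_params(seed = 22, n_genes = 150,
                  fraction_regulated_splicing = 0,
                  fraction_regulated_expression = 0,
                  fraction_unexpressed = 0)
  d <- generate_design(p)
  sim <- simulate_experiment(d, p)
  pre <- preprocess(sim$intensities, d)
  si <- splicing_index(pre$corrected, pre$index, d)
  pp <- probe_si_ttest(si)
  # restrict to junction probes (independent across events)
  pv <- pp[d$table$role == "junction" & d$table$group != "constitutive"]
  ks <- stats::ks.test(pv, "punif")
  expect_gt(ks$p.value, 1e-3)
  expect_equal(mean(pv <= 0.05), 0.05, tolerance = 0.35)
})

test_that("probeset stats combine member probes correctly", {
  d <- tiny_design()
  set.seed(23)
  vals <- matrix(2^runif(48, 6, 11), nrow = 8)
  m <- tiny_matrix(d, vals, state = "background_corrected")
  idx <- matrix(800, nrow = 1, ncol = 6,
                dimnames = list("G1", colnames(m$values)))
  si <- splicing_index(m, idx, d)
  pp <- probe_si_ttest(si)
  st <- probeset_stats(si, pp, d)
  expect_setequal(st$probeset_id, unique(d$table$probeset_id))
  for (i in seq_len(nrow(st))) {
    members <- d$table$probe_id[d$table$probeset_id == st$probeset_id[i]]
    expect_equal(st$fisher_p[i], fisher_combine(pp[members]))
    expect_equal(st$delta_si[i], mean(si$delta_si[members]))
    expect_equal(st$direction[i], sign(st$delta_si[i]))
    expect_equal(st$significant[i], st$fisher_p[i] <= 0.01)
  }
  # all-null probes: fisher_p 1, not significant
  m1 <- tiny_matrix(d, matrix(1000, 8, 6), state = "background_corrected")
  si1 <- splicing_index(m1, idx * 0 + 1000, d)
  st1 <- probeset_stats(si1, probe_si_ttest(si1), d)
  expect_true(all(st1$fisher_p == 1))
  expect_true(!any(st1$significant))
})

test_that("the cassette rule calls the canonical evidence patterns", {
  d <- tiny_design()
  # exclusion junction significant +1.0; exon body significant -0.8;
  # inclusion junction not significant -> called, inclusion-down
  st <- rbind(ps_row("ps_excl", "E1", "exclusion", 0.005, 1.0),
              ps_row("ps_body", "E1", "inclusion", 0.004, -0.8),
              ps_row("ps_incj", "E1", "inclusion", 0.2, -0.1))
  calls <- call_events(st, d)
  expect_true(calls$called)
  expect_equal(calls$direction, -1L)

  # same but the significant inclusion probeset moves WITH the exclusion
  st2 <- rbind(ps_row("ps_excl", "E1", "exclusion", 0.005, 1.0),
               ps_row("ps_body", "E1", "inclusion", 0.004, 0.8),
               ps_row("ps_incj", "E1", "inclusion", 0.2, -0.1))
  expect_false(call_events(st2, d)$called)

  # nothing significant -> not called
  st3 <- rbind(ps_row("ps_excl", "E1", "exclusion", 0.5, 1.0),
               ps_row("ps_body", "E1", "inclusion", 0.5, -0.8),
               ps_row("ps_incj", "E1", "inclusion", 0.5, -0.1))
  expect_false(call_events(st3, d)$called)

  # exclusion side not significant -> not called even with strong inclusion
  st4 <- rbind(ps_row("ps_excl", "E1", "exclusion", 0.2, 1.0),
               ps_row("ps_body", "E1", "inclusion", 0.001, -0.8),
               ps_row("ps_incj", "E1", "inclusion", 0.001, -0.9))
  expect_false(call_events(st4, d)$called)
})

test_that("the one-third rule uses the ceiling", {
  expect_equal(spliceArray:::min_one_third(1), 1L)
  expect_equal(spliceArray:::min_one_third(2), 1L)
  expect_equal(spliceArray:::min_one_third(3), 1L)
  expect_equal(spliceArray:::min_one_third(4), 2L)
  expect_equal(spliceArray:::min_one_third(6), 2L)
  expect_equal(spliceArray:::min_one_third(7), 3L)
})

test_that("event summaries count by category and always sum to the total", {
  s <- summarize_events(call_rows(c("cassette", "cassette",
                                    "mutually_exclusive")))
  expect_equal(s$cassette, 2)
  expect_equal(s$mutually_exclusive, 1)
  expect_equal(s$alt_ss, 0)
  expect_equal(s$total, 3)

  s0 <- summarize_events(call_rows(character(0)))
  expect_equal(s0$total, 0)

  set.seed(24)
  for (i in 1:20) {
    types <- sample(c("cassette", "alt5", "alt3", "mutually_exclusive"),
                    sample(0:30, 1), replace = TRUE)
    called <- sample(c(TRUE, FALSE), length(types), replace = TRUE)
    s <- summarize_events(call_rows(types, called))
    expect_equal(s$total, s$cassette + s$mutually_exclusive + s$alt_ss)
    expect_equal(s$total, sum(called))
  }
})

test_that("label swap negates delta_si but preserves the called set", {
  p <- sim_params(seed = 25, n_genes = 150)
  d <- generate_design(p)
  sim <- simulate_experiment(d, p)
  pre <- preprocess(sim$intensities, d)
  sp1 <- call_splicing(pre$corrected, pre$index, d)
  flip <- pre$corrected
  flip$conditions <- stats::setNames(
    ifelse(flip$conditions == "control", "treated", "control"),
    names(flip$conditions))
  sp2 <- call_splicing(flip, pre$index, d)
  expect_equal(sp2$si$delta_si, -sp1$si$delta_si, tolerance = 1e-12)
  expect_equal(sp2$probe_p, sp1$probe_p, tolerance = 1e-12)
  expect_equal(sp2$probeset_stats$significant, sp1$probeset_stats$significant)
  expect_equal(sp2$calls$called, sp1$calls$called)
  expect_equal(sp2$calls$direction, -sp1$calls$direction)
})

test_that("calling is monotone in the probeset alpha", {
  p <- sim_params(seed = 26, n_genes = 200)
  d <- generate_design(p)
  sim <- simulate_experiment(d, p)
  pre <- preprocess(sim$intensities, d)
  loose <- call_splicing(pre$corrected, pre$index, d, alpha_ps = 0.01)
  strict <- call_splicing(pre$corrected, pre$index, d, alpha_ps = 0.001)
  expect_true(all(loose$calls$called[strict$calls$called]))
})

test_that("an indeterminate exclusion consensus blocks the call", {
  d <- tiny_design()
  st <- rbind(ps_row("ps_excl", "E1", "exclusion", 0.005, 0),
              ps_row("ps_body", "E1", "inclusion", 0.004, -0.8),
              ps_row("ps_incj", "E1", "inclusion", 0.2, -0.1))
  calls <- call_events(st, d)
  expect_false(calls$called)
  expect_equal(calls$direction, 0L)
})
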