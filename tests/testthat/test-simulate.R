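test_that("simulation is bit-identical under a fixed seed and config", {
  cfg <- sim_config(n_tumor = 6, n_normal = 5, n_mirna = 60, n_de = 5,
                    seed = 1)
  expect_identical(simulate_counts(cfg), simulate_counts(cfg))
  expect_identical(simulate_ct(cfg), simulate_ct(cfg))
  t1 <- tempfile(); t2 <- tempfile()
  truth <- simulate_counts(cfg)$truth
  write_gmt(simulate_annotation(cfg, truth, n_mirna_universe = 200)$pathways, t1)
  write_gmt(simulate_annotation(cfg, truth, n_mirna_universe = 200)$pathways, t2)
  expect_identical(readLines(t1), readLines(t2))
})

test_that("invalid configuration fields are rejected by name", {
  expect_error(sim_config(n_de = 10, n_mirna = 10), "n_de")
  expect_error(sim_config(fold_changes = 0.5), "fold_changes")
  expect_error(sim_config(zero_inflation = 1.2), "zero_inflation")
  expect_error(sim_config(dispersion = -1), "dispersion")
  cfg <- sim_config(n_mirna = 50, seed = 3)
  truth <- simulate_counts(cfg)$truth
  expect_error(simulate_annotation(cfg, truth, enrichment = 2), "enrichment")
  expect_error(simulate_annotation(cfg, truth, n_mirna_universe = 10),
               "n_mirna_universe")
})

test_that("counts model plants effects and contamination where promised", {
  cfg <- sim_config(n_tumor = 10, n_normal = 10, n_mirna = 300, n_de = 12,
                    fold_changes = 4, zero_inflation = 0.2, rbc_spike = 8,
                    seed = 5)
  sim <- simulate_counts(cfg)
  truth <- sim$truth
  expect_length(intersect(names(truth$de_mirnas), truth$contamination_markers),
                0)
  expect_setequal(truth$contamination_markers, rbc_markers())
  expect_true(all(truth$contamination_markers %in% mirna_ids(sim$matrix)))
  # markers enriched in tumor samples
  tum <- sim$matrix$labels == "tumor"
  mk <- sim$matrix$values[truth$contamination_markers, , drop = FALSE]
  expect_gt(sum(mk[, tum]), 4 * sum(mk[, !tum]))
  # zero fraction tracks zero_inflation (NB zeros add a little on top)
  expect_gt(mean(sim$matrix$values == 0), 0.2 - 0.02)
  expect_lt(mean(sim$matrix$values == 0), 0.2 + 0.15)
})

test_that("planted tumor/normal mean ratios recover the planted fold change", {
  # geometric-mean estimated/true fold ratio, averaged over 5 seeds to damp
  # the shared library-size sampling noise
  log_ratio <- vapply(1:5, function(s) {
    cfg <- sim_config(n_tumor = 10, n_normal = 10, n_mirna = 400, n_de = 15,
                      fold_changes = 4, zero_inflation = 0.1, seed = s)
    sim <- simulate_counts(cfg)
    tum <- sim$matrix$labels == "tumor"
    planted <- names(sim$truth$de_mirnas)
    est <- rowMeans(sim$matrix$values[planted, tum]) /
      rowMeans(sim$matrix$values[planted, !tum])
    mean(log2(est) - log2(sim$truth$de_mirnas[planted]))
  }, 0)
  expect_lt(abs(mean(log_ratio)), log2(1.25))
})

test_that("null counts give calibrated downstream two-class p-values", {
  ks_p <- rej <- numeric(5)
  for (i in 1:5) {
    cfg <- sim_config(n_tumor = 10, n_normal = 10, n_mirna = 2003, n_de = 0,
                      zero_inflation = 0, seed = 300 + i)
    sim <- simulate_counts(cfg)
    nr <- normalize_to_reference(detection_filter(sim$matrix), panel_size = 50)
    de <- two_class_test(nr)
    p <- de$p[!is.na(de$p)]
    expect_gte(length(p), 2000)
    rej[i] <- mean(p < 0.05)
    ks_p[i] <- stats::ks.test(p, "punif")$p.value
  }
  # factor-estimation noise correlates features within one dataset, so the
  # uniformity check is taken as the median over independent simulations
  expect_gt(median(ks_p), 0.01)
  expect_lt(abs(mean(rej) - 0.05), 0.015)
})

test_that("ct model maps fold changes to -log2(f) cycle differences and censors", {
  cfg <- sim_config(n_tumor = 40, n_normal = 40, n_mirna = 200, n_de = 20,
                    fold_changes = 2, zero_inflation = 0, ct_ceiling = 45,
                    seed = 9)
  sim <- simulate_ct(cfg)
  tum <- sim$matrix$labels == "tumor"
  up <- names(sim$truth$de_mirnas)[sim$truth$de_mirnas > 1]
  diffs <- rowMeans(sim$matrix$values[up, tum], na.rm = TRUE) -
    rowMeans(sim$matrix$values[up, !tum], na.rm = TRUE)
  expect_lt(abs(mean(diffs) - (-1)), 0.2)
  # censoring contract at a low ceiling
  cfg2 <- sim_config(n_tumor = 10, n_normal = 10, n_mirna = 200,
                     ct_ceiling = 30, seed = 9)
  sim2 <- simulate_ct(cfg2)
  expect_true(all(sim2$matrix$values <= 30, na.rm = TRUE))
  expect_true(anyNA(sim2$matrix$values))
})

test_that("annotation enrichment is real when planted and null when disabled", {
  cfg <- sim_config(n_tumor = 4, n_normal = 4, n_mirna = 100, n_de = 11,
                    fold_changes = 4, seed = 2)
  truth <- simulate_counts(cfg)$truth
  ann <- simulate_annotation(cfg, truth, n_mirna_universe = 500)
  enr <- enrich(union_targets(names(truth$de_mirnas), ann$target_map),
                ann$pathways)
  expect_lt(enr$p[enr$pathway == truth$planted_pathway], 1e-6)
  # enrichment disabled: planted-pathway p behaves like a null p-value
  p0 <- vapply(1:60, function(s) {
    cfg_s <- sim_config(n_tumor = 4, n_normal = 4, n_mirna = 100, n_de = 11,
                        fold_changes = 4, seed = 1000 + s)
    tr <- simulate_counts(cfg_s)$truth
    an <- simulate_annotation(cfg_s, tr, n_mirna_universe = 300,
                              enrichment = 0)
    e <- enrich(union_targets(names(tr$de_mirnas), an$target_map),
                an$pathways)
    e$p[e$pathway == tr$planted_pathway]
  }, 0)
  expect_lte(mean(p0 <= 0.1), 0.25)           # P(p <= t) <= t up to noise
  expect_equal(sum(p0 < 1e-6), 0)
  expect_gt(mean(p0 > 0.2), 0.4)
})
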