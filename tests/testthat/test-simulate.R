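test_that("methylation generator is deterministic and respects feasibility", {
  p <- methyl_sim_params(n_genes = 50, cpg_per_gene = 2, hyper_planted = 5,
                         hypo_planted = 4, concordant_hyper = 3,
                         concordant_hypo = 2, seed = 9)
  a <- gen_methylation(p)
  b <- gen_methylation(p)
  expect_identical(a$human$values, b$human$values)
  expect_identical(a$truth, b$truth)
  expect_true(all(a$human$values >= 0 & a$human$values <= 1))
  # ortholog map is a bijection over the universe
  expect_equal(anyDuplicated(a$ortholog_map$human), 0)
  expect_equal(anyDuplicated(a$ortholog_map$mouse), 0)
  expect_equal(nrow(a$ortholog_map), 50)
  expect_error(methyl_sim_params(concordant_hyper = 200,
                                 hyper_planted = 100),
               "infeasible")
  expect_error(methyl_sim_params(delta_beta = 0.5,
                                 baseline_range = c(0.3, 0.6)),
               "exceeds 1")
})

test_that("null methylation generator plants nothing and yields no calls", {
  sim <- gen_methylation(methyl_sim_params(delta_beta = 0, seed = 3))
  expect_equal(nrow(sim$truth), 0)
  dm <- differential_methylation(sim$human)
  expect_lte(mean(dm$direction != "ns"), 0.001)
})

test_that("planted global hypomethylation lowers tumor medians", {
  lower <- vapply(1:20, function(s) {
    sim <- gen_methylation(methyl_sim_params(
      n_genes = 150, cpg_per_gene = 4, hyper_planted = 5, hypo_planted = 5,
      concordant_hyper = 5, concordant_hypo = 5,
      global_delta = -0.1, seed = s))
    med <- global_median_methylation(sim$human)
    g <- sim$human$sample_groups
    median(med[g == "tumor"]) < median(med[g == "control"])
  }, logical(1))
  expect_gte(mean(lower), 0.95)
})

test_that("single-cell generator hits population fractions and is reproducible", {
  p <- sc_sim_params("wt", n_cells = 3000, seed = 5)
  sim <- gen_sc(p)
  expect_identical(gen_sc(p)$cm$counts, sim$cm$counts)
  # realized fractions within 3 multinomial SDs of the configured mixture
  fr <- table(sim$truth$population) / nrow(sim$truth)
  for (nm in names(p$fractions)) {
    f0 <- p$fractions[[nm]]
    sd3 <- 3 * sqrt(f0 * (1 - f0) / 3000)
    expect_lt(abs(fr[[nm]] - f0), sd3 + 1e-12)
  }
  expect_error(sc_sim_params("custom", fractions = c(B = 0.5, Tumor = 0.4)),
               "sum to 1")
})

test_that("tumor population carries the five-criterion profile", {
  sim <- gen_sc(sc_sim_params("ptcl", n_cells = 2000, seed = 6))
  cm <- normalize_cells(sim$cm)
  prof <- cluster_profile(cm)
  m <- prof$mean
  expect_lt(m["Tumor", "SMARCB1"], 0.1)
  expect_gt(min(m[setdiff(rownames(m), "Tumor"), "SMARCB1"]), 0.3)
  expect_equal(rownames(m)[which.max(m[, "EZH2"])], "Tumor")
  expect_equal(rownames(m)[which.max(m[, "KIT"])], "Tumor")
  expect_gt(prof$pct["Tumor", "MKI67"],
            2 * median(prof$pct[, "MKI67"]))
})

test_that("screen generator: planted effects and noise behave as stated", {
  # no hits, cv = 0: all relative efficacies exactly 0
  none <- screen_sim_params(cv = 0, hits = data.frame(compound = "BETi_01",
                                                      fold_kill = 1 + 1e-9),
                            seed = 1)
  eff0 <- relative_efficacy(normalize_viability(gen_screen(none)), "T15")
  expect_true(all(abs(eff0$relative_log2fc) < 1e-6))
  # 4-fold selective kill, cv = 0: exactly -2
  p4 <- screen_sim_params(cv = 0,
                          hits = data.frame(compound = "HDACi_01",
                                            fold_kill = 4), seed = 1)
  eff <- relative_efficacy(normalize_viability(gen_screen(p4)), "T15")
  expect_equal(eff$relative_log2fc[eff$compound == "HDACi_01"], -2)
  # cv = 0.1, 5 replicates: within +/- 0.3 of -2 in >= 95% of 200 seeds
  close <- vapply(1:200, function(s) {
    p <- screen_sim_params(cv = 0.1,
                           hits = data.frame(compound = "HDACi_01",
                                             fold_kill = 4), seed = s)
    e <- relative_efficacy(normalize_viability(gen_screen(p)), "T15")
    abs(e$relative_log2fc[e$compound == "HDACi_01"] + 2) <= 0.3
  }, logical(1))
  expect_gte(mean(close), 0.95)
  expect_error(screen_sim_params(n_replicates = 1), ">= 2")
  expect_error(screen_sim_params(hits = data.frame(compound = "HDACi_01",
                                                   fold_kill = 0.5)),
               "exceed 1")
})

test_that("ROI generator produces integer counts and exact separation p", {
  roi <- gen_roi(seed = 2)
  counts <- unlist(roi[, c("ezh2_hi", "b220_pos", "ly6g_pos")])
  expect_true(all(counts >= 0 & counts == round(counts)))
  # B220 means 400 vs 40 never overlap at these Poisson rates
  rc <- roi_compare(roi, "b220_pos")
  expect_equal(rc$test$p, 2 / 70, tolerance = 1e-12)
  # identical means: the exact MWU null at n = 4/4 has median p near 0.55
  meds <- vapply(1:60, function(s) {
    r <- gen_roi(means = list(WT = c(m = 100), Tumor = c(m = 100)), seed = s)
    roi_compare(r, "m")$test$p
  }, numeric(1))
  expect_gt(median(meds), 0.3)
  expect_lt(median(meds), 0.9)
})

test_that("cohort generator reproduces the deterministic contingency table", {
  co <- gen_cohort(seed = 8)
  expect_equal(cohort_contingency(co),
               matrix(c(4L, 1L, 9L, 27L), 2,
                      dimnames = list(c("CAYA", "adult"),
                                      c("negative", "positive"))))
  expect_identical(gen_cohort(seed = 8), gen_cohort(seed = 8))
  # p = 0 in both groups: Fisher p = 1
  co0 <- gen_cohort(p_neg_caya = 0, p_neg_adult = 0, seed = 1)
  expect_equal(fisher_exact_two_sided(cohort_contingency(co0))$p, 1)
})
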