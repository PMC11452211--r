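# One shared tumor-bearing dataset for the whole file (2,500 cells keeps
# the rank-sum scans quick; the acceptance suite re-runs at full size).
sc_sim <- gen_sc(sc_sim_params("ptcl", n_cells = 2500, seed = 51))
sc_cm <- normalize_cells(sc_sim$cm)
sc_prof <- cluster_profile(sc_cm)

test_that("normalisation is depth-invariant and matches a two-line oracle", {
  counts <- matrix(c(1, 2, 3, 2, 4, 6, 0, 5, 5), nrow = 3,
                   dimnames = list(paste0("g", 1:3), paste0("c", 1:3)))
  cm <- normalize_cells(cell_matrix(counts, clusters = c("A", "A", "B"),
                                    groups = rep("G", 3)),
                        target_sum = 6)
  # cell at target sum: log1p of raw counts
  expect_equal(cm$normalized[, "c1"], log1p(c(g1 = 1, g2 = 2, g3 = 3)))
  # doubled depth, same composition: identical normalised vector
  expect_equal(cm$normalized[, "c2"], cm$normalized[, "c1"])
  # independent oracle
  oracle <- log1p(t(t(counts) / colSums(counts)) * 6)
  expect_equal(cm$normalized, oracle, ignore_attr = TRUE)
  # zero-count cells are dropped and tallied
  counts0 <- cbind(counts, c4 = c(0, 0, 0))
  cm0 <- normalize_cells(cell_matrix(counts0,
                                     clusters = c("A", "A", "B", "B"),
                                     groups = rep("G", 4)))
  expect_equal(ncol(cm0$counts), 3)
  expect_equal(attr(cm0$normalized, "dropped_cells"), 1)
})

test_that("cluster profile equals brute-force per-cell aggregation", {
  cm <- tiny_cells()
  cm <- normalize_cells(cm)
  prof <- cluster_profile(cm)
  for (cl in c("A", "B")) {
    idx <- cm$clusters == cl
    expect_equal(prof$mean[cl, ], rowMeans(cm$normalized[, idx]),
                 tolerance = 1e-12)
    expect_equal(prof$pct[cl, ], rowMeans(cm$counts[, idx] > 0),
                 tolerance = 1e-12)
  }
  expect_true(all(prof$pct >= 0 & prof$pct <= 1))
  # profile statistics are invariant to cell order
  perm <- sample(ncol(cm$counts))
  cm2 <- normalize_cells(cell_matrix(cm$counts[, perm],
                                     clusters = cm$clusters[perm],
                                     groups = cm$groups[perm]))
  prof2 <- cluster_profile(cm2)
  expect_equal(prof2$mean, prof$mean, tolerance = 1e-12)
})

test_that("tumor classifier agrees exactly with the generator truth", {
  flags <- classify_tumor_clusters(sc_prof)
  truth_tumor <- unique(sc_sim$truth$population[
    sc_sim$truth$cell_type == "Tumor"])
  expect_setequal(flags$cluster[flags$tumor], truth_tumor)
  # conjunction: every non-tumor cluster fails at least one criterion,
  # and the T clusters fail specifically on SMARCB1
  expect_false(any(flags$tumor[!flags$cluster %in% truth_tumor]))
  expect_false(flags$smarcb1_negligible[flags$cluster == "Tex"])
  # a WT dataset flags nothing
  wt <- normalize_cells(gen_sc(sc_sim_params("wt", n_cells = 1500,
                                             seed = 52))$cm)
  expect_equal(sum(classify_tumor_clusters(cluster_profile(wt))$tumor), 0)
  # missing rubric gene is reported by name
  prof_missing <- sc_prof
  keep <- colnames(sc_prof$mean) != "KIT"
  prof_missing$mean <- sc_prof$mean[, keep]
  prof_missing$pct <- sc_prof$pct[, keep]
  expect_error(classify_tumor_clusters(prof_missing), "KIT")
})

test_that("rubric annotation labels every cluster correctly", {
  ann <- annotate_clusters(sc_prof)
  truth_map <- unique(sc_sim$truth[, c("population", "cell_type")])
  expected <- setNames(truth_map$cell_type, truth_map$population)
  expect_gte(mean(ann$labels[names(expected)] == expected), 0.95)
  # evidence table covers every rubric criterion per cluster
  expect_true(all(c("cluster", "rubric", "gene", "sense", "pass") %in%
                    names(ann$evidence)))
  # empty rubric list leaves everything unassigned
  ann0 <- annotate_clusters(sc_prof, rubrics = list())
  expect_true(all(ann0$labels == "Unassigned"))
})

test_that("one-vs-rest DEG recovers a planted program and controls the null", {
  ranks <- gene_ranks(sc_cm$normalized)
  deg <- deg_one_vs_rest(sc_cm, "Tumor", ranks = ranks)
  mp <- toy_metaprogram_gmt()[["MP1_G2M"]]
  expect_gte(length(intersect(deg$gene, mp)), 45)
  # a gene expressed only in the cluster tops the list region
  expect_true(all(c("EZH2", "KIT") %in% deg$gene))
  # spot-check p-values against the scalar rank-sum test
  g <- mp[1]
  inn <- sc_cm$clusters == "Tumor"
  ref <- stats::wilcox.test(sc_cm$normalized[g, inn],
                            sc_cm$normalized[g, !inn],
                            exact = FALSE, correct = FALSE)
  full <- deg_one_vs_rest(sc_cm, "Tumor", ranks = ranks,
                          config = within(default_config()$sc, {
                            deg_q <- 1.1; deg_lfc <- -Inf; deg_min_pct <- 0
                          }))
  expect_equal(full$p[full$gene == g], ref$p.value, tolerance = 1e-8)
  # permuted labels: a null scan retains (almost) nothing
  set.seed(53)
  null_cm <- sc_cm
  null_cm$clusters <- sample(sc_cm$clusters)
  retained <- vapply(1:5, function(i) {
    null_cm$clusters <- sample(sc_cm$clusters)
    nrow(deg_one_vs_rest(null_cm, "Tumor", ranks = ranks))
  }, numeric(1))
  expect_equal(median(retained), 0)
})

test_that("metaprogram overlap scores hits, p, and row z-scores", {
  deg <- deg_all_clusters(sc_cm)
  mps <- toy_metaprogram_gmt()
  N <- sum(rowSums(sc_cm$counts > 0) > 0)
  hits <- metaprogram_overlap(deg, mps, N)
  tum <- hits[hits$cluster == "Tumor", ]
  expect_equal(tum$metaprogram[which.max(tum$k)], "MP1_G2M")
  expect_gte(max(tum$k), 45)
  expect_gt(tum$z[tum$metaprogram == "MP1_G2M"], 2)
  # disjoint DEG list: k = 0, p = 1, z below the row mean
  h0 <- metaprogram_overlap(list(X = c("NOPE1", "NOPE2")), mps, N)
  expect_true(all(h0$k == 0) && all(h0$p == 1) && all(h0$z == 0))
  # superset DEG list: k = signature size
  h1 <- metaprogram_overlap(list(X = c(mps[["MP20_MYC"]], "extra")), mps, N)
  expect_equal(h1$k[h1$metaprogram == "MP20_MYC"], 50)
})

test_that("signature scores separate planted-program cells", {
  mp <- toy_metaprogram_gmt()[["MP1_G2M"]]
  sc <- signature_score(sc_cm, mp)
  planted <- sc_sim$truth$metaprogram == "MP1_G2M" &
    !is.na(sc_sim$truth$metaprogram)
  expect_lt(mann_whitney_exact_two_sided(sc[planted], sc[!planted])$p, 1e-6)
  expect_gt(mean(sc[planted]), mean(sc[!planted]))
  # single-gene signature is that gene's normalised value
  expect_equal(signature_score(sc_cm, "CD3E"), sc_cm$normalized["CD3E", ])
  expect_error(signature_score(sc_cm, "NOT_A_GENE"), "no signature gene")
})

test_that("functional-state ladder reproduces planted states and tie rule", {
  tcl <- c("Tumor", "CTL", "Tex", "Treg", "NaiveT")
  states <- call_functional_state(sc_prof, clusters = tcl)
  truth_states <- unique(sc_sim$truth[, c("population", "state")])
  truth_states <- setNames(truth_states$state, truth_states$population)[tcl]
  expect_gte(mean(states$state[match(tcl, states$cluster)] == truth_states),
             0.9)
  # exactly one state per cluster by construction
  expect_equal(nrow(states), length(tcl))
  # all means exactly at the median resolve to not-high -> Other is
  # unreachable without an above-median marker; a flat profile is Naive-like
  flat <- sc_prof
  genes <- unique(unlist(ptclscape:::state_marker_panels()))
  flat$mean[, genes] <- 0.5
  st_flat <- call_functional_state(flat, clusters = tcl)
  expect_true(all(st_flat$state == "Naive-like"))
})

test_that("compartment proportions, exclusions, and the B:myeloid ratio", {
  labels <- c(rep("B-cell", 70), rep("Mono/Mac", 5), rep("T-cell", 25))
  groups <- rep("WT", 100)
  pr <- compartment_proportions(labels, groups)
  fr <- pr$fractions
  expect_equal(fr$fraction[fr$compartment == "B-cell"], 0.70)
  expect_equal(pr$ratio[["WT"]], 14)
  expect_equal(sum(fr$fraction), 1, tolerance = 1e-12)
  # stromal exclusion renormalises
  labels2 <- c(labels, rep("Stromal", 100))
  pr2 <- compartment_proportions(labels2, rep("WT", 200),
                                 exclude = "Stromal")
  expect_equal(pr2$fractions$fraction[pr2$fractions$compartment == "B-cell"],
               0.70)
  # zero myeloid cells: infinite sentinel
  pr3 <- compartment_proportions(rep("B-cell", 5), rep("WT", 5))
  expect_true(is.infinite(pr3$ratio[["WT"]]))
})

test_that("treatment contrasts carry the generator's marker directions", {
  sims <- lapply(c(ptcl = "ptcl", saha = "saha"), function(s) {
    gen_sc(sc_sim_params(s, n_cells = 1500, seed = 54))
  })
  counts <- cbind(sims$ptcl$cm$counts, sims$saha$cm$counts)
  colnames(counts) <- sprintf("cell%05d", seq_len(ncol(counts)))
  cm <- normalize_cells(cell_matrix(
    counts,
    clusters = c(sims$ptcl$cm$clusters, sims$saha$cm$clusters),
    groups = c(sims$ptcl$cm$groups, sims$saha$cm$groups)))
  tcells <- cm$clusters %in% c("CTL", "Tex", "Treg", "NaiveT")
  markers <- c("PDCD1", "HAVCR2", "LAG3", "TIGIT", "GZMB", "PRF1")
  tab <- treatment_contrast(cm, markers, cells = tcells,
                            contrast = c("PTCL", "SAHA"))
  expect_equal(nrow(tab), length(markers) * 2)
  get_mean <- function(m, g) tab$mean[tab$marker == m & tab$group == g]
  # exhaustion markers drop after treatment (Tex compartment shrinks)...
  for (m in c("HAVCR2", "LAG3")) {
    expect_gt(get_mean(m, "PTCL"), get_mean(m, "SAHA"))
  }
  # ...while cytotoxicity markers recover (CTL compartment expands)
  for (m in c("GZMB", "PRF1")) {
    expect_lt(get_mean(m, "PTCL"), get_mean(m, "SAHA"))
  }
  # absent marker: all means 0
  cm0 <- cm
  cm0$counts["PDCD1", ] <- 0L
  cm0 <- normalize_cells(cell_matrix(cm0$counts, clusters = cm$clusters,
                                     groups = cm$groups))
  tab0 <- treatment_contrast(cm0, "PDCD1")
  expect_true(all(tab0$mean == 0))
})
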