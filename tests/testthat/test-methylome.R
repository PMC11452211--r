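test_that("global medians and variable-CpG selection match simple oracles", {
  b <- tiny_beta()
  expect_equal(unname(global_median_methylation(b)),
               c(0.2, 0.25, 0.6, 0.65))
  const <- beta_matrix(matrix(0.5, 3, 4,
                              dimnames = dimnames(b$values)),
                       b$sample_groups)
  expect_true(all(global_median_methylation(const) == 0.5))
  # top-k by sd, ties by row order
  set.seed(21)
  v <- matrix(runif(60), 10,
              dimnames = list(sprintf("cg%02d", 1:10), paste0("s", 1:6)))
  bm <- beta_matrix(v, setNames(rep(c("tumor", "control"), 3),
                                paste0("s", 1:6)))
  sds <- apply(v, 1, sd)
  expect_equal(top_variable_cpgs(bm, 4),
               rownames(v)[order(-sds)][1:4])
  expect_setequal(top_variable_cpgs(bm, 10), rownames(v))
  expect_error(top_variable_cpgs(bm, 0), "positive")
})

test_that("sigma ratio is sd over max sd, with the constant-matrix edge case", {
  b <- tiny_beta()
  sds <- apply(b$values, 1, sd)
  expect_equal(unname(sigma_ratio(b)), unname(sds / max(sds)))
  expect_equal(max(sigma_ratio(b)), 1)
  v <- b$values; v["cg01", ] <- 0.4
  b2 <- beta_matrix(v, b$sample_groups)
  expect_equal(unname(sigma_ratio(b2))[1], 0)
  const <- beta_matrix(matrix(0.5, 2, 4,
                              dimnames = list(c("a", "b"),
                                              names(b$sample_groups))),
                       b$sample_groups)
  expect_warning(r <- sigma_ratio(const), "constant")
  expect_true(all(r == 0))
  # theoretical sigma_max = 0.5
  expect_equal(unname(sigma_ratio(b, "theoretical")), unname(sds / 0.5))
})

test_that("differential methylation matches the scalar t-test and filter rules", {
  sim <- gen_methylation(methyl_sim_params(n_genes = 60, cpg_per_gene = 3,
                                           hyper_planted = 8,
                                           hypo_planted = 6,
                                           concordant_hyper = 5,
                                           concordant_hypo = 4, seed = 31))
  b <- sim$human
  dm <- differential_methylation(b)
  g <- b$sample_groups
  # row-wise agreement with the scalar implementation
  for (i in sample(nrow(b$values), 12)) {
    ref <- t_test_two_sample(b$values[i, g == "tumor"],
                             b$values[i, g == "control"])
    expect_equal(dm$t_stat[i], ref$statistic, tolerance = 1e-10)
    expect_equal(dm$p[i], ref$p, tolerance = 1e-10)
  }
  # q is BH over tested CpGs only
  expect_equal(dm$q[dm$tested], bh_adjust(dm$p[dm$tested]))
  expect_true(all(is.na(dm$q[!dm$tested])))
  # filter precedence: an untested CpG is ns no matter how small its p
  expect_true(all(dm$direction[!dm$tested] == "ns"))
  # direction calls respect sign and cutoff
  sig <- dm$direction != "ns"
  expect_true(all(dm$q[sig] < 0.01))
  expect_true(all(sign(dm$delta[dm$direction == "hyper"]) == 1))
  expect_true(all(sign(dm$delta[dm$direction == "hypo"]) == -1))
})

test_that("permuted group labels yield a controlled false-call rate", {
  sim <- gen_methylation(methyl_sim_params(n_genes = 400, cpg_per_gene = 3,
                                           hyper_planted = 40,
                                           hypo_planted = 30,
                                           concordant_hyper = 30,
                                           concordant_hypo = 20, seed = 32))
  b <- sim$human
  set.seed(33)
  fracs <- vapply(1:10, function(i) {
    g <- b$sample_groups
    names(g) <- names(b$sample_groups)
    g[] <- sample(g)   # break the group-column association
    bp <- beta_matrix(b$values, g)
    mean(differential_methylation(bp)$direction != "ns")
  }, numeric(1))
  expect_lte(median(fracs), 0.02)
})

test_that("dm_proportions sums to one over significant calls", {
  dm <- data.frame(direction = c(rep("hyper", 70), rep("hypo", 30),
                                 rep("ns", 50)))
  expect_equal(dm_proportions(dm),
               c(frac_hyper = 0.7, frac_hypo = 0.3))
  expect_equal(dm_proportions(data.frame(direction = rep("hyper", 5))),
               c(frac_hyper = 1, frac_hypo = 0))
  expect_true(all(is.na(dm_proportions(data.frame(direction = "ns")))))
})

test_that("gene-level calls follow the >=1-CpG rule and tally discordance", {
  dm <- data.frame(cpg = c("c1", "c2", "c3", "c4"),
                   direction = c("hyper", "ns", "hyper", "hypo"))
  map <- data.frame(cpg = c("c1", "c2", "c3", "c4"),
                    gene = c("GA", "GA", "GB", "GB"))
  hyper <- genes_from_cpgs(dm, map, "hyper")
  hypo <- genes_from_cpgs(dm, map, "hypo")
  expect_setequal(as.character(hyper), c("GA", "GB"))
  expect_setequal(as.character(hypo), "GB")    # GB is in both sets
  expect_equal(attr(hyper, "discordant"), 1)
  # unmapped significant CpGs are tallied
  dm2 <- rbind(dm, data.frame(cpg = "c9", direction = "hyper"))
  expect_equal(attr(genes_from_cpgs(dm2, map, "hyper"), "unmapped"), 1)
})

test_that("concordance intersects through the ortholog map symmetrically", {
  map <- data.frame(human = c("G1", "G2", "G3", "G4"),
                    mouse = c("g1", "g2", "g3", "g4"))
  conc <- concordant_genes(c("G1", "G2", "G3"), c("g2", "g3", "g4"), map)
  expect_setequal(as.character(conc), c("G2", "G3"))
  expect_equal(attr(conc, "count"), 2)
  expect_length(concordant_genes("G1", "g2", map), 0)
  # symmetry: swapping species and inverting the map preserves cardinality
  inv <- data.frame(human = map$mouse, mouse = map$human)
  conc_sw <- concordant_genes(c("g2", "g3", "g4"), c("G1", "G2", "G3"), inv)
  expect_equal(attr(conc_sw, "count"), attr(conc, "count"))
  # genes without orthologs are excluded and tallied
  conc2 <- concordant_genes(c("G1", "GX"), c("g1"), map)
  expect_equal(attr(conc2, "no_ortholog"), 1)
})

test_that("ORA enrichment ratio, strict size filter, and planted recovery", {
  universe <- paste0("U", 1:1000)
  sets <- list(big = universe[1:100], ten = universe[1:10])
  query <- universe[c(1:10, 101:140)]   # k = 10 in 'big', n = 50
  res <- ora(query, universe, sets, min_size = 10)
  expect_equal(res$set, "big")          # size-10 set excluded (strict >)
  expect_equal(res$enrichment_ratio, 10 / (50 * 100 / 1000))
  expect_equal(res$p, hypergeom_upper_tail(10, 100, 50, 1000))
  expect_error(ora(character(), universe, sets), "empty query")
  expect_error(ora("NOT_THERE", universe, sets), "outside the universe")
  # mean enrichment ratio ~ 1 for uniform random queries
  set.seed(34)
  sets2 <- list(s1 = universe[1:60], s2 = universe[61:150])
  ratios <- vapply(1:200, function(i) {
    q <- sample(universe, 80)
    mean(ora(q, universe, sets2, min_size = 10)$enrichment_ratio)
  }, numeric(1))
  expect_lt(abs(mean(ratios) - 1), 0.15)
})

test_that("full methylome stage recovers planted concordant sets", {
  sim <- gen_methylation(methyl_sim_params(seed = 41))
  res <- methylome_concordance(sim$human, sim$mouse, sim$ortholog_map)
  truth <- sim$truth
  for (dir in c("hyper", "hypo")) {
    planted <- truth$gene[truth$species == "human" &
                            truth$direction == dir & truth$concordant]
    got <- if (dir == "hyper") res$concordant_hyper else res$concordant_hypo
    expect_gte(mean(planted %in% got), 0.95)   # recall
    expect_gte(mean(got %in% planted), 0.90)   # precision
  }
  # planted 2:1 hyper:hypo CpG ratio shows in the proportions
  props <- res$proportions$human
  expect_gt(props[["frac_hyper"]], props[["frac_hypo"]])
})
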