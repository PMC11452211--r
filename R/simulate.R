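#' Parameters for the two-species methylation simulator
#'
#' Defines the study conditions the methylome stage is tested against:
#' two species ("human", "mouse"), tumor vs control groups, genes with a
#' fixed number of CpGs each, and planted hyper-/hypomethylated gene sets
#' of which a stated subset is concordant across species.
#'
#' @param n_genes genes per species (ortholog universe size).
#' @param cpg_per_gene CpGs per gene locus; methylation arrays typically
#'   interrogate on the order of ten or more probes per gene, so 10 is the
#'   default density.
#' @param n_per_group samples per group per species.
#' @param hyper_planted,hypo_planted genes planted hyper-/hypomethylated
#'   in EACH species.
#' @param concordant_hyper,concordant_hypo sizes of the cross-species
#'   concordant subsets (must not exceed the per-species planted counts);
#'   the non-concordant remainder is planted in disjoint genes per
#'   species, so the truth table's concordant flag is exact.
#' @param delta_beta planted group difference on the beta scale.
#' @param noise_sd within-group noise. Noise is normal on the logit (M
#'   value) scale with constant sd, the standard heteroscedastic model for
#'   beta values (variance shrinks toward 0 and 1); `noise_sd` is the
#'   implied beta-scale sd at beta = 0.5 (logit sd = 4 * noise_sd).
#' @param baseline_range uniform range of per-CpG baseline beta;
#'   `max(baseline_range) + delta_beta` must not exceed 1.
#' @param global_delta additive shift applied to ALL tumor CpGs
#'   (global hypomethylation when negative); default 0 so the planted
#'   truth table is the complete ground truth.
#' @param seed integer seed.
#' @return list of class `methyl_sim_params`.
#' @export
methyl_sim_params <- function(n_genes = 2000L, cpg_per_gene = 10L,
                              n_per_group = 5L,
                              hyper_planted = 150L, hypo_planted = 75L,
                              concordant_hyper = 100L, concordant_hypo = 50L,
                              delta_beta = 0.3, noise_sd = 0.05,
                              baseline_range = c(0.25, 0.65),
                              global_delta = 0, seed = 1L) {
  if (concordant_hyper > hyper_planted || concordant_hypo > hypo_planted) {
    stop("infeasible parameters: concordant subset larger than planted count")
  }
  if (delta_beta < 0 || delta_beta > 1) stop("delta_beta must be in [0, 1]")
  if (max(baseline_range) + delta_beta > 1) {
    stop("delta_beta + max baseline exceeds 1")
  }
  n_specific_h <- hyper_planted - concordant_hyper
  n_specific_l <- hypo_planted - concordant_hypo
  if (concordant_hyper + concordant_hypo + 2 * (n_specific_h + n_specific_l) >
      n_genes) {
    stop("planted sets do not fit in the gene universe")
  }
  structure(as.list(environment()), class = "methyl_sim_params")
}

#' Simulate paired human/mouse methylation data with planted truth
#'
#' Generates one beta matrix per species (tumor vs control), a one-to-one
#' ortholog map over the shared gene universe, and a truth table listing
#' every planted gene's direction per species and its concordance flag.
#' Beta values follow a logit-normal noise model around group means, so
#' they lie strictly inside (0, 1).
#'
#' @param params a [methyl_sim_params()] object.
#' @return list with elements `human` and `mouse` (`beta_matrix`),
#'   `ortholog_map` (data.frame `human`, `mouse`) and `truth` (data.frame
#'   `species`, `gene`, `direction`, `concordant`).
#' @export
gen_methylation <- function(params) {
  stopifnot(inherits(params, "methyl_sim_params"))
  set.seed(params$seed)
  p <- params
  genes_h <- sprintf("G%04d", seq_len(p$n_genes))
  genes_m <- sprintf("g%04d", seq_len(p$n_genes))
  omap <- data.frame(human = genes_h, mouse = genes_m,
                     stringsAsFactors = FALSE)

  nsh <- p$hyper_planted - p$concordant_hyper
  nsl <- p$hypo_planted - p$concordant_hypo
  pool <- sample.int(p$n_genes)   # randomised planted positions
  take <- function(n) { out <- pool[seq_len(n)]; pool <<- pool[-seq_len(n)]; out }
  idx_ch <- take(p$concordant_hyper)
  idx_cl <- take(p$concordant_hypo)
  idx_hh <- take(nsh)   # human-specific hyper
  idx_mh <- take(nsh)   # mouse-specific hyper
  idx_hl <- take(nsl)
  idx_ml <- take(nsl)

  dir_for <- function(sp_hyper, sp_hypo) {
    d <- rep("ns", p$n_genes)
    d[c(idx_ch, sp_hyper)] <- "hyper"
    d[c(idx_cl, sp_hypo)] <- "hypo"
    d
  }
  dir_h <- dir_for(idx_hh, idx_hl)
  dir_m <- dir_for(idx_mh, idx_ml)
  if (p$delta_beta == 0) {   # zero effect: nothing is truly planted
    dir_h[] <- "ns"
    dir_m[] <- "ns"
  }
  conc <- rep(FALSE, p$n_genes)
  conc[c(idx_ch, idx_cl)] <- TRUE

  truth <- rbind(
    data.frame(species = "human", gene = genes_h, direction = dir_h,
               concordant = conc & dir_h != "ns", stringsAsFactors = FALSE),
    data.frame(species = "mouse", gene = genes_m, direction = dir_m,
               concordant = conc & dir_m != "ns", stringsAsFactors = FALSE)
  )
  truth <- truth[truth$direction != "ns", ]

  one_species <- function(genes, dirs, species) {
    n_cpg <- p$n_genes * p$cpg_per_gene
    gene_of <- rep(seq_len(p$n_genes), each = p$cpg_per_gene)
    cpg_ids <- sprintf("%s_cg%02d", genes[gene_of],
                       rep(seq_len(p$cpg_per_gene), p$n_genes))
    base <- stats::runif(n_cpg, p$baseline_range[1], p$baseline_range[2])
    shift <- c(hyper = p$delta_beta, hypo = -p$delta_beta, ns = 0)[dirs[gene_of]]
    samples <- c(paste0("tumor_", seq_len(p$n_per_group)),
                 paste0("control_", seq_len(p$n_per_group)))
    groups <- stats::setNames(rep(c("tumor", "control"), each = p$n_per_group),
                              samples)
    mu <- cbind(matrix(pmin(pmax(base + shift + p$global_delta, 1e-4),
                            1 - 1e-4),
                       n_cpg, p$n_per_group),
                matrix(pmin(pmax(base, 1e-4), 1 - 1e-4),
                       n_cpg, p$n_per_group))
    # homoscedastic logit-scale (M-value) noise; beta-scale sd is
    # noise_sd at beta = 0.5 and shrinks toward the boundaries
    vals <- stats::plogis(stats::qlogis(mu) +
                            matrix(stats::rnorm(length(mu), sd = 4 * p$noise_sd),
                                   nrow(mu)))
    dimnames(vals) <- list(cpg_ids, samples)
    beta_matrix(vals, groups, species = species,
                cpg_gene_map = data.frame(cpg = cpg_ids,
                                          gene = genes[gene_of],
                                          stringsAsFactors = FALSE))
  }
  list(human = one_species(genes_h, dir_h, "human"),
       mouse = one_species(genes_m, dir_m, "mouse"),
       ortholog_map = omap,
       truth = truth)
}

#' Toy cancer-hallmark metaprogram collection
#'
#' Twelve disjoint 50-gene signatures named after recurrent pan-cancer
#' transcriptional metaprograms (Cycling/G2M, MYC, EMT, Stress, ...).
#' Gene identifiers are synthetic (`MPxx_Gyy`); the collection stands in
#' for published metaprogram signatures in tests and simulations.
#'
#' @param n_sets number of programs (default 12).
#' @param set_size genes per program (default 50).
#' @return named list of class `gene_sets`.
#' @export
toy_metaprogram_gmt <- function(n_sets = 12L, set_size = 50L) {
  base_names <- c("MP1_G2M", "MP20_MYC", "MP12_EMT", "MP5_Stress",
                  "MP2_Ribo", "MP6_Hypoxia", "MP9_Interferon", "MP13_Metal",
                  "MP15_Secreted", "MP17_Respiration", "MP19_Epithelial",
                  "MP24_Protein")
  nms <- if (n_sets <= length(base_names)) base_names[seq_len(n_sets)] else
    c(base_names, sprintf("MP_extra%02d", seq_len(n_sets - length(base_names))))
  sets <- lapply(seq_len(n_sets), function(i) {
    sprintf("%s_G%02d", nms[i], seq_len(set_size))
  })
  structure(stats::setNames(sets, nms), class = "gene_sets")
}

# Curated marker folds per population. Baseline weight for all named
# marker genes is low (sparse detection); folds lift the positive
# populations well clear of the rubric thresholds.
sc_marker_genes <- function() {
  c("SMARCB1", "CD2", "EZH2", "KIT", "MKI67", "CD3E", "LCK", "CD4", "CD8A",
    "FOXP3", "IL2RA", "CTLA4", "PDCD1", "TIGIT", "HAVCR2", "LAG3",
    "GZMB", "PRF1", "NKG7", "CCR7", "SELL", "LEF1",
    "CD79A", "MS4A1", "CD19", "MZB1", "JCHAIN", "SDC1",
    "LYZ", "CD68", "CD14", "S100A8", "ITGAM")
}

sc_lr_genes <- function() {
  c("CXCL12", "CXCR4", "CD70", "CD27", "CXCL9", "CXCR3",
    "FN1", "ITGA4", "PECAM1", "CD38")
}

sc_population_profiles <- function() {
  t_common <- c(CD3E = 8, LCK = 6, CD2 = 6)
  list(
    Tumor  = list(cell_type = "Tumor", state = "Tpex",
                  markers = c(SMARCB1 = 0.02, CD2 = 12, EZH2 = 10, KIT = 10,
                              PDCD1 = 6, TIGIT = 6, CD3E = 0.1, LCK = 0.1),
                  mki67_high_frac = 0.45),
    CTL    = list(cell_type = "T-cell", state = "CTL",
                  markers = c(t_common, CD8A = 8, GZMB = 10, PRF1 = 8,
                              NKG7 = 8),
                  mki67_high_frac = 0.05),
    Tex    = list(cell_type = "T-cell", state = "Tex",
                  markers = c(t_common, CD8A = 8, HAVCR2 = 8, LAG3 = 8,
                              PDCD1 = 8, TIGIT = 5, GZMB = 3),
                  mki67_high_frac = 0.05),
    Treg   = list(cell_type = "T-cell", state = "Treg",
                  markers = c(t_common, CD4 = 6, FOXP3 = 10, IL2RA = 6,
                              CTLA4 = 6),
                  mki67_high_frac = 0.05),
    NaiveT = list(cell_type = "T-cell", state = "Naive-like",
                  markers = c(t_common, CD4 = 5, CCR7 = 6, SELL = 6,
                              LEF1 = 6),
                  mki67_high_frac = 0.05),
    B      = list(cell_type = "B-cell", state = NA_character_,
                  markers = c(CD79A = 10, MS4A1 = 10, CD19 = 8),
                  mki67_high_frac = 0.05),
    Plasma = list(cell_type = "Plasma", state = NA_character_,
                  markers = c(MZB1 = 12, JCHAIN = 10, SDC1 = 8, CD79A = 3,
                              MS4A1 = 0.2),
                  mki67_high_frac = 0.05),
    Myeloid = list(cell_type = "Mono/Mac", state = NA_character_,
                   markers = c(LYZ = 10, CD68 = 8, CD14 = 8, S100A8 = 6,
                               ITGAM = 6),
                   mki67_high_frac = 0.05)
  )
}

# Profiles for a scenario: the named immune/tumor populations, or
# featureless identical clusters for the exchangeable "null" scenario.
scenario_profiles <- function(scenario, populations) {
  if (scenario == "null") {
    neutral <- list(cell_type = "Generic", state = NA_character_,
                    markers = c(CD2 = 1), mki67_high_frac = 0.05)
    return(stats::setNames(rep(list(neutral), length(populations)),
                           populations))
  }
  sc_population_profiles()
}

#' Parameters for the single-cell simulator
#'
#' Populations are the clusters of the simulated dataset (clustering is an
#' input to the pipeline, so each cell's cluster label equals its
#' population of origin). Counts follow a gamma-Poisson mixture per gene
#' with log-normal library sizes.
#'
#' @param scenario preset population mixtures: `"ptcl"` (tumor-bearing:
#'   B-cells collapse to 10%, myeloid expands to 30%), `"wt"` (healthy:
#'   70% B-cells, 5% myeloid), `"saha"` (HDAC-inhibitor-treated:
#'   partial restoration, B 40% / myeloid 15%), `"null"` (eight clusters
#'   with IDENTICAL expression profiles — no marker folds, metaprograms
#'   or channels — the exchangeable null for permutation-test
#'   calibration), or `"custom"` with `fractions` supplied.
#' @param n_cells total cells.
#' @param n_genes gene universe size (markers, metaprogram genes and
#'   ligand/receptor genes are always included; the remainder are filler
#'   genes).
#' @param fractions named population fractions (must sum to 1) overriding
#'   the scenario preset.
#' @param metaprograms named character vector: population -> planted
#'   metaprogram (a set name of [toy_metaprogram_gmt()]); default plants
#'   `MP1_G2M` on the tumor population in tumor-bearing scenarios.
#' @param mp_fold expression fold applied to planted metaprogram genes.
#' @param lr_channels data.frame (`sender`, `receiver`, `ligand`,
#'   `receptor`, `fold`) of planted ligand-receptor channels; NULL for
#'   none. Default plants CXCL12->CXCR4 (Myeloid to Tumor) and autocrine
#'   CD70->CD27 (Tumor) in the `"ptcl"` scenario.
#' @param lib_size_meanlog,lib_size_sdlog log-normal library-size model.
#' @param dispersion gamma-Poisson overdispersion (gamma variance).
#' @param seed integer seed.
#' @return list of class `sc_sim_params`.
#' @export
sc_sim_params <- function(scenario = c("ptcl", "wt", "saha", "null",
                                       "custom"),
                          n_cells = 5000L, n_genes = 1500L,
                          fractions = NULL, metaprograms = NULL,
                          mp_fold = 6, lr_channels = NULL,
                          lib_size_meanlog = log(2000),
                          lib_size_sdlog = 0.3,
                          dispersion = 0.25, seed = 1L) {
  scenario <- match.arg(scenario)
  preset <- switch(scenario,
    ptcl = c(Tumor = 0.30, B = 0.10, Myeloid = 0.30, Tex = 0.08, CTL = 0.06,
             Treg = 0.05, NaiveT = 0.06, Plasma = 0.05),
    wt   = c(B = 0.70, Myeloid = 0.05, NaiveT = 0.10, CTL = 0.06, Tex = 0.02,
             Treg = 0.04, Plasma = 0.03),
    saha = c(Tumor = 0.10, B = 0.40, Myeloid = 0.15, NaiveT = 0.10,
             CTL = 0.10, Tex = 0.02, Treg = 0.05, Plasma = 0.08),
    null = stats::setNames(rep(1 / 8, 8), paste0("C", 1:8)),
    custom = NULL)
  fractions <- fractions %||% preset
  if (is.null(fractions)) stop("custom scenario requires `fractions`")
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("population fractions must sum to 1 (got ", sum(fractions), ")")
  }
  profiles <- scenario_profiles(scenario, names(fractions))
  unknown <- setdiff(names(fractions), names(profiles))
  if (length(unknown)) stop("unknown population(s): ",
                            paste(unknown, collapse = ", "))
  if (is.null(metaprograms) && "Tumor" %in% names(fractions)) {
    metaprograms <- c(Tumor = "MP1_G2M")
  }
  if (is.null(lr_channels) && scenario == "ptcl") {
    lr_channels <- data.frame(
      sender = c("Myeloid", "Tumor"), receiver = c("Tumor", "Tumor"),
      ligand = c("CXCL12", "CD70"), receptor = c("CXCR4", "CD27"),
      fold = c(4, 4), stringsAsFactors = FALSE)
  }
  structure(list(scenario = scenario, n_cells = as.integer(n_cells),
                 n_genes = as.integer(n_genes), fractions = fractions,
                 metaprograms = metaprograms, mp_fold = mp_fold,
                 lr_channels = lr_channels,
                 lib_size_meanlog = lib_size_meanlog,
                 lib_size_sdlog = lib_size_sdlog,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "sc_sim_params")
}

#' Simulate a single-cell count matrix with planted truth
#'
#' Draws a population per cell (multinomial on the configured fractions),
#' a library size per cell (log-normal), and gene counts from a
#' gamma-Poisson mixture whose gene weights carry the planted marker,
#' metaprogram and ligand-receptor folds. The tumor population has
#' SMARCB1 scaled to near zero, elevated CD2/EZH2/KIT, and a large
#' MKI67-high fraction, matching the five-criterion tumor rubric.
#'
#' @param params an [sc_sim_params()] object.
#' @return list with `cm` (a `cell_matrix` with cluster labels equal to
#'   the population of origin) and `truth` (data.frame `cell`,
#'   `population`, `cell_type`, `state`, `metaprogram`).
#' @export
gen_sc <- function(params) {
  stopifnot(inherits(params, "sc_sim_params"))
  set.seed(params$seed)
  p <- params
  profiles <- scenario_profiles(p$scenario, names(p$fractions))[names(p$fractions)]
  mps <- toy_metaprogram_gmt()
  markers <- sc_marker_genes()
  lr <- sc_lr_genes()
  mp_genes <- unlist(mps, use.names = FALSE)
  special <- c(markers, lr, mp_genes)
  if (!is.null(p$lr_channels)) {
    missing_lr <- setdiff(c(p$lr_channels$ligand, p$lr_channels$receptor),
                          special)
    if (length(missing_lr)) stop("planted L-R gene(s) not in universe: ",
                                 paste(missing_lr, collapse = ", "))
  }
  n_fill <- p$n_genes - length(special)
  if (n_fill < 0) stop("n_genes too small for the marker/metaprogram universe")
  genes <- c(special, sprintf("FILLER%04d", seq_len(n_fill)))

  # baseline weights: housekeeping-level SMARCB1, sparse markers and
  # metaprogram genes, broadly detected ligand/receptor genes, log-normal
  # filler genes
  w <- stats::setNames(rep(0.08, length(genes)), genes)
  w[lr] <- 0.6
  w["SMARCB1"] <- 0.5
  w[sprintf("FILLER%04d", seq_len(n_fill))] <-
    stats::rlnorm(n_fill, meanlog = 0, sdlog = 1.2)

  pop <- sample(names(p$fractions), p$n_cells, replace = TRUE,
                prob = p$fractions)
  lib <- stats::rlnorm(p$n_cells, p$lib_size_meanlog, p$lib_size_sdlog)
  counts <- matrix(0L, nrow = length(genes), ncol = p$n_cells,
                   dimnames = list(genes, sprintf("cell%05d", seq_len(p$n_cells))))
  mki67_high <- logical(p$n_cells)
  shape <- 1 / p$dispersion

  for (nm in names(p$fractions)) {
    cells <- which(pop == nm)
    if (!length(cells)) next
    prof <- profiles[[nm]]
    wp <- w
    wp[names(prof$markers)] <- wp[names(prof$markers)] * prof$markers
    if (!is.null(p$metaprograms) && nm %in% names(p$metaprograms)) {
      wp[mps[[p$metaprograms[[nm]]]]] <-
        wp[mps[[p$metaprograms[[nm]]]]] * p$mp_fold
    }
    if (!is.null(p$lr_channels)) {
      ch <- p$lr_channels
      for (i in seq_len(nrow(ch))) {
        if (ch$sender[i] == nm) wp[ch$ligand[i]] <- wp[ch$ligand[i]] * ch$fold[i]
        if (ch$receiver[i] == nm) {
          wp[ch$receptor[i]] <- wp[ch$receptor[i]] * ch$fold[i]
        }
      }
    }
    hi <- stats::runif(length(cells)) < prof$mki67_high_frac
    mki67_high[cells[hi]] <- TRUE
    wmat <- matrix(wp, nrow = length(genes), ncol = length(cells),
                   dimnames = list(genes, NULL))
    wmat["MKI67", ] <- wp["MKI67"] * ifelse(hi, 25, 1)
    wmat <- sweep(wmat, 2, colSums(wmat), "/")
    lam <- sweep(wmat, 2, lib[cells], "*") *
      matrix(stats::rgamma(length(wmat), shape = shape, rate = shape),
             nrow(wmat))
    counts[, cells] <- stats::rpois(length(lam), lam)
  }

  truth <- data.frame(
    cell = colnames(counts),
    population = pop,
    cell_type = vapply(profiles[pop], `[[`, character(1), "cell_type"),
    state = vapply(profiles[pop], `[[`, character(1), "state"),
    metaprogram = ifelse(pop %in% names(p$metaprograms %||% character()),
                         unname(unlist(p$metaprograms)[pop]), NA_character_),
    mki67_high = mki67_high,
    stringsAsFactors = FALSE
  )
  cm <- cell_matrix(counts, clusters = pop,
                    groups = rep(toupper(p$scenario), p$n_cells))
  list(cm = cm, truth = truth)
}

#' Parameters for the epigenetic drug-screen simulator
#'
#' @param classes compound classes and the number of compounds per class.
#' @param n_replicates replicates per condition (default 5, matching a
#'   five-replicate single-dose screen).
#' @param cv coefficient of variation of replicate readings (log-normal
#'   multiplicative noise, mean-preserving; `cv = 0` is noiseless).
#' @param hits data.frame (`compound`, `fold_kill`) of compounds planted
#'   selectively toxic to the index line (`fold_kill` > 1); default plants
#'   five HDAC-inhibitor hits, the strongest at 8-fold.
#' @param index_line the SMARCB1-deficient line the screen indexes on.
#' @param reference_lines the comparison lymphoma panel.
#' @param seed integer seed.
#' @return list of class `screen_sim_params`.
#' @export
screen_sim_params <- function(classes = c(HDACi = 10L, DNMTi = 10L,
                                          BETi = 10L, HMTi = 10L),
                              n_replicates = 5L, cv = 0.1,
                              hits = NULL,
                              index_line = "T15",
                              reference_lines = c("Jurkat", "Karpas-299",
                                                  "SR-786", "SU-DHL-1",
                                                  "Raji", "Daudi", "U-937"),
                              seed = 1L) {
  if (n_replicates < 2) stop("replicate count must be >= 2")
  if (is.null(hits)) {
    hits <- data.frame(compound = sprintf("HDACi_%02d", 1:5),
                       fold_kill = c(8, 3, 3, 3, 3),
                       stringsAsFactors = FALSE)
  }
  if (any(hits$fold_kill <= 1)) stop("fold_kill must exceed 1 for planted hits")
  compounds <- unlist(lapply(names(classes), function(cl) {
    sprintf("%s_%02d", cl, seq_len(classes[[cl]]))
  }))
  unknown <- setdiff(hits$compound, compounds)
  if (length(unknown)) stop("planted hit(s) not in compound library: ",
                            paste(unknown, collapse = ", "))
  structure(list(classes = classes, compounds = compounds,
                 n_replicates = as.integer(n_replicates), cv = cv,
                 hits = hits, index_line = index_line,
                 reference_lines = reference_lines, seed = as.integer(seed)),
            class = "screen_sim_params")
}

#' Simulate a single-dose viability screen
#'
#' Vehicle replicates are included per cell line; a planted selective
#' compound reduces index-line viability by its `fold_kill` while leaving
#' the reference panel untouched. Replicate noise is mean-preserving
#' log-normal with the configured coefficient of variation.
#'
#' @param params a [screen_sim_params()] object.
#' @return long-format `viability_table` data.frame plus a `truth`
#'   attribute naming the planted hits.
#' @export
gen_screen <- function(params) {
  stopifnot(inherits(params, "screen_sim_params"))
  set.seed(params$seed)
  p <- params
  lines <- c(p$index_line, p$reference_lines)
  cls <- rep(names(p$classes), times = unlist(p$classes))
  comp_class <- stats::setNames(cls, p$compounds)
  grid <- expand.grid(compound = c("vehicle", p$compounds),
                      cell_line = lines,
                      replicate = seq_len(p$n_replicates),
                      stringsAsFactors = FALSE)
  mu <- rep(1, nrow(grid))
  hit_rows <- grid$compound %in% p$hits$compound &
    grid$cell_line == p$index_line
  fk <- p$hits$fold_kill[match(grid$compound[hit_rows], p$hits$compound)]
  mu[hit_rows] <- 1 / fk
  noise <- if (p$cv > 0) {
    sdl <- sqrt(log(1 + p$cv^2))
    stats::rlnorm(nrow(grid), meanlog = -sdl^2 / 2, sdlog = sdl)
  } else rep(1, nrow(grid))
  df <- data.frame(compound = grid$compound,
                   class = ifelse(grid$compound == "vehicle", "vehicle",
                                  comp_class[grid$compound]),
                   cell_line = grid$cell_line,
                   replicate = grid$replicate,
                   viability = mu * noise,
                   stringsAsFactors = FALSE)
  out <- viability_table(df)
  attr(out, "truth") <- p$hits
  out
}

#' Simulate an immunofluorescence ROI count table
#'
#' Per-ROI counts of marker-positive cells (tumor marker Ezh2-high,
#' pan-B marker B220+, neutrophil marker Ly6g+) drawn from per-group
#' Poisson means. Default means emulate a tumor-bearing spleen losing
#' B-cells and gaining neutrophils relative to wild type.
#'
#' @param rois_per_group ROIs per group (>= 1; default 4).
#' @param means named list: group -> named vector of Poisson means per
#'   marker column.
#' @param roi_size_um edge length of the square ROI in micrometres
#'   (default 1500).
#' @param seed integer seed.
#' @return `roi_table` data.frame.
#' @export
gen_roi <- function(rois_per_group = 4L,
                    means = list(
                      WT = c(ezh2_hi = 30, b220_pos = 400, ly6g_pos = 20),
                      Tumor = c(ezh2_hi = 500, b220_pos = 40, ly6g_pos = 200)),
                    roi_size_um = 1500, seed = 1L) {
  if (rois_per_group < 1) stop("rois_per_group must be >= 1")
  set.seed(seed)
  groups <- names(means)
  markers <- names(means[[1]])
  rows <- do.call(rbind, lapply(groups, function(g) {
    counts <- vapply(markers,
                     function(m) stats::rpois(rois_per_group, means[[g]][[m]]),
                     numeric(rois_per_group))
    counts <- matrix(counts, nrow = rois_per_group,
                     dimnames = list(NULL, markers))
    data.frame(roi = paste0(g, "_roi", seq_len(rois_per_group)), group = g,
               counts, area_um2 = roi_size_um^2, stringsAsFactors = FALSE)
  }))
  roi_table(rows)
}

#' Simulate a patient cohort table
#'
#' Per-patient age, age group and binary SMARCB1 protein status. In
#' deterministic-count mode (the default) exactly `round(p * n)` patients
#' per group are negative, so printed contingency tables are reproducible
#' bit-exactly; otherwise status is Bernoulli.
#'
#' @param n_caya,n_adult patients per age group.
#' @param p_neg_caya,p_neg_adult probability (or deterministic fraction)
#'   of SMARCB1 loss per group.
#' @param age_range_caya,age_range_adult uniform age ranges in years.
#' @param deterministic logical, exact planted counts vs Bernoulli draws.
#' @param seed integer seed.
#' @return `cohort_table` data.frame (`patient`, `age`, `group`,
#'   `smarcb1_status`; status 0 = negative).
#' @export
gen_cohort <- function(n_caya = 13L, n_adult = 28L,
                       p_neg_caya = 4 / 13, p_neg_adult = 1 / 28,
                       age_range_caya = c(5, 24),
                       age_range_adult = c(25, 80),
                       deterministic = TRUE, seed = 1L) {
  if (any(c(p_neg_caya, p_neg_adult) < 0 | c(p_neg_caya, p_neg_adult) > 1)) {
    stop("probabilities must lie in [0, 1]")
  }
  set.seed(seed)
  one <- function(n, pneg, range, group) {
    age <- stats::runif(n, range[1], range[2])
    neg <- if (deterministic) {
      k <- round(pneg * n)
      sample(c(rep(TRUE, k), rep(FALSE, n - k)))
    } else stats::runif(n) < pneg
    data.frame(age = age, group = group,
               smarcb1_status = as.integer(!neg), stringsAsFactors = FALSE)
  }
  df <- rbind(one(n_caya, p_neg_caya, age_range_caya, "CAYA"),
              one(n_adult, p_neg_adult, age_range_adult, "adult"))
  df <- cbind(patient = sprintf("P%03d", seq_len(nrow(df))), df)
  class(df) <- c("cohort_table", "data.frame")
  df
}

#' Cohort contingency table of SMARCB1 loss by age group
#'
#' @param cohort a `cohort_table`.
#' @return 2x2 matrix, rows CAYA/adult, columns negative/positive.
#' @export
cohort_contingency <- function(cohort) {
  tab <- table(factor(cohort$group, levels = c("CAYA", "adult")),
               factor(cohort$smarcb1_status, levels = c(0, 1)))
  m <- matrix(as.integer(tab), 2, 2,
              dimnames = list(c("CAYA", "adult"), c("negative", "positive")))
  m
}
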