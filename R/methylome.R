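#' Per-sample median global methylation
#'
#' One median beta value per sample, the global-methylation summary used
#' to compare tumor and control methylomes.
#'
#' @param b a `beta_matrix`.
#' @return named numeric vector of per-sample medians in \[0, 1\].
#' @export
global_median_methylation <- function(b) {
  stopifnot(inherits(b, "beta_matrix"))
  if (nrow(b$values) < 1) stop("beta matrix has no CpGs")
  apply(b$values, 2, stats::median)
}

#' Select the most variable CpGs
#'
#' The `k` CpGs with the largest across-sample standard deviation; ties
#' broken by row (CpG identifier) order. This is the variable-site
#' selection feeding embedding and heatmap views.
#'
#' @param b a `beta_matrix`.
#' @param k number of CpGs to keep (default 10000, capped at the number
#'   of rows).
#' @return character vector of CpG identifiers.
#' @export
top_variable_cpgs <- function(b, k = 10000L) {
  stopifnot(inherits(b, "beta_matrix"))
  if (k <= 0) stop("k must be positive")
  k <- min(k, nrow(b$values))
  sds <- row_sds(b$values)
  ord <- order(-sds, seq_along(sds))   # stable: ties by row order
  rownames(b$values)[ord[seq_len(k)]]
}

#' Per-CpG sigma/sigma_max variance ratio
#'
#' sigma_i is the across-sample standard deviation of CpG i; sigma_max is,
#' by default, the empirical maximum sd over all CpGs in the matrix (a
#' `"theoretical"` alternative uses 0.5, the maximum attainable sd of a
#' \[0,1\] variable). CpGs pass the variance filter when the ratio
#' exceeds the configured cutoff.
#'
#' @param b a `beta_matrix`.
#' @param sigma_max `"empirical"` or `"theoretical"`.
#' @return numeric vector of ratios in \[0, 1\] (all 0, with a warning,
#'   if the matrix is constant).
#' @export
sigma_ratio <- function(b, sigma_max = c("empirical", "theoretical")) {
  stopifnot(inherits(b, "beta_matrix"))
  if (ncol(b$values) < 2) stop("need >= 2 samples")
  sigma_max <- match.arg(sigma_max)
  sds <- row_sds(b$values)
  smax <- if (sigma_max == "empirical") max(sds) else 0.5
  if (smax == 0) {
    warning("all CpGs constant: sigma_max is 0, ratios set to 0")
    return(stats::setNames(rep(0, length(sds)), rownames(b$values)))
  }
  stats::setNames(sds / smax, rownames(b$values))
}

row_sds <- function(m) {
  mu <- rowMeans(m)
  sqrt(rowSums((m - mu)^2) / (ncol(m) - 1))
}

#' Per-CpG differential methylation calls
#'
#' The core of the cross-species comparison: CpGs passing the
#' sigma/sigma_max variance filter are tested tumor vs control with a
#' pooled-variance Student t-test, BH-adjusted over the tested CpGs, and
#' called `hyper` (delta > 0) or `hypo` (delta < 0) at the respective q
#' cutoff. CpGs failing the variance filter are reported `ns` regardless
#' of p. Hyper- and hypomethylation support distinct cutoffs (both 0.01
#' by default; a stringent hyper cutoff such as 1e-5 reproduces the
#' reduced high-confidence call set).
#'
#' @param b a `beta_matrix` with groups `tumor` and `control` (>= 2
#'   samples each).
#' @param sigma_cut variance-filter cutoff on sigma/sigma_max
#'   (default 0.4).
#' @param q_cut_hyper,q_cut_hypo BH q cutoffs per direction.
#' @param sigma_max see [sigma_ratio()].
#' @param tumor,control group labels.
#' @return data.frame (one row per CpG): `cpg`, `sigma_ratio`, `tested`,
#'   `t_stat`, `p`, `q`, `delta` (tumor mean - control mean), `direction`.
#' @export
differential_methylation <- function(b, sigma_cut = 0.4,
                                     q_cut_hyper = 0.01, q_cut_hypo = 0.01,
                                     sigma_max = "empirical",
                                     tumor = "tumor", control = "control") {
  stopifnot(inherits(b, "beta_matrix"))
  g <- b$sample_groups
  for (grp in c(tumor, control)) {
    if (sum(g == grp) < 2) stop("group '", grp, "' needs >= 2 samples")
  }
  x <- b$values[, g == tumor, drop = FALSE]
  y <- b$values[, g == control, drop = FALSE]
  n1 <- ncol(x); n2 <- ncol(y)
  ratio <- sigma_ratio(b, sigma_max)
  tested <- ratio > sigma_cut

  # vectorised pooled-variance Student t (identical formula to
  # t_test_two_sample, applied row-wise)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- rowSums((x - mx)^2) / (n1 - 1)
  vy <- rowSums((y - my)^2) / (n2 - 1)
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * vx + (n2 - 1) * vy) / df
  tstat <- (mx - my) / sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat[sp2 == 0 & mx == my] <- 0
  p <- 2 * stats::pt(-abs(tstat), df)
  p[sp2 == 0 & mx != my] <- 0

  q <- rep(NA_real_, length(p))
  q[tested] <- bh_adjust(p[tested])
  delta <- mx - my
  direction <- rep("ns", length(p))
  direction[tested & delta > 0 & q < q_cut_hyper] <- "hyper"
  direction[tested & delta < 0 & q < q_cut_hypo] <- "hypo"
  data.frame(cpg = rownames(b$values), sigma_ratio = unname(ratio),
             tested = unname(tested), t_stat = unname(tstat),
             p = unname(p), q = unname(q), delta = unname(delta),
             direction = direction, stringsAsFactors = FALSE)
}

#' Proportions of hyper- vs hypomethylated calls
#'
#' Fractions of significant CpGs per direction (they sum to 1). With no
#' significant CpGs both fractions are NA.
#'
#' @param dm output of [differential_methylation()].
#' @return named numeric vector `c(frac_hyper, frac_hypo)`.
#' @export
dm_proportions <- function(dm) {
  sig <- dm$direction != "ns"
  if (!any(sig)) {
    return(c(frac_hyper = NA_real_, frac_hypo = NA_real_))
  }
  nh <- sum(dm$direction == "hyper")
  nl <- sum(dm$direction == "hypo")
  c(frac_hyper = nh / (nh + nl), frac_hypo = nl / (nh + nl))
}

#' Gene-level direction calls from CpG calls
#'
#' A gene carries a direction if at least one of its mapped CpGs is called
#' in that direction; a gene with CpGs called in both directions appears
#' in both sets and is counted in the `discordant` attribute. Significant
#' CpGs without a map entry are dropped and tallied in the `unmapped`
#' attribute.
#'
#' @param dm output of [differential_methylation()].
#' @param map data.frame (`cpg`, `gene`).
#' @param direction `"hyper"` or `"hypo"`.
#' @return character vector of genes, with attributes `discordant`
#'   (count of genes in both direction sets) and `unmapped` (significant
#'   CpGs without a gene).
#' @export
genes_from_cpgs <- function(dm, map, direction = c("hyper", "hypo")) {
  direction <- match.arg(direction)
  sig <- dm[dm$direction != "ns", c("cpg", "direction")]
  merged <- merge(sig, map, by = "cpg")
  unmapped <- sum(!sig$cpg %in% map$cpg)
  genes_dir <- unique(merged$gene[merged$direction == direction])
  other <- setdiff(c("hyper", "hypo"), direction)
  genes_other <- unique(merged$gene[merged$direction == other])
  out <- genes_dir
  attr(out, "discordant") <- length(intersect(genes_dir, genes_other))
  attr(out, "unmapped") <- unmapped
  out
}

#' Cross-species concordant genes
#'
#' Human genes whose mapped mouse ortholog carries the same call in the
#' mouse set. Human genes without an ortholog are excluded and tallied in
#' the `no_ortholog` attribute.
#'
#' @param human_set,mouse_set gene sets in each species' own identifiers.
#' @param map ortholog data.frame (`human`, `mouse`), one-to-one.
#' @return character vector of concordant human genes with attributes
#'   `count` and `no_ortholog`.
#' @export
concordant_genes <- function(human_set, mouse_set, map) {
  map <- ortholog_map(map)
  m <- map$mouse[match(human_set, map$human)]
  no_orth <- sum(is.na(m))
  conc <- human_set[!is.na(m) & m %in% mouse_set]
  attr(conc, "count") <- length(conc)
  attr(conc, "no_ortholog") <- no_orth
  conc
}

#' Over-representation analysis
#'
#' Hypergeometric enrichment of a query gene set against a gene-set
#' collection. Sets are intersected with the universe first and retained
#' only when still larger than `min_size` ("more than `min_size` genes",
#' strict). The enrichment ratio is observed/expected overlap,
#' k / (n * K / N); p is the hypergeometric upper tail, q the BH
#' adjustment over the retained sets.
#'
#' @param query gene set (non-empty, contained in `universe`).
#' @param universe background gene set.
#' @param sets named list of gene sets (`gene_sets` or plain list).
#' @param min_size strict lower bound on post-intersection set size
#'   (default 10).
#' @return data.frame sorted by p: `set`, `k`, `K`, `n`, `N`,
#'   `enrichment_ratio`, `p`, `q`.
#' @export
ora <- function(query, universe, sets, min_size = 10L) {
  if (!length(query)) stop("empty query gene set")
  query <- unique(query)
  universe <- unique(universe)
  if (!all(query %in% universe)) {
    stop("query contains genes outside the universe")
  }
  N <- length(universe)
  n <- length(query)
  sets <- lapply(sets, intersect, y = universe)
  keep <- vapply(sets, length, integer(1)) > min_size
  sets <- sets[keep]
  if (!length(sets)) {
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(),
                      enrichment_ratio = numeric(), p = numeric(),
                      q = numeric(), stringsAsFactors = FALSE))
  }
  k <- vapply(sets, function(s) length(intersect(query, s)), integer(1))
  K <- vapply(sets, length, integer(1))
  p <- mapply(hypergeom_upper_tail, k = k, K = K,
              MoreArgs = list(n = n, N = N))
  out <- data.frame(set = names(sets), k = k, K = K, n = n, N = N,
                    enrichment_ratio = k / (n * K / N),
                    p = p, q = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(out$p, out$set), ]
}

#' Run the full methylome concordance stage
#'
#' Convenience wrapper chaining differential methylation per species,
#' gene-level direction calls, cross-species concordance, and (when a
#' gene-set collection is given) over-representation analysis of the
#' concordant sets against the human gene universe.
#'
#' @param human,mouse `beta_matrix` objects with `cpg_gene_map` attached.
#' @param map ortholog data.frame.
#' @param sets optional gene-set collection for ORA (human identifiers).
#' @param config `methylome` section of [default_config()].
#' @return list: `dm_human`, `dm_mouse`, `proportions` (per species),
#'   `genes` (per species hyper/hypo sets), `concordant_hyper`,
#'   `concordant_hypo`, `ora_hyper`, `ora_hypo`.
#' @export
methylome_concordance <- function(human, mouse, map, sets = NULL,
                                  config = default_config()$methylome) {
  run_dm <- function(b) {
    differential_methylation(b, sigma_cut = config$sigma_cut,
                             q_cut_hyper = config$q_cut_hyper,
                             q_cut_hypo = config$q_cut_hypo,
                             sigma_max = config$sigma_max)
  }
  dm_h <- run_dm(human)
  dm_m <- run_dm(mouse)
  gh <- list(hyper = genes_from_cpgs(dm_h, human$cpg_gene_map, "hyper"),
             hypo = genes_from_cpgs(dm_h, human$cpg_gene_map, "hypo"))
  gm <- list(hyper = genes_from_cpgs(dm_m, mouse$cpg_gene_map, "hyper"),
             hypo = genes_from_cpgs(dm_m, mouse$cpg_gene_map, "hypo"))
  ch <- concordant_genes(gh$hyper, gm$hyper, map)
  cl <- concordant_genes(gh$hypo, gm$hypo, map)
  universe <- unique(map$human)
  res <- list(dm_human = dm_h, dm_mouse = dm_m,
              proportions = list(human = dm_proportions(dm_h),
                                 mouse = dm_proportions(dm_m)),
              genes = list(human = gh, mouse = gm),
              concordant_hyper = ch, concordant_hypo = cl)
  if (!is.null(sets)) {
    res$ora_hyper <- if (length(ch)) {
      ora(ch, universe, sets, config$ora_min_size)
    }
    res$ora_hypo <- if (length(cl)) {
      ora(cl, universe, sets, config$ora_min_size)
    }
  }
  res
}
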