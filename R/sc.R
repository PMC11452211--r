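#' Depth-normalise a count matrix
#'
#' Scales each cell to a fixed target sum and applies log1p; the raw
#' counts are retained alongside the normalised layer. Cells with zero
#' total count are dropped (tallied in the `dropped_cells` attribute).
#' The transform is depth-invariant: doubling every count of a cell
#' leaves its normalised vector unchanged.
#'
#' @param cm a `cell_matrix`.
#' @param target_sum per-cell target (default 10000).
#' @return the `cell_matrix` with `$normalized` filled in.
#' @export
normalize_cells <- function(cm, target_sum = 10000) {
  stopifnot(inherits(cm, "cell_matrix"))
  lib <- colSums(cm$counts)
  drop <- lib == 0
  if (any(drop)) {
    cm$counts <- cm$counts[, !drop, drop = FALSE]
    cm$clusters <- cm$clusters[!drop]
    cm$groups <- cm$groups[!drop]
    lib <- lib[!drop]
  }
  cm$normalized <- log1p(sweep(cm$counts, 2, lib, "/") * target_sum)
  attr(cm$normalized, "dropped_cells") <- sum(drop)
  cm
}

get_norm <- function(cm) {
  if (is.null(cm$normalized)) {
    stop("no normalized layer: run normalize_cells() first")
  }
  cm$normalized
}

get_clusters <- function(cm) {
  if (is.null(cm$clusters)) stop("cell_matrix has no cluster labels")
  cm$clusters
}

#' Per-cluster expression profile
#'
#' Mean log-normalised expression and fraction of expressing cells
#' (count > 0) per cluster and gene — the quantities every marker rubric
#' operates on.
#'
#' @param cm a normalised `cell_matrix` with cluster labels.
#' @return `cluster_profile` list: `mean` and `pct` (cluster x gene
#'   matrices), `n_cells` per cluster.
#' @export
cluster_profile <- function(cm) {
  norm <- get_norm(cm)
  cl <- get_clusters(cm)
  clusters <- sort(unique(cl))
  n <- vapply(clusters, function(k) sum(cl == k), integer(1))
  if (any(n == 0)) stop("empty cluster")
  ind <- vapply(clusters, function(k) as.numeric(cl == k),
                numeric(length(cl)))
  means <- t(norm %*% ind) / n
  pct <- t((cm$counts > 0) %*% ind) / n
  rownames(means) <- rownames(pct) <- clusters
  structure(list(mean = means, pct = pct,
                 n_cells = stats::setNames(n, clusters)),
            class = "cluster_profile")
}

#' @export
print.cluster_profile <- function(x, ...) {
  cat("cluster_profile:", nrow(x$mean), "clusters x", ncol(x$mean),
      "genes\n")
  invisible(x)
}

#' Five-criterion tumor-cluster classifier
#'
#' Flags a cluster as tumor when all five criteria hold:
#' (i) negligible SMARCB1 (cluster mean at or below the low quantile of
#' cluster means), (ii) CD2 positivity (mature T-cell origin), (iii) EZH2
#' positivity, (iv) KIT positivity (means at or above the high quantile),
#' and (v) high proliferative activity (MKI67-expressing fraction at
#' least `mki67_pct_factor` times the median cluster fraction).
#'
#' @param profile a [cluster_profile()].
#' @param config `sc` section of [default_config()] (quantile and
#'   proliferation thresholds).
#' @return data.frame per cluster: the five criterion flags and `tumor`.
#' @export
classify_tumor_clusters <- function(profile, config = default_config()$sc) {
  need <- c("SMARCB1", "CD2", "EZH2", "KIT", "MKI67")
  missing <- setdiff(need, colnames(profile$mean))
  if (length(missing)) {
    stop("rubric gene(s) missing from matrix: ",
         paste(missing, collapse = ", "))
  }
  m <- profile$mean
  lo <- stats::quantile(m[, "SMARCB1"], config$negligible_quantile)
  hi <- function(g) m[, g] >= stats::quantile(m[, g], config$high_quantile)
  mki_pct <- profile$pct[, "MKI67"]
  crit <- data.frame(
    cluster = rownames(m),
    smarcb1_negligible = m[, "SMARCB1"] <= lo,
    cd2_positive = hi("CD2"),
    ezh2_positive = hi("EZH2"),
    kit_positive = hi("KIT"),
    mki67_proliferative = mki_pct >= config$mki67_pct_factor *
      stats::median(mki_pct),
    row.names = NULL, stringsAsFactors = FALSE
  )
  crit$tumor <- crit$smarcb1_negligible & crit$cd2_positive &
    crit$ezh2_positive & crit$kit_positive & crit$mki67_proliferative
  crit
}

#' A marker rubric
#'
#' One annotation rule: a label emitted when every criterion holds for a
#' cluster. Senses: `high` / `low` compare the cluster mean against the
#' high/negligible quantile of cluster means; `expressed` / `absent`
#' compare the expressing-cell fraction against fixed gates.
#'
#' @param label label emitted on match.
#' @param ... named senses, e.g. `CD79A = "expressed"`, `SMARCB1 = "low"`.
#' @return `marker_rubric` object.
#' @export
marker_rubric <- function(label, ...) {
  criteria <- c(...)
  if (!length(criteria)) stop("rubric needs at least one criterion")
  if (anyDuplicated(names(criteria))) stop("genes must be unique in a rubric")
  bad <- setdiff(criteria, c("high", "low", "expressed", "absent"))
  if (length(bad)) stop("unknown sense: ", paste(bad, collapse = ", "))
  structure(list(label = label, criteria = criteria),
            class = "marker_rubric")
}

#' Default cell-type rubric set
#'
#' Priority-ordered rubrics for the cell types of the lymphoma
#' microenvironment: tumor (the five-criterion rubric), plasma cells,
#' B-cells, monocytes/macrophages, T-cells.
#'
#' @return list of [marker_rubric()] objects.
#' @export
default_marker_rubrics <- function() {
  list(
    marker_rubric("Tumor", SMARCB1 = "low", CD2 = "high", EZH2 = "high",
                  KIT = "high", MKI67 = "expressed"),
    marker_rubric("Plasma", MZB1 = "expressed", JCHAIN = "expressed",
                  MS4A1 = "absent"),
    marker_rubric("B-cell", MS4A1 = "expressed", CD79A = "expressed"),
    marker_rubric("Mono/Mac", LYZ = "expressed", CD68 = "expressed"),
    marker_rubric("T-cell", CD3E = "expressed", CD2 = "expressed")
  )
}

#' Annotate clusters with marker rubrics
#'
#' Assigns each cluster the label of the first rubric (in priority order)
#' whose criteria all hold; clusters matching none are `"Unassigned"`.
#' An evidence table records every criterion evaluation.
#'
#' @param profile a [cluster_profile()].
#' @param rubrics list of [marker_rubric()] objects (default
#'   [default_marker_rubrics()]).
#' @param config `sc` section of [default_config()].
#' @return list: `labels` (named character vector per cluster),
#'   `evidence` (data.frame cluster x rubric x gene with pass flags).
#' @export
annotate_clusters <- function(profile, rubrics = default_marker_rubrics(),
                              config = default_config()$sc) {
  clusters <- rownames(profile$mean)
  labels <- stats::setNames(rep("Unassigned", length(clusters)), clusters)
  evidence <- list()
  for (rb in rubrics) {
    genes <- names(rb$criteria)
    missing <- setdiff(genes, colnames(profile$mean))
    if (length(missing)) {
      stop("rubric '", rb$label, "' gene(s) missing: ",
           paste(missing, collapse = ", "))
    }
    pass <- matrix(FALSE, length(clusters), length(genes),
                   dimnames = list(clusters, genes))
    for (g in genes) {
      mu <- profile$mean[, g]
      pc <- profile$pct[, g]
      pass[, g] <- switch(rb$criteria[[g]],
        high = mu >= stats::quantile(mu, config$high_quantile),
        low = mu <= stats::quantile(mu, config$negligible_quantile),
        expressed = pc >= config$expressed_pct,
        absent = pc <= config$absent_pct)
    }
    ok <- rowSums(pass) == length(genes)
    hit <- ok & labels == "Unassigned"
    labels[hit] <- rb$label
    evidence[[rb$label]] <- data.frame(
      cluster = rep(clusters, length(genes)),
      rubric = rb$label,
      gene = rep(genes, each = length(clusters)),
      sense = rep(unname(rb$criteria), each = length(clusters)),
      pass = as.vector(pass), stringsAsFactors = FALSE)
  }
  list(labels = labels, evidence = do.call(rbind, evidence))
}

#' One-vs-rest differential expression for a cluster
#'
#' Rank-sum (Wilcoxon) test of each gene in the cluster's cells against
#' all other cells, with BH adjustment and a log fold-change of mean
#' log-normalised expression. Genes are retained at `q < deg_q`,
#' `lfc > deg_lfc` and expressing fraction in the cluster
#' `>= deg_min_pct`, sorted by decreasing fold change. The test uses the
#' tie-corrected normal approximation (cluster sizes here are far beyond
#' the exact-enumeration regime).
#'
#' @param cm a normalised `cell_matrix` with cluster labels.
#' @param cluster cluster identifier.
#' @param config `sc` section of [default_config()].
#' @param ranks optional pre-computed per-gene rank matrix (see
#'   [gene_ranks()]), reused across clusters for speed.
#' @return data.frame: `gene`, `lfc`, `pct_in`, `pct_out`, `p`, `q`.
#' @export
deg_one_vs_rest <- function(cm, cluster, config = default_config()$sc,
                            ranks = NULL) {
  norm <- get_norm(cm)
  cl <- get_clusters(cm)
  inn <- cl == cluster
  if (!any(inn)) stop("cluster not found or empty: ", cluster)
  if (all(inn)) stop("rest is empty")
  if (is.null(ranks)) ranks <- gene_ranks(norm)
  n1 <- sum(inn); n2 <- sum(!inn); n <- n1 + n2
  w <- ranks$r[, inn, drop = FALSE] %*% rep(1, n1)
  u <- w - n1 * (n1 + 1) / 2
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - ranks$tie_term)
  z <- (u - n1 * n2 / 2) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 == 0] <- 1   # constant gene
  q <- bh_adjust(p)
  lfc <- rowMeans(norm[, inn, drop = FALSE]) -
    rowMeans(norm[, !inn, drop = FALSE])
  pct_in <- rowMeans(cm$counts[, inn, drop = FALSE] > 0)
  pct_out <- rowMeans(cm$counts[, !inn, drop = FALSE] > 0)
  res <- data.frame(gene = rownames(norm), lfc = as.vector(lfc),
                    pct_in = pct_in, pct_out = pct_out,
                    p = as.vector(p), q = q,
                    row.names = NULL, stringsAsFactors = FALSE)
  res <- res[res$q < config$deg_q & res$lfc > config$deg_lfc &
               res$pct_in >= config$deg_min_pct, ]
  res[order(-res$lfc), ]
}

#' Pre-compute per-gene cell ranks
#'
#' Mid-ranks of every gene's expression across cells, plus the per-gene
#' tie-correction term of the rank-sum variance. Computing this once and
#' passing it to [deg_one_vs_rest()] makes all-cluster DEG scans linear
#' in the number of clusters.
#'
#' @param norm genes x cells matrix.
#' @return list `r` (rank matrix), `tie_term` (per-gene correction).
#' @export
gene_ranks <- function(norm) {
  n <- ncol(norm)
  r <- t(apply(norm, 1, rank))
  tie_term <- apply(r, 1, function(v) {
    tab <- table(v)
    sum(tab^3 - tab) / (n * (n - 1))
  })
  list(r = r, tie_term = tie_term)
}

#' DEG lists for all clusters
#'
#' @param cm a normalised `cell_matrix` with cluster labels.
#' @param config `sc` section of [default_config()].
#' @return named list: cluster -> character vector of retained genes.
#' @export
deg_all_clusters <- function(cm, config = default_config()$sc) {
  cl <- sort(unique(get_clusters(cm)))
  ranks <- gene_ranks(get_norm(cm))
  stats::setNames(
    lapply(cl, function(k) deg_one_vs_rest(cm, k, config, ranks)$gene), cl)
}

#' Metaprogram overlap scoring
#'
#' Overlap of each cluster's DEG list with each metaprogram signature:
#' hit count k, hypergeometric upper-tail p (universe N = genes detected
#' in at least one cell, draws n = DEG list size), and a per-cluster
#' (row-wise) z-score of the hit counts across metaprograms.
#'
#' @param deg_lists named list cluster -> DEG gene vector.
#' @param mps metaprogram `gene_sets`.
#' @param N gene-universe size.
#' @return data.frame: `cluster`, `metaprogram`, `k`, `size`, `p`, `z`.
#' @export
metaprogram_overlap <- function(deg_lists, mps, N) {
  if (!length(mps)) stop("empty metaprogram collection")
  rows <- lapply(names(deg_lists), function(cl) {
    deg <- deg_lists[[cl]]
    k <- vapply(mps, function(s) length(intersect(deg, s)), integer(1))
    size <- vapply(mps, length, integer(1))
    p <- mapply(function(ki, Ki) {
      hypergeom_upper_tail(min(ki, length(deg)), Ki, length(deg), N)
    }, k, size)
    s <- stats::sd(k)
    z <- if (is.na(s) || s == 0) rep(0, length(k)) else (k - mean(k)) / s
    data.frame(cluster = cl, metaprogram = names(mps), k = k, size = size,
               p = p, z = z, row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-cell signature score
#'
#' Mean log-normalised expression of the signature genes per cell — the
#' average-expression view of a metaprogram signature.
#'
#' @param cm a normalised `cell_matrix`.
#' @param genes signature gene set (at least one present in the matrix).
#' @return named numeric vector, one score per cell.
#' @export
signature_score <- function(cm, genes) {
  norm <- get_norm(cm)
  genes <- intersect(genes, rownames(norm))
  if (!length(genes)) stop("no signature gene present in the matrix")
  colMeans(norm[genes, , drop = FALSE])
}

state_marker_panels <- function() {
  list(treg = "FOXP3",
       tex = c("HAVCR2", "LAG3"),
       tpex = c("PDCD1", "TIGIT"),
       ctl = c("GZMB", "PRF1"))
}

#' Functional-state calls for T and tumor clusters
#'
#' Decision ladder over marker evidence, assigning exactly one state per
#' cluster: Treg (FOXP3 high), else Tex (HAVCR2 and LAG3 high, terminal
#' exhaustion), else Tpex (PDCD1 and TIGIT high with HAVCR2/LAG3 low,
#' precursor exhaustion), else CTL (granzyme/perforin high), else
#' Naive-like (no activation marker high), else Other. "High" means the
#' cluster mean lies strictly above the cross-cluster median of that
#' gene's means AND at or above an absolute expression floor (so that
#' near-zero noise differences between non-expressing clusters never
#' count as high); exact ties at the median resolve to not-high.
#'
#' @param profile a [cluster_profile()] restricted to (or computed over)
#'   the clusters to call — typically the T/tumor compartment.
#' @param clusters optional subset of cluster ids to call (medians are
#'   computed over this subset); default all clusters in the profile.
#' @param config `sc` section of [default_config()] (`state_floor`).
#' @return data.frame `cluster`, `state`, plus the marker-evidence flags.
#' @export
call_functional_state <- function(profile, clusters = NULL,
                                  config = default_config()$sc) {
  panels <- state_marker_panels()
  genes <- unique(unlist(panels))
  missing <- setdiff(genes, colnames(profile$mean))
  if (length(missing)) stop("state marker gene(s) missing: ",
                            paste(missing, collapse = ", "))
  m <- profile$mean[clusters %||% rownames(profile$mean), genes,
                    drop = FALSE]
  med <- apply(m, 2, stats::median)
  high <- sweep(m, 2, med, ">") & m >= config$state_floor
  is_high <- function(cl, gs) all(high[cl, gs])
  states <- vapply(rownames(m), function(cl) {
    if (is_high(cl, panels$treg)) return("Treg")
    if (is_high(cl, panels$tex)) return("Tex")
    if (is_high(cl, panels$tpex) && !any(high[cl, panels$tex])) {
      return("Tpex")
    }
    if (is_high(cl, panels$ctl)) return("CTL")
    if (!any(high[cl, ])) return("Naive-like")
    "Other"
  }, character(1))
  data.frame(cluster = rownames(m), state = unname(states),
             as.data.frame(high), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Compartment proportions and B:myeloid ratio
#'
#' Per-group fractions of each labelled compartment (summing to 1 within
#' group after optional exclusions, e.g. stromal cells), and the ratio of
#' B-cell to myeloid counts per group. A group with zero myeloid cells
#' reports an infinite ratio.
#'
#' @param labels per-cell compartment labels.
#' @param groups per-cell sample-group labels.
#' @param exclude labels removed before quantification (default none).
#' @param b_label,myeloid_label the compartment names entering the ratio.
#' @return list: `fractions` (data.frame `group`, `compartment`,
#'   `fraction`), `ratio` (named numeric per group).
#' @export
compartment_proportions <- function(labels, groups, exclude = character(),
                                    b_label = "B-cell",
                                    myeloid_label = "Mono/Mac") {
  if (length(labels) != length(groups)) stop("labels/groups length mismatch")
  if (any(is.na(labels))) stop("every cell must be labeled")
  keep <- !labels %in% exclude
  labels <- labels[keep]; groups <- groups[keep]
  tab <- table(groups, labels)
  frac <- sweep(tab, 1, rowSums(tab), "/")
  fractions <- as.data.frame(as.table(frac), stringsAsFactors = FALSE)
  names(fractions) <- c("group", "compartment", "fraction")
  ratio <- vapply(rownames(tab), function(g) {
    b <- if (b_label %in% colnames(tab)) tab[g, b_label] else 0
    m <- if (myeloid_label %in% colnames(tab)) tab[g, myeloid_label] else 0
    if (m == 0) Inf else b / m
  }, numeric(1))
  list(fractions = fractions, ratio = ratio)
}

#' Marker expression contrasts across treatment groups
#'
#' Long-form summary of mean expression and expressing fraction per
#' marker and sample group (e.g. exhaustion and cytotoxicity markers in
#' WT vs untreated vs HDACi-treated tumors), with a rank-sum p-value for
#' the configured contrast pair.
#'
#' @param cm a normalised `cell_matrix` with per-cell group labels.
#' @param markers marker genes to summarise.
#' @param cells optional logical mask restricting to a compartment
#'   (e.g. non-tumor T/NK cells).
#' @param contrast length-2 group vector tested per marker (rank-sum);
#'   NULL skips testing.
#' @return data.frame: `marker`, `group`, `mean`, `pct`, `n`, and (for
#'   contrast rows) `p_contrast`.
#' @export
treatment_contrast <- function(cm, markers, cells = NULL,
                               contrast = NULL) {
  norm <- get_norm(cm)
  if (is.null(cm$groups)) stop("cell_matrix has no group labels")
  if (is.null(cells)) cells <- rep(TRUE, ncol(norm))
  grp <- cm$groups[cells]
  if (length(unique(grp)) < 2) stop("need >= 2 groups")
  missing <- setdiff(markers, rownames(norm))
  if (length(missing)) stop("marker(s) missing: ",
                            paste(missing, collapse = ", "))
  sub <- norm[markers, cells, drop = FALSE]
  det <- cm$counts[markers, cells, drop = FALSE] > 0
  groups <- sort(unique(grp))
  out <- do.call(rbind, lapply(groups, function(g) {
    data.frame(marker = markers,
               group = g,
               mean = rowMeans(sub[, grp == g, drop = FALSE]),
               pct = rowMeans(det[, grp == g, drop = FALSE]),
               n = sum(grp == g),
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  if (!is.null(contrast)) {
    stopifnot(length(contrast) == 2, all(contrast %in% grp))
    out$p_contrast <- NA_real_
    for (mk in markers) {
      x <- sub[mk, grp == contrast[1]]
      y <- sub[mk, grp == contrast[2]]
      out$p_contrast[out$marker == mk] <-
        mann_whitney_exact_two_sided(x, y)$p
    }
  }
  out
}
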