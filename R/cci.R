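#' Ligand-receptor interaction scores with a permutation null
#'
#' For every ordered sender/receiver cluster pair and every single-gene
#' ligand-receptor pair, the interaction score is the average of the mean
#' ligand expression in the sender and the mean receptor expression in
#' the receiver (log-normalised layer). A pair is evaluated only when the
#' ligand is detected in more than `min_pct` of sender cells and the
#' receptor in more than `min_pct` of receiver cells; otherwise it is
#' reported not-expressed with no p-value. Significance comes from a
#' cluster-label permutation null: labels are shuffled over all cells,
#' the same permutation reused across pairs within an iteration, and the
#' one-sided p is `(1 + #{permuted score >= observed}) / (1 + n_perm)` —
#' never exactly zero.
#'
#' @param cm a normalised `cell_matrix` with cluster labels.
#' @param pairs data.frame (`pair`, `ligand`, `receptor`); pairs whose
#'   genes are absent from the matrix are skipped and tallied in the
#'   `skipped_pairs` attribute.
#' @param n_perm number of permutations (>= 100; default 999).
#' @param seed integer seed for the permutations.
#' @param min_pct expression gate (default 0.10).
#' @return data.frame: `sender`, `receiver`, `pair`, `ligand`,
#'   `receptor`, `score`, `ligand_pct`, `receptor_pct`, `expressed`, `p`.
#' @export
lr_scores <- function(cm, pairs, n_perm = 999L, seed = 1L, min_pct = 0.10) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  norm <- get_norm(cm)
  cl <- get_clusters(cm)
  clusters <- sort(unique(cl))
  if (length(clusters) < 2) stop("need >= 2 clusters")
  present <- pairs$ligand %in% rownames(norm) &
    pairs$receptor %in% rownames(norm)
  skipped <- sum(!present)
  pairs <- pairs[present, , drop = FALSE]
  if (!nrow(pairs)) stop("no ligand-receptor pair has both genes present")
  genes <- unique(c(pairs$ligand, pairs$receptor))
  sub <- norm[genes, , drop = FALSE]
  det <- cm$counts[genes, , drop = FALSE] > 0
  nc <- length(clusters)

  cluster_means <- function(labels) {
    ind <- vapply(clusters, function(k) as.numeric(labels == k),
                  numeric(length(labels)))
    sweep(sub %*% ind, 2, colSums(ind), "/")   # genes x clusters
  }
  mu <- cluster_means(cl)
  ind0 <- vapply(clusters, function(k) as.numeric(cl == k),
                 numeric(length(cl)))
  pct <- sweep(det %*% ind0, 2, colSums(ind0), "/")
  colnames(mu) <- colnames(pct) <- clusters

  grid <- expand.grid(sender = clusters, receiver = clusters,
                      pair_idx = seq_len(nrow(pairs)),
                      stringsAsFactors = FALSE)
  lig <- pairs$ligand[grid$pair_idx]
  rec <- pairs$receptor[grid$pair_idx]
  score <- 0.5 * (mu[cbind(lig, grid$sender)] + mu[cbind(rec, grid$receiver)])
  lig_pct <- pct[cbind(lig, grid$sender)]
  rec_pct <- pct[cbind(rec, grid$receiver)]
  expressed <- lig_pct > min_pct & rec_pct > min_pct

  set.seed(seed)
  exceed <- integer(nrow(grid))
  for (b in seq_len(n_perm)) {
    mu_b <- cluster_means(sample(cl))
    colnames(mu_b) <- clusters
    s_b <- 0.5 * (mu_b[cbind(lig, grid$sender)] +
                    mu_b[cbind(rec, grid$receiver)])
    exceed <- exceed + (s_b >= score)
  }
  p <- (1 + exceed) / (1 + n_perm)
  out <- data.frame(sender = grid$sender, receiver = grid$receiver,
                    pair = pairs$pair[grid$pair_idx],
                    ligand = lig, receptor = rec,
                    score = as.vector(score),
                    ligand_pct = as.vector(lig_pct),
                    receptor_pct = as.vector(rec_pct),
                    expressed = as.vector(expressed),
                    p = ifelse(expressed, p, NA_real_),
                    stringsAsFactors = FALSE)
  attr(out, "skipped_pairs") <- skipped
  out
}

#' Significant-interaction counts per compartment pair
#'
#' Collapses ligand-receptor results to a compartment-level count matrix:
#' entry (A, B) is the number of expressed, significant (p < alpha)
#' results whose sender cluster maps to compartment A and receiver to B.
#' The row+column sums identify interaction hubs.
#'
#' @param results output of [lr_scores()].
#' @param compartment_map named character vector: cluster -> compartment.
#' @param alpha significance threshold (default 0.05).
#' @return compartment x compartment integer matrix.
#' @export
interaction_counts <- function(results, compartment_map, alpha = 0.05) {
  unmapped <- setdiff(unique(c(results$sender, results$receiver)),
                      names(compartment_map))
  if (length(unmapped)) {
    stop("cluster(s) not mapped to a compartment: ",
         paste(unmapped, collapse = ", "))
  }
  comps <- sort(unique(compartment_map))
  m <- matrix(0L, length(comps), length(comps),
              dimnames = list(sender = comps, receiver = comps))
  sig <- results[results$expressed & !is.na(results$p) & results$p < alpha, ]
  if (nrow(sig)) {
    tab <- table(factor(compartment_map[sig$sender], levels = comps),
                 factor(compartment_map[sig$receiver], levels = comps))
    m[] <- as.integer(tab)
  }
  m
}
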