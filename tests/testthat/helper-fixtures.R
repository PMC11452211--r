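# Small in-code fixtures shared across test files.

# Hand-sized beta matrix: 3 CpGs x 4 samples, two groups.
tiny_beta <- function(values = NULL) {
  v <- values %||% matrix(c(0.10, 0.20, 0.30,
                            0.15, 0.25, 0.35,
                            0.50, 0.60, 0.70,
                            0.55, 0.65, 0.75),
                          nrow = 3,
                          dimnames = list(c("cg01", "cg02", "cg03"),
                                          c("t1", "t2", "c1", "c2")))
  beta_matrix(v, c(t1 = "tumor", t2 = "tumor",
                   c1 = "control", c2 = "control"))
}

# Tiny cell matrix with two clearly separated clusters.
tiny_cells <- function(seed = 1) {
  set.seed(seed)
  n <- 40
  counts <- matrix(rpois(5 * n, 2), nrow = 5,
                   dimnames = list(paste0("gene", 1:5),
                                   paste0("cell", seq_len(n))))
  clusters <- rep(c("A", "B"), each = n / 2)
  counts["gene1", clusters == "A"] <- counts["gene1", clusters == "A"] + 10
  cell_matrix(counts, clusters = clusters,
              groups = rep("G1", n))
}

# Brute-force two-sided Fisher p by enumeration over tables with fixed
# margins (point-probability convention).
fisher_brute <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  lo <- max(0, c1 - r2); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(a) {
    dhyper(a, r1, r2, c1)
  }, numeric(1))
  obs <- dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force exact two-sided Mann-Whitney p over all label reassignments.
mwu_brute <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  eu <- n1 * (length(y)) / 2
  dev <- abs(sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2 - eu)
  idx <- utils::combn(n, n1)
  us <- apply(idx, 2, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  mean(abs(us - eu) >= dev - 1e-9)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
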