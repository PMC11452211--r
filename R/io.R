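#' Read a beta-value methylation matrix
#'
#' Reads a CpG x sample table of methylation beta values (CSV, header row,
#' first column CpG identifiers) together with a sample-to-group
#' assignment, and validates it: all values must be numbers in \[0, 1\]
#' and CpG identifiers must be unique. Violations are reported with the
#' offending CpG and sample.
#'
#' @param path CSV file, first column CpG ids, remaining columns samples.
#' @param groups named character vector or data.frame (columns `sample`,
#'   `group`) assigning every sample column to a group (e.g. tumor /
#'   control).
#' @param species `"human"` or `"mouse"` (metadata tag).
#' @param cpg_gene_map optional data.frame (columns `cpg`, `gene`) linking
#'   CpGs to gene identifiers.
#' @return a `beta_matrix` object.
#' @export
read_beta_matrix <- function(path, groups, species = "human",
                             cpg_gene_map = NULL) {
  if (!file.exists(path)) stop("beta matrix file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  cpgs <- as.character(df[[1]])
  values <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(values) <- "double"
  rownames(values) <- cpgs
  if (is.data.frame(groups)) {
    groups <- stats::setNames(as.character(groups$group),
                              as.character(groups$sample))
  }
  beta_matrix(values, groups, species = species, cpg_gene_map = cpg_gene_map)
}

#' Construct a beta_matrix
#'
#' Validating constructor for the methylation container used by the
#' cross-species concordance stage.
#'
#' @param values CpG x sample numeric matrix with row and column names.
#' @param sample_groups named character vector, one group per sample.
#' @param species metadata tag.
#' @param cpg_gene_map optional data.frame (`cpg`, `gene`); one CpG may
#'   map to several genes (one row each).
#' @return object of class `beta_matrix`.
#' @export
beta_matrix <- function(values, sample_groups, species = "human",
                        cpg_gene_map = NULL) {
  if (anyDuplicated(rownames(values))) {
    stop("duplicate CpG identifiers: ",
         paste(utils::head(rownames(values)[duplicated(rownames(values))], 3),
               collapse = ", "))
  }
  bad <- which(!is.finite(values) | values < 0 | values > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop("beta value outside [0,1] at CpG '", rownames(values)[bad[1, 1]],
         "', sample '", colnames(values)[bad[1, 2]], "' (value ",
         values[bad[1, , drop = FALSE]], ")")
  }
  missing_grp <- setdiff(colnames(values), names(sample_groups))
  if (length(missing_grp)) {
    stop("no group assigned for sample(s): ",
         paste(missing_grp, collapse = ", "))
  }
  structure(
    list(values = values,
         sample_groups = sample_groups[colnames(values)],
         species = species,
         cpg_gene_map = cpg_gene_map),
    class = "beta_matrix"
  )
}

#' @export
print.beta_matrix <- function(x, ...) {
  cat("beta_matrix:", nrow(x$values), "CpGs x", ncol(x$values), "samples (",
      x$species, ")\n")
  print(table(x$sample_groups))
  invisible(x)
}

#' Write a beta_matrix to CSV
#'
#' Inverse of [read_beta_matrix()]: values round-trip at full double
#' precision (15 significant digits).
#'
#' @param b `beta_matrix`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_beta_matrix <- function(b, path) {
  df <- data.frame(cpg = rownames(b$values),
                   format(b$values, digits = 15, trim = TRUE),
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a single-cell count matrix (MatrixMarket)
#'
#' Reads a genes x cells count matrix in MatrixMarket coordinate format
#' with its features and barcodes sidecars, validating that sidecar line
#' counts match the matrix dimensions, that counts are non-negative
#' integers, and that identifiers are unique. Cluster and sample-group
#' labels may be supplied via a metadata sidecar (CSV with columns
#' `barcode`, `cluster`, `group`).
#'
#' @param mtx_path MatrixMarket file.
#' @param features_path one gene id per line (TSV; first column used).
#' @param barcodes_path one cell barcode per line.
#' @param meta_path optional per-cell metadata CSV.
#' @return a `cell_matrix` object.
#' @export
read_cell_matrix <- function(mtx_path, features_path, barcodes_path,
                             meta_path = NULL) {
  for (p in c(mtx_path, features_path, barcodes_path)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  m <- Matrix::readMM(mtx_path)
  feats <- utils::read.delim(features_path, header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  bcs <- readLines(barcodes_path)
  if (length(feats) != nrow(m)) {
    stop("features/matrix dimension mismatch: expected ", nrow(m),
         " features, found ", length(feats))
  }
  if (length(bcs) != ncol(m)) {
    stop("barcodes/matrix dimension mismatch: expected ", ncol(m),
         " barcodes, found ", length(bcs))
  }
  counts <- as.matrix(m)
  dimnames(counts) <- list(feats, bcs)
  clusters <- groups <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    meta <- meta[match(bcs, meta$barcode), ]
    clusters <- meta$cluster
    groups <- meta$group
  }
  cell_matrix(counts, clusters = clusters, groups = groups)
}

#' Read a single-cell count matrix from dense CSV
#'
#' Alternative reader for the same container: genes in rows (first column
#' gene ids), cells in columns. Produces a matrix identical to the MTX
#' reader on equivalent input.
#'
#' @param path CSV file.
#' @inheritParams read_cell_matrix
#' @return a `cell_matrix` object.
#' @export
read_cell_matrix_csv <- function(path, meta_path = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- as.character(df[[1]])
  clusters <- groups <- NULL
  if (!is.null(meta_path)) {
    meta <- utils::read.csv(meta_path, stringsAsFactors = FALSE)
    meta <- meta[match(colnames(counts), meta$barcode), ]
    clusters <- meta$cluster
    groups <- meta$group
  }
  cell_matrix(counts, clusters = clusters, groups = groups)
}

#' Construct a cell_matrix
#'
#' Validating constructor for the single-cell container: genes x cells
#' non-negative integer counts, unique identifiers, optional per-cell
#' cluster and sample-group labels (clustering itself is an input to this
#' pipeline, not something it computes).
#'
#' @param counts genes x cells matrix, non-negative integers, dimnames set.
#' @param clusters per-cell cluster labels or NULL.
#' @param groups per-cell sample-group labels or NULL.
#' @param normalized optional pre-computed log-normalised layer.
#' @return object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, clusters = NULL, groups = NULL,
                        normalized = NULL) {
  if (any(counts < 0)) {
    bad <- which(counts < 0, arr.ind = TRUE)[1, ]
    stop("negative count at gene '", rownames(counts)[bad[1]], "', cell '",
         colnames(counts)[bad[2]], "'")
  }
  if (any(counts != round(counts))) stop("counts must be integers")
  if (anyDuplicated(rownames(counts))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(counts))) stop("duplicate cell identifiers")
  if (!is.null(clusters) && length(clusters) != ncol(counts)) {
    stop("cluster labels must match the number of cells")
  }
  if (!is.null(groups) && length(groups) != ncol(counts)) {
    stop("group labels must match the number of cells")
  }
  structure(list(counts = counts,
                 clusters = if (!is.null(clusters)) as.character(clusters),
                 groups = if (!is.null(groups)) as.character(groups),
                 normalized = normalized),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix:", nrow(x$counts), "genes x", ncol(x$counts), "cells\n")
  if (!is.null(x$clusters)) {
    cat("clusters:", length(unique(x$clusters)), "\n")
  }
  cat("normalized layer:", if (is.null(x$normalized)) "absent" else "present",
      "\n")
  invisible(x)
}

#' Write a cell_matrix as MatrixMarket + sidecars
#'
#' @param cm `cell_matrix`.
#' @param dir output directory (created if needed); writes `matrix.mtx`,
#'   `features.tsv`, `barcodes.tsv` and, when labels are present,
#'   `meta.csv`.
#' @return the directory, invisibly.
#' @export
write_cell_matrix <- function(cm, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(methods::as(Matrix::Matrix(cm$counts, sparse = TRUE),
                              "generalMatrix"),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(cm$counts), file.path(dir, "features.tsv"))
  writeLines(colnames(cm$counts), file.path(dir, "barcodes.tsv"))
  if (!is.null(cm$clusters) || !is.null(cm$groups)) {
    utils::write.csv(
      data.frame(barcode = colnames(cm$counts),
                 cluster = cm$clusters %||% NA,
                 group = cm$groups %||% NA),
      file.path(dir, "meta.csv"), row.names = FALSE)
  }
  invisible(dir)
}

#' Read a GMT gene-set collection
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Genes are
#' deduplicated preserving order; empty sets and lines with fewer than
#' three fields are rejected with the line number.
#'
#' @param path GMT file.
#' @return named list of character vectors, class `gene_sets`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- vector("list", length(lines))
  nms <- character(length(lines))
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("GMT line ", i, ": fewer than 3 fields")
    genes <- unique(f[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stop("GMT line ", i, ": empty gene set '", f[1], "'")
    nms[i] <- f[1]
    sets[[i]] <- genes
  }
  if (anyDuplicated(nms)) stop("duplicate gene-set names in GMT")
  structure(stats::setNames(sets, nms), class = "gene_sets")
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors.
#' @param path output file.
#' @param descriptions optional per-set description column (defaults to
#'   the set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an ortholog map
#'
#' Two-column table (CSV; columns `human`, `mouse`) mapping human genes to
#' mouse orthologs. The v1 map must be one-to-one; conflicting duplicates
#' are rejected.
#'
#' @param path CSV file.
#' @return data.frame with columns `human`, `mouse`.
#' @export
read_ortholog_map <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ortholog_map(df)
}

#' Validate an ortholog map
#' @param df data.frame with columns `human`, `mouse`.
#' @return the validated data.frame.
#' @export
ortholog_map <- function(df) {
  if (!all(c("human", "mouse") %in% names(df))) {
    stop("ortholog map needs columns 'human' and 'mouse'")
  }
  df <- unique(df[, c("human", "mouse")])
  if (anyDuplicated(df$human) || anyDuplicated(df$mouse)) {
    stop("ortholog map must be one-to-one: conflicting duplicate entries")
  }
  df
}

#' Read a ligand-receptor pair table
#'
#' @param path CSV with columns `pair`, `ligand`, `receptor`.
#' @return validated data.frame.
#' @export
read_lr_pairs <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("pair", "ligand", "receptor") %in% names(df))) {
    stop("L-R table needs columns 'pair', 'ligand', 'receptor'")
  }
  if (anyDuplicated(df$pair)) stop("pair names must be unique")
  if (any(!nzchar(df$ligand)) || any(!nzchar(df$receptor))) {
    stop("every pair must name both a ligand and a receptor gene")
  }
  df
}

#' Read a drug-screen viability table
#'
#' Long-format CSV with columns `compound`, `class`, `cell_line`,
#' `replicate`, `viability`; vehicle controls are rows with
#' `compound == "vehicle"`. Every cell line must have vehicle replicates
#' and every condition at least 2 replicates.
#'
#' @param path CSV file.
#' @return validated data.frame, class `viability_table`.
#' @export
read_viability_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  viability_table(df)
}

#' Validate a viability table
#' @param df long-format data.frame (see [read_viability_table()]).
#' @return the validated data.frame with class `viability_table`.
#' @export
viability_table <- function(df) {
  need <- c("compound", "class", "cell_line", "replicate", "viability")
  if (!all(need %in% names(df))) {
    stop("viability table needs columns: ", paste(need, collapse = ", "))
  }
  lines <- unique(df$cell_line)
  no_vehicle <- lines[!lines %in% df$cell_line[df$compound == "vehicle"]]
  if (length(no_vehicle)) {
    stop("missing vehicle controls for cell line(s): ",
         paste(no_vehicle, collapse = ", "))
  }
  reps <- stats::aggregate(replicate ~ compound + cell_line, df, length)
  if (any(reps$replicate < 2)) stop("every condition needs >= 2 replicates")
  class(df) <- c("viability_table", "data.frame")
  df
}

#' Read an immunofluorescence ROI table
#'
#' @param path CSV with columns `roi`, `group`, per-marker count columns
#'   (e.g. `ezh2_hi`, `b220_pos`, `ly6g_pos`), and `area_um2`.
#' @return validated data.frame, class `roi_table`.
#' @export
read_roi_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  roi_table(df)
}

#' Validate an ROI table
#' @param df data.frame (see [read_roi_table()]).
#' @return the validated data.frame with class `roi_table`.
#' @export
roi_table <- function(df) {
  if (!all(c("roi", "group", "area_um2") %in% names(df))) {
    stop("ROI table needs columns 'roi', 'group', 'area_um2'")
  }
  counts <- df[, setdiff(names(df), c("roi", "group", "area_um2")),
               drop = FALSE]
  num <- vapply(counts, is.numeric, logical(1))
  if (any(unlist(counts[num]) < 0) ||
      any(unlist(counts[num]) != round(unlist(counts[num])))) {
    stop("marker counts must be non-negative integers")
  }
  if (any(df$area_um2 <= 0)) stop("ROI area must be positive")
  class(df) <- c("roi_table", "data.frame")
  df
}

#' Read a patient cohort table
#'
#' @param path CSV with columns `patient`, `age`, `group`
#'   (CAYA / adult), `smarcb1_status` (0 = negative, 1 = positive).
#' @return validated data.frame, class `cohort_table`.
#' @export
read_cohort_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient", "age", "group", "smarcb1_status")
  if (!all(need %in% names(df))) {
    stop("cohort table needs columns: ", paste(need, collapse = ", "))
  }
  if (!all(df$smarcb1_status %in% c(0, 1))) {
    stop("smarcb1_status must be binary 0/1")
  }
  class(df) <- c("cohort_table", "data.frame")
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
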