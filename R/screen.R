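#' Normalise screen viability to vehicle controls
#'
#' Per compound and cell line: mean of treated replicates divided by the
#' mean of that line's vehicle replicates, floored at `epsilon` before
#' any log is taken (single-dose screens routinely exceed 90% kill; the
#' floor keeps log fold changes finite).
#'
#' @param raw a `viability_table` (long format, vehicle rows present per
#'   line).
#' @param epsilon viability floor (default 1e-4).
#' @return data.frame: `compound`, `class`, `cell_line`, `fraction`.
#' @export
normalize_viability <- function(raw, epsilon = 1e-4) {
  raw <- viability_table(as.data.frame(raw))
  veh <- raw[raw$compound == "vehicle", ]
  veh_mean <- tapply(veh$viability, veh$cell_line, mean)
  if (any(veh_mean <= 0)) stop("vehicle mean must be positive")
  trt <- raw[raw$compound != "vehicle", ]
  agg <- stats::aggregate(viability ~ compound + class + cell_line, trt, mean)
  agg$fraction <- pmax(agg$viability / veh_mean[agg$cell_line], epsilon)
  agg[, c("compound", "class", "cell_line", "fraction")]
}

#' Relative efficacy against a reference panel
#'
#' Per compound: log2 fold change of viability per line, then the index
#' line's log2FC referenced to the mean log2FC over the reference lines.
#' Negative values mean the compound kills the index line selectively.
#' The result is sorted ascending, most selectively toxic first. The
#' statistic is translation-invariant: shifting every line's log2FC by a
#' constant leaves it unchanged.
#'
#' @param fractions output of [normalize_viability()].
#' @param index_line the line of interest (e.g. a SMARCB1-deficient
#'   model line).
#' @param reference_lines comparison panel (must not contain
#'   `index_line`; at least one line).
#' @return data.frame: `compound`, `class`, `log2fc_index`,
#'   `log2fc_reference_mean`, `relative_log2fc`.
#' @export
relative_efficacy <- function(fractions, index_line,
                              reference_lines = NULL) {
  lines <- unique(fractions$cell_line)
  reference_lines <- reference_lines %||% setdiff(lines, index_line)
  if (index_line %in% reference_lines) {
    stop("index line must not be in the reference set")
  }
  if (!length(reference_lines)) stop("need >= 1 reference line")
  l2 <- fractions
  l2$log2fc <- log2(l2$fraction)
  idx <- l2[l2$cell_line == index_line, ]
  ref <- l2[l2$cell_line %in% reference_lines, ]
  ref_mean <- tapply(ref$log2fc, ref$compound, mean)
  out <- data.frame(compound = idx$compound, class = idx$class,
                    log2fc_index = idx$log2fc,
                    log2fc_reference_mean = unname(ref_mean[idx$compound]),
                    stringsAsFactors = FALSE)
  out$relative_log2fc <- out$log2fc_index - out$log2fc_reference_mean
  out[order(out$relative_log2fc, out$compound), ]
}

#' Per-class activity summary of a screen
#'
#' Counts compounds active at `active_cut` (relative log2FC at or below
#' the cutoff; default -1, i.e. at least 2-fold selective kill) and the
#' median relative log2FC per compound class, sorted by active count.
#'
#' @param efficacy output of [relative_efficacy()].
#' @param active_cut activity threshold (default -1).
#' @return data.frame: `class`, `n_compounds`, `n_active`,
#'   `median_relative_log2fc`, sorted by decreasing `n_active`.
#' @export
rank_classes <- function(efficacy, active_cut = -1) {
  if (any(is.na(efficacy$class))) stop("every compound must be classed")
  sp <- split(efficacy$relative_log2fc, efficacy$class)
  out <- data.frame(
    class = names(sp),
    n_compounds = vapply(sp, length, integer(1)),
    n_active = vapply(sp, function(v) sum(v <= active_cut), integer(1)),
    median_relative_log2fc = vapply(sp, stats::median, numeric(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n_active, out$median_relative_log2fc), ]
}

#' Compare ROI marker counts between groups
#'
#' Per-group median and quartiles of a marker's per-ROI cell counts (and
#' densities per mm^2), with an exact two-sided Mann-Whitney test between
#' the two groups — at four ROIs per group the minimal attainable p under
#' complete separation is 2/70 = 0.0286.
#'
#' @param roi a `roi_table`.
#' @param marker marker count column name (e.g. `"b220_pos"`).
#' @return list: `test` (a `test_result`), `summary` (per-group median
#'   and quartiles of counts and density).
#' @export
roi_compare <- function(roi, marker) {
  if (!marker %in% names(roi)) stop("marker column absent: ", marker)
  groups <- unique(roi$group)
  if (length(groups) != 2) stop("need exactly 2 groups")
  cnt <- split(roi[[marker]], roi$group)
  if (any(vapply(cnt, length, integer(1)) < 2)) {
    stop("need >= 2 ROIs per group")
  }
  dens <- split(roi[[marker]] / (roi$area_um2 / 1e6), roi$group)
  summ <- do.call(rbind, lapply(names(cnt), function(g) {
    q <- stats::quantile(cnt[[g]], c(0.25, 0.5, 0.75))
    data.frame(group = g, n_roi = length(cnt[[g]]),
               q25 = q[[1]], median = q[[2]], q75 = q[[3]],
               median_density_mm2 = stats::median(dens[[g]]),
               stringsAsFactors = FALSE)
  }))
  list(test = mann_whitney_exact_two_sided(cnt[[groups[1]]],
                                           cnt[[groups[2]]]),
       summary = summ)
}
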