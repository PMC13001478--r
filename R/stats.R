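# Single-cell OMI statistics: Cohen's d effect sizes with the conventional
# magnitude categories, coefficient-of-variation heterogeneity, per-variable
# z-scoring and Ward hierarchical clustering.

#' Cohen's d effect size
#'
#' d = (M1 - M2) / sqrt((SD1^2 + SD2^2) / 2), using sample (n-1) standard
#' deviations and the equal-weight root-mean-square of the two group SDs as
#' denominator. Magnitude categories: |d| < 0.2 none, 0.2 <= |d| < 0.5
#' small, 0.5 <= |d| < 0.8 medium, |d| >= 0.8 large (boundaries fall in the
#' higher category). Direction is the sign of M1 - M2. Intended for large
#' single-cell samples; a warning is emitted below `min_n` per group.
#'
#' @param group1,group2 Numeric vectors (group1 first, so with activation
#'   comparisons group1 = activated gives the direction of change).
#' @param min_n Advisory minimum group size (default 100 cells).
#' @return An `effect_size` list: `d`, `category`, `direction`, `n1`, `n2`,
#'   `m1`, `m2`, `sd1`, `sd2`.
#' @export
cohens_d <- function(group1, group2, min_n = 100) {
  group1 <- group1[!is.na(group1)]; group2 <- group2[!is.na(group2)]
  n1 <- length(group1); n2 <- length(group2)
  if (n1 < 2 || n2 < 2) stop("cohens_d needs >= 2 values per group", call. = FALSE)
  if (min(n1, n2) < min_n) {
    warning("fewer than ", min_n, " cells in a group; effect size may be noisy")
  }
  m1 <- mean(group1); m2 <- mean(group2)
  s1 <- stats::sd(group1); s2 <- stats::sd(group2)
  denom <- sqrt((s1^2 + s2^2) / 2)
  d <- if (denom == 0) {
    if (m1 == m2) 0 else NA_real_
  } else (m1 - m2) / denom
  if (is.na(d)) warning("both group SDs are zero with unequal means: d undefined")
  structure(list(d = d, category = effect_size_category(d),
                 direction = if (is.na(d) || m1 == m2) "none" else
                   if (m1 > m2) "increase" else "decrease",
                 n1 = n1, n2 = n2, m1 = m1, m2 = m2, sd1 = s1, sd2 = s2),
            class = "effect_size")
}

#' @export
print.effect_size <- function(x, ...) {
  cat(sprintf("<effect_size> d = %.3f (%s, %s; n = %d vs %d)\n",
              x$d, x$category, x$direction, x$n1, x$n2))
  invisible(x)
}

#' Effect-size magnitude category
#' @param d Cohen's d (scalar or vector).
#' @return Character: "none", "small", "medium", or "large".
#' @export
effect_size_category <- function(d) {
  a <- abs(d)
  out <- rep(NA_character_, length(a))
  out[a < 0.2] <- "none"
  out[a >= 0.2 & a < 0.5] <- "small"
  out[a >= 0.5 & a < 0.8] <- "medium"
  out[a >= 0.8] <- "large"
  out
}

#' Coefficient of variation
#'
#' SD / mean with the sample (n-1) standard deviation; a normalised measure
#' of single-cell heterogeneity. Undefined (NA with a warning) for
#' non-positive means.
#'
#' @param values Numeric vector, length >= 2.
#' @return Scalar COV.
#' @export
coefficient_of_variation <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("COV needs >= 2 values", call. = FALSE)
  m <- mean(values)
  if (m <= 0) {
    warning("non-positive mean: COV undefined")
    return(NA_real_)
  }
  stats::sd(values) / m
}

#' Z-score a feature matrix
#'
#' Standardises each variable to mean 0, SD 1 across all (QC-passed) cells.
#' Zero-variance columns are dropped with a warning. The per-column centre
#' and scale are stored as attributes so the transform can be inverted.
#'
#' @param table Cell feature table (QC-passed rows).
#' @param variables Columns to standardise (default the 10 OMI variables).
#' @return Numeric matrix with attributes `center`, `scale`,
#'   `dropped` (names of zero-variance columns).
#' @export
zscore_features <- function(table, variables = omi_variables()) {
  missing_v <- setdiff(variables, names(table))
  if (length(missing_v)) {
    stop("variables absent from table: ", paste(missing_v, collapse = ", "),
         call. = FALSE)
  }
  x <- as.matrix(table[, variables, drop = FALSE])
  if (anyNA(x)) stop("missing values in feature matrix: apply QC first", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  dropped <- variables[sds == 0]
  if (length(dropped)) {
    warning("dropping zero-variance column(s): ", paste(dropped, collapse = ", "))
  }
  keep <- sds > 0
  z <- scale(x[, keep, drop = FALSE])
  out <- z[, , drop = FALSE]
  attributes(out)$center <- attr(z, "scaled:center")
  attributes(out)$scale <- attr(z, "scaled:scale")
  attributes(out)$dropped <- dropped
  dimnames(out) <- list(NULL, variables[keep])
  out
}

#' Ward hierarchical clustering of single cells
#'
#' Agglomerative clustering of the standardised feature matrix under Ward's
#' minimum-variance criterion with Euclidean distance (Lance-Williams
#' recurrence, `stats::hclust(method = "ward.D2")`). Annotations (condition,
#' donor, cell type) are carried alongside and never enter the distances.
#' The first split (k = 2) assignment is reported.
#'
#' @param z Standardised matrix from [zscore_features()].
#' @param annotations Optional data.frame of row annotations.
#' @param k Number of clusters for the reported cut (default 2).
#' @return A `ward_clustering` list: `hclust` (merge tree), `assignments`
#'   (cut at `k`), `annotations`, `k`.
#' @export
ward_cluster <- function(z, annotations = NULL, k = 2L) {
  if (anyNA(z)) stop("missing values in the matrix: filter with QC first", call. = FALSE)
  if (nrow(z) < 2) stop("clustering needs >= 2 rows", call. = FALSE)
  if (!is.null(annotations)) stopifnot(nrow(annotations) == nrow(z))
  hc <- stats::hclust(stats::dist(z, method = "euclidean"), method = "ward.D2")
  structure(list(hclust = hc,
                 assignments = stats::cutree(hc, k = k),
                 annotations = annotations, k = k),
            class = "ward_clustering")
}

#' Export a clustering merge tree as Newick text
#' @param wc A [ward_cluster()] result.
#' @return Newick string (with branch lengths from merge heights).
#' @export
dendrogram_newick <- function(wc) {
  stopifnot(inherits(wc, "ward_clustering"))
  ape::write.tree(ape::as.phylo(wc$hclust))
}

#' Per-population heterogeneity table
#'
#' Mean, sample SD, coefficient of variation and n for every
#' (cell type, condition, variable) stratum.
#'
#' @param table Cell feature table (QC-passed rows).
#' @param variables Variables to summarise.
#' @param group_cols Stratifying columns.
#' @return Long-format data.frame: group columns, `variable`, `mean`, `sd`,
#'   `cov`, `n`.
#' @export
heterogeneity_table <- function(table, variables = omi_variables(),
                                group_cols = c("cell_type", "condition")) {
  stopifnot(all(group_cols %in% names(table)))
  groups <- unique(table[, group_cols, drop = FALSE])
  out <- do.call(rbind, lapply(seq_len(nrow(groups)), function(g) {
    sel <- rep(TRUE, nrow(table))
    for (gc in group_cols) sel <- sel & table[[gc]] == groups[[gc]][g]
    do.call(rbind, lapply(variables, function(v) {
      vals <- table[[v]][sel]
      cbind(groups[g, , drop = FALSE],
            data.frame(variable = v, mean = mean(vals), sd = stats::sd(vals),
                       cov = if (mean(vals) > 0) stats::sd(vals) / mean(vals)
                             else NA_real_,
                       n = sum(sel)))
    }))
  }))
  row.names(out) <- NULL
  out
}

#' Activation effect-size matrix
#'
#' Cohen's d of activated vs quiescent (group1 = activated, so the sign is
#' the direction of change with activation) for every variable within each
#' stratum — per (cell type, donor) by default, or pooled across donors.
#'
#' @param table Feature table containing both conditions in a `condition`
#'   column.
#' @param variables Variables to compare.
#' @param by Stratifying columns (besides condition); use `"cell_type"` for
#'   the pooled-by-donor variant.
#' @param min_n Advisory minimum cells per group passed to [cohens_d()].
#' @return Long-format data.frame: strata, `variable`, `d`, `category`,
#'   `direction`, `n_activated`, `n_quiescent`.
#' @export
activation_effect_sizes <- function(table, variables = omi_variables(),
                                    by = c("cell_type", "donor"),
                                    min_n = 100) {
  stopifnot("condition" %in% names(table), all(by %in% names(table)))
  strata <- unique(table[, by, drop = FALSE])
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(s) {
    sel <- rep(TRUE, nrow(table))
    for (bc in by) sel <- sel & table[[bc]] == strata[[bc]][s]
    act <- table[sel & table$condition == "activated", , drop = FALSE]
    qui <- table[sel & table$condition == "quiescent", , drop = FALSE]
    if (nrow(act) < 2 || nrow(qui) < 2) return(NULL)
    do.call(rbind, lapply(variables, function(v) {
      es <- cohens_d(act[[v]], qui[[v]], min_n = min_n)
      cbind(strata[s, , drop = FALSE],
            data.frame(variable = v, d = es$d, category = es$category,
                       direction = es$direction,
                       n_activated = es$n1, n_quiescent = es$n2))
    }))
  }))
  row.names(out) <- NULL
  out
}
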