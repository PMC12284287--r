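# Population analysis: z-scored feature matrix, correlation-matrix PCA,
# Ward hierarchical clustering on squared Euclidean distances, and the
# normality-gated one-way group-comparison dispatcher with Tukey / Dunn
# post hoc tests.

#' Build the z-scored feature matrix
#'
#' Selects the named features from per-cell profile rows, drops every row
#' with a missing value (ids recorded, never imputed), excludes constant
#' columns (z-score undefined) with a warning, and z-scores each remaining
#' column to mean 0, SD 1.
#'
#' @param profiles data.frame of intrinsic profiles (one row per cell) with
#'   columns \code{cell_id}, \code{group} and the features.
#' @param feature_list feature columns to use (default the 15 of
#'   \code{\link{gpe_feature_names}}).
#' @return object of class \code{feature_matrix}: list with the z-scored
#'   matrix \code{x}, \code{cell_id}, \code{group}, \code{features},
#'   \code{dropped} (ids of removed rows), \code{excluded_features}.
#' @export
build_feature_matrix <- function(profiles, feature_list = gpe_feature_names()) {
  missing_cols <- setdiff(feature_list, names(profiles))
  if (length(missing_cols))
    stopf("profiles lack feature columns: %s",
          paste(missing_cols, collapse = ", "))
  x <- as.matrix(profiles[, feature_list, drop = FALSE])
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  dropped <- profiles$cell_id[!complete]
  if (length(dropped))
    message(sprintf("dropping %d rows with missing features: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  x <- x[complete, , drop = FALSE]
  if (nrow(x) < 2) stopf("fewer than 2 complete rows")
  sds <- apply(x, 2, stats::sd)
  excluded <- feature_list[sds == 0]
  if (length(excluded)) {
    warnf("excluding constant feature(s): %s", paste(excluded, collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  z <- scale(x)
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  structure(list(x = z, cell_id = profiles$cell_id[complete],
                 group = profiles$group[complete],
                 features = colnames(z), dropped = dropped,
                 excluded_features = excluded, z_scored = TRUE),
            class = "feature_matrix")
}

#' Correlation-matrix PCA
#'
#' Eigendecomposition of the correlation matrix of the z-scored features.
#' Eigenvalues sum to the feature count; the number of retained components
#' follows the eigenvalue > 1 rule (the scree-plot elbow is returned as a
#' diagnostic only).  Scores and loadings are returned for all components;
#' eigenvalues below 1e-10 are zeroed and flagged (rank deficiency).
#'
#' @param fm a \code{feature_matrix}.
#' @return object of class \code{gpe_pca}: \code{eigenvalues} (descending),
#'   \code{explained} (fractions summing to 1), \code{loadings} (feature x
#'   PC, orthonormal columns), \code{scores} (cell x PC), \code{n_retained},
#'   \code{rank_deficient}.
#' @export
run_pca <- function(fm) {
  stopifnot(inherits(fm, "feature_matrix"))
  x <- fm$x
  C <- stats::cor(x)
  e <- eigen(C, symmetric = TRUE)
  vals <- e$values
  rank_deficient <- any(vals < 1e-10)
  vals[vals < 1e-10] <- 0
  loadings <- e$vectors
  rownames(loadings) <- fm$features
  colnames(loadings) <- paste0("PC", seq_along(vals))
  scores <- x %*% loadings
  structure(list(eigenvalues = vals, explained = vals / sum(vals),
                 loadings = loadings, scores = scores,
                 n_retained = sum(vals > 1),
                 rank_deficient = rank_deficient),
            class = "gpe_pca")
}

#' @export
print.gpe_pca <- function(x, ...) {
  cat(sprintf("<pca> %d features; %d components with eigenvalue > 1 (%.0f%% of variance)\n",
              length(x$eigenvalues), x$n_retained,
              100 * sum(x$explained[seq_len(x$n_retained)])))
  invisible(x)
}

#' Ward hierarchical clustering on squared Euclidean distances
#'
#' Agglomerative clustering with Ward's minimum-variance linkage on squared
#' Euclidean distances over the z-scored features, cut into k flat clusters.
#' Purity is reported per true group: the fraction of that group's cells
#' assigned to the group's majority cluster.
#'
#' @param fm a \code{feature_matrix}.
#' @param k number of flat clusters (2 <= k <= n).
#' @return object of class \code{gpe_clust}: \code{hclust} (merge heights
#'   non-decreasing), \code{labels}, \code{purity} (named by group),
#'   \code{k}.
#' @export
hier_cluster <- function(fm, k) {
  stopifnot(inherits(fm, "feature_matrix"))
  n <- nrow(fm$x)
  if (k < 2 || k > n) stopf("k must lie in [2, %d]", n)
  hc <- stats::hclust(stats::dist(fm$x)^2, method = "ward.D")
  labels <- stats::cutree(hc, k = k)
  purity <- cluster_purity(labels, fm$group)
  structure(list(hclust = hc, labels = labels, purity = purity, k = k),
            class = "gpe_clust")
}

#' Per-group cluster purity
#'
#' @param labels integer cluster labels.
#' @param group true group labels.
#' @return named numeric: for each group, the fraction assigned to its
#'   majority cluster.
#' @export
cluster_purity <- function(labels, group) {
  vapply(split(labels, group), function(l) max(table(l)) / length(l),
         numeric(1))
}

# ---- group comparison dispatcher --------------------------------------------

#' Dunn's post hoc test (rank sums, Bonferroni-adjusted)
#'
#' Pairwise z statistics on mean ranks with the tie correction
#' \eqn{z_{ij} = (\bar R_i - \bar R_j) / \sqrt{(N(N+1)/12 - T)(1/n_i + 1/n_j)}},
#' \eqn{T = \sum (t^3 - t) / (12 (N - 1))}; two-sided p-values multiplied by
#' the number of comparisons (capped at 1).
#'
#' @param values numeric vector.
#' @param group factor of the same length.
#' @return data.frame \code{comparison}, \code{z}, \code{p_unadj}, \code{p}.
#' @export
dunn_test <- function(values, group) {
  group <- factor(group)
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, group, mean)
  n <- tapply(r, group, length)
  ties <- table(values)
  Tcorr <- sum(ties^3 - ties) / (12 * (N - 1))
  lv <- levels(group)
  combs <- utils::combn(lv, 2)
  m <- ncol(combs)
  out <- data.frame(comparison = character(m), z = numeric(m),
                    p_unadj = numeric(m), p = numeric(m),
                    stringsAsFactors = FALSE)
  for (i in seq_len(m)) {
    a <- combs[1, i]; b <- combs[2, i]
    se <- sqrt((N * (N + 1) / 12 - Tcorr) * (1 / n[[a]] + 1 / n[[b]]))
    z <- (rbar[[a]] - rbar[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out$comparison[i] <- paste(a, b, sep = " - ")
    out$z[i] <- z
    out$p_unadj[i] <- p
    out$p[i] <- min(1, p * m)
  }
  out
}

#' Normality-gated one-way group comparison
#'
#' The dispatcher used for every violin-plot comparison: each group is tested
#' for normality (Shapiro-Wilk, alpha 0.05); if all groups pass, a two-sided
#' one-way ANOVA with Tukey's HSD post hoc is run, otherwise Kruskal-Wallis
#' with Dunn's test (Bonferroni).  A degenerate (constant) group forces the
#' non-parametric branch with a flag.
#'
#' @param values_by_group named list of numeric vectors (>= 2 groups, >= 3
#'   values each).
#' @param alpha normality alpha.
#' @return object of class \code{group_comparison}: \code{branch}
#'   (\code{"anova"} or \code{"kruskal"}), \code{normality_p},
#'   \code{omnibus_p}, \code{pairwise} (data.frame with \code{comparison},
#'   \code{p}, \code{stars}), \code{flags}.
#' @export
compare_groups <- function(values_by_group, alpha = 0.05) {
  if (length(values_by_group) < 2) stopf("need at least 2 groups")
  if (any(vapply(values_by_group, length, integer(1)) < 3))
    stopf("each group needs at least 3 values")
  flags <- character(0)
  norm_p <- vapply(values_by_group, function(v) {
    if (stats::sd(v) == 0) return(0)  # constant: treat as non-normal
    stats::shapiro.test(v)$p.value
  }, numeric(1))
  if (any(vapply(values_by_group, function(v) stats::sd(v) == 0, logical(1))))
    flags <- c(flags, "degenerate_group_forced_nonparametric")
  values <- unlist(values_by_group, use.names = FALSE)
  group <- factor(rep(names(values_by_group),
                      vapply(values_by_group, length, integer(1))))
  if (all(norm_p > alpha)) {
    branch <- "anova"
    fit <- stats::aov(values ~ group)
    omnibus <- summary(fit)[[1]][["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit)$group
    pairwise <- data.frame(comparison = rownames(tk), p = tk[, "p adj"],
                           stringsAsFactors = FALSE)
  } else {
    branch <- "kruskal"
    omnibus <- stats::kruskal.test(values, group)$p.value
    dn <- dunn_test(values, group)
    pairwise <- data.frame(comparison = dn$comparison, p = dn$p,
                           stringsAsFactors = FALSE)
  }
  pairwise$stars <- p_stars(pairwise$p)
  rownames(pairwise) <- NULL
  structure(list(branch = branch, normality_p = norm_p, omnibus_p = omnibus,
                 pairwise = pairwise, flags = flags),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> branch: %s, omnibus p = %.3g %s\n",
              x$branch, x$omnibus_p, p_stars(x$omnibus_p)))
  for (i in seq_len(nrow(x$pairwise)))
    cat(sprintf("  %-28s p = %.3g %s\n", x$pairwise$comparison[i],
                x$pairwise$p[i], x$pairwise$stars[i]))
  invisible(x)
}
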