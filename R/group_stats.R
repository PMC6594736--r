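# Permutation and rank statistics used on the partitioned groups. The
# heavy lifting is delegated to vegan (adonis2 / anosim / mrpp / mantel);
# these wrappers fix the interface to (distance, grouping, n_perm, seed),
# validate inputs, and return a flat result record.

perm_result <- function(test, statistic, p_value, n_perm, effect_r2 = NA) {
  structure(list(test_name = test, statistic = unname(statistic),
                 effect_r2 = unname(effect_r2),
                 p_value = unname(p_value), n_permutations = n_perm),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g", x$test_name, x$statistic))
  if (!is.na(x$effect_r2)) cat(sprintf(", R2 = %.3f", x$effect_r2))
  cat(sprintf(", P = %.4g (%d permutations)\n", x$p_value,
              x$n_permutations))
  invisible(x)
}

check_grouping <- function(d, grouping) {
  n <- attr(d, "Size")
  labs <- attr(d, "Labels")
  if (!is.null(names(grouping)) && !is.null(labs)) {
    missing <- setdiff(labs, names(grouping))
    if (length(missing))
      stop("grouping misses sample(s): ", paste(missing, collapse = ", "))
    grouping <- grouping[labs]
  }
  if (length(grouping) != n)
    stop("grouping must cover all ", n, " samples")
  g <- factor(grouping)
  if (nlevels(g) < 2)
    stop("need at least 2 groups")
  g
}

#' One-way PERMANOVA (Adonis) on a distance matrix
#'
#' Partitions squared dissimilarities between and within groups;
#' `F = (SS_between/(a-1)) / (SS_within/(N-a))`, `R2 = SS_between/SS_total`,
#' with a permutation P-value using the `(hits + 1)/(n_perm + 1)`
#' convention. Delegated to [vegan::adonis2]; with few samples vegan
#' enumerates the complete permutation set, making P exact.
#'
#' @param d a `dist` object.
#' @param grouping sample labels (named by sample id, or in `d`'s order).
#' @param n_perm number of permutations (default 999).
#' @param seed integer seed (`NULL` uses current RNG stream).
#' @return a `perm_test_result` with the F statistic, `effect_r2`, and P.
#' @export
adonis_test <- function(d, grouping, n_perm = 999, seed = NULL) {
  g <- check_grouping(d, grouping)
  dat <- data.frame(g = g)
  fit <- with_seed_local(seed,
    vegan::adonis2(d ~ g, data = dat, permutations = n_perm))
  perm_result("adonis", fit$F[1], fit$`Pr(>F)`[1], n_perm,
              effect_r2 = fit$R2[1])
}

#' Analysis of similarities (ANOSIM)
#'
#' `R = (mean between-group rank - mean within-group rank) / (M/2)` on the
#' ranked pairwise dissimilarities (average ranks for ties),
#' `M = N(N-1)/2`. Delegated to [vegan::anosim].
#'
#' @inheritParams adonis_test
#' @return a `perm_test_result` with the R statistic.
#' @export
anosim_test <- function(d, grouping, n_perm = 999, seed = NULL) {
  g <- check_grouping(d, grouping)
  fit <- with_seed_local(seed, vegan::anosim(d, g, permutations = n_perm))
  perm_result("anosim", fit$statistic, fit$signif, n_perm)
}

#' Multi-response permutation procedure (MRPP)
#'
#' `delta` is the group-size-weighted mean within-group dissimilarity;
#' small observed delta relative to permuted delta indicates cohesive
#' groups, with `P = (count(delta_perm <= delta_obs) + 1)/(n_perm + 1)`.
#' Delegated to [vegan::mrpp] (weights `n_g`).
#'
#' @inheritParams adonis_test
#' @return a `perm_test_result` with the delta statistic.
#' @export
mrpp_test <- function(d, grouping, n_perm = 999, seed = NULL) {
  g <- check_grouping(d, grouping)
  fit <- with_seed_local(seed, vegan::mrpp(d, g, permutations = n_perm))
  perm_result("mrpp", fit$delta, fit$Pvalue, n_perm)
}

#' Mantel test between two distance matrices
#'
#' Correlation of the two upper triangles, P by simultaneously permuting
#' rows/columns of one matrix. Delegated to [vegan::mantel].
#'
#' @param d1,d2 `dist` objects over the same samples (same labels/order).
#' @param method `"spearman"` (default) or `"pearson"`.
#' @inheritParams adonis_test
#' @return a `perm_test_result` with the r statistic.
#' @export
mantel_test <- function(d1, d2, method = c("spearman", "pearson"),
                        n_perm = 999, seed = NULL) {
  method <- match.arg(method)
  if (attr(d1, "Size") != attr(d2, "Size"))
    stop("distance matrices have different sizes")
  l1 <- attr(d1, "Labels"); l2 <- attr(d2, "Labels")
  if (!is.null(l1) && !is.null(l2) && !identical(l1, l2))
    stop("distance matrices are labelled by different samples")
  fit <- with_seed_local(seed,
    vegan::mantel(d1, d2, method = method, permutations = n_perm))
  perm_result("mantel", fit$statistic, fit$signif, n_perm)
}

#' Principal coordinates analysis (PCoA)
#'
#' Gower double-centering of `-0.5 * d^2` followed by eigendecomposition
#' ([stats::cmdscale] with `eig = TRUE`). Coordinates are eigenvectors
#' scaled by the square root of their (positive) eigenvalues, so their
#' Euclidean distances reproduce any Euclidean-embeddable input exactly.
#' Negative eigenvalues (possible for non-Euclidean dissimilarities such
#' as Bray-Curtis) are reported with a warning, not corrected.
#'
#' @param d a `dist` object or square symmetric matrix.
#' @return list `coordinates` (samples x axes), `eigenvalues`
#'   (non-increasing, all of them), `proportion_explained` (per positive
#'   eigenvalue, summing to 1 over positive axes).
#' @export
pcoa_ord <- function(d) {
  if (!inherits(d, "dist")) {
    m <- as.matrix(d)
    if (max(abs(m - t(m))) > 1e-8)
      stop("input distance matrix is not symmetric")
    d <- stats::as.dist(m)
  }
  n <- attr(d, "Size")
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- sort(fit$eig, decreasing = TRUE)
  if (any(eig < -1e-8))
    warning("negative eigenvalues present (non-Euclidean dissimilarity); ",
            "reported uncorrected")
  pos <- eig[eig > 1e-12]
  prop <- if (length(pos)) pos / sum(pos) else numeric(0)
  coords <- fit$points
  if (!is.null(coords) && ncol(coords) > 0)
    colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords, eigenvalues = eig,
       proportion_explained = prop)
}

#' Wilcoxon rank-sum test
#'
#' Average ranks for ties; exact enumeration when both samples are small
#' (`n_x + n_y <= 12`) and tie-free, otherwise the normal approximation
#' with continuity correction — via [stats::wilcox.test].
#'
#' @param x,y numeric vectors.
#' @param alternative `"two.sided"` (default), `"less"`, `"greater"`.
#' @param mode `"auto"` (size/tie rule above), `"exact"`, or
#'   `"normal_approx"`.
#' @return list `statistic` (Mann-Whitney W for `x`), `p_value`.
#' @export
wilcoxon_test <- function(x, y, alternative = "two.sided",
                          mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both samples must be nonempty")
  exact <- switch(mode,
                  auto = length(x) + length(y) <= 12 &&
                    !anyDuplicated(c(x, y)),
                  exact = TRUE,
                  normal_approx = FALSE)
  w <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = alternative, exact = exact, correct = TRUE))
  list(statistic = unname(w$statistic), p_value = w$p.value)
}

#' Abundance-occupancy regression
#'
#' OLS of `log10(mean abundance)` on occupancy (number of occupied
#' samples), across OTUs with nonzero totals; zero counts are included in
#' the mean. A positive slope is the classic abundance-occupancy
#' relationship: regionally abundant taxa are found at more sites.
#'
#' @param x an [otu_table].
#' @return list `slope`, `intercept`, `r_squared`, `p_value`, `n_otus`,
#'   and the per-OTU `data` used for the fit.
#' @export
abundance_occupancy <- function(x) {
  m <- x$counts
  keep <- rowSums(m) > 0
  df <- data.frame(otu_id = rownames(m)[keep],
                   mean_abundance = rowMeans(m[keep, , drop = FALSE]),
                   occupancy = rowSums(m[keep, , drop = FALSE] > 0),
                   stringsAsFactors = FALSE)
  if (nrow(df) < 3) stop("need at least 3 OTUs with nonzero totals")
  if (length(unique(df$occupancy)) < 2)
    stop("all OTUs have identical occupancy; slope undefined")
  fit <- stats::lm(log10(mean_abundance) ~ occupancy, data = df)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r_squared = s$r.squared,
       p_value = s$coefficients[2, 4],
       n_otus = nrow(df), data = df)
}

#' Per-group taxonomic composition
#'
#' Sums reads per taxon (at a chosen lineage rank) within each ecological
#' group and normalizes within group; taxa below `min_frac` of a group's
#' reads are collapsed into `"Other"` (taxa at exactly the threshold are
#' retained).
#'
#' @param x an [otu_table] with taxonomy.
#' @param groups named character vector `otu_id -> group label` (OTUs
#'   absent from `groups` are ignored).
#' @param rank 1-based lineage level (e.g. 2 = phylum in a
#'   domain-rooted lineage); lineages shorter than `rank` use their last
#'   field.
#' @param min_frac collapse threshold on within-group relative abundance
#'   (default 0.005).
#' @return data.frame `group`, `taxon`, `fraction`; fractions sum to 1
#'   within each group.
#' @export
taxon_composition <- function(x, groups, rank = 2, min_frac = 0.005) {
  if (is.null(x$taxonomy)) stop("table has no taxonomy")
  ids <- intersect(names(groups), otu_ids(x))
  if (!length(ids)) stop("no labelled OTUs present in the table")
  taxon_of <- function(id) {
    lin <- x$taxonomy[id]
    if (is.na(lin) || !nzchar(lin)) return("Unclassified")
    parts <- trimws(strsplit(lin, ";", fixed = TRUE)[[1]])
    parts[min(rank, length(parts))]
  }
  tx <- vapply(ids, taxon_of, character(1))
  reads <- rowSums(x$counts[ids, , drop = FALSE])
  out <- do.call(rbind, lapply(unique(groups[ids]), function(g) {
    sel <- groups[ids] == g
    agg <- tapply(reads[sel], tx[sel], sum)
    frac <- agg / sum(agg)
    small <- frac < min_frac
    if (any(small)) {
      frac <- c(frac[!small], Other = sum(frac[small]))
    }
    data.frame(group = g, taxon = names(frac),
               fraction = as.numeric(frac), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
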