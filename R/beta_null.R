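#' Bray-Curtis dissimilarity between samples
#'
#' `BC(x, y) = sum|x_i - y_i| / sum(x_i + y_i)` over OTUs. A pair of
#' all-zero samples is assigned 0 by convention (with a message), so the
#' matrix is always complete.
#'
#' @param x an [otu_table], a count/abundance matrix (OTUs x samples), or
#'   the output of [hellinger_transform()].
#' @return a `dist` object labelled by sample id.
#' @export
bray_curtis <- function(x) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (ncol(m) < 2) stop("need at least 2 samples")
  d <- suppressWarnings(vegan::vegdist(t(m), method = "bray"))
  if (anyNA(d)) {
    message("all-zero sample pair(s): Bray-Curtis set to 0 by convention")
    d[is.na(d)] <- 0
  }
  d
}

#' Abundance-based beta-null deviation for one ecological group
#'
#' The statistic separating deterministic from stochastic assembly.
#' The table is restricted to the group's OTUs; observed beta-diversity is
#' the pairwise Bray-Curtis matrix on counts. Null metacommunities are
#' then generated `n_null` times by redrawing each sample's group read
#' total from the regional relative abundance distribution (group row
#' totals summed over samples, normalized) — preserving local community
#' size and the regional SAD while randomizing composition. The deviation
#' for a sample pair is observed minus the per-pair mean of the null
#' dissimilarities; values near zero indicate assembly indistinguishable
#' from stochastic sampling of the regional pool, values away from zero
#' indicate deterministic (niche) structuring.
#'
#' @param x an [otu_table].
#' @param group_otus ids of the group's OTUs (`NULL` = whole table).
#' @param n_null number of null metacommunities (default 999).
#' @param seed integer seed.
#' @param replace draw null counts with replacement (multinomial, default)
#'   or without replacement by shuffling the pooled reads across samples
#'   (`FALSE`); at sequencing depths far below pool size the two agree.
#' @param group_label optional label stored on the result.
#' @return object of class `beta_null_result`: list with
#'   `group_label`, `observed_mean_beta`, `expected_mean_beta`,
#'   `deviation_mean`, `pairwise_deviations` (named per sample pair),
#'   `observed_pairwise`, `expected_pairwise`, `null_sd`, `n_null`,
#'   `sample_ids`.
#' @export
beta_null_deviation <- function(x, group_otus = NULL, n_null = 999,
                                seed = 1L, replace = TRUE,
                                group_label = "all") {
  if (!is.null(group_otus)) {
    if (length(group_otus) == 0) stop("empty group")
    x <- subset_otus(x, group_otus)
  }
  m <- x$counts
  totals <- colSums(m)
  if (any(totals == 0)) {
    warning("excluding sample(s) with zero group reads: ",
            paste(colnames(m)[totals == 0], collapse = ", "))
    m <- m[, totals > 0, drop = FALSE]
    totals <- colSums(m)
  }
  if (ncol(m) < 2) stop("need at least 2 samples with nonzero group reads")
  if (n_null < 1) stop("n_null must be >= 1")

  obs <- bray_curtis(m)
  pool <- rowSums(m)
  pi0 <- pool / sum(pool)
  np <- length(obs)

  res <- with_seed_local(seed, {
    acc <- numeric(np)
    iter_means <- numeric(n_null)
    for (b in seq_len(n_null)) {
      nullm <- if (replace) {
        vapply(totals, function(N) stats::rmultinom(1, N, pi0)[, 1],
               numeric(nrow(m)))
      } else {
        reads <- sample(rep.int(seq_len(nrow(m)), pool))
        idx <- c(0, cumsum(totals))
        vapply(seq_along(totals), function(j) {
          tabulate(reads[(idx[j] + 1):idx[j + 1]], nbins = nrow(m))
        }, numeric(nrow(m)))
      }
      d <- suppressWarnings(vegan::vegdist(t(nullm), method = "bray"))
      d[is.na(d)] <- 0
      acc <- acc + as.numeric(d)
      iter_means[b] <- mean(d)
    }
    list(expected = acc / n_null, iter_means = iter_means)
  })

  pair_names <- apply(utils::combn(colnames(m), 2), 2, paste,
                      collapse = "-")
  deviation <- as.numeric(obs) - res$expected
  structure(list(group_label = group_label,
                 observed_mean_beta = mean(obs),
                 expected_mean_beta = mean(res$expected),
                 deviation_mean = mean(deviation),
                 pairwise_deviations = stats::setNames(deviation,
                                                       pair_names),
                 observed_pairwise = stats::setNames(as.numeric(obs),
                                                     pair_names),
                 expected_pairwise = stats::setNames(res$expected,
                                                     pair_names),
                 null_sd = stats::sd(res$iter_means),
                 n_null = n_null,
                 sample_ids = colnames(m)),
            class = "beta_null_result")
}

#' @export
print.beta_null_result <- function(x, ...) {
  cat("beta-null deviation [", x$group_label, "]\n", sep = "")
  cat(sprintf("  observed mean beta: %.4f\n", x$observed_mean_beta))
  cat(sprintf("  expected mean beta: %.4f (%d nulls, sd %.4f)\n",
              x$expected_mean_beta, x$n_null, x$null_sd))
  cat(sprintf("  deviation mean:     %+.4f over %d sample pairs\n",
              x$deviation_mean, length(x$pairwise_deviations)))
  invisible(x)
}

#' Compare beta-null deviations of two groups
#'
#' Two-sided Wilcoxon rank-sum test on the two sets of pairwise
#' deviations; used to ask whether, e.g., the core group sits further from
#' its null expectation than the satellite group.
#'
#' @param a,b `beta_null_result` objects computed on the same sample set.
#' @return list `statistic`, `p_value`, `median_difference`
#'   (`median(a) - median(b)`), `sign` of that difference.
#' @export
compare_group_deviations <- function(a, b) {
  stopifnot(inherits(a, "beta_null_result"),
            inherits(b, "beta_null_result"))
  if (!setequal(a$sample_ids, b$sample_ids))
    stop("results were computed on different sample sets")
  w <- wilcoxon_test(a$pairwise_deviations, b$pairwise_deviations)
  md <- stats::median(a$pairwise_deviations) -
    stats::median(b$pairwise_deviations)
  list(statistic = w$statistic, p_value = w$p_value,
       median_difference = md, sign = sign(md))
}
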