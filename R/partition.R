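#' Index of dispersion of one OTU's counts
#'
#' Variance-to-mean based aggregation statistic across samples, including
#' zero counts in both moments. Two forms are provided:
#' \describe{
#'   \item{occurrence}{`(variance / mean) * occupancy` — the occurrence-weighted
#'     form used for the core/satellite split in activated-sludge surveys.}
#'   \item{classic}{`(n - 1) * variance / mean` — the textbook Poisson
#'     dispersion statistic, whose null distribution is exactly
#'     chi-squared with `n - 1` df.}
#' }
#' Both are referred to the same chi-squared band by [core_satellite()].
#'
#' @param x integer vector of per-sample counts (length >= 2).
#' @param mode `"occurrence"` (default) or `"classic"`.
#' @return the dispersion index `D` (>= 0), or `NA` for an all-zero row
#'   (untestable).
#' @export
dispersion_index <- function(x, mode = c("occurrence", "classic")) {
  mode <- match.arg(mode)
  if (length(x) < 2) stop("need counts from at least 2 samples")
  if (all(x == 0)) return(NA_real_)
  m <- mean(x)
  v <- stats::var(x)
  if (mode == "occurrence") (v / m) * sum(x > 0) else (length(x) - 1) * v / m
}

#' Core/satellite partition by chi-squared dispersion test
#'
#' Computes the index of dispersion for every OTU and compares it to the
#' 2.5/97.5% quantiles of the chi-squared distribution with
#' `n_samples - 1` degrees of freedom. OTUs inside the band are consistent
#' with random (Poisson) placement across sites; above the band they are
#' aggregated. Labels:
#' \itemize{
#'   \item `core`: over-dispersed (`D > chi2_upper`) AND occupancy at least
#'     `core_min_occupancy_frac` of samples — widely distributed and
#'     locally abundant.
#'   \item `satellite`: randomly distributed (inside the band), or
#'     over-dispersed but too restricted to qualify as core.
#'   \item `unclassified`: under-dispersed (`D < chi2_lower`) or untestable
#'     (all-zero row).
#' }
#'
#' @param x an [otu_table].
#' @param mode dispersion form, see [dispersion_index()].
#' @param alpha_band lower/upper chi-squared probabilities, default
#'   `c(0.025, 0.975)`.
#' @param core_min_occupancy_frac minimum fraction of samples a core OTU
#'   must occupy (default 0.5); guards against calling an OTU that is
#'   aggregated into a single site "widely distributed".
#' @return data.frame with one row per OTU: `otu_id`, `mean_abundance`,
#'   `variance`, `occupancy`, `dispersion_index`, `chi2_lower`,
#'   `chi2_upper`, `cs_label`.
#' @export
core_satellite <- function(x, mode = c("occurrence", "classic"),
                           alpha_band = c(0.025, 0.975),
                           core_min_occupancy_frac = 0.5) {
  mode <- match.arg(mode)
  if (length(alpha_band) != 2 || any(alpha_band <= 0) ||
      any(alpha_band >= 1) || diff(alpha_band) <= 0)
    stop("alpha_band must be increasing probabilities inside (0, 1)")
  m <- x$counts
  ns <- ncol(m)
  if (ns < 3)
    warning("fewer than 3 samples: the dispersion test has little power")
  df <- ns - 1
  lo <- stats::qchisq(alpha_band[1], df)
  hi <- stats::qchisq(alpha_band[2], df)
  means <- rowMeans(m)
  vars <- apply(m, 1, stats::var)
  occ <- rowSums(m > 0)
  D <- if (mode == "occurrence") (vars / means) * occ else df * vars / means
  D[occ == 0] <- NA_real_
  lab <- rep("unclassified", nrow(m))
  lab[!is.na(D) & D >= lo & D <= hi] <- "satellite"
  over <- !is.na(D) & D > hi
  lab[over & occ >= core_min_occupancy_frac * ns] <- "core"
  lab[over & occ < core_min_occupancy_frac * ns] <- "satellite"
  data.frame(otu_id = rownames(m), mean_abundance = means,
             variance = vars, occupancy = occ, dispersion_index = D,
             chi2_lower = lo, chi2_upper = hi, cs_label = lab,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Random contingency table with fixed margins (Patefield sampler)
#'
#' Draws one integer matrix with exactly the given row and column sums,
#' uniformly over the conditional (hypergeometric) distribution —
#' Patefield's (1981) algorithm as implemented by [stats::r2dtable].
#' This is the standard initializer for quasiswap randomization.
#'
#' @param row_sums,col_sums non-negative integer margins with equal totals.
#' @param seed integer seed (`NULL` uses the current RNG stream).
#' @return an integer matrix with the requested margins.
#' @export
patefield_sample <- function(row_sums, col_sums, seed = NULL) {
  if (any(row_sums < 0) || any(col_sums < 0))
    stop("margins must be non-negative")
  if (sum(row_sums) != sum(col_sums))
    stop("margin totals differ: rows sum to ", sum(row_sums),
         ", columns sum to ", sum(col_sums))
  # a single row or column forces the table outright (r2dtable needs >= 2)
  if (length(row_sums) == 1)
    return(matrix(as.integer(col_sums), nrow = 1))
  if (length(col_sums) == 1)
    return(matrix(as.integer(row_sums), ncol = 1))
  with_seed_local(seed, stats::r2dtable(1, row_sums, col_sums))[[1]]
}

#' Quasiswap null tables for a count matrix
#'
#' Generates null OTU tables that preserve, exactly, every row sum, every
#' column sum, and the number of non-zero cells (fill) of the observed
#' table: the count-matrix quasiswap scheme (Patefield start, then 2x2
#' swaps that annihilate surplus non-zero cells), delegated to vegan's C
#' implementation (`nullmodel(x, "quasiswap_count")`).
#'
#' @param x an [otu_table] or integer matrix (OTUs x samples).
#' @param n number of null tables.
#' @param seed integer seed; output is reproducible given `(x, n, seed)`.
#' @return integer array of dim `(n_otus, n_samples, n)`.
#' @export
quasiswap_null <- function(x, n = 1, seed = 1L) {
  m <- if (inherits(x, "otu_table")) x$counts else as.matrix(x)
  if (length(m) == 0) stop("empty table")
  sims <- stats::simulate(vegan::nullmodel(m, "quasiswap_count"),
                          nsim = n, seed = as.integer(seed))
  array(sims, dim = c(nrow(m), ncol(m), n),
        dimnames = list(rownames(m), colnames(m), NULL))
}

#' Generalist/specialist classification by occurrence null model
#'
#' For each of `n_null` quasiswap null tables the per-OTU niche metric is
#' recorded; an OTU whose observed metric exceeds the null's upper 95%
#' bound occurs more widely than its abundance warrants (habitat
#' generalist), and below the lower bound, less widely (habitat
#' specialist).
#'
#' @param x an [otu_table].
#' @param n_null number of null tables (>= 100; 1000 is the conventional
#'   choice).
#' @param ci lower/upper null quantiles, default `c(0.025, 0.975)`.
#' @param metric `"occurrence"` (number of samples with count > 0, the
#'   default) or `"levins_b"` (Levins' niche breadth
#'   `1 / sum(p_ij^2)` on the OTU's across-sample proportions).
#' @param ci_method `"percentile"` (empirical quantiles of the null,
#'   default) or `"normal"` (null mean +/- 1.96 sd).
#' @param seed integer seed.
#' @return data.frame with `otu_id`, `observed`, `null_mean`,
#'   `null_lower`, `null_upper`, `gs_label` in
#'   `{generalist, specialist, nonsignificant}`.
#' @export
generalist_specialist <- function(x, n_null = 1000, ci = c(0.025, 0.975),
                                  metric = c("occurrence", "levins_b"),
                                  ci_method = c("percentile", "normal"),
                                  seed = 1L) {
  metric <- match.arg(metric)
  ci_method <- match.arg(ci_method)
  if (n_null < 100) stop("n_null must be >= 100 for a stable 95% interval")
  m <- x$counts
  metric_fun <- if (metric == "occurrence") {
    function(mm) rowSums(mm > 0)
  } else {
    function(mm) {
      p <- mm / pmax(rowSums(mm), 1)
      b <- 1 / rowSums(p^2)
      b[rowSums(mm) == 0] <- NA_real_
      b
    }
  }
  obs <- metric_fun(m)
  sims <- quasiswap_null(m, n = n_null, seed = seed)
  nulls <- apply(sims, 3, metric_fun)          # n_otus x n_null
  if (is.null(dim(nulls))) nulls <- matrix(nulls, nrow = nrow(m))
  if (ci_method == "percentile") {
    qs <- apply(nulls, 1, stats::quantile, probs = ci, na.rm = TRUE,
                names = FALSE)
    lo <- qs[1, ]; hi <- qs[2, ]
  } else {
    mu <- rowMeans(nulls); sdv <- apply(nulls, 1, stats::sd)
    z <- stats::qnorm(ci[2])
    lo <- mu - z * sdv; hi <- mu + z * sdv
  }
  lab <- rep("nonsignificant", nrow(m))
  lab[!is.na(obs) & obs > hi] <- "generalist"
  lab[!is.na(obs) & obs < lo] <- "specialist"
  data.frame(otu_id = rownames(m), observed = obs,
             null_mean = rowMeans(nulls), null_lower = lo, null_upper = hi,
             gs_label = lab, row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine partition results into one label table
#'
#' @param cs output of [core_satellite()].
#' @param gs output of [generalist_specialist()] on the same table.
#' @return data.frame `otu_id`, `cs_label`, `gs_label`.
#' @export
assign_groups <- function(cs, gs) {
  if (!setequal(cs$otu_id, gs$otu_id))
    stop("core/satellite and generalist/specialist results cover ",
         "different OTU sets")
  merge(cs[, c("otu_id", "cs_label")], gs[, c("otu_id", "gs_label")],
        by = "otu_id", sort = FALSE)
}

group_members <- function(assignment) {
  list(core = assignment$otu_id[assignment$cs_label == "core"],
       satellite = assignment$otu_id[assignment$cs_label == "satellite"],
       generalist = assignment$otu_id[assignment$gs_label == "generalist"],
       specialist = assignment$otu_id[assignment$gs_label == "specialist"])
}

#' Per-group OTU counts and read fractions
#'
#' The summary behind statements like "core OTUs were 25.4% of OTUs but
#' 84.4% of reads".
#'
#' @param x the [otu_table] the labels were computed on.
#' @param assignment output of [assign_groups()].
#' @return data.frame `group`, `n_otus`, `pct_otus`, `reads`,
#'   `read_fraction` (percentages half-up rounded to 1 decimal).
#' @export
group_summary <- function(x, assignment) {
  total_otus <- n_otus(x)
  total_reads <- sum(x$counts)
  mem <- group_members(assignment)
  do.call(rbind, lapply(names(mem), function(g) {
    ids <- mem[[g]]
    reads <- if (length(ids)) sum(x$counts[ids, , drop = FALSE]) else 0
    data.frame(group = g, n_otus = length(ids),
               pct_otus = percentage(length(ids), total_otus),
               reads = reads,
               read_fraction = reads / total_reads,
               stringsAsFactors = FALSE)
  }))
}

#' Pairwise overlap between ecological groups
#'
#' Shared OTU counts and percentages for every pair among core, satellite,
#' generalist, specialist (the Venn-diagram numbers). Percentages are of
#' each group's own total, half-up rounded to one decimal.
#'
#' @param assignment output of [assign_groups()], or a list of id vectors
#'   named by group.
#' @return data.frame `group_a`, `group_b`, `n_a`, `n_b`, `shared`,
#'   `pct_of_a`, `pct_of_b`.
#' @export
group_overlap <- function(assignment) {
  mem <- if (is.data.frame(assignment)) group_members(assignment)
         else assignment
  gs <- names(mem)
  pairs <- utils::combn(gs, 2)
  do.call(rbind, apply(pairs, 2, function(p) {
    a <- mem[[p[1]]]; b <- mem[[p[2]]]
    sh <- length(intersect(a, b))
    data.frame(group_a = p[1], group_b = p[2],
               n_a = length(a), n_b = length(b), shared = sh,
               pct_of_a = if (length(a)) percentage(sh, length(a)) else NA,
               pct_of_b = if (length(b)) percentage(sh, length(b)) else NA,
               stringsAsFactors = FALSE)
  }))
}
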