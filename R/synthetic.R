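#' Parameterize a synthetic metacommunity
#'
#' Describes a simulated multi-plant survey: a regional lognormal species
#' abundance distribution (SAD) sampled multinomially into per-sample read
#' vectors, under one of two assembly modes. `neutral` draws every sample
#' from the same regional pool (purely stochastic assembly); `niche` gives
#' each OTU a Gaussian response to a 1-D environmental axis (deterministic
#' filtering), sharpening as `niche_sd` shrinks.
#'
#' Defaults mirror a 13-plant activated-sludge survey: 13 samples, 500
#' OTUs, 7000 reads per sample, lognormal SAD with log-sd 2 (several orders
#' of magnitude between dominant and rare taxa, which also produces the
#' characteristic positive abundance-occupancy relationship).
#'
#' @param n_samples number of samples (>= 2).
#' @param n_otus regional richness (>= 2).
#' @param reads_per_sample sequencing depth per sample.
#' @param sad_log_mean,sad_log_sd meanlog/sdlog of the regional lognormal
#'   SAD (the mean only sets scale and cancels on normalization).
#' @param assembly `"neutral"` or `"niche"`.
#' @param niche_sd Gaussian niche breadth on the environmental axis, same
#'   units as `env`; ignored under neutral assembly.
#' @param env per-sample environmental value; default an even gradient on
#'   `[0, 1]`.
#' @param seed integer seed; simulation is deterministic given the scenario.
#' @return a `metacommunity_scenario` list.
#' @export
metacommunity_scenario <- function(n_samples = 13, n_otus = 500,
                                   reads_per_sample = 7000,
                                   sad_log_mean = 0, sad_log_sd = 2,
                                   assembly = c("neutral", "niche"),
                                   niche_sd = 0.15, env = NULL,
                                   seed = 1L) {
  assembly <- match.arg(assembly)
  if (n_samples < 2) stop("invalid scenario field n_samples: need >= 2")
  if (n_otus < 2) stop("invalid scenario field n_otus: need >= 2")
  if (reads_per_sample < 1) stop("invalid scenario field reads_per_sample")
  if (niche_sd <= 0) stop("invalid scenario field niche_sd: must be > 0")
  env <- env %||% seq(0, 1, length.out = n_samples)
  if (length(env) != n_samples)
    stop("invalid scenario field env: length must equal n_samples")
  structure(list(n_samples = n_samples, n_otus = n_otus,
                 reads_per_sample = reads_per_sample,
                 sad_log_mean = sad_log_mean, sad_log_sd = sad_log_sd,
                 assembly = assembly, niche_sd = niche_sd, env = env,
                 seed = as.integer(seed)),
            class = "metacommunity_scenario")
}

#' Simulate an OTU table from a scenario
#'
#' Regional relative abundances `pi` are drawn from the lognormal SAD and
#' normalized. Under neutral assembly each sample is one multinomial draw
#' of `reads_per_sample` reads with probabilities `pi`. Under niche
#' assembly each OTU receives an optimum uniform over the environmental
#' range, and sample `j` uses probabilities proportional to
#' `pi_i * exp(-(env_j - mu_i)^2 / (2 * niche_sd^2))`, renormalized.
#'
#' Sample metadata carries the environmental value and a two-level
#' `location` factor (8 + 5 when `n_samples` is 13, mimicking a two-city
#' design; otherwise a near-even split) for use with the permutation tests.
#'
#' @param scenario a [metacommunity_scenario].
#' @return list with `table` (an [otu_table]), `regional_abundance`
#'   (normalized `pi`), and `optima` (niche mode only, else `NULL`).
#' @export
simulate_metacommunity <- function(scenario) {
  stopifnot(inherits(scenario, "metacommunity_scenario"))
  s <- scenario
  out <- with_seed_local(s$seed, {
    pi0 <- stats::rlnorm(s$n_otus, s$sad_log_mean, s$sad_log_sd)
    pi0 <- pi0 / sum(pi0)
    optima <- NULL
    if (s$assembly == "niche") {
      optima <- stats::runif(s$n_otus, min(s$env), max(s$env))
      counts <- vapply(seq_len(s$n_samples), function(j) {
        w <- pi0 * exp(-(s$env[j] - optima)^2 / (2 * s$niche_sd^2))
        stats::rmultinom(1, s$reads_per_sample, w / sum(w))[, 1]
      }, integer(s$n_otus))
    } else {
      counts <- stats::rmultinom(s$n_samples, s$reads_per_sample, pi0)
    }
    list(counts = counts, pi = pi0, optima = optima)
  })
  counts <- out$counts
  rownames(counts) <- sprintf("OTU_%04d", seq_len(s$n_otus))
  colnames(counts) <- sprintf("S%02d", seq_len(s$n_samples))
  n_a <- if (s$n_samples == 13) 8 else ceiling(s$n_samples / 2)
  meta <- data.frame(
    env = s$env,
    location = rep(c("Chongqing", "Xiamen"),
                   c(n_a, s$n_samples - n_a)),
    row.names = colnames(counts), stringsAsFactors = FALSE)
  list(table = otu_table(counts, metadata = meta),
       regional_abundance = stats::setNames(out$pi, rownames(counts)),
       optima = out$optima)
}

#' Plant ground-truth ecological groups into a table
#'
#' Appends OTU rows with known group identity so that partition recovery
#' can be scored against truth:
#' \describe{
#'   \item{core}{abundant in every sample but aggregated: per-sample Poisson
#'     means share a lognormal site effect, so variance across sites far
#'     exceeds the mean (widely distributed AND locally abundant).}
#'   \item{satellite}{a handful of reads concentrated in 1-2 random samples,
#'     zero elsewhere (rare and restricted).}
#'   \item{generalist}{a moderate read total spread evenly over all
#'     samples, so observed occurrence exceeds any marginal-preserving
#'     null's expectation for that row total.}
#'   \item{specialist}{a moderate read total confined to
#'     `specialist_samples`, so observed occurrence falls below the null.}
#' }
#'
#' @param table an [otu_table] background (typically a neutral simulation).
#' @param n_core,n_satellite,n_generalist,n_specialist how many OTUs of
#'   each kind to plant (any may be 0).
#' @param specialist_samples indices of the samples that planted
#'   specialists occupy (default the first two).
#' @param core_mean mean per-sample Poisson rate of planted core OTUs.
#' @param core_site_sd lognormal sd of the per-site rate multiplier.
#' @param satellite_reads approximate reads of a planted satellite OTU.
#' @param generalist_reads_per_sample reads per sample of planted
#'   generalists.
#' @param specialist_reads total reads of a planted specialist.
#' @param seed integer seed.
#' @return list with `table` (planted rows appended) and `truth` (named
#'   character vector `otu_id -> group` for the planted rows).
#' @export
plant_group_structure <- function(table, n_core = 20, n_satellite = 20,
                                  n_generalist = 20, n_specialist = 20,
                                  specialist_samples = 1:2,
                                  core_mean = 60, core_site_sd = 1,
                                  satellite_reads = 30,
                                  generalist_reads_per_sample = 1,
                                  specialist_reads = 100,
                                  seed = 1L) {
  ns <- n_samples(table)
  if (any(specialist_samples < 1 | specialist_samples > ns))
    stop("specialist_samples out of range")
  rows <- list(); truth <- character(0)
  add <- function(id, group, counts) {
    rows[[id]] <<- counts
    truth[id] <<- group
  }
  with_seed_local(seed, {
    for (i in seq_len(n_core)) {
      lam <- core_mean * stats::rlnorm(ns, 0, core_site_sd)
      x <- stats::rpois(ns, lam)
      x[x == 0] <- 1L  # core is by definition present everywhere
      add(sprintf("CORE_%03d", i), "core", x)
    }
    for (i in seq_len(n_satellite)) {
      x <- integer(ns)
      occ <- sample(ns, sample(1:2, 1))
      x[occ] <- pmax(1L, stats::rpois(length(occ), satellite_reads / 2))
      add(sprintf("SAT_%03d", i), "satellite", x)
    }
    for (i in seq_len(n_generalist)) {
      add(sprintf("GEN_%03d", i), "generalist",
          rep(as.integer(generalist_reads_per_sample), ns))
    }
    for (i in seq_len(n_specialist)) {
      x <- integer(ns)
      x[specialist_samples] <- stats::rmultinom(
        1, specialist_reads, rep(1, length(specialist_samples)))[, 1]
      add(sprintf("SPEC_%03d", i), "specialist", x)
    }
  })
  if (length(rows)) {
    planted <- do.call(rbind, rows)
    storage.mode(planted) <- "integer"
    colnames(planted) <- sample_ids(table)
    counts <- rbind(table$counts, planted)
  } else counts <- table$counts
  list(table = otu_table(counts, taxonomy = table$taxonomy,
                         metadata = table$metadata),
       truth = truth)
}
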