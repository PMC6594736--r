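test_that("dispersion index matches hand arithmetic in both modes", {
  # [4,0,0,0]: mean 1, unbiased variance 4, occupancy 1
  expect_equal(dispersion_index(c(4, 0, 0, 0), "occurrence"), 4)
  expect_equal(dispersion_index(c(4, 0, 0, 0), "classic"), 12)
  # [2,4]: mean 3, variance 2, occupancy 2
  expect_equal(dispersion_index(c(2, 4), "occurrence"), (2 / 3) * 2)
  # constant counts: zero variance in either mode
  expect_equal(dispersion_index(rep(7, 5), "occurrence"), 0)
  expect_equal(dispersion_index(rep(7, 5), "classic"), 0)
  # all-zero row is untestable, not an error
  expect_true(is.na(dispersion_index(c(0, 0, 0))))
  expect_error(dispersion_index(3), "at least 2 samples")
})

test_that("core_satellite labels follow the chi-squared band rules", {
  m <- rbind(
    aggregated  = c(100L, rep(1L, 12)),   # D far above the 97.5% quantile
    constant    = rep(5L, 13),            # D = 0: under-dispersed
    empty       = rep(0L, 13),            # untestable
    restricted  = c(40L, 2L, rep(0L, 11)) # aggregated but occupancy 2
  )
  colnames(m) <- paste0("S", 1:13)
  cs <- core_satellite(otu_table(m), mode = "occurrence")
  expect_equal(cs$chi2_upper[1], qchisq(0.975, 12), tolerance = 1e-10)
  expect_gt(cs$dispersion_index[cs$otu_id == "aggregated"], 23.337)
  labs <- setNames(cs$cs_label, cs$otu_id)
  expect_identical(unname(labs["aggregated"]), "core")
  expect_identical(unname(labs["constant"]), "unclassified")
  expect_identical(unname(labs["empty"]), "unclassified")
  # over-dispersed but too restricted for core -> satellite
  expect_identical(unname(labs["restricted"]), "satellite")
  expect_error(core_satellite(otu_table(m), alpha_band = c(0.9, 0.1)),
               "alpha_band")
})

test_that("classic dispersion test holds its nominal 5% level under Poisson", {
  set.seed(42)
  m <- matrix(rpois(4000 * 13, lambda = 20), ncol = 13)
  rownames(m) <- paste0("o", seq_len(nrow(m)))
  cs <- core_satellite(otu_table(m), mode = "classic")
  outside <- mean(cs$dispersion_index < cs$chi2_lower |
                    cs$dispersion_index > cs$chi2_upper)
  se <- sqrt(0.05 * 0.95 / 4000)
  expect_lt(abs(outside - 0.05), 3 * se + 0.002)
})

test_that("patefield sampler honors margins and degenerate cases", {
  for (s in 1:50) {
    tab <- patefield_sample(c(7, 3, 5), c(6, 9), seed = s)
    expect_equal(rowSums(tab), c(7, 3, 5))
    expect_equal(colSums(tab), c(6, 9))
  }
  expect_identical(patefield_sample(4, c(1, 3), seed = 1),
                   matrix(c(1L, 3L), 1))
  expect_error(patefield_sample(c(2, 2), c(3, 2)), "4.*5|totals differ")
  expect_identical(patefield_sample(c(2, 2), c(2, 2), seed = 8),
                   patefield_sample(c(2, 2), c(2, 2), seed = 8))
})

test_that("patefield draws follow the conditional hypergeometric law", {
  # margins (2,2)/(2,2): top-left cell is Hypergeometric(2,2,2) with
  # P(0)=1/6, P(1)=4/6, P(2)=1/6 (exhaustive enumeration of the three
  # feasible tables)
  n <- 12000
  draws <- withr::with_seed(99, stats::r2dtable(n, c(2, 2), c(2, 2)))
  x11 <- vapply(draws, function(t) t[1, 1], numeric(1))
  freq <- tabulate(x11 + 1, 3) / n
  expected <- c(1, 4, 1) / 6
  se <- sqrt(expected * (1 - expected) / n)
  expect_true(all(abs(freq - expected) < 3 * se))
})

test_that("quasiswap nulls preserve margins and fill on every draw", {
  set.seed(7)
  m <- matrix(rpois(50 * 13, 3) * rbinom(50 * 13, 1, 0.6), 50, 13)
  rownames(m) <- paste0("o", 1:50); colnames(m) <- paste0("s", 1:13)
  sims <- quasiswap_null(m, n = 200, seed = 1)
  ok <- apply(sims, 3, function(x)
    all(rowSums(x) == rowSums(m)) && all(colSums(x) == colSums(m)) &&
      sum(x > 0) == sum(m > 0))
  expect_true(all(ok))
  # deterministic given seed
  expect_identical(quasiswap_null(m, n = 3, seed = 5),
                   quasiswap_null(m, n = 3, seed = 5))
})

test_that("quasiswap on a 2x2 diagonal table yields only the two
           margin-and-fill-preserving tables", {
  m <- matrix(c(2L, 0L, 0L, 2L), 2, 2)
  sims <- quasiswap_null(m, n = 50, seed = 3)
  keys <- unique(apply(sims, 3, paste, collapse = ","))
  expect_true(all(keys %in% c("2,0,0,2", "0,2,2,0")))
  expect_length(keys, 2)  # both orientations appear in 50 draws
})

test_that("occurrence null recovers planted generalists and specialists", {
  bg <- neutral_background(n_otus = 150)
  pl <- plant_group_structure(bg, n_core = 0, n_satellite = 0,
                              n_generalist = 15, n_specialist = 15,
                              seed = 21)
  gs <- generalist_specialist(pl$table, n_null = 300, seed = 4)
  labs <- setNames(gs$gs_label, gs$otu_id)
  gen <- names(pl$truth)[pl$truth == "generalist"]
  spec <- names(pl$truth)[pl$truth == "specialist"]
  expect_gte(mean(labs[gen] == "generalist"), 0.9)
  expect_gte(mean(labs[spec] == "specialist"), 0.9)
  expect_error(generalist_specialist(pl$table, n_null = 50), "n_null")
})

test_that("an OTU pinned at its null occurrence is nonsignificant", {
  bg <- neutral_background(n_otus = 80)
  # the most abundant OTU occupies every sample in every null table:
  # observed equals the degenerate null interval -> nonsignificant
  gs <- generalist_specialist(bg, n_null = 150, seed = 2)
  top <- gs$otu_id[which.max(rowSums(bg$counts))]
  rec <- gs[gs$otu_id == top, ]
  expect_identical(rec$gs_label, "nonsignificant")
  expect_equal(rec$observed, rec$null_upper)
})

test_that("labels are invariant to row and column shuffling", {
  bg <- neutral_background(n_otus = 100)
  pl <- plant_group_structure(bg, n_core = 0, n_satellite = 0,
                              n_generalist = 8, n_specialist = 8,
                              seed = 31)
  gs1 <- generalist_specialist(pl$table, n_null = 200, seed = 6)
  perm <- pl$table$counts[sample(nrow(pl$table$counts)),
                          sample(ncol(pl$table$counts))]
  gs2 <- generalist_specialist(otu_table(perm), n_null = 200, seed = 6)
  planted <- names(pl$truth)
  l1 <- setNames(gs1$gs_label, gs1$otu_id)[planted]
  l2 <- setNames(gs2$gs_label, gs2$otu_id)[planted]
  expect_identical(l1, l2)
})

test_that("Levins niche breadth flags even spreaders as generalists", {
  bg <- neutral_background(n_otus = 100)
  pl <- plant_group_structure(bg, n_core = 0, n_satellite = 0,
                              n_generalist = 8, n_specialist = 8,
                              seed = 13)
  gs <- generalist_specialist(pl$table, n_null = 200,
                              metric = "levins_b", seed = 9)
  labs <- setNames(gs$gs_label, gs$otu_id)
  spec <- names(pl$truth)[pl$truth == "specialist"]
  expect_gte(mean(labs[spec] == "specialist"), 0.9)
  gen <- names(pl$truth)[pl$truth == "generalist"]
  expect_gte(mean(labs[gen] == "generalist"), 0.8)
})

test_that("group overlaps use half-up percentages of each group's size", {
  mem <- list(core = c("a", "b", "c"), satellite = character(0),
              generalist = c("b", "c", "d"), specialist = c("x"))
  ov <- group_overlap(mem)
  cg <- ov[ov$group_a == "core" & ov$group_b == "generalist", ]
  expect_identical(cg$shared, 2L)
  expect_equal(cg$pct_of_a, 66.7)
  expect_identical(ov[ov$group_a == "generalist" &
                        ov$group_b == "specialist", "shared"], 0L)
  # worked percentage on published core counts: 113 of 1388 -> 8.1
  expect_equal(percentage(113, 1388), 8.1)
  # half-up rounding, not banker's
  expect_equal(round_half_up(0.25, 1), 0.3)
})

test_that("assign_groups joins label tables and group_summary adds up", {
  bg <- neutral_background(n_otus = 60)
  cs <- core_satellite(bg)
  gs <- generalist_specialist(bg, n_null = 150, seed = 3)
  asg <- assign_groups(cs, gs)
  expect_identical(sort(asg$otu_id), sort(otu_ids(bg)))
  summ <- group_summary(bg, asg)
  expect_true(all(summ$read_fraction >= 0 & summ$read_fraction <= 1))
  expect_identical(summ$n_otus[summ$group == "core"],
                   sum(asg$cs_label == "core"))
  gs_bad <- gs[-1, ]
  expect_error(assign_groups(cs, gs_bad), "different OTU sets")
})
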