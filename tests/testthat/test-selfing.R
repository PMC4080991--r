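test_that("pollinium classification follows the any-difference rule", {
  mat <- c(L1 = "a/b", L2 = "c/c", L3 = "d/e", L4 = "f/f")
  expect_equal(classify_pollinium(mat, mat), "self")
  off <- mat; off["L3"] <- "d/d"
  expect_equal(classify_pollinium(mat, off), "outcross")
  partial <- c(L1 = "a/b", L2 = "c/c", L3 = NA, L4 = NA)
  expect_equal(classify_pollinium(mat, partial), "self")
  expect_error(classify_pollinium(mat, c(L1 = NA, L2 = NA, L3 = NA, L4 = NA)),
               "co-genotyped")
})

test_that("direct selfing rate counts per group and equals 1 - t_d", {
  mats <- mk_mlg(M1 = c(L1 = "a/a"), M2 = c(L1 = "b/b"))
  # M1: 3 self + 1 outcross; M2: 2 self
  pols <- mk_mlg(P1 = c(L1 = "a/a"), P2 = c(L1 = "a/a"),
                 P3 = c(L1 = "a/a"), P4 = c(L1 = "c/c"),
                 P5 = c(L1 = "b/b"), P6 = c(L1 = "b/b"))
  visits <- mk_visits(list(visit_id = "V3", taxon = "honeybee",
                           flowers_visited = 5, inflorescence_size = 30,
                           stem_size = 60, insertions = 2, removals = 0,
                           maternal_genotype_id = "M1", period = "diurnal"))
  visits$maternal_genotype_id <- c("M1", "M2", "M2", "M1")
  gt <- mk_genotable(mats, pols,
                     list(P1 = "V1", P2 = "V1", P3 = "V3", P4 = "V3",
                          P5 = "V2", P6 = "V2"))
  pd <- build_pollinium_data(visits, gt)
  by_taxon <- direct_selfing_rate(pd, "taxon")
  expect_equal(by_taxon$S_d[by_taxon$group == "honeybee"], 0.75)
  expect_equal(by_taxon$S_d[by_taxon$group == "bumblebee"], 1)
  expect_equal(by_taxon$n, c(2L, 4L))
  # independent per-record tally
  oracle <- tapply(pd$records$class == "self", pd$records$taxon, mean)
  expect_equal(by_taxon$S_d, as.numeric(oracle[by_taxon$group]))
})

test_that("grouped direct rates match an independent tally on a larger fixture", {
  set.seed(81)
  st <- simulate_study(simulation_config(seed = 81, control_count = 20L))
  pd <- build_pollinium_data(st$visits, st$genotypes)
  got <- direct_selfing_rate(pd, "taxon")
  rec <- pd$records[!is.na(pd$records$class) & !pd$records$is_control, ]
  for (tx in unique(rec$taxon)) {
    expect_equal(got$S_d[got$group == tx],
                 mean(rec$class[rec$taxon == tx] == "self"))
  }
})

test_that("alpha_direct is the weighted mean of per-locus products", {
  ft1 <- mk_freqs(list(L1 = c("a/a" = 0.5, "x/x" = 0.5),
                       L2 = c("b/b" = 0.5, "y/y" = 0.5)))
  single <- mk_mlg(P1 = c(L1 = "a/a", L2 = "b/b"))
  expect_equal(alpha_direct(single, ft1), 0.25)

  ft2 <- mk_freqs(list(L1 = c("a/a" = 0.5, "c/c" = 0.2, "e/e" = 0.3),
                       L2 = c("b/b" = 0.5, "d/d" = 0.2, "f/f" = 0.3)))
  two <- mk_mlg(P1 = c(L1 = "a/a", L2 = "b/b"),
                P2 = c(L1 = "c/c", L2 = "d/d"))
  expect_equal(alpha_direct(two, ft2), 0.5 * 0.25 + 0.5 * 0.04)
  expect_equal(alpha_direct(two, ft2, weights = c(1, 3)),
               0.25 * 0.25 + 0.75 * 0.04)
})

test_that("alpha_direct equals brute-force enumeration on small pools", {
  set.seed(82)
  for (rep in 1:5) {
    m <- t(replicate(sample(4:8, 1), vapply(1:4, function(k)
      canonical_call(sample(as.character(1:4), 1),
                     sample(as.character(1:4), 1)), character(1))))
    dimnames(m) <- list(paste0("p", seq_len(nrow(m))), paste0("L", 1:4))
    class(m) <- c("mlg_matrix", class(m))
    ft <- naive_frequencies(m)
    expect_equal(alpha_direct(m, ft), enumeration_alpha(m, m),
                 tolerance = 1e-12)
  }
})

test_that("partition_alpha does the mixture arithmetic and honours policy", {
  expect_equal(as.numeric(partition_alpha(0.3, 0.2, 1)), 0.3)
  expect_equal(as.numeric(partition_alpha(0.3, 0.2, 0.5)), 0.4)
  out <- partition_alpha(0.05, 0.2, 0.5)
  expect_equal(as.numeric(out), 0)
  expect_true(attr(out, "clamped"))
  expect_error(partition_alpha(0.05, 0.2, 0.5, policy = "error"),
               "alpha_dT > alpha_dc")
  expect_error(partition_alpha(0.3, 0.2, 0), "r_p")
})

test_that("visitor selfing partition reduces and clamps correctly", {
  expect_equal(as.numeric(visitor_selfing_direct(0.46, 0, 1)), 0.54)
  expect_equal(as.numeric(visitor_selfing_direct(0.4, 0.8, 0.5)), 1)
  high <- visitor_selfing_direct(0.9, 0.1, 0.5)
  expect_equal(as.numeric(high), 0)   # visitor outcrossing rate 1.7 -> clamp
  expect_true(attr(high, "clamped"))
  expect_error(visitor_selfing_direct(0.9, 0.1, 0.5, policy = "error"),
               "S_dp")
})

test_that("method-of-moments correction has the right limits", {
  expect_equal(as.numeric(mom_selfing(0.6, 0)), 0.6)
  expect_equal(as.numeric(mom_selfing(0.3, 0.3)), 0)
  expect_equal(as.numeric(mom_selfing(0.75, 0.5)), 0.5)
  expect_error(mom_selfing(0.5, 1), "alpha_dp >= 1")
  low <- mom_selfing(0.1, 0.3)
  expect_equal(as.numeric(low), 0)
  expect_true(attr(low, "clamped"))
})

test_that("correction never raises the selfing estimate", {
  set.seed(83)
  for (rep in 1:50) {
    s_dp <- runif(1)
    a <- runif(1, 0, 0.99)
    expect_lte(as.numeric(mom_selfing(s_dp, a)), s_dp + 1e-12)
  }
})

test_that("weak loci inflate the raw rate and the correction removes it", {
  # 500 pollinia, true S = 0.5, deliberately weak loci (alpha ~ 0.3):
  # raw S_d overestimates, S_mp recovers the truth
  set.seed(84)
  n <- 500
  p_match <- 0.3
  true_self <- runif(n) < 0.5
  observed_self <- true_self | (!true_self & runif(n) < p_match)
  s_d <- mean(observed_self)
  truth <- mean(true_self)
  expect_gt(s_d, truth + 0.05)
  s_mp <- as.numeric(mom_selfing(s_d, p_match))
  expect_lt(abs(s_mp - truth), 0.05)
})

test_that("per-genotype S_dp reconciles with grouped direct rates", {
  set.seed(85)
  st <- simulate_study(simulation_config(seed = 85, contamination_rate = 0,
                                         control_count = 5L))
  pd <- build_pollinium_data(st$visits, st$genotypes)
  tab <- suppressWarnings(per_genotype_sdp(pd, st$visits))
  # zero contamination: no control pollinia -> r_p = 1, S_dp = S_d per group
  cls <- pollmate:::maternal_class_of(pd)
  rec <- pd$records[!is.na(pd$records$class) & !pd$records$is_control, ]
  for (i in seq_len(nrow(tab))) {
    sel <- rec$taxon == tab$taxon[i] &
      cls[rec$maternal_genotype_id] == tab$maternal_genotype[i]
    expect_equal(tab$S_dp[i], mean(rec$class[sel] == "self"),
                 tolerance = 1e-12)
  }
  expect_equal(sum(tab$n_pollinia), nrow(rec))
})

test_that("per-genotype table averages display sizes over inflorescences", {
  mats <- mk_mlg(M1 = c(L1 = "a/a"), M2 = c(L1 = "a/a"))  # same genotype
  pols <- mk_mlg(P1 = c(L1 = "a/a"), P2 = c(L1 = "a/a"))
  visits <- mk_visits()
  visits$maternal_genotype_id <- c("M1", "M2", "M1")
  visits$inflorescence_size <- c(40, 60, 50)
  visits$taxon <- c("honeybee", "honeybee", "CONTROL")
  gt <- mk_genotable(mats, pols, list(P1 = "V1", P2 = "V2"))
  pd <- build_pollinium_data(visits, gt)
  tab <- suppressWarnings(per_genotype_sdp(pd, visits))
  expect_equal(nrow(tab), 1L)       # M1 and M2 collapse to one genotype
  expect_equal(tab$mean_inflorescence_size, 50)
  expect_equal(tab$S_dp, 1)
})

test_that("unclassifiable pollinia are excluded with a warning", {
  mats <- mk_mlg(M1 = c(L1 = "a/a", L2 = NA))
  pols <- mk_mlg(P1 = c(L1 = NA, L2 = "b/b"), P2 = c(L1 = "a/a", L2 = NA))
  visits <- mk_visits()
  visits$maternal_genotype_id <- "M1"
  gt <- mk_genotable(mats, pols, list(P1 = "V1", P2 = "V1"))
  expect_warning(pd <- build_pollinium_data(visits, gt), "co-genotyped")
  expect_equal(pd$n_unclassifiable, 1L)
  expect_equal(sum(!is.na(pd$records$class)), 1L)
})
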