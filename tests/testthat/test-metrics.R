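test_that("control means are per-flower averages over control inflorescences", {
  visits <- mk_visits()
  visits <- visits[visits$taxon == "CONTROL", , drop = FALSE]
  visits <- rbind(visits, visits)
  visits$visit_id <- c("C1", "C2")
  visits$inflorescence_size <- c(50, 50)
  visits$insertions <- c(1, 2)     # per-flower 0.02 and 0.04
  visits$removals <- c(0, 5)       # per-flower 0 and 0.1
  cm <- control_mean_rates(visits)
  expect_equal(unname(cm["insertion"]), 0.03)
  expect_equal(unname(cm["removal"]), 0.05)
  expect_warning(z <- control_mean_rates(mk_visits()[1:2, ]), "no control")
  expect_equal(unname(z), c(0, 0))
})

test_that("effectiveness subtracts the control mean and floors at zero", {
  visits <- mk_visits()
  visits$insertions <- c(2, 1, 1)       # V1: 2/40 = 0.05
  visits$inflorescence_size <- c(40, 60, 50)
  cm <- c(insertion = 0.02, removal = 0)
  eff <- effectiveness(visits, cm)
  expect_equal(eff$per_visit$pe_female[eff$per_visit$visit_id == "V1"],
               0.05 - 0.02)
  low <- visits
  low$insertions <- c(0, 0, 1)          # both visits below the control mean
  eff_low <- effectiveness(low, cm)
  expect_true(all(eff_low$per_visit$pe_female == 0))
})

test_that("per-taxon mean effectiveness equals a brute-force average", {
  set.seed(91)
  st <- simulate_study(simulation_config(seed = 91))
  cm <- control_mean_rates(st$visits)
  eff <- effectiveness(st$visits, cm)
  fv <- st$visits[st$visits$taxon != "CONTROL", ]
  for (tx in unique(fv$taxon)) {
    d <- fv[fv$taxon == tx, ]
    oracle <- mean(pmax(0, d$insertions / d$inflorescence_size -
                          cm[["insertion"]]))
    expect_equal(eff$per_taxon$pe_female[eff$per_taxon$taxon == tx], oracle)
  }
})

test_that("relative abundance normalises counts and applies effort weighting", {
  counts <- c(honeybee = 75, bumblebee = 271, lepidopteran = 43)
  visits <- data.frame(
    visit_id = paste0("V", seq_len(sum(counts))),
    taxon = rep(names(counts), counts),
    flowers_visited = 1, inflorescence_size = 10, stem_size = 20,
    insertions = 0, removals = 0,
    period = rep(c("diurnal", "diurnal", "nocturnal"), counts),
    stringsAsFactors = FALSE)
  ab <- relative_abundance(visits, effort_ratio = 1)
  expect_equal(round(as.numeric(ab[c("honeybee", "bumblebee",
                                     "lepidopteran")]), 3),
               c(0.193, 0.697, 0.111))
  expect_equal(sum(ab), 1, tolerance = 1e-9)

  one <- relative_abundance(visits[visits$taxon == "honeybee", ])
  expect_equal(unname(one), 1)

  # doubling the effort ratio doubles the nocturnal weight pre-normalisation
  ab2 <- relative_abundance(visits, effort_ratio = 2)
  w1 <- ab["lepidopteran"] / (1 - ab["lepidopteran"])
  w2 <- ab2["lepidopteran"] / (1 - ab2["lepidopteran"])
  expect_equal(unname(w2 / w1), 2, tolerance = 1e-9)
  expect_equal(sum(ab2), 1, tolerance = 1e-9)
  expect_error(relative_abundance(visits, effort_ratio = 0), "> 0")
})

test_that("importance is the effectiveness-abundance product", {
  expect_equal(importance(0, 0.7), 0)
  expect_equal(importance(0.04, 0.5), 0.02)
  pe <- runif(5)
  ab <- runif(5)
  expect_true(all(importance(pe, ab) <= pe))
})

test_that("SICPI identities and clamps hold", {
  expect_equal(sicpi_insertions(0.3, 0, 0.95), 0.3)
  expect_equal(sicpi_insertions(0.3, 0.5, 0), 0.3)
  expect_equal(sicpi_insertions(1, 0.88, 0.95), 1 - 0.88 * 0.95)
  expect_equal(as.numeric(sicpi_removals(0.1, 0.05, 0.88, 0.95)),
               0.1 - 0.05 * 0.88 * 0.95)
  expect_equal(as.numeric(sicpi_removals(0.3, 0, 0.5, 0.95)), 0.3)
  clamped <- sicpi_removals(0.01, 1, 1, 1)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
  # discounting never raises importance
  for (i in 1:20) {
    pi_i <- runif(1); s <- runif(1); si <- runif(1)
    expect_lte(sicpi_insertions(pi_i, s, si), pi_i)
    pi_r <- runif(1)
    expect_lte(as.numeric(sicpi_removals(pi_r, pi_i, s, si)), pi_r)
  }
})

test_that("behaviour summary reports means, SEs, and n = 1 as missing SE", {
  visits <- mk_visits(list(visit_id = "V9", taxon = "honeybee",
                           flowers_visited = 30, inflorescence_size = 40,
                           stem_size = 80, insertions = 4, removals = 1,
                           maternal_genotype_id = "M1", period = "diurnal"))
  bs <- summarize_behavior(visits)
  hb <- bs[bs$taxon == "honeybee", ]
  expect_equal(hb$flowers_visited_mean, mean(c(10, 30)))
  expect_equal(hb$flowers_visited_se, sd(c(10, 30)) / sqrt(2))
  bb <- bs[bs$taxon == "bumblebee", ]
  expect_true(is.na(bb$flowers_visited_se))
  expect_equal(bb$n_visits, 1L)
})

test_that("importance fit combines selfing bootstraps and keeps identities", {
  set.seed(92)
  st <- simulate_study(simulation_config(seed = 92))
  cfg <- run_config(n_bootstrap = 150, rng_seed = 9)
  fit <- fit_selfing(st$visits, st$genotypes, cfg)
  imp <- pollinator_importance(st$visits, selfing = fit, config = cfg)
  tab <- imp$table
  expect_true(all(tab$PE >= 0))
  expect_true(all(tab$PI <= tab$PE + 1e-12))
  expect_true(all(tab$SICPI <= tab$PI + 1e-12))
  ab <- imp$abundance
  expect_equal(sum(ab), 1, tolerance = 1e-9)
  # SICPI == PI when selfing is zero for every taxon
  imp0 <- pollinator_importance(st$visits, selfing = NULL, config = cfg)
  expect_equal(imp0$table$SICPI, imp0$table$PI, tolerance = 1e-12)
  # named-vector selfing input: point S_mp drives the point SICPI
  s_named <- c(honeybee = 0.5)
  imp_n <- pollinator_importance(st$visits, selfing = s_named, config = cfg)
  hb_f <- imp_n$table[imp_n$table$taxon == "honeybee" &
                        imp_n$table$fun == "female", ]
  expect_equal(hb_f$SICPI, hb_f$PI * (1 - 0.5 * imp_n$SI), tolerance = 1e-12)
})
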