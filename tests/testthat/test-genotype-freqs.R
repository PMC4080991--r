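test_that("canonical calls are unordered and missing-aware", {
  expect_equal(canonical_call("104", "98"), "104/98")
  expect_equal(canonical_call("98", "104"), "104/98")
  expect_true(is.na(canonical_call("104", NA)))
  expect_true(is.na(canonical_call("", "104")))
})

test_that("clone collapsing finds distinct multilocus genotypes", {
  g <- c(L1 = "a/a", L2 = "b/c", L3 = "d/d")
  all_same <- mk_mlg(s1 = g, s2 = g, s3 = g, s4 = g, s5 = g)
  expect_equal(nrow(collapse_clones(all_same)), 1L)
  expect_length(attr(collapse_clones(all_same), "members")[[1L]], 5L)

  distinct <- mk_mlg(
    s1 = c(L1 = "a/a", L2 = "b/b"), s2 = c(L1 = "a/b", L2 = "b/b"),
    s3 = c(L1 = "a/a", L2 = "b/c"), s4 = c(L1 = "c/c", L2 = "b/b"),
    s5 = c(L1 = "a/a", L2 = "c/c"))
  expect_equal(nrow(collapse_clones(distinct)), 5L)
})

test_that("leave-one-locus-out collapsing merges genotypes differing only there", {
  # 4 samples x 3 loci, distinct only at L3: hand enumeration says
  # 4 classes with all loci, 1 class when L3 is excluded
  m <- mk_mlg(
    s1 = c(L1 = "a/a", L2 = "b/b", L3 = "x/x"),
    s2 = c(L1 = "a/a", L2 = "b/b", L3 = "x/y"),
    s3 = c(L1 = "a/a", L2 = "b/b", L3 = "y/y"),
    s4 = c(L1 = "a/a", L2 = "b/b", L3 = "x/z"))
  expect_equal(nrow(collapse_clones(m)), 4L)
  expect_equal(nrow(collapse_clones(m, exclude_locus = "L3")), 1L)
  expect_error(collapse_clones(m, exclude_locus = "L9"), "not present")
})

test_that("missing-call samples join a class only when the match is unique", {
  m <- mk_mlg(
    full_a = c(L1 = "a/a", L2 = "b/b"),
    full_b = c(L1 = "c/c", L2 = "b/b"),
    part_u = c(L1 = "a/a", L2 = NA),        # unique match -> joins full_a
    part_m = c(L1 = NA, L2 = "b/b"))        # matches both -> own class
  reps <- collapse_clones(m)
  expect_equal(nrow(reps), 3L)
  members <- attr(reps, "members")
  expect_true(any(vapply(members, function(x)
    setequal(x, c("full_a", "part_u")), logical(1))))
  expect_true(any(vapply(members, function(x)
    identical(x, "part_m"), logical(1))))
})

test_that("naive frequencies count ramets directly", {
  m <- mk_mlg(s1 = c(L1 = "A/A"), s2 = c(L1 = "A/B"))
  ft <- naive_frequencies(m)
  expect_equal(unname(ft$loci$L1$allele[["A"]]), 0.75)
  expect_equal(unname(ft$loci$L1$allele[["B"]]), 0.25)
  expect_equal(unname(ft$loci$L1$genotype[["A/A"]]), 0.5)
  expect_equal(unname(ft$loci$L1$genotype[["A/B"]]), 0.5)
})

test_that("all-missing loci are omitted with a warning", {
  m <- mk_mlg(s1 = c(L1 = "A/A", L2 = NA), s2 = c(L1 = "A/B", L2 = NA))
  expect_warning(ft <- naive_frequencies(m), "no genotyped sample")
  expect_named(ft$loci, "L1")
})

test_that("naive frequencies match an independent tally on a random fixture", {
  set.seed(71)
  alleles <- as.character(101:106)
  m <- mk_mlg(loci = paste0("L", 1:3), s1 = c(L1 = "x", L2 = "x", L3 = "x"))
  raw <- replicate(50, {
    calls <- vapply(1:3, function(k)
      canonical_call(sample(alleles, 1), sample(alleles, 1)), character(1))
    calls
  })
  m <- t(raw)
  dimnames(m) <- list(paste0("s", 1:50), paste0("L", 1:3))
  class(m) <- c("mlg_matrix", class(m))
  ft <- naive_frequencies(m)
  for (loc in paste0("L", 1:3)) {
    oracle_g <- tally_frequencies(m, loc, "genotype")
    oracle_a <- tally_frequencies(m, loc, "allele")
    expect_equal(ft$loci[[loc]]$genotype[names(oracle_g)],
                 c(oracle_g)[names(oracle_g)], tolerance = 1e-12)
    expect_equal(ft$loci[[loc]]$allele[names(oracle_a)],
                 c(oracle_a)[names(oracle_a)], tolerance = 1e-12)
  }
})

test_that("round-robin counts genets, not ramets, for private alleles", {
  # one genet contributes 10 ramets with a private allele at L1; two other
  # distinct genets. Round-robin collapses the 10 ramets into one class,
  # so at L1 the private genotype has frequency 1/3, not 10/12.
  ramet <- c(L1 = "199/199", L2 = "b/b", L3 = "c/c")
  args <- c(
    stats::setNames(rep(list(ramet), 10), paste0("r", 1:10)),
    list(g2 = c(L1 = "101/101", L2 = "d/d", L3 = "e/e"),
         g3 = c(L1 = "103/105", L2 = "f/f", L3 = "g/g")))
  m <- do.call(mk_mlg, args)
  rr <- round_robin_frequencies(m)
  expect_equal(unname(rr$loci$L1$genotype[["199/199"]]), 1 / 3)
  expect_equal(unname(rr$loci$L1$allele[["199"]]), 1 / 3)
  nf <- naive_frequencies(m)
  expect_equal(unname(nf$loci$L1$genotype[["199/199"]]), 10 / 12)
})

test_that("round-robin equals naive when no multilocus genotype repeats", {
  set.seed(72)
  for (rep in 1:20) {
    repeat {
      m <- t(replicate(8, vapply(1:3, function(k)
        canonical_call(sample(as.character(101:112), 1),
                       sample(as.character(101:112), 1)), character(1))))
      dimnames(m) <- list(paste0("s", 1:8), paste0("L", 1:3))
      if (anyDuplicated(apply(m, 1, paste, collapse = "|")) == 0L) break
    }
    class(m) <- c("mlg_matrix", class(m))
    rr <- round_robin_frequencies(m)
    nf <- naive_frequencies(m)
    for (loc in colnames(m)) {
      expect_equal(sort(rr$loci[[loc]]$genotype), sort(nf$loci[[loc]]$genotype),
                   tolerance = 1e-12)
      expect_equal(sort(rr$loci[[loc]]$allele), sort(nf$loci[[loc]]$allele),
                   tolerance = 1e-12)
    }
  }
})

test_that("fully clonal datasets collapse to single classes at frequency 1", {
  g <- c(L1 = "a/a", L2 = "b/b")
  m <- mk_mlg(s1 = g, s2 = g, s3 = g)
  rr <- round_robin_frequencies(m)
  expect_equal(unname(rr$loci$L1$genotype[["a/a"]]), 1)
  expect_equal(unname(rr$loci$L2$genotype[["b/b"]]), 1)
})

test_that("round-robin refuses single-locus data", {
  m <- mk_mlg(s1 = c(L1 = "a/a"), s2 = c(L1 = "a/b"))
  expect_error(round_robin_frequencies(m), "naive_frequencies")
})

test_that("frequencies normalise to 1 per locus", {
  set.seed(73)
  st <- simulate_study(simulation_config(seed = 73, control_count = 10L))
  m <- mlg_matrix(st$genotypes, kind = "pollinium")
  for (ft in list(naive_frequencies(m), round_robin_frequencies(m))) {
    for (loc in names(ft$loci)) {
      expect_equal(sum(ft$loci[[loc]]$allele), 1, tolerance = 1e-9)
      expect_equal(sum(ft$loci[[loc]]$genotype), 1, tolerance = 1e-9)
      expect_true(all(ft$loci[[loc]]$allele >= 0 &
                        ft$loci[[loc]]$allele <= 1))
    }
  }
})

test_that("match probability is the per-locus product and zero for unseen", {
  ft <- mk_freqs(list(L1 = c("a/a" = 0.5, "b/b" = 0.5),
                      L2 = c("c/c" = 0.5, "d/d" = 0.5)))
  expect_equal(genotype_match_probability(ft, c(L1 = "a/a", L2 = "c/c")), 0.25)
  expect_equal(genotype_match_probability(ft, c(L1 = "z/z", L2 = "c/c")), 0)
  expect_error(genotype_match_probability(ft, c(L1 = NA, L2 = NA)),
               "no scored locus")
  expect_error(genotype_match_probability(ft, c(L9 = "a/a")), "L9")
})

test_that("match probability never increases as loci are added", {
  set.seed(74)
  st <- simulate_study(simulation_config(seed = 74, control_count = 10L))
  pool <- mlg_matrix(st$genotypes, kind = "pollinium")
  ft <- naive_frequencies(pool)
  g <- unclass(pool)[1L, ]
  probs <- vapply(seq_along(g), function(k)
    genotype_match_probability(ft, g[seq_len(k)]), numeric(1))
  expect_true(all(diff(probs) <= 1e-15))
})

test_that("match probability agrees with donor enumeration on a toy pool", {
  # 6-plant pool; oracle counts per-locus matches and multiplies
  set.seed(75)
  m <- t(replicate(6, vapply(1:3, function(k)
    canonical_call(sample(c("a", "b", "c"), 1),
                   sample(c("a", "b", "c"), 1)), character(1))))
  dimnames(m) <- list(paste0("p", 1:6), paste0("L", 1:3))
  class(m) <- c("mlg_matrix", class(m))
  ft <- naive_frequencies(m)
  for (i in 1:6) {
    g <- unclass(m)[i, ]
    oracle <- prod(vapply(names(g), function(loc)
      mean(unclass(m)[, loc] == g[[loc]]), numeric(1)))
    expect_equal(genotype_match_probability(ft, g), oracle,
                 tolerance = 1e-12)
  }
})
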