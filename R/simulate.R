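#' Visitor-taxon specification for the study simulator
#'
#' One entry per visitor taxon: how often it visits, how it behaves on an
#' inflorescence, and its selfing model. Per visit, flowers visited is drawn
#' from a negative binomial (mean \code{flowers_mean}, dispersion
#' \code{flowers_size}) floored at 1; insertions and removals are binomial
#' per flower visited and capped at five per open flower (five stigmatic
#' slits / pollinaria per flower). Each inserted pollinium is self with
#' probability \code{plogis(beta0 + beta1 (I - I0) + beta2 (Z - Z0))} where
#' I and Z are inflorescence and stem size and I0/Z0 centring constants from
#' the population config - a logit-linear display-size effect mirroring how
#' the exported per-genotype table is analysed downstream.
#'
#' @param name taxon label.
#' @param visit_count number of observed visits.
#' @param flowers_mean,flowers_size negative-binomial parameters for flowers
#'   visited per visit.
#' @param p_insert,p_remove per-flower-visited insertion and removal
#'   probabilities.
#' @param beta0,beta1,beta2 selfing-model coefficients (logit scale;
#'   intercept, inflorescence-size and stem-size slopes).
#' @param period \code{"diurnal"} or \code{"nocturnal"}.
#' @return a \code{taxon_spec} list.
#' @export
taxon_spec <- function(name, visit_count, flowers_mean, flowers_size = 2,
                       p_insert, p_remove, beta0, beta1 = 0.01,
                       beta2 = 0.002, period = "diurnal") {
  stopifnot(visit_count >= 1, p_insert >= 0, p_insert <= 1,
            p_remove >= 0, p_remove <= 1,
            period %in% c("diurnal", "nocturnal"))
  structure(list(name = name, visit_count = as.integer(visit_count),
                 flowers_mean = flowers_mean, flowers_size = flowers_size,
                 p_insert = p_insert, p_remove = p_remove,
                 beta0 = beta0, beta1 = beta1, beta2 = beta2,
                 period = period), class = "taxon_spec")
}

default_taxa <- function() {
  # visit counts, behaviour means and selfing levels patterned after a
  # milkweed visitor assemblage: an efficient, high-selfing honeybee, an
  # abundant low-deposition bumblebee, and sparse nocturnal lepidopterans
  list(
    taxon_spec("honeybee", visit_count = 75, flowers_mean = 22,
               p_insert = 0.12, p_remove = 0.38,
               beta0 = stats::qlogis(0.85), period = "diurnal"),
    taxon_spec("bumblebee", visit_count = 271, flowers_mean = 48,
               p_insert = 0.011, p_remove = 0.055,
               beta0 = stats::qlogis(0.5), period = "diurnal"),
    taxon_spec("lepidopteran", visit_count = 43, flowers_mean = 6,
               p_insert = 0.24, p_remove = 0.65,
               beta0 = stats::qlogis(0.4), period = "nocturnal"))
}

#' Configuration of a synthetic pollination study
#'
#' Defines the generative model end to end: a clonal population (few genets,
#' many ramets), codominant microsatellite genotypes, taxon-specific
#' visitation and pollinium movement, display-size-dependent selfing, and
#' low-rate through-bag contamination measured on bagged controls. The same
#' contamination process also deposits pollinia on focal inflorescences
#' before their observed visit, which is exactly what the control partition
#' in [fit_selfing()] corrects for.
#'
#' @param n_genets number of genetic individuals (default 20).
#' @param ramet_mean mean ramets (stems) per genet, geometric distribution
#'   (default 10).
#' @param n_loci microsatellite loci (default 4).
#' @param alleles_per_locus alleles per locus (default 6; >= 2).
#' @param allele_freq \code{"dirichlet"} (default, symmetric concentration
#'   \code{dirichlet_theta}) or \code{"uniform"} allele frequencies.
#' @param dirichlet_theta Dirichlet concentration (default 0.5: a skewed
#'   spectrum whose most-common-genotype frequency per locus lands around
#'   0.5-0.65, typical of microsatellite panels in clonal plant
#'   populations).
#' @param taxa list of [taxon_spec()]s (default: a three-taxon milkweed
#'   assemblage).
#' @param inflorescence_range integer range of open flowers per focal
#'   inflorescence (default 15-150).
#' @param stem_extra_mean mean additional open flowers on the rest of the
#'   stem (Poisson; default 100), so stem size >= inflorescence size.
#' @param control_count bagged control inflorescences (default 100).
#' @param contamination_rate expected through-bag insertions per bagged
#'   inflorescence (Poisson; default 0.3).
#' @param control_beta0 logit-scale selfing intercept of through-bag
#'   insertions (display-size slopes are zero for bagged inflorescences);
#'   default: mean of the taxa's intercepts.
#' @param missingness per locus-call probability of a failed genotype
#'   (default 0.05).
#' @param donor_draw \code{"genet"} (default: outcross donors uniform over
#'   the other genets) or \code{"ramet"} (donors uniform over all other
#'   stems; draws landing in the focal genet count as self, modelling
#'   geitonogamous carryover within spatially aggregated clones).
#' @param seed integer seed used by [simulate_study()].
#' @return object of class \code{"simulation_config"}.
#' @export
simulation_config <- function(n_genets = 20L, ramet_mean = 10,
                              n_loci = 4L, alleles_per_locus = 6L,
                              allele_freq = c("dirichlet", "uniform"),
                              dirichlet_theta = 0.5,
                              taxa = default_taxa(),
                              inflorescence_range = c(15L, 150L),
                              stem_extra_mean = 100,
                              control_count = 100L,
                              contamination_rate = 0.3,
                              control_beta0 = NULL,
                              missingness = 0.05,
                              donor_draw = c("genet", "ramet"),
                              seed = NULL) {
  allele_freq <- match.arg(allele_freq)
  donor_draw <- match.arg(donor_draw)
  stopifnot(n_genets >= 1, ramet_mean >= 1, n_loci >= 1,
            alleles_per_locus >= 2,
            length(inflorescence_range) == 2L,
            inflorescence_range[1L] >= 1,
            inflorescence_range[2L] >= inflorescence_range[1L],
            control_count >= 0, contamination_rate >= 0,
            missingness >= 0, missingness < 1)
  if (is.null(control_beta0))
    control_beta0 <- mean(vapply(taxa, `[[`, numeric(1), "beta0"))
  structure(list(n_genets = as.integer(n_genets), ramet_mean = ramet_mean,
                 n_loci = as.integer(n_loci),
                 alleles_per_locus = as.integer(alleles_per_locus),
                 allele_freq = allele_freq,
                 dirichlet_theta = dirichlet_theta, taxa = taxa,
                 inflorescence_range = as.integer(inflorescence_range),
                 stem_extra_mean = stem_extra_mean,
                 control_count = as.integer(control_count),
                 contamination_rate = contamination_rate,
                 control_beta0 = control_beta0,
                 missingness = missingness, donor_draw = donor_draw,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "simulation_config")
}

#' Simulate the clonal population
#'
#' Draws per-locus allele frequencies, one multilocus genotype per genet
#' (two independent allele draws per locus; by chance two genets may share
#' a genotype), and a geometric number of ramets per genet. Genotypes here
#' are the true calls; genotyping missingness is applied later, when tables
#' are emitted.
#'
#' @param config a [simulation_config()].
#' @return list with \code{genets} (true [mlg_matrix()], one row per
#'   genet), \code{stems} (data frame \code{stem_id}, \code{genet_id}),
#'   and \code{allele_freqs} (per-locus numeric vectors).
#' @export
simulate_population <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  loci <- paste0("L", seq_len(config$n_loci))
  alleles <- sprintf("%03d", seq_len(config$alleles_per_locus) + 100L)
  freqs <- lapply(loci, function(l) {
    f <- if (config$allele_freq == "dirichlet") {
      g <- stats::rgamma(length(alleles), shape = config$dirichlet_theta)
      g / sum(g)
    } else rep(1 / length(alleles), length(alleles))
    stats::setNames(f, alleles)
  })
  names(freqs) <- loci
  m <- matrix(NA_character_, config$n_genets, length(loci),
              dimnames = list(paste0("G", sprintf("%03d",
                                                  seq_len(config$n_genets))),
                              loci))
  for (l in loci) {
    a1 <- sample(alleles, config$n_genets, replace = TRUE, prob = freqs[[l]])
    a2 <- sample(alleles, config$n_genets, replace = TRUE, prob = freqs[[l]])
    m[, l] <- canonical_call(a1, a2)
  }
  class(m) <- c("mlg_matrix", class(m))
  n_ramets <- 1L + stats::rgeom(config$n_genets,
                                prob = 1 / config$ramet_mean)
  stems <- data.frame(
    stem_id = paste0("S", sprintf("%04d", seq_len(sum(n_ramets)))),
    genet_id = rep(rownames(m), n_ramets),
    stringsAsFactors = FALSE)
  list(genets = m, stems = stems, allele_freqs = freqs)
}

# draw display sizes for one inflorescence
draw_display <- function(config) {
  infl <- sample(seq(config$inflorescence_range[1L],
                     config$inflorescence_range[2L]), 1L)
  c(infl = infl, stem = infl + stats::rpois(1L, config$stem_extra_mean))
}

# selfing probability of one inserted pollinium
self_prob <- function(spec, infl, stem, config) {
  i0 <- mean(config$inflorescence_range)
  z0 <- i0 + config$stem_extra_mean
  stats::plogis(spec$beta0 + spec$beta1 * (infl - i0) +
                  spec$beta2 * (stem - z0))
}

# donor genet for one pollinium given its self/outcross label
draw_donor <- function(self, focal_genet, population, config) {
  if (self) return(focal_genet)
  if (config$donor_draw == "ramet") {
    others <- population$stems$genet_id[
      population$stems$genet_id != focal_genet]
    if (length(others) == 0L)
      stop("single genet population cannot supply an outcross donor")
    sample(others, 1L)
  } else {
    others <- setdiff(rownames(population$genets), focal_genet)
    if (length(others) == 0L)
      stop("single genet population cannot supply an outcross donor")
    sample(others, 1L)
  }
}

#' Simulate observed visits and their inserted pollinia
#'
#' For each taxon in the config, draws its visits: a random focal stem,
#' display sizes, flowers visited, and binomial insertions and removals
#' capped at five per flower. Each focal inflorescence additionally receives
#' Poisson through-bag insertions (the bags are only opened for the watched
#' visit), generated by the same contamination process as the controls.
#' Every inserted pollinium gets a true origin (visitor or bag), a true
#' self/outcross label from the logit display-size model, and a donor
#' genotype (the focal genet if self). Under \code{donor_draw = "ramet"} an
#' outcross draw landing in the focal genet is relabelled self
#' (geitonogamy by clone carryover).
#'
#' @param population from [simulate_population()].
#' @param config a [simulation_config()].
#' @return list with \code{visits} (visit table rows), \code{pollinia}
#'   (data frame: \code{pollinium_id}, \code{visit_id}, \code{donor_genet},
#'   \code{true_self}, \code{origin}).
#' @export
simulate_visits <- function(population, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (nrow(population$stems) == 0L) stop("empty population")
  visits <- list()
  pollinia <- list()
  vno <- 0L
  pno <- 0L
  for (spec in config$taxa) {
    for (k in seq_len(spec$visit_count)) {
      vno <- vno + 1L
      vid <- paste0("V", sprintf("%04d", vno))
      stem_row <- population$stems[sample.int(nrow(population$stems), 1L), ]
      disp <- draw_display(config)
      flowers <- max(1L, stats::rnbinom(1L, size = spec$flowers_size,
                                        mu = spec$flowers_mean))
      cap <- 5L * disp[["infl"]]
      ins_visitor <- min(stats::rbinom(1L, flowers, spec$p_insert), cap)
      ins_bag <- stats::rpois(1L, config$contamination_rate)
      removals <- min(stats::rbinom(1L, flowers, spec$p_remove), cap)
      ins_total <- min(ins_visitor + ins_bag, cap)
      ins_bag <- ins_total - ins_visitor          # cap eats bag excess
      p_self_v <- self_prob(spec, disp[["infl"]], disp[["stem"]], config)
      p_self_c <- stats::plogis(config$control_beta0)
      for (j in seq_len(ins_total)) {
        pno <- pno + 1L
        origin <- if (j <= ins_visitor) "visitor" else "bag"
        self <- stats::runif(1L) <
          (if (origin == "visitor") p_self_v else p_self_c)
        donor <- draw_donor(self, stem_row$genet_id, population, config)
        if (!self && donor == stem_row$genet_id) self <- TRUE  # ramet mode
        pollinia[[pno]] <- data.frame(
          pollinium_id = paste0("P", sprintf("%05d", pno)),
          visit_id = vid, donor_genet = donor,
          true_self = self, origin = origin, stringsAsFactors = FALSE)
      }
      visits[[vno]] <- data.frame(
        visit_id = vid, taxon = spec$name, flowers_visited = flowers,
        inflorescence_size = disp[["infl"]], stem_size = disp[["stem"]],
        insertions = ins_total, removals = removals,
        maternal_genotype_id = stem_row$stem_id, period = spec$period,
        stringsAsFactors = FALSE)
    }
  }
  list(visits = do.call(rbind, c(visits, make.row.names = FALSE)),
       pollinia = if (pno > 0L)
         do.call(rbind, c(pollinia, make.row.names = FALSE))
       else data.frame(pollinium_id = character(0), visit_id = character(0),
                       donor_genet = character(0), true_self = logical(0),
                       origin = character(0)))
}

#' Simulate bagged control inflorescences
#'
#' Controls never have their bags removed: \code{flowers_visited = 0},
#' \code{taxon = "CONTROL"}, and Poisson(\code{contamination_rate})
#' through-bag insertions whose selfing follows the control model
#' (display-size slopes zero). Removals through a bag are rare and set
#' to 0.
#'
#' @inheritParams simulate_visits
#' @return same shape as [simulate_visits()].
#' @export
simulate_controls <- function(population, config) {
  stopifnot(inherits(config, "simulation_config"))
  if (config$control_count == 0L)
    return(list(visits = NULL, pollinia = NULL))
  visits <- list()
  pollinia <- list()
  pno <- 0L
  p_self <- stats::plogis(config$control_beta0)
  for (k in seq_len(config$control_count)) {
    vid <- paste0("C", sprintf("%04d", k))
    stem_row <- population$stems[sample.int(nrow(population$stems), 1L), ]
    disp <- draw_display(config)
    ins <- min(stats::rpois(1L, config$contamination_rate),
               5L * disp[["infl"]])
    for (j in seq_len(ins)) {
      pno <- pno + 1L
      self <- stats::runif(1L) < p_self
      donor <- draw_donor(self, stem_row$genet_id, population, config)
      if (!self && donor == stem_row$genet_id) self <- TRUE
      pollinia[[pno]] <- data.frame(
        pollinium_id = paste0("Q", sprintf("%05d", pno)),
        visit_id = vid, donor_genet = donor, true_self = self,
        origin = "bag", stringsAsFactors = FALSE)
    }
    visits[[k]] <- data.frame(
      visit_id = vid, taxon = "CONTROL", flowers_visited = 0L,
      inflorescence_size = disp[["infl"]], stem_size = disp[["stem"]],
      insertions = ins, removals = 0L,
      maternal_genotype_id = stem_row$stem_id, period = "diurnal",
      stringsAsFactors = FALSE)
  }
  list(visits = do.call(rbind, c(visits, make.row.names = FALSE)),
       pollinia = if (pno > 0L)
         do.call(rbind, c(pollinia, make.row.names = FALSE)) else NULL)
}

#' Simulate a complete study with attached ground truth
#'
#' Orchestrates [simulate_population()], [simulate_visits()] and
#' [simulate_controls()] under one seed and emits exactly the two tables
#' the pipeline reads - the visit table and the long genotype table (with
#' per-call missingness applied) - plus the truth needed for parameter
#' recovery: per-pollinium origin and self labels, per-taxon true
#' visitor-only selfing rates, and the exhaustive chance-match probability
#' (for each inserted pollinium, the fraction of genets whose true
#' multilocus genotype is identical to the donor's, averaged per taxon).
#'
#' @param config a [simulation_config()].
#' @param seed overrides \code{config$seed} when given.
#' @return list of class \code{"sim_study"}: \code{visits},
#'   \code{genotypes}, \code{truth} (list: \code{pollinia},
#'   \code{per_taxon}, \code{genet_of_stem}), \code{population},
#'   \code{config}.
#' @export
simulate_study <- function(config = simulation_config(), seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(config$seed)) set.seed(config$seed)

  population <- simulate_population(config)
  obs <- simulate_visits(population, config)
  ctl <- simulate_controls(population, config)
  visits <- rbind(obs$visits, ctl$visits)
  pollinia <- rbind(obs$pollinia, ctl$pollinia)

  # genotype table: maternal stems that appear in the visit table, plus
  # every inserted pollinium (its donor genet's true genotype), with
  # per-call missingness
  loci <- colnames(population$genets)
  stems_used <- unique(visits$maternal_genotype_id)
  genet_of <- stats::setNames(population$stems$genet_id,
                              population$stems$stem_id)
  rows <- list()
  emit <- function(sample_id, kind, genotype, visit_id = NA_character_) {
    a <- do.call(rbind, strsplit(genotype, "/", fixed = TRUE))
    drop <- stats::runif(length(loci)) < config$missingness
    data.frame(sample_id = sample_id, sample_kind = kind, locus = loci,
               allele1 = ifelse(drop, NA_character_, a[, 1L]),
               allele2 = ifelse(drop, NA_character_, a[, 2L]),
               visit_id = visit_id, stringsAsFactors = FALSE)
  }
  for (s in stems_used)
    rows[[length(rows) + 1L]] <-
      emit(s, "maternal", unclass(population$genets)[genet_of[[s]], ])
  if (!is.null(pollinia) && nrow(pollinia) > 0L)
    for (i in seq_len(nrow(pollinia)))
      rows[[length(rows) + 1L]] <-
        emit(pollinia$pollinium_id[i], "pollinium",
             unclass(population$genets)[pollinia$donor_genet[i], ],
             pollinia$visit_id[i])
  genotypes <- do.call(rbind, c(rows, make.row.names = FALSE))

  truth <- sim_truth(visits, pollinia, population)
  structure(list(visits = visits, genotypes = genotypes, truth = truth,
                 population = population, config = config),
            class = "sim_study")
}

sim_truth <- function(visits, pollinia, population) {
  genets <- unclass(population$genets)
  taxon_of_visit <- stats::setNames(visits$taxon, visits$visit_id)
  if (is.null(pollinia) || nrow(pollinia) == 0L)
    return(list(pollinia = pollinia, per_taxon = NULL,
                genet_of_stem = stats::setNames(population$stems$genet_id,
                                                population$stems$stem_id)))
  pollinia$taxon <- unname(taxon_of_visit[pollinia$visit_id])
  # exhaustive chance-match probability: per locus, the share of genets
  # carrying the donor's single-locus genotype, multiplied across loci
  donor_rows <- match(pollinia$donor_genet, rownames(genets))
  pollinia$match_share <- vapply(donor_rows, function(r) {
    prod(vapply(seq_len(ncol(genets)),
                function(k) mean(genets[, k] == genets[r, k]), numeric(1)))
  }, numeric(1))
  vis <- pollinia[pollinia$origin == "visitor", , drop = FALSE]
  per_taxon <- do.call(rbind, c(lapply(split(vis, vis$taxon), function(d)
    data.frame(taxon = d$taxon[1L], n_pollinia = nrow(d),
               true_S_visitor = mean(d$true_self),
               alpha_true = mean(d$match_share),
               stringsAsFactors = FALSE)), make.row.names = FALSE))
  list(pollinia = pollinia, per_taxon = per_taxon,
       genet_of_stem = stats::setNames(population$stems$genet_id,
                                       population$stems$stem_id))
}

#' @export
print.sim_study <- function(x, ...) {
  cat("sim_study:", nrow(x$visits), "visit rows (",
      sum(x$visits$taxon == "CONTROL"), "controls ),",
      sum(x$genotypes$sample_kind == "pollinium") /
        length(unique(x$genotypes$locus)), "genotyped pollinia,",
      x$config$n_genets, "genets\n")
  invisible(x)
}
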