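#' Mean through-bag insertion and removal rates on control inflorescences
#'
#' Controls are inflorescences bagged for the whole season; pollinia found
#' on them arrived through the bags. Rates are per flower (counts divided by
#' inflorescence size) and averaged over control inflorescences.
#'
#' @param visits visit table; control rows have \code{taxon = "CONTROL"}.
#' @return named numeric vector \code{c(insertion = , removal = )}; zeros
#'   with a warning when there are no controls.
#' @export
control_mean_rates <- function(visits) {
  cv <- visits[visits$taxon == "CONTROL", , drop = FALSE]
  if (nrow(cv) == 0L) {
    warning("no control inflorescences: control-corrected effectiveness ",
            "assumes zero through-bag rates")
    return(c(insertion = 0, removal = 0))
  }
  c(insertion = mean(cv$insertions / cv$inflorescence_size),
    removal = mean(cv$removals / cv$inflorescence_size))
}

#' Pollinator effectiveness per visit and per taxon
#'
#' Effectiveness for female function is pollinium insertions per
#' focal-inflorescence flower, and for male function removals per flower,
#' each corrected by subtracting the mean per-flower control rate; negative
#' values are set to zero. Computed per visit, then averaged per taxon (the
#' per-visit vector is what the permutation tests operate on).
#'
#' @param visits visit table (control rows are excluded from the output).
#' @param control_means per-flower control rates, as from
#'   [control_mean_rates()]; computed from \code{visits} when omitted.
#' @return list with \code{per_visit} (columns \code{visit_id},
#'   \code{taxon}, \code{pe_female}, \code{pe_male}) and \code{per_taxon}
#'   (mean PE per taxon and function, with n).
#' @export
effectiveness <- function(visits, control_means = NULL) {
  if (is.null(control_means)) control_means <- control_mean_rates(visits)
  fv <- visits[visits$taxon != "CONTROL", , drop = FALSE]
  if (nrow(fv) == 0L) stop("no non-control visits")
  stopifnot(all(fv$inflorescence_size > 0))
  per_visit <- data.frame(
    visit_id = as.character(fv$visit_id),
    taxon = as.character(fv$taxon),
    pe_female = pmax(0, fv$insertions / fv$inflorescence_size -
                        control_means[["insertion"]]),
    pe_male = pmax(0, fv$removals / fv$inflorescence_size -
                      control_means[["removal"]]),
    stringsAsFactors = FALSE)
  agg_f <- tapply(per_visit$pe_female, per_visit$taxon, mean)
  agg_m <- tapply(per_visit$pe_male, per_visit$taxon, mean)
  per_taxon <- data.frame(taxon = names(agg_f),
                          pe_female = as.numeric(agg_f),
                          pe_male = as.numeric(agg_m[names(agg_f)]),
                          n_visits = as.integer(table(per_visit$taxon)[
                            names(agg_f)]),
                          row.names = NULL, stringsAsFactors = FALSE)
  list(per_visit = per_visit, per_taxon = per_taxon)
}

#' Relative visit abundance with sampling-effort correction
#'
#' The share of visits made by each taxon among all included visits.
#' Nocturnal taxa are typically watched for fewer hours than diurnal ones;
#' their visit counts are multiplied by the sampling-effort ratio (diurnal
#' observation hours / nocturnal observation hours) before normalisation,
#' so the proportions reflect equal effort. Proportions sum to 1 over the
#' included taxa for any positive ratio.
#'
#' @param visits visit table (controls excluded automatically); a
#'   \code{period} column (\code{"diurnal"}/\code{"nocturnal"}) marks
#'   nocturnal visits, otherwise all visits are treated as diurnal.
#' @param effort_ratio positive real; default 1 (equal effort).
#' @return named vector of proportions per taxon.
#' @export
relative_abundance <- function(visits, effort_ratio = 1) {
  if (effort_ratio <= 0) stop("effort_ratio must be > 0")
  fv <- visits[visits$taxon != "CONTROL", , drop = FALSE]
  if (nrow(fv) == 0L) stop("no non-control visits")
  w <- rep(1, nrow(fv))
  if ("period" %in% names(fv)) w[fv$period == "nocturnal"] <- effort_ratio
  counts <- tapply(w, as.character(fv$taxon), sum)
  out <- counts / sum(counts)
  out[order(names(out))]
}

#' Pollinator importance
#'
#' Effectiveness weighted by how often the taxon actually visits:
#' \code{PI = PE x relative abundance}, per taxon and reproductive function.
#' Always \code{PI <= PE} since abundance is a proportion.
#'
#' @param PE per-taxon mean effectiveness (nonnegative).
#' @param abundance relative abundance proportion(s).
#' @return \code{PE * abundance}.
#' @export
importance <- function(PE, abundance) {
  stopifnot(all(PE >= 0), all(abundance >= 0), all(abundance <= 1))
  PE * abundance
}

#' Self-incompatibility-controlled importance, female function
#'
#' Discounts the self-pollination that a self-incompatible plant wastes:
#' with \code{S_mp} the taxon's self-pollination rate and \code{SI} the
#' self-incompatibility rate (1 - self-compatibility),
#' \deqn{SICPI_I = PI_I\,(1 - S_{mp}\,SI).}
#' It reduces to \code{PI_I} when either selfing or self-incompatibility
#' vanishes, and never exceeds it.
#'
#' @param PI_I pollinator importance for insertions.
#' @param S_mp self-pollination rate in \code{[0, 1]}.
#' @param SI self-incompatibility rate in \code{[0, 1]}.
#' @return \code{SICPI_I}.
#' @export
sicpi_insertions <- function(PI_I, S_mp, SI) {
  stopifnot(all(S_mp >= 0), all(S_mp <= 1), all(SI >= 0), all(SI <= 1))
  PI_I * (1 - S_mp * SI)
}

#' Self-incompatibility-controlled importance, male function
#'
#' Removed pollinia spent on self-incompatible matings sire nothing, so the
#' male-function importance is reduced by the self-incompatible share of
#' the insertions: \deqn{SICPI_R = PI_R - PI_I\,S_{mp}\,SI,} clamped at zero
#' (with a \code{"clamped"} attribute) if the subtraction goes negative.
#'
#' @param PI_R pollinator importance for removals.
#' @inheritParams sicpi_insertions
#' @return \code{SICPI_R} with logical attribute \code{"clamped"}.
#' @export
sicpi_removals <- function(PI_R, PI_I, S_mp, SI) {
  stopifnot(all(PI_R >= 0), all(PI_I >= 0),
            all(S_mp >= 0), all(S_mp <= 1), all(SI >= 0), all(SI <= 1))
  raw <- PI_R - PI_I * S_mp * SI
  structure(pmax(raw, 0), clamped = any(raw < 0))
}

#' Per-taxon visit-behaviour summary
#'
#' Arithmetic means and standard errors of flowers visited, insertions per
#' visit, and removals per visit, per visitor taxon. SE is reported as
#' \code{NA} for taxa observed once.
#'
#' @param visits visit table (controls excluded).
#' @return data frame, one row per taxon.
#' @export
summarize_behavior <- function(visits) {
  fv <- visits[visits$taxon != "CONTROL", , drop = FALSE]
  if (nrow(fv) == 0L) stop("no non-control visits")
  se <- function(x) if (length(x) < 2L) NA_real_ else
    stats::sd(x) / sqrt(length(x))
  one <- function(v) c(mean = mean(v), se = se(v))
  out <- lapply(split(fv, as.character(fv$taxon)), function(d) {
    data.frame(taxon = d$taxon[1L], n_visits = nrow(d),
               flowers_visited_mean = mean(d$flowers_visited),
               flowers_visited_se = se(d$flowers_visited),
               insertions_mean = mean(d$insertions),
               insertions_se = se(d$insertions),
               removals_mean = mean(d$removals),
               removals_se = se(d$removals),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, make.row.names = FALSE))
}

#' Pollinator effectiveness, importance, and SICPI with bootstrap intervals
#'
#' Computes the full importance table per visitor taxon and reproductive
#' function (female = insertions, male = removals): control-corrected
#' effectiveness ([effectiveness()]), effort-adjusted relative abundance
#' ([relative_abundance()]), importance \code{PI = PE x abundance}, and the
#' self-incompatibility-controlled variants (Eqs. via
#' [sicpi_insertions()]/[sicpi_removals()]). Uncertainty follows the
#' Monte-Carlo product scheme: per-visit effectiveness vectors and the
#' visit list are each bootstrapped B times, replicate means are multiplied
#' replicate-wise ([mc_product_ci()]), and SICPI additionally combines the
#' self-pollination bootstrap replicates from a [fit_selfing()] object.
#' Intervals are 2.5/97.5 percentile ranks of the B combined replicates.
#'
#' @param visits visit table including controls.
#' @param selfing a \code{selfing_fit} (preferred: supplies per-taxon
#'   \code{S_mp} bootstrap replicates), a named numeric vector of per-taxon
#'   \code{S_mp} values, or \code{NULL} (treated as \code{S_mp = 0}, i.e.
#'   SICPI = PI).
#' @param config a [run_config()]; supplies B, the sampling-effort ratio
#'   and the self-compatibility (SI = 1 - self_compatibility).
#' @return object of class \code{"importance_fit"} with \code{table} (one
#'   row per taxon x function: PE, abundance, PI, SICPI and their CIs) and
#'   the per-quantity [boot_result()]s. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{plot}.
#' @export
pollinator_importance <- function(visits, selfing = NULL,
                                  config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed + 1L)
  B <- config$n_bootstrap
  SI <- 1 - config$self_compatibility

  eff <- effectiveness(visits)
  abund <- relative_abundance(visits, config$sampling_effort_ratio)
  taxa <- eff$per_taxon$taxon

  s_mp <- smp_replicates(selfing, taxa, B)

  fv <- visits[visits$taxon != "CONTROL", , drop = FALSE]
  w <- rep(1, nrow(fv))
  if ("period" %in% names(fv))
    w[fv$period == "nocturnal"] <- config$sampling_effort_ratio
  tax_chr <- as.character(fv$taxon)
  # abundance bootstrap: resample the visit list, recompute weighted shares
  ab_rep <- matrix(0, nrow = B, ncol = length(taxa),
                   dimnames = list(NULL, taxa))
  for (b in seq_len(B)) {
    idx <- sample.int(nrow(fv), nrow(fv), replace = TRUE)
    cnt <- tapply(w[idx], tax_chr[idx], sum)
    ab_rep[b, names(cnt)] <- cnt / sum(cnt)
  }

  rows <- list()
  boots <- list()
  seed_val <- if (is.null(config$rng_seed)) NA_integer_ else config$rng_seed
  for (tx in taxa) {
    pv <- eff$per_visit[eff$per_visit$taxon == tx, , drop = FALSE]
    n <- nrow(pv)
    idx <- matrix(sample.int(n, n * B, replace = TRUE), n, B)
    pe_f_rep <- colMeans(matrix(pv$pe_female[idx], n, B))
    pe_m_rep <- colMeans(matrix(pv$pe_male[idx], n, B))
    comp <- list(
      pe_female = boot_result(pe_f_rep, B, seed_val),
      pe_male = boot_result(pe_m_rep, B, seed_val),
      abundance = boot_result(ab_rep[, tx], B, seed_val),
      s_mp = boot_result(s_mp[[tx]], B, seed_val))
    pi_f <- mc_product_ci(list(comp$pe_female, comp$abundance))
    pi_m <- mc_product_ci(list(comp$pe_male, comp$abundance))
    sicpi_f <- mc_product_ci(list(pi_f, comp$s_mp),
                             combiner = function(pi, s) pi * (1 - s * SI))
    sicpi_m <- mc_product_ci(list(pi_m, pi_f, comp$s_mp),
                             combiner = function(pr, pf, s)
                               pmax(pr - pf * s * SI, 0))
    boots[[tx]] <- c(comp, list(pi_female = pi_f, pi_male = pi_m,
                                sicpi_female = sicpi_f,
                                sicpi_male = sicpi_m))

    pe_f <- eff$per_taxon$pe_female[eff$per_taxon$taxon == tx]
    pe_m <- eff$per_taxon$pe_male[eff$per_taxon$taxon == tx]
    s_pt <- mean(s_mp[[tx]])
    mk <- function(fun, pe, pe_b, pi_b, sic_b, pi_pt, sic_pt)
      data.frame(taxon = tx, fun = fun, n_visits = n,
                 PE = pe, PE_lo = pe_b$ci_low, PE_hi = pe_b$ci_high,
                 abundance = unname(abund[tx]),
                 PI = pi_pt, PI_lo = pi_b$ci_low, PI_hi = pi_b$ci_high,
                 SICPI = sic_pt, SICPI_lo = sic_b$ci_low,
                 SICPI_hi = sic_b$ci_high, SI = SI,
                 stringsAsFactors = FALSE)
    rows[[paste0(tx, ".F")]] <- mk("female", pe_f, comp$pe_female, pi_f,
                                   sicpi_f,
                                   importance(pe_f, abund[[tx]]),
                                   sicpi_insertions(
                                     importance(pe_f, abund[[tx]]), s_pt, SI))
    rows[[paste0(tx, ".M")]] <- mk("male", pe_m, comp$pe_male, pi_m,
                                   sicpi_m,
                                   importance(pe_m, abund[[tx]]),
                                   as.numeric(sicpi_removals(
                                     importance(pe_m, abund[[tx]]),
                                     importance(pe_f, abund[[tx]]),
                                     s_pt, SI)))
  }
  structure(list(table = do.call(rbind, c(rows, make.row.names = FALSE)),
                 boot = boots, effectiveness = eff, abundance = abund,
                 SI = SI, config = config),
            class = "importance_fit")
}

# per-taxon S_mp replicate vectors of length B, whatever `selfing` is
smp_replicates <- function(selfing, taxa, B) {
  out <- list()
  for (tx in taxa) {
    if (is.null(selfing)) {
      out[[tx]] <- rep(0, B)
    } else if (inherits(selfing, "selfing_fit")) {
      if (!tx %in% names(selfing$boot)) {
        out[[tx]] <- rep(0, B)
      } else {
        est <- selfing$boot[[tx]]$S_mp$estimates
        out[[tx]] <- if (length(est) == B) est else
          est[sample.int(length(est), B, replace = TRUE)]
      }
    } else if (is.numeric(selfing)) {
      out[[tx]] <- rep(if (tx %in% names(selfing)) selfing[[tx]] else 0, B)
    } else stop("selfing must be a selfing_fit, a named numeric, or NULL")
  }
  out
}

#' @export
print.importance_fit <- function(x, digits = 4, ...) {
  cat("Pollinator effectiveness / importance (SI =", format(x$SI), ")\n")
  tab <- x$table
  for (i in seq_len(nrow(tab)))
    cat(sprintf(
      "  %-14s %-6s PE %.*f  PI %.*f [%.*f, %.*f]  SICPI %.*f [%.*f, %.*f]\n",
      tab$taxon[i], tab$fun[i], digits, tab$PE[i], digits, tab$PI[i],
      digits, tab$PI_lo[i], digits, tab$PI_hi[i], digits, tab$SICPI[i],
      digits, tab$SICPI_lo[i], digits, tab$SICPI_hi[i]))
  invisible(x)
}

#' @export
summary.importance_fit <- function(object, ...) object$table

#' @export
coef.importance_fit <- function(object, ...) {
  tab <- object$table
  stats::setNames(tab$PI, paste(tab$taxon, tab$fun, sep = "."))
}

#' @export
plot.importance_fit <- function(x, fun = c("female", "male"), ...) {
  fun <- match.arg(fun)
  tab <- x$table[x$table$fun == fun, , drop = FALSE]
  h <- rbind(PE = tab$PE, PI = tab$PI, SICPI = tab$SICPI)
  graphics::barplot(h, beside = TRUE, names.arg = tab$taxon,
                    legend.text = rownames(h),
                    ylab = "pollinia per focal-inflorescence flower",
                    main = paste0("Pollinator metrics (", fun,
                                  " function)"), ...)
  invisible(x)
}
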