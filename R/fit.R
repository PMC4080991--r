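# Per-taxon estimator chain and the user-facing fit.
#
# Chain, per visitor taxon T:
#   S_dT, alpha_dT  over T's focal genotyped pollinia (visitor + through-bag
#                   mixture; self flags and pool match probabilities)
#   S_dc, alpha_dc  over control-inflorescence pollinia
#   r_p             share of T's insertions attributable to the visitor,
#                   1 - (per-flower control rate x T's focal flowers) /
#                   (T's total insertions)
#   Eq. chain       alpha_dp, S_dp (partitions), S_mp (method of moments)

# mean control insertions per flower, from control visit rows
control_insertion_rate <- function(visits) {
  cv <- visits[visits$taxon == "CONTROL", , drop = FALSE]
  if (nrow(cv) == 0L) return(NA_real_)
  mean(cv$insertions / cv$inflorescence_size)
}

# r_p for a set of focal visit rows given the per-flower bag rate
attributed_proportion <- function(visit_rows, lambda_c) {
  total <- sum(visit_rows$insertions)
  if (total <= 0) return(1)
  expected_bag <- lambda_c * sum(visit_rows$inflorescence_size)
  r_p <- 1 - expected_bag / total
  if (r_p <= 0)
    stop("expected through-bag insertions meet or exceed observed ",
         "insertions (r_p <= 0): no insertions attributable to the visitor")
  min(r_p, 1)
}

# vectorised chain used by the bootstrap; returns S_mp/S_dp/alpha_dp
# replicate vectors plus the validity mask (Eq. 2/3 domain respected)
chain_replicates <- function(sT, aT, sc, ac, r_p) {
  tT <- 1 - sT
  tc <- 1 - sc
  alpha_dp <- (aT - (1 - r_p) * ac) / r_p
  s_dp <- 1 - (tT - (1 - r_p) * tc) / r_p
  valid <- alpha_dp >= 0 & alpha_dp < 1 & s_dp >= 0 & s_dp <= 1
  s_mp <- ifelse(valid, pmin(pmax((s_dp - alpha_dp) / (1 - alpha_dp), 0), 1),
                 NA_real_)
  list(alpha_dp = alpha_dp, s_dp = s_dp, s_mp = s_mp, valid = valid)
}

#' Fit visitor-taxon self-pollination rates from genotyped pollinia
#'
#' The package's central estimator. For every visitor taxon with at least
#' one classifiable genotyped pollinium it computes the full chain: the
#' observed direct self fraction and chance-match probability over the
#' taxon's focal pollinia, the through-bag control partition
#' ([partition_alpha()], [visitor_selfing_direct()]), and the
#' method-of-moments self-pollination rate ([mom_selfing()]), together with
#' a bootstrap (inserted pollinium as the resampling unit; taxon and control
#' pollinium sets resampled independently at their original sizes) giving
#' the SE as the replicate standard deviation and the 2.5/97.5 percentile
#' confidence interval. Pool genotype frequencies are estimated once from
#' the full pollen pool (round-robin by default) and held fixed across
#' replicates; the attributed-insertion proportion r_p is likewise held at
#' its point estimate. Bootstrap replicates breaching the partition domain
#' are dropped and counted, not clamped.
#'
#' @param visits visit table including \code{CONTROL} rows (see
#'   [read_visit_table()]).
#' @param genotypes long genotype table (see [build_pollinium_data()]).
#' @param config a [run_config()].
#' @return object of class \code{"selfing_fit"} with components
#'   \code{estimates} (one row per taxon: \code{S_d}, \code{alpha_dT},
#'   \code{alpha_dc}, \code{alpha_dp}, \code{r_p}, \code{t_dT}, \code{t_dc},
#'   \code{S_dp}, \code{S_mp}, \code{se_S_mp}, CI bounds, clamp flag,
#'   dropped-replicate count), \code{boot} (per-taxon [boot_result()]s for
#'   \code{S_mp}, \code{S_dp}, \code{alpha_dp}), \code{per_genotype}
#'   ([per_genotype_sdp()] table), \code{freqs}, \code{data}, and
#'   \code{config}. Methods: \code{print}, \code{summary}, \code{coef}
#'   (named \code{S_mp} vector), \code{confint}, \code{plot}.
#' @examples
#' study <- simulate_study(simulation_config(seed = 1))
#' fit <- fit_selfing(study$visits, study$genotypes,
#'                    run_config(n_bootstrap = 100, rng_seed = 1))
#' coef(fit)
#' @export
fit_selfing <- function(visits, genotypes, config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)

  pd <- build_pollinium_data(visits, genotypes)
  rec <- pd$records[!is.na(pd$records$class), , drop = FALSE]
  if (nrow(rec[!rec$is_control, ]) == 0L)
    stop("no classifiable genotyped pollinia for any visitor taxon")

  freqs <- pool_frequencies(pd, config)
  match_prob <- vapply(rec$pollinium_id, function(id)
    genotype_match_probability(freqs, mlg_row(pd$pollinia, id)),
    numeric(1))
  wts <- alpha_weights(rec, config$alpha_weighting)
  is_self <- as.numeric(rec$class == "self")

  lambda_c <- control_insertion_rate(visits)
  ctrl <- rec$is_control
  n_ctrl <- sum(ctrl)
  zero_contamination <- FALSE
  if (is.na(lambda_c) || n_ctrl == 0L) {
    if (is.na(lambda_c))
      warning("no control (bagged) inflorescences in the visit table: ",
              "proceeding under the zero-contamination assumption")
    else
      warning("control inflorescences present but no genotyped control ",
              "pollinia: proceeding under the zero-contamination assumption")
    zero_contamination <- TRUE
    lambda_c <- 0
  }
  sc <- is_self[ctrl]
  mc <- match_prob[ctrl]
  wc <- wts[ctrl]

  taxa <- sort(unique(rec$taxon[!ctrl]))
  B <- config$n_bootstrap
  rows <- list()
  boot <- list()
  for (tx in taxa) {
    sel <- !ctrl & rec$taxon == tx
    sT <- is_self[sel]
    mT <- match_prob[sel]
    wT <- wts[sel]
    n_T <- length(sT)
    tv <- visits[as.character(visits$visit_id) %in% rec$visit_id[sel], ,
                 drop = FALSE]
    r_p <- if (zero_contamination) 1 else
      attributed_proportion(tv, lambda_c)

    # point estimates
    a_dT <- sum(wT * mT) / sum(wT)
    a_dc <- if (n_ctrl > 0L) sum(wc * mc) / sum(wc) else 0
    S_dT <- mean(sT)
    t_dT <- 1 - S_dT
    t_dc <- if (n_ctrl > 0L) 1 - mean(sc) else 0
    alpha_dp <- partition_alpha(a_dT, a_dc, r_p, config$clamp_policy)
    S_dp <- visitor_selfing_direct(t_dT, t_dc, r_p, config$clamp_policy)
    S_mp <- mom_selfing(as.numeric(S_dp), as.numeric(alpha_dp))
    clamped <- isTRUE(attr(alpha_dp, "clamped")) ||
      isTRUE(attr(S_dp, "clamped")) || isTRUE(attr(S_mp, "clamped"))

    # bootstrap: resample taxon and control pollinium sets independently
    idxT <- matrix(sample.int(n_T, n_T * B, replace = TRUE), n_T, B)
    sT_rep <- colMeans(matrix(sT[idxT], n_T, B))
    aT_rep <- colSums(matrix((wT * mT)[idxT], n_T, B)) /
      colSums(matrix(wT[idxT], n_T, B))
    if (n_ctrl > 1L) {
      idxC <- matrix(sample.int(n_ctrl, n_ctrl * B, replace = TRUE),
                     n_ctrl, B)
      sc_rep <- colMeans(matrix(sc[idxC], n_ctrl, B))
      ac_rep <- colSums(matrix((wc * mc)[idxC], n_ctrl, B)) /
        colSums(matrix(wc[idxC], n_ctrl, B))
    } else if (n_ctrl == 1L) {
      sc_rep <- rep(sc, B)
      ac_rep <- rep(mc, B)
    } else {
      sc_rep <- rep(1, B)   # t_dc = 0
      ac_rep <- rep(0, B)
    }
    reps <- chain_replicates(sT_rep, aT_rep, sc_rep, ac_rep, r_p)
    dropped <- sum(!reps$valid)
    sm_boot <- boot_result(reps$s_mp[reps$valid], B = B,
                           seed = if (is.null(config$rng_seed))
                             NA_integer_ else config$rng_seed,
                           dropped = dropped)
    boot[[tx]] <- list(
      S_mp = sm_boot,
      S_dp = boot_result(reps$s_dp[reps$valid], B, sm_boot$seed, dropped),
      alpha_dp = boot_result(reps$alpha_dp[reps$valid], B, sm_boot$seed,
                             dropped))

    rows[[tx]] <- data.frame(
      taxon = tx, n_pollinia = n_T,
      S_d = S_dT, alpha_dT = a_dT, alpha_dc = a_dc,
      alpha_dp = as.numeric(alpha_dp), r_p = r_p,
      t_dT = t_dT, t_dc = t_dc,
      S_dp = as.numeric(S_dp), S_mp = as.numeric(S_mp),
      se_S_mp = sm_boot$se,
      ci_low = sm_boot$ci_low, ci_high = sm_boot$ci_high,
      clamped = clamped, boot_dropped = dropped,
      stringsAsFactors = FALSE)
  }

  structure(list(estimates = do.call(rbind, c(rows, make.row.names = FALSE)),
                 boot = boot,
                 per_genotype = per_genotype_sdp(pd, visits,
                                                 policy = config$clamp_policy),
                 freqs = freqs, data = pd, config = config,
                 lambda_c = lambda_c,
                 zero_contamination = zero_contamination),
            class = "selfing_fit")
}

pool_frequencies <- function(pd, config) {
  pool <- if (config$freq_basis == "maternal") pd$maternal else pd$pollinia
  if (config$freq_method == "round_robin" && length(pd$loci) >= 2L)
    round_robin_frequencies(pool, basis = config$freq_basis)
  else {
    if (config$freq_method == "round_robin")
      message("single-locus dataset: falling back to naive frequencies")
    naive_frequencies(pool, basis = config$freq_basis)
  }
}

alpha_weights <- function(rec, weighting) {
  if (weighting == "per_inflorescence") {
    1 / as.numeric(table(rec$visit_id)[rec$visit_id])
  } else rep(1, nrow(rec))
}

#' Per-maternal-genotype direct self-pollination rate
#'
#' For the display-size analysis: maternal stems are collapsed to distinct
#' multilocus genotypes, each genotype's pollinia (per visitor taxon) are
#' pooled across all inflorescences sharing the genotype, the total direct
#' outcrossing rate t_dT is computed over that pool, and the
#' control-corrected S_dp follows from [visitor_selfing_direct()] with the
#' group-level attributed proportion r_p and the global control outcrossing
#' rate. Floral-display sizes are averaged over the group's inflorescences.
#' The table is exported for external regression tooling (e.g. a
#' quasi-binomial GLMM of S_dp on display size); this package does not fit
#' such models.
#'
#' @param pd a [build_pollinium_data()] object.
#' @param visits the visit table.
#' @param policy clamp policy for the partition (default \code{"clamp"}).
#' @return data frame with columns \code{maternal_genotype}, \code{taxon},
#'   \code{n_pollinia}, \code{S_dp}, \code{mean_inflorescence_size},
#'   \code{mean_stem_size}.
#' @export
per_genotype_sdp <- function(pd, visits, policy = "clamp") {
  stopifnot(inherits(pd, "pollinium_data"))
  rec <- pd$records[!is.na(pd$records$class) & !pd$records$is_control, ,
                    drop = FALSE]
  if (nrow(rec) == 0L) stop("no classifiable visitor pollinia")
  cls <- maternal_class_of(pd)
  rec$mclass <- cls[rec$maternal_genotype_id]

  lambda_c <- control_insertion_rate(visits)
  zero_cont <- is.na(lambda_c) || !any(pd$records$is_control)
  if (is.na(lambda_c)) lambda_c <- 0
  crec <- pd$records[pd$records$is_control & !is.na(pd$records$class), ,
                     drop = FALSE]
  t_dc <- if (nrow(crec) > 0L) mean(crec$class == "outcross") else 0

  out <- list()
  for (key in unique(paste(rec$mclass, rec$taxon, sep = "\x1f"))) {
    parts <- strsplit(key, "\x1f", fixed = TRUE)[[1L]]
    sel <- rec$mclass == parts[1L] & rec$taxon == parts[2L]
    grp <- rec[sel, , drop = FALSE]
    tv <- visits[as.character(visits$visit_id) %in% unique(grp$visit_id), ,
                 drop = FALSE]
    r_p <- if (zero_cont) 1 else attributed_proportion(tv, lambda_c)
    t_dT <- mean(grp$class == "outcross")
    S_dp <- visitor_selfing_direct(t_dT, t_dc, r_p, policy)
    out[[key]] <- data.frame(
      maternal_genotype = parts[1L], taxon = parts[2L],
      n_pollinia = nrow(grp),
      S_dp = as.numeric(S_dp),
      mean_inflorescence_size = mean(tv$inflorescence_size, na.rm = TRUE),
      mean_stem_size = mean(tv$stem_size, na.rm = TRUE),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, c(out, make.row.names = FALSE))
  res$mean_inflorescence_size[is.nan(res$mean_inflorescence_size)] <- NA
  res$mean_stem_size[is.nan(res$mean_stem_size)] <- NA
  res[order(res$taxon, res$maternal_genotype), , drop = FALSE]
}

#' @export
print.selfing_fit <- function(x, digits = 3, ...) {
  cat("Self-pollination rates by visitor taxon",
      "(method of moments, bootstrap SE)\n")
  est <- x$estimates
  for (i in seq_len(nrow(est)))
    cat(sprintf("  %-14s S_mp = %.*f (SE %.*f, 95%% CI %.*f-%.*f, n = %d)%s\n",
                est$taxon[i], digits, est$S_mp[i], digits, est$se_S_mp[i],
                digits, est$ci_low[i], digits, est$ci_high[i],
                est$n_pollinia[i],
                if (est$clamped[i]) " [clamped]" else ""))
  if (x$zero_contamination)
    cat("  (zero-contamination assumption: no genotyped control pollinia)\n")
  invisible(x)
}

#' @export
summary.selfing_fit <- function(object, ...) {
  structure(list(estimates = object$estimates,
                 freq_method = object$freqs$method,
                 freq_basis = object$freqs$basis,
                 n_unclassifiable = object$data$n_unclassifiable,
                 lambda_c = object$lambda_c,
                 zero_contamination = object$zero_contamination,
                 B = object$config$n_bootstrap),
            class = "summary.selfing_fit")
}

#' @export
print.summary.selfing_fit <- function(x, ...) {
  cat("Selfing-rate fit:", nrow(x$estimates), "visitor taxa;",
      "pool frequencies:", x$freq_method, "on", x$freq_basis, "\n")
  cat("Per-flower control insertion rate:",
      format(x$lambda_c, digits = 4), "\n")
  if (x$n_unclassifiable > 0L)
    cat(x$n_unclassifiable, "unclassifiable pollinia excluded\n")
  cat("\n")
  print(x$estimates, digits = 4, row.names = FALSE)
  invisible(x)
}

#' @export
coef.selfing_fit <- function(object, ...) {
  stats::setNames(object$estimates$S_mp, object$estimates$taxon)
}

#' @export
confint.selfing_fit <- function(object, parm, level = 0.95, ...) {
  est <- object$estimates
  out <- cbind(est$ci_low, est$ci_high)
  dimnames(out) <- list(est$taxon, c("2.5 %", "97.5 %"))
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @export
plot.selfing_fit <- function(x, ...) {
  est <- x$estimates
  mid <- graphics::barplot(est$S_mp, names.arg = est$taxon, ylim = c(0, 1),
                           ylab = expression(S[mp]),
                           main = "Method-of-moments self-pollination rate",
                           ...)
  graphics::arrows(mid, est$ci_low, mid, est$ci_high,
                   angle = 90, code = 3, length = 0.05)
  invisible(x)
}
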