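#' Bootstrap summary container
#'
#' Holds the replicate values of a bootstrapped statistic together with the
#' summaries the pipeline reports: the replicate mean and standard deviation
#' (used as point SE), and the percentile confidence interval taken as the
#' 25th and 975th ranked values when B = 1000 (generalised to the 2.5th and
#' 97.5th percentile ranks otherwise).
#'
#' @param estimates numeric vector of replicate values (invalid replicates
#'   already removed).
#' @param B number of replicates attempted.
#' @param seed the seed the resampling ran under (may be \code{NA}).
#' @param dropped number of replicates dropped because the statistic was
#'   undefined on the resample (for example an out-of-domain partition in
#'   the contamination correction).
#' @return object of class \code{"boot_result"} with fields
#'   \code{estimates}, \code{mean}, \code{se}, \code{ci_low}, \code{ci_high},
#'   \code{B}, \code{seed}, \code{dropped}.
#' @export
boot_result <- function(estimates, B, seed = NA_integer_, dropped = 0L) {
  estimates <- as.numeric(estimates)
  if (length(estimates) == 0L)
    stop("no valid bootstrap replicates (all ", B, " dropped)")
  s <- sort(estimates)
  n <- length(s)
  lo <- max(1L, round(0.025 * n))
  hi <- min(n, round(0.975 * n))
  structure(list(estimates = estimates,
                 mean = mean(estimates),
                 se = stats::sd(estimates),
                 ci_low = s[lo], ci_high = s[hi],
                 B = as.integer(B), seed = seed,
                 dropped = as.integer(dropped)),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("bootstrap: mean %.4f, se %.4f, 95%% CI [%.4f, %.4f] (B = %d%s)\n",
              x$mean, ifelse(is.na(x$se), NA, x$se), x$ci_low, x$ci_high, x$B,
              if (x$dropped > 0L) paste0(", ", x$dropped, " dropped") else ""))
  invisible(x)
}

#' Nonparametric bootstrap of a statistic
#'
#' Resamples the record collection with replacement at its original size B
#' times and applies \code{statistic} to each resample. The resampling unit
#' is one record: one element of a vector or list, or one row of a data
#' frame (for the selfing pipeline the record is one inserted pollinium).
#' Replicates on which \code{statistic} errors or returns a non-finite value
#' are dropped and counted in the result rather than clamped, so the spread
#' of the surviving replicates is not biased toward zero.
#'
#' @param records vector, list, or data frame of resampling units (>= 2).
#' @param statistic function taking a resample of \code{records} and
#'   returning a single number.
#' @param B number of bootstrap replicates (default 1000).
#' @param seed optional integer seed for reproducibility.
#' @return a [boot_result()].
#' @examples
#' b <- bootstrap(rnorm(50), mean, B = 200, seed = 1)
#' b$se  # close to sd/sqrt(50)
#' @export
bootstrap <- function(records, statistic, B = 1000L, seed = NULL) {
  n <- if (is.data.frame(records)) nrow(records) else length(records)
  if (n < 2L) stop("need >= 2 records to bootstrap")
  stopifnot(is.function(statistic), B >= 1L)
  if (!is.null(seed)) set.seed(seed)
  take <- if (is.data.frame(records)) {
    function(idx) records[idx, , drop = FALSE]
  } else {
    function(idx) records[idx]
  }
  est <- numeric(B)
  ok <- logical(B)
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    val <- tryCatch(statistic(take(idx)), error = function(e) NA_real_)
    if (length(val) == 1L && is.finite(val)) {
      est[b] <- val
      ok[b] <- TRUE
    }
  }
  boot_result(est[ok], B = B, seed = if (is.null(seed)) NA_integer_ else seed,
              dropped = sum(!ok))
}

#' Pairwise bootstrap comparison of two estimates
#'
#' Two bootstrap distributions are compared by drawing B randomly selected
#' pairs (one replicate from each, independent index draws) and counting how
#' many differences \code{a - b} are greater than zero. The two estimates
#' are declared significantly different (two-tailed) if more than 97.5\% or
#' fewer than 2.5\% of the differences are positive - for B = 1000, the
#' "> 975 or < 25 of 1000" rule. Ties (difference exactly 0) count as
#' not-greater.
#'
#' @param a,b [boot_result()] objects with the same \code{B}.
#' @param seed optional integer seed for the pair draws.
#' @return list with \code{prop_positive} (proportion of positive
#'   differences), \code{n_positive}, \code{B}, and \code{significant}.
#' @export
pairwise_bootstrap_test <- function(a, b, seed = NULL) {
  stopifnot(inherits(a, "boot_result"), inherits(b, "boot_result"))
  if (a$B != b$B)
    stop("bootstrap results have different B (", a$B, " vs ", b$B, ")")
  B <- a$B
  if (!is.null(seed)) set.seed(seed)
  i <- sample.int(length(a$estimates), B, replace = TRUE)
  j <- sample.int(length(b$estimates), B, replace = TRUE)
  npos <- sum(a$estimates[i] - b$estimates[j] > 0)
  list(prop_positive = npos / B,
       n_positive = npos,
       B = B,
       significant = npos > 0.975 * B || npos < 0.025 * B)
}

#' Permutation test for group differences
#'
#' Monte-Carlo permutation test with no distributional assumptions,
#' appropriate for zero-inflated continuous responses such as per-visit
#' pollinator effectiveness. For two groups the statistic is the absolute
#' difference of group means (two-sided); for k > 2 groups it is the
#' between-group sum of squares of group means about the grand mean,
#' weighted by group size. Group labels are permuted B times and the
#' p-value uses the add-one Monte-Carlo estimator
#' \code{(1 + #(permuted >= observed)) / (B + 1)}, which cannot return 0 at
#' finite B.
#'
#' @param values numeric response vector.
#' @param labels group labels, same length as \code{values}; >= 2 nonempty
#'   groups.
#' @param B number of permutations (default 1000).
#' @param seed optional integer seed.
#' @return list with \code{p_value}, \code{observed} statistic, \code{B}.
#' @export
permutation_test <- function(values, labels, B = 1000L, seed = NULL) {
  stopifnot(length(values) == length(labels), B >= 1L)
  labels <- as.character(labels)
  groups <- unique(labels)
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(table(labels) == 0L)) stop("empty group")
  if (!is.null(seed)) set.seed(seed)

  if (length(groups) == 2L) {
    g1 <- labels == groups[1L]
    stat <- function(v) abs(mean(v[g1]) - mean(v[!g1]))
  } else {
    idx <- split(seq_along(values), labels)
    sizes <- lengths(idx)
    stat <- function(v) {
      gm <- vapply(idx, function(ii) mean(v[ii]), numeric(1))
      sum(sizes * (gm - mean(v))^2)
    }
  }
  obs <- stat(values)
  if (obs == 0) return(list(p_value = 1, observed = 0, B = B))
  ge <- 0L
  for (b in seq_len(B)) {
    if (stat(values[sample.int(length(values))]) >= obs) ge <- ge + 1L
  }
  list(p_value = (1 + ge) / (B + 1), observed = obs, B = B)
}

#' Monte-Carlo interval for a product (or other combination) of estimates
#'
#' Uncertainty in a product of random variables - pollinator importance
#' (effectiveness x abundance) and its self-incompatibility-controlled
#' variants (three components) - is propagated by combining the component
#' bootstrap distributions replicate-wise: replicate k of the combined
#' quantity is \code{combiner} applied to replicate k of every component.
#' The confidence interval is again the 2.5th/97.5th percentile ranks of the
#' combined replicates.
#'
#' @param components list of 2 or 3 [boot_result()] objects sharing the same
#'   number of replicates.
#' @param combiner function of as many numeric vectors as there are
#'   components, applied vectorised over replicates (default elementwise
#'   product).
#' @return a [boot_result()] for the combined quantity.
#' @export
mc_product_ci <- function(components, combiner = `*`) {
  stopifnot(is.list(components), length(components) >= 2L)
  lapply(components, function(x) stopifnot(inherits(x, "boot_result")))
  lens <- vapply(components, function(x) length(x$estimates), integer(1))
  if (length(unique(lens)) != 1L)
    stop("components have differing replicate counts: ",
         paste(lens, collapse = ", "))
  combined <- do.call(combiner, lapply(components, `[[`, "estimates"))
  if (length(combined) != lens[1L])
    stop("combiner must return one value per replicate")
  boot_result(combined, B = components[[1L]]$B,
              seed = components[[1L]]$seed,
              dropped = sum(vapply(components, `[[`, integer(1), "dropped")))
}
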