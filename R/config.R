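#' Run configuration for the estimation pipeline
#'
#' Collects every tunable the estimators and resampling machinery use, with
#' the defaults the package's analyses run under.
#'
#' @param n_bootstrap bootstrap replicates for the selfing chain and the
#'   importance metrics (default 1000).
#' @param n_permutation permutations per permutation test (default 1000).
#' @param rng_seed integer seed set at the start of every fit; \code{NULL}
#'   leaves the RNG state alone.
#' @param self_compatibility proportion of self insertions able to sire
#'   seed, in \code{[0, 1]}; the self-incompatibility rate used by the
#'   importance metrics is \code{SI = 1 - self_compatibility}. Default 0.05,
#'   a conservative literature value for a strongly self-incompatible
#'   milkweed.
#' @param sampling_effort_ratio diurnal observation hours divided by
#'   nocturnal observation hours; nocturnal visit counts are multiplied by
#'   this ratio before relative abundances are formed. Must be supplied by
#'   the user when diurnal and nocturnal effort differ (default 1).
#' @param clamp_policy \code{"clamp"} (default: out-of-domain partition
#'   results are clamped into \code{[0, 1]} and flagged) or \code{"error"}.
#' @param freq_method \code{"round_robin"} (default) or \code{"naive"}
#'   frequency estimation for the pollen pool.
#' @param freq_basis which samples define the pool genotype frequencies:
#'   \code{"pollen_pool"} (default; all genotyped inserted pollinia) or
#'   \code{"maternal"} (maternal stems).
#' @param alpha_weighting \code{"per_pollinium"} (default; each genotyped
#'   pollinium counts once, matching the bootstrap's resampling unit) or
#'   \code{"per_inflorescence"} (each inflorescence's pollinia share unit
#'   weight).
#' @return object of class \code{"run_config"}.
#' @export
run_config <- function(n_bootstrap = 1000L,
                       n_permutation = 1000L,
                       rng_seed = NULL,
                       self_compatibility = 0.05,
                       sampling_effort_ratio = 1,
                       clamp_policy = c("clamp", "error"),
                       freq_method = c("round_robin", "naive"),
                       freq_basis = c("pollen_pool", "maternal"),
                       alpha_weighting = c("per_pollinium",
                                           "per_inflorescence")) {
  stopifnot(n_bootstrap >= 1L, n_permutation >= 1L,
            self_compatibility >= 0, self_compatibility <= 1,
            sampling_effort_ratio > 0)
  structure(list(n_bootstrap = as.integer(n_bootstrap),
                 n_permutation = as.integer(n_permutation),
                 rng_seed = if (is.null(rng_seed)) NULL else
                   as.integer(rng_seed),
                 self_compatibility = self_compatibility,
                 sampling_effort_ratio = sampling_effort_ratio,
                 clamp_policy = match.arg(clamp_policy),
                 freq_method = match.arg(freq_method),
                 freq_basis = match.arg(freq_basis),
                 alpha_weighting = match.arg(alpha_weighting)),
            class = "run_config")
}

#' @export
print.run_config <- function(x, ...) {
  cat("run_config:\n")
  for (nm in names(x))
    cat("  ", nm, ": ",
        if (is.null(x[[nm]])) "NULL" else format(x[[nm]]), "\n", sep = "")
  invisible(x)
}
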