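#' Partition the chance-match probability between visitor and bag insertions
#'
#' Focal inflorescences are bagged until the watched visit begins, but
#' insects occasionally insert pollinia through the bags, so the pollinia
#' recovered from a focal inflorescence are a mixture of visitor-inserted
#' and through-bag insertions. Writing alpha_dT for the erroneous-assignment
#' probability over all of a taxon's focal pollinia, alpha_dc for the same
#' quantity over pollinia from permanently bagged control inflorescences,
#' and r_p for the proportion of insertions attributed to the visitor taxon,
#' the visitor-only value is
#' \deqn{\alpha_{dp} = \frac{\alpha_{dT} - (1 - r_p)\,\alpha_{dc}}{r_p},}
#' defined on the domain \eqn{\alpha_{dT} > \alpha_{dc}(1 - r_p)}. Small
#' samples can breach the domain; under \code{policy = "clamp"} (default)
#' the result is clamped into \code{[0, 1]} and flagged via the
#' \code{"clamped"} attribute, under \code{"error"} it aborts naming the
#' condition.
#'
#' @param alpha_dT chance-match probability over all of the taxon's focal
#'   pollinia (mixture of visitor and through-bag origin).
#' @param alpha_dc chance-match probability over control pollinia.
#' @param r_p proportion of insertions attributed to the visitor taxon, in
#'   (0, 1].
#' @param policy \code{"clamp"} or \code{"error"}.
#' @return \code{alpha_dp} with logical attribute \code{"clamped"}.
#' @export
partition_alpha <- function(alpha_dT, alpha_dc, r_p,
                            policy = c("clamp", "error")) {
  policy <- match.arg(policy)
  if (r_p <= 0) stop("r_p must be in (0, 1]: no insertions attributed ",
                     "to the taxon leaves alpha_dp undefined")
  if (r_p > 1) stop("r_p must be in (0, 1]")
  raw <- (alpha_dT - (1 - r_p) * alpha_dc) / r_p
  clamp01(raw, policy,
          what = "alpha_dp",
          condition = "alpha_dT > alpha_dc * (1 - r_p)")
}

#' Visitor-only direct self-pollination rate (control-corrected)
#'
#' The complement of the outcrossing-rate partition: with t_dT the total
#' direct-outcrossing rate over a taxon's focal pollinia and t_dc the
#' direct-outcrossing rate for pollinia inserted into control
#' inflorescences,
#' \deqn{S_{dp} = 1 - \frac{t_{dT} - (1 - r_p)\,t_{dc}}{r_p},}
#' on the domain \eqn{t_{dT} > t_{dc}(1 - r_p)}. Out-of-domain values are
#' clamped into \code{[0, 1]} and flagged, or raise an error, per
#' \code{policy}. With no through-bag contamination (\code{r_p = 1}) this
#' reduces to \code{1 - t_dT}.
#'
#' @param t_dT total direct-outcrossing rate over the taxon's focal
#'   pollinia.
#' @param t_dc direct-outcrossing rate over control pollinia.
#' @inheritParams partition_alpha
#' @return \code{S_dp} with logical attribute \code{"clamped"}.
#' @export
visitor_selfing_direct <- function(t_dT, t_dc, r_p,
                                   policy = c("clamp", "error")) {
  policy <- match.arg(policy)
  if (r_p <= 0 || r_p > 1) stop("r_p must be in (0, 1]")
  raw <- 1 - (t_dT - (1 - r_p) * t_dc) / r_p
  clamp01(raw, policy,
          what = "S_dp",
          condition = "t_dT > t_dc * (1 - r_p)")
}

clamp01 <- function(raw, policy, what, condition) {
  clamped <- raw < 0 || raw > 1
  if (clamped && policy == "error")
    stop(what, " = ", format(raw), " outside [0, 1]: domain condition ",
         condition, " violated")
  structure(min(max(raw, 0), 1), clamped = clamped)
}

#' Method-of-moments self-pollination rate
#'
#' An outcross pollinium is misclassified as self whenever its multilocus
#' genotype happens to match the maternal genotype, which occurs with
#' probability alpha. The observed self fraction therefore satisfies
#' \code{S_dp = S + (1 - S) alpha}, and solving for the true rate gives the
#' method-of-moments estimator
#' \deqn{S_{mp} = \frac{S_{dp} - \alpha_{dp}}{1 - \alpha_{dp}}.}
#' The correction can only lower the estimate: \code{S_mp <= S_dp} whenever
#' \code{alpha_dp > 0}. Values outside \code{[0, 1]} (sampling noise) are
#' clamped and flagged.
#'
#' @param S_dp visitor-only direct self-pollination rate.
#' @param alpha_dp visitor-only chance-match probability; must be < 1.
#' @return \code{S_mp} with logical attribute \code{"clamped"}.
#' @export
mom_selfing <- function(S_dp, alpha_dp) {
  if (alpha_dp >= 1)
    stop("alpha_dp >= 1: chance matches explain any observation, ",
         "no information about the self-pollination rate")
  raw <- (S_dp - alpha_dp) / (1 - alpha_dp)
  clamp01(raw, "clamp", what = "S_mp", condition = "S_dp >= alpha_dp")
}

#' Weighted chance-match probability over a set of inserted pollinia
#'
#' The direct erroneous-assignment probability: the sum over distinct
#' pollinium multilocus genotypes i of w_i times the pool-frequency product
#' of genotype i ([genotype_match_probability()]). With the default
#' per-pollinium weights (each genotyped pollinium counts once) this equals
#' the mean per-pollinium match probability.
#'
#' @param pollinia an [mlg_matrix()] whose rows are inserted-pollinium
#'   genotypes (duplicates allowed - they carry the weighting).
#' @param freqs a \code{freq_table} for the pollen pool.
#' @param weights optional nonnegative per-pollinium weights (normalised
#'   internally); e.g. per-inflorescence weighting assigns each pollinium
#'   1 / (number of genotyped pollinia on its inflorescence).
#' @return alpha in \code{[0, 1]}.
#' @export
alpha_direct <- function(pollinia, freqs, weights = NULL) {
  m <- unclass(pollinia)
  if (nrow(m) == 0L) stop("empty pollinium collection")
  p <- vapply(seq_len(nrow(m)),
              function(i) genotype_match_probability(freqs, mlg_row(m, i)),
              numeric(1))
  if (is.null(weights)) weights <- rep(1, nrow(m))
  stopifnot(length(weights) == nrow(m), all(weights >= 0), sum(weights) > 0)
  sum(p * weights) / sum(weights)
}

#' Assemble pollinium records from the visit and genotype tables
#'
#' Links every genotyped pollinium to its visit (hence visitor taxon and
#' control status) and to its maternal stem genotype, and classifies it as
#' self or outcross ([classify_pollinium()]). Pollinia with no co-genotyped
#' locus against their maternal genotype are unclassifiable; they are kept
#' with \code{NA} class, counted, and excluded from the estimators with a
#' warning.
#'
#' @param visits visit table (see [read_visit_table()]); control rows carry
#'   \code{taxon = "CONTROL"}.
#' @param genotypes long genotype table with columns \code{sample_id},
#'   \code{sample_kind} (\code{maternal}|\code{pollinium}), \code{locus},
#'   \code{allele1}, \code{allele2}, and \code{visit_id} on pollinium rows.
#' @return object of class \code{"pollinium_data"}: \code{records} (one row
#'   per pollinium: \code{pollinium_id}, \code{visit_id}, \code{taxon},
#'   \code{maternal_genotype_id}, \code{is_control}, \code{class}),
#'   \code{maternal} and \code{pollinia} genotype matrices, and the locus
#'   set.
#' @export
build_pollinium_data <- function(visits, genotypes) {
  stopifnot(is.data.frame(visits), is.data.frame(genotypes))
  if (!"visit_id" %in% names(genotypes))
    stop("genotype table needs a visit_id column on pollinium rows to ",
         "link pollinia to visits")
  loci <- unique(as.character(genotypes$locus))
  maternal <- mlg_matrix(genotypes, kind = "maternal", loci = loci)
  pollinia <- mlg_matrix(genotypes, kind = "pollinium", loci = loci)

  prow <- unique(genotypes[genotypes$sample_kind == "pollinium",
                           c("sample_id", "visit_id")])
  prow$sample_id <- as.character(prow$sample_id)
  prow$visit_id <- as.character(prow$visit_id)
  if (anyDuplicated(prow$sample_id))
    stop("pollinium sample(s) linked to more than one visit: ",
         paste(unique(prow$sample_id[duplicated(prow$sample_id)]),
               collapse = ", "))
  vi <- match(prow$visit_id, as.character(visits$visit_id))
  if (anyNA(vi))
    stop("pollinium visit_id(s) absent from the visit table: ",
         paste(unique(prow$visit_id[is.na(vi)]), collapse = ", "))
  records <- data.frame(pollinium_id = prow$sample_id,
                        visit_id = prow$visit_id,
                        taxon = as.character(visits$taxon)[vi],
                        maternal_genotype_id =
                          as.character(visits$maternal_genotype_id)[vi],
                        stringsAsFactors = FALSE)
  records$is_control <- records$taxon == "CONTROL"
  absent <- setdiff(records$maternal_genotype_id, rownames(maternal))
  if (length(absent) > 0L)
    stop("maternal genotype(s) missing from the genotype table: ",
         paste(absent, collapse = ", "))

  records$class <- vapply(seq_len(nrow(records)), function(i) {
    tryCatch(classify_pollinium(
      mlg_row(maternal, records$maternal_genotype_id[i]),
      mlg_row(pollinia, records$pollinium_id[i])),
      error = function(e) NA_character_)
  }, character(1))
  n_bad <- sum(is.na(records$class))
  if (n_bad > 0L)
    warning(n_bad, " pollinium/pollinia with no co-genotyped locus against ",
            "the maternal genotype: unclassifiable, excluded from estimators")
  structure(list(records = records, maternal = maternal,
                 pollinia = pollinia, loci = loci,
                 n_unclassifiable = n_bad),
            class = "pollinium_data")
}

#' @export
print.pollinium_data <- function(x, ...) {
  cat("pollinium_data:", nrow(x$records), "genotyped pollinia (",
      sum(x$records$is_control), "control ),",
      nrow(x$maternal), "maternal samples,", length(x$loci), "loci\n")
  if (x$n_unclassifiable > 0L)
    cat("  ", x$n_unclassifiable, "unclassifiable (no shared locus)\n")
  invisible(x)
}

#' Direct self-pollination rate by group
#'
#' The direct estimate: the fraction of classifiable genotyped pollinia
#' whose multilocus genotype matches the maternal genotype, grouped by
#' visitor taxon or by maternal genotype (maternal stems are collapsed to
#' distinct multilocus genotypes first, so inflorescences sharing a genotype
#' pool their pollinia). The direct outcrossing rate is \code{t_d = 1 - S_d}
#' by construction.
#'
#' @param pd a [build_pollinium_data()] object.
#' @param group_by \code{"taxon"} or \code{"maternal_genotype"}.
#' @param include_controls keep \code{CONTROL} pollinia as their own group
#'   (default FALSE for taxon grouping).
#' @return data frame with columns \code{group}, \code{S_d}, \code{n}.
#' @export
direct_selfing_rate <- function(pd, group_by = c("taxon", "maternal_genotype"),
                                include_controls = FALSE) {
  stopifnot(inherits(pd, "pollinium_data"))
  group_by <- match.arg(group_by)
  rec <- pd$records[!is.na(pd$records$class), , drop = FALSE]
  if (group_by == "taxon") {
    if (!include_controls) rec <- rec[!rec$is_control, , drop = FALSE]
    g <- rec$taxon
  } else {
    g <- maternal_class_of(pd)[rec$maternal_genotype_id]
  }
  if (nrow(rec) == 0L) stop("no classifiable pollinia in any group")
  agg <- tapply(rec$class == "self", g, function(z) c(mean(z), length(z)))
  data.frame(group = names(agg),
             S_d = vapply(agg, `[[`, numeric(1), 1L),
             n = as.integer(vapply(agg, `[[`, numeric(1), 2L)),
             row.names = NULL, stringsAsFactors = FALSE)
}

# map maternal sample id -> representative id of its distinct-genotype class
maternal_class_of <- function(pd) {
  reps <- collapse_clones(pd$maternal)
  members <- attr(reps, "members")
  out <- character(0)
  for (j in seq_along(members)) {
    out[members[[j]]] <- rownames(reps)[j]
  }
  out
}
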