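#' Canonicalise a diploid allele call
#'
#' Allele pairs are unordered: \code{A/B} and \code{B/A} are the same diploid
#' genotype. Calls with either allele missing are treated as missing at the
#' whole locus, since a half-called microsatellite peak cannot be scored
#' against another genotype.
#'
#' @param allele1,allele2 character or integer allele labels; \code{NA} or
#'   \code{""} marks a missing allele.
#' @return character vector of canonical \code{"a/b"} strings (alleles sorted
#'   lexicographically), \code{NA} where the call is missing.
#' @examples
#' canonical_call(c("104", "98"), c("98", "104"))  # both "104/98"
#' @export
canonical_call <- function(allele1, allele2) {
  a1 <- as.character(allele1)
  a2 <- as.character(allele2)
  a1[!is.na(a1) & a1 == ""] <- NA_character_
  a2[!is.na(a2) & a2 == ""] <- NA_character_
  out <- ifelse(is.na(a1) | is.na(a2), NA_character_,
                ifelse(a1 <= a2, paste(a1, a2, sep = "/"),
                       paste(a2, a1, sep = "/")))
  out
}

#' Build a multilocus-genotype matrix from a long genotype table
#'
#' The long table has one row per sample x locus with columns
#' \code{sample_id}, \code{locus}, \code{allele1}, \code{allele2} (a
#' \code{sample_kind} column, if present, can be used to filter). The result
#' is a character matrix with one row per sample, one column per locus, and
#' canonical \code{"a/b"} diploid calls (\code{NA} = missing). Locus order is
#' taken from first appearance so it is consistent across a dataset.
#'
#' @param genotypes long-format data frame.
#' @param kind optional value of \code{sample_kind} to keep
#'   (\code{"maternal"} or \code{"pollinium"}).
#' @param loci optional character vector fixing the locus set and order.
#' @return character matrix with \code{rownames} = sample ids, class
#'   \code{"mlg_matrix"} prepended.
#' @export
mlg_matrix <- function(genotypes, kind = NULL, loci = NULL) {
  stopifnot(is.data.frame(genotypes))
  need <- c("sample_id", "locus", "allele1", "allele2")
  miss <- setdiff(need, names(genotypes))
  if (length(miss) > 0L)
    stop("genotype table lacks column(s): ", paste(miss, collapse = ", "))
  g <- genotypes
  if (!is.null(kind)) {
    if (!"sample_kind" %in% names(g))
      stop("genotype table has no sample_kind column but kind= was given")
    g <- g[g$sample_kind == kind, , drop = FALSE]
  }
  if (nrow(g) == 0L) stop("no genotype rows to build an mlg matrix from")
  if (is.null(loci)) loci <- unique(as.character(g$locus))
  samples <- unique(as.character(g$sample_id))
  m <- matrix(NA_character_, nrow = length(samples), ncol = length(loci),
              dimnames = list(samples, loci))
  calls <- canonical_call(g$allele1, g$allele2)
  keep <- as.character(g$locus) %in% loci
  m[cbind(as.character(g$sample_id)[keep], as.character(g$locus)[keep])] <-
    calls[keep]
  class(m) <- c("mlg_matrix", class(m))
  m
}

# number of loci with a scored call, per sample
n_genotyped <- function(m) rowSums(!is.na(unclass(m)))

# one sample's calls as a named vector (names survive single-locus matrices)
mlg_row <- function(m, id) {
  m <- unclass(m)
  stats::setNames(as.vector(m[id, , drop = FALSE]), colnames(m))
}

#' Classify an inserted pollinium as self or outcross
#'
#' A pollinium is an aggregate of pollen grains from one donor flower, so its
#' multilocus genotype is the donor's diploid genotype. The pollinium is
#' classified \code{"self"} iff its unordered diploid genotype is identical
#' to the maternal genotype at every co-genotyped locus; any allele
#' difference at any compared locus makes it \code{"outcross"}. Loci missing
#' in either genotype are excluded from the comparison.
#'
#' @param maternal,pollinium named character vectors of canonical calls
#'   (names = loci), e.g. single rows of an [mlg_matrix()].
#' @return \code{"self"} or \code{"outcross"}.
#' @export
classify_pollinium <- function(maternal, pollinium) {
  shared <- intersect(names(maternal)[!is.na(maternal)],
                      names(pollinium)[!is.na(pollinium)])
  if (length(shared) == 0L)
    stop("no co-genotyped locus between maternal and pollinium genotypes")
  if (all(maternal[shared] == pollinium[shared])) "self" else "outcross"
}
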