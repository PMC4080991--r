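#' Collapse clonal replicates to distinct multilocus genotypes
#'
#' Clonal plants present many stems (ramets) per genetic individual (genet);
#' counting every stem inflates the frequency of whatever alleles the large
#' clones carry. This collapses a sample set to one representative per
#' distinct multilocus genotype over the retained loci.
#'
#' Missing-data rule: classes are first formed from samples fully genotyped
#' at the retained loci. A sample with missing calls joins a class only if it
#' is identical to it at all co-genotyped loci (at least one) and exactly one
#' such class exists; otherwise it founds its own class (samples with the
#' same incomplete pattern share that new class). This is conservative
#' against over-collapsing, which would re-inflate rare-allele frequencies.
#'
#' @param mlg an [mlg_matrix()].
#' @param exclude_locus optional locus name dropped before comparing
#'   genotypes (the leave-one-out step of the round-robin estimator).
#' @return an \code{mlg_matrix} of class representatives (all original loci
#'   retained), with attribute \code{"members"}: a list of member sample-id
#'   vectors per class. The representative is the member with the fewest
#'   missing calls overall (first on ties).
#' @export
collapse_clones <- function(mlg, exclude_locus = NULL) {
  m <- unclass(mlg)
  if (nrow(m) == 0L) stop("empty genotype collection")
  retained <- colnames(m)
  if (!is.null(exclude_locus)) {
    if (!exclude_locus %in% retained)
      stop("exclude_locus '", exclude_locus, "' not present in dataset")
    retained <- setdiff(retained, exclude_locus)
  }
  if (length(retained) == 0L) stop("no loci retained for collapsing")
  sub <- m[, retained, drop = FALSE]
  complete <- rowSums(is.na(sub)) == 0L
  key <- apply(sub, 1L, paste, collapse = "\x1f")

  classes <- list()   # each: list(profile = named chr vector, members = chr)
  class_key <- character(0)
  for (i in which(complete)) {
    k <- key[i]
    j <- match(k, class_key)
    if (is.na(j)) {
      classes[[length(classes) + 1L]] <- list(profile = sub[i, ],
                                              members = rownames(m)[i])
      class_key <- c(class_key, k)
    } else {
      classes[[j]]$members <- c(classes[[j]]$members, rownames(m)[i])
    }
  }
  n_complete_classes <- length(classes)
  incomplete_key <- character(0)  # keys of classes founded by incomplete rows
  for (i in which(!complete)) {
    prof <- sub[i, ]
    scored <- !is.na(prof)
    hit <- 0L
    if (any(scored) && n_complete_classes > 0L) {
      for (j in seq_len(n_complete_classes)) {
        if (all(classes[[j]]$profile[scored] == prof[scored])) {
          hit <- c(hit, j)
        }
      }
      hit <- hit[hit > 0L]
    } else hit <- integer(0)
    if (length(hit) == 1L) {
      classes[[hit]]$members <- c(classes[[hit]]$members, rownames(m)[i])
    } else {
      k <- key[i]
      j <- match(k, incomplete_key)
      if (is.na(j)) {
        classes[[length(classes) + 1L]] <- list(profile = prof,
                                                members = rownames(m)[i])
        incomplete_key <- c(incomplete_key, k)
      } else {
        jj <- n_complete_classes + j
        classes[[jj]]$members <- c(classes[[jj]]$members, rownames(m)[i])
      }
    }
  }

  reps <- vapply(classes, function(cl) {
    mem <- cl$members
    mem[which.max(rowSums(!is.na(m[mem, , drop = FALSE])))]
  }, character(1))
  out <- m[reps, , drop = FALSE]
  class(out) <- c("mlg_matrix", class(out))
  attr(out, "members") <- lapply(classes, `[[`, "members")
  out
}

new_freq_table <- function(loci, method, basis) {
  structure(list(loci = loci, method = method, basis = basis),
            class = "freq_table")
}

# tabulate allele and unordered-genotype frequencies at one locus
tabulate_locus <- function(calls) {
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0L) return(NULL)
  gt <- table(calls) / length(calls)
  alleles <- unlist(strsplit(calls, "/", fixed = TRUE), use.names = FALSE)
  at <- table(alleles) / length(alleles)
  list(allele = c(at), genotype = c(gt))
}

#' Naive per-locus allele and genotype frequencies
#'
#' Straight counting over all samples: every stem (ramet) counts once.
#' Missing calls are dropped locus-wise from the denominator. Diploid
#' genotype frequencies are observed (counted) frequencies, not
#' Hardy-Weinberg products; clonal structure violates HWE so the observed
#' pollen-pool frequencies are the quantity of interest.
#'
#' @param mlg an [mlg_matrix()].
#' @param basis label recording which pool the table describes
#'   (\code{"pollen_pool"} or \code{"maternal"}).
#' @return a \code{freq_table}: per-locus allele and unordered diploid
#'   genotype frequencies, each summing to 1 per locus; loci with no scored
#'   sample are omitted with a warning. Use [as.data.frame()] for the long
#'   form.
#' @export
naive_frequencies <- function(mlg, basis = "pollen_pool") {
  m <- unclass(mlg)
  if (nrow(m) == 0L) stop("empty genotype collection")
  loci <- list()
  for (loc in colnames(m)) {
    tab <- tabulate_locus(m[, loc])
    if (is.null(tab)) {
      warning("locus '", loc, "' has no genotyped sample; omitted")
    } else loci[[loc]] <- tab
  }
  new_freq_table(loci, method = "naive", basis = basis)
}

#' Round-robin per-locus allele and genotype frequencies
#'
#' Leave-one-locus-out frequency estimation for clonal populations: for each
#' locus k, distinct-genotype classes are formed over all loci except k
#' ([collapse_clones()]), and locus-k allele and diploid-genotype frequencies
#' are then tabulated over one representative per class. A genet contributing
#' many ramets therefore counts once, so private alleles of big clones are
#' not inflated, while the left-out locus cannot bias its own collapsing.
#'
#' @inheritParams naive_frequencies
#' @return a \code{freq_table} with \code{method = "round_robin"}.
#' @export
round_robin_frequencies <- function(mlg, basis = "pollen_pool") {
  m <- unclass(mlg)
  if (nrow(m) == 0L) stop("empty genotype collection")
  if (ncol(m) < 2L)
    stop("round-robin estimation needs >= 2 loci (one is left out at a ",
         "time); use naive_frequencies() for a single-locus dataset")
  loci <- list()
  for (loc in colnames(m)) {
    reps <- collapse_clones(mlg, exclude_locus = loc)
    tab <- tabulate_locus(unclass(reps)[, loc])
    if (is.null(tab)) {
      warning("locus '", loc, "' has no genotyped representative; omitted")
    } else loci[[loc]] <- tab
  }
  new_freq_table(loci, method = "round_robin", basis = basis)
}

#' @export
as.data.frame.freq_table <- function(x, ...) {
  rows <- lapply(names(x$loci), function(loc) {
    al <- x$loci[[loc]]$allele
    gt <- x$loci[[loc]]$genotype
    data.frame(locus = loc,
               kind = c(rep("allele", length(al)), rep("genotype", length(gt))),
               label = c(names(al), names(gt)),
               frequency = c(unname(al), unname(gt)),
               method = x$method, basis = x$basis,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' @export
print.freq_table <- function(x, ...) {
  cat("Frequency table (", x$method, ", basis: ", x$basis, ")\n", sep = "")
  for (loc in names(x$loci)) {
    cat("  ", loc, ": ", length(x$loci[[loc]]$allele), " alleles, ",
        length(x$loci[[loc]]$genotype), " diploid genotypes\n", sep = "")
  }
  invisible(x)
}

#' Chance-match probability of a multilocus genotype
#'
#' The probability that a genotype drawn at random from the tabulated pool
#' matches \code{genotype} at every scored locus, assuming independence
#' across loci: the product over the genotype's scored loci of the pool
#' frequency of that unordered diploid genotype. A genotype unseen in the
#' pool at any locus contributes a factor of 0. This is the building block
#' of the erroneous-assignment probability alpha.
#'
#' @param freqs a \code{freq_table}.
#' @param genotype named character vector of canonical calls (names = loci),
#'   e.g. one row of an [mlg_matrix()]; must have >= 1 scored locus, and
#'   every scored locus must be present in \code{freqs}.
#' @return probability in \code{[0, 1]}.
#' @export
genotype_match_probability <- function(freqs, genotype) {
  stopifnot(inherits(freqs, "freq_table"))
  scored <- names(genotype)[!is.na(genotype)]
  if (length(scored) == 0L) stop("genotype has no scored locus")
  absent <- setdiff(scored, names(freqs$loci))
  if (length(absent) > 0L)
    stop("locus ", paste(absent, collapse = ", "),
         " not present in the frequency table")
  p <- 1
  for (loc in scored) {
    gt <- freqs$loci[[loc]]$genotype
    f <- unname(gt[match(genotype[[loc]], names(gt))])
    if (is.na(f)) return(0)
    p <- p * f
  }
  unname(p)
}
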