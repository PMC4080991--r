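# Small programmatic fixtures shared across the suite.

# mlg matrix straight from a named list of per-sample call vectors
mk_mlg <- function(..., loci = NULL) {
  rows <- list(...)
  if (is.null(loci)) loci <- names(rows[[1L]])
  m <- do.call(rbind, lapply(rows, function(r) unname(r[loci])))
  dimnames(m) <- list(names(rows), loci)
  class(m) <- c("mlg_matrix", class(m))
  m
}

# a freq_table with prescribed per-locus genotype (and derived allele)
# frequencies, for arithmetic checks
mk_freqs <- function(genotype_freqs, method = "naive",
                     basis = "pollen_pool") {
  loci <- lapply(genotype_freqs, function(g) {
    al <- unlist(lapply(names(g), function(lbl) {
      a <- strsplit(lbl, "/", fixed = TRUE)[[1L]]
      stats::setNames(rep(g[[lbl]] / 2, 2L), a)
    }))
    list(allele = tapply(al, names(al), sum), genotype = g)
  })
  structure(list(loci = loci, method = method, basis = basis),
            class = "freq_table")
}

# minimal well-formed visit table; extra rows appended as lists
mk_visits <- function(...) {
  base <- data.frame(
    visit_id = c("V1", "V2", "C1"),
    taxon = c("honeybee", "bumblebee", "CONTROL"),
    flowers_visited = c(10, 20, 0),
    inflorescence_size = c(40, 60, 50),
    stem_size = c(100, 120, 110),
    insertions = c(2, 1, 0),
    removals = c(5, 2, 0),
    maternal_genotype_id = c("M1", "M2", "M3"),
    period = "diurnal",
    stringsAsFactors = FALSE)
  extra <- list(...)
  for (e in extra) base <- rbind(base, as.data.frame(e))
  base
}

# long genotype table from mlg matrices (no missingness)
mk_genotable <- function(maternal, pollinia, visit_of) {
  emit <- function(m, kind) {
    do.call(rbind, lapply(rownames(m), function(id) {
      calls <- unclass(m)[id, ]
      a <- do.call(rbind, lapply(calls, function(cc) {
        if (is.na(cc)) c(NA_character_, NA_character_)
        else strsplit(cc, "/", fixed = TRUE)[[1L]]
      }))
      data.frame(sample_id = id, sample_kind = kind,
                 locus = colnames(m), allele1 = a[, 1L], allele2 = a[, 2L],
                 visit_id = if (kind == "pollinium") visit_of[[id]]
                 else NA_character_,
                 stringsAsFactors = FALSE)
    }))
  }
  rbind(emit(maternal, "maternal"), emit(pollinia, "pollinium"))
}

# independent per-locus tally of allele/genotype frequencies (oracle)
tally_frequencies <- function(m, locus, what = c("genotype", "allele")) {
  what <- match.arg(what)
  calls <- unclass(m)[, locus]
  calls <- calls[!is.na(calls)]
  if (what == "genotype") return(table(calls) / length(calls))
  al <- unlist(strsplit(calls, "/", fixed = TRUE))
  table(al) / length(al)
}

# brute-force expected match fraction: donors assembled locus-wise from the
# tabulated pool (counting path, independent of freq_table machinery)
enumeration_alpha <- function(pool, pollinia) {
  pm <- unclass(pool)
  qm <- unclass(pollinia)
  per <- vapply(seq_len(nrow(qm)), function(i) {
    p <- 1
    for (loc in colnames(qm)) {
      if (is.na(qm[i, loc])) next
      col <- pm[, loc]
      col <- col[!is.na(col)]
      p <- p * sum(col == qm[i, loc]) / length(col)
    }
    p
  }, numeric(1))
  mean(per)
}
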