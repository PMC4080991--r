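# Reading the two study tables, validating them, and writing result bundles.

default_visit_aliases <- function() c(
  # verbose supplementary-table-style headers -> canonical field names
  sample_number = "visit_id",
  visitor_taxon = "taxon",
  number_of_flowers_visited = "flowers_visited",
  number_of_pollinium_insertions = "insertions",
  number_of_insertions = "insertions",
  number_of_pollinium_removals = "removals",
  number_of_removals = "removals",
  number_of_flowers_on_the_inflorescence = "inflorescence_size",
  number_of_flowers_on_the_inflorescence_s_stem = "stem_size",
  number_of_flowers_on_the_stem = "stem_size",
  visiting_time = "visit_time",
  maternal_genotype = "maternal_genotype_id")

normalise_header <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[^a-z0-9]+", "_", x)
  gsub("^_|_$", "", x)
}

sniff_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header, fixed = TRUE)) "\t" else ","
}

visit_fields <- function() {
  list(mandatory = c("visit_id", "taxon", "flowers_visited",
                     "inflorescence_size", "stem_size", "insertions",
                     "removals"),
       optional = c("visit_time", "maternal_genotype_id", "site", "period"),
       counts = c("flowers_visited", "inflorescence_size", "stem_size",
                  "insertions", "removals"))
}

#' Read and validate a visit table
#'
#' One row per observed inflorescence visit or bagged control
#' (\code{taxon = "CONTROL"}). Comma or tab delimited (auto-detected from
#' the header, overridable). Verbose supplementary-style headers such as
#' "number of pollinium insertions" are mapped onto the canonical field
#' names via an alias table; unknown extra columns are dropped with a
#' warning. All rows are validated ([validate_visit_table()]) - counts must
#' be numeric and nonnegative, insertions and removals can be at most five
#' per open flower (five stigmatic slits and five pollinaria per flower),
#' the inflorescence cannot hold more flowers than its stem, and control
#' rows must have zero flowers visited. Violations abort with the offending
#' row numbers.
#'
#' @param path file path.
#' @param delim \code{","} or \code{"\t"}; \code{NULL} auto-detects.
#' @param aliases named character vector mapping normalised input headers
#'   to canonical names, merged over [default_visit_aliases()].
#' @return validated visit data frame.
#' @export
read_visit_table <- function(path, delim = NULL, aliases = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(delim)) delim <- sniff_delim(path)
  raw <- utils::read.table(path, header = TRUE, sep = delim,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "\"", comment.char = "")
  names(raw) <- normalise_header(names(raw))
  amap <- default_visit_aliases()
  if (!is.null(aliases)) amap[names(aliases)] <- aliases
  hit <- names(raw) %in% names(amap)
  names(raw)[hit] <- amap[names(raw)[hit]]

  ff <- visit_fields()
  missing_cols <- setdiff(ff$mandatory, names(raw))
  if (length(missing_cols) > 0L)
    stop("visit table lacks mandatory column(s): ",
         paste(missing_cols, collapse = ", "))
  extra <- setdiff(names(raw), c(ff$mandatory, ff$optional))
  if (length(extra) > 0L) {
    warning("ignoring unknown visit-table column(s): ",
            paste(extra, collapse = ", "))
    raw <- raw[, setdiff(names(raw), extra), drop = FALSE]
  }
  for (col in intersect(c(ff$counts, "visit_time"), names(raw))) {
    v <- raw[[col]]
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !is.na(v) & trimws(as.character(v)) != "")
    if (length(bad) > 0L)
      stop("non-numeric value in column '", col, "' at row(s) ",
           paste(bad, collapse = ", "))
    raw[[col]] <- num
  }
  if (!"period" %in% names(raw)) raw$period <- "diurnal"
  if (!"maternal_genotype_id" %in% names(raw))
    raw$maternal_genotype_id <- NA_character_
  validate_visit_table(raw)
}

#' Validate visit-table invariants
#'
#' @param visits visit data frame with canonical column names.
#' @return the data frame, invisibly unchanged, or an error naming every
#'   offending row.
#' @export
validate_visit_table <- function(visits) {
  ff <- visit_fields()
  problems <- character(0)
  flag <- function(rows, msg) {
    if (length(rows) > 0L)
      problems <<- c(problems, paste0(msg, " (row ",
                                      paste(rows, collapse = ", "), ")"))
  }
  for (col in ff$counts)
    flag(which(is.na(visits[[col]]) | visits[[col]] < 0),
         paste0("negative or missing ", col))
  if (length(problems) == 0L) {
    flag(which(visits$insertions > 5 * visits$inflorescence_size),
         "insertions exceed 5 per open flower")
    flag(which(visits$removals > 5 * visits$inflorescence_size),
         "removals exceed 5 per open flower")
    flag(which(visits$inflorescence_size > visits$stem_size),
         "inflorescence_size exceeds stem_size")
    flag(which(visits$inflorescence_size < 1),
         "inflorescence_size must be >= 1")
    flag(which(visits$taxon == "CONTROL" & visits$flowers_visited != 0),
         "CONTROL rows must have flowers_visited = 0")
    if ("period" %in% names(visits))
      flag(which(!visits$period %in% c("diurnal", "nocturnal")),
           "period must be diurnal or nocturnal")
  }
  if (anyDuplicated(visits$visit_id))
    problems <- c(problems, "duplicated visit_id values")
  if (length(problems) > 0L)
    stop("invalid visit table:\n  ", paste(problems, collapse = "\n  "))
  invisible(visits)
}

#' Read a long-format genotype table
#'
#' Columns \code{sample_id}, \code{sample_kind}
#' (\code{maternal}|\code{pollinium}), \code{locus}, \code{allele1},
#' \code{allele2}, and \code{visit_id} on pollinium rows; missing calls are
#' coded as empty fields.
#'
#' @inheritParams read_visit_table
#' @return genotype data frame with empty allele fields as \code{NA}.
#' @export
read_genotype_table <- function(path, delim = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(delim)) delim <- sniff_delim(path)
  g <- utils::read.table(path, header = TRUE, sep = delim,
                         stringsAsFactors = FALSE, check.names = FALSE,
                         quote = "\"", comment.char = "",
                         colClasses = "character")
  names(g) <- normalise_header(names(g))
  need <- c("sample_id", "sample_kind", "locus", "allele1", "allele2")
  missing_cols <- setdiff(need, names(g))
  if (length(missing_cols) > 0L)
    stop("genotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!g$sample_kind %in% c("maternal", "pollinium"))
  if (length(bad) > 0L)
    stop("sample_kind must be maternal or pollinium at row(s) ",
         paste(bad, collapse = ", "))
  for (col in c("allele1", "allele2"))
    g[[col]][trimws(g[[col]]) == ""] <- NA_character_
  g
}

# numeric columns written at full precision so round-trips are exact
write_table_exact <- function(df, path) {
  out <- df
  for (col in names(out))
    if (is.numeric(out[[col]]))
      out[[col]] <- formatC(out[[col]], digits = 17, format = "g")
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
}

read_table_exact <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA",
                    check.names = FALSE, quote = "", comment.char = "")
}

#' Run the whole estimation pipeline
#'
#' Orchestrates the full analysis: selfing-rate fit ([fit_selfing()]),
#' importance metrics fed by the selfing bootstrap
#' ([pollinator_importance()]), the per-genotype display-size export table,
#' and the behaviour summary. Deterministic given \code{config$rng_seed}.
#' When \code{out_dir} is given the bundle is written there as delimited
#' text plus a JSON run manifest ([write_results()]).
#'
#' @param visits visit table (e.g. from [read_visit_table()] or
#'   [simulate_study()]).
#' @param genotypes long genotype table.
#' @param config a [run_config()].
#' @param out_dir optional output directory.
#' @return object of class \code{"pollmate_run"}: \code{selfing},
#'   \code{importance}, \code{behavior}, \code{config}.
#' @export
run_pipeline <- function(visits, genotypes, config = run_config(),
                         out_dir = NULL) {
  validate_visit_table(visits)
  fit <- fit_selfing(visits, genotypes, config)
  imp <- pollinator_importance(visits, selfing = fit, config = config)
  behavior <- summarize_behavior(visits)
  run <- structure(list(selfing = fit, importance = imp,
                        behavior = behavior, config = config),
                   class = "pollmate_run")
  if (!is.null(out_dir)) write_results(run, out_dir)
  run
}

#' @export
print.pollmate_run <- function(x, ...) {
  print(x$selfing)
  cat("\n")
  print(x$importance)
  invisible(x)
}

#' Write a pipeline result bundle as delimited text plus a manifest
#'
#' Emits \code{selfing_estimates.tsv}, \code{importance.tsv},
#' \code{per_genotype_sdp.tsv}, \code{frequencies.tsv},
#' \code{behavior.tsv}, and \code{manifest.json} (config echo, package
#' version, seed, unclassifiable and dropped-replicate counts). Numeric
#' fields are written at full precision, so [read_results()] reproduces
#' them exactly.
#'
#' @param run a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "pollmate_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_exact(run$selfing$estimates,
                    file.path(dir, "selfing_estimates.tsv"))
  write_table_exact(run$importance$table, file.path(dir, "importance.tsv"))
  write_table_exact(run$selfing$per_genotype,
                    file.path(dir, "per_genotype_sdp.tsv"))
  write_table_exact(as.data.frame(run$selfing$freqs),
                    file.path(dir, "frequencies.tsv"))
  write_table_exact(run$behavior, file.path(dir, "behavior.tsv"))
  cfg <- run$config
  manifest <- list(
    package = "pollmate",
    version = as.character(utils::packageVersion("pollmate")),
    config = cfg[!vapply(cfg, is.null, logical(1))],
    seed = if (is.null(cfg$rng_seed)) NA else cfg$rng_seed,
    n_unclassifiable = run$selfing$data$n_unclassifiable,
    zero_contamination = run$selfing$zero_contamination,
    boot_dropped = stats::setNames(
      as.list(run$selfing$estimates$boot_dropped),
      run$selfing$estimates$taxon))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read back a result bundle written by [write_results()]
#'
#' @param dir the bundle directory.
#' @return list of data frames (\code{selfing_estimates},
#'   \code{importance}, \code{per_genotype_sdp}, \code{frequencies},
#'   \code{behavior}) plus the parsed \code{manifest}.
#' @export
read_results <- function(dir) {
  files <- c(selfing_estimates = "selfing_estimates.tsv",
             importance = "importance.tsv",
             per_genotype_sdp = "per_genotype_sdp.tsv",
             frequencies = "frequencies.tsv",
             behavior = "behavior.tsv")
  out <- lapply(files, function(f) read_table_exact(file.path(dir, f)))
  out$manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                      simplifyVector = TRUE)
  out
}

#' Write simulated study tables as delimited text
#'
#' @param study a [simulate_study()] result.
#' @param dir output directory; writes \code{visits.tsv},
#'   \code{genotypes.tsv}, and \code{truth.tsv} (per-pollinium origin and
#'   self labels).
#' @return \code{dir}, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "sim_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_exact(study$visits, file.path(dir, "visits.tsv"))
  write_table_exact(study$genotypes, file.path(dir, "genotypes.tsv"))
  if (!is.null(study$truth$pollinia))
    write_table_exact(study$truth$pollinia, file.path(dir, "truth.tsv"))
  invisible(dir)
}
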