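#' Read a FASTA file
#'
#' Thin wrapper over `Biostrings` that returns plain named character
#' sequences, preserves record order and rejects empty records.
#'
#' @param path FASTA file (LF or CRLF line endings).
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no FASTA records in ", path)
  seqs <- as.character(set)
  # readBStringSet keeps full headers; use the first token as the name
  names(seqs) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  empty <- !nzchar(seqs)
  if (any(empty)) {
    stop("empty FASTA record: '", names(seqs)[empty][1L], "'")
  }
  seqs
}

#' Write named sequences as FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1L, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Parse variant notation
#'
#' Accepts `"H558R"` and `"p.H558R"` tokens and returns the substitution
#' triplet.
#'
#' @param x character vector of variant tokens.
#' @return data.frame with columns `position`, `from_aa`, `to_aa`.
#' @export
parse_variant <- function(x) {
  m <- regmatches(x, regexec("^(?:p\\.)?([A-Za-z])([0-9]+)([A-Za-z])$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) stop("cannot parse variant token: '", x[bad][1L], "'")
  out <- data.frame(
    position = as.integer(vapply(m, `[`, character(1), 3L)),
    from_aa = toupper(vapply(m, `[`, character(1), 2L)),
    to_aa = toupper(vapply(m, `[`, character(1), 4L)),
    stringsAsFactors = FALSE)
  check_residues(out$from_aa, out$to_aa)
  out
}

#' Renumber isoform-2 positions to isoform-1 numbering
#'
#' Isoform 2 of the channel lacks the glutamine at position 1077 and is one
#' residue shorter; variants reported on isoform-2 numbering must be
#' shifted by +1 at and beyond that position to land on the 2016-residue
#' isoform-1 coordinates used everywhere in this package.
#'
#' @param position integer positions on isoform-2 numbering.
#' @return Positions on isoform-1 numbering.
#' @export
renumber_isoform2_to_1 <- function(position) {
  ifelse(position >= 1077L, position + 1L, as.integer(position))
}

#' Published summary counts of the curated EP literature database
#'
#' @param path optional alternative counts TSV (`key`/`value`).
#' @return Named numeric vector of counts.
#' @export
published_counts <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "published_counts.tsv", package = "navvar")
  }
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stats::setNames(as.numeric(tab$value), tab$key)
}

#' Summary statistics derived from the published database counts
#'
#' Recomputes, from the published marginal counts, the derived quantities
#' reported for the curated database: possible substitutions per residue,
#' coverage percentages, the fraction of variants with no measured change,
#' the multi-report and conflict fractions, and the Zero-R baseline accuracy
#' of the zero-current problem (majority-class prevalence).
#'
#' @param counts named counts as returned by [published_counts()].
#' @return Named numeric vector; percentages on the 0-100 scale.
#' @export
summary_statistics <- function(counts = published_counts()) {
  need <- c("protein_length", "possible_unique", "possible_with_duplicates",
            "total_found_variants", "ep_variants", "ep_unchanged",
            "multireport_variants", "multireport_conflicting", "zero_current",
            "total_found_positions", "ep_positions")
  missing <- setdiff(need, names(counts))
  if (length(missing) > 0L) {
    stop("missing counts: ", paste(missing, collapse = ", "))
  }
  with(as.list(counts), c(
    possible_per_position = possible_unique / protein_length,
    pct_found_of_possible = 100 * total_found_variants / possible_unique,
    pct_ep_of_possible = 100 * ep_variants / possible_unique,
    pct_positions_found = 100 * total_found_positions / protein_length,
    pct_positions_ep = 100 * ep_positions / protein_length,
    pct_unchanged = 100 * ep_unchanged / ep_variants,
    pct_multireport = 100 * multireport_variants / ep_variants,
    pct_conflicting_of_multireport =
      100 * multireport_conflicting / multireport_variants,
    zero_r_accuracy_zero_current =
      100 * (ep_variants - zero_current) / ep_variants))
}

#' Write / read an EP report table
#'
#' Tab-separated interchange format for [ep_reports] tables; the round trip
#' is lossless field by field (missing shifts serialise as `NA`).
#'
#' @param reports EP report data.frame.
#' @param path file path.
#' @export
write_ep_reports <- function(reports, path) {
  utils::write.table(reports, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_ep_reports
#' @export
read_ep_reports <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           na.strings = "NA",
                           colClasses = c(alpha_subunit = "character",
                                          beta1 = "character"))
  tab$position <- as.integer(tab$position)
  tab$year <- as.integer(tab$year)
  tab
}

#' Run the full analysis pipeline on a synthetic dataset
#'
#' Generates (or ingests) an EP-report table, resolves labels, assembles
#' features with conservation from a synthetic homolog alignment, computes
#' density reports, evaluates each requested classification problem with
#' each requested method, and writes all artifacts to `out_dir`:
#' `reports.tsv`, `resolved.tsv`, `features.tsv`, `density_*.tsv`,
#' `metrics_<problem>.tsv`, ROC tables, and `manifest.json` (seed, package
#' version, input checksums). The run is fully deterministic in `seed`, so
#' identical invocations produce byte-identical outputs.
#'
#' @param out_dir output directory (created if needed).
#' @param config a [generator_config()].
#' @param topology a `protein_topology`.
#' @param seed integer seed.
#' @param problems classification problems to evaluate.
#' @param methods classifier families to run on each problem.
#' @param reports optional pre-existing EP report table; when supplied the
#'   generator is skipped and `reference`/`conservation` features are
#'   computed only if `protein` is also given.
#' @param protein optional reference residue vector for `reports`.
#' @return Invisibly, a list with the in-memory artifacts (`resolved`,
#'   `features`, `densities`, `evals`, `manifest`).
#' @export
run_pipeline <- function(out_dir, config = generator_config(),
                         topology = load_topology(), seed = 1L,
                         problems = ep_problems(),
                         methods = "naive_bayes",
                         reports = NULL, protein = NULL) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  if (is.null(reports)) {
    sim <- stage("generate", generate_ep_reports(config, topology, seed))
    reports <- sim$reports
    protein <- sim$protein
  }
  write_ep_reports(reports, file.path(out_dir, "reports.tsv"))

  resolved <- stage("resolve", resolve_variants(reports))
  utils::write.table(resolved, file.path(out_dir, "resolved.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  cons <- NULL
  if (!is.null(protein)) {
    aln <- stage("alignment", generate_homolog_alignment(protein, seed = seed))
    cons <- stage("conservation", conservedness(aln))
  } else {
    warning("no reference protein available: conservedness feature omitted")
  }
  feats <- stage("featurize",
                 featurize(resolved, topology, conservation = cons,
                           reference = protein))
  utils::write.table(feats, file.path(out_dir, "features.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  densities <- lapply(c(region = "region", domain = "domain",
                        `region-class` = "region-class"), function(g) {
    d <- stage("density", relative_density(resolved, topology, g))
    utils::write.table(d, file.path(out_dir, paste0("density_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    d
  })

  full <- cbind(resolved[, c("variant", ep_outcomes(), "changed_unchanged")],
                feats[, feature_columns(feats)])
  evals <- list()
  for (problem in problems) {
    ds <- stage("dataset", build_problem_dataset(full, problem))
    ds <- ds[, c("label", feature_columns(feats))]
    met_rows <- list()
    for (m in methods) {
      ev <- stage(paste0("train:", problem, ":", m),
                  tune_and_evaluate(ds, m, seed = seed))
      evals[[paste(problem, m, sep = ":")]] <- ev
      met_rows[[m]] <- data.frame(
        problem = problem, method = m, n_train = ev$n_train,
        n_test = ev$n_test, accuracy = ev$accuracy, auc = ev$auc,
        mcc = ev$mcc, zero_r_accuracy = ev$baseline$accuracy,
        zero_r_auc = ev$baseline$auc, zero_r_mcc = ev$baseline$mcc,
        stringsAsFactors = FALSE)
      if (!is.null(ev$roc)) {
        utils::write.table(
          ev$roc, file.path(out_dir, paste0("roc_", problem, "_", m, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    utils::write.table(do.call(rbind, met_rows),
                       file.path(out_dir, paste0("metrics_", problem, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("navvar")),
    problems = problems, methods = methods,
    checksums = as.list(tools::md5sum(file.path(out_dir, files))))
  names(manifest$checksums) <- files
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(resolved = resolved, features = feats,
                 densities = densities, evals = evals, manifest = manifest))
}
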