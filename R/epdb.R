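#' @name ep_reports
#' @title Electrophysiology report tables
#'
#' @description
#' An EP report is one published whole-cell measurement of one variant. The
#' canonical representation is a data.frame with one row per report and
#' columns:
#'
#' * `variant`, `position`, `from_aa`, `to_aa` — the substitution;
#' * `study_id`, `year` — citation key and publication year;
#' * `cell_type` (`HEK`, `oocyte`, `CHO`, `COS`, `myocyte`, `unknown`),
#'   `alpha_subunit` (`a`, `a*`, `b`, `b*`, `unknown`), `beta1`
#'   (`yes`, `no`, `unknown`) — the experimental set-up;
#' * one finding column per outcome (`zero_current`, `activation`,
#'   `inactivation`, `late`), each `affected`, `unaffected` or
#'   `not_measured`;
#' * `act_shift_mV`, `inact_shift_mV` — optional midpoint shifts, present
#'   only when the corresponding outcome was measured.
NULL

ep_outcomes <- function() c("zero_current", "activation", "inactivation", "late")

ep_problems <- function() {
  c("changed_unchanged", "activation", "inactivation", "late", "zero_current")
}

finding_levels <- function() c("affected", "unaffected", "not_measured")

#' Resolve conflicting findings by majority vote
#'
#' Counts, over all reports of one variant, the reports that measured the
#' outcome and found it affected versus unaffected. A strict majority wins;
#' equal non-zero counts mark the variant as an excluded tie (such variants
#' are dropped from classification datasets); no measured report at all
#' yields `unknown`.
#'
#' @param findings character vector of per-report findings for one outcome
#'   (`affected` / `unaffected` / `not_measured`).
#' @return One of `"affected"`, `"unaffected"`, `"excluded_tie"`,
#'   `"unknown"`.
#' @export
majority_vote <- function(findings) {
  bad <- !findings %in% finding_levels()
  if (any(bad)) stop("unknown finding value: '", findings[bad][1L], "'")
  n_aff <- sum(findings == "affected")
  n_un <- sum(findings == "unaffected")
  if (n_aff == 0L && n_un == 0L) return("unknown")
  if (n_aff > n_un) return("affected")
  if (n_un > n_aff) return("unaffected")
  "excluded_tie"
}

#' Discretise a midpoint shift into three voltage bins
#'
#' Shifts in the half-(in)activation voltage are grouped into
#' `(-Inf, -3)` -> `neg`, `[-3, 3]` -> `mid`, `(3, Inf)` -> `pos`
#' (millivolts; boundary values fall in the middle bin).
#'
#' @param shift_mV numeric vector of shifts in mV.
#' @return Factor with levels `neg`, `mid`, `pos`.
#' @export
discretize_shift <- function(shift_mV) {
  if (any(!is.finite(shift_mV))) stop("shift values must be finite")
  out <- ifelse(shift_mV < -3, "neg", ifelse(shift_mV > 3, "pos", "mid"))
  factor(out, levels = c("neg", "mid", "pos"))
}

#' Select the preferred report under the experimental-condition cascade
#'
#' When several reports measured the same quantitative value, a single one
#' is chosen by a lexicographic filter cascade: (1) reports co-expressing
#' the beta-1 subunit; (2) reports using the `b` alpha-subunit (isoform 2);
#' (3) reports in HEK cells; (4) the most recent report. Each filter is
#' applied only if at least one report survives it; remaining ties break
#' deterministically on `study_id` order.
#'
#' @param reports data.frame of EP reports for a single variant.
#' @return The selected single-row report.
#' @export
select_preferred_report <- function(reports) {
  if (nrow(reports) == 0L) stop("no reports to select from")
  if (length(unique(reports$variant)) > 1L) {
    stop("select_preferred_report expects reports for a single variant")
  }
  narrow <- function(df, keep) if (any(keep)) df[keep, , drop = FALSE] else df
  r <- reports
  r <- narrow(r, r$beta1 == "yes")
  r <- narrow(r, r$alpha_subunit == "b")
  r <- narrow(r, r$cell_type == "HEK")
  r <- narrow(r, r$year == max(r$year))
  r[order(r$study_id), , drop = FALSE][1L, , drop = FALSE]
}

#' Resolve reports into per-variant records
#'
#' Applies [majority_vote()] per outcome to every variant, derives the
#' overall changed/unchanged status (affected if any individual outcome is
#' affected; unaffected only when at least one outcome was measured and
#' none affected), and picks the preferred report for quantitative shifts
#' via [select_preferred_report()].
#'
#' @param reports EP report data.frame (see [ep_reports]).
#' @return data.frame with one row per variant: identity columns, one
#'   resolved label column per outcome, `changed_unchanged`, the chosen
#'   `act_shift_mV` / `inact_shift_mV`, and `n_reports`.
#' @export
resolve_variants <- function(reports) {
  split_idx <- split(seq_len(nrow(reports)), reports$variant)
  rows <- lapply(split_idx, function(idx) {
    rep_v <- reports[idx, , drop = FALSE]
    res <- vapply(ep_outcomes(), function(o) majority_vote(rep_v[[o]]),
                  character(1))
    any_aff <- any(res == "affected")
    any_unaff <- any(res == "unaffected")
    any_tie <- any(res == "excluded_tie")
    changed <- if (any_aff) "affected"
               else if (any_tie) "excluded_tie"
               else if (any_unaff) "unaffected"
               else "unknown"
    pref <- select_preferred_report(rep_v)
    data.frame(
      variant = rep_v$variant[1L], position = rep_v$position[1L],
      from_aa = rep_v$from_aa[1L], to_aa = rep_v$to_aa[1L],
      zero_current = res[["zero_current"]], activation = res[["activation"]],
      inactivation = res[["inactivation"]], late = res[["late"]],
      changed_unchanged = changed,
      act_shift_mV = pref$act_shift_mV, inact_shift_mV = pref$inact_shift_mV,
      n_reports = nrow(rep_v),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build the labelled dataset for one classification problem
#'
#' Keeps only variants whose resolved label for the requested outcome is
#' `affected` or `unaffected`; tie variants are dropped and their fraction
#' recorded. The `changed_unchanged` problem uses the any-outcome-affected
#' label from [resolve_variants()].
#'
#' @param records resolved variant records from [resolve_variants()].
#' @param outcome one of `changed_unchanged`, `activation`, `inactivation`,
#'   `late`, `zero_current`.
#' @return data.frame of the retained records plus a `label` factor
#'   (`unaffected` < `affected`); the fraction of labelled variants lost to
#'   ties is attached as attribute `tie_fraction`.
#' @export
build_problem_dataset <- function(records, outcome) {
  outcome <- match.arg(outcome, ep_problems())
  lab <- records[[outcome]]
  keep <- lab %in% c("affected", "unaffected")
  ties <- sum(lab == "excluded_tie")
  out <- records[keep, , drop = FALSE]
  out$label <- factor(lab[keep], levels = c("unaffected", "affected"))
  attr(out, "tie_fraction") <- if (ties + nrow(out) > 0) {
    ties / (ties + nrow(out))
  } else 0
  out
}

#' Stratified train/test split
#'
#' Splits a labelled dataset into a training and an independent test set,
#' stratified on the label so both sides keep the class balance of small,
#' imbalanced datasets. Reproducible under a fixed seed.
#'
#' @param dataset data.frame with a `label` column.
#' @param train_fraction fraction of rows in the training set (default 2/3).
#' @param seed integer seed.
#' @return List with elements `train` and `test` (disjoint, exhaustive).
#' @export
train_test_split <- function(dataset, train_fraction = 2 / 3, seed = 1L) {
  stopifnot("label" %in% names(dataset), nrow(dataset) >= 3L)
  if (nlevels(droplevels(as.factor(dataset$label))) < 2L) {
    warning("dataset has a single label class")
  }
  idx_by_class <- split(seq_len(nrow(dataset)), dataset$label, drop = TRUE)
  train_idx <- integer(0)
  rng <- local_rng(seed)
  for (idx in idx_by_class) {
    n_train <- round(length(idx) * train_fraction)
    n_train <- min(max(n_train, 1L), length(idx))
    train_idx <- c(train_idx, rng(function() sample(idx, n_train)))
  }
  train_idx <- sort(train_idx)
  list(train = dataset[train_idx, , drop = FALSE],
       test = dataset[setdiff(seq_len(nrow(dataset)), train_idx), , drop = FALSE])
}

# Run `f` under a private RNG state seeded once at first call, restoring the
# caller's state. Returns a closure usable for successive draws.
local_rng <- function(seed) {
  state <- NULL
  first <- TRUE
  function(f) {
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    if (first) {
      set.seed(seed)
      first <<- FALSE
    } else {
      assign(".Random.seed", state, globalenv())
    }
    out <- f()
    state <<- get(".Random.seed", globalenv())
    out
  }
}
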