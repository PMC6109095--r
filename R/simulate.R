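#' Configuration for the synthetic EP-report generator
#'
#' The defaults encode the statistical structure of the curated literature
#' database: 243 variants with cellular EP data, 72% of them showing some
#' change to the current, 74/243 covered by more than one report, 58% of
#' those multi-report variants with conflicting findings, per-outcome
#' observed-affected rates proportional to the published tallies
#' (zero current 30, activation 69, inactivation 125, late 40, out of 243),
#' and region-dependent outcome probabilities (odds multipliers on top of a
#' calibrated base rate, e.g. activation changes concentrated in the
#' voltage-sensing S4 segments and zero-current variants in the pore-forming
#' S5-S6 linkers).
#'
#' @param n_variants number of distinct variants.
#' @param p_changed marginal probability that a variant shows any measured
#'   change.
#' @param p_multireport probability a variant has more than one report.
#' @param p_conflict_given_multi probability that a multi-report variant
#'   carries one conflicting report.
#' @param outcome_rates relative observed-affected rates per outcome; they
#'   are rescaled jointly so the implied changed fraction equals
#'   `p_changed`.
#' @param measurement_rates probability each outcome is measured for a
#'   conducting channel (zero current is always assessed first; kinetics
#'   cannot be measured on a channel conducting no current).
#' @param region_effects named list per outcome of region-class odds
#'   multipliers (selectors as in [distance_to()]).
#' @param position_weights region-class sampling weights for variant
#'   positions (regions not listed have weight 1).
#' @param shift_sd_affected,shift_sd_unaffected standard deviation (mV) of
#'   the true midpoint shift for affected / unaffected gating outcomes.
#' @param cell_type_probs,alpha_probs,beta1_probs metadata marginals.
#' @param year_range publication-year range (uniform).
#' @return A validated `generator_config` list.
#' @export
generator_config <- function(
    n_variants = 243L,
    p_changed = 0.72,
    p_multireport = 74 / 243,
    p_conflict_given_multi = 0.58,
    outcome_rates = c(zero_current = 30, activation = 69,
                      inactivation = 125, late = 40) / 243,
    measurement_rates = c(zero_current = 1, activation = 0.85,
                          inactivation = 0.85, late = 0.5),
    region_effects = list(
      zero_current = c(L56 = 8),
      activation = c(S4 = 8),
      inactivation = c(S4 = 3, C = 2, "domain-linker" = 2),
      late = c(C = 3, "domain-linker" = 2)),
    position_weights = c(S4 = 3, L34 = 3, L56 = 1.5),
    shift_sd_affected = 12,
    shift_sd_unaffected = 1.5,
    cell_type_probs = c(HEK = 0.55, oocyte = 0.25, CHO = 0.12, COS = 0.03,
                        myocyte = 0.02, unknown = 0.03),
    alpha_probs = c(a = 0.25, "a*" = 0.12, b = 0.40, "b*" = 0.05,
                    unknown = 0.18),
    beta1_probs = c(yes = 0.5, no = 0.4, unknown = 0.1),
    year_range = c(1995L, 2017L)) {
  cfg <- list(n_variants = as.integer(n_variants), p_changed = p_changed,
              p_multireport = p_multireport,
              p_conflict_given_multi = p_conflict_given_multi,
              outcome_rates = outcome_rates,
              measurement_rates = measurement_rates,
              region_effects = region_effects,
              position_weights = position_weights,
              shift_sd_affected = shift_sd_affected,
              shift_sd_unaffected = shift_sd_unaffected,
              cell_type_probs = cell_type_probs, alpha_probs = alpha_probs,
              beta1_probs = beta1_probs, year_range = year_range)
  probs <- c(p_changed, p_multireport, p_conflict_given_multi,
             outcome_rates, measurement_rates)
  if (any(probs < 0 | probs > 1)) {
    stop("all probabilities must lie in [0, 1]")
  }
  if (p_conflict_given_multi > 0 && p_multireport == 0) {
    stop("infeasible config: conflicts require multi-report variants")
  }
  if (any(unlist(region_effects) <= 0)) {
    stop("region odds multipliers must be positive")
  }
  stopifnot(setequal(names(outcome_rates), ep_outcomes()),
            setequal(names(measurement_rates), ep_outcomes()))
  class(cfg) <- "generator_config"
  cfg
}

#' A null generator configuration with no positional signal
#'
#' Identical to [generator_config()] but with all region odds multipliers
#' removed and uniform position sampling, so no feature carries information
#' about the outcomes.
#'
#' @param ... overrides passed on to [generator_config()].
#' @export
null_generator_config <- function(...) {
  generator_config(region_effects = list(
    zero_current = c(S4 = 1), activation = c(S4 = 1),
    inactivation = c(S4 = 1), late = c(S4 = 1)),
    position_weights = c(S4 = 1), ...)
}

# Per-region multiplier vector over topology regions for one outcome.
region_multipliers <- function(topology, effects) {
  mult <- rep(1, nrow(topology$regions))
  for (cls in names(effects)) {
    mult[match_region_class(topology, cls)] <- effects[[cls]]
  }
  mult
}

# Calibrate per-outcome base odds so that the expected observed-affected
# rate per outcome stays proportional to `outcome_rates` and the implied
# changed fraction equals `p_changed`, given the sampled positions.
calibrate_outcome_probs <- function(config, topology, positions) {
  reg <- region_index_of(topology, positions)
  mult <- lapply(ep_outcomes(), function(o) {
    region_multipliers(topology, config$region_effects[[o]])[reg]
  })
  names(mult) <- ep_outcomes()
  m_rate <- config$measurement_rates
  t_rate <- config$outcome_rates

  probs_for <- function(c_global) {
    # zero current first (always measured, gates the rest)
    solve_base <- function(target, mult_v, weight_v) {
      if (target <= 0) return(rep(0, length(mult_v)))
      if (target >= mean(weight_v) * 0.9999) {
        stop("infeasible outcome rate", call. = FALSE)
      }
      f <- function(lb) {
        odds <- exp(lb) * mult_v
        mean(weight_v * odds / (1 + odds)) - target
      }
      lb <- stats::uniroot(f, c(-30, 30), tol = 1e-10)$root
      odds <- exp(lb) * mult_v
      odds / (1 + odds)
    }
    p_zero <- solve_base(c_global * t_rate[["zero_current"]],
                         mult[["zero_current"]], rep(1, length(positions)))
    others <- setdiff(ep_outcomes(), "zero_current")
    p_other <- lapply(others, function(o) {
      solve_base(c_global * t_rate[[o]], mult[[o]],
                 (1 - p_zero) * m_rate[[o]])
    })
    names(p_other) <- others
    c(list(zero_current = p_zero), p_other)
  }

  changed_frac <- function(c_global) {
    p <- probs_for(c_global)
    others <- setdiff(ep_outcomes(), "zero_current")
    p_none <- Reduce(`*`, lapply(others, function(o) {
      1 - m_rate[[o]] * p[[o]]
    }))
    mean(p$zero_current + (1 - p$zero_current) * (1 - p_none))
  }

  # bracket the feasible range: changed_frac is increasing in the global
  # rate factor; grow the upper bound until it crosses the target or the
  # per-outcome rates become unattainable
  f <- function(cg) changed_frac(cg) - config$p_changed
  lo <- 1e-4
  if (f(lo) > 0) stop("p_changed unattainably low for these outcome rates")
  hi <- 1
  repeat {
    val <- tryCatch(f(hi), error = function(e) NA_real_)
    if (is.na(val)) {
      stop("infeasible config: p_changed = ", config$p_changed,
           " is not reachable with these measurement/outcome rates")
    }
    if (val > 0) break
    hi <- hi * 1.4
    if (hi > 1e3) stop("calibration failed to bracket p_changed")
  }
  c_global <- stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  probs_for(c_global)
}

#' Generate a synthetic EP-report dataset
#'
#' Emulates the study conditions end to end: draws a random stop-free
#' coding sequence of the topology's length, enumerates its reachable
#' missense substitutions, samples variants with region-class weights,
#' assigns per-outcome true statuses from region-modulated logistic odds
#' (calibrated so the marginal changed fraction matches the configuration),
#' and emits one or more per-publication reports per variant, with
#' conflicting findings injected into a configurable fraction of
#' multi-report variants, midpoint shifts drawn conditional on the true
#' status, and experimental metadata drawn from the configured marginals.
#' Fully reproducible from the seed.
#'
#' @param config a [generator_config()].
#' @param topology a `protein_topology`; default the shipped Nav1.5 model.
#' @param seed integer seed.
#' @return List with `cds` (character), `protein` (residue vector),
#'   `census` (the `substitution_census`), `variants` (ground truth: one
#'   row per variant with true per-outcome findings and true shifts),
#'   `reports` (the EP-report table, see [ep_reports]), `config`, `seed`.
#' @export
generate_ep_reports <- function(config = generator_config(),
                                topology = load_topology(), seed = 1L) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  sense_codons <- names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
  cds <- paste(sample(sense_codons, topology$length, replace = TRUE),
               collapse = "")
  census <- enumerate_missense(cds)
  protein <- census$protein

  pos_weight <- rep(1, nrow(topology$regions))
  for (cls in names(config$position_weights)) {
    pos_weight[match_region_class(topology, cls)] <- config$position_weights[[cls]]
  }
  sub_w <- pos_weight[region_index_of(topology, census$substitutions$position)]
  pick <- sample(nrow(census$substitutions), config$n_variants, prob = sub_w)
  vars <- census$substitutions[sort(pick), c("position", "from_aa", "to_aa")]
  rownames(vars) <- NULL
  vars$variant <- paste0(vars$from_aa, vars$position, vars$to_aa)

  p <- calibrate_outcome_probs(config, topology, vars$position)
  n <- nrow(vars)
  status <- lapply(ep_outcomes(), function(o) {
    stats::rbinom(n, 1L, p[[o]]) == 1L
  })
  names(status) <- ep_outcomes()
  measured <- list(zero_current = rep(TRUE, n))
  for (o in setdiff(ep_outcomes(), "zero_current")) {
    measured[[o]] <- !status$zero_current &
      stats::rbinom(n, 1L, config$measurement_rates[[o]]) == 1L
  }
  finding <- lapply(ep_outcomes(), function(o) {
    ifelse(!measured[[o]], "not_measured",
           ifelse(status[[o]], "affected", "unaffected"))
  })
  names(finding) <- ep_outcomes()

  true_shift <- function(o, sd_a, sd_u) {
    ifelse(measured[[o]],
           stats::rnorm(n, 0, ifelse(status[[o]], sd_a, sd_u)), NA_real_)
  }
  act_shift <- true_shift("activation", config$shift_sd_affected,
                          config$shift_sd_unaffected)
  inact_shift <- true_shift("inactivation", config$shift_sd_affected,
                            config$shift_sd_unaffected)

  variants <- data.frame(vars,
    zero_current = finding$zero_current, activation = finding$activation,
    inactivation = finding$inactivation, late = finding$late,
    act_shift_mV = act_shift, inact_shift_mV = inact_shift,
    stringsAsFactors = FALSE)

  multi <- stats::rbinom(n, 1L, config$p_multireport) == 1L
  n_rep <- ifelse(multi, 2L + stats::rbinom(n, 2L, 0.3), 1L)
  conflict <- multi & stats::rbinom(n, 1L, config$p_conflict_given_multi) == 1L

  ri <- rep(seq_len(n), n_rep)
  m <- length(ri)
  reports <- data.frame(
    variant = vars$variant[ri], position = vars$position[ri],
    from_aa = vars$from_aa[ri], to_aa = vars$to_aa[ri],
    study_id = sprintf("study%05d", seq_len(m)),
    year = sample(seq(config$year_range[1L], config$year_range[2L]), m,
                  replace = TRUE),
    cell_type = sample(names(config$cell_type_probs), m, replace = TRUE,
                       prob = config$cell_type_probs),
    alpha_subunit = sample(names(config$alpha_probs), m, replace = TRUE,
                           prob = config$alpha_probs),
    beta1 = sample(names(config$beta1_probs), m, replace = TRUE,
                   prob = config$beta1_probs),
    zero_current = finding$zero_current[ri],
    activation = finding$activation[ri],
    inactivation = finding$inactivation[ri],
    late = finding$late[ri],
    act_shift_mV = ifelse(measured$activation[ri],
                          act_shift[ri] + stats::rnorm(m, 0, 1), NA_real_),
    inact_shift_mV = ifelse(measured$inactivation[ri],
                            inact_shift[ri] + stats::rnorm(m, 0, 1), NA_real_),
    stringsAsFactors = FALSE)
  for (i in which(conflict)) {
    rows <- which(ri == i)
    meas <- ep_outcomes()[vapply(ep_outcomes(), function(o) {
      reports[[o]][rows[1L]] != "not_measured"
    }, logical(1))]
    o <- if (length(meas) == 1L) meas else sample(meas, 1L)
    j <- if (length(rows) == 1L) rows else sample(rows, 1L)
    reports[[o]][j] <- if (reports[[o]][j] == "affected") "unaffected"
                       else "affected"
  }

  list(cds = cds, protein = protein, census = census, variants = variants,
       reports = reports, conflict = conflict, config = config, seed = seed)
}

#' Generate a synthetic homolog alignment for conservation scoring
#'
#' Produces aligned rows derived from the reference protein by random
#' substitutions (at increasing divergence per row) and occasional gaps, so
#' the conservation module can run without a real homolog set. The
#' reference row is ungapped.
#'
#' @param protein reference residue vector (or single string).
#' @param n_homologs number of non-reference rows.
#' @param divergence per-row substitution probabilities; recycled.
#' @param gap_rate per-site gap probability in homolog rows.
#' @param seed integer seed.
#' @return An `msa_alignment` with reference row `"reference"`.
#' @export
generate_homolog_alignment <- function(protein, n_homologs = 10L,
                                       divergence = seq(0.05, 0.5,
                                                        length.out = n_homologs),
                                       gap_rate = 0.02, seed = 1L) {
  if (length(protein) == 1L) protein <- strsplit(protein, "")[[1L]]
  set.seed(seed)
  divergence <- rep_len(divergence, n_homologs)
  aas <- amino_acids()
  rows <- vapply(seq_len(n_homologs), function(i) {
    s <- protein
    mut <- stats::runif(length(s)) < divergence[i]
    s[mut] <- sample(aas, sum(mut), replace = TRUE)
    gap <- stats::runif(length(s)) < gap_rate
    s[gap] <- "-"
    paste(s, collapse = "")
  }, character(1))
  seqs <- c(reference = paste(protein, collapse = ""),
            stats::setNames(rows, paste0("homolog", seq_len(n_homologs))))
  msa_alignment(seqs, "reference")
}

#' Signal-recovery experiment on synthetic data
#'
#' Runs the full pipeline (generate, resolve, featurize, train, evaluate
#' each classification problem with each method) over several seeds. The
#' pipeline is a system of independent classifiers, one per outcome, so
#' recovery is judged the way the study reports its results: per seed, the
#' best test-set MCC over all problem/method combinations, and whether a
#' region-derived feature (region type, segment type, side, or any
#' residue-count distance) ranks in the top `k` features by information
#' gain for the best combination. With the default strong region effects
#' the planted positional signal should be recovered; with
#' [null_generator_config()] the best MCC should centre on zero.
#'
#' @param config a [generator_config()].
#' @param problems classification problems to evaluate (default all five).
#' @param methods classifier families to try.
#' @param seeds integer vector of seeds (one pipeline run each).
#' @param topology a `protein_topology`.
#' @param top_k information-gain rank threshold.
#' @return data.frame with one row per seed: `best_problem`, `best_mcc`,
#'   `best_method`, `best_auc`, `zero_r_accuracy`, `top_region_rank`,
#'   `region_in_top_k`.
#' @export
recovery_experiment <- function(config = generator_config(),
                                problems = ep_problems(),
                                methods = c("naive_bayes", "random_forest",
                                            "knn", "svm"),
                                seeds = 1:20,
                                topology = load_topology(),
                                top_k = 3L) {
  props <- load_aa_properties()
  grantham <- load_grantham()
  gonnet <- load_gonnet()
  rows <- lapply(seeds, function(s) {
    sim <- generate_ep_reports(config, topology, seed = s)
    resolved <- resolve_variants(sim$reports)
    aln <- generate_homolog_alignment(sim$protein, seed = s)
    cons <- conservedness(aln, gonnet = gonnet)
    feats <- featurize(resolved, topology, props, grantham, gonnet,
                       conservation = cons, reference = sim$protein)
    resolved_feats <- cbind(resolved[, c("variant", ep_outcomes(),
                                         "changed_unchanged")],
                            feats[, feature_columns(feats)])
    evals <- list()
    for (problem in problems) {
      ds <- build_problem_dataset(resolved_feats, problem)
      ds <- ds[, c("label", feature_columns(feats))]
      for (m in methods) {
        evals[[paste(problem, m, sep = ":")]] <-
          c(tune_and_evaluate(ds, m, seed = s), problem = problem)
      }
    }
    mccs <- vapply(evals, function(e) e$mcc, numeric(1))
    best <- which.max(mccs)
    ev <- evals[[best]]
    ig <- ev$info_gain
    region_feats <- c("region_type", "segment_type", "side",
                      grep("^dist_", names(ig), value = TRUE))
    rank_region <- min(match(region_feats, names(ig)), na.rm = TRUE)
    data.frame(seed = s, best_problem = ev$problem, best_mcc = ev$mcc,
               best_method = ev$method, best_auc = ev$auc,
               zero_r_accuracy = ev$baseline$accuracy,
               top_region_rank = rank_region,
               region_in_top_k = rank_region <= top_k,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "problems") <- problems
  attr(out, "top_k") <- top_k
  out
}
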