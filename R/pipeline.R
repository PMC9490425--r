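#' Bonferroni-adjusted significance threshold
#'
#' Divides the family-wise level by the number of tests. For a 3-exposure by
#' 3-outcome design at a nominal 0.05 this gives 0.05/9 = 0.0056 (4 dp).
#'
#' @param alpha_family family-wise error level in (0,1).
#' @param n_tests number of tests (>= 1).
#' @return The per-test threshold.
#' @export
bonferroni_threshold <- function(alpha_family, n_tests) {
  if (!is_scalar_number(alpha_family) || alpha_family <= 0 || alpha_family >= 1) {
    stop("`alpha_family` must lie in (0,1)", call. = FALSE)
  }
  if (!is_scalar_number(n_tests) || n_tests < 1 || n_tests != round(n_tests)) {
    stop("`n_tests` must be a positive integer", call. = FALSE)
  }
  alpha_family / n_tests
}

#' Classify a p-value into significance tiers
#'
#' `significant` below the multiplicity-corrected threshold, `suggestive`
#' between the corrected threshold and the nominal level, `null` otherwise.
#'
#' @param pvalue p-value(s) in (0,1].
#' @param threshold corrected threshold (e.g. [bonferroni_threshold()]).
#' @param alpha_nominal nominal level (default 0.05); must exceed
#'   `threshold`.
#' @return Character vector: `"significant"`, `"suggestive"` or `"null"`.
#' @export
classify_tier <- function(pvalue, threshold, alpha_nominal = 0.05) {
  if (!is_scalar_number(threshold) || !is_scalar_number(alpha_nominal) ||
      threshold >= alpha_nominal) {
    stop("`threshold` must be smaller than `alpha_nominal`", call. = FALSE)
  }
  if (any(is.na(pvalue) | pvalue <= 0 | pvalue > 1)) {
    stop("p-values must lie in (0,1]", call. = FALSE)
  }
  ifelse(pvalue < threshold, "significant",
         ifelse(pvalue < alpha_nominal, "suggestive", "null"))
}

#' Run every MR estimator and diagnostic on one harmonized pair
#'
#' The per-pair workhorse: IVW (both variants), weighted median, MR-Egger
#' slope and intercept, Cochran's Q, leave-one-out, and plot-ready forest
#' and scatter tables.
#'
#' @param h a `harmonized_set` with at least 3 usable instruments.
#' @param n_boot,seed weighted-median bootstrap settings.
#' @param ci_level confidence level.
#' @return List of class `mr_analysis`: `estimates` (five-method data frame
#'   with both IVW variants' intervals), `heterogeneity`, `loo`, `forest`,
#'   `scatter`, `exposure`, `outcome`.
#' @export
mr_analysis <- function(h, n_boot = 5000, seed = 1, ci_level = 0.95) {
  d <- usable_instruments(h)
  if (nrow(d) < 3L) {
    stop("a full MR analysis requires at least 3 usable instruments (got ",
         nrow(d), ")", call. = FALSE)
  }
  ivw_f <- mr_ivw(h, "fixed", ci_level)
  ivw_m <- mr_ivw(h, "multiplicative_random", ci_level)
  wm <- mr_weighted_median(h, n_boot = n_boot, seed = seed,
                           ci_level = ci_level)
  eg <- mr_egger(h, ci_level)
  q <- cochran_q(h)
  estimates <- do.call(rbind, lapply(list(ivw_f, ivw_m, wm, eg$slope,
                                          eg$intercept), as.data.frame))
  structure(list(estimates = estimates, heterogeneity = q,
                 loo = leave_one_out(h),
                 forest = single_snp_forest(h),
                 scatter = scatter_data(h, list(ivw_f, wm, eg)),
                 exposure = attr(h, "exposure_name"),
                 outcome = attr(h, "outcome_name")),
            class = "mr_analysis")
}

# One Tables-style result row per method for a completed analysis.
analysis_rows <- function(an, tier_threshold = NULL, alpha_nominal = 0.05,
                          headline_model = "fixed") {
  est <- an$estimates
  q <- an$heterogeneity
  ivw_f <- est[est$method == "ivw_fixed", ]
  ivw_m <- est[est$method == "ivw_mre", ]
  int <- est[est$method == "egger_intercept", ]
  ivw_head <- if (headline_model == "fixed") ivw_f else ivw_m
  ivw_alt <- if (headline_model == "fixed") ivw_m else ivw_f
  row <- function(label, e, q_stat = NA, q_p = NA, int_b = NA, int_p = NA,
                  alt = NULL) {
    data.frame(EXPOSURE = an$exposure, OUTCOME = an$outcome, METHOD = label,
               NSNP = e$n_snps, OR = e$odds_ratio, CI_LOW = e$ci_low,
               CI_HIGH = e$ci_high,
               CI_LOW_ALT = if (is.null(alt)) NA_real_ else alt$ci_low,
               CI_HIGH_ALT = if (is.null(alt)) NA_real_ else alt$ci_high,
               P = e$pvalue, Q = q_stat, Q_P = q_p,
               EGGER_INTERCEPT = int_b, EGGER_INTERCEPT_P = int_p,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    row("Inverse-variance weighted", ivw_head, q$q_stat, q$pvalue,
        alt = ivw_alt),
    row("Weighted median", est[est$method == "weighted_median", ]),
    row("MR-Egger regression", est[est$method == "egger_slope", ],
        int_b = int$beta, int_p = int$pvalue))
  if (!is.null(tier_threshold)) {
    out$TIER <- NA_character_
    out$TIER[1] <- classify_tier(out$P[1], tier_threshold, alpha_nominal)
  }
  out
}

#' Read an analysis configuration file
#'
#' YAML with top-level keys `exposures` (list of `trait`, `file`,
#' `p_threshold`, optional `column_map`), `outcomes` (list of `trait`,
#' `file`, optional `column_map`), optional `proxy_maps` (list of
#' `exposure`, `outcome`, `file`), and scalar options
#' `palindromic_eaf_window`, `ivw_model` (`fixed` or
#' `multiplicative_random`), `n_boot`, `seed`, `alpha_family`, `n_tests`,
#' `output_dir`.
#'
#' @param path YAML file path.
#' @return Validated config list of class `mr_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg, base_dir = dirname(path))
}

validate_config <- function(cfg, base_dir = ".") {
  if (is.null(cfg$exposures) || is.null(cfg$outcomes)) {
    stop("config must list `exposures` and `outcomes`", call. = FALSE)
  }
  resolve <- function(f) {
    if (file.exists(f)) f else file.path(base_dir, f)
  }
  for (i in seq_along(cfg$exposures)) {
    e <- cfg$exposures[[i]]
    if (is.null(e$trait) || is.null(e$file)) {
      stop("each exposure needs `trait` and `file`", call. = FALSE)
    }
    cfg$exposures[[i]]$file <- resolve(e$file)
    cfg$exposures[[i]]$p_threshold <- e$p_threshold %||% 5e-8
  }
  for (i in seq_along(cfg$outcomes)) {
    o <- cfg$outcomes[[i]]
    if (is.null(o$trait) || is.null(o$file)) {
      stop("each outcome needs `trait` and `file`", call. = FALSE)
    }
    cfg$outcomes[[i]]$file <- resolve(o$file)
  }
  for (i in seq_along(cfg$proxy_maps)) {
    cfg$proxy_maps[[i]]$file <- resolve(cfg$proxy_maps[[i]]$file)
  }
  all_files <- c(vapply(cfg$exposures, `[[`, "", "file"),
                 vapply(cfg$outcomes, `[[`, "", "file"),
                 vapply(cfg$proxy_maps %||% list(), `[[`, "", "file"))
  missing_files <- all_files[!file.exists(all_files)]
  if (length(missing_files)) {
    stop("config references missing file(s): ",
         paste(missing_files, collapse = ", "), call. = FALSE)
  }
  cfg$palindromic_eaf_window <- cfg$palindromic_eaf_window %||% 0.08
  cfg$ivw_model <- cfg$ivw_model %||% "fixed"
  cfg$n_boot <- cfg$n_boot %||% 5000
  cfg$seed <- cfg$seed %||% 1
  cfg$alpha_family <- cfg$alpha_family %||% 0.05
  cfg$n_tests <- cfg$n_tests %||%
    (length(cfg$exposures) * length(cfg$outcomes))
  cfg$alpha_nominal <- cfg$alpha_nominal %||% 0.05
  structure(cfg, class = "mr_config")
}

#' Run a configured set of exposure-outcome MR analyses
#'
#' For every exposure-outcome pair: select instruments, substitute proxies
#' if a map is configured, harmonize, run all estimators and diagnostics,
#' and classify the headline IVW p-value into significance tiers under the
#' Bonferroni threshold. Pairs with fewer than 3 usable instruments are
#' reported as failed and the run continues.
#'
#' @param config an `mr_config` (see [read_analysis_config()]) or a list
#'   with the same shape.
#' @param output_dir directory for result TSVs, plot data and the run log;
#'   `NULL` (default) writes nothing.
#' @return List of class `mr_run`: `results` (master Tables-style data
#'   frame, one tier-annotated IVW row plus sensitivity rows per pair),
#'   `analyses` (named list of `mr_analysis` objects), `failures` (named
#'   reasons), `threshold`, `log` (character vector of JSON lines).
#' @export
run_mr_config <- function(config, output_dir = NULL) {
  cfg <- if (inherits(config, "mr_config")) config else validate_config(config)
  threshold <- bonferroni_threshold(cfg$alpha_family, cfg$n_tests)
  log <- character()
  note <- function(...) {
    rec <- list(...)
    rec$time <- format(Sys.time(), "%Y-%m-%dT%H:%M:%S")
    log <<- c(log, jsonlite::toJSON(rec, auto_unbox = TRUE))
  }
  note(event = "run_start", seed = cfg$seed, ivw_model = cfg$ivw_model,
       n_boot = cfg$n_boot, alpha_family = cfg$alpha_family,
       n_tests = cfg$n_tests, threshold = threshold,
       package_version = as.character(utils::packageVersion("mrkit")))

  outcomes <- lapply(cfg$outcomes, function(o) {
    read_summary_table(o$file, trait_name = o$trait, role = "outcome",
                       column_map = o$column_map)
  })
  names(outcomes) <- vapply(cfg$outcomes, `[[`, "", "trait")

  results <- list()
  analyses <- list()
  failures <- list()
  for (e in cfg$exposures) {
    exposure_full <- read_summary_table(e$file, trait_name = e$trait,
                                        role = "exposure",
                                        column_map = e$column_map)
    instruments <- select_instruments(exposure_full, e$p_threshold)
    note(event = "instrument_selection", exposure = e$trait,
         p_threshold = e$p_threshold, n_selected = nrow(instruments))
    for (o_trait in names(outcomes)) {
      pair <- paste0(e$trait, "->", o_trait)
      res <- tryCatch({
        expo <- instruments
        pm <- Filter(function(p) p$exposure == e$trait && p$outcome == o_trait,
                     cfg$proxy_maps %||% list())
        if (length(pm)) {
          expo <- apply_proxy_map(expo, outcomes[[o_trait]],
                                  read_proxy_map(pm[[1]]$file))
          note(event = "proxy_substitution", pair = pair,
               log = attr(expo, "proxy_log"))
        }
        h <- harmonize_sets(expo, outcomes[[o_trait]],
                            palindromic_eaf_window = cfg$palindromic_eaf_window)
        audit <- attr(h, "audit")
        note(event = "harmonization", pair = pair,
             audit = as.list(table(audit$STATUS)))
        an <- mr_analysis(h, n_boot = cfg$n_boot, seed = cfg$seed)
        analyses[[pair]] <- an
        analysis_rows(an, tier_threshold = threshold,
                      alpha_nominal = cfg$alpha_nominal,
                      headline_model = if (cfg$ivw_model == "fixed")
                        "fixed" else "mre")
      }, error = function(err) {
        failures[[pair]] <<- conditionMessage(err)
        note(event = "pair_failed", pair = pair,
             reason = conditionMessage(err))
        NULL
      })
      if (!is.null(res)) results[[pair]] <- res
    }
  }
  master <- if (length(results)) do.call(rbind, results) else NULL
  if (!is.null(master)) rownames(master) <- NULL
  note(event = "run_end", n_pairs_done = length(results),
       n_pairs_failed = length(failures))

  run <- structure(list(results = master, analyses = analyses,
                        failures = failures, threshold = threshold,
                        config = cfg, log = log),
                   class = "mr_run")
  if (!is.null(output_dir)) write_mr_run(run, output_dir)
  run
}

#' Write the outputs of an MR run to disk
#'
#' Emits `results.tsv` (master table, p-values to 3 significant figures and
#' ORs/CIs to 3 decimals in the companion `results_formatted.tsv`),
#' per-pair leave-one-out / forest / scatter TSVs, and `run.log`
#' (line-delimited JSON events).
#'
#' @param run an `mr_run`.
#' @param output_dir directory, created if needed.
#' @return `output_dir`, invisibly.
#' @export
write_mr_run <- function(run, output_dir) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  tsv <- function(d, f) {
    utils::write.table(d, file.path(output_dir, f), sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  if (!is.null(run$results)) {
    tsv(run$results, "results.tsv")
    fmt <- run$results
    for (col in c("OR", "CI_LOW", "CI_HIGH", "CI_LOW_ALT", "CI_HIGH_ALT",
                  "EGGER_INTERCEPT")) {
      fmt[[col]] <- ifelse(is.na(fmt[[col]]), NA,
                           sprintf("%.3f", fmt[[col]]))
    }
    for (col in c("P", "Q_P", "EGGER_INTERCEPT_P")) {
      fmt[[col]] <- ifelse(is.na(fmt[[col]]), NA,
                           signif(fmt[[col]], 3))
    }
    fmt$Q <- ifelse(is.na(fmt$Q), NA, sprintf("%.3f", fmt$Q))
    tsv(fmt, "results_formatted.tsv")
  }
  for (pair in names(run$analyses)) {
    an <- run$analyses[[pair]]
    slug <- gsub("[^A-Za-z0-9]+", "_", pair)
    tsv(an$loo, paste0(slug, "_leave_one_out.tsv"))
    tsv(an$forest, paste0(slug, "_forest.tsv"))
    tsv(an$scatter$points, paste0(slug, "_scatter_points.tsv"))
    tsv(an$scatter$lines, paste0(slug, "_scatter_lines.tsv"))
  }
  writeLines(run$log, file.path(output_dir, "run.log"))
  invisible(output_dir)
}

#' @export
print.mr_run <- function(x, ...) {
  cat(sprintf("<mr_run> %d analysis pair(s), %d failure(s), Bonferroni ",
              length(x$analyses), length(x$failures)))
  cat(sprintf("threshold %.4g\n", x$threshold))
  if (!is.null(x$results)) {
    print.data.frame(x$results[, c("EXPOSURE", "OUTCOME", "METHOD", "NSNP",
                                   "OR", "P", "TIER")], digits = 4)
  }
  invisible(x)
}

#' Recompute published-style result tables from harmonized fixtures
#'
#' Runs the full estimator battery on each harmonized instrument TSV in a
#' directory (files named `<exposure>_<outcome>.tsv` in the
#' [write_harmonized()] format) and returns one Tables-style block per
#' file. This is the drop-in route for reproducing a published analysis
#' from its curated per-SNP instrument tables: place the harmonized tables
#' in `dir` and compare the returned ORs, Q and Egger intercepts with the
#' published rows.
#'
#' @param dir directory of harmonized TSVs.
#' @param n_boot,seed weighted-median bootstrap settings.
#' @return Data frame of Tables-style rows for all files.
#' @export
reproduce_tables <- function(dir, n_boot = 5000, seed = 1) {
  files <- list.files(dir, pattern = "\\.tsv$", full.names = TRUE)
  if (!length(files)) {
    stop("no harmonized instrument tables (*.tsv) found in ", dir,
         call. = FALSE)
  }
  rows <- lapply(files, function(f) {
    traits <- strsplit(sub("\\.tsv$", "", basename(f)), "_")[[1]]
    h <- read_harmonized(f, exposure_name = traits[1],
                         outcome_name = traits[length(traits)])
    analysis_rows(mr_analysis(h, n_boot = n_boot, seed = seed))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Published IVW p-values bundled for threshold-logic checks
#'
#' Returns the nine printed IVW p-values (three neurotransmitter exposures
#' by three neurodegenerative-disease outcomes) shipped with the package,
#' used to exercise the Bonferroni tier classification against a known
#' published classification.
#'
#' @return Data frame with columns `EXPOSURE`, `OUTCOME`, `P`.
#' @export
published_ivw_pvalues <- function() {
  path <- system.file("extdata", "published_ivw_pvalues.tsv",
                      package = "mrkit", mustWork = TRUE)
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
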