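# Full pipeline: configuration, stage orchestration, and report output
# (JSON + TSVs). Reports carry no timestamps so that identical config +
# seed yields byte-identical output.

#' Analysis configuration
#'
#' @param traits constant-condition traits for the group comparison stage.
#' @param ancova_traits traits for the development-time-controlled stage.
#' @param plasticity_traits plasticity scales for the group comparison of
#'   plasticity.
#' @param interaction_responses responses for the time-plasticity x risk
#'   interaction stage.
#' @param plasticity_vs_mean_pairs list of `c(plasticity_trait, mean_trait)`
#'   pairs.
#' @param epsilon_frac replicate-branch length as a fraction of tree height.
#' @param min_per_group minimum paired cases per risk group for plasticity
#'   stages.
#' @param time_scale scale for the time-plasticity trait: `"period"` or
#'   `"rate"`.
#' @param seed integer seed recorded in the report (the pipeline itself is
#'   deterministic; the seed matters when the input data were simulated).
#' @return an `analysis_config` list.
#' @export
analysis_config <- function(traits = c("log10_dev_rate",
                                       "log10_growth_rate", "log10_mass"),
                            ancova_traits = c("log10_growth_rate",
                                              "log10_mass"),
                            plasticity_traits = c("dev_time", "growth_rate",
                                                  "mass"),
                            interaction_responses = c("mass", "growth_rate"),
                            plasticity_vs_mean_pairs = list(
                              c("mass", "log10_mass"),
                              c("growth_rate", "log10_growth_rate"),
                              c("dev_time", "log10_dev_rate")),
                            epsilon_frac = 1e-6,
                            min_per_group = 3,
                            time_scale = "period",
                            seed = 1L) {
  structure(list(
    traits = traits, ancova_traits = ancova_traits,
    plasticity_traits = plasticity_traits,
    interaction_responses = interaction_responses,
    plasticity_vs_mean_pairs = plasticity_vs_mean_pairs,
    epsilon_frac = epsilon_frac, min_per_group = min_per_group,
    time_scale = time_scale, seed = as.integer(seed)
  ), class = "analysis_config")
}

# deterministic 31-bit polynomial hash of a string (config provenance)
.config_hash <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run the full comparative analysis pipeline
#'
#' Executes, in order: the venue screen, trait derivation, and every
#' configured model stage (group comparisons, development-time ANCOVAs,
#' plasticity comparisons, time-plasticity x risk interactions, and
#' plasticity-vs-mean regressions). Each stage is run independently; a
#' failing stage is recorded with status `"failed"` and its error message,
#' a skipped stage with status `"skipped"`, and the pipeline continues.
#'
#' @param config an [analysis_config()].
#' @param cases validated case table (see [read_cases()]).
#' @param tree a rooted `"phylo"` covering the species in `cases`.
#' @return an `analysis_report`: list with `stages` (each holding `status`
#'   and `result`), `polytomies`, `dataset_summary`, `derived`,
#'   `plasticity`, and `provenance`.
#' @export
run_full_analysis <- function(config, cases, tree) {
  stopifnot(inherits(config, "analysis_config"))
  cases <- validate_cases(cases)
  validate_tree(tree)

  run_stage <- function(fun, ...) {
    res <- tryCatch(fun(...), error = function(e) e)
    if (is_stage_skip(res)) {
      list(status = "skipped", reason = conditionMessage(res), result = NULL)
    } else if (inherits(res, "error")) {
      list(status = "failed", reason = conditionMessage(res), result = NULL)
    } else {
      list(status = "ok", reason = NULL, result = res)
    }
  }

  stages <- list()
  stages[["venue_screen"]] <- run_stage(venue_screen, cases, tree)
  for (tr in config$traits) {
    stages[[paste0("compare_groups:", tr)]] <-
      run_stage(compare_groups, cases, tree, tr,
                epsilon_frac = config$epsilon_frac)
  }
  for (tr in config$ancova_traits) {
    stages[[paste0("ancova_devtime:", tr)]] <-
      run_stage(ancova_controlling_devtime, cases, tree, tr,
                epsilon_frac = config$epsilon_frac)
  }
  for (tr in config$plasticity_traits) {
    stages[[paste0("compare_plasticity:", tr)]] <-
      run_stage(compare_plasticity, cases, tree, tr,
                epsilon_frac = config$epsilon_frac,
                min_per_group = config$min_per_group)
  }
  for (tr in config$interaction_responses) {
    stages[[paste0("plasticity_interaction:", tr)]] <-
      run_stage(plasticity_interaction, cases, tree, tr,
                epsilon_frac = config$epsilon_frac,
                min_per_group = config$min_per_group)
  }
  for (pair in config$plasticity_vs_mean_pairs) {
    stages[[paste0("plasticity_vs_mean:", pair[1], "~", pair[2])]] <-
      run_stage(plasticity_vs_mean, cases, tree, pair[1], pair[2],
                epsilon_frac = config$epsilon_frac,
                min_per_group = config$min_per_group)
  }

  der <- derive_all(cases, time_scale = config$time_scale)
  cons <- der$derived[der$derived$treatment == "constant", ]
  paired <- unique(der$plasticity$case_id)

  # whole-dataset polytomy accounting: prune to species used, attach all
  # cases as replicates
  poly <- tryCatch({
    sc <- .stage_covariance(cons, tree, config$epsilon_frac)
    sc$polytomies
  }, error = function(e) NULL)

  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE)
  report <- structure(list(
    stages = stages,
    polytomies = poly,
    dataset_summary = list(
      n_cases = length(unique(cons$case_id)),
      n_species = length(unique(cons$species)),
      cases_per_group = as.list(table(cons$risk_group)),
      n_paired_cases = length(paired),
      n_rejected = nrow(der$rejected)
    ),
    derived = der$derived,
    plasticity = der$plasticity,
    provenance = list(
      package = "phyloplast",
      version = as.character(utils::packageVersion("phyloplast")),
      config = unclass(config),
      config_hash = .config_hash(as.character(cfg_json)),
      seed = config$seed
    )
  ), class = "analysis_report")
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Comparative analysis report\n")
  cat(sprintf("  cases: %d (%d species, %d with both treatments)\n",
              x$dataset_summary$n_cases, x$dataset_summary$n_species,
              x$dataset_summary$n_paired_cases))
  if (!is.null(x$polytomies))
    cat("  soft polytomies (full augmented tree):",
        x$polytomies$n_soft_polytomies, "\n")
  st <- vapply(x$stages, `[[`, character(1), "status")
  cat(sprintf("  stages: %d ok, %d skipped, %d failed\n",
              sum(st == "ok"), sum(st == "skipped"), sum(st == "failed")))
  for (nm in names(x$stages))
    cat(sprintf("    [%s] %s\n", x$stages[[nm]]$status, nm))
  invisible(x)
}

# Table-1-shaped summary: one row per stage x model for the focal
# coefficient (the last non-intercept coefficient of each stage's model).
.model_table <- function(report) {
  rows <- list()
  for (nm in names(report$stages)) {
    st <- report$stages[[nm]]
    if (st$status != "ok" || !inherits(st$result, "model_comparison")) next
    mc <- st$result
    tt <- mc$tests
    focal <- setdiff(unique(tt$coefficient), "(Intercept)")
    focal <- focal[length(focal)]
    for (m in c("star", "grafen")) {
      r <- tt[tt$model == m & tt$coefficient == focal, ]
      rows[[paste(nm, m)]] <- data.frame(
        stage = nm,
        model = if (m == "star") "conventional" else "phylogenetic",
        coefficient = focal, estimate = r$estimate, se = r$se, t = r$t,
        df = r$df_used, p = r$p,
        AIC = unname(mc$aic[m]), AICw = unname(mc$akaike_weights[m]),
        best = (mc$best == m), stringsAsFactors = FALSE
      )
    }
  }
  if (length(rows) == 0) return(data.frame())
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Write an analysis report to disk
#'
#' Writes `report.json` (stages, model comparisons, polytomy report,
#' provenance), `derived_traits.tsv`, `plasticity.tsv`, and
#' `model_tables.tsv` (a Table-1-shaped per-stage, per-model summary of the
#' focal coefficient with AIC and Akaike weights).
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "analysis_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  stages_json <- lapply(report$stages, function(st) {
    out <- list(status = st$status)
    if (!is.null(st$reason)) out$reason <- st$reason
    if (inherits(st$result, "model_comparison")) {
      out$comparison <- comparison_to_list(st$result)
      if (!is.null(attr(st$result, "slopes")))
        out$slopes <- as.list(attr(st$result, "slopes"))
    } else if (is.data.frame(st$result)) {
      out$table <- st$result
    }
    out
  })
  payload <- list(
    stages = stages_json,
    polytomies = if (is.null(report$polytomies)) NULL else
      unclass(report$polytomies),
    dataset_summary = report$dataset_summary,
    provenance = report$provenance
  )
  jsonlite::write_json(payload, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  write.table(report$derived, file.path(dir, "derived_traits.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(report$plasticity, file.path(dir, "plasticity.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(.model_table(report), file.path(dir, "model_tables.tsv"),
              sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(dir)
}
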