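# The four analysis questions as pipeline stages over a case table plus a
# phylogeny. Every stage prunes the tree to the species it uses, re-derives
# Grafen branch lengths on the pruned tree (so the height stays 1), attaches
# replicate cases as tip polytomies, and hands a response/design/covariance
# triple to model_comparison().

# condition for a stage that is skipped (not failed)
stage_skip <- function(reason) {
  structure(class = c("stage_skip", "condition"),
            list(message = reason, call = NULL))
}

#' @export
print.stage_skip <- function(x, ...) {
  cat("stage skipped:", x$message, "\n")
  invisible(x)
}

is_stage_skip <- function(x) inherits(x, "stage_skip")

# Prune + re-Grafen + attach replicates; returns per-case table aligned to
# the covariance matrix. `tab` must have case_id and species columns, one
# row per case.
.stage_covariance <- function(tab, tree, epsilon_frac = 1e-6) {
  species <- unique(tab$species)
  missing_sp <- setdiff(species, tree$tip.label)
  if (length(missing_sp) > 0)
    stop("species missing from tree: ",
         paste(sort(missing_sp), collapse = ", "), call. = FALSE)
  sub <- if (length(setdiff(tree$tip.label, species)) > 0) {
    ape::keep.tip(tree, species)
  } else tree
  if (length(sub$tip.label) < 2)
    stop("need at least two species for a phylogenetic analysis",
         call. = FALSE)
  sub <- grafen_branch_lengths(sub)   # unit height on the pruned tree
  case_map <- split(tab$case_id, tab$species)
  att <- attach_replicates(sub, case_map, epsilon = epsilon_frac * 1)
  V <- phylo_covariance(att$tree)
  ord <- match(colnames(V), tab$case_id)
  list(tab = tab[ord, , drop = FALSE], V = V,
       polytomies = att$polytomies, tree = att$tree)
}

# per-case constant-condition derived traits, one row per case
.constant_table <- function(cases, time_scale = "period") {
  der <- derive_all(cases, time_scale = time_scale)
  cons <- der$derived[der$derived$treatment == "constant", , drop = FALSE]
  list(constant = cons, plasticity = der$plasticity, derived = der$derived,
       rejected = der$rejected)
}

# wide per-case plasticity table (one row per complete case)
.plasticity_wide <- function(plasticity) {
  if (nrow(plasticity) == 0) return(plasticity)
  ids <- unique(plasticity$case_id)
  time_trait <- intersect(c("dev_time", "dev_rate"), unique(plasticity$trait))[1]
  out <- do.call(rbind, lapply(ids, function(cid) {
    pp <- plasticity[plasticity$case_id == cid, ]
    data.frame(
      case_id = cid, species = pp$species[1], risk_group = pp$risk_group[1],
      venue = pp$venue[1],
      p_time = pp$percent[pp$trait == time_trait],
      p_growth = pp$percent[pp$trait == "growth_rate"],
      p_mass = pp$percent[pp$trait == "mass"],
      stringsAsFactors = FALSE
    )
  }))
  out
}

.risk_factor <- function(x) factor(x, levels = c("Low", "High"))

#' Screen for experimental-venue effects
#'
#' Preliminary check that values from laboratory, mesocosm and field studies
#' can be pooled: for each constant-condition trait (log10 developmental
#' rate, log10 mean growth rate, log10 mass), an ordinary (star-covariance)
#' least-squares fit of the trait on the venue factor, summarized by the
#' joint F-test of all venue terms. If only one venue is represented the
#' stage is skipped (a `stage_skip`, not an error).
#'
#' @param cases validated case table.
#' @param tree phylogeny (unused by the conventional screen; accepted for a
#'   uniform stage signature).
#' @return data.frame with one row per trait: `trait`, `F_statistic`,
#'   `df1`, `df2`, `p`, plus attribute `pooled` (TRUE if no trait rejects
#'   at alpha = 0.05); or a `stage_skip`.
#' @export
venue_screen <- function(cases, tree = NULL) {
  ct <- .constant_table(cases)$constant
  venues <- unique(ct$venue)
  if (length(venues) < 2)
    return(stage_skip("only one experimental venue represented"))
  traits <- c("log10_dev_rate", "log10_growth_rate", "log10_mass")
  res <- do.call(rbind, lapply(traits, function(tr) {
    y <- ct[[tr]]
    X1 <- model.matrix(~ factor(venue), data = ct)
    f1 <- fit_gls(y, X1, V = NULL)
    f0 <- fit_gls(y, matrix(1, length(y), 1,
                            dimnames = list(NULL, "(Intercept)")), V = NULL)
    df1 <- ncol(X1) - 1
    df2 <- length(y) - ncol(X1)
    rss1 <- sum(f1$residuals^2)
    rss0 <- sum(f0$residuals^2)
    Fstat <- ((rss0 - rss1) / df1) / (rss1 / df2)
    data.frame(trait = tr, F_statistic = Fstat, df1 = df1, df2 = df2,
               p = pf(Fstat, df1, df2, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  attr(res, "pooled") <- all(res$p > 0.05)
  res
}

#' Compare mean traits between High- and Low-risk breeders
#'
#' Fits `trait ~ risk_group` under both the star (conventional) and Grafen
#' (phylogenetic) covariance structures, on constant-condition values only.
#' The risk coefficient (High minus Low) is tested with raw df in the
#' conventional fit and polytomy-corrected df in the phylogenetic fit.
#'
#' @param cases validated case table.
#' @param tree phylogeny covering all species in `cases`.
#' @param trait one of `"log10_dev_rate"`, `"log10_growth_rate"`,
#'   `"log10_mass"`.
#' @param epsilon_frac replicate-branch length as a fraction of (unit) tree
#'   height.
#' @return a [model_comparison()].
#' @export
compare_groups <- function(cases, tree,
                           trait = c("log10_dev_rate", "log10_growth_rate",
                                     "log10_mass"),
                           epsilon_frac = 1e-6) {
  trait <- match.arg(trait)
  ct <- .constant_table(cases)$constant
  sc <- .stage_covariance(ct, tree, epsilon_frac)
  tab <- sc$tab
  y <- tab[[trait]]
  X <- model.matrix(~ .risk_factor(risk_group), data = tab)
  colnames(X) <- c("(Intercept)", "riskHigh")
  model_comparison(y, X, sc$V, sc$polytomies$n_soft_polytomies)
}

#' Compare growth or mass between risk groups controlling for development time
#'
#' As [compare_groups()] but with log10 developmental time (constant
#' conditions) as a covariable: `trait ~ risk_group + log10_dev_time`.
#'
#' @inheritParams compare_groups
#' @param trait `"log10_growth_rate"` or `"log10_mass"`.
#' @return a [model_comparison()].
#' @export
ancova_controlling_devtime <- function(cases, tree,
                                       trait = c("log10_growth_rate",
                                                 "log10_mass"),
                                       epsilon_frac = 1e-6) {
  trait <- match.arg(trait)
  ct <- .constant_table(cases)$constant
  sc <- .stage_covariance(ct, tree, epsilon_frac)
  tab <- sc$tab
  y <- tab[[trait]]
  X <- model.matrix(~ .risk_factor(risk_group) + log10_dev_time, data = tab)
  colnames(X) <- c("(Intercept)", "riskHigh", "log10_dev_time")
  model_comparison(y, X, sc$V, sc$polytomies$n_soft_polytomies)
}

# shared guard for plasticity stages; returns the wide table or a skip
.plasticity_stage_table <- function(cases, min_per_group = 3) {
  der <- .constant_table(cases)
  pw <- .plasticity_wide(der$plasticity)
  if (nrow(pw) == 0)
    return(stage_skip("no cases with both constant and drying treatments"))
  counts <- table(factor(pw$risk_group, levels = c("Low", "High")))
  if (any(counts == 0))
    return(stage_skip("only one risk group has paired cases"))
  if (any(counts < min_per_group))
    return(stage_skip(sprintf(
      "fewer than %d paired cases in a risk group (Low = %d, High = %d)",
      min_per_group, counts["Low"], counts["High"])))
  pw
}

#' Compare percent plasticity between risk groups
#'
#' Percent plasticity of the chosen trait (developmental time, mean growth
#' rate, or mass) regressed on the risk factor under both covariance
#' structures. Requires at least `min_per_group` cases with both treatments
#' in each risk group; otherwise the stage is skipped.
#'
#' @inheritParams compare_groups
#' @param trait `"dev_time"`, `"growth_rate"` or `"mass"` (plasticity
#'   scale).
#' @param min_per_group minimum paired cases per risk group.
#' @return a [model_comparison()] or a `stage_skip`.
#' @export
compare_plasticity <- function(cases, tree,
                               trait = c("dev_time", "growth_rate", "mass"),
                               epsilon_frac = 1e-6, min_per_group = 3) {
  trait <- match.arg(trait)
  pw <- .plasticity_stage_table(cases, min_per_group)
  if (is_stage_skip(pw)) return(pw)
  sc <- .stage_covariance(pw, tree, epsilon_frac)
  tab <- sc$tab
  y <- switch(trait, dev_time = tab$p_time, growth_rate = tab$p_growth,
              mass = tab$p_mass)
  X <- model.matrix(~ .risk_factor(risk_group), data = tab)
  colnames(X) <- c("(Intercept)", "riskHigh")
  model_comparison(y, X, sc$V, sc$polytomies$n_soft_polytomies)
}

#' Interaction between time plasticity and risk on mass/growth plasticity
#'
#' Models mass (or growth-rate) percent plasticity as a function of
#' developmental-time percent plasticity, the risk factor, and their
#' interaction. A significant positive interaction means High-risk species'
#' mass plasticity tracks their time plasticity more steeply than Low-risk
#' species' (the compensation-vs-tracking contrast). Per-group slopes are
#' attached as attribute `"slopes"`.
#'
#' @inheritParams compare_plasticity
#' @param response `"mass"` or `"growth_rate"` (plasticity response).
#' @return a [model_comparison()] with attribute `slopes`
#'   (`c(Low = ..., High = ...)`), or a `stage_skip`.
#' @export
plasticity_interaction <- function(cases, tree,
                                   response = c("mass", "growth_rate"),
                                   epsilon_frac = 1e-6, min_per_group = 3) {
  response <- match.arg(response)
  pw <- .plasticity_stage_table(cases, min_per_group)
  if (is_stage_skip(pw)) return(pw)
  if (length(unique(pw$risk_group)) < 2)
    return(stage_skip("single risk group present; interaction undefined"))
  sc <- .stage_covariance(pw, tree, epsilon_frac)
  tab <- sc$tab
  y <- if (response == "mass") tab$p_mass else tab$p_growth
  X <- model.matrix(~ p_time * .risk_factor(risk_group), data = tab)
  colnames(X) <- c("(Intercept)", "p_time", "riskHigh", "p_time:riskHigh")
  mc <- model_comparison(y, X, sc$V, sc$polytomies$n_soft_polytomies)
  bf <- mc$fits[[mc$best]]$coefficients
  attr(mc, "slopes") <- c(Low = unname(bf["p_time"]),
                          High = unname(bf["p_time"] +
                                          bf["p_time:riskHigh"]))
  mc
}

#' Regression of plasticity on the mean trait under constant conditions
#'
#' Percent plasticity of one trait regressed on the log10 mean of another
#' (or the same) trait measured under constant conditions, under both
#' covariance structures — the "do larger/faster species lose
#' proportionally more?" question.
#'
#' @inheritParams compare_plasticity
#' @param plasticity_trait `"dev_time"`, `"growth_rate"` or `"mass"`.
#' @param mean_trait `"log10_dev_rate"`, `"log10_growth_rate"` or
#'   `"log10_mass"`.
#' @return a [model_comparison()] or a `stage_skip`.
#' @export
plasticity_vs_mean <- function(cases, tree,
                               plasticity_trait = c("mass", "growth_rate",
                                                    "dev_time"),
                               mean_trait = c("log10_mass",
                                              "log10_growth_rate",
                                              "log10_dev_rate"),
                               epsilon_frac = 1e-6, min_per_group = 3) {
  plasticity_trait <- match.arg(plasticity_trait)
  mean_trait <- match.arg(mean_trait)
  der <- .constant_table(cases)
  pw <- .plasticity_stage_table(cases, min_per_group)
  if (is_stage_skip(pw)) return(pw)
  cons <- der$constant
  pw[[mean_trait]] <- cons[[mean_trait]][match(pw$case_id, cons$case_id)]
  sc <- .stage_covariance(pw, tree, epsilon_frac)
  tab <- sc$tab
  y <- switch(plasticity_trait, dev_time = tab$p_time,
              growth_rate = tab$p_growth, mass = tab$p_mass)
  X <- cbind("(Intercept)" = 1, tab[[mean_trait]])
  colnames(X) <- c("(Intercept)", mean_trait)
  model_comparison(y, X, sc$V, sc$polytomies$n_soft_polytomies)
}
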