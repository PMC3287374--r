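# Derived developmental traits, unit conversions, plasticity percentages,
# and Hedges' d effect sizes.

#' Developmental rate from larval period
#'
#' @param period_mean larval period in days (> 0).
#' @return developmental rate in days^-1, `1 / period_mean`.
#' @examples
#' developmental_rate(106)  # ~0.0094 days^-1
#' @export
developmental_rate <- function(period_mean) {
  if (any(!is.finite(period_mean)) || any(period_mean <= 0))
    stop("developmental period must be > 0", call. = FALSE)
  1 / period_mean
}

#' Mean growth rate
#'
#' Mass at metamorphosis divided by larval period: a coarse summary of the
#' whole larval growth outcome, deliberately agnostic about the (nonlinear)
#' shape of the growth trajectory.
#'
#' @param mass_mean mass at metamorphosis in grams (> 0).
#' @param period_mean larval period in days (> 0).
#' @return mean growth rate in g day^-1.
#' @export
mean_growth_rate <- function(mass_mean, period_mean) {
  if (any(!is.finite(mass_mean)) || any(mass_mean <= 0))
    stop("mass must be > 0", call. = FALSE)
  if (any(!is.finite(period_mean)) || any(period_mean <= 0))
    stop("developmental period must be > 0", call. = FALSE)
  mass_mean / period_mean
}

#' Convert body volume to mass
#'
#' Tadpole tissue density is close to 1 g/mL, so studies reporting body
#' volume convert to mass by the identity map.
#'
#' @param volume body volume in mL (> 0).
#' @return mass in grams.
#' @export
volume_to_mass <- function(volume) {
  if (any(!is.finite(volume)) || any(volume <= 0))
    stop("volume must be > 0", call. = FALSE)
  volume * 1.0
}

#' Percent plasticity of a trait under drying
#'
#' `100 * (trait_d - trait_c) / trait_c`, where `c` and `d` denote the
#' constant and drying water-level treatments. A reduction under drying is
#' negative.
#'
#' @param trait_c trait value under constant conditions (> 0).
#' @param trait_d trait value under drying conditions.
#' @return percent change, dimensionless.
#' @export
plasticity_percent <- function(trait_c, trait_d) {
  if (any(!is.finite(trait_c)) || any(trait_c <= 0))
    stop("constant-condition trait value must be > 0", call. = FALSE)
  100 * (trait_d - trait_c) / trait_c
}

#' Hedges' d standardized mean difference (drying minus constant)
#'
#' Small-sample-corrected standardized mean difference between the drying
#' and constant treatments, with its large-sample sampling variance:
#' \deqn{d = J \frac{\bar x_d - \bar x_c}{s_p}, \quad
#'       s_p^2 = \frac{(n_d-1)s_d^2 + (n_c-1)s_c^2}{n_d+n_c-2}, \quad
#'       J = 1 - \frac{3}{4(n_d+n_c-2)-1}}
#' \deqn{\mathrm{var}(d) = \frac{n_d+n_c}{n_d n_c} +
#'       \frac{d^2}{2(n_d+n_c-2)}}
#' The sign convention (drying minus constant) matches
#' [plasticity_percent()].
#'
#' @param mean_d,sd_d,n_d drying-treatment mean, SD, sample size.
#' @param mean_c,sd_c,n_c constant-treatment mean, SD, sample size.
#' @return list with `d` and `var_d`.
#' @export
hedges_d <- function(mean_d, sd_d, n_d, mean_c, sd_c, n_c) {
  if (n_d < 2 || n_c < 2)
    stop("Hedges' d requires n >= 2 in both groups", call. = FALSE)
  if (sd_d < 0 || sd_c < 0) stop("SDs must be >= 0", call. = FALSE)
  m <- n_d + n_c - 2
  sp2 <- ((n_d - 1) * sd_d^2 + (n_c - 1) * sd_c^2) / m
  if (sp2 == 0) {
    if (mean_d != mean_c)
      stop("pooled SD is 0 but treatment means differ; d undefined",
           call. = FALSE)
    d <- 0
  } else {
    J <- 1 - 3 / (4 * m - 1)
    d <- J * (mean_d - mean_c) / sqrt(sp2)
  }
  var_d <- (n_d + n_c) / (n_d * n_c) + d^2 / (2 * m)
  list(d = d, var_d = var_d)
}

# --- dataset ingestion -------------------------------------------------

.case_columns <- c("case_id", "species", "population", "risk_group", "venue",
                   "treatment", "period_mean", "period_sd", "period_n",
                   "mass_mean", "mass_sd", "mass_n", "mass_is_volume")

#' Read a study-case table
#'
#' One row per case x treatment. Required columns: `case_id`, `species`,
#' `risk_group` (High/Low), `venue` (laboratory/mesocosm/field), `treatment`
#' (constant/drying), `period_mean`, `period_sd`, `period_n`, `mass_mean`,
#' `mass_sd`, `mass_n`. Optional: `population`, `mass_is_volume` (logical;
#' volumes in mL are converted to grams at density 1 g/mL on ingestion).
#'
#' @param path path to a TSV (or CSV if `sep = ","`) file.
#' @param sep field separator.
#' @return a validated data.frame of cases.
#' @export
read_cases <- function(path, sep = "\t") {
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  validate_cases(df)
}

#' Validate (and normalize) a study-case table
#'
#' Checks required columns, positivity of means, non-negative SDs, n >= 1,
#' the High/Low risk factor and constant/drying treatment labels, and that
#' no case has duplicated treatment rows. Volumes are converted to mass.
#'
#' @param df a data.frame as described in [read_cases()].
#' @return the normalized data.frame.
#' @export
validate_cases <- function(df) {
  req <- setdiff(.case_columns, c("population", "mass_is_volume"))
  miss <- setdiff(req, names(df))
  if (length(miss) > 0)
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!"population" %in% names(df)) df$population <- NA_character_
  if (!"mass_is_volume" %in% names(df)) df$mass_is_volume <- FALSE
  df$mass_is_volume <- as.logical(df$mass_is_volume)
  df$mass_is_volume[is.na(df$mass_is_volume)] <- FALSE

  if (!all(df$risk_group %in% c("High", "Low")))
    stop("risk_group must be 'High' or 'Low'", call. = FALSE)
  if (!all(df$treatment %in% c("constant", "drying")))
    stop("treatment must be 'constant' or 'drying'", call. = FALSE)
  if (!all(df$venue %in% c("laboratory", "mesocosm", "field")))
    stop("venue must be laboratory, mesocosm or field", call. = FALSE)
  if (anyDuplicated(df[, c("case_id", "treatment")]))
    stop("duplicated case_id x treatment rows", call. = FALSE)

  num <- c("period_mean", "period_sd", "period_n",
           "mass_mean", "mass_sd", "mass_n")
  for (cc in num) df[[cc]] <- as.numeric(df[[cc]])
  if (any(df$period_mean <= 0) || any(df$mass_mean <= 0))
    stop("period_mean and mass_mean must be > 0", call. = FALSE)
  if (any(df$period_sd < 0) || any(df$mass_sd < 0))
    stop("SD columns must be >= 0", call. = FALSE)
  if (any(df$period_n < 1) || any(df$mass_n < 1))
    stop("sample sizes must be >= 1", call. = FALSE)

  # a case must map to a single species / risk group / venue
  by_case <- split(df, df$case_id)
  bad <- names(by_case)[vapply(by_case, function(d) {
    length(unique(d$species)) > 1 || length(unique(d$risk_group)) > 1 ||
      length(unique(d$venue)) > 1
  }, logical(1))]
  if (length(bad) > 0)
    stop("inconsistent species/risk_group/venue within case(s): ",
         paste(bad, collapse = ", "), call. = FALSE)

  vol <- df$mass_is_volume
  if (any(vol)) {
    df$mass_mean[vol] <- volume_to_mass(df$mass_mean[vol])
    df$mass_sd[vol] <- df$mass_sd[vol] * 1.0
    df$mass_is_volume <- FALSE
  }
  df
}

# delta-method SDs for derived traits; rate = 1/period, growth = mass/period
.rate_sd <- function(period_mean, period_sd) period_sd / period_mean^2
.growth_sd <- function(mass_mean, mass_sd, period_mean, period_sd) {
  (mass_mean / period_mean) *
    sqrt((mass_sd / mass_mean)^2 + (period_sd / period_mean)^2)
}

#' Derive traits and plasticity records for a whole dataset
#'
#' For every case x treatment: developmental rate, mean growth rate and the
#' log10-transformed traits used in the mean-trait analyses. For every case
#' with both treatments: percent plasticity and Hedges' d for the
#' developmental-time trait, mean growth rate, and mass at metamorphosis
#' (sign convention: drying minus constant, so reductions under drying are
#' negative on both scales).
#'
#' Time plasticity is computed on the period scale by default
#' (`time_scale = "period"`); set `time_scale = "rate"` to express it on the
#' developmental-rate scale instead. Hedges' d for derived traits (rate,
#' growth) uses delta-method SDs from the period/mass summaries; it is `NA`
#' when either treatment has `n < 2` or the pooled SD degenerates.
#'
#' Cases lacking a constant-condition row are rejected (listed in
#' `$rejected` with a reason); cases lacking a drying row contribute derived
#' traits but no plasticity records.
#'
#' @param df a validated case table ([validate_cases()]).
#' @param time_scale `"period"` (default) or `"rate"`.
#' @return list with data.frames `derived` (per case x treatment),
#'   `plasticity` (per case x trait, 3 traits per complete case), and
#'   `rejected` (case_id, reason).
#' @export
derive_all <- function(df, time_scale = c("period", "rate")) {
  time_scale <- match.arg(time_scale)
  df <- validate_cases(df)

  derived <- df[, c("case_id", "species", "population", "risk_group",
                    "venue", "treatment", "period_mean", "period_sd",
                    "period_n", "mass_mean", "mass_sd", "mass_n")]
  derived$dev_rate <- developmental_rate(derived$period_mean)
  derived$growth_rate <- mean_growth_rate(derived$mass_mean,
                                          derived$period_mean)
  derived$log10_dev_rate <- log10(derived$dev_rate)
  derived$log10_growth_rate <- log10(derived$growth_rate)
  derived$log10_mass <- log10(derived$mass_mean)
  derived$log10_dev_time <- log10(derived$period_mean)

  rejected <- data.frame(case_id = character(0), reason = character(0))
  plast <- list()
  time_trait <- if (time_scale == "period") "dev_time" else "dev_rate"

  for (cid in unique(df$case_id)) {
    rows <- derived[derived$case_id == cid, ]
    cc <- rows[rows$treatment == "constant", ]
    dd <- rows[rows$treatment == "drying", ]
    if (nrow(cc) == 0L) {
      rejected <- rbind(rejected, data.frame(
        case_id = cid, reason = "no constant-condition summaries"))
      derived <- derived[derived$case_id != cid, ]
      next
    }
    if (nrow(dd) == 0L) next

    d_or_na <- function(md, sdd, nd, mc, sdc, nc) {
      if (nd < 2 || nc < 2) return(list(d = NA_real_, var_d = NA_real_))
      tryCatch(hedges_d(md, sdd, nd, mc, sdc, nc),
               error = function(e) list(d = NA_real_, var_d = NA_real_))
    }

    if (time_trait == "dev_time") {
      tp <- plasticity_percent(cc$period_mean, dd$period_mean)
      th <- d_or_na(dd$period_mean, dd$period_sd, dd$period_n,
                    cc$period_mean, cc$period_sd, cc$period_n)
    } else {
      tp <- plasticity_percent(cc$dev_rate, dd$dev_rate)
      th <- d_or_na(dd$dev_rate, .rate_sd(dd$period_mean, dd$period_sd),
                    dd$period_n,
                    cc$dev_rate, .rate_sd(cc$period_mean, cc$period_sd),
                    cc$period_n)
    }
    gp <- plasticity_percent(cc$growth_rate, dd$growth_rate)
    gh <- d_or_na(dd$growth_rate,
                  .growth_sd(dd$mass_mean, dd$mass_sd,
                             dd$period_mean, dd$period_sd),
                  min(dd$period_n, dd$mass_n),
                  cc$growth_rate,
                  .growth_sd(cc$mass_mean, cc$mass_sd,
                             cc$period_mean, cc$period_sd),
                  min(cc$period_n, cc$mass_n))
    mp <- plasticity_percent(cc$mass_mean, dd$mass_mean)
    mh <- d_or_na(dd$mass_mean, dd$mass_sd, dd$mass_n,
                  cc$mass_mean, cc$mass_sd, cc$mass_n)

    plast[[cid]] <- data.frame(
      case_id = cid, species = cc$species, risk_group = cc$risk_group,
      venue = cc$venue,
      trait = c(time_trait, "growth_rate", "mass"),
      percent = c(tp, gp, mp),
      hedges_d = c(th$d, gh$d, mh$d),
      hedges_d_var = c(th$var_d, gh$var_d, mh$var_d),
      stringsAsFactors = FALSE
    )
  }

  plasticity <- if (length(plast) > 0) {
    do.call(rbind, c(plast, list(make.row.names = FALSE)))
  } else {
    data.frame(case_id = character(0), species = character(0),
               risk_group = character(0), venue = character(0),
               trait = character(0), percent = numeric(0),
               hedges_d = numeric(0), hedges_d_var = numeric(0))
  }
  list(derived = derived, plasticity = plasticity, rejected = rejected)
}
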