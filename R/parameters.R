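# Model parameters: probabilities, utilities, costs, distribution specs and
# global settings, with validation and config-file round-tripping.

#' Distribution specification
#'
#' A small tagged container describing how a parameter is resampled in
#' probabilistic sensitivity analysis.
#'
#' * `beta_counts`: Beta distribution parameterised by event count `p1 = n`
#'   and denominator `p2 = N`, i.e. shape parameters `alpha = n`,
#'   `beta = N - n` (mean `n/N`).
#' * `lognormal_mean_median`: lognormal with stated arithmetic mean `p1` and
#'   median `p2`; `mu = log(median)`, `sigma = sqrt(2 * log(mean/median))`.
#' * `fixed`: degenerate at `p1`.
#'
#' @param kind one of `"beta_counts"`, `"lognormal_mean_median"`, `"fixed"`.
#' @param p1,p2 numeric parameters, interpreted per `kind`.
#' @return An object of class `dist_spec`.
#' @export
dist_spec <- function(kind = c("beta_counts", "lognormal_mean_median", "fixed"),
                      p1, p2 = NA_real_) {
  kind <- match.arg(kind)
  p1 <- as.numeric(p1); p2 <- as.numeric(p2)
  if (kind == "beta_counts" && !(p1 > 0 && p1 <= p2))
    stop("beta_counts requires 0 < n <= N, got n=", p1, ", N=", p2)
  if (kind == "lognormal_mean_median" && !(p1 >= p2 && p2 > 0))
    stop("lognormal_mean_median requires mean >= median > 0, got mean=",
         p1, ", median=", p2)
  structure(list(kind = kind, p1 = p1, p2 = p2), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_beta <- function(p1, p2) dist_spec("beta_counts", p1, p2)

#' @rdname dist_spec
#' @export
dist_lnorm <- function(p1, p2) dist_spec("lognormal_mean_median", p1, p2)

#' @rdname dist_spec
#' @export
dist_fixed <- function(p1) dist_spec("fixed", p1, p1)

#' Adverse-event profile
#'
#' One cetuximab-related adverse event (AE): its monthly probability, the
#' window in which it can occur (`"first_month_only"` for the infusion-type
#' reactions and severe skin reactions, `"while_on_cetuximab"` for anorexia,
#' hypomagnesemia and sepsis), the fractional utility reduction applied to
#' the stable-state utility while the disutility lasts, the disutility
#' duration in months (`Inf` = lifetime), and the management cost (per case
#' for severe events; the mild-event costs are carried on the cost schedule).
#'
#' @param name AE identifier.
#' @param monthly_prob probability per month, in `[0, 1]`.
#' @param window `"first_month_only"` or `"while_on_cetuximab"`.
#' @param utility_reduction fraction in `[0, 1]`.
#' @param disutility_duration months; `Inf` for lifetime.
#' @param management_cost CAD per case (severe) or 0 (mild; see costs).
#' @param prob_dist,cost_dist,ur_dist [dist_spec] objects for PSA.
#' @return An object of class `ae_profile`.
#' @export
ae_profile <- function(name, monthly_prob, window, utility_reduction,
                       disutility_duration, management_cost,
                       prob_dist, cost_dist = dist_fixed(management_cost),
                       ur_dist = dist_fixed(utility_reduction)) {
  stopifnot(monthly_prob >= 0, monthly_prob <= 1,
            utility_reduction >= 0, utility_reduction <= 1,
            management_cost >= 0, disutility_duration >= 0)
  window <- match.arg(window, c("first_month_only", "while_on_cetuximab"))
  structure(list(name = name, monthly_prob = monthly_prob, window = window,
                 utility_reduction = utility_reduction,
                 disutility_duration = disutility_duration,
                 management_cost = management_cost,
                 prob_dist = prob_dist, cost_dist = cost_dist,
                 ur_dist = ur_dist),
            class = "ae_profile")
}

ae_names <- function() c("mild", "allergy_anaphylaxis", "dyspnea",
                         "hypotension", "skin_severe", "anorexia",
                         "hypomagnesemia", "sepsis")

first_month_aes <- function() c("mild", "allergy_anaphylaxis", "dyspnea",
                                "hypotension", "skin_severe")

ongoing_aes <- function() c("anorexia", "hypomagnesemia", "sepsis")

#' Base-case parameter set
#'
#' Returns the full base case of the model: the eight cetuximab-related
#' adverse-event profiles, health-state utilities (stable 0.65, progression
#' 0.52, dead 0), the cost schedule in 2011 CAD (platinum-based chemotherapy
#' $4,293/month for the first 5 months; cetuximab dosing, infusion chair
#' time and pharmacy preparation; AE management; inpatient hospice care
#' $25,333/month with progression), global settings (36-month horizon,
#' 1-month cycles, 5% annual discounting, half-cycle correction, $100,000
#' willingness-to-pay) and the survival-curve calibration anchors (overall
#' survival medians 7.4 / 10.1 months, 24-month survival 16% / 18%,
#' progression-free survival medians 3.3 / 5.6 months).
#'
#' Cetuximab dosing costs are recomputed from the dosing rule (400 mg/m2
#' loading then 250 mg/m2 weekly, body surface area 1.8 m2, $3.24/mg) rather
#' than stored, so that price sensitivity analyses propagate consistently.
#'
#' @return An object of class `cea_parameters`.
#' @seealso [load_parameters()], [write_parameters()], [cea_model()]
#' @export
default_parameters <- function() {
  aes <- list(
    ae_profile("mild", 0.292, "first_month_only",
               utility_reduction = 0, disutility_duration = 0,
               management_cost = 0,
               prob_dist = dist_beta(292, 1000)),
    ae_profile("allergy_anaphylaxis", 0.0183, "first_month_only", 0.15, 1,
               3764, dist_beta(183, 10000), dist_lnorm(3764, 3420),
               dist_beta(150, 1000)),
    ae_profile("dyspnea", 0.0046, "first_month_only", 0.36, 1,
               3991, dist_beta(46, 10000), dist_lnorm(3991, 3590),
               dist_beta(360, 1000)),
    ae_profile("hypotension", 0.0046, "first_month_only", 0.088, 1,
               3234, dist_beta(46, 10000), dist_lnorm(3234, 2780),
               dist_beta(88, 1000)),
    ae_profile("skin_severe", 0.0867, "first_month_only", 0.657, 2,
               2912, dist_beta(867, 10000), dist_lnorm(2919, 2670),
               dist_beta(657, 1000)),
    ae_profile("anorexia", 0.0061, "while_on_cetuximab", 0.20, 20,
               8436, dist_beta(61, 10000), dist_lnorm(8436, 7250),
               dist_beta(200, 1000)),
    ae_profile("hypomagnesemia", 0.0061, "while_on_cetuximab", 0.24, 20,
               5516, dist_beta(61, 10000), dist_lnorm(5516, 4720),
               dist_beta(240, 1000)),
    ae_profile("sepsis", 0.0061, "while_on_cetuximab", 0.41, Inf,
               32462, dist_beta(61, 10000), dist_lnorm(32462, 26860),
               dist_beta(410, 1000))
  )
  names(aes) <- vapply(aes, `[[`, "", "name")

  params <- list(
    settings = list(
      horizon = 36L, cycle_length = 1, annual_discount = 0.05,
      chemo_max_months = 5L, sex_mix = 0.9, wtp = 1e5, half_cycle = TRUE,
      km_followup = 24L
    ),
    utilities = list(
      stable = 0.65, progression = 0.52, death = 0,
      stable_dist = dist_beta(650, 1000),
      progression_dist = dist_beta(520, 1000)
    ),
    costs = list(
      chemo_monthly_total = 4293,
      chemo_monthly_total_dist = dist_lnorm(4293, 3850),
      unit_price_per_mg = 3.24, bsa = 1.8,
      loading_dose_mg_m2 = 400, weekly_dose_mg_m2 = 250,
      chair_rate = 103.64, prep_rate = 40,
      pharmacy_prep = 160, pharmacy_prep_dist = dist_lnorm(160, 143),
      # Explicit overrides for the derived cetuximab components; NA means
      # "recompute from the dosing rule above".  PSA fills these in.
      cetuximab_dose_month1 = NA_real_, cetuximab_dose_later = NA_real_,
      infusion_month1 = NA_real_, infusion_later = NA_real_,
      cetuximab_dose_month1_dist = dist_lnorm(6707, 6300),
      cetuximab_dose_later_dist = dist_lnorm(5832, 5285),
      infusion_month1_dist = dist_lnorm(518.2, 470),
      infusion_later_dist = dist_lnorm(414.5, 380),
      progression_monthly = 25333,
      progression_monthly_dist = dist_lnorm(25333, 22870),
      mild_ae_consult = 143.4,
      mild_ae_monthly_antihistamine = 804,
      mild_ae_monthly_antihistamine_dist = dist_lnorm(804, 665),
      mild_ae_monthly_skin = 56,
      mild_ae_monthly_skin_dist = dist_lnorm(56, 52)
    ),
    adverse_events = aes,
    survival = list(
      os_control = list(median = 7.4, s24 = 0.16),
      os_cetuximab = list(median = 10.1, s24 = 0.18),
      pfs_control_median = 3.3, pfs_gain = 2.3,
      pfs_shape = "os",  # share the arm's fitted OS Weibull shape; or numeric
      life_table = list(male_annual = 0.010, female_annual = 0.006)
    )
  )
  validate_parameters(structure(params, class = "cea_parameters"))
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter set: probabilities and utility
#' reductions in `[0, 1]`, `0 <= progression <= stable <= 1` utilities,
#' non-negative costs, well-formed distribution specs, exactly the eight
#' expected AE profiles with the correct occurrence windows, and settings
#' ranges. Returns the object invisibly-validated, or stops with a message
#' naming the offending field.
#'
#' @param params a `cea_parameters` object.
#' @return `params`, unchanged, if valid.
#' @export
validate_parameters <- function(params) {
  s <- params$settings
  chk <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
  chk(s$horizon >= 1, "settings.horizon: must be >= 1")
  chk(s$annual_discount >= 0 && s$annual_discount < 1,
      "settings.annual_discount: must be a fraction in [0, 1)")
  chk(s$sex_mix >= 0 && s$sex_mix <= 1, "settings.sex_mix: must be in [0, 1]")
  chk(s$wtp >= 0, "settings.wtp: must be >= 0")
  chk(s$chemo_max_months >= 0, "settings.chemo_max_months: must be >= 0")

  u <- params$utilities
  chk(u$death == 0, "utilities.death: must be 0")
  chk(u$progression >= 0 && u$progression <= u$stable && u$stable <= 1,
      "utilities: require 0 <= progression <= stable <= 1")

  co <- params$costs
  for (nm in c("chemo_monthly_total", "unit_price_per_mg", "bsa",
               "loading_dose_mg_m2", "weekly_dose_mg_m2", "chair_rate",
               "prep_rate", "pharmacy_prep", "progression_monthly",
               "mild_ae_consult", "mild_ae_monthly_antihistamine",
               "mild_ae_monthly_skin"))
    chk(is.numeric(co[[nm]]) && co[[nm]] >= 0,
        paste0("costs.", nm, ": must be >= 0"))

  chk(setequal(names(params$adverse_events), ae_names()),
      paste("adverse_events: exactly these profiles are required:",
            paste(ae_names(), collapse = ", ")))
  for (ae in params$adverse_events) {
    chk(ae$monthly_prob >= 0 && ae$monthly_prob <= 1,
        paste0("adverse_events.", ae$name,
               ".monthly_prob: probability in [0,1]"))
    chk(ae$utility_reduction >= 0 && ae$utility_reduction <= 1,
        paste0("adverse_events.", ae$name,
               ".utility_reduction: fraction in [0,1]"))
    chk(ae$management_cost >= 0,
        paste0("adverse_events.", ae$name, ".management_cost: must be >= 0"))
    expected_window <- if (ae$name %in% ongoing_aes())
      "while_on_cetuximab" else "first_month_only"
    chk(ae$window == expected_window,
        paste0("adverse_events.", ae$name, ".window: must be ",
               expected_window))
  }

  sv <- params$survival
  for (arm in c("os_control", "os_cetuximab")) {
    chk(sv[[arm]]$median > 0, paste0("survival.", arm, ".median: must be > 0"))
    chk(sv[[arm]]$s24 > 0 && sv[[arm]]$s24 < 1,
        paste0("survival.", arm, ".s24: must be in (0, 1)"))
  }
  chk(sv$pfs_control_median > 0, "survival.pfs_control_median: must be > 0")
  chk(sv$pfs_gain >= 0, "survival.pfs_gain: must be >= 0")
  lt <- sv$life_table
  chk(lt$male_annual >= 0 && lt$male_annual <= 1 &&
        lt$female_annual >= 0 && lt$female_annual <= 1,
      "survival.life_table: annual probabilities must be in [0, 1]")
  params
}

#' @export
print.cea_parameters <- function(x, ...) {
  s <- x$settings
  cat("Cost-effectiveness model parameter set (2011 CAD)\n")
  cat(sprintf("  horizon %d months, discount %.1f%%/yr, half-cycle %s, WTP $%s/QALY\n",
              s$horizon, 100 * s$annual_discount,
              if (s$half_cycle) "on" else "off",
              format(s$wtp, big.mark = ",")))
  cat(sprintf("  utilities: stable %.2f, progression %.2f, dead %.2f\n",
              x$utilities$stable, x$utilities$progression, x$utilities$death))
  cat(sprintf("  cetuximab $%.2f/mg (BSA %.1f m2); chemo $%s/mo (first %d mo); hospice $%s/mo\n",
              x$costs$unit_price_per_mg, x$costs$bsa,
              format(x$costs$chemo_monthly_total, big.mark = ","),
              s$chemo_max_months,
              format(x$costs$progression_monthly, big.mark = ",")))
  cat(sprintf("  %d adverse-event profiles: %s\n",
              length(x$adverse_events),
              paste(names(x$adverse_events), collapse = ", ")))
  invisible(x)
}

# -- config-file plumbing -----------------------------------------------------

# Recursively overlay `over` onto `base`, keeping classes of leaves in `base`
# where `over` supplies plain lists (as parsed from YAML/JSON).
merge_config <- function(base, over, path = "") {
  for (nm in names(over)) {
    here <- if (nzchar(path)) paste0(path, ".", nm) else nm
    if (!nm %in% names(base))
      stop("unknown parameter key: ", here, call. = FALSE)
    b <- base[[nm]]; o <- over[[nm]]
    if (inherits(b, "dist_spec")) {
      base[[nm]] <- dist_spec(o$kind, o$p1, o$p2)
    } else if (inherits(b, "ae_profile")) {
      for (f in names(o)) {
        if (!f %in% names(b)) stop("unknown parameter key: ", here, ".", f,
                                   call. = FALSE)
        b[[f]] <- if (inherits(b[[f]], "dist_spec"))
          dist_spec(o[[f]]$kind, o[[f]]$p1, o[[f]]$p2) else coerce_leaf(o[[f]])
      }
      base[[nm]] <- b  # range checks happen in validate_parameters
    } else if (is.list(b) && !is.null(names(b))) {
      base[[nm]] <- merge_config(b, o, here)
    } else {
      base[[nm]] <- coerce_leaf(o)
    }
  }
  base
}

coerce_leaf <- function(x) {
  if (identical(x, ".inf") || identical(x, "Inf")) return(Inf)
  if (is.null(x) || identical(x, ".na") || identical(x, "NA") ||
      (length(x) == 1 && is.na(x))) return(NA_real_)
  x
}

#' Load a parameter set from a configuration document
#'
#' Reads a YAML or JSON configuration file (or an already-parsed list) and
#' overlays it on the base case: any omitted key keeps its
#' [default_parameters()] value, unknown keys raise an error naming the key,
#' and the merged set is re-validated so out-of-range overrides fail with
#' the violated invariant.
#'
#' @param config path to a `.yaml`/`.yml`/`.json` file, a named list of
#'   overrides, or `NULL` for the pure base case.
#' @return A validated `cea_parameters` object.
#' @export
load_parameters <- function(config = NULL) {
  base <- default_parameters()
  if (is.null(config)) return(base)
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    ext <- tolower(tools::file_ext(config))
    config <- if (ext == "json") {
      jsonlite::read_json(config, simplifyVector = TRUE,
                          simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
    } else {
      yaml::read_yaml(config)
    }
  }
  stopifnot(is.list(config))
  validate_parameters(merge_config(base, config))
}

# Convert params to plain nested lists (dist_spec/ae_profile unclassed).
as_plain_list <- function(x) {
  if (inherits(x, "dist_spec")) return(unclass(x))
  if (inherits(x, "ae_profile")) x <- unclass(x)
  if (is.list(x)) return(lapply(x, as_plain_list))
  if (is.numeric(x) && length(x) == 1 && is.infinite(x)) return(".inf")
  if (length(x) == 1 && is.na(x)) return(".na")
  x
}

#' Serialize a parameter set to a configuration file
#'
#' Writes the complete parameter set as YAML (default) or JSON. The output
#' round-trips: `load_parameters(write_parameters(p, f))` reproduces `p`
#' field for field. Used by the CLI `init-config` subcommand to emit a fully
#' explicit base-case configuration.
#'
#' @param params a `cea_parameters` object.
#' @param path output path; format chosen by extension (`.json` for JSON,
#'   YAML otherwise).
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  plain <- as_plain_list(unclass(params))
  if (tolower(tools::file_ext(path)) == "json") {
    jsonlite::write_json(plain, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    yaml::write_yaml(plain, path)
  }
  invisible(path)
}

# Address single parameters by id for sensitivity sweeps.  Ids:
#   "annual_discount", "wtp", "sex_mix",
#   "utility_stable", "utility_progression",
#   "cost:<field>"  (a costs field), "price_per_mg",
#   "ae_prob:<ae>", "ae_cost:<ae>", "ae_ur:<ae>"
set_parameter <- function(params, id, value) {
  if (grepl("^cost:", id)) {
    f <- sub("^cost:", "", id)
    if (!f %in% names(params$costs)) stop("unknown parameter: ", id)
    params$costs[[f]] <- value
  } else if (grepl("^ae_(prob|cost|ur):", id)) {
    parts <- strsplit(id, ":", fixed = TRUE)[[1]]
    what <- sub("^ae_", "", parts[1]); ae <- parts[2]
    if (!ae %in% names(params$adverse_events)) stop("unknown parameter: ", id)
    field <- switch(what, prob = "monthly_prob", cost = "management_cost",
                    ur = "utility_reduction")
    params$adverse_events[[ae]][[field]] <- value
  } else {
    switch(id,
      annual_discount = params$settings$annual_discount <- value,
      wtp = params$settings$wtp <- value,
      sex_mix = params$settings$sex_mix <- value,
      utility_stable = params$utilities$stable <- value,
      utility_progression = params$utilities$progression <- value,
      price_per_mg = params$costs$unit_price_per_mg <- value,
      stop("unknown parameter: ", id)
    )
  }
  validate_parameters(params)
}
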