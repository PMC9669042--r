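#' Physiology parameters for the fluid-balance forward model
#'
#' The synthetic cohort generator produces 24 h urine osmolality from an
#' osmolar-clearance ratio: the daily osmolar load (mOsm excreted) divided by
#' the net urine volume (L). Net urine volume is total water intake plus
#' metabolic water minus insensible (non-urinary) losses, floored at a
#' physiologic minimum. Multiplicative lognormal noise and clipping to
#' physiologic bounds are applied on top of the deterministic ratio.
#'
#' @param osmolar_load_per_kg mOsm excreted per kg body weight per day from
#'   basal metabolism (default 10).
#' @param dietary_osmole_coefficients named numeric vector, mOsm per unit of
#'   each food variable; names must match food-variable columns. Defaults
#'   approximate urea from protein (2.5 mOsm/g) and salt from sodium
#'   (0.032 mOsm/mg, i.e. Na+ with its anion).
#' @param insensible_loss_mL daily trans-epidermal/respiratory/fecal water
#'   loss (default 900 mL).
#' @param metabolic_water_mL daily water produced by metabolism
#'   (default 300 mL, within the accepted 250-350 mL/day span).
#' @param food_water_fraction fraction of total water intake contributed by
#'   food moisture, in (0,1) (default 0.20, the conventional 80/20
#'   fluid/food division).
#' @param uosm_noise_sd_log SD of the lognormal multiplicative noise on
#'   urine osmolality (default 0.20).
#' @param uosm_floor,uosm_ceiling physiologic clip bounds for urine
#'   osmolality in mOsm/kg (defaults 50 and 1400).
#' @param urine_volume_floor_mL minimum net urine volume (default 300 mL);
#'   anuric states are out of scope.
#' @return An object of class `physiology_params`.
#' @export
physiology_params <- function(osmolar_load_per_kg = 10,
                              dietary_osmole_coefficients = c(
                                protein_g = 2.5, sodium_mg = 0.032,
                                energy_kcal = 0, food_moisture_mL = 0),
                              insensible_loss_mL = 900,
                              metabolic_water_mL = 300,
                              food_water_fraction = 0.20,
                              uosm_noise_sd_log = 0.20,
                              uosm_floor = 50,
                              uosm_ceiling = 1400,
                              urine_volume_floor_mL = 300) {
  stopifnot_scalar_num(osmolar_load_per_kg, "osmolar_load_per_kg", positive = TRUE)
  stopifnot_scalar_num(insensible_loss_mL, "insensible_loss_mL", positive = TRUE)
  stopifnot_scalar_num(metabolic_water_mL, "metabolic_water_mL", positive = TRUE)
  stopifnot_scalar_num(urine_volume_floor_mL, "urine_volume_floor_mL", positive = TRUE)
  stopifnot_scalar_num(uosm_noise_sd_log, "uosm_noise_sd_log")
  if (uosm_noise_sd_log < 0) stop("`uosm_noise_sd_log` must be >= 0")
  stopifnot_scalar_num(uosm_floor, "uosm_floor", positive = TRUE)
  stopifnot_scalar_num(uosm_ceiling, "uosm_ceiling", positive = TRUE)
  if (uosm_floor >= uosm_ceiling) stop("`uosm_floor` must be < `uosm_ceiling`")
  if (!is.numeric(food_water_fraction) || food_water_fraction <= 0 ||
      food_water_fraction >= 1)
    stop("`food_water_fraction` must lie in (0, 1)")
  if (length(dietary_osmole_coefficients) &&
      is.null(names(dietary_osmole_coefficients)))
    stop("`dietary_osmole_coefficients` must be named")
  if (any(dietary_osmole_coefficients < 0))
    stop("dietary osmole coefficients must be non-negative")
  structure(list(
    osmolar_load_per_kg = osmolar_load_per_kg,
    dietary_osmole_coefficients = dietary_osmole_coefficients,
    insensible_loss_mL = insensible_loss_mL,
    metabolic_water_mL = metabolic_water_mL,
    food_water_fraction = food_water_fraction,
    uosm_noise_sd_log = uosm_noise_sd_log,
    uosm_floor = uosm_floor,
    uosm_ceiling = uosm_ceiling,
    urine_volume_floor_mL = urine_volume_floor_mL
  ), class = "physiology_params")
}

#' Cohort specification for the synthetic generator
#'
#' @param n_participants number of participants (>= 1).
#' @param visits_per_participant integer vector of possible visit counts, or a
#'   named list `list(values=, probs=)`; each participant's visit count is
#'   drawn from it. Default `1:4` with probabilities favouring repeat visits,
#'   giving roughly 2.8 rows per participant.
#' @param female_fraction proportion of female participants in `[0,1]`
#'   (default 0.63).
#' @param age_range years, default `c(19, 51)`.
#' @param bmi_range kg/m^2, default `c(18, 30)`.
#' @param water_intake_distribution list with `meanlog`, `sdlog`, `min`,
#'   `max` (mL) for the lognormal plain-water draw, plus `p_zero`, the
#'   probability of a zero-plain-water day.
#' @param missing_fluid_fraction proportion of participants whose intake
#'   fields (plain water, total fluid, total water) are all missing
#'   (default 0.19).
#' @param seed integer random seed (mandatory for reproducibility).
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 600,
                        visits_per_participant = list(values = 1:4,
                                                      probs = c(0.15, 0.25, 0.30, 0.30)),
                        female_fraction = 0.63,
                        age_range = c(19, 51),
                        bmi_range = c(18, 30),
                        water_intake_distribution = list(
                          meanlog = log(1000), sdlog = 0.65,
                          min = 0, max = 4050, p_zero = 0.03),
                        missing_fluid_fraction = 0.19,
                        seed = 1L) {
  if (!is.numeric(n_participants) || n_participants < 1)
    stop("`n_participants` must be >= 1")
  if (is.numeric(visits_per_participant))
    visits_per_participant <- list(values = as.integer(visits_per_participant),
                                   probs = NULL)
  if (female_fraction < 0 || female_fraction > 1)
    stop("`female_fraction` must lie in [0, 1]")
  for (rg in list(age_range = age_range, bmi_range = bmi_range)) {
    if (length(rg) != 2L || diff(rg) <= 0) stop("ranges must be non-degenerate")
  }
  if (missing_fluid_fraction < 0 || missing_fluid_fraction > 1)
    stop("`missing_fluid_fraction` must lie in [0, 1]")
  if (is.null(seed)) stop("`seed` is mandatory")
  structure(list(
    n_participants = as.integer(n_participants),
    visits_per_participant = visits_per_participant,
    female_fraction = female_fraction,
    age_range = age_range,
    bmi_range = bmi_range,
    water_intake_distribution = water_intake_distribution,
    missing_fluid_fraction = missing_fluid_fraction,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

osmolar_load <- function(records, params) {
  load <- params$osmolar_load_per_kg * records$weight
  co <- params$dietary_osmole_coefficients
  for (nm in names(co)) {
    if (co[[nm]] != 0 && nm %in% names(records))
      load <- load + co[[nm]] * records[[nm]]
  }
  load
}

net_urine_volume_mL <- function(records, params) {
  vol <- records$total_water_intake + params$metabolic_water_mL -
    params$insensible_loss_mL
  pmax(vol, params$urine_volume_floor_mL)
}

#' Forward fluid-balance model: urine osmolality from a visit record
#'
#' Deterministic core: `U_Osm = osmolar_load / net_urine_volume`, where the
#' load is `osmolar_load_per_kg * weight` plus dietary terms and the net
#' urine volume (L) is total water intake plus metabolic water minus
#' insensible losses, floored at `urine_volume_floor_mL`. Lognormal noise
#' `exp(uosm_noise_sd_log * noise_draw)` then multiplies the ratio, and the
#' result is clipped to `[uosm_floor, uosm_ceiling]`.
#'
#' With `noise_draw = 0` the returned value is the (clipped) deterministic
#' ratio, which is non-increasing in plain water intake holding everything
#' else fixed.
#'
#' @param records one or more visit records (data.frame rows) carrying
#'   `weight`, `total_water_intake` and any food variables named in the
#'   dietary coefficients.
#' @param params a [physiology_params()] object.
#' @param noise_draw standard-normal draw(s), length 1 or `nrow(records)`.
#' @return urine osmolality in mOsm/kg (vector of length `nrow(records)`).
#' @export
forward_uosm <- function(records, params = physiology_params(), noise_draw = 0) {
  if (!inherits(params, "physiology_params")) stop("`params` must be physiology_params()")
  records <- as.data.frame(records)
  need <- c("weight", "total_water_intake")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack required fields: ", paste(miss, collapse = ", "))
  if (anyNA(records$total_water_intake) || anyNA(records$weight))
    stop("forward model requires non-missing weight and total water intake")
  vol_mL <- net_urine_volume_mL(records, params)
  if (any(vol_mL <= 0)) stop("inconsistent params: non-positive urine volume after flooring")
  uosm <- osmolar_load(records, params) / (vol_mL / 1000)
  uosm <- uosm * exp(params$uosm_noise_sd_log * noise_draw)
  pmin(pmax(uosm, params$uosm_floor), params$uosm_ceiling)
}

draw_visits <- function(vspec, n) {
  vals <- vspec$values
  if (length(vals) == 1L) return(rep(vals, n))
  sample(vals, n, replace = TRUE, prob = vspec$probs)
}

#' Generate a synthetic fluid-balance cohort
#'
#' Emits one row per participant visit with anthropometrics, plasma
#' osmolality, fluid/food intakes, the forward-model urine osmolality, and
#' the correlated urine features (24 h urine volume, number of micturitions)
#' that downstream feature selection is expected to discover and then
#' exclude. Time-invariant fields (sex, height) are shared across a
#' participant's visits; age and weight drift slightly. A
#' `missing_fluid_fraction` share of participants has all intake fields
#' missing. Seeding is hierarchical (cohort -> participant), so enlarging
#' the cohort leaves existing participants' rows unchanged.
#'
#' @param spec a [cohort_spec()].
#' @param params a [physiology_params()].
#' @return A data.frame of visit records, one row per participant-visit.
#' @export
generate_cohort <- function(spec = cohort_spec(), params = physiology_params()) {
  if (!inherits(spec, "cohort_spec")) stop("`spec` must be a cohort_spec()")
  if (!inherits(params, "physiology_params")) stop("`params` must be physiology_params()")
  n <- spec$n_participants
  wd <- spec$water_intake_distribution

  per_part <- lapply(seq_len(n), function(i) {
    withr::with_seed(child_seed(spec$seed, i), {
      # all participant-level draws live inside the participant's own
      # stream, so enlarging the cohort never perturbs earlier participants
      female <- runif(1) < spec$female_fraction
      missing_intake <- runif(1) < spec$missing_fluid_fraction
      nv <- draw_visits(spec$visits_per_participant, 1)
      height <- if (female) rnorm(1, 163, 6) else rnorm(1, 176, 7)
      height <- round(max(min(height, 200), 145), 1)
      # right-skewed age with mean near 30 inside the configured range
      age0 <- spec$age_range[1] + rgamma(1, shape = 2.2, scale = 5)
      age0 <- min(age0, spec$age_range[2])
      bmi0 <- spec$bmi_range[1] + diff(spec$bmi_range) * rbeta(1, 2, 2.8)
      w_habit <- rnorm(1, 0, 0.25)  # participant-level drinking habit (log scale)

      rows <- lapply(seq_len(nv), function(v) {
        bmi <- round(min(max(bmi0 + rnorm(1, 0, 0.15), spec$bmi_range[1]),
                         spec$bmi_range[2]), 1)
        weight <- round(bmi * (height / 100)^2, 1)
        plain <- if (runif(1) < wd$p_zero) 0 else
          rlnorm(1, wd$meanlog + w_habit, wd$sdlog)
        plain <- round(min(max(plain, wd$min), wd$max))
        # everyone consumes some non-water fluids (milk, soups, hot drinks)
        other_fluids <- round(200 + rlnorm(1, log(450), 0.45))
        tfi <- plain + other_fluids
        # food water scales with the amount of food eaten (energy), not with
        # beverage intake; at default energy and food_water_fraction this
        # averages the conventional ~20% share of total water
        energy <- round(max(rnorm(1, 2000, 350), 900))
        fwf <- params$food_water_fraction
        food_moist <- round(energy * 0.95 * fwf / (1 - fwf) * rlnorm(1, 0, 0.2))
        twi <- tfi + food_moist
        rec <- data.frame(
          participant_id = sprintf("P%05d", i),
          visit_index = v,
          age = round(min(age0 + (v - 1) * 0.05, spec$age_range[2])),
          sex = if (female) "female" else "male",
          height = height,
          weight = weight,
          bmi = bmi,
          plasma_osm = round(min(max(rnorm(1, 287, 4.5), 270), 305), 1),
          plain_water = plain,
          total_fluid_intake = tfi,
          total_water_intake = twi,
          energy_kcal = energy,
          protein_g = round(max(rnorm(1, 80, 18), 25), 1),
          sodium_mg = round(max(rnorm(1, 2800, 600), 800)),
          food_moisture_mL = food_moist
        )
        vol <- net_urine_volume_mL(rec, params)
        rec$urine_osm <- round(forward_uosm(rec, params, noise_draw = rnorm(1)), 1)
        rec$urine_volume <- round(vol)
        rec$n_micturitions <- max(1L, as.integer(round(vol / 250 + rnorm(1, 0, 0.6))))
        rec
      })
      out <- do.call(rbind, rows)
      # participant-level missingness of the intake fields
      if (missing_intake) out[, INTAKE_FIELDS] <- NA_real_
      out
    })
  })
  cohort <- do.call(rbind, per_part)
  rownames(cohort) <- NULL
  cohort
}

#' Inject eligibility-filter outliers into a cohort
#'
#' Marks `n_dehydrated` records as dehydrated (plasma osmolality above
#' 310 mOsm/kg) and `n_low_tfi` distinct records as implausibly low drinkers
#' (total fluid intake below 200 mL), to exercise the eligibility filters.
#' Assignments are disjoint and drawn among records with observed intake.
#'
#' @param cohort a cohort data.frame.
#' @param n_dehydrated,n_low_tfi counts of records to alter.
#' @param seed integer seed.
#' @return The modified cohort.
#' @export
inject_outliers <- function(cohort, n_dehydrated, n_low_tfi, seed = 1L) {
  if (n_dehydrated == 0 && n_low_tfi == 0) return(cohort)
  eligible <- which(!is.na(cohort$total_fluid_intake))
  if (n_dehydrated + n_low_tfi > length(eligible))
    stop("not enough records with observed intake to inject outliers")
  withr::with_seed(as.integer(seed), {
    picks <- sample(eligible, n_dehydrated + n_low_tfi)
  })
  dehyd <- picks[seq_len(n_dehydrated)]
  lowtfi <- picks[n_dehydrated + seq_len(n_low_tfi)]
  if (length(dehyd))
    cohort$plasma_osm[dehyd] <- round(311 + (seq_along(dehyd) %% 20), 1)
  if (length(lowtfi)) {
    tfi <- 100 + (seq_along(lowtfi) %% 10) * 10
    cohort$total_fluid_intake[lowtfi] <- tfi
    cohort$plain_water[lowtfi] <- round(tfi / 2)
    cohort$total_water_intake[lowtfi] <- tfi + cohort$food_moisture_mL[lowtfi]
  }
  cohort
}

#' Write / read a cohort CSV with a schema sidecar
#'
#' The CSV stores missing values as empty fields; a JSON sidecar
#' (`<path>.schema.json`) records the column names, units and a schema
#' version so files are self-describing.
#'
#' @param cohort cohort data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  units <- c(participant_id = "id", visit_index = "ordinal", age = "years",
             sex = "category", height = "cm", weight = "kg", bmi = "kg/m2",
             plasma_osm = "mOsm/kg", plain_water = "mL/24h",
             total_fluid_intake = "mL/24h", total_water_intake = "mL/24h",
             energy_kcal = "kcal/24h", protein_g = "g/24h",
             sodium_mg = "mg/24h", food_moisture_mL = "mL/24h",
             urine_osm = "mOsm/kg", urine_volume = "mL/24h",
             n_micturitions = "count/24h")
  schema <- list(schema_version = "1.0",
                 columns = lapply(names(cohort), function(nm)
                   list(name = nm, unit = unname(units[nm]) %||% "unknown")))
  jsonlite::write_json(schema, paste0(path, ".schema.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
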