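`%||%` <- function(x, y) if (is.null(x)) y else x

stopifnot_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be positive", name), call. = FALSE)
  invisible(x)
}

# derive a 32-bit child seed from a parent seed and an index; keeps
# per-participant streams independent of cohort size
child_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483647)
}

# intake columns that may legitimately be missing and are exempt from the
# completeness filter
INTAKE_FIELDS <- c("plain_water", "total_fluid_intake", "total_water_intake")

# anthropometric + response fields required by the completeness filter
CORE_FIELDS <- c("urine_osm", "age", "sex", "height", "weight", "bmi")
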