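DYE_CHANNELS <- c("violet", "far_red")

#' Treatment as a pure parameter modifier
#'
#' Treatments act multiplicatively on the motility speed and the division
#' rate before a run; no dose-response model is implied. Presets follow the
#' pharmacology they emulate: an actin depolymerizer (cytochalasin D-like)
#' suppresses speed, a cell-cycle antagonist (mitomycin C-like) suppresses
#' division, serum/ECM stimulation raises speed.
#'
#' @param name Label.
#' @param speed_multiplier,division_multiplier Non-negative multipliers.
#' @return An object of class `treatment`.
#' @examples
#' treatment("cytoD", speed_multiplier = 0.1)
#' @export
treatment <- function(name, speed_multiplier = 1, division_multiplier = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  if (speed_multiplier < 0 || division_multiplier < 0)
    stop("treatment: multipliers must be >= 0")
  structure(list(name = name,
                 speed_multiplier = speed_multiplier,
                 division_multiplier = division_multiplier),
            class = "treatment")
}

#' Built-in treatment presets
#'
#' @param name One of `"cytochalasin_D"` (speed x0.1), `"mitomycin_C"`
#'   (division x0), `"serum_ECM"` (speed x1.5).
#' @return A [treatment()].
#' @export
treatment_preset <- function(name = c("cytochalasin_D", "mitomycin_C",
                                      "serum_ECM")) {
  name <- match.arg(name)
  switch(name,
         cytochalasin_D = treatment("cytochalasin_D", speed_multiplier = 0.1),
         mitomycin_C = treatment("mitomycin_C", division_multiplier = 0),
         serum_ECM = treatment("serum_ECM", speed_multiplier = 1.5))
}

#' Simulation configuration for one assay run
#'
#' Defaults describe a highly motile epithelial line seeded to confluence
#' around the exclusion zone and followed over a 24 h migration window. The
#' motility parameters are effective values chosen so that zone occupancy at
#' the endpoint is well above background but far from complete fill (see the
#' methods vignette). `speed` and `persistence_time` parameterize a
#' persistent random walk whose velocity autocorrelation time equals
#' `persistence_time`.
#'
#' @param n_cells Number of seeded cells.
#' @param duration Migration window, h.
#' @param dt Time step, h.
#' @param speed Cell speed, um/h.
#' @param persistence_time Velocity correlation time of the persistent random
#'   walk, h.
#' @param division_rate Per-cell division rate, 1/h (`log(2)/24` doubles the
#'   population in 24 h).
#' @param dye_split_fraction Fraction of parental dye given to the first
#'   daughter at division; `0.5` is the symmetric 2-fold dilution.
#' @param dye_decay_rate First-order dye decay rate per channel, 1/h. Either
#'   a single value applied to both channels or a named vector with entries
#'   `violet` and `far_red`.
#' @param transfer_rate Pairwise neighbor dye-exchange rate, 1/h.
#' @param transfer_radius Neighbor radius for dye exchange (also the scale of
#'   daughter placement at division), um.
#' @param initial_dye Named per-channel dye content of a seeded cell,
#'   arbitrary units.
#' @param seed_exclusion Keep the exclusion zone cell-free at seeding
#'   (`TRUE`, the barrier assay) or seed the whole well (`FALSE`, plain
#'   cultures used for retention/transfer experiments).
#' @param rng_seed Integer seed; `NULL` leaves the RNG state alone.
#' @param treatments List of [treatment()] objects applied multiplicatively.
#' @return An object of class `assay_config`.
#' @examples
#' cfg <- assay_config(n_cells = 500, duration = 2, division_rate = log(2)/24)
#' @export
assay_config <- function(n_cells = 30000, duration = 24, dt = 0.1,
                         speed = 120, persistence_time = 2,
                         division_rate = 0, dye_split_fraction = 0.5,
                         dye_decay_rate = c(violet = 0, far_red = 0),
                         transfer_rate = 0, transfer_radius = 25,
                         initial_dye = c(violet = 1, far_red = 0),
                         seed_exclusion = TRUE,
                         rng_seed = NULL, treatments = list()) {
  if (length(dye_decay_rate) == 1L && is.null(names(dye_decay_rate)))
    dye_decay_rate <- c(violet = unname(dye_decay_rate),
                        far_red = unname(dye_decay_rate))
  dye_decay_rate <- dye_decay_rate[DYE_CHANNELS]
  initial_dye <- initial_dye[DYE_CHANNELS]
  initial_dye[is.na(initial_dye)] <- 0
  names(initial_dye) <- DYE_CHANNELS
  num <- c(n_cells = n_cells, duration = duration, dt = dt, speed = speed,
           persistence_time = persistence_time, division_rate = division_rate,
           dye_split_fraction = dye_split_fraction,
           transfer_rate = transfer_rate, transfer_radius = transfer_radius,
           dye_decay_rate, initial_dye)
  if (any(!is.finite(num))) stop("assay_config: non-finite parameter")
  if (dt <= 0 || duration < dt) stop("assay_config: need dt > 0 and duration >= dt")
  if (speed < 0 || division_rate < 0 || transfer_rate < 0 ||
      any(dye_decay_rate < 0) || any(initial_dye < 0))
    stop("assay_config: rates, speed and dye content must be >= 0")
  if (dye_split_fraction <= 0 || dye_split_fraction > 1)
    stop("assay_config: dye_split_fraction must be in (0, 1]")
  if (n_cells < 0 || n_cells != round(n_cells))
    stop("assay_config: n_cells must be a non-negative integer")
  if (persistence_time <= 0)
    stop("assay_config: persistence_time must be > 0")
  if (!is.null(rng_seed))
    stopifnot(is.numeric(rng_seed), length(rng_seed) == 1L)
  stopifnot(is.list(treatments))
  for (tr in treatments)
    if (!inherits(tr, "treatment")) stop("treatments must be treatment objects")
  structure(list(n_cells = as.integer(n_cells), duration = duration, dt = dt,
                 speed = speed, persistence_time = persistence_time,
                 division_rate = division_rate,
                 dye_split_fraction = dye_split_fraction,
                 dye_decay_rate = dye_decay_rate,
                 transfer_rate = transfer_rate,
                 transfer_radius = transfer_radius,
                 initial_dye = initial_dye,
                 seed_exclusion = isTRUE(seed_exclusion),
                 rng_seed = if (is.null(rng_seed)) NULL else as.integer(rng_seed),
                 treatments = treatments),
            class = "assay_config")
}

#' @export
print.assay_config <- function(x, ...) {
  cat(sprintf(
    paste0("assay_config: %d cells, %g h @ dt %g h, speed %g um/h ",
           "(P = %g h), division %g /h, split %g\n"),
    x$n_cells, x$duration, x$dt, x$speed, x$persistence_time,
    x$division_rate, x$dye_split_fraction))
  if (length(x$treatments))
    cat("  treatments:",
        paste(vapply(x$treatments, `[[`, "", "name"), collapse = ", "), "\n")
  invisible(x)
}

# Resolve treatments into effective speed / division_rate.
effective_config <- function(config) {
  for (tr in config$treatments) {
    config$speed <- config$speed * tr$speed_multiplier
    config$division_rate <- config$division_rate * tr$division_multiplier
  }
  config
}

#' Read / write an assay configuration (plus geometry) as YAML
#'
#' The file mirrors the [assay_config()] and [well_geometry()] field names
#' verbatim under top-level keys `assay_config` and `well_geometry`;
#' treatments are a list of `{name, speed_multiplier, division_multiplier}`
#' mappings.
#'
#' @param path YAML file path.
#' @param config An [assay_config()]; `geometry` a [well_geometry()].
#' @return `read_assay_config` returns `list(config =, geometry =)`;
#'   `write_assay_config` returns `path` invisibly.
#' @export
read_assay_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  gy <- y$well_geometry
  geometry <- well_geometry(
    well_radius = gy$well_radius %||% 3200,
    zone_radius = gy$zone_radius %||% 1000,
    zone_center_offset = unlist(gy$zone_center_offset %||% c(0, 0)),
    pixel_size = gy$pixel_size %||% 12.5)
  cy <- y$assay_config %||% list()
  trs <- lapply(cy$treatments %||% list(), function(t)
    treatment(t$name, t$speed_multiplier %||% 1, t$division_multiplier %||% 1))
  cy$treatments <- NULL
  args <- cy
  if (!is.null(args$dye_decay_rate)) args$dye_decay_rate <- unlist(args$dye_decay_rate)
  if (!is.null(args$initial_dye)) args$initial_dye <- unlist(args$initial_dye)
  config <- do.call(assay_config, c(args, list(treatments = trs)))
  list(config = config, geometry = geometry)
}

#' @rdname read_assay_config
#' @param geometry A [well_geometry()].
#' @export
write_assay_config <- function(config, geometry, path) {
  y <- list(
    assay_config = list(
      n_cells = config$n_cells, duration = config$duration, dt = config$dt,
      speed = config$speed, persistence_time = config$persistence_time,
      division_rate = config$division_rate,
      dye_split_fraction = config$dye_split_fraction,
      dye_decay_rate = as.list(config$dye_decay_rate),
      transfer_rate = config$transfer_rate,
      transfer_radius = config$transfer_radius,
      initial_dye = as.list(config$initial_dye),
      seed_exclusion = config$seed_exclusion,
      rng_seed = config$rng_seed,
      treatments = lapply(config$treatments, function(t)
        list(name = t$name, speed_multiplier = t$speed_multiplier,
             division_multiplier = t$division_multiplier))),
    well_geometry = list(
      well_radius = geometry$well_radius, zone_radius = geometry$zone_radius,
      zone_center_offset = as.list(geometry$zone_center_offset),
      pixel_size = geometry$pixel_size))
  yaml::write_yaml(y, path, precision = 15)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
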