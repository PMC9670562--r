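# Synthetic host/environment amplicon survey with planted core taxa.
#
# Each ASV gets a log-normal baseline intensity. Host samples multiply the
# planted core taxa by an enrichment factor (with per-sample Bernoulli
# dropout controlling occupancy); rock and seawater samples multiply the
# environmental taxa by their own enrichment, symmetrically; transient taxa
# get event-specific log-normal intensity multipliers shared by all samples
# in the event. Counts are multinomial draws at negative-binomial depths.
# Truth labels make detector sensitivity/false-positive rates computable.

#' Specification for a synthetic host/environment survey
#'
#' Defaults describe a multi-site, multi-year intertidal survey: 11 sampling
#' events of 5 host + 3 rock + 2 seawater samples (110 samples), 300 ASVs of
#' which 15 are planted host cores (enrichment 50, occupancy 0.95) and 60 are
#' environmental taxa enriched 20-fold on rock/seawater, the remainder
#' transient with event-specific intensities; per-sample depths are negative
#' binomial with mean 5000 and dispersion 10 (the 10^3-10^4 range).
#'
#' @param n_events Number of sampling events (site x time units).
#' @param n_host,n_rock,n_water Samples of each type per event.
#' @param n_asvs Total ASVs.
#' @param n_core Planted host-core ASVs.
#' @param n_env_taxa Environmental (rock/seawater-enriched) ASVs.
#' @param enrichment Host enrichment factor of core taxa (>= 1; 1 gives a
#'   null community with no planted signal).
#' @param occupancy Per-host-sample presence probability of a core ASV
#'   (Bernoulli dropout with rate 1 - occupancy), in (0, 1].
#' @param env_enrichment Rock/seawater enrichment factor of environmental
#'   taxa.
#' @param seasonal_amplitude Amplitude of a sinusoidal seasonal modulation of
#'   core host intensities (0 = none).
#' @param depth_mean,depth_dispersion Negative-binomial mean and size of
#'   per-sample read totals.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline intensity
#'   parameters.
#' @param transient_sdlog Log-sd of the event-specific transient multipliers.
#' @param seed Integer master seed.
#' @return Validated list of class `"sim_spec"`.
#' @export
sim_spec <- function(n_events = 11L, n_host = 5L, n_rock = 3L, n_water = 2L,
                     n_asvs = 300L, n_core = 15L, n_env_taxa = 60L,
                     enrichment = 50, occupancy = 0.95, env_enrichment = 20,
                     seasonal_amplitude = 0, depth_mean = 5000,
                     depth_dispersion = 10, baseline_meanlog = 0,
                     baseline_sdlog = 1.2, transient_sdlog = 1.5,
                     seed = 1L) {
  spec <- list(n_events = as.integer(n_events), n_host = as.integer(n_host),
               n_rock = as.integer(n_rock), n_water = as.integer(n_water),
               n_asvs = as.integer(n_asvs), n_core = as.integer(n_core),
               n_env_taxa = as.integer(n_env_taxa), enrichment = enrichment,
               occupancy = occupancy, env_enrichment = env_enrichment,
               seasonal_amplitude = seasonal_amplitude,
               depth_mean = depth_mean, depth_dispersion = depth_dispersion,
               baseline_meanlog = baseline_meanlog,
               baseline_sdlog = baseline_sdlog,
               transient_sdlog = transient_sdlog, seed = as.integer(seed))
  if (spec$n_events < 1L) stop("need at least one sampling event")
  if (spec$n_host + spec$n_rock + spec$n_water < 1L) {
    stop("spec yields zero samples per event")
  }
  if (spec$n_host < 1L) stop("need at least one host sample per event")
  if (spec$n_asvs < 1L) stop("need at least one ASV")
  if (spec$n_core + spec$n_env_taxa > spec$n_asvs) {
    stop("n_core + n_env_taxa exceeds n_asvs")
  }
  if (spec$enrichment < 1) stop("enrichment must be >= 1")
  if (spec$occupancy <= 0 || spec$occupancy > 1) {
    stop("occupancy must be in (0, 1]")
  }
  if (spec$depth_mean < 1) stop("depth_mean must be >= 1")
  class(spec) <- "sim_spec"
  spec
}

#' Simulate a host/environment amplicon survey
#'
#' @param spec A [sim_spec()] object.
#' @return List with `counts` (samples x ASVs integer matrix; row sums equal
#'   the drawn depths exactly), `metadata` (sample_id, sample_type, site,
#'   date, host_species, sampling_event), `truth` (data.frame `asv_id`,
#'   `role` in core/environmental/transient), and the `spec`. Identical seed,
#'   identical output; the caller's RNG state is restored.
#' @export
simulate_survey <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  set.seed(spec$seed)

  asv_ids <- sprintf("ASV%04d", seq_len(spec$n_asvs))
  role <- rep("transient", spec$n_asvs)
  role[seq_len(spec$n_core)] <- "core"
  if (spec$n_env_taxa > 0L) {
    role[spec$n_core + seq_len(spec$n_env_taxa)] <- "environmental"
  }
  is_core <- role == "core"
  is_env <- role == "environmental"
  is_tr <- role == "transient"

  lambda <- rlnorm(spec$n_asvs, spec$baseline_meanlog, spec$baseline_sdlog)
  events <- sprintf("E%02d", seq_len(spec$n_events))
  dates <- seq(as.Date("2018-03-15"), by = "month",
               length.out = spec$n_events)
  months <- as.integer(format(dates, "%m"))
  # event-specific multipliers for transient taxa
  tr_mult <- matrix(1, spec$n_asvs, spec$n_events)
  if (any(is_tr)) {
    tr_mult[is_tr, ] <- matrix(
      rlnorm(sum(is_tr) * spec$n_events, 0, spec$transient_sdlog),
      sum(is_tr), spec$n_events)
  }

  per_event <- c(rep("host", spec$n_host), rep("rock", spec$n_rock),
                 rep("seawater", spec$n_water))
  abbrev <- c(host = "H", rock = "R", seawater = "W")
  n_samples <- spec$n_events * length(per_event)
  counts <- matrix(0L, n_samples, spec$n_asvs,
                   dimnames = list(character(n_samples), asv_ids))
  meta <- data.frame(sample_id = character(n_samples),
                     sample_type = character(n_samples),
                     site = character(n_samples),
                     date = rep(dates[1], n_samples),
                     host_species = NA_character_,
                     sampling_event = character(n_samples),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (e in seq_len(spec$n_events)) {
    season <- exp(spec$seasonal_amplitude * sin(2 * pi * (months[e] - 5) / 12))
    counters <- c(host = 0L, rock = 0L, seawater = 0L)
    for (ty in per_event) {
      row <- row + 1L
      counters[ty] <- counters[ty] + 1L
      sid <- sprintf("%s_%s%02d", events[e], abbrev[[ty]], counters[ty])
      lam <- lambda
      lam[is_tr] <- lam[is_tr] * tr_mult[is_tr, e]
      if (ty == "host") {
        keep <- rbinom(sum(is_core), 1L, spec$occupancy) == 1L
        mult <- ifelse(keep, spec$enrichment * season, 0)
        lam[is_core] <- lam[is_core] * mult
      } else {
        lam[is_env] <- lam[is_env] * spec$env_enrichment
      }
      depth <- max(1L, rnbinom(1L, mu = spec$depth_mean,
                               size = spec$depth_dispersion))
      counts[row, ] <- as.integer(rmultinom(1L, depth, lam))
      rownames(counts)[row] <- sid
      meta$sample_id[row] <- sid
      meta$sample_type[row] <- ty
      meta$site[row] <- events[e]
      meta$date[row] <- dates[e]
      meta$host_species[row] <- if (ty == "host") "focal_host" else NA_character_
      meta$sampling_event[row] <- events[e]
    }
  }
  list(counts = as_count_table(counts), metadata = meta,
       truth = data.frame(asv_id = asv_ids, role = role,
                          stringsAsFactors = FALSE),
       spec = spec)
}

#' Recovery of planted core taxa by each definition
#'
#' Scores a core fit against the generator's truth labels: sensitivity is the
#' fraction of planted core ASVs flagged by a definition; the false-positive
#' rate is the fraction of non-core ASVs in the report (all of which carry
#' non-zero reads after filtering) that were flagged.
#'
#' @param truth Truth data.frame from [simulate_survey()] (`asv_id`, `role`).
#' @param fit A `core_fit` object or its `report` data.frame.
#' @return data.frame with one row per definition (`frequency`, `indval`,
#'   `twostep`): `n_flagged`, `sensitivity`, `false_positive_rate`.
#' @export
recovery_report <- function(truth, fit) {
  report <- if (inherits(fit, "core_fit")) fit$report else fit
  stray <- setdiff(report$asv_id, truth$asv_id)
  if (length(stray) > 0L) {
    stop("report contains ASVs absent from the truth set: ",
         paste(utils::head(stray, 5), collapse = ", "))
  }
  planted <- truth$asv_id[truth$role == "core"]
  flags <- list(frequency = "is_freq_core", indval = "is_indval_core",
                twostep = "is_twostep_core")
  rows <- lapply(names(flags), function(meth) {
    flagged <- report$asv_id[report[[flags[[meth]]]]]
    noncore_in_report <- setdiff(report$asv_id, planted)
    data.frame(
      method = meth,
      n_flagged = length(flagged),
      sensitivity = if (length(planted)) {
        mean(planted %in% flagged)
      } else NA_real_,
      false_positive_rate = if (length(noncore_in_report)) {
        mean(noncore_in_report %in% flagged)
      } else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}
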