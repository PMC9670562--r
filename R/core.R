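# Three routes to a host core microbiome:
#   1. frequency_core  — occupancy threshold on host samples alone
#   2. indval_core     — whole-dataset IndVal of host vs environment
#   3. twostep_core    — IndVal per sampling event, then a tally across events
# core_microbiome() runs all three and returns a classed fit.

#' Frequency (occupancy) core membership
#'
#' The simplest core definition: an ASV is core when it occurs (count > 0) in
#' at least `freq_threshold` of the host samples. The threshold is inclusive,
#' so an ASV present in exactly half the host samples is core at 0.5. Also
#' reports each ASV's mean per-sample relative abundance on the host.
#'
#' @param x Samples x ASVs count matrix (filtered counts).
#' @param meta Metadata data.frame aligned to `x` (see [align_samples()]).
#' @param target_type Sample type treated as the host (default `"host"`).
#' @param freq_threshold Occupancy fraction required (default 0.5).
#' @return data.frame: `asv_id`, `frequency`, `mean_rel_abund`, `is_freq_core`.
#' @export
frequency_core <- function(x, meta, target_type = "host",
                           freq_threshold = 0.5) {
  stopifnot(freq_threshold > 0, freq_threshold <= 1)
  host <- meta$sample_id[meta$sample_type == target_type]
  host <- intersect(rownames(x), host)
  if (length(host) == 0L) stop("no samples of type '", target_type, "'")
  xh <- x[host, , drop = FALSE]
  freq <- colSums(xh > 0) / length(host)
  ra <- relative_abundance(xh)
  data.frame(
    asv_id = colnames(x),
    frequency = unname(freq),
    mean_rel_abund = unname(colMeans(ra)),
    is_freq_core = unname(freq >= freq_threshold),
    stringsAsFactors = FALSE
  )
}

# subset counts+meta to the host and environmental types, in table order
.host_env_subset <- function(x, meta, target_type, env_types) {
  keep <- meta$sample_id[meta$sample_type %in% c(target_type, env_types)]
  keep <- intersect(rownames(x), keep)
  m <- meta[match(keep, meta$sample_id), , drop = FALSE]
  list(counts = x[keep, , drop = FALSE], metadata = m)
}

#' Whole-dataset IndVal core membership
#'
#' Runs [indval()] over all host and environmental samples with the host as
#' target group (environmental types kept as separate groups by default) and
#' declares an ASV core when its indicator value reaches `indval_threshold`
#' and its permutation p-value is at most `alpha`.
#'
#' @inheritParams frequency_core
#' @param env_types Sample types forming the environmental comparison.
#' @param indval_threshold Indicator-value cutoff (default 0.7).
#' @param alpha Permutation-test significance level (default 0.05).
#' @param n_perm,seed,variant,pool_env Passed to [indval()].
#' @param abundance `"relative"` (default) to run IndVal on per-sample
#'   relative abundances, or `"counts"` for raw counts.
#' @return data.frame of class `indval_result` with an extra
#'   `is_indval_core` column.
#' @export
indval_core <- function(x, meta, target_type = "host",
                        env_types = c("rock", "seawater"),
                        indval_threshold = 0.7, alpha = 0.05,
                        n_perm = 999L, seed = NULL,
                        abundance = c("relative", "counts"),
                        variant = c("sqrt", "product"), pool_env = FALSE) {
  abundance <- match.arg(abundance)
  variant <- match.arg(variant)
  sub <- .host_env_subset(x, meta, target_type, env_types)
  if (!any(sub$metadata$sample_type %in% env_types)) {
    stop("no environmental samples (types: ",
         paste(env_types, collapse = ", "), ") present")
  }
  ab <- if (abundance == "relative") relative_abundance(sub$counts) else sub$counts
  res <- indval(ab, sub$metadata$sample_type, target = target_type,
                n_perm = n_perm, seed = seed, variant = variant,
                pool_env = pool_env)
  res$is_indval_core <- res$stat >= indval_threshold & res$p_value <= alpha
  res
}

#' Two-step per-event IndVal core membership
#'
#' Step 1 runs [indval()] independently within every sampling event (site x
#' time combination), using only that event's host and environmental samples;
#' an ASV is an indicator of the event when its statistic reaches
#' `indval_threshold` with p-value at most `alpha`. Step 2 tallies, per ASV,
#' the number of events in which it was an indicator, and declares it core
#' when the tally reaches `min_events` (default 7, i.e. an indicator in more
#' than 6 of 11 sampling events; designs with fewer events must set it
#' explicitly). Events lacking either host or environmental samples cannot
#' support the comparison and are excluded (and recorded).
#'
#' Per-event permutation seeds are derived deterministically from `seed` and
#' the event's rank among the sorted event labels, so a full run is
#' reproducible regardless of event order.
#'
#' @inheritParams indval_core
#' @param min_events Events required for core status (default 7; must not
#'   exceed the number of usable events).
#' @return List with `event_indicators` (ASVs x events logical matrix),
#'   `event_tally`, `is_twostep_core`, `min_events`, `events_used`,
#'   `events_excluded`, and `per_event` (list of `indval_result` objects).
#' @export
twostep_core <- function(x, meta, target_type = "host",
                         env_types = c("rock", "seawater"),
                         indval_threshold = 0.7, alpha = 0.05,
                         min_events = 7L, n_perm = 999L, seed = 1L,
                         abundance = c("relative", "counts"),
                         variant = c("sqrt", "product")) {
  abundance <- match.arg(abundance)
  variant <- match.arg(variant)
  if (!"sampling_event" %in% colnames(meta) ||
      any(is.na(meta$sampling_event) | !nzchar(meta$sampling_event))) {
    stop("every sample needs a non-empty sampling_event label")
  }
  sub <- .host_env_subset(x, meta, target_type, env_types)
  events <- sort(unique(sub$metadata$sampling_event))
  usable <- logical(length(events))
  names(usable) <- events
  for (ev in events) {
    ty <- sub$metadata$sample_type[sub$metadata$sampling_event == ev]
    usable[ev] <- any(ty == target_type) && any(ty %in% env_types)
  }
  if (!any(usable)) {
    stop("no sampling event contains both host and environmental samples")
  }
  if (any(!usable)) {
    message("twostep: excluding event(s) without a host/environment pair: ",
            paste(events[!usable], collapse = ", "))
  }
  used <- events[usable]
  if (is.null(min_events)) min_events <- 7L
  if (min_events < 1L || min_events > length(used)) {
    stop("min_events (", min_events, ") must be between 1 and the number ",
         "of usable events (", length(used), ")")
  }

  ind <- matrix(FALSE, nrow = ncol(x), ncol = length(used),
                dimnames = list(colnames(x), used))
  per_event <- vector("list", length(used))
  names(per_event) <- used
  for (ev in used) {
    sel <- sub$metadata$sampling_event == ev
    xe <- sub$counts[sub$metadata$sample_id[sel], , drop = FALSE]
    ge <- sub$metadata$sample_type[sel]
    ab <- if (abundance == "relative") relative_abundance(xe) else xe
    ev_seed <- (seed + 7919L * match(ev, used)) %% .Machine$integer.max
    res <- indval(ab, ge, target = target_type, n_perm = n_perm,
                  seed = ev_seed, variant = variant)
    ind[, ev] <- res$stat >= indval_threshold & res$p_value <= alpha
    per_event[[ev]] <- res
  }
  tally <- rowSums(ind)
  list(
    event_indicators = ind,
    event_tally = tally,
    is_twostep_core = tally >= min_events,
    min_events = min_events,
    events_used = used,
    events_excluded = events[!usable],
    per_event = per_event
  )
}

#' Combine the three core definitions into one ledger
#'
#' @param freq Output of [frequency_core()].
#' @param indv Output of [indval_core()].
#' @param twostep Output of [twostep_core()].
#' @return data.frame, one row per ASV, with the per-definition flags,
#'   `met_all` / `met_any` set-algebra columns, sorted by event tally then
#'   host frequency, descending.
#' @export
compare_cores <- function(freq, indv, twostep) {
  stopifnot(identical(sort(freq$asv_id), sort(indv$asv_id)),
            identical(sort(freq$asv_id), sort(rownames(twostep$event_indicators))))
  df <- freq
  i <- match(df$asv_id, indv$asv_id)
  df$indval_A <- indv$A[i]
  df$indval_B <- indv$B[i]
  df$indval_stat <- indv$stat[i]
  df$indval_p <- indv$p_value[i]
  df$is_indval_core <- indv$is_indval_core[i]
  j <- match(df$asv_id, rownames(twostep$event_indicators))
  df$event_tally <- unname(twostep$event_tally[j])
  df$is_twostep_core <- unname(twostep$is_twostep_core[j])
  df$met_all <- df$is_freq_core & df$is_indval_core & df$is_twostep_core
  df$met_any <- df$is_freq_core | df$is_indval_core | df$is_twostep_core
  df[order(-df$event_tally, -df$frequency, df$asv_id), , drop = FALSE]
}

#' Identify core host-associated ASVs by three definitions
#'
#' The package's central fitting function. Given a filtered count table and
#' sample metadata it runs the frequency (occupancy) definition on host
#' samples, whole-dataset IndVal against the environmental samples, and the
#' two-step per-sampling-event IndVal tally, plus each ASV's overall host
#' specificity (read share on host versus environment), and assembles the
#' per-ASV comparison ledger.
#'
#' Core identification runs on the (unrarefied) filtered counts; rarefaction
#' is only involved in beta-diversity summaries (see [bray_curtis()] and
#' [permanova()]).
#'
#' @inheritParams twostep_core
#' @param freq_threshold Occupancy fraction for the frequency core
#'   (default 0.5).
#' @param run_twostep Set FALSE to skip the per-event analysis (e.g. when the
#'   metadata carries no sampling events).
#' @return Object of class `"core_fit"`: a list with `report` (the per-ASV
#'   ledger; see [compare_cores()], plus `overall_specificity`),
#'   `event_indicators`, `indval` (the whole-dataset `indval_result`),
#'   `twostep`, `params`, and sample bookkeeping. Has `print`, `summary` and
#'   `plot` methods.
#' @examples
#' sim <- simulate_survey(sim_spec(n_events = 3, n_asvs = 60,
#'                                 n_core = 4, seed = 1))
#' fit <- core_microbiome(sim$counts, sim$metadata, min_events = 2,
#'                        n_perm = 99, seed = 1)
#' summary(fit)
#' @export
core_microbiome <- function(x, meta, target_type = "host",
                            env_types = c("rock", "seawater"),
                            freq_threshold = 0.5, indval_threshold = 0.7,
                            alpha = 0.05, min_events = 7L,
                            n_perm = 999L, seed = 1L,
                            abundance = c("relative", "counts"),
                            variant = c("sqrt", "product"),
                            pool_env = FALSE, run_twostep = TRUE) {
  abundance <- match.arg(abundance)
  variant <- match.arg(variant)
  al <- align_samples(x, meta, policy = "intersect")
  x <- al$counts
  meta <- al$metadata

  freq <- frequency_core(x, meta, target_type, freq_threshold)
  indv <- indval_core(x, meta, target_type, env_types,
                      indval_threshold, alpha, n_perm, seed,
                      abundance, variant, pool_env)
  if (run_twostep) {
    two <- twostep_core(x, meta, target_type, env_types,
                        indval_threshold, alpha, min_events,
                        n_perm, seed, abundance, variant)
  } else {
    two <- list(
      event_indicators = matrix(FALSE, ncol(x), 0,
                                dimnames = list(colnames(x), NULL)),
      event_tally = setNames(rep(0L, ncol(x)), colnames(x)),
      is_twostep_core = setNames(rep(FALSE, ncol(x)), colnames(x)),
      min_events = NA_integer_, events_used = character(0),
      events_excluded = character(0), per_event = list()
    )
  }
  report <- compare_cores(freq, indv, two)
  spec <- overall_specificity(x, meta, focal_type = target_type,
                              env_types = env_types)
  report$overall_specificity <-
    spec$specificity[match(report$asv_id, spec$asv_id)]

  fit <- list(
    report = report,
    event_indicators = two$event_indicators,
    indval = indv,
    twostep = two[c("event_tally", "is_twostep_core", "min_events",
                    "events_used", "events_excluded", "per_event")],
    params = list(target_type = target_type, env_types = env_types,
                  freq_threshold = freq_threshold,
                  indval_threshold = indval_threshold, alpha = alpha,
                  min_events = two$min_events, n_perm = n_perm, seed = seed,
                  abundance = abundance, variant = variant,
                  pool_env = pool_env),
    n_samples = table(meta$sample_type),
    n_asvs = ncol(x)
  )
  class(fit) <- "core_fit"
  fit
}

#' @export
print.core_fit <- function(x, ...) {
  r <- x$report
  cat("Core microbiome fit (", x$n_asvs, " ASVs, ",
      sum(x$n_samples), " samples: ",
      paste(names(x$n_samples), x$n_samples, sep = "=", collapse = ", "),
      ")\n", sep = "")
  cat(sprintf("  frequency core (>= %.2f occupancy): %d ASVs\n",
              x$params$freq_threshold, sum(r$is_freq_core)))
  cat(sprintf("  IndVal core (stat >= %.2f, p <= %.2g): %d ASVs\n",
              x$params$indval_threshold, x$params$alpha,
              sum(r$is_indval_core)))
  if (length(x$twostep$events_used) > 0L) {
    cat(sprintf("  two-step core (indicator in >= %d of %d events): %d ASVs\n",
                x$twostep$min_events, length(x$twostep$events_used),
                sum(r$is_twostep_core)))
  }
  cat(sprintf("  met all definitions: %d; met any: %d\n",
              sum(r$met_all), sum(r$met_any)))
  invisible(x)
}

#' @export
summary.core_fit <- function(object, n = 15L, ...) {
  r <- object$report
  out <- list(
    n_asvs = object$n_asvs,
    n_samples = object$n_samples,
    n_core = c(frequency = sum(r$is_freq_core),
               indval = sum(r$is_indval_core),
               twostep = sum(r$is_twostep_core),
               all = sum(r$met_all), any = sum(r$met_any)),
    overlap = c(
      freq_and_indval = sum(r$is_freq_core & r$is_indval_core),
      freq_and_twostep = sum(r$is_freq_core & r$is_twostep_core),
      indval_and_twostep = sum(r$is_indval_core & r$is_twostep_core)
    ),
    events_used = object$twostep$events_used,
    events_excluded = object$twostep$events_excluded,
    top = utils::head(r[r$met_any, , drop = FALSE], n),
    params = object$params
  )
  class(out) <- "summary.core_fit"
  out
}

#' @export
print.summary.core_fit <- function(x, ...) {
  cat("Core membership by definition:\n")
  print(x$n_core)
  cat("Pairwise overlaps:\n")
  print(x$overlap)
  if (length(x$events_used)) {
    cat(length(x$events_used), "sampling events used")
    if (length(x$events_excluded)) {
      cat(";", length(x$events_excluded), "excluded:",
          paste(x$events_excluded, collapse = ", "))
    }
    cat("\n")
  }
  if (nrow(x$top)) {
    cat("Top ASVs meeting any definition:\n")
    cols <- c("asv_id", "frequency", "mean_rel_abund", "indval_stat",
              "indval_p", "event_tally", "overall_specificity",
              "is_freq_core", "is_indval_core", "is_twostep_core")
    print(x$top[, intersect(cols, colnames(x$top))], digits = 3,
          row.names = FALSE)
  }
  invisible(x)
}

#' Plot the per-event indicator matrix of a core fit
#'
#' Draws the ASVs-by-events indicator grid (the "grey boxes" view): ASVs that
#' met at least one core definition, ordered by event tally, with a filled
#' cell where the ASV was a significant indicator of the event.
#'
#' @param x A `core_fit` object.
#' @param max_asvs Show at most this many ASVs (by tally).
#' @param ... Ignored.
#' @export
plot.core_fit <- function(x, max_asvs = 40L, ...) {
  r <- x$report
  sel <- r$asv_id[r$met_any]
  if (length(sel) == 0L) {
    warning("no ASVs met any core definition; nothing to plot")
    return(invisible(NULL))
  }
  sel <- utils::head(sel, max_asvs)
  m <- x$event_indicators[sel, , drop = FALSE]
  if (ncol(m) == 0L) {
    warning("no per-event indicators in this fit")
    return(invisible(NULL))
  }
  op <- graphics::par(mar = c(5, 8, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(ncol(m)), seq_len(nrow(m)),
                  t(m[rev(seq_len(nrow(m))), , drop = FALSE]) * 1,
                  col = c("white", "grey40"), axes = FALSE,
                  xlab = "sampling event", ylab = "")
  graphics::axis(1, at = seq_len(ncol(m)), labels = colnames(m), las = 2,
                 cex.axis = 0.7)
  graphics::axis(2, at = seq_len(nrow(m)), labels = rev(rownames(m)),
                 las = 1, cex.axis = 0.6)
  graphics::box()
  invisible(x)
}
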