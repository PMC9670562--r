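# Host specificity, host range across macroalgal species, and seasonal
# summaries of core taxa.

#' Overall host specificity of each ASV
#'
#' The read-based specificity of an ASV for the focal host: reads on focal
#' samples divided by reads on focal plus environmental samples, a fraction
#' in \[0, 1\] (1 = found only on the host). Being a ratio of read totals it
#' is invariant to duplicating every sample. ASVs with zero reads across the
#' focal and environmental samples get `NA`.
#'
#' @param x Samples x ASVs count matrix.
#' @param meta Metadata data.frame.
#' @param focal_type Sample type of the focal host (default `"host"`).
#' @param env_types Environmental sample types (default rock + seawater).
#' @return data.frame: `asv_id`, `focal_reads`, `env_reads`, `specificity`.
#' @export
overall_specificity <- function(x, meta, focal_type = "host",
                                env_types = c("rock", "seawater")) {
  foc <- intersect(rownames(x), meta$sample_id[meta$sample_type == focal_type])
  env <- intersect(rownames(x),
                   meta$sample_id[meta$sample_type %in% env_types])
  if (length(foc) == 0L) stop("no samples of focal type '", focal_type, "'")
  if (length(env) == 0L) stop("no environmental samples")
  fr <- colSums(x[foc, , drop = FALSE])
  er <- colSums(x[env, , drop = FALSE])
  tot <- fr + er
  data.frame(
    asv_id = colnames(x),
    focal_reads = unname(fr),
    env_reads = unname(er),
    specificity = unname(ifelse(tot > 0, fr / tot, NA_real_)),
    stringsAsFactors = FALSE
  )
}

#' Host range: specialists and macroalgal generalists
#'
#' Classifies each ASV by how many host species it is "present" on, where
#' presence on a species means its mean per-sample relative abundance across
#' that species' samples reaches `presence_threshold` (default 0.1 percent, a
#' guard against transient settlers). Generalists are present on more than
#' one species; specialists are present on the focal host and nowhere else.
#'
#' @param x Samples x ASVs count matrix covering the multi-species survey.
#' @param meta Metadata; host species are read from `host_species` for rows
#'   with `sample_type` in `host`/`other_host`.
#' @param focal_host Species label of the focal host.
#' @param presence_threshold Mean relative-abundance cutoff for presence.
#' @return List with `species_means` (ASVs x species matrix of mean relative
#'   abundances) and `classification` (data.frame: `asv_id`,
#'   `n_hosts_present`, `present_on_focal`, `is_generalist`, `is_specialist`).
#' @export
host_range <- function(x, meta, focal_host, presence_threshold = 0.001) {
  stopifnot(presence_threshold >= 0, presence_threshold < 1)
  if (!"host_species" %in% colnames(meta)) {
    stop("metadata has no host_species column")
  }
  hm <- meta[meta$sample_type %in% c("host", "other_host"), , drop = FALSE]
  hm <- hm[hm$sample_id %in% rownames(x), , drop = FALSE]
  species <- sort(unique(hm$host_species))
  if (length(species) < 2L) stop("need at least 2 host species")
  if (!focal_host %in% species) {
    stop("focal host '", focal_host, "' absent from metadata")
  }
  ra <- relative_abundance(x[hm$sample_id, , drop = FALSE])
  sp <- factor(hm$host_species, levels = species)
  means <- rowsum(ra, sp) / as.vector(table(sp))
  present <- t(means) >= presence_threshold  # ASVs x species
  n_hosts <- rowSums(present)
  on_focal <- present[, focal_host]
  list(
    species_means = t(means),
    classification = data.frame(
      asv_id = colnames(x),
      n_hosts_present = unname(n_hosts),
      present_on_focal = unname(on_focal),
      is_generalist = unname(n_hosts > 1),
      is_specialist = unname(on_focal & n_hosts == 1),
      stringsAsFactors = FALSE
    )
  )
}

#' IndVal enrichment of the focal host against other host species
#'
#' Runs [indval()] with the focal host species as target and every other
#' host species as its own group (group-equalized). The `A` component is the
#' specificity of each ASV for the focal host in the multi-species sense.
#'
#' @inheritParams host_range
#' @param n_perm,seed,mode Passed to [indval()].
#' @return An `indval_result` data.frame.
#' @export
host_enrichment_indval <- function(x, meta, focal_host, n_perm = 999L,
                                   seed = NULL,
                                   mode = c("monte_carlo", "exhaustive")) {
  mode <- match.arg(mode)
  if (!"host_species" %in% colnames(meta)) {
    stop("metadata has no host_species column")
  }
  hm <- meta[meta$sample_type %in% c("host", "other_host"), , drop = FALSE]
  hm <- hm[hm$sample_id %in% rownames(x), , drop = FALSE]
  if (!focal_host %in% hm$host_species) {
    stop("focal host '", focal_host, "' absent from metadata")
  }
  if (length(unique(hm$host_species)) < 2L) {
    stop("need at least one other host species")
  }
  ra <- relative_abundance(x[hm$sample_id, , drop = FALSE])
  indval(ra, hm$host_species, target = focal_host, n_perm = n_perm,
         seed = seed, mode = mode)
}

#' Monthly frequency and abundance profile of selected ASVs
#'
#' Groups host samples by calendar month (across years) and reports, per ASV
#' and month, the presence frequency and mean per-sample relative abundance.
#' Months with no host samples are omitted, not zero-filled.
#'
#' @param x Samples x ASVs count matrix.
#' @param meta Metadata with a parsed `date` column.
#' @param asv_ids ASVs to profile; default all.
#' @param target_type Sample type to profile (default `"host"`).
#' @return Long data.frame: `asv_id`, `month` (1-12), `month_label`,
#'   `n_samples`, `frequency`, `mean_rel_abund`.
#' @export
seasonal_profile <- function(x, meta, asv_ids = NULL, target_type = "host") {
  if (!"date" %in% colnames(meta)) stop("metadata has no date column")
  hm <- meta[meta$sample_type == target_type &
               meta$sample_id %in% rownames(x), , drop = FALSE]
  hm <- hm[!is.na(hm$date), , drop = FALSE]
  if (nrow(hm) == 0L) stop("no dated samples of type '", target_type, "'")
  if (is.null(asv_ids)) asv_ids <- colnames(x)
  stopifnot(all(asv_ids %in% colnames(x)))
  ra <- relative_abundance(x[hm$sample_id, , drop = FALSE])[, asv_ids,
                                                            drop = FALSE]
  pres <- x[hm$sample_id, asv_ids, drop = FALSE] > 0
  mon <- as.integer(format(hm$date, "%m"))
  out <- lapply(sort(unique(mon)), function(m) {
    sel <- mon == m
    data.frame(
      asv_id = asv_ids,
      month = m,
      month_label = month.abb[m],
      n_samples = sum(sel),
      frequency = unname(colSums(pres[sel, , drop = FALSE]) / sum(sel)),
      mean_rel_abund = unname(colMeans(ra[sel, , drop = FALSE])),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, out)
}
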