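# End-to-end orchestration: read, filter, identify cores, summarize,
# write result tables and a run manifest.

#' Assemble and validate a pipeline configuration
#'
#' Checks that the input files exist and the parameters are coherent before
#' any computation starts. Every parameter of the downstream stages is
#' carried in the returned object and recorded in the run manifest.
#'
#' @param counts_path Path to the count table (TSV/CSV/BIOM).
#' @param metadata_path Path to the metadata TSV.
#' @param out_dir Output directory (created if absent).
#' @param orientation Count-table layout on disk; see [read_count_table()].
#' @param type_map Optional sample-type translation; see [read_metadata()].
#' @param min_count_per_cell,min_total_share,min_prevalence,combine_mode
#'   Filtering parameters; see [zero_low_cells()] and [filter_asvs()].
#' @param rarefaction_depth Depth for the beta-diversity branch (default
#'   1500); set `NA` to skip rarefaction/PERMANOVA.
#' @param freq_threshold,indval_threshold,alpha,min_events Core parameters;
#'   see [core_microbiome()].
#' @param n_perm Permutations for all permutation tests.
#' @param seed Master seed (mandatory; drives rarefaction and every
#'   permutation test).
#' @param focal_host Host species label used for host-range classification
#'   when other host species are present.
#' @return List of class `"run_config"`.
#' @export
run_config <- function(counts_path, metadata_path, out_dir,
                       orientation = "asvs_as_rows", type_map = NULL,
                       min_count_per_cell = 5L, min_total_share = 0.001,
                       min_prevalence = 5L, combine_mode = "any",
                       rarefaction_depth = 1500L, freq_threshold = 0.5,
                       indval_threshold = 0.7, alpha = 0.05,
                       min_events = 7L, n_perm = 999L, seed,
                       focal_host = "focal_host") {
  if (missing(seed) || is.null(seed)) stop("a master seed is mandatory")
  if (!file.exists(counts_path)) {
    stop("counts file does not exist: ", counts_path)
  }
  if (!file.exists(metadata_path)) {
    stop("metadata file does not exist: ", metadata_path)
  }
  cfg <- list(counts_path = counts_path, metadata_path = metadata_path,
              out_dir = out_dir, orientation = orientation,
              type_map = type_map, min_count_per_cell = min_count_per_cell,
              min_total_share = min_total_share,
              min_prevalence = min_prevalence, combine_mode = combine_mode,
              rarefaction_depth = rarefaction_depth,
              freq_threshold = freq_threshold,
              indval_threshold = indval_threshold, alpha = alpha,
              min_events = min_events, n_perm = as.integer(n_perm),
              seed = as.integer(seed), focal_host = focal_host)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full core-identification pipeline
#'
#' Reads and aligns the inputs, applies the cell-zeroing and rare-ASV
#' filters, identifies core ASVs by all three definitions, computes overall
#' specificity, seasonal profiles (when dates are present) and host-range
#' classification (when other host species are present), rarefies and runs a
#' Bray-Curtis PERMANOVA of sample type, and writes each result as TSV into
#' `out_dir` along with a manifest of parameters, input checksums and
#' package version. Reruns with the same configuration are byte-identical.
#'
#' @param config A [run_config()] object.
#' @param overwrite Allow writing into a directory that already holds
#'   results from a previous run? Default FALSE (write-once).
#' @return Invisibly, a list with the `core_fit`, the PERMANOVA result (or
#'   NULL), and the paths written.
#' @export
run_pipeline <- function(config, overwrite = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest_path <- file.path(config$out_dir, "manifest.txt")
  if (!overwrite && file.exists(manifest_path)) {
    stop("output directory already contains a run (", manifest_path,
         "); use overwrite = TRUE")
  }
  paths <- character(0)
  emit <- function(df, name) {
    p <- file.path(config$out_dir, name)
    write_result_tsv(df, p)
    paths[[name]] <<- p
  }

  counts <- read_count_table(config$counts_path, config$orientation)
  meta <- read_metadata(config$metadata_path, config$type_map)
  al <- align_samples(counts, meta, policy = "intersect")

  zeroed <- zero_low_cells(al$counts, config$min_count_per_cell)
  filt <- filter_asvs(zeroed, config$min_total_share,
                      config$min_prevalence, config$combine_mode)
  x <- filt$counts
  emit(filt$removed, "removal_log.tsv")
  write_count_table(x, file.path(config$out_dir, "filtered_counts.tsv"))
  paths[["filtered_counts.tsv"]] <- file.path(config$out_dir,
                                              "filtered_counts.tsv")

  has_events <- "sampling_event" %in% colnames(al$metadata) &&
    all(nzchar(al$metadata$sampling_event))
  fit <- core_microbiome(
    x, al$metadata,
    freq_threshold = config$freq_threshold,
    indval_threshold = config$indval_threshold, alpha = config$alpha,
    min_events = config$min_events, n_perm = config$n_perm,
    seed = config$seed, run_twostep = has_events
  )
  emit(fit$report, "core_report.tsv")
  iv <- as.data.frame(fit$indval)
  iv$target_group <- attr(fit$indval, "target")
  gs <- attr(fit$indval, "group_sizes")
  iv$n_target_samples <- as.integer(gs[[attr(fit$indval, "target")]])
  iv$n_env_samples <- sum(gs) - iv$n_target_samples
  emit(iv, "indval_whole.tsv")
  if (ncol(fit$event_indicators) > 0L) {
    ei <- data.frame(asv_id = rownames(fit$event_indicators),
                     fit$event_indicators * 1L, check.names = FALSE,
                     stringsAsFactors = FALSE)
    emit(ei, "event_indicators.tsv")
  }

  spec_tab <- overall_specificity(x, al$metadata)
  emit(spec_tab, "specificity.tsv")

  if ("date" %in% colnames(al$metadata) &&
      any(!is.na(al$metadata$date[al$metadata$sample_type == "host"]))) {
    core_ids <- fit$report$asv_id[fit$report$met_any]
    if (length(core_ids) > 0L) {
      emit(seasonal_profile(x, al$metadata, core_ids), "seasonal.tsv")
    }
  }

  hs <- al$metadata$host_species[al$metadata$sample_type %in%
                                   c("host", "other_host")]
  if (length(unique(hs[!is.na(hs)])) >= 2L) {
    hr <- host_range(x, al$metadata, focal_host = config$focal_host)
    emit(hr$classification, "hostrange.tsv")
  }

  pmv <- NULL
  if (!is.na(config$rarefaction_depth)) {
    rar <- rarefy(x, depth = config$rarefaction_depth,
                  seed = config$seed, drop_shallow = TRUE)
    if (nrow(rar) >= 4L) {
      m2 <- al$metadata[match(rownames(rar), al$metadata$sample_id), ,
                        drop = FALSE]
      g <- m2$sample_type
      if (length(unique(g)) >= 2L && all(table(g) >= 2L)) {
        d <- bray_curtis(relative_abundance(rar))
        pmv <- permanova(d, g, n_perm = config$n_perm, seed = config$seed)
        emit(data.frame(pseudo_F = pmv$pseudo_F, R2 = pmv$R2,
                        p_value = pmv$p_value, df_between = pmv$df_between,
                        df_within = pmv$df_within,
                        n_permutations = pmv$n_permutations),
             "permanova.tsv")
      }
    }
  }

  cfg_flat <- config[!vapply(config, is.null, logical(1))]
  cfg_flat$type_map <- NULL
  cfg_flat$out_dir <- NULL # run-location, not a parameter of the analysis
  manifest <- c(
    paste0("epicore_version\t", as.character(packageVersion("epicore"))),
    paste0("input_counts_md5\t", unname(tools::md5sum(config$counts_path))),
    paste0("input_metadata_md5\t",
           unname(tools::md5sum(config$metadata_path))),
    vapply(names(cfg_flat), function(k) {
      paste0(k, "\t", paste(format(cfg_flat[[k]]), collapse = ","))
    }, character(1))
  )
  writeLines(manifest, manifest_path)
  paths[["manifest.txt"]] <- manifest_path

  invisible(list(fit = fit, permanova = pmv, paths = paths))
}
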