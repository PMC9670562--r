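#' Zero out low-count cells
#'
#' Sets every cell strictly below `min_count` reads to zero, a guard against
#' index/barcode switching that otherwise scatters a handful of spurious reads
#' across samples. Cells at or above the threshold are untouched, so the
#' operation is idempotent and never changes the table's dimensions.
#'
#' @param x Samples x ASVs count matrix.
#' @param min_count Minimum reads for a cell to survive (default 5).
#' @return The filtered count matrix.
#' @export
zero_low_cells <- function(x, min_count = 5L) {
  x <- as_count_table(x)
  stopifnot(min_count >= 0)
  x[x < min_count] <- 0L
  x
}

#' Discard rare ASVs by overall share and prevalence
#'
#' Removes ASVs that are too rare across the whole table. An ASV fails the
#' abundance criterion when its total reads are below `min_total_share` of the
#' grand total, and the prevalence criterion when it occurs (count > 0) in
#' fewer than `min_prevalence` samples. Under `combine = "any"` (the default,
#' the literal reading of an "or" filter) failing either criterion removes the
#' ASV; under `"all"` both must fail.
#'
#' @param x Samples x ASVs count matrix, typically after [zero_low_cells()].
#' @param min_total_share Minimum fraction of the grand total (default 0.001,
#'   i.e. 0.1 percent).
#' @param min_prevalence Minimum number of samples with a non-zero count
#'   (default 5).
#' @param combine `"any"` or `"all"`; how the two criteria are combined.
#' @return List with `counts` (the retained table) and `removed`, a data.frame
#'   logging each removed ASV with its total reads, share of the grand total,
#'   prevalence, and which criterion fired (`abundance`, `prevalence`, `both`).
#' @export
filter_asvs <- function(x, min_total_share = 0.001, min_prevalence = 5L,
                        combine = c("any", "all")) {
  combine <- match.arg(combine)
  x <- as_count_table(x)
  stopifnot(min_total_share >= 0, min_total_share < 1, min_prevalence >= 0)
  if (ncol(x) == 0L) stop("count table has no ASVs")
  totals <- colSums(x)
  grand <- sum(totals)
  share <- if (grand > 0) totals / grand else rep(0, length(totals))
  prevalence <- colSums(x > 0)
  fail_ab <- share < min_total_share
  fail_prev <- prevalence < min_prevalence
  drop <- if (combine == "any") fail_ab | fail_prev else fail_ab & fail_prev
  criterion <- ifelse(fail_ab & fail_prev, "both",
                      ifelse(fail_ab, "abundance", "prevalence"))
  removed <- data.frame(
    asv_id = colnames(x)[drop],
    total_reads = unname(totals[drop]),
    share_of_total = unname(share[drop]),
    prevalence = unname(prevalence[drop]),
    criterion = unname(criterion[drop]),
    stringsAsFactors = FALSE
  )
  kept <- x[, !drop, drop = FALSE]
  if (ncol(kept) == 0L) warning("all ASVs removed by filtering")
  list(counts = kept, removed = removed)
}

#' Per-sample relative abundances
#'
#' Divides each sample's counts by its total. Samples with zero total reads
#' are returned as all-zero rows and flagged in the `"zero_rows"` attribute
#' rather than producing NaN.
#'
#' @param x Samples x ASVs matrix of counts.
#' @return Numeric matrix of the same shape; rows with non-zero input sum to 1.
#' @export
relative_abundance <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  rs <- rowSums(x)
  out <- x / ifelse(rs > 0, rs, 1)
  storage.mode(out) <- "double"
  attr(out, "zero_rows") <- rownames(x)[rs == 0]
  out
}

#' Rarefy samples to a fixed depth
#'
#' Subsamples each sample's reads uniformly at random without replacement to
#' exactly `depth` reads (via [vegan::rrarefy()]), the standard equalisation
#' of sequencing effort before beta-diversity analysis. Samples whose total is
#' below `depth` are dropped when `drop_shallow` is TRUE (default), otherwise
#' kept unrarefied with a warning.
#'
#' @param x Samples x ASVs count matrix.
#' @param depth Target reads per sample (default 1500).
#' @param seed Integer seed; the same seed gives a bit-identical result. The
#'   caller's RNG state is restored on exit.
#' @param drop_shallow Drop samples with fewer than `depth` reads?
#' @return Rarefied count matrix; every rarefied row sums to exactly `depth`.
#' @export
rarefy <- function(x, depth = 1500L, seed = NULL, drop_shallow = TRUE) {
  x <- as_count_table(x)
  stopifnot(depth >= 1)
  totals <- rowSums(x)
  shallow <- totals < depth
  if (any(shallow)) {
    if (drop_shallow) {
      x <- x[!shallow, , drop = FALSE]
      totals <- totals[!shallow]
    } else {
      warning(sum(shallow), " sample(s) below depth ", depth,
              " kept unrarefied")
    }
  }
  if (nrow(x) == 0L) return(x)
  if (!is.null(seed)) {
    if (exists(".Random.seed", envir = globalenv())) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
  }
  deep <- rowSums(x) >= depth
  out <- x
  if (any(deep)) {
    # rrarefy guesses non-count input whenever the smallest non-zero cell
    # exceeds 1; counts are already validated here, so muffle that warning
    out[deep, ] <- withCallingHandlers(
      vegan::rrarefy(x[deep, , drop = FALSE], depth),
      warning = function(w) {
        if (grepl("observed counts", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
  }
  storage.mode(out) <- "integer"
  out
}
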