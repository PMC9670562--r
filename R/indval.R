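# Indicator-value (IndVal) analysis.
#
# The group-equalized indicator value of a taxon for a target group combines
# specificity A (the target group's mean abundance divided by the sum of
# within-group mean abundances over all groups, so unequal group sizes do not
# bias A) with fidelity B (the fraction of target-group samples where the
# taxon occurs). The default statistic is sqrt(A * B); the plain product
# A * B is available behind `variant = "product"`. Significance is assessed
# by permuting sample group labels, one-sided for enrichment in the target.

# all distinct arrangements of the multiset of group labels, as a matrix of
# level codes (one row per arrangement); first row is the identity
.multiset_arrangements <- function(g, cap = 100000L) {
  g <- as.factor(g)
  counts <- tabulate(g, nbins = nlevels(g))
  n_arr <- round(exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))))
  if (n_arr > cap) {
    stop("number of distinct relabelings (", n_arr,
         ") exceeds the exhaustive cap (", cap, ")")
  }
  rec <- function(cnt) {
    n <- sum(cnt)
    if (n == 0L) return(matrix(integer(0), nrow = 1L, ncol = 0L))
    parts <- list()
    for (k in seq_along(cnt)) {
      if (cnt[k] > 0L) {
        c2 <- cnt
        c2[k] <- c2[k] - 1L
        sub <- rec(c2)
        parts[[length(parts) + 1L]] <- cbind(k, sub, deparse.level = 0L)
      }
    }
    do.call(rbind, parts)
  }
  arr <- rec(counts)
  # put the identity labeling first
  id_code <- as.integer(g)
  hit <- which(apply(arr, 1L, function(r) all(r == id_code)))[1L]
  arr[c(hit, setdiff(seq_len(nrow(arr)), hit)), , drop = FALSE]
}

# vectorized components for all columns of x under grouping g
.indval_components <- function(x, g, target, variant) {
  n_g <- tabulate(g, nbins = nlevels(g))
  gs <- rowsum(x, g)
  gm <- gs / n_g[match(rownames(gs), levels(g))]
  denom <- colSums(gm)
  A <- gm[target, ] / ifelse(denom > 0, denom, 1)
  A[denom == 0] <- 0
  tgt <- g == target
  B <- colSums(x[tgt, , drop = FALSE] > 0) / sum(tgt)
  stat <- if (variant == "sqrt") sqrt(A * B) else A * B
  list(A = unname(A), B = unname(B), stat = unname(stat))
}

#' Indicator-value statistic for one taxon
#'
#' Computes specificity `A`, fidelity `B` and the indicator value for a single
#' abundance vector, without any permutation test. See [indval()] for the
#' definitions.
#'
#' @param abund Non-negative abundance per sample (counts or relative
#'   abundances; the statistic is scale-invariant per taxon).
#' @param groups Group label per sample; if named, aligned to `names(abund)`.
#' @param target The target group label.
#' @param variant `"sqrt"` (group-equalized IndVal, default) or `"product"`.
#' @return List with elements `A`, `B`, `stat`.
#' @export
indval_stat <- function(abund, groups, target, variant = c("sqrt", "product")) {
  variant <- match.arg(variant)
  x <- matrix(abund, ncol = 1L, dimnames = list(names(abund), "taxon"))
  if (is.null(rownames(x))) rownames(x) <- paste0("s", seq_along(abund))
  g <- .check_design(x, groups, target)
  comp <- .indval_components(x, g, target, variant)
  lapply(comp, function(v) v[[1L]])
}

.check_design <- function(x, groups, target) {
  if (!is.null(names(groups))) {
    missing_ab <- setdiff(names(groups), rownames(x))
    if (length(missing_ab) > 0L) {
      stop("sample(s) in the design have no abundances: ",
           paste(missing_ab, collapse = ", "))
    }
    groups <- groups[rownames(x)]
    if (anyNA(groups)) {
      stop("sample(s) in the table have no group label: ",
           paste(rownames(x)[is.na(groups)], collapse = ", "))
    }
  }
  if (length(groups) != nrow(x)) {
    stop("groups must have one label per sample (",
         length(groups), " labels for ", nrow(x), " samples)")
  }
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (!target %in% levels(g)) {
    stop("target group '", target, "' not present in the design")
  }
  g
}

#' Indicator-value analysis with a permutation test
#'
#' For every ASV (column) computes the group-equalized indicator value of the
#' `target` group — specificity `A` = within-target mean abundance over the
#' sum of within-group means, fidelity `B` = occurrence fraction in target
#' samples, statistic `sqrt(A * B)` — and a one-sided permutation p-value for
#' enrichment in the target group. Monte-Carlo p-values use the add-one
#' convention, `p = (b + 1) / (n_perm + 1)`, where `b` counts permuted
#' statistics at or above the observed one (ties count, conservatively).
#' Exhaustive mode enumerates every distinct relabeling of the group
#' multiset and reports the exact fraction attaining the observed statistic,
#' identity included.
#'
#' @param x Samples x ASVs matrix (relative abundances or counts).
#' @param groups Group label per sample; if named, matched to `rownames(x)`.
#' @param target Target group label (the host group, in a core analysis).
#' @param n_perm Number of Monte-Carlo permutations (default 999).
#' @param seed Optional integer seed; same seed, same p-values. RNG state is
#'   restored on exit.
#' @param mode `"monte_carlo"` (default) or `"exhaustive"`.
#' @param variant `"sqrt"` or `"product"`; see [indval_stat()].
#' @param pool_env Merge all non-target groups into a single environmental
#'   group before computing? Default FALSE (groups kept separate).
#' @param max_exhaustive Cap on the number of relabelings enumerated.
#' @return A data.frame of class `"indval_result"` with columns `asv_id`,
#'   `A`, `B`, `stat`, `p_value`, `n_perm`; the design is carried in
#'   attributes `target`, `group_sizes`, `mode`, `variant`.
#' @examples
#' x <- matrix(c(8, 4, 0, 2, 0), ncol = 1,
#'             dimnames = list(paste0("s", 1:5), "ASV1"))
#' g <- c("host", "host", "host", "env", "env")
#' indval(x, g, target = "host", n_perm = 99, seed = 1)
#' @export
indval <- function(x, groups, target, n_perm = 999L, seed = NULL,
                   mode = c("monte_carlo", "exhaustive"),
                   variant = c("sqrt", "product"), pool_env = FALSE,
                   max_exhaustive = 100000L) {
  mode <- match.arg(mode)
  variant <- match.arg(variant)
  if (!is.matrix(x)) x <- as.matrix(x)
  g <- .check_design(x, groups, target)
  if (pool_env) {
    lab <- ifelse(as.character(g) == target, target, "env")
    g <- factor(lab, levels = c(target, "env"))
  }
  obs <- .indval_components(x, g, target, variant)
  tol <- 1e-12

  if (mode == "exhaustive") {
    arr <- .multiset_arrangements(g, cap = max_exhaustive)
    n_arr <- nrow(arr)
    ge <- integer(ncol(x))
    for (i in seq_len(n_arr)) {
      gi <- factor(levels(g)[arr[i, ]], levels = levels(g))
      st <- .indval_components(x, gi, target, variant)$stat
      ge <- ge + (st >= obs$stat - tol)
    }
    p <- ge / n_arr
    n_used <- n_arr
  } else {
    stopifnot(n_perm >= 1)
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(seed)
    }
    b <- integer(ncol(x))
    n <- nrow(x)
    for (i in seq_len(n_perm)) {
      gi <- g[sample.int(n)]
      st <- .indval_components(x, gi, target, variant)$stat
      b <- b + (st >= obs$stat - tol)
    }
    p <- (b + 1) / (n_perm + 1)
    n_used <- n_perm
  }

  res <- data.frame(
    asv_id = colnames(x),
    A = obs$A, B = obs$B, stat = obs$stat,
    p_value = p, n_perm = n_used,
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(res, "target") <- target
  attr(res, "group_sizes") <- table(g)
  attr(res, "mode") <- mode
  attr(res, "variant") <- variant
  class(res) <- c("indval_result", "data.frame")
  res
}

#' @export
print.indval_result <- function(x, n = 10L, ...) {
  gs <- attr(x, "group_sizes")
  cat("Indicator-value analysis (", attr(x, "variant"), " variant, ",
      attr(x, "mode"), ")\n", sep = "")
  cat("Target group:", attr(x, "target"), "| group sizes:",
      paste(names(gs), gs, sep = "=", collapse = ", "), "\n")
  ord <- order(-x$stat)
  cat("Top taxa by indicator value:\n")
  print.data.frame(head(as.data.frame(x)[ord, ], n), digits = 4,
                   row.names = FALSE)
  invisible(x)
}
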