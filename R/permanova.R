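# Community-level context: Bray-Curtis dissimilarity and a one-factor
# distance-based PERMANOVA.

#' Bray-Curtis dissimilarity matrix
#'
#' Pairwise Bray-Curtis dissimilarity, `sum |x_i - y_i| / sum (x_i + y_i)`,
#' computed with [vegan::vegdist()]. A pair of all-zero samples has an
#' undefined ratio; it is set to 0 (identical emptiness) with a warning.
#'
#' @param x Samples x ASVs abundance matrix (counts or relative abundances;
#'   typically the rarefied table).
#' @return A `dist` object with sample labels.
#' @export
bray_curtis <- function(x) {
  if (!is.matrix(x)) x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 samples")
  if (any(x < 0)) stop("abundances must be non-negative")
  zero <- rowSums(x) == 0
  d <- suppressWarnings(vegan::vegdist(x, method = "bray"))
  if (any(zero)) {
    warning(sum(zero), " all-zero sample(s); their mutual dissimilarity set to 0")
    m <- as.matrix(d)
    m[zero, zero] <- 0
    m[zero, !zero] <- 1
    m[!zero, zero] <- 1
    diag(m) <- 0
    d <- stats::as.dist(m)
  }
  d
}

# sums of squares decomposition of a distance matrix under a grouping
.permanova_ss <- function(dm2, g) {
  # dm2: full squared distance matrix; g: factor
  n <- nrow(dm2)
  ss_total <- sum(dm2[upper.tri(dm2)]) / n
  ss_within <- 0
  for (lev in levels(g)) {
    idx <- which(g == lev)
    if (length(idx) > 1L) {
      sub <- dm2[idx, idx, drop = FALSE]
      ss_within <- ss_within + sum(sub[upper.tri(sub)]) / length(idx)
    }
  }
  c(total = ss_total, within = ss_within, between = ss_total - ss_within)
}

.permanova_F <- function(dm2, g, df_b, df_w) {
  ss <- .permanova_ss(dm2, g)
  (ss[["between"]] / df_b) / (ss[["within"]] / df_w)
}

#' One-factor PERMANOVA on a distance matrix
#'
#' Distance-based permutational analysis of variance for a single grouping
#' factor. The total sum of squares is `sum_{i<j} d_ij^2 / N`, the within-
#' group sum of squares adds the analogous term per group, and the
#' pseudo-F statistic is `(SS_between / (g - 1)) / (SS_within / (N - g))`
#' with `R^2 = SS_between / SS_total`. Significance comes from freely
#' permuting the sample labels (Monte-Carlo, add-one convention) or, for
#' tiny designs, from exhaustive enumeration of all distinct relabelings
#' (identity included).
#'
#' With Euclidean distances on 1-D data the pseudo-F equals the classical
#' one-way ANOVA F, a useful correctness check.
#'
#' @param d A `dist` object or symmetric dissimilarity matrix.
#' @param groups Group label per sample; if named, matched to the labels of
#'   `d`. Every group needs at least 2 samples.
#' @param n_perm Number of Monte-Carlo permutations (default 999; the
#'   published convention for final results is 9999).
#' @param seed Optional integer seed; RNG state restored on exit.
#' @param mode `"monte_carlo"` or `"exhaustive"`.
#' @param max_exhaustive Cap on enumerated relabelings.
#' @return Object of class `"permanova"`: list with `pseudo_F`, `R2`,
#'   `p_value`, `df_between`, `df_within`, `n_permutations`, `ss`.
#' @examples
#' d <- dist(c(0, 2, 6, 8))
#' permanova(d, c("a", "a", "b", "b"), mode = "exhaustive")
#' @export
permanova <- function(d, groups, n_perm = 999L, seed = NULL,
                      mode = c("monte_carlo", "exhaustive"),
                      max_exhaustive = 100000L) {
  mode <- match.arg(mode)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m) || any(abs(m - t(m)) > 1e-10)) {
    stop("d must be a dist object or symmetric matrix")
  }
  if (!is.null(names(groups)) && !is.null(rownames(m))) {
    groups <- groups[rownames(m)]
  }
  if (length(groups) != nrow(m)) {
    stop("groups must have one label per sample")
  }
  g <- droplevels(as.factor(groups))
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  if (any(tabulate(g) < 2L)) {
    stop("every group needs at least 2 samples (within-group df)")
  }
  n <- nrow(m)
  df_b <- nlevels(g) - 1L
  df_w <- n - nlevels(g)
  dm2 <- m^2
  ss <- .permanova_ss(dm2, g)
  F_obs <- (ss[["between"]] / df_b) / (ss[["within"]] / df_w)
  tol <- 1e-12

  if (mode == "exhaustive") {
    arr <- .multiset_arrangements(g, cap = max_exhaustive)
    Fs <- vapply(seq_len(nrow(arr)), function(i) {
      .permanova_F(dm2, factor(levels(g)[arr[i, ]], levels = levels(g)),
                   df_b, df_w)
    }, numeric(1))
    p <- mean(Fs >= F_obs - tol)
    n_used <- nrow(arr)
  } else {
    stopifnot(n_perm >= 1)
    if (!is.null(seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
      }
      set.seed(seed)
    }
    b <- 0L
    for (i in seq_len(n_perm)) {
      Fi <- .permanova_F(dm2, g[sample.int(n)], df_b, df_w)
      b <- b + (Fi >= F_obs - tol)
    }
    p <- (b + 1) / (n_perm + 1)
    n_used <- n_perm
  }

  out <- list(
    pseudo_F = unname(F_obs),
    R2 = unname(ss[["between"]] / ss[["total"]]),
    p_value = p,
    df_between = df_b,
    df_within = df_w,
    n_permutations = n_used,
    ss = ss,
    groups = table(g),
    mode = mode
  )
  class(out) <- "permanova"
  out
}

#' @export
print.permanova <- function(x, ...) {
  cat("One-factor PERMANOVA (", x$mode, ", ", x$n_permutations,
      if (x$mode == "exhaustive") " relabelings" else " permutations",
      ")\n", sep = "")
  cat(sprintf("  Pseudo-F(%d:%d) = %.4g, R2 = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$pseudo_F, x$R2, x$p_value))
  cat("  Groups:", paste(names(x$groups), x$groups, sep = "=",
                         collapse = ", "), "\n")
  invisible(x)
}
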