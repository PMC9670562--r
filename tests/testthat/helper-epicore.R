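# Test helpers: fixture builders and independent oracles. The oracles are
# deliberately naive re-derivations (loops, enumeration, classical ANOVA)
# kept separate from the package's code paths.

# small count matrix with identifiers
toy_counts <- function(m, samples = NULL, asvs = NULL) {
  m <- as.matrix(m)
  rownames(m) <- samples %||% rownames(m) %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- asvs %||% colnames(m) %||% paste0("ASV", seq_len(ncol(m)))
  storage.mode(m) <- "integer"
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

toy_metadata <- function(ids, types, site = "siteA", event = "E1",
                         date = NA, host_species = NA) {
  data.frame(sample_id = ids, sample_type = types, site = site,
             date = as.Date(date), host_species = host_species,
             sampling_event = event, stringsAsFactors = FALSE)
}

# naive per-taxon IndVal components, computed with explicit loops
oracle_indval <- function(abund, groups, target, variant = "sqrt") {
  levs <- unique(groups)
  means <- sapply(levs, function(l) mean(abund[groups == l]))
  A <- if (sum(means) > 0) means[[target]] / sum(means) else 0
  tgt <- abund[groups == target]
  B <- sum(tgt > 0) / length(tgt)
  stat <- if (variant == "sqrt") sqrt(A * B) else A * B
  list(A = unname(A), B = unname(B), stat = unname(stat))
}

# exhaustive permutation p for one taxon, by brute-force enumeration of all
# distinct label assignments (nested position choices, independent of the
# package's enumeration code)
oracle_exhaustive_p_indval <- function(abund, groups, target,
                                       variant = "sqrt") {
  n <- length(abund)
  levs <- sort(unique(groups))
  sizes <- table(factor(groups, levels = levs))
  obs <- oracle_indval(abund, groups, target, variant)$stat
  assignments <- list(list(avail = seq_len(n), lab = character(n)))
  for (l in levs) {
    nxt <- list()
    for (a in assignments) {
      for (pick in utils::combn(length(a$avail), sizes[[l]],
                                simplify = FALSE)) {
        lab <- a$lab
        lab[a$avail[pick]] <- l
        nxt[[length(nxt) + 1L]] <- list(avail = a$avail[-pick], lab = lab)
      }
    }
    assignments <- nxt
  }
  stats <- vapply(assignments, function(a) {
    oracle_indval(abund, a$lab, target, variant)$stat
  }, numeric(1))
  list(p = mean(stats >= obs - 1e-12), n = length(stats))
}

# classical one-way ANOVA F on 1-D data (oracle for Euclidean PERMANOVA)
oracle_anova_F <- function(values, groups) {
  unname(summary(stats::aov(values ~ factor(groups)))[[1]][["F value"]][1])
}

# a random host/rock/seawater community with a few host-skewed taxa
random_host_env_table <- function(n_host = 5, n_rock = 4, n_sea = 3,
                                  n_asvs = 30) {
  n <- n_host + n_rock + n_sea
  m <- matrix(rpois(n * n_asvs, lambda = 8), n, n_asvs)
  skew <- sample(n_asvs, max(2L, n_asvs %/% 5))
  m[seq_len(n_host), skew] <- m[seq_len(n_host), skew] +
    rpois(n_host * length(skew), 40)
  ids <- paste0("s", seq_len(n))
  counts <- toy_counts(m, samples = ids)
  meta <- toy_metadata(ids, c(rep("host", n_host), rep("rock", n_rock),
                              rep("seawater", n_sea)))
  list(counts = counts, metadata = meta)
}
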