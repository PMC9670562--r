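test_that("overall specificity is the focal read share and sample-duplication invariant", {
  m <- rbind(c(45, 0, 10), c(45, 0, 0), c(10, 8, 0), c(0, 2, 0))
  x <- toy_counts(m)
  meta <- toy_metadata(rownames(x), c("host", "host", "rock", "seawater"))
  sp <- overall_specificity(x, meta)
  expect_equal(sp$specificity, c(90 / 100, 0, 1))
  # zero-read ASV undefined
  x2 <- cbind(x, ASV4 = 0L)
  sp2 <- overall_specificity(x2, meta)
  expect_true(is.na(sp2$specificity[4]))
  # duplicating every sample changes nothing (reads ratio, not sample ratio)
  xd <- rbind(x, x)
  rownames(xd) <- c(rownames(x), paste0(rownames(x), "_dup"))
  md <- rbind(meta, transform(meta, sample_id = paste0(sample_id, "_dup")))
  expect_equal(overall_specificity(as_count_table(xd), md)$specificity,
               sp$specificity)
})

hostrange_fixture <- function() {
  # 3 species x 2 samples; totals per sample = 1000
  m <- rbind(
    f1 = c(5, 30, 1, 964), f2 = c(3, 10, 1, 986),     # focal
    u1 = c(0, 25, 1, 974), u2 = c(0, 15, 1, 984),     # ulva-like
    k1 = c(0, 40, 0, 960), k2 = c(0, 20, 2, 978)      # kelp-like
  )
  x <- toy_counts(m, asvs = paste0("ASV", 1:4))
  meta <- toy_metadata(rownames(x),
                       c("host", "host", rep("other_host", 4)),
                       host_species = c("focal", "focal", "ulva", "ulva",
                                        "kelp", "kelp"))
  list(x = x, meta = meta)
}

test_that("host range classifies specialists and generalists at the 0.1% mean threshold", {
  fx <- hostrange_fixture()
  hr <- host_range(fx$x, fx$meta, focal_host = "focal",
                   presence_threshold = 0.001)
  cl <- hr$classification
  # ASV1: mean 0.4% on focal only -> specialist
  expect_equal(cl$n_hosts_present[1], 1)
  expect_true(cl$is_specialist[1])
  expect_false(cl$is_generalist[1])
  # ASV2: ~2% everywhere -> generalist on 3 species
  expect_equal(cl$n_hosts_present[2], 3)
  expect_true(cl$is_generalist[2])
  # ASV3: 0.1% mean on focal/ulva exactly at threshold (inclusive), 0.1% on
  # kelp too: (1+1)/2 per sample of 1000 reads = 0.001
  expect_equal(unname(hr$species_means["ASV3", "focal"]), 0.001)
  expect_true(cl$present_on_focal[3])
  # below-threshold everywhere -> present on 0 hosts
  hr9 <- host_range(fx$x, fx$meta, focal_host = "focal",
                    presence_threshold = 0.0041)
  expect_equal(hr9$classification$n_hosts_present[1], 0)
  expect_error(host_range(fx$x, fx$meta, focal_host = "nope"), "absent")
})

test_that("hosts-present is monotone non-increasing in the presence threshold", {
  fx <- hostrange_fixture()
  thr <- c(0, 0.0005, 0.001, 0.005, 0.02, 0.5)
  n <- sapply(thr, function(t) {
    host_range(fx$x, fx$meta, focal_host = "focal",
               presence_threshold = t)$classification$n_hosts_present
  })
  expect_true(all(apply(n, 1, function(v) all(diff(v) <= 0))))
})

test_that("host-enrichment IndVal behaves like a multi-species design", {
  fx <- hostrange_fixture()
  res <- host_enrichment_indval(fx$x, fx$meta, "focal", n_perm = 99,
                                seed = 1)
  # ASV1 occurs on the focal species only -> A = 1
  expect_equal(res$A[res$asv_id == "ASV1"], 1)
  # uniform taxon -> A = 1 / number of species groups
  xu <- fx$x
  xu[, "ASV4"] <- 500L
  ra_check <- host_enrichment_indval(xu, fx$meta, "focal", n_perm = 9,
                                     seed = 1)
  expect_equal(ra_check$A[ra_check$asv_id == "ASV4"], 1 / 3,
               tolerance = 0.05)
  # A across species sums to 1 for any ASV with reads
  ra <- relative_abundance(fx$x)
  for (asv in colnames(fx$x)) {
    As <- vapply(unique(fx$meta$host_species), function(t) {
      indval_stat(ra[, asv], fx$meta$host_species, t)$A
    }, numeric(1))
    expect_equal(sum(As), 1, tolerance = 1e-12)
  }
})

test_that("host-enrichment exhaustive p matches Monte-Carlo within binomial error", {
  fx <- hostrange_fixture()
  ex <- host_enrichment_indval(fx$x, fx$meta, "focal", mode = "exhaustive")
  mc <- host_enrichment_indval(fx$x, fx$meta, "focal", n_perm = 999,
                               seed = 4)
  for (k in seq_len(nrow(ex))) {
    se <- sqrt(ex$p_value[k] * (1 - ex$p_value[k]) / 999)
    expect_lt(abs(mc$p_value[k] - ex$p_value[k]), 3 * se + 2 / 1000)
  }
})

test_that("seasonal profiles aggregate host samples by calendar month", {
  m <- rbind(j1 = c(20, 0), j2 = c(40, 0), a1 = c(0, 10), r1 = c(5, 5))
  x <- toy_counts(m)
  meta <- toy_metadata(rownames(x),
                       c("host", "host", "host", "rock"),
                       date = c("2018-06-10", "2018-06-20", "2018-08-05",
                                "2018-06-10"))
  # per-sample totals: j1=20, j2=40, a1=10 -> ASV1 rel ab 1, 1, 0
  prof <- seasonal_profile(x, meta)
  jun1 <- prof[prof$month == 6 & prof$asv_id == "ASV1", ]
  expect_equal(jun1$frequency, 1)
  expect_equal(jun1$mean_rel_abund, 1)
  expect_equal(jun1$n_samples, 2)
  expect_false(7 %in% prof$month)   # no July samples -> month omitted
  expect_setequal(unique(prof$month), c(6, 8))
  # arithmetic mean of per-sample relative abundances
  m2 <- rbind(a = c(2, 98), b = c(4, 96))
  x2 <- toy_counts(m2)
  meta2 <- toy_metadata(rownames(x2), c("host", "host"),
                        date = c("2018-06-01", "2018-06-02"))
  p2 <- seasonal_profile(x2, meta2, asv_ids = "ASV1")
  expect_equal(p2$mean_rel_abund, 0.03)
  meta_nodate <- meta[, setdiff(names(meta), "date")]
  expect_error(seasonal_profile(x, meta_nodate), "no date column")
  meta_na <- meta
  meta_na$date <- as.Date(NA)
  expect_error(seasonal_profile(x, meta_na), "no dated samples")
})
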