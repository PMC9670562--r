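test_that("frequency core counts host occupancy with an inclusive threshold", {
  m <- rbind(c(5, 9, 0, 6), c(8, 0, 0, 6), c(7, 0, 0, 6),
             c(6, 9, 0, 0), c(5, 0, 0, 0),
             c(1, 1, 1, 1)) # a rock sample, must be ignored
  x <- toy_counts(m)
  meta <- toy_metadata(rownames(x), c(rep("host", 5), "rock"))
  fc <- frequency_core(x, meta, freq_threshold = 0.5)
  expect_equal(fc$frequency, c(1, 0.4, 0, 0.6))
  expect_equal(fc$is_freq_core, c(TRUE, FALSE, FALSE, TRUE))
  # presence in exactly half of the host samples is core (inclusive)
  m2 <- rbind(c(4, 0), c(4, 0), c(0, 1), c(0, 1))
  x2 <- toy_counts(m2)
  meta2 <- toy_metadata(rownames(x2), rep("host", 4))
  fc2 <- frequency_core(x2, meta2, freq_threshold = 0.5)
  expect_true(all(fc2$is_freq_core))
  expect_error(frequency_core(x, toy_metadata(rownames(x), rep("rock", 6))),
               "no samples of type")
})

test_that("IndVal core flags require both the value threshold and significance", {
  set.seed(14)
  tab <- random_host_env_table()
  res <- indval_core(tab$counts, tab$metadata, n_perm = 99, seed = 1)
  expect_identical(res$is_indval_core,
                   res$stat >= 0.7 & res$p_value <= 0.05)
})

test_that("IndVal core at 0.7 implies host frequency of at least 0.49", {
  set.seed(77)
  for (i in 1:20) {
    tab <- random_host_env_table(n_host = sample(4:7, 1),
                                 n_rock = sample(2:4, 1),
                                 n_sea = sample(2:4, 1))
    iv <- indval_core(tab$counts, tab$metadata, n_perm = 49, seed = i)
    fc <- frequency_core(tab$counts, tab$metadata, freq_threshold = 0.49)
    hit <- iv$asv_id[iv$is_indval_core]
    expect_true(all(fc$frequency[match(hit, fc$asv_id)] >= 0.49))
    expect_true(all(hit %in% fc$asv_id[fc$is_freq_core]))
  }
})

# three sampling events; ASV1 a clean host indicator in events 1 and 2 only,
# ASV2 never an indicator, ASV3 an environment indicator, ASV4 filler that
# keeps every sample at 100 reads (so relative abundances are comparable)
twostep_toy <- function() {
  build_event <- function(ev, indicator) {
    ids <- paste0(ev, "_", c("h1", "h2", "h3", "h4", "r1", "r2", "w1", "w2"))
    a1 <- if (indicator) c(50L, 60L, 55L, 45L, 0L, 0L, 0L, 0L)
          else rep(10L, 8)
    a3 <- c(0L, 0L, 0L, 0L, 30L, 30L, 30L, 30L)
    a2 <- rep(10L, 8)
    m <- cbind(ASV1 = a1, ASV2 = a2, ASV3 = a3,
               ASV4 = 100L - a1 - a2 - a3)
    rownames(m) <- ids
    meta <- toy_metadata(ids, c(rep("host", 4), "rock", "rock",
                                "seawater", "seawater"), event = ev)
    list(m = m, meta = meta)
  }
  evs <- list(build_event("E1", TRUE), build_event("E2", TRUE),
              build_event("E3", FALSE))
  list(counts = as_count_table(do.call(rbind, lapply(evs, `[[`, "m"))),
       metadata = do.call(rbind, lapply(evs, `[[`, "meta")))
}

test_that("two-step tally counts per-event indicators and applies min_events", {
  toy <- twostep_toy()
  two <- twostep_core(toy$counts, toy$metadata, min_events = 2,
                      n_perm = 199, seed = 7)
  expect_equal(unname(two$event_tally["ASV1"]), 2)
  expect_equal(unname(two$event_tally["ASV2"]), 0)
  expect_true(two$is_twostep_core[["ASV1"]])
  expect_false(two$is_twostep_core[["ASV2"]])
  expect_false(two$is_twostep_core[["ASV3"]])
  # ASV indicator in 0 events is never core even at min_events 1
  two1 <- twostep_core(toy$counts, toy$metadata, min_events = 1,
                       n_perm = 199, seed = 7)
  expect_false(two1$is_twostep_core[["ASV2"]])
})

test_that("two-step tally is invariant to sample and event order", {
  toy <- twostep_toy()
  two <- twostep_core(toy$counts, toy$metadata, min_events = 2,
                      n_perm = 99, seed = 3)
  perm <- sample(nrow(toy$counts))
  two_shuf <- twostep_core(toy$counts[perm, ],
                           toy$metadata[perm, ], min_events = 2,
                           n_perm = 99, seed = 3)
  expect_equal(two$event_tally, two_shuf$event_tally)
  expect_equal(two$event_indicators, two_shuf$event_indicators)
})

test_that("lowering min_events can only grow the two-step core set", {
  toy <- twostep_toy()
  sets <- lapply(1:3, function(k) {
    two <- twostep_core(toy$counts, toy$metadata, min_events = k,
                        n_perm = 99, seed = 5)
    names(which(two$is_twostep_core))
  })
  expect_true(all(sets[[3]] %in% sets[[2]]))
  expect_true(all(sets[[2]] %in% sets[[1]]))
})

test_that("events without an environmental comparison are excluded", {
  toy <- twostep_toy()
  # strip environmental samples from E3
  drop <- toy$metadata$sampling_event == "E3" &
    toy$metadata$sample_type != "host"
  meta <- toy$metadata[!drop, ]
  counts <- toy$counts[meta$sample_id, ]
  expect_message(
    two <- twostep_core(counts, meta, min_events = 2, n_perm = 99, seed = 1),
    "E3")
  expect_equal(two$events_used, c("E1", "E2"))
  expect_equal(two$events_excluded, "E3")
  # no usable events at all -> design error
  host_only <- toy$metadata[toy$metadata$sample_type == "host", ]
  expect_error(twostep_core(toy$counts[host_only$sample_id, ], host_only,
                            min_events = 1),
               "host and environmental")
})

test_that("the comparison ledger combines the three definitions", {
  toy <- twostep_toy()
  fit <- core_microbiome(toy$counts, toy$metadata, min_events = 2,
                         n_perm = 199, seed = 7)
  r <- fit$report
  a1 <- r[r$asv_id == "ASV1", ]
  expect_true(a1$is_freq_core && a1$is_indval_core && a1$is_twostep_core)
  expect_true(a1$met_all && a1$met_any)
  a3 <- r[r$asv_id == "ASV3", ]
  expect_false(a3$met_any)
  # sorted by event tally then frequency, descending
  expect_true(all(diff(r$event_tally) <= 0))
  # overall specificity: ASV3 is environment-only
  expect_equal(a3$overall_specificity, 0)
  expect_equal(a1$overall_specificity,
               sum(toy$counts[toy$metadata$sample_type == "host", "ASV1"]) /
                 sum(toy$counts[, "ASV1"]))
})

test_that("core_fit print and summary report membership counts", {
  toy <- twostep_toy()
  fit <- core_microbiome(toy$counts, toy$metadata, min_events = 2,
                         n_perm = 99, seed = 7)
  expect_s3_class(fit, "core_fit")
  expect_output(print(fit), "frequency core")
  s <- summary(fit)
  expect_equal(unname(s$n_core["twostep"]),
               sum(fit$report$is_twostep_core))
  expect_output(print(s), "Core membership")
})
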