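test_that("RT-RSD is the sample-SD percent of the mean, 0 for singletons", {
  expect_equal(rt_rsd(c(10, 10, 10)), 0)
  expect_equal(rt_rsd(c(9.9, 10.0, 10.1)), 1.0)   # sd 0.1 / mean 10 * 100
  expect_equal(rt_rsd(12.5), 0)
  expect_error(rt_rsd(c(10, -1)), "positive")
})

test_that("replicate merging counts replicates and averages over representatives", {
  prot <- fixture_protein(40)
  base <- pep_row(5, 8, prot)
  tabs <- lapply(1:3, function(r) {
    df <- base
    df$replicate_id <- paste0("rep", r)
    df$rt <- c(9.9, 10.0, 10.1)[r]
    df$plgs_score <- 7 + r
    df
  })
  m <- merge_replicates(tabs)
  expect_equal(nrow(m), 1)
  expect_equal(m$replicate_count, 3L)
  expect_equal(m$rt_mean, 10.0)
  expect_equal(m$rt_rsd, 1.0)
  expect_equal(m$plgs_score, mean(8:10))
  expect_equal(m$source_tags, "11_13")

  # a replicate containing the key twice is represented by its top score
  dup <- dplyr::bind_rows(tabs[[1]], tabs[[1]])
  dup$plgs_score <- c(7.0, 8.0)
  dup$rt <- c(5, 11)
  m2 <- merge_replicates(list(dup, tabs[[2]]))
  expect_equal(m2$replicate_count, 2L)
  expect_equal(m2$rt_mean, mean(c(11, 10.0)))  # the 8.0-score instance represents rep1
  expect_equal(m2$plgs_score, mean(c(8.0, 9)))

  expect_equal(nrow(merge_replicates(list())), 0)
  mixed <- dplyr::bind_rows(base, pep_row(5, 8, prot, trendline_tag = "1_1"))
  expect_error(merge_replicates(mixed), "single trendline")
})

test_that("replicate-count and RT-RSD filters keep qualifying rows in order", {
  m <- merge_replicates(random_tag_tables(11, tags = "11_13", n_ids = 12,
                                          n_reps = 3)[["11_13"]])
  th <- loose_thresholds()
  kept <- apply_replicate_and_rsd_filters(m, th)
  expect_true(all(kept$replicate_count >= th$min_replicates))
  expect_true(all(kept$rt_rsd <= th$max_rt_rsd))
  # order preserved
  expect_equal(kept$sequence, m$sequence[m$sequence %in% kept$sequence])
  # no-op thresholds are the identity
  expect_equal(apply_replicate_and_rsd_filters(m, no_op_thresholds()), m)

  counts <- m
  counts$replicate_count <- rep_len(c(3L, 1L, 2L), nrow(m))
  counts$rt_rsd <- 0
  th2 <- filter_thresholds(min_replicates = 2)
  expect_equal(nrow(apply_replicate_and_rsd_filters(counts[1:3, ], th2)), 2)
})

test_that("metric filters enforce every rule inclusively and audit removals", {
  m <- merge_replicates(random_tag_tables(12, tags = "11_13", n_ids = 15,
                                          n_reps = 2)[["11_13"]])
  th <- loose_thresholds()
  kept <- apply_metric_filters(m, th, audit = TRUE)
  expect_true(all(nchar(kept$sequence) >= th$min_length))
  expect_true(all(nchar(kept$sequence) <= th$max_length))
  expect_true(all(kept$plgs_score >= th$min_plgs_score))
  expect_true(all(kept$mh_ppm_error_abs <= th$max_abs_ppm_error))
  aud <- attr(kept, "audit")
  expect_setequal(setdiff(m$sequence, kept$sequence), unique(aud$sequence))

  # a record failing exactly one rule is removed, audit names that rule
  one <- merge_replicates(pep_row(1, 4, fixture_protein(40)))
  short_th <- filter_thresholds(min_replicates = 1, min_length = 5)
  out <- apply_metric_filters(one, short_th, audit = TRUE)
  expect_equal(nrow(out), 0)
  expect_equal(attr(out, "audit")$rule, "min_length")

  expect_equal(apply_metric_filters(m, no_op_thresholds()), m)
})

test_that("ranking keeps the top PLGS score per sequence and unions source tags", {
  prot <- fixture_protein(40)
  a <- merge_replicates(pep_row(3, 6, prot, plgs_score = 8.1))
  b <- merge_replicates(pep_row(3, 6, prot, plgs_score = 7.3,
                                trendline_tag = "1_1"))
  out <- rank_and_dedup(dplyr::bind_rows(a, b))
  expect_equal(nrow(out), 1)
  expect_equal(out$plgs_score, 8.1)
  expect_equal(out$source_tags, "11_13;1_1")  # byte-order union of both tags

  # idempotence and order invariance
  m <- merge_replicates(random_tag_tables(13, tags = "11_13", n_ids = 12,
                                          n_reps = 2)[["11_13"]])
  once <- rank_and_dedup(m)
  expect_equal(rank_and_dedup(once), once)
  shuffled <- m[sample(nrow(m)), ]
  expect_equal(rank_and_dedup(shuffled), once)
  # ranked output is score-sorted
  expect_true(all(diff(once$plgs_score) <= 0))
})

test_that("best-trendline selection is argmax on unique counts with a stable tie-break", {
  th <- loose_thresholds()
  tabs <- random_tag_tables(14, tags = c("5_8", "11_14", "81_84"), n_ids = 14,
                            n_reps = 3)
  # make 11_14 strictly richer by dropping rows from the others
  tabs[["5_8"]] <- lapply(tabs[["5_8"]], function(d) d[seq_len(min(4, nrow(d))), ])
  tabs[["81_84"]] <- lapply(tabs[["81_84"]], function(d) d[seq_len(min(2, nrow(d))), ])
  fix_tag <- function(tbls, tag) lapply(tbls, function(d) { d$trendline_tag <- tag; d })
  for (tg in names(tabs)) tabs[[tg]] <- fix_tag(tabs[[tg]], tg)
  rep <- identify_best_trendline(tabs, th)
  counts <- setNames(rep$counts$n_unique, rep$counts$tag)
  expect_equal(rep$best_tag, names(which.max(counts)))
  expect_equal(nrow(rep$best_list), max(counts))

  # single tag is trivially best
  one <- identify_best_trendline(tabs["11_14"], th)
  expect_equal(one$best_tag, "11_14")

  # exact tie: the smaller fwhm_start anchor wins
  same <- tabs[["11_14"]]
  tie <- list("9_11" = fix_tag(same, "9_11"), "11_13" = fix_tag(same, "11_13"))
  tied <- identify_best_trendline(tie, th)
  expect_equal(length(unique(tied$counts$n_unique)), 1)
  expect_equal(tied$best_tag, "9_11")
})

test_that("multi-sequence pooling is a filtered union with top-score survivors", {
  th <- loose_thresholds()
  prot <- fixture_protein(80, seed = 55)
  mk <- function(starts, tag, score = 9) {
    merge_replicates(lapply(1:2, function(r) {
      dplyr::bind_rows(lapply(starts, function(s)
        pep_row(s, 6, prot, plgs_score = score, trendline_tag = tag,
                replicate_id = paste0("rep", r))))
    }))
  }
  sp <- mk(seq(1, 28, by = 3), "1_1")            # 10 peptides
  mp <- mk(seq(41, 59, by = 3), "11_13")         # 7 disjoint peptides
  out <- merge_multisequence(sp, mp, th)
  expect_equal(nrow(out), 17)                    # disjoint union

  same <- merge_multisequence(sp, sp, th)
  expect_setequal(pep_key(same), pep_key(sp))

  # shared key: the higher-scoring single-pass instance survives, tags merge
  mp2 <- mk(1, "11_13", score = 7)
  sp2 <- mk(1, "1_1", score = 9)
  both <- merge_multisequence(sp2, mp2, th)
  expect_equal(nrow(both), 1)
  expect_equal(both$plgs_score, 9)
  expect_equal(both$source_tags, "11_13;1_1")
})

test_that("multi-trendline pooling equals the per-tag set union", {
  th <- loose_thresholds()
  tabs <- random_tag_tables(15, n_ids = 14, n_reps = 3)
  pooled <- merge_multitrendline(tabs, th)
  per_tag_keys <- lapply(names(tabs), function(tag) {
    m <- apply_replicate_and_rsd_filters(merge_replicates(tabs[[tag]]), th)
    pep_key(rank_and_dedup(apply_metric_filters(m, th)))
  })
  expect_setequal(pep_key(pooled), unique(unlist(per_tag_keys)))
  # union dominates any member
  for (k in per_tag_keys) expect_true(all(k %in% pep_key(pooled)))

  # all tags identical collapses to the single-tag result
  same <- list("1_1" = tabs[["1_1"]],
               "11_13" = lapply(tabs[["1_1"]], function(d) {
                 d$trendline_tag <- "11_13"; d
               }))
  collapsed <- merge_multitrendline(same, th)
  single <- rank_and_dedup(apply_metric_filters(
    apply_replicate_and_rsd_filters(merge_replicates(tabs[["1_1"]]), th), th))
  expect_setequal(pep_key(collapsed), pep_key(single))

  expect_error(merge_multitrendline(tabs["11_13"], th), "1_1")
})

test_that("tightening any single threshold never grows the surviving set", {
  th0 <- loose_thresholds()
  tighten <- list(min_replicates = 3, max_rt_rsd = 0.3,
                  min_products_per_aa = 1.5, min_intensity = 5e4,
                  min_length = 6, max_length = 7, min_matched_products = 10,
                  min_consecutive_products = 6,
                  min_sum_product_intensity = 5e3, min_plgs_score = 9,
                  max_abs_ppm_error = 2)
  for (s in 1:10) {
    tabs <- random_tag_tables(300 + s, tags = "11_13", n_ids = 16, n_reps = 3)
    m <- merge_replicates(tabs[["11_13"]])
    run <- function(th) {
      pep_key(rank_and_dedup(apply_metric_filters(
        apply_replicate_and_rsd_filters(m, th), th)))
    }
    base_keys <- run(th0)
    for (f in names(tighten)) {
      args <- unclass(th0)
      args[[f]] <- tighten[[f]]
      strict <- do.call(filter_thresholds, args)
      expect_true(all(run(strict) %in% base_keys),
                  info = paste("threshold", f, "seed", s))
    }
  }
})

test_that("threshold profiles read from flat YAML key/value files", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "th.yaml")
  writeLines(c("min_replicates: 3", "max_rt_rsd: 2.5", "min_plgs_score: 7"), f)
  th <- read_thresholds(f)
  expect_equal(th$min_replicates, 3L)
  expect_equal(th$max_rt_rsd, 2.5)
  expect_equal(th$min_plgs_score, 7)
  expect_equal(th$min_length, filter_thresholds()$min_length)  # default kept
  writeLines("not_a_threshold: 1", f)
  expect_error(read_thresholds(f), "unknown threshold")
  expect_error(filter_thresholds(min_length = 10, max_length = 5), "max_length")
})
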