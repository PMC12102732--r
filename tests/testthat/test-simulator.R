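test_that("cyclic wrap-around folds drift times into the acquisition window", {
  expect_equal(wrap_dt(50, 1), 50)
  expect_equal(wrap_dt(120, 2), 40)    # 240 mod 200
  expect_equal(wrap_dt(40, 5), 0)      # 200 mod 200
  expect_true(all(wrap_dt(runif(100, 1, 500), 6) >= 0 &
                    wrap_dt(runif(100, 1, 500), 6) < 200))
})

test_that("in-silico digestion is seeded, bounded, and can tile the protein", {
  prot <- fixture_protein(30, seed = 31)
  d1 <- digest_in_silico(prot, 5, 10, density = 3, seed = 9)
  d2 <- digest_in_silico(prot, 5, 10, density = 3, seed = 9)
  expect_identical(d1, d2)
  expect_false(identical(d1, digest_in_silico(prot, 5, 10, density = 3, seed = 10)))
  expect_true(all(nchar(d1$sequence) >= 5 & nchar(d1$sequence) <= 10))
  expect_true(all(d1$sequence == substr(rep(prot$sequence, nrow(d1)),
                                        d1$start, d1$end)))
  expect_false(any(duplicated(d1[, c("start", "end")])))

  # high density tiles the full sequence
  dense <- digest_in_silico(prot, 5, 10, density = 30, seed = 9)
  cov <- coverage_report(dense, prot)
  expect_equal(cov$coverage_percent, 100)

  tiny <- fixture_protein(4, seed = 32)
  expect_error(digest_in_silico(tiny, 5, 10), "shorter than")
})

test_that("simulated tables are reproducible and saturate when mismatch is free", {
  prot <- fixture_protein(90, seed = 41)
  gt <- simulate_ground_truth(prot, seed = 5)
  plan <- build_processing_plan("11-13,21-23",
    single_pass_points = data.frame(dt_bin = gt$true_peptides$dt_single,
                                    fwhm = gt$true_peptides$fwhm_single))
  s1 <- simulate_tables(gt, plan, n_replicates = 3, seed = 5)
  s2 <- simulate_tables(gt, plan, n_replicates = 3, seed = 5)
  expect_identical(s1, s2)
  expect_setequal(names(s1), c("11_13", "21_23", "1_1"))
  expect_length(s1[["11_13"]], 3)

  # sigma -> Inf with p_max = 1: every true peptide in every table
  sat_model <- detection_model(p_max = 1, sigma = 1e9)
  gt_sat <- simulate_ground_truth(prot, model = sat_model, seed = 5)
  sat <- simulate_tables(gt_sat, plan, n_replicates = 2, seed = 5)
  n_true <- nrow(gt_sat$true_peptides)
  for (tag in names(sat)) {
    for (rep in sat[[tag]]) {
      expect_true(all(pep_key(gt_sat$true_peptides) %in% pep_key(rep)))
      expect_gte(nrow(rep), n_true)
    }
  }
})

test_that("matched trendlines detect their own FWHM component; the union is larger", {
  prot <- fixture_protein(150, seed = 42)
  gt <- simulate_ground_truth(prot, density = 2.5, seed = 17)
  plan <- build_processing_plan("11-13,21-23",
    single_pass_points = data.frame(dt_bin = gt$true_peptides$dt_single,
                                    fwhm = gt$true_peptides$fwhm_single))
  sim <- simulate_tables(gt, plan, n_replicates = 3, seed = 17)
  tp <- gt$true_peptides
  keys <- pep_key(tp)
  emitted <- function(tag) unique(pep_key(dplyr::bind_rows(sim[[tag]])))
  in_comp <- function(tag, comp) mean(keys[tp$component == comp] %in% emitted(tag))
  # each trendline detects its matching mixture component at high rate
  expect_gt(in_comp("11_13", 1), 0.8)
  expect_gt(in_comp("21_23", 2), 0.8)
  # and mostly misses the other component
  expect_lt(in_comp("11_13", 2), 0.3)
  expect_lt(in_comp("21_23", 1), 0.3)
  # the union across the two trendlines beats either alone
  u <- length(union(emitted("11_13"), emitted("21_23")))
  expect_gt(u, length(emitted("11_13")))
  expect_gt(u, length(emitted("21_23")))
})

test_that("planted false positives are removed by their rule and survive without it", {
  prot <- fixture_protein(120, seed = 43)
  th <- filter_thresholds()
  gt <- simulate_ground_truth(prot, decoy_thresholds = th, seed = 23)
  plan <- build_processing_plan("11-13,21-23",
    single_pass_points = data.frame(dt_bin = gt$true_peptides$dt_single,
                                    fwhm = gt$true_peptides$fwhm_single))
  sim <- simulate_tables(gt, plan, n_replicates = 3, seed = 23)
  decoy_keys <- setNames(pep_key(gt$false_positives), gt$false_positives$fails_rule)

  final <- merge_multitrendline(sim, th)
  expect_length(intersect(pep_key(final), decoy_keys), 0)

  no_op <- unclass(no_op_thresholds())
  for (rule in names(decoy_keys)) {
    args <- unclass(th)
    args[[rule]] <- no_op[[rule]]
    relaxed <- do.call(filter_thresholds, args)
    out_keys <- pep_key(merge_multitrendline(sim, relaxed))
    expect_true(decoy_keys[[rule]] %in% out_keys,
                info = paste("decoy for", rule, "should survive when disabled"))
    expect_length(intersect(out_keys, decoy_keys[names(decoy_keys) != rule]), 0)
  }
})

test_that("precision and recall follow their set definitions", {
  fake_gt <- structure(list(true_peptides = tibble::tibble(
    protein_id = "P", sequence = paste0("SEQ", 1:9), modification = "")),
    class = "sim_ground_truth")
  truth <- tibble::tibble(protein_id = "P", sequence = paste0("SEQ", 1:9),
                          modification = "")
  expect_equal(score_against_truth(truth, fake_gt),
               c(precision = 1, recall = 1))
  plus_decoy <- dplyr::bind_rows(truth, tibble::tibble(
    protein_id = "P", sequence = "DECOY", modification = ""))
  expect_equal(score_against_truth(plus_decoy, fake_gt)[["precision"]], 0.9)
  expect_equal(score_against_truth(truth[0, ], fake_gt),
               c(precision = 0, recall = 0))
  half <- score_against_truth(truth[1:4, ], fake_gt,
                              detectable = pep_key(truth)[1:8])
  expect_equal(half[["recall"]], 0.5)
})
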