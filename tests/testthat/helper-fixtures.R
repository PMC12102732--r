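# programmatic fixtures: small peptide tables, proteins, random instances

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

fixture_protein <- function(len = 60, seed = 101, id = "P1") {
  set.seed(seed)
  tibble::tibble(protein_id = id,
                 sequence = paste(sample(AA20, len, replace = TRUE), collapse = ""),
                 length = len)
}

# a peptide-ID row in the canonical schema; sequence taken from `protein`
# when given, otherwise synthesised to match start/end
pep_row <- function(start = 1, len = 7, protein = NULL, protein_id = "P1",
                    sequence = NULL, modification = "", plgs_score = 8,
                    rt = 10, dt_bin = 50, intensity = 1e5,
                    products_per_aa = 1.5, matched_products = 10,
                    consecutive_products = 5, sum_product_intensity = 1e4,
                    mh_ppm_error = 1, replicate_id = "rep1",
                    trendline_tag = "11_13") {
  if (is.null(sequence)) {
    sequence <- if (!is.null(protein)) {
      substr(protein$sequence, start, start + len - 1)
    } else {
      paste(rep(AA20, length.out = len), collapse = "")
    }
  }
  tibble::tibble(protein_id = protein_id, sequence = sequence,
                 modification = modification, start = start,
                 end = start + nchar(sequence) - 1,
                 plgs_score = plgs_score, rt = rt, dt_bin = dt_bin,
                 intensity = intensity, products_per_aa = products_per_aa,
                 matched_products = matched_products,
                 consecutive_products = consecutive_products,
                 sum_product_intensity = sum_product_intensity,
                 mh_ppm_error = mh_ppm_error, replicate_id = replicate_id,
                 trendline_tag = trendline_tag)
}

# random replicate tables over a shared identity pool; metrics straddle the
# `loose_thresholds()` profile so every filter rule can bite
random_identity_pool <- function(n_ids, protein, seed) {
  set.seed(seed)
  len <- pmin(sample(3:12, n_ids, replace = TRUE), protein$length)
  start <- vapply(len, function(l) sample.int(protein$length - l + 1L, 1L),
                  integer(1))
  tibble::tibble(
    protein_id = protein$protein_id,
    sequence = substr(rep(protein$sequence, n_ids), start, start + len - 1),
    start = start, end = start + len - 1,
    plgs_score = stats::runif(n_ids, 2, 12),
    rt = stats::runif(n_ids, 4, 12),
    dt_bin = stats::runif(n_ids, 5, 195),
    intensity = stats::rlnorm(n_ids, log(2e4), 1),
    products_per_aa = stats::runif(n_ids, 0, 3),
    matched_products = sample(0:20, n_ids, replace = TRUE),
    consecutive_products = sample(0:10, n_ids, replace = TRUE),
    sum_product_intensity = stats::rlnorm(n_ids, log(2e3), 1),
    mh_ppm_error = stats::rnorm(n_ids, 0, 8)) |>
    dplyr::distinct(sequence, .keep_all = TRUE)
}

random_tag_tables <- function(seed, tags = c("11_13", "21_23", "1_1"),
                              n_ids = 10, n_reps = 2, protein = NULL) {
  if (is.null(protein)) protein <- fixture_protein(40, seed = seed + 900)
  pool <- random_identity_pool(n_ids, protein, seed)
  set.seed(seed + 1)
  out <- lapply(tags, function(tag) {
    lapply(seq_len(n_reps), function(r) {
      keep <- stats::runif(nrow(pool)) < 0.7
      df <- pool[keep, , drop = FALSE]
      if (nrow(df) == 0L) df <- pool[1, , drop = FALSE]
      df$modification <- ""
      df$rt <- df$rt + stats::rnorm(nrow(df), 0, 0.03)
      df$plgs_score <- pmax(0, df$plgs_score + stats::rnorm(nrow(df), 0, 0.2))
      df$replicate_id <- paste0("rep", r)
      df$trendline_tag <- tag
      df[, cimmerge::peptide_columns()]
    })
  })
  names(out) <- tags
  out
}

# a permissive profile under which random instances keep a healthy mix of
# passing and failing records
loose_thresholds <- function(...) {
  cimmerge::filter_thresholds(min_replicates = 2, max_rt_rsd = 5,
                              min_products_per_aa = 0.5, min_intensity = 5000,
                              min_length = 4, max_length = 10,
                              min_matched_products = 4,
                              min_consecutive_products = 2,
                              min_sum_product_intensity = 800,
                              min_plgs_score = 5, max_abs_ppm_error = 10, ...)
}

pep_key <- function(df) paste(df$protein_id, df$sequence, df$modification,
                              sep = "\r")

write_fixture_csv <- function(df, dir, tag, name) {
  d <- file.path(dir, tag)
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  p <- file.path(d, name)
  readr::write_csv(df, p, progress = FALSE)
  p
}

fixture_fasta <- function(dir, proteins) {
  path <- file.path(dir, "targets.fasta")
  writeLines(unlist(lapply(seq_len(nrow(proteins)), function(i) {
    c(paste0(">", proteins$protein_id[i]), proteins$sequence[i])
  })), path)
  path
}
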