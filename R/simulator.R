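#' Cyclic drift-time wrap-around
#'
#' In multipass separations an ion's detected drift-time bin is its periodic
#' drift time (one traversal of the cyclic cell) multiplied by the number of
#' passes, folded into the fixed 200-push acquisition window: faster ions lap
#' slower ones, which destroys the linear DT-vs-FWHM relationship that
#' single-pass data shows.
#'
#' @param periodic_dt Periodic drift time in DT bins (> 0); vectorised.
#' @param n_passes Number of passes around the cyclic cell (>= 1).
#' @param window Acquisition window size in bins; default 200.
#' @return The wrapped DT bin in `[0, window)`.
#' @examples
#' wrap_dt(120, 2)  # 240 %% 200 = 40
#' @export
wrap_dt <- function(periodic_dt, n_passes, window = 200) {
  stopifnot(is.numeric(periodic_dt), all(periodic_dt > 0),
            is.numeric(n_passes), all(n_passes >= 1))
  (periodic_dt * n_passes) %% window
}

#' Detection model for the synthetic peptide-ID backend
#'
#' Encodes how likely the (simulated) peak-detection engine is to identify a
#' true peptide under a given smoothing trendline. Each multipass peptide has
#' a true ion-mobility peak FWHM drawn from a two-component mixture (emulating
#' wrapped vs unwrapped ion populations whose widths respond differently to
#' multipass separation), while single-pass peptides draw from one narrow
#' unwrapped component. The probability of detection under trendline `t` at
#' DT bin `d` is a Gaussian mismatch kernel
#' `p_max * exp(-(fwhm_at(t, d) - true_fwhm)^2 / (2 * sigma^2))`:
#' the further the applied smoothing width is from the true peak width (under-
#' or over-smoothing), the more identifications are lost.
#'
#' @param p_max Detection probability under perfectly matched smoothing.
#' @param sigma Width tolerance of the mismatch kernel, in DT bins.
#' @param mixture_means,mixture_sds,mixture_weights Parameters of the
#'   multipass true-FWHM mixture (>= 2 components).
#' @param single_pass_mean,single_pass_sd The unwrapped single-pass FWHM
#'   population.
#' @param rt_jitter_sd Replicate-to-replicate retention-time jitter SD, minutes.
#' @param score_jitter_sd Replicate-to-replicate PLGS-score jitter SD.
#' @return An object of class `detection_model`.
#' @export
detection_model <- function(p_max = 0.97, sigma = 2,
                            mixture_means = c(12, 22),
                            mixture_sds = c(1.5, 1.5),
                            mixture_weights = c(0.5, 0.5),
                            single_pass_mean = 6, single_pass_sd = 1,
                            rt_jitter_sd = 0.05, score_jitter_sd = 0.3) {
  stopifnot(p_max >= 0, p_max <= 1, sigma > 0,
            length(mixture_means) >= 2,
            length(mixture_sds) == length(mixture_means),
            length(mixture_weights) == length(mixture_means),
            all(mixture_sds > 0), all(mixture_weights > 0),
            single_pass_sd > 0, rt_jitter_sd > 0, score_jitter_sd > 0)
  structure(list(p_max = p_max, sigma = sigma,
                 mixture_means = mixture_means, mixture_sds = mixture_sds,
                 mixture_weights = mixture_weights / sum(mixture_weights),
                 single_pass_mean = single_pass_mean,
                 single_pass_sd = single_pass_sd,
                 rt_jitter_sd = rt_jitter_sd,
                 score_jitter_sd = score_jitter_sd),
            class = "detection_model")
}

#' Nonspecific in-silico digestion of a protein
#'
#' Emulates nonspecific (pepsin-like) digestion by sampling overlapping
#' subsequences with uniformly distributed start positions and lengths;
#' duplicates (same start and end) are dropped. Reproducible for a seed.
#'
#' @param protein A single-row protein record from [read_fasta()].
#' @param min_length,max_length Peptide length bounds, within `[4, 60]`.
#' @param density Expected sampled peptides per residue of protein length
#'   (before deduplication).
#' @param seed Integer RNG seed.
#' @return A tibble with `protein_id`, `sequence`, `start`, `end`.
#' @export
digest_in_silico <- function(protein, min_length = 5L, max_length = 20L,
                             density = 2, seed = 1L) {
  stopifnot(min_length >= 4L, max_length <= 60L, min_length <= max_length,
            density > 0)
  len <- as.integer(protein$length)
  if (len < min_length) {
    stop("protein ", protein$protein_id, " (length ", len,
         ") is shorter than min_length ", min_length, call. = FALSE)
  }
  n <- max(1L, as.integer(round(density * len)))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  span <- seq(min_length, min(max_length, len))
  L <- if (length(span) == 1L) rep(span, n) else sample(span, n, replace = TRUE)
  start <- vapply(L, function(l) sample.int(len - l + 1L, 1L), integer(1))
  end <- start + L - 1L
  keep <- !duplicated(paste(start, end))
  start <- start[keep]; end <- end[keep]
  ord <- order(start, end)
  start <- start[ord]; end <- end[ord]
  tibble::tibble(protein_id = protein$protein_id,
                 sequence = substr(rep(protein$sequence, length(start)), start, end),
                 start = start, end = end)
}

#' Ground truth for a simulated peptide-mapping experiment
#'
#' Generates the planted truth a simulation run is scored against: an
#' in-silico digest of the protein with per-peptide chromatographic and
#' ion-mobility properties (retention time, periodic drift time, wrapped
#' multipass DT bin, true peak FWHM per the mixture in
#' [detection_model()]), baseline identification metrics, and a set of
#' planted false positives each designed to violate one filtering rule.
#'
#' @param protein A single-row protein record from [read_fasta()].
#' @param model A [detection_model()].
#' @param n_passes Number of cyclic passes in the multipass experiment.
#' @param min_length,max_length,density Digest parameters, see
#'   [digest_in_silico()].
#' @param decoy_thresholds The [filter_thresholds()] profile the false
#'   positives are designed against (each decoy violates one rule with a wide
#'   margin).
#' @param seed Integer RNG seed; all downstream simulation randomness derives
#'   from it.
#' @return An object of class `sim_ground_truth`: list with `true_peptides`,
#'   `false_positives` (column `fails_rule` names the violated rule),
#'   `model`, `n_passes`, `protein`, `seed`.
#' @export
simulate_ground_truth <- function(protein, model = detection_model(),
                                  n_passes = 6L,
                                  min_length = 5L, max_length = 20L,
                                  density = 2, decoy_thresholds = filter_thresholds(),
                                  seed = 1L) {
  stopifnot(inherits(model, "detection_model"))
  digest <- digest_in_silico(protein, min_length, max_length, density,
                             seed = seed)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed + 1L)
  n <- nrow(digest)
  comp <- sample.int(length(model$mixture_means), n, replace = TRUE,
                     prob = model$mixture_weights)
  tp <- digest
  tp$modification <- ""
  tp$component <- comp
  tp$base_rt <- stats::runif(n, 3, 12)
  tp$periodic_dt <- stats::runif(n, 30, 190)
  tp$dt_multipass <- wrap_dt(tp$periodic_dt, n_passes)
  tp$dt_single <- tp$periodic_dt
  tp$fwhm_multipass <- stats::rnorm(n, model$mixture_means[comp],
                                    model$mixture_sds[comp])
  tp$fwhm_single <- stats::rnorm(n, model$single_pass_mean, model$single_pass_sd)
  tp$base_plgs_score <- pmax(stats::rnorm(n, 8.5, 0.8), 7)
  tp$base_intensity <- stats::rlnorm(n, log(5e4), 0.4)
  tp$products_per_aa <- stats::runif(n, 1.0, 2.5)
  tp$matched_products <- pmax(3L, as.integer(round(
    tp$products_per_aa * nchar(tp$sequence) * 0.8)))
  tp$consecutive_products <- pmax(2L, pmin(tp$matched_products,
                                           as.integer(round(stats::runif(n, 3, 8)))))
  tp$sum_product_intensity <- tp$base_intensity * stats::runif(n, 0.2, 0.5)
  tp$base_ppm <- stats::rnorm(n, 0, 1.5)
  fp <- plant_false_positives(protein, peptide_key(tp), decoy_thresholds,
                              seed = seed + 2L)
  structure(list(true_peptides = tp, false_positives = fp, model = model,
                 n_passes = as.integer(n_passes), protein = protein,
                 seed = as.integer(seed)),
            class = "sim_ground_truth")
}

# one decoy per violated rule; all other fields comfortably pass `th`
plant_false_positives <- function(protein, true_keys, th = filter_thresholds(),
                                  seed = 1L) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  len <- as.integer(protein$length)
  rules <- c("min_plgs_score", "max_abs_ppm_error", "min_intensity",
             "min_products_per_aa", "min_length", "max_length",
             "min_matched_products", "min_consecutive_products",
             "min_sum_product_intensity", "min_replicates", "max_rt_rsd")
  pick_span <- function(L) {
    L <- min(L, len)
    s <- sample.int(len - L + 1L, 1L)
    c(s, s + L - 1L)
  }
  rows <- list()
  for (rule in rules) {
    L <- switch(rule,
                min_length = max(1L, th$min_length - 1L),
                max_length = th$max_length + 5L,
                as.integer(round(stats::runif(1, th$min_length + 1,
                                              min(th$max_length, len)))))
    if (rule == "max_length" && L > len) next  # protein too short to plant it
    span <- pick_span(L)
    d <- tibble::tibble(
      protein_id = protein$protein_id,
      sequence = substr(protein$sequence, span[1], span[2]),
      start = span[1], end = span[2], modification = "",
      base_rt = stats::runif(1, 3, 12),
      dt = stats::runif(1, 20, 180),
      base_plgs_score = 9, base_intensity = 5e4,
      products_per_aa = 1.5, matched_products = 12L,
      consecutive_products = 5L, sum_product_intensity = 1e4,
      base_ppm = 1, fails_rule = rule)
    d <- switch(rule,
      min_plgs_score = { d$base_plgs_score <- max(0, th$min_plgs_score - 3); d },
      max_abs_ppm_error = { d$base_ppm <- th$max_abs_ppm_error * 2.5; d },
      min_intensity = { d$base_intensity <- th$min_intensity * 0.1; d },
      min_products_per_aa = { d$products_per_aa <- th$min_products_per_aa * 0.25; d },
      min_matched_products = { d$matched_products <- max(0L, th$min_matched_products - 2L); d },
      min_consecutive_products = { d$consecutive_products <- max(0L, th$min_consecutive_products - 2L); d },
      min_sum_product_intensity = { d$sum_product_intensity <- th$min_sum_product_intensity * 0.1; d },
      d)
    rows[[rule]] <- d
  }
  fp <- dplyr::bind_rows(rows)
  # decoy keys must not collide with planted truth
  fp[!(peptide_key(fp) %in% true_keys), , drop = FALSE]
}

#' Simulate per-trendline, per-replicate peptide-ID tables
#'
#' The synthetic stand-in for the vendor peak-detection and search engine:
#' for every trendline tag in the processing plan and every replicate, each
#' true peptide is emitted with probability
#' `p_max * exp(-(fwhm_at(trendline, dt_bin) - true_fwhm)^2 / (2 sigma^2))`
#' (single-pass uses the unwrapped single-component population and the plan's
#' auto-calculated trendline), with per-replicate jitter on retention time,
#' score, intensities and ppm error. Planted false positives are appended to
#' every replicate — except the replicate-count decoy, which appears in one
#' replicate only, and the RT-RSD decoy, whose retention time receives heavy
#' jitter. Output is fully reproducible for a seed: one sub-stream per
#' (tag, replicate).
#'
#' @param gt A [simulate_ground_truth()] object.
#' @param plan A [build_processing_plan()] object whose single-pass entry is
#'   a fitted trendline.
#' @param n_replicates Number of replicate injections per tag.
#' @param seed Integer seed; defaults to the ground truth's seed.
#' @return Named list: folder tag -> list of per-replicate peptide-ID tibbles
#'   in the canonical schema.
#' @export
simulate_tables <- function(gt, plan, n_replicates = 3L, seed = gt$seed) {
  stopifnot(inherits(gt, "sim_ground_truth"), inherits(plan, "processing_plan"),
            n_replicates >= 1L)
  if (is.null(plan$single_pass)) {
    stop("processing plan lacks a fitted single-pass trendline; supply ",
         "single_pass_points to build_processing_plan()", call. = FALSE)
  }
  model <- gt$model
  tp <- gt$true_peptides
  fp <- gt$false_positives
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  out <- list()
  for (ti in seq_along(plan$tags)) {
    tag <- plan$tags[ti]
    is_sp <- tag == single_pass_tag()
    trl <- if (is_sp) plan$single_pass else plan$multipass[[tag]]
    dt <- if (is_sp) tp$dt_single else tp$dt_multipass
    dt <- pmin(pmax(dt, 0), 200)
    fwhm <- if (is_sp) tp$fwhm_single else tp$fwhm_multipass
    p_det <- model$p_max * exp(-(fwhm_at(trl, dt) - fwhm)^2 / (2 * model$sigma^2))
    reps <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      set.seed((seed + 7919L * ti + 131L * r) %% 2147483647L)
      hit <- stats::runif(nrow(tp)) < p_det
      rows <- emit_rows(tp[hit, , drop = FALSE], dt[hit], model,
                        tag = tag, replicate_id = paste0("rep", r))
      fp_r <- fp[fp$fails_rule != "min_replicates" | r == 1L, , drop = FALSE]
      fp_rows <- emit_decoy_rows(fp_r, model, tag = tag,
                                 replicate_id = paste0("rep", r))
      reps[[r]] <- dplyr::bind_rows(rows, fp_rows)
    }
    names(reps) <- paste0("rep", seq_len(n_replicates))
    out[[tag]] <- reps
  }
  out
}

emit_rows <- function(tp, dt, model, tag, replicate_id) {
  n <- nrow(tp)
  if (n == 0L) return(empty_peptide_table())
  tibble::tibble(
    protein_id = tp$protein_id,
    sequence = tp$sequence,
    modification = tp$modification,
    start = as.numeric(tp$start), end = as.numeric(tp$end),
    plgs_score = pmax(0, tp$base_plgs_score + stats::rnorm(n, 0, model$score_jitter_sd)),
    rt = pmax(0.5, tp$base_rt + stats::rnorm(n, 0, model$rt_jitter_sd)),
    dt_bin = pmin(pmax(dt + stats::rnorm(n, 0, 1), 0), 200),
    intensity = tp$base_intensity * exp(stats::rnorm(n, 0, 0.1)),
    products_per_aa = pmax(0, tp$products_per_aa + stats::rnorm(n, 0, 0.05)),
    matched_products = as.numeric(tp$matched_products),
    consecutive_products = as.numeric(tp$consecutive_products),
    sum_product_intensity = tp$sum_product_intensity * exp(stats::rnorm(n, 0, 0.1)),
    mh_ppm_error = tp$base_ppm + stats::rnorm(n, 0, 0.5),
    replicate_id = replicate_id,
    trendline_tag = tag)
}

emit_decoy_rows <- function(fp, model, tag, replicate_id) {
  n <- nrow(fp)
  if (n == 0L) return(empty_peptide_table())
  rt_sd <- ifelse(fp$fails_rule == "max_rt_rsd", 2.0, model$rt_jitter_sd)
  tibble::tibble(
    protein_id = fp$protein_id,
    sequence = fp$sequence,
    modification = fp$modification,
    start = as.numeric(fp$start), end = as.numeric(fp$end),
    plgs_score = pmax(0, fp$base_plgs_score + stats::rnorm(n, 0, model$score_jitter_sd)),
    rt = pmax(0.5, fp$base_rt + stats::rnorm(n, 0, rt_sd)),
    dt_bin = pmin(pmax(fp$dt + stats::rnorm(n, 0, 1), 0), 200),
    intensity = fp$base_intensity * exp(stats::rnorm(n, 0, 0.1)),
    products_per_aa = pmax(0, fp$products_per_aa + stats::rnorm(n, 0, 0.02)),
    matched_products = as.numeric(fp$matched_products),
    consecutive_products = as.numeric(fp$consecutive_products),
    sum_product_intensity = fp$sum_product_intensity * exp(stats::rnorm(n, 0, 0.1)),
    mh_ppm_error = fp$base_ppm + stats::rnorm(n, 0, 0.5),
    replicate_id = replicate_id,
    trendline_tag = tag)
}

#' Write simulated tables in the per-trendline folder layout
#'
#' Creates one subfolder per trendline tag under `out_dir`, one CSV per
#' replicate inside it, plus a `ground_truth.csv` sidecar of the planted true
#' peptides and false positives for later scoring.
#'
#' @param sim Output of [simulate_tables()].
#' @param gt The matching [simulate_ground_truth()] object.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_simulation <- function(sim, gt, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tag in names(sim)) {
    d <- file.path(out_dir, tag)
    dir.create(d, showWarnings = FALSE)
    for (rep in names(sim[[tag]])) {
      readr::write_csv(sim[[tag]][[rep]], file.path(d, paste0(rep, ".csv")),
                       progress = FALSE)
    }
  }
  truth <- dplyr::bind_rows(
    dplyr::mutate(gt$true_peptides, fails_rule = NA_character_),
    gt$false_positives)
  readr::write_csv(truth, file.path(out_dir, "ground_truth.csv"),
                   progress = FALSE)
  invisible(out_dir)
}

#' Read back a per-trendline folder layout of peptide tables
#'
#' Scans `dir` for trendline subfolders (names of the form `A_B`) and reads
#' every CSV inside each as one replicate table.
#'
#' @param dir Parent directory of the per-tag subfolders.
#' @param fasta Optional protein table for sequence validation.
#' @return Named list: tag -> list of replicate tibbles.
#' @export
read_tag_folders <- function(dir, fasta = NULL) {
  tags <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  tags <- tags[grepl("^[0-9.]+_[0-9.]+$", tags)]
  if (length(tags) == 0L) stop("no trendline subfolders under ", dir, call. = FALSE)
  out <- lapply(tags, function(tag) {
    files <- list.files(file.path(dir, tag), pattern = "\\.csv$",
                        full.names = TRUE)
    lapply(files, read_peptide_table, fasta = fasta)
  })
  names(out) <- tags
  out
}

#' True keys detectable under a simulation
#'
#' A planted true peptide counts as detectable if it was emitted in at least
#' `min_replicates` distinct replicates of at least one trendline tag — i.e.
#' it could in principle survive the replicate-count filter somewhere.
#'
#' @param sim Output of [simulate_tables()].
#' @param gt The matching ground truth.
#' @param min_replicates Replicate threshold used downstream.
#' @return Character vector of identity keys.
#' @export
detectable_keys <- function(sim, gt, min_replicates = 2L) {
  true_keys <- peptide_key(gt$true_peptides)
  det <- character(0)
  for (tag in names(sim)) {
    df <- dplyr::bind_rows(sim[[tag]])
    if (nrow(df) == 0L) next
    df$.key <- peptide_key(df)
    tab <- dplyr::distinct(df, .data$.key, .data$replicate_id) |>
      dplyr::count(.data$.key)
    det <- union(det, tab$.key[tab$n >= min_replicates])
  }
  intersect(det, true_keys)
}

#' Score a final peptide list against simulation ground truth
#'
#' Precision is the fraction of the final list's identity keys that are
#' planted true peptides; recall is the fraction of detectable true keys
#' present in the final list. Both are 0 when their denominator is empty.
#'
#' @param final_list A final merged-peptide tibble.
#' @param gt A [simulate_ground_truth()] object.
#' @param detectable Optional character vector of detectable true keys (from
#'   [detectable_keys()]); defaults to all planted true keys.
#' @return Named numeric vector with elements `precision` and `recall`.
#' @export
score_against_truth <- function(final_list, gt, detectable = NULL) {
  true_keys <- peptide_key(gt$true_peptides)
  if (is.null(detectable)) detectable <- true_keys
  final_keys <- unique(peptide_key(final_list))
  tp <- length(intersect(final_keys, true_keys))
  precision <- if (length(final_keys) == 0L) 0 else tp / length(final_keys)
  recall <- if (length(detectable) == 0L) 0 else
    length(intersect(final_keys, detectable)) / length(detectable)
  c(precision = precision, recall = recall)
}
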