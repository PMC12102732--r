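#' Filtering thresholds for peptide-identification lists
#'
#' The threshold set applied when merging and filtering peptide-ID lists:
#' a sample-replicate count, retention-time relative standard deviation
#' (RT-RSD, %), and the per-peptide metric thresholds (products per amino
#' acid, intensity, sequence length bounds, matched products, consecutive
#' products, summed product intensity, PLGS score, and absolute MH+ ppm
#' error). All comparisons are inclusive. Defaults are a field-typical
#' profile and are meant to be edited per dataset (see
#' [read_thresholds()] for the file form).
#'
#' @param min_replicates Minimum number of replicates a peptide must appear in.
#' @param max_rt_rsd Maximum RT-RSD in percent.
#' @param min_products_per_aa Minimum fragment products per amino acid.
#' @param min_intensity Minimum precursor intensity.
#' @param min_length,max_length Peptide sequence length bounds (residues).
#' @param min_matched_products Minimum matched product ions.
#' @param min_consecutive_products Minimum consecutive product ions.
#' @param min_sum_product_intensity Minimum summed product-ion intensity.
#' @param min_plgs_score Minimum PLGS identification score.
#' @param max_abs_ppm_error Maximum absolute MH+ mass error in ppm.
#' @return An object of class `filter_thresholds` (a validated named list).
#' @export
filter_thresholds <- function(min_replicates = 2L,
                              max_rt_rsd = 5,
                              min_products_per_aa = 0.2,
                              min_intensity = 5000,
                              min_length = 4L,
                              max_length = 30L,
                              min_matched_products = 3L,
                              min_consecutive_products = 2L,
                              min_sum_product_intensity = 500,
                              min_plgs_score = 6.62,
                              max_abs_ppm_error = 10) {
  th <- list(min_replicates = as.integer(min_replicates),
             max_rt_rsd = as.numeric(max_rt_rsd),
             min_products_per_aa = as.numeric(min_products_per_aa),
             min_intensity = as.numeric(min_intensity),
             min_length = as.integer(min_length),
             max_length = as.integer(max_length),
             min_matched_products = as.integer(min_matched_products),
             min_consecutive_products = as.integer(min_consecutive_products),
             min_sum_product_intensity = as.numeric(min_sum_product_intensity),
             min_plgs_score = as.numeric(min_plgs_score),
             max_abs_ppm_error = as.numeric(max_abs_ppm_error))
  if (th$min_replicates < 1L) stop("min_replicates must be >= 1", call. = FALSE)
  if (th$min_length > th$max_length) {
    stop("min_length must not exceed max_length", call. = FALSE)
  }
  if (any(is.na(unlist(th)))) stop("thresholds must not be NA", call. = FALSE)
  if (th$max_rt_rsd < 0) stop("max_rt_rsd must be >= 0", call. = FALSE)
  structure(th, class = "filter_thresholds")
}

#' A threshold profile that removes nothing
#'
#' Every threshold at its no-op extreme; useful for auditing what filtering
#' alone removes.
#' @return A `filter_thresholds` object.
#' @export
no_op_thresholds <- function() {
  filter_thresholds(min_replicates = 1L, max_rt_rsd = Inf,
                    min_products_per_aa = -Inf, min_intensity = -Inf,
                    min_length = 1L, max_length = .Machine$integer.max,
                    min_matched_products = 0L, min_consecutive_products = 0L,
                    min_sum_product_intensity = -Inf, min_plgs_score = -Inf,
                    max_abs_ppm_error = Inf)
}

#' Read a threshold profile from a flat key/value YAML file
#'
#' Keys mirror the arguments of [filter_thresholds()]; absent keys keep their
#' defaults.
#'
#' @param path Path to a YAML (or plain `key: value`) file.
#' @return A `filter_thresholds` object.
#' @export
read_thresholds <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(filter_thresholds)))
  if (length(unknown) > 0L) {
    stop("unknown threshold key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(filter_thresholds, vals)
}

#' @export
print.filter_thresholds <- function(x, ...) {
  cat("Filter thresholds:\n")
  for (k in names(x)) cat(sprintf("  %-26s %s\n", k, format(x[[k]])))
  invisible(x)
}

#' Retention-time relative standard deviation
#'
#' `100 * sd / mean` with the sample (n-1) standard deviation. A single value
#' returns 0 by convention, so that singletons are governed by the
#' replicate-count filter rather than by RSD.
#'
#' @param rts Numeric vector of retention times (minutes), all > 0.
#' @return RT-RSD in percent.
#' @export
rt_rsd <- function(rts) {
  stopifnot(is.numeric(rts), length(rts) >= 1L)
  if (any(rts <= 0)) stop("retention times must be positive", call. = FALSE)
  if (length(rts) == 1L) return(0)
  100 * stats::sd(rts) / mean(rts)
}

# join/split helpers for the source-tag set stored as a sorted ";"-string
tags_join <- function(tags) {
  paste(sort(unique(tags), method = "radix"), collapse = ";")
}
tags_split <- function(s) strsplit(s, ";", fixed = TRUE)
tags_union <- function(strings) tags_join(unlist(tags_split(strings)))

#' Merge replicate peptide-ID lists within one trendline
#'
#' Groups records by identity key (`protein_id`, `sequence`, `modification`)
#' across the replicate tables of a single trendline folder. If a replicate
#' contains a key more than once, its highest-PLGS-score instance represents
#' it. For each key, the replicate count is the number of distinct replicates
#' containing it; RT mean and RT-RSD are computed over the per-replicate
#' representatives, and all other metrics are arithmetic means over those
#' representatives (ppm error is averaged on its absolute value, column
#' `mh_ppm_error_abs`). Coordinates are taken from the overall
#' highest-scoring instance.
#'
#' @param tables A peptide-ID tibble or a list of them (one per replicate);
#'   all records must share one `trendline_tag`.
#' @return A tibble of merged peptides with columns `protein_id`, `sequence`,
#'   `modification`, `start`, `end`, `replicate_count`, `rt_mean`, `rt_rsd`,
#'   `dt_bin`, `plgs_score`, `intensity`, `products_per_aa`,
#'   `matched_products`, `consecutive_products`, `sum_product_intensity`,
#'   `mh_ppm_error_abs`, `source_tags`.
#' @export
merge_replicates <- function(tables) {
  df <- if (is.data.frame(tables)) tables else dplyr::bind_rows(tables)
  if (nrow(df) == 0L) return(empty_merged_table())
  tags <- unique(df$trendline_tag)
  if (length(tags) != 1L) {
    stop("merge_replicates expects records from a single trendline; got tags: ",
         paste(tags, collapse = ", "), call. = FALSE)
  }
  df$.key <- peptide_key(df)
  # one representative per (key, replicate): highest PLGS score
  reps <- df |>
    dplyr::group_by(.data$.key, .data$replicate_id) |>
    dplyr::slice_max(.data$plgs_score, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup()
  merged <- reps |>
    dplyr::group_by(.data$.key) |>
    dplyr::arrange(dplyr::desc(.data$plgs_score), .by_group = TRUE) |>
    dplyr::summarise(
      protein_id = .data$protein_id[1],
      sequence = .data$sequence[1],
      modification = .data$modification[1],
      start = .data$start[1],
      end = .data$end[1],
      replicate_count = dplyr::n_distinct(.data$replicate_id),
      rt_mean = mean(.data$rt),
      rt_rsd = rt_rsd(.data$rt),
      dt_bin = mean(.data$dt_bin),
      plgs_score = mean(.data$plgs_score),
      intensity = mean(.data$intensity),
      products_per_aa = mean(.data$products_per_aa),
      matched_products = mean(.data$matched_products),
      consecutive_products = mean(.data$consecutive_products),
      sum_product_intensity = mean(.data$sum_product_intensity),
      mh_ppm_error_abs = mean(abs(.data$mh_ppm_error)),
      source_tags = tags_join(.data$trendline_tag),
      .groups = "drop") |>
    dplyr::arrange(.data$.key) |>
    dplyr::select(-".key")
  merged
}

empty_merged_table <- function() {
  tibble::tibble(protein_id = character(0), sequence = character(0),
                 modification = character(0), start = numeric(0),
                 end = numeric(0), replicate_count = integer(0),
                 rt_mean = numeric(0), rt_rsd = numeric(0),
                 dt_bin = numeric(0), plgs_score = numeric(0),
                 intensity = numeric(0), products_per_aa = numeric(0),
                 matched_products = numeric(0), consecutive_products = numeric(0),
                 sum_product_intensity = numeric(0),
                 mh_ppm_error_abs = numeric(0), source_tags = character(0))
}

#' Replicate-count and RT-RSD filters
#'
#' The first filtering stage after replicate merging: keep peptides seen in at
#' least `min_replicates` replicates whose RT-RSD does not exceed
#' `max_rt_rsd`. Row order is preserved.
#'
#' @param merged Output of [merge_replicates()].
#' @param th A [filter_thresholds()] object.
#' @return The surviving subset of `merged`.
#' @export
apply_replicate_and_rsd_filters <- function(merged, th) {
  stopifnot(inherits(th, "filter_thresholds"))
  merged[merged$replicate_count >= th$min_replicates &
           merged$rt_rsd <= th$max_rt_rsd, , drop = FALSE]
}

# metric rules as predicates over a merged table; names are the audit labels
metric_rules <- function(th) {
  list(
    min_products_per_aa = function(d) d$products_per_aa >= th$min_products_per_aa,
    min_intensity = function(d) d$intensity >= th$min_intensity,
    min_length = function(d) nchar(d$sequence) >= th$min_length,
    max_length = function(d) nchar(d$sequence) <= th$max_length,
    min_matched_products = function(d) d$matched_products >= th$min_matched_products,
    min_consecutive_products = function(d) d$consecutive_products >= th$min_consecutive_products,
    min_sum_product_intensity = function(d) d$sum_product_intensity >= th$min_sum_product_intensity,
    min_plgs_score = function(d) d$plgs_score >= th$min_plgs_score,
    max_abs_ppm_error = function(d) d$mh_ppm_error_abs <= th$max_abs_ppm_error)
}

#' Per-peptide metric threshold filters
#'
#' The second filtering stage: keep peptides whose averaged metrics satisfy
#' every metric threshold (all comparisons inclusive). With `audit = TRUE` the
#' result carries an attribute `"audit"`: a tibble naming, for each removed
#' peptide, every rule it failed.
#'
#' @param merged A merged-peptide tibble.
#' @param th A [filter_thresholds()] object.
#' @param audit Record per-removal reasons? Default `FALSE`.
#' @return The surviving subset of `merged`, order preserved.
#' @export
apply_metric_filters <- function(merged, th, audit = FALSE) {
  stopifnot(inherits(th, "filter_thresholds"))
  rules <- metric_rules(th)
  if (nrow(merged) == 0L) {
    out <- merged
    if (audit) attr(out, "audit") <- tibble::tibble(sequence = character(0),
                                                    rule = character(0))
    return(out)
  }
  pass <- vapply(rules, function(f) f(merged), logical(nrow(merged)))
  pass <- matrix(pass, nrow = nrow(merged))
  keep <- rowSums(!pass) == 0L
  out <- merged[keep, , drop = FALSE]
  if (audit) {
    fail_idx <- which(!pass, arr.ind = TRUE)
    attr(out, "audit") <- tibble::tibble(
      sequence = merged$sequence[fail_idx[, 1]],
      modification = merged$modification[fail_idx[, 1]],
      rule = names(rules)[fail_idx[, 2]])
  }
  out
}

#' Rank by PLGS score and keep the top-scoring record per peptide
#'
#' Sorts merged peptides by PLGS score (descending; ties broken by higher
#' summed product intensity, then smaller absolute ppm error, then the
#' lexicographic identity key) and keeps one record per identity key. The
#' survivor's `source_tags` is the union of the tags of all records that
#' collapsed into it.
#'
#' @param merged A merged-peptide tibble.
#' @return The deduplicated tibble, in rank order.
#' @export
rank_and_dedup <- function(merged) {
  if (nrow(merged) == 0L) return(merged)
  key <- peptide_key(merged)
  ord <- order(-merged$plgs_score, -merged$sum_product_intensity,
               merged$mh_ppm_error_abs, key)
  merged <- merged[ord, , drop = FALSE]
  key <- key[ord]
  tag_union <- vapply(split(merged$source_tags, key), tags_union, character(1))
  first <- !duplicated(key)
  out <- merged[first, , drop = FALSE]
  out$source_tags <- unname(tag_union[key[first]])
  out
}

# the full per-trendline pipeline: replicate merge -> replicate/RSD filters
# -> metric filters -> rank/dedup (stage order is load-bearing)
filter_one_tag <- function(tables, th) {
  m <- merge_replicates(tables)
  m <- apply_replicate_and_rsd_filters(m, th)
  m <- apply_metric_filters(m, th)
  rank_and_dedup(m)
}

# numeric (start, end) anchors from a folder tag like "11_13"; NA if not numeric
tag_anchors <- function(tag) {
  parts <- strsplit(tag, "_", fixed = TRUE)[[1]]
  if (length(parts) == 2L) suppressWarnings(as.numeric(parts)) else c(NA_real_, NA_real_)
}

#' Identify the best-performing trendline
#'
#' Runs the full merge-and-filter pipeline independently on each trendline's
#' replicate tables and counts unique peptides surviving per trendline. The
#' trendline with the most unique peptides is selected; ties are broken in
#' favour of the smaller `fwhm_start` anchor (less smoothing, less risk of
#' merging distinct ion-mobility features), then smaller `fwhm_end`, then the
#' lexicographically smaller tag.
#'
#' @param per_tag_tables Named list: folder tag -> peptide-ID tibble or list
#'   of replicate tibbles.
#' @param th A [filter_thresholds()] object.
#' @return An object of class `trendline_report`: list with `counts` (tibble
#'   of `tag`, `n_unique`), `best_tag`, and `best_list` (the winning
#'   trendline's final filtered peptide tibble).
#' @export
identify_best_trendline <- function(per_tag_tables, th) {
  stopifnot(length(per_tag_tables) >= 1L, !is.null(names(per_tag_tables)))
  finals <- lapply(per_tag_tables, filter_one_tag, th = th)
  counts <- tibble::tibble(tag = names(finals),
                           n_unique = unname(vapply(finals, nrow, integer(1))))
  anchors <- t(vapply(counts$tag, tag_anchors, numeric(2)))
  ord <- order(-counts$n_unique, anchors[, 1], anchors[, 2], counts$tag)
  best <- counts$tag[ord[1]]
  structure(list(counts = counts[order(counts$tag), , drop = FALSE],
                 best_tag = best,
                 best_list = finals[[best]]),
            class = "trendline_report")
}

#' @export
print.trendline_report <- function(x, ...) {
  cat("Unique peptides per trendline:\n")
  for (i in seq_len(nrow(x$counts))) {
    mark <- if (x$counts$tag[i] == x$best_tag) "  <- best" else ""
    cat(sprintf("  %-10s %5d%s\n", x$counts$tag[i], x$counts$n_unique[i], mark))
  }
  invisible(x)
}

#' Merge single- and multipass final lists (multi-sequence pooling)
#'
#' Pools the replicate-merged, replicate/RSD-filtered peptide lists from the
#' single-pass experiment (auto-calculated trendline) and the best multipass
#' trendline, applies the metric thresholds to the pool, then ranks by PLGS
#' score and removes redundant IDs so that only the top-scoring record per
#' peptide remains.
#'
#' @param single_pass_final,multipass_final Merged-peptide tibbles that have
#'   already passed [apply_replicate_and_rsd_filters()].
#' @param th A [filter_thresholds()] object.
#' @return The final pooled, filtered, deduplicated peptide tibble.
#' @export
merge_multisequence <- function(single_pass_final, multipass_final, th) {
  pooled <- dplyr::bind_rows(single_pass_final, multipass_final)
  rank_and_dedup(apply_metric_filters(pooled, th))
}

#' Merge results across all trendlines (multi-trendline pooling)
#'
#' Runs replicate merging and the replicate/RSD filters independently per
#' trendline, pools every trendline's survivors (single-pass `"1_1"`
#' included), applies the metric thresholds, and ranks/deduplicates. Because
#' different trendlines optimally smooth different ion-mobility features,
#' each contributes partly unique peptides, and the pooled unique-key set is
#' the union of the per-trendline filtered sets.
#'
#' @param all_tag_tables Named list: folder tag -> peptide-ID tibble or list
#'   of replicate tibbles; must include the single-pass tag `"1_1"` and at
#'   least one multipass tag.
#' @param th A [filter_thresholds()] object.
#' @return The final pooled, filtered, deduplicated peptide tibble.
#' @export
merge_multitrendline <- function(all_tag_tables, th) {
  tags <- names(all_tag_tables)
  if (!(single_pass_tag() %in% tags) || length(setdiff(tags, single_pass_tag())) < 1L) {
    stop("multi-trendline pooling needs the single-pass tag '1_1' and at ",
         "least one multipass tag", call. = FALSE)
  }
  per_tag <- lapply(all_tag_tables, function(tbl) {
    apply_replicate_and_rsd_filters(merge_replicates(tbl), th)
  })
  pooled <- dplyr::bind_rows(per_tag)
  rank_and_dedup(apply_metric_filters(pooled, th))
}
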