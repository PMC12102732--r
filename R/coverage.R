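#' Sequence coverage and redundancy of a peptide map
#'
#' Computes the per-residue depth (number of unique peptides whose
#' `[start, end]` span contains the residue), percent sequence coverage
#' (residues with depth >= 1, as a percent of protein length) and redundancy.
#' Redundancy is the mean depth over *covered* residues by default — the
#' average number of unique peptides covering each covered position — with
#' the full-length denominator available via `denominator = "total"`. With no
#' covered residue both coverage and redundancy are 0.
#'
#' @param peptides A peptide tibble with columns `start` and `end` (e.g. a
#'   final merged list); rows are assumed unique peptides.
#' @param protein A single-row protein record from [read_fasta()] (or any
#'   list with `protein_id` and `length`).
#' @param denominator `"covered"` (default) or `"total"`: the residue set
#'   averaged over for redundancy.
#' @return An object of class `coverage_report`: list with `protein_id`,
#'   `n_peptides`, `coverage_percent`, `redundancy` and `per_residue_depth`
#'   (integer vector of length `protein$length`).
#' @examples
#' prot <- list(protein_id = "P1", length = 10)
#' peps <- tibble::tibble(start = c(1, 4), end = c(5, 8))
#' coverage_report(peps, prot)  # 80% coverage, redundancy 1.25
#' @export
coverage_report <- function(peptides, protein, denominator = c("covered", "total")) {
  denominator <- match.arg(denominator)
  len <- as.integer(protein$length)
  stopifnot(length(len) == 1L, len > 0L)
  n <- nrow(peptides)
  if (n > 0L) {
    bad <- which(peptides$start < 1L | peptides$end > len |
                   peptides$end < peptides$start)
    if (length(bad) > 0L) {
      lab <- if ("sequence" %in% names(peptides)) peptides$sequence[bad[1]]
             else paste0("[", peptides$start[bad[1]], ",", peptides$end[bad[1]], "]")
      stop("peptide ", lab, " falls outside protein ", protein$protein_id,
           " (length ", len, ")", call. = FALSE)
    }
  }
  # depth by difference-array scan: +1 at each start, -1 after each end
  delta <- integer(len + 1L)
  if (n > 0L) {
    starts <- tabulate(peptides$start, nbins = len + 1L)
    ends <- tabulate(peptides$end + 1L, nbins = len + 1L)
    delta <- starts - ends
  }
  depth <- cumsum(delta)[seq_len(len)]
  covered <- sum(depth >= 1L)
  redundancy <- if (covered == 0L) 0 else {
    sum(depth) / if (denominator == "covered") covered else len
  }
  structure(list(protein_id = protein$protein_id,
                 n_peptides = n,
                 coverage_percent = 100 * covered / len,
                 redundancy = redundancy,
                 per_residue_depth = as.integer(depth)),
            class = "coverage_report")
}

#' @export
print.coverage_report <- function(x, ...) {
  cat(sprintf("Coverage report for %s: %d peptides, %.1f%% coverage, redundancy %.2f\n",
              x$protein_id, x$n_peptides, x$coverage_percent, x$redundancy))
  invisible(x)
}

#' Export per-residue depth as a two-column table
#'
#' @param report A [coverage_report()] object.
#' @return A tibble with columns `residue` and `depth`.
#' @export
depth_table <- function(report) {
  stopifnot(inherits(report, "coverage_report"))
  tibble::tibble(residue = seq_along(report$per_residue_depth),
                 depth = report$per_residue_depth)
}

#' Compare two coverage reports of the same protein
#'
#' Tabulates, per metric, the absolute difference `a - b` and the percent
#' change `100 * (a - b) / b`, e.g. for contrasting multi-trendline against
#' single-trendline processing of the same dataset.
#'
#' @param a,b [coverage_report()] objects for the same protein.
#' @return A tibble with columns `metric`, `a`, `b`, `abs_diff`, `pct_change`.
#' @export
compare_reports <- function(a, b) {
  stopifnot(inherits(a, "coverage_report"), inherits(b, "coverage_report"))
  if (!identical(a$protein_id, b$protein_id)) {
    stop("reports describe different proteins: ", a$protein_id, " vs ",
         b$protein_id, call. = FALSE)
  }
  metric <- c("n_peptides", "coverage_percent", "redundancy")
  av <- unname(vapply(a[metric], as.numeric, numeric(1)))
  bv <- unname(vapply(b[metric], as.numeric, numeric(1)))
  tibble::tibble(metric = metric, a = av, b = bv,
                 abs_diff = av - bv,
                 pct_change = ifelse(bv == 0, NA_real_, 100 * (av - bv) / bv))
}

#' Percentage of a part relative to a whole
#'
#' Plain accounting arithmetic for peptide-map attrition bookkeeping, e.g. the
#' share of removed peptides that originated uniquely from one processing
#' mode.
#'
#' @param part,whole Non-negative counts, `whole > 0`.
#' @return `100 * part / whole`.
#' @export
percent_of <- function(part, whole) {
  stopifnot(is.numeric(part), is.numeric(whole), whole > 0, part >= 0)
  100 * part / whole
}

#' Curation and monitorability accounting for a peptide map
#'
#' Summarises the attrition of a peptide list through the two manual stages
#' that follow automated filtering: spectral curation of the peptide-mapping
#' data (removing false positives and low-quality IDs that passed the
#' thresholds) and validation under deuteration (peptides that cannot be
#' reliably monitored across labelling timepoints are dropped). For each
#' stage the removal percentage is relative to the stage's input.
#'
#' @param n_raw Peptides in the raw filtered database (uncurated).
#' @param n_curated Peptides surviving manual curation of the mapping data.
#' @param n_monitored Peptides still monitorable in the deuterated data;
#'   optional.
#' @return A tibble with columns `stage`, `n_in`, `n_out`, `removed`,
#'   `removed_percent`, `retained_percent`.
#' @export
curation_summary <- function(n_raw, n_curated, n_monitored = NA_integer_) {
  stopifnot(n_raw >= n_curated, is.na(n_monitored) || n_curated >= n_monitored)
  stage <- c("curation", if (!is.na(n_monitored)) "hdx_monitoring")
  n_in <- c(n_raw, if (!is.na(n_monitored)) n_curated)
  n_out <- c(n_curated, if (!is.na(n_monitored)) n_monitored)
  tibble::tibble(stage = stage, n_in = n_in, n_out = n_out,
                 removed = n_in - n_out,
                 removed_percent = percent_of(n_in - n_out, n_in),
                 retained_percent = percent_of(n_out, n_in))
}
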