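#' Drift-time vs drift-FWHM trendlines
#'
#' In multipass cyclic ion-mobility (cIM) HDMS-E data the relationship between
#' an ion's drift-time (DT) bin and the full width at half maximum (FWHM) of
#' its ion-mobility peak loses the positive linear correlation seen in
#' single-pass data, because faster ions "wrap around" the cyclic cell and lap
#' slower ones within the fixed 200-push acquisition window. Peak detection
#' therefore needs an explicit smoothing trendline: a line giving the assumed
#' drift FWHM (in DT bins) at DT bin 0 (`fwhm_start`) and at DT bin 200
#' (`fwhm_end`). Trendlines are written in the field's hyphenated notation,
#' e.g. `"11-13"` means FWHM 11 at bin 0 rising linearly to FWHM 13 at bin 200.
#'
#' @param fwhm_start Drift FWHM (DT bins) at DT bin 0. Must be finite and > 0.
#' @param fwhm_end Drift FWHM (DT bins) at DT bin 200. Must be finite and > 0.
#' @return An object of class `trendline`: a list with elements `fwhm_start`
#'   and `fwhm_end`.
#' @examples
#' t <- trendline(11, 13)
#' fwhm_at(t, 100)   # 12
#' folder_tag(t)     # "11_13"
#' @export
trendline <- function(fwhm_start, fwhm_end) {
  stopifnot(is.numeric(fwhm_start), is.numeric(fwhm_end),
            length(fwhm_start) == 1L, length(fwhm_end) == 1L)
  if (!is.finite(fwhm_start) || !is.finite(fwhm_end) ||
      fwhm_start <= 0 || fwhm_end <= 0) {
    stop("trendline anchors must be finite and strictly positive", call. = FALSE)
  }
  structure(list(fwhm_start = as.numeric(fwhm_start),
                 fwhm_end = as.numeric(fwhm_end)),
            class = "trendline")
}

#' @export
print.trendline <- function(x, ...) {
  cat("<trendline ", render_trendline(x), ">  FWHM ", x$fwhm_start,
      " at DT bin 0, ", x$fwhm_end, " at DT bin 200\n", sep = "")
  invisible(x)
}

#' @export
format.trendline <- function(x, ...) render_trendline(x)

# render a number without trailing zeros / decimal point (11 not 11.0)
fmt_num <- function(x) {
  out <- trimws(formatC(x, format = "fg", digits = 15))
  has_dec <- grepl(".", out, fixed = TRUE)
  out[has_dec] <- sub("\\.$", "", sub("0+$", "", out[has_dec]))
  out
}

#' Parse a trendline from its hyphenated text form
#'
#' Accepts `"<start>-<end>"` with an ASCII hyphen or typographic en-dash and
#' optional surrounding whitespace, e.g. `"11-13"` or `"11–13"`.
#'
#' @param text A single string such as `"11-13"`.
#' @return A [trendline()] object.
#' @seealso [parse_trendline_list()] for comma-separated lists.
#' @export
parse_trendline <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  txt <- trimws(gsub("–|—", "-", text))
  m <- regmatches(txt, regexec(
    "^([0-9]*\\.?[0-9]+)\\s*-\\s*([0-9]*\\.?[0-9]+)$", txt))[[1]]
  if (length(m) != 3L) {
    stop("malformed trendline '", text,
         "': expected '<number>-<number>' (e.g. '11-13')", call. = FALSE)
  }
  trendline(as.numeric(m[2]), as.numeric(m[3]))
}

#' Parse a comma-separated list of trendlines
#'
#' The conventional user input for iterative multipass processing: the desired
#' trendlines separated by commas, e.g. `"9-11, 21-23"`.
#'
#' @param text A single string of comma-separated hyphenated trendlines.
#' @return A list of [trendline()] objects (may contain duplicates; see
#'   [build_processing_plan()] which collapses them).
#' @export
parse_trendline_list <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0L) {
    stop("no trendlines found in '", text, "'", call. = FALSE)
  }
  lapply(parts, parse_trendline)
}

render_trendline <- function(t) {
  paste0(fmt_num(t$fwhm_start), "-", fmt_num(t$fwhm_end))
}

#' Folder tag for a trendline
#'
#' Per-trendline outputs are sorted into subfolders named after the trendline
#' with the hyphen replaced by an underscore (`11-13` becomes `"11_13"`);
#' single-pass output, processed with an auto-calculated trendline, always
#' lives under `"1_1"`.
#'
#' @param t A [trendline()] object.
#' @return A string such as `"11_13"`.
#' @export
folder_tag <- function(t) {
  stopifnot(inherits(t, "trendline"))
  paste0(fmt_num(t$fwhm_start), "_", fmt_num(t$fwhm_end))
}

#' Folder tag reserved for single-pass data
#' @return The string `"1_1"`.
#' @export
single_pass_tag <- function() "1_1"

#' Evaluate a trendline at a DT bin
#'
#' Linear interpolation between the two anchors (FWHM at DT bin 0 and 200).
#' DT bins outside \eqn{[0, 200]} are clamped to the nearest boundary: the
#' 200-push gated acquisition window bounds physically meaningful bins.
#'
#' @param t A [trendline()] object.
#' @param dt_bin Numeric vector of DT bins.
#' @return Drift FWHM (DT bins) at each `dt_bin`.
#' @export
fwhm_at <- function(t, dt_bin) {
  stopifnot(inherits(t, "trendline"), is.numeric(dt_bin), all(is.finite(dt_bin)))
  d <- pmin(pmax(dt_bin, 0), 200)
  t$fwhm_start + (t$fwhm_end - t$fwhm_start) * d / 200
}

#' Fit an auto-calculated trendline from observed (DT bin, FWHM) pairs
#'
#' Emulates the automatic trendline generation used for single-pass data: an
#' ordinary-least-squares line `fwhm = a + b * dt_bin` fitted to observed peak
#' widths, then evaluated at the anchor bins 0 and 200. Anchor values that come
#' out non-positive (possible with a steep negative slope) are clamped to
#' `floor`, keeping the result a valid smoothing width.
#'
#' @param points A data frame (or list convertible to one) with numeric
#'   columns `dt_bin` and `fwhm`.
#' @param floor Lower clamp for the fitted anchors, in DT bins. Default 1.0.
#' @return A [trendline()] object.
#' @export
fit_auto_trendline <- function(points, floor = 1.0) {
  points <- as.data.frame(points)
  stopifnot(all(c("dt_bin", "fwhm") %in% names(points)))
  if (nrow(points) < 2L || length(unique(points$dt_bin)) < 2L) {
    stop("degenerate fit: need at least 2 points with distinct DT bins",
         call. = FALSE)
  }
  fit <- stats::lm(fwhm ~ dt_bin, data = points)
  a <- unname(stats::coef(fit)[1])
  b <- unname(stats::coef(fit)[2])
  trendline(max(a, floor), max(a + 200 * b, floor))
}

#' Build an iterative processing plan over a set of trendlines
#'
#' Multipass data is processed once per user trendline, each run writing its
#' peptide-ID lists into a subfolder named by [folder_tag()]; single-pass data
#' is processed once with an auto-calculated trendline under the fixed tag
#' `"1_1"`. The plan records that layout. Duplicate trendlines are collapsed.
#'
#' @param trendline_texts Comma-separated trendline string, e.g. `"11-13,21-23"`.
#' @param single_pass_points Optional (DT bin, FWHM) observations used to fit
#'   the single-pass auto trendline via [fit_auto_trendline()]; if `NULL` the
#'   plan records the single-pass entry without a fitted line.
#' @return An object of class `processing_plan`: list with `multipass` (named
#'   list of trendlines, names = folder tags), `single_pass` (a trendline or
#'   `NULL`) and `tags` (all folder tags, multipass first then `"1_1"`).
#' @export
build_processing_plan <- function(trendline_texts, single_pass_points = NULL) {
  tls <- parse_trendline_list(trendline_texts)
  tags <- vapply(tls, folder_tag, character(1))
  keep <- !duplicated(tags)
  tls <- tls[keep]
  tags <- tags[keep]
  if (any(tags == single_pass_tag())) {
    stop("tag '1_1' is reserved for single-pass data", call. = FALSE)
  }
  names(tls) <- tags
  sp <- if (!is.null(single_pass_points)) fit_auto_trendline(single_pass_points)
  structure(list(multipass = tls,
                 single_pass = sp,
                 tags = c(tags, single_pass_tag())),
            class = "processing_plan")
}

#' @export
print.processing_plan <- function(x, ...) {
  cat("Processing plan:", length(x$multipass), "multipass trendline(s) + single-pass\n")
  for (tag in names(x$multipass)) {
    cat("  ", tag, " <- ", render_trendline(x$multipass[[tag]]), "\n", sep = "")
  }
  cat("  ", single_pass_tag(), " <- auto-calculated",
      if (!is.null(x$single_pass)) paste0(" (", render_trendline(x$single_pass), ")"),
      "\n", sep = "")
  invisible(x)
}
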