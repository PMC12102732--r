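# canonical peptide-ID table schema: column -> storage type
PEP_NUMERIC <- c("start", "end", "plgs_score", "rt", "dt_bin", "intensity",
                 "products_per_aa", "matched_products", "consecutive_products",
                 "sum_product_intensity", "mh_ppm_error")
PEP_CHARACTER <- c("protein_id", "sequence", "modification",
                   "replicate_id", "trendline_tag")
PEP_REQUIRED <- c("protein_id", "sequence", PEP_NUMERIC)

#' Canonical column names of a peptide-identification table
#'
#' The package's CSV dialect for per-replicate peptide-ID exports. Vendor
#' exports use other headers; map them with the `col_map` argument of
#' [read_peptide_table()].
#'
#' @return Character vector of canonical column names, in canonical order.
#' @export
peptide_columns <- function() c(PEP_CHARACTER[1:3], PEP_NUMERIC,
                                PEP_CHARACTER[4:5])

#' Default identity mapping from canonical to file column names
#'
#' A named character vector `canonical = file_column`; edit entries to adapt a
#' vendor export whose headers differ from [peptide_columns()].
#'
#' @return Named character vector.
#' @export
default_col_map <- function() stats::setNames(peptide_columns(), peptide_columns())

# identity key of a peptide: one peptide "sequence" for dedup purposes
peptide_key <- function(df) {
  paste(df$protein_id, df$sequence, df$modification, sep = "\r")
}

empty_peptide_table <- function() {
  cols <- c(lapply(stats::setNames(PEP_CHARACTER[1:3], PEP_CHARACTER[1:3]),
                   function(x) character(0)),
            lapply(stats::setNames(PEP_NUMERIC, PEP_NUMERIC),
                   function(x) numeric(0)),
            lapply(stats::setNames(PEP_CHARACTER[4:5], PEP_CHARACTER[4:5]),
                   function(x) character(0)))
  tibble::as_tibble(cols)
}

#' Read a per-replicate peptide-identification table
#'
#' Reads one replicate's peptide-ID list from CSV (UTF-8, comma-separated,
#' header row) into the canonical schema (see [peptide_columns()]). Required
#' columns are the identity and metric fields; `modification` defaults to the
#' empty string, `replicate_id` to the file stem, and `trendline_tag` to the
#' name of the file's parent folder — the per-trendline folder convention,
#' so a file under `.../11_13/rep2.csv` is tagged `"11_13"`.
#'
#' Rows are validated: numeric fields must parse, coordinates must satisfy
#' `end >= start` and `end - start + 1 == nchar(sequence)`, and when `fasta`
#' is supplied each sequence must match the protein at its coordinates.
#'
#' @param path Path to the CSV file.
#' @param col_map Named character vector mapping canonical names to the file's
#'   column names; defaults to [default_col_map()].
#' @param fasta Optional protein table from [read_fasta()] used to verify
#'   sequence/coordinate agreement.
#' @return A tibble with the canonical columns, one row per peptide ID.
#' @export
read_peptide_table <- function(path, col_map = default_col_map(), fasta = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  # translate file headers to canonical names
  stopifnot(is.character(col_map), !is.null(names(col_map)))
  have <- intersect(names(col_map), peptide_columns())
  rename_from <- col_map[have]
  present <- have[rename_from %in% names(raw)]
  missing_req <- setdiff(PEP_REQUIRED, present)
  if (length(missing_req) > 0L) {
    stop("peptide table ", basename(path), " is missing required column(s): ",
         paste(missing_req, collapse = ", "), call. = FALSE)
  }
  df <- raw[, unname(rename_from[present]), drop = FALSE]
  names(df) <- present

  # defaults inferred from the folder convention
  if (!"modification" %in% names(df)) df$modification <- ""
  df$modification[is.na(df$modification)] <- ""
  if (!"replicate_id" %in% names(df)) {
    df$replicate_id <- sub("\\.[^.]*$", "", basename(path))
  }
  if (!"trendline_tag" %in% names(df)) {
    df$trendline_tag <- basename(dirname(normalizePath(path, mustWork = FALSE)))
  }

  # numeric parsing with row-level diagnostics
  for (col in PEP_NUMERIC) {
    parsed <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(parsed) & !is.na(df[[col]]))
    bad <- c(bad, which(is.na(df[[col]])))
    if (length(bad) > 0L) {
      stop("non-numeric value in column '", col, "' of ", basename(path),
           " at data row(s) ", paste(sort(unique(bad)), collapse = ", "),
           call. = FALSE)
    }
    df[[col]] <- parsed
  }
  df$sequence <- toupper(df$sequence)
  validate_peptides(df, fasta = fasta, context = basename(path))
  df <- df[, peptide_columns(), drop = FALSE]
  tibble::as_tibble(df)
}

validate_peptides <- function(df, fasta = NULL, context = "peptide table") {
  n <- nrow(df)
  if (n == 0L) return(invisible(df))
  bad_coord <- which(df$end < df$start)
  if (length(bad_coord) > 0L) {
    stop(context, ": end < start at row(s) ",
         paste(bad_coord, collapse = ", "), call. = FALSE)
  }
  len_mismatch <- which(df$end - df$start + 1 != nchar(df$sequence))
  if (length(len_mismatch) > 0L) {
    r <- len_mismatch[1]
    stop(context, ": sequence length mismatch at row ", r, " ('", df$sequence[r],
         "' has ", nchar(df$sequence[r]), " residues but start/end span ",
         df$end[r] - df$start[r] + 1, ")", call. = FALSE)
  }
  if (any(df$dt_bin < 0 | df$dt_bin > 200)) {
    stop(context, ": dt_bin outside [0, 200]", call. = FALSE)
  }
  if (!is.null(fasta)) {
    idx <- match(df$protein_id, fasta$protein_id)
    known <- !is.na(idx)
    if (any(known)) {
      ref <- substr(fasta$sequence[idx[known]], df$start[known], df$end[known])
      off <- which(ref != df$sequence[known])
      if (length(off) > 0L) {
        r <- which(known)[off[1]]
        stop(context, ": sequence '", df$sequence[r],
             "' does not match protein ", df$protein_id[r],
             " at [", df$start[r], ", ", df$end[r], "]", call. = FALSE)
      }
    }
  }
  invisible(df)
}

#' Read target protein sequences from FASTA
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `protein_id` (first whitespace-delimited
#'   token of the header), `sequence` (uppercased, whitespace-free) and
#'   `length`, one row per entry in file order.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  ids <- vapply(strsplit(trimws(names(aa)), "\\s+"), `[`, character(1), 1)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA IDs: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  seqs <- unname(toupper(gsub("\\s", "", as.character(aa))))
  tibble::tibble(protein_id = ids, sequence = seqs, length = nchar(seqs))
}

#' Write the final merged peptide list
#'
#' Writes a merged/filtered peptide list as CSV into `out_dir` with an
#' ISO-8601 basic timestamp (`YYYYMMDDThhmmss`) embedded in the filename, the
#' convention for the final list saved at the end of a merge-and-filter run.
#'
#' @param peptides A merged-peptide tibble (see [merge_replicates()]).
#' @param out_dir Directory to write into; must exist and be writable.
#' @param prefix Filename prefix, default `"final_peptide_list"`.
#' @return The path of the written file, invisibly-visible (returned).
#' @export
write_final_list <- function(peptides, out_dir, prefix = "final_peptide_list") {
  if (!dir.exists(out_dir)) stop("not a directory: ", out_dir, call. = FALSE)
  stamp <- format(Sys.time(), "%Y%m%dT%H%M%S")
  path <- file.path(out_dir, paste0(prefix, "_", stamp, ".csv"))
  readr::write_csv(peptides, path, progress = FALSE)
  path
}
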