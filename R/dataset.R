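#' Build an activity dataset of fixed-length sequence fragments
#'
#' Couples mature miRNA sequences with a per-sequence activity value
#' (ln-abundance, ln-affinity, or any real measurement) and extracts the
#' fixed-length analysis fragment of each sequence (see
#' [extract_fragment()] for the capitals convention).
#'
#' @param ids Character vector of unique record ids.
#' @param sequences Character vector of raw sequences (case meaningful).
#' @param activity Numeric vector of activities, same length.
#' @param fragment_length Analysis window length `L` (>= 4). When `NULL`,
#'   inferred as the common uppercase-run length of the inputs.
#' @param label Free-text provenance label.
#' @param extra Optional data.frame of per-record annotations (e.g. the
#'   Ago2/Ago3 affinity pairs of the human training table).
#' @return An object of class `activity_dataset`: a list with `id`, `raw`,
#'   `fragment`, `fragment_offset`, `activity`, `fragment_length`, `label`
#'   and `extra`.
#' @export
activity_dataset <- function(ids, sequences, activity, fragment_length = NULL,
                             label = "", extra = NULL) {
  n <- length(ids)
  if (length(sequences) != n || length(activity) != n)
    stop("ids, sequences and activity must have equal length", call. = FALSE)
  if (n < 2L) stop("an activity dataset needs at least 2 records", call. = FALSE)
  if (anyDuplicated(ids))
    stop("duplicate ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  if (!is.numeric(activity) || anyNA(activity) || any(!is.finite(activity)))
    stop("activity values must all be finite numbers", call. = FALSE)
  if (is.null(fragment_length)) {
    runs <- vapply(sequences, function(s) {
      ns <- normalize_sequence(s)
      if (any(ns$lowercase) && !all(ns$lowercase)) {
        r <- rle(!ns$lowercase)
        max(r$lengths[r$values])
      } else nchar(ns$sequence)
    }, integer(1))
    fragment_length <- min(runs)
  }
  fragment_length <- as.integer(fragment_length)
  if (fragment_length < 4L) stop("fragment_length must be >= 4", call. = FALSE)
  recs <- lapply(seq_len(n), function(i)
    extract_fragment(sequences[i], fragment_length, id = ids[i]))
  structure(
    list(
      id = as.character(ids),
      raw = vapply(recs, `[[`, character(1), "raw"),
      fragment = vapply(recs, `[[`, character(1), "fragment"),
      fragment_offset = vapply(recs, `[[`, integer(1), "fragment_offset"),
      activity = as.numeric(activity),
      fragment_length = fragment_length,
      label = label,
      extra = extra
    ),
    class = "activity_dataset"
  )
}

#' @export
print.activity_dataset <- function(x, ...) {
  cat("<activity_dataset> ", length(x$id), " records, fragment length ",
      x$fragment_length, if (nzchar(x$label)) paste0("  [", x$label, "]"), "\n",
      sep = "")
  cat("  activity range: [", format(min(x$activity)), ", ",
      format(max(x$activity)), "]\n", sep = "")
  invisible(x)
}

#' @export
length.activity_dataset <- function(x) length(x$id)

#' Read sequences from a FASTA file
#'
#' @param path Path to a plain FASTA file (single-line or wrapped records).
#'   Case is preserved so the capitals fragment convention survives I/O.
#' @return A data.frame with columns `id` and `sequence`, in file order.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  data.frame(id = ids, sequence = as.character(set),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write sequences to a FASTA file
#'
#' @param ids,sequences Parallel character vectors.
#' @param path Output path.
#' @export
write_fasta <- function(ids, sequences, path) {
  set <- Biostrings::BStringSet(sequences)
  names(set) <- ids
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read / write activity tables (TSV)
#'
#' Activity tables are UTF-8 tab-separated files with header columns
#' `id`, `sequence`, `activity`; extra columns are carried along in
#' `$extra`. Writing then re-reading is the identity on
#' (id, sequence, activity) with activities kept to 6 decimals.
#'
#' @param path TSV path.
#' @param fragment_length Passed to [activity_dataset()].
#' @param label Provenance label for the returned dataset.
#' @return [read_activity_tsv()] returns an `activity_dataset`.
#' @export
read_activity_tsv <- function(path, fragment_length = NULL, label = basename(path)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  need <- c("id", "sequence", "activity")
  if (!all(need %in% names(df)))
    stop("activity TSV must have header columns id, sequence, activity", call. = FALSE)
  act <- suppressWarnings(as.numeric(df$activity))
  if (anyNA(act)) {
    bad <- which(is.na(act))[1L]
    stop("non-numeric activity '", df$activity[bad], "' in row ", bad,
         " (id '", df$id[bad], "')", call. = FALSE)
  }
  extra_cols <- setdiff(names(df), need)
  extra <- if (length(extra_cols)) {
    e <- df[extra_cols]
    for (cc in extra_cols) {
      v <- suppressWarnings(as.numeric(e[[cc]]))
      if (!anyNA(v)) e[[cc]] <- v
    }
    e
  } else NULL
  activity_dataset(df$id, df$sequence, act, fragment_length = fragment_length,
                   label = label, extra = extra)
}

#' @param ds An `activity_dataset`.
#' @rdname read_activity_tsv
#' @export
write_activity_tsv <- function(ds, path) {
  stopifnot(inherits(ds, "activity_dataset"))
  df <- data.frame(id = ds$id, sequence = ds$raw,
                   activity = formatC(ds$activity, digits = 6, format = "f"),
                   stringsAsFactors = FALSE)
  if (!is.null(ds$extra)) df <- cbind(df, ds$extra)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Packaged training tables
#'
#' `load_table1()` returns the Arabidopsis training set: 17 mature miRNA
#' 20-nt fragments with ln-abundance activities and the two published
#' feature columns (`wrhw_f1`, `dryd_f2`). `load_table2()` returns the
#' human Argonaute training set: 12 miRNA 22-nt fragments with ln-affinities
#' for Ago2 (`x2`) and Ago3 (`x3`), their half-sum `sigma` and
#' half-difference `delta`, and the published feature columns (`rhhk_f3`,
#' `yrhb_f4`). Values carry the 2-decimal precision of the source tables;
#' the published feature columns are data (their exact weight profiles were
#' never disclosed), not quantities this package recomputes.
#'
#' @return An `activity_dataset`; the annotation columns are in `$extra`.
#' @examples
#' length(load_table1())          # 17
#' load_table2()$extra$x2[1]      # 7.81
#' @export
load_table1 <- function() {
  suppressWarnings(read_activity_tsv(
    system.file("extdata", "table1_arabidopsis.tsv", package = "tetractivity",
                mustWork = TRUE),
    fragment_length = 20L, label = "arabidopsis ln-abundance training set"
  ))
}

#' @rdname load_table1
#' @export
load_table2 <- function() {
  df <- utils::read.delim(
    system.file("extdata", "table2_human_ago.tsv", package = "tetractivity",
                mustWork = TRUE),
    stringsAsFactors = FALSE
  )
  # the dataset's working activity is Delta (the Ago2-vs-Ago3 preference);
  # Sigma and the raw affinities stay available as annotations
  activity_dataset(df$id, df$sequence, df$delta, fragment_length = 22L,
                   label = "human Ago2/Ago3 ln-affinity training set",
                   extra = df[c("x2", "x3", "delta", "rhhk_f3", "sigma", "yrhb_f4")])
}

#' Half-sum and half-difference of Ago2/Ago3 ln-affinities
#'
#' `sigma = (x2 + x3) / 2` summarizes overall Argonaute loading;
#' `delta = (x2 - x3) / 2` is the Ago2-vs-Ago3 preference (positive means
#' Ago2). The map is an exact bijection: `x2 = sigma + delta`,
#' `x3 = sigma - delta`.
#'
#' @param x2,x3 Numeric vectors of ln-affinities for Ago2 and Ago3.
#' @return A data.frame with columns `sigma` and `delta`.
#' @examples
#' sigma_delta(7.81, 4.85)  # sigma 6.33, delta 1.48
#' @export
sigma_delta <- function(x2, x3) {
  if (!is.numeric(x2) || !is.numeric(x3) || any(!is.finite(c(x2, x3))))
    stop("x2 and x3 must be finite numerics", call. = FALSE)
  data.frame(sigma = (x2 + x3) / 2, delta = (x2 - x3) / 2)
}
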