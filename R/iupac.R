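#' IUPAC degenerate nucleotide codes (RNA alphabet)
#'
#' The 15 non-gap IUPAC nucleotide codes, each naming a non-empty subset of
#' \{A, U, G, C\}. A degenerate tetranucleotide is any string of four such
#' codes, giving 15^4 = 50625 distinct patterns.
#'
#' @return Named list mapping each code to its character vector of concrete
#'   bases, e.g. `R` -> `c("A","G")`.
#' @examples
#' iupac_codes()[["H"]]   # A, C, U
#' @export
iupac_codes <- function() {
  list(
    A = "A", C = "C", G = "G", U = "U",
    W = c("A", "U"), S = c("C", "G"),
    M = c("A", "C"), K = c("G", "U"),
    R = c("A", "G"), Y = c("C", "U"),
    B = c("C", "G", "U"), D = c("A", "G", "U"),
    H = c("A", "C", "U"), V = c("A", "C", "G"),
    N = c("A", "C", "G", "U")
  )
}

# base -> integer encoding used throughout: A=0, C=1, G=2, U=3
.base_order <- c("A", "C", "G", "U")

# 15 x 4 logical membership matrix: row = IUPAC code, col = concrete base
.iupac_membership <- local({
  codes <- iupac_codes()
  m <- matrix(FALSE, length(codes), 4, dimnames = list(names(codes), .base_order))
  for (nm in names(codes)) m[nm, codes[[nm]]] <- TRUE
  m
})

.check_tetra <- function(tetra) {
  if (!is.character(tetra) || length(tetra) != 1L || is.na(tetra))
    stop("degenerate tetranucleotide must be a single string", call. = FALSE)
  tetra <- toupper(chartr("T", "U", tetra))
  if (nchar(tetra) != 4L)
    stop("degenerate tetranucleotide must have exactly 4 codes, got '", tetra, "'", call. = FALSE)
  cs <- strsplit(tetra, "", fixed = TRUE)[[1L]]
  bad <- !(cs %in% rownames(.iupac_membership))
  if (any(bad))
    stop("invalid IUPAC code(s) in '", tetra, "': ", paste(cs[bad], collapse = ", "),
         call. = FALSE)
  tetra
}

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases the sequence, maps T to U (DNA-alphabet input, e.g. miRBase,
#' is accepted silently), and records which input positions were lowercase.
#' Lowercase marks trimmed flanks in the packaged training tables: the
#' fixed-length analysis fragment is the run typed in capitals, so the case
#' mask is returned separately for [extract_fragment()].
#'
#' @param text A single nucleotide string over `A,C,G,T,U` in either case.
#' @return A list with `sequence` (uppercase RNA string) and `lowercase`
#'   (logical vector flagging positions that were lowercase in the input).
#' @examples
#' normalize_sequence("uCUCA")$lowercase
#' normalize_sequence("acgt")$sequence   # "ACGU"
#' @export
normalize_sequence <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("sequence must be a single non-empty string", call. = FALSE)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  up <- toupper(chars)
  ok <- up %in% c("A", "C", "G", "T", "U")
  if (!all(ok)) {
    pos <- which(!ok)[1L]
    stop("invalid character '", chars[pos], "' at position ", pos,
         " (alphabet is A, C, G, T, U)", call. = FALSE)
  }
  list(
    sequence = paste(chartr("T", "U", up), collapse = ""),
    lowercase = chars != up
  )
}

#' Extract the fixed-length analysis fragment of a sequence
#'
#' Follows the capitals convention of the training tables: when the input
#' mixes cases, the fragment is the longest run of uppercase positions
#' (trimmed flanks are typed in lowercase). All-uppercase input falls back
#' to the leading window of `target_length` bases, with a warning when the
#' sequence is longer than the window.
#'
#' @param text Raw nucleotide string (case-sensitive; see
#'   [normalize_sequence()]).
#' @param target_length Required fragment length (>= 4).
#' @param id Optional record id used in messages.
#' @return A list (`sequence_record`) with `id`, `raw` (full normalized RNA
#'   string), `fragment`, and `fragment_offset` (1-based start of the
#'   fragment within `raw`).
#' @examples
#' extract_fragment("UUGACAGAAGAUAGAGAGCAc", 20)$fragment_offset  # 1
#' extract_fragment("uAUGACACGAUCACUCCCGUUGA", 22)$fragment_offset  # 2
#' @export
extract_fragment <- function(text, target_length, id = NA_character_) {
  target_length <- as.integer(target_length)
  if (is.na(target_length) || target_length < 4L)
    stop("target_length must be an integer >= 4", call. = FALSE)
  ns <- normalize_sequence(text)
  n <- nchar(ns$sequence)
  who <- if (is.na(id)) "" else paste0(" for '", id, "'")
  if (any(ns$lowercase) && !all(ns$lowercase)) {
    r <- rle(!ns$lowercase)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    run_start <- starts[best]
    run_len <- r$lengths[best]
    if (run_len < target_length)
      stop("uppercase run of length ", run_len, " is shorter than the target fragment length ",
           target_length, who, call. = FALSE)
    if (run_len > target_length)
      warning("uppercase run longer than target", who,
              "; using its first ", target_length, " bases", call. = FALSE)
    offset <- run_start
  } else {
    if (n < target_length)
      stop("sequence of length ", n, " is shorter than the target fragment length ",
           target_length, who, call. = FALSE)
    if (n > target_length)
      warning("no case information", who,
              "; using the leading ", target_length, " bases", call. = FALSE)
    offset <- 1L
  }
  structure(
    list(
      id = id,
      raw = ns$sequence,
      fragment = substr(ns$sequence, offset, offset + target_length - 1L),
      fragment_offset = offset
    ),
    class = "sequence_record"
  )
}

#' Expand a degenerate tetranucleotide to its concrete matches
#'
#' @param tetra A 4-character string of IUPAC codes, e.g. `"RHHK"`.
#' @return Character vector of all concrete tetranucleotides over
#'   \{A,U,G,C\} matched by the pattern (the Cartesian product of the four
#'   codes' base sets).
#' @examples
#' length(expand_degenerate("RHHK"))  # 2*3*3*2 = 36
#' expand_degenerate("AUGC")          # "AUGC"
#' @export
expand_degenerate <- function(tetra) {
  tetra <- .check_tetra(tetra)
  sets <- iupac_codes()[strsplit(tetra, "", fixed = TRUE)[[1L]]]
  g <- expand.grid(b4 = sets[[4L]], b3 = sets[[3L]], b2 = sets[[2L]],
                   b1 = sets[[1L]], stringsAsFactors = FALSE)
  sort(paste0(g$b1, g$b2, g$b3, g$b4))
}

#' Number of concrete tetranucleotides matched by a degenerate pattern
#'
#' @param tetra Character vector of 4-code IUPAC patterns.
#' @return Integer vector of expansion sizes (product of the per-position
#'   code set sizes); used as the specificity tie-break in ranking.
#' @export
degeneracy <- function(tetra) {
  sizes <- rowSums(.iupac_membership)
  vapply(tetra, function(t) {
    t <- .check_tetra(t)
    prod(sizes[strsplit(t, "", fixed = TRUE)[[1L]]])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Test concrete 4-base windows against a degenerate tetranucleotide
#'
#' Position-wise membership test, equivalent to membership of the window in
#' [expand_degenerate()]'s set.
#'
#' @param window Character vector of concrete 4-base windows (A/U/G/C; T
#'   accepted and read as U).
#' @param tetra A single degenerate tetranucleotide pattern.
#' @return Logical vector, one entry per window.
#' @examples
#' tetra_matches(c("AGAA", "UGAC"), "WRHW")  # TRUE, FALSE
#' @export
tetra_matches <- function(window, tetra) {
  tetra <- .check_tetra(tetra)
  codes <- strsplit(tetra, "", fixed = TRUE)[[1L]]
  vapply(window, function(w) {
    w <- toupper(chartr("T", "U", w))
    if (nchar(w) != 4L) stop("window must have exactly 4 bases", call. = FALSE)
    bs <- strsplit(w, "", fixed = TRUE)[[1L]]
    if (!all(bs %in% .base_order)) stop("window must be concrete A/U/G/C", call. = FALSE)
    all(.iupac_membership[cbind(codes, bs)])
  }, logical(1), USE.NAMES = FALSE)
}

#' All 50625 degenerate tetranucleotides
#'
#' @return Character vector of every 4-code combination of the 15 IUPAC
#'   codes, in a fixed lexicographic-by-position order.
#' @export
tetra_space <- function() {
  codes <- names(iupac_codes())
  g <- expand.grid(z4 = codes, z3 = codes, z2 = codes, z1 = codes,
                   stringsAsFactors = FALSE)
  paste0(g$z1, g$z2, g$z3, g$z4)
}
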