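# Position-weighted degenerate tetranucleotide features.
#
# The core quantity is, for a fragment xi_1..xi_L and pattern z1z2z3z4,
#   [z1z2z3z4]_F = sum_{i=1}^{L-3} 1[xi_i..xi_{i+3} matches z1z2z3z4] * F(i),
# i.e. every start position contributes its weight whenever the (possibly
# overlapping) window matches; no overlap exclusion.

# integer codes 1..256 of the windows of a fragment (A=0,C=1,G=2,U=3)
.encode_windows <- function(fragment) {
  b <- match(strsplit(chartr("T", "U", toupper(fragment)), "", fixed = TRUE)[[1L]],
             .base_order) - 1L
  if (anyNA(b)) stop("fragment must be concrete A/C/G/U", call. = FALSE)
  n <- length(b)
  if (n < 4L) stop("fragment shorter than 4 bases", call. = FALSE)
  i <- seq_len(n - 3L)
  b[i] * 64L + b[i + 1L] * 16L + b[i + 2L] * 4L + b[i + 3L] + 1L
}

# logical 256-vector: which concrete window codes match the pattern
.window_index <- local({
  idx <- 0:255
  list(
    b1 = idx %/% 64L + 1L,
    b2 = idx %/% 16L %% 4L + 1L,
    b3 = idx %/% 4L %% 4L + 1L,
    b4 = idx %% 4L + 1L
  )
})

.tetra_mask <- function(tetra) {
  tetra <- .check_tetra(tetra)
  codes <- strsplit(tetra, "", fixed = TRUE)[[1L]]
  m <- .iupac_membership
  m[codes[1L], .window_index$b1] & m[codes[2L], .window_index$b2] &
    m[codes[3L], .window_index$b3] & m[codes[4L], .window_index$b4]
}

.profile_values <- function(profile, P) {
  v <- if (inherits(profile, "weight_profile")) profile$values else as.numeric(profile)
  if (length(v) != P)
    stop("profile length ", length(v), " does not match the ", P,
         " tetranucleotide start positions", call. = FALSE)
  if (any(v < 0 | v > 1)) stop("profile weights must lie in [0, 1]", call. = FALSE)
  v
}

#' Weighted abundance of a degenerate tetranucleotide in one fragment
#'
#' Sums the position weight `F(i)` over every start position `i` whose
#' 4-base window matches the degenerate pattern; overlapping matches each
#' contribute. The value lies in `[0, L - 3]`.
#'
#' @param fragment Concrete RNA fragment (A/C/G/U).
#' @param tetra Degenerate tetranucleotide pattern, e.g. `"WRHW"`.
#' @param profile A `weight_profile` or bare numeric weight vector of
#'   length `nchar(fragment) - 3`, values in `[0, 1]`.
#' @return A single numeric feature value.
#' @examples
#' feature_value("UGACAGAAGAGAGUGAGCAC", "WRHW", flat_profile(17))  # 2
#' @export
feature_value <- function(fragment, tetra, profile) {
  codes <- .encode_windows(fragment)
  F <- .profile_values(profile, length(codes))
  sum(F[.tetra_mask(tetra)[codes]])
}

#' Feature matrix of a dataset over a set of feature variants
#'
#' A feature variant is a (degenerate tetranucleotide, weight profile)
#' pair. Computation goes through per-position window-code indexing so
#' that large variant sets (up to the full 360 x 50625 library on a few
#' dozen sequences) stay tractable.
#'
#' @param ds An `activity_dataset`.
#' @param tetras Character vector of degenerate tetranucleotides.
#' @param profiles A `profile_library`, a single `weight_profile`, or a
#'   `P x K` numeric matrix of weight columns.
#' @return Numeric matrix, `length(ds)` rows x (`length(tetras) * K`)
#'   columns named `"<tetra>:<k>"`, tetra-major; attribute `variants` is a
#'   data.frame mapping columns to (tetra, profile index).
#' @export
feature_matrix <- function(ds, tetras, profiles) {
  stopifnot(inherits(ds, "activity_dataset"))
  P <- ds$fragment_length - 3L
  W <- .profile_matrix(profiles, P)
  K <- ncol(W)
  codes <- t(vapply(ds$fragment, .encode_windows, integer(P), USE.NAMES = FALSE))
  n <- length(ds$id)
  out <- matrix(NA_real_, n, length(tetras) * K)
  vt <- character(ncol(out)); vp <- integer(ncol(out))
  for (j in seq_along(tetras)) {
    B <- matrix(as.numeric(.tetra_mask(tetras[j])[codes]), n, P)
    cols <- (j - 1L) * K + seq_len(K)
    out[, cols] <- B %*% W
    vt[cols] <- tetras[j]; vp[cols] <- seq_len(K)
  }
  colnames(out) <- paste0(vt, ":", vp)
  rownames(out) <- ds$id
  attr(out, "variants") <- data.frame(tetra = vt, profile = vp,
                                      stringsAsFactors = FALSE)
  out
}

# normalize a profiles argument to a P x K matrix
.profile_matrix <- function(profiles, P) {
  if (inherits(profiles, "profile_library")) {
    if (profiles$P != P)
      stop("profile library P = ", profiles$P, " does not match dataset (", P, ")",
           call. = FALSE)
    profiles$values
  } else if (inherits(profiles, "weight_profile")) {
    matrix(.profile_values(profiles, P), ncol = 1L)
  } else if (is.matrix(profiles)) {
    if (nrow(profiles) != P) stop("profile matrix must have ", P, " rows", call. = FALSE)
    profiles
  } else {
    matrix(.profile_values(profiles, P), ncol = 1L)
  }
}
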