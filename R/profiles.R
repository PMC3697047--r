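#' Relative tetranucleotide start positions
#'
#' A fragment of length `L` has `P = L - 3` tetranucleotide start positions.
#' Profiles are parameterized on the unit interval, so position `i` maps to
#' `t(i) = (i - 1) / (P - 1)`; the degenerate case `P = 1` maps to 0.5.
#'
#' @param L Fragment length (>= 5 for the standard case; L = 4 gives the
#'   single-window degenerate case).
#' @return Numeric vector of length `P` spanning `[0, 1]`.
#' @export
relative_positions <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < 4L) stop("fragment length must be >= 4", call. = FALSE)
  P <- L - 3L
  if (P == 1L) return(0.5)
  (seq_len(P) - 1) / (P - 1)
}

.profile_centers <- seq(0.1, 0.9, by = 0.1)
.profile_widths <- c(0.02, 0.05, 0.1, 0.2, 0.4)
.profile_floors <- c(0, 0.25)

.check_profile_params <- function(c, w, floor, orientation, allowed) {
  if (!isTRUE(any(abs(.profile_centers - c) < 1e-9)))
    stop("center must be one of ", paste(.profile_centers, collapse = ", "), call. = FALSE)
  if (!isTRUE(any(abs(.profile_widths - w) < 1e-9)))
    stop("width must be one of ", paste(.profile_widths, collapse = ", "), call. = FALSE)
  if (!isTRUE(any(abs(.profile_floors - floor) < 1e-9)))
    stop("floor must be one of ", paste(.profile_floors, collapse = ", "), call. = FALSE)
  match.arg(orientation, allowed)
}

.new_profile <- function(family, c, w, orientation, floor, values) {
  structure(
    list(family = family, center = c, width = w, orientation = orientation,
         floor = floor, values = values),
    class = "weight_profile"
  )
}

#' @export
print.weight_profile <- function(x, ...) {
  cat("<weight_profile> family=", x$family,
      if (x$family != "FLAT")
        paste0(" c=", x$center, " w=", x$width, " orientation=", x$orientation,
               " floor=", x$floor),
      "  P=", length(x$values), "\n", sep = "")
  invisible(x)
}

#' S-shaped position-weight profile
#'
#' A max-normalized logistic ramp over relative position: weight rises
#' (`orientation = "up"`) or falls (`"down"`) through the center `c` with
#' steepness set by `w`. S profiles with `c` near 1 concentrate weight at
#' the 3'-end of the miRNA, the shape family behind the published
#' 3'-end-weighted features.
#'
#' @param c Center, on the grid `0.1 ... 0.9`.
#' @param w Width, one of `0.02, 0.05, 0.1, 0.2, 0.4`.
#' @param orientation `"up"` or `"down"`.
#' @param floor Baseline weight before normalization, `0` or `0.25`.
#' @param P Number of tetranucleotide start positions (`L - 3`).
#' @return A `weight_profile` with `values` in `[0, 1]` and `max = 1`.
#' @export
s_profile <- function(c, w, orientation = c("up", "down"), floor = 0, P) {
  orientation <- .check_profile_params(c, w, floor, orientation, c("up", "down"))
  t <- relative_positions(P + 3L)
  s <- if (orientation == "up") 1 else -1
  raw <- floor + (1 - floor) * stats::plogis(s * (t - c) / w)
  .new_profile("S", c, w, orientation, floor, raw / max(raw))
}

#' U-shaped (bell / valley) position-weight profile
#'
#' A max-normalized Gaussian bump over relative position
#' (`orientation = "peak"`), or its pointwise 1-complement before
#' renormalization (`"valley"`). Peak profiles with `c = 0.5` weight the
#' center of the miRNA, the shape family behind the published
#' center-weighted features.
#'
#' @inheritParams s_profile
#' @param orientation `"peak"` or `"valley"`.
#' @return A `weight_profile` with `values` in `[0, 1]` and `max = 1`.
#' @export
u_profile <- function(c, w, orientation = c("peak", "valley"), floor = 0, P) {
  orientation <- .check_profile_params(c, w, floor, orientation, c("peak", "valley"))
  t <- relative_positions(P + 3L)
  raw <- floor + (1 - floor) * exp(-((t - c) / w)^2)
  if (orientation == "valley") raw <- 1 - raw
  if (max(raw) <= 0) raw[] <- 1  # valley of a flat peak degenerates to flat
  .new_profile("U", c, w, orientation, floor, raw / max(raw))
}

#' Flat position-weight profile
#'
#' `F(i) = 1` everywhere: with it the weighted tetranucleotide abundance
#' reduces to a plain (overlapping) motif count. Kept outside the built-in
#' library of 360, mainly for diagnostics and tests.
#'
#' @param P Number of tetranucleotide start positions.
#' @export
flat_profile <- function(P) {
  .new_profile("FLAT", NA_real_, NA_real_, "flat", 0, rep(1, P))
}

#' The built-in library of 360 position-weight profiles
#'
#' 180 U-shaped and 180 S-shaped deterministic profiles: each family runs a
#' 9-center x 5-width x 2-orientation x 2-floor grid. Together with the
#' 15^4 degenerate tetranucleotides the library spans
#' 360 x 50625 = 18,225,000 feature variants. The functional forms and
#' grids are this package's parameterization of the published counts of
#' curve shapes; an optional flat profile can be prepended (profile id 0)
#' for diagnostics.
#'
#' @param L Fragment length; profiles have `P = L - 3` values.
#' @param include_flat Prepend the flat profile as id 0.
#' @return An object of class `profile_library`: list with `L`, `P`,
#'   `meta` (data.frame: profile_id, family, center, width, orientation,
#'   floor) and `values` (`P x nrow(meta)` matrix, columns in meta order).
#' @examples
#' lib <- builtin_profiles(20)
#' table(lib$meta$family)   # 180 S, 180 U
#' @export
builtin_profiles <- function(L, include_flat = FALSE) {
  L <- as.integer(L)
  if (L < 5L) stop("fragment length must be >= 5", call. = FALSE)
  P <- L - 3L
  grids <- expand.grid(
    floor = .profile_floors,
    orientation_i = 1:2,
    width = .profile_widths,
    center = .profile_centers,
    family = c("U", "S"),
    stringsAsFactors = FALSE
  )
  grids$orientation <- ifelse(grids$family == "S",
                              c("up", "down")[grids$orientation_i],
                              c("peak", "valley")[grids$orientation_i])
  # deterministic ordering: family, center, width, orientation, floor
  ord <- order(grids$family, grids$center, grids$width, grids$orientation,
               grids$floor)
  grids <- grids[ord, c("family", "center", "width", "orientation", "floor")]
  rownames(grids) <- NULL
  vals <- vapply(seq_len(nrow(grids)), function(k) {
    g <- grids[k, ]
    if (g$family == "S")
      s_profile(g$center, g$width, g$orientation, g$floor, P)$values
    else
      u_profile(g$center, g$width, g$orientation, g$floor, P)$values
  }, numeric(P))
  vals <- matrix(vals, nrow = P)
  grids$profile_id <- seq_len(nrow(grids))
  if (include_flat) {
    grids <- rbind(
      data.frame(family = "FLAT", center = NA_real_, width = NA_real_,
                 orientation = "flat", floor = 0, profile_id = 0L),
      grids
    )
    vals <- cbind(rep(1, P), vals)
  }
  grids <- grids[c("profile_id", "family", "center", "width", "orientation", "floor")]
  structure(list(L = L, P = P, meta = grids, values = vals),
            class = "profile_library")
}

#' @export
print.profile_library <- function(x, ...) {
  cat("<profile_library> ", ncol(x$values), " profiles (",
      paste(names(table(x$meta$family)), table(x$meta$family),
            sep = ":", collapse = ", "),
      "), P = ", x$P, "\n", sep = "")
  invisible(x)
}

#' Export a profile library as a TSV audit table
#'
#' @param lib A `profile_library`.
#' @param path Output path.
#' @export
write_profiles_tsv <- function(lib, path) {
  stopifnot(inherits(lib, "profile_library"))
  w <- t(lib$values)
  colnames(w) <- paste0("F", seq_len(lib$P))
  utils::write.table(cbind(lib$meta, as.data.frame(w)), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
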