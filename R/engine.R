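# Search engine: utility mapping of significance levels, the 7 data
# subsets, the 77-test aggregate score Xi, staged search over the feature
# variant space, and permutation verification of the best variant.

#' Utility of a significance level
#'
#' Monotone piecewise log-linear map of a test's significance level alpha
#' to a utility, zero at the alpha = 0.05 reference. For correlation tests
#' (`"favourable"`) significance earns positive utility (saturating at +1
#' for alpha <= 1e-6) and non-significance negative utility (saturating at
#' -1 at alpha = 1). The applicability diagnostics (`"unfavourable"`) are
#' penalty-only: a significant departure from a regression assumption
#' costs up to -1, while a passed check contributes 0 rather than a
#' reward. This keeps a positive aggregate score equivalent to "many
#' correlation tests genuinely significant", so the engine's usefulness
#' gate rejects chance-level best variants instead of crediting them for
#' merely having well-behaved residuals.
#'
#' @param alpha Significance level(s) in `[1e-10, 1]`.
#' @param direction `"favourable"` (correlation tests) or `"unfavourable"`
#'   (applicability departure tests).
#' @return Numeric utility in `[-1, 1]`.
#' @examples
#' utility(0.05)    # 0
#' utility(1e-6)    # 1
#' utility(1)       # -1
#' @export
utility <- function(alpha, direction = c("favourable", "unfavourable")) {
  direction <- match.arg(direction)
  if (any(!is.finite(alpha)) || any(alpha < .ALPHA_FLOOR - 1e-15) || any(alpha > 1))
    stop("alpha must lie in [1e-10, 1]", call. = FALSE)
  u <- ifelse(
    alpha <= 0.05,
    pmin(1, log10(0.05 / alpha) / log10(0.05 / 1e-6)),
    -pmin(1, log10(alpha / 0.05) / log10(1 / 0.05))
  )
  if (direction == "unfavourable") pmin(0, -u) else u
}

#' The seven data subsets scored by the engine
#'
#' Subset 1 is the entire dataset; subsets 2-7 each keep `ceiling(n / 2)`
#' records: (2) lowest feature values, (3) highest feature values,
#' (4) closest to the feature mean, (5) lowest activities, (6) highest
#' activities, (7) closest to the activity mean. Ties in the sort are
#' broken by record index. Scoring the same feature on systematically
#' varied halves of the data is what makes the aggregate robust to any
#' single influential subset.
#'
#' @param ds An `activity_dataset` (or bare numeric activity vector).
#' @param f Feature vector, same length, `n >= 6`.
#' @return List of 7 integer index vectors named `all`, `low_f`, `high_f`,
#'   `mid_f`, `low_x`, `high_x`, `mid_x`.
#' @export
make_subsets <- function(ds, f) {
  x <- if (inherits(ds, "activity_dataset")) ds$activity else as.numeric(ds)
  n <- length(x)
  if (length(f) != n) stop("feature vector length must match the dataset", call. = FALSE)
  if (n < 6L) stop("need at least 6 records for half-splits", call. = FALSE)
  h <- ceiling(n / 2)
  idx <- seq_len(n)
  take <- function(key) sort(order(key, idx)[seq_len(h)])
  list(
    all = idx,
    low_f = take(f), high_f = take(-f), mid_f = take(abs(f - mean(f))),
    low_x = take(x), high_x = take(-x), mid_x = take(abs(x - mean(x)))
  )
}

#' The 77-test utility score of a feature
#'
#' Runs the 11 statistical criteria (5 correlation tests, favourable; 6
#' regression-applicability diagnostics, unfavourable penalty-only) on
#' each of the 7 subsets, maps every significance level through
#' [utility()], and aggregates as the plain mean of the 77 utilities.
#' The maximum attainable score is therefore 5/11 (all correlation tests
#' saturated, no applicability penalty); `xi > 0` requires genuinely
#' significant correlations across the subsets. An all-constant feature
#' scores `xi = -1` by convention.
#'
#' @param ds An `activity_dataset`.
#' @param f Feature vector for the dataset's records.
#' @return A `utility_breakdown`: list with `alphas` (7x11), `utilities`
#'   (7x11) and `xi` (their mean).
#' @export
xi_score <- function(ds, f) {
  x <- if (inherits(ds, "activity_dataset")) ds$activity else as.numeric(ds)
  crit <- c("pearson", "spearman", "kendall", "chi2", "fisher",
            "unif_x", "unif_f", "norm_fx", "indep_fx", "norm_xf", "indep_xf")
  sub_names <- c("all", "low_f", "high_f", "mid_f", "low_x", "high_x", "mid_x")
  alphas <- matrix(NA_real_, 7, 11, dimnames = list(sub_names, crit))
  utils_m <- alphas
  if (stats::sd(f) == 0) {
    alphas[] <- 1
    utils_m[] <- NA_real_
    out <- list(alphas = alphas, utilities = utils_m, xi = -1)
    class(out) <- "utility_breakdown"
    return(out)
  }
  subsets <- make_subsets(x, f)
  dirs <- c(rep("favourable", 5), rep("unfavourable", 6))
  for (k in seq_along(subsets)) {
    res <- all_criteria(x[subsets[[k]]], f[subsets[[k]]])
    alphas[k, ] <- vapply(res, `[[`, numeric(1), "alpha")
    utils_m[k, ] <- utility(alphas[k, 1:5], "favourable") |>
      c(utility(alphas[k, 6:11], "unfavourable"))
  }
  out <- list(alphas = alphas, utilities = utils_m, xi = mean(utils_m))
  class(out) <- "utility_breakdown"
  out
}

#' @export
print.utility_breakdown <- function(x, ...) {
  cat(sprintf("<utility_breakdown> Xi = %.4f (mean of %d utilities)\n",
              x$xi, length(x$utilities)))
  invisible(x)
}

# fast per-variant Pearson screen over a tetra x profile grid.
# Returns a data.frame (tetra, profile_id, r) ordered as enumerated.
.screen_pearson <- function(ds, tetras, W) {
  P <- ds$fragment_length - 3L
  n <- length(ds$id)
  codes <- t(vapply(ds$fragment, .encode_windows, integer(P), USE.NAMES = FALSE))
  x <- ds$activity
  xc <- x - mean(x)
  sx <- sqrt(sum(xc^2))
  K <- ncol(W)
  r_all <- matrix(0, length(tetras), K)
  for (j in seq_along(tetras)) {
    B <- matrix(as.numeric(.tetra_mask(tetras[j])[codes]), n, P)
    Feat <- B %*% W
    cs <- colSums(Feat)
    num <- as.numeric(crossprod(Feat, xc))
    sf2 <- colSums(Feat^2) - cs^2 / n
    r <- ifelse(sf2 > 1e-12, num / (sqrt(pmax(sf2, 0)) * sx), 0)
    r_all[j, ] <- r
  }
  data.frame(
    tetra = rep(tetras, each = K),
    profile_id = rep.int(seq_len(K), length(tetras)),
    r = as.numeric(t(r_all)),
    stringsAsFactors = FALSE
  )
}

#' Staged search of the weighted-tetranucleotide feature space
#'
#' Enumerates every (degenerate tetranucleotide, weight profile) variant,
#' screens all of them by the absolute full-dataset Pearson correlation
#' with the activity, computes the full 77-test score [xi_score()] for the
#' `screen_top_k` best-screening variants, and ranks those by `xi`
#' (descending; ties broken by tetra specificity, then tetra
#' lexicographically, then profile id). With `screen_top_k >= `the variant
#' count the search is exhaustive in `xi`. When no scored variant exceeds
#' `min_xi` the search reports that no useful correlation was found rather
#' than returning a best variant.
#'
#' @param ds An `activity_dataset`.
#' @param tetras Character vector of degenerate tetranucleotides to search
#'   (defaults to all 50625).
#' @param profiles A `profile_library` (defaults to the built-in 360 for
#'   the dataset's fragment length).
#' @param screen_top_k Number of screened variants promoted to full
#'   scoring.
#' @param min_xi Usefulness threshold on the best `xi` (default 0).
#' @return A `tetra_search`: list with `ranked` (data.frame: tetra,
#'   profile_id, xi, pearson_r_full), `best` (list or `NULL`), `useful`
#'   (logical), and search metadata.
#' @export
search_features <- function(ds, tetras = tetra_space(),
                            profiles = builtin_profiles(ds$fragment_length),
                            screen_top_k = 1000L, min_xi = 0) {
  stopifnot(inherits(ds, "activity_dataset"))
  if (length(tetras) < 1L) stop("empty tetranucleotide space", call. = FALSE)
  if (screen_top_k < 1L) stop("screen_top_k must be >= 1", call. = FALSE)
  W <- .profile_matrix(profiles, ds$fragment_length - 3L)
  screen <- .screen_pearson(ds, tetras, W)
  n_variants <- nrow(screen)
  keep <- utils::head(order(-abs(screen$r)), min(screen_top_k, n_variants))
  scored <- screen[keep, , drop = FALSE]
  scored$xi <- NA_real_
  feats <- vector("list", nrow(scored))
  for (i in seq_len(nrow(scored))) {
    f <- .variant_feature(ds, scored$tetra[i], W[, scored$profile_id[i]])
    feats[[i]] <- f
    scored$xi[i] <- xi_score(ds, f)$xi
  }
  deg <- degeneracy(scored$tetra)
  ord <- order(-scored$xi, deg, scored$tetra, scored$profile_id)
  scored <- scored[ord, , drop = FALSE]
  feats <- feats[ord]
  ranked <- data.frame(
    rank = seq_len(nrow(scored)),
    tetra = scored$tetra,
    profile_id = scored$profile_id,
    xi = scored$xi,
    pearson_r_full = scored$r,
    stringsAsFactors = FALSE
  )
  useful <- nrow(ranked) > 0 && ranked$xi[1] > min_xi
  best <- if (useful) {
    list(tetra = ranked$tetra[1], profile_id = ranked$profile_id[1],
         profile = W[, ranked$profile_id[1]], xi = ranked$xi[1],
         feature = feats[[1]])
  } else NULL
  structure(
    list(ranked = ranked, best = best, useful = useful,
         n_variants = n_variants, screen_top_k = screen_top_k,
         min_xi = min_xi),
    class = "tetra_search"
  )
}

.variant_feature <- function(ds, tetra, weights) {
  vapply(ds$fragment, feature_value, numeric(1), tetra = tetra,
         profile = weights, USE.NAMES = FALSE)
}

#' @export
print.tetra_search <- function(x, ...) {
  cat("<tetra_search> ", x$n_variants, " variants screened, ",
      nrow(x$ranked), " fully scored\n", sep = "")
  if (x$useful) {
    cat(sprintf("  best: [%s] profile %d, Xi = %.4f\n",
                x$best$tetra, x$best$profile_id, x$best$xi))
  } else {
    cat("  no useful correlation found (max Xi <= ", x$min_xi, ")\n", sep = "")
  }
  invisible(x)
}

#' Permutation verification of a search result
#'
#' Re-runs the identical search on `cycles` datasets whose activities have
#' been randomly permuted against the sequences. A cycle scores a
#' recurrence when the permuted search's best variant is the original best
#' variant, or one whose feature vector on the original dataset has
#' `|Pearson r| >= corr_threshold` with the original best feature. The
#' reported alpha is the lower binomial tail
#' `P(X <= recurrences | cycles, p = 0.05)`: finding the feature absent
#' (or nearly so) across all permuted datasets is the significant event
#' that verifies it.
#'
#' @param ds The original `activity_dataset`.
#' @param result A `tetra_search` with a `best` variant.
#' @param tetras,profiles,screen_top_k,min_xi Search settings; must match
#'   the original search.
#' @param cycles Number of permutation cycles (default 100).
#' @param corr_threshold Feature-vector correlation above which a permuted
#'   best counts as a recurrence (default 0.8).
#' @param seed Integer seed driving the permutations.
#' @return List with `recurrences`, `cycles`, `alpha`, and `verified`
#'   (`alpha < 0.05`).
#' @export
permutation_verify <- function(ds, result, tetras = tetra_space(),
                               profiles = builtin_profiles(ds$fragment_length),
                               screen_top_k = 1000L, min_xi = 0,
                               cycles = 100L, corr_threshold = 0.8,
                               seed = 1L) {
  stopifnot(inherits(result, "tetra_search"))
  if (is.null(result$best)) stop("search result has no best variant to verify",
                                 call. = FALSE)
  if (cycles < 1L) stop("cycles must be >= 1", call. = FALSE)
  set.seed(seed)
  f0 <- result$best$feature
  rec <- 0L
  for (cy in seq_len(cycles)) {
    perm <- ds
    perm$activity <- sample(ds$activity)
    rs <- search_features(perm, tetras = tetras, profiles = profiles,
                          screen_top_k = screen_top_k, min_xi = min_xi)
    if (!rs$useful) next
    same <- rs$best$tetra == result$best$tetra &&
      rs$best$profile_id == result$best$profile_id
    if (!same) {
      f1 <- .variant_feature(ds, rs$best$tetra, rs$best$profile)
      same <- stats::sd(f1) > 0 && stats::sd(f0) > 0 &&
        abs(stats::cor(f0, f1)) >= corr_threshold
    }
    if (same) rec <- rec + 1L
  }
  alpha <- stats::pbinom(rec, cycles, 0.05)
  list(recurrences = rec, cycles = cycles, alpha = alpha,
       verified = alpha < 0.05)
}
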