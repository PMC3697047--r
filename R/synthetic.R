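# Seeded generator of sequence-activity datasets with a planted
# weighted-tetranucleotide signal, used for engine recovery tests and
# permutation null controls. The generator realizes the engine's own
# linear-additive premise: activity = intercept + slope * feature + noise.

#' Base compositions for synthetic sequences
#'
#' `uniform_composition()` draws each base with probability 0.25;
#' `au_rich_composition()` mirrors the A/U bias typical of plant mature
#' miRNAs (A 0.30, U 0.35, G 0.20, C 0.15).
#'
#' @return Named numeric probability vector over A, C, G, U.
#' @export
uniform_composition <- function() c(A = 0.25, C = 0.25, G = 0.25, U = 0.25)

#' @rdname uniform_composition
#' @export
au_rich_composition <- function() c(A = 0.30, C = 0.15, G = 0.20, U = 0.35)

#' Generate a synthetic sequence-activity dataset with a planted signal
#'
#' Sequences are i.i.d. per-base draws from `base_composition`; the
#' activity of each sequence is
#' `intercept + slope * feature_value(seq, tetra, profile) + N(0, noise_sd)`.
#' With `slope = 0` the activity is independent of the sequence (a null
#' dataset); with `noise_sd = 0` it is an exact linear function of the
#' planted feature. Fully deterministic given `seed`.
#'
#' @param n Number of records (>= 6).
#' @param L Fragment length (>= 8).
#' @param tetra Planted degenerate tetranucleotide.
#' @param profile Planted `weight_profile` (or numeric weight vector of
#'   length `L - 3`).
#' @param slope,intercept Linear activity law parameters.
#' @param noise_sd Gaussian noise sd (>= 0).
#' @param base_composition Named probability vector over A, C, G, U.
#' @param seed Integer seed.
#' @return List with `dataset` (an `activity_dataset`) and `truth`
#'   (planted tetra, profile, slope, intercept, noise_sd, seed, and the
#'   noiseless feature values).
#' @export
synthetic_dataset <- function(n, L, tetra, profile, slope = 1, intercept = 0,
                              noise_sd = 0.1,
                              base_composition = uniform_composition(),
                              seed = 1L) {
  n <- as.integer(n); L <- as.integer(L)
  if (n < 6L) stop("n must be >= 6", call. = FALSE)
  if (L < 8L) stop("L must be >= 8", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  p <- base_composition[c("A", "C", "G", "U")]
  if (anyNA(p) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop("base_composition must be probabilities over A, C, G, U summing to 1",
         call. = FALSE)
  tetra <- .check_tetra(tetra)
  w <- .profile_values(profile, L - 3L)
  set.seed(seed)
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "U"), L, replace = TRUE, prob = p),
          collapse = ""), character(1))
  feat <- vapply(seqs, feature_value, numeric(1), tetra = tetra, profile = w,
                 USE.NAMES = FALSE)
  act <- intercept + slope * feat + stats::rnorm(n, 0, noise_sd)
  ds <- activity_dataset(sprintf("syn-%03d", seq_len(n)), seqs, act,
                         fragment_length = L, label = "synthetic planted-signal dataset")
  list(
    dataset = ds,
    truth = list(tetra = tetra, profile = w, slope = slope,
                 intercept = intercept, noise_sd = noise_sd, seed = seed,
                 feature = feat)
  )
}

#' Permute activities against sequences (null rearrangement)
#'
#' Randomly rearranges the pairing of activities and sequences with a
#' seeded permutation, preserving the activity multiset. This is the
#' rearrangement underlying the permutation verification of a search
#' result.
#'
#' @param ds An `activity_dataset`.
#' @param seed Integer seed.
#' @return A new `activity_dataset` with permuted activities.
#' @export
null_permute <- function(ds, seed = 1L) {
  stopifnot(inherits(ds, "activity_dataset"))
  set.seed(seed)
  out <- ds
  out$activity <- sample(ds$activity)
  out
}
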