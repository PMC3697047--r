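# Independent oracles used across the suite. These deliberately use the
# slowest, most literal formulation of each quantity so they stay
# independent of the package's fast paths.

# random concrete RNA fragment
random_fragment <- function(L) {
  paste(sample(c("A", "C", "G", "U"), L, replace = TRUE), collapse = "")
}

# random degenerate tetranucleotide
random_tetra <- function() {
  paste(sample(names(iupac_codes()), 4, replace = TRUE), collapse = "")
}

# literal double-loop evaluation of the weighted tetranucleotide abundance:
# enumerate windows, test membership against the expanded concrete set
naive_feature_value <- function(fragment, tetra, weights) {
  concrete <- expand_degenerate(tetra)
  L <- nchar(fragment)
  total <- 0
  for (i in seq_len(L - 3)) {
    w <- substr(fragment, i, i + 3)
    if (w %in% concrete) total <- total + weights[i]
  }
  total
}

# definitional Pearson r
naive_pearson <- function(x, y) {
  n <- length(x)
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# definitional Kendall tau-b by pair enumeration
naive_kendall_taub <- function(x, y) {
  n <- length(x)
  s <- 0; tx <- 0; ty <- 0; n0 <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    n0 <- n0 + 1
    dx <- sign(x[i] - x[j]); dy <- sign(y[i] - y[j])
    if (dx == 0) tx <- tx + 1
    if (dy == 0) ty <- ty + 1
    s <- s + dx * dy
  }
  s / sqrt((n0 - tx) * (n0 - ty))
}

# exact two-sided Fisher p by brute-force enumeration of all tables with
# the observed margins (probability-ordering rule)
naive_fisher2x2 <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1]); c2 <- sum(tab[, 2])
  n <- r1 + r2
  prob_of <- function(a) {
    # a = count in cell [1,1]
    b <- r1 - a; c <- c1 - a; d <- r2 - c
    if (min(b, c, d) < 0) return(NA_real_)
    exp(lchoose(r1, a) + lchoose(r2, c) - lchoose(n, c1))
  }
  ps <- vapply(0:min(r1, c1), prob_of, numeric(1))
  ps <- ps[!is.na(ps)]
  obs <- prob_of(tab[1, 1])
  sum(ps[ps <= obs * (1 + 1e-7)])
}

# O(n^3) literal single-linkage agglomeration down to two clusters
brute_single_linkage_2 <- function(points) {
  n <- nrow(points)
  d <- as.matrix(dist(points))
  clusters <- as.list(seq_len(n))
  while (length(clusters) > 2) {
    best <- c(NA, NA); bd <- Inf
    for (a in seq_len(length(clusters) - 1)) for (b in (a + 1):length(clusters)) {
      dd <- min(d[clusters[[a]], clusters[[b]]])
      if (dd < bd) { bd <- dd; best <- c(a, b) }
    }
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  labels <- integer(n)
  labels[clusters[[1]]] <- 1L
  labels[clusters[[2]]] <- 2L
  labels
}

# same partition irrespective of labelling?
same_partition <- function(a, b) {
  all(outer(a, a, "==") == outer(b, b, "=="))
}

# a small planted-signal dataset shared by engine tests
planted_sim <- function(seed, n = 24, L = 22, noise_to_signal = 0.2) {
  prof <- u_profile(0.5, 0.2, "peak", 0, L - 3)
  base <- synthetic_dataset(n, L, "RHHK", prof, slope = 2, noise_sd = 0,
                            seed = seed)
  sig_sd <- sd(2 * base$truth$feature)
  synthetic_dataset(n, L, "RHHK", prof, slope = 2,
                    noise_sd = noise_to_signal * sig_sd, seed = seed)
}

# restricted tetra search space of a given size that contains `include`,
# drawn deterministically from the full space
restricted_tetras <- function(size, include, seed) {
  set.seed(seed)
  unique(c(include, sample(tetra_space(), size)))[seq_len(size)]
}
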