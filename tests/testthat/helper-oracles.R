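# Independent oracles and small fixture builders used across the suite.
# The oracles deliberately use naive element-by-element logic, independent
# of the vectorised implementation paths they check.

ACGT <- c("A", "C", "G", "T")

# Brute-force K2P: explicit per-site classification into
# identical / transition / transversion / excluded.
oracle_k2p <- function(a, b) {
  L <- 0L; ts <- 0L; tv <- 0L
  for (i in seq_along(a)) {
    x <- a[i]; y <- b[i]
    if (!(x %in% ACGT) || !(y %in% ACGT)) next
    L <- L + 1L
    if (x == y) next
    pur_x <- x %in% c("A", "G")
    pur_y <- y %in% c("A", "G")
    if (pur_x == pur_y) ts <- ts + 1L else tv <- tv + 1L
  }
  if (L == 0L) return(list(d = NA_real_, flag = "undefined", L = 0L))
  P <- ts / L; Q <- tv / L
  if (1 - 2 * P - Q <= 0 || 1 - 2 * Q <= 0) {
    return(list(d = NA_real_, flag = "saturated", L = L))
  }
  list(d = -0.5 * log(1 - 2 * P - Q) - 0.25 * log(1 - 2 * Q),
       flag = "ok", L = L)
}

# Random aligned pair with gaps/ambiguities mixed in.
random_pair <- function(L = 400, p_diff = 0.1, p_missing = 0.05) {
  a <- sample(c(ACGT, "N", "-"), L, replace = TRUE,
              prob = c(rep((1 - p_missing) / 4, 4), p_missing / 2,
                       p_missing / 2))
  b <- a
  flip <- runif(L) < p_diff
  b[flip] <- vapply(b[flip], function(x) {
    if (x %in% ACGT) sample(setdiff(ACGT, x), 1) else sample(ACGT, 1)
  }, character(1))
  miss <- runif(L) < p_missing
  b[miss] <- sample(c("N", "-"), sum(miss), replace = TRUE)
  list(a = a, b = b)
}

# Alternating-series closed form of the segregating-sites pmf
# (inclusion-exclusion over the oldest-epoch lineage count). Numerically
# fine at small n; used as an independent check of the convolution.
alt_prob_segsites <- function(n, theta, k) {
  if (theta == 0) return(as.numeric(k == 0))
  s <- 0
  for (i in 2:n) {
    s <- s + (-1)^i * choose(n - 1, i - 1) *
      ((i - 1) / (theta + i - 1)) * (theta / (theta + i - 1))^k
  }
  s
}

# Monte-Carlo coalescent sample of S_n: epoch durations are exponential
# with rate choose(i, 2), mutations Poisson on total branch length.
mc_segsites <- function(n, theta, reps) {
  Ltot <- 0
  for (i in 2:n) Ltot <- Ltot + i * rexp(reps, i * (i - 1) / 2)
  rpois(reps, theta * Ltot / 2)
}

# Quick library builder from a named list of sequence strings/vectors.
make_lib <- function(seqs, species, subspecies = NULL) {
  meta <- data.frame(id = names(seqs), species = species,
                     stringsAsFactors = FALSE)
  if (!is.null(subspecies)) meta$subspecies <- subspecies
  barcode_library(seqs, meta)
}

# Mutate k random positions of a sequence vector (always to a different
# unambiguous base).
mutate_sites <- function(sv, k) {
  if (k == 0L) return(sv)
  idx <- sample(length(sv), k)
  sv[idx] <- vapply(sv[idx], function(b)
    sample(setdiff(ACGT, b), 1), character(1))
  sv
}

# Barcode-frame amplicon free of incidental NlaIII/BamHI motifs outside the
# planted windows, for exact fragment-size assertions.
clean_nb_sequence <- function(N, B, seed = 1,
                              windows = default_nb_windows()) {
  set.seed(seed)
  repeat {
    sv <- sample(ACGT, windows$frame_length, replace = TRUE)
    sv[windows$n_mono_start:(windows$n_mono_start + 3)] <-
      strsplit("CATG", "")[[1]]
    sv[windows$n_diag_start:(windows$n_diag_start + 3)] <-
      strsplit(if (N) "CATG" else "CACG", "")[[1]]
    sv[windows$b_diag_start:(windows$b_diag_start + 5)] <-
      strsplit(if (B) "GGATCC" else "GGATAC", "")[[1]]
    s <- paste(sv, collapse = "")
    starts_n <- gregexpr("CATG", s, fixed = TRUE)[[1]]
    starts_b <- gregexpr("GGATCC", s, fixed = TRUE)[[1]]
    ok_n <- setdiff(starts_n[starts_n > 0],
                    c(windows$n_mono_start,
                      if (N) windows$n_diag_start))
    ok_b <- setdiff(starts_b[starts_b > 0],
                    if (B) windows$b_diag_start else integer(0))
    if (length(ok_n) == 0 && length(ok_b) == 0) return(sv)
  }
}
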