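test_that("K2P matches hand-computed worked cases", {
  # identical sequences
  s <- paste(rep("ACGT", 25), collapse = "")
  r <- k2p(s, s)
  expect_equal(r$d, 0)
  expect_equal(r$P, 0)
  expect_equal(r$Q, 0)
  expect_equal(r$L_comp, 100L)

  # 100 sites, 10 transitions, 5 transversions:
  # d = -0.5 log(0.75) - 0.25 log(0.9) = 0.1701812...
  a <- rep("A", 100)
  b <- a
  b[1:10] <- "G"            # transitions
  b[11:15] <- "C"           # transversions
  r <- k2p(a, b)
  expect_equal(r$P, 0.10)
  expect_equal(r$Q, 0.05)
  expect_equal(r$d, -0.5 * log(0.75) - 0.25 * log(0.9), tolerance = 1e-12)
  expect_equal(r$d, 0.1701812, tolerance = 1e-6)

  # pairwise deletion: differences hidden behind N do not count
  a2 <- rep("A", 100)
  b2 <- a2
  b2[1:2] <- "G"
  a2[1:2] <- "N"
  r2 <- k2p(a2, b2)
  expect_equal(r2$L_comp, 98L)
  expect_equal(r2$d, 0)
})

test_that("K2P flags undefined and saturated pairs", {
  expect_identical(k2p(rep("N", 50), rep("A", 50))$flag, "undefined")
  a <- rep(c("A", "C"), 50)
  b <- rep(c("G", "T"), 50)  # all transitions: P = 1
  expect_identical(k2p(a, b)$flag, "saturated")
  expect_true(is.na(k2p(a, b)$d))
})

test_that("distance matrix agrees with the per-pair implementation and ape", {
  set.seed(101)
  m <- matrix(sample(c(ACGT, "N", "-"), 12 * 300, TRUE,
                     prob = c(rep(0.23, 4), 0.04, 0.04)), 12, 300)
  rownames(m) <- paste0("s", 1:12)
  dm <- distance_matrix(m)
  expect_true(isSymmetric(dm$d))
  expect_true(all(diag(dm$d) == 0))
  for (i in 1:11) for (j in (i + 1):12) {
    r <- k2p(m[i, ], m[j, ])
    expect_equal(dm$d[i, j], r$d, tolerance = 1e-12)
    expect_equal(dm$comparable[i, j], r$L_comp)
  }
  dnab <- ape::as.DNAbin(lapply(seq_len(nrow(m)), function(i) tolower(m[i, ])))
  names(dnab) <- rownames(m)
  da <- as.matrix(ape::dist.dna(dnab, model = "K80",
                                pairwise.deletion = TRUE))
  da <- da[rownames(dm$d), colnames(dm$d)]
  # ape leaves NaN/Inf where the log arguments go non-positive; we flag
  # those pairs, so compare the defined entries only
  ok <- dm$flag == "ok"
  expect_equal(dm$d[ok], da[ok], tolerance = 1e-9)
  expect_true(all(!is.finite(da[!ok & upper.tri(da)])))
})

test_that("K2P is monotone in divergence when transitions equal transversions", {
  # with P = Q the distance grows with the difference fraction up to
  # saturation (Jukes-Cantor-like regime)
  ds <- vapply(seq(0.02, 0.3, by = 0.02), function(f) {
    n <- 600 * f / 2
    a <- rep("A", 600)
    b <- a
    b[seq_len(n)] <- "G"
    b[n + seq_len(n)] <- "C"
    k2p(a, b)$d
  }, numeric(1))
  expect_true(all(diff(ds) > 0))
})

test_that("divergence summaries pool intra pairs and average inter pairs", {
  set.seed(5)
  base <- sample(ACGT, 200, TRUE)
  lib <- make_lib(list(a1 = base, a2 = base, a3 = base,
                       b1 = mutate_sites(base, 30),
                       c1 = mutate_sites(base, 40)),
                  c("spA", "spA", "spA", "spB", "spC"))
  dm <- distance_matrix(lib)
  sm <- divergence_summaries(dm, taxon_labels(lib))
  expect_equal(sm$intra$n, 3L)            # C(3,2) within spA
  expect_equal(sm$intra$mean, 0)
  expect_equal(sm$inter$n, choose(3, 2))  # one value per species pair
  # single species, identical members: inter empty
  lib1 <- make_lib(list(x = base, y = base, z = base), rep("spA", 3))
  sm1 <- divergence_summaries(distance_matrix(lib1), taxon_labels(lib1))
  expect_equal(sm1$intra$mean, 0)
  expect_true(sm1$inter$empty)
})

test_that("interspecific comparison count is always choose(k, 2)", {
  for (k in c(4, 9, 36)) {
    sim <- simulate_library(sim_config(n_species = k,
                                       members_per_species = 2,
                                       seq_length = 200,
                                       nb_site_plan = NULL, seed = k))
    sm <- divergence_summaries(distance_matrix(sim$library),
                               taxon_labels(sim$library))
    expect_equal(sm$inter$n, choose(k, 2))
  }
})

test_that("overlap window counting uses a closed interval", {
  # fabricated distances: ref-vs-variant pairs at exactly
  # {1.9, 2.0, 3.0, 4.0, 4.1}% -> 3 inside the closed window [2, 4];
  # variant-variant pairs placed far outside it
  vals <- c(1.9, 2.0, 3.0, 4.0, 4.1) / 100
  labs <- c("ref", paste0("v", 1:5))
  D <- matrix(0.10, 6, 6, dimnames = list(labs, labs))
  D["ref", -1] <- vals
  D[-1, "ref"] <- vals
  diag(D) <- 0
  species_of <- setNames(rep("spA", 6), labs)
  ov <- overlap_analysis(D, species_of, 2, 4)
  expect_equal(ov$n_intra_in_window, 3)
  expect_equal(ov$n_intra_total, choose(6, 2))
  expect_equal(ov$n_inter_total, 0)
  expect_identical(ov$offending_taxa, "spA")
  # all intra below the window: nothing counted
  ov0 <- overlap_analysis(D / 100, species_of, 2, 4)
  expect_equal(ov0$n_intra_in_window, 0)
})

test_that("overlap analysis names species with in-window splits", {
  fx <- simulate_paraphyly_library(seed = 11)
  dm <- distance_matrix(fx$library)
  ov <- overlap_analysis(dm, taxon_labels(fx$library), 2, 4)
  expect_true(fx$paraphyletic_species %in% ov$offending_taxa)
})

test_that("histogram counts conserve totals", {
  sim <- simulate_library(sim_config(n_species = 5, members_per_species = 3,
                                     seq_length = 300,
                                     nb_site_plan = NULL, seed = 2))
  dm <- distance_matrix(sim$library)
  sp <- taxon_labels(sim$library)
  h <- histogram_export(dm, sp, 1)
  sm <- divergence_summaries(dm, sp)
  expect_equal(sum(h$intra_count), sm$intra$n)
  expect_equal(sum(h$inter_count), sm$inter$n)
  # bimodal: no mass between the intra mode and the inter mode
  gap_bins <- h$bin_lo >= 4 & h$bin_hi <= 10
  expect_true(all(h$intra_count[gap_bins] == 0))
  # empty inter set
  lib1 <- make_lib(list(x = rep("A", 120), y = rep("A", 120)), rep("spA", 2))
  h1 <- histogram_export(distance_matrix(lib1), taxon_labels(lib1), 1)
  expect_true(all(h1$inter_count == 0))
})
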