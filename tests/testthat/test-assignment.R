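test_that("segregating sites counts columns with two unambiguous states", {
  base <- rep("A", 50)
  expect_equal(segregating_sites(rbind(base, base, base)), 0L)
  b2 <- base; b2[c(3, 9, 21, 40)] <- "G"
  expect_equal(segregating_sites(rbind(base, b2)), 4L)
  # {A, N, G} at a column segregates; {A, N, A} does not
  m <- rbind(base, base, base)
  m[2, 5] <- "N"; m[3, 5] <- "G"
  m[2, 7] <- "N"
  expect_equal(segregating_sites(m), 1L)
})

test_that("Watterson estimator and its sampling behaviour", {
  expect_equal(watterson_theta(10, 2), 10)
  expect_equal(watterson_theta(11, 5), 11 / (1 + 1/2 + 1/3 + 1/4))
  expect_true(is.na(watterson_theta(0, 1)))
  # parameter recovery on simulated coalescent samples: n = 20, theta = 5
  set.seed(77)
  a_n <- sum(1 / (1:19))
  th <- vapply(mc_segsites(20, 5, 1000), watterson_theta, numeric(1), n = 20)
  se <- sd(th) / sqrt(length(th))
  expect_lt(abs(mean(th) - 5), 3 * se)
})

test_that("segregating-sites distribution matches closed forms", {
  # n = 2: geometric; P(S = 0 | theta = 1) = 1/2, P(S = 1 | theta = 2) = 2/9
  expect_equal(prob_segsites(2, 1, 0), 0.5, tolerance = 1e-12)
  expect_equal(prob_segsites(2, 2, 1), (1 / 3) * (2 / 3), tolerance = 1e-12)
  # theta = 0 degenerates to a point mass at zero
  expect_equal(prob_segsites(5, 0, 0), 1)
  expect_equal(prob_segsites(5, 0, 3), 0)
  # agreement with the independent alternating-series form
  for (n in c(2, 3, 5, 10)) for (th in c(0.5, 2, 10)) {
    k <- 0:25
    expect_equal(prob_segsites(n, th, k),
                 vapply(k, alt_prob_segsites, numeric(1), n = n, theta = th),
                 tolerance = 1e-12)
  }
})

test_that("segregating-sites distribution is normalised", {
  for (n in c(2, 5, 10)) for (th in c(0.5, 2, 10)) {
    expect_lt(abs(1 - sum(prob_segsites(n, th, 0:400))), 1e-10)
  }
})

test_that("diagnostic sites are fixed, taxon-exclusive states", {
  others <- rbind(rep("G", 10), rep("G", 10))
  taxon <- rbind(rep("A", 10), rep("A", 10))
  expect_equal(diagnostic_sites(taxon, others), 10L)
  # polymorphic column in the taxon is not diagnostic
  taxon2 <- taxon; taxon2[1, 1] <- "G"
  expect_equal(diagnostic_sites(taxon2, others), 9L)
  # state present in others is not diagnostic
  others2 <- others; others2[1, 2] <- "A"
  expect_equal(diagnostic_sites(taxon, others2), 9L)
  # distinct haplotypes can still have zero diagnostic sites when every
  # taxon state recurs somewhere in the comparison set
  tx <- rbind(c("A", "C"), c("A", "T"))
  ot <- rbind(c("A", "C"), c("G", "T"))
  expect_equal(diagnostic_sites(tx, ot), 0L)
})

test_that("assignment favours the taxon the query perturbs least", {
  set.seed(55)
  base <- sample(ACGT, 120, TRUE)
  farA <- mutate_sites(base, 25)
  # A monomorphic and identical to the query; B would gain ~10 new sites
  lib <- make_lib(list(a1 = base, a2 = base,
                       b1 = farA, b2 = mutate_sites(farA, 2)),
                  c("spA", "spA", "spB", "spB"))
  res <- assign_query(lib, base, query_id = "q")
  expect_identical(res$assigned, "spA")
  expect_gt(res$posterior, 0.99)
  expect_equal(sum(res$table$posterior), 1, tolerance = 1e-9)
  expect_equal(res$risk, 1 - res$posterior)
})

test_that("symmetric candidates tie and break lexicographically", {
  base <- rep("A", 100)
  a2 <- base; a2[1] <- "G"
  b2 <- base; b2[50] <- "T"
  q <- base; q[90] <- "C"
  lib <- make_lib(list(a1 = base, a2 = a2, b1 = base, b2 = b2),
                  c("spA", "spA", "spB", "spB"))
  res <- assign_query(lib, q)
  expect_true(res$tie)
  expect_identical(res$assigned, "spA")
  expect_equal(res$table$posterior, c(0.5, 0.5), tolerance = 1e-12)
})

test_that("posteriors are invariant to record order and to duplicate support", {
  set.seed(66)
  sim <- simulate_library(sim_config(n_species = 5, members_per_species = 4,
                                     seq_length = 300,
                                     nb_site_plan = NULL, seed = 33))
  lib <- sim$library
  q <- mutate_sites(lib$seq["sp03_01", ], 2)
  r1 <- assign_query(lib, q)
  perm <- sample(rownames(lib$seq))
  r2 <- assign_query(subset_library(lib, perm), q)
  expect_identical(r1$assigned, r2$assigned)
  expect_equal(r1$table$posterior[order(r1$table$taxon)],
               r2$table$posterior[order(r2$table$taxon)], tolerance = 1e-12)
  # adding a sequence identical to the query to the winning taxon never
  # hurts that taxon
  m <- rbind(lib$seq, qcopy = q)
  meta <- rbind(lib$meta,
                data.frame(id = "qcopy", species = r1$assigned,
                           subspecies = NA, country = NA, locality = NA,
                           lat = NA, lon = NA, source = "synthetic"))
  r3 <- assign_query(barcode_library(m, meta), q)
  p1 <- r1$table$posterior[r1$table$taxon == r1$assigned]
  p3 <- r3$table$posterior[r3$table$taxon == r1$assigned]
  expect_gte(p3, p1 - 1e-9)
})

test_that("query-wise pairwise deletion restricts scoring to covered columns", {
  set.seed(67)
  base <- sample(ACGT, 200, TRUE)
  other <- mutate_sites(base, 40)
  lib <- make_lib(list(a1 = base, a2 = mutate_sites(base, 1),
                       b1 = other, b2 = mutate_sites(other, 1)),
                  c("spA", "spA", "spB", "spB"))
  # query identical to spA on its covered half, gaps elsewhere
  q <- base
  q[101:200] <- "-"
  res <- assign_query(lib, q)
  expect_identical(res$assigned, "spA")
  # a fully ambiguous query is rejected
  expect_error(assign_query(lib, rep("N", 200)), "unambiguous")
})

test_that("leave-one-out validation is seeded and correct on clean libraries", {
  set.seed(68)
  base <- sample(ACGT, 150, TRUE)
  seqs <- list()
  species <- character(0)
  for (s in 1:4) {
    anc <- mutate_sites(base, 25 * s)
    for (i in 1:3) {
      seqs[[sprintf("sp%02d_%02d", s, i)]] <- anc
      species <- c(species, sprintf("sp%02d", s))
    }
  }
  lib <- make_lib(seqs, species)
  t1 <- loo_validate(lib, "species", seed = 4)
  t2 <- loo_validate(lib, "species", seed = 4)
  expect_identical(t1$query_id, t2$query_id)
  expect_true(all(t1$correct))
  expect_equal(nrow(t1), 4L)
})

test_that("subspecies-level assignment is less confident than species-level", {
  cfg <- sim_config(n_species = 5, members_per_species = c(12, 5, 5, 5, 5),
                    subspecies_spec = list(
                      sp01 = list(labels = c("alpha", "beta"),
                                  divergence = 0.004)),
                    seed = 5)
  sim <- simulate_library(cfg)
  sp <- loo_validate(sim$library, "species", seed = 9)
  ss <- loo_validate(sim$library, "subspecies", seed = 9)
  expect_lt(max(ss$posterior), min(sp$posterior))
})
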