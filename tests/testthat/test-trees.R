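test_that("NJ solves the 3-taxon star exactly", {
  D <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  lens <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(lens[["A"]], 1)
  expect_equal(lens[["B"]], 2)
  expect_equal(lens[["C"]], 4)
})

test_that("NJ recovers the additive 4-taxon tree with its edge lengths", {
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  tr <- nj_tree(D)
  # AB|CD topology with tip edges A=1, B=2, C=3, D=4 and internal edge 1
  expect_true(ape::is.monophyletic(ape::root(tr, "D"), c("A", "B")))
  tips <- setNames(tr$edge.length[tr$edge[, 2] <= 4],
                   tr$tip.label[tr$edge[, 2][tr$edge[, 2] <= 4]])
  expect_equal(tips[LETTERS[1:4]], c(A = 1, B = 2, C = 3, D = 4))
  expect_equal(unname(tr$edge.length[tr$edge[, 2] > 4]), 1)
  # path lengths reproduce the input exactly
  expect_equal(cophenetic(tr)[rownames(D), colnames(D)], D,
               tolerance = 1e-12)
})

test_that("NJ is exact on additive matrices and matches ape's NJ", {
  set.seed(31)
  for (r in 1:25) {
    n <- sample(5:12, 1)
    true <- ape::rtree(n)
    true$edge.length <- runif(nrow(true$edge), 0.05, 1)
    D <- cophenetic(true)
    D <- D[sort(rownames(D)), sort(rownames(D))]
    fit <- nj_tree(D)
    expect_equal(cophenetic(fit)[rownames(D), colnames(D)], D,
                 tolerance = 1e-9)
    expect_equal(ape::dist.topo(ape::unroot(true), fit)[[1]], 0)
    expect_equal(ape::dist.topo(ape::nj(D), fit)[[1]], 0)
  }
})

test_that("NJ bipartitions are invariant to input label order", {
  set.seed(32)
  sim <- simulate_library(sim_config(n_species = 4, members_per_species = 3,
                                     seq_length = 300,
                                     nb_site_plan = NULL, seed = 8))
  dm <- distance_matrix(sim$library)
  tr1 <- nj_tree(dm)
  perm <- sample(rownames(dm$d))
  tr2 <- nj_tree(dm$d[perm, perm])
  expect_equal(ape::dist.topo(tr1, tr2)[[1]], 0)
})

test_that("NJ rejects degenerate inputs", {
  D <- matrix(0, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_error(nj_tree(D), "at least 3")
  D3 <- matrix(c(0, 1, NA, 1, 0, 1, NA, 1, 0), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_error(nj_tree(D3), "a/c")
})

test_that("bootstrap supports are high for well-separated clades", {
  # two clades separated by 20 fixed substitutions over 300 columns
  for (sd in 1:3) {
    set.seed(100 + sd)
    base <- sample(ACGT, 300, TRUE)
    other <- base
    idx <- sample(300, 20)
    other[idx] <- vapply(other[idx], function(b)
      sample(setdiff(ACGT, b), 1), character(1))
    seqs <- c(lapply(1:3, function(i) mutate_sites(base, 1)),
              lapply(1:3, function(i) mutate_sites(other, 1)))
    names(seqs) <- c(paste0("a", 1:3), paste0("b", 1:3))
    lib <- make_lib(seqs, rep(c("spA", "spB"), each = 3))
    tr <- bootstrap_supports(lib, replicates = 100, seed = sd)
    # root outside each clade under test
    expect_true(is_monophyletic(tr, paste0("a", 1:3), outgroup = "b1"))
    expect_true(is_monophyletic(tr, paste0("b", 1:3), outgroup = "a1"))
    # the a-clade bipartition is an internal node of the unrooted tree;
    # with 20 fixed differences its support should be near-certain
    expect_gte(max(tr$node.label), 95)
  }
})

test_that("bootstrap supports are reproducible and bounded", {
  sim <- simulate_library(sim_config(n_species = 3, members_per_species = 3,
                                     seq_length = 300,
                                     nb_site_plan = NULL, seed = 14))
  t1 <- bootstrap_supports(sim$library, replicates = 25, seed = 5)
  t2 <- bootstrap_supports(sim$library, replicates = 25, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100))
  tr1 <- bootstrap_supports(sim$library, replicates = 1, seed = 6)
  expect_true(all(tr1$node.label %in% c(0L, 100L)))
})

test_that("monophyly testing honours the rooting", {
  tr <- ape::read.tree(text = "((A1:1,A2:1):1,(B1:3,(A3:1,B2:1):1):1);")
  expect_false(is_monophyletic(tr, c("A1", "A2", "A3"), outgroup = "B1"))
  expect_true(is_monophyletic(tr, c("A1", "A2"), outgroup = "B1"))
  expect_true(is_monophyletic(tr, tr$tip.label))
  expect_error(is_monophyletic(tr, "nope"), "unknown")
})

test_that("differentiation requires monophyly and unshared haplotypes", {
  set.seed(41)
  sim <- simulate_library(sim_config(n_species = 6, members_per_species = 3,
                                     seed = 19))
  lib <- sim$library
  dm <- distance_matrix(lib)
  tr <- nj_tree(dm)
  haps <- collapse_haplotypes(lib)
  sp <- taxon_labels(lib)
  rep0 <- differentiation_report(tr, haps, sp)
  expect_equal(attr(rep0, "success_fraction"), 1)
  # plant a shared haplotype between sp01 and sp02: both species fail,
  # success = (n - 2) / n
  m <- lib$seq
  m["sp02_01", ] <- m["sp01_01", ]
  lib2 <- barcode_library(m, lib$meta)
  haps2 <- collapse_haplotypes(lib2)
  rep2 <- differentiation_report(nj_tree(distance_matrix(lib2)), haps2, sp)
  expect_false(rep2$success[rep2$species == "sp01"])
  expect_false(rep2$success[rep2$species == "sp02"])
  expect_equal(attr(rep2, "success_fraction"), (6 - 2) / 6)
})

test_that("a nested singleton leaves only the paraphyletic species failing", {
  fx <- simulate_paraphyly_library(seed = 11, n_species = 12)
  lib <- fx$library
  tr <- nj_tree(distance_matrix(lib))
  haps <- collapse_haplotypes(lib)
  rep <- differentiation_report(tr, haps, taxon_labels(lib))
  expect_false(rep$success[rep$species == fx$paraphyletic_species])
  expect_identical(rep$status[rep$species == fx$paraphyletic_species],
                   "non-monophyletic")
  expect_true(rep$success[rep$species == fx$singleton_species])
  expect_identical(rep$status[rep$species == fx$singleton_species],
                   "singleton")
  expect_equal(attr(rep, "success_fraction"), 11 / 12)
})
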