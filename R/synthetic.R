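#' Configuration for the barcode-library simulator
#'
#' The simulator emulates the statistical structure of a multi-species COI
#' barcode reference library: tight within-species haplotype clusters
#' (default mean pairwise divergence 0.66 percent) separated by much deeper
#' between-species divergence (default mean 14.02 percent), optional
#' subspecies structure, singleton species, degraded (truncated) sequences,
#' and planted NlaIII/BamHI restriction-site states for NB-system typing.
#'
#' @param n_species number of species
#' @param members_per_species scalar or length-`n_species` vector of sample
#'   sizes (1 allowed: singleton species)
#' @param seq_length alignment length (barcode frame; >= 100)
#' @param kappa transition/transversion rate ratio of the K80 mutation
#'   process (the fraction of substitutions that are transitions is
#'   `kappa / (kappa + 2)`)
#' @param mean_intra_divergence target mean within-species pairwise K2P
#'   divergence (substitutions/site)
#' @param mean_inter_divergence target mean between-species pairwise K2P
#'   divergence (substitutions/site)
#' @param subspecies_spec optional named list: for each species to split,
#'   `list(labels = c(...), divergence = x)`; members are assigned to
#'   subspecies round-robin and subspecies ancestors diverge from the
#'   species ancestor so that between-subspecies distance averages
#'   `divergence`
#' @param nb_site_plan `"random"` (default: each species drawn one NB class
#'   with realistic weights), `NULL` (no planting), or a data frame with
#'   columns `species`, `N`, `B` (logical)
#' @param degradation list(`fraction`, `length_range`): that fraction of
#'   records is truncated to a contiguous stretch whose length is drawn
#'   uniformly from the range, the rest replaced by gaps
#' @param seed integer seed (mandatory; the whole simulation is reproducible
#'   from it)
#' @return list of class `sim_config`
#' @export
sim_config <- function(n_species = 36,
                       members_per_species = 5,
                       seq_length = 658,
                       kappa = 2,
                       mean_intra_divergence = 0.0066,
                       mean_inter_divergence = 0.1402,
                       subspecies_spec = NULL,
                       nb_site_plan = "random",
                       degradation = list(fraction = 0,
                                          length_range = c(375, 450)),
                       seed) {
  if (missing(seed)) stop("a seed is mandatory for reproducible simulation")
  stopifnot(n_species >= 1, seq_length >= 100,
            mean_intra_divergence >= 0, mean_intra_divergence < 0.75,
            mean_inter_divergence > 0, mean_inter_divergence < 0.75,
            kappa > 0)
  members <- if (length(members_per_species) == 1L)
    rep(members_per_species, n_species) else members_per_species
  if (length(members) != n_species || any(members < 1)) {
    stop("members_per_species must be a scalar or length-n_species vector of counts >= 1")
  }
  structure(list(n_species = n_species, members_per_species = members,
                 seq_length = as.integer(seq_length), kappa = kappa,
                 mean_intra_divergence = mean_intra_divergence,
                 mean_inter_divergence = mean_inter_divergence,
                 subspecies_spec = subspecies_spec,
                 nb_site_plan = nb_site_plan,
                 degradation = degradation, seed = as.integer(seed)),
            class = "sim_config")
}

# One K80 substitution at a uniformly chosen site: transition with
# probability kappa/(kappa+2), otherwise one of the two transversions.
# Multiple hits at a site are allowed (this is what shrinks realized
# distances below the expected substitution count at high divergence).
.mutate <- function(sv, n_mut, kappa) {
  if (n_mut == 0L) return(sv)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  sites <- sample.int(length(sv), n_mut, replace = TRUE)
  p_ts <- kappa / (kappa + 2)
  for (s in sites) {
    b <- sv[s]
    sv[s] <- if (stats::runif(1) < p_ts) ts_map[[b]] else
      sample(tv_map[[b]], 1L)
  }
  sv
}

# Broken motif variants used to plant site absence: one substitution away
# from the recognition motif.
.NB_ABSENT <- list(NlaIII = "CACG", BamHI = "GGATAC")

.plant_windows <- function(sv, N, B, windows) {
  put <- function(sv, start, motif) {
    sv[start:(start + nchar(motif) - 1L)] <-
      strsplit(motif, "")[[1L]]
    sv
  }
  sv <- put(sv, windows$n_mono_start, windows$enzymes$NlaIII$motif)
  sv <- put(sv, windows$n_diag_start,
            if (N) windows$enzymes$NlaIII$motif else .NB_ABSENT$NlaIII)
  put(sv, windows$b_diag_start,
      if (B) windows$enzymes$BamHI$motif else .NB_ABSENT$BamHI)
}

#' Simulate a barcode reference library with known truth
#'
#' A root sequence is drawn uniformly over A/C/G/T; each species ancestor
#' diverges from it by a Poisson number of K80 substitutions with mean
#' `mean_inter_divergence * L / 2` (star phylogeny, so the expected pairwise
#' distance between two species is the configured inter-species mean); each
#' individual then diverges from its species (or subspecies) ancestor by a
#' Poisson number with mean `mean_intra_divergence * L / 2`, so the expected
#' within-species pairwise distance is the configured intra-species mean.
#' NB windows are overwritten per the site plan, and degradation (gap
#' truncation) is applied last. Everything is reproducible from the seed.
#'
#' @param cfg a `sim_config`
#' @param windows NB window configuration (must fit inside `seq_length`)
#' @return list with `library` (a `barcode_library`) and `truth` (data frame
#'   of class `truth_table`: per-record id, species, subspecies, planted NB
#'   class, haplotype id over full-length pre-degradation sequences, and
#'   mutation counts from the ancestor). The root sequence, the realized
#'   ancestor divergences and the config are kept as attributes of `truth`.
#' @export
simulate_library <- function(cfg, windows = default_nb_windows()) {
  stopifnot(inherits(cfg, "sim_config"))
  L <- cfg$seq_length
  win_end <- max(windows$n_mono_start + 3L, windows$n_diag_start + 3L,
                 windows$b_diag_start + 5L)
  if (!is.null(cfg$nb_site_plan) && win_end > L) {
    stop("NB windows extend past seq_length (need >= ", win_end, " columns)")
  }
  set.seed(cfg$seed)
  root <- sample(BASES, L, replace = TRUE)
  species <- sprintf("sp%02d", seq_len(cfg$n_species))
  # NB plan
  plan <- cfg$nb_site_plan
  if (identical(plan, "random")) {
    classes <- c("N+B-", "N-B-", "N+B+", "N-B+")
    drawn <- sample(classes, cfg$n_species, replace = TRUE,
                    prob = c(0.6, 0.25, 0.1, 0.05))
    plan <- data.frame(species = species,
                       N = substr(drawn, 2, 2) == "+",
                       B = substr(drawn, 4, 4) == "+",
                       stringsAsFactors = FALSE)
  }
  if (!is.null(plan) && !all(species %in% plan$species)) {
    stop("nb_site_plan must cover every species")
  }
  anc_mut <- stats::rpois(cfg$n_species, cfg$mean_inter_divergence * L / 2)
  ancestors <- lapply(seq_len(cfg$n_species), function(i)
    .mutate(root, anc_mut[i], cfg$kappa))
  names(ancestors) <- species
  rows <- list(); meta <- list(); truth <- list()
  for (i in seq_len(cfg$n_species)) {
    sp <- species[i]
    n_i <- cfg$members_per_species[i]
    sub_spec <- cfg$subspecies_spec[[sp]]
    if (!is.null(sub_spec)) {
      sub_labels <- sub_spec$labels
      sub_anc <- lapply(sub_labels, function(lab)
        .mutate(ancestors[[sp]],
                stats::rpois(1, sub_spec$divergence * L / 2), cfg$kappa))
      names(sub_anc) <- sub_labels
      member_sub <- rep(sub_labels, length.out = n_i)
    } else {
      member_sub <- rep(NA_character_, n_i)
    }
    for (k in seq_len(n_i)) {
      id <- sprintf("%s_%02d", sp, k)
      anc <- if (is.na(member_sub[k])) ancestors[[sp]] else
        sub_anc[[member_sub[k]]]
      nm <- stats::rpois(1, cfg$mean_intra_divergence * L / 2)
      sv <- .mutate(anc, nm, cfg$kappa)
      nb_class <- NA_character_
      if (!is.null(plan)) {
        pr <- plan[plan$species == sp, ]
        sv <- .plant_windows(sv, pr$N[1], pr$B[1], windows)
        nb_class <- paste0("N", if (pr$N[1]) "+" else "-",
                           "B", if (pr$B[1]) "+" else "-")
      }
      rows[[id]] <- sv
      meta[[id]] <- data.frame(id = id, species = sp,
                               subspecies = member_sub[k],
                               country = NA, locality = NA,
                               lat = NA, lon = NA, source = "synthetic",
                               stringsAsFactors = FALSE)
      truth[[id]] <- data.frame(id = id, species = sp,
                                subspecies = member_sub[k],
                                nb_class = nb_class, n_mut = nm,
                                truncated = FALSE,
                                stringsAsFactors = FALSE)
    }
  }
  m <- do.call(rbind, rows)
  truth_df <- do.call(rbind, truth)
  rownames(truth_df) <- NULL
  # haplotype ids over full-length (pre-degradation) sequences
  full_str <- apply(m, 1, paste, collapse = "")
  truth_df$haplotype <- sprintf("T%03d",
                                as.integer(factor(full_str,
                                                  levels = unique(full_str))))
  # degradation last
  frac <- cfg$degradation$fraction
  if (frac > 0) {
    n_all <- nrow(m)
    n_trunc <- round(frac * n_all)
    if (n_trunc > 0) {
      victims <- sample.int(n_all, n_trunc)
      for (v in victims) {
        keep_len <- sample(seq(cfg$degradation$length_range[1],
                               cfg$degradation$length_range[2]), 1L)
        keep_len <- min(keep_len, L)
        start <- if (stats::runif(1) < 0.5) 1L else L - keep_len + 1L
        gap <- rep("-", L)
        gap[start:(start + keep_len - 1L)] <- m[v, start:(start + keep_len - 1L)]
        m[v, ] <- gap
        truth_df$truncated[v] <- TRUE
      }
    }
  }
  lib <- barcode_library(m, do.call(rbind, meta))
  attr(truth_df, "config") <- cfg
  attr(truth_df, "root") <- root
  attr(truth_df, "ancestor_mutations") <-
    stats::setNames(anc_mut, species)
  attr(truth_df, "windows") <- windows
  class(truth_df) <- c("truth_table", class(truth_df))
  list(library = lib, truth = truth_df)
}

#' Simulate query specimens against a simulated library
#'
#' `held_out` draws existing records (at most `n_i - min_remaining` per
#' species, so every queried species keeps a usable reference sample) and
#' removes them from the returned library copy. `novel_species` generates
#' queries from a previously unseen species ancestor, emulating a
#' surveillance interception of a taxon absent from the reference library.
#'
#' @param lib the simulated `barcode_library`
#' @param truth its `truth_table` (carries the simulation config and root)
#' @param n_queries number of queries
#' @param mode `"held_out"` or `"novel_species"`
#' @param seed integer seed
#' @param min_remaining for `held_out`, minimum members a species must
#'   retain in the reduced library (default 2)
#' @return list with `queries` (a `barcode_library`), `library` (reduced
#'   copy for `held_out`, unchanged otherwise) and `answer_key` (data frame
#'   id, species, subspecies; species is `"novel"` for novel-species
#'   queries)
#' @export
simulate_queries <- function(lib, truth, n_queries,
                             mode = c("held_out", "novel_species"),
                             seed = 1, min_remaining = 2) {
  mode <- match.arg(mode)
  set.seed(seed)
  cfg <- attr(truth, "config")
  if (mode == "held_out") {
    counts <- table(lib$meta$species)
    avail <- sum(pmax(0L, as.integer(counts) - min_remaining))
    if (n_queries > avail) {
      stop("only ", avail, " records can be held out while keeping ",
           min_remaining, " per species")
    }
    order_ids <- sample(rownames(lib$seq))
    left <- as.list(counts)
    chosen <- character(0)
    for (id in order_ids) {
      if (length(chosen) == n_queries) break
      sp <- lib$meta$species[lib$meta$id == id]
      if (left[[sp]] > min_remaining) {
        chosen <- c(chosen, id)
        left[[sp]] <- left[[sp]] - 1L
      }
    }
    queries <- subset_library(lib, chosen)
    reduced <- subset_library(lib, setdiff(rownames(lib$seq), chosen))
    key <- queries$meta[, c("id", "species", "subspecies")]
    list(queries = queries, library = reduced, answer_key = key)
  } else {
    root <- attr(truth, "root")
    windows <- attr(truth, "windows")
    L <- cfg$seq_length
    anc <- .mutate(root, stats::rpois(1, cfg$mean_inter_divergence * L / 2),
                   cfg$kappa)
    rows <- list()
    for (k in seq_len(n_queries)) {
      sv <- .mutate(anc, stats::rpois(1, cfg$mean_intra_divergence * L / 2),
                    cfg$kappa)
      if (!is.null(cfg$nb_site_plan)) {
        sv <- .plant_windows(sv, TRUE, FALSE, windows)
      }
      rows[[sprintf("novel_%02d", k)]] <- sv
    }
    m <- do.call(rbind, rows)
    meta <- data.frame(id = rownames(m), species = "novel",
                       stringsAsFactors = FALSE)
    queries <- barcode_library(m, meta)
    list(queries = queries, library = lib,
         answer_key = data.frame(id = rownames(m), species = "novel",
                                 subspecies = NA_character_,
                                 stringsAsFactors = FALSE))
  }
}

#' Simulate a library with one engineered paraphyly
#'
#' Reproduces the one failure mode the differentiation criterion is designed
#' to catch: a species whose barcodes carry a deep internal split (default
#' 2.9 percent K2P) with a singleton of a second species nested inside the
#' split, so the first species is paraphyletic with respect to the
#' singleton. All other species are generated under the default study
#' conditions. The multi-member species fails the monophyly criterion while
#' the nested singleton, carrying its own haplotype, still succeeds, so the
#' expected differentiation tally over `n_species` species is
#' `(n_species - 1) / n_species` (35/36 = 97.2 percent at the default size).
#'
#' @param seed integer seed
#' @param n_species total species count including the nested singleton
#' @param split_divergence depth of the engineered intraspecific split
#'   (substitutions/site)
#' @return list with `library` (a `barcode_library`), `paraphyletic_species`
#'   and `singleton_species` (labels)
#' @export
simulate_paraphyly_library <- function(seed, n_species = 36,
                                       split_divergence = 0.029) {
  stopifnot(n_species >= 4)
  base_n <- n_species - 1L
  split_sp <- sprintf("sp%02d", base_n)
  nested_sp <- sprintf("sp%02d", n_species)
  members <- c(rep(5L, base_n - 1L), 3L)
  spec <- list(list(labels = c("main", "deep"),
                    divergence = split_divergence))
  names(spec) <- split_sp
  cfg <- sim_config(n_species = base_n, members_per_species = members,
                    subspecies_spec = spec, seed = seed)
  sim <- simulate_library(cfg)
  windows <- attr(sim$truth, "windows")
  L <- cfg$seq_length
  # member 2 of the split species sits on the deep side (round-robin
  # subspecies assignment); derive the nested singleton from it
  deep_id <- sprintf("%s_02", split_sp)
  sv <- .mutate(sim$library$seq[deep_id, ],
                stats::rpois(1, cfg$mean_intra_divergence * L / 2) + 1L,
                cfg$kappa)
  sv <- .plant_windows(sv, TRUE, FALSE, windows)
  nid <- sprintf("%s_01", nested_sp)
  m <- rbind(sim$library$seq, sv)
  rownames(m) <- c(rownames(sim$library$seq), nid)
  meta <- rbind(sim$library$meta,
                data.frame(id = nid, species = nested_sp,
                           subspecies = NA, country = NA, locality = NA,
                           lat = NA, lon = NA, source = "synthetic",
                           stringsAsFactors = FALSE))
  list(library = barcode_library(m, meta),
       paraphyletic_species = split_sp,
       singleton_species = nested_sp)
}
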