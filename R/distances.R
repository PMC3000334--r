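#' Kimura 2-parameter distance between two aligned sequences
#'
#' Computes the K2P distance with pairwise deletion: every alignment column
#' where either sequence carries a gap, N, or another ambiguity code is
#' excluded, and the proportions of transition (`P`) and transversion (`Q`)
#' differences are taken over the remaining comparable columns.
#' The distance is `d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q)`.
#'
#' Transitions are A<->G and C<->T; every other differing unambiguous pair is
#' a transversion. When no comparable columns remain the distance is flagged
#' `"undefined"`; when an argument of a logarithm is non-positive (too many
#' differences for the model) it is flagged `"saturated"`. Flagged distances
#' are `NA` and are excluded from (but counted by) the summary functions.
#'
#' @param seq_a,seq_b sequences of equal padded length (strings or character
#'   vectors)
#' @return list of class `k2p_pair` with elements `P`, `Q`, `L_comp`
#'   (comparable sites), `n_ts`, `n_tv`, `d`, `flag` (one of `"ok"`,
#'   `"undefined"`, `"saturated"`)
#' @export
k2p <- function(seq_a, seq_b) {
  a <- .as_seqvec(seq_a)
  b <- .as_seqvec(seq_b)
  if (length(a) != length(b)) {
    stop("sequences must have equal padded length (", length(a), " vs ",
         length(b), ")")
  }
  ok <- a %in% BASES & b %in% BASES
  L <- sum(ok)
  if (L == 0L) {
    return(structure(list(P = NA_real_, Q = NA_real_, L_comp = 0L,
                          n_ts = NA_integer_, n_tv = NA_integer_,
                          d = NA_real_, flag = "undefined"),
                     class = "k2p_pair"))
  }
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine_a <- a %in% c("A", "G")
  purine_b <- b %in% c("A", "G")
  n_ts <- sum(diff & purine_a == purine_b)
  n_tv <- sum(diff) - n_ts
  P <- n_ts / L
  Q <- n_tv / L
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    d <- NA_real_; flag <- "saturated"
  } else {
    d <- -0.5 * log(w1) - 0.25 * log(w2); flag <- "ok"
  }
  structure(list(P = P, Q = Q, L_comp = L, n_ts = n_ts, n_tv = n_tv,
                 d = d, flag = flag), class = "k2p_pair")
}

#' Pairwise K2P distance matrix for a library
#'
#' All unordered pairs are computed with pairwise deletion (see [k2p()]).
#' The computation is vectorised through indicator-matrix cross-products, so
#' libraries of several hundred records are handled in well under a second.
#'
#' @param lib a `barcode_library` (or character matrix of aligned sequences)
#' @return list of class `k2p_matrix` with elements `labels`, `d` (symmetric
#'   distance matrix, `NA` where flagged), `comparable` (matrix of
#'   comparable-site counts) and `flag` (character matrix: `"ok"`,
#'   `"undefined"`, `"saturated"`)
#' @export
distance_matrix <- function(lib) {
  m <- .as_seqmat(lib)
  if (nrow(m) < 2L) stop("need at least 2 records for a distance matrix")
  pc <- .pair_counts(m)
  AG <- tcrossprod(pc$ind[[1]], pc$ind[[3]])
  CT <- tcrossprod(pc$ind[[2]], pc$ind[[4]])
  ts <- AG + t(AG) + CT + t(CT)
  diffs <- pc$comparable - pc$matches
  tv <- diffs - ts
  P <- ts / pc$comparable
  Q <- tv / pc$comparable
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  # flagged entries are overwritten with NA below, so log() domain warnings
  # on saturated pairs are spurious
  d <- suppressWarnings(-0.5 * log(w1) - 0.25 * log(w2))
  flag <- matrix("ok", nrow(m), nrow(m))
  flag[w1 <= 0 | w2 <= 0] <- "saturated"
  flag[pc$comparable == 0] <- "undefined"
  d[flag != "ok"] <- NA_real_
  diag(d) <- 0
  diag(flag) <- "ok"
  dimnames(d) <- dimnames(flag) <- dimnames(pc$comparable) <-
    list(rownames(m), rownames(m))
  structure(list(labels = rownames(m), d = d, comparable = pc$comparable,
                 flag = flag), class = "k2p_matrix")
}

#' @export
print.k2p_matrix <- function(x, ...) {
  cat("k2p_matrix:", length(x$labels), "records;",
      sum(x$flag[upper.tri(x$flag)] != "ok"), "flagged pairs\n")
  invisible(x)
}

.as_dmatrix <- function(dm) {
  if (inherits(dm, "k2p_matrix")) return(dm$d)
  if (inherits(dm, "dist")) return(as.matrix(dm))
  as.matrix(dm)
}

# Pooled intraspecific distances (species with >= 2 members) and per-pair
# interspecific means, in percent. Flagged (NA) pairs are dropped and counted.
.divergence_sets <- function(dm, species_of) {
  d <- .as_dmatrix(dm)
  labs <- rownames(d)
  sp <- unname(species_of[labs])
  if (any(is.na(sp))) stop("species_of must cover every matrix label")
  species <- sort(unique(sp))
  intra <- numeric(0)
  intra_sp <- character(0)
  n_flagged <- 0L
  for (s in species) {
    idx <- which(sp == s)
    if (length(idx) < 2L) next
    v <- d[idx, idx][upper.tri(diag(length(idx)))]
    n_flagged <- n_flagged + sum(is.na(v))
    intra_sp <- c(intra_sp, rep(s, sum(!is.na(v))))
    intra <- c(intra, v[!is.na(v)])
  }
  inter <- numeric(0)
  inter_pairs <- data.frame(sp1 = character(), sp2 = character(),
                            mean_d_pct = numeric(), stringsAsFactors = FALSE)
  if (length(species) >= 2L) {
    combs <- utils::combn(species, 2)
    inter <- apply(combs, 2, function(pr) {
      v <- d[sp == pr[1], sp == pr[2]]
      mean(v, na.rm = TRUE)
    })
    n_flagged <- n_flagged + sum(is.nan(inter))
    keep <- !is.nan(inter)
    inter_pairs <- data.frame(sp1 = combs[1, keep], sp2 = combs[2, keep],
                              mean_d_pct = 100 * inter[keep],
                              stringsAsFactors = FALSE)
    inter <- inter[keep]
  }
  list(intra_pct = 100 * intra, intra_species = intra_sp,
       inter_pct = 100 * inter, inter_pairs = inter_pairs,
       n_flagged = n_flagged)
}

.summarise_set <- function(x) {
  if (length(x) == 0L) {
    return(list(mean = NA_real_, sd = NA_real_, min = NA_real_,
                max = NA_real_, n = 0L, empty = TRUE))
  }
  list(mean = mean(x), sd = stats::sd(x), min = min(x), max = max(x),
       n = length(x), empty = FALSE)
}

#' Intra- and interspecific divergence summaries
#'
#' The intraspecific set pools all within-species pairwise distances over
#' species with at least two members. The interspecific set contains one
#' value per unordered species pair: the mean of all cross-species pairwise
#' distances for that pair (so a library of k species always yields
#' `choose(k, 2)` interspecific comparisons). Values are reported in percent.
#'
#' @param dm a `k2p_matrix` (or plain distance matrix)
#' @param species_of character vector mapping record id to species
#'   (e.g. from [taxon_labels()])
#' @return list of class `divergence_summary` with elements `intra`, `inter`
#'   (each: `mean`, `sd`, `min`, `max`, `n`, `empty`), `fold_ratio`
#'   (inter mean / intra mean) and `n_flagged` (excluded pairs)
#' @export
divergence_summaries <- function(dm, species_of) {
  sets <- .divergence_sets(dm, species_of)
  intra <- .summarise_set(sets$intra_pct)
  inter <- .summarise_set(sets$inter_pct)
  structure(list(intra = intra, inter = inter,
                 fold_ratio = if (!intra$empty && intra$mean > 0)
                   inter$mean / intra$mean else NA_real_,
                 n_flagged = sets$n_flagged),
            class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  fmt <- function(s, label) {
    if (s$empty) return(cat(label, ": (empty)\n", sep = ""))
    cat(sprintf("%s: mean %.2f%%; SD %.2f%%; range %.2f-%.2f%% (n = %d)\n",
                label, s$mean, s$sd, s$min, s$max, s$n))
  }
  fmt(x$intra, "intraspecific")
  fmt(x$inter, "interspecific")
  if (!is.na(x$fold_ratio)) {
    cat(sprintf("inter/intra fold ratio: %.1f\n", x$fold_ratio))
  }
  invisible(x)
}

#' Divergence-overlap (barcode gap) analysis
#'
#' Counts how many intraspecific distances (pooled) and interspecific
#' species-pair means fall inside a window of percent divergence, and lists
#' the species involved. The window is a closed interval by default.
#'
#' @param dm a `k2p_matrix`
#' @param species_of id -> species mapping
#' @param window_lo_pct,window_hi_pct window bounds in percent
#' @return list with `n_intra_total`, `n_intra_in_window`, `n_inter_total`,
#'   `n_inter_in_window`, `offending_taxa` (species appearing in any
#'   in-window comparison) and `offending_pairs` (data frame of in-window
#'   species pairs)
#' @export
overlap_analysis <- function(dm, species_of, window_lo_pct = 2,
                             window_hi_pct = 4) {
  stopifnot(window_lo_pct < window_hi_pct)
  sets <- .divergence_sets(dm, species_of)
  in_intra <- sets$intra_pct >= window_lo_pct & sets$intra_pct <= window_hi_pct
  in_inter <- sets$inter_pct >= window_lo_pct & sets$inter_pct <= window_hi_pct
  pairs <- sets$inter_pairs[in_inter, , drop = FALSE]
  list(n_intra_total = length(sets$intra_pct),
       n_intra_in_window = sum(in_intra),
       n_inter_total = length(sets$inter_pct),
       n_inter_in_window = sum(in_inter),
       offending_taxa = sort(unique(c(sets$intra_species[in_intra],
                                      pairs$sp1, pairs$sp2))),
       offending_pairs = pairs)
}

#' Histogram of intra- vs interspecific divergences
#'
#' Bins the pooled intraspecific distances and the interspecific species-pair
#' means (both in percent) into left-closed, right-open bins of equal width;
#' the final bin is closed so counts conserve totals.
#'
#' @param dm a `k2p_matrix`
#' @param species_of id -> species mapping
#' @param bin_width_pct bin width in percent
#' @return data frame with columns `bin_lo`, `bin_hi`, `intra_count`,
#'   `inter_count`
#' @export
histogram_export <- function(dm, species_of, bin_width_pct = 1) {
  stopifnot(bin_width_pct > 0)
  sets <- .divergence_sets(dm, species_of)
  top <- max(c(sets$intra_pct, sets$inter_pct, bin_width_pct))
  breaks <- seq(0, ceiling(top / bin_width_pct) * bin_width_pct,
                by = bin_width_pct)
  binify <- function(x) {
    if (length(x) == 0L) return(integer(length(breaks) - 1L))
    idx <- pmin(findInterval(x, breaks, rightmost.closed = TRUE),
                length(breaks) - 1L)
    tabulate(idx, nbins = length(breaks) - 1L)
  }
  data.frame(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1L],
             intra_count = binify(sets$intra_pct),
             inter_count = binify(sets$inter_pct))
}
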