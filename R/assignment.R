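#' Number of segregating sites in an aligned sample
#'
#' A column segregates when at least two distinct unambiguous bases occur
#' among the sequences; gaps, N and other ambiguity codes are ignored at that
#' column (so a column `{A, N, G}` segregates on the strength of A vs G).
#'
#' @param seqs aligned sequences (character matrix, library, or vector of
#'   equal-length strings)
#' @return integer count of segregating columns
#' @export
segregating_sites <- function(seqs) {
  m <- .as_seqmat(seqs)
  states <- Reduce(`+`, lapply(BASES, function(b) (colSums(m == b) > 0) * 1L))
  sum(states >= 2L)
}

#' Watterson's estimator of the population mutation rate
#'
#' `theta_hat = S / a_n` with `a_n = sum_{i=1}^{n-1} 1/i`; per locus, not per
#' site, matching the segregating-sites assignment model. Undefined for
#' `n = 1`.
#'
#' @param S number of segregating sites
#' @param n sample size
#' @return numeric estimate (NA for n < 2)
#' @export
watterson_theta <- function(S, n) {
  if (n < 2L) return(NA_real_)
  S / sum(1 / seq_len(n - 1L))
}

# Full pmf of the number of segregating sites S_n for k = 0..kmax under the
# neutral coalescent with infinite sites. While i lineages remain, the
# number of mutations in that epoch is geometric with success probability
# (i-1)/(theta+i-1), independently across epochs; S_n is their sum, so the
# pmf is a convolution of geometrics. The convolution uses the O(kmax)
# geometric recurrence and involves only positive terms, avoiding the
# catastrophic cancellation of the equivalent alternating-series closed form
# at large n.
.segsites_pmf <- function(n, theta, kmax) {
  stopifnot(n >= 2, theta >= 0, kmax >= 0)
  if (theta == 0) return(c(1, rep(0, kmax)))
  pmf <- c(1, rep(0, kmax))
  for (i in 2:n) {
    p <- (i - 1) / (theta + i - 1)
    q <- 1 - p
    out <- numeric(kmax + 1L)
    out[1L] <- p * pmf[1L]
    if (kmax >= 1L) {
      for (k in 2:(kmax + 1L)) out[k] <- q * out[k - 1L] + p * pmf[k]
    }
    pmf <- out
  }
  pmf
}

#' Probability of observing k segregating sites
#'
#' Distribution of the number of segregating sites in a sample of `n`
#' sequences under the neutral coalescent with infinite-sites mutation at
#' rate `theta` (per locus). Computed as a convolution of independent
#' geometric epoch contributions, which is numerically stable for any `n`.
#' For `theta = 0` the distribution is a point mass at zero.
#'
#' @param n sample size (>= 2)
#' @param theta population mutation rate (>= 0)
#' @param k number of segregating sites (vectorised, >= 0)
#' @return probability (vector along `k`)
#' @export
prob_segsites <- function(n, theta, k) {
  stopifnot(n >= 2, theta >= 0, all(k >= 0))
  pmf <- .segsites_pmf(n, theta, max(k))
  pmf[k + 1L]
}

#' Count simple diagnostic sites for a taxon
#'
#' A column is a simple (pure) diagnostic character for the focal taxon when
#' every unambiguous base the taxon carries there is one single state, and
#' that state never occurs unambiguously in the comparison sequences at that
#' column. Columns where the taxon has no unambiguous base do not count.
#'
#' @param taxon_seqs aligned sequences of the focal taxon
#' @param other_seqs aligned sequences of all other taxa (same frame)
#' @return integer count of diagnostic columns
#' @export
diagnostic_sites <- function(taxon_seqs, other_seqs) {
  mt <- .as_seqmat(taxon_seqs)
  mo <- .as_seqmat(other_seqs)
  if (ncol(mt) != ncol(mo)) stop("alignments must share the same frame")
  pres_t <- sapply(BASES, function(b) colSums(mt == b) > 0)
  pres_o <- sapply(BASES, function(b) colSums(mo == b) > 0)
  if (is.null(dim(pres_t))) pres_t <- matrix(pres_t, nrow = 1)
  if (is.null(dim(pres_o))) pres_o <- matrix(pres_o, nrow = 1)
  fixed_one <- rowSums(pres_t) == 1L
  absent_in_others <- rowSums(pres_t & pres_o) == 0L
  sum(fixed_one & absent_in_others)
}

# Library-wide fallback theta: median Watterson estimate over taxa with
# n >= 2 and at least one segregating site, on the given columns.
.median_theta <- function(m, taxa_of, cols) {
  vals <- c()
  for (tx in unique(taxa_of)) {
    rows <- which(taxa_of == tx)
    if (length(rows) < 2L) next
    S <- segregating_sites(m[rows, cols, drop = FALSE])
    if (S > 0L) vals <- c(vals, watterson_theta(S, length(rows)))
  }
  if (length(vals) == 0L) 0 else stats::median(vals)
}

#' Bayesian assignment of a query sequence by segregating sites
#'
#' For each candidate taxon the query is provisionally added to the taxon's
#' sample and the number of segregating sites recomputed; the likelihood of
#' the enlarged count under the taxon's own Watterson estimate of theta
#' (neutral coalescent, infinite sites) scores the membership hypothesis. A
#' query that belongs adds few or no new segregating sites; a foreign query
#' adds many, and the coalescent distribution penalises the excess sharply.
#' Posterior probabilities follow from the prior (uniform by default);
#' the reported risk of mis-assignment is `1 - posterior` (0-1 loss).
#'
#' Alignment columns where the query carries a gap or ambiguity code are
#' dropped for all of this query's computations (query-wise pairwise
#' deletion), so degraded queries are scored only on the region they cover.
#'
#' Degenerate candidates are handled by empirical borrowing: a taxon sampled
#' once is scored as a two-sequence sample (singleton + query), and a taxon
#' with no observed polymorphism (theta_hat = 0, a degenerate maximum
#' likelihood estimate under which any new variant would be impossible)
#' borrows the library-wide median theta. Both cases are flagged in the
#' per-candidate table.
#'
#' @param lib a `barcode_library` of reference sequences
#' @param query_seq query sequence in the same alignment frame (string or
#'   character vector)
#' @param query_id identifier used in the output
#' @param level `"species"` or `"subspecies"` (see [taxon_labels()]);
#'   records without a subspecies label are excluded at subspecies level
#' @param prior optional named numeric vector of prior weights over candidate
#'   taxa (need not be normalised); default uniform
#' @return list of class `assignment_result`: `query_id`, `assigned`
#'   (taxon label or NA), `posterior`, `risk`, `n_diagnostic_sites`,
#'   `unassignable`, `tie` (logical), and `table` (per-candidate data frame
#'   with `taxon`, `n`, `S`, `theta`, `S_new`, `likelihood`, `posterior`,
#'   `risk`, `flag`)
#' @export
assign_query <- function(lib, query_seq, query_id = "query",
                         level = c("species", "subspecies"), prior = NULL) {
  level <- match.arg(level)
  q <- .as_seqvec(query_seq)
  m <- lib$seq
  if (length(q) != ncol(m)) {
    stop("query length ", length(q), " does not match alignment frame ",
         ncol(m))
  }
  cols <- which(q %in% BASES)
  if (length(cols) == 0L) stop("query has no unambiguous bases")
  taxa_of <- taxon_labels(lib, level)[rownames(m)]
  keep <- !is.na(taxa_of)
  m <- m[keep, , drop = FALSE]
  taxa_of <- taxa_of[keep]
  taxa <- sort(unique(unname(taxa_of)))
  if (length(taxa) < 2L) stop("need at least 2 candidate taxa")
  theta_med <- .median_theta(m, taxa_of, cols)
  qc <- q[cols]
  rows_of <- split(seq_len(nrow(m)), unname(taxa_of))
  tab <- do.call(rbind, lapply(taxa, function(tx) {
    rows <- rows_of[[tx]]
    sub <- m[rows, cols, drop = FALSE]
    n <- length(rows)
    S <- segregating_sites(sub)
    S_new <- segregating_sites(rbind(sub, qc))
    flag <- ""
    if (n == 1L) {
      theta <- theta_med
      n_eff <- 1L
      flag <- "singleton: borrowed median theta"
    } else {
      theta <- watterson_theta(S, n)
      n_eff <- n
      if (theta == 0 && theta_med > 0) {
        theta <- theta_med
        flag <- "monomorphic: borrowed median theta"
      }
    }
    lik <- prob_segsites(n_eff + 1L, theta, S_new)
    data.frame(taxon = tx, n = n, S = S, theta = theta, S_new = S_new,
               likelihood = lik, flag = flag, stringsAsFactors = FALSE)
  }))
  if (is.null(prior)) {
    pw <- rep(1, length(taxa))
  } else {
    pw <- prior[tab$taxon]
    if (anyNA(pw)) stop("prior must cover every candidate taxon")
  }
  joint <- pw * tab$likelihood
  total <- sum(joint)
  unassignable <- total <= 0
  tab$posterior <- if (unassignable) rep(NA_real_, nrow(tab)) else
    joint / total
  tab$risk <- 1 - tab$posterior
  if (unassignable) {
    assigned <- NA_character_; post <- NA_real_; ndx <- NA_integer_
    tie <- FALSE
  } else {
    best <- which(tab$posterior == max(tab$posterior))
    tie <- length(best) > 1L
    best <- best[order(tab$taxon[best])][1L]  # lexicographic tie-break
    assigned <- tab$taxon[best]
    post <- tab$posterior[best]
    rows <- rows_of[[assigned]]
    ndx <- diagnostic_sites(m[rows, cols, drop = FALSE],
                            m[-rows, cols, drop = FALSE])
  }
  structure(list(query_id = query_id, assigned = assigned, posterior = post,
                 risk = if (is.na(post)) NA_real_ else 1 - post,
                 n_diagnostic_sites = ndx, unassignable = unassignable,
                 tie = tie, table = tab),
            class = "assignment_result")
}

#' @export
print.assignment_result <- function(x, ...) {
  if (x$unassignable) {
    cat("query", x$query_id, "-> unassignable (all likelihoods zero)\n")
  } else {
    cat(sprintf("query %s -> %s (posterior %.3f, risk %.2e, %d diagnostic sites)%s\n",
                x$query_id, x$assigned, x$posterior, x$risk,
                x$n_diagnostic_sites, if (x$tie) " [tie]" else ""))
  }
  invisible(x)
}

#' Leave-one-out assignment validation
#'
#' For every taxon with at least three members, one randomly chosen sequence
#' is removed from the library and assigned back against the remainder. The
#' output mirrors the columns of a typical assignment-test report: query
#' taxon, query id, sample size used, diagnostic sites, posterior and risk.
#'
#' @param lib a `barcode_library`
#' @param level `"species"` or `"subspecies"`
#' @param seed integer seed controlling query selection
#' @return data frame of class `loo_table` with columns `taxon`, `query_id`,
#'   `n` (taxon sample size after removal), `n_diagnostic_sites`,
#'   `posterior` (of the true taxon), `risk`, `assigned`, `correct`
#' @export
loo_validate <- function(lib, level = c("species", "subspecies"), seed = 1) {
  level <- match.arg(level)
  set.seed(seed)
  taxa_of <- taxon_labels(lib, level)
  counts <- table(taxa_of[!is.na(taxa_of)])
  taxa <- sort(names(counts[counts >= 3L]))
  rows <- lapply(taxa, function(tx) {
    ids <- names(taxa_of)[!is.na(taxa_of) & taxa_of == tx]
    qid <- sample(ids, 1L)
    rest <- subset_library(lib, setdiff(rownames(lib$seq), qid))
    res <- assign_query(rest, lib$seq[qid, ], query_id = qid, level = level)
    true_row <- res$table[res$table$taxon == tx, ]
    data.frame(taxon = tx, query_id = qid,
               n = if (nrow(true_row) == 1L) true_row$n else NA_integer_,
               n_diagnostic_sites = res$n_diagnostic_sites,
               posterior = if (nrow(true_row) == 1L) true_row$posterior
                           else NA_real_,
               risk = if (nrow(true_row) == 1L) true_row$risk else NA_real_,
               assigned = res$assigned,
               correct = identical(res$assigned, tx),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("loo_table", class(out))
  out
}
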