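#' Full reference-library audit
#'
#' Runs the complete library-quality pipeline on a barcode library:
#' length filtering, K2P distance matrix, intra/inter divergence summaries,
#' overlap (barcode-gap) analysis, divergence histogram, NJ tree with
#' bootstrap supports, haplotype accounting, the species-differentiation
#' tally, and the NB-system comparison. Every headline statistic is echoed
#' in a machine-readable summary; when `out_dir` is given the tables, the
#' Newick tree and a JSON summary are written there.
#'
#' @param lib a `barcode_library`
#' @param min_length length-filter threshold (unambiguous bases; records at
#'   or below it are dropped before analysis)
#' @param bootstrap_replicates bootstrap replicates for node supports
#'   (0 skips the bootstrap)
#' @param overlap_window two-element percent window for overlap counting
#' @param bin_width_pct histogram bin width (percent)
#' @param min_overlap haplotype-collapsing overlap threshold
#' @param outgroup optional outgroup record id (used for rooting; excluded
#'   from the differentiation tally)
#' @param seed integer seed (bootstrap resampling)
#' @param out_dir optional output directory
#' @return (invisibly) a list of class `audit_report` with elements
#'   `summary` (named list of headline numbers), `divergence`, `overlap`,
#'   `histogram`, `tree`, `haplotypes`, `differentiation`, `nb`
#' @export
run_library_audit <- function(lib, min_length = 600,
                              bootstrap_replicates = 100,
                              overlap_window = c(2, 4),
                              bin_width_pct = 1,
                              min_overlap = 300,
                              outgroup = NULL,
                              seed = 1,
                              out_dir = NULL) {
  n_input <- n_records(lib)
  lib <- filter_by_length(lib, min_length)
  if (n_records(lib) < 3L) stop("fewer than 3 records pass the length filter")
  species_of <- taxon_labels(lib, "species")
  dm <- distance_matrix(lib)
  div <- divergence_summaries(dm, species_of)
  ov <- overlap_analysis(dm, species_of, overlap_window[1], overlap_window[2])
  hist_tab <- histogram_export(dm, species_of, bin_width_pct)
  tree <- if (bootstrap_replicates > 0) {
    bootstrap_supports(lib, replicates = bootstrap_replicates, seed = seed)
  } else {
    nj_tree(dm)
  }
  haps <- collapse_haplotypes(lib, min_overlap = min_overlap)
  diff_rep <- differentiation_report(tree, haps, species_of,
                                     outgroup = outgroup)
  nb <- nb_vs_barcode_report(lib, min_overlap = min_overlap)
  hap_per_species <- table(unlist(lapply(seq_len(nrow(haps)), function(r)
    unique(unname(species_of[haps$member_ids[[r]]])))))
  summary <- list(
    n_records_input = n_input,
    n_records_analysed = n_records(lib),
    n_species = length(unique(lib$meta$species)),
    mean_intra_pct = div$intra$mean,
    sd_intra_pct = div$intra$sd,
    max_intra_pct = div$intra$max,
    mean_inter_pct = div$inter$mean,
    sd_inter_pct = div$inter$sd,
    min_inter_pct = div$inter$min,
    max_inter_pct = div$inter$max,
    fold_ratio = div$fold_ratio,
    n_intra_comparisons = div$intra$n,
    n_inter_comparisons = div$inter$n,
    n_intra_in_window = ov$n_intra_in_window,
    n_inter_in_window = ov$n_inter_in_window,
    n_haplotypes = nrow(haps),
    n_shared_haplotypes = sum(haps$shared),
    n_species_differentiated = attr(diff_rep, "n_success"),
    success_fraction = attr(diff_rep, "success_fraction"),
    n_nb_classes = nrow(nb$class_summary),
    n_nb_collisions = nrow(nb$collisions),
    seed = seed)
  out <- structure(list(summary = summary, divergence = div, overlap = ov,
                        histogram = hist_tab, tree = tree, haplotypes = haps,
                        differentiation = diff_rep, nb = nb),
                   class = "audit_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(hist_tab, "histogram.tsv")
    wt(as.data.frame(diff_rep), "differentiation.tsv")
    wt(nb$per_sequence, "nb_per_sequence.tsv")
    wt(nb$class_summary, "nb_class_summary.tsv")
    hap_flat <- data.frame(haplotype = haps$haplotype,
                           n_members = haps$n_members,
                           shared = haps$shared,
                           members = vapply(haps$member_ids, paste,
                                            character(1), collapse = ","),
                           species = vapply(haps$species, paste,
                                            character(1), collapse = ","))
    wt(hap_flat, "haplotypes.tsv")
    ape::write.tree(tree, file.path(out_dir, "nj_tree.nwk"))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}

#' @export
print.audit_report <- function(x, ...) {
  s <- x$summary
  cat(sprintf("library audit: %d records, %d species\n",
              s$n_records_analysed, s$n_species))
  cat(sprintf("  intra: mean %.2f%% (SD %.2f, max %.2f); inter: mean %.2f%% (SD %.2f, range %.2f-%.2f); ratio %.1fx\n",
              s$mean_intra_pct, s$sd_intra_pct, s$max_intra_pct,
              s$mean_inter_pct, s$sd_inter_pct, s$min_inter_pct,
              s$max_inter_pct, s$fold_ratio))
  cat(sprintf("  overlap window: %d of %d intra, %d of %d inter comparisons\n",
              s$n_intra_in_window, s$n_intra_comparisons,
              s$n_inter_in_window, s$n_inter_comparisons))
  cat(sprintf("  haplotypes: %d (%d shared between species)\n",
              s$n_haplotypes, s$n_shared_haplotypes))
  cat(sprintf("  differentiation: %d of %d species (%.1f%%)\n",
              s$n_species_differentiated, s$n_species,
              100 * s$success_fraction))
  invisible(x)
}

#' Assign a batch of query specimens against a reference library
#'
#' Runs [assign_query()] for every record of `queries` and returns an
#' assignment-report table (one row per query) shaped like a standard
#' assignment-test report: taxon assigned, sample size, diagnostic sites,
#' posterior, risk. Unassignable queries are retained with `NA` fields and
#' listed in the `unassignable` attribute.
#'
#' @param lib reference `barcode_library`
#' @param queries a `barcode_library` of query records (same frame)
#' @param level `"species"` or `"subspecies"`
#' @param prior optional prior over taxa (see [assign_query()])
#' @param out_dir optional output directory (writes `assignment_<level>.tsv`)
#' @return data frame with columns `query_id`, `assigned`, `n`,
#'   `n_diagnostic_sites`, `posterior`, `risk`, `unassignable`
#' @export
run_assignment <- function(lib, queries, level = c("species", "subspecies"),
                           prior = NULL, out_dir = NULL) {
  level <- match.arg(level)
  ids <- rownames(queries$seq)
  if (length(ids) == 0L) {
    warning("no query records; returning empty report")
    return(data.frame(query_id = character(), assigned = character(),
                      n = integer(), n_diagnostic_sites = integer(),
                      posterior = numeric(), risk = numeric(),
                      unassignable = logical()))
  }
  rows <- lapply(ids, function(id) {
    res <- assign_query(lib, queries$seq[id, ], query_id = id, level = level,
                        prior = prior)
    n_assigned <- if (res$unassignable) NA_integer_ else
      res$table$n[res$table$taxon == res$assigned]
    data.frame(query_id = id, assigned = res$assigned, n = n_assigned,
               n_diagnostic_sites = res$n_diagnostic_sites,
               posterior = res$posterior, risk = res$risk,
               unassignable = res$unassignable, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "unassignable") <- out$query_id[out$unassignable]
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(out, file.path(out_dir,
                                      paste0("assignment_", level, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
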