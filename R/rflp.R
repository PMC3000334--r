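#' Default NB-system window configuration
#'
#' Coordinates (1-based, inclusive) on the 658-bp COI barcode frame locating
#' the restriction sites of the two-enzyme 'NB' typing system: the
#' diagnostic NlaIII (N) and BamHI (B) sites within the 3' region covered by
#' the legacy ~378-bp amplicon, plus the monomorphic NlaIII site in the 5'
#' region of the barcode (which adds one band to barcode-amplicon digests).
#' NlaIII (CATG) cuts after position 4 of its motif; BamHI (GGATCC) after
#' position 1. The exact in-gene coordinates of the historical assay are not
#' fixed by this package; these defaults place the sites so that the legacy
#' amplicon digests reproduce the classic ~350/~28 bp (NlaIII, N+) and
#' ~360/~18 bp (BamHI, B+) patterns. The same configuration drives the
#' synthetic-data generator, so typing is testable end to end.
#'
#' @return list with `frame_length`, motif windows (`n_mono_start`,
#'   `n_diag_start`, `b_diag_start`), legacy amplicon bounds
#'   (`legacy_start`, `legacy_end`) and an `enzymes` list
#'   (`motif`, `cut_offset` per enzyme)
#' @export
default_nb_windows <- function() {
  list(frame_length = 658L,
       n_mono_start = 120L,
       n_diag_start = 305L,
       b_diag_start = 640L,
       legacy_start = 281L,
       legacy_end = 658L,
       enzymes = list(
         NlaIII = list(motif = "CATG", cut_offset = 4L),
         BamHI = list(motif = "GGATCC", cut_offset = 1L)))
}

#' Read / write an NB window configuration (JSON)
#'
#' @param path file path
#' @return for `read_nb_windows`, a windows list as in
#'   [default_nb_windows()]
#' @export
read_nb_windows <- function(path) {
  w <- jsonlite::read_json(path, simplifyVector = TRUE)
  w$enzymes <- lapply(w$enzymes, as.list)
  w
}

#' @rdname read_nb_windows
#' @param windows a windows list
#' @export
write_nb_windows <- function(windows, path) {
  jsonlite::write_json(windows, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

# All motif start positions of an enzyme in an ungapped sequence string.
.motif_starts <- function(seq_string, motif) {
  hits <- gregexpr(motif, seq_string, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) integer(0) else as.integer(hits)
}

.window_state <- function(sv, start, motif) {
  end <- start + nchar(motif) - 1L
  if (end > length(sv)) return("undeterminable")
  win <- sv[start:end]
  if (!all(win %in% BASES)) return("undeterminable")
  if (paste(win, collapse = "") == motif) "present" else "absent"
}

#' Scan a barcode sequence for NB-system restriction sites
#'
#' Reports every exact NlaIII/BamHI motif occurrence with its 1-based start
#' position on the barcode frame and a role assigned by window: the
#' diagnostic N and B windows, the monomorphic 5' NlaIII window, or
#' `"other"` elsewhere. Ambiguity codes and gaps never match, and a
#' diagnostic window that the sequence does not cover with unambiguous bases
#' is reported as `"undeterminable"`.
#'
#' @param seq a sequence on the barcode frame (string or character vector;
#'   gaps allowed, they simply never match)
#' @param windows window configuration, see [default_nb_windows()]
#' @return data frame with columns `enzyme`, `position`, `role`
#'   (`diagnostic_N`, `diagnostic_B`, `monomorphic`, `other`,
#'   `undeterminable`)
#' @export
scan_sites <- function(seq, windows = default_nb_windows()) {
  sv <- .as_seqvec(seq)
  s <- paste(sv, collapse = "")
  rows <- list()
  for (enz in names(windows$enzymes)) {
    motif <- windows$enzymes[[enz]]$motif
    for (pos in .motif_starts(s, motif)) {
      role <- "other"
      if (enz == "NlaIII" && pos == windows$n_diag_start) role <- "diagnostic_N"
      if (enz == "NlaIII" && pos == windows$n_mono_start) role <- "monomorphic"
      if (enz == "BamHI" && pos == windows$b_diag_start) role <- "diagnostic_B"
      rows[[length(rows) + 1L]] <-
        data.frame(enzyme = enz, position = pos, role = role,
                   stringsAsFactors = FALSE)
    }
  }
  # uncovered diagnostic windows are reported explicitly
  specs <- list(c("NlaIII", windows$n_diag_start, "diagnostic_N"),
                c("BamHI", windows$b_diag_start, "diagnostic_B"))
  for (spc in specs) {
    motif <- windows$enzymes[[spc[1L]]]$motif
    if (.window_state(sv, as.integer(spc[2L]), motif) == "undeterminable") {
      rows[[length(rows) + 1L]] <-
        data.frame(enzyme = spc[1L], position = NA_integer_,
                   role = paste0(spc[3L], ":undeterminable"),
                   stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(enzyme = character(), position = integer(),
                      role = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out[order(out$enzyme, out$position), , drop = FALSE]
}

#' Predict restriction fragments of an amplicon
#'
#' Cuts the (gap-stripped) amplicon at every motif occurrence of the given
#' enzymes, at each enzyme's cut offset within its motif. Overlapping motif
#' occurrences are resolved left to right. Fragment lengths always sum to
#' the amplicon length and are returned sorted descending.
#'
#' @param amplicon_seq amplicon sequence (string or character vector; gaps
#'   are stripped first)
#' @param enzymes which enzymes to digest with (names of
#'   `windows$enzymes`)
#' @param windows window/enzyme configuration
#' @return integer vector of fragment lengths, descending
#' @export
digest_fragments <- function(amplicon_seq, enzymes = c("NlaIII", "BamHI"),
                             windows = default_nb_windows()) {
  sv <- .as_seqvec(amplicon_seq)
  sv <- sv[sv != "-" & sv != "?"]
  s <- paste(sv, collapse = "")
  len <- nchar(s)
  cuts <- integer(0)
  for (enz in enzymes) {
    spec <- windows$enzymes[[enz]]
    if (is.null(spec)) stop("unknown enzyme: ", enz)
    starts <- .motif_starts(s, spec$motif)
    cuts <- c(cuts, starts + spec$cut_offset - 1L)
  }
  cuts <- sort(unique(cuts[cuts >= 1L & cuts < len]))
  sort(diff(c(0L, cuts, len)), decreasing = TRUE)
}

#' Type a barcode sequence in the NB system
#'
#' Determines presence/absence of the diagnostic NlaIII (N) and BamHI (B)
#' sites from the sequence at the two diagnostic windows and reports the NB
#' haplotype (`N+B+`, `N+B-`, `N-B+`, `N-B-`). A window covered by gaps or
#' ambiguity codes makes the haplotype `"undeterminable"` (distinct from
#' site absence). When the corresponding amplicon region is fully covered,
#' predicted digest fragments are included for the legacy amplicon
#' (NlaIII and BamHI digests separately, as in the classic assay) and for
#' the whole barcode amplicon (NlaIII digest, where the 5' monomorphic site
#' yields two bands for N- and three for N+).
#'
#' @param seq sequence on the barcode frame
#' @param windows window configuration
#' @param id identifier carried into the output
#' @return list of class `nb_profile`: `id`, `N_present`, `B_present`
#'   (logical or NA), `haplotype`, `fragments_legacy` (list with `NlaIII`
#'   and `BamHI` digests of the legacy amplicon, or NULL), and
#'   `fragments_barcode` (NlaIII digest of the barcode frame, or NULL)
#' @export
nb_type <- function(seq, windows = default_nb_windows(), id = NA_character_) {
  sv <- .as_seqvec(seq)
  if (length(sv) < windows$frame_length) {
    sv <- c(sv, rep("-", windows$frame_length - length(sv)))
  }
  stN <- .window_state(sv, windows$n_diag_start,
                       windows$enzymes$NlaIII$motif)
  stB <- .window_state(sv, windows$b_diag_start,
                       windows$enzymes$BamHI$motif)
  N_present <- if (stN == "undeterminable") NA else stN == "present"
  B_present <- if (stB == "undeterminable") NA else stB == "present"
  haplotype <- if (is.na(N_present) || is.na(B_present)) "undeterminable"
  else paste0("N", if (N_present) "+" else "-",
              "B", if (B_present) "+" else "-")
  legacy <- sv[windows$legacy_start:min(windows$legacy_end, length(sv))]
  fragments_legacy <- NULL
  if (all(legacy %in% BASES)) {
    fragments_legacy <- list(
      NlaIII = digest_fragments(legacy, "NlaIII", windows),
      BamHI = digest_fragments(legacy, "BamHI", windows))
  }
  fragments_barcode <- NULL
  if (all(sv %in% BASES)) {
    fragments_barcode <- digest_fragments(sv, "NlaIII", windows)
  }
  structure(list(id = id, N_present = N_present, B_present = B_present,
                 haplotype = haplotype, fragments_legacy = fragments_legacy,
                 fragments_barcode = fragments_barcode),
            class = "nb_profile")
}

#' @export
print.nb_profile <- function(x, ...) {
  cat("NB haplotype:", x$haplotype, "\n")
  if (!is.null(x$fragments_legacy)) {
    cat("legacy amplicon NlaIII:",
        paste(x$fragments_legacy$NlaIII, collapse = "/"), "bp; BamHI:",
        paste(x$fragments_legacy$BamHI, collapse = "/"), "bp\n")
  }
  invisible(x)
}

#' Text rendering of a digest as gel bands
#'
#' Collapses fragment lengths into co-migrating bands (fragments within
#' `resolution` relative length of each other merge into one band) and
#' renders them largest first, one line per band.
#'
#' @param fragments integer vector of fragment lengths
#' @param resolution relative length difference below which two fragments
#'   co-migrate (default 5 percent)
#' @return character vector of band descriptions (invisibly printed)
#' @export
render_gel <- function(fragments, resolution = 0.05) {
  fr <- sort(fragments, decreasing = TRUE)
  bands <- list()
  for (f in fr) {
    if (length(bands) > 0L) {
      last <- bands[[length(bands)]]
      if ((last[1L] - f) / last[1L] <= resolution) {
        bands[[length(bands)]] <- c(last, f)
        next
      }
    }
    bands[[length(bands) + 1L]] <- f
  }
  vapply(bands, function(b) {
    sprintf("%5d bp %s %s", round(mean(b)),
            strrep("=", max(1L, round(mean(b) / 25))),
            if (length(b) > 1L) sprintf("(x%d)", length(b)) else "")
  }, character(1))
}

#' Compare NB-system typing with barcode haplotypes across a library
#'
#' Types every record, tabulates NB haplotype classes per species, and
#' contrasts the coarse four-class NB partition with the full barcode
#' haplotype partition. NB classes occurring in more than one species are
#' flagged as collisions: a specimen misidentified to species before an NB
#' assay could be typed to a class that reads as a different species'
#' provenance, which is the central failure mode of single-enzyme typing
#' relative to sequencing.
#'
#' @param lib a `barcode_library`
#' @param windows window configuration
#' @param min_overlap haplotype-collapsing overlap threshold (see
#'   [collapse_haplotypes()])
#' @return list with `per_sequence` (id, species, NB haplotype, barcode
#'   haplotype), `per_species` (species, NB class(es)), `class_summary`
#'   (NB class, number of species, number of barcode haplotypes),
#'   `collisions` (NB classes shared by several species) and
#'   `barcode_haplotypes_unique` (TRUE when no barcode haplotype is shared
#'   between species)
#' @export
nb_vs_barcode_report <- function(lib, windows = default_nb_windows(),
                                 min_overlap = 300) {
  ids <- rownames(lib$seq)
  nb <- vapply(ids, function(i)
    nb_type(lib$seq[i, ], windows, id = i)$haplotype, character(1))
  haps <- collapse_haplotypes(lib, min_overlap = min_overlap)
  hap_of <- rep(NA_character_, length(ids))
  names(hap_of) <- ids
  for (r in seq_len(nrow(haps))) {
    hap_of[haps$member_ids[[r]]] <- haps$haplotype[r]
  }
  per_sequence <- data.frame(id = ids, species = lib$meta$species,
                             nb_haplotype = unname(nb),
                             barcode_haplotype = unname(hap_of[ids]),
                             stringsAsFactors = FALSE)
  per_species <- stats::aggregate(nb_haplotype ~ species, per_sequence,
                                  function(x) paste(sort(unique(x)),
                                                    collapse = ","))
  classes <- sort(unique(nb[nb != "undeterminable"]))
  class_summary <- do.call(rbind, lapply(classes, function(cl) {
    sel <- per_sequence$nb_haplotype == cl
    data.frame(nb_class = cl,
               n_species = length(unique(per_sequence$species[sel])),
               n_barcode_haplotypes =
                 length(unique(stats::na.omit(
                   per_sequence$barcode_haplotype[sel]))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(class_summary)) {
    class_summary <- data.frame(nb_class = character(),
                                n_species = integer(),
                                n_barcode_haplotypes = integer())
  }
  collisions <- class_summary[class_summary$n_species > 1L, , drop = FALSE]
  list(per_sequence = per_sequence,
       per_species = per_species,
       class_summary = class_summary,
       collisions = collisions,
       barcode_haplotypes_unique = !any(haps$shared))
}
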