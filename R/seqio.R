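#' Construct a barcode library
#'
#' A barcode library couples an aligned set of COI sequences (a common
#' coordinate frame, by convention the 658-bp barcode region) with a specimen
#' metadata table. All downstream analyses (distances, trees, assignment,
#' restriction typing) operate on this object.
#'
#' @param seqs aligned sequences: a character matrix (rows = records, one
#'   letter per cell), or a named list/vector of equal-length strings.
#'   Stored upper-case. Gaps are `-`; IUPAC ambiguity codes are allowed.
#' @param meta data frame with at least columns `id` and `species`; optional
#'   columns `subspecies`, `country`, `locality`, `lat`, `lon`, `source`.
#'   Row order must match `seqs` ids (they are joined by id).
#' @return An object of class `barcode_library`: a list with elements
#'   `seq` (character matrix, rownames = ids) and `meta` (data frame).
#' @export
barcode_library <- function(seqs, meta) {
  m <- .as_seqmat(seqs)
  if (nrow(m) < 1L) stop("a library needs at least one record")
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (!all(c("id", "species") %in% names(meta))) {
    stop("metadata must contain columns 'id' and 'species'")
  }
  for (col in c("subspecies", "country", "locality", "lat", "lon", "source")) {
    if (is.null(meta[[col]])) meta[[col]] <- NA
  }
  meta$id <- as.character(meta$id)
  if (anyDuplicated(meta$id)) {
    stop("duplicated ids in metadata: ",
         paste(unique(meta$id[duplicated(meta$id)]), collapse = ", "))
  }
  orphans <- setdiff(rownames(m), meta$id)
  if (length(orphans) > 0L) {
    stop("sequence ids missing from metadata: ",
         paste(orphans, collapse = ", "))
  }
  meta <- meta[match(rownames(m), meta$id), , drop = FALSE]
  rownames(meta) <- NULL
  if (any(is.na(meta$species)) || any(!nzchar(meta$species))) {
    stop("species labels must be non-empty for every record")
  }
  bad <- !(m %in% IUPAC_CHARS)
  if (any(bad)) {
    stop("non-IUPAC characters in sequences: ",
         paste(unique(m[bad]), collapse = ", "))
  }
  structure(list(seq = m, meta = meta), class = "barcode_library")
}

#' @export
print.barcode_library <- function(x, ...) {
  cat("barcode_library:", nrow(x$seq), "records,",
      length(unique(x$meta$species)), "species,",
      ncol(x$seq), "alignment columns\n")
  invisible(x)
}

#' Number of records in a library
#' @param lib a `barcode_library`
#' @return integer
#' @export
n_records <- function(lib) nrow(lib$seq)

#' Named species vector for a library
#'
#' @param lib a `barcode_library`
#' @param level `"species"` or `"subspecies"`. At subspecies level the label
#'   is `"<species>/<subspecies>"`; records without a subspecies get `NA`.
#' @return character vector named by record id
#' @export
taxon_labels <- function(lib, level = c("species", "subspecies")) {
  level <- match.arg(level)
  if (level == "species") {
    stats::setNames(lib$meta$species, lib$meta$id)
  } else {
    lab <- ifelse(is.na(lib$meta$subspecies) | !nzchar(lib$meta$subspecies),
                  NA_character_,
                  paste(lib$meta$species, lib$meta$subspecies, sep = "/"))
    stats::setNames(lab, lib$meta$id)
  }
}

#' Subset a library by record id
#' @param lib a `barcode_library`
#' @param ids record ids to keep (order preserved as given)
#' @return a `barcode_library`
#' @export
subset_library <- function(lib, ids) {
  missing <- setdiff(ids, rownames(lib$seq))
  if (length(missing) > 0L) {
    stop("unknown ids: ", paste(missing, collapse = ", "))
  }
  if (length(ids) == 0L) {
    return(structure(list(seq = lib$seq[0, , drop = FALSE],
                          meta = lib$meta[0, , drop = FALSE]),
                     class = "barcode_library"))
  }
  barcode_library(lib$seq[ids, , drop = FALSE],
                  lib$meta[match(ids, lib$meta$id), , drop = FALSE])
}

#' Read a barcode library from FASTA + metadata TSV
#'
#' The FASTA must contain an alignment (equal sequence lengths) unless
#' `assume_5prime_anchored = TRUE`, in which case shorter sequences are
#' right-padded with gaps (COI barcodes are length-conserved and amplified
#' from a fixed 5' primer, so ragged input usually means 3' truncation).
#' The metadata TSV needs a header with at least `id` and `species`;
#' lines starting with `#` are ignored. Every FASTA id must appear in the
#' metadata; metadata rows without a sequence are dropped with a warning.
#'
#' @param fasta_path path to FASTA file
#' @param metadata_path path to tab-separated metadata file
#' @param assume_5prime_anchored pad ragged sequences on the right instead of
#'   rejecting them
#' @return a `barcode_library`
#' @export
read_library <- function(fasta_path, metadata_path,
                         assume_5prime_anchored = FALSE) {
  dna <- ape::read.FASTA(fasta_path)
  rows <- lapply(as.character(dna), function(s) toupper(s))
  lens <- lengths(rows)
  if (length(unique(lens)) > 1L) {
    if (!assume_5prime_anchored) {
      stop("ragged alignment: sequence lengths ",
           paste(sort(unique(lens)), collapse = ", "),
           " (set assume_5prime_anchored = TRUE to right-pad)")
    }
    L <- max(lens)
    rows <- lapply(rows, function(s) c(s, rep("-", L - length(s))))
  }
  m <- do.call(rbind, rows)
  rownames(m) <- names(dna)
  meta <- utils::read.delim(metadata_path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE,
                            na.strings = c("", "NA"), colClasses = NA)
  extra <- setdiff(meta$id, rownames(m))
  if (length(extra) > 0L) {
    warning("metadata rows without sequences dropped: ",
            paste(extra, collapse = ", "))
    meta <- meta[meta$id %in% rownames(m), , drop = FALSE]
  }
  barcode_library(m, meta)
}

#' Write a barcode library to FASTA + metadata TSV
#'
#' Inverse of [read_library()]: reading the written files reproduces the
#' library's sequences and metadata fields.
#'
#' @param lib a `barcode_library`
#' @param fasta_path,metadata_path output paths
#' @return invisibly, `lib`
#' @export
write_library <- function(lib, fasta_path, metadata_path) {
  seqs <- lapply(seq_len(nrow(lib$seq)), function(i) tolower(lib$seq[i, ]))
  names(seqs) <- rownames(lib$seq)
  ape::write.FASTA(ape::as.DNAbin(seqs), fasta_path)
  utils::write.table(lib$meta, metadata_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(lib)
}

#' Count unambiguous bases per record
#' @param lib a `barcode_library` (or character matrix)
#' @return integer vector named by id
#' @export
unambiguous_counts <- function(lib) {
  m <- .as_seqmat(lib)
  stats::setNames(rowSums(matrix(m %in% BASES, nrow = nrow(m))), rownames(m))
}

#' Filter a library by unambiguous sequence length
#'
#' Retains records whose count of unambiguous bases (A/C/G/T; gaps, N and
#' other ambiguity codes do not count) strictly exceeds the threshold.
#' This mirrors the common practice of restricting tree-based analyses to
#' near-full-length barcodes (e.g. keeping only sequences >600 bp).
#'
#' @param lib a `barcode_library`
#' @param min_unambiguous_bases retain records with strictly more unambiguous
#'   bases than this
#' @return a `barcode_library` (possibly with zero records, with a warning)
#' @export
filter_by_length <- function(lib, min_unambiguous_bases = 600) {
  stopifnot(min_unambiguous_bases >= 1)
  keep <- unambiguous_counts(lib) > min_unambiguous_bases
  if (!any(keep)) {
    warning("no records exceed ", min_unambiguous_bases,
            " unambiguous bases; returning empty library")
    out <- list(seq = lib$seq[keep, , drop = FALSE],
                meta = lib$meta[keep, , drop = FALSE])
    class(out) <- "barcode_library"
    return(out)
  }
  subset_library(lib, rownames(lib$seq)[keep])
}

# Pairwise identity structure over unambiguous columns, via indicator
# cross-products: for each pair, the number of comparable columns (both
# unambiguous) and the number of those that match.
.pair_counts <- function(m) {
  ind <- lapply(BASES, function(b) (m == b) * 1)
  U <- Reduce(`+`, ind)
  comparable <- tcrossprod(U)
  matches <- Reduce(`+`, lapply(ind, tcrossprod))
  list(comparable = comparable, matches = matches, ind = ind, U = U)
}

#' Collapse a library into haplotypes
#'
#' Two records belong to the same haplotype if they are identical at every
#' column where both carry an unambiguous base and that shared coverage is at
#' least `min_overlap` columns; grouping is the transitive closure of this
#' relation (a short sequence may link two long ones it matches). Ambiguity
#' codes never match anything. Records with fewer than `min_overlap`
#' unambiguous bases are excluded from collapsing and reported in the
#' `excluded_ids` attribute.
#'
#' @param lib a `barcode_library`
#' @param min_overlap minimum shared unambiguous coverage (columns) for two
#'   records to be comparable
#' @return A data frame of class `haplotype_set`, one row per haplotype:
#'   `haplotype` (id), `n_members`, `member_ids` (list column),
#'   `species` (list column of species carrying it), `shared` (TRUE when
#'   more than one species carries the haplotype), `canonical_id` (member
#'   with the most unambiguous bases). Attributes: `excluded_ids`.
#' @export
collapse_haplotypes <- function(lib, min_overlap = 300) {
  m <- lib$seq
  species_of <- taxon_labels(lib, "species")
  nb <- unambiguous_counts(lib)
  eligible <- nb >= min_overlap
  excluded <- rownames(m)[!eligible]
  m2 <- m[eligible, , drop = FALSE]
  n <- nrow(m2)
  comp <- numeric(0)
  if (n > 0L) {
    pc <- .pair_counts(m2)
    adj <- pc$matches == pc$comparable & pc$comparable >= min_overlap
    diag(adj) <- TRUE
    # connected components by BFS over the compatibility graph
    comp <- integer(n)
    cur <- 0L
    for (i in seq_len(n)) {
      if (comp[i] != 0L) next
      cur <- cur + 1L
      queue <- i
      comp[i] <- cur
      while (length(queue) > 0L) {
        v <- queue[[1L]]
        queue <- queue[-1L]
        nb_v <- which(adj[v, ] & comp == 0L)
        comp[nb_v] <- cur
        queue <- c(queue, nb_v)
      }
    }
  }
  rows <- lapply(seq_len(max(comp, 0L)), function(k) {
    ids <- rownames(m2)[comp == k]
    sp <- sort(unique(unname(species_of[ids])))
    canonical <- ids[which.max(nb[ids])]
    data.frame(haplotype = sprintf("H%03d", k),
               n_members = length(ids),
               member_ids = I(list(ids)),
               species = I(list(sp)),
               shared = length(sp) > 1L,
               canonical_id = canonical,
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(haplotype = character(), n_members = integer(),
               member_ids = I(list()), species = I(list()),
               shared = logical(), canonical_id = character())
  attr(out, "excluded_ids") <- excluded
  class(out) <- c("haplotype_set", class(out))
  out
}

#' Species sharing a haplotype with another species
#'
#' @param haps a `haplotype_set` from [collapse_haplotypes()]
#' @return character vector of species that occur in a haplotype whose
#'   members span more than one species
#' @export
shared_haplotype_species <- function(haps) {
  sort(unique(unlist(haps$species[haps$shared])))
}
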