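#' Read an aligned FASTA file together with per-individual metadata
#'
#' Reads a multiple-sequence alignment of mtDNA sequences and a tab-separated
#' metadata table assigning every individual to a sampled population (and,
#' optionally, a mitochondrial lineage and coordinates). All sequences must
#' have identical length; a ragged alignment is an error naming the offending
#' record.
#'
#' @param fasta Path to a FASTA file of aligned sequences (A, C, G, T, `-`,
#'   `N`; case-insensitive). Any other IUPAC ambiguity code is coerced to `N`
#'   with a warning.
#' @param meta Path to a tab-separated file with header columns
#'   `individual_id`, `population_id` and optionally `lineage`, `lat`, `lon`;
#'   alternatively a `data.frame` with those columns.
#' @return An object of class `hap_alignment`: a list with elements `ids`
#'   (individual identifiers), `pops` (population of each individual), `seq`
#'   (character matrix, individuals x sites), `L` (alignment length) and
#'   `meta` (the metadata table).
#' @seealso [collapse_haplotypes()], [pairwise_differences()]
#' @export
read_alignment <- function(fasta, meta) {
  if (!file.exists(fasta)) stopf("FASTA file not found: %s", fasta)
  recs <- ape::read.FASTA(fasta)
  if (length(recs) == 0L) stopf("no sequences in %s", fasta)
  seqs <- lapply(as.character(recs), toupper)
  lens <- lengths(seqs)
  if (length(unique(lens)) != 1L) {
    bad <- which(lens != lens[1L])[1L]  # first record deviating from the first
    stopf("ragged alignment: record '%s' has length %d, expected %d",
          names(recs)[bad], lens[bad], lens[1L])
  }
  if (is.character(meta)) {
    meta <- utils::read.delim(meta, stringsAsFactors = FALSE)
  }
  new_alignment(names(recs), meta, do.call(rbind, seqs))
}

# Shared constructor/validator used by read_alignment() and the simulators.
new_alignment <- function(ids, meta, mat) {
  if (anyDuplicated(ids)) stopf("duplicated individual ids in alignment")
  if (!all(c("individual_id", "population_id") %in% names(meta))) {
    stopf("metadata must have columns individual_id and population_id")
  }
  miss <- setdiff(ids, meta$individual_id)
  if (length(miss) > 0L) {
    stopf("individuals absent from metadata: %s",
          paste(utils::head(miss, 5L), collapse = ", "))
  }
  extra <- setdiff(meta$individual_id, ids)
  if (length(extra) > 0L) {
    message(sprintf("%d metadata rows without sequences were dropped (%s%s)",
                    length(extra), paste(utils::head(extra, 3L), collapse = ", "),
                    if (length(extra) > 3L) ", ..." else ""))
    meta <- meta[meta$individual_id %in% ids, , drop = FALSE]
  }
  bad <- !(mat %in% c("A", "C", "G", "T", "-", "N"))
  if (any(bad)) {
    warning(sprintf("%d ambiguous (non-ACGT-N) sites treated as N", sum(bad)),
            call. = FALSE)
    mat[bad] <- "N"
  }
  rownames(mat) <- ids
  pops <- meta$population_id[match(ids, meta$individual_id)]
  structure(list(ids = ids, pops = pops, seq = mat, L = ncol(mat), meta = meta),
            class = "hap_alignment")
}

#' @export
print.hap_alignment <- function(x, ...) {
  cat(sprintf("mtDNA alignment: %d individuals, %d populations, %d sites\n",
              length(x$ids), length(unique(x$pops)), x$L))
  invisible(x)
}

#' Collapse an alignment to haplotypes with per-population counts
#'
#' Identical sequences are assigned to a single haplotype; haplotype ids are
#' `H1..HK` in order of first appearance in the alignment. The result also
#' carries the number of segregating (variable) sites.
#'
#' @param a A `hap_alignment` from [read_alignment()] or the simulators.
#' @return An object of class `haplotype_table`: list with `sequences`
#'   (character matrix, haplotypes x sites, rownames `H1..HK`), `counts`
#'   (integer matrix, haplotypes x populations), `lineages` (per-population
#'   lineage labels if present in the metadata), `K`, `N`, `S_seg`, `L`.
#' @export
collapse_haplotypes <- function(a) {
  stopifnot(inherits(a, "hap_alignment"))
  if (length(a$ids) == 0L) stopf("empty alignment")
  key <- apply(a$seq, 1L, paste, collapse = "")
  first <- !duplicated(key)
  hap_of <- match(key, key[first])
  K <- sum(first)
  hap_ids <- paste0("H", seq_len(K))
  pops <- unique(a$pops)
  counts <- table(factor(hap_of, levels = seq_len(K)),
                  factor(a$pops, levels = pops))
  counts <- matrix(as.integer(counts), nrow = K,
                   dimnames = list(hap_ids, pops))
  seqs <- a$seq[first, , drop = FALSE]
  rownames(seqs) <- hap_ids
  lineages <- NULL
  if (!is.null(a$meta) && "lineage" %in% names(a$meta)) {
    lineages <- vapply(pops, function(p) {
      as.character(a$meta$lineage[match(p, a$meta$population_id)])
    }, character(1L))
  }
  haplotype_table(counts, sequences = seqs, lineages = lineages)
}

#' Construct a haplotype table from a count matrix
#'
#' Builds the central container of the package directly from per-population
#' haplotype counts, e.g. a published haplotype-frequency table. Sequences
#' are optional; operations that need them (segregating sites, pairwise
#' differences) require `sequences`.
#'
#' @param counts Integer matrix, haplotypes x populations; row/column names
#'   are used as haplotype and population ids.
#' @param sequences Optional character matrix (haplotypes x sites) whose
#'   rownames match those of `counts`.
#' @param lineages Optional character vector of lineage labels, one per
#'   population (same order as `colnames(counts)`).
#' @return A `haplotype_table` (see [collapse_haplotypes()]).
#' @export
haplotype_table <- function(counts, sequences = NULL, lineages = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  if (any(counts < 0L)) stopf("negative haplotype counts")
  if (any(rowSums(counts) < 1L)) stopf("every haplotype needs total count >= 1")
  if (is.null(rownames(counts))) rownames(counts) <- paste0("H", seq_len(nrow(counts)))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("P", seq_len(ncol(counts)))
  S_seg <- NA_integer_
  L <- NA_integer_
  if (!is.null(sequences)) {
    sequences <- as.matrix(sequences)
    if (nrow(sequences) != nrow(counts)) {
      stopf("sequences (%d) and counts (%d) disagree on haplotype number",
            nrow(sequences), nrow(counts))
    }
    if (anyDuplicated(apply(sequences, 1L, paste, collapse = ""))) {
      stopf("haplotype sequences must be pairwise distinct")
    }
    L <- ncol(sequences)
    S_seg <- count_segregating(sequences)
  }
  if (!is.null(lineages)) {
    lineages <- as.character(lineages)
    if (length(lineages) != ncol(counts)) {
      stopf("need one lineage label per population")
    }
    names(lineages) <- colnames(counts)
  }
  structure(list(sequences = sequences, counts = counts, lineages = lineages,
                 K = nrow(counts), N = sum(counts), S_seg = S_seg, L = L),
            class = "haplotype_table")
}

# Variable columns, ignoring gaps and Ns (a site segregates when it carries
# at least two distinct unambiguous nucleotides).
count_segregating <- function(seqs) {
  sum(apply(seqs, 2L, function(col) {
    col <- col[col %in% c("A", "C", "G", "T")]
    length(unique(col)) > 1L
  }))
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat(sprintf("haplotype table: K = %d haplotypes, N = %d individuals, %d populations",
              x$K, x$N, ncol(x$counts)))
  if (!is.na(x$S_seg)) cat(sprintf(", S = %d segregating sites (L = %d)", x$S_seg, x$L))
  cat("\n")
  invisible(x)
}

#' Pairwise site differences between haplotypes
#'
#' Counts, for every pair of haplotypes, the number of sites at which both
#' carry an unambiguous nucleotide and the nucleotides differ. Sites with a
#' gap (`-`) or `N` in either sequence of a pair are excluded from that
#' pair's count (pairwise deletion).
#'
#' @param t A `haplotype_table` carrying sequences.
#' @return Symmetric integer matrix of pairwise differences (sites), with a
#'   zero diagonal.
#' @export
pairwise_differences <- function(t) {
  stopifnot(inherits(t, "haplotype_table"))
  if (is.null(t$sequences)) stopf("haplotype table carries no sequences")
  seqs <- t$sequences
  K <- nrow(seqs)
  ok <- seqs == "A" | seqs == "C" | seqs == "G" | seqs == "T"
  d <- matrix(0L, K, K, dimnames = list(rownames(seqs), rownames(seqs)))
  if (K > 1L) {
    for (i in seq_len(K - 1L)) {
      si <- seqs[i, ]
      oi <- ok[i, ]
      for (j in (i + 1L):K) {
        use <- oi & ok[j, ]
        dij <- sum(si[use] != seqs[j, use])
        d[i, j] <- dij
        d[j, i] <- dij
      }
    }
  }
  d
}

#' Per-population haplotype counts restricted to a scope
#'
#' @param t A `haplotype_table`.
#' @param scope Either `"all"`, a vector of population ids, or (when the
#'   table has lineage labels) a single lineage label.
#' @return Named integer vector of haplotype counts (only haplotypes with
#'   nonzero total within the scope).
#' @export
scope_counts <- function(t, scope = "all") {
  stopifnot(inherits(t, "haplotype_table"))
  pops <- scope_populations(t, scope)
  cc <- rowSums(t$counts[, pops, drop = FALSE])
  cc[cc > 0L]
}

scope_populations <- function(t, scope) {
  if (identical(scope, "all")) return(colnames(t$counts))
  if (length(scope) == 1L && !is.null(t$lineages) &&
      scope %in% t$lineages && !(scope %in% colnames(t$counts))) {
    return(names(t$lineages)[t$lineages == scope])
  }
  miss <- setdiff(scope, colnames(t$counts))
  if (length(miss) > 0L) {
    stopf("unknown population(s): %s", paste(miss, collapse = ", "))
  }
  scope
}
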