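## Aligned COI barcodes: parsing, site statistics, haplotype collapsing.

new_aligned_seqs <- function(mat) {
  stopifnot(is.matrix(mat), is.character(mat))
  bad <- !mat %in% c("A", "C", "G", "T", "N", "-")
  if (any(bad))
    stop("unexpected residue(s) in alignment: ",
         paste(unique(mat[bad]), collapse = ", "))
  if (is.null(rownames(mat)) || anyDuplicated(rownames(mat)))
    stop("sequence IDs must be present and unique")
  structure(mat, class = c("aligned_seqs", "matrix"))
}

#' Build an aligned sequence set from character strings
#'
#' @param seqs named character vector of equal-length nucleotide strings
#'   (alphabet A, C, G, T, N, `-`; case-insensitive).
#' @return Object of class `aligned_seqs`: a character matrix, one row per
#'   sequence, one column per alignment site.
#' @export
aligned_seqs <- function(seqs) {
  if (!length(seqs)) stop("no sequences given")
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L)
    stop("ragged alignment; offending IDs: ",
         paste(names(seqs)[lens != stats::median(lens)], collapse = ", "))
  mat <- do.call(rbind, strsplit(toupper(seqs), ""))
  rownames(mat) <- names(seqs)
  new_aligned_seqs(mat)
}

#' @export
print.aligned_seqs <- function(x, ...) {
  cat("Aligned sequence set:", nrow(x), "sequences x", ncol(x), "sites\n")
  invisible(x)
}

#' Read an aligned FASTA file
#'
#' Parses with [ape::read.FASTA()], upper-cases residues and rejects ragged
#' alignments, naming the offending sequences.
#'
#' @param path FASTA file path.
#' @return An `aligned_seqs` object.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dna <- ape::read.FASTA(path)
  if (!length(dna)) stop("no sequences in ", path)
  lens <- lengths(dna)
  if (length(unique(lens)) != 1L) {
    common <- as.integer(names(sort(table(lens), decreasing = TRUE))[1])
    stop("ragged alignment in ", path, "; offending IDs: ",
         paste(names(dna)[lens != common], collapse = ", "))
  }
  mat <- toupper(as.character(as.matrix(dna)))
  rownames(mat) <- names(dna)
  new_aligned_seqs(mat)
}

#' Write an aligned sequence set as FASTA
#'
#' @param seqs an `aligned_seqs` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_aligned_fasta <- function(seqs, path) {
  lines <- character(2L * nrow(seqs))
  lines[c(TRUE, FALSE)] <- paste0(">", rownames(seqs))
  lines[c(FALSE, TRUE)] <- apply(unclass(seqs), 1, paste, collapse = "")
  writeLines(lines, path)
  invisible(path)
}

is_unambiguous <- function(x) x %in% c("A", "C", "G", "T")

#' Per-site alignment statistics
#'
#' Classifies alignment columns, ignoring ambiguous residues (N and gaps):
#' a site is variable when it carries at least two distinct unambiguous
#' states, and parsimony-informative when at least two states are each
#' carried by at least two sequences. Sites with fewer than two unambiguous
#' residues are not evaluable.
#'
#' @param seqs an `aligned_seqs` object with at least two sequences.
#' @return Object of class `site_stats`: list with `total_sites`,
#'   `evaluable_sites`, `constant_sites`, `variable_sites`,
#'   `informative_sites`.
#' @export
site_statistics <- function(seqs) {
  stopifnot(inherits(seqs, "aligned_seqs"))
  if (nrow(seqs) < 2L)
    stop("site statistics need at least two sequences")
  m <- unclass(seqs)
  variable <- logical(ncol(m)); informative <- logical(ncol(m))
  evaluable <- logical(ncol(m))
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[is_unambiguous(col)]
    if (length(col) < 2L) next
    evaluable[j] <- TRUE
    tab <- table(col)
    variable[j] <- length(tab) >= 2L
    informative[j] <- sum(tab >= 2L) >= 2L
  }
  structure(
    list(total_sites = ncol(m), evaluable_sites = sum(evaluable),
         constant_sites = sum(evaluable & !variable),
         variable_sites = sum(variable),
         informative_sites = sum(informative)),
    class = "site_stats"
  )
}

#' @export
print.site_stats <- function(x, ...) {
  cat("Alignment of", x$total_sites, "sites:", x$variable_sites,
      "variable,", x$informative_sites, "parsimony-informative",
      sprintf("(%d evaluable)\n", x$evaluable_sites))
  invisible(x)
}

#' Pairwise mutational-step (Hamming) distance matrix
#'
#' Counts differing positions over sites where both sequences carry an
#' unambiguous residue; N and gap positions are excluded pairwise so that
#' end-trimmed sequences of unequal effective length do not inflate
#' distances.
#'
#' @param seqs an `aligned_seqs` object.
#' @return Symmetric integer matrix with zero diagonal, dimnames = sequence
#'   IDs.
#' @export
pairwise_difference_matrix <- function(seqs) {
  stopifnot(inherits(seqs, "aligned_seqs"))
  m <- unclass(seqs)
  n <- nrow(m)
  ok <- is_unambiguous(m); dim(ok) <- dim(m)
  d <- matrix(0L, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    both <- ok[i, ] & ok[j, ]
    d[i, j] <- d[j, i] <- sum(m[i, both] != m[j, both])
  }
  d
}

#' Collapse identical sequences into haplotypes
#'
#' Sequences identical over their jointly unambiguous positions are merged,
#' greedily in input order: each sequence joins the first existing haplotype
#' it matches at zero mutational steps, otherwise founds a new one. When a
#' member resolves a position that is ambiguous in the current
#' representative, the representative is filled in, so representatives
#' converge on the least-ambiguous consensus. Frequencies are conserved:
#' they sum to the number of input sequences.
#'
#' @param seqs an `aligned_seqs` object.
#' @return Object of class `haplotype_set`: list with `table` (data frame:
#'   `haplotype`, `frequency`, `members` as a list-column) and
#'   `representatives` (`aligned_seqs` of one sequence per haplotype).
#' @export
collapse_haplotypes <- function(seqs) {
  stopifnot(inherits(seqs, "aligned_seqs"))
  m <- unclass(seqs)
  reps <- list(); members <- list()
  for (i in seq_len(nrow(m))) {
    s <- m[i, ]
    placed <- FALSE
    for (h in seq_along(reps)) {
      r <- reps[[h]]
      both <- is_unambiguous(s) & is_unambiguous(r)
      if (!any(s[both] != r[both])) {
        fill <- !is_unambiguous(r) & is_unambiguous(s)
        r[fill] <- s[fill]
        reps[[h]] <- r
        members[[h]] <- c(members[[h]], rownames(m)[i])
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      reps[[length(reps) + 1L]] <- s
      members[[length(members) + 1L]] <- rownames(m)[i]
    }
  }
  ids <- sprintf("H%02d", seq_along(reps))
  rep_mat <- do.call(rbind, reps)
  rownames(rep_mat) <- ids
  tab <- data.frame(haplotype = ids,
                    frequency = lengths(members),
                    stringsAsFactors = FALSE)
  tab$members <- members
  structure(list(table = tab, representatives = new_aligned_seqs(rep_mat)),
            class = "haplotype_set")
}

#' @export
print.haplotype_set <- function(x, ...) {
  cat("Haplotype set:", nrow(x$table), "haplotypes from",
      sum(x$table$frequency), "sequences\n")
  invisible(x)
}

#' Write a haplotype table as TSV
#'
#' @param haps a `haplotype_set`.
#' @param path output path; columns haplotype, frequency, members
#'   (comma-separated).
#' @return `path`, invisibly.
#' @export
write_haplotype_tsv <- function(haps, path) {
  tab <- data.frame(haplotype = haps$table$haplotype,
                    frequency = haps$table$frequency,
                    members = vapply(haps$table$members, paste, "",
                                     collapse = ","))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a pairwise mutational-step matrix as TSV
#'
#' @param seqs an `aligned_seqs` object or `haplotype_set` (representatives
#'   are used).
#' @param path output path: a square tab-separated matrix with an `id`
#'   column.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(seqs, path) {
  if (inherits(seqs, "haplotype_set")) seqs <- seqs$representatives
  d <- pairwise_difference_matrix(seqs)
  utils::write.table(cbind(id = rownames(d), as.data.frame(d)), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
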