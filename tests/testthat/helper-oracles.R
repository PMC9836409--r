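# Independent oracles and small generators used across the suite.

# Disjoint-set-union oracle for the metaphase-I element count: a second,
# independent route to the number of connected components of the
# arm-homology graph.
dsu_visible_count_oracle <- function(genotype) {
  chromA <- genotype$haplotype_a$chromosomes
  chromB <- genotype$haplotype_b$chromosomes
  nA <- length(chromA)
  n <- nA + length(chromB)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  carrier <- function(chroms) {
    arms <- unlist(chroms, use.names = FALSE)
    stats::setNames(rep(seq_along(chroms), lengths(chroms)), arms)
  }
  ca <- carrier(chromA); cb <- carrier(chromB)
  for (arm in as.character(genotype$universe))
    union_(ca[[arm]], nA + cb[[arm]])
  length(unique(vapply(seq_len(n), find, 1L)))
}

# all partitions of a set (restricted growth strings), as lists of
# character vectors — used for exhaustive small-universe checks
all_partitions <- function(items) {
  n <- length(items)
  out <- list()
  recurse <- function(assign, nblocks, i) {
    if (i > n) {
      blocks <- split(items, assign[seq_len(n)])
      out[[length(out) + 1L]] <<- unname(blocks)
      return(invisible())
    }
    for (b in seq_len(nblocks + 1L)) {
      assign[i] <- b
      recurse(assign, max(nblocks, b), i + 1L)
    }
  }
  recurse(integer(n), 0L, 1L)
  out
}

# random fusion state over a given arm universe: random partition with
# geometric-ish block sizes
random_karyotype <- function(universe) {
  arms <- sample(as.character(universe))
  chroms <- list()
  while (length(arms)) {
    k <- min(length(arms), sample(c(1L, 1L, 2L, 2L, 3L), 1L))
    chroms[[length(chroms) + 1L]] <- arms[seq_len(k)]
    arms <- arms[-seq_len(k)]
  }
  haploid_karyotype(chroms, universe)
}

# brute-force per-column site classification
site_stats_oracle <- function(mat) {
  variable <- 0L; informative <- 0L
  for (j in seq_len(ncol(mat))) {
    col <- mat[, j]
    col <- col[col %in% c("A", "C", "G", "T")]
    if (length(col) < 2L) next
    tab <- table(col)
    if (length(tab) >= 2L) variable <- variable + 1L
    if (sum(tab >= 2L) >= 2L) informative <- informative + 1L
  }
  c(variable = variable, informative = informative)
}

# brute-force pairwise Hamming distances over unambiguous sites
hamming_oracle <- function(mat) {
  n <- nrow(mat)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    cnt <- 0L
    for (p in seq_len(ncol(mat))) {
      a <- mat[i, p]; b <- mat[j, p]
      if (a %in% c("A", "C", "G", "T") && b %in% c("A", "C", "G", "T") &&
          a != b) cnt <- cnt + 1L
    }
    d[i, j] <- cnt
  }
  d
}

# random aligned sequences (with occasional ambiguity)
random_alignment <- function(n, len, p_ambig = 0.05) {
  pool <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n), function(i) {
    s <- sample(pool, len, replace = TRUE)
    amb <- stats::runif(len) < p_ambig
    s[amb] <- sample(c("N", "-"), sum(amb), replace = TRUE)
    paste(s, collapse = "")
  }, "")
  names(seqs) <- sprintf("s%02d", seq_len(n))
  aligned_seqs(seqs)
}
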