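#' Define an arm universe
#'
#' The arm universe is the finest segmentation of the chromosome complement
#' shared by all taxa under comparison: a set of chromosome arms that fusion
#' states partition into chromosomes. Every karyotype in a comparison must be
#' a partition of the same universe.
#'
#' @param arm_ids character vector of unique, non-empty arm identifiers.
#' @return An object of class `arm_universe` (a character vector).
#' @export
#' @examples
#' arm_universe(c("a1", "a2", "P1", "P2"))
arm_universe <- function(arm_ids) {
  arm_ids <- as.character(arm_ids)
  if (length(arm_ids) == 0L)
    stop("arm universe must be non-empty")
  if (anyDuplicated(arm_ids))
    stop("duplicated arm identifiers: ",
         paste(unique(arm_ids[duplicated(arm_ids)]), collapse = ", "))
  structure(arm_ids, class = "arm_universe")
}

#' @export
print.arm_universe <- function(x, ...) {
  cat("Arm universe with", length(x), "arms\n")
  invisible(x)
}

#' Construct a haploid karyotype as a fusion state over an arm universe
#'
#' A haploid karyotype is a partition of the arm universe into chromosomes:
#' single-arm chromosomes are unfused, multi-arm chromosomes are (possibly
#' chained) fusion products. The haploid number n is the number of
#' chromosomes.
#'
#' @param chromosomes list of character vectors; each vector is the arm
#'   content of one chromosome.
#' @param universe an [arm_universe()]; defaults to the union of the arms in
#'   `chromosomes`.
#' @return Object of class `haploid_karyotype` with elements `chromosomes`,
#'   `universe` and `n`.
#' @export
#' @examples
#' u <- arm_universe(c("a", "b", "c"))
#' haploid_karyotype(list(c("a", "b"), "c"), u)  # n = 2, one fusion
haploid_karyotype <- function(chromosomes, universe = NULL) {
  chromosomes <- lapply(chromosomes, as.character)
  arms <- unlist(chromosomes, use.names = FALSE)
  if (is.null(universe)) universe <- arm_universe(sort(arms))
  if (!inherits(universe, "arm_universe")) universe <- arm_universe(universe)
  if (anyDuplicated(arms))
    stop("arm(s) present in more than one chromosome: ",
         paste(unique(arms[duplicated(arms)]), collapse = ", "))
  missing <- setdiff(universe, arms)
  if (length(missing))
    stop("arm(s) missing from karyotype: ", paste(missing, collapse = ", "))
  extra <- setdiff(arms, universe)
  if (length(extra))
    stop("arm(s) not in universe: ", paste(extra, collapse = ", "))
  if (any(vapply(chromosomes, length, 1L) == 0L))
    stop("empty chromosome in karyotype")
  structure(
    list(chromosomes = chromosomes, universe = universe,
         n = length(chromosomes)),
    class = "haploid_karyotype"
  )
}

#' @export
print.haploid_karyotype <- function(x, ...) {
  fused <- vapply(x$chromosomes, length, 1L) > 1L
  cat("Haploid karyotype: n =", x$n, "over", length(x$universe), "arms;",
      sum(fused), "fused chromosome(s)\n")
  if (any(fused))
    cat("  fusions:",
        paste(vapply(x$chromosomes[fused], paste, "", collapse = "+"),
              collapse = ", "), "\n")
  invisible(x)
}

# canonical string key for a chromosome / karyotype, used for deduplication
chrom_key <- function(arms) paste(sort(arms), collapse = "+")

karyotype_key <- function(k) {
  paste(sort(vapply(k$chromosomes, chrom_key, "")), collapse = "|")
}

#' Construct a diploid genotype from two haploid complements
#'
#' Both haplotypes must partition the same arm universe. The diploid number
#' 2n is the total chromosome count, `n_a + n_b`; it differs between fusion
#' homozygotes and heterozygotes even when the metaphase-I visible-element
#' count does not.
#'
#' @param haplotype_a,haplotype_b [haploid_karyotype()] objects over the same
#'   universe.
#' @return Object of class `diploid_genotype` with elements `haplotype_a`,
#'   `haplotype_b`, `universe`, `diploid_number`.
#' @export
diploid_genotype <- function(haplotype_a, haplotype_b) {
  stopifnot(inherits(haplotype_a, "haploid_karyotype"),
            inherits(haplotype_b, "haploid_karyotype"))
  if (!setequal(haplotype_a$universe, haplotype_b$universe))
    stop("haplotypes are defined over different arm universes")
  structure(
    list(haplotype_a = haplotype_a, haplotype_b = haplotype_b,
         universe = haplotype_a$universe,
         diploid_number = haplotype_a$n + haplotype_b$n),
    class = "diploid_genotype"
  )
}

#' @export
print.diploid_genotype <- function(x, ...) {
  cat("Diploid genotype: 2n =", x$diploid_number,
      "(", x$haplotype_a$n, "+", x$haplotype_b$n, ") over",
      length(x$universe), "arms\n")
  invisible(x)
}

genotype_key <- function(g) {
  paste(sort(c(karyotype_key(g$haplotype_a), karyotype_key(g$haplotype_b))),
        collapse = "//")
}

#' The fully unfused haploid karyotype over a universe
#'
#' Every arm is its own chromosome, so n equals the universe size.
#'
#' @param universe an [arm_universe()] (or character vector of arm ids).
#' @return A [haploid_karyotype()].
#' @export
unfused_karyotype <- function(universe) {
  haploid_karyotype(as.list(as.character(universe)), universe)
}
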