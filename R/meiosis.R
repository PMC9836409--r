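#' Compute the metaphase-I pairing configuration of a diploid genotype
#'
#' Builds the arm-homology graph — one node per chromosome of either
#' haplotype, and for every arm an edge joining its carrier chromosome in
#' haplotype A to its carrier in haplotype B — and returns its connected
#' components as meiotic elements. A component of two chromosomes is a
#' bivalent, of three a trivalent (fusion heterozygote), of four a
#' quadrivalent, and so on. The number of components is the count of
#' elements visible under the microscope at metaphase I: the quantity
#' reported as the haploid number n in karyotype work.
#'
#' Counting is purely structural: chiasma formation or failure is not
#' modelled, so every homologous set is assumed to associate.
#'
#' @param genotype a [diploid_genotype()].
#' @return Object of class `meiotic_config`: list with `elements` (each a
#'   list with `members` — arm content per member chromosome —, `haplotype`
#'   — `"A"`/`"B"` origin per member —, `arity` and `kind`),
#'   `visible_count`, `stage` (`"MI"`) and the `genotype`.
#' @export
#' @examples
#' u <- arm_universe(as.character(1:42))
#' het <- diploid_genotype(
#'   haploid_karyotype(c(list(c("1", "2")), as.list(as.character(3:42))), u),
#'   unfused_karyotype(u))
#' pair_meiosis(het)  # 40 bivalents + 1 trivalent = 41 visible elements
pair_meiosis <- function(genotype) {
  stopifnot(inherits(genotype, "diploid_genotype"))
  chromA <- genotype$haplotype_a$chromosomes
  chromB <- genotype$haplotype_b$chromosomes
  u <- as.character(genotype$universe)

  arm_carrier <- function(chroms, hap) {
    arms <- unlist(chroms, use.names = FALSE)
    idx <- rep(seq_along(chroms), vapply(chroms, length, 1L))
    if (anyDuplicated(arms))
      stop("duplicated arm in haplotype ", hap, ": ",
           paste(unique(arms[duplicated(arms)]), collapse = ", "))
    missing <- setdiff(u, arms)
    if (length(missing))
      stop("arm missing from haplotype ", hap, ": ",
           paste(missing, collapse = ", "))
    stats::setNames(idx, arms)
  }
  carrierA <- arm_carrier(chromA, "A")
  carrierB <- arm_carrier(chromB, "B")

  # adjacency between A- and B-chromosomes induced by shared arms
  adjAB <- split(unname(carrierB[u]), carrierA[u])   # A index -> B indices
  adjBA <- split(unname(carrierA[u]), carrierB[u])   # B index -> A indices

  seenA <- logical(length(chromA))
  seenB <- logical(length(chromB))
  elements <- list()
  for (start in seq_along(chromA)) {
    if (seenA[start]) next
    compA <- integer(); compB <- integer()
    queueA <- start; seenA[start] <- TRUE
    queueB <- integer()
    while (length(queueA) || length(queueB)) {
      if (length(queueA)) {
        a <- queueA[1L]; queueA <- queueA[-1L]
        compA <- c(compA, a)
        for (b in unique(adjAB[[as.character(a)]])) {
          if (!seenB[b]) { seenB[b] <- TRUE; queueB <- c(queueB, b) }
        }
      } else {
        b <- queueB[1L]; queueB <- queueB[-1L]
        compB <- c(compB, b)
        for (a in unique(adjBA[[as.character(b)]])) {
          if (!seenA[a]) { seenA[a] <- TRUE; queueA <- c(queueA, a) }
        }
      }
    }
    members <- c(chromA[compA], chromB[compB])
    hap <- c(rep("A", length(compA)), rep("B", length(compB)))
    arity <- length(members)
    kind <- if (arity == 2L) "bivalent" else if (arity == 3L) "trivalent"
            else if (arity == 4L) "quadrivalent" else "multivalent"
    elements[[length(elements) + 1L]] <-
      list(members = members, haplotype = hap, arity = arity, kind = kind)
  }
  structure(
    list(elements = elements, visible_count = length(elements),
         stage = "MI", genotype = genotype),
    class = "meiotic_config"
  )
}

#' @export
print.meiotic_config <- function(x, ...) {
  kinds <- vapply(x$elements, `[[`, "", "kind")
  tab <- table(factor(kinds, levels = c("bivalent", "trivalent",
                                        "quadrivalent", "multivalent")))
  cat("Metaphase-I configuration:", x$visible_count, "visible elements (",
      paste(tab[tab > 0], names(tab)[tab > 0], collapse = " + "), ")\n")
  invisible(x)
}

#' @export
summary.meiotic_config <- function(object, ...) {
  kinds <- vapply(object$elements, `[[`, "", "kind")
  out <- list(visible_count = object$visible_count,
              kinds = table(kinds),
              diploid_number = object$genotype$diploid_number)
  class(out) <- "summary.meiotic_config"
  out
}

#' @export
print.summary.meiotic_config <- function(x, ...) {
  cat("MI visible elements:", x$visible_count, " (2n =", x$diploid_number,
      ")\n")
  print(x$kinds)
  invisible(x)
}

# enumerate exact covers of an element's arms by subsets of its member
# chromosomes; returns a list of integer member-index vectors
exact_covers <- function(members) {
  arms <- sort(unique(unlist(members, use.names = FALSE)))
  member_sets <- lapply(members, function(m) match(m, arms))
  narms <- length(arms)
  out <- list()
  recurse <- function(covered, chosen) {
    nxt <- which(!covered)[1L]
    if (is.na(nxt)) { out[[length(out) + 1L]] <<- chosen; return(invisible()) }
    for (i in seq_along(member_sets)) {
      s <- member_sets[[i]]
      if (nxt %in% s && !any(covered[s])) {
        covered2 <- covered; covered2[s] <- TRUE
        recurse(covered2, c(chosen, i))
      }
    }
  }
  recurse(logical(narms), integer())
  out
}

#' Enumerate balanced gametes of a meiotic configuration
#'
#' Within each metaphase-I element, a balanced segregation product is a
#' subset of the element's chromosomes that covers each of its arms exactly
#' once (an exact cover). A trivalent formed by a fused chromosome facing its
#' two unfused homologues thus yields two choices — the fused chromosome, or
#' both singles — while a homozygous bivalent yields a single distinct
#' choice. Gametes are all combinations of per-element choices; unbalanced
#' (aneuploid) products are excluded, and distinct choices within an element
#' are taken as equiprobable.
#'
#' @param config a `meiotic_config` from [pair_meiosis()], or a
#'   [diploid_genotype()] (paired on the fly).
#' @return List of distinct [haploid_karyotype()] gametes, with attribute
#'   `"prob"` giving each gamete's probability (sums to 1).
#' @export
#' @examples
#' u <- arm_universe(c("A", "B"))
#' het <- diploid_genotype(haploid_karyotype(list(c("A", "B")), u),
#'                         unfused_karyotype(u))
#' g <- enumerate_balanced_gametes(het)
#' sapply(g, function(k) k$n)  # 1 (fused) and 2 (unfused)
enumerate_balanced_gametes <- function(config) {
  if (inherits(config, "diploid_genotype")) config <- pair_meiosis(config)
  stopifnot(inherits(config, "meiotic_config"))
  universe <- config$genotype$universe

  per_element <- lapply(config$elements, function(el) {
    covers <- exact_covers(el$members)
    if (!length(covers))
      stop("element admits no balanced segregation product")
    # deduplicate covers by chromosome content
    keys <- vapply(covers, function(idx)
      paste(sort(vapply(el$members[idx], chrom_key, "")), collapse = "|"),
      "")
    covers[!duplicated(keys)]
  })

  # cartesian product over elements
  gametes <- list(list())
  for (j in seq_along(per_element)) {
    el <- config$elements[[j]]
    choices <- per_element[[j]]
    w <- 1 / length(choices)
    new <- vector("list", length(gametes) * length(choices))
    k <- 0L
    for (g in gametes) for (ch in choices) {
      k <- k + 1L
      new[[k]] <- c(g, list(list(chroms = el$members[ch], w = w)))
    }
    gametes <- new
  }
  karyos <- vector("list", length(gametes))
  prob <- numeric(length(gametes))
  for (i in seq_along(gametes)) {
    chroms <- unlist(lapply(gametes[[i]], `[[`, "chroms"), recursive = FALSE)
    karyos[[i]] <- haploid_karyotype(chroms, universe)
    prob[i] <- prod(vapply(gametes[[i]], `[[`, 1, "w"))
  }
  keys <- vapply(karyos, karyotype_key, "")
  first <- !duplicated(keys)
  prob <- as.numeric(tapply(prob, factor(keys, levels = keys[first]), sum))
  out <- karyos[first]
  attr(out, "prob") <- prob
  out
}
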