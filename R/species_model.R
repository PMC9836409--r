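#' Describe a species' karyotype as fixed and polymorphic fusions
#'
#' A species karyotype specification lists the fusions fixed in the taxon and
#' the fusions segregating within it, each polymorphic fusion with the
#' population frequency of its fused allele. Haploid variants of the species
#' are all fused/unfused combinations of the polymorphic fusions on top of
#' the fixed ones.
#'
#' @param name species label.
#' @param universe an [arm_universe()].
#' @param fixed_fusions list of character vectors, each a set of arms always
#'   fused into one chromosome in this taxon.
#' @param polymorphic_fusions list of character vectors, fusions segregating
#'   fused/unfused.
#' @param fused_freq numeric vector, one frequency in \[0, 1\] per polymorphic
#'   fusion (frequency of the fused allele).
#' @param chained logical; allow fusion arm-sets to share arms (chained
#'   fusions). Disallowed by default.
#' @return Object of class `species_karyotype_spec`.
#' @export
species_karyotype_spec <- function(name, universe, fixed_fusions = list(),
                                   polymorphic_fusions = list(),
                                   fused_freq = numeric(),
                                   chained = FALSE) {
  if (!inherits(universe, "arm_universe")) universe <- arm_universe(universe)
  fixed_fusions <- lapply(fixed_fusions, as.character)
  polymorphic_fusions <- lapply(polymorphic_fusions, as.character)
  if (length(fused_freq) != length(polymorphic_fusions))
    stop("need one fused-allele frequency per polymorphic fusion")
  if (length(fused_freq) && (any(fused_freq < 0) || any(fused_freq > 1)))
    stop("fused-allele frequencies must lie in [0, 1]")
  all_sets <- c(fixed_fusions, polymorphic_fusions)
  arms <- unlist(all_sets, use.names = FALSE)
  if (length(arms) && any(!arms %in% universe))
    stop("fusion references arms outside the universe: ",
         paste(setdiff(arms, universe), collapse = ", "))
  if (!chained && anyDuplicated(arms))
    stop("fusion arm-sets share arms; set chained = TRUE to allow chains")
  if (any(vapply(all_sets, length, 1L) < 2L))
    stop("a fusion must involve at least two arms")
  structure(
    list(name = name, universe = universe, fixed_fusions = fixed_fusions,
         polymorphic_fusions = polymorphic_fusions, fused_freq = fused_freq,
         chained = chained),
    class = "species_karyotype_spec"
  )
}

#' @export
print.species_karyotype_spec <- function(x, ...) {
  v <- haploid_variants(x)
  ns <- sort(unique(vapply(v, function(k) k$n, 1L)))
  cat("Species karyotype spec '", x$name, "': ", length(x$fixed_fusions),
      " fixed fusion(s), ", length(x$polymorphic_fusions),
      " polymorphic fusion(s); haploid n in {",
      paste(ns, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Enumerate the haploid karyotype variants of a species
#'
#' All combinations of the polymorphic fusions being fused or unfused, with
#' the fixed fusions always present.
#'
#' @param spec a [species_karyotype_spec()].
#' @return List of [haploid_karyotype()] objects with attribute `"prob"`:
#'   the variant frequency under the spec's fused-allele frequencies.
#' @export
haploid_variants <- function(spec) {
  stopifnot(inherits(spec, "species_karyotype_spec"))
  npoly <- length(spec$polymorphic_fusions)
  states <- if (npoly) expand.grid(rep(list(c(TRUE, FALSE)), npoly))
            else data.frame(row.names = 1)
  out <- vector("list", nrow(states))
  prob <- numeric(nrow(states))
  for (i in seq_len(nrow(states))) {
    on <- if (npoly) as.logical(states[i, ]) else logical()
    fusions <- c(spec$fixed_fusions, spec$polymorphic_fusions[on])
    fused_arms <- unlist(fusions, use.names = FALSE)
    singles <- setdiff(spec$universe, fused_arms)
    out[[i]] <- haploid_karyotype(c(fusions, as.list(singles)),
                                  spec$universe)
    prob[i] <- if (npoly)
      prod(ifelse(on, spec$fused_freq, 1 - spec$fused_freq)) else 1
  }
  attr(out, "prob") <- prob
  out
}

#' Build the default two-species fusion/fission model
#'
#' Reconstructs the unique disjoint-arm configuration consistent with two
#' parapatric taxa whose haploid counts are n = 41--42 (species O) and
#' n = 42--43 (species L), each polymorphic for one fusion/fission in a
#' different chromosome pair and separated by one fixed fusion difference.
#' The universe holds 44 arms: 38 singletons shared unfused by both taxa and
#' three two-arm pairs,
#' \describe{
#'   \item{F1a+F1b}{fixed fused in species O, fixed unfused in species L —
#'     the diagnostic fixed difference;}
#'   \item{Qa+Qb}{fixed fused in species O, polymorphic in species L;}
#'   \item{Pa+Pb}{polymorphic in species O, fixed fused in species L.}
#' }
#' Hence species O haploid variants have n = 41 (fused) or 42, species L
#' n = 42 (fused) or 43, and every F1 combination shows 41 visible elements
#' at metaphase I.
#'
#' @param freq_O fused-allele frequency of species O's polymorphic fusion
#'   (pair P). Default 0: every sample of the studied population shows
#'   n = 42, i.e. the fused allele is locally absent (the fusion is known
#'   to segregate in other populations; set a positive frequency to model
#'   them). Scenario supports ([achievable_visible_counts()]) cover
#'   positive-probability genotypes, while [haploid_variants()] always
#'   enumerates both states of a polymorphic fusion.
#' @param freq_L fused-allele frequency of species L's polymorphic fusion
#'   (pair Q). Default 0.5: both n = 42 and n = 43 segregate.
#' @param haplogroup_map named character vector mapping mitochondrial
#'   haplogroup labels to parent taxa (`"O"` or `"L"`).
#' @param hybrid_maternal_haplogroups haplogroups for which hybrid-generation
#'   scenarios are entertained in consistency classification. Default the
#'   orph2 analogue: observed hybrids all carry the O-side mitochondrion,
#'   implying O-female founding crosses.
#' @return Object of class `two_species_model`: list with `universe`,
#'   `species_O`, `species_L`, `haplogroup_map`,
#'   `hybrid_maternal_haplogroups`.
#' @export
#' @examples
#' m <- build_two_species_model()
#' sapply(haploid_variants(m$species_O), function(k) k$n)  # 41 42
#' sapply(haploid_variants(m$species_L), function(k) k$n)  # 42 43
build_two_species_model <- function(freq_O = 0, freq_L = 0.5,
                                    haplogroup_map = c(orph1 = "O",
                                                       orph2 = "O",
                                                       aroa3 = "L"),
                                    hybrid_maternal_haplogroups = "orph2") {
  singles <- sprintf("s%02d", seq_len(38))
  pairP <- c("Pa", "Pb"); pairF <- c("F1a", "F1b"); pairQ <- c("Qa", "Qb")
  u <- arm_universe(c(singles, pairP, pairF, pairQ))
  species_O <- species_karyotype_spec(
    "species-O", u,
    fixed_fusions = list(pairF, pairQ),
    polymorphic_fusions = list(pairP), fused_freq = freq_O)
  species_L <- species_karyotype_spec(
    "species-L", u,
    fixed_fusions = list(pairP),
    polymorphic_fusions = list(pairQ), fused_freq = freq_L)
  structure(
    list(universe = u, species_O = species_O, species_L = species_L,
         haplogroup_map = haplogroup_map,
         hybrid_maternal_haplogroups = hybrid_maternal_haplogroups),
    class = "two_species_model"
  )
}

#' @export
print.two_species_model <- function(x, ...) {
  cat("Two-species fusion/fission model over", length(x$universe), "arms\n")
  print(x$species_O); print(x$species_L)
  cat("Haplogroup map:",
      paste(names(x$haplogroup_map), x$haplogroup_map, sep = "->",
            collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a karyotype model as a YAML configuration
#'
#' Serializes the arm universe and both species specifications (fixed and
#' polymorphic fusions with fused-allele frequencies) so a model can be
#' shared and re-read.
#'
#' @param model a `two_species_model`.
#' @param path file path.
#' @return `write_model_yaml` returns `path` invisibly; `read_model_yaml`
#'   returns a `two_species_model`.
#' @export
write_model_yaml <- function(model, path) {
  spec_to_list <- function(s) list(
    name = s$name,
    fixed_fusions = lapply(s$fixed_fusions, as.list),
    polymorphic_fusions = lapply(seq_along(s$polymorphic_fusions),
      function(i) list(arms = as.list(s$polymorphic_fusions[[i]]),
                       fused_freq = s$fused_freq[i])))
  obj <- list(arms = as.list(as.character(model$universe)),
              species_O = spec_to_list(model$species_O),
              species_L = spec_to_list(model$species_L),
              haplogroup_map = as.list(model$haplogroup_map),
              hybrid_maternal_haplogroups =
                as.list(model$hybrid_maternal_haplogroups))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  u <- arm_universe(unlist(obj$arms))
  list_to_spec <- function(s) {
    poly <- lapply(s$polymorphic_fusions, function(p) unlist(p$arms))
    freq <- vapply(s$polymorphic_fusions, function(p) p$fused_freq, 1)
    species_karyotype_spec(s$name, u,
                           fixed_fusions = lapply(s$fixed_fusions, unlist),
                           polymorphic_fusions = poly, fused_freq = freq)
  }
  structure(
    list(universe = u,
         species_O = list_to_spec(obj$species_O),
         species_L = list_to_spec(obj$species_L),
         haplogroup_map = unlist(obj$haplogroup_map),
         hybrid_maternal_haplogroups =
           unlist(obj$hybrid_maternal_haplogroups)),
    class = "two_species_model"
  )
}
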