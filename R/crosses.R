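## Crossing machinery: distributions over genotypes and pedigree scenarios.

new_genotype_distribution <- function(genotypes, prob) {
  keep <- prob > 0
  genotypes <- genotypes[keep]; prob <- prob[keep]
  keys <- vapply(genotypes, genotype_key, "")
  first <- !duplicated(keys)
  prob <- as.numeric(tapply(prob, factor(keys, levels = keys[first]), sum))
  structure(list(genotypes = genotypes[first], prob = prob),
            class = "genotype_distribution")
}

#' @export
print.genotype_distribution <- function(x, ...) {
  counts <- vapply(x$genotypes,
                   function(g) pair_meiosis(g)$visible_count, 1L)
  cat("Genotype distribution:", length(x$genotypes), "distinct genotype(s)\n")
  agg <- tapply(x$prob, counts, sum)
  for (nm in names(agg))
    cat(sprintf("  MI visible elements %s: p = %.4g\n", nm, agg[[nm]]))
  invisible(x)
}

# mixture of balanced gamete pools over a genotype distribution;
# zero-probability gametes are dropped (distributions carry support only)
gamete_pool <- function(dist) {
  karyos <- list(); prob <- numeric()
  for (i in seq_along(dist$genotypes)) {
    g <- enumerate_balanced_gametes(dist$genotypes[[i]])
    karyos <- c(karyos, g)
    prob <- c(prob, attr(g, "prob") * dist$prob[i])
  }
  keep <- prob > 0
  karyos <- karyos[keep]; prob <- prob[keep]
  keys <- vapply(karyos, karyotype_key, "")
  first <- !duplicated(keys)
  prob <- as.numeric(tapply(prob, factor(keys, levels = keys[first]), sum))
  out <- karyos[first]
  attr(out, "prob") <- prob
  out
}

# pair two gamete pools into a genotype distribution (random union)
pair_pools <- function(pool1, pool2) {
  p1 <- attr(pool1, "prob"); p2 <- attr(pool2, "prob")
  genos <- list(); prob <- numeric()
  for (i in seq_along(pool1)) for (j in seq_along(pool2)) {
    genos[[length(genos) + 1L]] <- diploid_genotype(pool1[[i]], pool2[[j]])
    prob <- c(prob, p1[i] * p2[j])
  }
  new_genotype_distribution(genos, prob)
}

#' Cross two diploid genotypes
#'
#' Enumerates the balanced gametes of each parent (equal weights across the
#' distinct per-element segregation choices) and returns the distribution of
#' offspring genotypes over all gamete combinations. Probabilities sum to 1.
#'
#' @param parent1,parent2 [diploid_genotype()] objects over the same arm
#'   universe.
#' @return A `genotype_distribution`: list with parallel `genotypes` (list of
#'   [diploid_genotype()]) and `prob` (numeric).
#' @export
cross <- function(parent1, parent2) {
  stopifnot(inherits(parent1, "diploid_genotype"),
            inherits(parent2, "diploid_genotype"))
  if (!setequal(parent1$universe, parent2$universe))
    stop("parents are defined over different arm universes")
  pair_pools(enumerate_balanced_gametes(parent1),
             enumerate_balanced_gametes(parent2))
}

# species-level gamete pool and Hardy-Weinberg genotype distribution
species_gamete_pool <- function(spec) {
  v <- haploid_variants(spec)
  out <- v
  attr(out, "prob") <- attr(v, "prob")
  out
}

species_genotype_distribution <- function(spec) {
  pool <- species_gamete_pool(spec)
  pair_pools(pool, pool)
}

#' Define a pedigree scenario over the two-species model
#'
#' Standard scenarios: `"pure-O"` and `"pure-L"` (random mating within the
#' species under its fused-allele frequencies), `"F1"` (one gamete from each
#' species' pool), `"BC1"` (gamete of an F1 individual crossed back to a
#' parental-species gamete), `"F2"` (F1 x F1).
#'
#' @param label one of `"pure-O"`, `"pure-L"`, `"F1"`, `"BC1"`, `"F2"`.
#' @param model a [build_two_species_model()] model.
#' @param backcross_to for `"BC1"`, which parental species receives the
#'   backcross; `"L"` (default, the direction supported by the observed
#'   n = 43 hybrids) or `"O"`.
#' @return Object of class `pedigree_scenario`.
#' @export
pedigree_scenario <- function(label = c("pure-O", "pure-L", "F1", "BC1",
                                        "F2"),
                              model, backcross_to = "L") {
  label <- match.arg(label)
  stopifnot(inherits(model, "two_species_model"))
  if (!backcross_to %in% c("L", "O"))
    stop("backcross_to must be 'L' or 'O'")
  structure(list(label = label, model = model, backcross_to = backcross_to),
            class = "pedigree_scenario")
}

scenario_distribution <- function(scenario) {
  stopifnot(inherits(scenario, "pedigree_scenario"))
  m <- scenario$model
  poolO <- species_gamete_pool(m$species_O)
  poolL <- species_gamete_pool(m$species_L)
  switch(scenario$label,
    "pure-O" = pair_pools(poolO, poolO),
    "pure-L" = pair_pools(poolL, poolL),
    "F1" = pair_pools(poolO, poolL),
    "BC1" = {
      f1 <- pair_pools(poolO, poolL)
      back <- if (scenario$backcross_to == "L") poolL else poolO
      pair_pools(gamete_pool(f1), back)
    },
    "F2" = {
      f1 <- pair_pools(poolO, poolL)
      gp <- gamete_pool(f1)
      pair_pools(gp, gp)
    })
}

#' Achievable metaphase-I visible-element counts under a pedigree scenario
#'
#' Enumerates every genotype reachable under the scenario (exhaustively, via
#' balanced-gamete enumeration) and aggregates the probability of each
#' metaphase-I visible-element count. Deterministic given the model.
#'
#' @param scenario a [pedigree_scenario()].
#' @return Data frame with columns `visible_count` and `probability`
#'   (summing to 1), ordered by count, with the scenario label as attribute
#'   `"scenario"`.
#' @export
#' @examples
#' m <- build_two_species_model()
#' achievable_visible_counts(pedigree_scenario("F1", m))   # 41 only
#' achievable_visible_counts(pedigree_scenario("BC1", m))  # 41, 42, 43
achievable_visible_counts <- function(scenario) {
  dist <- scenario_distribution(scenario)
  if (!length(dist$genotypes)) stop("empty scenario")
  counts <- vapply(dist$genotypes,
                   function(g) pair_meiosis(g)$visible_count, 1L)
  agg <- tapply(dist$prob, counts, sum)
  out <- data.frame(visible_count = as.integer(names(agg)),
                    probability = as.numeric(agg))
  out <- out[order(out$visible_count), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "scenario") <- scenario$label
  out
}

#' Classify an observed karyotype count against the two-species model
#'
#' Tests membership of the observed metaphase-I element count in the
#' achievable-count set of each scenario compatible with the specimen's
#' mitochondrial haplogroup, and returns the minimal-generation category
#' that explains the observation: the pure species of the mito parent first,
#' then F1, then first-generation backcross. Hybrid-generation scenarios are
#' only entertained for haplogroups listed in the model's
#' `hybrid_maternal_haplogroups` (mitochondria are maternally inherited, so
#' hybrids carry the founding female lineage's haplogroup; in the study
#' system every putative hybrid carried the O-side haplogroup).
#'
#' @param observed_n observed count of visible elements (positive integer).
#' @param haplogroup mitochondrial haplogroup label, present in the model's
#'   `haplogroup_map`.
#' @param model a [build_two_species_model()] model.
#' @return Object of class `karyotype_consistency`: list with `category`
#'   (one of `"pure-O-consistent"`, `"pure-L-consistent"`, `"F1-consistent"`,
#'   `"backcross-consistent"`, `"inconsistent"`), `matching_scenarios` (all
#'   scenarios whose achievable set contains the count), `observed_n`,
#'   `haplogroup`, `parent_taxon`.
#' @export
#' @examples
#' m <- build_two_species_model()
#' classify_karyotype_consistency(43, "orph2", m)$category  # backcross
classify_karyotype_consistency <- function(observed_n, haplogroup, model) {
  stopifnot(inherits(model, "two_species_model"))
  observed_n <- as.integer(observed_n)
  if (is.na(observed_n) || observed_n <= 0L)
    stop("observed_n must be a positive count")
  if (!haplogroup %in% names(model$haplogroup_map))
    stop("unknown haplogroup label: ", haplogroup)
  parent <- model$haplogroup_map[[haplogroup]]

  pure_label <- if (parent == "O") "pure-O" else "pure-L"
  candidates <- pure_label
  if (haplogroup %in% model$hybrid_maternal_haplogroups)
    candidates <- c(candidates, "F1", "BC1")

  achieved <- lapply(candidates, function(lb)
    achievable_visible_counts(pedigree_scenario(lb, model))$visible_count)
  hit <- vapply(achieved, function(s) observed_n %in% s, TRUE)
  matching <- candidates[hit]

  category <- if (!any(hit)) "inconsistent"
    else switch(matching[1L],
                "pure-O" = "pure-O-consistent",
                "pure-L" = "pure-L-consistent",
                "F1" = "F1-consistent",
                "BC1" = "backcross-consistent")
  structure(
    list(category = category, matching_scenarios = matching,
         observed_n = observed_n, haplogroup = haplogroup,
         parent_taxon = parent),
    class = "karyotype_consistency"
  )
}

#' @export
print.karyotype_consistency <- function(x, ...) {
  cat("n =", x$observed_n, "with haplogroup", x$haplogroup, "->",
      x$category, "\n")
  if (length(x$matching_scenarios))
    cat("  scenarios containing the count:",
        paste(x$matching_scenarios, collapse = ", "), "\n")
  invisible(x)
}

#' Export scenarios' achievable counts
#'
#' `write_scenario_counts_tsv` writes one row per (scenario, count) with
#' columns scenario, visible_count, probability;
#' `write_scenario_counts_json` writes the same table as JSON keyed by
#' scenario label.
#'
#' @param scenarios list of [pedigree_scenario()] objects.
#' @param path output path.
#' @return The combined data frame, invisibly.
#' @export
write_scenario_counts_tsv <- function(scenarios, path) {
  rows <- lapply(scenarios, function(sc) {
    a <- achievable_visible_counts(sc)
    cbind(scenario = attr(a, "scenario"), a)
  })
  out <- do.call(rbind, rows)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}

#' @rdname write_scenario_counts_tsv
#' @export
write_scenario_counts_json <- function(scenarios, path) {
  obj <- lapply(scenarios, function(sc) {
    a <- achievable_visible_counts(sc)
    list(visible_count = a$visible_count, probability = a$probability)
  })
  names(obj) <- vapply(scenarios, `[[`, "", "label")
  jsonlite::write_json(obj, path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  out <- do.call(rbind, lapply(scenarios, function(sc) {
    a <- achievable_visible_counts(sc)
    cbind(scenario = attr(a, "scenario"), a)
  }))
  invisible(out)
}
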