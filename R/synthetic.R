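## Synthetic study generator: sequences, karyotypes, colours and a joined
## specimen table with planted truth, for end-to-end testing without data
## downloads.

#' Configuration for the synthetic study generator
#'
#' Defaults emulate the study conditions of a two-species contact zone with
#' context taxa: five mitochondrial haplogroups on a star phylogeny, a focal
#' set of 27 specimens (10 species O, 13 species L, 4 putative hybrids — the
#' size of the morphometric data set), hybrids all first-generation
#' backcrosses carrying the O-side mitochondrion, the species-O fusion
#' locally fixed unfused (all samples n = 42) and the species-L fusion
#' segregating at frequency 0.5, and dark-ophiolite
#' versus paler-karst colour means separated by roughly four within-group
#' standard deviations in RGB space.
#'
#' @param seed integer seed (mandatory; every simulator output is a pure
#'   function of the configuration).
#' @param groups haplogroup labels; the O- and L-side focal groups must be
#'   named by `focal_O` / `focal_L`.
#' @param centroid_steps named integer vector: mutational steps from the
#'   shared ancestor to each haplogroup centroid. Centroid site sets are
#'   disjoint (infinite-sites), so the realized divergence between groups i
#'   and j is `centroid_steps[i] + centroid_steps[j]`.
#' @param within_rate mean (Poisson) private mutations per specimen.
#' @param barcode_length alignment length (default 657).
#' @param n_O,n_L,n_hybrid focal sample sizes.
#' @param n_context named vector of sample sizes for context haplogroups.
#' @param hybrid_mix named proportions over hybrid generations `F1`, `BC1`
#'   (must sum to 1); realized deterministically by largest remainder.
#' @param fused_freq_O,fused_freq_L fused-allele frequencies of the two
#'   species' polymorphic fusions.
#' @param colour_mean_O,colour_mean_L RGB means of the two species; hybrids
#'   draw from the parental midpoint.
#' @param colour_sd per-channel Gaussian noise SD.
#' @param n_discs measurement discs per specimen.
#' @param contact_fraction fraction of pure specimens collected in the
#'   contact-zone locality (hybrids are always from the contact zone).
#' @param focal_O,focal_L haplogroup labels of the focal species.
#' @param prob_male probability a specimen is male.
#' @return Object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(seed,
                              groups = c("orph1", "orph2", "aroa1",
                                         "aroa2", "aroa3"),
                              centroid_steps = c(orph1 = 7, orph2 = 7,
                                                 aroa1 = 9, aroa2 = 10,
                                                 aroa3 = 10),
                              within_rate = 1,
                              barcode_length = 657,
                              n_O = 10, n_L = 13, n_hybrid = 4,
                              n_context = c(orph1 = 3, aroa1 = 3,
                                            aroa2 = 3),
                              hybrid_mix = c(F1 = 0, BC1 = 1),
                              fused_freq_O = 0, fused_freq_L = 0.5,
                              colour_mean_O = c(105, 92, 70),
                              colour_mean_L = c(62, 48, 40),
                              colour_sd = 10,
                              n_discs = 3,
                              contact_fraction = 0.2,
                              focal_O = "orph2", focal_L = "aroa3",
                              prob_male = 0.85) {
  if (missing(seed)) stop("a seed is mandatory")
  seed <- as.integer(seed)
  stopifnot(length(groups) >= 2L, focal_O %in% groups, focal_L %in% groups,
            all(names(centroid_steps) %in% groups),
            all(groups %in% names(centroid_steps)))
  if (abs(sum(hybrid_mix) - 1) > 1e-9)
    stop("hybrid_mix proportions must sum to 1")
  if (sum(centroid_steps) + 50 > barcode_length)
    stop("haplogroup divergence exceeds what the sequence length allows")
  if (any(!names(n_context) %in% setdiff(groups, c(focal_O, focal_L))))
    stop("n_context must name non-focal groups")
  structure(
    list(seed = seed, groups = groups, centroid_steps = centroid_steps,
         within_rate = within_rate, barcode_length = barcode_length,
         n_O = n_O, n_L = n_L, n_hybrid = n_hybrid,
         n_context = n_context, hybrid_mix = hybrid_mix,
         fused_freq_O = fused_freq_O, fused_freq_L = fused_freq_L,
         colour_mean_O = colour_mean_O, colour_mean_L = colour_mean_L,
         colour_sd = colour_sd, n_discs = n_discs,
         contact_fraction = contact_fraction,
         focal_O = focal_O, focal_L = focal_L, prob_male = prob_male),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation config: seed", x$seed, "-", x$n_O, "species-O +", x$n_L,
      "species-L +", x$n_hybrid, "hybrid specimens,",
      sum(x$n_context), "context specimens,", length(x$groups),
      "haplogroups\n")
  invisible(x)
}

# deterministic specimen frame: IDs, species truth and hybrid classes
specimen_frame <- function(config) {
  mix <- config$hybrid_mix
  nh <- config$n_hybrid
  counts <- floor(mix * nh)
  rem <- nh - sum(counts)
  if (rem > 0) {
    frac <- mix * nh - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1
  }
  hyb_class <- rep(names(mix), counts)
  focal <- data.frame(
    specimen_id = c(sprintf("O%02d", seq_len(config$n_O)),
                    sprintf("L%02d", seq_len(config$n_L)),
                    if (nh) sprintf("HY%02d", seq_len(nh))),
    species = c(rep("O", config$n_O), rep("L", config$n_L),
                rep("hybrid", nh)),
    hybrid_class = c(rep(NA_character_, config$n_O + config$n_L),
                     hyb_class),
    haplogroup = c(rep(config$focal_O, config$n_O),
                   rep(config$focal_L, config$n_L),
                   rep(config$focal_O, nh)),  # maternal O-line hybrids
    focal = TRUE, stringsAsFactors = FALSE)
  ctx <- do.call(rbind, lapply(names(config$n_context), function(g)
    if (config$n_context[[g]] > 0)
      data.frame(specimen_id = sprintf("%s_%02d", g,
                                       seq_len(config$n_context[[g]])),
                 species = "context", hybrid_class = NA_character_,
                 haplogroup = g, focal = FALSE,
                 stringsAsFactors = FALSE)))
  rbind(focal, ctx)
}

#' Simulate aligned barcodes with planted haplogroup structure
#'
#' A random ancestor is mutated to one centroid per haplogroup at the
#' configured step counts, on disjoint site sets (infinite-sites, no back
#' mutation); each specimen then receives Poisson-distributed private
#' mutations at sites untouched by any centroid.
#'
#' @param config a [simulation_config()].
#' @return List with `seqs` (an `aligned_seqs` of all specimens) and `truth`
#'   (data frame: `specimen_id`, `haplogroup`, `species`).
#' @export
simulate_haplotypes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  frame <- specimen_frame(config)
  set.seed(config$seed + 1L)
  len <- config$barcode_length
  bases <- c("A", "C", "G", "T")
  ancestor <- sample(bases, len, replace = TRUE)

  steps <- config$centroid_steps[config$groups]
  if (sum(steps) > len) stop("divergence exceeds sequence length")
  pool <- sample.int(len)  # shuffled site order; centroids take a prefix
  centroids <- list(); used <- 0L
  for (g in config$groups) {
    s <- ancestor
    k <- steps[[g]]
    if (k > 0) {
      sites <- pool[(used + 1L):(used + k)]
      for (p in sites) s[p] <- sample(setdiff(bases, s[p]), 1L)
      used <- used + k
    }
    centroids[[g]] <- s
  }
  free_sites <- pool[seq.int(used + 1L, len)]

  seqs <- character(nrow(frame))
  for (i in seq_len(nrow(frame))) {
    s <- centroids[[frame$haplogroup[i]]]
    k <- stats::rpois(1L, config$within_rate)
    k <- min(k, length(free_sites))
    if (k > 0) {
      sites <- sample(free_sites, k)
      for (p in sites) s[p] <- sample(setdiff(bases, s[p]), 1L)
    }
    seqs[i] <- paste(s, collapse = "")
  }
  names(seqs) <- frame$specimen_id
  list(seqs = aligned_seqs(seqs),
       truth = frame[, c("specimen_id", "haplogroup", "species")])
}

# draw one gamete from a species spec (fused alleles Bernoulli(freq))
draw_species_gamete <- function(spec) {
  on <- stats::runif(length(spec$polymorphic_fusions)) < spec$fused_freq
  fusions <- c(spec$fixed_fusions, spec$polymorphic_fusions[on])
  singles <- setdiff(spec$universe, unlist(fusions))
  haploid_karyotype(c(fusions, as.list(singles)), spec$universe)
}

# draw one balanced gamete from a diploid genotype
draw_balanced_gamete <- function(genotype) {
  g <- enumerate_balanced_gametes(genotype)
  g[[sample.int(length(g), 1L, prob = attr(g, "prob"))]]
}

#' Simulate per-specimen karyotype observations
#'
#' Pure-species genotypes are drawn under Hardy-Weinberg from the species'
#' fused-allele frequencies; F1 hybrids take one gamete from each species'
#' pool; first-generation backcrosses take a balanced gamete of a simulated
#' F1 against a species-L gamete. The reported count is the metaphase-I
#' visible-element count from [pair_meiosis()].
#'
#' @param config a [simulation_config()].
#' @param model a [build_two_species_model()]; defaults to one built from
#'   the config's fused-allele frequencies.
#' @return Data frame: `specimen_id`, `visible_n`, `multivalents`,
#'   `diploid_2n` for every focal specimen.
#' @export
simulate_karyotype_observations <- function(config,
                                            model = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(model))
    model <- build_two_species_model(config$fused_freq_O,
                                     config$fused_freq_L)
  frame <- specimen_frame(config)
  frame <- frame[frame$focal, , drop = FALSE]
  set.seed(config$seed + 2L)
  rows <- lapply(seq_len(nrow(frame)), function(i) {
    sp <- frame$species[i]
    geno <- if (sp == "O") {
      diploid_genotype(draw_species_gamete(model$species_O),
                       draw_species_gamete(model$species_O))
    } else if (sp == "L") {
      diploid_genotype(draw_species_gamete(model$species_L),
                       draw_species_gamete(model$species_L))
    } else if (frame$hybrid_class[i] == "F1") {
      diploid_genotype(draw_species_gamete(model$species_O),
                       draw_species_gamete(model$species_L))
    } else {  # BC1
      f1 <- diploid_genotype(draw_species_gamete(model$species_O),
                             draw_species_gamete(model$species_L))
      diploid_genotype(draw_balanced_gamete(f1),
                       draw_species_gamete(model$species_L))
    }
    conf <- pair_meiosis(geno)
    data.frame(specimen_id = frame$specimen_id[i],
               visible_n = conf$visible_count,
               multivalents = sum(vapply(conf$elements, `[[`, 1L,
                                         "arity") > 2L),
               diploid_2n = geno$diploid_number,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate disc-level colour measurements
#'
#' Each focal specimen receives `n_discs` measurements drawn per channel
#' from its group's RGB mean plus Gaussian noise, rounded and clamped to
#' 0--255; hybrids draw from the midpoint of the parental means.
#'
#' @param config a [simulation_config()].
#' @return Data frame: `specimen_id`, `disc`, `R`, `G`, `B`.
#' @export
simulate_colours <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  frame <- specimen_frame(config)
  frame <- frame[frame$focal, , drop = FALSE]
  set.seed(config$seed + 3L)
  mid <- (config$colour_mean_O + config$colour_mean_L) / 2
  rows <- lapply(seq_len(nrow(frame)), function(i) {
    mu <- switch(frame$species[i], O = config$colour_mean_O,
                 L = config$colour_mean_L, hybrid = mid)
    vals <- matrix(stats::rnorm(3L * config$n_discs, rep(mu, config$n_discs),
                                config$colour_sd),
                   ncol = 3L, byrow = TRUE)
    vals <- pmin(pmax(round(vals), 0), 255)
    data.frame(specimen_id = frame$specimen_id[i],
               disc = seq_len(config$n_discs),
               R = vals[, 1], G = vals[, 2], B = vals[, 3],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Simulate the joined study table with its truth bundle
#'
#' Runs the sequence, karyotype and colour simulators under sub-seeds of one
#' configuration seed and joins them with localities, substrates and sexes:
#' species O is collected on karst sites, species L on ophiolite sites,
#' hybrids (and a configured fraction of pure specimens) in a mixed-soil
#' contact-zone locality. Identical configurations give identical output.
#'
#' @param config a [simulation_config()].
#' @param model optional [build_two_species_model()].
#' @return Object of class `synthetic_study`: list with `specimens` (data
#'   frame: specimen_id, sex, locality, substrate, haplogroup,
#'   karyotype_n, multivalents), `sequences` (`aligned_seqs`, focal +
#'   context), `colours` (disc-level data frame), and `truth` (list with
#'   per-specimen species/hybrid-class/haplogroup truth and the config).
#' @export
simulate_specimen_table <- function(config, model = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(model))
    model <- build_two_species_model(config$fused_freq_O,
                                     config$fused_freq_L)
  haps <- simulate_haplotypes(config)
  karyo <- simulate_karyotype_observations(config, model)
  colours <- simulate_colours(config)
  frame <- specimen_frame(config)
  focal <- frame[frame$focal, , drop = FALSE]

  set.seed(config$seed + 4L)
  sites <- list(O = c("karst-1", "karst-2"),
                L = c("ophiolite-1", "ophiolite-2"))
  locality <- character(nrow(focal))
  for (i in seq_len(nrow(focal))) {
    sp <- focal$species[i]
    locality[i] <- if (sp == "hybrid") "contact-zone"
      else if (stats::runif(1) < config$contact_fraction) "contact-zone"
      else sample(sites[[sp]], 1L)
  }
  substrate <- ifelse(locality == "contact-zone", "mixed",
                      ifelse(startsWith(locality, "karst"), "karst",
                             "ophiolite"))
  sex <- ifelse(stats::runif(nrow(focal)) < config$prob_male, "M", "F")

  specimens <- data.frame(
    specimen_id = focal$specimen_id, sex = sex, locality = locality,
    substrate = substrate, haplogroup = focal$haplogroup,
    karyotype_n = karyo$visible_n[match(focal$specimen_id,
                                        karyo$specimen_id)],
    multivalents = karyo$multivalents[match(focal$specimen_id,
                                            karyo$specimen_id)],
    stringsAsFactors = FALSE)
  structure(
    list(specimens = specimens, sequences = haps$seqs, colours = colours,
         truth = list(frame = frame, haplogroups = haps$truth,
                      karyotypes = karyo, config = config)),
    class = "synthetic_study"
  )
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat("Synthetic study:", nrow(x$specimens), "focal specimens,",
      nrow(x$sequences), "sequences,",
      length(unique(x$colours$specimen_id)), "colour-profiled specimens\n")
  invisible(x)
}

#' Write a synthetic study to disk
#'
#' Emits the aligned FASTA, disc-level colour CSV, specimen TSV and truth
#' JSON into a directory.
#'
#' @param study a `synthetic_study`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_simulation <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_aligned_fasta(study$sequences, file.path(dir, "barcodes.fasta"))
  utils::write.csv(study$colours, file.path(dir, "colour_discs.csv"),
                   row.names = FALSE)
  utils::write.table(study$specimens, file.path(dir, "specimens.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- study$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
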