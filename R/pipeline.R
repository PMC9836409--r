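## Integrative delimitation: contact zones, per-specimen calls, pipeline.

#' Detect contact-zone localities
#'
#' A contact zone is a locality where two or more focal mitochondrial
#' haplogroups co-occur.
#'
#' @param records data frame with columns `locality` and `haplogroup`.
#' @param focal_haplogroups haplogroups whose co-occurrence defines a
#'   contact zone; default all haplogroups present.
#' @return Data frame: `locality`, `n_focal_haplogroups`, `flagged`.
#' @export
detect_contact_zones <- function(records, focal_haplogroups = NULL) {
  stopifnot(all(c("locality", "haplogroup") %in% names(records)))
  if (is.null(focal_haplogroups))
    focal_haplogroups <- unique(records$haplogroup)
  sub <- records[records$haplogroup %in% focal_haplogroups, , drop = FALSE]
  locs <- unique(records$locality)
  n_hg <- vapply(locs, function(lc)
    length(unique(sub$haplogroup[sub$locality == lc])), 1L)
  data.frame(locality = locs, n_focal_haplogroups = n_hg,
             flagged = n_hg >= 2L, row.names = NULL,
             stringsAsFactors = FALSE)
}

# is a colour profile intermediate between the two species' centroids?
# TRUE when the profile is nearer the inter-centroid midpoint than it is to
# either centroid (in RGB space).
colour_intermediate <- function(profile_rgb, centroid_O, centroid_L) {
  mid <- (centroid_O + centroid_L) / 2
  d_mid <- sqrt(sum((profile_rgb - mid)^2))
  d_O <- sqrt(sum((profile_rgb - centroid_O)^2))
  d_L <- sqrt(sum((profile_rgb - centroid_L)^2))
  d_mid < d_O && d_mid < d_L
}

#' Integrative per-specimen species/hybrid classification
#'
#' Combines the mitochondrial haplogroup, the karyotype (metaphase-I
#' visible-element count) and wing-colour evidence into one call per
#' specimen. Concordant mitochondrion and karyotype give a species call;
#' a karyotype outside the mito parent's achievable set but inside a
#' hybrid-generation scenario gives a putative-hybrid call with the minimal
#' generation class ([classify_karyotype_consistency()]). Colour
#' intermediacy — the specimen's RGB profile lying nearer the inter-centroid
#' midpoint than either species centroid — is recorded as supporting
#' evidence only, never sufficient for a hybrid call (the species' colour
#' clouds overlap). Specimens lacking a karyotype are called from the
#' mitochondrion alone. Hybrid-consistent specimens outside a flagged
#' contact zone are marked dispersive rather than discarded.
#'
#' @param records specimen data frame with columns `specimen_id`,
#'   `haplogroup`, optionally `karyotype_n`, `locality`.
#' @param model a [build_two_species_model()].
#' @param profiles optional `colour_profiles` from [average_discs()] for
#'   the colour-intermediacy flag. Species centroids are computed from the
#'   specimens whose mitochondrion and karyotype concordantly identify them.
#' @param contact_zones optional output of [detect_contact_zones()];
#'   computed from `records` when localities are present.
#' @return Data frame of class `integrative_calls`: `specimen_id`, `call`
#'   (`species-A` = species O, `species-B` = species L, `putative-hybrid`,
#'   `unresolved`), `generation_class`, `karyotype_category`,
#'   `colour_intermediate`, `dispersive`, `evidence`.
#' @export
integrative_classify <- function(records, model, profiles = NULL,
                                 contact_zones = NULL) {
  stopifnot(inherits(model, "two_species_model"),
            all(c("specimen_id", "haplogroup") %in% names(records)))
  n <- nrow(records)
  has_karyo <- "karyotype_n" %in% names(records)
  if (is.null(contact_zones) && "locality" %in% names(records))
    contact_zones <- detect_contact_zones(
      records, focal_haplogroups = names(model$haplogroup_map))

  consistency <- vector("list", n)
  call <- character(n); gen <- rep(NA_character_, n)
  category <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hg <- records$haplogroup[i]
    if (!hg %in% names(model$haplogroup_map))
      stop("unknown haplogroup label: ", hg)
    parent_call <- if (model$haplogroup_map[[hg]] == "O") "species-A"
                   else "species-B"
    kn <- if (has_karyo) records$karyotype_n[i] else NA
    if (is.na(kn)) {
      call[i] <- parent_call  # mito alone, unambiguous haplogroup
      category[i] <- "no-karyotype"
      next
    }
    cons <- classify_karyotype_consistency(kn, hg, model)
    category[i] <- cons$category
    call[i] <- switch(cons$category,
      "pure-O-consistent" = "species-A",
      "pure-L-consistent" = "species-B",
      "F1-consistent" = "putative-hybrid",
      "backcross-consistent" = "putative-hybrid",
      "inconsistent" = "unresolved")
    if (call[i] == "putative-hybrid")
      gen[i] <- if (cons$category == "F1-consistent") "F1" else "BC1"
  }

  inter <- rep(NA, n)
  if (!is.null(profiles)) {
    idx <- match(records$specimen_id, profiles$specimen_id)
    pureA <- which(call == "species-A" & category != "no-karyotype")
    pureB <- which(call == "species-B" & category != "no-karyotype")
    if (length(pureA) >= 2L && length(pureB) >= 2L) {
      rgbm <- as.matrix(profiles[, c("R", "G", "B")])
      centA <- colMeans(rgbm[idx[pureA], , drop = FALSE], na.rm = TRUE)
      centB <- colMeans(rgbm[idx[pureB], , drop = FALSE], na.rm = TRUE)
      for (i in seq_len(n)) {
        if (is.na(idx[i])) next
        inter[i] <- colour_intermediate(rgbm[idx[i], ], centA, centB)
      }
    }
  }

  dispersive <- rep(NA, n)
  if (!is.null(contact_zones) && "locality" %in% names(records)) {
    flagged <- contact_zones$locality[contact_zones$flagged]
    dispersive <- call == "putative-hybrid" &
      !records$locality %in% flagged
  }

  evidence <- vapply(seq_len(n), function(i) {
    parts <- c(paste0("mito:", records$haplogroup[i]),
               if (!is.na(category[i]) && category[i] != "no-karyotype")
                 paste0("karyotype:", category[i]),
               if (isTRUE(inter[i])) "colour:intermediate",
               if (isTRUE(dispersive[i])) "dispersive")
    paste(parts, collapse = ";")
  }, "")

  out <- data.frame(specimen_id = records$specimen_id, call = call,
                    generation_class = gen, karyotype_category = category,
                    colour_intermediate = inter, dispersive = dispersive,
                    evidence = evidence, stringsAsFactors = FALSE)
  class(out) <- c("integrative_calls", "data.frame")
  out
}

#' Run the integrative delimitation pipeline
#'
#' Orchestrates the stages: haplogroup assignment from aligned barcodes,
#' karyotype-consistency classification, colour morphometrics (profiles,
#' NMDS, PERMANOVA by call and by substrate), integrative per-specimen
#' calls and contact-zone detection. Inputs come either from files or from
#' the synthetic generator; outputs are written as TSV/JSON plus a run log
#' recording seeds and parameters (no timestamps, so reruns are
#' byte-identical).
#'
#' @param config list (or path to a YAML file) with either
#'   `simulation = list(seed = ...)` (passed to [simulation_config()]) or
#'   `inputs = list(fasta = , colours = , specimens = )`; optional entries
#'   `out_dir`, `seed` (analysis seed, default 1), `max_within_steps`
#'   (haplogroup cut, default 5), `n_permutations` (default 999),
#'   `haplogroup_labels` (labels for the discovered groups).
#' @return Object of class `pipeline_report` (list with `calls`,
#'   `contact_zones`, `network`, `permanova_species`,
#'   `permanova_substrate`, `ordination`, `profiles`, `specimens`,
#'   `skipped`), invisibly written under `out_dir` when given.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cut <- if (is.null(config$max_within_steps)) 5L
         else as.integer(config$max_within_steps)
  nperm <- if (is.null(config$n_permutations)) 999L
           else as.integer(config$n_permutations)
  skipped <- character()

  if (!is.null(config$simulation)) {
    sim_args <- config$simulation
    sim_cfg <- do.call(simulation_config, sim_args)
    model <- build_two_species_model(sim_cfg$fused_freq_O,
                                     sim_cfg$fused_freq_L)
    study <- simulate_specimen_table(sim_cfg, model)
    seqs <- study$sequences
    colours <- study$colours
    specimens <- study$specimens
  } else if (!is.null(config$inputs)) {
    inp <- config$inputs
    for (key in c("fasta", "specimens")) {
      if (is.null(inp[[key]]))
        stop("config inputs$", key, " is mandatory")
      if (!file.exists(inp[[key]]))
        stop("input file not found: ", inp[[key]],
             " (config key inputs$", key, ")")
    }
    model <- if (!is.null(inp$model)) read_model_yaml(inp$model)
             else build_two_species_model()
    seqs <- read_aligned_fasta(inp$fasta)
    specimens <- utils::read.delim(inp$specimens, stringsAsFactors = FALSE)
    colours <- if (!is.null(inp$colours) && file.exists(inp$colours) &&
                   length(readLines(inp$colours, n = 2)) > 1)
      utils::read.csv(inp$colours, stringsAsFactors = FALSE)
    else NULL
    study <- NULL
  } else stop("config must contain a 'simulation' or an 'inputs' block")

  # --- haplogroups from sequences
  haps <- collapse_haplotypes(seqs)
  net <- build_parsimony_network(haps, connection_limit = Inf)
  net <- assign_haplogroups(net, max_within_steps = cut)
  sg <- net$specimen_groups

  # name discovered groups after the specimen-table haplogroup labels when
  # available (majority vote per component), else keep HG labels
  if ("haplogroup" %in% names(specimens)) {
    lab_map <- tapply(
      specimens$haplogroup[match(sg$specimen, specimens$specimen_id)],
      sg$haplogroup,
      function(v) { v <- v[!is.na(v)]
                    if (length(v)) names(sort(table(v),
                                              decreasing = TRUE))[1]
                    else NA_character_ })
    assigned <- unname(lab_map[sg$haplogroup])
    sg$haplogroup_assigned <- ifelse(is.na(assigned), sg$haplogroup,
                                     assigned)
  } else sg$haplogroup_assigned <- sg$haplogroup

  records <- specimens
  records$haplogroup <- sg$haplogroup_assigned[match(records$specimen_id,
                                                     sg$specimen)]
  records <- records[!is.na(records$haplogroup) &
                     records$haplogroup %in% names(model$haplogroup_map), ,
                     drop = FALSE]

  # --- morphometrics
  profiles <- NULL; ord <- NULL
  perm_species <- NULL; perm_substrate <- NULL
  if (!is.null(colours) && nrow(colours)) {
    profiles <- average_discs(colours)
  } else skipped <- c(skipped, "morphometrics (no colour measurements)")

  # --- contact zones + calls
  cz <- detect_contact_zones(records,
                             focal_haplogroups = names(model$haplogroup_map))
  calls <- integrative_classify(records, model, profiles = profiles,
                                contact_zones = cz)

  if (!is.null(profiles)) {
    keep <- profiles$specimen_id %in% records$specimen_id
    prof <- profiles[keep, , drop = FALSE]
    if (nrow(prof) >= 3L) {
      d <- colour_distance_matrix(prof, "RGB")
      ord <- nmds_ordination(d, n_starts = 10, seed = seed)
      grp <- calls$call[match(prof$specimen_id, calls$specimen_id)]
      if (length(unique(grp)) >= 2L)
        perm_species <- permanova(d, grp, n_permutations = nperm,
                                  seed = seed)
      sub <- records$substrate[match(prof$specimen_id,
                                     records$specimen_id)]
      if (!all(is.na(sub)) && length(unique(sub)) >= 2L)
        perm_substrate <- permanova(d, sub, n_permutations = nperm,
                                    seed = seed + 1L)
    }
  }

  report <- structure(
    list(calls = calls, contact_zones = cz, network = net,
         permanova_species = perm_species,
         permanova_substrate = perm_substrate,
         ordination = ord, profiles = profiles, specimens = records,
         truth = if (!is.null(config$simulation)) study$truth else NULL,
         skipped = skipped,
         params = list(seed = seed, max_within_steps = cut,
                       n_permutations = nperm,
                       package_version =
                         as.character(utils::packageVersion("karyodelim")))),
    class = "pipeline_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  invisible(report)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Integrative delimitation report\n")
  cat("  calls:", paste(sprintf("%s=%d", names(table(x$calls$call)),
                                table(x$calls$call)), collapse = ", "), "\n")
  cat("  contact zones flagged:",
      paste(x$contact_zones$locality[x$contact_zones$flagged],
            collapse = ", "), "\n")
  if (!is.null(x$permanova_species))
    cat(sprintf("  PERMANOVA (call groups): F = %.3f, P = %.4g\n",
                x$permanova_species$pseudo_F, x$permanova_species$p_value))
  if (!is.null(x$ordination))
    cat(sprintf("  NMDS stress: %.4f\n", x$ordination$stress))
  if (length(x$skipped))
    cat("  skipped:", paste(x$skipped, collapse = "; "), "\n")
  invisible(x)
}

#' Write a pipeline report bundle to a directory
#'
#' Emits calls.tsv, contact_zones.tsv, network_edges.tsv,
#' haplogroups.tsv, ordination.tsv, permanova.json, report.md and a
#' run_log.json with seeds and parameters. Content is a pure function of
#' the inputs (no timestamps).
#'
#' @param report a `pipeline_report`.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, f) utils::write.table(
    x, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(report$calls, "calls.tsv")
  wt(report$contact_zones, "contact_zones.tsv")
  wt(report$network$edges, "network_edges.tsv")
  wt(report$network$specimen_groups, "haplogroups.tsv")
  if (!is.null(report$profiles)) wt(report$profiles, "profiles.tsv")
  if (!is.null(report$ordination))
    wt(data.frame(specimen_id = rownames(report$ordination$points),
                  report$ordination$points,
                  stress = report$ordination$stress), "ordination.tsv")
  pj <- function(p) if (is.null(p)) NULL else
    list(df_between = unname(p$df["between"]),
         df_within = unname(p$df["within"]),
         pseudo_F = unname(p$pseudo_F), p_value = p$p_value,
         n_permutations = p$n_permutations, seed = p$seed)
  jsonlite::write_json(
    list(species = pj(report$permanova_species),
         substrate = pj(report$permanova_substrate)),
    file.path(dir, "permanova.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  jsonlite::write_json(report$params, file.path(dir, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  md <- c("# Integrative delimitation report", "",
          sprintf("- specimens analysed: %d", nrow(report$calls)),
          sprintf("- calls: %s",
                  paste(sprintf("%s = %d", names(table(report$calls$call)),
                                table(report$calls$call)),
                        collapse = ", ")),
          sprintf("- contact zones: %s",
                  paste(report$contact_zones$locality[
                    report$contact_zones$flagged], collapse = ", ")),
          if (!is.null(report$permanova_species))
            sprintf("- PERMANOVA by call: F = %.3f, P = %.4g",
                    report$permanova_species$pseudo_F,
                    report$permanova_species$p_value),
          if (!is.null(report$ordination))
            sprintf("- NMDS stress: %.4f", report$ordination$stress),
          if (length(report$skipped))
            sprintf("- skipped: %s", paste(report$skipped,
                                           collapse = "; ")))
  writeLines(md, file.path(dir, "report.md"))
  invisible(dir)
}
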