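test_that("simulation configuration is validated", {
  expect_error(simulation_config(), "mandatory")
  expect_error(simulation_config(seed = 1,
                                 hybrid_mix = c(F1 = 0.6, BC1 = 0.6)),
               "sum to 1")
  expect_error(simulation_config(seed = 1, barcode_length = 20),
               "divergence exceeds")
  cfg <- simulation_config(seed = 1)
  expect_s3_class(cfg, "sim_config")
})

test_that("sequence simulation realizes the planted divergence structure", {
  # zero divergence and zero within-group rate: all sequences identical
  cfg <- simulation_config(seed = 5,
                           centroid_steps = c(orph1 = 0, orph2 = 0,
                                              aroa1 = 0, aroa2 = 0,
                                              aroa3 = 0),
                           within_rate = 0)
  sim <- simulate_haplotypes(cfg)
  expect_equal(nrow(collapse_haplotypes(sim$seqs)$table), 1L)

  # two groups, 10 planted steps, no within-group noise
  cfg <- simulation_config(seed = 5, groups = c("orph2", "aroa3"),
                           centroid_steps = c(orph2 = 4, aroa3 = 6),
                           within_rate = 0, n_hybrid = 0,
                           n_context = c())
  sim <- simulate_haplotypes(cfg)
  d <- pairwise_difference_matrix(sim$seqs)
  truth <- sim$truth$haplogroup
  between <- d[truth == "orph2", truth == "aroa3"]
  expect_true(all(between == 10L))
  expect_true(all(d[truth == "orph2", truth == "orph2"] == 0L))
})

test_that("karyotype draws honour allele frequencies and hybrid classes", {
  # species-L fused frequency 0: every L specimen reports n = 43
  cfg <- simulation_config(seed = 9, fused_freq_L = 0, n_hybrid = 0)
  k <- simulate_karyotype_observations(cfg)
  ids_L <- grepl("^L", k$specimen_id)
  expect_true(all(k$visible_n[ids_L] == 43L))
  expect_true(all(k$visible_n[!ids_L] == 42L))  # O fused allele absent

  # F1-only hybrids always report 41
  cfg <- simulation_config(seed = 9, hybrid_mix = c(F1 = 1, BC1 = 0))
  k <- simulate_karyotype_observations(cfg)
  expect_true(all(k$visible_n[grepl("^HY", k$specimen_id)] == 41L))

  # Hardy-Weinberg draws at frequency 0.5: genotype proportions within a
  # binomial-style tolerance of 1/4, 1/2, 1/4 (judged via visible counts:
  # 42 pools the fused homozygote and the heterozygote)
  cfg <- simulation_config(seed = 17, n_O = 0, n_L = 1000, n_hybrid = 0,
                           fused_freq_L = 0.5)
  k <- simulate_karyotype_observations(cfg)
  p43 <- mean(k$visible_n == 43L)          # unfused homozygote
  expect_lt(abs(p43 - 0.25), 3 * sqrt(0.25 * 0.75 / 1000))
  p_tri <- mean(k$multivalents == 1L)      # heterozygote
  expect_lt(abs(p_tri - 0.5), 3 * sqrt(0.5 * 0.5 / 1000))
})

test_that("colour draws centre on group means with hybrids at the midpoint", {
  cfg <- simulation_config(seed = 3, colour_sd = 0)
  cols <- simulate_colours(cfg)
  o <- cols[grepl("^O", cols$specimen_id), ]
  l <- cols[grepl("^L", cols$specimen_id), ]
  hy <- cols[grepl("^HY", cols$specimen_id), ]
  expect_true(all(o$R == cfg$colour_mean_O[1] &
                  o$G == cfg$colour_mean_O[2] &
                  o$B == cfg$colour_mean_O[3]))
  expect_true(all(l$R == cfg$colour_mean_L[1]))
  mid <- (cfg$colour_mean_O + cfg$colour_mean_L) / 2
  expect_true(all(hy$R == round(mid[1]) | hy$R == mid[1]))
  expect_true(all(cols$R >= 0 & cols$R <= 255))
})

test_that("the joined study table is deterministic and internally consistent", {
  cfg <- simulation_config(seed = 1234)
  s1 <- simulate_specimen_table(cfg)
  s2 <- simulate_specimen_table(cfg)
  expect_identical(s1$specimens, s2$specimens)
  expect_identical(unclass(s1$sequences), unclass(s2$sequences))
  expect_identical(s1$colours, s2$colours)

  # byte-identical files on rerun
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))

  # hybrids live in the contact zone; substrates follow localities
  sp <- s1$specimens
  expect_true(all(sp$locality[grepl("^HY", sp$specimen_id)] ==
                  "contact-zone"))
  expect_true(all(sp$substrate[sp$locality == "contact-zone"] == "mixed"))

  # with no contact and no hybrids, no locality mixes focal haplogroups
  cfg0 <- simulation_config(seed = 2, contact_fraction = 0, n_hybrid = 0)
  s0 <- simulate_specimen_table(cfg0)
  cz <- detect_contact_zones(s0$specimens,
                             focal_haplogroups = c("orph2", "aroa3"))
  expect_false(any(cz$flagged))
})
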