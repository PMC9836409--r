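test_that("karyotype constructors enforce the partition invariants", {
  u <- arm_universe(c("a", "b", "c"))
  expect_error(arm_universe(character()), "non-empty")
  expect_error(arm_universe(c("a", "a")), "duplicated")
  expect_error(haploid_karyotype(list("a", "b"), u), "missing.*c")
  expect_error(haploid_karyotype(list(c("a", "b"), c("b", "c")), u),
               "more than one chromosome")
  expect_error(haploid_karyotype(list("a", "b", "c", "d"), u),
               "not in universe")
  k <- haploid_karyotype(list(c("a", "b"), "c"), u)
  expect_equal(k$n, 2L)
  g <- diploid_genotype(k, unfused_karyotype(u))
  expect_equal(g$diploid_number, 5L)
  u2 <- arm_universe(c("x", "y", "z"))
  expect_error(diploid_genotype(k, unfused_karyotype(u2)),
               "different arm universes")
})

test_that("the default two-species model reproduces every printed count", {
  m <- build_two_species_model()
  expect_length(m$universe, 44L)

  nsO <- sort(vapply(haploid_variants(m$species_O), function(k) k$n, 1L))
  nsL <- sort(vapply(haploid_variants(m$species_L), function(k) k$n, 1L))
  expect_equal(nsO, c(41L, 42L))
  expect_equal(nsL, c(42L, 43L))

  # species-O fused homozygote: 41 elements, one pair of fused chromosomes
  vO <- haploid_variants(m$species_O)
  fusedO <- vO[[which(vapply(vO, function(k) k$n, 1L) == 41L)]]
  homo <- pair_meiosis(diploid_genotype(fusedO, fusedO))
  expect_equal(homo$visible_count, 41L)
  expect_true(all(vapply(homo$elements, `[[`, "", "kind") == "bivalent"))

  # species-L unfused homozygote: 2n = 86, 43 bivalents
  vL <- haploid_variants(m$species_L)
  unfL <- vL[[which(vapply(vL, function(k) k$n, 1L) == 43L)]]
  cfg <- pair_meiosis(diploid_genotype(unfL, unfL))
  expect_equal(cfg$visible_count, 43L)
  expect_equal(cfg$genotype$diploid_number, 86L)
})

test_that("fusion heterozygotes pair as one trivalent among bivalents", {
  # 42-arm universe: fused 1+2 against fully unfused -> 40 bivalents + 1
  # trivalent (2n = 83), 41 visible elements
  u42 <- arm_universe(as.character(1:42))
  hetO <- diploid_genotype(
    haploid_karyotype(c(list(c("1", "2")), as.list(as.character(3:42))),
                      u42),
    unfused_karyotype(u42))
  cfg <- pair_meiosis(hetO)
  expect_equal(cfg$visible_count, 41L)
  expect_equal(hetO$diploid_number, 83L)
  kinds <- table(vapply(cfg$elements, `[[`, "", "kind"))
  expect_equal(unname(kinds[["bivalent"]]), 40L)
  expect_equal(unname(kinds[["trivalent"]]), 1L)

  # 43-arm analogue: 41 bivalents + 1 trivalent, 42 visible (2n = 85)
  u43 <- arm_universe(as.character(1:43))
  hetL <- diploid_genotype(
    haploid_karyotype(c(list(c("1", "2")), as.list(as.character(3:43))),
                      u43),
    unfused_karyotype(u43))
  cfg <- pair_meiosis(hetL)
  expect_equal(cfg$visible_count, 42L)
  expect_equal(hetL$diploid_number, 85L)
  expect_equal(sum(vapply(cfg$elements, `[[`, 1L, "arity") == 3L), 1L)
})

test_that("element arities always sum to 2n and arms appear twice", {
  set.seed(11)
  for (rep in 1:50) {
    u <- arm_universe(sprintf("a%d", seq_len(sample(3:12, 1))))
    g <- diploid_genotype(random_karyotype(u), random_karyotype(u))
    cfg <- pair_meiosis(g)
    expect_equal(sum(vapply(cfg$elements, `[[`, 1L, "arity")),
                 g$diploid_number)
    arm_tally <- table(unlist(lapply(cfg$elements, function(el)
      unlist(el$members))))
    expect_true(all(arm_tally == 2L))
  }
})

test_that("pairing agrees with a disjoint-set oracle on small universes", {
  for (narms in 2:4) {
    u <- arm_universe(letters[seq_len(narms)])
    parts <- all_partitions(letters[seq_len(narms)])
    got <- integer(); want <- integer()
    for (pa in parts) for (pb in parts) {
      g <- diploid_genotype(haploid_karyotype(pa, u),
                            haploid_karyotype(pb, u))
      got <- c(got, pair_meiosis(g)$visible_count)
      want <- c(want, dsu_visible_count_oracle(g))
    }
    expect_identical(got, want)
  }
})

test_that("pairing agrees with disjoint-set and igraph oracles on random instances", {
  set.seed(7)
  for (rep in 1:200) {
    u <- arm_universe(sprintf("a%d", seq_len(sample(2:12, 1))))
    ka <- random_karyotype(u); kb <- random_karyotype(u)
    g <- diploid_genotype(ka, kb)
    got <- pair_meiosis(g)$visible_count
    expect_identical(got, dsu_visible_count_oracle(g))
    # third route: explicit igraph on the homology graph
    arms <- as.character(u)
    ca <- stats::setNames(rep(seq_along(ka$chromosomes),
                              lengths(ka$chromosomes)),
                          unlist(ka$chromosomes))
    cb <- stats::setNames(rep(seq_along(kb$chromosomes),
                              lengths(kb$chromosomes)),
                          unlist(kb$chromosomes))
    edges <- cbind(paste0("A", ca[arms]), paste0("B", cb[arms]))
    gr <- igraph::graph_from_edgelist(edges, directed = FALSE)
    expect_equal(got, as.integer(igraph::components(gr)$no))
  }
})

test_that("model round-trips through the YAML configuration format", {
  m <- build_two_species_model(freq_O = 0.2, freq_L = 0.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(m, path)
  m2 <- read_model_yaml(path)
  expect_equal(sort(as.character(m2$universe)),
               sort(as.character(m$universe)))
  expect_equal(m2$species_O$fused_freq, m$species_O$fused_freq)
  expect_equal(m2$haplogroup_map, m$haplogroup_map)
  f1 <- achievable_visible_counts(pedigree_scenario("F1", m2))
  expect_equal(f1$visible_count, 41L)
})
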