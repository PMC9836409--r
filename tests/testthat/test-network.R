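test_that("two close haplotypes form a single plain edge", {
  h <- collapse_haplotypes(aligned_seqs(c(a = "AAAA", b = "AAAT")))
  net <- build_parsimony_network(h)
  expect_equal(nrow(net$edges), 1L)
  expect_equal(net$edges$steps, 1L)
  expect_equal(net$edges$missing_nodes, 0L)
})

test_that("multi-step edges imply intermediate missing haplotypes", {
  h <- collapse_haplotypes(aligned_seqs(c(a = "AAAAAA", b = "TTTTAA")))
  net <- build_parsimony_network(h, connection_limit = Inf)
  expect_equal(net$edges$steps, 4L)
  expect_equal(net$edges$missing_nodes, 3L)
  g <- karyodelim:::expand_missing_nodes(net)
  expect_equal(sum(!igraph::V(g)$observed), 3L)
  expect_equal(igraph::diameter(g), 4)  # a path through the intermediates

  # beyond the connection limit the haplotypes stay unconnected
  net <- build_parsimony_network(h, connection_limit = 3)
  expect_equal(nrow(net$edges), 0L)
})

test_that("a planted star topology is recovered", {
  centre <- "AAAAAAAAAA"
  leaves <- vapply(1:5, function(i) {
    s <- strsplit(centre, "")[[1]]
    s[i] <- "T"
    paste(s, collapse = "")
  }, "")
  seqs <- c(stats::setNames(centre, "hub"),
            stats::setNames(leaves, paste0("leaf", 1:5)))
  net <- build_parsimony_network(collapse_haplotypes(aligned_seqs(seqs)))
  expect_equal(nrow(net$edges), 5L)
  expect_true(all(net$edges$steps == 1L))
  hub <- net$nodes$haplotype[vapply(net$nodes$members, function(mm)
    "hub" %in% mm, TRUE)]
  expect_true(all(net$edges$from == hub | net$edges$to == hub))
})

test_that("an unlimited network is connected with at least h-1 edges", {
  set.seed(3)
  for (rep in 1:5) {
    al <- random_alignment(12, 30, p_ambig = 0)
    h <- collapse_haplotypes(al)
    net <- build_parsimony_network(h, connection_limit = Inf)
    expect_gte(nrow(net$edges), nrow(h$table) - 1L)
    g <- karyodelim:::network_igraph(net)
    expect_true(igraph::is_connected(g))
  }
})

test_that("haplogroups split at long branches and recover planted groups", {
  # two tight clusters separated by a long branch
  base <- strsplit("AAAAAAAAAAAAAAAAAAAA", "")[[1]]
  far <- base; far[1:8] <- "T"
  mk <- function(s, i) { s[20 - i] <- "C"; paste(s, collapse = "") }
  seqs <- c(g1a = paste(base, collapse = ""), g1b = mk(base, 1),
            g2a = paste(far, collapse = ""), g2b = mk(far, 2))
  net <- build_parsimony_network(collapse_haplotypes(aligned_seqs(seqs)))
  net <- assign_haplogroups(net, max_within_steps = 3)
  expect_equal(length(unique(net$nodes$haplogroup)), 2L)
  sg <- net$specimen_groups
  expect_equal(sg$haplogroup[sg$specimen == "g1a"],
               sg$haplogroup[sg$specimen == "g1b"])
  expect_false(sg$haplogroup[sg$specimen == "g1a"] ==
               sg$haplogroup[sg$specimen == "g2a"])

  # within the limit everything is one group
  all_one <- assign_haplogroups(net, max_within_steps = 100)
  expect_equal(length(unique(all_one$nodes$haplogroup)), 1L)

  # five planted haplogroups from the generator, specimen map exact
  cfg <- simulation_config(seed = 7)
  sim <- simulate_haplotypes(cfg)
  net <- build_parsimony_network(collapse_haplotypes(sim$seqs))
  net <- assign_haplogroups(net, max_within_steps = 5)
  sg <- net$specimen_groups
  truth <- sim$truth$haplogroup[match(sg$specimen, sim$truth$specimen_id)]
  expect_equal(length(unique(sg$haplogroup)), 5L)
  # assignment is a relabelling of the planted partition
  expect_true(all(table(sg$haplogroup, truth) %in%
                  c(0L, rowSums(table(sg$haplogroup, truth)))))
  cross_tab <- table(sg$haplogroup, truth)
  expect_true(all(rowSums(cross_tab > 0) == 1L))
  expect_true(all(colSums(cross_tab > 0) == 1L))
})

test_that("networks export as edge TSV and GraphML", {
  h <- collapse_haplotypes(aligned_seqs(c(a = "AAAA", b = "AATT",
                                          c = "AAAT")))
  net <- build_parsimony_network(h)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  gml <- withr::local_tempfile(fileext = ".graphml")
  write_network_tsv(net, tsv)
  expect_equal(names(read.delim(tsv)),
               c("from", "to", "steps", "missing_nodes"))
  write_network_graphml(net, gml)
  expect_true(any(grepl("graphml", readLines(gml, n = 5))))
})
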