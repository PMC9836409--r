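## Minimum-spanning haplotype network with tie retention, in the spirit of
## the TCS / statistical-parsimony construction.

#' Build a mutational-step haplotype network
#'
#' Minimum-spanning-network construction: haplotype pairs are connected in
#' order of increasing mutational steps (Hamming distance between
#' representatives); within one distance level every pair whose endpoints
#' lay in different components before the level is connected, so alternative
#' equal-length connections (reticulations) are retained, as in TCS/POPART
#' networks. Pairs farther apart than `connection_limit` steps are never
#' joined and their haplotypes remain in separate components. Edges of more
#' than one step imply unobserved intermediate ("missing") haplotypes, one
#' fewer than the step count.
#'
#' @param haplotypes a `haplotype_set` from [collapse_haplotypes()].
#' @param connection_limit maximum steps joined by an edge; `Inf` for no
#'   limit. The statistical-parsimony 95% limit is not computed; an integer
#'   limit set by the user plays its role.
#' @return Object of class `haplotype_network`: list with `nodes` (data
#'   frame: haplotype, frequency, members), `edges` (data frame: from, to,
#'   steps, missing_nodes), `distances` (full step matrix) and
#'   `connection_limit`.
#' @export
build_parsimony_network <- function(haplotypes, connection_limit = Inf) {
  stopifnot(inherits(haplotypes, "haplotype_set"))
  if (!(is.infinite(connection_limit) || connection_limit >= 1))
    stop("connection_limit must be >= 1 or Inf")
  d <- pairwise_difference_matrix(haplotypes$representatives)
  ids <- rownames(d)
  h <- length(ids)

  parent <- seq_len(h)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }

  edges <- data.frame(from = character(), to = character(),
                      steps = integer(), stringsAsFactors = FALSE)
  if (h > 1L) {
    pairs <- which(upper.tri(d), arr.ind = TRUE)
    steps <- d[pairs]
    keep <- steps <= connection_limit
    pairs <- pairs[keep, , drop = FALSE]; steps <- steps[keep]
    for (lev in sort(unique(steps))) {
      at <- which(steps == lev)
      # decide against the components as of before this level (tie retention)
      roots_before <- vapply(seq_len(h), find, 1L)
      take <- at[roots_before[pairs[at, 1]] != roots_before[pairs[at, 2]]]
      for (e in take) {
        i <- pairs[e, 1]; j <- pairs[e, 2]
        edges[nrow(edges) + 1L, ] <- list(ids[i], ids[j], as.integer(lev))
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  edges$missing_nodes <- pmax(edges$steps - 1L, 0L)
  nodes <- haplotypes$table
  structure(
    list(nodes = nodes, edges = edges, distances = d,
         connection_limit = connection_limit),
    class = "haplotype_network"
  )
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Haplotype network:", nrow(x$nodes), "haplotypes,", nrow(x$edges),
      "edges,", sum(x$edges$missing_nodes), "inferred missing haplotypes\n")
  if (!is.null(x$nodes$haplogroup))
    cat("  haplogroups:",
        paste(sort(unique(x$nodes$haplogroup)), collapse = ", "), "\n")
  invisible(x)
}

# igraph over observed haplotypes only (edge weight = steps)
network_igraph <- function(net, max_steps = Inf) {
  e <- net$edges[net$edges$steps <= max_steps, , drop = FALSE]
  igraph::graph_from_data_frame(e, directed = FALSE,
                                vertices = net$nodes[, c("haplotype",
                                                         "frequency")])
}

# igraph with inferred intermediate nodes expanded along multi-step edges
expand_missing_nodes <- function(net) {
  verts <- data.frame(name = net$nodes$haplotype, observed = TRUE,
                      frequency = net$nodes$frequency)
  from <- character(); to <- character()
  k <- 0L
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$from[i]; b <- net$edges$to[i]
    s <- net$edges$steps[i]
    chain <- a
    if (s > 1L) for (j in seq_len(s - 1L)) {
      k <- k + 1L
      mid <- sprintf("m%03d", k)
      verts <- rbind(verts, data.frame(name = mid, observed = FALSE,
                                       frequency = 0L))
      chain <- c(chain, mid)
    }
    chain <- c(chain, b)
    from <- c(from, chain[-length(chain)]); to <- c(to, chain[-1L])
  }
  igraph::graph_from_data_frame(data.frame(from, to), directed = FALSE,
                                vertices = verts)
}

#' Assign haplogroups by cutting long network edges
#'
#' Haplogroups are the connected components of the network after removing
#' every edge longer than `max_within_steps` mutational steps. Labels are
#' stable: components are numbered by their lowest haplotype index.
#'
#' @param network a `haplotype_network`.
#' @param max_within_steps edges longer than this are cut before taking
#'   components.
#' @param labels optional character vector of group labels, recycled over
#'   components in label order.
#' @return The network with a `haplogroup` column added to `nodes` and a
#'   `specimen_groups` data frame (`specimen`, `haplotype`, `haplogroup`)
#'   attached.
#' @export
assign_haplogroups <- function(network, max_within_steps,
                               labels = NULL) {
  stopifnot(inherits(network, "haplotype_network"))
  g <- network_igraph(network, max_steps = max_within_steps)
  comp <- igraph::components(g)$membership
  comp <- comp[network$nodes$haplotype]
  # stable renumbering by first appearance
  comp <- match(comp, unique(comp))
  lab <- if (is.null(labels)) sprintf("HG%d", comp)
         else {
           if (length(labels) < max(comp))
             stop("need at least ", max(comp), " labels")
           labels[comp]
         }
  network$nodes$haplogroup <- lab
  sg <- do.call(rbind, lapply(seq_len(nrow(network$nodes)), function(i)
    data.frame(specimen = network$nodes$members[[i]],
               haplotype = network$nodes$haplotype[i],
               haplogroup = lab[i], stringsAsFactors = FALSE)))
  network$specimen_groups <- sg
  network$max_within_steps <- max_within_steps
  network
}

#' Export a haplotype network
#'
#' `write_network_tsv` writes the edge list (from, to, steps,
#' missing_nodes); `write_network_graphml` writes GraphML with inferred
#' intermediate nodes expanded (attribute `observed` distinguishes them).
#'
#' @param net a `haplotype_network`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_network_tsv <- function(net, path) {
  utils::write.table(net$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_network_tsv
#' @export
write_network_graphml <- function(net, path) {
  igraph::write_graph(expand_missing_nodes(net), path, format = "graphml")
  invisible(path)
}

#' @export
plot.haplotype_network <- function(x, ...) {
  g <- expand_missing_nodes(x)
  obs <- igraph::V(g)$observed
  size <- ifelse(obs, 8 + 2 * sqrt(igraph::V(g)$frequency), 2)
  col <- if (!is.null(x$nodes$haplogroup)) {
    pal <- grDevices::hcl.colors(max(1L, length(unique(x$nodes$haplogroup))),
                                 "Dark 3")
    grp <- x$nodes$haplogroup[match(igraph::V(g)$name, x$nodes$haplotype)]
    ifelse(obs, pal[match(grp, sort(unique(x$nodes$haplogroup)))], "black")
  } else ifelse(obs, "steelblue", "black")
  igraph::plot.igraph(g, vertex.size = size, vertex.color = col,
                      vertex.label = ifelse(obs, igraph::V(g)$name, NA),
                      ...)
  invisible(x)
}
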