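test_that("tissue selection filters rows and rejects unknown tissues", {
  edges <- tibble::tibble(node_a = 1:10, node_b = 11:20,
                          tissue = rep(c("kidney", "liver"), c(4, 6)))
  expect_equal(nrow(select_tissue_edges(edges, "kidney")), 4)
  single <- edges[edges$tissue == "kidney", ]
  expect_identical(select_tissue_edges(single, "kidney"), single)
  expect_error(select_tissue_edges(edges, "brain"), "available")
})

test_that("ID translation reports unmapped symbols instead of dropping them", {
  map <- simulate_id_map(c("A", "B", "C"))
  tr <- translate_gene_ids(c("A", "X", "C", "Y", "B"), map)
  expect_equal(tr$ids, map$entrez_id[c(1, 3, 2)])
  expect_identical(tr$unmapped, c("X", "Y"))
  empty <- translate_gene_ids(character(), map)
  expect_length(empty$ids, 0)
  expect_length(empty$unmapped, 0)
})

test_that("pruning removes self-loops and small components, and is idempotent", {
  # a 10-node component with one self-loop, a triangle, and a 5-node path
  edges <- tibble::tibble(
    node_a = c(1:9, 3, 101, 102, 103, 201:204),
    node_b = c(2:10, 3, 102, 103, 101, 202:205),
    tissue = "kidney"
  )
  g <- survae:::edges_to_graph(edges)
  pruned <- prune_graph(g)
  expect_equal(sum(igraph::which_loop(pruned)), 0)
  comps <- igraph::components(pruned)$csize
  expect_true(all(comps >= 5))
  expect_true("3" %in% igraph::V(pruned)$name)        # self-loop node kept
  expect_false("101" %in% igraph::V(pruned)$name)     # triangle removed
  expect_true(all(as.character(201:205) %in% igraph::V(pruned)$name))  # 5-path kept
  again <- prune_graph(pruned)
  expect_equal(igraph::vcount(again), igraph::vcount(pruned))
  expect_equal(igraph::ecount(again), igraph::ecount(pruned))
})

test_that("seed expansion equals shortest-path reachability", {
  # path a-b-c-d-e, seeds {a}, depth 3 -> {a,b,c,d}
  path <- igraph::make_graph(~ a - b, b - c, c - d, d - e)
  expect_setequal(expand_seed_genes(path, "a", 3), c("a", "b", "c", "d"))
  expect_setequal(expand_seed_genes(path, "a", 0), "a")
  expect_setequal(expand_seed_genes(path, letters[1:5], 1), letters[1:5])
  expect_error(expand_seed_genes(path, "z", 3), "no seed")

  # brute-force oracle on random graphs
  survae:::with_seed(11, {
    for (i in 1:10) {
      n <- sample(20:200, 1)
      g <- igraph::sample_gnp(n, 2 / n)
      igraph::V(g)$name <- as.character(seq_len(n))
      seeds <- as.character(sample(n, 3))
      depth <- sample(0:4, 1)
      expect_identical(sort(expand_seed_genes(g, seeds, depth)),
                       reach_within(g, seeds, depth))
    }
  })
})

test_that("graph statistics match closed forms on canonical graphs", {
  ring <- igraph::make_ring(6)
  igraph::V(ring)$name <- as.character(1:6)
  expect_equal(nrow(graph_statistics(ring)$bridges), 0)

  star <- igraph::make_star(7, mode = "undirected")
  igraph::V(star)$name <- as.character(1:7)
  st <- graph_statistics(star)
  btw <- igraph::betweenness(star, normalized = TRUE)
  expect_equal(unname(btw[1]), 1)                      # hub
  expect_equal(unname(btw[2]), 0)                      # leaf
  expect_equal(st$betweenness_mean, mean(btw))

  path <- igraph::make_graph(~ a - b, b - c)
  ps <- graph_statistics(path)
  expect_equal(nrow(ps$bridges), 2)                    # every tree edge is a bridge
  expect_equal(ps$closeness_mean,
               mean(igraph::closeness(path, normalized = TRUE)))
})

test_that("patient graphs share topology and attribute expression exactly", {
  genes <- sprintf("G%03d", 1:5)
  map <- simulate_id_map(genes)
  edges <- tibble::tibble(node_a = map$entrez_id[c(1, 2, 3, 4)],
                          node_b = map$entrez_id[c(2, 3, 4, 5)],
                          tissue = "kidney")
  g <- prune_graph(survae:::edges_to_graph(edges))
  expr <- expr_tbl(matrix(runif(10), 2, 5), genes)
  hist <- tibble::tibble(patient_id = expr$patient_id, h1 = c(0.2, 0.8))
  graphs <- build_patient_graphs(g, expr, hist, map)
  expect_length(graphs, 2)
  expect_identical(graphs[[1]]$topology, graphs[[2]]$topology)
  gid <- igraph::V(g)$name[1]
  sym <- map$symbol[match(as.integer(gid), map$entrez_id)]
  expect_equal(graphs[[2]]$node_attr[[gid]], expr[[sym]][2])
  expect_equal(graphs[[1]]$graph_attr[["h1"]], 0.2)

  # fallback attribution for nodes outside the filtered matrix
  filtered <- expr[c("patient_id", genes[1:3])]
  expect_error(build_patient_graphs(g, filtered, hist, map), "no expression source")
  graphs2 <- build_patient_graphs(g, filtered, hist, map, fallback_expr = expr)
  expect_equal(unname(graphs2[[1]]$node_attr[as.character(map$entrez_id[5])]),
               expr[[genes[5]]][1])
})

test_that("graph pipeline composition expands monotonically with depth", {
  edges <- simulate_interactome(120, m_attach = 2, seed = 21)
  genes <- sprintf("G%04d", 1:120)
  map <- simulate_id_map(genes)
  seeds <- genes[1:5]
  sizes <- vapply(1:3, function(d) {
    igraph::vcount(build_ppi_graph(edges, "kidney", seeds, map, depth = d)$graph)
  }, numeric(1))
  expect_true(all(diff(sizes) >= 0))
})
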