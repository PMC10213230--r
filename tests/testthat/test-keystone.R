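# two 4-cliques joined by one bridge edge, plus helpers for role fixtures
twoCliqueNet <- function() {
  g <- igraph::disjoint_union(igraph::make_full_graph(4),
                              igraph::make_full_graph(4))
  g <- igraph::set_vertex_attr(g, "name",
                               value = c(paste0("a", 1:4), paste0("b", 1:4)))
  g <- igraph::add_edges(g, c("a1", "b1"))
  g <- igraph::set_edge_attr(g, "correlation", value = 0.9)
  g <- igraph::set_edge_attr(g, "sign", value = "+")
  new("CoNetwork", graph = g, cutoff = 0.5)
}

manualModules <- function(net, assign) {
  new("ModulePartition",
      membership = stats::setNames(as.integer(assign),
                                   igraph::V(networkGraph(net))$name),
      Q = igraph::modularity(networkGraph(net), assign))
}

test_that("Zi and Pi follow their connectivity definitions", {
  net <- twoCliqueNet()
  mods <- manualModules(net, rep(1:2, each = 4))
  zp <- ziPi(net, mods)
  zp <- zp[order(zp$node), ]

  # purely internal nodes: Pi = 0
  expect_equal(zp$Pi[zp$node == "a2"], 0)
  # bridge node a1: degree 4, 3 internal + 1 external
  expect_equal(zp$Pi[zp$node == "a1"], 1 - (3 / 4)^2 - (1 / 4)^2)

  # within-module degrees are all 3: sd = 0 so Zi = 0 everywhere
  expect_equal(zp$Zi, rep(0, 8))

  # node with half its links in each of two modules
  g <- igraph::make_star(5, mode = "undirected", center = 1)
  g <- igraph::add_edges(g, c(2, 3, 4, 5))
  igraph::V(g)$name <- c("c", "m1a", "m1b", "m2a", "m2b")
  net2 <- new("CoNetwork", graph = g, cutoff = 0.5)
  mods2 <- manualModules(net2, c(1, 1, 1, 2, 2))
  zp2 <- ziPi(net2, mods2)
  expect_equal(zp2$Pi[zp2$node == "c"], 0.5)
})

test_that("role thresholds classify with boundaries on the <= branch", {
  nodes <- data.frame(
    node = c("p", "edge", "mh", "nh", "con"),
    Zi = c(0, 2.5, 3.0, 3.0, 0),
    Pi = c(0, 0.62, 0.10, 0.70, 0.70))
  out <- classifyRoles(nodes)
  expect_equal(out$role,
               c("peripheral", "peripheral", "module hub", "network hub",
                 "connector"))
  expect_equal(out$keystone, c(FALSE, FALSE, TRUE, TRUE, TRUE))
  # just over the boundary flips the role
  eps <- classifyRoles(data.frame(node = "x", Zi = 2.5 + 1e-9,
                                  Pi = 0.62 + 1e-9))
  expect_equal(eps$role, "network hub")
})

test_that("a node bridging five modules is a connector (Pi = 0.8)", {
  blocks <- lapply(1:5, function(i) igraph::make_full_graph(5))
  g <- do.call(igraph::disjoint_union, blocks)
  igraph::V(g)$name <- paste0("m", rep(1:5, each = 5), "_", rep(1:5, 5))
  g <- igraph::add_vertices(g, 1, name = "hubby")
  g <- igraph::add_edges(g, as.vector(rbind("hubby",
                                            paste0("m", 1:5, "_1"))))
  g <- igraph::set_edge_attr(g, "correlation", value = 0.9)
  g <- igraph::set_edge_attr(g, "sign", value = "+")
  net <- new("CoNetwork", graph = g, cutoff = 0.5)
  mods <- manualModules(net, c(rep(1:5, each = 5), 1L))
  roles <- classifyRoles(ziPi(net, mods))
  hub <- roles[roles$node == "hubby", ]
  expect_equal(hub$Pi, 0.8)
  expect_lte(hub$Zi, 2.5)
  expect_equal(hub$role, "connector")

  # Pi never exceeds 1 - 1/m for a node touching m modules
  expect_lte(max(roles$Pi), 1 - 1 / 5)
  # single-module nodes have Pi = 0 exactly
  expect_true(all(roles$Pi[roles$node != "hubby" &
                           !grepl("_1$", roles$node)] == 0))
})

test_that("a planted intra-module hub is labelled module hub", {
  # hub-and-spoke module (star of 11) next to an ordinary clique
  g <- igraph::disjoint_union(
    igraph::make_star(11, mode = "undirected", center = 1),
    igraph::make_full_graph(5))
  igraph::V(g)$name <- c("hub", paste0("leaf", 1:10), paste0("k", 1:5))
  g <- igraph::set_edge_attr(g, "correlation", value = 0.95)
  g <- igraph::set_edge_attr(g, "sign", value = "+")
  net <- new("CoNetwork", graph = g, cutoff = 0.5)
  roles <- classifyRoles(ziPi(net, detectModules(net)))
  expect_equal(roles$role[roles$node == "hub"], "module hub")

  ks <- keystoneTable(roles)
  expect_equal(ks$node[1], "hub")
  expect_equal(nrow(ks), sum(roles$keystone))
})

test_that("keystone tables carry taxonomy and sort by role then Zi", {
  roles <- data.frame(
    node = c("t1", "t2", "t3", "t4"),
    module = 1:4, degree = c(5, 5, 5, 5),
    Zi = c(3.5, 2.8, 0.2, 0.1),
    Pi = c(0.7, 0.1, 0.8, 0.2))
  roles <- classifyRoles(roles)
  tax <- c(t1 = "Bacteria;Proteobacteria;;;;Bradyrhizobium",
           t2 = "Fungi;Ascomycota;;;Helotiaceae;",
           t3 = "Bacteria;Acidobacteria;;;;", t4 = "Bacteria;;;;;")
  ks <- keystoneTable(roles, taxonomy = tax)
  expect_equal(ks$role, c("network hub", "module hub", "connector"))
  expect_equal(ks$phylum[1], "Proteobacteria")
  expect_equal(ks$lowest_rank[1], "Bradyrhizobium")
  expect_equal(ks$lowest_rank[2], "Helotiaceae")

  allPeripheral <- classifyRoles(data.frame(node = c("x", "y"),
                                            Zi = c(0, 1), Pi = c(0, 0.3)))
  expect_equal(nrow(keystoneTable(allPeripheral)), 0L)
})
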