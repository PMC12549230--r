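test_that("perfectly monotone feature pairs yield rho = 1 edges", {
  vals <- cbind(f1 = c(1, 2, 3, 4, 5, 6), f2 = c(2, 4, 5, 7, 9, 20),
                f3 = rep(1, 6))
  rownames(vals) <- paste0("s", 1:6)
  edges <- spearman_edges(feature_table(vals))
  expect_equal(nrow(edges), 1)  # constant f3 skipped
  expect_equal(edges$rho, 1)
  expect_equal(edges$feature_a, "f1")
  expect_true(is.finite(edges$weight))
  expect_error(spearman_edges(feature_table(vals[1:3, ])), ">= 4 samples")
})

test_that("t-approximate Spearman p tracks exhaustive rank enumeration", {
  set.seed(81)
  for (rep in 1:10) {
    x <- sample(100, 6)
    y <- sample(100, 6)
    rho <- cor(x, y, method = "spearman")
    tval <- rho * sqrt(4 / (1 - rho^2))
    p_t <- 2 * pt(-abs(tval), 4)
    expect_lt(abs(p_t - enum_spearman_p(x, y)), 0.06)
  }
})

test_that("independent features rarely pass the joint edge filter", {
  set.seed(82)
  hits <- replicate(500, {
    vals <- matrix(rnorm(20), 10, 2,
                   dimnames = list(paste0("s", 1:10), c("a", "b")))
    nrow(spearman_edges(feature_table(vals, value_kind = "normalized"))) > 0
  })
  expect_lt(mean(hits), 0.05)
})

test_that("network properties match closed forms", {
  empty <- build_network(data.frame(feature_a = character(0),
                                    feature_b = character(0),
                                    rho = numeric(0), p = numeric(0),
                                    weight = numeric(0)))
  expect_equal(empty$properties$density, 0)
  expect_equal(empty$properties$average_neighbors, 0)

  k5 <- net_from_adjacency(matrix(1, 5, 5) - diag(5))
  expect_equal(k5$properties$density, 1)
  expect_equal(k5$properties$average_neighbors, 4)

  set.seed(83)
  a <- matrix(0, 8, 8)
  pairs <- which(upper.tri(a), arr.ind = TRUE)
  on <- sample(nrow(pairs), 12)
  a[pairs[on, ]] <- 1
  a <- a + t(a)
  net <- net_from_adjacency(a)
  expect_equal(net$properties$density, 2 * 12 / (8 * 7))

  bad <- data.frame(feature_a = c("a", "b"), feature_b = c("b", "a"),
                    rho = c(0.6, 0.7), p = c(0.01, 0.01), weight = c(2, 2))
  expect_error(build_network(bad), "duplicate edges")
  loop <- data.frame(feature_a = "a", feature_b = "a", rho = 0.6,
                     p = 0.01, weight = 2)
  expect_error(build_network(loop), "self-loop")
})

test_that("community clustering separates components and reports true Q", {
  clique <- function(n) matrix(1, n, n) - diag(n)
  two <- rbind(cbind(clique(4), matrix(0, 4, 4)),
               cbind(matrix(0, 4, 4), clique(4)))
  net <- net_from_adjacency(two)
  cl <- community_clusters(net)
  expect_equal(cl$n_clusters, 2)
  split_ids <- split(names(cl$labels), cl$labels)
  expect_true(all(lengths(split_ids) == 4))
  # each cluster is one of the planted cliques
  expect_setequal(split_ids[[1]],
                  paste0("n", if ("n1" %in% split_ids[[1]]) 1:4 else 5:8))
  expect_equal(cl$modularity, direct_modularity(two, cl$labels),
               tolerance = 1e-12)

  one <- community_clusters(net_from_adjacency(clique(5)))
  expect_equal(one$n_clusters, 1)
  expect_error(community_clusters(net_from_adjacency(matrix(0, 3, 3))),
               "edge")

  set.seed(84)
  a <- matrix(0, 10, 10)
  pairs <- which(upper.tri(a), arr.ind = TRUE)
  a[pairs[sample(nrow(pairs), 18), ]] <- 1
  a <- a + t(a)
  cl <- community_clusters(net_from_adjacency(a))
  expect_equal(cl$modularity, direct_modularity(a, cl$labels),
               tolerance = 1e-12)
})

test_that("centralities reproduce hand values on the star and clique", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  cm <- centrality_metrics(net_from_adjacency(star))
  expect_equal(cm$betweenness[cm$node == "n1"], 6)  # C(4,2) pairs
  expect_equal(cm$betweenness[cm$node != "n1"], rep(0, 4))
  expect_equal(cm$neighborhood_connectivity[cm$node == "n1"], 1)
  expect_equal(cm$neighborhood_connectivity[cm$node != "n1"], rep(4, 4))

  k4 <- matrix(1, 4, 4) - diag(4)
  cm4 <- centrality_metrics(net_from_adjacency(k4))
  expect_equal(cm4$betweenness, rep(0, 4))
  expect_equal(cm4$degree, rep(3L, 4))
  expect_equal(cm4$neighborhood_connectivity, rep(3, 4))
})

test_that("centralities match brute force on random small graphs", {
  set.seed(85)
  for (rep in 1:60) {
    n <- sample(3:6, 1)
    a <- matrix(0, n, n)
    pairs <- which(upper.tri(a), arr.ind = TRUE)
    m <- sample(seq_len(nrow(pairs)), sample(seq_len(nrow(pairs)), 1))
    a[pairs[m, , drop = FALSE]] <- 1
    a <- a + t(a)
    cm <- centrality_metrics(net_from_adjacency(a))
    ord <- match(paste0("n", seq_len(n)), cm$node)
    expect_equal(cm$betweenness[ord], brute_betweenness(a), tolerance = 1e-9)
    expect_equal(cm$neighborhood_connectivity[ord],
                 brute_neighborhood_connectivity(a), tolerance = 1e-12)
    expect_equal(cm$degree[ord], as.integer(rowSums(a)))
  }
})

test_that("hub calls follow the quantile rule with boundary ties included", {
  star <- matrix(0, 5, 5)
  star[1, 2:5] <- star[2:5, 1] <- 1
  cm <- centrality_metrics(net_from_adjacency(star))
  hubs <- identify_hubs(cm, quantile = 0.5, min_degree = 1)
  expect_setequal(hubs$node[hubs$hub], paste0("n", 2:5))
  expect_false(hubs$hub[hubs$node == "n1"])

  k4 <- centrality_metrics(net_from_adjacency(matrix(1, 4, 4) - diag(4)))
  all_tied <- identify_hubs(k4, quantile = 0.9, min_degree = 2)
  expect_true(all(all_tied$hub))
  expect_error(identify_hubs(k4[0, ]), "empty")
})

test_that("hub identity is invariant to node relabeling", {
  set.seed(86)
  a <- matrix(0, 9, 9)
  pairs <- which(upper.tri(a), arr.ind = TRUE)
  a[pairs[sample(nrow(pairs), 14), ]] <- 1
  a <- a + t(a)
  ids <- paste0("v", 1:9)
  h1 <- identify_hubs(centrality_metrics(net_from_adjacency(a, ids)))
  perm <- sample(9)
  h2 <- identify_hubs(centrality_metrics(
    net_from_adjacency(a[perm, perm], ids[perm])))
  expect_setequal(h1$node[h1$hub], h2$node[h2$hub])
})

test_that("gene-family association table matches hand enumeration", {
  # two aaRS genes of one microbe linked to 3 annotated host genes
  edges <- data.frame(
    feature_a = c("aaRS1|E_coli", "aaRS1|E_coli", "aaRS2|E_coli",
                  "aaRS2|E_coli", "otherg|E_coli"),
    feature_b = c("hostA", "hostB", "hostB", "hostC", "hostA"),
    rho = c(0.9, 0.8, 0.7, 0.6, 0.95),
    p = rep(0.01, 5), weight = rep(2, 5), stringsAsFactors = FALSE)
  meta <- data.frame(
    row.names = c("aaRS1|E_coli", "aaRS2|E_coli", "otherg|E_coli",
                  "hostA", "hostB", "hostC"),
    layer = c("microbial_gene", "microbial_gene", "microbial_gene",
              "host_gene", "host_gene", "host_gene"),
    is_aars = c(TRUE, TRUE, FALSE, FALSE, FALSE, FALSE),
    taxon = c("E_coli", "E_coli", "E_coli", NA, NA, NA),
    stringsAsFactors = FALSE)
  net <- build_network(edges, node_meta = meta)
  anno <- data.frame(
    gene_id = c("hostA", "hostB", "hostC", "hostC",
                paste0("bg", 1:150)),
    go_term = c("GO:small1", "GO:small1", "GO:small2", "GO:big",
                rep("GO:big", 150)),
    stringsAsFactors = FALSE)
  tab <- extract_gene_family_associations(net, anno)
  expect_setequal(tab$go_term, c("GO:small1", "GO:small2"))
  s1 <- tab[tab$go_term == "GO:small1", ]
  expect_equal(s1$n_host_genes, 2)          # hostA, hostB (distinct genes)
  expect_equal(s1$mean_rho, mean(c(0.9, 0.8, 0.7)))  # three qualifying edges
  s2 <- tab[tab$go_term == "GO:small2", ]
  expect_equal(s2$n_host_genes, 1)
  expect_equal(s2$mean_rho, 0.6)
  expect_false("GO:big" %in% tab$go_term)   # >= 100 annotated genes

  no_flag <- build_network(edges,
                           node_meta = transform(meta, is_aars = FALSE))
  expect_equal(nrow(extract_gene_family_associations(no_flag, anno)), 0)
  expect_error(extract_gene_family_associations(net, NULL), "required")
})
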