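test_that("the AABBA corpus yields the hand-enumerated transition network", {
  net <- build_network(make_songs(c("AAB", "BA")))
  # concatenated string AABBA: pairs AA, AB, BB, BA (song break ignored)
  expect_equal(net$edges,
               data.frame(from = c("A", "A", "B", "B"),
                          to = c("A", "B", "A", "B"),
                          count = c(1L, 1L, 1L, 1L), stringsAsFactors = FALSE))
  expect_equal(net$node_usage, c(A = 3L, B = 2L))
  expect_equal(igraph::ecount(net$graph_undirected), 1L)  # single edge {A,B}
  expect_equal(net$n_tokens, 5L)
})

test_that("a pure trill gives one node and an edgeless undirected view", {
  net <- build_network(make_songs("AAAA"))
  expect_equal(net$nodes, "A")
  expect_equal(net$edges$count, 3L)          # the A->A self-loop
  expect_equal(igraph::ecount(net$graph_undirected), 0L)
  expect_true(is.na(average_path_length(net)))
  expect_true(is.na(network_density(net)))
})

test_that("directed counts equal a sliding-window bigram oracle, with and without song breaks", {
  withr::with_seed(31, {
    for (rep in 1:5) {
      songs <- random_songs(30, min_len = 2, max_len = 15)
      net <- build_network(songs)
      toks <- unlist(lapply(songs, `[[`, "tokens"))
      oracle <- table(paste(head(toks, -1), toks[-1]))
      got <- stats::setNames(net$edges$count, paste(net$edges$from, net$edges$to))
      expect_equal(got[sort(names(got))], c(oracle[sort(names(oracle))]))
      # conservation: directed counts sum to tokens - 1
      expect_equal(sum(net$edges$count), length(toks) - 1L)

      netb <- build_network(songs, respect_song_breaks = TRUE)
      oracle_b <- table(unlist(lapply(songs, function(s) {
        tk <- s$tokens
        if (length(tk) < 2) character(0) else paste(head(tk, -1), tk[-1])
      })))
      got_b <- stats::setNames(netb$edges$count, paste(netb$edges$from, netb$edges$to))
      expect_equal(got_b[sort(names(got_b))], c(oracle_b[sort(names(oracle_b))]))
      expect_equal(sum(netb$edges$count),
                   sum(vapply(songs, function(s) length(s$tokens), 1L)) - 30L)
    }
  })
})

test_that("path length and density match hand-computed fixtures", {
  # complete graph K4: every pair adjacent
  k4 <- net_from_adjacency(matrix(1, 4, 4) - diag(4))
  expect_equal(average_path_length(k4), 1.0)
  expect_equal(network_density(k4), 1.0)

  # path graph A-B-C-D: distances 1,2,3,1,2,1
  p4 <- net_from_adjacency(rbind(c(0,1,0,0), c(1,0,1,0), c(0,1,0,1), c(0,0,1,0)))
  expect_equal(average_path_length(p4), 5 / 3)
  expect_equal(network_density(p4), 0.5)

  # two disjoint K2 components: unreachable pairs are ignored
  kk <- net_from_adjacency(rbind(c(0,1,0,0), c(1,0,0,0), c(0,0,0,1), c(0,0,1,0)))
  expect_equal(average_path_length(kk), 1.0)
  expect_equal(network_density(kk), 2 / 6)
})

test_that("path length agrees with a Floyd-Warshall oracle on random graphs", {
  withr::with_seed(32, {
    for (rep in 1:40) {
      n <- sample(2:8, 1)
      adj <- matrix(0L, n, n)
      adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, runif(1, 0.2, 0.9))
      adj <- adj + t(adj)
      net <- net_from_adjacency(adj)
      expect_equal(average_path_length(net), fw_mean_path(adj))
      expect_equal(network_density(net), sum(adj) / 2 / choose(n, 2))
    }
  })
})

test_that("metrics are invariant under bijective relabeling of syllable types", {
  withr::with_seed(33, {
    songs <- random_songs(20, min_len = 3, max_len = 12)
    net <- build_network(songs)
    map <- stats::setNames(sprintf("z%02d", sample(5)), c("A", "B", "C", "D", "E"))
    songs2 <- lapply(songs, function(s) list(tokens = unname(map[s$tokens]),
                                             duration = s$duration))
    net2 <- build_network(songs2)
    expect_equal(average_path_length(net2), average_path_length(net))
    expect_equal(network_density(net2), network_density(net))
  })
})

test_that("networks with three or fewer syllable types are excluded", {
  three <- build_network(make_songs(c("ABC", "CAB")))
  four <- build_network(make_songs(c("ABCD", "DCBA")))
  expect_true(network_metrics(three)$excluded)
  expect_true(is.na(network_metrics(three)$path_length))
  expect_false(network_metrics(four)$excluded)
  expect_false(is.na(network_metrics(four)$path_length))

  nets <- list(b1 = three, b2 = four, b3 = build_network(make_songs("AAB")))
  ex <- exclude_small(nets)
  expect_equal(names(ex$retained), "b2")
  expect_equal(ex$exclusion_log$excluded, c(TRUE, FALSE, TRUE))
  expect_equal(ex$exclusion_log$n_nodes, c(3L, 4L, 2L))
})

test_that("diagram export writes image, GraphML and edge list deterministically", {
  net <- build_network(make_songs(c("AAB", "BA")))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "net1.svg")
  export_diagram(net, p1, seed = 5)
  expect_true(file.exists(p1))
  expect_true(file.exists(file.path(dir, "net1.graphml")))
  edges <- read.csv(file.path(dir, "net1_edges.csv"), stringsAsFactors = FALSE)
  expect_equal(edges$count, net$edges$count)
  # identical input and seed render identical graph files
  p2 <- file.path(dir, "net2.svg")
  export_diagram(net, p2, seed = 5)
  g1 <- readLines(file.path(dir, "net1.graphml"))
  g2 <- readLines(file.path(dir, "net2.graphml"))
  expect_identical(g1, g2)
})
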