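square <- as_interactome(tibble::tibble(from = c("a", "b", "a", "d"),
                                        to = c("b", "c", "d", "c")))

test_that("gene sets map onto the interactome with drops reported", {
  net <- as_interactome(tibble::tibble(from = c("A", "B"), to = c("B", "C")))
  m <- map_to_interactome(c("A", "B", "X"), net)
  expect_equal(m$mapped, c("A", "B"))
  expect_equal(m$dropped, "X")
  m0 <- map_to_interactome(character(), net)
  expect_equal(m0$mapped, character())
  expect_equal(m0$dropped, character())
  expect_warning(map_to_interactome("nope", net), "map")

  # published 30-gene disease list against a fixture covering 28 of them
  disease <- read_gene_list(system.file("extdata", "prostate_disease_genes.txt",
                                        package = "moanet"))
  expect_length(disease, 30)
  covered <- setdiff(disease, c("FSD1L", "PLAG1"))
  fixture <- as_interactome(tibble::tibble(from = covered, to = "HUB1"))
  m28 <- map_to_interactome(disease, fixture)
  expect_length(m28$mapped, 28)
  expect_equal(m28$dropped, c("FSD1L", "PLAG1"))
})

test_that("shortest paths are deterministic under lexicographic tie-breaking", {
  expect_equal(shortest_path(square, "a", "c"), c("a", "b", "c"))
  all_paths <- shortest_path(square, "a", "c", tie_break = "all")
  expect_equal(canon_paths(all_paths),
               canon_paths(brute_all_shortest_paths(square, "a", "c")))
  expect_equal(shortest_path(square, "a", "a"), "a")
  disconnected <- as_interactome(tibble::tibble(from = c("a", "x"), to = c("b", "y")))
  expect_equal(shortest_path(disconnected, "a", "y"), character(0))
  expect_equal(shortest_path(disconnected, "a", "y", tie_break = "all"), list())
  expect_error(shortest_path(square, "zz", "c"), "zz")
})

test_that("a single chain assembles with the expected roles and edge flags", {
  chain <- as_interactome(tibble::tibble(from = c("s", "x", "g"), to = c("x", "t", "s")))
  net <- build_signaling_network(chain, sources = "s", tfs = "t",
                                 reg_targets = "g",
                                 tfmap = tibble::tibble(tf = "t", target = "g"))
  nd <- network_nodes(net)
  expect_equal(nd$roles[nd$gene == "s"], "source")
  expect_equal(nd$roles[nd$gene == "x"], "linker")
  expect_equal(nd$roles[nd$gene == "t"], "tf")
  expect_equal(nd$roles[nd$gene == "g"], "target")
  ed <- network_edges(net)
  expect_equal(ed$type[ed$from == "g" & ed$to == "t"], "regulatory")
  expect_setequal(ed$type[!(ed$from == "g" & ed$to == "t")], "ppi")
  expect_equal(nrow(ed), 3)
})

test_that("a source that is itself an activated TF carries both roles", {
  tri <- as_interactome(tibble::tibble(from = c("s", "x"), to = c("x", "t")))
  net <- build_signaling_network(tri, sources = c("s", "t"), tfs = c("t", "s"))
  nd <- network_nodes(net)
  expect_true(all(nd$source[nd$gene %in% c("s", "t")]))
  expect_true(all(nd$tf[nd$gene %in% c("s", "t")]))
  # no self-loop edges were introduced
  expect_true(all(net$edges$from != net$edges$to))
})

test_that("network assembly equals the brute-force union of all shortest paths", {
  withr::local_seed(202)
  for (rep in 1:40) {
    g <- random_connected_graph(sample(6:12, 1), extra = sample(3:10, 1))
    nodes <- interactome_nodes(g)
    sources <- sample(nodes, 3)
    tfs <- sample(setdiff(nodes, sources), 2)
    net <- build_signaling_network(g, sources, tfs, tie_break = "all")
    oracle_paths <- list()
    for (s in sources) for (t in tfs) {
      oracle_paths <- c(oracle_paths, brute_all_shortest_paths(g, s, t))
    }
    oracle_nodes <- sort(unique(unlist(oracle_paths)))
    oracle_edges <- dplyr::distinct(dplyr::bind_rows(lapply(oracle_paths, function(p) {
      tibble::tibble(from = pmin(p[-length(p)], p[-1]), to = pmax(p[-length(p)], p[-1]))
    }))) |> dplyr::arrange(from, to)
    expect_equal(net$nodes$gene, oracle_nodes)
    expect_equal(dplyr::select(net$edges, from, to), oracle_edges, ignore_attr = TRUE)
  }
})

test_that("lexicographic assembly is byte-identical across runs", {
  withr::local_seed(303)
  g <- random_connected_graph(15, extra = 15)
  nodes <- interactome_nodes(g)
  sources <- nodes[1:3]; tfs <- nodes[13:15]
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_network(build_signaling_network(g, sources, tfs), f1)
  write_network(build_signaling_network(g, sources, tfs), f2)
  expect_identical(readr::read_file(f1), readr::read_file(f2))
  expect_identical(readr::read_file(node_sidecar_path(f1)),
                   readr::read_file(node_sidecar_path(f2)))
})

test_that("adding interactome edges never lengthens shortest paths", {
  withr::local_seed(404)
  for (rep in 1:10) {
    g <- random_connected_graph(10, extra = 5)
    nodes <- interactome_nodes(g)
    d0 <- brute_distances(g, nodes[1])
    extra <- sample(nodes, 2)
    g2 <- as_interactome(dplyr::bind_rows(
      tibble::as_tibble(g), tibble::tibble(from = extra[1], to = extra[2])))
    d1 <- brute_distances(g2, nodes[1])
    expect_true(all(d1[names(d0)] <= d0))
  }
})

test_that("every network node is on a retained path or is a regulated target", {
  withr::local_seed(505)
  for (rep in 1:10) {
    g <- random_connected_graph(10, extra = 8)
    nodes <- interactome_nodes(g)
    tfmap <- tibble::tibble(tf = nodes[9], target = nodes[5])
    net <- build_signaling_network(g, sources = nodes[1:2], tfs = nodes[9],
                                   reg_targets = nodes[5], tfmap = tfmap)
    nd <- network_nodes(net)
    expect_true(all(nd$source | nd$linker | nd$tf | nd$target))
    # every ppi edge exists in the input interactome
    ppi <- net$edges[net$edges$type == "ppi", c("from", "to")]
    expect_true(all(paste(ppi$from, ppi$to) %in% paste(g$from, g$to)))
  }
})

test_that("unreachable pairs and empty cores are handled per contract", {
  two_islands <- as_interactome(tibble::tibble(from = c("a", "x"), to = c("b", "y")))
  expect_error(build_signaling_network(two_islands, sources = "a", tfs = "y"),
               "connected")
  # one reachable pair is enough; the unreachable one is logged
  net <- build_signaling_network(two_islands, sources = c("a", "x"), tfs = c("b", "y"))
  expect_equal(net$log$n_unreachable, 2L)
  expect_setequal(net$nodes$gene, c("a", "b", "x", "y"))
})

test_that("max_path_len caps retained paths", {
  chain <- as_interactome(tibble::tibble(from = c("a", "b", "c"), to = c("b", "c", "d")))
  expect_error(build_signaling_network(chain, "a", "d", max_path_len = 2), "connected")
  net <- build_signaling_network(chain, "a", "d", max_path_len = 3)
  expect_equal(nrow(net$nodes), 4)
})

test_that("build_pnet composes the pipeline and fails when no TF activates", {
  genes <- c("s1", "t1", "l1", "g1")
  interactome <- as_interactome(tibble::tibble(from = c("s1", "l1", "g1"),
                                               to = c("l1", "t1", "t1")))
  tfmap <- tibble::tibble(tf = "t1", target = c("g1", "g2"))
  expr <- tibble::tibble(gene = rep(c("g1", "g2"), each = 2),
                         sample = rep(c("s", "c"), 2),
                         group = rep(c("case", "control"), 2),
                         value = c(30, 10, 30, 10))
  pnet <- build_pnet(expr, interactome, tfmap, disease_genes = "s1")
  expect_equal(pnet$provenance$label, "pnet")
  nd <- network_nodes(pnet)
  expect_setequal(nd$gene, c("s1", "l1", "t1", "g1"))
  expect_true(nd$target[nd$gene == "g1"])

  flat <- dplyr::mutate(expr, value = 10)
  expect_error(build_pnet(flat, interactome, tfmap, "s1"), "activated")
})

test_that("build_moanet links drug targets to profile-activated TFs", {
  # drug target two hops from the TF its profile activates
  interactome <- as_interactome(tibble::tibble(
    from = c("tgt", "mid", "r1", "r2"), to = c("mid", "TFX", "TFX", "mid")))
  tfmap <- tibble::tibble(tf = c("TFX", "TFY"), target = c("r1", "r2"))
  meta <- tmp_lines(c("i1\tD1\tA549\t24\t10 uM", "i2\tD1\tA549\t24\t10 uM"))
  mat <- tmp_tsv(tibble::tibble(gene = c("r1", "r2"), i1 = c(5, 0), i2 = c(0, 0)))
  profiles <- read_instance_profiles(mat, meta)
  catalog <- tibble::tibble(drug_id = "D1", drug_name = "DrugOne", target = "tgt")

  net <- build_moanet(profiles, "i1", interactome, tfmap, catalog)
  expect_equal(net$provenance$label, "moanet")
  expect_equal(net$provenance$drug_id, "D1")
  expect_setequal(net$nodes$gene, c("tgt", "mid", "TFX", "r1"))
  expect_equal(net$edges$type[net$edges$from == "TFX" & net$edges$to == "r1"],
               "regulatory")

  # all-zero profile: no TF activates, instance skipped
  expect_message(out <- build_moanet(profiles, "i2", interactome, tfmap, catalog),
                 "no activated TF")
  expect_null(out)
  # drug without targets: skipped
  expect_message(
    out2 <- build_moanet(profiles, "i1", interactome, tfmap, catalog[0, ]),
    "no catalogued target")
  expect_null(out2)
})
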