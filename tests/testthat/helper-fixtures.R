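# Shared test helpers: in-code fixtures and independent brute-force oracles.

# Write a tibble as TSV into a temp file owned by the calling test.
tmp_tsv <- function(df, ..., col_names = TRUE) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  readr::write_tsv(df, path, col_names = col_names, progress = FALSE)
  path
}

tmp_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  readr::write_lines(lines, path)
  path
}

# Adjacency list of an undirected edge tibble.
adj_list <- function(edges) {
  nodes <- sort(unique(c(edges$from, edges$to)))
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges$from[i]; b <- edges$to[i]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  adj
}

# Independent oracle: every shortest path between src and dst, by exhaustive
# depth-first enumeration of all simple paths. Only for tiny graphs.
brute_all_shortest_paths <- function(edges, src, dst) {
  adj <- adj_list(edges)
  if (src == dst) return(list(src))
  found <- list()
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb %in% path) next
      if (nb == dst) {
        found[[length(found) + 1L]] <<- c(path, nb)
      } else {
        walk(c(path, nb))
      }
    }
  }
  walk(src)
  if (length(found) == 0) return(list())
  lens <- vapply(found, length, integer(1))
  found[lens == min(lens)]
}

# BFS distances from src over an edge tibble (independent of igraph).
brute_distances <- function(edges, src) {
  adj <- adj_list(edges)
  dist <- stats::setNames(rep(Inf, length(adj)), names(adj))
  dist[src] <- 0
  frontier <- src
  while (length(frontier) > 0) {
    nxt <- character()
    for (v in frontier) for (nb in adj[[v]]) {
      if (is.infinite(dist[nb])) {
        dist[nb] <- dist[v] + 1
        nxt <- c(nxt, nb)
      }
    }
    frontier <- nxt
  }
  dist
}

canon_paths <- function(paths) {
  sort(vapply(paths, paste, character(1), collapse = ">"), method = "radix")
}

# Random connected undirected graph on n nodes (spanning tree + extra edges).
random_connected_graph <- function(n, extra = n) {
  nodes <- sprintf("n%02d", seq_len(n))
  tree <- tibble::tibble(
    from = nodes[vapply(2:n, function(i) sample.int(i - 1, 1), integer(1))],
    to = nodes[2:n])
  pool <- t(utils::combn(nodes, 2))
  pick <- pool[sample.int(nrow(pool), min(extra, nrow(pool))), , drop = FALSE]
  as_interactome(dplyr::bind_rows(tree, tibble::tibble(from = pick[, 1], to = pick[, 2])))
}

# Bare signaling network over a node set (for overlap/scoring tests where
# only node identity matters).
make_net <- function(genes, instance_id = NA_character_, label = "moanet") {
  genes <- sort(unique(genes))
  moanet:::new_signaling_network(
    nodes = tibble::tibble(gene = genes, roles = rep(list("linker"), length(genes))),
    edges = tibble::tibble(from = character(), to = character(), type = character()),
    provenance = list(label = label, instance_id = instance_id))
}

# The published PC-3 worked example: ten active drugs among the top-30 ranks.
top30_table <- function() {
  readr::read_tsv(system.file("extdata", "pc3_top30_active_drugs.tsv", package = "moanet"),
                  col_types = "icdd", progress = FALSE)
}

# Ranking of `n_total` drugs placing the worked example's actives at their
# published ranks; all other positions are filler drugs.
example_ranking <- function(n_total = 402) {
  t4 <- top30_table()
  drug <- sprintf("filler_%03d", seq_len(n_total))
  drug[t4$rank] <- t4$drug_name
  # strictly decreasing synthetic scores keep every drug at its assigned rank
  rank_drugs(tibble::tibble(drug_id = drug,
                            score = seq(1, 0.01, length.out = n_total)))
}
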