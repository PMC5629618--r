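#' Map a gene set onto an interactome
#'
#' @param genes Character vector of gene symbols.
#' @param interactome Edge table (see [read_interactome()]).
#' @return A list with `mapped` (genes present in the interactome, sorted) and
#'   `dropped` (genes absent from it, sorted). Warns when nothing maps.
#' @export
map_to_interactome <- function(genes, interactome) {
  genes <- unique(genes)
  nodes <- interactome_nodes(interactome)
  mapped <- sort(intersect(genes, nodes))
  dropped <- sort(setdiff(genes, nodes))
  if (length(genes) > 0 && length(mapped) == 0) {
    warning("none of the ", length(genes), " genes map onto the interactome")
  }
  list(mapped = mapped, dropped = dropped)
}

# TRUE if node sequence a sorts strictly before b (same-length sequences).
# Byte-order (radix) comparison, independent of the session locale.
lex_before <- function(a, b) {
  i <- which(a != b)
  if (length(i) == 0) return(FALSE)
  order(c(a[i[1]], b[i[1]]), method = "radix")[1] == 1
}

# Pick the lexicographically smallest node sequence from a list of paths.
lex_min_path <- function(paths) {
  Reduce(function(best, p) if (lex_before(p, best)) p else best, paths)
}

#' Shortest path(s) between two genes on the interactome
#'
#' Edges are unweighted (unit length), so Dijkstra's algorithm reduces to
#' breadth-first search. With `tie_break = "lexicographic"` the unique path
#' returned is the lexicographically smallest node sequence among all shortest
#' paths, which is deterministic across platforms; with `"all"` every shortest
#' path is returned.
#'
#' @param interactome Edge table (see [read_interactome()]).
#' @param src,dst Gene symbols, both present in the interactome.
#' @param tie_break `"lexicographic"` (default) or `"all"`.
#' @return For `"lexicographic"`, a character vector of node symbols from
#'   `src` to `dst` (length 1 when `src == dst`; `character(0)` when `dst` is
#'   unreachable). For `"all"`, a list of such vectors (empty list when
#'   unreachable).
#' @export
shortest_path <- function(interactome, src, dst, tie_break = c("lexicographic", "all")) {
  tie_break <- match.arg(tie_break)
  g <- interactome_graph(interactome)
  nodes <- igraph::V(g)$name
  if (!src %in% nodes) stop("source gene not in interactome: ", src)
  if (!dst %in% nodes) stop("destination gene not in interactome: ", dst)
  if (src == dst) {
    return(if (tie_break == "all") list(src) else src)
  }
  paths <- all_paths_to(g, src, dst)[[dst]]
  if (is.null(paths) || length(paths) == 0) {
    return(if (tie_break == "all") list() else character(0))
  }
  if (tie_break == "all") paths else lex_min_path(paths)
}

interactome_graph <- function(interactome) {
  if (inherits(interactome, "igraph")) return(interactome)
  stopifnot(is.data.frame(interactome))
  igraph::graph_from_data_frame(interactome[, c("from", "to")], directed = FALSE)
}

# All shortest paths from src to each destination, as a named list
# (destination -> list of character node sequences).
all_paths_to <- function(g, src, dsts) {
  dsts <- setdiff(unique(dsts), src)
  if (length(dsts) == 0) return(list())
  res <- suppressWarnings(
    igraph::all_shortest_paths(g, from = src, to = dsts, mode = "all"))$res
  seqs <- lapply(res, function(vp) igraph::V(g)$name[as.integer(vp)])
  ends <- vapply(seqs, function(s) s[length(s)], character(1))
  split(seqs, factor(ends, levels = unique(ends)))
}

#' Assemble a signaling network from sources, TFs and regulated targets
#'
#' The network-building step shared by Pnet and MoAnet construction: map the
#' three gene sets onto the interactome, link every (source, TF) pair by its
#' shortest path(s), take the union of all retained path nodes and edges
#' (edge flag `ppi`; intermediate nodes get role `linker`), then attach each
#' up-regulated target to the activated TF(s) that regulate it with a
#' `regulatory` edge. Regulatory edges are inserted whether or not a physical
#' interaction exists. Unmapped genes and unreachable pairs are dropped (and
#' counted in the returned object's `log`), never kept as isolated nodes.
#'
#' @param interactome Edge table (see [read_interactome()]).
#' @param sources Source gene symbols (disease genes or drug targets).
#' @param tfs Activated transcription-factor symbols.
#' @param reg_targets Up-regulated target gene symbols (may be empty).
#' @param tfmap TF-target tibble used to attribute each regulated target to
#'   its TF(s); required when `reg_targets` is non-empty.
#' @param tie_break `"lexicographic"` for one deterministic path per pair,
#'   `"all"` to take the union of every shortest path.
#' @param max_path_len Optional cap on path length in edges; pairs farther
#'   apart contribute nothing. Default `Inf` (no cap).
#' @param provenance A list recorded on the result, e.g.
#'   `list(label = "pnet")`.
#' @return An object of class `signaling_network`: a list with `nodes`
#'   (tibble `gene`, `roles` list-column over `source`/`linker`/`tf`/`target`),
#'   `edges` (tibble `from`, `to`, `type` in `ppi`/`regulatory`),
#'   `provenance`, and `log` (drop counts).
#' @export
build_signaling_network <- function(interactome, sources, tfs,
                                    reg_targets = character(), tfmap = NULL,
                                    tie_break = c("lexicographic", "all"),
                                    max_path_len = Inf,
                                    provenance = list(label = "network")) {
  tie_break <- match.arg(tie_break)
  if (length(reg_targets) > 0 && is.null(tfmap)) {
    stop("tfmap is required to attribute regulated targets to their TFs")
  }
  g <- interactome_graph(interactome)
  msrc <- map_to_interactome(sources, interactome)
  mtf <- map_to_interactome(tfs, interactome)
  mtgt <- if (length(reg_targets) > 0) map_to_interactome(reg_targets, interactome)
          else list(mapped = character(), dropped = character())
  if (length(msrc$mapped) == 0 || length(mtf$mapped) == 0) {
    stop("no mapped source or TF genes; cannot build a signaling network")
  }

  path_nodes <- character()
  path_edges <- list()
  n_pairs <- 0L
  n_unreachable <- 0L
  for (s in msrc$mapped) {
    dsts <- setdiff(mtf$mapped, s)
    if (length(dsts) == 0) next
    by_dst <- all_paths_to(g, s, dsts)
    for (d in dsts) {
      n_pairs <- n_pairs + 1L
      paths <- by_dst[[d]]
      if (is.null(paths) || length(paths) == 0) {
        n_unreachable <- n_unreachable + 1L
        next
      }
      if (length(paths[[1]]) - 1 > max_path_len) {
        n_unreachable <- n_unreachable + 1L
        next
      }
      keep <- if (tie_break == "lexicographic") list(lex_min_path(paths)) else paths
      for (p in keep) {
        path_nodes <- c(path_nodes, p)
        if (length(p) > 1) {
          path_edges[[length(path_edges) + 1L]] <-
            tibble::tibble(from = p[-length(p)], to = p[-1])
        }
      }
    }
  }
  if (length(path_nodes) == 0) {
    stop("no (source, TF) pair is connected on the interactome; the core network is empty")
  }
  path_nodes <- unique(path_nodes)
  ppi <- dplyr::bind_rows(path_edges) |>
    dplyr::mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
    dplyr::transmute(from = .data$a, to = .data$b, type = "ppi") |>
    dplyr::distinct()

  net_tfs <- intersect(mtf$mapped, path_nodes)
  reg <- if (length(mtgt$mapped) > 0) {
    regulatory_pairs(net_tfs, mtgt$mapped, tfmap) |>
      dplyr::transmute(from = pmin(.data$tf, .data$target),
                       to = pmax(.data$tf, .data$target),
                       type = "regulatory") |>
      dplyr::distinct()
  } else {
    tibble::tibble(from = character(), to = character(), type = character())
  }
  reg_kept <- if (nrow(reg) > 0) {
    intersect(mtgt$mapped, unique(c(reg$from, reg$to)))
  } else character()

  all_nodes <- sort(unique(c(path_nodes, reg_kept)))
  roles <- lapply(all_nodes, function(n) {
    r <- character()
    if (n %in% msrc$mapped && n %in% path_nodes) r <- c(r, "source")
    if (n %in% net_tfs) r <- c(r, "tf")
    if (n %in% reg_kept) r <- c(r, "target")
    if (n %in% path_nodes && !(n %in% msrc$mapped) && !(n %in% net_tfs)) r <- c(r, "linker")
    sort(r)
  })
  edges <- dplyr::bind_rows(ppi, reg) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$from, .data$to, .data$type)

  new_signaling_network(
    nodes = tibble::tibble(gene = all_nodes, roles = roles),
    edges = edges,
    provenance = provenance,
    log = list(
      dropped_sources = msrc$dropped, dropped_tfs = mtf$dropped,
      dropped_reg_targets = union(mtgt$dropped, setdiff(mtgt$mapped, reg_kept)),
      n_pairs = n_pairs, n_unreachable = n_unreachable))
}

new_signaling_network <- function(nodes, edges, provenance, log = list()) {
  structure(list(nodes = nodes, edges = edges, provenance = provenance, log = log),
            class = "signaling_network")
}

#' @export
print.signaling_network <- function(x, ...) {
  lab <- x$provenance$label %||% "network"
  cat(sprintf("<signaling_network:%s> %d nodes, %d edges (%d ppi, %d regulatory)\n",
              lab, nrow(x$nodes), nrow(x$edges),
              sum(x$edges$type == "ppi"), sum(x$edges$type == "regulatory")))
  invisible(x)
}

#' Node table of a signaling network
#'
#' @param net A `signaling_network`.
#' @return A tibble with `gene`, comma-joined `roles`, and one logical column
#'   per role (`source`, `linker`, `tf`, `target`).
#' @export
network_nodes <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  tibble::tibble(
    gene = net$nodes$gene,
    roles = vapply(net$nodes$roles, paste, character(1), collapse = ","),
    source = vapply(net$nodes$roles, function(r) "source" %in% r, logical(1)),
    linker = vapply(net$nodes$roles, function(r) "linker" %in% r, logical(1)),
    tf = vapply(net$nodes$roles, function(r) "tf" %in% r, logical(1)),
    target = vapply(net$nodes$roles, function(r) "target" %in% r, logical(1)))
}

#' Edge table of a signaling network
#' @param net A `signaling_network`.
#' @return A tibble with `from`, `to`, `type`.
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "signaling_network"))
  net$edges
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a signaling network into its edge table
#' @param x A `signaling_network`.
#' @param ... Unused.
#' @return The edge tibble (`from`, `to`, `type`).
#' @export
tidy.signaling_network <- function(x, ...) network_edges(x)

#' One-row summary of a signaling network
#' @param x A `signaling_network`.
#' @param ... Unused.
#' @return A one-row tibble with node/edge counts and per-role node counts.
#' @export
glance.signaling_network <- function(x, ...) {
  nd <- network_nodes(x)
  tibble::tibble(
    label = x$provenance$label %||% "network",
    n_nodes = nrow(nd), n_edges = nrow(x$edges),
    n_ppi = sum(x$edges$type == "ppi"),
    n_regulatory = sum(x$edges$type == "regulatory"),
    n_sources = sum(nd$source), n_linkers = sum(nd$linker),
    n_tfs = sum(nd$tf), n_targets = sum(nd$target))
}

#' Build a patient-specific disease signaling network (Pnet)
#'
#' Composes the pipeline for one patient: fold changes from the case/control
#' expression table, activated TFs, their up-regulated targets, and the
#' shortest-path assembly with the disease-associated genes as sources.
#'
#' @param expr Long expression tibble (see [read_expression_table()]).
#' @param interactome Edge table.
#' @param tfmap TF-target tibble.
#' @param disease_genes Character vector of disease-associated source genes.
#' @param tf_threshold TF-activation cutoff on the score (default 2.0).
#' @param fc_threshold Up-regulation fold-change cutoff (default 2.0).
#' @param tie_break,max_path_len Passed to [build_signaling_network()].
#' @return A `signaling_network` with provenance label `"pnet"`; the TF
#'   activation table and fold-change profile are attached under `$meta`.
#' @export
build_pnet <- function(expr, interactome, tfmap, disease_genes,
                       tf_threshold = 2.0, fc_threshold = 2.0,
                       tie_break = c("lexicographic", "all"), max_path_len = Inf) {
  tie_break <- match.arg(tie_break)
  profile <- compute_fold_change(expr)
  activated <- identify_activated_tfs(profile, tfmap, threshold = tf_threshold)
  act_tfs <- activated$tf[activated$activated]
  if (length(act_tfs) == 0) stop("no transcription factor is activated at threshold ", tf_threshold)
  up <- upregulated_targets(activated, profile, tfmap, fc_threshold = fc_threshold)
  net <- build_signaling_network(interactome, sources = disease_genes, tfs = act_tfs,
                                 reg_targets = up, tfmap = tfmap,
                                 tie_break = tie_break, max_path_len = max_path_len,
                                 provenance = list(label = "pnet"))
  net$meta <- list(activated = activated, upregulated = up, fold_change = profile)
  net
}

#' Build the mechanism-of-action network (MoAnet) of one drug instance
#'
#' Sources are the instance's drug targets from the catalog; TF activation and
#' target up-regulation are computed from the instance's z-score profile
#' (`zscore` mode) with the same top-3 rule and cutoffs as the Pnet.
#' Instances whose drug has no catalogued target, or whose profile activates
#' no TF, are skipped (returns `NULL` with a message).
#'
#' @param profiles An `instance_profiles` object (see
#'   [read_instance_profiles()]).
#' @param instance_id The instance to build.
#' @param interactome Edge table.
#' @param tfmap TF-target tibble.
#' @param catalog Drug catalog tibble (`drug_id`, `drug_name`, `target`).
#' @param tf_threshold,z_threshold TF-activation and up-regulation cutoffs on
#'   the z-score scale (both default 2.0).
#' @param tie_break,max_path_len Passed to [build_signaling_network()].
#' @return A `signaling_network` with provenance
#'   `list(label = "moanet", drug_id, instance_id, cell_line)`, or `NULL`
#'   when the instance is skipped.
#' @export
build_moanet <- function(profiles, instance_id, interactome, tfmap, catalog,
                         tf_threshold = 2.0, z_threshold = 2.0,
                         tie_break = c("lexicographic", "all"), max_path_len = Inf) {
  tie_break <- match.arg(tie_break)
  stopifnot(inherits(profiles, "instance_profiles"))
  meta <- profiles$instances[profiles$instances$instance_id == instance_id, ]
  if (nrow(meta) != 1) stop("unknown instance id: ", instance_id)
  targets <- catalog$target[catalog$drug_id == meta$drug_id]
  if (length(targets) == 0) {
    message("skipping instance ", instance_id, ": drug ", meta$drug_id,
            " has no catalogued target")
    return(NULL)
  }
  z <- profiles$profiles |>
    dplyr::filter(.data$instance_id == !!instance_id) |>
    dplyr::select("gene", value = "zscore")
  profile <- fc_profile(z, mode = "zscore")
  activated <- identify_activated_tfs(profile, tfmap, threshold = tf_threshold)
  act_tfs <- activated$tf[activated$activated]
  if (length(act_tfs) == 0) {
    message("skipping instance ", instance_id, ": no activated TF in its z-score profile")
    return(NULL)
  }
  up <- upregulated_targets(activated, profile, tfmap, fc_threshold = z_threshold)
  net <- build_signaling_network(interactome, sources = targets, tfs = act_tfs,
                                 reg_targets = up, tfmap = tfmap,
                                 tie_break = tie_break, max_path_len = max_path_len,
                                 provenance = list(label = "moanet",
                                                   drug_id = meta$drug_id,
                                                   instance_id = instance_id,
                                                   cell_line = meta$cell_line))
  net$meta <- list(activated = activated, upregulated = up)
  net
}

#' Build MoAnets for every instance in a profile set
#'
#' @inheritParams build_moanet
#' @return A tibble with one row per successfully built instance:
#'   `instance_id`, `drug_id`, `cell_line` and a `network` list-column of
#'   `signaling_network` objects. Skipped instances are omitted.
#' @export
build_moanet_all <- function(profiles, interactome, tfmap, catalog,
                             tf_threshold = 2.0, z_threshold = 2.0,
                             tie_break = c("lexicographic", "all"), max_path_len = Inf) {
  tie_break <- match.arg(tie_break)
  nets <- purrr::map(profiles$instances$instance_id, function(id) {
    build_moanet(profiles, id, interactome, tfmap, catalog,
                 tf_threshold = tf_threshold, z_threshold = z_threshold,
                 tie_break = tie_break, max_path_len = max_path_len)
  })
  keep <- !purrr::map_lgl(nets, is.null)
  out <- profiles$instances[keep, c("instance_id", "drug_id", "cell_line")]
  out$network <- nets[keep]
  tibble::as_tibble(out)
}
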