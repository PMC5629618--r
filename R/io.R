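#' Read a case/control expression table
#'
#' Reads a tab-separated expression matrix (first column gene symbol, header
#' row of sample ids), keeps only the listed case and control samples, and
#' returns the data in long (tidy) form with one row per (gene, sample) cell.
#' Multiple rows for the same gene (e.g. several probes per gene) are collapsed
#' by the arithmetic mean (or the maximum, see `collapse`).
#'
#' @param path Path to a TSV file; first column gene symbols, remaining
#'   columns one per sample, header required.
#' @param case_ids,control_ids Character vectors of sample ids assigned to the
#'   case and control groups. Every id must appear as a column of the table.
#' @param collapse How duplicate gene rows are combined: `"mean"` (default)
#'   or `"max"`.
#' @return A tibble with columns `gene`, `sample`, `group` (`"case"` or
#'   `"control"`) and `value`, carrying attribute `n_collapsed` (number of
#'   duplicated gene symbols that were collapsed).
#' @export
read_expression_table <- function(path, case_ids, control_ids,
                                  collapse = c("mean", "max")) {
  collapse <- match.arg(collapse)
  stopifnot(length(case_ids) >= 1, length(control_ids) >= 1)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (ncol(raw) < 2) stop("expression table needs a gene column plus sample columns: ", path)
  names(raw)[1] <- "gene"
  wanted <- c(case_ids, control_ids)
  if (anyDuplicated(wanted)) {
    stop("sample ids listed twice across case/control: ",
         paste(unique(wanted[duplicated(wanted)]), collapse = ", "))
  }
  missing <- setdiff(wanted, names(raw)[-1])
  if (length(missing) > 0) {
    stop("sample id(s) not found in expression table: ", paste(missing, collapse = ", "))
  }
  long <- raw |>
    dplyr::select("gene", dplyr::all_of(wanted)) |>
    dplyr::mutate(gene = trimws(.data$gene)) |>
    tidyr::pivot_longer(-"gene", names_to = "sample", values_to = "value_chr")
  vals <- suppressWarnings(as.numeric(long$value_chr))
  if (anyNA(vals)) {
    bad <- long[is.na(vals), ][1, ]
    stop(sprintf("non-numeric expression value '%s' for gene '%s', sample '%s'",
                 bad$value_chr, bad$gene, bad$sample))
  }
  long$value <- vals
  if (any(!is.finite(long$value))) stop("non-finite expression values in ", path)
  if (any(long$value < 0)) stop("negative expression intensities in ", path)

  n_genes_raw <- dplyr::n_distinct(long$gene)
  dup_genes <- raw$gene[duplicated(trimws(raw$gene))]
  fun <- if (collapse == "mean") mean else max
  out <- long |>
    dplyr::summarise(value = fun(.data$value), .by = c("gene", "sample")) |>
    dplyr::mutate(group = dplyr::if_else(.data$sample %in% case_ids, "case", "control")) |>
    dplyr::select("gene", "sample", "group", "value") |>
    dplyr::arrange(.data$gene, .data$sample)
  attr(out, "n_collapsed") <- length(unique(trimws(dup_genes)))
  out
}

#' Read a protein-protein interactome
#'
#' Loads an undirected gene-symbol interaction graph from either a plain
#' two-column file or the BioGRID tab format (official-symbol columns).
#' Self-loops are removed and duplicate edges (including reversed duplicates)
#' are collapsed, so the result is a simple undirected graph.
#'
#' @param path Path to the edge-list file.
#' @param dialect `"two_column"` for whitespace/tab separated symbol pairs,
#'   `"biogrid_tab"` for a tab file containing the columns
#'   `Official Symbol Interactor A` / `Official Symbol Interactor B`.
#' @return A tibble of class `interactome_tbl` with columns `from` and `to`
#'   (each edge stored once, `from` < `to`), and attributes
#'   `n_self_loops_dropped` and `n_duplicates_dropped`.
#' @export
read_interactome <- function(path, dialect = c("two_column", "biogrid_tab")) {
  dialect <- match.arg(dialect)
  if (dialect == "two_column") {
    lines <- readr::read_lines(path, progress = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(as_interactome(tibble::tibble(from = character(), to = character())))
    parts <- strsplit(trimws(lines), "[ \t]+")
    bad <- which(vapply(parts, length, integer(1)) < 2)
    if (length(bad) > 0) {
      stop("unparseable interactome line ", bad[1], ": '", lines[bad[1]], "'")
    }
    edges <- tibble::tibble(
      from = vapply(parts, `[[`, character(1), 1),
      to   = vapply(parts, `[[`, character(1), 2)
    )
  } else {
    tab <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                           progress = FALSE)
    cols <- c("Official Symbol Interactor A", "Official Symbol Interactor B")
    if (!all(cols %in% names(tab))) {
      stop("biogrid_tab file lacks the official-symbol interactor columns: ", path)
    }
    edges <- tibble::tibble(from = tab[[cols[1]]], to = tab[[cols[2]]])
  }
  as_interactome(edges)
}

#' Coerce an edge table to a validated interactome
#'
#' Normalises any two-column data frame of gene-symbol pairs into the
#' package's canonical undirected edge list: symbols trimmed, self-loops
#' dropped, duplicate and reversed-duplicate edges collapsed, each edge stored
#' once with `from` lexicographically before `to`.
#'
#' @param edges A data frame whose first two columns are interacting gene
#'   symbols.
#' @return A tibble of class `interactome_tbl`; see [read_interactome()].
#' @export
as_interactome <- function(edges) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 2)
  e <- tibble::tibble(from = trimws(as.character(edges[[1]])),
                      to   = trimws(as.character(edges[[2]])))
  if (any(!nzchar(e$from) | !nzchar(e$to))) stop("empty gene symbol in interactome edge list")
  n0 <- nrow(e)
  e <- dplyr::filter(e, .data$from != .data$to)
  n_self <- n0 - nrow(e)
  e <- dplyr::mutate(e,
                     a = pmin(.data$from, .data$to),
                     b = pmax(.data$from, .data$to)) |>
    dplyr::select(from = "a", to = "b")
  n1 <- nrow(e)
  e <- dplyr::distinct(e) |> dplyr::arrange(.data$from, .data$to)
  out <- structure(e, class = c("interactome_tbl", class(tibble::tibble())))
  attr(out, "n_self_loops_dropped") <- n_self
  attr(out, "n_duplicates_dropped") <- n1 - nrow(e)
  out
}

#' Gene symbols present in an interactome
#' @param interactome An edge table as returned by [read_interactome()].
#' @return Sorted character vector of node symbols.
#' @export
interactome_nodes <- function(interactome) {
  sort(unique(c(interactome$from, interactome$to)))
}

#' Read a TF-to-target interaction table
#'
#' @param path Two-column TSV `(tf, target)`, one interaction per row, with or
#'   without a header line named `tf`/`target`.
#' @return A tibble with columns `tf` and `target` (distinct pairs, trimmed
#'   symbols).
#' @export
read_tf_targets <- function(path) {
  tab <- read_two_col(path, c("tf", "target"))
  if (any(!nzchar(tab$tf) | !nzchar(tab$target))) stop("empty symbol in TF-target table: ", path)
  dplyr::distinct(tab) |> dplyr::arrange(.data$tf, .data$target)
}

#' Read a drug catalog (drug-target table)
#'
#' @param path TSV with columns `(drug_id, drug_name, target)`, one target per
#'   row; header optional.
#' @return A tibble with columns `drug_id`, `drug_name`, `target`. Each drug id
#'   must map to a single drug name.
#' @export
read_drug_catalog <- function(path) {
  tab <- readr::read_tsv(path, col_types = "ccc", progress = FALSE,
                         col_names = c("drug_id", "drug_name", "target"))
  if (nrow(tab) > 0 && identical(unname(unlist(tab[1, ])), c("drug_id", "drug_name", "target"))) {
    tab <- tab[-1, ]
  }
  tab <- dplyr::mutate(tab, dplyr::across(dplyr::everything(), trimws))
  if (any(!nzchar(tab$drug_id) | !nzchar(tab$target))) stop("empty drug id or target in ", path)
  names_per_id <- dplyr::summarise(tab, n = dplyr::n_distinct(.data$drug_name), .by = "drug_id")
  clash <- names_per_id$drug_id[names_per_id$n > 1]
  if (length(clash) > 0) {
    stop("drug id(s) mapped to more than one name: ", paste(clash, collapse = ", "))
  }
  dplyr::distinct(tab) |> dplyr::arrange(.data$drug_id, .data$target)
}

#' Read drug-instance z-score profiles with their metadata sidecar
#'
#' @param matrix_path TSV matrix: first column gene symbol, one column per
#'   instance id, z-scores in the cells.
#' @param metadata_path TSV with columns
#'   `(instance_id, drug_id, cell_line, time_h, dose)`; header optional.
#' @return An object of class `instance_profiles`: a list with
#'   `$instances` (metadata tibble) and `$profiles` (long tibble
#'   `gene`, `instance_id`, `zscore`).
#' @export
read_instance_profiles <- function(matrix_path, metadata_path) {
  meta <- readr::read_tsv(metadata_path, col_types = "ccccc", progress = FALSE,
                          col_names = c("instance_id", "drug_id", "cell_line", "time_h", "dose"))
  if (nrow(meta) > 0 && meta$instance_id[1] == "instance_id") meta <- meta[-1, ]
  meta <- dplyr::mutate(meta,
                        dplyr::across(dplyr::everything(), trimws),
                        time_h = as.numeric(.data$time_h))
  if (anyNA(meta$time_h)) stop("non-numeric time_h in instance metadata: ", metadata_path)
  if (anyDuplicated(meta$instance_id)) {
    stop("duplicate instance id(s): ",
         paste(unique(meta$instance_id[duplicated(meta$instance_id)]), collapse = ", "))
  }
  mat <- readr::read_tsv(matrix_path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  names(mat)[1] <- "gene"
  absent <- setdiff(meta$instance_id, names(mat)[-1])
  if (length(absent) > 0) {
    stop("instance id(s) in metadata but not in the profile matrix: ",
         paste(absent, collapse = ", "))
  }
  prof <- mat |>
    dplyr::select("gene", dplyr::all_of(meta$instance_id)) |>
    dplyr::mutate(gene = trimws(.data$gene)) |>
    tidyr::pivot_longer(-"gene", names_to = "instance_id", values_to = "zscore") |>
    dplyr::mutate(zscore = as.numeric(.data$zscore))
  if (anyNA(prof$zscore)) stop("non-numeric z-score value in ", matrix_path)
  new_instance_profiles(meta, prof)
}

new_instance_profiles <- function(instances, profiles) {
  structure(list(instances = instances, profiles = profiles),
            class = "instance_profiles")
}

#' @export
print.instance_profiles <- function(x, ...) {
  cat("<instance_profiles> ", nrow(x$instances), " instances, ",
      dplyr::n_distinct(x$instances$drug_id), " drugs, ",
      dplyr::n_distinct(x$profiles$gene), " genes\n", sep = "")
  invisible(x)
}

#' Read a plain gene list
#'
#' @param path Text file with one gene symbol per line (blank lines and lines
#'   starting with `#` ignored).
#' @return Character vector of unique, trimmed symbols in file order.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readr::read_lines(path, progress = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  unique(x)
}

#' Read a drug-screening table of growth rates
#'
#' @param path TSV with columns `(drug_name, growth_rate)`; header optional.
#' @return A tibble with columns `drug_name` and `growth_rate` (numeric,
#'   finite), one row per drug name.
#' @export
read_screening_table <- function(path) {
  tab <- read_two_col(path, c("drug_name", "growth_rate"))
  tab <- dplyr::mutate(tab, growth_rate = as.numeric(.data$growth_rate))
  if (anyNA(tab$growth_rate) || any(!is.finite(tab$growth_rate))) {
    stop("non-numeric or non-finite growth rate in ", path)
  }
  dups <- unique(tab$drug_name[duplicated(tab$drug_name)])
  if (length(dups) > 0) stop("duplicate drug name(s) in screening table: ", paste(dups, collapse = ", "))
  tab
}

# Shared 2-column TSV reader: trims symbols, drops an optional header row
# matching the expected column names.
read_two_col <- function(path, col_names) {
  tab <- readr::read_tsv(path, col_types = "cc", progress = FALSE, col_names = col_names)
  if (nrow(tab) > 0 && identical(unname(unlist(tab[1, ])), col_names)) tab <- tab[-1, ]
  dplyr::mutate(tab, dplyr::across(dplyr::everything(), trimws))
}

#' Write a signaling network to disk
#'
#' Three formats are supported: `sif` (Cytoscape simple interaction format,
#' relation = edge type), `graphml` (node attribute `role` carries the
#' comma-joined role set, edge attribute `type`), and `edge_tsv` (edge table
#' plus a companion `<path>.nodes.tsv` with per-node roles). `edge_tsv` and
#' `graphml` round-trip through [read_network()] with nodes, edges and roles
#' intact.
#'
#' @param net A `signaling_network` (see [build_signaling_network()]).
#' @param path Output file path.
#' @param format One of `"sif"`, `"graphml"`, `"edge_tsv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("edge_tsv", "sif", "graphml")) {
  stopifnot(inherits(net, "signaling_network"))
  format <- match.arg(format)
  if (nrow(net$nodes) == 0) stop("refusing to write an empty network")
  nodes <- dplyr::arrange(net$nodes, .data$gene)
  edges <- dplyr::arrange(net$edges, .data$from, .data$to, .data$type)
  if (format == "sif") {
    readr::write_lines(sprintf("%s\t%s\t%s", edges$from, edges$type, edges$to), path)
  } else if (format == "edge_tsv") {
    readr::write_tsv(edges, path, progress = FALSE)
    readr::write_tsv(
      tibble::tibble(gene = nodes$gene, roles = vapply(nodes$roles, paste, character(1), collapse = ",")),
      node_sidecar_path(path), progress = FALSE)
  } else {
    g <- igraph::graph_from_data_frame(
      edges, directed = FALSE,
      vertices = tibble::tibble(
        name = nodes$gene,
        role = vapply(nodes$roles, paste, character(1), collapse = ",")))
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

node_sidecar_path <- function(path) paste0(path, ".nodes.tsv")

#' Read a signaling network written by [write_network()]
#'
#' @param path File produced by [write_network()].
#' @param format `"edge_tsv"` or `"graphml"` (sif does not carry node roles and
#'   is write-only).
#' @return A `signaling_network`.
#' @export
read_network <- function(path, format = c("edge_tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "edge_tsv") {
    edges <- readr::read_tsv(path, col_types = "ccc", progress = FALSE)
    nodes <- readr::read_tsv(node_sidecar_path(path), col_types = "cc", progress = FALSE)
    roles <- strsplit(nodes$roles, ",", fixed = TRUE)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    edf <- igraph::as_data_frame(g, what = "edges")
    edges <- tibble::tibble(from = edf$from, to = edf$to, type = edf$type)
    vdf <- igraph::as_data_frame(g, what = "vertices")
    nodes <- tibble::tibble(gene = vdf$name)
    roles <- strsplit(vdf$role, ",", fixed = TRUE)
  }
  new_signaling_network(
    nodes = tibble::tibble(gene = nodes$gene, roles = roles),
    edges = dplyr::mutate(edges,
                          a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
      dplyr::select(from = "a", to = "b", "type") |>
      dplyr::distinct() |>
      dplyr::arrange(.data$from, .data$to, .data$type),
    provenance = list(label = "restored"))
}
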