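#' Specification for a synthetic fixture universe
#'
#' Describes the miniature data universe emitted by [generate_fixture()]:
#' a random background interactome, a TF-target map, case/control expression
#' with a planted set of activated TFs, a drug catalog and per-instance
#' z-score profiles engineered so each drug's MoAnet overlaps the patient
#' Pnet by a planted fraction, and a screening table in which high-overlap
#' drugs suppress growth.
#'
#' @param seed Integer seed; every random choice flows from it.
#' @param n_genes Total genes in the universe.
#' @param n_tfs Transcription factors (disjoint target blocks each).
#' @param n_targets_per_tf Targets per TF.
#' @param n_disease_genes Disease-associated source genes.
#' @param n_drugs Drugs in the catalog.
#' @param n_instances_per_drug Perturbation instances per drug.
#' @param edge_density Expected degree of the background graph.
#' @param planted_activated_tfs How many TFs the patient profile activates.
#' @param planted_overlap_fractions Per-drug MoAnet/Pnet overlap fraction in
#'   \[0, 1\]; length `n_drugs`.
#' @param noise_sd Multiplicative log-normal noise scale on expression and
#'   additive Gaussian noise scale on z-scores; 0 = noise-free.
#' @param graph_model Background random-graph model:
#'   `"pa"` (preferential attachment, scale-free-like degree distribution
#'   resembling protein interactomes) or `"er"` (Erdos-Renyi).
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         n_genes = 300L,
                         n_tfs = 20L,
                         n_targets_per_tf = 4L,
                         n_disease_genes = 10L,
                         n_drugs = 10L,
                         n_instances_per_drug = 3L,
                         edge_density = 4,
                         planted_activated_tfs = 5L,
                         planted_overlap_fractions = seq(0, 0.9, by = 0.1),
                         noise_sd = 0,
                         graph_model = c("pa", "er")) {
  graph_model <- match.arg(graph_model)
  spec <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
               n_tfs = as.integer(n_tfs), n_targets_per_tf = as.integer(n_targets_per_tf),
               n_disease_genes = as.integer(n_disease_genes), n_drugs = as.integer(n_drugs),
               n_instances_per_drug = as.integer(n_instances_per_drug),
               edge_density = edge_density,
               planted_activated_tfs = as.integer(planted_activated_tfs),
               planted_overlap_fractions = planted_overlap_fractions,
               noise_sd = noise_sd, graph_model = graph_model)
  counts <- spec[c("n_genes", "n_tfs", "n_targets_per_tf", "n_disease_genes",
                   "n_drugs", "n_instances_per_drug", "planted_activated_tfs")]
  if (any(unlist(counts) <= 0)) stop("all fixture counts must be positive")
  if (length(spec$planted_overlap_fractions) != spec$n_drugs) {
    stop("planted_overlap_fractions must have one entry per drug (",
         spec$n_drugs, ")")
  }
  if (any(spec$planted_overlap_fractions < 0 | spec$planted_overlap_fractions > 1)) {
    stop("planted overlap fractions must lie in [0, 1]")
  }
  if (spec$planted_activated_tfs + spec$n_drugs > spec$n_tfs) {
    stop("infeasible spec: need n_tfs >= planted_activated_tfs + n_drugs ",
         "(each drug is driven by its own non-patient TF)")
  }
  n_named <- spec$n_tfs + spec$n_tfs * spec$n_targets_per_tf +
    spec$n_disease_genes + spec$n_drugs
  if (n_named > spec$n_genes) {
    stop("infeasible spec: ", n_named, " role-bearing genes exceed n_genes = ",
         spec$n_genes)
  }
  structure(spec, class = "fixture_spec")
}

#' Generate a synthetic fixture directory with planted ground truth
#'
#' Emits every input file the pipeline consumes (interactome, TF-target map,
#' case/control expression, disease-gene list, drug catalog, instance z-score
#' matrix + metadata, screening table) plus ground-truth TSVs, constructed so
#' that in noise-free mode the full pipeline recovers the planted truth
#' exactly: the planted TFs are the activated set, the Pnet node set is the
#' planted disease genes + activated TFs + their boosted targets, and each
#' drug's sensitivity score equals its planted overlap fraction.
#'
#' Planting works by adding direct interactome edges between each source and
#' the TF it must reach, so every planted source-TF shortest path has length
#' one and cannot be perturbed by the random background graph; each drug's
#' targets are drawn from the Pnet node set (its planted overlap) and its
#' profile activates one dedicated non-patient TF (its non-overlap part).
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Directory to write into (created if needed).
#' @return Invisibly, a list of class `fixture_truth`: `spec`, `dir`,
#'   `paths` (named file paths), `case_ids`/`control_ids`,
#'   `activated_tfs` (planted patient TF set), `pnet_nodes` (planted Pnet
#'   node set), `drugs` (tibble `drug_id`, `drug_name`, `fraction`,
#'   `n_overlap`, `growth_rate`, `active`) and `active_cutoff` (the declared
#'   growth-rate cutoff, 50, separating planted actives).
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(spec$seed)

  width <- max(3L, nchar(as.character(spec$n_genes)))
  genes <- sprintf("G%0*d", width, seq_len(spec$n_genes))
  tf_genes <- genes[seq_len(spec$n_tfs)]
  off <- spec$n_tfs
  target_blocks <- lapply(seq_len(spec$n_tfs), function(i) {
    genes[off + (i - 1L) * spec$n_targets_per_tf + seq_len(spec$n_targets_per_tf)]
  })
  off <- off + spec$n_tfs * spec$n_targets_per_tf
  disease_genes <- genes[off + seq_len(spec$n_disease_genes)]
  off <- off + spec$n_disease_genes
  filler_targets <- genes[off + seq_len(spec$n_drugs)]

  patient_tfs <- tf_genes[seq_len(spec$planted_activated_tfs)]
  drug_tfs <- tf_genes[spec$planted_activated_tfs + seq_len(spec$n_drugs)]
  n_boost <- min(3L, spec$n_targets_per_tf)
  boosted <- lapply(target_blocks, function(b) b[seq_len(n_boost)])
  names(boosted) <- tf_genes

  tfmap <- tibble::tibble(
    tf = rep(tf_genes, each = spec$n_targets_per_tf),
    target = unlist(target_blocks))

  # Background random graph over all genes, vertex identity shuffled so graph
  # structure is independent of the role allocation above.
  m <- max(1L, ceiling(spec$edge_density / 2))
  bg <- if (spec$graph_model == "pa") {
    igraph::sample_pa(spec$n_genes, m = m, directed = FALSE)
  } else {
    igraph::sample_gnm(spec$n_genes, ceiling(spec$n_genes * spec$edge_density / 2))
  }
  perm <- sample(genes)
  bg_edges <- igraph::as_edgelist(bg, names = FALSE)
  edges <- tibble::tibble(from = perm[bg_edges[, 1]], to = perm[bg_edges[, 2]])
  # Planted direct source-TF edges: patient sources to patient TFs ...
  planted_edges <- tidyr::expand_grid(from = disease_genes, to = patient_tfs)

  # Pnet node set is fully determined by the direct edges.
  pnet_nodes <- sort(unique(c(disease_genes, patient_tfs,
                              unlist(boosted[patient_tfs]))))
  p_size <- length(pnet_nodes)

  drug_ids <- sprintf("D%02d", seq_len(spec$n_drugs))
  drug_names <- sprintf("Drug%02d", seq_len(spec$n_drugs))
  n_overlap <- round(spec$planted_overlap_fractions * p_size)
  drug_targets <- lapply(seq_len(spec$n_drugs), function(i) {
    tg <- if (n_overlap[i] > 0) sort(sample(pnet_nodes, n_overlap[i])) else character()
    if (length(tg) == 0) tg <- filler_targets[i]
    tg
  })
  drug_edges <- purrr::map2_dfr(drug_targets, drug_tfs, function(tg, u) {
    tibble::tibble(from = tg, to = u)
  })
  interactome <- as_interactome(dplyr::bind_rows(edges, planted_edges, drug_edges))

  # Case/control expression: 2 + 2 samples; boosted targets of patient TFs at
  # fold change 4, everything else at 1, with multiplicative log-normal noise.
  case_ids <- c("case_1", "case_2")
  control_ids <- c("control_1", "control_2")
  base <- 10
  fc <- stats::setNames(rep(1, spec$n_genes), genes)
  fc[unlist(boosted[patient_tfs])] <- 4
  noise <- function(n) exp(stats::rnorm(n, 0, spec$noise_sd))
  expr <- tibble::tibble(
    gene = genes,
    case_1 = base * fc * noise(spec$n_genes),
    case_2 = base * fc * noise(spec$n_genes),
    control_1 = base * noise(spec$n_genes),
    control_2 = base * noise(spec$n_genes))

  # Instance z-score profiles: each drug's instances put z = 4 on the boosted
  # targets of the drug's dedicated TF, ~0 elsewhere.
  cell_pool <- c("A549", "MCF7", "HT29")
  meta <- tidyr::expand_grid(i = seq_len(spec$n_drugs),
                             j = seq_len(spec$n_instances_per_drug)) |>
    dplyr::mutate(instance_id = sprintf("%s_inst%02d", drug_ids[.data$i], .data$j),
                  drug_id = drug_ids[.data$i],
                  cell_line = cell_pool[(.data$j - 1L) %% length(cell_pool) + 1L],
                  time_h = 24, dose = "10 uM") |>
    dplyr::select("instance_id", "drug_id", "cell_line", "time_h", "dose")
  zmat <- matrix(stats::rnorm(spec$n_genes * nrow(meta), 0, spec$noise_sd),
                 nrow = spec$n_genes,
                 dimnames = list(genes, meta$instance_id))
  for (i in seq_len(spec$n_drugs)) {
    ids <- meta$instance_id[meta$drug_id == drug_ids[i]]
    zmat[boosted[[drug_tfs[i]]], ids] <- zmat[boosted[[drug_tfs[i]]], ids] + 4
  }

  growth <- 100 - 100 * spec$planted_overlap_fractions +
    stats::rnorm(spec$n_drugs, 0, 10 * spec$noise_sd)
  screening <- tibble::tibble(drug_name = drug_names, growth_rate = growth)

  catalog <- tibble::tibble(
    drug_id = rep(drug_ids, lengths(drug_targets)),
    drug_name = rep(drug_names, lengths(drug_targets)),
    target = unlist(drug_targets))

  paths <- c(
    interactome = file.path(out_dir, "interactome.tsv"),
    tf_targets = file.path(out_dir, "tf_targets.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    disease_genes = file.path(out_dir, "disease_genes.txt"),
    drug_catalog = file.path(out_dir, "drug_catalog.tsv"),
    instance_zscores = file.path(out_dir, "instance_zscores.tsv"),
    instance_metadata = file.path(out_dir, "instance_metadata.tsv"),
    screening = file.path(out_dir, "screening.tsv"),
    ground_truth_drugs = file.path(out_dir, "ground_truth_drugs.tsv"),
    ground_truth_tfs = file.path(out_dir, "ground_truth_tfs.txt"))

  readr::write_tsv(interactome, paths[["interactome"]], col_names = FALSE, progress = FALSE)
  readr::write_tsv(tfmap, paths[["tf_targets"]], progress = FALSE)
  readr::write_tsv(expr, paths[["expression"]], progress = FALSE)
  readr::write_lines(disease_genes, paths[["disease_genes"]])
  readr::write_tsv(catalog, paths[["drug_catalog"]], progress = FALSE)
  readr::write_tsv(tibble::as_tibble(zmat, rownames = "gene"),
                   paths[["instance_zscores"]], progress = FALSE)
  readr::write_tsv(meta, paths[["instance_metadata"]], progress = FALSE)
  readr::write_tsv(screening, paths[["screening"]], progress = FALSE)

  # Declared fixture convention: drugs at or below growth rate 50 are the
  # planted actives (noise-free, exactly the drugs with fraction >= 0.5).
  truth_drugs <- tibble::tibble(
    drug_id = drug_ids, drug_name = drug_names,
    fraction = spec$planted_overlap_fractions,
    n_overlap = as.integer(n_overlap),
    growth_rate = growth,
    active = growth <= 50)
  readr::write_tsv(truth_drugs, paths[["ground_truth_drugs"]], progress = FALSE)
  readr::write_lines(patient_tfs, paths[["ground_truth_tfs"]])

  invisible(structure(
    list(spec = spec, dir = out_dir, paths = as.list(paths),
         case_ids = case_ids, control_ids = control_ids,
         activated_tfs = patient_tfs, pnet_nodes = pnet_nodes,
         drugs = truth_drugs, active_cutoff = 50),
    class = "fixture_truth"))
}

#' @export
print.fixture_truth <- function(x, ...) {
  cat(sprintf("<fixture_truth> %d genes, %d drugs, |Pnet| = %d, seed %d, dir %s\n",
              x$spec$n_genes, x$spec$n_drugs, length(x$pnet_nodes),
              x$spec$seed, x$dir))
  invisible(x)
}
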