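#' Filter drug instances by treatment time, dose and cell line
#'
#' Keeps the instances whose metadata match the stated treatment time and
#' dose label, optionally excluding a cell line (typically the patient's own
#' line, to avoid scoring a drug against profiles measured on the very line
#' being predicted).
#'
#' @param profiles An `instance_profiles` object.
#' @param time_h Treatment time in hours to keep (default 24); `NULL` keeps
#'   all times.
#' @param dose_label Dose label to keep, compared verbatim (default
#'   `"10 uM"`); `NULL` keeps all doses.
#' @param exclude_cell_line Cell line to drop, or `NULL` (default) to keep
#'   all lines.
#' @return A filtered `instance_profiles`; its `n_dropped` attribute counts
#'   the removed instances.
#' @export
filter_instances <- function(profiles, time_h = 24, dose_label = "10 uM",
                             exclude_cell_line = NULL) {
  stopifnot(inherits(profiles, "instance_profiles"))
  meta <- profiles$instances
  keep <- rep(TRUE, nrow(meta))
  if (!is.null(time_h)) keep <- keep & meta$time_h == time_h
  if (!is.null(dose_label)) keep <- keep & meta$dose == dose_label
  if (!is.null(exclude_cell_line)) keep <- keep & meta$cell_line != exclude_cell_line
  kept <- meta[keep, ]
  out <- new_instance_profiles(
    kept,
    dplyr::filter(profiles$profiles, .data$instance_id %in% kept$instance_id))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Node overlap between two signaling networks
#'
#' The number of gene symbols present in both networks; roles are ignored and
#' a gene counts once however many roles it carries.
#'
#' @param moanet,pnet `signaling_network` objects.
#' @return Integer overlap count.
#' @export
node_overlap <- function(moanet, pnet) {
  stopifnot(inherits(moanet, "signaling_network"), inherits(pnet, "signaling_network"))
  length(intersect(moanet$nodes$gene, pnet$nodes$gene))
}

#' Sensitivity score of one drug
#'
#' The drug's score is the average, over its instances, of the node overlap
#' between the instance's MoAnet and the patient Pnet, normalized by the Pnet
#' node count:
#' \deqn{S_i = \frac{1}{N_i} \sum_j \frac{|MoAnet_i^j \cap Pnet|}{|Pnet|}}
#' so the score always lies in \[0, 1\].
#'
#' @param drug_id Drug identifier.
#' @param instance_networks List of the drug's per-instance
#'   `signaling_network` objects (at least one).
#' @param pnet The patient `signaling_network`.
#' @return A one-row tibble: `drug_id`, `score`, `n_instances`, and a
#'   `per_instance` list-column holding a tibble
#'   (`instance_id`, `overlap`) for the drug's instances.
#' @export
sensitivity_score <- function(drug_id, instance_networks, pnet) {
  stopifnot(inherits(pnet, "signaling_network"))
  if (length(instance_networks) == 0) stop("at least one instance network is required")
  p_size <- nrow(pnet$nodes)
  if (p_size == 0) stop("empty Pnet")
  overlaps <- vapply(instance_networks, node_overlap, numeric(1), pnet = pnet)
  ids <- vapply(instance_networks, function(n) n$provenance$instance_id %||% NA_character_,
                character(1))
  tibble::tibble(
    drug_id = drug_id,
    score = sum(overlaps / p_size) / length(overlaps),
    n_instances = length(overlaps),
    per_instance = list(tibble::tibble(instance_id = ids, overlap = as.integer(overlaps))))
}

#' Score every drug from a table of instance MoAnets
#'
#' @param moanets Tibble from [build_moanet_all()] (columns `drug_id`,
#'   `instance_id`, `network`).
#' @param pnet The patient `signaling_network`.
#' @return A tibble with one row per drug (`drug_id`, `score`, `n_instances`,
#'   `per_instance`), unsorted; pass to [rank_drugs()].
#' @export
score_drugs <- function(moanets, pnet) {
  stopifnot(all(c("drug_id", "network") %in% names(moanets)))
  if (nrow(moanets) == 0) stop("no instance networks to score")
  moanets |>
    dplyr::group_by(.data$drug_id) |>
    dplyr::group_map(function(rows, key) {
      sensitivity_score(key$drug_id, rows$network, pnet)
    }) |>
    dplyr::bind_rows()
}

#' Rank drugs by decreasing sensitivity score
#'
#' @param scores Tibble with at least `drug_id` and `score` (one row per
#'   drug, ids unique).
#' @return The input sorted by decreasing score (ties broken by drug id,
#'   ascending) with a `rank` column 1..n prepended; class `ranked_drugs`.
#' @export
rank_drugs <- function(scores) {
  stopifnot(is.data.frame(scores), all(c("drug_id", "score") %in% names(scores)),
            nrow(scores) >= 1)
  if (anyDuplicated(scores$drug_id)) {
    stop("duplicate drug id(s) in score table: ",
         paste(unique(scores$drug_id[duplicated(scores$drug_id)]), collapse = ", "))
  }
  out <- scores |>
    dplyr::arrange(dplyr::desc(.data$score), .data$drug_id) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
  class(out) <- c("ranked_drugs", class(tibble::tibble()))
  out
}

#' One-row summary of a drug ranking
#' @param x A `ranked_drugs` tibble.
#' @param ... Unused.
#' @return Tibble with drug count and score range.
#' @export
glance.ranked_drugs <- function(x, ...) {
  tibble::tibble(n_drugs = nrow(x), top_score = max(x$score), min_score = min(x$score))
}
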