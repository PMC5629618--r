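#' Per-gene fold change between case and control samples
#'
#' For every gene, the fold change is the mean expression over case samples
#' divided by the mean over control samples (a plain ratio, not a log-ratio).
#' Genes whose control mean is zero have no defined ratio; they are dropped
#' and counted in the `n_dropped` attribute.
#'
#' @param expr Long-form expression tibble from [read_expression_table()]
#'   (columns `gene`, `sample`, `group`, `value`).
#' @return A tibble with columns `gene` and `value` (the fold change), sorted
#'   by gene, with attributes `mode = "ratio"` and `n_dropped`.
#' @export
compute_fold_change <- function(expr) {
  stopifnot(all(c("gene", "group", "value") %in% names(expr)))
  if (!any(expr$group == "case") || !any(expr$group == "control")) {
    stop("need at least one case and one control sample")
  }
  means <- expr |>
    dplyr::summarise(m = mean(.data$value), .by = c("gene", "group")) |>
    tidyr::pivot_wider(names_from = "group", values_from = "m")
  if (!all(c("case", "control") %in% names(means))) stop("missing case or control group")
  means <- dplyr::filter(means, !is.na(.data$case), !is.na(.data$control))
  if (nrow(means) == 0) stop("no genes measured in both case and control groups")
  n_zero <- sum(means$control == 0)
  out <- means |>
    dplyr::filter(.data$control != 0) |>
    dplyr::transmute(gene = .data$gene, value = .data$case / .data$control) |>
    dplyr::arrange(.data$gene)
  fc_profile(out, mode = "ratio", n_dropped = n_zero)
}

#' Build a profile tibble in the package's fold-change layout
#'
#' Internal-style constructor also useful for turning one drug instance's
#' z-scores into the profile shape the TF-activation functions expect.
#'
#' @param values A data frame with columns `gene` and `value`, or a named
#'   numeric vector.
#' @param mode `"ratio"` (case/control expression ratio) or `"zscore"`
#'   (standardized differential expression of a drug instance).
#' @param n_dropped Count of genes excluded upstream (zero control mean).
#' @return A tibble `gene`/`value` with attributes `mode` and `n_dropped`.
#' @export
fc_profile <- function(values, mode = c("ratio", "zscore"), n_dropped = 0L) {
  mode <- match.arg(mode)
  if (!is.data.frame(values)) {
    values <- tibble::tibble(gene = names(values), value = unname(values))
  }
  stopifnot(all(c("gene", "value") %in% names(values)))
  if (anyDuplicated(values$gene)) stop("duplicate gene in profile")
  if (any(!is.finite(values$value))) stop("non-finite profile value")
  if (mode == "ratio" && any(values$value < 0)) stop("negative fold-change ratio")
  out <- tibble::as_tibble(values[, c("gene", "value")])
  attr(out, "mode") <- mode
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Profile mode ("ratio" or "zscore")
#' @param profile A profile tibble (see [fc_profile()]).
#' @return The mode string; `"ratio"` if the attribute is absent.
#' @export
fc_mode <- function(profile) attr(profile, "mode") %||% "ratio"

#' Activation score of one transcription factor
#'
#' The activation score of a TF is the mean fold change of its three target
#' genes with the greatest fold change when at least three of its targets are
#' measured in the profile, or the mean over all measured targets when only
#' one or two are. A TF with no measured target has no score (`NA`).
#'
#' @param tf A TF gene symbol present in `tfmap`.
#' @param profile Profile tibble (`gene`, `value`) from
#'   [compute_fold_change()] or [fc_profile()].
#' @param tfmap TF-target tibble (`tf`, `target`) from [read_tf_targets()].
#' @return A single numeric score, or `NA_real_` if none of the TF's targets
#'   is measured.
#' @export
activation_score <- function(tf, profile, tfmap) {
  stopifnot(length(tf) == 1)
  if (!tf %in% tfmap$tf) stop("unknown transcription factor: ", tf)
  targets <- tfmap$target[tfmap$tf == tf]
  vals <- profile$value[match(targets, profile$gene)]
  vals <- vals[!is.na(vals)]
  if (length(vals) == 0) return(NA_real_)
  if (length(vals) >= 3) mean(sort(vals, decreasing = TRUE)[1:3]) else mean(vals)
}

#' Identify activated transcription factors
#'
#' Scores every TF in the map against the profile (see [activation_score()])
#' and calls a TF activated when its score is at or above the threshold
#' (inclusive). TFs with none of their targets measured are skipped and
#' counted in the `n_skipped` attribute.
#'
#' @param profile Profile tibble (`gene`, `value`).
#' @param tfmap TF-target tibble (`tf`, `target`).
#' @param threshold Activation cutoff on the score; default 2.0.
#' @return A tibble with one row per scored TF: `tf`, `score`, `n_available`
#'   (measured targets), `contributing_targets` (comma-joined genes averaged;
#'   ties at the third-largest value broken by gene symbol) and `activated`.
#'   Sorted by decreasing score, then TF symbol.
#' @export
identify_activated_tfs <- function(profile, tfmap, threshold = 2.0) {
  stopifnot(threshold > 0)
  if (nrow(tfmap) == 0) stop("empty TF-target map")
  per_tf <- tfmap |>
    dplyr::inner_join(profile, by = c(target = "gene")) |>
    dplyr::arrange(dplyr::desc(.data$value), .data$target)
  scored <- per_tf |>
    dplyr::summarise(
      n_available = dplyr::n(),
      score = if (dplyr::n() >= 3) mean(.data$value[1:3]) else mean(.data$value),
      contributing_targets = paste(.data$target[seq_len(min(3, dplyr::n()))], collapse = ","),
      .by = "tf") |>
    dplyr::mutate(activated = .data$score >= threshold) |>
    dplyr::arrange(dplyr::desc(.data$score), .data$tf) |>
    dplyr::select("tf", "score", "n_available", "contributing_targets", "activated")
  attr(scored, "n_skipped") <- dplyr::n_distinct(tfmap$tf) - nrow(scored)
  attr(scored, "threshold") <- threshold
  scored
}

#' Up-regulated target genes of the activated TFs
#'
#' The union, over all activated TFs, of their target genes whose profile
#' value meets the up-regulation cutoff (inclusive).
#'
#' @param activated TF activation tibble from [identify_activated_tfs()]
#'   (only rows with `activated == TRUE` are used), or a character vector of
#'   activated TF symbols.
#' @param profile Profile tibble (`gene`, `value`).
#' @param tfmap TF-target tibble (`tf`, `target`).
#' @param fc_threshold Up-regulation cutoff; default 2.0.
#' @return Sorted character vector of up-regulated target gene symbols.
#' @export
upregulated_targets <- function(activated, profile, tfmap, fc_threshold = 2.0) {
  stopifnot(fc_threshold > 0)
  tfs <- if (is.data.frame(activated)) activated$tf[activated$activated] else activated
  if (length(tfs) == 0) return(character())
  hits <- tfmap |>
    dplyr::filter(.data$tf %in% tfs) |>
    dplyr::inner_join(profile, by = c(target = "gene")) |>
    dplyr::filter(.data$value >= fc_threshold)
  sort(unique(hits$target))
}

#' TF-to-target regulatory pairs behind an up-regulated gene set
#'
#' Helper used when assembling networks: which activated TF regulates which
#' up-regulated target.
#'
#' @inheritParams upregulated_targets
#' @param targets Character vector of up-regulated targets (from
#'   [upregulated_targets()]).
#' @return A tibble (`tf`, `target`) restricted to activated TFs and the
#'   given targets.
#' @export
regulatory_pairs <- function(activated, targets, tfmap) {
  tfs <- if (is.data.frame(activated)) activated$tf[activated$activated] else activated
  tfmap |>
    dplyr::filter(.data$tf %in% tfs, .data$target %in% targets) |>
    dplyr::distinct() |>
    dplyr::arrange(.data$tf, .data$target)
}
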