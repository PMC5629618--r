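#' Growth-rate cutoff for calling screened drugs active
#'
#' Drugs that reduce the mean growth rate to at least `k_sd` standard
#' deviations below the screen-wide average are considered active; this
#' returns that cutoff, `mean(rates) - k_sd * sd(rates)`.
#'
#' @param growth_rates Numeric vector of per-drug mean growth rates (at least
#'   two values).
#' @param k_sd Number of standard deviations below the mean (default 1.5).
#' @param sd_type `"sample"` (n-1 denominator, default) or `"population"`.
#' @return The numeric cutoff.
#' @export
active_threshold <- function(growth_rates, k_sd = 1.5, sd_type = c("sample", "population")) {
  sd_type <- match.arg(sd_type)
  if (length(growth_rates) < 2) stop("need at least two growth rates")
  s <- stats::sd(growth_rates)
  if (sd_type == "population") s <- s * sqrt((length(growth_rates) - 1) / length(growth_rates))
  mean(growth_rates) - k_sd * s
}

#' Label screening-active drugs
#'
#' @param screen Screening tibble (`drug_name`, `growth_rate`), e.g. from
#'   [read_screening_table()].
#' @param cutoff Growth-rate cutoff; drugs at or below it (inclusive) are
#'   active. Typically from [active_threshold()].
#' @return A list of class `active_labels`: `actives` (sorted drug names),
#'   `cutoff`, `n_total` (screened drugs).
#' @export
classify_actives <- function(screen, cutoff) {
  stopifnot(is.finite(cutoff), all(c("drug_name", "growth_rate") %in% names(screen)))
  structure(list(actives = sort(screen$drug_name[screen$growth_rate <= cutoff]),
                 cutoff = cutoff,
                 n_total = nrow(screen)),
            class = "active_labels")
}

#' @export
print.active_labels <- function(x, ...) {
  cat(sprintf("<active_labels> %d of %d screened drugs active (growth rate <= %.4g)\n",
              length(x$actives), x$n_total, x$cutoff))
  invisible(x)
}

#' Top-k enrichment of active drugs in a ranking
#'
#' For each cutoff k, counts the labeled actives among ranks 1..k and
#' compares with the expectation under uniformly random selection
#' (`k * a / n`, the hypergeometric mean, where a actives sit among the n
#' ranked drugs).
#'
#' @param ranked A `ranked_drugs` tibble from [rank_drugs()]; drug identity
#'   for label matching is `drug_name` if present, else `drug_id`.
#' @param labels An `active_labels` object (see [classify_actives()]) or a
#'   character vector of active drug names.
#' @param ks Cutoffs, sorted ascending, each at most the ranking length.
#' @return A tibble of class `enrichment_curve`: `k`, `n_active`, `fraction`
#'   (`n_active / k`), `expected_count`, `expected_fraction`; attributes
#'   `n_ranked` and `n_active_total` record the baseline inputs. Actives
#'   named in the labels but absent from the ranking are recorded in the
#'   `unmatched` attribute and excluded from the baseline.
#' @export
topk_metrics <- function(ranked, labels, ks = c(30, 50, 70, 100)) {
  stopifnot(is.data.frame(ranked), "rank" %in% names(ranked))
  actives <- if (inherits(labels, "active_labels")) labels$actives else labels
  actives <- trimws(actives)
  if (is.unsorted(ks)) stop("ks must be sorted ascending")
  too_big <- ks[ks > nrow(ranked)]
  if (length(too_big) > 0) {
    stop("k = ", too_big[1], " exceeds the ranking length (", nrow(ranked), ")")
  }
  name_col <- if ("drug_name" %in% names(ranked)) "drug_name" else "drug_id"
  names_ranked <- trimws(ranked[[name_col]][order(ranked$rank)])
  is_active <- names_ranked %in% actives
  unmatched <- setdiff(actives, names_ranked)
  if (length(unmatched) > 0) {
    warning(length(unmatched), " active drug(s) not present in the ranking")
  }
  n <- length(names_ranked)
  a <- sum(is_active)
  out <- tibble::tibble(
    k = as.integer(ks),
    n_active = vapply(ks, function(k) sum(is_active[seq_len(k)]), numeric(1)),
    fraction = .data$n_active / .data$k,
    expected_count = .data$k * a / n,
    expected_fraction = a / n)
  class(out) <- c("enrichment_curve", class(tibble::tibble()))
  attr(out, "n_ranked") <- n
  attr(out, "n_active_total") <- a
  attr(out, "unmatched") <- unmatched
  out
}

#' Expected actives under uniformly random selection
#'
#' Picking k of n drugs uniformly at random, of which a are active, recovers
#' on average `k * a / n` actives (the hypergeometric mean); the expected
#' active fraction among the picks is `a / n` regardless of k.
#'
#' @param n_total Number of ranked drugs n.
#' @param n_active Number of actives a among them.
#' @param k Selection size.
#' @return A one-row tibble (`expected_count`, `expected_fraction`).
#' @export
random_expectation <- function(n_total, n_active, k) {
  if (!(n_active >= 0 && n_active <= n_total)) stop("need 0 <= n_active <= n_total")
  if (!(k > 0 && k <= n_total)) stop("need 0 < k <= n_total")
  tibble::tibble(expected_count = k * n_active / n_total,
                 expected_fraction = n_active / n_total)
}

#' Plot an enrichment curve
#'
#' Bar panels of the active-drug fraction and count among the top-k ranked
#' drugs, with the random-selection expectation alongside.
#'
#' @param object An `enrichment_curve` tibble from [topk_metrics()].
#' @param ... Unused.
#' @return A ggplot object with two facets (fraction and count).
#' @export
autoplot.enrichment_curve <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(k = object$k, panel = "fraction of active drugs",
                   method = "ranked", value = object$fraction),
    tibble::tibble(k = object$k, panel = "fraction of active drugs",
                   method = "random", value = object$expected_fraction),
    tibble::tibble(k = object$k, panel = "number of active drugs",
                   method = "ranked", value = object$n_active),
    tibble::tibble(k = object$k, panel = "number of active drugs",
                   method = "random", value = object$expected_count))
  ggplot2::ggplot(long, ggplot2::aes(x = factor(.data$k), y = .data$value,
                                     fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~panel, scales = "free_y") +
    ggplot2::labs(x = "top-k ranked drugs", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
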