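#' Omit one marker from a superset frequency table
#'
#' Deletes the call at `index` from every superset and merges rows whose
#' reduced texts coincide, summing per-group counts. This is the elementary
#' "knockout" move: supersets that differed only at the omitted SNP collapse
#' to a single node, so the node count can only shrink while every individual
#' is conserved.
#'
#' @param freq A `superset_freq`.
#' @param index Marker position to remove (1-based).
#' @return A `superset_freq` over the remaining M-1 markers.
#' @export
omit_marker <- function(freq, index) {
  stopifnot(inherits(freq, "superset_freq"))
  markers <- attr(freq, "markers")
  m <- length(strsplit(freq$superset[[1]], " ", fixed = TRUE)[[1]])
  if (m < 2) stop("cannot omit a marker from a 1-marker table", call. = FALSE)
  if (index < 1 || index > m) {
    stop("marker index out of range: ", index, call. = FALSE)
  }
  groups <- attr(freq, "groups")
  calls <- strsplit(freq$superset, " ", fixed = TRUE)
  reduced <- vapply(calls, function(cc) paste(cc[-index], collapse = " "), "")
  out <- tibble::as_tibble(freq)
  out$superset <- reduced
  out <- out |>
    dplyr::group_by(.data$superset) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(groups), sum),
                     .groups = "drop")
  out <- out[order_c(out$superset), , drop = FALSE]
  new_superset_freq(out, groups = groups,
                    markers = if (!is.null(markers)) markers[-index])
}

#' Leave-one-SNP-out knockout scan
#'
#' For each marker in turn: rebuild the network without it, partition the
#' collapsed nodes, and record how the focal-group-specific and
#' reference-group-specific node counts (and individuals-basis fractions)
#' restructure relative to the full M-marker network. A Yates-corrected
#' chi-square compares the (focal-specific, reference-specific) node counts
#' of each reduced network against the full network's.
#'
#' @param cohort A `geno_cohort` with at least two markers and two groups.
#' @param focal Focal group label (e.g. the case group).
#' @param reference Reference group label (e.g. the control group).
#' @return A `knockout_scan` object: `results` (one tibble row per omitted
#'   marker with `n_nodes` = N', class counts, fractions, `statistic`,
#'   `p.value`), `baseline` (the full-network row), plus the scan
#'   configuration.
#' @examples
#' cohort <- generate_cohort(synth_preset("acs-like", seed = 1))
#' scan <- knockout_scan(cohort, focal = "case", reference = "control")
#' rank_markers(scan)
#' @export
knockout_scan <- function(cohort, focal, reference) {
  groups <- group_levels(cohort)
  if (length(groups) < 2) stop("need at least 2 groups", call. = FALSE)
  if (!all(c(focal, reference) %in% groups) || focal == reference) {
    stop("focal and reference must be distinct declared groups",
         call. = FALSE)
  }
  markers <- marker_names(cohort)
  if (length(markers) < 2) stop("need at least 2 markers", call. = FALSE)
  freq <- superset_table(cohort)
  baseline <- knockout_row(freq, focal, reference)
  results <- purrr::map_dfr(seq_along(markers), function(i) {
    row <- knockout_row(omit_marker(freq, i), focal, reference)
    test <- tryCatch(
      knockout_association_test(
        c(baseline$focal_specific, baseline$reference_specific),
        c(row$focal_specific, row$reference_specific)),
      error = function(e) tibble::tibble(statistic = NA_real_,
                                         p.value = NA_real_))
    dplyr::bind_cols(
      tibble::tibble(marker = markers[i], index = i),
      row, test[c("statistic", "p.value")])
  })
  structure(
    list(results = results,
         baseline = dplyr::bind_cols(
           tibble::tibble(marker = "(none)", index = NA_integer_), baseline),
         focal = focal, reference = reference,
         markers = markers, groups = groups),
    class = "knockout_scan"
  )
}

# Summary row for one network configuration: node counts by specificity and
# individuals-basis specific fractions.
knockout_row <- function(freq, focal, reference) {
  net <- build_network(freq)
  part <- partition_nodes(net)
  focal_nodes <- part$superset[part$membership == focal]
  ref_nodes <- part$superset[part$membership == reference]
  w <- net$edges$weight
  tibble::tibble(
    n_nodes = length(net$nodes),
    focal_specific = length(focal_nodes),
    reference_specific = length(ref_nodes),
    shared = length(net$nodes) - length(focal_nodes) - length(ref_nodes),
    focal_fraction_ind = sum(w[net$edges$superset %in% focal_nodes]) / sum(w),
    reference_fraction_ind = sum(w[net$edges$superset %in% ref_nodes]) / sum(w)
  )
}

#' @export
print.knockout_scan <- function(x, ...) {
  cat("Knockout scan (focal = ", x$focal, ", reference = ", x$reference,
      ")\n", sep = "")
  cat("Baseline: N = ", x$baseline$n_nodes, ", focal-specific = ",
      x$baseline$focal_specific, ", reference-specific = ",
      x$baseline$reference_specific, "\n\n", sep = "")
  print(x$results)
  invisible(x)
}

#' @rdname knockout_scan
#' @param x A `knockout_scan`.
#' @param ... Unused.
#' @export
tidy.knockout_scan <- function(x, ...) x$results

#' @rdname knockout_scan
#' @export
glance.knockout_scan <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(focal = x$focal, reference = x$reference,
                   n_markers = length(x$markers)),
    x$baseline[setdiff(names(x$baseline), c("marker", "index"))])
}

#' Rank markers from a knockout scan
#'
#' Rank 1 is the strongest risk candidate: the marker whose omission leaves
#' the smallest focal-specific node count (`"case_specific_nodes"`) or the
#' smallest focal/reference specific-node ratio (`"case_control_ratio"`).
#' Ties are broken by marker input order. When the reference-specific count
#' is zero under the ratio criterion, 0.5 is added to both counts
#' (continuity rule) so the ranking stays total.
#'
#' @param scan A `knockout_scan`.
#' @param criterion Ranking criterion.
#' @return Tibble with columns `rank`, `marker`, `value` (the criterion value
#'   after that marker's omission).
#' @export
rank_markers <- function(scan,
                         criterion = c("case_specific_nodes",
                                       "case_control_ratio")) {
  stopifnot(inherits(scan, "knockout_scan"))
  criterion <- match.arg(criterion)
  res <- scan$results
  value <- if (criterion == "case_specific_nodes") {
    as.numeric(res$focal_specific)
  } else {
    ifelse(res$reference_specific == 0,
           (res$focal_specific + 0.5) / (res$reference_specific + 0.5),
           res$focal_specific / res$reference_specific)
  }
  ord <- order(value, res$index)
  tibble::tibble(rank = seq_along(ord),
                 marker = res$marker[ord],
                 value = value[ord])
}

#' Chi-square test for knockout restructuring
#'
#' Yates-corrected chi-square (df = 1) on the 2x2 table
#' `[full vs omitted] x [focal-specific vs reference-specific]` node counts,
#' testing whether one marker's omission changed the case/control-specific
#' composition of the network. Note this contrasts node counts, the simplest
#' table consistent with a per-omission restructuring test; it is an
#' interpretation, reported as such.
#'
#' @param full Length-2 numeric: (focal-specific, reference-specific) node
#'   counts of the full network.
#' @param omitted Same for the reduced network.
#' @return Tibble with `statistic`, `df`, `p.value`.
#' @export
knockout_association_test <- function(full, omitted) {
  stopifnot(length(full) == 2, length(omitted) == 2)
  yates_chi_square(full[1], full[2], omitted[1], omitted[2])
}

#' Plot a knockout scan
#'
#' Bar chart of focal- and reference-specific node counts after each single
#' marker omission, with the full-network baseline as dashed lines.
#'
#' @param object A `knockout_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.knockout_scan <- function(object, ...) {
  long <- object$results |>
    dplyr::select("marker", "focal_specific", "reference_specific") |>
    tidyr::pivot_longer(-"marker", names_to = "class", values_to = "n_nodes")
  base <- tibble::tibble(
    class = c("focal_specific", "reference_specific"),
    n_nodes = c(object$baseline$focal_specific,
                object$baseline$reference_specific))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$marker, y = .data$n_nodes,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(data = base,
                        ggplot2::aes(yintercept = .data$n_nodes,
                                     colour = .data$class),
                        linetype = "dashed") +
    ggplot2::labs(x = "omitted marker", y = "group-specific supersets",
                  fill = NULL, colour = "full network")
}
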