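#' Genotype-shuffling null models
#'
#' Two seeded shuffles of a cohort that preserve per-marker summary counts
#' while destroying the joint (multi-SNP) genotype structure:
#'
#' * **Type 1 (genotype-count preserving):** each marker's column of
#'   genotype calls is independently permuted, so per-marker genotype counts
#'   are exactly conserved.
#' * **Type 2 (allele-count preserving):** each marker's alleles are pooled,
#'   permuted, and re-paired consecutively into new canonical calls, so
#'   per-marker allele counts are exactly conserved but genotype counts
#'   (hom/het composition) may change.
#'
#' With the default `within = "group"`, permutation happens inside each group
#' separately: per-group genotype (Type 1) or allele (Type 2) counts — and
#' hence every single-marker case-control chi-square — are exactly unchanged,
#' and only the combinatorial structure across SNPs is randomized. With
#' `within = "population"` the permutation runs across the pooled cohort,
#' which additionally destroys single-marker group association (a fully null
#' shuffle). Group labels stay attached to individuals in both variants.
#'
#' @param cohort A `geno_cohort`.
#' @param seed Integer seed; the same seed reproduces the same shuffle. The
#'   global RNG state is left untouched.
#' @param within `"group"` (default) or `"population"`; see Details.
#' @return A `geno_cohort` of the same shape.
#' @export
shuffle_type1 <- function(cohort, seed, within = c("group", "population")) {
  within <- match.arg(within)
  markers <- marker_names(cohort)
  out <- tibble::as_tibble(cohort)
  blocks <- shuffle_blocks(out$group, within)
  withr::with_seed(seed, {
    for (m in markers) {
      for (rows in blocks) out[[m]][rows] <- out[[m]][rows[sample.int(length(rows))]]
    }
  })
  new_geno_cohort(out, markers = markers, groups = group_levels(cohort),
                  dropped = attr(cohort, "dropped"))
}

#' @rdname shuffle_type1
#' @export
shuffle_type2 <- function(cohort, seed, within = c("group", "population")) {
  within <- match.arg(within)
  markers <- marker_names(cohort)
  out <- tibble::as_tibble(cohort)
  blocks <- shuffle_blocks(out$group, within)
  withr::with_seed(seed, {
    for (m in markers) {
      for (rows in blocks) {
        p <- length(rows)
        alleles <- unlist(strsplit(out[[m]][rows], "", fixed = TRUE),
                          use.names = FALSE)
        alleles <- alleles[sample.int(2 * p)]
        calls <- paste0(alleles[seq(1, 2 * p, by = 2)],
                        alleles[seq(2, 2 * p, by = 2)])
        out[[m]][rows] <- canonicalize_call(calls)
      }
    }
  })
  new_geno_cohort(out, markers = markers, groups = group_levels(cohort),
                  dropped = attr(cohort, "dropped"))
}

# Row-index blocks over which a shuffle permutes: one block per group, or a
# single pooled block.
shuffle_blocks <- function(group, within) {
  if (within == "group") {
    split(seq_along(group), group)
  } else {
    list(seq_along(group))
  }
}

#' Rank conservation under a shuffling null
#'
#' Computes the original knockout ranking, then for each of `n_reps`
#' replicates shuffles the cohort (Type 1 or Type 2), re-runs the knockout
#' scan and ranking, and scores for each original rank the percentage of
#' replicates in which the same marker occupies that exact rank.
#'
#' @inheritParams shuffle_type1
#' @param method `"type1"` (genotype-count preserving) or `"type2"`
#'   (allele-count preserving).
#' @param n_reps Number of shuffled replicates (1000 by default).
#' @param criterion Ranking criterion, see [rank_markers()].
#' @param focal,reference Group labels, see [knockout_scan()].
#' @param within Shuffle scope, see [shuffle_type1()].
#' @return A `rank_conservation` tibble: `rank`, `marker` (from the original
#'   data), `conservation_pct` in `[0, 100]`; attributes record the method
#'   and replicate count. Per-replicate substreams use `seed + replicate`.
#' @examples
#' \donttest{
#' cohort <- generate_cohort(synth_preset("acs-like", seed = 1))
#' rank_conservation(cohort, method = "type1", n_reps = 50, seed = 7,
#'                   focal = "case", reference = "control")
#' }
#' @export
rank_conservation <- function(cohort, method = c("type1", "type2"),
                              n_reps = 1000, seed = 1,
                              criterion = c("case_specific_nodes",
                                            "case_control_ratio"),
                              focal, reference,
                              within = c("group", "population")) {
  method <- match.arg(method)
  criterion <- match.arg(criterion)
  within <- match.arg(within)
  stopifnot(n_reps >= 1)
  shuffle <- if (method == "type1") shuffle_type1 else shuffle_type2
  orig <- rank_markers(knockout_scan(cohort, focal, reference), criterion)
  matches <- integer(nrow(orig))
  for (r in seq_len(n_reps)) {
    shuffled <- shuffle(cohort, seed = seed + r, within = within)
    rep_marker <- knockout_rank_fast(shuffled, criterion, focal, reference)
    matches <- matches + (rep_marker == orig$marker)
  }
  structure(
    tibble::tibble(rank = orig$rank, marker = orig$marker,
                   conservation_pct = 100 * matches / n_reps),
    method = method, n_reps = n_reps, criterion = criterion,
    class = c("rank_conservation", class(tibble::tibble()))
  )
}

# Lean knockout ranking used inside the replicate loop: for each omitted
# marker, counts supersets seen only in the focal / only in the reference
# group. Must agree with rank_markers(knockout_scan(...)) (property-tested).
knockout_rank_fast <- function(cohort, criterion, focal, reference) {
  markers <- marker_names(cohort)
  tb <- tibble::as_tibble(cohort)
  focal_rows <- tb$group == focal
  ref_rows <- tb$group == reference
  vals <- vapply(seq_along(markers), function(i) {
    ss <- superset_strings(cohort, markers[-i])
    in_focal <- unique(ss[focal_rows])
    in_ref <- unique(ss[ref_rows])
    not_focal <- unique(ss[!focal_rows])
    not_ref <- unique(ss[!ref_rows])
    fs <- length(setdiff(in_focal, not_focal))
    rs <- length(setdiff(in_ref, not_ref))
    if (criterion == "case_specific_nodes") {
      fs
    } else if (rs == 0) {
      (fs + 0.5) / (rs + 0.5)
    } else {
      fs / rs
    }
  }, numeric(1))
  markers[order(vals, seq_along(markers))]
}

#' @export
print.rank_conservation <- function(x, ...) {
  cat("# Rank conservation (", attr(x, "method"), ", ", attr(x, "n_reps"),
      " replicates, criterion = ", attr(x, "criterion"), ")\n", sep = "")
  NextMethod()
}

#' Plot rank conservation percentages
#'
#' @param object A `rank_conservation` table.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rank_conservation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- sprintf("%d (%s)", df$rank, df$marker)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$label, .data$rank),
                                   y = .data$conservation_pct)) +
    ggplot2::geom_col() +
    ggplot2::ylim(0, 100) +
    ggplot2::labs(x = "original rank (marker)", y = "rank conservation (%)")
}

#' Shared-superset segregation curve
#'
#' For each SNP subset size, repeatedly samples that many markers uniformly
#' without replacement (keeping original marker order within a subset),
#' builds genotype supersets per group, and counts supersets present in every
#' group (the "common" nodes). Past some subset size all supersets become
#' group-unique and the shared count sits at zero — the segregation point of
#' the panel.
#'
#' @inheritParams shuffle_type1
#' @param sizes Strictly increasing SNP subset sizes, each `<= M`.
#' @param n_reps Replicates per size (1000 by default). A size equal to M has
#'   no sampling freedom and is deterministic (sd 0).
#' @return A `segregation_curve` tibble: `n_snps`, `mean_shared`,
#'   `sd_shared`.
#' @export
segregation_curve <- function(cohort, sizes, n_reps = 1000, seed = 1) {
  markers <- marker_names(cohort)
  m <- length(markers)
  sizes <- as.integer(sizes)
  if (any(sizes < 1) || any(sizes > m)) {
    stop("subset sizes must be between 1 and M = ", m, call. = FALSE)
  }
  if (is.unsorted(sizes, strictly = TRUE)) {
    stop("sizes must be strictly increasing", call. = FALSE)
  }
  groups <- group_levels(cohort)
  tb <- tibble::as_tibble(cohort)
  group_rows <- lapply(groups, function(g) which(tb$group == g))
  out <- purrr::map_dfr(seq_along(sizes), function(si) {
    s <- sizes[si]
    shared <- withr::with_seed(seed + si, {
      vapply(seq_len(n_reps), function(r) {
        cols <- sort(sample.int(m, s))
        ss <- superset_strings(cohort, markers[cols])
        per_group <- lapply(group_rows, function(rows) unique(ss[rows]))
        length(Reduce(intersect, per_group))
      }, integer(1))
    })
    tibble::tibble(n_snps = s, mean_shared = mean(shared),
                   sd_shared = stats::sd(shared))
  })
  structure(out, n_reps = n_reps,
            class = c("segregation_curve", class(tibble::tibble())))
}

#' Plot a segregation curve
#'
#' Mean shared-superset count against SNP subset size with +/- 1 sd error
#' bars.
#'
#' @param object A `segregation_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.segregation_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_snps, y = .data$mean_shared)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean_shared - .data$sd_shared),
                   ymax = .data$mean_shared + .data$sd_shared),
      width = 2) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "number of SNPs in subset",
                  y = "supersets shared by all groups")
}
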