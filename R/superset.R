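#' Build the genotype-superset frequency table
#'
#' A genotype superset is the ordered, space-separated concatenation of an
#' individual's canonical calls across all M markers (e.g.
#' `"12 22 11 22 11"`). Locus order is significant: supersets are equal iff
#' their texts are equal. This tabulates how many individuals of each group
#' carry each distinct superset.
#'
#' @param cohort A `geno_cohort` from [parse_genotypes()].
#' @return A `superset_freq`: a tibble with a `superset` column and one
#'   integer count column per group (declared group order), rows in
#'   lexicographic superset order. Carries attributes `groups` and `markers`.
#' @examples
#' cohort <- generate_cohort(synth_preset("acs-like", seed = 1))
#' superset_table(cohort)
#' @export
superset_table <- function(cohort) {
  groups <- group_levels(cohort)
  ss <- superset_strings(cohort)
  tab <- table(superset = ss, group = factor(cohort$group, levels = groups))
  out <- tibble::as_tibble(as.data.frame.matrix(tab), rownames = "superset")
  out <- out[order_c(out$superset), , drop = FALSE]
  out[groups] <- lapply(out[groups], as.integer)
  new_superset_freq(out, groups = groups, markers = marker_names(cohort))
}

# Space-joined canonical call strings, one per individual.
superset_strings <- function(cohort, markers = marker_names(cohort)) {
  do.call(paste, c(as.list(tibble::as_tibble(cohort)[markers]), sep = " "))
}

# Locale-independent lexicographic ordering (calls are digits and spaces).
order_c <- function(x) order(x, method = "radix")

new_superset_freq <- function(x, groups, markers = NULL) {
  structure(
    tibble::as_tibble(x),
    groups = groups,
    markers = markers,
    class = c("superset_freq", class(tibble::tibble()))
  )
}

#' @export
print.superset_freq <- function(x, ...) {
  cat("# Superset frequency table: ", nrow(x), " distinct supersets, groups: ",
      paste(attr(x, "groups"), collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' @export
`[.superset_freq` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("superset", attr(x, "groups")) %in% names(out))) {
    attr(out, "groups") <- attr(x, "groups")
    attr(out, "markers") <- attr(x, "markers")
    class(out) <- class(x)
  }
  out
}

#' Number of possible genotype supersets for M biallelic markers
#'
#' Each marker has three canonical genotypes, so M markers admit `3^M`
#' distinct supersets (243 for M = 5). The count is exact: a double for
#' M <= 33 (where IEEE doubles hold it exactly), otherwise a decimal string
#' computed with digit-vector arithmetic.
#'
#' @param m Number of markers (non-negative integer).
#' @return Exact `3^m` as numeric (m <= 33) or character (m > 33).
#' @examples
#' count_possible_supersets(5) # 243
#' @export
count_possible_supersets <- function(m) {
  if (length(m) != 1 || is.na(m) || m < 0 || m != floor(m)) {
    stop("m must be a single non-negative integer", call. = FALSE)
  }
  if (m <= 33) return(3^m)
  # little-endian decimal digits; multiply by 3, m times
  digits <- 1L
  for (i in seq_len(m)) {
    prod <- digits * 3L
    carry <- 0L
    for (d in seq_along(prod)) {
      v <- prod[d] + carry
      prod[d] <- v %% 10L
      carry <- v %/% 10L
    }
    while (carry > 0L) {
      prod <- c(prod, carry %% 10L)
      carry <- carry %/% 10L
    }
    digits <- prod
  }
  paste(rev(digits), collapse = "")
}

#' Read/write superset frequency tables
#'
#' The TSV layout is `superset<TAB><group1>...<groupk>` with the superset
#' rendered as a quoted space-separated call string — the layout used for
#' published per-superset count tables.
#'
#' @param x A `superset_freq` (for writing).
#' @param path File path.
#' @param markers Optional marker names for the read table (defaults to
#'   `M1..Mm` inferred from the first superset).
#' @return `read_superset_table()` returns a `superset_freq`;
#'   `write_superset_table()` returns `path` invisibly.
#' @export
write_superset_table <- function(x, path) {
  stopifnot(inherits(x, "superset_freq"))
  readr::write_tsv(tibble::as_tibble(x), path, quote = "all", progress = FALSE)
  invisible(path)
}

#' @rdname write_superset_table
#' @export
read_superset_table <- function(path, markers = NULL) {
  tb <- readr::read_tsv(path, col_types = readr::cols(
    superset = "c", .default = "i"), progress = FALSE)
  groups <- setdiff(names(tb), "superset")
  if (length(groups) < 1) stop("no group columns found", call. = FALSE)
  calls <- strsplit(tb$superset, " ", fixed = TRUE)
  m <- length(calls[[1]])
  if (any(lengths(calls) != m)) {
    stop("supersets have inconsistent marker counts", call. = FALSE)
  }
  tb$superset <- vapply(calls, function(cc) paste(canonicalize_call(cc),
                                                  collapse = " "), "")
  tb <- tb |>
    dplyr::group_by(.data$superset) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(groups), sum),
                     .groups = "drop")
  tb <- tb[order_c(tb$superset), , drop = FALSE]
  if (is.null(markers)) markers <- paste0("M", seq_len(m))
  new_superset_freq(tb, groups = groups, markers = markers)
}

#' Expand a superset frequency table back into a cohort
#'
#' Reconstructs one individual row per counted chromosome-set; useful for
#' running cohort-level analyses on published per-superset count tables.
#'
#' @param freq A `superset_freq`.
#' @return A `geno_cohort` with synthetic sample ids.
#' @export
expand_superset_table <- function(freq) {
  stopifnot(inherits(freq, "superset_freq"))
  groups <- attr(freq, "groups")
  markers <- attr(freq, "markers")
  long <- tidyr::pivot_longer(tibble::as_tibble(freq),
                              dplyr::all_of(groups),
                              names_to = "group", values_to = "n")
  long <- long[long$n > 0, , drop = FALSE]
  rows <- long[rep(seq_len(nrow(long)), long$n), c("superset", "group")]
  calls <- strsplit(rows$superset, " ", fixed = TRUE)
  mat <- do.call(rbind, calls)
  colnames(mat) <- markers
  tb <- tibble::tibble(
    sample_id = sprintf("ind%05d", seq_len(nrow(rows))),
    group = rows$group
  )
  tb <- dplyr::bind_cols(tb, tibble::as_tibble(mat))
  parse_genotypes(tb, groups = groups)
}
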