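#' Canonicalize two-character genotype calls
#'
#' Genotype calls are two characters over the alphabet `{1, 2}` ("1" = wild
#' allele, "2" = mutant allele). Heterozygotes are stored in the canonical
#' order `"12"`, so `"21"` and `"12"` denote the same unordered genotype.
#'
#' @param x Character vector of raw two-character calls (e.g. `"21"`).
#' @return Character vector of canonical calls, each one of `"11"`, `"12"`,
#'   `"22"`. `NA` values pass through unchanged.
#' @examples
#' canonicalize_call(c("21", "11", "12"))
#' @export
canonicalize_call <- function(x) {
  x <- as.character(x)
  bad <- !is.na(x) & !grepl("^[12]{2}$", x)
  if (any(bad)) {
    stop("invalid genotype call(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (expected two characters over {1,2})", call. = FALSE)
  }
  ifelse(x == "21", "12", x)
}

# Cell values treated as missing genotype data; individuals carrying any of
# these at any marker are removed at parse time (never imputed).
MISSING_CODES <- c("NA", "00", "--", "")

#' Parse a genotype table into a cohort
#'
#' Takes a data frame with columns `sample_id`, `group` and one column per
#' SNP. Calls may be numeric pairs over `{1,2}` (`"11"`, `"21"`, ...) or
#' allele-letter pairs (`"AG"`) translated through a per-marker allele map.
#' Individuals with a missing call at any marker are dropped (and counted in
#' the parse report); heterozygotes are canonicalized to `"12"`.
#'
#' @param x Data frame with `sample_id`, `group`, and at least one marker
#'   column. Marker order is the column order.
#' @param allele_map Optional data frame with columns `marker`, `wild`,
#'   `mutant` giving the letter-to-digit translation per SNP. Markers absent
#'   from the map are assumed numeric.
#' @param groups Optional character vector declaring the group labels and
#'   their order. If omitted, groups are taken in order of first appearance.
#' @return A `geno_cohort`: a tibble of surviving individuals with canonical
#'   calls, carrying attributes `markers`, `groups` and `dropped` (sample ids
#'   removed for missing data).
#' @examples
#' tb <- tibble::tibble(
#'   sample_id = c("s1", "s2", "s3"),
#'   group = c("case", "case", "control"),
#'   SNP1 = c("11", "21", "11"),
#'   SNP2 = c("12", "NA", "22")
#' )
#' parse_genotypes(tb)
#' @export
parse_genotypes <- function(x, allele_map = NULL, groups = NULL) {
  x <- tibble::as_tibble(x)
  if (!all(c("sample_id", "group") %in% names(x))) {
    stop("genotype table must have 'sample_id' and 'group' columns",
         call. = FALSE)
  }
  markers <- setdiff(names(x), c("sample_id", "group"))
  if (length(markers) < 1) stop("no marker columns found", call. = FALSE)

  x$sample_id <- as.character(x$sample_id)
  x$group <- as.character(x$group)
  if (anyDuplicated(x$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(x$sample_id[duplicated(x$sample_id)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- unique(x$group)
  } else {
    groups <- as.character(groups)
    unknown <- setdiff(unique(x$group), groups)
    if (length(unknown) > 0) {
      stop("unknown group label(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
  }

  for (m in markers) {
    col <- toupper(trimws(as.character(x[[m]])))
    col[col %in% MISSING_CODES | is.na(col)] <- NA_character_
    col <- translate_letter_calls(col, m, allele_map)
    x[[m]] <- canonicalize_call(col)
  }

  complete <- stats::complete.cases(x[markers])
  dropped <- x$sample_id[!complete]
  x <- x[complete, , drop = FALSE]
  if (nrow(x) == 0) {
    stop("no individuals survive missing-data removal", call. = FALSE)
  }
  new_geno_cohort(x, markers = markers, groups = groups, dropped = dropped)
}

# Map letter-pair calls (e.g. "AG") to digit pairs using the per-marker
# wild/mutant designation. Numeric-looking calls bypass the map.
translate_letter_calls <- function(col, marker, allele_map) {
  letters_idx <- !is.na(col) & grepl("^[A-Z]{2}$", col)
  if (!any(letters_idx)) return(col)
  if (is.null(allele_map)) {
    stop("marker '", marker, "' has letter calls but no allele map supplied",
         call. = FALSE)
  }
  am <- tibble::as_tibble(allele_map)
  row <- am[am$marker == marker, , drop = FALSE]
  if (nrow(row) != 1) {
    stop("allele map has no entry for marker '", marker, "'", call. = FALSE)
  }
  wild <- toupper(row$wild[[1]])
  mutant <- toupper(row$mutant[[1]])
  trans <- function(ch) {
    out <- rep(NA_character_, length(ch))
    out[ch == wild] <- "1"
    out[ch == mutant] <- "2"
    bad <- !is.na(ch) & is.na(out)
    if (any(bad)) {
      stop("invalid allele letter(s) at marker '", marker, "': ",
           paste(unique(ch[bad]), collapse = ", "), call. = FALSE)
    }
    out
  }
  a1 <- trans(substr(col[letters_idx], 1, 1))
  a2 <- trans(substr(col[letters_idx], 2, 2))
  col[letters_idx] <- paste0(a1, a2)
  col
}

new_geno_cohort <- function(x, markers, groups, dropped = character()) {
  structure(
    tibble::as_tibble(x),
    markers = markers,
    groups = groups,
    dropped = dropped,
    class = c("geno_cohort", class(tibble::tibble()))
  )
}

#' Read a genotype TSV (and optional allele-map TSV) into a cohort
#'
#' The genotype file has header `sample_id`, `group`, then one column per
#' marker; the allele map has header `marker`, `wild`, `mutant`.
#'
#' @param path Path to the genotype TSV.
#' @param allele_map_path Optional path to the allele-map TSV.
#' @param groups Optional declared group labels (see [parse_genotypes()]).
#' @return A `geno_cohort` tibble.
#' @export
read_genotypes <- function(path, allele_map_path = NULL, groups = NULL) {
  tb <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  am <- if (!is.null(allele_map_path)) {
    readr::read_tsv(allele_map_path, col_types = readr::cols(.default = "c"),
                    progress = FALSE)
  }
  parse_genotypes(tb, allele_map = am, groups = groups)
}

#' Write a cohort back to a genotype TSV
#'
#' @param cohort A `geno_cohort`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(cohort, path) {
  readr::write_tsv(tibble::as_tibble(cohort), path, progress = FALSE)
  invisible(path)
}

#' @export
print.geno_cohort <- function(x, ...) {
  cat("# Genotype cohort: ", nrow(x), " individuals, ",
      length(marker_names(x)), " markers, ",
      length(group_levels(x)), " groups (",
      paste(group_levels(x), collapse = ", "), ")\n", sep = "")
  nd <- length(attr(x, "dropped"))
  if (nd > 0) cat("# dropped for missing calls: ", nd, "\n", sep = "")
  NextMethod()
}

#' Cohort accessors
#'
#' `marker_names()` returns the ordered marker (SNP) names, `group_levels()`
#' the declared group labels in report order, `group_sizes()` a tibble of
#' per-group individual counts, and `parse_report()` the sample ids dropped
#' for missing genotype data.
#'
#' @param cohort A `geno_cohort`.
#' @return See description.
#' @export
marker_names <- function(cohort) attr(cohort, "markers")

#' @rdname marker_names
#' @export
group_levels <- function(cohort) attr(cohort, "groups")

#' @rdname marker_names
#' @export
group_sizes <- function(cohort) {
  g <- factor(cohort$group, levels = group_levels(cohort))
  tibble::tibble(group = group_levels(cohort),
                 n = as.integer(table(g)))
}

#' @rdname marker_names
#' @export
parse_report <- function(cohort) {
  ids <- attr(cohort, "dropped")
  tibble::tibble(dropped = length(ids), sample_ids = list(ids))
}

# Keep attributes across dplyr-style subsetting of rows.
#' @export
`[.geno_cohort` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(marker_names(x) %in% names(out))) {
    attr(out, "markers") <- attr(x, "markers")
    attr(out, "groups") <- attr(x, "groups")
    attr(out, "dropped") <- attr(x, "dropped")
    class(out) <- class(x)
  }
  out
}
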