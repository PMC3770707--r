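#' Yates-corrected chi-square test on a 2x2 table
#'
#' Pearson chi-square with continuity correction,
#' `chi2 = sum((|O - E| - 0.5)^2 / E)` where the 0.5 correction is capped at
#' `|O - E|` (never negative), df = 1, two-sided p from the upper tail.
#'
#' @param a,b,c,d Cell counts: row 1 = `(a, b)`, row 2 = `(c, d)`. `a` may
#'   instead be a 2x2 matrix or table.
#' @return One-row tibble with `statistic`, `df`, `p.value`.
#' @examples
#' yates_chi_square(73, 15, 66, 11)
#' @export
yates_chi_square <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- as_table_2x2(a, b, c, d)
  if (any(rowSums(x) == 0) || any(colSums(x) == 0)) {
    stop("chi-square undefined: a table margin is zero", call. = FALSE)
  }
  e <- outer(rowSums(x), colSums(x)) / sum(x)
  adj <- pmin(0.5, abs(x - e))
  stat <- sum((abs(x - e) - adj)^2 / e)
  tibble::tibble(statistic = stat, df = 1,
                 p.value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

as_table_2x2 <- function(a, b, c, d) {
  x <- if (is.matrix(a) || is.table(a)) {
    matrix(as.numeric(a), 2, 2)[1:2, 1:2]
  } else {
    matrix(as.numeric(c(a, b, c, d)), nrow = 2, byrow = TRUE)
  }
  if (any(is.na(x)) || any(x < 0)) {
    stop("counts must be four non-negative numbers", call. = FALSE)
  }
  x
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' `OR = (a/b) / (c/d)` with
#' `CI = exp(log(OR) +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))`. If any cell is
#' zero, 0.5 is added to all four cells first (Haldane-Anscombe correction,
#' flagged in the output); if both cells of one row are zero the odds ratio
#' is undefined and an error is raised.
#'
#' @inheritParams yates_chi_square
#' @return One-row tibble with `estimate`, `conf.low`, `conf.high`,
#'   `corrected` (whether the continuity correction was applied).
#' @examples
#' odds_ratio_woolf(102, 74, 135, 19)
#' @export
odds_ratio_woolf <- function(a, b = NULL, c = NULL, d = NULL) {
  x <- as_table_2x2(a, b, c, d)
  if (any(rowSums(x == 0) == 2)) {
    stop("odds ratio undefined: both cells of a row are zero", call. = FALSE)
  }
  corrected <- any(x == 0)
  if (corrected) x <- x + 0.5
  or <- (x[1, 1] / x[1, 2]) / (x[2, 1] / x[2, 2])
  se <- sqrt(sum(1 / x))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se)
  tibble::tibble(estimate = or, conf.low = ci[1], conf.high = ci[2],
                 corrected = corrected)
}

#' One-vs-rest haplotype odds ratios
#'
#' For every haplotype whose chromosome frequency exceeds `min_freq` in
#' either group, forms the 2x2 table (this haplotype vs all others) x
#' (case vs control) and reports the Woolf odds ratio, 95% CI and the
#' Yates-corrected p-value. The odds are oriented as haplotype odds in cases
#' over controls, so a protective haplotype yields OR < 1.
#'
#' @param hap_counts Data frame with columns `haplotype`, `case`, `control`
#'   (chromosome counts per group).
#' @param n_case,n_control Total chromosomes per group; default to the column
#'   sums.
#' @param min_freq Frequency threshold for inclusion (default 0.03: present
#'   in more than 3% of either group's chromosomes).
#' @return Tibble with one row per retained haplotype: counts, frequencies,
#'   `estimate`, `conf.low`, `conf.high`, `statistic`, `p.value`.
#' @examples
#' tab2 <- tibble::tibble(
#'   haplotype = c("C-C", "T-C", "T-T"),
#'   case = c(13, 102, 61), control = c(17, 135, 2)
#' )
#' haplotype_case_control_or(tab2)
#' @export
haplotype_case_control_or <- function(hap_counts, n_case = NULL,
                                      n_control = NULL, min_freq = 0.03) {
  hap_counts <- tibble::as_tibble(hap_counts)
  stopifnot(all(c("haplotype", "case", "control") %in% names(hap_counts)))
  if (is.null(n_case)) n_case <- sum(hap_counts$case)
  if (is.null(n_control)) n_control <- sum(hap_counts$control)
  if (any(hap_counts$case > n_case) || any(hap_counts$control > n_control)) {
    stop("haplotype counts exceed group chromosome totals", call. = FALSE)
  }
  out <- hap_counts |>
    dplyr::mutate(case_freq = .data$case / n_case,
                  control_freq = .data$control / n_control) |>
    dplyr::filter(.data$case_freq > min_freq | .data$control_freq > min_freq)
  stats <- purrr::pmap_dfr(
    out[c("case", "control")],
    function(case, control) {
      or <- odds_ratio_woolf(case, n_case - case, control, n_control - control)
      p <- tryCatch(
        yates_chi_square(case, n_case - case, control, n_control - control),
        error = function(e) tibble::tibble(statistic = NA_real_,
                                           p.value = NA_real_))
      dplyr::bind_cols(or, p[c("statistic", "p.value")])
    })
  dplyr::bind_cols(out, stats)
}

#' Two-locus haplotype frequencies by EM
#'
#' Maximum-likelihood estimation of the four two-locus haplotype frequencies
#' from unphased genotypes under Hardy-Weinberg random mating. Only double
#' heterozygotes (12 at both loci) are phase-ambiguous; the E-step splits
#' them between the cis (1-1 / 2-2) and trans (1-2 / 2-1) resolutions in
#' proportion to `p11*p22` vs `p12*p21`, and the M-step re-estimates
#' frequencies from expected haplotype counts. The log-likelihood is
#' monotonically non-decreasing across iterations.
#'
#' @param cohort A `geno_cohort`.
#' @param i,j Marker indices (1-based, in `marker_names()` order).
#' @param scope Optional group labels to restrict the estimation to; default
#'   uses all individuals (the combined cohort).
#' @param init Initial haplotype frequencies `(p11, p12, p21, p22)`; the
#'   uniform default suffices for non-degenerate data.
#' @param tol Convergence threshold on `max |delta freq|`.
#' @param max_iter Iteration cap.
#' @return A `two_locus_em` object: `freqs` (named `p11, p12, p21, p22`,
#'   first index = allele at locus `i`, 1 = wild), `pA`/`pB` (allele-1
#'   frequencies), `loglik`, `loglik_trace`, `iterations`, `converged`, `n`.
#' @export
em_two_locus <- function(cohort, i, j, scope = NULL,
                         init = rep(0.25, 4), tol = 1e-8, max_iter = 1000) {
  markers <- marker_names(cohort)
  stopifnot(i >= 1, j >= 1, i <= length(markers), j <= length(markers), i != j)
  tb <- tibble::as_tibble(cohort)
  if (!is.null(scope)) tb <- tb[tb$group %in% scope, , drop = FALSE]
  if (nrow(tb) == 0) stop("no individuals in scope", call. = FALSE)
  ga <- factor(tb[[markers[i]]], levels = c("11", "12", "22"))
  gb <- factor(tb[[markers[j]]], levels = c("11", "12", "22"))
  counts <- table(ga, gb)
  if (allele2_count(counts, 1) %in% c(0, 2 * sum(counts)) ||
      allele2_count(counts, 2) %in% c(0, 2 * sum(counts))) {
    stop("marker is monomorphic in scope; LD undefined", call. = FALSE)
  }
  em_two_locus_counts(counts, init = init, tol = tol, max_iter = max_iter)
}

# total "2" alleles at locus 1 (margin = 1) or locus 2 (margin = 2)
allele2_count <- function(counts, margin) {
  m <- apply(counts, margin, sum)
  sum(m * c(0, 1, 2))
}

# EM on a 3x3 genotype count table (rows = locus A genotype 11/12/22,
# columns = locus B genotype).
em_two_locus_counts <- function(counts, init = rep(0.25, 4), tol = 1e-8,
                                max_iter = 1000) {
  counts <- matrix(as.numeric(counts), 3, 3)
  n <- sum(counts)
  # fixed haplotype contributions from phase-unambiguous genotypes:
  # base[h] = number of haplotypes of type h (11,12,21,22) carried outside
  # the double-heterozygote class
  a_alleles <- list(c(1, 1), c(1, 2), c(2, 2))  # alleles at A per genotype
  base <- c(`11` = 0, `12` = 0, `21` = 0, `22` = 0)
  for (ra in 1:3) for (rb in 1:3) {
    if (ra == 2 && rb == 2) next
    ndx <- counts[ra, rb]
    if (ndx == 0) next
    if (ra == 2) {            # A het, B hom: haplotypes 1b and 2b
      bal <- a_alleles[[rb]][1]
      base[paste0(1, bal)] <- base[paste0(1, bal)] + ndx
      base[paste0(2, bal)] <- base[paste0(2, bal)] + ndx
    } else if (rb == 2) {     # B het, A hom
      aal <- a_alleles[[ra]][1]
      base[paste0(aal, 1)] <- base[paste0(aal, 1)] + ndx
      base[paste0(aal, 2)] <- base[paste0(aal, 2)] + ndx
    } else {                  # both hom: two identical haplotypes
      h <- paste0(a_alleles[[ra]][1], a_alleles[[rb]][1])
      base[h] <- base[h] + 2 * ndx
    }
  }
  ndh <- counts[2, 2]
  p <- init / sum(init)
  names(p) <- c("11", "12", "21", "22")
  trace <- em_loglik(p, counts, ndh)
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    denom <- p["11"] * p["22"] + p["12"] * p["21"]
    cis <- if (denom > 0) as.numeric(p["11"] * p["22"] / denom) else 0.5
    expected <- base +
      ndh * c(cis, 1 - cis, 1 - cis, cis)  # each dh individual: 2 haplotypes
    p_new <- expected / (2 * n)
    ll <- em_loglik(p_new, counts, ndh)
    if (ll < trace[length(trace)] - 1e-9) {
      stop("EM log-likelihood decreased; numerical failure", call. = FALSE)
    }
    trace <- c(trace, ll)
    delta <- max(abs(p_new - p))
    p <- p_new
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  structure(
    list(freqs = p,
         pA = unname(p["11"] + p["12"]),
         pB = unname(p["11"] + p["21"]),
         loglik = trace[length(trace)],
         loglik_trace = trace,
         iterations = iter,
         converged = converged,
         n = n),
    class = "two_locus_em"
  )
}

# multinomial log-likelihood of the 3x3 genotype counts given haplotype
# frequencies p (named 11,12,21,22), HWE phases
em_loglik <- function(p, counts, ndh = counts[2, 2]) {
  probs <- genotype_probs(p)
  keep <- counts > 0
  sum(counts[keep] * log(probs[keep]))
}

# 3x3 genotype-pair probabilities under HWE from haplotype frequencies
genotype_probs <- function(p) {
  hap_a <- c(`11` = 1, `12` = 1, `21` = 2, `22` = 2)
  hap_b <- c(`11` = 1, `12` = 2, `21` = 1, `22` = 2)
  probs <- matrix(0, 3, 3)
  haps <- names(p)
  for (h1 in haps) for (h2 in haps) {
    ga <- hap_a[h1] + hap_a[h2] - 1   # 1=11, 2=12, 3=22
    gb <- hap_b[h1] + hap_b[h2] - 1
    probs[ga, gb] <- probs[ga, gb] + p[h1] * p[h2]
  }
  probs
}

#' @export
print.two_locus_em <- function(x, ...) {
  cat("Two-locus haplotype EM (n = ", x$n, ", ", x$iterations,
      " iterations, ", if (x$converged) "converged" else "NOT converged",
      ")\n", sep = "")
  print(round(x$freqs, 6))
  cat("allele-1 freqs: pA = ", round(x$pA, 6), ", pB = ", round(x$pB, 6),
      "; loglik = ", round(x$loglik, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname em_two_locus
#' @param x A `two_locus_em`.
#' @param ... Unused.
#' @export
tidy.two_locus_em <- function(x, ...) {
  tibble::tibble(haplotype = names(x$freqs), frequency = unname(x$freqs))
}

#' @rdname em_two_locus
#' @export
glance.two_locus_em <- function(x, ...) {
  tibble::tibble(pA = x$pA, pB = x$pB, loglik = x$loglik,
                 iterations = x$iterations, converged = x$converged, n = x$n)
}

#' Pairwise linkage-disequilibrium statistics
#'
#' From two-locus haplotype frequencies: `D = p11 - pA*pB`,
#' `r2 = D^2 / (pA(1-pA) pB(1-pB))`, and `D' = D / Dmax` with
#' `Dmax = min(pA(1-pB), (1-pA)pB)` for positive D and
#' `min(pA*pB, (1-pA)(1-pB))` otherwise.
#'
#' @param h A `two_locus_em` object, or a named numeric vector of haplotype
#'   frequencies `c(p11 = , p12 = , p21 = , p22 = )`.
#' @return One-row tibble with `D`, `D_prime`, `r2`, `pA`, `pB`.
#' @export
ld_stats <- function(h) {
  if (inherits(h, "two_locus_em")) {
    p <- h$freqs
  } else {
    stopifnot(all(c("11", "12", "21", "22") %in% names(p <- fix_p_names(h))))
  }
  pa <- unname(p["11"] + p["12"])
  pb <- unname(p["11"] + p["21"])
  if (pa <= 0 || pa >= 1 || pb <= 0 || pb >= 1) {
    stop("LD undefined: a locus is monomorphic", call. = FALSE)
  }
  d <- unname(p["11"]) - pa * pb
  dmax <- if (d > 0) min(pa * (1 - pb), (1 - pa) * pb)
          else min(pa * pb, (1 - pa) * (1 - pb))
  tibble::tibble(
    D = d,
    D_prime = if (abs(d) < .Machine$double.eps) 0 else d / dmax,
    r2 = d^2 / (pa * (1 - pa) * pb * (1 - pb)),
    pA = pa, pB = pb
  )
}

fix_p_names <- function(h) {
  names(h) <- sub("^p", "", names(h))
  h
}
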