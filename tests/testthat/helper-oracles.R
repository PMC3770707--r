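# Fixture builders and independent oracles shared across test files.
# Oracles are deliberately written from first principles (apply/table/explicit
# formulas) so they share no code path with the package implementation.

# A small fully-specified cohort used by several files.
tiny_cohort <- function() {
  parse_genotypes(tibble::tibble(
    sample_id = paste0("s", 1:7),
    group = c("case", "case", "case", "case", "control", "control", "control"),
    SNP1 = c("12", "12", "12", "11", "11", "11", "12"),
    SNP2 = c("22", "22", "22", "11", "11", "12", "22"),
    SNP3 = c("11", "11", "11", "12", "12", "11", "11")
  ))
}

# Random cohort with uniform random calls (no structure).
random_cohort <- function(p, m, k = 2, seed = 1) {
  withr::with_seed(seed, {
    tb <- tibble::tibble(
      sample_id = sprintf("s%03d", seq_len(p)),
      group = sample(paste0("g", seq_len(k)), p, replace = TRUE)
    )
    for (i in seq_len(m)) {
      tb[[paste0("SNP", i)]] <- sample(c("11", "12", "22"), p, replace = TRUE)
    }
    tb
  })
  parse_genotypes(tb, groups = paste0("g", seq_len(k)))
}

# Brute-force per-group superset counts via apply/paste/table.
bf_superset_counts <- function(cohort) {
  tb <- as.data.frame(cohort)
  ss <- apply(tb[marker_names(cohort)], 1, paste, collapse = " ")
  as.data.frame.matrix(table(ss, factor(tb$group,
                                        levels = group_levels(cohort))))
}

# Brute-force string-collapse knockout: drop marker `idx` from raw genotype
# strings and recount group-specific supersets from scratch.
bf_knockout_counts <- function(cohort, idx, focal, reference) {
  tb <- as.data.frame(cohort)
  keep <- marker_names(cohort)[-idx]
  ss <- apply(tb[keep], 1, paste, collapse = " ")
  seen <- split(ss, tb$group)
  focal_ss <- unique(seen[[focal]])
  other_f <- unique(unlist(seen[names(seen) != focal]))
  ref_ss <- unique(seen[[reference]])
  other_r <- unique(unlist(seen[names(seen) != reference]))
  c(n_nodes = length(unique(ss)),
    focal_specific = length(setdiff(focal_ss, other_f)),
    reference_specific = length(setdiff(ref_ss, other_r)))
}

# Independent multinomial log-likelihood of a 3x3 genotype count table given
# the free haplotype frequency p11 with allele-frequency margins fixed.
# Explicit closed-form genotype probabilities (no shared code with the EM).
bf_two_locus_loglik <- function(counts, p11, pa, pb) {
  p12 <- pa - p11
  p21 <- pb - p11
  p22 <- 1 - p11 - p12 - p21
  if (min(p11, p12, p21, p22) < -1e-12) return(-Inf)
  probs <- matrix(c(
    p11^2,            2 * p11 * p12,                     p12^2,
    2 * p11 * p21,    2 * p11 * p22 + 2 * p12 * p21,     2 * p12 * p22,
    p21^2,            2 * p21 * p22,                     p22^2
  ), nrow = 3, byrow = TRUE)
  keep <- counts > 0
  if (any(probs[keep] <= 0)) return(-Inf)
  sum(counts[keep] * log(probs[keep]))
}

# Grid-search maximizer of the two-locus multinomial likelihood over p11
# (margins fixed at the observed allele frequencies): 1e-3 grid, then two
# zoom passes so the maximizer is localized well below 1e-4.
bf_grid_em <- function(cohort, i, j) {
  tb <- as.data.frame(cohort)
  ga <- factor(tb[[marker_names(cohort)[i]]], levels = c("11", "12", "22"))
  gb <- factor(tb[[marker_names(cohort)[j]]], levels = c("11", "12", "22"))
  counts <- table(ga, gb)
  n <- sum(counts)
  pa <- sum(rowSums(counts) * c(2, 1, 0)) / (2 * n)  # allele-1 freq, locus A
  pb <- sum(colSums(counts) * c(2, 1, 0)) / (2 * n)
  lo <- max(0, pa + pb - 1)
  hi <- min(pa, pb)
  step <- 1e-3
  for (pass in 1:3) {
    grid <- seq(lo, hi, by = step * (hi - lo + 1e-12))
    ll <- vapply(grid, function(x) bf_two_locus_loglik(counts, x, pa, pb),
                 numeric(1))
    best <- grid[which.max(ll)]
    lo <- max(max(0, pa + pb - 1), best - 2 * step * (hi - lo))
    hi <- min(min(pa, pb), best + 2 * step * (hi - lo))
  }
  c(p11 = best, p12 = pa - best, p21 = pb - best, p22 = 1 - pa - pb + best)
}

# Genotype call multiset of a call vector, as a sorted character vector.
call_multiset <- function(calls) sort(calls)

# Allele multiset of a call vector.
allele_multiset <- function(calls) {
  sort(unlist(strsplit(calls, "", fixed = TRUE)))
}
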