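#' Specify a synthetic cohort
#'
#' `group_spec()` declares one group (label, size, per-marker mutant-allele
#' frequencies); `ld_pair_spec()` declares a pair of linked markers with an
#' explicit haplotype distribution (overriding the group allele frequencies
#' at those two markers); `synth_config()` assembles the full generator
#' configuration.
#'
#' Haplotype frequencies are named by the allele pair: `p11` = wild-wild,
#' `p22` = mutant-mutant, etc., first index = first marker of the pair.
#'
#' @param label Group label (free string).
#' @param n Number of individuals (`>= 1`).
#' @param maf Numeric vector of per-marker mutant-allele ("2") frequencies,
#'   length M.
#' @return `group_spec()` / `ld_pair_spec()` return spec lists;
#'   `synth_config()` returns a `synth_config` object.
#' @examples
#' cfg <- synth_config(
#'   groups = list(group_spec("case", 50, c(0.4, 0.2)),
#'                 group_spec("control", 50, c(0.1, 0.2))),
#'   seed = 1
#' )
#' generate_cohort(cfg)
#' @export
group_spec <- function(label, n, maf) {
  stopifnot(is.character(label), length(label) == 1, n >= 1,
            all(maf >= 0 & maf <= 1))
  list(label = label, n = as.integer(n), maf = as.numeric(maf))
}

#' @rdname group_spec
#' @param markers Integer pair `(i, j)` of linked marker positions.
#' @param haplotype_freqs Numeric vector `c(p11, p12, p21, p22)` summing
#'   to 1.
#' @export
ld_pair_spec <- function(markers, haplotype_freqs) {
  stopifnot(length(markers) == 2, markers[1] != markers[2],
            length(haplotype_freqs) == 4,
            all(haplotype_freqs >= 0),
            abs(sum(haplotype_freqs) - 1) < 1e-8)
  list(markers = as.integer(markers),
       haplotype_freqs = as.numeric(haplotype_freqs))
}

#' @rdname group_spec
#' @param groups List of `group_spec()`s; all `maf` vectors must share one
#'   length M, and the label order fixes the report order.
#' @param ld_pairs List of `ld_pair_spec()`s over disjoint marker sets.
#' @param missing_rate Probability that any one call is replaced by a missing
#'   code (`"NA"`); missing calls are then handled by the parser, which drops
#'   the individual.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @param marker_names Optional marker names (default `SNP1..SNPM`).
#' @export
synth_config <- function(groups, ld_pairs = list(), missing_rate = 0,
                         seed = 1, marker_names = NULL) {
  stopifnot(length(groups) >= 1, missing_rate >= 0, missing_rate < 1)
  m <- unique(vapply(groups, function(g) length(g$maf), integer(1)))
  if (length(m) != 1) {
    stop("all groups must declare maf vectors of the same length",
         call. = FALSE)
  }
  ld_markers <- unlist(lapply(ld_pairs, `[[`, "markers"))
  if (anyDuplicated(ld_markers)) {
    stop("ld_pairs must cover disjoint marker sets", call. = FALSE)
  }
  if (length(ld_markers) > 0 && (max(ld_markers) > m || min(ld_markers) < 1)) {
    stop("ld_pair marker index out of range", call. = FALSE)
  }
  if (is.null(marker_names)) marker_names <- paste0("SNP", seq_len(m))
  stopifnot(length(marker_names) == m)
  structure(
    list(groups = groups, m = m, ld_pairs = ld_pairs,
         missing_rate = missing_rate, seed = as.integer(seed),
         marker_names = marker_names),
    class = "synth_config"
  )
}

#' Generate a synthetic cohort
#'
#' Unlinked markers are drawn per group under Hardy-Weinberg equilibrium
#' from that group's mutant-allele frequency; for each LD pair, two
#' haplotypes per individual are drawn from the pair's haplotype distribution
#' and combined into the two genotype calls. Missing calls are injected at
#' `missing_rate` and then removed by the parser (dropping the individual),
#' exactly as real incomplete records would be.
#'
#' @param cfg A `synth_config` (or a panel config from
#'   [synth_preset()]`("panel-like")`).
#' @param raw If `TRUE`, return the raw genotype tibble (including any
#'   missing codes) instead of the parsed cohort.
#' @return A `geno_cohort` (or raw tibble).
#' @export
generate_cohort <- function(cfg, raw = FALSE) {
  if (inherits(cfg, "panel_config")) {
    return(generate_large_panel(cfg$n_snps, cfg$n_individuals,
                                seed = cfg$seed))
  }
  stopifnot(inherits(cfg, "synth_config"))
  hap_alleles <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  tb <- withr::with_seed(cfg$seed, {
    parts <- lapply(cfg$groups, function(g) {
      calls <- matrix(NA_character_, nrow = g$n, ncol = cfg$m)
      linked <- unlist(lapply(cfg$ld_pairs, `[[`, "markers"))
      for (mk in setdiff(seq_len(cfg$m), linked)) {
        gsum <- stats::rbinom(g$n, 1, g$maf[mk]) +
          stats::rbinom(g$n, 1, g$maf[mk])
        calls[, mk] <- c("11", "12", "22")[gsum + 1]
      }
      for (pair in cfg$ld_pairs) {
        h1 <- sample.int(4, g$n, replace = TRUE, prob = pair$haplotype_freqs)
        h2 <- sample.int(4, g$n, replace = TRUE, prob = pair$haplotype_freqs)
        a1 <- vapply(h1, function(h) hap_alleles[[h]][1], numeric(1))
        a2 <- vapply(h2, function(h) hap_alleles[[h]][1], numeric(1))
        b1 <- vapply(h1, function(h) hap_alleles[[h]][2], numeric(1))
        b2 <- vapply(h2, function(h) hap_alleles[[h]][2], numeric(1))
        calls[, pair$markers[1]] <- c("11", "12", "22")[a1 + a2 - 1]
        calls[, pair$markers[2]] <- c("11", "12", "22")[b1 + b2 - 1]
      }
      if (cfg$missing_rate > 0) {
        miss <- stats::runif(length(calls)) < cfg$missing_rate
        calls[miss] <- "NA"
      }
      colnames(calls) <- cfg$marker_names
      dplyr::bind_cols(
        tibble::tibble(sample_id = sprintf("%s_%04d", g$label, seq_len(g$n)),
                       group = g$label),
        tibble::as_tibble(calls))
    })
    dplyr::bind_rows(parts)
  })
  if (raw) return(tb)
  parse_genotypes(tb, groups = vapply(cfg$groups, `[[`, "", "label"))
}

#' Generate a large independent-marker panel
#'
#' A two-group cohort of arbitrary dimensions with per-marker mutant-allele
#' frequency drawn from `maf_sampler` (default uniform on `[0.05, 0.5]`),
#' independent markers, and Hardy-Weinberg genotypes shared across groups
#' (a null panel: no planted association). Used to study how the shared
#' superset count decays with SNP subset size.
#'
#' @param n_snps,n_individuals Panel dimensions (`>= 1`).
#' @param maf_sampler Function of one argument (the number of markers)
#'   returning that many allele frequencies.
#' @param seed Integer seed.
#' @param group_labels Two labels; individuals are split between them as
#'   evenly as possible.
#' @return A `geno_cohort` with M = `n_snps`, P = `n_individuals`.
#' @export
generate_large_panel <- function(n_snps, n_individuals,
                                 maf_sampler = function(m) {
                                   stats::runif(m, 0.05, 0.5)
                                 },
                                 seed = 1,
                                 group_labels = c("case", "control")) {
  stopifnot(n_snps >= 1, n_individuals >= 1, length(group_labels) == 2)
  tb <- withr::with_seed(seed, {
    maf <- maf_sampler(n_snps)
    gsum <- matrix(
      stats::rbinom(n_individuals * n_snps, 2,
                    rep(maf, each = n_individuals)),
      nrow = n_individuals, ncol = n_snps)
    calls <- matrix(c("11", "12", "22")[gsum + 1],
                    nrow = n_individuals, ncol = n_snps)
    colnames(calls) <- paste0("SNP", seq_len(n_snps))
    n_case <- ceiling(n_individuals / 2)
    dplyr::bind_cols(
      tibble::tibble(
        sample_id = sprintf("ind_%05d", seq_len(n_individuals)),
        group = rep(group_labels, c(n_case, n_individuals - n_case))),
      tibble::as_tibble(calls))
  })
  parse_genotypes(tb, groups = group_labels)
}

#' Built-in synthetic study presets
#'
#' Three ready-made configurations covering the study designs the method is
#' aimed at:
#'
#' * `"acs-like"`: a 2-group cohort (91 cases / 86 controls) over 5 SNPs,
#'   with per-group allele frequencies patterned on a small coronary-syndrome
#'   candidate-gene panel. SNP4 is the planted risk marker (mutant-allele
#'   frequency 0.40 in cases vs 0.03 in controls); SNP2 and SNP3 form a
#'   linked pair (allele frequency 0.15 at both loci, haplotype frequencies
#'   chosen so r-squared = 0.7); SNP1 (0.23/0.15) and SNP5 (0.165/0.143) are
#'   unlinked background markers.
#' * `"oral-like"`: a 3-group cohort (369 controls, 219 precancer, 298
#'   cancer) over 5 independent SNPs with moderate frequency differences.
#' * `"panel-like"`: a 1804-SNP x 635-individual two-group null panel.
#'
#' @param name Preset name.
#' @param seed Integer seed stored in the config.
#' @return A `synth_config` (or a `panel_config` for `"panel-like"`); pass to
#'   [generate_cohort()].
#' @export
synth_preset <- function(name = c("acs-like", "oral-like", "panel-like"),
                         seed = 1) {
  name <- match.arg(name)
  if (name == "acs-like") {
    # r2 = 0.7 linked pair at equal allele freq 0.15:
    # D = sqrt(0.7) * 0.15 * 0.85, p22 = 0.15^2 + D, etc.
    d <- sqrt(0.7) * 0.15 * 0.85
    hf <- c(0.85^2 + d, 0.15 * 0.85 - d, 0.15 * 0.85 - d, 0.15^2 + d)
    synth_config(
      groups = list(
        group_spec("case", 91, c(0.23, 0.15, 0.15, 0.40, 0.165)),
        group_spec("control", 86, c(0.15, 0.15, 0.15, 0.03, 0.143))),
      ld_pairs = list(ld_pair_spec(c(2, 3), hf)),
      missing_rate = 0, seed = seed)
  } else if (name == "oral-like") {
    synth_config(
      groups = list(
        group_spec("control", 369, c(0.25, 0.30, 0.20, 0.35, 0.15)),
        group_spec("precancer", 219, c(0.28, 0.36, 0.22, 0.30, 0.17)),
        group_spec("cancer", 298, c(0.30, 0.42, 0.24, 0.27, 0.20))),
      missing_rate = 0, seed = seed)
  } else {
    structure(list(n_snps = 1804L, n_individuals = 635L,
                   seed = as.integer(seed)),
              class = "panel_config")
  }
}
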