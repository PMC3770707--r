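test_that("Yates chi-square reproduces published allele-table p-values", {
  expect_equal(round(yates_chi_square(73, 15, 66, 11)$p.value, 2), 0.79)
  expect_equal(round(yates_chi_square(9, 79, 14, 63)$p.value, 2), 0.21)
  flat <- yates_chi_square(10, 10, 10, 10)
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p.value, 1)
})

test_that("Yates statistic agrees with the base-R oracle and is conservative", {
  withr::with_seed(14, {
    for (rep in 1:20) {
      x <- matrix(rpois(4, 20) + 1, 2, 2)
      ours <- yates_chi_square(x)
      ref <- suppressWarnings(stats::chisq.test(x, correct = TRUE))
      expect_equal(ours$statistic, unname(ref$statistic))
      expect_equal(ours$p.value, unname(ref$p.value))
      plain <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
      expect_lte(ours$statistic, unname(plain$statistic) + 1e-12)
    }
  })
  expect_error(yates_chi_square(0, 0, 3, 4), "margin")
})

test_that("Woolf odds ratios match the closed form on published counts", {
  expect_equal(round(odds_ratio_woolf(102, 74, 135, 19)$estimate, 2), 0.19)
  expect_equal(odds_ratio_woolf(5, 5, 5, 5)$estimate, 1)
  big <- odds_ratio_woolf(61, 115, 2, 152)
  expect_equal(round(big$estimate, 2), 40.31)
  expect_equal(round(big$conf.low, 2), 9.66)
  expect_equal(round(big$conf.high, 1), 168.3)
})

test_that("odds-ratio exposure flip inverts the estimate", {
  withr::with_seed(3, {
    for (rep in 1:10) {
      x <- rpois(4, 15) + 1
      a <- odds_ratio_woolf(x[1], x[2], x[3], x[4])$estimate
      b <- odds_ratio_woolf(x[2], x[1], x[4], x[3])$estimate
      expect_equal(a * b, 1)
    }
  })
})

test_that("zero cells trigger the Haldane correction; zero rows error", {
  res <- odds_ratio_woolf(5, 0, 3, 4)
  expect_true(res$corrected)
  expect_equal(res$estimate, (5.5 / 0.5) / (3.5 / 4.5))
  expect_true(res$conf.low <= res$estimate && res$estimate <= res$conf.high)
  expect_error(odds_ratio_woolf(0, 0, 3, 4), "row")
})

test_that("one-vs-rest haplotype odds ratios reproduce the published table", {
  tab2 <- tibble::tibble(
    haplotype = c("C-C", "T-C", "T-T", "C-T"),
    case = c(13, 102, 61, 0),
    control = c(17, 135, 2, 0)
  )
  res <- haplotype_case_control_or(tab2, n_case = 176, n_control = 154)
  # the absent C-T haplotype fails the >3% filter
  expect_setequal(res$haplotype, c("C-C", "T-C", "T-T"))
  tc <- res[res$haplotype == "T-C", ]
  expect_equal(round(tc$estimate, 2), 0.19)
  expect_lt(tc$p.value, 1e-4)
  tt <- res[res$haplotype == "T-T", ]
  expect_equal(round(tt$estimate, 2), 40.31)
  expect_lt(tt$p.value, 1e-4)
  # C-C is non-significant and mildly protective
  cc <- res[res$haplotype == "C-C", ]
  expect_lt(cc$estimate, 1)
  expect_gt(cc$p.value, 0.05)
})

test_that("haplotype odds ratios equal the per-row closed-form oracle", {
  withr::with_seed(8, {
    counts <- tibble::tibble(
      haplotype = paste0("h", 1:4),
      case = as.numeric(rmultinom(1, 120, c(.4, .3, .2, .1))),
      control = as.numeric(rmultinom(1, 100, c(.25, .35, .25, .15)))
    )
  })
  res <- haplotype_case_control_or(counts)
  for (r in seq_len(nrow(res))) {
    a <- res$case[r]; b <- 120 - a; c <- res$control[r]; d <- 100 - c
    expect_equal(res$estimate[r], (a / b) / (c / d))
    expect_equal(res$conf.low[r],
                 exp(log((a / b) / (c / d)) -
                       qnorm(0.975) * sqrt(1 / a + 1 / b + 1 / c + 1 / d)))
  }
})

# deterministic two-locus cohort builder: genotype pairs given explicitly
two_locus_cohort <- function(ga, gb) {
  parse_genotypes(tibble::tibble(
    sample_id = sprintf("s%03d", seq_along(ga)),
    group = "all", A = ga, B = gb))
}

test_that("EM with no double heterozygotes equals direct gamete counting", {
  ga <- c("11", "11", "12", "22", "12", "11")
  gb <- c("11", "12", "11", "22", "22", "11")
  em <- em_two_locus(two_locus_cohort(ga, gb), 1, 2)
  # count haplotypes by hand: every phase is unambiguous
  # s1: 11,11  s2: 11,12  s3: 11,21  s4: 22,22  s5: 12,22  s6: 11,11
  hand <- c(`11` = 6, `12` = 2, `21` = 1, `22` = 3) / 12
  expect_equal(em$freqs, hand, tolerance = 1e-6)
  expect_true(em$converged)
})

test_that("EM matches the grid-search likelihood maximizer on 20-individual fixtures", {
  for (seed in c(2, 5, 11)) {
    withr::with_seed(seed, {
      # correlated pair: draw haplotypes with coupling
      hf <- c(0.45, 0.1, 0.1, 0.35)
      h1 <- sample(1:4, 20, replace = TRUE, prob = hf)
      h2 <- sample(1:4, 20, replace = TRUE, prob = hf)
    })
    al <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
    ga <- paste0(pmin(sapply(al[h1], `[`, 1), sapply(al[h2], `[`, 1)),
                 pmax(sapply(al[h1], `[`, 1), sapply(al[h2], `[`, 1)))
    gb <- paste0(pmin(sapply(al[h1], `[`, 2), sapply(al[h2], `[`, 2)),
                 pmax(sapply(al[h1], `[`, 2), sapply(al[h2], `[`, 2)))
    co <- two_locus_cohort(ga, gb)
    em <- em_two_locus(co, 1, 2, tol = 1e-12)
    oracle <- bf_grid_em(co, 1, 2)
    expect_equal(unname(em$freqs), unname(oracle), tolerance = 1e-4)
    # log-likelihood is non-decreasing at every iteration
    expect_true(all(diff(em$loglik_trace) >= -1e-9))
  }
})

test_that("EM converges to the same optimum from perturbed initializations", {
  co <- generate_cohort(synth_preset("acs-like", seed = 3))
  em_a <- em_two_locus(co, 2, 3, init = rep(0.25, 4), tol = 1e-12)
  em_b <- em_two_locus(co, 2, 3, init = c(0.1, 0.4, 0.3, 0.2), tol = 1e-12)
  expect_equal(em_a$freqs, em_b$freqs, tolerance = 1e-6)
})

test_that("monomorphic loci are rejected for EM and LD", {
  co <- two_locus_cohort(rep("11", 6), c("11", "12", "22", "11", "12", "22"))
  expect_error(em_two_locus(co, 1, 2), "monomorphic")
  expect_error(ld_stats(c(p11 = 0.5, p12 = 0.5, p21 = 0, p22 = 0)),
               "monomorphic")
})

test_that("LD statistics satisfy the standard identities", {
  # independence: p11 = pA * pB
  ind <- ld_stats(c(p11 = 0.35, p12 = 0.35, p21 = 0.15, p22 = 0.15))
  expect_equal(ind$D, 0)
  expect_equal(ind$r2, 0)
  # perfect coupling with equal allele frequencies
  per <- ld_stats(c(p11 = 0.3, p12 = 0, p21 = 0, p22 = 0.7))
  expect_equal(per$D_prime, 1)
  expect_equal(per$r2, 1)
  # r2 and |D'| invariant under allele relabeling at either locus
  p <- c(p11 = 0.5, p12 = 0.2, p21 = 0.1, p22 = 0.2)
  base <- ld_stats(p)
  swap_a <- ld_stats(c(p11 = p[["p21"]], p12 = p[["p22"]],
                       p21 = p[["p11"]], p22 = p[["p12"]]))
  swap_b <- ld_stats(c(p11 = p[["p12"]], p12 = p[["p11"]],
                       p21 = p[["p22"]], p22 = p[["p21"]]))
  expect_equal(base$r2, swap_a$r2)
  expect_equal(base$r2, swap_b$r2)
  expect_equal(abs(base$D_prime), abs(swap_a$D_prime))
  expect_equal(abs(base$D_prime), abs(swap_b$D_prime))
  # r2 definition holds on EM output
  co <- generate_cohort(synth_preset("acs-like", seed = 2))
  em <- em_two_locus(co, 2, 3)
  ld <- ld_stats(em)
  expect_equal(ld$r2, ld$D^2 / (ld$pA * (1 - ld$pA) * ld$pB * (1 - ld$pB)))
})
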