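test_that("type-1 shuffling preserves per-marker genotype multisets", {
  co <- random_cohort(p = 40, m = 4, k = 2, seed = 6)
  for (within in c("group", "population")) {
    sh <- shuffle_type1(co, seed = 17, within = within)
    expect_equal(nrow(sh), nrow(co))
    expect_equal(group_levels(sh), group_levels(co))
    for (mk in marker_names(co)) {
      expect_equal(call_multiset(sh[[mk]]), call_multiset(co[[mk]]))
      if (within == "group") {
        # per-group genotype counts are preserved too
        for (g in group_levels(co)) {
          expect_equal(call_multiset(sh[[mk]][sh$group == g]),
                       call_multiset(co[[mk]][co$group == g]))
        }
      }
    }
  }
})

test_that("type-2 shuffling preserves allele multisets but not genotype counts", {
  co <- random_cohort(p = 60, m = 3, k = 2, seed = 13)
  sh <- shuffle_type2(co, seed = 5)
  for (mk in marker_names(co)) {
    expect_equal(allele_multiset(sh[[mk]]), allele_multiset(co[[mk]]))
    expect_true(all(sh[[mk]] %in% c("11", "12", "22")))
  }
  # an all-heterozygote marker can (and with 30 individuals virtually must)
  # produce homozygotes once alleles are re-paired
  tb <- tibble::tibble(sample_id = paste0("s", 1:30), group = "case",
                       SNP1 = rep("12", 30))
  het <- parse_genotypes(tb)
  sh2 <- shuffle_type2(het, seed = 2)
  expect_equal(allele_multiset(sh2$SNP1), allele_multiset(het$SNP1))
  expect_true(any(sh2$SNP1 != "12"))
  # a monomorphic marker is a fixed point of both shuffles
  tb$SNP1 <- "11"
  mono <- parse_genotypes(tb)
  expect_equal(shuffle_type2(mono, seed = 3)$SNP1, mono$SNP1)
  expect_equal(shuffle_type1(mono, seed = 3)$SNP1, mono$SNP1)
})

test_that("shuffles are seed-deterministic and seed-sensitive", {
  co <- random_cohort(p = 50, m = 4, k = 2, seed = 20)
  for (fn in list(shuffle_type1, shuffle_type2)) {
    a <- fn(co, seed = 7)
    b <- fn(co, seed = 7)
    expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
    c <- fn(co, seed = 8)
    expect_false(identical(tibble::as_tibble(a), tibble::as_tibble(c)))
  }
  # a single individual per group cannot move under within-group shuffling
  one <- random_cohort(p = 2, m = 3, k = 2, seed = 2)
  expect_identical(tibble::as_tibble(shuffle_type1(one, seed = 1)),
                   tibble::as_tibble(one))
})

test_that("within-group type-1 shuffling leaves per-marker association untouched", {
  co <- generate_cohort(synth_preset("acs-like", seed = 4))
  sh <- shuffle_type1(co, seed = 9, within = "group")
  for (mk in marker_names(co)) {
    tab_of <- function(x) {
      a <- table(factor(x$group, group_levels(x)),
                 factor(x[[mk]], c("11", "12", "22")))
      # allele counts per group
      cbind(2 * a[, 1] + a[, 2], 2 * a[, 3] + a[, 2])
    }
    expect_equal(tab_of(sh), tab_of(co))
  }
})

test_that("the fast ranking path equals the full scan-and-rank pipeline", {
  co <- generate_cohort(synth_preset("acs-like", seed = 15))
  reps <- list(co,
               shuffle_type1(co, seed = 100),
               shuffle_type2(co, seed = 101),
               shuffle_type1(co, seed = 102, within = "population"))
  for (crit in c("case_specific_nodes", "case_control_ratio")) {
    for (r in reps) {
      fast <- snpsupernet:::knockout_rank_fast(r, crit, "case", "control")
      full <- rank_markers(knockout_scan(r, "case", "control"), crit)$marker
      expect_equal(fast, full)
    }
  }
})

test_that("group-constant cohorts are shuffle fixed points: 100% conservation", {
  # every marker is monomorphic within each group, so within-group type-1
  # shuffling cannot move any call and every rank is conserved always
  tb <- tibble::tibble(
    sample_id = paste0("s", 1:12),
    group = rep(c("case", "control"), each = 6),
    SNP1 = rep(c("11", "22"), each = 6),
    SNP2 = rep(c("12", "11"), each = 6),
    SNP3 = rep("11", 12)
  )
  co <- parse_genotypes(tb)
  expect_identical(tibble::as_tibble(shuffle_type1(co, seed = 2)),
                   tibble::as_tibble(co))
  rc <- rank_conservation(co, method = "type1", n_reps = 20, seed = 1,
                          focal = "case", reference = "control")
  expect_equal(rc$conservation_pct, rep(100, 3))
})

test_that("sampled conservation matches exhaustive enumeration on a tiny cohort", {
  # P = 4 (2 per group), M = 2; within-group type-1 shuffling of each marker
  # independently permutes the two calls inside each group. Enumerate all
  # 2^4 = 16 equally likely arrangements of the two markers directly.
  tb <- tibble::tibble(
    sample_id = paste0("s", 1:4),
    group = c("case", "case", "control", "control"),
    SNP1 = c("11", "12", "22", "22"),
    SNP2 = c("12", "12", "11", "22")
  )
  co <- parse_genotypes(tb)
  perms2 <- list(1:2, 2:1)
  hits <- matrix(0, 2, 2, dimnames = list(NULL, c("SNP1", "SNP2")))
  total <- 0
  base <- snpsupernet:::knockout_rank_fast(co, "case_specific_nodes",
                                           "case", "control")
  for (a in perms2) for (b in perms2) for (cc in perms2) for (d in perms2) {
    tb2 <- tb
    tb2$SNP1[1:2] <- tb$SNP1[1:2][a]
    tb2$SNP1[3:4] <- tb$SNP1[3:4][b]
    tb2$SNP2[1:2] <- tb$SNP2[1:2][cc]
    tb2$SNP2[3:4] <- tb$SNP2[3:4][d]
    rk <- snpsupernet:::knockout_rank_fast(parse_genotypes(tb2),
                                           "case_specific_nodes",
                                           "case", "control")
    total <- total + 1
    for (pos in 1:2) {
      if (rk[pos] == base[pos]) hits[pos, base[pos]] <- hits[pos, base[pos]] + 1
    }
  }
  exact <- 100 * c(hits[1, base[1]], hits[2, base[2]]) / total
  rc <- rank_conservation(co, method = "type1", n_reps = 400, seed = 6,
                          focal = "case", reference = "control")
  obs <- rc$conservation_pct[match(base, rc$marker)]
  # binomial sampling noise: stay within ~3 standard errors
  se <- 100 * sqrt(pmax(exact / 100 * (1 - exact / 100), 0.25 / 400) / 400)
  expect_true(all(abs(obs - exact) <= pmax(3 * se, 1e-8)))
})

test_that("conservation results are reproducible and well-formed", {
  co <- generate_cohort(synth_preset("acs-like", seed = 5))
  rc1 <- rank_conservation(co, method = "type2", n_reps = 15, seed = 3,
                           focal = "case", reference = "control")
  rc2 <- rank_conservation(co, method = "type2", n_reps = 15, seed = 3,
                           focal = "case", reference = "control")
  expect_identical(tibble::as_tibble(rc1), tibble::as_tibble(rc2))
  expect_equal(rc1$rank, 1:5)
  expect_true(all(rc1$conservation_pct >= 0 & rc1$conservation_pct <= 100))
  expect_equal(attr(rc1, "n_reps"), 15)
})

test_that("segregation curves are deterministic at the boundary sizes", {
  co <- random_cohort(p = 40, m = 5, k = 2, seed = 19)
  # size = M: only one subset exists, sd must be 0 and the mean must equal
  # the directly computed shared-superset count
  full <- segregation_curve(co, sizes = 5, n_reps = 10, seed = 1)
  ss_all <- snpsupernet:::superset_strings(co)
  shared_full <- length(intersect(unique(ss_all[co$group == "g1"]),
                                  unique(ss_all[co$group == "g2"])))
  expect_equal(full$mean_shared, shared_full)
  expect_equal(full$sd_shared, 0)
  expect_error(segregation_curve(co, sizes = 6, n_reps = 2, seed = 1),
               "between 1 and M")
  # size = 1 where both groups carry all three calls at every marker:
  # the shared count is always 3
  tb <- tibble::tibble(
    sample_id = paste0("s", 1:6),
    group = rep(c("case", "control"), each = 3),
    SNP1 = rep(c("11", "12", "22"), 2),
    SNP2 = rep(c("22", "11", "12"), 2)
  )
  co3 <- parse_genotypes(tb)
  one <- segregation_curve(co3, sizes = 1, n_reps = 25, seed = 2)
  expect_equal(one$mean_shared, 3)
  expect_equal(one$sd_shared, 0)
})

test_that("segregation curves decrease on average and are seed-stable", {
  co <- generate_large_panel(n_snps = 120, n_individuals = 80, seed = 30)
  a <- segregation_curve(co, sizes = c(2, 10, 40, 120), n_reps = 12, seed = 4)
  b <- segregation_curve(co, sizes = c(2, 10, 40, 120), n_reps = 12, seed = 4)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_true(all(diff(a$mean_shared) <= 0))
  expect_gte(a$mean_shared[1], a$mean_shared[4])
})
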