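test_that("allele frequencies are estimated by direct counting", {
  g <- make_geno(list(I1 = list(c("A", "A")), I2 = list(c("A", "B"))))
  f <- estimate_allele_freqs(g)
  expect_equal(f$freq[f$allele == "A"], 0.75)
  expect_equal(f$freq[f$allele == "B"], 0.25)

  g2 <- make_geno(list(I1 = list(c("A", "A")), I2 = list(c("A", "A"))))
  f2 <- estimate_allele_freqs(g2)
  expect_equal(f2$freq, 1)

  # a locus missing in every individual is an error
  g3 <- g
  g3$allele_1[g3$locus == 1] <- NA
  g3$allele_2[g3$locus == 1] <- NA
  expect_error(estimate_allele_freqs(g3), "zero typed")
})

test_that("frequency estimates converge on simulated founders", {
  founders <- tibble::tibble(
    id = sprintf("F%03d", 1:500), sex = "F",
    dam = NA_character_, sire = NA_character_, generation = 0L
  )
  p <- c(a = 0.4, b = 0.35, c = 0.25)
  withr::with_seed(41, g <- sim_genotypes(founders, list(p)))
  f <- estimate_allele_freqs(g)
  expect_true(all(abs(f$freq - p[f$allele]) < 0.03))
})

test_that("IBD-conditional genotype-pair probabilities normalise at each vertex", {
  freq_sets <- list(
    c(a = 0.5, b = 0.5),
    c(a = 0.5, b = 0.3, c = 0.2),
    c(a = 0.4, b = 0.3, c = 0.2, d = 0.1)
  )
  for (p in freq_sets) {
    als <- names(p)
    gts <- list()
    for (i in seq_along(als)) for (j in i:length(als)) {
      gts[[length(gts) + 1]] <- c(als[i], als[j])
    }
    tot <- c(0, 0, 0)
    for (g1 in gts) for (g2 in gts)

      tot <- tot + ibd_pair_probs(g1, g2, p)
    expect_equal(unname(tot), c(1, 1, 1), tolerance = 1e-12)
  }
})

test_that("pair log-likelihood reduces to known closed forms", {
  fr <- list(c(A = 0.5, B = 0.5))
  ga <- make_geno(list(I1 = list(c("A", "A"))))
  gb <- make_geno(list(I2 = list(c("B", "B"))))
  # IBD-incompatible genotypes: only the k0 term survives
  for (k0 in c(1, 0.5, 0.2)) {
    k <- c(k0, (1 - k0) / 2, (1 - k0) / 2)
    expect_equal(pair_loglik(ga, gb, fr, k),
                 log(k0 * 0.25 * 0.25), tolerance = 1e-12)
  }
  # k = (1,0,0) is the product of HWE genotype probabilities
  gc <- make_geno(list(I3 = list(c("A", "B"))))
  expect_equal(pair_loglik(ga, gc, fr, c(1, 0, 0)),
               log(0.25) + log(0.5), tolerance = 1e-12)
  # (AB, AB) at two p = 0.5 loci, k = (0,1,0): per-locus joint is
  # p_A p_B (p_A + p_B) = 0.25
  fr2 <- list(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5))
  gd <- make_geno(list(I4 = list(c("A", "B"), c("A", "B"))))
  ge <- make_geno(list(I5 = list(c("A", "B"), c("A", "B"))))
  expect_equal(pair_loglik(gd, ge, fr2, c(0, 1, 0)), 2 * log(0.25),
               tolerance = 1e-12)
  expect_error(pair_loglik(gd, ge, fr2, c(0.5, 0.2, 0.2)), "simplex")
  expect_error(pair_loglik(gd, make_geno(list(I6 = list(c("Z", "Z"),
                                                        c("A", "B")))),
                           fr2, c(1, 0, 0)), "absent")
})

test_that("identical multilocus genotypes are estimated as full IBD", {
  withr::with_seed(42, fr <- sim_allele_freqs(8, allele_range = 4:6))
  founders <- tibble::tibble(id = c("T1", "T2"), sex = "F",
                             dam = NA_character_, sire = NA_character_,
                             generation = 0L)
  withr::with_seed(43, g <- sim_genotypes(founders[1, ], fr))
  twin <- dplyr::bind_rows(g, dplyr::mutate(g, id = "T2"))
  rel <- ml_relatedness(twin, fr)
  expect_gt(rel$k2, 0.95)
  expect_gt(rel$r, 0.95)
})

test_that("the optimiser tracks a fine exhaustive grid and dominates the vertices", {
  withr::with_seed(44, {
    ped <- sim_pedigree(10, 1, litter_rate = 2)
    fr <- sim_allele_freqs(13)
    g <- sim_genotypes(ped, fr)
  })
  ids <- unique(g$id)
  rel <- ml_relatedness(g, fr)
  fl <- kinforage:::freqs_as_list(fr)
  fine <- kinforage:::simplex_grid(0.01)
  n_checked <- 0
  for (row in seq_len(min(20, nrow(rel)))) {
    ga <- g[g$id == rel$id_a[row], ]
    gb <- g[g$id == rel$id_b[row], ]
    P <- kinforage:::pair_prob_table(ga, gb, fl)
    ll <- rowSums(log(fine %*% P))
    best <- fine[which.max(ll), ]
    r_grid <- best[["k1"]] / 2 + best[["k2"]]
    expect_lt(abs(rel$r[row] - r_grid), 0.02)
    # vertex dominance
    khat <- c(rel$k0[row], rel$k1[row], rel$k2[row])
    ll_hat <- pair_loglik(ga, gb, fr, khat)
    for (v in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
      expect_gte(ll_hat, pair_loglik(ga, gb, fr, v) - 1e-9)
    }
    n_checked <- n_checked + 1
  }
  expect_gte(n_checked, 20)
})

test_that("pairs without shared typed loci are reported as missing", {
  g <- make_geno(list(I1 = list(c("A", "A"), c("B", "B")),
                      I2 = list(c("A", "B"), c("A", "B"))))
  g$allele_1[g$id == "I1" & g$locus == 1] <- NA
  g$allele_2[g$id == "I1" & g$locus == 1] <- NA
  g$allele_1[g$id == "I2" & g$locus == 2] <- NA
  g$allele_2[g$id == "I2" & g$locus == 2] <- NA
  fr <- list(c(A = 0.5, B = 0.5), c(A = 0.5, B = 0.5))
  rel <- ml_relatedness(g, fr)
  expect_true(is.na(rel$r))
  M <- relatedness_matrix(rel)
  expect_equal(dim(M), c(2L, 2L))
})

test_that("KS statistic matches stats::ks.test and hits its extremes", {
  withr::with_seed(45, {
    for (i in 1:10) {
      x <- rnorm(30); y <- rnorm(45, 0.3)
      expect_equal(kinforage:::ks_stat(x, y),
                   unname(suppressWarnings(stats::ks.test(x, y)$statistic)),
                   tolerance = 1e-12)
      # with heavy ties
      xt <- sample(1:4, 30, TRUE); yt <- sample(1:4, 25, TRUE)
      expect_equal(kinforage:::ks_stat(xt, yt),
                   unname(suppressWarnings(stats::ks.test(xt, yt)$statistic)),
                   tolerance = 1e-12)
    }
  })
  ids <- sprintf("i%02d", 1:8)
  M <- matrix(0, 8, 8, dimnames = list(ids, ids))
  M[1:4, 1:4] <- 1; diag(M) <- 0
  seasons <- stats::setNames(rep(c("w", "s"), each = 4), ids)
  res <- compare_r_distributions(M, seasons, n_perm = 99)
  expect_equal(unname(res$statistic[1]), 1)  # within-w all 1, within-s all 0
  expect_error(compare_r_distributions(M, stats::setNames(rep("w", 8), ids)),
               "2 season groups")
})

test_that("season-label permutation p-values are calibrated under the null", {
  withr::with_seed(46, {
    ids <- sprintf("i%02d", 1:24)
    rejections <- replicate(300, {
      # exchangeable dyadic values: no season structure by construction;
      # groups of 12 give 66 within-group pairs, a fine enough grid for the
      # D statistic that tie-induced conservatism is negligible
      M <- matrix(0, 24, 24, dimnames = list(ids, ids))
      vals <- rnorm(24 * 23 / 2)
      M[upper.tri(M)] <- vals
      M <- M + t(M)
      seasons <- stats::setNames(sample(rep(c("w", "s"), each = 12)), ids)
      compare_r_distributions(M, seasons, n_perm = 999)$p_value <= 0.05
    })
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})
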