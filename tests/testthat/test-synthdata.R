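test_that("pedigree simulation yields the expected relative categories", {
  expect_error(sim_pedigree(1, 1), "insufficient founders")

  # two founders, one generation: any offspring has r = 0.5 with each parent
  withr::with_seed(11, {
    ped <- sim_pedigree(2, 1, litter_rate = 4)
  })
  expect_gt(nrow(ped), 2)
  K <- kinship_matrix(ped)
  kid <- ped$id[ped$generation == 1][1]
  expect_equal(K[kid, ped$dam[ped$id == kid]], 0.5)
  expect_equal(K[kid, ped$sire[ped$id == kid]], 0.5)

  # larger pedigree: full sibs (r = 0.5 sharing both parents) exist, plus
  # half sibs and unrelated pairs
  withr::with_seed(12, ped2 <- sim_pedigree(20, 2, litter_rate = 2))
  off <- ped2[!is.na(ped2$dam), ]
  fam <- paste(off$dam, off$sire)
  expect_gte(max(table(fam)), 2)          # at least one full-sib pair
  K2 <- kinship_matrix(ped2)
  vals <- K2[upper.tri(K2)]
  expect_true(any(vals == 0))             # unrelated pairs
  expect_true(any(abs(vals - 0.5) < 1e-12))
})

test_that("kinship matrix reproduces path-counting values on a hand pedigree", {
  ped <- tibble::tibble(
    id = c("d", "s", "s2", "a", "b", "c"),
    sex = c("F", "M", "M", "F", "M", "F"),
    dam = c(NA, NA, NA, "d", "d", "d"),
    sire = c(NA, NA, NA, "s", "s", "s2"),
    generation = c(0, 0, 0, 1, 1, 1)
  )
  K <- kinship_matrix(ped)
  expect_equal(K["a", "b"], 0.5)   # full sibs
  expect_equal(K["a", "c"], 0.25)  # half sibs (share dam)
  expect_equal(K["a", "d"], 0.5)   # parent-offspring
  expect_equal(K["d", "s"], 0)     # founders
})

test_that("genotype inheritance is Mendelian", {
  ped <- tibble::tibble(
    id = c("mum", "dad", "kid"), sex = c("F", "M", "F"),
    dam = c(NA, NA, "mum"), sire = c(NA, NA, "dad"),
    generation = c(0, 0, 1)
  )
  # monomorphic locus: everyone homozygous
  g <- sim_genotypes(ped, list(c(A = 1)))
  expect_true(all(g$allele_1 == "A" & g$allele_2 == "A"))

  # AA x BB -> all offspring AB
  freqs <- list(c(A = 0.5, B = 0.5))
  withr::with_seed(3, {
    reps <- purrr::map(1:20, function(i) {
      g <- sim_genotypes(ped, freqs)
      g
    })
  })
  for (g in reps) {
    mum <- g[g$id == "mum", ]
    dad <- g[g$id == "dad", ]
    kid <- g[g$id == "kid", ]
    if (all(c(mum$allele_1, mum$allele_2) == "A") &&
        all(c(dad$allele_1, dad$allele_2) == "B")) {
      expect_setequal(c(kid$allele_1, kid$allele_2), c("A", "B"))
    }
    # one allele always from each parent
    expect_true(kid$allele_1 %in% c(mum$allele_1, mum$allele_2))
    expect_true(kid$allele_2 %in% c(dad$allele_1, dad$allele_2))
  }

  expect_error(sim_genotypes(ped, list(c(A = 0.6, B = 0.3))), "sum to 1")
})

test_that("founder heterozygosity matches Hardy-Weinberg expectation", {
  founders <- tibble::tibble(
    id = sprintf("F%05d", 1:10000), sex = "F",
    dam = NA_character_, sire = NA_character_, generation = 0L
  )
  withr::with_seed(4, g <- sim_genotypes(founders, list(c(A = 0.5, B = 0.5))))
  het <- mean(g$allele_1 != g$allele_2)
  expect_lt(abs(het - 0.5), 0.02)

  # skewed locus: expected heterozygosity 1 - sum(p^2)
  p <- c(a = 0.7, b = 0.2, c = 0.1)
  withr::with_seed(5, g2 <- sim_genotypes(founders, list(p)))
  expect_lt(abs(mean(g2$allele_1 != g2$allele_2) - (1 - sum(p^2))), 0.02)
})

test_that("allele counts per locus stay in the configured range", {
  withr::with_seed(6, fr <- sim_allele_freqs(50, allele_range = 3:10))
  ks <- vapply(fr, length, 1L)
  expect_true(all(ks >= 3 & ks <= 10))
  expect_true(all(abs(vapply(fr, sum, 1) - 1) < 1e-12))
})

test_that("with no availability contrast, no fidelity and no kin attraction, site choice is uniform", {
  # landscape with equal tree counts everywhere
  ls <- structure(list(
    sites = tibble::tibble(site_id = sprintf("S%d", 1:5),
                           x = seq(500, 4500, length.out = 5), y = 2500,
                           radius = 70.7),
    trees = tibble::tibble(site_id = sprintf("S%d", 1:5), season = "w",
                           species = "dates", n_trees = 10L),
    roosts = tibble::tibble(roost_id = "R1", x = 0, y = 0),
    extent = c(0, 5000, 0, 5000)
  ), class = "landscape")
  ped <- tibble::tibble(id = sprintf("B%02d", 1:50), sex = "F",
                        dam = NA_character_, sire = NA_character_,
                        generation = 0L)
  K <- kinship_matrix(ped)
  cfg <- sim_config(n_bats = 50, n_nights = 200, gamma = 0, phi = 0,
                    sites_per_night = 1, fixes_per_visit = 1)
  withr::with_seed(7, mv <- sim_movement(ls, K, cfg, "w", bats = ped$id))
  counts <- table(mv$visits$site_id)
  expect_equal(sum(counts), 50 * 200)
  gof <- stats::chisq.test(counts)
  expect_gt(gof$p.value, 0.01)
})

test_that("strong kin attraction raises the kinship of co-visiting pairs", {
  withr::with_seed(8, {
    s <- sim_season(n_bats = 20, gamma = 5, n_nights = 5)
    co <- dplyr::inner_join(s$visits, s$visits, by = c("night", "site_id"),
                            relationship = "many-to-many")
    co <- co[co$bat_id.x < co$bat_id.y, ]
    co_kin <- mean(s$K[cbind(co$bat_id.x, co$bat_id.y)])
    pop_kin <- mean(s$K[upper.tri(s$K)])
    expect_gt(co_kin, pop_kin)
  })
})

test_that("study simulation is reproducible and writes consistent artifacts", {
  cfg <- sim_config(n_bats = 6, n_nights = 3, seed = 99)
  st1 <- sim_study(cfg)
  st2 <- sim_study(cfg)
  expect_identical(st1$fixes, st2$fixes)
  expect_identical(st1$genotypes, st2$genotypes)

  dir <- withr::local_tempdir()
  write_study(st1, dir)
  expect_true(all(file.exists(file.path(dir,
    c("fixes.csv", "sites.csv", "genotypes.csv", "truth_visits.csv",
      "manifest.yaml")))))
  # genotype round trip through the wide on-disk layout
  g2 <- read_genotypes(file.path(dir, "genotypes.csv"))
  g1 <- dplyr::arrange(st1$genotypes, id, locus)
  expect_equal(g2$allele_1, g1$allele_1)
  expect_equal(g2$allele_2, g1$allele_2)
})
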