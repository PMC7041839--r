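#' Simulate a breeding pedigree
#'
#' Generates a discrete-generation pedigree starting from unrelated founders.
#' Each generation, every available dam is paired with one randomly chosen
#' sire from the previous generation and produces a Poisson-distributed
#' litter, so the result contains parent-offspring, full-sib, half-sib
#' (dams sharing a sire) and unrelated pairs. Ground-truth relatedness for
#' any pair is available via [kinship_matrix()].
#'
#' Randomness is drawn from the session RNG; call `set.seed()` (or wrap in
#' `withr::with_seed()`) for reproducible pedigrees.
#'
#' @param founders Number of unrelated founders (>= 2); sexes alternate.
#' @param generations Number of offspring generations to simulate (>= 1).
#' @param litter_rate Mean litter size per dam (Poisson).
#' @return A tibble with columns `id`, `sex` ("F"/"M"), `dam`, `sire`
#'   (`NA` for founders) and `generation` (0 for founders). Parents always
#'   precede their offspring.
#' @examples
#' set.seed(1)
#' ped <- sim_pedigree(founders = 10, generations = 2)
#' table(ped$generation)
#' @export
sim_pedigree <- function(founders, generations, litter_rate = 2) {
  if (founders < 2) stop("insufficient founders", call. = FALSE)
  if (generations < 1) stop("`generations` must be >= 1", call. = FALSE)
  ped <- tibble::tibble(
    id = sprintf("I%04d", seq_len(founders)),
    sex = rep(c("F", "M"), length.out = founders),
    dam = NA_character_,
    sire = NA_character_,
    generation = 0L
  )
  next_id <- founders + 1L
  for (g in seq_len(generations)) {
    dams <- ped$id[ped$sex == "F" & ped$generation == g - 1L]
    sires <- ped$id[ped$sex == "M" & ped$generation == g - 1L]
    if (length(dams) == 0L || length(sires) == 0L) break
    kids <- purrr::map(dams, function(d) {
      s <- if (length(sires) == 1L) sires else sample(sires, 1L)
      n_off <- rpois(1L, litter_rate)
      if (n_off == 0L) return(NULL)
      tibble::tibble(
        sex = sample(c("F", "M"), n_off, replace = TRUE),
        dam = d, sire = s, generation = g
      )
    })
    kids <- dplyr::bind_rows(kids)
    if (nrow(kids) == 0L) next
    kids <- dplyr::mutate(kids,
      id = sprintf("I%04d", next_id + dplyr::row_number() - 1L),
      .before = 1L
    )
    next_id <- next_id + nrow(kids)
    ped <- dplyr::bind_rows(ped, kids)
  }
  ped
}

#' Ground-truth relatedness from a pedigree
#'
#' Computes the additive relationship matrix by the standard tabular
#' (recursive) method; the off-diagonal entries are the expected fraction of
#' alleles shared identical-by-descent (0.5 for parent-offspring and full
#' sibs, 0.25 for half sibs, 0 for founders' pairs).
#'
#' @param pedigree A pedigree tibble as produced by [sim_pedigree()].
#' @return A symmetric numeric matrix with individual ids as dimnames.
#'   Diagonal entries are `1 + F_i` (inbreeding coefficient).
#' @export
kinship_matrix <- function(pedigree) {
  ids <- pedigree$id
  n <- length(ids)
  pos <- stats::setNames(seq_len(n), ids)
  di <- ifelse(is.na(pedigree$dam), 0L, pos[pedigree$dam])
  si <- ifelse(is.na(pedigree$sire), 0L, pos[pedigree$sire])
  if (any(di >= seq_len(n) & di > 0L) || any(si >= seq_len(n) & si > 0L)) {
    stop("parents must precede offspring in the pedigree", call. = FALSE)
  }
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    d <- di[i]; s <- si[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aj <- 0.5 * ((if (d > 0L) A[j, d] else 0) + (if (s > 0L) A[j, s] else 0))
      A[j, i] <- aj
      A[i, j] <- aj
    }
    A[i, i] <- 1 + if (d > 0L && s > 0L) 0.5 * A[d, s] else 0
  }
  A
}

#' Simulate microsatellite allele frequencies
#'
#' Draws per-locus allele counts uniformly from `allele_range` and allele
#' frequencies from a symmetric Dirichlet, giving polymorphic loci of the
#' kind used for relatedness estimation. Allele labels mimic fragment sizes.
#'
#' @param n_loci Number of loci (default 13).
#' @param allele_range Integer vector of possible allele counts per locus
#'   (default `3:10`, mean 6.5).
#' @param concentration Dirichlet concentration; larger values give more even
#'   frequencies (default 3).
#' @return A list of length `n_loci`; each element a named numeric vector of
#'   frequencies summing to 1.
#' @export
sim_allele_freqs <- function(n_loci = 13, allele_range = 3:10, concentration = 3) {
  purrr::map(seq_len(n_loci), function(l) {
    k <- if (length(allele_range) == 1L) allele_range else sample(allele_range, 1L)
    w <- rgamma(k, shape = concentration)
    p <- w / sum(w)
    names(p) <- as.character(100 + 2L * seq_len(k))
    p
  })
}

check_allele_freqs <- function(freqs) {
  ok <- vapply(freqs, function(p) abs(sum(p) - 1) <= 1e-9 && all(p >= 0), logical(1))
  if (!all(ok)) {
    stop("allele frequencies must sum to 1 within 1e-9 at every locus",
         call. = FALSE)
  }
  invisible(freqs)
}

#' Simulate diploid genotypes down a pedigree
#'
#' Founders draw two alleles per locus from the supplied population
#' frequencies (Hardy-Weinberg); every non-founder inherits one allele from
#' each parent, chosen uniformly — plain Mendelian segregation with
#' unlinked loci.
#'
#' @param pedigree A pedigree tibble from [sim_pedigree()].
#' @param freqs Per-locus allele frequencies as from [sim_allele_freqs()].
#' @param missing_rate Probability an individual-locus call is missing
#'   (default 0 — no missing data).
#' @return A genotype tibble in long form: `id`, `locus` (integer),
#'   `allele_1`, `allele_2` (character labels, `NA` when missing).
#' @export
sim_genotypes <- function(pedigree, freqs, missing_rate = 0) {
  check_allele_freqs(freqs)
  n <- nrow(pedigree)
  n_loci <- length(freqs)
  pos <- stats::setNames(seq_len(n), pedigree$id)
  # allele stores: [individual, locus, chromosome]
  a1 <- matrix(NA_character_, n, n_loci)
  a2 <- matrix(NA_character_, n, n_loci)
  for (i in seq_len(n)) {
    d <- pedigree$dam[i]; s <- pedigree$sire[i]
    if (is.na(d) || is.na(s)) {
      for (l in seq_len(n_loci)) {
        p <- freqs[[l]]
        draw <- sample(names(p), 2L, replace = TRUE, prob = p)
        a1[i, l] <- draw[1L]; a2[i, l] <- draw[2L]
      }
    } else {
      id <- pos[[d]]; is_ <- pos[[s]]
      pick1 <- runif(n_loci) < 0.5
      pick2 <- runif(n_loci) < 0.5
      a1[i, ] <- ifelse(pick1, a1[id, ], a2[id, ])
      a2[i, ] <- ifelse(pick2, a1[is_, ], a2[is_, ])
    }
  }
  out <- tibble::tibble(
    id = rep(pedigree$id, each = n_loci),
    locus = rep(seq_len(n_loci), times = n),
    allele_1 = as.vector(t(a1)),
    allele_2 = as.vector(t(a2))
  )
  if (missing_rate > 0) {
    miss <- runif(nrow(out)) < missing_rate
    out$allele_1[miss] <- NA_character_
    out$allele_2[miss] <- NA_character_
  }
  out
}

#' Default seasonal landscape regimes
#'
#' Two contrasting food-availability regimes: a rich season with many
#' scattered food patches carrying several fruit species, and a poor season
#' in which food is restricted to a couple of date-palm sites clustered in
#' one corner of the study area. Site geometry is circular with radius
#' 70.7 m (area roughly one hectare, matching a 100 x 100 m patch).
#'
#' @return A named list of regime definitions usable with [sim_landscape()].
#' @export
default_regimes <- function() {
  list(
    winter = list(
      n_sites = 12,
      species = c("dates", "mango", "citrus", "figs", "jujube", "guava", "banana"),
      species_per_site = 1:3,
      mean_trees = 15,
      extent = c(0, 5000, 0, 5000),
      site_radius = 70.7,
      cluster = NULL
    ),
    spring = list(
      n_sites = 2,
      species = "dates",
      species_per_site = 1,
      mean_trees = 30,
      extent = c(0, 5000, 0, 5000),
      site_radius = 70.7,
      cluster = c(x = 4000, y = 2500, sd = 400)
    )
  )
}

#' Simulate a foraging landscape for one season
#'
#' Places non-overlapping circular foraging sites (uniformly over the extent,
#' or clustered when the regime specifies a cluster centre) plus day roosts,
#' and assigns per-site fruit-tree counts by species.
#'
#' @param regime A regime definition (see [default_regimes()]).
#' @param season Season label attached to the tree counts.
#' @param n_roosts Number of day roosts (default 3).
#' @return An object of class `landscape`: a list with tibbles `sites`
#'   (`site_id`, `x`, `y`, `radius`), `trees` (`site_id`, `season`,
#'   `species`, `n_trees`), `roosts` (`roost_id`, `x`, `y`) and the numeric
#'   `extent` (xmin, xmax, ymin, ymax).
#' @export
sim_landscape <- function(regime, season = "winter", n_roosts = 3) {
  if (regime$n_sites < 1) stop("regime must define at least one site", call. = FALSE)
  ext <- regime$extent
  r <- regime$site_radius
  min_sep <- 3 * r
  pts <- matrix(NA_real_, 0, 2)
  tries <- 0L
  while (nrow(pts) < regime$n_sites && tries < 10000L) {
    tries <- tries + 1L
    cand <- if (is.null(regime$cluster)) {
      c(runif(1, ext[1] + r, ext[2] - r), runif(1, ext[3] + r, ext[4] - r))
    } else {
      cl <- regime$cluster
      pmin(pmax(rnorm(2, mean = cl[c("x", "y")], sd = cl[["sd"]]),
                ext[c(1, 3)] + r), ext[c(2, 4)] - r)
    }
    if (nrow(pts) == 0L ||
        all(sqrt(colSums((t(pts) - cand)^2)) >= min_sep)) {
      pts <- rbind(pts, cand)
    }
  }
  if (nrow(pts) < regime$n_sites) {
    stop("could not place non-overlapping sites; enlarge the extent",
         call. = FALSE)
  }
  sites <- tibble::tibble(
    site_id = sprintf("S%02d", seq_len(regime$n_sites)),
    x = pts[, 1], y = pts[, 2], radius = r
  )
  trees <- purrr::map(seq_len(nrow(sites)), function(i) {
    k <- if (length(regime$species_per_site) == 1L) regime$species_per_site
         else sample(regime$species_per_site, 1L)
    k <- min(k, length(regime$species))
    sp <- if (length(regime$species) == 1L) regime$species else sample(regime$species, k)
    tibble::tibble(
      site_id = sites$site_id[i], season = season, species = sp,
      n_trees = rpois(k, regime$mean_trees) + 1L
    )
  })
  roosts <- tibble::tibble(
    roost_id = sprintf("R%02d", seq_len(n_roosts)),
    x = runif(n_roosts, ext[1], ext[2]),
    y = runif(n_roosts, ext[3], ext[4])
  )
  structure(
    list(sites = sites, trees = dplyr::bind_rows(trees), roosts = roosts,
         extent = ext),
    class = "landscape"
  )
}

site_availability <- function(landscape, season = NULL) {
  tr <- landscape$trees
  if (!is.null(season) && season %in% tr$season) {
    tr <- tr[tr$season == season, , drop = FALSE]
  }
  av <- stats::setNames(rep(0, nrow(landscape$sites)), landscape$sites$site_id)
  if (nrow(tr) > 0) {
    agg <- tapply(tr$n_trees, tr$site_id, sum)
    av[names(agg)] <- agg
  }
  if (all(av == 0)) av[] <- 1
  av
}

#' Simulation configuration
#'
#' Bundles the tunable parameters of the movement and genotype simulator.
#' `gamma` is the kin-attraction strength: each night a bat's probability of
#' picking a site is proportional to
#' `availability * fidelity_boost * exp(gamma * mean relatedness to bats
#' already at the site that night)`, so `gamma = 0` makes site choice
#' independent of kinship (the null used for calibration). `phi` in \[0, 1\]
#' is site fidelity: sites a bat has visited on earlier nights get their
#' weight multiplied by `1 + 9 * phi`.
#'
#' @param n_bats Bats tracked per season.
#' @param n_nights Tracked nights per bat.
#' @param gamma Kin-attraction strength (>= 0, default 0).
#' @param phi Site fidelity in \[0, 1\] (default 0.5).
#' @param fix_noise_sd Gaussian telemetry error around site centres, metres.
#' @param fixes_per_visit Location fixes emitted per site visit (default 5).
#' @param n_commute_fixes Commuting fixes per bat-night along the
#'   roost-to-site path (default 1).
#' @param sites_per_night Possible numbers of sites visited per night
#'   (default `1:3`, drawn uniformly).
#' @param n_loci,allele_range,missing_rate Genotype simulator settings
#'   (13 loci; 3-10 alleles per locus; no missing calls).
#' @param start_date First night of tracking (Date).
#' @param seed Optional integer seed recorded in the study manifest.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_bats = 30, n_nights = 8, gamma = 0, phi = 0.5,
                       fix_noise_sd = 25, fixes_per_visit = 5,
                       n_commute_fixes = 1, sites_per_night = 1:3,
                       n_loci = 13, allele_range = 3:10, missing_rate = 0,
                       start_date = as.Date("2010-11-01"), seed = NULL) {
  stopifnot(n_bats >= 2, n_nights >= 1, fixes_per_visit >= 1, n_loci >= 1)
  if (gamma < 0) stop("`gamma` must be >= 0", call. = FALSE)
  if (phi < 0 || phi > 1) stop("`phi` must be in [0, 1]", call. = FALSE)
  structure(
    list(n_bats = n_bats, n_nights = n_nights, gamma = gamma, phi = phi,
         fix_noise_sd = fix_noise_sd, fixes_per_visit = fixes_per_visit,
         n_commute_fixes = n_commute_fixes, sites_per_night = sites_per_night,
         n_loci = n_loci, allele_range = allele_range,
         missing_rate = missing_rate, start_date = start_date, seed = seed),
    class = "sim_config"
  )
}

#' Simulate nightly foraging movement
#'
#' Each night, bats (in a freshly shuffled order) each choose 1-3 foraging
#' sites. A site's weight is the product of its food availability, a
#' fidelity boost for sites the bat used on earlier nights, and a
#' kin-attraction term `exp(gamma * mean relatedness)` towards bats already
#' assigned to the site that night. Location fixes are emitted as Gaussian
#' scatter around the chosen site centres plus commuting fixes between the
#' bat's roost and its first site; the true visit table is returned for
#' oracle comparisons.
#'
#' @param landscape A `landscape` from [sim_landscape()].
#' @param kinship Symmetric ground-truth relatedness matrix whose dimnames
#'   cover `bats` (e.g. from [kinship_matrix()]).
#' @param config A [sim_config()].
#' @param season Season label used to look up food availability.
#' @param bats Character vector of bat ids to simulate (defaults to the
#'   first `n_bats` rows of `kinship`).
#' @return A list with `fixes` (tibble: `bat_id`, `night`, `timestamp`,
#'   `x`, `y`, `source`) and `visits` (tibble: `bat_id`, `night`,
#'   `site_id`) — the ground truth.
#' @export
sim_movement <- function(landscape, kinship, config, season = "winter",
                         bats = NULL) {
  if (nrow(landscape$sites) == 0L) stop("empty site list", call. = FALSE)
  if (is.null(bats)) bats <- rownames(kinship)[seq_len(min(config$n_bats, nrow(kinship)))]
  stopifnot(all(bats %in% rownames(kinship)))
  avail <- site_availability(landscape, season)
  site_ids <- landscape$sites$site_id
  n_sites <- length(site_ids)
  sx <- stats::setNames(landscape$sites$x, site_ids)
  sy <- stats::setNames(landscape$sites$y, site_ids)
  home_roost <- stats::setNames(
    sample(seq_len(nrow(landscape$roosts)), length(bats), replace = TRUE), bats)
  seen <- matrix(FALSE, length(bats), n_sites, dimnames = list(bats, site_ids))
  K <- kinship[bats, bats, drop = FALSE]
  diag(K) <- 0

  visits <- vector("list", config$n_nights)
  fixes <- vector("list", config$n_nights)
  for (t in seq_len(config$n_nights)) {
    occupants <- stats::setNames(vector("list", n_sites), site_ids)
    order_t <- sample(bats)
    night_visits <- vector("list", length(bats))
    night_fixes <- vector("list", length(bats))
    for (bi in seq_along(order_t)) {
      b <- order_t[bi]
      k_n <- if (length(config$sites_per_night) == 1L) config$sites_per_night
             else sample(config$sites_per_night, 1L)
      k_n <- min(k_n, n_sites)
      kin_term <- vapply(site_ids, function(s) {
        occ <- occupants[[s]]
        if (length(occ) == 0L) 0 else mean(K[b, occ])
      }, numeric(1))
      w <- avail * (1 + 9 * config$phi * seen[b, ]) * exp(config$gamma * kin_term)
      chosen <- if (n_sites == 1L) site_ids else {
        sample(site_ids, k_n, prob = w)
      }
      for (s in chosen) occupants[[s]] <- c(occupants[[s]], b)
      seen[b, chosen] <- TRUE
      night_visits[[bi]] <- tibble::tibble(bat_id = b, night = t, site_id = chosen)
      # site fixes: Gaussian scatter around centres, spread through the night
      nf <- config$fixes_per_visit * length(chosen)
      hrs <- sort(runif(nf, 19.5, 28.5))  # 19:30 to 04:30 next day
      site_rep <- rep(chosen, each = config$fixes_per_visit)
      fx <- rnorm(nf, sx[site_rep], config$fix_noise_sd)
      fy <- rnorm(nf, sy[site_rep], config$fix_noise_sd)
      src <- sample(c("triangulated", "manual_bearing", "exact_sighting"),
                    nf, replace = TRUE, prob = c(0.7, 0.2, 0.1))
      # commuting fixes between roost and first site
      if (config$n_commute_fixes > 0) {
        ro <- landscape$roosts[home_roost[[b]], ]
        fr <- runif(config$n_commute_fixes, 0.2, 0.5)
        cx <- ro$x + fr * (sx[chosen[1L]] - ro$x)
        cy <- ro$y + fr * (sy[chosen[1L]] - ro$y)
        fx <- c(cx, fx); fy <- c(cy, fy)
        hrs <- c(runif(config$n_commute_fixes, 19.0, 19.4), hrs)
        src <- c(rep("triangulated", config$n_commute_fixes), src)
      }
      date0 <- config$start_date + (t - 1L)
      ts <- as.POSIXct(paste(date0, "00:00:00"), tz = "UTC") + hrs * 3600
      night_fixes[[bi]] <- tibble::tibble(
        bat_id = b, night = t, timestamp = ts, x = fx, y = fy, source = src
      )
    }
    visits[[t]] <- dplyr::bind_rows(night_visits)
    fixes[[t]] <- dplyr::bind_rows(night_fixes)
  }
  list(
    fixes = dplyr::arrange(dplyr::bind_rows(fixes), .data$bat_id, .data$timestamp),
    visits = dplyr::arrange(dplyr::bind_rows(visits), .data$bat_id, .data$night,
                            .data$site_id)
  )
}

#' Simulate day-roost occupancy
#'
#' Each bat has a home roost and, on any given day, switches to a random
#' other roost with probability `switch_prob` — enough structure to make the
#' co-roosting matrix non-trivial.
#'
#' @param bats Character vector of bat ids.
#' @param landscape A `landscape` (for the roost list).
#' @param n_days Number of days recorded.
#' @param switch_prob Daily probability of roosting away from home.
#' @return Tibble with columns `bat_id`, `day`, `roost_id`.
#' @export
sim_roosts <- function(bats, landscape, n_days = 10, switch_prob = 0.2) {
  roost_ids <- landscape$roosts$roost_id
  home <- stats::setNames(sample(roost_ids, length(bats), replace = TRUE), bats)
  purrr::map(bats, function(b) {
    r <- ifelse(runif(n_days) < switch_prob & length(roost_ids) > 1L,
                sample(roost_ids, n_days, replace = TRUE), home[[b]])
    tibble::tibble(bat_id = b, day = seq_len(n_days), roost_id = r)
  }) |> dplyr::bind_rows()
}

#' Simulate a complete two-season study
#'
#' End-to-end synthetic dataset: pedigree, genotypes, per-season landscapes,
#' nightly movement with ground-truth visits and kinship, and day-roost
#' records — everything the downstream pipeline consumes, plus the truth
#' needed for parameter-recovery tests.
#'
#' @param config A [sim_config()]. `config$seed`, when set, seeds the RNG so
#'   reruns are byte-identical.
#' @param regimes Named list of seasonal regimes (default [default_regimes()]).
#' @param kin_seasons Seasons in which kin attraction (`config$gamma`)
#'   operates; in other seasons gamma is forced to 0. Default: all seasons.
#' @return A list of class `sim_study` with elements `pedigree`, `kinship`,
#'   `freqs`, `genotypes`, `bats` (per-season id list), `landscapes`,
#'   `fixes`, `truth_visits`, `roost_records` (all tibbles keyed by season
#'   where relevant) and `config`.
#' @export
sim_study <- function(config = sim_config(), regimes = default_regimes(),
                      kin_seasons = names(regimes)) {
  if (!is.null(config$seed)) set.seed(config$seed)
  seasons <- names(regimes)
  n_total <- config$n_bats * length(seasons)
  ped <- sim_pedigree(founders = max(10, n_total), generations = 2,
                      litter_rate = 2)
  # track the most recent generation first so related pairs are common
  cand <- rev(ped$id)
  if (length(cand) < n_total) {
    stop("pedigree too small for the requested number of bats", call. = FALSE)
  }
  K <- kinship_matrix(ped)
  freqs <- sim_allele_freqs(config$n_loci, config$allele_range)
  geno <- sim_genotypes(ped, freqs, config$missing_rate)
  bats <- split(cand[seq_len(n_total)],
                rep(seasons, each = config$n_bats))[seasons]
  landscapes <- fixes <- truth <- roosts <- list()
  for (i in seq_along(seasons)) {
    s <- seasons[i]
    cfg_s <- config
    if (!s %in% kin_seasons) cfg_s$gamma <- 0
    cfg_s$start_date <- config$start_date + (i - 1L) * 120L
    landscapes[[s]] <- sim_landscape(regimes[[s]], season = s)
    mv <- sim_movement(landscapes[[s]], K, cfg_s, season = s, bats = bats[[s]])
    fixes[[s]] <- dplyr::mutate(mv$fixes, season = s)
    truth[[s]] <- dplyr::mutate(mv$visits, season = s)
    roosts[[s]] <- dplyr::mutate(
      sim_roosts(bats[[s]], landscapes[[s]], n_days = config$n_nights),
      season = s
    )
  }
  structure(
    list(pedigree = ped, kinship = K, freqs = freqs, genotypes = geno,
         bats = bats, landscapes = landscapes,
         fixes = dplyr::bind_rows(fixes),
         truth_visits = dplyr::bind_rows(truth),
         roost_records = dplyr::bind_rows(roosts),
         config = config),
    class = "sim_study"
  )
}

#' Write a simulated study to disk
#'
#' Writes the standard pipeline input files: `fixes.csv`, `sites.csv`,
#' `roosts.csv`, `genotypes.csv` (wide, two columns per locus),
#' `roost_records.csv`, `truth_visits.csv`, `truth_kinship.csv` and a
#' `manifest.yaml` recording the configuration and seed.
#'
#' @param study A `sim_study`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(study$fixes, file.path(dir, "fixes.csv"))
  sites <- purrr::imap(study$landscapes, function(ls, s) {
    dplyr::left_join(ls$sites,
      tidyr::pivot_wider(ls$trees, names_from = "species",
                         values_from = "n_trees", values_fill = 0L),
      by = "site_id")
  })
  readr::write_csv(dplyr::bind_rows(sites, .id = "season"),
                   file.path(dir, "sites.csv"))
  readr::write_csv(dplyr::bind_rows(purrr::map(study$landscapes, "roosts"),
                                    .id = "season"),
                   file.path(dir, "roosts.csv"))
  readr::write_csv(genotypes_wide(study$genotypes), file.path(dir, "genotypes.csv"))
  readr::write_csv(study$roost_records, file.path(dir, "roost_records.csv"))
  readr::write_csv(study$truth_visits, file.path(dir, "truth_visits.csv"))
  kin <- study$kinship
  readr::write_csv(
    tibble::as_tibble(kin, rownames = "id"), file.path(dir, "truth_kinship.csv"))
  cfg <- study$config
  cfg$start_date <- as.character(cfg$start_date)
  yaml::write_yaml(list(config = unclass(cfg)), file.path(dir, "manifest.yaml"))
  invisible(dir)
}

#' Pivot a long genotype table to the wide on-disk layout
#'
#' @param genotypes Long genotype tibble (`id`, `locus`, `allele_1`,
#'   `allele_2`).
#' @return A tibble with one row per individual and columns
#'   `locus_<l>_a`, `locus_<l>_b`.
#' @export
genotypes_wide <- function(genotypes) {
  long <- tidyr::pivot_longer(genotypes, c("allele_1", "allele_2"),
                              names_to = "chrom", values_to = "allele")
  long$col <- paste0("locus_", long$locus, "_",
                     ifelse(long$chrom == "allele_1", "a", "b"))
  tidyr::pivot_wider(long[, c("id", "col", "allele")],
                     names_from = "col", values_from = "allele")
}

#' Read a wide genotype CSV back into long form
#'
#' @param path CSV with columns `id` and `locus_<l>_a` / `locus_<l>_b`.
#' @return A long genotype tibble as produced by [sim_genotypes()].
#' @export
read_genotypes <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  long <- tidyr::pivot_longer(wide, -"id", names_to = "col", values_to = "allele")
  m <- regmatches(long$col, regexec("^locus_([0-9]+)_([ab])$", long$col))
  long$locus <- as.integer(vapply(m, `[`, "", 2L))
  long$chrom <- ifelse(vapply(m, `[`, "", 3L) == "a", "allele_1", "allele_2")
  tidyr::pivot_wider(long[, c("id", "locus", "chrom", "allele")],
                     names_from = "chrom", values_from = "allele") |>
    dplyr::arrange(.data$id, .data$locus)
}
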