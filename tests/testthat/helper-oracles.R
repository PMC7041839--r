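# Independent brute-force oracles used across the test files. These are kept
# deliberately naive (exhaustive loops) so they cannot share a defect with
# the package implementations they check.

# convex hull by exhaustive edge test: a point pair (i, j) is a hull edge iff
# every other point lies on one side of the line through them; hull vertices
# are the endpoints of hull edges. Valid for small n with no duplicate points.
brute_hull_vertices <- function(x, y) {
  n <- length(x)
  pts <- unique(cbind(x, y))
  n <- nrow(pts)
  if (n <= 2) return(pts)
  on_hull <- rep(FALSE, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      cr <- (pts[, 1] - pts[i, 1]) * (pts[j, 2] - pts[i, 2]) -
            (pts[, 2] - pts[i, 2]) * (pts[j, 1] - pts[i, 1])
      cr <- cr[-c(i, j)]
      if (all(cr <= 1e-9) || all(cr >= -1e-9)) {
        on_hull[c(i, j)] <- TRUE
      }
    }
  }
  pts[on_hull, , drop = FALSE]
}

# polygon area by summing triangle areas from the centroid of the hull,
# independent of the shoelace route used in the package
brute_hull_area <- function(x, y) {
  v <- brute_hull_vertices(x, y)
  if (nrow(v) < 3) return(0)
  ctr <- colMeans(v)
  ang <- atan2(v[, 2] - ctr[2], v[, 1] - ctr[1])
  v <- v[order(ang), , drop = FALSE]
  n <- nrow(v)
  s <- 0
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    s <- s + abs((v[i, 1] - ctr[1]) * (v[j, 2] - ctr[2]) -
                 (v[j, 1] - ctr[1]) * (v[i, 2] - ctr[2])) / 2
  }
  unname(s)
}

# network metrics by explicit edge / triangle counting on an adjacency matrix
brute_metrics <- function(A) {
  n <- nrow(A)
  deg <- rowSums(A > 0)
  edges <- sum(A[upper.tri(A)] > 0)
  cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] > 0)
    if (length(nb) < 2) { cc[i] <- 0; next }
    links <- 0
    for (a in seq_along(nb)) for (b in seq_along(nb)) {
      if (a < b && A[nb[a], nb[b]] > 0) links <- links + 1
    }
    cc[i] <- 2 * links / (length(nb) * (length(nb) - 1))
  }
  list(density = edges / (n * (n - 1) / 2), k = deg / (n - 1), clustering = cc)
}

# all permutations of 1..n (n small)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L)) {
    for (pos in 0:(n - 1L)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos)
    }
  }
  out
}

# exhaustive single-predictor QAP p-value on the DSP residual scale:
# enumerate every simultaneous row/column permutation of the centred
# predictor and count |beta*| >= |beta_obs|
exhaustive_qap_p <- function(Y, X) {
  n <- nrow(Y)
  idx <- which(row(Y) != col(Y))
  yv <- Y[idx]; y_res <- yv - mean(yv)
  e <- X - mean(X[idx])
  diag(e) <- 0
  e_obs <- e[idx] - mean(e[idx])
  b_obs <- sum(y_res * e_obs) / sum(e_obs^2)
  cnt <- 0L; tot <- 0L
  for (pm in all_perms(n)) {
    ev <- e[pm, pm][idx]
    er <- ev - mean(ev)
    b <- sum(y_res * er) / sum(er^2)
    tot <- tot + 1L
    if (abs(b) >= abs(b_obs) - 1e-12) cnt <- cnt + 1L
  }
  cnt / tot
}

# a small long-format genotype tibble from a compact list spec:
# list(I1 = list(c("a","a"), c("b","c")), ...), one element per locus
make_geno <- function(spec) {
  purrr::imap(spec, function(loci, id) {
    tibble::tibble(
      id = id,
      locus = seq_along(loci),
      allele_1 = vapply(loci, `[`, "", 1),
      allele_2 = vapply(loci, `[`, "", 2)
    )
  }) |> dplyr::bind_rows()
}

# single-season simulation used by power/calibration checks: pedigree with
# 2 x n_bats founders, two generations, youngest bats tracked
sim_season <- function(n_bats = 20, gamma = 0, regime = default_regimes()$winter,
                       season = "winter", n_nights = 8, phi = 0.5) {
  ped <- sim_pedigree(2 * n_bats, 2)
  K <- kinship_matrix(ped)
  bats <- rev(ped$id)[seq_len(n_bats)]
  ls <- sim_landscape(regime, season)
  cfg <- sim_config(n_bats = n_bats, n_nights = n_nights, gamma = gamma,
                    phi = phi)
  mv <- sim_movement(ls, K, cfg, season, bats = bats)
  Kb <- K[bats, bats]; diag(Kb) <- 0
  list(ped = ped, K = Kb, bats = bats, landscape = ls, fixes = mv$fixes,
       visits = mv$visits)
}
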