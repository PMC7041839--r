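#' Estimate population allele frequencies from a genotype table
#'
#' Simple counting estimator: per locus, each observed allele copy counts
#' once; frequencies are counts over `2 x` (typed individuals). Missing
#' cells are excluded. The full sample is used, including any focal pair —
#' the usual default for pairwise-relatedness software.
#'
#' @param genotypes Long genotype tibble (`id`, `locus`, `allele_1`,
#'   `allele_2`).
#' @return A tibble with columns `locus`, `allele`, `freq`.
#' @export
estimate_allele_freqs <- function(genotypes) {
  g <- dplyr::filter(genotypes, !is.na(.data$allele_1) & !is.na(.data$allele_2))
  all_loci <- unique(genotypes$locus)
  if (!all(all_loci %in% g$locus)) {
    stop("locus with zero typed individuals", call. = FALSE)
  }
  n_typed <- dplyr::count(dplyr::distinct(g, .data$locus, .data$id), .data$locus,
                          name = "n_typed")
  if (any(n_typed$n_typed < 2L)) {
    stop("each locus needs at least 2 typed individuals", call. = FALSE)
  }
  long <- tidyr::pivot_longer(g, c("allele_1", "allele_2"), values_to = "allele")
  long |>
    dplyr::count(.data$locus, .data$allele) |>
    dplyr::left_join(n_typed, by = "locus") |>
    dplyr::mutate(freq = .data$n / (2 * .data$n_typed)) |>
    dplyr::select("locus", "allele", "freq") |>
    dplyr::arrange(.data$locus, .data$allele)
}

# tibble -> list of named per-locus frequency vectors, indexed by locus label
freqs_as_list <- function(freqs) {
  if (is.list(freqs) && !is.data.frame(freqs)) {
    if (is.null(names(freqs))) names(freqs) <- as.character(seq_along(freqs))
    return(freqs)
  }
  sp <- split(freqs, freqs$locus)
  stats::setNames(
    lapply(sp, function(d) stats::setNames(d$freq, d$allele)),
    names(sp)
  )
}

#' Joint genotype-pair probabilities conditional on IBD state
#'
#' For one locus, returns the joint probability of observing an (ordered)
#' pair of unordered diploid genotypes given that the pair shares 0, 1 or 2
#' alleles identical by descent, under Hardy-Weinberg with no inbreeding —
#' the classical conditional table underlying maximum-likelihood pairwise
#' relatedness.
#'
#' @param g1,g2 Length-2 character vectors: the two alleles of each
#'   individual at this locus (order within a genotype irrelevant).
#' @param p Named numeric vector of allele frequencies at the locus.
#' @return Numeric vector `c(P0, P1, P2)`.
#' @export
ibd_pair_probs <- function(g1, g2, p) {
  al <- unique(c(g1, g2))
  if (!all(al %in% names(p))) stop("allele absent from frequencies", call. = FALSE)
  hom1 <- g1[1] == g1[2]; hom2 <- g2[1] == g2[2]
  pg <- function(g, hom) if (hom) p[[g[1]]]^2 else 2 * p[[g[1]]] * p[[g[2]]]
  P0 <- pg(g1, hom1) * pg(g2, hom2)
  same <- setequal(g1, g2) && hom1 == hom2
  shared <- intersect(g1, g2)
  if (hom1 && hom2) {
    # (aa, aa) or (aa, bb)
    P2 <- if (same) p[[g1[1]]]^2 else 0
    P1 <- if (same) p[[g1[1]]]^3 else 0
  } else if (hom1 || hom2) {
    # one homozygote: (aa, ac-type)
    hom_g <- if (hom1) g1 else g2
    het_g <- if (hom1) g2 else g1
    P2 <- 0
    P1 <- if (hom_g[1] %in% het_g) {
      other <- het_g[het_g != hom_g[1]][1]
      p[[hom_g[1]]]^2 * p[[other]]
    } else 0
  } else {
    # both heterozygous
    if (same) {
      a <- g1[1]; b <- g1[2]
      P2 <- 2 * p[[a]] * p[[b]]
      P1 <- p[[a]] * p[[b]] * (p[[a]] + p[[b]])
    } else if (length(shared) >= 1L) {
      a <- shared[1]
      b <- setdiff(g1, a)[1]; cc <- setdiff(g2, a)[1]
      P2 <- 0
      P1 <- p[[a]] * p[[b]] * p[[cc]]
    } else {
      P2 <- 0; P1 <- 0
    }
  }
  c(P0 = unname(P0), P1 = unname(P1), P2 = unname(P2))
}

#' Log-likelihood of a genotype pair given IBD coefficients
#'
#' Sums, over loci typed in both individuals, the log of
#' `k0 * P0 + k1 * P1 + k2 * P2` where the `P`s are the IBD-conditional
#' joint genotype probabilities of [ibd_pair_probs()].
#'
#' @param geno_a,geno_b Long genotype tibbles for one individual each
#'   (`locus`, `allele_1`, `allele_2`).
#' @param freqs Allele frequencies: tibble from [estimate_allele_freqs()]
#'   or a per-locus list.
#' @param k Numeric `c(k0, k1, k2)` on the 2-simplex.
#' @return The log-likelihood (scalar). Loci missing in either individual
#'   are skipped.
#' @export
pair_loglik <- function(geno_a, geno_b, freqs, k) {
  check_simplex(k)
  P <- pair_prob_table(geno_a, geno_b, freqs)
  if (ncol(P) == 0L) return(NA_real_)
  sum(log(colSums(P * k)))
}

check_simplex <- function(k) {
  if (length(k) != 3L || any(k < -1e-12) || abs(sum(k) - 1) > 1e-6) {
    stop("`k` must lie on the 2-simplex", call. = FALSE)
  }
  invisible(k)
}

# 3 x n_loci matrix of (P0, P1, P2) for the loci typed in both individuals
pair_prob_table <- function(geno_a, geno_b, freqs) {
  fl <- freqs_as_list(freqs)
  a <- geno_a[!is.na(geno_a$allele_1) & !is.na(geno_a$allele_2), ]
  b <- geno_b[!is.na(geno_b$allele_1) & !is.na(geno_b$allele_2), ]
  loci <- intersect(a$locus, b$locus)
  out <- vapply(loci, function(l) {
    ga <- unlist(a[a$locus == l, c("allele_1", "allele_2")], use.names = FALSE)
    gb <- unlist(b[b$locus == l, c("allele_1", "allele_2")], use.names = FALSE)
    ibd_pair_probs(ga, gb, fl[[as.character(l)]])
  }, numeric(3))
  matrix(out, nrow = 3L, dimnames = list(c("P0", "P1", "P2"), NULL))
}

# grid of simplex points (k0, k1, k2) at the given step
simplex_grid <- function(step) {
  k1 <- seq(0, 1, by = step)
  g <- expand.grid(k1 = k1, k2 = k1)
  g <- g[g$k1 + g$k2 <= 1 + 1e-12, ]
  cbind(k0 = pmax(0, 1 - g$k1 - g$k2), k1 = g$k1, k2 = g$k2)
}

# maximize sum(log(G %*% P)) over the simplex: coarse grid then shrinking
# local grids until the log-likelihood gain drops below `tol`
ml_pair_k <- function(P, grid_step = 0.02, tol = 1e-6) {
  eval_grid <- function(G) {
    L <- log(G %*% P)
    rowSums(L)
  }
  G <- simplex_grid(grid_step)
  ll <- eval_grid(G)
  best <- which.max(ll)
  k_best <- G[best, ]; ll_best <- ll[best]
  step <- grid_step
  repeat {
    step <- step / 2
    if (step < 1e-9) break
    d <- seq(-2, 2) * step
    loc <- expand.grid(k1 = k_best[2] + d, k2 = k_best[3] + d)
    loc <- loc[loc$k1 >= 0 & loc$k2 >= 0 & loc$k1 + loc$k2 <= 1, ]
    if (nrow(loc) == 0L) next
    Gl <- cbind(k0 = 1 - loc$k1 - loc$k2, k1 = loc$k1, k2 = loc$k2)
    lll <- eval_grid(Gl)
    i <- which.max(lll)
    if (lll[i] > ll_best) {
      gain <- lll[i] - ll_best
      k_best <- Gl[i, ]; ll_best <- lll[i]
      if (gain < tol && step < grid_step / 8) break
    } else if (step < tol) break
  }
  list(k = k_best, loglik = ll_best)
}

#' Maximum-likelihood pairwise relatedness
#'
#' For every pair of individuals, maximises the genotype-pair likelihood
#' over the IBD simplex (k0, k1, k2) — a 0.02-step grid search followed by
#' local refinement to a log-likelihood tolerance of 1e-6 — and reports the
#' relatedness coefficient `r = k1/2 + k2`. Deterministic given its inputs.
#' Pairs sharing no typed locus get `NA` estimates.
#'
#' @param genotypes Long genotype tibble (`id`, `locus`, `allele_1`,
#'   `allele_2`) for two or more individuals.
#' @param freqs Allele frequencies; defaults to
#'   [estimate_allele_freqs()] on `genotypes`.
#' @param grid_step Coarse grid resolution on the simplex (default 0.02).
#' @param tol Log-likelihood refinement tolerance (default 1e-6).
#' @return A tibble of class `relatedness_df`: one row per unordered pair
#'   (`id_a`, `id_b`, `k0`, `k1`, `k2`, `r`, `n_loci`, `loglik`), with the
#'   individual ordering stored in `attr(, "ids")`.
#' @export
ml_relatedness <- function(genotypes, freqs = NULL, grid_step = 0.02,
                           tol = 1e-6) {
  ids <- unique(genotypes$id)
  if (length(ids) < 2L) stop("need at least 2 individuals", call. = FALSE)
  if (is.null(freqs)) freqs <- estimate_allele_freqs(genotypes)
  fl <- freqs_as_list(freqs)
  # per-individual allele matrices for speed
  g <- genotypes[!is.na(genotypes$allele_1) & !is.na(genotypes$allele_2), ]
  by_id <- split(g[, c("locus", "allele_1", "allele_2")], g$id)[ids]
  pairs <- utils::combn(length(ids), 2L)
  res <- purrr::map(seq_len(ncol(pairs)), function(pi) {
    i <- pairs[1L, pi]; j <- pairs[2L, pi]
    P <- pair_prob_table(by_id[[i]], by_id[[j]], fl)
    if (ncol(P) == 0L) {
      return(tibble::tibble(id_a = ids[i], id_b = ids[j], k0 = NA_real_,
                            k1 = NA_real_, k2 = NA_real_, r = NA_real_,
                            n_loci = 0L, loglik = NA_real_))
    }
    fit <- ml_pair_k(P, grid_step = grid_step, tol = tol)
    tibble::tibble(
      id_a = ids[i], id_b = ids[j],
      k0 = fit$k[[1]], k1 = fit$k[[2]], k2 = fit$k[[3]],
      r = fit$k[[2]] / 2 + fit$k[[3]],
      n_loci = ncol(P), loglik = fit$loglik
    )
  })
  out <- dplyr::bind_rows(res)
  attr(out, "ids") <- ids
  class(out) <- c("relatedness_df", class(out))
  out
}

#' Square relatedness matrix from pairwise estimates
#'
#' @param rel A `relatedness_df` from [ml_relatedness()] (or any tibble
#'   with `id_a`, `id_b`, `r`).
#' @param ids Individual ordering (default: the ordering stored on `rel`).
#' @return Symmetric numeric matrix of `r` with zero diagonal.
#' @export
relatedness_matrix <- function(rel, ids = attr(rel, "ids")) {
  if (is.null(ids)) ids <- sort(unique(c(rel$id_a, rel$id_b)))
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  ia <- match(rel$id_a, ids); ib <- match(rel$id_b, ids)
  keep <- !is.na(ia) & !is.na(ib)
  M[cbind(ia[keep], ib[keep])] <- rel$r[keep]
  M[cbind(ib[keep], ia[keep])] <- rel$r[keep]
  M
}

# two-sample Kolmogorov-Smirnov D statistic; matches stats::ks.test (ties
# handled by evaluating the ECDF difference only at distinct jump points)
ks_stat <- function(x, y) {
  nx <- length(x); ny <- length(y)
  z <- c(x, y)
  ord <- order(z)
  steps <- cumsum(ifelse(ord <= nx, 1 / nx, -1 / ny))
  zs <- z[ord]
  keep <- c(diff(zs) != 0, TRUE)
  max(abs(steps[keep]))
}

#' Compare within-season relatedness distributions
#'
#' Kolmogorov-Smirnov D between the two seasons' within-season pairwise
#' relatedness values, with significance from node-based permutations:
#' individuals' season labels are shuffled and the within-group pair sets
#' (and D) recomputed, so the dyadic dependence between pairs sharing an
#' individual is respected.
#'
#' @param rel A `relatedness_df` or square relatedness matrix.
#' @param seasons Named character vector: individual id -> season label
#'   (exactly two distinct seasons, each with >= 2 individuals).
#' @param n_perm Number of permutations (default 10000).
#' @return A `node_perm_test` object with statistic `D` and permutation p.
#' @export
compare_r_distributions <- function(rel, seasons, n_perm = 10000) {
  M <- if (is.matrix(rel)) rel else relatedness_matrix(rel)
  ids <- intersect(rownames(M), names(seasons))
  lab <- seasons[ids]
  lv <- unique(lab)
  if (length(lv) != 2L) stop("need exactly 2 season groups", call. = FALSE)
  if (min(table(lab)) < 2L) stop("each season needs >= 2 individuals",
                                 call. = FALSE)
  M <- M[ids, ids]
  ut <- which(upper.tri(M), arr.ind = TRUE)
  vals <- M[ut]
  ok <- !is.na(vals)
  ut <- ut[ok, , drop = FALSE]; vals <- vals[ok]
  ia <- ut[, 1]; ib <- ut[, 2]
  stat_for <- function(lab) {
    la <- lab[ia]; lb <- lab[ib]
    ks_stat(vals[la == lv[1] & lb == lv[1]],
            vals[la == lv[2] & lb == lv[2]])
  }
  D <- stat_for(lab)
  count <- 0L
  for (b in seq_len(n_perm)) {
    if (stat_for(sample(lab)) >= D - 1e-12) count <- count + 1L
  }
  new_node_perm_test(
    statistic = c(D = D), p_value = perm_pvalue(count, n_perm),
    n_perm = n_perm, method = "Kolmogorov-Smirnov (node permutation)",
    estimate = NULL
  )
}
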