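new_node_perm_test <- function(statistic, p_value, n_perm, method,
                               estimate = NULL, extra = list()) {
  structure(
    c(list(statistic = statistic, estimate = estimate, p_value = p_value,
           n_perm = n_perm, method = method), extra),
    class = "node_perm_test"
  )
}

#' @export
print.node_perm_test <- function(x, ...) {
  cat(x$method, "\n")
  cat(sprintf("  %s = %.4f, p = %.4g (%d permutations)\n",
              names(x$statistic)[1], x$statistic[[1]], x$p_value, x$n_perm))
  invisible(x)
}

#' @method tidy node_perm_test
#' @export
tidy.node_perm_test <- function(x, ...) {
  tibble::tibble(
    statistic = unname(x$statistic[[1]]),
    term = names(x$statistic)[1],
    estimate = if (is.null(x$estimate)) NA_real_ else unname(x$estimate[[1]]),
    p.value = x$p_value
  )
}

#' @method glance node_perm_test
#' @export
glance.node_perm_test <- function(x, ...) {
  tibble::tibble(statistic = unname(x$statistic[[1]]), p.value = x$p_value,
                 n.perm = x$n_perm, method = x$method)
}

# off-diagonal vectorization index for an n x n matrix
offdiag_idx <- function(n) which(row(diag(n)) != col(diag(n)))

#' MR-QAP with double semi-partialling
#'
#' Multiple regression of a dyadic (square) matrix on one or more predictor
#' matrices, with significance from the quadratic assignment procedure in
#' the double-semi-partialling variant: each predictor is residualised on
#' the remaining predictors, the residual matrix is subjected to
#' simultaneous row/column (node) permutations, the model is refitted, and
#' the permutation distribution of the refitted coefficient yields a
#' two-sided p-value under the add-one convention. Diagonals are excluded;
#' for symmetric matrices both triangles enter, which leaves coefficients
#' unchanged.
#'
#' @param y Dependent n x n matrix.
#' @param x A single n x n matrix or a named list of predictor matrices.
#' @param n_perm Number of node permutations (default 10000).
#' @return An object of class `qap_fit` with per-predictor `estimate` and
#'   permutation `p.value` (see [tidy()]), the model correlation `r`
#'   (signed Pearson correlation for one predictor, multiple correlation
#'   otherwise), `r.squared`, `n_nodes` and `n_perm`.
#' @examples
#' set.seed(1)
#' a <- matrix(rnorm(64), 8); a <- a + t(a); diag(a) <- 0
#' fit <- mrqap_dsp(a, a, n_perm = 99)
#' tidy(fit)
#' @export
mrqap_dsp <- function(y, x, n_perm = 10000) {
  if (is.matrix(x)) x <- list(x1 = x)
  if (is.null(names(x)) || any(names(x) == "")) {
    names(x) <- paste0("x", seq_along(x))
  }
  n <- nrow(y)
  if (n < 4L) stop("need at least 4 nodes", call. = FALSE)
  if (any(!vapply(x, function(m) all(dim(m) == c(n, n)), logical(1))) ||
      ncol(y) != n) {
    stop("all matrices must share the same dimensions", call. = FALSE)
  }
  idx <- offdiag_idx(n)
  yv <- y[idx]
  Xv <- vapply(x, function(m) m[idx], numeric(length(idx)))
  const <- apply(Xv, 2L, function(v) diff(range(v)) == 0)
  if (any(const)) {
    stop(sprintf("constant predictor after vectorization: %s",
                 paste(names(x)[const], collapse = ", ")), call. = FALSE)
  }
  design <- cbind(`(Intercept)` = 1, Xv)
  qr_d <- qr(design)
  if (qr_d$rank < ncol(design)) {
    bad <- setdiff(colnames(design), colnames(design)[qr_d$pivot[seq_len(qr_d$rank)]])
    stop(sprintf("rank-deficient design; collinear predictor(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  beta <- qr.coef(qr_d, yv)
  fitted <- drop(design %*% beta)
  r2 <- 1 - sum((yv - fitted)^2) / sum((yv - mean(yv))^2)
  r <- if (length(x) == 1L) cor(yv, Xv[, 1L]) else sqrt(max(r2, 0))

  p_vals <- numeric(length(x))
  for (j in seq_along(x)) {
    Z <- design[, -(j + 1L), drop = FALSE]
    Hz <- solve(crossprod(Z), t(Z))          # (Z'Z)^-1 Z'
    y_res <- yv - Z %*% (Hz %*% yv)
    e_vec <- Xv[, j] - Z %*% (Hz %*% Xv[, j])
    e_mat <- matrix(0, n, n)
    e_mat[idx] <- e_vec
    b_obs <- sum(y_res * e_vec) / sum(e_vec^2)
    count <- 0L
    for (b in seq_len(n_perm)) {
      pm <- sample.int(n)
      ev <- e_mat[pm, pm][idx]
      er <- ev - Z %*% (Hz %*% ev)
      ss <- sum(er^2)
      b_star <- if (ss > 0) sum(y_res * er) / ss else 0
      if (abs(b_star) >= abs(b_obs) - 1e-12) count <- count + 1L
    }
    p_vals[j] <- perm_pvalue(count, n_perm)
  }
  structure(
    list(
      coefficients = tibble::tibble(
        term = names(x),
        estimate = unname(beta[-1L]),
        p.value = p_vals
      ),
      intercept = unname(beta[1L]),
      r = unname(r), r.squared = r2,
      n_nodes = n, n_perm = n_perm
    ),
    class = "qap_fit"
  )
}

#' @export
print.qap_fit <- function(x, ...) {
  cat(sprintf("MR-QAP (double semi-partialling), n = %d nodes, %d permutations\n",
              x$n_nodes, x$n_perm))
  cat(sprintf("  model r = %.4f (r^2 = %.4f)\n", x$r, x$r.squared))
  print(x$coefficients)
  invisible(x)
}

#' Per-predictor coefficients of a QAP fit
#' @param x A `qap_fit`.
#' @param ... Unused.
#' @return Tibble `term`, `estimate`, `p.value`.
#' @method tidy qap_fit
#' @export
tidy.qap_fit <- function(x, ...) x$coefficients

#' One-row model summary of a QAP fit
#' @param x A `qap_fit`.
#' @param ... Unused.
#' @return Tibble `r`, `r.squared`, `n.nodes`, `n.perm`.
#' @method glance qap_fit
#' @export
glance.qap_fit <- function(x, ...) {
  tibble::tibble(r = x$r, r.squared = x$r.squared, n.nodes = x$n_nodes,
                 n.perm = x$n_perm)
}

# Welch t statistic, defined as 0 when both groups have zero variance and
# equal means (degenerate data where stats::t.test refuses to run)
welch_t <- function(x1, x2) {
  se2 <- var(x1) / length(x1) + var(x2) / length(x2)
  d <- mean(x1) - mean(x2)
  if (se2 == 0) return(if (d == 0) 0 else sign(d) * Inf)
  d / sqrt(se2)
}

#' Node-permutation t-test
#'
#' Welch's t statistic for a node-level metric between two groups, with a
#' two-sided p-value from shuffling the group labels over nodes — the
#' node-based permutation appropriate for network-derived metrics whose
#' values are not independent observations.
#'
#' @param values Numeric vector of node values.
#' @param groups Factor/character of group labels (exactly 2 groups,
#'   each with >= 2 nodes).
#' @param n_perm Number of label permutations (default 10000).
#' @return A `node_perm_test` with statistic `t`, the mean difference as
#'   `estimate`, and permutation `p_value`.
#' @export
node_perm_ttest <- function(values, groups, n_perm = 10000) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) != 2L) stop("need exactly 2 groups", call. = FALSE)
  if (min(table(groups)) < 2L) stop("each group needs >= 2 nodes", call. = FALSE)
  g1 <- values[groups == lv[1]]; g2 <- values[groups == lv[2]]
  t_obs <- welch_t(g1, g2)
  n1 <- length(g1)
  count <- 0L
  for (b in seq_len(n_perm)) {
    pv <- sample(values)
    ts <- welch_t(pv[seq_len(n1)], pv[-seq_len(n1)])
    if (abs(ts) >= abs(t_obs) - 1e-12) count <- count + 1L
  }
  new_node_perm_test(
    statistic = c(t = t_obs), p_value = perm_pvalue(count, n_perm),
    n_perm = n_perm, method = "Welch t-test (node permutation)",
    estimate = c(mean_diff = mean(g1) - mean(g2))
  )
}

# tie-corrected Kruskal-Wallis H; 0 when every value is tied
kruskal_h <- function(values, groups) {
  n <- length(values)
  r <- rank(values)
  grp <- split(r, groups)
  H <- 12 / (n * (n + 1)) * sum(vapply(grp, function(g)
    length(g) * (mean(g) - (n + 1) / 2)^2, numeric(1)))
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr == 0) return(0)
  H / corr
}

#' Node-permutation Kruskal-Wallis test
#'
#' Tie-corrected Kruskal-Wallis H over node groups, with a p-value from
#' node-label permutations, plus Bonferroni-corrected pairwise Wilcoxon
#' rank-sum post-hoc comparisons on the observed data.
#'
#' @param values Numeric vector of node values.
#' @param groups Group labels (>= 2 groups, total n >= 5).
#' @param n_perm Number of permutations (default 10000).
#' @return A `node_perm_test` with statistic `H`, permutation `p_value`,
#'   and a `posthoc` tibble of Bonferroni-adjusted pairwise p-values.
#' @export
node_perm_kruskal <- function(values, groups, n_perm = 10000) {
  groups <- as.character(groups)
  lv <- unique(groups)
  if (length(lv) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (length(values) < 5L) stop("need total n >= 5", call. = FALSE)
  H_obs <- kruskal_h(values, groups)
  if (H_obs == 0) {
    p <- 1
  } else {
    count <- 0L
    for (b in seq_len(n_perm)) {
      if (kruskal_h(sample(values), groups) >= H_obs - 1e-12) count <- count + 1L
    }
    p <- perm_pvalue(count, n_perm)
  }
  ph <- NULL
  if (length(lv) > 2L || TRUE) {
    pw <- suppressWarnings(
      stats::pairwise.wilcox.test(values, groups, p.adjust.method = "bonferroni",
                                  exact = FALSE))
    ph <- tibble::as_tibble(as.table(pw$p.value), .name_repair = "minimal")
    names(ph) <- c("group_a", "group_b", "p.adj")
    ph <- ph[!is.na(ph$p.adj), ]
  }
  new_node_perm_test(
    statistic = c(H = H_obs), p_value = p, n_perm = n_perm,
    method = "Kruskal-Wallis (node permutation)",
    extra = list(posthoc = ph)
  )
}

#' Node-permutation linear regression
#'
#' OLS of one node metric on another (e.g. degree on the number of sites
#' visited). The slope and adjusted r-squared are taken from the usual
#' least-squares fit; the two-sided p-value for the slope comes from
#' permuting the response over nodes.
#'
#' @param y,x Numeric node vectors of equal length (n >= 4); `x` must not
#'   be constant.
#' @param n_perm Number of permutations (default 10000).
#' @return A `node_perm_test` with statistic `slope`, `adj_r_squared`, and
#'   permutation `p_value`.
#' @export
node_perm_regression <- function(y, x, n_perm = 10000) {
  n <- length(y)
  if (n < 4L) stop("need n >= 4", call. = FALSE)
  if (diff(range(x)) == 0) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(y ~ x)
  slope <- unname(stats::coef(fit)[2L])
  adj_r2 <- summary(fit)$adj.r.squared
  xc <- x - mean(x)
  ssx <- sum(xc^2)
  count <- 0L
  for (b in seq_len(n_perm)) {
    b_star <- sum(xc * sample(y)) / ssx
    if (abs(b_star) >= abs(slope) - 1e-12) count <- count + 1L
  }
  new_node_perm_test(
    statistic = c(slope = slope), p_value = perm_pvalue(count, n_perm),
    n_perm = n_perm, method = "Linear regression (node permutation)",
    estimate = c(slope = slope),
    extra = list(adj_r_squared = adj_r2)
  )
}
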