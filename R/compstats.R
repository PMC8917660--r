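## Compositional analysis of behavioral time budgets: log-ratio transforms,
## a rank-based Wilks'-lambda-type multivariate permutation test, and
## percentile-bootstrap confidence intervals of per-behavior log-ratio
## differences between groups.

#' Multiplicative zero replacement
#'
#' Zeros become `delta` (default half the smallest nonzero fraction in the
#' table) and nonzero parts are rescaled so each row still sums to 1.
#'
#' @param x numeric matrix or data frame of compositions (rows sum to 1).
#' @param delta replacement value; NULL for the default rule.
#' @return matrix of strictly positive compositions, rows summing to 1.
#' @export
zero_replace <- function(x, delta = NULL) {
  x <- as.matrix(x)
  if (any(x < 0)) stop("compositions must be non-negative", call. = FALSE)
  if (any(rowSums(x) == 0)) stop("a row is entirely zero", call. = FALSE)
  if (!any(x == 0)) return(x)
  if (is.null(delta)) delta <- min(x[x > 0]) / 2
  out <- x
  for (i in seq_len(nrow(x))) {
    z <- x[i, ] == 0
    if (!any(z)) next
    out[i, z] <- delta
    out[i, !z] <- x[i, !z] * (1 - sum(z) * delta) / sum(x[i, !z])
  }
  out
}

#' Centered log-ratio transform
#' @param x strictly positive composition matrix (rows are compositions).
#' @return matrix of clr coordinates (rows sum to 0).
#' @export
clr <- function(x) {
  x <- as.matrix(x)
  if (any(x <= 0)) stop("clr requires strictly positive parts", call. = FALSE)
  lx <- log(x)
  sweep(lx, 1, rowMeans(lx))
}

## Orthonormal sequential-binary-partition basis (D x (D-1)): balance j
## contrasts the first j parts against part j+1.
.ilr_basis <- function(D) {
  V <- matrix(0, D, D - 1)
  for (j in seq_len(D - 1)) {
    V[seq_len(j), j] <- sqrt(1 / (j * (j + 1)))
    V[j + 1, j] <- -sqrt(j / (j + 1))
  }
  V
}

#' Isometric log-ratio transform
#'
#' `y = clr(x) %*% V` with `V` an orthonormal balance basis (default: the
#' sequential binary partition in the fixed column order), mapping
#' D-part compositions to D-1 unconstrained coordinates.
#'
#' @param x strictly positive composition matrix.
#' @param basis optional `D x (D-1)` orthonormal basis.
#' @return matrix of ilr coordinates (`n x (D-1)`), with the basis in
#'   attribute `basis`.
#' @export
ilr <- function(x, basis = NULL) {
  x <- as.matrix(x)
  D <- ncol(x)
  if (is.null(basis)) basis <- .ilr_basis(D)
  stopifnot(nrow(basis) == D, ncol(basis) == D - 1)
  y <- clr(x) %*% basis
  colnames(y) <- paste0("ilr", seq_len(D - 1))
  attr(y, "basis") <- basis
  y
}

#' Inverse isometric log-ratio transform
#' @param y ilr coordinate matrix (`n x (D-1)`).
#' @param basis the basis used by [ilr()] (taken from `y`'s attribute if
#'   present).
#' @return composition matrix with rows summing to 1.
#' @export
ilr_inverse <- function(y, basis = NULL) {
  y <- as.matrix(y)
  if (is.null(basis)) basis <- attr(y, "basis")
  if (is.null(basis)) basis <- .ilr_basis(ncol(y) + 1)
  z <- exp(y %*% t(basis))
  sweep(z, 1, rowSums(z), "/")
}

## Rank-based Wilks' lambda: det(W) / det(T) on component-wise mid-ranks.
.rank_wilks <- function(ranks, groups) {
  n <- nrow(ranks)
  tot <- sweep(ranks, 2, colMeans(ranks))
  Tm <- crossprod(tot)
  W <- matrix(0, ncol(ranks), ncol(ranks))
  for (g in unique(groups)) {
    xg <- ranks[groups == g, , drop = FALSE]
    cg <- sweep(xg, 2, colMeans(xg))
    W <- W + crossprod(cg)
  }
  dT <- det(Tm)
  if (dT <= 0) return(NA_real_)
  det(W) / dT
}

#' Nonparametric multivariate group test (Wilks'-lambda type)
#'
#' Component-wise rank transform across all observations, Wilks' lambda
#' from the between/within rank scatter, and a permutation p-value over
#' group-label permutations: small lambda means group separation, so the
#' p-value is `(1 + #{perm lambda <= observed}) / (1 + n_perm)`.
#'
#' @param coords numeric matrix (observations x coordinates), e.g. ilr
#'   coordinates of behavioral time budgets.
#' @param groups group factor (>= 2 groups, each with >= 3 observations).
#' @param n_perm number of permutations (default 10000).
#' @param seed integer seed.
#' @return object of class `comp_test`: `statistic` (observed lambda),
#'   `p_value`, `n_perm`, `groups`, `dropped` (constant coordinates
#'   removed), `seed`.
#' @export
multivariate_group_test <- function(coords, groups, n_perm = 10000, seed = 1) {
  coords <- as.matrix(coords)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need >= 2 groups", call. = FALSE)
  if (any(table(groups) < 3)) stop("each group needs >= 3 observations", call. = FALSE)
  keep <- apply(coords, 2, function(v) stats::sd(v) > 0)
  dropped <- colnames(coords)[!keep]
  if (length(dropped) > 0) {
    warning("dropping constant coordinate(s): ", paste(dropped, collapse = ", "))
    coords <- coords[, keep, drop = FALSE]
  }
  if (ncol(coords) == 0) stop("no non-constant coordinates", call. = FALSE)
  ranks <- apply(coords, 2, rank)
  obs <- .rank_wilks(ranks, groups)
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  n <- nrow(ranks)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    lam <- .rank_wilks(ranks, groups[sample.int(n)])
    if (!is.na(lam) && lam <= obs) hits <- hits + 1L
  }
  structure(
    list(statistic = obs, p_value = (1 + hits) / (1 + n_perm),
         n_perm = n_perm, groups = table(groups), dropped = dropped,
         seed = as.integer(seed)),
    class = "comp_test"
  )
}

#' @export
print.comp_test <- function(x, ...) {
  cat(sprintf("<comp_test> rank Wilks' lambda = %.4f, permutation p = %.4g (%d perms)\n",
              x$statistic, x$p_value, x$n_perm))
  invisible(x)
}

#' @rdname tidy.keypoints
#' @export
glance.comp_test <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 n_perm = x$n_perm, seed = x$seed)
}

## clr of the geometric-mean composition of a sample of compositions
.clr_center <- function(x) {
  lx <- log(x)
  g <- colMeans(lx)
  g - mean(g)
}

#' Bootstrap log-ratio differences between two groups
#'
#' For each behavior, the estimate is the clr coordinate of group 1's
#' geometric-mean composition minus group 2's; the confidence interval is
#' a percentile bootstrap resampling mice within groups.
#'
#' @param x strictly positive composition matrix (use [zero_replace()]
#'   first if needed).
#' @param groups factor with exactly 2 levels (order defines the sign),
#'   each with >= 3 observations.
#' @param n_boot bootstrap resamples (default 5000).
#' @param conf confidence level (default 0.95).
#' @param seed integer seed.
#' @return tibble of class `logratio_ci`: `behavior`, `estimate`, `lo`,
#'   `hi`, plus attributes `n_boot`, `seed`.
#' @export
logratio_difference_ci <- function(x, groups, n_boot = 5000, conf = 0.95,
                                   seed = 1) {
  x <- as.matrix(x)
  groups <- as.factor(groups)
  lv <- levels(droplevels(groups))
  if (length(lv) != 2) stop("exactly 2 groups required", call. = FALSE)
  x1 <- x[groups == lv[1], , drop = FALSE]
  x2 <- x[groups == lv[2], , drop = FALSE]
  if (nrow(x1) < 3 || nrow(x2) < 3) stop("both groups need >= 3 mice", call. = FALSE)
  est <- .clr_center(x1) - .clr_center(x2)
  rs <- .local_rng(seed)
  on.exit(.restore_rng(rs), add = TRUE)
  n1 <- nrow(x1); n2 <- nrow(x2)
  l1 <- log(x1); l2 <- log(x2)
  boots <- matrix(0, n_boot, ncol(x))
  for (b in seq_len(n_boot)) {
    g1 <- colMeans(l1[sample.int(n1, n1, TRUE), , drop = FALSE])
    g2 <- colMeans(l2[sample.int(n2, n2, TRUE), , drop = FALSE])
    boots[b, ] <- (g1 - mean(g1)) - (g2 - mean(g2))
  }
  if (all(apply(boots, 2, stats::sd) == 0) && n1 + n2 > 2) {
    message("degenerate bootstrap: all resamples identical")
  }
  alpha <- (1 - conf) / 2
  qs <- apply(boots, 2, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  beh <- colnames(x)
  if (is.null(beh)) beh <- paste0("part", seq_len(ncol(x)))
  out <- tibble::tibble(
    behavior = beh, estimate = unname(est),
    lo = pmin(qs[1, ], est), hi = pmax(qs[2, ], est)
  )
  attr(out, "n_boot") <- n_boot
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("logratio_ci", class(out))
  out
}

#' Full compositional comparison of behavioral time budgets
#'
#' Convenience wrapper: zero replacement, ilr transform, multivariate
#' permutation test, and per-behavior bootstrap log-ratio differences for
#' a pair of groups.
#'
#' @param usage_tbl usage table (one row per mouse) as from
#'   [usage_table()], with a `mouse` column and one column per class.
#' @param groups per-mouse group factor.
#' @param n_perm,n_boot,seed see the underlying functions.
#' @return list with `test` (`comp_test`) and `log_ratios`
#'   (`logratio_ci`; NULL when more than two groups).
#' @export
compare_time_budgets <- function(usage_tbl, groups, n_perm = 10000,
                                 n_boot = 5000, seed = 1) {
  x <- as.matrix(usage_tbl[, setdiff(names(usage_tbl), "mouse")])
  x <- zero_replace(x)
  y <- ilr(x)
  test <- multivariate_group_test(y, groups, n_perm = n_perm, seed = seed)
  lr <- NULL
  if (nlevels(as.factor(groups)) == 2) {
    lr <- logratio_difference_ci(x, groups, n_boot = n_boot, seed = seed + 1)
  }
  list(test = test, log_ratios = lr)
}
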