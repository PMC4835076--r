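# Site-wise permutation comparison of patient vs control profiles.

#' Site-wise permutation test map
#'
#' At every site the observed statistic is `T = mean(controls) -
#' mean(patients)` (positive under atrophy). Group labels are randomly
#' permuted with fixed group sizes; one shuffle is applied to all sites
#' (shared permutation sequence), and the add-one estimator
#' `p = (1 + #\{T* >= T\}) / (n_perm + 1)` is used, so the smallest
#' attainable p-value is `1 / (n_perm + 1)` (1e-5 at 100,000 permutations).
#' With equal group sizes relabelings are drawn in antithetic pairs (each
#' shuffle plus its group-swap), which makes the null distribution exactly
#' symmetric in the sampled set.
#'
#' @param patients,controls numeric matrices, subjects x sites (vectors are
#'   treated as one-site columns; 3D arrays subjects x L x angles are
#'   flattened and the p-map is returned with matching shape).
#' @param n_perm number of permutations (default 100,000; a warning is
#'   issued below 100).
#' @param alpha supra-significance level for the `significant` map (default
#'   1e-3).
#' @param side `"decrease"` (one-sided: values lower in patients, the
#'   default), `"increase"`, or `"two-sided"`.
#' @param statistic `"mean_diff"` (default) or `"t"` (Welch t statistic).
#' @param seed RNG seed for the shared shuffle sequence.
#' @param antithetic draw relabelings in group-swap pairs when group sizes
#'   are equal.
#' @param chunk_sites number of sites processed per block (memory control).
#' @return A `comparison_map`: list with `p`, `statistic`, `significant`
#'   (all shaped like one subject's profile), `n_perm`, `alpha`, `side`,
#'   `se_p` (binomial standard error of each p).
#' @export
permutation_map <- function(patients, controls, n_perm = 100000L,
                            alpha = 1e-3, side = c("decrease", "increase", "two-sided"),
                            statistic = c("mean_diff", "t"),
                            seed = 1L, antithetic = TRUE, chunk_sites = 4000L) {
  side <- match.arg(side)
  statistic <- match.arg(statistic)
  shp <- NULL
  to_mat <- function(x) {
    if (is.array(x) && length(dim(x)) == 3L) {
      shp <<- dim(x)[2:3]
      return(matrix(x, nrow = dim(x)[1L]))
    }
    if (is.null(dim(x))) matrix(x, ncol = 1L) else as.matrix(x)
  }
  P <- to_mat(patients); C <- to_mat(controls)
  if (ncol(P) != ncol(C)) stop("patients and controls must have the same sites")
  if (nrow(P) < 2L || nrow(C) < 2L) stop("need >= 2 subjects per group")
  if (n_perm < 100L) warning("n_perm < 100 gives a very coarse p-value grid")
  np <- nrow(P); nc <- nrow(C); n <- np + nc
  X <- rbind(C, P)                       # controls first
  is_ctrl <- c(rep(TRUE, nc), rep(FALSE, np))

  stat_fun <- function(ctrl_idx_mat, Xb) {
    # ctrl_idx_mat: n_perm x n logical; Xb: n x sites
    if (statistic == "mean_diff") {
      W <- ctrl_idx_mat / nc - (!ctrl_idx_mat) / np
      W %*% Xb
    } else {
      m1 <- (ctrl_idx_mat / nc) %*% Xb
      m2 <- ((!ctrl_idx_mat) / np) %*% Xb
      s1 <- (ctrl_idx_mat / nc) %*% Xb^2 - m1^2
      s2 <- ((!ctrl_idx_mat) / np) %*% Xb^2 - m2^2
      (m1 - m2) / sqrt(pmax(s1 / (nc - 1), 0) + pmax(s2 / (np - 1), 0) + 1e-12)
    }
  }

  set.seed(seed)
  use_pairs <- antithetic && np == nc
  n_draw <- if (use_pairs) ceiling(n_perm / 2) else n_perm
  lab <- matrix(FALSE, if (use_pairs) 2L * n_draw else n_draw, n)
  for (b in seq_len(n_draw)) {
    pick <- sample.int(n, nc)
    lab[b, pick] <- TRUE
    if (use_pairs) lab[n_draw + b, -pick] <- TRUE
  }
  lab <- lab[seq_len(n_perm), , drop = FALSE]

  obs_lab <- matrix(is_ctrl, 1L, n)
  n_sites <- ncol(X)
  pvals <- numeric(n_sites)
  tobs_all <- numeric(n_sites)
  for (s0 in seq(1L, n_sites, by = chunk_sites)) {
    s1 <- min(n_sites, s0 + chunk_sites - 1L)
    Xb <- X[, s0:s1, drop = FALSE]
    tobs <- stat_fun(obs_lab, Xb)[1L, ]
    tperm <- stat_fun(lab, Xb)
    tol <- 1e-12 * (1 + abs(tobs))
    cnt <- switch(side,
      decrease  = colSums(tperm >= rep(tobs - tol, each = n_perm)),
      increase  = colSums(tperm <= rep(tobs + tol, each = n_perm)),
      "two-sided" = colSums(abs(tperm) >= rep(abs(tobs) - tol, each = n_perm)))
    pvals[s0:s1] <- (1 + cnt) / (n_perm + 1)
    tobs_all[s0:s1] <- tobs
  }
  reshape_map <- function(v) if (is.null(shp)) v else matrix(v, shp[1L], shp[2L])
  structure(list(p = reshape_map(pvals),
                 statistic = reshape_map(tobs_all),
                 significant = reshape_map(pvals < alpha),
                 n_perm = as.integer(n_perm), alpha = alpha, side = side,
                 stat_name = statistic, seed = as.integer(seed),
                 se_p = reshape_map(sqrt(pvals * (1 - pvals) / n_perm))),
            class = "comparison_map")
}

#' @export
print.comparison_map <- function(x, ...) {
  pmin_ <- min(x$p)
  cat(sprintf("<comparison_map> %d sites, %d permutations (%s, %s)\n",
              length(x$p), x$n_perm, x$side, x$stat_name))
  cat(sprintf("  min p = %.3g (SEp = %.2g), %d sites < alpha = %g\n",
              pmin_, sqrt(pmin_ * (1 - pmin_) / x$n_perm),
              sum(x$significant), x$alpha))
  invisible(x)
}

#' Cord atrophy rate profile
#'
#' `rate(z) = 100 * (mean_ctrl(z) - mean_pat(z)) / mean_ctrl(z)`, in percent
#' of the mean control CSA.
#'
#' @param patients,controls CSA matrices (subjects x L) or vectors.
#' @param map optional [permutation_map()] result; when given, the returned
#'   object carries a `significant` attribute for range reporting.
#' @return Length-`L` numeric vector (percent), class `atrophy_rate_profile`.
#' @export
atrophy_rate <- function(patients, controls, map = NULL) {
  P <- if (is.null(dim(patients))) matrix(patients, nrow = 1L) else as.matrix(patients)
  C <- if (is.null(dim(controls))) matrix(controls, nrow = 1L) else as.matrix(controls)
  if (ncol(P) != ncol(C)) stop("profiles must share slice count")
  mc <- colMeans(C); mp <- colMeans(P)
  if (any(mc <= 0)) stop("mean control CSA must be positive everywhere")
  rate <- 100 * (mc - mp) / mc
  if (!is.null(map)) attr(rate, "significant") <- as.vector(map$significant)
  class(rate) <- "atrophy_rate_profile"
  rate
}
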