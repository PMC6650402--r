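#' Steel many-to-one rank test by permutation
#'
#' Compares each treatment group against a shared control with the
#' Wilcoxon rank-sum statistic (midranks for ties) and controls the
#' family-wise error rate through the permutation distribution of the
#' maximum standardized statistic across treatments, with group labels
#' permuted jointly between the control and all treatments. This replaces
#' the classical equicorrelated-normal critical value tables: for the
#' small group sizes typical of tissue experiments (n = 4-5) the
#' permutation null is enumerated exactly; larger problems fall back to
#' seeded Monte Carlo.
#'
#' Adjusted p-values are single-step max-statistic probabilities
#' \eqn{p_i = P(\max_j T_j \ge T_i^{obs})}; Monte-Carlo p-values use the
#' add-one convention `(1 + #exceedances) / (n_perm + 1)`.
#'
#' @param control Numeric vector of control measurements (length >= 2).
#' @param treatments Named list of numeric treatment vectors (a single
#'   numeric vector is accepted for one treatment).
#' @param alternative `"two.sided"` (default; the experiments do not fix a
#'   direction), `"greater"` (treatment exceeds control) or `"less"`.
#' @param max_exact Enumerate the permutation null exactly when the total
#'   number of label arrangements is at most this (default 20000).
#' @param n_perm Monte-Carlo permutations otherwise (default 10000,
#'   the minimum recommended).
#' @param seed Integer seed, required for reproducible Monte-Carlo mode.
#' @return An object of class `steel_test`: a per-treatment table
#'   (standardized rank statistic, adjusted p-value, significance flag at
#'   the conventional 0.05 `*` and 0.01 `**` levels), the method used
#'   (`"exact_permutation"` or `"monte_carlo"`) and the number of
#'   arrangements/permutations.
#' @export
#' @examples
#' steel_test(c(1, 2), list(trt = c(3, 4)), alternative = "greater")
steel_test <- function(control, treatments,
                       alternative = c("two.sided", "greater", "less"),
                       max_exact = 20000, n_perm = 10000, seed = NULL) {
  alternative <- match.arg(alternative)
  if (!is.numeric(control) || length(control) < 2 || any(!is.finite(control)))
    stop_input("'control' must be finite numeric of length >= 2")
  if (is.numeric(treatments)) treatments <- list(treatments)
  if (!is.list(treatments) || length(treatments) == 0L)
    stop_input("'treatments' must be a non-empty list of numeric vectors")
  if (is.null(names(treatments)) || any(names(treatments) == ""))
    names(treatments) <- paste0("trt", seq_along(treatments))
  for (nm in names(treatments)) {
    v <- treatments[[nm]]
    if (!is.numeric(v) || length(v) < 1 || any(!is.finite(v)))
      stop_input("treatment '%s' must be finite numeric of length >= 1", nm)
  }
  check_scalar(max_exact, "max_exact")
  check_scalar(n_perm, "n_perm")
  if (n_perm < 1) stop_input("'n_perm' must be >= 1")

  pooled <- c(control, unlist(treatments, use.names = FALSE))
  sizes <- c(length(control), vapply(treatments, length, integer(1)))
  n0 <- sizes[1]
  k <- length(treatments)
  N <- length(pooled)
  if (diff(range(pooled)) == 0)
    warning("all measurements are tied across every group; p-values are 1")

  has_ties <- anyDuplicated(pooled) > 0

  # standardized midrank Mann-Whitney statistic for control vs one group
  pair_stat <- function(cv, tv) {
    nt <- length(tv)
    nc <- length(cv)
    m <- nc + nt
    r <- rank(c(cv, tv))
    U <- sum(r[(nc + 1):m]) - nt * (nt + 1) / 2
    tie <- table(c(cv, tv))
    v <- nc * nt / 12 * ((m + 1) - sum(tie^3 - tie) / (m * (m - 1)))
    if (v <= 0) 0 else (U - nc * nt / 2) / sqrt(v)
  }
  directed <- switch(alternative,
                     two.sided = abs,
                     greater = identity,
                     less = function(s) -s)

  offsets <- cumsum(c(0, sizes))
  grp_idx <- lapply(seq_along(sizes), function(g)
    (offsets[g] + 1):offsets[g + 1])
  stats_for <- function(assign_idx) {
    cv <- pooled[assign_idx[[1]]]
    vapply(seq_len(k), function(i)
      directed(pair_stat(cv, pooled[assign_idx[[i + 1]]])), numeric(1))
  }
  obs <- stats_for(grp_idx)

  n_arr <- prod(choose(N - offsets[-length(offsets)], sizes))
  eps <- 1e-9
  if (is.finite(n_arr) && n_arr <= max_exact) {
    splits <- enum_splits(seq_len(N), sizes)
    maxima <- vapply(splits, function(s) max(stats_for(s)), numeric(1))
    p_adj <- vapply(obs, function(o) mean(maxima >= o - eps), numeric(1))
    method <- "exact_permutation"
    n_used <- length(splits)
  } else {
    maxima <- with_seed(seed, {
      if (!has_ties) {
        steel_mc_fast(pooled, sizes, n_perm, directed)
      } else {
        vapply(seq_len(n_perm), function(p) {
          prm <- sample.int(N)
          idx <- lapply(seq_along(sizes), function(g) prm[grp_idx[[g]]])
          max(stats_for(idx))
        }, numeric(1))
      }
    })
    p_adj <- vapply(obs, function(o)
      (1 + sum(maxima >= o - eps)) / (n_perm + 1), numeric(1))
    method <- "monte_carlo"
    n_used <- n_perm
  }

  tab <- data.frame(
    treatment = names(treatments),
    n = sizes[-1],
    statistic = vapply(seq_len(k), function(i)
      pair_stat(control, treatments[[i]]), numeric(1)),
    p_adj = p_adj,
    signif = ifelse(p_adj < 0.01, "**", ifelse(p_adj < 0.05, "*", "")),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab, alternative = alternative, method = method,
                 n_permutations = n_used, control_n = n0),
            class = "steel_test")
}

# all ways to split `indices` into consecutive groups of the given sizes
enum_splits <- function(indices, sizes) {
  if (length(sizes) == 1L) return(list(list(indices)))
  first <- utils::combn(indices, sizes[1], simplify = FALSE)
  unlist(lapply(first, function(f) {
    lapply(enum_splits(setdiff(indices, f), sizes[-1]),
           function(r) c(list(f), r))
  }), recursive = FALSE)
}

# vectorized Monte-Carlo maxima for tie-free data: U statistics computed
# from the pairwise comparison matrix, variance constant per group size
steel_mc_fast <- function(pooled, sizes, n_perm, directed) {
  N <- length(pooled)
  n0 <- sizes[1]
  k <- length(sizes) - 1
  W <- outer(pooled, pooled, ">") + 0
  perms <- vapply(seq_len(n_perm), function(p) sample.int(N), integer(N))
  z0 <- matrix(0, N, n_perm)
  z0[cbind(as.vector(perms[seq_len(n0), , drop = FALSE]),
           rep(seq_len(n_perm), each = n0))] <- 1
  wz0 <- W %*% z0
  maxima <- rep(-Inf, n_perm)
  off <- n0
  for (i in seq_len(k)) {
    ni <- sizes[i + 1]
    idx <- perms[off + seq_len(ni), , drop = FALSE]
    U <- colSums(matrix(wz0[cbind(as.vector(idx),
                                  rep(seq_len(n_perm), each = ni))],
                        ni, n_perm))
    v <- n0 * ni * (n0 + ni + 1) / 12
    maxima <- pmax(maxima, directed((U - n0 * ni / 2) / sqrt(v)))
    off <- off + ni
  }
  maxima
}

#' @export
print.steel_test <- function(x, ...) {
  cat("Steel many-to-one rank test (", x$alternative, ", ", x$method,
      ", ", x$n_permutations, " arrangements; control n = ", x$control_n,
      ")\n", sep = "")
  print(x$table, row.names = FALSE)
  cat("signif: ** p < 0.01, * p < 0.05\n")
  invisible(x)
}

#' Spearman rank correlation and its square
#'
#' Spearman's rho on midranks; squared rho is the figure of merit used
#' when relating uptake rates to destructive comparator readouts (DNA
#' content, viability).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return A list with `rho`, `rho_squared` and `n`. A constant input
#'   vector makes the correlation undefined: `rho` is `NA` with a warning,
#'   not 0.
#' @export
spearman_correlation <- function(x, y) {
  if (!is.numeric(x) || !is.numeric(y) || length(x) != length(y))
    stop_input("'x' and 'y' must be numeric vectors of equal length")
  if (length(x) < 3) stop_input("need at least 3 observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_input("'x' and 'y' must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input; Spearman correlation undefined")
    return(list(rho = NA_real_, rho_squared = NA_real_, n = length(x)))
  }
  rho <- stats::cor(x, y, method = "spearman")
  list(rho = rho, rho_squared = rho^2, n = length(x))
}

#' Coefficient of variation in percent
#'
#' `100 * dispersion / mean`, with the dispersion either the standard
#' error of the mean (`"sem"`, the convention used when comparing the
#' precision of bioradiography and plate-reader assays) or the standard
#' deviation (`"sd"`).
#'
#' @param values Numeric vector, length >= 2.
#' @param dispersion `"sem"` (default) or `"sd"`.
#' @return CV in percent.
#' @export
coefficient_of_variation <- function(values, dispersion = c("sem", "sd")) {
  dispersion <- match.arg(dispersion)
  if (!is.numeric(values) || length(values) < 2 || any(!is.finite(values)))
    stop_input("'values' must be finite numeric of length >= 2")
  m <- mean(values)
  if (m == 0) stop_input("mean is zero; CV undefined")
  s <- stats::sd(values)
  if (dispersion == "sem") s <- s / sqrt(length(values))
  100 * s / m
}
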