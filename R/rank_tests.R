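#' Tie-corrected Kruskal-Wallis rank test
#'
#' The k-group rank test used throughout the analysis. Values are
#' midranked across groups, the statistic
#' \deqn{H = \frac{12}{N(N+1)} \sum_i R_i^2 / n_i - 3(N+1)}
#' is divided by the tie correction
#' \eqn{1 - \sum (t^3 - t) / (N^3 - N)} over tie groups of size t, and
#' the p-value comes from the upper tail of the chi-square distribution
#' with k - 1 degrees of freedom (the test's only tail). When every
#' value is identical the statistic is defined as 0 with p = 1.
#'
#' For small samples an exact permutation p-value is available: all
#' distinct assignments of the observed values to the group sizes are
#' enumerated and p is the proportion with H at least as large as
#' observed.
#'
#' @param values Numeric measurements.
#' @param groups Group labels, same length as `values`; >= 2 non-empty
#'   groups after NA removal. Groups of size 1 are allowed.
#' @param p_method `"chisq"` (default) or `"exact"` (full enumeration;
#'   total N must be <= 10).
#' @return List with `statistic` (H), `df`, `p`, `group_sizes`,
#'   `p_method`.
#' @examples
#' kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
kruskal_wallis <- function(values, groups,
                           p_method = c("chisq", "exact")) {
  p_method <- match.arg(p_method)
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(groups[keep])
  n_i <- table(groups)
  if (nlevels(groups) < 2) stop("need >= 2 non-empty groups")
  if (any(n_i == 0)) stop("empty group")
  n_tot <- length(values)
  if (n_tot < 3) stop("need total N >= 3")

  h <- .kw_statistic(values, as.integer(groups), nlevels(groups))
  df <- nlevels(groups) - 1
  if (p_method == "chisq") {
    p <- if (is.na(h)) 1 else stats::pchisq(h, df, lower.tail = FALSE)
  } else {
    if (n_tot > 10)
      stop("exact enumeration limited to N <= 10; use p_method = 'chisq'")
    p <- .kw_exact_p(values, as.integer(groups), nlevels(groups))
  }
  h_out <- if (is.na(h)) 0 else h
  list(statistic = h_out, df = df, p = p,
       group_sizes = as.integer(n_i), p_method = p_method)
}

# H with midranks and tie correction; NA when all values tie (caller
# maps that to H = 0, p = 1)
.kw_statistic <- function(values, g_idx, k) {
  n <- length(values)
  r <- rank(values)
  rsum <- vapply(seq_len(k), function(j) sum(r[g_idx == j]), numeric(1))
  n_i <- tabulate(g_idx, k)
  h0 <- 12 / (n * (n + 1)) * sum(rsum^2 / n_i) - 3 * (n + 1)
  t_sizes <- table(values)
  corr <- 1 - sum(t_sizes^3 - t_sizes) / (n^3 - n)
  if (corr <= 0) return(NA_real_)
  h0 / corr
}

# exact p by enumerating all distinct assignments of observations to the
# group sizes (multinomial combinations, built recursively)
.kw_exact_p <- function(values, g_idx, k) {
  n <- length(values)
  n_i <- tabulate(g_idx, k)
  h_obs <- .kw_statistic(values, g_idx, k)
  if (is.na(h_obs)) return(1)
  assignments <- .group_assignments(n, n_i)
  h_all <- vapply(assignments, function(g) {
    h <- .kw_statistic(values, g, k)
    if (is.na(h)) 0 else h
  }, numeric(1))
  mean(h_all >= h_obs - 1e-10)
}

.group_assignments <- function(n, n_i) {
  out <- list()
  recurse <- function(remaining, g, j) {
    if (j > length(n_i)) {
      out[[length(out) + 1]] <<- g
      return(invisible(NULL))
    }
    if (length(remaining) == n_i[j]) {
      g[remaining] <- j
      recurse(integer(0), g, j + 1)
      return(invisible(NULL))
    }
    picks <- utils::combn(remaining, n_i[j], simplify = FALSE)
    for (p in picks) {
      g2 <- g
      g2[p] <- j
      recurse(setdiff(remaining, p), g2, j + 1)
    }
  }
  recurse(seq_len(n), integer(n), 1L)
  out
}

#' Spearman rank-order correlation with midranks
#'
#' Pearson correlation of the midranks of the two vectors; significance
#' by the t approximation with n - 2 degrees of freedom. Both the
#' two-sided p-value (reported as `p`) and the one-sided upper-tail
#' p-value for a positive association are returned.
#'
#' @param x,y Paired numeric vectors, n >= 3, each with nonzero rank
#'   variance.
#' @return List with `rho`, `p` (two-sided), `p_one_sided` (positive
#'   association), `n`.
#' @export
spearman_rank <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need n >= 3 pairs")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    stop("zero rank variance: correlation undefined")
  rho <- stats::cor(rx, ry)
  if (abs(rho) >= 1 - 1e-12) {
    p_two <- 0
    p_one <- if (rho > 0) 0 else 1
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p_two <- 2 * stats::pt(-abs(tstat), df = n - 2)
    p_one <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  }
  list(rho = rho, p = p_two, p_one_sided = p_one, n = n)
}

#' Group tooth records for rank testing
#'
#' Pools the nine tooth positions into the three developmental classes
#' (DM1-DM3 into deciduous molars, M1-M3 into molars, P1-P3 into
#' premolars), drops records whose status marks the tooth as fallen out
#' or failed in chemical separation, and returns the values grouped by
#' the requested factor (tooth group or area).
#'
#' @param teeth Data frame with columns `area`, `tooth_class`, `status`
#'   and the value column.
#' @param by `"tooth_group"` or `"area"`.
#' @param value_col Name of the value column.
#' @return Tibble with columns `label` (the grouping factor) and
#'   `value`, records with non-`"ok"` status excluded.
#' @export
group_teeth <- function(teeth, by = c("tooth_group", "area"),
                        value_col = "value") {
  by <- match.arg(by)
  teeth <- as.data.frame(teeth)
  need <- c("area", "tooth_class", "status", value_col)
  if (!all(need %in% names(teeth)))
    stop("teeth must have columns area, tooth_class, status, ", value_col)
  map <- c(DM1 = "DM", DM2 = "DM", DM3 = "DM",
           M1 = "M", M2 = "M", M3 = "M",
           P1 = "P", P2 = "P", P3 = "P")
  grp <- map[as.character(teeth$tooth_class)]
  if (any(is.na(grp)))
    stop("unknown tooth code: ",
         paste(unique(teeth$tooth_class[is.na(grp)]), collapse = ", "))
  ok <- teeth$status == "ok" & !is.na(teeth[[value_col]])
  if (!any(ok)) stop("no usable records after status filtering")
  tibble::tibble(
    label = if (by == "tooth_group") unname(grp[ok]) else teeth$area[ok],
    value = teeth[[value_col]][ok]
  )
}
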