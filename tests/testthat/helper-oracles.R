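# independent oracles used across the suite

# all permutations of 1..n (recursive; small n only)
all_perms <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_perms(n - 1L)
  out <- vector("list", 0L)
  for (p in sub) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(p, n, after = pos - 1L)
    }
  }
  out
}

# exact permutation p for the Kruskal-Wallis H, with H taken from
# stats::kruskal.test (independent of the package's statistic and of its
# multiset-combination enumeration)
kw_exact_oracle <- function(values, groups) {
  h_of <- function(v) unname(stats::kruskal.test(v, factor(groups))$statistic)
  h_obs <- h_of(values)
  perms <- all_perms(length(values))
  h_all <- vapply(perms, function(p) h_of(values[p]), numeric(1))
  mean(h_all >= h_obs - 1e-10)
}

# midrank Spearman rho from first principles (no rank())
spearman_oracle <- function(x, y) {
  midrank <- function(v) {
    vapply(v, function(vi) sum(v < vi) + (sum(v == vi) + 1) / 2, numeric(1))
  }
  rx <- midrank(x)
  ry <- midrank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# noiseless counting series generated straight from the forward model
make_series <- function(activity_bq, t_hours, duration_min, thickness = 24,
                        calib = assay_calibration(),
                        constants = nuclide_constants()) {
  rate <- expected_gross_rate(activity_bq, t_hours, thickness, calib,
                              constants)
  data.frame(t_hours = t_hours, duration_min = duration_min,
             gross_counts = rate * duration_min)
}

# Table-2 stable Sr values of the two adult animals, pooled by class
adult_molars <- c(187, 205, 204, 190, 155, 126)
adult_premolars <- c(211, 213, 197, 137, 134, 121)
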