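test_that("adult molars and premolars have equal rank sums", {
  kw <- kruskal_wallis(c(adult_molars, adult_premolars),
                       rep(c("M", "P"), each = 6))
  r <- rank(c(adult_molars, adult_premolars))
  expect_equal(sum(r[1:6]), 39)
  expect_equal(sum(r[7:12]), 39)
  expect_identical(kw$statistic, 0)
  expect_equal(kw$p, 1)
})

test_that("statistic and p agree with the reference implementation,
           with and without ties", {
  set.seed(31)
  for (i in 1:20) {
    k <- sample(2:4, 1)
    n_i <- sample(3:9, k, replace = TRUE)
    v <- round(rnorm(sum(n_i), 100, 15), sample(c(0, 1), 1))  # forces ties
    g <- rep(seq_len(k), n_i)
    kw <- kruskal_wallis(v, g)
    ref <- stats::kruskal.test(v, factor(g))
    expect_equal(kw$statistic, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(kw$p, ref$p.value, tolerance = 1e-10)
    expect_equal(kw$df, unname(ref$parameter))
  }
})

test_that("H is invariant under strictly monotone transformation", {
  set.seed(32)
  v <- rlnorm(18, 3, 0.4)
  g <- rep(1:3, each = 6)
  h1 <- kruskal_wallis(v, g)$statistic
  h2 <- kruskal_wallis(log(v), g)$statistic
  h3 <- kruskal_wallis(v^3, g)$statistic
  expect_equal(h1, h2, tolerance = 1e-12)
  expect_equal(h1, h3, tolerance = 1e-12)
})

test_that("all-identical values give H = 0 and p = 1", {
  kw <- kruskal_wallis(rep(5, 9), rep(1:3, each = 3))
  expect_equal(kw$statistic, 0)
  expect_equal(kw$p, 1)
})

test_that("two-group H equals the squared standardised rank-sum
           statistic", {
  set.seed(33)
  for (i in 1:10) {
    n1 <- sample(4:8, 1)
    n2 <- sample(4:8, 1)
    v <- round(rnorm(n1 + n2, 50, 8), 1)
    g <- rep(1:2, c(n1, n2))
    n <- n1 + n2
    r <- rank(v)
    w <- sum(r[g == 1])
    t_sizes <- table(v)
    var_w <- n1 * n2 / 12 *
      ((n + 1) - sum(t_sizes^3 - t_sizes) / (n * (n - 1)))
    z2 <- (w - n1 * (n + 1) / 2)^2 / var_w
    expect_equal(kruskal_wallis(v, g)$statistic, z2, tolerance = 1e-10)
  }
})

test_that("exact permutation p matches a full-enumeration oracle", {
  cases <- list(
    list(v = c(3.1, 4.7, 2.2, 8.8, 6.1, 5.0, 7.3), g = c(1, 1, 1, 2, 2, 3, 3)),
    list(v = c(1, 2, 2, 4, 5, 6, 7, 8), g = rep(1:2, each = 4)),  # a tie
    list(v = c(10, 12, 9, 30, 31, 11, 13), g = c(1, 1, 1, 2, 2, 3, 3))
  )
  for (cs in cases) {
    p_pkg <- kruskal_wallis(cs$v, cs$g, p_method = "exact")$p
    p_orc <- kw_exact_oracle(cs$v, cs$g)
    expect_equal(p_pkg, p_orc, tolerance = 1e-12)
  }
  expect_error(kruskal_wallis(rnorm(12), rep(1:3, 4), p_method = "exact"),
               "N <= 10")
})

test_that("type-I error of the chi-square approximation is near nominal
           at the study's group sizes", {
  set.seed(34)
  n_i <- c(16, 24, 21)
  g <- rep(1:3, n_i)
  reps <- 2000
  rejected <- vapply(seq_len(reps), function(i) {
    kruskal_wallis(rnorm(sum(n_i)), g)$p < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.03)
  expect_lte(mean(rejected), 0.07)
})

test_that("rank correlation hits its closed-form anchors and the
           midrank oracle", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(spearman_rank(x, x * 2 + 1)$rho, 1)
  expect_equal(spearman_rank(x, rev(x))$rho, -1)
  expect_equal(spearman_rank(c(5, 1, 4, 2, 3), c(5, 1, 4, 2, 3))$rho, 1)
  # tied data against the brute-force midrank correlation
  xt <- c(1, 2, 2, 4, 5)
  yt <- c(3, 1, 4, 4, 6)
  s <- spearman_rank(xt, yt)
  expect_equal(s$rho, spearman_oracle(xt, yt), tolerance = 1e-12)
  ref <- suppressWarnings(stats::cor.test(xt, yt, method = "spearman"))
  expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_error(spearman_rank(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_error(spearman_rank(c(1, 2), c(1, 2)), "n >= 3")
})

test_that("tooth grouping pools classes and drops missing teeth", {
  tab <- stable_sr_table()
  young <- tab[tab$animal_id %in% c("H-young-1", "H-young-2",
                                    "L-young-1", "L-young-2"), ]
  g <- group_teeth(young, by = "tooth_group", value_col = "sr_ug_g")
  expect_equal(as.integer(table(g$label)[c("DM", "M", "P")]),
               c(11, 12, 10))
  # whole-table deciduous molar count matches the study's usable N
  g_all <- group_teeth(tab, by = "tooth_group", value_col = "sr_ug_g")
  expect_equal(sum(g_all$label == "DM"), 16)
  bad <- young
  bad$tooth_class[1] <- "Q9"
  expect_error(group_teeth(bad, value_col = "sr_ug_g"), "unknown tooth")
  none <- young
  none$status <- "fallen_out"
  expect_error(group_teeth(none, value_col = "sr_ug_g"), "no usable")
})
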