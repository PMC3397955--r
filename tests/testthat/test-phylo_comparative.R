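balanced4 <- ape::read.tree(text = "((a:10,b:10):90,(c:10,d:10):90);")

test_that("clades_at_cutoff: hand-traversed partitions", {
  # two cherries at age 10, root at 100
  p50 <- clades_at_cutoff(balanced4, 50)
  expect_identical(p50$n_clades, 2L)
  expect_identical(unname(p50$clade_of[c("a", "b")]), c(1L, 1L))
  expect_identical(unname(p50$clade_of[c("c", "d")]), c(2L, 2L))
  # cutoff above the root age: one clade with all leaves
  expect_identical(clades_at_cutoff(balanced4, 200)$n_clades, 1L)
  # strict "younger than": cherries at exactly the cutoff stay split
  expect_identical(clades_at_cutoff(balanced4, 10)$n_clades, 4L)
  expect_identical(clades_at_cutoff(balanced4, 10.5)$n_clades, 2L)
  expect_error(clades_at_cutoff(balanced4, -1), "positive")
  nonultra <- ape::read.tree(text = "((a:5,b:10):90,(c:10,d:10):90);")
  expect_error(clades_at_cutoff(nonultra, 50), "ultrametric")
})

test_that("partition property and monotone clade counts", {
  set.seed(31)
  for (i in 1:15) {
    tr <- simulate_yule_tree(sample(5:40, 1), 900, seed = i)
    counts <- vapply(c(50, seq(100, 900, 100)), function(ct) {
      p <- clades_at_cutoff(tr, ct)
      expect_identical(sort(names(p$clade_of)), sort(tr$tip.label))
      expect_identical(length(unique(p$clade_of)), p$n_clades)
      p$n_clades
    }, integer(1))
    expect_true(all(diff(counts) <= 0))  # non-increasing with cutoff
  }
})

test_that("morans_i: hand example, errors, affine invariance", {
  p <- clades_at_cutoff(balanced4, 50)
  m <- morans_i(c(a = 1, b = 1, c = 2, d = 2), p)
  expect_equal(m$I, 1.0)
  expect_equal(m$expected_I, -1 / 3)
  # undefined cases
  psing <- clades_at_cutoff(balanced4, 5)
  expect_error(morans_i(c(a = 1, b = 2, c = 3, d = 4), psing), "singleton")
  expect_error(morans_i(c(a = 1, b = 1, c = 1, d = 1), p), "zero variance")
  expect_error(morans_i(c(1, 1, 2, 2), p), "named")
  # affine invariance
  set.seed(32)
  tr <- simulate_yule_tree(15, 500, seed = 3)
  x <- simulate_trait(tr, "brownian", sigma2 = 0.01, seed = 4)
  part <- clades_at_cutoff(tr, 150)
  m1 <- morans_i(x, part)
  m2 <- morans_i(3.7 * x + 11, part)
  expect_equal(m1$I, m2$I)
  expect_equal(m1$p_value, m2$p_value)
  # log-base choice is an affine change, hence observationally irrelevant
  y <- exp(x)
  expect_equal(morans_i(log(y), part)$I, morans_i(log10(y), part)$I)
})

test_that("morans_i agrees with ape::Moran.I (randomisation variant)", {
  set.seed(33)
  for (i in 1:10) {
    tr <- simulate_yule_tree(sample(8:30, 1), 700, seed = i + 50)
    x <- simulate_trait(tr, "brownian", sigma2 = 0.01, seed = i + 90)
    part <- clades_at_cutoff(tr, sample(c(100, 200, 350), 1))
    if (all(tabulate(part$clade_of) <= 1)) next
    w <- outer(part$clade_of, part$clade_of, `==`) * 1
    diag(w) <- 0
    ref <- ape::Moran.I(x[names(part$clade_of)], w, scaled = FALSE)
    m <- morans_i(x, part)
    expect_equal(m$I, ref$observed, tolerance = 1e-10)
    expect_equal(m$expected_I, ref$expected, tolerance = 1e-10)
    expect_equal(m$sd_I, ref$sd, tolerance = 1e-10)
    expect_equal(m$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("morans_i null: permuted values average to -1/(n-1)", {
  set.seed(34)
  tr <- simulate_yule_tree(20, 600, seed = 8)
  part <- clades_at_cutoff(tr, 200)
  x <- stats::rnorm(20)
  names(x) <- names(part$clade_of)
  sims <- replicate(2000, {
    v <- sample(x)
    names(v) <- names(x)
    morans_i(v, part)$I
  })
  se <- stats::sd(sims) / sqrt(length(sims))
  expect_lt(abs(mean(sims) - (-1 / 19)), 4 * se)
})

test_that("correlogram keeps undefined cutoffs as NA rows", {
  vals <- c(a = 2, b = 2, c = 2, d = 2)  # constant: I undefined everywhere
  cg <- correlogram(balanced4, vals, cutoffs = c(50, 100, 200))
  expect_identical(nrow(cg), 3L)
  expect_true(all(is.na(cg$I)))
  expect_identical(cg$cutoff, c(50, 100, 200))
  expect_error(correlogram(balanced4, vals, cutoffs = c(100, 50)),
               "increasing")
  # default cutoffs: 50 then multiples of 100 to the root age
  cg2 <- correlogram(balanced4, c(a = 1, b = 1.5, c = 4, d = 3))
  expect_identical(cg2$cutoff, c(50, 100))
})

test_that("wilcoxon_rank_sum: enumeration oracle and identities", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5))$W, 0)
  expect_equal(wilcoxon_rank_sum(c(5, 6), c(1, 2, 3))$W, 6)
  x <- c(3, 1, 4, 1, 5)
  expect_equal(wilcoxon_rank_sum(x, x)$W, length(x)^2 / 2)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
  set.seed(35)
  for (i in 1:40) {
    a <- sample(0:8, sample(2:12, 1), replace = TRUE)  # ties likely
    b <- sample(0:8, sample(2:12, 1), replace = TRUE)
    wa <- wilcoxon_rank_sum(a, b)
    expect_equal(wa$W, oracle_wilcoxon_W(a, b), info = paste("iter", i))
    wb <- wilcoxon_rank_sum(b, a)
    expect_equal(wa$W + wb$W, length(a) * length(b))
    expect_equal(wa$p, suppressWarnings(stats::wilcox.test(a, b)$p.value))
  }
})

test_that("spearman_rho: monotone pairs, ties, oracle agreement", {
  expect_equal(spearman_rho(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_rho(1:10, -(1:10))$rho, -1)
  expect_equal(spearman_rho(1:10, (1:10)^3)$p, 0)
  expect_error(spearman_rho(1:3, 1:4), "equal length")
  expect_error(spearman_rho(c(1, 1, 1), c(1, 2, 3)), "zero rank variance")
  set.seed(36)
  for (i in 1:25) {
    n <- sample(5:40, 1)
    a <- sample(0:9, n, replace = TRUE)
    b <- a + sample(0:9, n, replace = TRUE)
    s <- spearman_rho(a, b)
    ref <- suppressWarnings(stats::cor.test(a, b, method = "spearman",
                                            exact = FALSE))
    expect_equal(s$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(s$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("normal-theory p agrees with the permutation oracle", {
  set.seed(37)
  cases <- list(
    list(model = "brownian", sigma2 = 0.002, cutoff = 200),
    list(model = "white_noise", sigma2 = 1, cutoff = 200),
    list(model = "white_noise", sigma2 = 1, cutoff = 100))
  for (cs in cases) {
    tr <- simulate_yule_tree(20, 600, seed = 71 + cs$cutoff)
    x <- simulate_trait(tr, cs$model, sigma2 = cs$sigma2, seed = 5)
    part <- clades_at_cutoff(tr, cs$cutoff)
    m <- morans_i(x, part)
    pp <- oracle_perm_moran_p(x, part, B = 4000L)
    expect_lt(abs(m$p_value - pp), 0.03)
  }
})
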