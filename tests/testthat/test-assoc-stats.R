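test_that("zscore standardizes to mean 0, sample SD 1, and is idempotent", {
  expect_equal(zscore(c(1, 2, 3)), c(-1, 0, 1))
  withr::with_seed(2, x <- rnorm(100, 50, 9))
  z <- zscore(x)
  expect_lt(abs(mean(z)), 1e-12)
  expect_lt(abs(sd(z) - 1), 1e-12)
  expect_equal(zscore(z), z, tolerance = 1e-12)
  expect_error(zscore(rep(5, 10)), "constant")
})

test_that("disadvantage score orients toward worse conditions", {
  tab <- tibble::tibble(
    area_id = c("A", "B"),
    pct_female_headed = c(40, 10), pct_poverty = c(30, 5),
    pct_unemployed = c(15, 3), pct_college = c(10, 50),
    median_income = c(25000, 90000)
  )
  out <- disadvantage_score(tab)
  expect_gt(out$disadvantage[1], out$disadvantage[2])  # A strictly worse
  expect_equal(sd(out$disadvantage), 1)
  expect_error(disadvantage_score(tab[, -2]), "missing component")
  # identical areas: no variance to decompose
  same <- tab[c(1, 1), ]
  expect_error(disadvantage_score(same), "constant")
})

test_that("disadvantage score recovers a latent factor", {
  withr::with_seed(33, {
    n <- 500
    latent <- rnorm(n)
    tab <- tibble::tibble(
      area_id = sprintf("A%03d", 1:n),
      pct_female_headed = 20 + 5 * latent + rnorm(n, 0, 2),
      pct_poverty = 15 + 6 * latent + rnorm(n, 0, 2),
      pct_unemployed = 8 + 3 * latent + rnorm(n, 0, 1.5),
      pct_college = 30 - 7 * latent + rnorm(n, 0, 3),     # reverse coded
      median_income = 55000 - 9000 * latent + rnorm(n, 0, 4000)
    )
  })
  out <- disadvantage_score(tab)
  expect_gt(cor(out$disadvantage, latent), 0.95)
  out_mean <- disadvantage_score(tab, method = "mean")
  expect_gt(cor(out_mean$disadvantage, latent), 0.95)
  expect_gt(cor(out$disadvantage, out_mean$disadvantage), 0.99)
})

test_that("ols_cluster recovers exact fits and rejects degenerate input", {
  df <- tibble::tibble(x = 1:20, y = 2 * (1:20),
                       county_id = rep(c("a", "b"), each = 10))
  fit <- ols_cluster(df, y ~ x, cluster = "county_id")
  co <- tidy(fit)
  expect_equal(co$estimate[co$term == "x"], 2, tolerance = 1e-12)
  expect_lt(co$std_error[co$term == "x"], 1e-10)
  # duplicated rows leave point estimates unchanged
  fit2 <- ols_cluster(dplyr::bind_rows(df, df), y ~ x, cluster = "county_id")
  expect_equal(tidy(fit2)$estimate, co$estimate, tolerance = 1e-12)
  # collinear predictors are named
  df$x2 <- 2 * df$x
  expect_error(ols_cluster(df, y ~ x + x2, cluster = "county_id"), "x2")
  # a single cluster is refused
  df$one <- "c"
  expect_error(ols_cluster(df, y ~ x, cluster = "one"), "2 clusters")
})

test_that("cluster-robust SEs match the independently computed sandwich", {
  skip_if_not_installed("sandwich")
  withr::with_seed(44, {
    G <- 12; m <- 8; n <- G * m
    cl <- rep(sprintf("c%02d", 1:G), each = m)
    u <- rnorm(G)[as.integer(factor(cl))]
    df <- tibble::tibble(
      x1 = rnorm(n), x2 = rnorm(n), county_id = cl,
      y = 1 + 0.5 * rnorm(n) + u
    )
    df$y <- df$y + 0.8 * df$x1 - 0.3 * df$x2
  })
  fit <- ols_cluster(df, y ~ x1 + x2, cluster = "county_id")
  lmfit <- lm(y ~ x1 + x2, data = df)
  v_ref <- sandwich::vcovCL(lmfit, cluster = df$county_id)
  expect_equal(unname(fit$vcov), unname(v_ref), tolerance = 1e-8)
  expect_equal(tidy(fit)$estimate, unname(coef(lmfit)), tolerance = 1e-10)
})

test_that("one observation per cluster reduces to HC1", {
  skip_if_not_installed("sandwich")
  withr::with_seed(45, {
    n <- 60
    df <- tibble::tibble(x = rnorm(n), county_id = sprintf("c%02d", 1:n))
    df$y <- 1 + 0.5 * df$x + rnorm(n) * (1 + abs(df$x))
  })
  fit <- ols_cluster(df, y ~ x, cluster = "county_id")
  lmfit <- lm(y ~ x, data = df)
  v_hc1 <- sandwich::vcovHC(lmfit, type = "HC1")
  # n/(n-1) * (n-1)/(n-k) = n/(n-k): identical to HC1 scaling
  expect_equal(unname(fit$vcov), unname(v_hc1), tolerance = 1e-8)
})

test_that("standardized coefficients are invariant to affine predictor rescaling", {
  withr::with_seed(46, {
    n <- 200
    df <- tibble::tibble(
      x = rnorm(n, 100, 15),
      county_id = rep(sprintf("c%02d", 1:20), each = 10)
    )
    df$y <- 3 + 0.4 * df$x + rnorm(n, 0, 10)
  })
  std <- function(x) zscore(x)
  f1 <- ols_cluster(dplyr::mutate(df, x = std(x), y = std(y)),
                    y ~ x, cluster = "county_id")
  f2 <- ols_cluster(dplyr::mutate(df, x = std(1000 + 42 * x), y = std(y)),
                    y ~ x, cluster = "county_id")
  expect_equal(tidy(f1)$estimate, tidy(f2)$estimate, tolerance = 1e-10)
  expect_equal(tidy(f1)$std_error, tidy(f2)$std_error, tolerance = 1e-10)
})

test_that("contiguity weights follow queen and rook rules", {
  l22 <- make_grid_layer(2, 2, 1, c(0, 0), 1)
  wq <- build_contiguity_weights(l22, "queen")
  # queen on a 2x2 grid: every cell touches the other 3 (corner counts)
  expect_true(all(rowSums(wq$adjacency) == 3))
  expect_true(all(abs(rowSums(wq$w) - 1) < 1e-12))
  expect_true(all(diag(wq$adjacency) == 0))
  wr <- build_contiguity_weights(l22, "rook")
  expect_true(all(rowSums(wr$adjacency) == 2))  # corners don't count
  # 1x3 strip: middle cell has 2 neighbors, ends 1
  l13 <- make_grid_layer(1, 3, 1, c(0, 0), 1)
  w13 <- build_contiguity_weights(l13, "queen")
  expect_equal(unname(rowSums(w13$adjacency)), c(1, 2, 1))
  expect_true(isSymmetric(wq$w * rowSums(wq$adjacency)))
})

test_that("morans_i matches the brute-force double sum", {
  brute_moran <- function(x, w) {
    n <- length(x); xb <- mean(x); num <- 0
    for (i in 1:n) for (j in 1:n) num <- num + w[i, j] * (x[i] - xb) * (x[j] - xb)
    (n / sum(w)) * num / sum((x - xb)^2)
  }
  withr::with_seed(55, {
    for (rep in 1:10) {
      r <- sample(3:5, 1); cc <- sample(3:5, 1)
      layer <- make_grid_layer(r, cc, 1, c(0, 0), 1)
      w <- build_contiguity_weights(layer, "queen")
      x <- rnorm(r * cc)
      expect_equal(morans_i(x, w), brute_moran(x, w$w), tolerance = 1e-12)
    }
  })
})

test_that("morans_i agrees with ape's implementation", {
  skip_if_not_installed("ape")
  layer <- make_grid_layer(4, 4, 1, c(0, 0), 2)
  w <- build_contiguity_weights(layer, "queen")
  withr::with_seed(56, x <- rnorm(16))
  ref <- ape::Moran.I(x, w$w, scaled = FALSE)
  expect_equal(morans_i(x, w), ref$observed, tolerance = 1e-10)
})

test_that("morans_i is negative on a checkerboard, positive on a gradient", {
  layer <- make_grid_layer(4, 4, 1, c(0, 0), 1)
  w <- build_contiguity_weights(layer, "rook")
  idx <- expand.grid(col = 1:4, row = 1:4)
  checker <- ifelse((idx$row + idx$col) %% 2 == 0, 1, -1)
  expect_lt(morans_i(checker, w), -0.9)     # strong negative autocorrelation
  gradient <- idx$row + idx$col
  expect_gt(morans_i(gradient, w), 0)
  expect_error(morans_i(rep(1, 16), w), "constant")
  expect_error(morans_i(1:2, w), "3 areas")
})

test_that("permutation null of morans_i has mean near -1/(n-1)", {
  layer <- make_grid_layer(4, 4, 1, c(0, 0), 1)
  w <- build_contiguity_weights(layer, "queen")
  withr::with_seed(57, {
    x <- rnorm(16)
    perms <- replicate(1000, morans_i(sample(x), w))
  })
  n <- 16
  expect_lt(abs(mean(perms) - (-1 / (n - 1))), 3 * sd(perms) / sqrt(1000))
})
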