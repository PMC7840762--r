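test_that("gamma tables normalize at the reference and decrease with the gap", {
  tab <- shipped_gamma()
  iR <- match(tab$reference["R"], tab$R)
  id <- match(tab$reference["d"], tab$d)
  iw <- match(tab$reference["w"], tab$w)
  expect_equal(tab$gamma[iR, id, iw], 1, tolerance = 1e-9)
  expect_true(all(tab$gamma > 0))
  ## monotone decreasing along d at every (R, w)
  for (i in seq_along(tab$R)) for (k in seq_along(tab$w))
    expect_true(all(diff(tab$gamma[i, , k]) < 0))
})

test_that("the normalized table is independent of the generating voltage", {
  t5 <- tiny_gamma(V = 5)
  t10 <- tiny_gamma(V = 10)
  expect_equal(t5$gamma, t10$gamma, tolerance = 1e-8)
})

test_that("trilinear interpolation is exact on nodes and linear tables", {
  tab <- linear_gamma()
  ## grid nodes return the stored values
  for (i in 1:2) for (j in 1:2) for (k in 1:2)
    expect_identical(interpolate_gamma(tab, tab$R[i], tab$d[j], tab$w[k]),
                     tab$gamma[i, j, k])
  ## cell midpoint of a trilinear table is the mean of the corners
  expect_equal(interpolate_gamma(tab, 6, 30, 20, scale = "linear"),
               mean(tab$gamma))
  ## a linear-in-all-axes function is reproduced exactly anywhere inside
  expect_equal(interpolate_gamma(tab, 5.2, 33, 14, scale = "linear"),
               0.2 + 0.05 * 5.2 + 0.01 * (60 - 33) + 0.02 * 14)
  ## out-of-hull queries error unless forced
  expect_error(interpolate_gamma(tab, 10, 30, 20), "extrapolation error")
  expect_warning(v <- interpolate_gamma(tab, 10, 30, 20, extrapolate = TRUE),
                 "extrapolating")
  expect_true(is.finite(v))
})

test_that("interpolated gamma predicts off-grid simulations within 5 percent", {
  tab <- shipped_gamma()
  cfg <- stretch_config(n_R = 16, R = 5, d = 35, w = 25)
  L_off <- suppressWarnings(simulate_stretch(cfg))$L_star
  ref <- tab$reference
  L_ref <- suppressWarnings(simulate_stretch(update_config(
    cfg, R = unname(ref["R"]), d = unname(ref["d"]),
    w = unname(ref["w"]))))$L_star
  expect_equal(interpolate_gamma(tab, 5, 35, 25), L_off / L_ref,
               tolerance = 0.05)
})

test_that("gamma tables round-trip through their text format", {
  tab <- tiny_gamma(V = 10)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gamma_table(tab, path)
  back <- read_gamma_table(path)
  expect_equal(back$gamma, tab$gamma, tolerance = 1e-9)
  expect_equal(back$R, tab$R)
  expect_equal(unname(back$reference), unname(tab$reference))
  expect_error(gamma_table(c(4, 8), c(20, 40), c(10, 30), rep(-1, 8),
                           c(R = 4, d = 20, w = 10)), "positive")
})

test_that("planted power-law exponents are recovered exactly", {
  set.seed(21)
  de <- c(15, 30, 45, 60, 90)
  for (alpha_true in c(0.6, 0.84, 1.1)) {
    dat <- do.call(rbind, lapply(1:5, function(g)
      data.frame(Lstar = runif(1, 0.5, 2) * de^alpha_true,
                 d_eps = de, geometry = paste0("g", g))))
    fit <- fit_alpha(dat)
    expect_equal(fit$alpha, alpha_true, tolerance = 5e-3)
    expect_lt(fit$max_relative_deviation, 1e-6)
  }
  ## fewer than three contrast levels per geometry is rejected
  expect_error(fit_alpha(data.frame(Lstar = 1:2, d_eps = c(10, 20),
                                    geometry = "g")), "contrast levels")
})

test_that("S is recovered from noiseless model data and scales linearly", {
  tab <- linear_gamma()
  set.seed(3)
  S_true <- 2.5e-3
  meas <- data.frame(V = rep(c(4, 8, 12), each = 4),
                     R = runif(12, 4, 8), d = runif(12, 20, 40),
                     w = runif(12, 10, 30))
  meas$Lstar <- predict_elongation(S_true, meas$V, meas$R, meas$d, meas$w,
                                   tab)
  fit <- fit_S(meas, tab)
  expect_equal(fit$S, S_true, tolerance = 1e-12)
  expect_lt(fit$se, 1e-12)
  ## scale equivariance
  meas2 <- meas
  meas2$Lstar <- 3 * meas$Lstar
  expect_equal(fit_S(meas2, tab)$S, 3 * S_true, tolerance = 1e-12)
  ## predict -> fit -> predict round trip is the identity
  pred <- predict_elongation(fit$S, meas$V, meas$R, meas$d, meas$w, tab)
  expect_equal(pred, meas$Lstar, tolerance = 1e-12)
  ## V = 0 predicts no elongation; doubling V quadruples the prediction
  expect_identical(predict_elongation(fit$S, 0, 5, 30, 20, tab), 0)
  expect_equal(predict_elongation(fit$S, 10, 5, 30, 20, tab),
               4 * predict_elongation(fit$S, 5, 5, 30, 20, tab))
  ## degenerate design
  meas$V <- 0; meas$Lstar <- 0
  expect_error(fit_S(meas, tab), "degenerate-design")
  ## D is reported when contrast and exponent are supplied
  fitD <- fit_S(meas2, tab, d_eps = 40, alpha = 0.84)
  expect_equal(fitD$D, fitD$S / 40^0.84)
})

test_that("distinct planted cell types separate as in a recovery study", {
  tab <- linear_gamma()
  set.seed(9)
  S_types <- c(a = 4e-3, b = 2e-3, c = 8e-4)
  rows <- list()
  for (ty in names(S_types)) for (cell in 1:6) {
    V <- c(4, 8, 12)
    Rr <- runif(1, 4, 8)
    noise <- rlnorm(3, -0.05^2 / 2, 0.05)
    rows[[paste(ty, cell)]] <- data.frame(
      cell_id = paste0(ty, cell), type = ty, V = V, R = Rr, d = 30, w = 20,
      Lstar = predict_elongation(S_types[[ty]], V, Rr, 30, 20, tab) * noise)
  }
  fit <- fit_S(do.call(rbind, rows), tab)
  pt <- fit$per_type[order(-fit$per_type$S_pooled), ]
  expect_identical(pt$type, c("a", "b", "c"))
  ## adjacent types separated by more than 3 standard errors
  expect_gt(pt$S_cell_mean[1] - pt$S_cell_mean[2],
            3 * sqrt(pt$S_cell_se[1]^2 + pt$S_cell_se[2]^2))
  expect_gt(pt$S_cell_mean[2] - pt$S_cell_mean[3],
            3 * sqrt(pt$S_cell_se[2]^2 + pt$S_cell_se[3]^2))
})

test_that("the factorized law collapses simulated data across V and geometry", {
  ## L*/(V^2 gamma) is constant over voltage and geometry for fixed
  ## materials: the lumped S of the simulator itself
  tab <- tiny_gamma(V = 10)
  combos <- expand.grid(V = c(5, 10), R = c(4, 6), d = c(30, 60))
  vals <- vapply(seq_len(nrow(combos)), function(i) {
    cfg <- stretch_config(n_R = 6, V = combos$V[i], R = combos$R[i],
                          d = combos$d[i], w = 20)
    L <- suppressWarnings(simulate_stretch(cfg))$L_star
    L / (combos$V[i]^2 *
           interpolate_gamma(tab, combos$R[i], combos$d[i], 20))
  }, numeric(1))
  expect_lt((max(vals) - min(vals)) / mean(vals), 1e-6)
})
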