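test_that("hdi is the narrowest window, with deterministic tie-breaking", {
  h <- hdi(1:100, 0.95)
  expect_equal(c(h$lo, h$hi), c(1, 95))  # all windows tie; lowest start wins

  set.seed(31)
  u <- runif(50000)
  h <- hdi(u)
  expect_lt(abs((h$hi - h$lo) - 0.95), 0.01)

  g <- rgamma(5000, shape = 2)
  h <- hdi(g)
  expect_equal(c(h$lo, h$hi), oracle_hdi(g), tolerance = 1e-12)

  expect_error(hdi(1:10), "at least 20")
  expect_error(hdi(1:100, mass = 1.2), "mass")
})

test_that("hdi equals the exhaustive-window oracle on random samples", {
  set.seed(32)
  for (i in 1:200) {
    n <- sample(25:400, 1)
    x <- switch(sample(3, 1),
                rnorm(n), rgamma(n, shape = runif(1, 0.5, 5)),
                rbeta(n, 2, 5))
    mass <- sample(c(0.5, 0.8, 0.9, 0.95), 1)
    h <- hdi(x, mass)
    expect_equal(c(h$lo, h$hi), oracle_hdi(x, mass), tolerance = 1e-12)
  }
})

test_that("symmetric unimodal samples give HDIs close to equal-tailed intervals", {
  set.seed(33)
  x <- rnorm(100000)
  h <- hdi(x)
  q <- quantile(x, c(0.025, 0.975))
  expect_lt(abs(h$lo - q[1]), 0.05)
  expect_lt(abs(h$hi - q[2]), 0.05)
})

test_that("posterior_mode finds the density peak", {
  expect_equal(posterior_mode(rep(3.7, 5)), 3.7)
  set.seed(34)
  x <- rbeta(100000, 2, 2)
  expect_lt(abs(posterior_mode(x) - 0.5), 0.02)
  # agreement with an independent coarse-histogram argmax within one bandwidth
  brk <- seq(min(x), max(x), length.out = 31)
  mids <- (brk[-1] + brk[-31]) / 2
  hist_mode <- mids[which.max(hist(x, brk, plot = FALSE)$counts)]
  expect_lt(abs(posterior_mode(x) - hist_mode), bw.nrd0(x) + diff(brk)[1])
  expect_error(posterior_mode(c(1, 2)), "at least 100")
})

ch0_ident <- function() {
  fake_chains(mu = setNames(as.list(rep(0.4, 4)), cell_labels()),
              kappa = setNames(as.list(rep(10, 4)), cell_labels()))
}

test_that("mu contrasts do the fixed-order cell arithmetic in items", {
  ch <- fake_chains(mu = list(enthusiastic.massed = 0.3, neutral.massed = 0.3,
                              enthusiastic.spaced = 0.5, neutral.spaced = 0.5),
                    kappa = list(enthusiastic.massed = 10, neutral.massed = 10,
                                 enthusiastic.spaced = 10, neutral.spaced = 10))
  sp <- mu_contrast_items(ch, "sequence")
  expect_equal(sp$mode, 7.2)
  expect_true(all(sp$draws == 7.2))
  en <- mu_contrast_items(ch, "enthusiasm")
  expect_equal(en$mode, 0)
  expect_false(en$excludes_zero)

  # all four cells identical: degenerate zero contrast
  ch0 <- fake_chains(mu = setNames(as.list(rep(0.4, 4)), cell_labels()),
                     kappa = setNames(as.list(rep(10, 4)), cell_labels()))
  z <- mu_contrast_items(ch0, "sequence")
  expect_equal(z$mode, 0)
  expect_equal(c(z$hdi$lo, z$hdi$hi), c(0, 0))
})

test_that("interaction and effect-size-difference contrasts are difference arithmetic", {
  # enthusiasm benefit 0.10 under massed, 0.05 under spaced -> 1.8 items
  ch <- fake_chains(mu = list(enthusiastic.massed = 0.40, neutral.massed = 0.30,
                              enthusiastic.spaced = 0.55, neutral.spaced = 0.50),
                    kappa = setNames(as.list(rep(10, 4)), cell_labels()))
  it <- interaction_contrast(ch, "items")
  expect_equal(it$mode, 36 * 0.05, tolerance = 1e-12)

  # additive cells: zero interaction
  ch_add <- fake_chains(mu = list(enthusiastic.massed = 0.40, neutral.massed = 0.30,
                                  enthusiastic.spaced = 0.60, neutral.spaced = 0.50),
                        kappa = setNames(as.list(rep(10, 4)), cell_labels()))
  expect_equal(interaction_contrast(ch_add, "items")$mode, 0, tolerance = 1e-12)

  # spacing main effect 8 items, enthusiasm 0.5 items -> difference 7.5
  d <- 8 / 36; e <- 0.5 / 36
  ch2 <- fake_chains(mu = list(enthusiastic.massed = 0.30 + e, neutral.massed = 0.30,
                               enthusiastic.spaced = 0.30 + d + e,
                               neutral.spaced = 0.30 + d),
                     kappa = setNames(as.list(rep(10, 4)), cell_labels()))
  expect_equal(effect_size_difference(ch2)$mode, 7.5, tolerance = 1e-9)
  expect_equal(mu_contrast_items(ch2, "sequence")$mode, 8, tolerance = 1e-9)
  expect_equal(mu_contrast_items(ch2, "enthusiasm")$mode, 0.5, tolerance = 1e-9)
  # identical factors cancel exactly
  expect_equal(effect_size_difference(ch0_ident())$mode, 0)
})

test_that("kappa contrasts work on the concentration scale, unscaled", {
  ch <- fake_chains(mu = setNames(as.list(rep(0.9, 4)), cell_labels()),
                    kappa = list(enthusiastic.massed = 14, neutral.massed = 10,
                                 enthusiastic.spaced = 14, neutral.spaced = 10))
  k <- kappa_contrast(ch, "enthusiasm")
  expect_equal(k$mode, 4)
  expect_equal(k$scale, "kappa")
  expect_equal(kappa_contrast(ch0_ident(), "sequence")$mode, 0)
})

test_that("swapping factor-level order negates the mode and reflects the HDI", {
  set.seed(35)
  mu <- list(enthusiastic.massed = runif(4000, 0.28, 0.34),
             neutral.massed = runif(4000, 0.25, 0.31),
             enthusiastic.spaced = runif(4000, 0.5, 0.56),
             neutral.spaced = runif(4000, 0.47, 0.53))
  ch <- fake_chains(mu = mu, kappa = setNames(as.list(rep(10, 4)), cell_labels()),
                    n_draws = 4000)
  # swap massed <-> spaced cell draws
  mu_sw <- list(enthusiastic.massed = mu$enthusiastic.spaced,
                neutral.massed = mu$neutral.spaced,
                enthusiastic.spaced = mu$enthusiastic.massed,
                neutral.spaced = mu$neutral.massed)
  ch_sw <- fake_chains(mu = mu_sw, kappa = setNames(as.list(rep(10, 4)), cell_labels()),
                       n_draws = 4000)
  a <- mu_contrast_items(ch, "sequence")
  b <- mu_contrast_items(ch_sw, "sequence")
  expect_equal(b$draws, -a$draws)
  expect_equal(c(b$hdi$lo, b$hdi$hi), c(-a$hdi$hi, -a$hdi$lo), tolerance = 1e-9)
  expect_equal(b$mode, -a$mode, tolerance = 2 * bw.nrd0(a$draws))
})

test_that("contrast summaries serialize to the JSON schema", {
  ch <- ch0_ident()
  ctr <- mu_contrast_items(ch, "sequence")
  path <- withr::local_tempfile(fileext = ".json")
  write_contrasts_json(list(ctr), path)
  j <- jsonlite::read_json(path)
  expect_named(j[[1]], c("name", "mode", "hdi_lo", "hdi_hi", "mass", "scale",
                         "excludes_zero"))
  expect_false(j[[1]]$excludes_zero)
})
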