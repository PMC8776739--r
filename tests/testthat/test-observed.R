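make_obs <- function(mu = 1.2, days = c(0, 3), a0 = 100, species = "SM",
                     treatment = "Control", replicate = 1) {
  tibble::tibble(replicate = replicate, treatment = treatment,
                 day = rep(days, each = length(species)),
                 species = rep(species, length(days)),
                 abundance = as.vector(sapply(days, function(d) a0 * exp(mu * d))))
}

test_that("interval growth rates recover the generating rate", {
  obs <- make_obs(mu = 1.2, days = c(0, 3))
  r <- interval_growth_rates(obs)
  expect_equal(r$mu, 1.2, tolerance = 1e-12)
  expect_false(r$extinct)
})

test_that("dilution correction re-inflates post-dilution densities", {
  # true growth 1.0/day over days 0-4-7; 100x dilution after sampling day 4
  ab <- c(100, 100 * exp(4), 100 * exp(4) / 100 * exp(3))
  obs <- tibble::tibble(replicate = 1, treatment = "Control",
                        day = c(0, 4, 7), species = "SM", abundance = ab)
  dil <- tibble::tibble(day = 4, factor = 100)
  r <- interval_growth_rates(obs, dilution = dil)
  expect_equal(r$mu, c(1, 1), tolerance = 1e-12)
  # without the correction the 4-7 interval is distorted by the dilution
  r0 <- interval_growth_rates(obs)
  expect_equal(r0$mu[2], 1 - log(100) / 3, tolerance = 1e-12)
  # per-treatment factors only apply to their own treatment
  dil_tr <- tibble::tibble(treatment = "Ag", day = 4, factor = 100)
  r1 <- interval_growth_rates(obs, dilution = dil_tr)
  expect_equal(r1$mu, r0$mu)
})

test_that("endpoints below detection yield missing rates with extinct flags", {
  obs <- tibble::tibble(replicate = 1, treatment = "Ag",
                        day = c(0, 4, 7), species = "TB",
                        abundance = c(100, 0.5, 0))
  r <- interval_growth_rates(obs, detection_limit = 1)
  expect_true(all(is.na(r$mu)))
  expect_true(all(r$extinct))
})

test_that("relative inhibition follows 1 - mu_t/mu_c and can exceed 1", {
  expect_equal(relative_inhibition(1.5, 1.5), 0)
  expect_equal(relative_inhibition(0.75, 1.5), 0.5)
  expect_equal(relative_inhibition(-0.2 * 1.5, 1.5), 1.2)
  expect_error(relative_inhibition(1, 0), class = "compsel_error")
  expect_error(relative_inhibition(1, -0.5), class = "compsel_error")
})

test_that("compute_inhibition pairs treatments with controls per interval", {
  days <- c(0, 4, 7)
  ctrl <- dplyr::bind_rows(lapply(1:2, function(r) {
    make_obs(mu = 1.0, days = days, replicate = r)
  }))
  trt <- make_obs(mu = 0.5, days = days, treatment = "Cd")
  rates <- interval_growth_rates(dplyr::bind_rows(ctrl, trt))
  inh <- compute_inhibition(rates)
  got <- inh$inhibition[inh$treatment == "Cd"]
  expect_equal(got, rep(0.5, 2), tolerance = 1e-12)
  # control against itself is identically 0
  expect_true(all(abs(inh$inhibition[inh$treatment == "Control"]) < 1e-12))
  # replicate pairing mode needs matching replicate ids
  inh2 <- compute_inhibition(rates, pairing = "replicate")
  expect_equal(inh2$inhibition[inh2$treatment == "Cd"], rep(0.5, 2),
               tolerance = 1e-12)
})

test_that("species relative biomass sums to 1 and floors extinct species", {
  obs <- tibble::tibble(replicate = 1, treatment = "Control", day = 0,
                        species = c("SM", "TB"), abundance = c(500, 500),
                        biomass = c(1000, 1000))
  sh <- species_relative_biomass(obs)
  expect_equal(sh$share, c(0.5, 0.5))
  ext <- tibble::tibble(replicate = 1, treatment = "Ag", day = 10,
                        species = c("SM", "TB"), abundance = c(0, 4000))
  sh2 <- species_relative_biomass(ext, measure = "abundance")
  expect_equal(sum(sh2$share), 1)
  expect_equal(sh2$share[1], 1 / 4001, tolerance = 1e-12)
})

test_that("inhibition summary produces interval rows plus unweighted averages", {
  inh <- tidyr::expand_grid(species = "SM", treatment = "Cd",
                            interval = c("0-4", "4-7", "7-10"),
                            replicate = 1:3) |>
    dplyr::mutate(inhibition = rep(c(0.3, 0.6, 0.6), each = 3) +
                    rep(c(-0.01, 0, 0.01), times = 3))
  tab <- summarize_inhibition(inh)
  ints <- tab[tab$interval != "Average", ]
  expect_equal(ints$mean_inhibition, c(0.3, 0.6, 0.6), tolerance = 1e-12)
  expect_equal(ints$n, rep(3L, 3))
  expect_equal(ints$sd, rep(0.01, 3), tolerance = 1e-12)
  avg <- tab[tab$interval == "Average", ]
  expect_equal(avg$mean_inhibition, 0.5, tolerance = 1e-12)
  # a single interval's average equals itself
  one <- summarize_inhibition(inh[inh$interval == "0-4", ])
  expect_equal(one$mean_inhibition[one$interval == "Average"], 0.3,
               tolerance = 1e-12)
})

test_that("coefficient of variation is scale-invariant and guards its domain", {
  withr::with_seed(3, x <- stats::runif(10, 1, 5))
  expect_equal(coefficient_of_variation(3 * x), coefficient_of_variation(x),
               tolerance = 1e-12)
  expect_equal(coefficient_of_variation(rep(2, 5)), 0)
  expect_equal(coefficient_of_variation(mean = 0.55, sd = 0.31), 0.31 / 0.55)
  expect_error(coefficient_of_variation(c(1, -1)), class = "compsel_error")
  expect_error(coefficient_of_variation(1), class = "compsel_error")
})

test_that("two-group comparisons behave on degenerate and simulated inputs", {
  a <- c(1, 2, 3, 4)
  r <- compare_groups(a, a, "welch_t")
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)
  rf <- compare_groups(a, rev(a), "var_f")
  expect_equal(rf$statistic, 1)
  rp <- compare_groups(a, a + c(0.9, 1.1, 1.0, 1.2), "paired_t")
  expect_lt(rp$p_value, 0.01)
  expect_error(compare_groups(c(-1, 2, 3), a[1:3], "welch_t", transform = "sqrt"),
               class = "compsel_transform_error")
  expect_error(compare_groups(1:3, 1:4, "paired_t"), class = "compsel_error")
  # power sanity: mean shift of 2 pooled SD at n = 4 rejects most of the time
  withr::with_seed(99, {
    rej <- sum(replicate(1000, {
      g1 <- stats::rnorm(4, 0, 1); g2 <- stats::rnorm(4, 2, 1)
      compare_groups(g1, g2, "welch_t")$p_value < 0.05
    }))
  })
  expect_gt(rej, 500)
})

test_that("PAM quantum yield is (Fm - F0)/Fm within [0, 1]", {
  expect_equal(fv_fm(0, 1), 1)
  expect_equal(fv_fm(1, 1), 0)
  expect_equal(fv_fm(0.35, 1), 0.65)
  expect_error(fv_fm(0.5, 0), class = "compsel_error")
  expect_error(fv_fm(1.2, 1), class = "compsel_error")
})
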