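test_that("specific growth rate follows its definition", {
  expect_equal(growth_rate_from_densities(1, exp(2), 0, 2), 1)
  expect_equal(growth_rate_from_densities(5, 5, 0, 3), 0)
  expect_lt(growth_rate_from_densities(10, 1, 0, 2), 0)
  # RFU-scale check: dilution floor to cap over one growth cycle
  expect_equal(growth_rate_from_densities(0.003, 0.5, 0, 3.3),
               log(0.5 / 0.003) / 3.3)
  expect_equal(growth_rate_from_densities(0.003, 0.5, 0, 3.3), 1.55,
               tolerance = 0.01)
  expect_error(growth_rate_from_densities(0, 1, 0, 1), class = "compsel_error")
  expect_error(growth_rate_from_densities(1, 1, 1, 1), class = "compsel_error")
})

test_that("inhibited growth rate applies the clamping policy", {
  expect_equal(inhibited_mu(1.5, 0), 1.5)
  expect_equal(inhibited_mu(1.5, 1), 0)
  expect_equal(inhibited_mu(1.5, 0.5), 0.75)
  expect_equal(inhibited_mu(1.5, 1.2, "clamp01"), 0)
  expect_equal(inhibited_mu(1.5, 1.2, "allow_negative"), -0.3)
  expect_equal(inhibited_mu(1.5, -0.2, "clamp01"), 1.5)    # no stimulation
  expect_equal(inhibited_mu(1.5, -0.2, "allow_negative"), 1.8)
})

test_that("exponential projection and its inverse are consistent", {
  expect_equal(project_density(2, 0, 10), 2)
  expect_equal(project_density(1, 1, 1), exp(1))
  expect_equal(project_density(1, -0.3, 10), exp(-3))
  expect_error(project_density(1, 1, -1), class = "compsel_error")
  withr::with_seed(5, {
    for (i in 1:20) {
      d0 <- stats::runif(1, 0.01, 100); mu <- stats::rnorm(1); t <- stats::runif(1, 0.1, 20)
      expect_equal(growth_rate_from_densities(d0, project_density(d0, mu, t), 0, t),
                   mu, tolerance = 1e-12)
    }
  })
})

test_that("relative density is a softmax of density projections", {
  # symmetry
  st <- two_species_strains(mu_sm = 1, mu_tb = 1)
  rd <- relative_density(st, times = c(0, 3, 17))
  expect_true(all(abs(rd$rd - 0.5) < 1e-12))
  # explicit-projection oracle, three strains at t = 10
  st3 <- tibble::tibble(strain_id = c("a", "b", "c"), species = "S",
                        mu = c(0.1, 0.2, 0.3))
  rd3 <- relative_density(st3, times = 10)
  direct <- project_density(1, st3$mu, 10)
  expect_equal(rd3$rd, direct / sum(direct), tolerance = 1e-12)
})

test_that("relative densities always sum to 1, even at extreme horizons", {
  withr::with_seed(21, {
    for (i in 1:25) {
      n <- sample(2:10, 1)
      st <- tibble::tibble(strain_id = paste0("s", 1:n), species = "S",
                           mu = stats::rnorm(n, 1, 0.5))
      d0 <- stats::runif(n, 0.1, 10)
      names(d0) <- st$strain_id
      rd <- relative_density(st, times = c(0, 1, 10, 1e4), initial_density = d0)
      sums <- tapply(rd$rd, rd$time, sum)
      expect_true(all(abs(sums - 1) < 1e-12))
      expect_true(all(rd$rd >= 0))
    }
  })
})

test_that("equal starts reduce to the share of exponential terms; unequal starts weight by D0", {
  st <- two_species_strains(mu_sm = c(1.4, 1.5, 1.6, 1.7),
                            mu_tb = c(0.2, 0.4, 0.6, 0.8))
  t <- 6
  rd <- relative_density(st, times = t)
  eq4 <- exp(st$mu * t) / sum(exp(st$mu * t))
  expect_equal(rd$rd, eq4, tolerance = 1e-12)
  d0 <- setNames(c(1, 2, 3, 4, 5, 6, 7, 8), st$strain_id)
  rdw <- relative_density(st, times = t, initial_density = d0)
  gen <- unname(d0) * exp(st$mu * t)
  expect_equal(rdw$rd, gen / sum(gen), tolerance = 1e-12)
})

test_that("the fittest strain dominates in the long run", {
  st <- two_species_strains(mu_sm = c(1.4, 1.5, 1.6, 1.75),
                            mu_tb = c(0.2, 0.4, 0.6, 0.8))
  rd <- relative_density(st, times = 1e4)
  expect_equal(rd$rd[rd$strain_id == "SM_4"], 1, tolerance = 1e-10)
})

test_that("treatment inhibition feeds the projection through I_<metal> columns", {
  st <- two_species_strains(I = list(Cd = c(rep(0.3, 4), rep(0.9, 4))))
  rd <- relative_density(st, metal = "Cd", times = 4)
  mu_mc <- inhibited_mu(st$mu, st[["I_Cd"]])
  expect_equal(unique(rd$mu_mc), unique(mu_mc))
  expect_error(relative_density(st, metal = "Cu", times = 1),
               "I_Cu", class = "compsel_schema_error")
})

test_that("population growth rate: uniform weights at t=0, species max at t->inf, monotone", {
  st <- two_species_strains(mu_sm = c(1.4, 1.5, 1.6, 1.7),
                            mu_tb = c(0.2, 0.4, 0.6, 0.8))
  pm0 <- population_mu(st, times = 0)
  expect_equal(pm0$mu_pop[pm0$species == "SM"], mean(c(1.4, 1.5, 1.6, 1.7)))
  expect_equal(pm0$mu_pop[pm0$species == "TB"], mean(c(0.2, 0.4, 0.6, 0.8)))
  pminf <- population_mu(st, times = 1e4)
  expect_equal(pminf$mu_pop, c(1.7, 0.8), tolerance = 1e-8)
  # deterministic Fisher-type property: selection only raises the mean
  pm <- population_mu(st, times = seq(0, 30, by = 0.5))
  for (sp in c("SM", "TB")) {
    expect_true(all(diff(pm$mu_pop[pm$species == sp]) >= -1e-12))
  }
  # identical strains: population rate equals the common rate at all times
  same <- two_species_strains()
  pmsame <- population_mu(same, times = c(0, 5, 50))
  expect_true(all(abs(pmsame$mu_pop[pmsame$species == "SM"] - 1.55) < 1e-12))
})

test_that("strain-by-strain matrix yields the full factorial of pairwise outcomes", {
  st <- two_species_strains(mu_sm = c(1.4, 1.5, 1.6, 1.7),
                            mu_tb = c(0.2, 0.4, 0.6, 0.8))
  m <- strain_by_strain_matrix(st[st$species == "SM", ], st[st$species == "TB", ],
                               times = 0:10)
  expect_equal(nrow(dplyr::distinct(m, strain_a, strain_b)), 16L)
  # a 1x1 matrix reproduces the two-strain relative density
  one <- strain_by_strain_matrix(st[1, ], st[5, ], times = 0:10)
  pair_rd <- relative_density(st[c(1, 5), ], times = 0:10)
  expect_equal(one$share_a, pair_rd$rd[pair_rd$strain_id == "SM_1"])
  # equal rates give a flat half-half trajectory
  flat <- strain_by_strain_matrix(
    tibble::tibble(strain_id = "a", species = "A", mu = 1),
    tibble::tibble(strain_id = "b", species = "B", mu = 1), times = 0:5)
  expect_true(all(abs(flat$share_a - 0.5) < 1e-12))
})

test_that("species share supports surface-area biomass weighting", {
  st <- two_species_strains()
  sh <- species_share(st, times = 0, biomass_per_cell = c(SM = 200, TB = 1600))
  expect_equal(sum(sh$share), 1)
  expect_equal(sh$share[sh$species == "TB"], 1600 / 1800, tolerance = 1e-12)
})
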