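# siting: coverage and weighted distance primitives, the greedy
# bi-objective loop against an exhaustive oracle, facility sizing,
# coverage reporting.

test_that("coverage is boundary-inclusive and matches a distance filter", {
  dem <- data.frame(id = c("a", "b", "c"), x = c(0, 300, 301), y = 0,
                    pop = c(5, 7, 11), stringsAsFactors = FALSE)
  cov <- coverage(c(0, 0), dem, 300)
  expect_setequal(cov$ids, c("a", "b"))  # 300 m exactly counts as covered
  expect_equal(cov$population, 12)
  expect_equal(coverage(c(5000, 5000), dem, 300), list(ids = character(0), population = 0))

  set.seed(81)
  dem <- random_demand(100)
  cand <- c(500, 500)
  cov <- coverage(cand, dem, 250)
  d <- sqrt((dem$x - 500)^2 + (dem$y - 500)^2)
  expect_setequal(cov$ids, dem$id[d <= 250])
})

test_that("weighted distance is the person-meter sum over the covered set", {
  one <- data.frame(id = "a", x = 100, y = 0, pop = 10)
  expect_equal(weighted_distance(c(0, 0), one), 1000)
  expect_equal(weighted_distance(c(100, 0), one), 0)
  expect_equal(weighted_distance(c(0, 0), one[0, ]), 0)

  set.seed(82)
  dem <- random_demand(50)
  wd <- weighted_distance(c(200, 700), dem)
  expect_equal(wd, sum(dem$pop * sqrt((dem$x - 200)^2 + (dem$y - 700)^2)))
})

test_that("greedy selection reproduces simple hand-built scenarios", {
  dem <- data.frame(id = paste0("d", 1:4), x = c(0, 50, 100, 150), y = 0,
                    pop = c(10, 10, 10, 10), stringsAsFactors = FALSE)
  cand <- data.frame(x = 75, y = 0)
  plan <- greedy_select(cand, dem, siting_config(service_radius = 300,
                                                 min_covered_population = 0))
  expect_equal(nrow(plan$rounds), 1)
  expect_length(plan$uncovered_demand_ids, 0)
  expect_equal(plan$rounds$covered_population, 40)

  # equal coverage, the nearer candidate wins the p-median tie-break
  dem <- data.frame(id = c("d1", "d2"), x = c(0, 1000), y = 0, pop = c(10, 10),
                    stringsAsFactors = FALSE)
  cand <- data.frame(x = c(200, 1001), y = 0)  # each covers one point
  plan <- greedy_select(cand, dem, siting_config(service_radius = 300,
                                                 min_covered_population = 0))
  expect_equal(plan$rounds$x[1], 1001)  # 1 m away beats 200 m away

  expect_error(greedy_select(cand[0, ], dem, siting_config()), "empty candidate")
})

test_that("greedy trace equals the exhaustive oracle on 100 random instances", {
  for (seed in 1:100) {
    set.seed(seed)
    nc <- sample(2:8, 1); nd <- sample(5:30, 1)
    cand <- data.frame(x = runif(nc, 0, 800), y = runif(nc, 0, 800))
    dem <- random_demand(nd, extent = 800)
    radius <- runif(1, 100, 400)
    plan <- greedy_select(cand, dem,
                          siting_config(service_radius = radius,
                                        min_covered_population = 0))
    picks <- oracle_greedy(cand, dem, radius)
    expect_equal(nrow(plan$rounds), length(picks))
    expect_equal(plan$rounds$x, cand$x[picks])
    expect_equal(plan$rounds$y, cand$y[picks])
  }
})

test_that("plans satisfy single assignment, monotone coverage and permutation invariance", {
  set.seed(301)
  for (rep in 1:10) {
    cand <- data.frame(x = runif(6, 0, 600), y = runif(6, 0, 600))
    dem <- random_demand(25, extent = 600)
    plan <- greedy_select(cand, dem, siting_config(service_radius = 200,
                                                   min_covered_population = 0))
    ids <- unlist(plan$covered_ids)
    expect_false(any(duplicated(ids)))                     # single assignment
    expect_setequal(c(ids, plan$uncovered_demand_ids), dem$id)
    expect_true(all(diff(plan$rounds$covered_population) <= 1e-9))  # non-increasing
    expect_equal(unname(plan$rounds$covered_population),
                 vapply(plan$covered_ids,
                        function(s) sum(dem$pop[dem$id %in% s]), numeric(1)))

    # shuffling demand order changes nothing (candidate order is the tie-break)
    perm <- sample(nrow(dem))
    plan2 <- greedy_select(cand, dem[perm, ], siting_config(service_radius = 200,
                                                            min_covered_population = 0))
    expect_equal(plan2$rounds$x, plan$rounds$x)
    expect_equal(plan2$rounds$y, plan$rounds$y)
  }
})

test_that("stopping rules respect the coverage floor and site cap", {
  set.seed(302)
  cand <- data.frame(x = c(100, 500), y = c(100, 500))
  dem <- data.frame(id = c("a", "b"), x = c(100, 500), y = c(100, 500),
                    pop = c(50, 20), stringsAsFactors = FALSE)
  plan <- greedy_select(cand, dem, siting_config(service_radius = 100,
                                                 min_covered_population = 30))
  expect_equal(nrow(plan$rounds), 1)  # second site would cover only 20 < 30
  expect_equal(plan$uncovered_demand_ids, "b")

  plan <- greedy_select(cand, dem, siting_config(service_radius = 100,
                                                 min_covered_population = 0,
                                                 max_sites = 1))
  expect_equal(nrow(plan$rounds), 1)
})

test_that("facility sizing follows the per-1000-person standard, rounded up", {
  expect_equal(size_facility(12430, 30), 373)
  expect_equal(size_facility(14390, 30), 432)
  expect_equal(size_facility(1000, 30), 30)
  expect_equal(size_facility(0, 30), 0)
  expect_error(size_facility(-1, 30), ">= 0")
  expect_error(size_facility(1000, 50), "standard")
  expect_equal(size_facility(1000, 50, allow_any_index = TRUE), 50)

  # non-decreasing in both arguments
  set.seed(83)
  pops <- sort(runif(20, 0, 2e4)); idx <- sort(runif(5, 15, 30))
  for (ai in idx) expect_true(all(diff(size_facility(pops, ai)) >= 0))
  by_index <- vapply(idx, function(ai) size_facility(5000, ai), numeric(1))
  expect_true(all(diff(by_index) >= 0))
})

test_that("coverage report computes the union-of-catchments fraction", {
  dem <- random_demand(60, extent = 1000)
  cand <- data.frame(x = 500, y = 500)
  plan <- greedy_select(cand, dem, siting_config(service_radius = 5000,
                                                 min_covered_population = 0))
  rep_all <- coverage_report(plan, NULL, dem, radius = 5000)
  expect_equal(rep_all$fraction_covered, 1.0)

  empty_plan <- greedy_select(cand, dem[0, ], siting_config(min_covered_population = 0))
  expect_equal(nrow(empty_plan$rounds), 0)
  expect_equal(coverage_report(empty_plan, NULL, dem, 300)$fraction_covered, 0)

  set.seed(84)
  existing <- data.frame(id = "c1", kind = "clinic", x = 200, y = 200,
                         service_radius = 250, stringsAsFactors = FALSE)
  plan <- greedy_select(data.frame(x = 800, y = 800), dem,
                        siting_config(service_radius = 300,
                                      min_covered_population = 0))
  rp <- coverage_report(plan, existing, dem, 300)
  served <- sqrt((dem$x - 200)^2 + (dem$y - 200)^2) <= 250 |
    sqrt((dem$x - 800)^2 + (dem$y - 800)^2) <= 300
  expect_equal(rp$fraction_covered, sum(dem$pop[served]) / sum(dem$pop))
})
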