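# Beach assignment, densities per 100 m, and pattern comparison.

small_coast <- function() {
  g <- grid_spec(-7, -2, 35, 37.5, 100, 50, daily_times(3))
  make_scenario("open_coast", g)
}

test_that("records map to the nearest segment with low-id tie-breaking", {
  sc <- small_coast()
  bd <- beaches_df(sc)
  s2 <- sc$beaches[[2]]
  mid <- colMeans(s2$vertices)
  expect_equal(assign_to_beach(data.frame(lon = mid[1], lat = mid[2]), sc),
               s2$id)
  # a point exactly below the shared endpoint of segments 2 and 3
  shared_lon <- sc$beaches[[2]]$vertices[2, 1]
  blat <- sc$beaches[[2]]$vertices[2, 2]
  expect_equal(assign_to_beach(data.frame(lon = shared_lon,
                                          lat = blat - 0.05), sc),
               sc$beaches[[2]]$id)
  # far inland (well beyond 2 cells) stays unassigned
  expect_true(is.na(assign_to_beach(data.frame(lon = mid[1],
                                               lat = blat - 1.5), sc)))
})

test_that("densities are 100 * count / length with zero-count beaches kept", {
  lengths <- data.frame(beach_id = c("P1", "P2", "P3"),
                        length_m = c(1000, 2000, 500),
                        lon_mid = c(1, 2, 3))
  tab <- density_per_100m(c(P1 = 50, P3 = 0), lengths)
  expect_s3_class(tab, "stranding_density_table")
  expect_equal(tab$density_per_100m, c(5, 0, 0))
  expect_equal(tab$count, c(50, 0, 0))
  expect_error(density_per_100m(c(P1 = -2), lengths), "non-negative")
  expect_error(density_per_100m(c(PX = 1), lengths), "not in")
})

test_that("density is scale-equivariant in the counts", {
  lengths <- data.frame(beach_id = c("P1", "P2", "P3"),
                        length_m = c(800, 1200, 650), lon_mid = 1:3)
  t1 <- density_per_100m(c(P1 = 10, P2 = 4, P3 = 7), lengths)
  t2 <- density_per_100m(c(P1 = 20, P2 = 8, P3 = 14), lengths)
  expect_equal(t2$density_per_100m, 2 * t1$density_per_100m)
})

test_that("an observed mass-stranding ledger carries through to densities", {
  csv <- tempfile(fileext = ".csv")
  writeLines(c("beach_id,date,count,mean_size_cm",
               "Donana,2010-02-22,2500,6.1",
               "Donana,2010-02-24,4873,5.8",
               "Donana,2010-02-26,3000,6.0",
               "EastBeach,2010-03-02,40,8.2"), csv)
  obs <- read_observed_strandings(csv)
  expect_equal(sum(obs$count), 10413)
  lengths <- data.frame(beach_id = c("Donana", "EastBeach"),
                        length_m = c(28000, 5000), lon_mid = c(-6.4, -6.0))
  tab <- observed_density(obs, lengths)
  expect_equal(tab$count[tab$beach_id == "Donana"], 10373)
  expect_equal(tab$density_per_100m[tab$beach_id == "Donana"],
               100 * 10373 / 28000)
  expect_equal(tab$first_arrival[tab$beach_id == "Donana"],
               as.POSIXct("2010-02-22", tz = "UTC"))
})

test_that("pattern comparison recovers identity, monotone and reversed ranks", {
  lengths <- data.frame(beach_id = sprintf("P%d", 1:6),
                        length_m = rep(1000, 6), lon_mid = 1:6)
  dens <- c(P1 = 5, P2 = 30, P3 = 11, P4 = 2, P5 = 44, P6 = 17)
  a <- density_per_100m(dens, lengths)
  cmp_id <- compare_patterns(a, a)
  expect_equal(cmp_id$spearman_density, 1.0)
  expect_equal(cmp_id$rms_log_density, 0)
  b <- a; b$density_per_100m <- (a$density_per_100m + 1)^2  # monotone map
  b$count <- b$density_per_100m * b$length_m / 100
  cmp_mono <- compare_patterns(a, b)
  expect_equal(cmp_mono$spearman_density, 1.0)
  expect_gt(cmp_mono$rms_log_density, 0)
  # a table whose per-beach ranking is the exact reverse of a's
  r <- a; r$density_per_100m <- 50 - a$density_per_100m
  r$count <- r$density_per_100m * r$length_m / 100
  cmp_rev <- compare_patterns(a, r)
  # oracle: Spearman by its rank-difference formula on the 6 values
  ra <- rank(a$density_per_100m); rr <- rank(r$density_per_100m)
  rho_brute <- 1 - 6 * sum((ra - rr)^2) / (6 * (6^2 - 1))
  expect_equal(cmp_rev$spearman_density, rho_brute)
  expect_equal(cmp_rev$spearman_density, -1.0)
})

test_that("pattern comparison is symmetric and needs three beaches", {
  lengths <- data.frame(beach_id = sprintf("P%d", 1:4),
                        length_m = rep(1000, 4), lon_mid = 1:4)
  a <- density_per_100m(c(P1 = 5, P2 = 30, P3 = 11, P4 = 2), lengths)
  b <- density_per_100m(c(P1 = 7, P2 = 3, P3 = 20, P4 = 9), lengths)
  expect_equal(compare_patterns(a, b)$spearman_density,
               compare_patterns(b, a)$spearman_density)
  two <- density_per_100m(c(X = 1, Y = 2),
                          data.frame(beach_id = c("X", "Y"),
                                     length_m = c(1, 1), lon_mid = 1:2))
  expect_error(compare_patterns(two, two), "fewer than 3")
})

test_that("per-beach counts plus unassigned account for every record", {
  ex <- transport_experiment(n = 300, seed = 5, days = 15)
  rec <- ex$run$strandings
  cnt <- count_strandings(rec, ex$scenario)
  expect_equal(sum(cnt$count) + attr(cnt, "unassigned"), nrow(rec))
  tab <- density_per_100m(cnt, ex$scenario)
  expect_equal(sum(tab$count), sum(cnt$count))
  expect_true(!is.unsorted(tab$lon_mid))
})
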