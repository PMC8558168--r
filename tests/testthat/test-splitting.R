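test_that("hand-traced 1-D sphere-exclusion split", {
  tab <- matrix(c(0.0, 0.1, 0.5, 0.9, 1.0), ncol = 1,
                dimnames = list(sprintf("m%d", 1:5), "d"))
  sp <- sphere_exclusion_split(tab, radius = 0.3, fraction = 0.4, init = "center")
  # centroid 0.5 -> first pick m3; MinMax tie 0.0 vs 1.0 -> lowest index m1
  expect_equal(sp$test_ids, c("m3", "m1"))
  expect_setequal(sp$train_ids, c("m2", "m4", "m5"))
  expect_null(sp$warning)
})

test_that("an oversized radius yields a short split with a warning record", {
  tab <- random_table(10, 2, seed = 2)
  sp <- sphere_exclusion_split(tab, radius = 10, fraction = 0.4, init = "center")
  expect_equal(length(sp$test_ids), 1)
  expect_match(sp$warning, "target 4")
})

test_that("the 24% stop rule reproduces both study test-set sizes", {
  for (cfg in list(list(n = 51, test = 12, train = 39),
                   list(n = 83, test = 19, train = 64))) {
    tab <- random_table(cfg$n, 5, seed = cfg$n)
    sp <- sphere_exclusion_split(tab, radius = 0.1, fraction = 0.24)
    expect_equal(length(sp$test_ids), cfg$test)
    expect_equal(length(sp$train_ids), cfg$train)
  }
})

test_that("test-test distances respect the radius and the split partitions", {
  for (i in 1:200) {
    n <- 8 + (i %% 13)
    tab <- random_table(n, 2 + (i %% 3), seed = 1000 + i)
    radius <- 0.1 + 0.4 * ((i %% 7) / 6)
    sp <- sphere_exclusion_split(tab, radius, fraction = 0.3)
    expect_setequal(c(sp$train_ids, sp$test_ids), rownames(tab))
    expect_length(intersect(sp$train_ids, sp$test_ids), 0)
    if (length(sp$test_ids) > 1) {
      d <- dist(tab[sp$test_ids, , drop = FALSE])
      expect_gte(min(d), radius)
    }
  }
})

test_that("random-init splits are deterministic under a fixed seed", {
  tab <- random_table(30, 4, seed = 77)
  a <- sphere_exclusion_split(tab, 0.3, 0.25, init = "random", seed = 5)
  b <- sphere_exclusion_split(tab, 0.3, 0.25, init = "random", seed = 5)
  expect_identical(a$test_ids, b$test_ids)
  other <- sphere_exclusion_split(tab, 0.3, 0.25, init = "random", seed = 6)
  expect_setequal(c(other$train_ids, other$test_ids), rownames(tab))
})

test_that("increasing the radius never increases the achievable test size", {
  for (s in 1:5) {
    tab <- random_table(40, 3, seed = 200 + s)
    sizes <- vapply(c(0.05, 0.15, 0.3, 0.5, 0.8, 1.2), function(r) {
      length(sphere_exclusion_split(tab, r, fraction = 0.5)$test_ids)
    }, numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("center-init splits are invariant to row permutation when distances are distinct", {
  tab <- random_table(20, 3, seed = 31)
  sp1 <- sphere_exclusion_split(tab, 0.25, 0.3)
  perm <- sample(nrow(tab))
  sp2 <- sphere_exclusion_split(tab[perm, ], 0.25, 0.3)
  expect_setequal(sp1$test_ids, sp2$test_ids)
})

test_that("alternative splits honor the reference class balance and seed ladder", {
  pre <- receptor_preset("or24", seed = 3)
  gen <- gen_qsar_dataset(pre$spec)
  norm <- apply_minmax(gen$table, fit_minmax(gen$table))
  labels <- gen$dataset$label

  expect_length(alternative_splits(norm, labels, 0, pre$radius, 0.24,
                                   c(2, 10), seed = 1), 0)

  alts <- alternative_splits(norm, labels, 5, pre$radius, 0.24,
                             reference_counts = c(2, 10), seed = 1,
                             max_attempts = 400)
  expect_length(alts, 5)
  for (sp in alts) {
    test_lab <- labels[match(sp$test_ids, gen$dataset$id)]
    expect_equal(sum(test_lab == "active"), 2)
    expect_equal(sum(test_lab == "inactive"), 10)
  }
  again <- alternative_splits(norm, labels, 5, pre$radius, 0.24,
                              c(2, 10), seed = 1, max_attempts = 400)
  expect_identical(lapply(alts, `[[`, "test_ids"), lapply(again, `[[`, "test_ids"))
})

test_that("an unreachable class balance errors with the matched count", {
  tab <- random_table(12, 2, seed = 8)
  labels <- rep(c("active", "inactive"), 6)
  expect_error(
    alternative_splits(tab, labels, 3, 0.1, 0.25, c(3, 0), seed = 1,
                       max_attempts = 20),
    "found only")
})

test_that("splits persist and reload with their metadata", {
  tab <- random_table(15, 3, seed = 55)
  sp <- sphere_exclusion_split(tab, 0.2, 0.3, init = "random", seed = 9)
  path <- withr::local_tempfile(fileext = ".csv")
  write_split(sp, path)
  sp2 <- read_split(path)
  expect_identical(sp2$test_ids, sp$test_ids)
  expect_identical(sp2$train_ids, sp$train_ids)
  expect_equal(sp2$radius, 0.2)
  expect_equal(sp2$init, "random")
  expect_equal(sp2$seed, 9L)
})
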