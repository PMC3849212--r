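test_that("an exactly shifted copy correlates perfectly at its shift", {
  v <- dnorm(0:50, 25, 8)
  mouse <- c(rep(0, 13), v, rep(0, 40))
  expect_equal(pearson_at_shift(v, mouse, 13), 1, tolerance = 1e-12)
  expect_lt(pearson_at_shift(v, mouse, 0), 1)
})

test_that("degenerate windows are undefined", {
  const <- rep(0.5, 30)
  expect_true(is.na(pearson_at_shift(const, const, 0)))
  # too little overlap
  expect_true(is.na(pearson_at_shift(1:30, 1:30, 25, min_overlap = 10)))
  # shift beyond the mouse vector
  expect_true(is.na(pearson_at_shift(1:30, 1:30, 40)))
})

test_that("anti-aligned patterns reach r = -1", {
  x <- c(rep(c(0, 1), 10))
  y <- 1 - x
  expect_equal(pearson_at_shift(x, y, 0), -1, tolerance = 1e-12)
})

test_that("best_shift matches the exhaustive naive-correlation oracle", {
  h <- dnorm(0:120, 60, 15)
  mouse <- numeric(1029)
  mouse[37 + seq_along(h)] <- h
  fit <- best_shift(h, mouse)
  expect_equal(fit$shift, 37)
  expect_equal(fit$r, 1, tolerance = 1e-9)
  oracle <- naive_best_shift(h, mouse, max_shift = 1028)
  expect_equal(fit$shift, oracle$shift)
  expect_equal(fit$r, oracle$r, tolerance = 1e-9)
  # and on a noisy pattern with no planted structure
  set.seed(13)
  mouse2 <- runif(400)
  h2 <- dnorm(0:120, 40, 20)
  fit2 <- best_shift(h2, mouse2, max_shift = 250)
  oracle2 <- naive_best_shift(h2, mouse2, max_shift = 250)
  expect_equal(fit2$shift, oracle2$shift)
  expect_equal(fit2$r, oracle2$r, tolerance = 1e-9)
})

test_that("ties break toward the smaller shift", {
  # a two-bin motif repeated: shifts 0 and 4 align equally well
  h <- rep(c(1, 0, 0, 0), 5)
  mouse <- rep(c(1, 0, 0, 0), 10)
  fit <- best_shift(h, mouse, max_shift = 20)
  expect_equal(fit$r, 1, tolerance = 1e-12)
  expect_equal(fit$shift, 0)
})

test_that("correlation is invariant under affine rescaling of either side", {
  set.seed(31)
  for (i in 1:50) {
    h <- runif(121)
    mouse <- runif(300)
    s <- sample(0:150, 1)
    a <- runif(1, 0.1, 5); b <- runif(1, -2, 2)
    r0 <- pearson_at_shift(h, mouse, s)
    r1 <- pearson_at_shift(a * h + b, mouse, s)
    r2 <- pearson_at_shift(h, a * mouse + b, s)
    expect_equal(r0, r1, tolerance = 1e-12)
    expect_equal(r0, r2, tolerance = 1e-12)
  }
})

test_that("planted related diseases are accepted, unrelated rejected", {
  specs <- c(planted_specs(c(30, 120, 310)),
             list(disease_spec("NOISE:1", "noisedisease1", related = FALSE),
                  disease_spec("NOISE:2", "noisedisease2", related = FALSE)))
  pair <- generate_matrix_pair(specs, noise_cv = 0, seed = 17)
  map <- map_diseases(pair$human, pair$mouse)
  expect_equal(map$n_compared, 5L)
  tab <- map$table
  accepted <- tab$disease[tab$accepted]
  expect_setequal(accepted, c("TEST:30", "TEST:120", "TEST:310"))
  for (s in c(30, 120, 310)) {
    expect_equal(tab$shift_days[tab$disease == paste0("TEST:", s)], s)
  }
})

test_that("diseases missing from either matrix are not compared", {
  pair_h <- generate_matrix_pair(planted_specs(50), seed = 1)$human
  pair_m <- generate_matrix_pair(planted_specs(60), seed = 1)$mouse
  expect_warning(map <- map_diseases(pair_h, pair_m), "no disease")
  expect_equal(map$n_compared, 0L)
})

test_that("mapping requires normalized matrices", {
  counts <- rbind(X = c(1, 2, 3))
  colnames(counts) <- as.character(0:2)
  raw <- agemapr:::new_age_disease_matrix(counts, "human", 365)
  expect_error(map_diseases(raw, raw), "normalized")
})

test_that("age conversions follow the additive-shift model", {
  map <- age_map(data.frame(disease = c("D:a", "D:b"),
                            shift_days = c(99, 265)))
  expect_equal(mouse_to_human_age(map, "D:a", 120), 21)
  expect_equal(human_to_mouse_age(map, "D:b", 30), 295)
  # boundary: a mouse at exactly the shift maps to human age 0
  expect_equal(mouse_to_human_age(map, "D:a", 99), 0)
  expect_equal(human_to_mouse_age(map, "D:a", 0), 99)
  # out of domain and unknown diseases
  expect_error(mouse_to_human_age(map, "D:a", 50), "negative")
  expect_error(mouse_to_human_age(map, "D:zzz", 120), "not in the age map")
})

test_that("the two conversions are exact inverses with unit slope", {
  map <- age_map(data.frame(disease = "D:a", shift_days = 142))
  ages <- 0:120
  there <- human_to_mouse_age(map, "D:a", ages)
  back <- mouse_to_human_age(map, "D:a", there)
  expect_equal(back, ages)
  expect_equal(unique(diff(there)), 1)  # strictly increasing, slope 1
})

test_that("age maps round-trip through JSON", {
  pair <- generate_matrix_pair(planted_specs(c(40, 200)), seed = 2)
  map <- map_diseases(pair$human, pair$mouse)
  path <- file.path(withr::local_tempdir(), "map.json")
  write_age_map(map, path)
  back <- read_age_map(path)
  expect_equal(back$n_accepted, map$n_accepted)
  expect_equal(mouse_to_human_age(back, "TEST:40", 100),
               mouse_to_human_age(map, "TEST:40", 100))
})
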