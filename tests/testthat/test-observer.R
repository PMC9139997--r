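# Cue measurement and the synthetic observer.

test_that("a mirrored sproutless shape has zero asymmetry and sprout cues", {
  cv <- measure_cues(paired_shape_fixture())
  expect_equal(cv$asymmetry, 0, tolerance = 1e-12)
  expect_equal(cv$sprout_prominence, 0)
  expect_gt(cv$curvedness, 50)  # curved fixture
  expect_equal(cv$n_pairs, 1L)
})

test_that("straightening scales the curvedness cue by the exact factor", {
  shp <- paired_shape_fixture()
  c0 <- measure_cues(shp)$curvedness
  for (f in c(0.05, 0.25, 0.6)) {
    cf <- measure_cues(straighten_shape(shp, f, compose = FALSE))$curvedness
    expect_equal(cf, f * c0, tolerance = 1e-12)
  }
})

test_that("asymmetry equals displacement over pair count", {
  shp <- skelmorph:::base_paired_shape(4L, 21L,
    function(sd) growth_params(n_joints = 4L))
  d <- displace_limb(shp, "L1", displacement_spec(0.08, "down"),
                     compose = FALSE)
  expect_equal(measure_cues(d)$asymmetry, 0.08 / 2, tolerance = 1e-6)
})

test_that("asymmetry is undefined (NA) without nominal pairs", {
  shp <- shape(main_body(), compose = FALSE)
  shp <- attach_part(shp, "body", 0.3, "left",
                     growth_params(n_joints = 3L), seed = 2, id = "solo")
  expect_true(is.na(measure_cues(shp)$asymmetry))
})

test_that("an indifferent observer chooses at chance", {
  pool <- cached_fixture("e1_small", function()
    build_experiment1("symmetry", seed = 7, n_reps = 1L))
  mod <- observer_model(w_asym = 0, w_curv = 0, w_sprout = 0, bias = 0,
                        lapse = 0)
  resp <- simulate_2afc(pool, mod, n_participants = 40L, seed = 31)
  n <- nrow(resp)
  expect_equal(mean(resp$chose_b), 0.5, tolerance = 3 * sqrt(0.25 / n) / 0.5)
})

test_that("an overwhelming cue difference saturates at 1 - lapse", {
  pool <- cached_fixture("e1_small", function()
    build_experiment1("symmetry", seed = 7, n_reps = 1L))
  mod <- observer_model(w_asym = 1e9, w_curv = 0, w_sprout = 0, bias = 0,
                        lapse = 0.1)
  resp <- simulate_2afc(pool, mod, n_participants = 60L, seed = 32)
  expect_equal(mean(resp$chose_b), 1 - 0.1,
               tolerance = 4 * sqrt(0.1 * 0.9 / nrow(resp)) / 0.9)
})

test_that("slider ratings stay in range and respond to the schedule", {
  sc <- exp3_cues()
  mod <- observer_model()
  sl <- simulate_slider(sc, mod, n_participants = 3L, seed = 41)
  expect_true(all(sl$rating >= 0 & sl$rating <= 1))
  means <- tapply(sl$rating, sl$step, mean)
  expect_true(all(diff(means) > 0))
  # zero noise and lapse: deterministic ratings
  det <- observer_model(noise = 0, lapse = 0)
  s1 <- simulate_slider(sc, det, n_participants = 1L, seed = 42)
  s2 <- simulate_slider(sc, det, n_participants = 1L, seed = 99)
  expect_equal(s1$rating, s2$rating)
})

test_that("plant-positive preferences reproduce the qualitative pattern", {
  mod <- observer_model()
  # asymmetric member preferred in the symmetry condition
  sym <- cached_fixture("e1_small", function()
    build_experiment1("symmetry", seed = 7, n_reps = 1L))
  r1 <- simulate_2afc(sym, mod, n_participants = 13L, seed = 51)
  expect_gt(binomial_preference(sum(r1$chose_b), nrow(r1))$proportion, 0.5)
  # transplanted (sprouting) member preferred
  e2 <- build_experiment2(seed = 52, n_per_type = 5L)
  r2 <- simulate_2afc(e2, mod, n_participants = 13L, seed = 53)
  expect_gt(binomial_preference(sum(r2$chose_b), nrow(r2))$proportion, 0.5)
})
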