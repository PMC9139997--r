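# Stimulus designs: factor crossings, pair isolation, reproducibility.
# (Full design counts are exercised in the acceptance suite; unit tests use
# reduced replicate numbers.)

test_that("experiment 1 crosses limb counts, levels and replicates", {
  e1 <- build_experiment1("symmetry", seed = 5, n_reps = 2L, compose = FALSE)
  expect_length(e1, 2 * 4 * 5)
  meta <- data.frame(n = vapply(e1, function(p) p$n_limbs, 0),
                     lv = vapply(e1, function(p) p$level, 0))
  expect_equal(sort(unique(meta$n)), 2:5)
  expect_equal(sort(unique(meta$lv)), c(0.025, 0.05, 0.075, 0.10, 0.125))
  expect_equal(nrow(unique(meta)), 20L)
})

test_that("symmetry pairs isolate the asymmetry cue", {
  e1 <- cached_fixture("e1_small", function()
    build_experiment1("symmetry", seed = 7, n_reps = 1L))
  for (p in e1[c(1, 7, 20)]) {
    ca <- measure_cues(p$a); cb <- measure_cues(p$b)
    expect_equal(ca$asymmetry, 0, tolerance = 1e-12)
    expect_gt(cb$asymmetry, 0)
    # limb geometry identical within the pair
    for (id in names(p$a$parts)) {
      expect_equal(p$a$parts[[id]]$turns_deg, p$b$parts[[id]]$turns_deg)
      expect_equal(p$a$parts[[id]]$seg_lengths, p$b$parts[[id]]$seg_lengths)
    }
  }
})

test_that("curvedness pairs share attachments and segment lengths exactly", {
  e1 <- build_experiment1("curvedness", seed = 8, n_reps = 1L, compose = FALSE)
  for (p in e1[c(3, 11)]) {
    for (id in names(p$a$parts)) {
      a <- p$a$parts[[id]]; b <- p$b$parts[[id]]
      expect_identical(a$attach_t, b$attach_t)
      expect_identical(a$seg_lengths, b$seg_lengths)
      expect_equal(b$turns_deg, a$turns_deg * p$level, tolerance = 1e-12)
    }
    # straightened member is less curved
    expect_lt(measure_cues(compose_shape(p$b))$curvedness,
              measure_cues(compose_shape(p$a))$curvedness)
  }
})

test_that("experiment 2 pairs differ only in part hierarchy", {
  e2 <- build_experiment2(seed = 9, n_per_type = 2L)
  expect_length(e2, 8L)
  types <- vapply(e2, function(p) p$level, "")
  expect_equal(sort(unique(types)),
               c("asym_curved", "asym_straight", "sym_curved", "sym_straight"))
  for (p in e2) {
    oa <- vapply(p$a$parts, function(x) x$order, 0L)
    ob <- vapply(p$b$parts, function(x) x$order, 0L)
    expect_equal(sum(oa == 2L), 0L)
    expect_equal(sum(ob == 2L), 2L)
    expect_equal(length(oa), length(ob))  # transplant conserves part count
  }
})

test_that("experiment 3 sequences hold limb count constant with zero step-1 displacement", {
  e3 <- build_experiment3(seed = 10, n_reps = 1L)
  expect_length(e3$sequences, 10L)
  expect_equal(nrow(e3$presentation), 50L)
  for (sq in e3$sequences) {
    expect_true(sq$spec$n_first_order %in% 2:6)
    expect_equal(sq$schedule$displacement[1], 0)
    n1 <- vapply(sq$steps, function(s)
      sum(vapply(s$parts, function(p) p$order == 1L, TRUE)), 0L)
    expect_true(all(n1 == sq$spec$n_first_order))
  }
  # presentation order covers every shape exactly once
  expect_equal(sort(e3$presentation$stim_id),
               sort(as.vector(outer(names(e3$sequences), 1:5,
                                    function(s, i) paste0(s, "_s", i)))))
})

test_that("designs and trial tables are reproducible from the seed", {
  a <- build_experiment1("symmetry", seed = 11, n_reps = 1L, compose = FALSE)
  b <- build_experiment1("symmetry", seed = 11, n_reps = 1L, compose = FALSE)
  expect_equal(a, b)
  ta <- trial_table(a, seed = 3); tb <- trial_table(b, seed = 3)
  expect_identical(ta, tb)
  tc <- trial_table(a, seed = 4)
  expect_false(identical(ta$pair_id, tc$pair_id))
  expect_setequal(ta$pair_id, tc$pair_id)
})
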