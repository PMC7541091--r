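exp_cfg <- function(...) {
  staircase_config("exponential", start = 6, step1 = 2^(1 / 2),
                   minimum = 0, maximum = 10000, ...)
}

test_that("two-down one-up steps apply the unequal-step geometry", {
  st <- staircase_new(exp_cfg())
  st <- staircase_update(st, TRUE)
  expect_equal(st$value, 6)                    # one correct: no movement
  st <- staircase_update(st, TRUE)
  expect_equal(st$value, 6 / sqrt(2))          # 4.2426: stage-1 down step

  st2 <- staircase_new(exp_cfg())
  st2 <- staircase_update(st2, FALSE)
  expect_equal(st2$value, 12)                  # up step = down^2 (2:1 in log)

  lin <- staircase_config("linear", start = 35, step1 = 6, step2 = 2,
                          minimum = 25, maximum = 90, harder = "larger")
  st3 <- staircase_new(lin)
  st3 <- staircase_update(st3, TRUE); st3 <- staircase_update(st3, TRUE)
  expect_equal(st3$value, 41)                  # harder = louder masker
  st3 <- staircase_update(st3, FALSE)
  expect_equal(st3$value, 41 - 12)             # easier = quieter, 2x step
})

test_that("stage-2 step defaults to one fifth of stage 1 in the adaptation domain", {
  expect_equal(exp_cfg()$step2, 2^(1 / 10))
  lin <- staircase_config("linear", start = 6, step1 = 0.5, minimum = 0.2,
                          maximum = 40)
  expect_equal(lin$step2, 0.1)
})

test_that("reversals are logged at direction flips and drive the stages", {
  # scripted responses: down, down, up, down, up ... around the start
  st <- staircase_new(exp_cfg())
  feed <- function(st, resp) {
    for (r in resp) st <- staircase_update(st, r)
    st
  }
  st <- feed(st, c(TRUE, TRUE))        # move harder (first movement)
  expect_equal(nrow(staircase_reversals(st)), 0)
  st <- feed(st, FALSE)                # flip: reversal 1
  expect_equal(nrow(staircase_reversals(st)), 1)
  expect_equal(st$stage, 1L)
  st <- feed(st, c(TRUE, TRUE))        # flip: reversal 2
  st <- feed(st, FALSE)                # flip: reversal 3 -> stage 2
  expect_equal(nrow(staircase_reversals(st)), 3)
  expect_equal(st$stage, 2L)
  expect_false(st$finished)
  # each correct-correct-error cycle yields two reversals (down then up)
  for (i in 1:3) st <- feed(st, c(TRUE, TRUE, FALSE))
  rev <- staircase_reversals(st)
  expect_equal(sum(rev$stage == 2), 6)
  expect_true(st$finished)
  expect_error(staircase_update(st, TRUE), "finished")
})

test_that("threshold is the geometric mean of stage-2 reversals", {
  fake <- function(values) {
    st <- staircase_new(exp_cfg())
    st$rev_stage <- rep(2L, length(values))
    st$rev_value <- values
    st$finished <- TRUE
    st
  }
  expect_equal(staircase_threshold(fake(rep(2, 6))), 2)
  expect_equal(staircase_threshold(fake(c(1, 4, 1, 4, 1, 4))), 2)
  expect_equal(staircase_threshold(fake(c(8, 2, 8, 2, 8, 2))), 4)
  expect_error(staircase_threshold(fake(c(1, -1, 1, 1, 1, 1))), "nonpositive")
  expect_error(staircase_threshold(staircase_new(exp_cfg())), "not finished")
})

test_that("clamping at a bound keeps the reversal log sane", {
  cfg <- staircase_config("linear", start = 26, step1 = 5, step2 = 5,
                          minimum = 25, maximum = 90, harder = "smaller")
  st <- staircase_new(cfg)
  # descend to the bound and sit on it through repeated correct pairs
  st <- staircase_update(st, TRUE); st <- staircase_update(st, TRUE) # 25 (clamped)
  for (i in 1:4) { st <- staircase_update(st, TRUE) }               # stays 25
  expect_equal(st$value, 25)
  expect_equal(nrow(staircase_reversals(st)), 0)   # no spurious reversals
  st <- staircase_update(st, FALSE)                # up: genuine reversal
  expect_equal(nrow(staircase_reversals(st)), 1)
  st <- staircase_update(st, TRUE); st <- staircase_update(st, TRUE)
  st <- staircase_update(st, TRUE); st <- staircase_update(st, TRUE) # clamped again
  expect_equal(nrow(staircase_reversals(st)), 2)   # one reversal per flip
  vals <- staircase_reversals(st)$value
  expect_true(all(vals >= 25 & vals <= 90))
})

test_that("the convergence target follows the drift-balance closed form", {
  expect_equal(convergence_target(2, 2), 81.65, tolerance = 0.005)
  expect_equal(convergence_target(2, 1.5), 77.46, tolerance = 0.005)
  expect_equal(convergence_target(3, 1), 79.37, tolerance = 0.005)
  expect_equal(convergence_target(1, 1), 50)   # 1-down/1-up equal steps
  expect_error(convergence_target(2, 0), "positive")
  expect_error(convergence_target(0, 1), "at least 1")
})

test_that("a constant-p responder at the equilibrium keeps the track stationary", {
  # Monte-Carlo drift balance: long stage-2-only tracks at p* should end
  # near where they started; above/below p* they drift harder/easier
  run_const <- function(p, n_trials = 300, n_tracks = 200) {
    cfg <- staircase_config("exponential", start = 8, step1 = 2^(1 / 10),
                            step2 = 2^(1 / 10), up_down_ratio = 2,
                            stage1_reversals = 0, minimum = 0,
                            maximum = 1e9, stage2_reversals = 1e6)
    finals <- replicate(n_tracks, {
      st <- staircase_new(cfg)
      ans <- constant_p_responder(p)
      for (i in seq_len(n_trials)) st <- staircase_update(st, ans())
      log2(st$value)
    })
    mean(finals) - log2(8)
  }
  set.seed(20)
  p_star <- convergence_target(2, 2) / 100
  expect_lt(abs(run_const(p_star)), 0.4)     # zero expected displacement
  expect_lt(run_const(0.95), -3)             # better than p*: drifts harder
  expect_gt(run_const(0.60), 3)              # worse than p*: drifts easier
})

test_that("stored histories replay to the same final state", {
  set.seed(21)
  obs <- simulated_observer(1, 0.5, lambda = 0.02, scale = "exponential")
  res <- simulate_track(obs, exp_cfg())
  h <- staircase_history(res$track)
  replayed <- staircase_replay(exp_cfg(), h$correct)
  expect_equal(replayed$value, res$track$value)
  expect_equal(staircase_reversals(replayed), staircase_reversals(res$track))
  expect_equal(staircase_threshold(replayed), res$threshold)
})

test_that("the progressive schedule spans ten TMRs twice each", {
  sched <- progressive_schedule()
  expect_equal(nrow(sched), 20)
  expect_equal(sched$masker_level, rep(seq(55, 73, 2), each = 2))
  expect_equal(length(unique(sched$tmr)), 10)
  expect_equal(sched$tmr[1], 10)
  expect_equal(sched$tmr[20], -8)
})

test_that("progressive scoring is 10 minus the number correct", {
  expect_equal(progressive_score(rep(FALSE, 20)), 10)
  expect_equal(progressive_score(rep(TRUE, 20)), -10)
  expect_equal(progressive_score(c(rep(TRUE, 14), rep(FALSE, 6))), -4)
  expect_error(progressive_score(rep(TRUE, 19)), "20")
  # monotone: adding a correct response never raises the threshold
  set.seed(22)
  for (i in 1:20) {
    r <- runif(20) < 0.5
    if (all(r)) next
    r2 <- r
    r2[which(!r)[1]] <- TRUE
    expect_lte(progressive_score(r2), progressive_score(r))
  }
})

test_that("spatial release is the colocated-minus-separated difference", {
  expect_equal(spatial_release(10, -10), 20)
  expect_equal(spatial_release(3, 3), 0)
  expect_equal(spatial_release(2, -4), 6)
  expect_error(spatial_release(11, 0), "\\[-10, 10\\]")
})
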