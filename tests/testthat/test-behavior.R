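test_that("condition accuracy counts correct responses, not outcomes", {
  # degenerate all-go responder
  tr <- random_trials(80, seed = 91)
  tr$action <- "go"
  acc <- accuracy_by_condition(tr)
  expect_equal(acc$accuracy[acc$condition == "go_to_win"], 1)
  expect_equal(acc$accuracy[acc$condition == "go_to_avoid"], 1)
  expect_equal(acc$accuracy[acc$condition == "nogo_to_win"], 0)
  expect_equal(acc$accuracy[acc$condition == "nogo_to_avoid"], 0)
  expect_equal(sum(acc$n), nrow(tr))

  # hand-built 12-trial table with known per-cell counts
  hand <- data.frame(
    subject_id = 1L, run = 1L, trial = 1:12,
    valence = rep(c("win", "avoid"), each = 6),
    required_action = rep(c("go", "nogo", "go"), 4),
    image_id = 1L,
    action = c("go", "go", "nogo", "nogo", "go", "go",
               "go", "nogo", "go", "go", "go", "nogo"),
    outcome = 0L, favorable = FALSE, shock_delivered = NA
  )
  hand$condition <- paste0(hand$required_action, "_to_", hand$valence)
  hand$image <- cue_image_index(hand$valence, hand$required_action, hand$image_id)
  acc2 <- accuracy_by_condition(hand)
  # manual enumeration: go_to_win 2/4 correct, nogo_to_win 0/2,
  # go_to_avoid 3/4, nogo_to_avoid 1/2
  expect_equal(acc2$accuracy[acc2$condition == "go_to_win"], 2 / 4)
  expect_equal(acc2$accuracy[acc2$condition == "nogo_to_win"], 0 / 2)
  expect_equal(acc2$accuracy[acc2$condition == "go_to_avoid"], 3 / 4)
  expect_equal(acc2$accuracy[acc2$condition == "nogo_to_avoid"], 1 / 2)

  # an empty cell is NA, not zero
  sub <- tr[tr$condition != "nogo_to_win", ]
  acc3 <- accuracy_by_condition(sub)
  expect_true(is.na(acc3$accuracy[acc3$condition == "nogo_to_win"]))
  expect_equal(acc3$n[acc3$condition == "nogo_to_win"], 0)
})

test_that("stay/switch index hits its degenerate bounds", {
  # one cue image repeatedly, all feedback unfavorable
  n <- 20
  tr <- data.frame(
    subject_id = 1L, run = 1L, trial = 1:n,
    valence = "win", required_action = "go", image_id = 1L,
    action = rep(c("go", "nogo"), length.out = n),
    outcome = 0L, favorable = FALSE, shock_delivered = NA
  )
  tr$condition <- "go_to_win"
  tr$image <- cue_image_index(tr$valence, tr$required_action, tr$image_id)
  sw <- stay_switch_index(tr)
  expect_equal(sw$switch_pct[sw$condition == "go_to_win"], 100)

  tr$action <- "go"   # constant responder never switches
  sw0 <- stay_switch_index(tr)
  expect_equal(sw0$switch_pct[sw0$condition == "go_to_win"], 0)
  # conditions never shown have no eligible events
  expect_true(all(is.na(sw0$switch_pct[sw0$condition != "go_to_win"])))
})

test_that("stay/switch equals the brute-force scan oracle on random sequences", {
  for (s in 1:20) {
    tr <- random_trials(100, seed = 900 + s)
    for (m in c("image", "category")) {
      got <- stay_switch_index(tr, match = m)
      want <- switch_scan_oracle(tr, match = m)
      expect_equal(got$switch_pct, want$switch_pct, tolerance = 1e-12)
      expect_equal(got$n_eligible, want$n_eligible)
    }
  }
})

test_that("metrics are invariant to relabeling images within a category", {
  tr <- random_trials(120, seed = 95)
  swapped <- tr
  swapped$image_id <- 3L - swapped$image_id   # 1 <-> 2 within every category
  swapped$image <- cue_image_index(swapped$valence, swapped$required_action,
                                   swapped$image_id)
  expect_equal(accuracy_by_condition(tr)$accuracy,
               accuracy_by_condition(swapped)$accuracy)
  expect_equal(stay_switch_index(tr)$switch_pct,
               stay_switch_index(swapped)$switch_pct)
})

test_that("value trajectories follow the learning closed forms", {
  spec <- base_spec()
  # eps = 0: no learning, flat zero trajectory
  tr <- random_trials(60, seed = 96)
  vt0 <- value_difference_trajectory(tr, c(eps = 1e-300, rho = 2), spec)
  expect_true(all(abs(vt0$value_diff) < 1e-250))

  # all-correct all-favorable go-to-win run: difference after k rewards is
  # 1 - (1 - eps)^k with eps = 0.5, rho = 1
  k <- 8
  go_win <- data.frame(
    subject_id = 1L, run = 1L, trial = 1:k,
    valence = "win", required_action = "go", image_id = 1L,
    action = "go", outcome = 1L, favorable = TRUE, shock_delivered = NA
  )
  go_win$condition <- "go_to_win"
  go_win$image <- cue_image_index("win", "go", 1L)
  vt <- value_difference_trajectory(go_win, c(eps = 0.5, rho = 1), spec)
  expect_equal(vt$value_diff, 1 - 0.5^(0:(k - 1)), tolerance = 1e-12)
  expect_equal(vt$presentation, 1:k)

  # the sign convention makes learning positive-going for no-go cues too
  nogo <- go_win
  nogo$required_action <- "nogo"; nogo$condition <- "nogo_to_win"
  nogo$action <- "nogo"
  nogo$image <- cue_image_index("win", "nogo", 1L)
  vtn <- value_difference_trajectory(nogo, c(eps = 0.5, rho = 1), spec)
  expect_equal(vtn$value_diff, 1 - 0.5^(0:(k - 1)), tolerance = 1e-12)
})

test_that("simulated learners show rising value differences in all conditions", {
  spec <- model_spec("single", "single", bias = TRUE, pavlovian = TRUE)
  params <- c(eps = 0.2, rho = 2, b = 0.3, pi = 0.3)
  rising <- 0L
  for (s in 1:5) {
    tr <- simulate_subject(params, spec, build_schedule(40, 2, seed = 970 + s),
                           seed = 980 + s)
    tr$subject_id <- 1L
    vt <- value_difference_trajectory(tr, params, spec)
    slopes <- vapply(split(vt, vt$condition), function(d) {
      unname(coef(lm(value_diff ~ presentation, data = d))[2])
    }, 0)
    rising <- rising + all(slopes > 0)
  }
  expect_gte(rising, 4L)
})
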