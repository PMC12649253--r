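test_that("scoring reverses items 5 and 8 and sums to 0..30", {
  expect_identical(score_cesd(rep(0L, 10)), 6L)     # two reversed items add 3 each
  expect_identical(score_cesd(rep(3L, 10)), 24L)    # reversed items contribute 0
  expect_identical(score_cesd(c(3, 3, 3, 3, 0, 3, 3, 0, 3, 3)), 30L)
  expect_identical(score_cesd(c(0, 0, 0, 0, 3, 0, 0, 3, 0, 0)), 0L)
  expect_error(score_cesd(c(4, rep(0, 9))), "item values")
  expect_error(score_cesd(rep(0L, 9)), "10 items")
})

test_that("waves with three or more missing items are invalid", {
  expect_identical(score_cesd(c(NA, NA, NA, rep(0L, 7))), NA_integer_)
  expect_identical(score_cesd(rep(NA_integer_, 10)), NA_integer_)
})

test_that("up to two missing items are filled with the rounded person-mean", {
  # nine items of post-reversal contribution 2, one missing -> mean 2 -> 20
  items <- rep(2L, 10)
  items[c(5, 8)] <- 1L   # raw 1 reverses to 2
  items[3] <- NA
  expect_identical(score_cesd(items), 20L)
  # two missing; remaining contributions average 1.25 -> round to 1 each
  items2 <- c(1L, 1L, 1L, 1L, 2L, 1L, 3L, 2L, NA, NA)
  obs <- c(1, 1, 1, 1, 1, 1, 3, 1)  # post-reversal
  expect_identical(score_cesd(items2),
                   as.integer(sum(obs) + 2 * round(mean(obs))))
})

test_that("matrix input scores row-wise", {
  m <- rbind(rep(0L, 10), rep(3L, 10))
  expect_identical(score_cesd(m), c(6L, 24L))
})

test_that("worked state sequences classify per the five-state rules", {
  a <- classify_states(c(5, 14, 14, 8), c(0, 2, 4, 7))
  expect_identical(a$states, c(1L, 2L, 3L, 4L))
  expect_identical(a$events$path, c("12", "23", "34"))
  expect_identical(a$events$time, c(2, 4, 7))

  b <- classify_states(c(5, 14, 8, 14), c(0, 2, 4, 7))
  expect_identical(b$states, c(1L, 2L, 4L, 5L))
  expect_identical(b$events$path, c("12", "24", "45"))

  expect_identical(classify_states(c(5, 5, 5, 5), c(0, 2, 4, 7))$states,
                   rep(1L, 4))
  # boundary: exactly 12 is symptomatic
  expect_identical(classify_states(c(5, 12, 11, 12), c(0, 2, 4, 7))$states,
                   c(1L, 2L, 4L, 5L))
})

test_that("symptomatic baselines are rejected as excluded subjects", {
  expect_error(classify_states(c(12, 5), c(0, 2)), "excluded")
})

test_that("relapse is absorbing within the observation window", {
  s <- classify_states(c(5, 14, 8, 14, 8, 20), 0:5)
  expect_identical(s$states, c(1L, 2L, 4L, 5L, 5L, 5L))
  expect_identical(s$events$path, c("12", "24", "45"))
})

test_that("classifier never emits a transition outside the permitted set", {
  set.seed(404)
  for (i in 1:2000) {
    scores <- c(sample(0:11, 1), sample(0:30, sample(1:6, 1), replace = TRUE))
    s <- classify_states(scores, seq_along(scores) - 1)
    if (nrow(s$events))
      expect_true(all(s$events$path %in% transition_paths()))
    # consecutive labels equal or a permitted path
    pairs <- paste0(s$states[-length(s$states)], s$states[-1])
    same <- substr(pairs, 1, 1) == substr(pairs, 2, 2)
    expect_true(all(same | pairs %in% transition_paths()))
  }
})

test_that("raising one wave's score cannot de-symptomatize that wave", {
  set.seed(405)
  for (i in 1:300) {
    scores <- c(sample(0:11, 1), sample(0:30, 3, replace = TRUE))
    s0 <- classify_states(scores, 0:3)$states
    w <- sample(2:4, 1)
    scores2 <- scores
    scores2[w] <- min(30, scores[w] + sample(1:10, 1))
    s1 <- classify_states(scores2, 0:3)$states
    if (s0[w] %in% c(2L, 3L, 5L)) expect_true(s1[w] %in% c(2L, 3L, 5L))
  }
})

test_that("event tabulation counts per path with zero fill", {
  a <- classify_states(c(5, 14, 14, 8), c(0, 2, 4, 7))
  b <- classify_states(c(5, 14, 8, 14), c(0, 2, 4, 7))
  expect_identical(tabulate_events(list(a, b)),
                   c(`12` = 2L, `23` = 1L, `24` = 1L, `34` = 1L, `45` = 1L))
  expect_identical(tabulate_events(list()),
                   c(`12` = 0L, `23` = 0L, `24` = 0L, `34` = 0L, `45` = 0L))
  single <- classify_states(5, 0)
  expect_identical(sum(tabulate_events(list(single, single))), 0L)
})

test_that("panel classification handles both dialects and exclusions", {
  panel <- data.frame(subject_id = rep(1:2, each = 2),
                      wave_time = rep(c(0, 2), 2),
                      cesd_total = c(5, 14, 13, 5))
  expect_message(cls <- classify_panel(panel), "1 symptomatic at baseline")
  expect_identical(unique(cls$states$subject_id), 1L)
  expect_identical(cls$events$path, "12")

  # item-level dialect scores first
  items <- matrix(0L, 2, 10)
  items[2, 1:4] <- 3L    # wave-2 total 18
  panel2 <- cbind(data.frame(subject_id = 1L, wave_time = c(0, 2)),
                  as.data.frame(items))
  names(panel2)[3:12] <- paste0("item_", 1:10)
  cls2 <- classify_panel(panel2)
  expect_identical(cls2$states$state, c(1L, 2L))
})
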