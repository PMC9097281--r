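pp <- protocol_params()

test_that("initial contact detection follows the persistence rule", {
  tbl <- tibble::tibble(a = rep(3.0, 10), b = rep(5.0, 10))
  cs <- detect_initial_contacts(tbl, pp)
  expect_equal(cs$status[cs$id == "a"], "active")
  expect_equal(cs$status[cs$id == "b"], "candidate")
  # all distant: empty active set, the protocol never starts
  cs2 <- detect_initial_contacts(tibble::tibble(a = rep(5, 10)), pp)
  expect_false(any(cs2$status == "active"))
  expect_error(detect_initial_contacts(tibble::tibble(), pp), "empty")
})

test_that("persistence counting matches a per-pair frame-count oracle", {
  set.seed(1)
  n <- 200
  d1 <- c(rep(3.0, 120), rep(4.0, 80))    # below d_in in 60% of frames
  d2 <- c(rep(3.0, 80), rep(4.0, 120))    # 40%
  tbl <- tibble::tibble(p60 = sample(d1), p40 = sample(d2))
  oracle_active <- vapply(tbl, function(d) sum(d < 3.5) / n > 0.5, logical(1))
  cs <- detect_initial_contacts(tbl, pp)
  expect_identical(cs$status == "active", unname(oracle_active))
})

test_that("the bias target grows by one increment per active distance", {
  expect_equal(bias_target(10, 5, pp), 15)
  expect_equal(bias_target(7, 1, protocol_params(d_tar = 0)), 7)
  expect_equal(bias_target(0, 3, pp), 3)
  expect_error(bias_target(1, 0, pp))
})

test_that("contact re-evaluation applies the removal and addition rules", {
  cs <- detect_initial_contacts(
    tibble::tibble(far = rep(3, 10), wobbly = rep(3, 10), cand = rep(9, 10),
                   half = rep(9, 10)), pp)
  set.seed(2)
  w <- 500
  window <- tibble::tibble(
    far = rep(7, w),                                   # mean beyond d_out
    wobbly = 4 + stats::rnorm(w, sd = sqrt(1.5)),      # variance beyond d_var
    cand = c(rep(3.0, w / 2 + 1), rep(9, w / 2 - 1)),  # just over half below
    half = c(rep(3.0, w / 2), rep(9, w / 2))           # exactly half below
  )
  out <- update_contacts(window, cs, pp, iteration = 3)
  expect_equal(out$status[out$id == "far"], "removed")
  expect_equal(out$removed_iteration[out$id == "far"], 3L)
  expect_equal(out$status[out$id == "wobbly"], "removed")
  expect_equal(out$status[out$id == "cand"], "active")
  # strictly *more than half*: an exact 50% split is not added
  expect_equal(out$status[out$id == "half"], "candidate")
})

test_that("variance rule can be switched to a standard-deviation rule", {
  cs <- detect_initial_contacts(tibble::tibble(a = rep(3, 10)), pp)
  window <- tibble::tibble(a = 4 + c(-1, 1)[rep(1:2, 250)] * 1.05)
  # sd ~ 1.05 (beyond 1 Å), variance ~ 1.1 (beyond 1 Å^2): removed in both
  out_var <- update_contacts(window, cs, pp)
  out_sd <- update_contacts(window, cs, protocol_params(var_mode = "sd"))
  expect_equal(out_var$status[1], "removed")
  expect_equal(out_sd$status[1], "removed")
  # sd 0.8: variance 0.64 stays under a variance threshold of 1
  window2 <- tibble::tibble(a = 4 + c(-1, 1)[rep(1:2, 250)] * 0.8)
  expect_equal(update_contacts(window2, cs, pp)$status[1], "active")
})

test_that("equivalent groups merge to unweighted centers of mass", {
  anchors <- rbind(a = c(1, 0), b = c(-1, 0), c = c(0, 2), d = c(4, 4))
  # singleton group: unchanged position under a new name
  m1 <- merge_equivalent(list(g = "a"), anchors)
  expect_equal(unname(m1["g", ]), c(1, 0))
  # two symmetric anchors merge to the origin
  m2 <- merge_equivalent(list(ring = c("a", "b")), anchors)
  expect_equal(unname(m2["ring", ]), c(0, 0))
  # three-member group: representative equals the arithmetic mean
  m3 <- merge_equivalent(list(grp = c("a", "b", "c")), anchors)
  expect_equal(unname(m3["grp", ]), colMeans(anchors[c("a", "b", "c"), ]))
  expect_error(merge_equivalent(list(g1 = c("a", "b"), g2 = c("b", "c")),
                                anchors), "overlapping")
})

test_that("the unbinding protocol ejects the particle from the toy pocket", {
  fx <- make_fixtures(1)$pocket
  pp_fast <- protocol_params(iteration_length = 3000, max_iterations = 25)
  run <- run_unbinding(fx$potential, fx$anchors, fx$x0, params = pp_fast,
                       kT = fx$kT, seed = 7)
  expect_true(run$terminated)
  expect_false(any(run$contacts$status == "active"))
  final <- run$trajectory$frames[1, dim(run$trajectory$frames)[2], ]
  dists <- sqrt(rowSums((fx$anchors -
                           matrix(final, nrow(fx$anchors), 2,
                                  byrow = TRUE))^2))
  expect_true(all(dists > pp_fast$d_out))
})

test_that("an empty initial contact set means zero biased iterations", {
  fx <- make_fixtures(1)$pocket
  pp_fast <- protocol_params(iteration_length = 1000, max_iterations = 5)
  far <- c(30, 30)   # exploration far from every anchor
  run <- run_unbinding(fx$potential, fx$anchors, far, params = pp_fast,
                       kT = fx$kT, seed = 1)
  expect_true(run$terminated)
  expect_equal(nrow(run$log), 0)
  expect_equal(dim(run$trajectory$frames)[2], pp_fast$iteration_length)
})

test_that("the iteration history is reproducible under a fixed seed", {
  fx <- make_fixtures(1)$pocket
  pp_fast <- protocol_params(iteration_length = 1500, max_iterations = 20)
  r1 <- run_unbinding(fx$potential, fx$anchors, fx$x0, params = pp_fast,
                      kT = fx$kT, seed = 3)
  r2 <- run_unbinding(fx$potential, fx$anchors, fx$x0, params = pp_fast,
                      kT = fx$kT, seed = 3)
  expect_identical(r1$log, r2$log)
  expect_identical(r1$trajectory$frames, r2$trajectory$frames)
})

test_that("every removal is auditable from the recorded distances", {
  fx <- make_fixtures(1)$pocket
  pp_fast <- protocol_params(iteration_length = 2000, max_iterations = 25)
  run <- run_unbinding(fx$potential, fx$anchors, fx$x0, params = pp_fast,
                       kT = fx$kT, seed = 11)
  removed <- run$contacts[run$contacts$status == "removed", ]
  expect_gt(nrow(removed), 0)
  L <- pp_fast$iteration_length; W <- pp_fast$evaluation_window
  for (i in seq_len(nrow(removed))) {
    it <- removed$removed_iteration[i]
    # distances rows: exploration occupies 1..L, iteration k occupies
    # k*L + 1 .. (k+1)*L; the evaluation window is the last W frames
    rows <- seq.int(it * L + (L - W) + 1L, (it + 1L) * L)
    d <- run$distances[[removed$id[i]]][rows]
    expect_true(mean(d) > pp_fast$d_out || stats::var(d) > pp_fast$d_var)
  }
})

test_that("the pulled collective variable escapes monotonically across iterations", {
  fx <- make_fixtures(1)$pocket
  pp_fast <- protocol_params(iteration_length = 2000, max_iterations = 25)
  run <- run_unbinding(fx$potential, fx$anchors, fx$x0, params = pp_fast,
                       kT = fx$kT, seed = 13)
  # while the active set is unchanged, iteration-end CV values rise;
  # allow thermal noise of ~0.5 Å and compare only within constant-M spans
  lg <- run$log
  for (m in unique(lg$M)) {
    ce <- lg$cv_end[lg$M == m]
    if (length(ce) > 1) expect_true(all(diff(ce) > -0.5))
  }
  expect_lte(nrow(lg), pp_fast$max_iterations)
})
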