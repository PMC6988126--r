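test_that("PRPP evaluates the printed formula exactly and is depth-invariant", {
  prof <- tibble::tibble(frag = 1:3, count = c(50, 0, 200))
  out <- prpp_normalize(prof, cov = 10000, nprom = 20)
  expect_equal(out$prpp, c(50 / 10000 * 20 * 100, 0, 200 / 10000 * 20 * 100))
  expect_equal(out$prpp[1], 10)
  expect_equal(out$prpp[2], 0)
  # counts scaling with cov leave PRPP unchanged (exact)
  out2 <- prpp_normalize(dplyr::mutate(prof, count = count * 8),
                         cov = 80000, nprom = 20)
  expect_equal(out2$prpp, out$prpp)
  # mPRPP display scaling
  expect_equal(prpp_normalize(prof, 10000, 20, milli = TRUE)$mprpp[1], 10000)
  # proportional samples with equal cov/nprom keep identical PRPP ratios
  a <- prpp_normalize(prof, 10000, 20)
  b <- prpp_normalize(dplyr::mutate(prof, count = count * 3), 10000, 20)
  nz <- prof$count > 0
  expect_equal(b$prpp[nz] / a$prpp[nz], rep(3, sum(nz)))
})

test_that("interaction scores behave as an upper-tail Poisson against the decay fit", {
  cp <- simulate_capture_profile(150, 400, depth = 2e5, seed = 21)
  sc <- score_interactions(cp$profile, viewpoint = 150)
  # a fragment near its background expectation is unremarkable
  near <- which(abs(sc$count - sc$bg_expected) < 0.2 * sqrt(sc$bg_expected) &
                sc$count > 20)[1]
  expect_gt(sc$p_value[near], 0.25)
  expect_lt(sc$score[near], 0.7)
  # planted strong distal peak clears the score threshold
  cps <- simulate_capture_profile(150, 400,
    planted_peaks = tibble::tibble(frag = 320L, fold = 8), depth = 1e5, seed = 22)
  scs <- score_interactions(cps$profile, viewpoint = 150)
  expect_gte(scs$score[scs$frag == 320], 5)
  # monotone in observed count at fixed expected
  tweak <- scs
  tweak$count[tweak$frag == 310] <- tweak$count[tweak$frag == 310] + 50
  expect_gt(
    -log10(ppois(tweak$count[tweak$frag == 310] - 1,
                 scs$bg_expected[scs$frag == 310], lower.tail = FALSE)),
    scs$score[scs$frag == 310])
})

test_that("peak merging chains fragments under the strict 10-fragment rule", {
  scored <- tibble::tibble(frag = 1:40, count = 5,
                           score = ifelse(frag %in% c(5, 9, 30), 10, 0))
  pk <- merge_peaks(scored, viewpoint = 1)
  expect_equal(pk$start_frag, c(5L, 30L))
  expect_equal(pk$end_frag, c(9L, 30L))
  expect_equal(pk$n_frags, c(2L, 1L))
  # gap of exactly 10 is not merged
  scored10 <- dplyr::mutate(scored, score = ifelse(frag %in% c(5, 15), 10, 0))
  expect_equal(nrow(merge_peaks(scored10, viewpoint = 1)), 2)
  scored9 <- dplyr::mutate(scored, score = ifelse(frag %in% c(5, 14), 10, 0))
  expect_equal(nrow(merge_peaks(scored9, viewpoint = 1)), 1)
  # single significant fragment forms a one-fragment peak
  one <- dplyr::mutate(scored, score = ifelse(frag == 20, 10, 0))
  expect_equal(merge_peaks(one, viewpoint = 1)$summit_frag, 20L)
  # order independence
  shuffled <- scored[sample(nrow(scored)), ]
  expect_equal(merge_peaks(shuffled, viewpoint = 1), pk)
})

test_that("summits prefer the control sample and break ties toward the viewpoint", {
  scored <- tibble::tibble(frag = 1:20, count = c(rep(1, 9), 5, 9, rep(1, 9)),
                           score = ifelse(frag %in% 10:11, 8, 0))
  # without control: summit at the higher count
  expect_equal(merge_peaks(scored, viewpoint = 1)$summit_frag, 11L)
  # control present: summit at the control maximum
  control <- tibble::tibble(frag = 1:20, count = c(rep(1, 9), 9, 5, rep(1, 9)))
  expect_equal(merge_peaks(scored, viewpoint = 1, control = control)$summit_frag, 10L)
  # tie in counts: nearest the viewpoint wins
  tied <- tibble::tibble(frag = 1:20, count = c(rep(1, 9), 7, 7, rep(1, 9)),
                         score = ifelse(frag %in% 10:11, 8, 0))
  expect_equal(merge_peaks(tied, viewpoint = 1)$summit_frag, 10L)
  expect_equal(merge_peaks(tied, viewpoint = 20)$summit_frag, 11L)
})

test_that("planted peaks are recovered with high recall and precision", {
  planted <- tibble::tibble(frag = c(250L, 340L), fold = 8)
  stats <- purrr::map(1:20, function(s) {
    sim <- simulate_capture_profile(150, 400, planted_peaks = planted,
                                    depth = 1e5, seed = 400 + s)
    sc <- score_interactions(sim$profile, viewpoint = 150)
    pk <- merge_peaks(sc, viewpoint = 150)
    hit <- vapply(planted$frag, function(f) {
      any(pk$start_frag - 2 <= f & pk$end_frag + 2 >= f)
    }, logical(1))
    true_call <- vapply(seq_len(nrow(pk)), function(k) {
      any(planted$frag >= pk$start_frag[k] - 2 & planted$frag <= pk$end_frag[k] + 2)
    }, logical(1))
    c(recall = mean(hit),
      precision = if (nrow(pk) == 0) 1 else mean(true_call))
  })
  stats <- do.call(rbind, stats)
  expect_gte(mean(stats[, "recall"]), 0.9)
  expect_gte(mean(stats[, "precision"]), 0.9)
})

test_that("aggregate profiles normalize to the control summit by distance group", {
  frag <- 1:200
  base <- 100 / (1 + abs(frag - 1))
  control <- tibble::tibble(frag = frag, prpp = base)
  # condition doubled only at the distal peak
  cond <- tibble::tibble(frag = frag,
                         prpp = base * ifelse(frag >= 140, 2, 1))
  peaks <- tibble::tibble(start_frag = c(40L, 150L), end_frag = c(40L, 150L),
                          n_frags = 1L, summit_frag = c(40L, 150L),
                          max_score = 10)
  agg <- aggregate_profiles(list(control = control, treated = cond), peaks,
                            viewpoint = 1, distance_groups = c(1L, 2L),
                            window_frags = 10)
  at_summit <- dplyr::filter(agg, offset == 0)
  expect_equal(at_summit$mean_rel_prpp[at_summit$condition == "control"], c(1, 1))
  tr <- at_summit[at_summit$condition == "treated", ]
  expect_equal(tr$mean_rel_prpp[tr$group == 1], 1)
  expect_equal(tr$mean_rel_prpp[tr$group == 2], 2)
  # identical condition reproduces control everywhere
  same <- aggregate_profiles(list(control = control, treated = control), peaks,
                             viewpoint = 1, window_frags = 10)
  ctl <- dplyr::filter(same, condition == "control")
  trt <- dplyr::filter(same, condition == "treated")
  expect_equal(trt$mean_rel_prpp, ctl$mean_rel_prpp)
  # an empty distance group is reported and excluded
  peaks2 <- dplyr::mutate(peaks, summit_frag = c(5L, 150L))
  expect_message(
    aggregate_profiles(list(control = control[1:20, ], treated = cond[1:20, ]),
                       peaks2, viewpoint = 1, distance_groups = c(1L, 2L),
                       window_frags = 3),
    "empty distance groups")
})
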