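test_that("extract_state max-normalizes excitatory counts", {
  empty <- spike_record(duration = 100, n_neurons = 3)
  expect_identical(extract_state(empty, n_e = 3), numeric(3))
  # counts (5, 0, 2) -> (1, 0, 0.4); inhibitory spikes (neuron 4) ignored
  rec <- spike_record(c(rep(1, 5), rep(3, 2), rep(4, 9)),
                      c(10, 20, 30, 40, 50, 15, 25, seq(5, 85, by = 10)),
                      duration = 100, n_neurons = 4)
  expect_identical(extract_state(rec, n_e = 3), c(1, 0, 0.4))
  # rate normalization divides by the ceiling T * r_max
  expect_equal(extract_state(rec, n_e = 3, normalize = "rate", r_max = 100),
               c(5, 0, 2) / 10)
  expect_true(all(extract_state(rec, n_e = 3) >= 0 &
                    extract_state(rec, n_e = 3) <= 1))
})

test_that("concatenated ensemble state preserves the excitatory dimension", {
  expect_identical(concatenate_states(list(c(1, 0))), c(1, 0))
  v <- concatenate_states(lapply(1:4, function(k) rep(k / 10, 200)))
  expect_length(v, 800)
  # permuting the blocks changes the vector but not its norm
  v2 <- concatenate_states(lapply(4:1, function(k) rep(k / 10, 200)))
  expect_false(identical(v, v2))
  expect_equal(sum(v^2), sum(v2^2))
  # MLSR dimensional conservation at a fixed budget
  spec <- connectivity_spec(p_in_e = 30)
  solo <- build_liquid(200, spec, 16, seed = 1)
  ens <- build_ensemble(200, 4, spec, 16, seed = 1)
  inp <- const_channel_input(0.1, 16, 300, seed = 3)
  st <- ensemble_state(run_ensemble(ens, inp), ens)
  expect_length(st, solo$n_e)
})

test_that("readout reaches 100% on linearly separable Gaussians within 50 epochs", {
  set.seed(4)
  x <- rbind(matrix(rnorm(60, -2, 0.5), 30), matrix(rnorm(60, 2, 0.5), 30))
  y <- rep(1:2, each = 30)
  model <- train_readout(x, y, config = readout_config(epochs = 50, seed = 2))
  expect_identical(unname(predict(model, x)$class), y)
})

test_that("loss trace decreases on average and chance holds without signal", {
  set.seed(6)
  x <- rbind(matrix(rnorm(80, -1), 40), matrix(rnorm(80, 1), 40))
  y <- rep(1:2, each = 40)
  traces <- vapply(1:5, function(s) {
    train_readout(x, y, config = readout_config(epochs = 40,
                                                seed = s))$loss_trace
  }, numeric(40))
  avg <- rowMeans(traces)
  expect_lt(avg[40], avg[1]) # mini-batch SGD: endpoint decrease on average
  # full-batch gradient descent on the convex objective is monotone
  gd <- train_readout(x, y, config = readout_config(learning_rate = 0.2,
                                                    epochs = 40,
                                                    batch_size = 80,
                                                    seed = 1))$loss_trace
  expect_true(all(diff(gd) <= 1e-10))
  # identical states across classes carry no signal: accuracy = 1/L exactly
  # (one class predicted for all samples of a balanced set)
  x0 <- matrix(1, 60, 5)
  y0 <- rep(1:3, each = 20)
  m0 <- train_readout(x0, y0, config = readout_config(epochs = 20, seed = 1))
  expect_equal(mean(predict(m0, x0)$class == y0), 1 / 3)
  expect_error(train_readout(matrix(numeric(0), 0, 3), integer(0)),
               class = "insufficient_data")
})

test_that("predict applies softmax with lowest-index tie-break", {
  zero <- structure(list(W = matrix(0, 3, 2), b = numeric(3), L = 3L, d = 2L,
                         loss_trace = 0, config = readout_config()),
                    class = "readout_model")
  pr <- predict(zero, c(1, 1))
  expect_equal(pr$scores[1, ], rep(1 / 3, 3))
  expect_identical(pr$class, 1L)
  ident <- structure(list(W = diag(2), b = numeric(2), L = 2L, d = 2L,
                          loss_trace = 0, config = readout_config()),
                     class = "readout_model")
  pr2 <- predict(ident, c(2, 1))
  expect_identical(pr2$class, 1L)
  expect_equal(rowSums(pr2$scores), 1)
  expect_error(predict(ident, c(1, 2, 3)), class = "incompatible_state")
})

test_that("random_division splits with the stated remainder rule", {
  div <- random_division(1594, 4, seed = 3)
  expect_identical(vapply(div, length, integer(1)),
                   c(`1` = 399L, `2` = 399L, `3` = 398L, `4` = 398L))
  expect_identical(sort(unname(unlist(div))), 1:1594)
  expect_identical(unname(random_division(10, 1, seed = 1)[[1]]),
                   withr::with_seed(1L, sample.int(10)))
  for (s in 1:5) {
    d <- random_division(23, 3, seed = s)
    expect_identical(sort(unname(unlist(d))), 1:23) # disjoint cover
  }
})

test_that("clustered_division realizes the inhibition criterion bookkeeping", {
  n_per <- 100
  L <- 10
  labels <- rep(rep(1:L, each = n_per / L), 4)
  clusters <- rep(c("original", "rotated", "shifted", "noisy"), each = n_per)
  cd <- clustered_division(labels, clusters, L = L, x_f = 10, seed = 2)
  expect_setequal(names(cd), unique(clusters))
  for (cl in names(cd)) {
    part <- cd[[cl]]
    # 100 own + 10% of each of the 3 other clusters = 130 instances
    expect_length(part$indices, 130)
    expect_identical(sum(part$foreign), 30L)
    # foreign fraction 23%; every foreign target entry = 1/L = 0.1
    expect_equal(100 * mean(part$foreign), 23.076923, tolerance = 1e-6)
    expect_true(all(part$targets[part$foreign, ] == 0.1))
    # own rows are one-hot for the true label
    own_rows <- part$targets[!part$foreign, ]
    expect_true(all(rowSums(own_rows) == 1))
    expect_identical(apply(own_rows, 1, which.max),
                     as.integer(labels[part$indices[!part$foreign]]))
    # foreign sampling is without replacement
    expect_identical(anyDuplicated(part$indices), 0L)
  }
  # x_f = 0 gives pure one-hot per-cluster sets
  cd0 <- clustered_division(labels, clusters, L = L, x_f = 0, seed = 2)
  expect_true(all(vapply(cd0, function(p) !any(p$foreign), logical(1))))
  expect_identical(foreign_instance_fraction(4, 0), 0)
})

test_that("analytic foreign-instance quantities match their formulas", {
  expect_equal(foreign_instance_fraction(4, 10), 30 / 130 * 100)
  expect_equal(per_set_share(10, 4), 100 / 13)
  expect_equal(inhibitory_label(10), rep(0.1, 10))
  expect_equal(sum(inhibitory_label(7)), 1)
})

test_that("mlmr_classify fuses local scores by max with stated tie-breaks", {
  expect_identical(mlmr_classify(list(c(0.1, 0.7, 0.2))), 2L)
  loc <- list(rep(0.1, 10), c(rep(0.01, 3), 0.9, rep(0.01, 6)))
  expect_identical(mlmr_classify(loc), 4L)
  expect_identical(mlmr_classify(list(rep(0.25, 4), rep(0.25, 4))), 1L)
  # majority-vote alternative with lowest-index ties
  votes <- list(c(0.6, 0.4), c(0.4, 0.6), c(0.9, 0.1), c(0.2, 0.8))
  expect_identical(mlmr_classify(votes, rule = "majority"), 1L)
})

test_that("inhibition criterion lowers foreign-cluster peak scores", {
  # two clusters of 1-D-separable synthetic states; the CD-trained local
  # readout for cluster A sees 10% of B with uniform targets and should give
  # lower max scores on B than on A (paired over seeds).
  L <- 2
  wins <- vapply(1:5, function(s) {
    set.seed(s)
    a <- cbind(rnorm(40, -1), rnorm(40, ifelse(rep(1:2, 20) == 1, -2, 2)))
    b <- cbind(rnorm(40, 3), rnorm(40, ifelse(rep(1:2, 20) == 1, -2, 2)))
    labels <- rep(rep(1:2, 20), 2)
    clusters <- rep(c("A", "B"), each = 40)
    states <- rbind(a, b)
    cd <- clustered_division(labels, clusters, L = L, x_f = 10, seed = s)
    pa <- cd[["A"]]
    model <- train_readout(states[pa$indices, ], pa$targets, L = L,
                           config = readout_config(epochs = 80, seed = s))
    own <- predict(model, a)$scores
    foreign <- predict(model, b)$scores
    mean(apply(foreign, 1, max)) < mean(apply(own, 1, max))
  }, logical(1))
  expect_true(mean(wins) > 0.5)
})
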