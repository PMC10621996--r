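test_that("the 15% ceil split reproduces the reference class sizes", {
  s <- split_counts(742, 735)
  expect_equal(s$test_a, 112L)
  expect_equal(s$test_b, 111L)
  expect_equal(s$test_a + s$train_a, 742)
  expect_equal(s$test_b + s$train_b, 735)
  expect_equal(split_counts(20, 20)$test_a, 3L)  # ceil(3.0)
  expect_error(split_counts(3, 3, test_fraction = 0.9), "entire class")
  # test + train == n, always
  for (n in c(7, 100, 733)) {
    s <- split_counts(n, n + 1)
    expect_equal(s$test_a + s$train_a, n)
    expect_equal(s$test_b + s$train_b, n + 1)
  }
})

test_that("separable synthetic classes are classified accurately", {
  gen_feats <- function(n_tub, seeds) {
    purrr::map(seeds, function(s) {
      sc <- generate_scene(scene_config(
        image_size_px = c(128, 128), n_round = 6, n_tubular = n_tub,
        noise_sd = 0.06, min_separation_um = 2.2, seed = s))
      image_features(sc$lyso[, , 1], 120)
    }) |> purrr::list_rbind()
  }
  wt <- gen_feats(5, 100 + 1:25)
  ko <- gen_feats(0, 200 + 1:25)
  feats <- dplyr::bind_rows(dplyr::mutate(wt, label = "wt"),
                            dplyr::mutate(ko, label = "ko_like"))
  clf <- train_classifier(feats, ko_label = "ko_like", seed = 1)
  expect_gt(clf$test_accuracy, 0.9)
  # KO-like images really score high probabilities
  expect_gt(mean(predict(clf, ko)), mean(predict(clf, wt)))
  # broom-style accessors
  td <- tidy(clf)
  expect_true(all(c("term", "estimate") %in% names(td)))
  gl <- glance(clf)
  expect_equal(gl$accuracy, clf$test_accuracy)
})

test_that("indistinguishable or label-permuted classes score at chance", {
  set.seed(42)
  n <- 300
  same <- tibble::tibble(
    f1 = rnorm(2 * n), f2 = rnorm(2 * n), f3 = rnorm(2 * n),
    label = rep(c("a", "b"), each = n))
  clf <- suppressMessages(train_classifier(same, seed = 2))
  expect_lt(abs(clf$test_accuracy - 0.5), 0.2)
  # permuting real labels destroys the signal
  sep <- tibble::tibble(
    f1 = c(rnorm(n, 0), rnorm(n, 3)),
    label = rep(c("a", "b"), each = n))
  sep$label <- sample(sep$label)
  clf2 <- suppressMessages(train_classifier(sep, seed = 3))
  expect_lt(abs(clf2$test_accuracy - 0.5), 0.2)
  # single class errors
  expect_error(
    train_classifier(tibble::tibble(f1 = rnorm(5), label = "a")),
    "two classes")
})

test_that("condition scoring averages probabilities and indexes density", {
  # mean of per-image probabilities: construct a trivial classifier stub
  feats <- tibble::tibble(f1 = c(-10, 10), tubule_density = c(0.02, 0.02))
  train <- tibble::tibble(f1 = c(rnorm(50, -5), rnorm(50, 5)),
                          tubule_density = 0.05,
                          label = rep(c("wt", "ko"), each = 50))
  clf <- train_classifier(train, ko_label = "ko", seed = 1)
  rec <- score_condition(feats, clf, wt_mean = 0.08, ko_mean = 0.02,
                         condition_id = "siX")
  expect_equal(rec$n_images, 2)
  expect_equal(rec$mean_ko_probability,
               mean(predict(clf, feats)), tolerance = 1e-12)
  expect_equal(rec$tubulation_index, 0)  # density at the KO mean
})

test_that("gates derive from the minimal positive-control effect", {
  ctl <- tibble::tibble(mean_ko_probability = c(0.36, 0.21, 0.26),
                        tubulation_index = c(0.55, 0.43, 0.50))
  g <- derive_gates(ctl)
  expect_equal(g$nn_min_probability, 0.21)
  expect_equal(g$tub_max_index, 0.55)
  g_strict <- derive_gates(ctl, rule = "all_controls")
  expect_equal(g_strict$nn_min_probability, 0.36)
  expect_equal(g_strict$tub_max_index, 0.43)
  same <- tibble::tibble(mean_ko_probability = rep(0.3, 3),
                         tubulation_index = rep(0.5, 3))
  gs <- derive_gates(same)
  expect_equal(gs$nn_min_probability, 0.3)
  expect_equal(gs$tub_max_index, 0.5)
  expect_error(derive_gates(ctl[0, ]), "at least one",
               ignore.case = TRUE)
})

test_that("hit calling is the intersection of the two pass sets", {
  g <- tibble::tibble(nn_min_probability = 0.21, tub_max_index = 0.55)
  rec <- tibble::tibble(
    condition_id = sprintf("c%02d", 1:10),
    mean_ko_probability = c(0.5, 0.1, 0.3, 0.25, 0.05, 0.9, 0.22, 0.15, 0.6, 0.4),
    tubulation_index =    c(0.2, 0.2, 0.9, 0.40, 0.30, 0.1, 0.80, 0.50, 0.3, 0.56))
  out <- call_hits(rec, g)
  expect_true(out$is_hit[out$condition_id == "c01"])
  expect_false(out$is_hit[out$condition_id == "c02"])  # fails NN gate
  expect_equal(sum(out$is_hit), 4)
  expect_equal(out$is_hit, out$passes_nn_gate & out$passes_tub_gate)
  expect_setequal(out$condition_id[out$is_hit],
                  intersect(out$condition_id[out$passes_nn_gate],
                            out$condition_id[out$passes_tub_gate]))
})

test_that("raising a score never turns a hit into a non-hit", {
  g <- tibble::tibble(nn_min_probability = 0.21, tub_max_index = 0.55)
  set.seed(7)
  rec <- tibble::tibble(condition_id = sprintf("c%02d", 1:20),
                        mean_ko_probability = runif(20),
                        tubulation_index = runif(20))
  base <- call_hits(rec, g)
  up <- call_hits(dplyr::mutate(rec, mean_ko_probability =
                                  pmin(mean_ko_probability + 0.2, 1)), g)
  expect_true(all(up$is_hit[base$is_hit]))
  down <- call_hits(dplyr::mutate(rec, tubulation_index =
                                    pmax(tubulation_index - 0.2, 0)), g)
  expect_true(all(down$is_hit[base$is_hit]))
})

test_that("the synthetic stand-in screen table encodes its programmed structure", {
  tab <- synthetic_screen_scores(seed = 5)
  g <- tibble::tibble(nn_min_probability = 0.21, tub_max_index = 0.55)
  out <- call_hits(tab, g)
  expect_equal(sum(out$passes_nn_gate), 28)
  expect_equal(sum(out$passes_tub_gate), 11)
  expect_equal(sum(out$is_hit), 8)
})
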