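test_that("all-subset search enumerates, recovers exactly, and ranks like refits", {
  set.seed(55)
  pool <- as.data.frame(matrix(rnorm(40 * 5), 40, 5))
  names(pool) <- paste0("d", 1:5)
  y <- 2 * pool$d3                    # depends on descriptor 3 alone
  pop <- all_subset_search(pool, y + rnorm(40, 0, 1e-8), max_size = 2)
  expect_length(pop$models, choose(5, 1) + choose(5, 2))   # 15
  size1 <- Filter(function(m) length(m$subset) == 1, pop$models)
  expect_equal(size1[[1]]$subset, "d3")
  expect_gt(size1[[1]]$fitness, 1 - 1e-6)
  # ranking agrees with an independent refit of every subset
  y2 <- pool$d1 - pool$d2 + rnorm(40, 0, 0.5)
  pop2 <- all_subset_search(pool, y2, max_size = 2)
  for (m in pop2$models[1:5]) {
    refit <- q2_loo(pool[, m$subset, drop = FALSE], y2)
    expect_equal(m$fitness, refit, tolerance = 1e-12)
  }
  expect_error(all_subset_search(pool, y2, max_size = 4, budget = 10),
               "ga_vss")
})

test_that("GA-VSS is seed-reproducible and recovers planted descriptor subsets", {
  pool <- synthetic_pool(150, 50, seed = 301)
  resp <- generate_response(pool, synthetic_spec(n_molecules = 150, n_true = 7,
                                                 noise_sd = 0.4, seed = 301))
  cfg <- ga_config(model_size = 7, population = 60, generations = 60, seed = 13)
  a <- ga_vss(pool, resp$y, cfg)
  b <- ga_vss(pool, resp$y, cfg)
  expect_identical(lapply(a$models, `[[`, "subset"),
                   lapply(b$models, `[[`, "subset"))
  expect_identical(vapply(a$models, `[[`, numeric(1), "fitness"),
                   vapply(b$models, `[[`, numeric(1), "fitness"))
  expect_gte(length(intersect(best_subset(a), resp$truth$names)), 6L)
  # reported fitness equals an independent Q2_LOO recomputation
  expect_equal(a$models[[1]]$fitness,
               q2_loo(pool[, best_subset(a), drop = FALSE], resp$y),
               tolerance = 1e-12)
})

test_that("GA preloaded with the all-subset optimum never loses it (elitism)", {
  set.seed(77)
  pool <- as.data.frame(matrix(rnorm(60 * 10), 60, 10))
  names(pool) <- paste0("d", 1:10)
  y <- pool$d2 - pool$d7 + rnorm(60, 0, 0.3)
  opt <- best_subset(all_subset_search(pool, y, max_size = 2))
  cfg <- ga_config(model_size = 2, population = 20, generations = 30,
                   mutation_rate = 1e-9, seed = 3)
  pop <- ga_vss(pool, y, cfg, init = list(opt))
  expect_identical(sort(best_subset(pop)), sort(opt))
  # GA reaches at least 95% of the exhaustive optimum when both run
  pool12 <- pool[, 1:8]
  popx <- all_subset_search(pool12, y, max_size = 2)
  popg <- ga_vss(pool12, y, ga_config(model_size = 2, population = 30,
                                      generations = 30, seed = 4))
  expect_gte(popg$models[[1]]$fitness, 0.95 * popx$models[[1]]$fitness)
})

test_that("recurrent outliers emerge from spike-ins and not from clean data", {
  pool <- synthetic_pool(100, 15, seed = 401)
  resp <- generate_response(pool, synthetic_spec(n_molecules = 100, n_true = 3,
                                                 noise_sd = 0.3, seed = 401))
  y <- resp$y
  pop <- ga_vss(pool, y, ga_config(model_size = 3, population = 30,
                                   generations = 25, seed = 7))
  clean <- detect_recurrent_outliers(pop, pool, y, top_k = 5)
  y_spiked <- y
  y_spiked[42] <- y[42] + 5 * sd(y - mean(y))
  pop2 <- ga_vss(pool, y_spiked, ga_config(model_size = 3, population = 30,
                                           generations = 25, seed = 7))
  spiked <- detect_recurrent_outliers(pop2, pool, y_spiked, top_k = 5)
  expect_true(42 %in% spiked$index)
  expect_equal(spiked$n_outlier[spiked$index == 42], 5L)
  expect_false(42 %in% clean$index)
})

test_that("recalibration reproduces original coefficients and pools correctly", {
  set.seed(91)
  X <- as.data.frame(matrix(rnorm(150 * 4), 150, 4))
  names(X) <- paste0("d", 1:4)
  beta <- c(0.8, -1.2, 0.5, 0)
  y <- -1 + drop(as.matrix(X) %*% beta) + rnorm(150, 0, 0.4)
  sp <- split_by_response(y, 4)
  fit_tr <- fit_ols(X[sp$train, ], y[sp$train])
  # refitting the same descriptor set on the training data is the identity
  m_tr <- recalibrate(fit_tr, X[sp$train, ], y[sp$train])
  expect_equal(coef(m_tr), coef(fit_tr), tolerance = 1e-12)
  # pooling train + test: coefficients move toward truth, SEs shrink
  m_all <- recalibrate(fit_tr, X, y, model_id = "pooled")
  expect_equal(m_all$training_n, 150L)
  expect_lt(mean(m_all$terms$se), mean(fit_tr$se[-1]))
  expect_true(all(abs(m_all$terms$coefficient - beta) < 3 * m_all$terms$se))
  expect_error(recalibrate(fit_tr, X[, 1:2], y), "lacks descriptor")
})

test_that("the full synthetic pipeline recovers its generating model end-to-end", {
  pool <- synthetic_pool(160, 30, seed = 501)
  spec <- synthetic_spec(n_molecules = 160, n_true = 4, noise_sd = 0.4,
                         seed = 501)
  resp <- generate_response(pool, spec)
  sp <- split_by_response(resp$y, 4)
  ga <- ga_vss(pool[sp$train, ], resp$y[sp$train],
               ga_config(model_size = 4, population = 50, generations = 50,
                         seed = 21))
  sel <- best_subset(ga)
  expect_gte(length(intersect(sel, resp$truth$names)), 3L)
  fit <- fit_ols(pool[sp$train, sel], resp$y[sp$train])
  vr <- validation_report(pool[sp$train, sel], resp$y[sp$train],
                          pool[sp$test, sel], resp$y[sp$test],
                          lmo_iterations = 100, seed = 31)
  expect_gt(vr$q2_loo, 0.5)
  expect_gt(vr$q2_f3, 0.5)
  expect_gt(vr$ccc_ext, 0.7)
  # coefficients of the true members within 3 SE of the generator
  common <- intersect(sel, resp$truth$names)
  dev <- abs(coef(fit)[common] - resp$truth$beta[match(common, resp$truth$names)])
  expect_true(all(dev < 3 * fit$se[common]))
  # AD of the training fit flags few training chemicals
  ad <- williams(fit)
  expect_gt(mean(ad$in_domain), 0.8)
})
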