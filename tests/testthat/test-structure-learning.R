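# BIC-scored greedy structure search over the two graph parts.

strong_config <- function(n_units, seed, taus = c(0.6, 0.6, 0.6)) {
  synthetic_config(
    n_units = n_units,
    edge_specs = list(
      list(from = "PS", to = "FS", family = "gaussian", tau = taus),
      list(from = "PS", to = "WQ", family = "gaussian", tau = taus)),
    persistence_specs = list(),
    confounding_smd = 0, seed = seed)
}

search_template <- function() {
  dynamic_dag(c("PS", "FS", "WQ", "MSW"),
              g0_edges = data.frame(from = c("PS", "PS", "PS", "WQ"),
                                    to = c("FS", "WQ", "MSW", "MSW")))
}

test_that("the score report satisfies the BIC identity and the empty-graph baseline", {
  panel <- generate_panel(strong_config(500, 1))
  empty <- dynamic_dag(c("PS", "FS", "WQ", "MSW", "CUS"))
  rep0 <- bic_score(panel, empty, "initial")
  expect_equal(rep0$penalty, 0)
  expect_equal(rep0$n_free_params, 0)
  expect_equal(rep0$bic, rep0$loglik - 0.5 * log(rep0$K) * rep0$n_free_params)
  expect_equal(rep0$K, 500)
  one <- dynamic_dag(c("PS", "FS", "WQ", "MSW", "CUS"),
                     g0_edges = data.frame(from = "PS", to = "FS"))
  rep1 <- bic_score(panel, one, "initial")
  expect_equal(rep1$bic, rep1$loglik - 0.5 * log(rep1$K) * rep1$n_free_params)
  expect_gt(rep1$n_free_params, 0)
  # transition K counts unit-transitions across the analysis waves
  rept <- bic_score(panel, empty, "transition")
  expect_equal(rept$K, 500 * 2)
})

test_that("a true strong edge raises the score and a spurious one lowers it", {
  up <- 0; down <- 0
  empty_tpl <- c("PS", "FS", "WQ", "MSW", "CUS")
  for (seed in 1:10) {
    strong <- generate_panel(synthetic_config(
      n_units = 1000,
      edge_specs = list(list(from = "PS", to = "FS", family = "clayton",
                             tau = c(0.6, 0.6, 0.6))),
      persistence_specs = list(), confounding_smd = 0, seed = seed))
    nullp <- generate_panel(null_config(1000, seed = seed + 100))
    e <- dynamic_dag(empty_tpl, g0_edges = data.frame(from = "PS", to = "FS"))
    b <- dynamic_dag(empty_tpl)
    if (bic_score(strong, e, "initial")$bic >
        bic_score(strong, b, "initial")$bic) up <- up + 1
    if (bic_score(nullp, e, "initial")$bic <
        bic_score(nullp, b, "initial")$bic) down <- down + 1
  }
  expect_equal(up, 10)
  expect_gte(down, 9)
})

test_that("greedy search recovers planted edges and rejects independent ones", {
  recovered <- 0
  for (seed in 1:10) {
    panel <- generate_panel(strong_config(2000, seed))
    res <- greedy_search(panel, search_template(), part = "initial",
                         restarts = 5, seed = seed,
                         catalogue = c("gaussian", "clayton"))
    found <- paste(res$edges$from, res$edges$to)
    if (all(c("PS FS", "PS WQ") %in% found) &&
        !any(grepl("MSW", found))) recovered <- recovered + 1
  }
  expect_gte(recovered, 8)
})

test_that("fully independent data yields the empty graph", {
  empties <- 0
  for (seed in 1:10) {
    panel <- generate_panel(null_config(2000, seed = seed))
    res <- greedy_search(panel, study_fixture(), part = "initial",
                         restarts = 3, seed = seed,
                         catalogue = c("gaussian", "clayton"))
    if (nrow(res$edges) == 0) empties <- empties + 1
  }
  expect_gte(empties, 9)
})

test_that("more restarts never lower the attained score", {
  panel <- generate_panel(strong_config(800, 3))
  r1 <- greedy_search(panel, search_template(), part = "initial",
                      restarts = 1, seed = 5, catalogue = "gaussian")
  r10 <- greedy_search(panel, search_template(), part = "initial",
                       restarts = 10, seed = 5, catalogue = "gaussian")
  expect_gte(r10$report$bic, r1$report$bic)
  # determinism given the seed
  r10b <- greedy_search(panel, search_template(), part = "initial",
                        restarts = 10, seed = 5, catalogue = "gaussian")
  expect_equal(r10$edges, r10b$edges)
  expect_equal(r10$report$bic, r10b$report$bic)
})

test_that("every learned graph respects the slice constraints", {
  panel <- generate_panel(strong_config(600, 11))
  res <- learn_dynamic_structure(panel, study_fixture(), restarts = 2,
                                 seed = 11, catalogue = "gaussian")
  expect_silent(validate_dag(res$dag))
  # decomposability: total score is the sum of the two part scores
  expect_equal(res$total_score,
               res$initial$report$bic + res$transition$report$bic)
})

test_that("with the penalty disabled the search keeps every true edge", {
  panel <- generate_panel(strong_config(1500, 23))
  res <- greedy_search(panel, search_template(), part = "initial",
                       restarts = 2, seed = 23, catalogue = "gaussian",
                       score = "none")
  found <- paste(res$edges$from, res$edges$to)
  expect_true(all(c("PS FS", "PS WQ") %in% found))
})

test_that("single-wave panels are rejected for dynamic learning", {
  panel <- generate_panel(strong_config(300, 2))
  one_wave <- panel_dataset(
    panel$data[panel$data$wave == "2009", ], panel$schema, waves = "2009")
  expect_error(learn_dynamic_structure(one_wave, study_fixture()),
               "at least 2")
})
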