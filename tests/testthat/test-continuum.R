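test_that("ordinal targets map the five stages onto 0..1 quarters", {
  expect_equal(ordinal_target(c("normal", "sclerosis", "mild", "moderate",
                                "severe")),
               c(0, 0.25, 0.5, 0.75, 1))
})

test_that("Bernoulli loss evaluates and is minimised at p = y", {
  expect_equal(loss_bernoulli(0.5, 1), log(2), tolerance = 1e-9)
  expect_lt(loss_bernoulli(1e-7, 0), 1e-6)
  expect_equal(loss_bernoulli(0.75, 0.75),
               -(0.75 * log(0.75) + 0.25 * log(0.25)), tolerance = 1e-9)
  expect_error(loss_bernoulli(0.5, 1.2), "\\[0, 1\\]")
  pgrid <- seq(0.01, 0.99, by = 0.01)
  for (y in c(0, 0.25, 0.5, 0.75, 1)) {
    best <- pgrid[which.min(loss_bernoulli(pgrid, y))]
    expect_equal(best, min(max(y, 0.01), 0.99), tolerance = 0.011)
  }
})

test_that("combined loss reduces to the Bernoulli term when weighted out", {
  expect_equal(loss_combined(0.6, 0.75, c(1, 2, 3), c(0, 0, 0),
                             lambda_weight = 0),
               loss_bernoulli(0.6, 0.75))
  expect_equal(loss_combined(0.6, 0.75, c(1, 2, 3), c(9, 9, 9),
                             aux_mask = c(0, 0, 0), lambda_weight = 5),
               loss_bernoulli(0.6, 0.75))
  expect_equal(loss_combined(0.5, 0.5, c(0.5, 0, 0), c(0, 0, 0),
                             lambda_weight = 1),
               log(2) + 0.25, tolerance = 1e-9)
  expect_error(loss_combined(0.5, 0.5, lambda_weight = -1), ">= 0")
})

test_that("patient aggregation follows the view-mean-then-average rule", {
  ps <- aggregate_patient(data.frame(view = c("PLAX", "PLAX", "PSAX"),
                                     score = c(60, 70, 50)))
  expect_equal(ps$per_view_mean$PLAX, 65)
  expect_equal(ps$per_view_mean$PSAX, 50)
  expect_equal(ps$dli_asc, 57.5)

  only <- aggregate_patient(data.frame(view = c("PSAX", "PSAX"),
                                       score = c(40, 60)))
  expect_equal(only$dli_asc, 50)

  single <- aggregate_patient(data.frame(view = "PLAX", score = 42))
  expect_equal(single$dli_asc, 42)
  expect_error(aggregate_patient(data.frame()), "no scores")
})

test_that("aggregation is order-invariant and bounded by its inputs", {
  set.seed(8)
  for (i in 1:25) {
    n <- sample(1:6, 1)
    df <- data.frame(view = sample(c("PLAX", "PSAX"), n, replace = TRUE),
                     score = runif(n, 0, 100))
    a <- aggregate_patient(df)
    b <- aggregate_patient(df[sample(n), ])
    expect_equal(a$dli_asc, b$dli_asc)
    expect_gte(a$dli_asc, min(df$score))
    expect_lte(a$dli_asc, max(df$score))
  }
})

test_that("cutoffs are consecutive-category midpoints", {
  stages <- rep(c("normal", "sclerosis", "mild", "moderate", "severe"),
                each = 4)
  scores <- rep(c(5, 20, 50, 60, 80), each = 4) + rep(c(-1, 1, -1, 1), 5)
  cuts <- derive_cutoffs(scores, stages)
  expect_equal(unlist(cuts), c(sclerosis = 12.5, mild = 35, moderate = 55,
                               severe = 70))
  expect_error(derive_cutoffs(scores[1:8], stages[1:8]), "mild")
})

test_that("classification by cutoffs is inclusive at the boundary", {
  cuts <- default_cutoffs()
  expect_equal(unlist(cuts), c(sclerosis = 24.6, mild = 45.4,
                               moderate = 53.7, severe = 69.7))
  expect_equal(classify_by_cutoffs(70, cuts), "severe")
  expect_equal(classify_by_cutoffs(10, cuts), "normal")
  expect_equal(classify_by_cutoffs(53.7, cuts), "moderate")
  expect_equal(classify_by_cutoffs(c(0, 24.6, 45.39), cuts),
               c("normal", "sclerosis", "sclerosis"))
  expect_error(cutoff_set(30, 20, 50, 60), "increasing")
  expect_error(classify_by_cutoffs(120, cuts), "\\[0, 100\\]")
})

small_training_set <- function(n_specs = 10, seed = 3) {
  specs <- sample_cohort(n_specs, rep(0.2, 5), seed = seed)
  list(videos = lapply(specs, function(sp) render_views(sp, 64, 16)$plax),
       labels = cohort_table(specs))
}

test_that("training is deterministic given the seed", {
  ts <- small_training_set(6)
  cfg <- asc_model_config(epochs = 3, batch_size = 3, seed = 21,
                          patience = 10)
  a <- train_continuum_model(ts$videos, ts$labels, cfg)
  b <- train_continuum_model(ts$videos, ts$labels, cfg)
  expect_identical(a$history, b$history)
  expect_equal(score_video(a, ts$videos[[1]]), score_video(b, ts$videos[[1]]))
})

test_that("lambda = 0 and fully masked auxiliaries train identically", {
  ts <- small_training_set(6)
  cfg0 <- asc_model_config(epochs = 3, batch_size = 3, seed = 21,
                           lambda_weight = 0, patience = 10)
  cfg1 <- asc_model_config(epochs = 3, batch_size = 3, seed = 21,
                           lambda_weight = 1, patience = 10)
  masked <- ts$labels
  masked$vmax <- masked$mpg <- masked$ava <- NA_real_
  a <- train_continuum_model(ts$videos, ts$labels, cfg0)
  b <- train_continuum_model(ts$videos, masked, cfg1)
  expect_equal(a$history$train_loss, b$history$train_loss, tolerance = 1e-10)
})

test_that("the network has capacity to fit ten phantoms", {
  ts <- small_training_set(10, seed = 3)
  cfg <- asc_model_config(epochs = 250, batch_size = 5, seed = 5,
                          patience = 250)
  scorer <- train_continuum_model(ts$videos, ts$labels, cfg, val_idx = 1:2,
                                  return_best = FALSE)
  y <- ordinal_target(ts$labels$stage)
  trained <- 3:10
  excess <- vapply(trained, function(i) {
    p <- score_video(scorer, ts$videos[[i]]) / 100
    loss_bernoulli(p, y[i]) - loss_bernoulli(y[i], y[i])
  }, numeric(1))
  # mean excess over the soft-target entropy floor on the fitted videos
  expect_lt(mean(excess), 0.1)
})

test_that("training validates its inputs", {
  ts <- small_training_set(4, seed = 9)
  one_class <- ts$labels; one_class$stage <- "mild"
  expect_error(train_continuum_model(ts$videos, one_class,
                                     asc_model_config(epochs = 1)),
               "two severity classes")
  expect_error(asc_model_config(lambda_weight = -2), ">= 0")
})

test_that("scores live on the 0-100 scale and views are checked", {
  scorer <- get_scorer300()
  co <- get_cohort300()
  sc <- held_out_scores()$score
  expect_true(all(sc >= 0 & sc <= 100))
  bad <- co$videos[[1]]; bad$view <- "A4C"
  expect_error(score_video(scorer, bad), "view")
})

test_that("held-out scores recover the severity continuum", {
  ho <- held_out_scores()
  ord <- asckit:::stage_ordinal(ho$stage)
  expect_gte(cor(ho$score, ord, method = "spearman"), 0.8)
  means <- tapply(ho$score, ord, mean)
  expect_true(all(diff(means) > 0))
  auc <- pROC::auc(pROC::roc(ord >= 4, ho$score, quiet = TRUE,
                             direction = "<", levels = c(FALSE, TRUE)))
  expect_gte(as.numeric(auc), 0.9)
})

test_that("auxiliary heads learn only when the multi-task weight is on", {
  specs <- sample_cohort(40, rep(0.2, 5), seed = 53)
  videos <- lapply(specs, function(sp) render_views(sp, 64, 16)$plax)
  labels <- cohort_table(specs)
  tr <- 1:32; ho <- 33:40
  run <- function(lam) {
    cfg <- asc_model_config(epochs = 10, seed = 13, lambda_weight = lam,
                            patience = 10)
    scorer <- train_continuum_model(videos[tr], labels[tr, ], cfg)
    mse <- 0
    for (i in ho) {
      z <- (c(labels$vmax[i], labels$mpg[i], labels$ava[i]) -
              scorer$aux_norm$mean) / scorer$aux_norm$sd
      pred <- (predict_aux(scorer, videos[[i]]) - scorer$aux_norm$mean) /
        scorer$aux_norm$sd
      mse <- mse + sum((pred - z)^2)
    }
    mse / length(ho)
  }
  expect_lt(run(1), run(0))
})

test_that("saliency maps are valid heatmaps that focus on the leaflets", {
  scorer <- get_scorer300()
  co <- get_cohort300()
  sal <- saliency_map(scorer, co$videos[[1]])
  expect_equal(dim(sal), c(64, 64, 16))
  expect_gte(min(sal), 0)
  expect_equal(max(sal), 1)

  flat <- co$videos[[1]]
  flat$frames[] <- 0.5
  expect_no_error(saliency_map(scorer, flat))

  # localisation: mean saliency inside the leaflet box beats outside on a
  # clear majority of held-out PLAX videos
  ho_plax <- co$held_out[co$held_out %% 2 == 1]   # odd indices are PLAX
  hits <- vapply(ho_plax, function(i) {
    sp <- co$specs[[ceiling(i / 2)]]
    rv <- render_views(sp, 64, 16)
    b <- rv$truth$leaflet_box
    s <- saliency_map(scorer, co$videos[[i]])
    inside <- s[b["row_min"]:b["row_max"], b["col_min"]:b["col_max"], ]
    mean(inside) > (sum(s) - sum(inside)) / (length(s) - length(inside))
  }, logical(1))
  expect_gte(mean(hits), 0.7)
})

test_that("feature embedding is reproducible and tracks the continuum", {
  scorer <- get_scorer300()
  co <- get_cohort300()
  vids <- co$videos[co$held_out]
  emb1 <- embed_features(scorer, vids, seed = 42)
  expect_equal(dim(emb1$embedding), c(length(vids), 2))
  emb2 <- embed_features(scorer, vids, seed = 42)
  expect_identical(emb1$embedding, emb2$embedding)

  ord <- asckit:::stage_ordinal(co$labels$stage[co$held_out])
  pc1 <- prcomp(emb1$embedding)$x[, 1]
  expect_gte(abs(cor(pc1, ord, method = "spearman")), 0.6)
  expect_error(embed_features(scorer, vids[1:10]), "16")
})
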