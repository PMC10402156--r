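# training-contract tests run on the small cached simulation with a couple of
# quick epochs; learning-quality checks live in test-acceptance.R
mini_cfg <- function(...) {
  miniature_train_config(max_epochs = 2L, patience = 2L,
                         examples_per_epoch = 8L, val_examples = 4L,
                         start_buffer = 2.2e5, end_buffer = 2.2e5, ...)
}

test_that("training examples respect buffers, shapes and reproducibility", {
  sd <- cached_sim()
  ds <- sd$bulk$chrA
  g <- miniature_geometry()
  cfg <- mini_cfg(seed = 1)
  tt <- usable_centers(ds, cfg)
  res <- ds$zmap$resolution
  expect_true(all((tt - 1) * res >= cfg$start_buffer))
  expect_true(all(tt * res <= chrom_length(ds$layout, "chrA") - cfg$end_buffer))
  expect_error(make_training_example(ds, min(tt) - 1L, g, cfg), "buffer")

  ex <- withr::with_seed(5, make_training_example(ds, tt[10], g, cfg))
  expect_equal(dim(ex$acc_ctcf), c(g$acc_window_len, 2L))
  expect_equal(dim(ex$coacc), c(g$center_coacc_bins, g$coacc_window_len))
  expect_true(all(ex$coacc >= 0 & ex$coacc <= 1))
  expect_length(ex$target$values, g$out_len)

  ex2 <- withr::with_seed(5, make_training_example(ds, tt[10], g, cfg))
  expect_identical(ex, ex2)  # same seed, bit-identical
  ex3 <- withr::with_seed(6, make_training_example(ds, tt[10], g, cfg))
  expect_false(identical(ex$acc_ctcf, ex3$acc_ctcf))  # augmentation active
})

test_that("a +50bp shift displaces the accessibility window by one bin", {
  sd <- cached_sim()
  ds <- sd$bulk$chrA
  g <- miniature_geometry()
  cfg <- mini_cfg()
  draws <- augmentation_draws(ds, cfg, augment = FALSE)
  d_plus <- draws; d_plus$shift <- 50L
  ex0 <- make_training_example(ds, 100L, g, cfg, augment = FALSE,
                               draws = draws, side = "right")
  exs <- make_training_example(ds, 100L, g, cfg, augment = FALSE,
                               draws = d_plus, side = "right")
  n <- nrow(ex0$acc_ctcf)
  expect_equal(exs$acc_ctcf[1:(n - 1), 1], ex0$acc_ctcf[2:n, 1])
})

test_that("masked MSE averages over valid entries only", {
  target <- list(values = c(1, 2, NA, 4), valid = c(TRUE, TRUE, FALSE, TRUE))
  expect_equal(as.numeric(masked_mse(c(1, 2, 99, 4), target)), 0)
  expect_equal(as.numeric(masked_mse(c(2, 3, 0, 5), target)), 1)
  half <- list(values = c(2, NA), valid = c(TRUE, FALSE))
  expect_equal(as.numeric(masked_mse(c(5, 100), half)), 9)
  none <- list(values = c(NA, NA), valid = c(FALSE, FALSE))
  l <- masked_mse(c(1, 2), none)
  expect_equal(as.numeric(l), 0)
  expect_equal(attr(l, "n_valid"), 0L)
})

test_that("stage-2 training freezes feature extractor 1 bit-for-bit", {
  sd <- cached_sim()
  g <- miniature_geometry()
  cfg <- mini_cfg(seed = 2)
  model <- chromafold_model(g, seed = 2)
  expect_error(train_stage2(model, sd$bulk, cfg), "stage-1")
  s1 <- train_stage1(model, sd$bulk, cfg)
  fe1_before <- s1$model$params[grepl("^fe1\\.", names(s1$model$params))]
  s2 <- train_stage2(s1$model, sd$bulk, cfg)
  fe1_after <- s2$model$params[grepl("^fe1\\.", names(s2$model$params))]
  expect_identical(fe1_before, fe1_after)
  # stage 2 did train the other parameters
  expect_false(identical(s1$model$params[["fe2.lin.W"]],
                         s2$model$params[["fe2.lin.W"]]))
  # stage 1 left feature extractor 2 untouched
  init <- chromafold_model(g, seed = 2)
  expect_identical(s1$model$params[["fe2.lin.W"]], init$params[["fe2.lin.W"]])
})

test_that("early stopping halts within patience and restores the best epoch", {
  sd <- cached_sim()
  g <- miniature_geometry()
  cfg <- mini_cfg(seed = 3, max_epochs = 6L, patience = 2L)
  model <- chromafold_model(g, seed = 3)
  s1 <- train_stage1(model, sd$bulk, cfg)
  h <- s1$history
  expect_lte(nrow(h), 6)
  best <- which.min(h$val_loss)
  expect_lte(nrow(h) - best, cfg$patience)
  # the restored parameters reproduce the recorded best validation loss
  vl <- chromstripe:::validation_loss(s1$model, sd$bulk, cfg, "stage1")
  expect_equal(vl, min(h$val_loss), tolerance = 1e-10)
})

test_that("training is reproducible under a fixed seed", {
  sd <- cached_sim()
  g <- miniature_geometry()
  cfg <- mini_cfg(seed = 4)
  m1 <- train_stage1(chromafold_model(g, seed = 4), sd$bulk, cfg)
  m2 <- train_stage1(chromafold_model(g, seed = 4), sd$bulk, cfg)
  expect_identical(m1$model$params, m2$model$params)
  expect_identical(m1$history, m2$history)
})

test_that("fine-tuning runs exactly one epoch on training chromosomes only", {
  sd <- cached_sim()
  g <- miniature_geometry()
  cfg <- mini_cfg(seed = 5)
  model <- chromafold_model(g, seed = 5)
  expect_error(finetune(model, sd$bulk, cfg), "pretrained")
  s1 <- train_stage1(model, sd$bulk, cfg)
  s2 <- train_stage2(s1$model, sd$bulk, cfg)
  ft <- finetune(s2$model, sd$bulk, cfg, epochs = 1L)
  expect_equal(nrow(ft$history), 1)
  expect_false(identical(ft$model$params, s2$model$params))
  # all-parameter training: feature extractor 1 moves during fine-tuning
  expect_false(identical(ft$model$params[["fe1.lin.W"]],
                         s2$model$params[["fe1.lin.W"]]))
})

test_that("augmentation subsample sizes respect the configured ranges", {
  sd <- cached_sim()
  ds <- sd$bulk$chrA
  cfg <- mini_cfg(cell_subsample = c(50L, 120L),
                  metacell_subsample = c(20L, 60L))
  set.seed(6)
  for (i in 1:20) {
    dr <- augmentation_draws(ds, cfg, augment = TRUE)
    expect_true(dr$pb$n_cells_used >= 50 && dr$pb$n_cells_used <= 120)
    expect_true(length(dr$mc_idx) >= 20 && length(dr$mc_idx) <= 60)
    expect_true(dr$shift %in% c(-50L, 50L))
  }
})
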