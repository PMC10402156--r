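# a tiny random example matching the miniature geometry
random_example <- function(g, seed = 1) {
  set.seed(seed)
  list(acc_ctcf = matrix(rnorm(g$acc_window_len * 2), g$acc_window_len, 2),
       coacc = matrix(runif(g$center_coacc_bins * g$coacc_window_len),
                      g$center_coacc_bins, g$coacc_window_len))
}

test_that("geometry derives consistent constants and rejects bad configs", {
  g <- model_geometry()
  expect_equal(g$acc_window_len, 80200L)       # 4.01 Mb / 50 bp
  expect_equal(g$hic_window_bins, 401L)
  expect_equal(g$out_len, 201L)                # 2 Mb / 10 kb + diagonal
  expect_equal(g$coacc_window_len, 8020L)
  expect_equal(g$reduction_factor, prod(g$pool_schedule))
  gm <- miniature_geometry()
  expect_equal(gm$acc_window_len, gm$hic_window_bins * gm$reduction_factor)
  expect_equal(gm$out_len, (gm$hic_window_bins + 1L) / 2L)
  expect_error(model_geometry(hic_window_bins = 40), "odd")
  expect_error(model_geometry(pool_schedule = c(2, 2)), "pool_schedule")
})

test_that("outer concatenation matches the index-loop oracle", {
  # enumeration: L = 2, C = 1
  f <- matrix(c(5, 7), 2, 1)
  oc <- outer_concat(f)
  expect_equal(oc[1, 1, ], c(5, 5))
  expect_equal(oc[1, 2, ], c(5, 7))
  expect_equal(oc[2, 1, ], c(7, 5))
  expect_equal(oc[2, 2, ], c(7, 7))
  # random instances against a brute-force loop
  set.seed(8)
  for (rep in 1:5) {
    L <- sample(2:16, 1); C <- sample(1:8, 1)
    f <- matrix(rnorm(L * C), L, C)
    oc <- outer_concat(f)
    for (i in seq_len(L)) for (j in seq_len(L))
      expect_equal(oc[i, j, ], c(f[i, ], f[j, ]))
  }
})

test_that("feature extractor output lengths follow the geometry", {
  g <- miniature_geometry()
  m <- chromafold_model(g, seed = 1)
  ex <- random_example(g)
  f1 <- chromstripe:::fe1_forward(m, ex$acc_ctcf)
  expect_equal(nrow(f1$F1), g$hic_window_bins)     # 41 under mini, 401 full
  f2 <- chromstripe:::fe2_forward(m, ex$coacc)
  expect_equal(nrow(f2$F2), g$out_len)
  pred <- predict_one_side(m, ex, stage = "stage1")
  expect_length(pred, g$out_len)
  expect_error(chromafold_model(g, channels = utils::modifyList(
    model_channels("mini"), list(fe1 = rep(8L, 10)))), "fifteen")
})

test_that("evaluation-mode forward is deterministic; zero input is bias-driven", {
  g <- miniature_geometry()
  m <- chromafold_model(g, seed = 2)
  ex <- random_example(g, 3)
  p1 <- predict_one_side(m, ex)
  p2 <- predict_one_side(m, ex)
  expect_identical(p1, p2)
  z <- list(acc_ctcf = matrix(0, g$acc_window_len, 2),
            coacc = matrix(0, g$center_coacc_bins, g$coacc_window_len))
  expect_identical(predict_one_side(m, z), predict_one_side(m, z))
  # stage-1 and stage-2 heads agree in output shape
  expect_length(predict_one_side(m, ex, stage = "stage1"), g$out_len)
  expect_length(predict_one_side(m, ex, stage = "full"), g$out_len)
})

test_that("input reversal is an involution and defines the left stripe", {
  g <- miniature_geometry()
  ex <- random_example(g, 4)
  expect_equal(reverse_example(reverse_example(ex))[c("acc_ctcf", "coacc")],
               ex[c("acc_ctcf", "coacc")])
  m <- chromafold_model(g, seed = 5)
  # left of x equals right of reverse(x) by definition
  expect_equal(predict_one_side(m, ex, side = "left"),
               predict_one_side(m, reverse_example(ex), side = "right"))
})

test_that("mirror-symmetric inputs give identical left/right stripes", {
  g <- miniature_geometry()
  set.seed(6)
  acc <- matrix(rnorm(g$acc_window_len * 2), g$acc_window_len, 2)
  acc <- (acc + acc[rev(seq_len(nrow(acc))), ]) / 2
  J <- matrix(runif(g$center_coacc_bins * g$coacc_window_len),
              g$center_coacc_bins, g$coacc_window_len)
  J <- (J + J[rev(seq_len(nrow(J))), rev(seq_len(ncol(J)))]) / 2
  m <- chromafold_model(g, seed = 7)
  vs <- predict_vstripe(m, list(acc_ctcf = acc, coacc = J))
  expect_equal(vs$left, vs$right, tolerance = 1e-10)
})

test_that("backward pass matches finite differences on sampled parameters", {
  g <- miniature_geometry()
  m <- chromafold_model(g, seed = 8)
  ex <- random_example(g, 9)
  target <- list(values = rnorm(g$out_len), valid = rep(TRUE, g$out_len))
  fw <- model_forward(m, ex$acc_ctcf, ex$coacc, stage = "full",
                      keep_cache = TRUE)
  gr <- chromstripe:::model_backward(
    m, chromstripe:::masked_mse_grad(fw$pred, target), fw$cache)
  lossfun <- function(mm)
    as.numeric(masked_mse(model_forward(mm, ex$acc_ctcf, ex$coacc)$pred,
                          target))
  eps <- 1e-5
  set.seed(10)
  for (nm in c("head.final.W", "fe2.lin.W", "fe2.res.1.a.W",
               "fe1.lin.W", "fe1.bn.10.gamma", "fe2.pn.beta")) {
    i <- sample(length(m$params[[nm]]), 1)
    m2 <- m; m2$params[[nm]][i] <- m2$params[[nm]][i] + eps
    m3 <- m; m3$params[[nm]][i] <- m3$params[[nm]][i] - eps
    num <- (lossfun(m2) - lossfun(m3)) / (2 * eps)
    expect_equal(gr[[nm]][i], num, tolerance = 5e-3,
                 label = paste("grad", nm))
  }
})

test_that("residual blocks become the identity when their weights are zeroed", {
  g <- miniature_geometry()
  m <- chromafold_model(g, seed = 11)
  ex <- random_example(g, 12)
  m0 <- m
  for (r in 1:2) for (s in c("a", "b")) {
    m0$params[[paste0("fe2.res.", r, ".", s, ".W")]][] <- 0
    m0$params[[paste0("fe2.res.", r, ".", s, ".b")]][] <- 0
    m0$params[[paste0("fe2.rbn.", r, ".", s, ".gamma")]][] <- 1
    m0$params[[paste0("fe2.rbn.", r, ".", s, ".beta")]][] <- 0
  }
  # oracle: same network with the residual blocks cut out entirely
  p <- m0$params; ch <- m0$channels; kf <- ch$fe2_kernel
  h <- t(ex$coacc)
  blk <- function(h, i) {
    cv <- chromstripe:::conv1d_fwd(h, p[[paste0("fe2.conv.", i, ".W")]],
                                   p[[paste0("fe2.conv.", i, ".b")]], kf)
    no <- chromstripe:::inorm_fwd(cv$y, p[[paste0("fe2.bn.", i, ".gamma")]],
                                  p[[paste0("fe2.bn.", i, ".beta")]])
    chromstripe:::relu_fwd(no$y)$y
  }
  for (i in 1:6) h <- blk(h, i)
  pl <- chromstripe:::pool1d_fwd(h, g$coacc_per_hic, ch$pool_type)
  right <- pl$y[(g$max_distance_bins + 1L):nrow(pl$y), , drop = FALSE]
  lin <- chromstripe:::linear_fwd(right, p[["fe2.lin.W"]], p[["fe2.lin.b"]])
  pn <- chromstripe:::inorm_fwd(lin$y, p[["fe2.pn.gamma"]], p[["fe2.pn.beta"]])
  expect_equal(chromstripe:::fe2_forward(m0, ex$coacc)$F2, pn$y,
               tolerance = 1e-12)
})

test_that("max pooling selects the maximum and routes gradient to it", {
  set.seed(13)
  x <- matrix(rnorm(40), 20, 2)
  mp <- chromstripe:::maxpool1d_fwd(x, 5)
  oracle <- apply(array(x, c(5, 4, 2)), c(2, 3), max)
  expect_equal(unname(mp$y), unname(oracle))
  dy <- matrix(rnorm(8), 4, 2)
  dx <- chromstripe:::maxpool1d_bwd(dy, mp$cache)
  expect_equal(sum(dx != 0), 8)
  expect_equal(colSums(dx), colSums(dy))
})
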