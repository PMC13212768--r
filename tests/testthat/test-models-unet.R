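test_that("U-Net forward honours shape contracts", {
  tx <- structure(array(with_seed(1, rnorm(16 * 8 * 8)), c(16, 8, 8)),
                  class = "input_tensor")
  um <- unet_init(c(16L, 8L), 8L, channels = c(4L, 6L), bottleneck = 8L,
                  seed = 3)
  pred <- unet_forward(tx, um)
  expect_equal(dim(pred), c(16L, 8L))
  expect_identical(pred, unet_forward(tx, um))   # deterministic at inference
  bad <- structure(array(0, c(16, 6, 8)), class = "input_tensor")
  expect_error(unet_forward(bad, um), "shape")
  # grid must divide by 2^depth
  expect_error(unet_init(c(18L, 8L), 8L, channels = c(4L, 6L)), "shape")
})

test_that("the composite U-Net loss matches a term-by-term hand computation", {
  P <- matrix(c(1, 2, 0, 3,
                2, 1, 1, 0,
                0, 1, 2, 1,
                3, 0, 1, 2), 4, 4, byrow = TRUE)
  Y <- matrix(c(1, 1, 1, 2,
                2, 2, 1, 1,
                1, 1, 2, 2,
                2, 0, 1, 1), 4, 4, byrow = TRUE)
  cfg <- unet_loss_config(lambda1 = 0.1, lambda2 = 0.05, eps_rel = 0.5)
  # independent spreadsheet-style evaluation
  err <- P - Y
  mse <- sum(err^2) / 16
  rel <- sum(abs(err) / (abs(Y) + 0.5)) / 16
  dax <- P[2:4, ] - P[1:3, ]
  dci <- P[, c(2, 3, 4, 1)] - P
  smo <- (sum(dax^2) + sum(dci^2)) / 16
  out <- unet_loss(P, Y, cfg)
  expect_equal(out$mse, mse, tolerance = 1e-8)
  expect_equal(out$relative, rel, tolerance = 1e-8)
  expect_equal(out$smoothness, smo, tolerance = 1e-8)
  expect_equal(out$total, mse + 0.1 * rel + 0.05 * smo, tolerance = 1e-8)
})

test_that("loss degenerate cases behave as prescribed", {
  Y <- matrix(with_seed(2, runif(32, 1, 5)), 8, 4)
  U <- matrix(3, 8, 4)
  expect_equal(unet_loss(U, U, unet_loss_config())$total, 0)  # uniform, exact
  ls <- unet_loss(Y + 0.5, Y, unet_loss_config(0, 0))
  expect_equal(ls$total, mean(0.5^2))            # lambdas 0 -> plain MSE
})

test_that("U-Net loss and parameter gradients match finite differences", {
  tx <- structure(array(with_seed(7, rnorm(16 * 8 * 8)), c(16, 8, 8)),
                  class = "input_tensor")
  um <- unet_init(c(16L, 8L), 8L, channels = c(4L, 6L), bottleneck = 8L,
                  seed = 4)
  Y <- matrix(with_seed(8, rnorm(16 * 8)), 16, 8)
  cfg <- unet_loss_config()
  fw <- unet_forward(tx, um, return_cache = TRUE)
  ls <- unet_loss(fw$pred, Y, cfg, return_grad = TRUE)
  # loss gradient
  eps <- 1e-6
  P2 <- fw$pred; P2[5, 3] <- P2[5, 3] + eps
  P3 <- fw$pred; P3[5, 3] <- P3[5, 3] - eps
  fd <- (unet_loss(P2, Y, cfg)$total - unet_loss(P3, Y, cfg)$total) / (2 * eps)
  expect_equal(ls$grad[5, 3], fd, tolerance = 1e-6)
  # parameter gradients through conv / norm / pool / tconv / skip
  g <- stenowss:::unet_backward(ls$grad, um, fw$cache)
  loss_of <- function(m) unet_loss(unet_forward(tx, m), Y, cfg)$total
  for (nm in c("e1K1", "e2K2", "bK1", "u2K", "d1K2", "outW", "e1g1")) {
    m2 <- um; m2$params[[nm]][1] <- m2$params[[nm]][1] + eps
    m3 <- um; m3$params[[nm]][1] <- m3$params[[nm]][1] - eps
    fd <- (loss_of(m2) - loss_of(m3)) / (2 * eps)
    expect_equal(unname(g[[nm]][1]), fd, tolerance = 1e-4)
  }
})

test_that("the full-resolution U-Net accepts the 560 x 40 x 8 tensor", {
  tx <- build_feature_tensor(fix_throat_lattice())
  um <- unet_init(c(560L, 40L), 8L, channels = c(8L, 12L, 16L),
                  bottleneck = 24L, seed = 1)
  pred <- unet_forward(tx, um)
  expect_equal(dim(pred), c(560L, 40L))
  expect_equal(length(pred), 22400L)
})
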