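test_that("bilinear decoder matches unit-vector and loop oracles", {
  e1 <- rbind(c(1, 0, 0))
  expect_equal(bilinear_decode(e1, e1, diag(3), diag(3)), matrix(1, 1, 1))
  Yl <- matrix(rnorm(6), 2, 3)
  expect_equal(bilinear_decode(Yl, matrix(0, 4, 3), diag(3), diag(3)),
               matrix(0, 2, 4))
  for (seed in 1:8) {
    set.seed(seed)
    Yl <- matrix(rnorm(5 * 4), 5, 4)
    Yd <- matrix(rnorm(6 * 4), 6, 4)
    Wl <- matrix(rnorm(4 * 2), 4, 2)
    Wd <- matrix(rnorm(4 * 2), 4, 2)
    expect_equal(bilinear_decode(Yl, Yd, Wl, Wd),
                 oracle_bilinear(Yl, Yd, Wl, Wd), tolerance = 1e-10)
  }
  expect_error(bilinear_decode(Yl, Yd, matrix(0, 3, 2), Wd), "shape")
})

test_that("class-balance parameter is the positive fraction", {
  LD <- rbind(c(1, 0), c(0, 1))
  expect_equal(balance_alpha(make_mask_pair(LD)), 0.5)
  LD2 <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(balance_alpha(make_mask_pair(LD2)), 0.25)
  # at the scale of the published compendium
  masks <- list(omega_P = matrix(1, 1, 2697), omega_N = matrix(1, 1, 96183))
  expect_equal(balance_alpha(masks), 2697 / 98880)
  expect_error(balance_alpha(make_mask_pair(matrix(1, 2, 2))), "negative")
})

test_that("masked reconstruction loss weighs classes and ignores test pairs", {
  LD <- rbind(c(1, 0), c(0, 1))
  masks <- make_mask_pair(LD)
  expect_equal(reconstruction_loss(LD, LD, masks, 0.3), 0)
  # one positive predicted 0 and one negative predicted 1, alpha = 0.5
  pred <- rbind(c(0, 1), c(0, 1))
  m2 <- list(omega_P = rbind(c(1, 0), c(0, 0)),
             omega_N = rbind(c(0, 1), c(0, 0)))
  expect_equal(reconstruction_loss(pred, LD, m2, 0.5), 1)
  # unmasked entries contribute nothing regardless of score
  pred2 <- pred; pred2[2, ] <- c(1e6, -1e6)
  expect_equal(reconstruction_loss(pred2, LD, m2, 0.5), 1)
})

test_that("regularization sums squared norms and is quadratic", {
  p0 <- structure(list(Wd = matrix(0, 2, 2), Wl = matrix(5, 2, 2)),
                  class = "lnclink_params")
  expect_equal(regularization_loss(p0), 0)  # Wl is not penalized
  p1 <- structure(list(Wd = matrix(c(3, 4), 1, 2)), class = "lnclink_params")
  expect_equal(regularization_loss(p1), 25)
  views <- build_views(tiny_dataset(), tiny_config())
  p <- init_model_params(views, tiny_config(), seed = 1)
  p2 <- unflatten_params(2 * flatten_params(p), p)
  expect_equal(regularization_loss(p2), 4 * regularization_loss(p))
  expect_equal(total_loss(1, 2, 0.5), 2)
  expect_equal(total_loss(3, 100, 0), 3)
})

test_that("analytic gradients match central finite differences", {
  ds <- tiny_dataset()
  cfg <- tiny_config(gamma_reg = 0.01)
  views <- build_views(ds, cfg)
  masks <- make_mask_pair(ds$LD)
  params <- init_model_params(views, cfg, seed = 7)
  lg <- model_loss_and_gradients(views, params, ds$LD, masks, cfg)
  v0 <- flatten_params(params)
  ga <- flatten_params(lg$grads)
  set.seed(1)
  idx <- sample(length(v0), 40)
  h <- 1e-5
  gn <- vapply(idx, function(i) {
    up <- v0; up[i] <- up[i] + h
    dn <- v0; dn[i] <- dn[i] - h
    (model_loss_and_gradients(views, unflatten_params(up, params),
                              ds$LD, masks, cfg)$loss -
       model_loss_and_gradients(views, unflatten_params(dn, params),
                                ds$LD, masks, cfg)$loss) / (2 * h)
  }, numeric(1))
  expect_lt(max(abs(ga[idx] - gn) / pmax(abs(gn), 1e-6)), 1e-4)
})

test_that("training is deterministic and reduces the loss", {
  ds <- tiny_dataset()
  cfg <- tiny_config(epochs = 40L)
  views <- build_views(ds, cfg)
  masks <- make_mask_pair(ds$LD)
  fit1 <- train_model(views, ds$LD, masks, cfg, seed = 0)
  fit2 <- train_model(views, ds$LD, masks, cfg, seed = 0)
  expect_identical(fit1$trace$loss, fit2$trace$loss)
  expect_identical(fit1$scores, fit2$scores)
  expect_lt(fit1$trace$loss[40], fit1$trace$loss[1])
})

test_that("extreme regularization shrinks parameter norms during training", {
  ds <- tiny_dataset()
  cfg <- tiny_config(epochs = 200L, gamma_reg = 1e6)
  views <- build_views(ds, cfg)
  masks <- make_mask_pair(ds$LD)
  p0 <- init_model_params(views, cfg, seed = 0)
  fit <- train_model(views, ds$LD, masks, cfg, seed = 0)
  # Wl is outside the regularizer, so compare only penalized parameters
  pen_norm <- function(p) {
    p$Wl <- NULL
    sqrt(sum(unlist(unclass(p))^2))
  }
  expect_lt(pen_norm(fit$params), 0.2 * pen_norm(p0))
})

test_that("fit tidiers expose scores and convergence summaries", {
  ds <- tiny_dataset()
  cfg <- tiny_config()
  views <- build_views(ds, cfg)
  fit <- train_model(views, ds$LD, make_mask_pair(ds$LD), cfg)
  td <- tidy(fit, LD = ds$LD)
  expect_identical(nrow(td), length(ds$LD))
  expect_named(td, c("lncrna", "disease", "score", "known"))
  gl <- glance(fit)
  expect_identical(gl$epochs, cfg$epochs)
  expect_s3_class(autoplot(fit), "ggplot")
})
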