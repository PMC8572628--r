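toy_system <- function(A) as_system_matrix(A, size = NULL)

test_that("initialization honours the configured starting image", {
  A <- toy_system(matrix(c(1, 0, 1, 1), 2, 2))
  y <- c(2, 3)

  st0 <- initialize_iteration(y, A, iter_config(init_mode = "zero"))
  expect_equal(st0$x, c(0, 0))
  expect_equal(st0$iteration, 0L)
  expect_length(st0$residual_norm_history, 0)
  expect_equal(st0$residuals, y)

  stu <- initialize_iteration(y, A, iter_config(init_mode = "uniform",
                                                uniform_value = 0.5))
  expect_equal(stu$x, c(0.5, 0.5))

  # FBP start: the supplied reconstruction (HU) becomes the initial
  # attenuation image
  gsz <- as_system_matrix(matrix(1, 2, 4), size = 2L, pixel_spacing = 1)
  fbp_img <- image_grid(matrix(c(0, -1000, 60, 40), 2, 2), 1, "HU")
  stf <- initialize_iteration(rep(0.1, 2), gsz,
                              iter_config(init_mode = "fbp"),
                              fbp_image = fbp_img)
  expect_equal(stf$x, as.vector(hu_to_mu(fbp_img)$pixels))

  expect_error(initialize_iteration(y, A, iter_config(init_mode = "fbp")),
               "FBP")
})

test_that("projection estimates, residuals and corrections follow the update algebra", {
  # 2-pixel toy: weights [1, 1], image [3, 4] -> Y* = 7
  A1 <- toy_system(matrix(c(1, 1), 1, 2))
  st <- initialize_iteration(7, A1, iter_config(init_mode = "uniform",
                                                uniform_value = 0))
  st$x <- c(3, 4)
  expect_equal(estimate_projections(st, A1), 7)

  expect_equal(compute_residuals(10, 7), 3)
  expect_equal(compute_residuals(7, 7), 0)
  expect_lt(compute_residuals(5, 7), 0)
  expect_error(compute_residuals(c(1, 2), 1), "length")

  # single ray, single pixel, weight w, residual phi, lambda 1 -> E = phi/w
  w <- 0.7; phi <- 2.1
  As <- toy_system(matrix(w, 1, 1))
  expect_equal(compute_corrections(phi, As, relaxation = 1), phi / w)

  # one ray crossing two pixels with equal weight w -> each E = phi/(2w)
  Ad <- toy_system(matrix(c(w, w), 1, 2))
  expect_equal(compute_corrections(phi, Ad, relaxation = 1),
               rep(phi / (2 * w), 2))

  # relaxation scales the correction linearly
  expect_equal(compute_corrections(phi, Ad, relaxation = 0.25),
               0.25 * rep(phi / (2 * w), 2))

  # zero residuals are a fixed point of the correction
  expect_equal(compute_corrections(c(0, 0), toy_system(diag(2))), c(0, 0))

  # a pixel crossed by no ray gets zero correction
  Az <- toy_system(matrix(c(1, 0), 1, 2))
  expect_equal(compute_corrections(3, Az)[2], 0)
})

test_that("image updates advance the state and annihilate one-ray residuals", {
  A <- toy_system(matrix(2, 1, 1))
  st <- initialize_iteration(5, A, iter_config(init_mode = "zero"))

  # zero correction leaves the image unchanged but advances the counter
  st1 <- update_image(st, 0, A)
  expect_equal(st1$x, st$x)
  expect_equal(st1$iteration, 1L)
  expect_length(st1$residual_norm_history, 1)

  # additive update: R = 2, E = 0.5 -> 2.5
  st$x <- 2
  st2 <- update_image(st, 0.5, A)
  expect_equal(st2$x, 2.5)

  # Kaczmarz exactness: a consistent single-ray system is solved in one
  # full update at lambda = 1
  st3 <- initialize_iteration(5, A, iter_config(init_mode = "zero"))
  E <- compute_corrections(st3$residuals, A, relaxation = 1)
  st3 <- update_image(st3, E, A)
  expect_equal(st3$residuals, 0)
})

test_that("a consistent starting image is a fixed point of the full loop", {
  set.seed(9)
  sys <- random_consistent_system()
  sm <- toy_system(sys$A)
  for (lam in c(0.3, 1, 1.7)) {
    # start from the true solution: zero residuals, zero corrections
    st <- initialize_iteration(sys$y, sm, iter_config(init_mode = "zero"))
    st$x <- sys$x_true
    st$residuals <- sys$y - as.numeric(sm$A %*% sys$x_true)
    E <- compute_corrections(st$residuals, sm, relaxation = lam)
    expect_equal(max(abs(E)), 0, tolerance = 1e-12)
  }

  # through the public entry point: measured = forward projection of the
  # initial image stops after one no-op iteration
  g <- default_geometry(16, n_angles = 12, field_of_view = 16)
  A <- build_system_matrix(g, 16)
  img <- image_grid(matrix(0.02, 16, 16), 1, "MU")
  sino <- forward_project(img, A)
  res <- reconstruct_iterative(sino, A,
                               iter_config(init_mode = "uniform",
                                           uniform_value = 0.02))
  expect_equal(res$iterations, 1L)
  expect_true(res$converged)
  expect_equal(as.vector(hu_to_mu(res$image)$pixels), rep(0.02, 256),
               tolerance = 1e-12)
})

test_that("the converged solution matches the pseudoinverse oracle on random systems", {
  skip_if_not_installed("MASS")
  set.seed(42)
  for (i in 1:20) {
    sys <- random_consistent_system()
    res <- reconstruct_iterative(sys$y, toy_system(sys$A),
                                 iter_config(max_iterations = 5000,
                                             tolerance = 1e-12))
    x_ls <- as.numeric(MASS::ginv(sys$A) %*% sys$y)
    rel <- sqrt(sum((solution_vector(res) - x_ls)^2)) / sqrt(sum(x_ls^2))
    expect_lt(rel, 1e-3)
  }
})

test_that("residual norms are non-increasing on consistent systems for lambda <= 1", {
  set.seed(7)
  for (i in 1:20) {
    sys <- random_consistent_system()
    lam <- sample(c(0.25, 0.5, 0.75, 1), 1)
    res <- reconstruct_iterative(sys$y, toy_system(sys$A),
                                 iter_config(max_iterations = 300,
                                             tolerance = 1e-12,
                                             relaxation = lam))
    h <- res$history$residual_norm
    expect_true(all(diff(h) <= 1e-8 * h[1]))
  }
})

test_that("reconstruction is deterministic and validates its inputs", {
  g <- default_geometry(32, n_angles = 24, field_of_view = 220)
  A <- build_system_matrix(g, 32)
  spec <- phantom_spec(list(ellipse(0, 0, 60, 40, 0, 50, "blob")),
                       field_of_view = 220)
  sino <- forward_project(hu_to_mu(render_phantom(spec, 32)), A)
  cfg <- iter_config(max_iterations = 15)
  r1 <- reconstruct_iterative(sino, A, cfg)
  r2 <- reconstruct_iterative(sino, A, cfg)
  expect_identical(r1$image$pixels, r2$image$pixels)
  expect_identical(r1$history, r2$history)

  expect_error(reconstruct_iterative(c(1, NA), toy_system(diag(2)),
                                     iter_config()), "finite")
})

test_that("blending mixes the iterative and FBP images linearly", {
  g <- default_geometry(32, n_angles = 48, field_of_view = 220)
  A <- build_system_matrix(g, 32)
  spec <- phantom_spec(list(ellipse(0, 0, 60, 40, 0, 50, "blob")),
                       field_of_view = 220)
  sino <- forward_project(hu_to_mu(render_phantom(spec, 32)), A)
  fbp_img <- fbp_reconstruct(sino, fbp_config("hann", 32))
  pure <- reconstruct_iterative(sino, A,
                                iter_config(max_iterations = 10,
                                            blend_fraction = 1),
                                fbp_image = fbp_img)
  half <- reconstruct_iterative(sino, A,
                                iter_config(max_iterations = 10,
                                            blend_fraction = 0.5),
                                fbp_image = fbp_img)
  none <- reconstruct_iterative(sino, A,
                                iter_config(max_iterations = 10,
                                            blend_fraction = 0),
                                fbp_image = fbp_img)
  expect_equal(none$image$pixels, fbp_img$pixels)
  expect_equal(half$image$pixels,
               0.5 * pure$image$pixels + 0.5 * fbp_img$pixels,
               tolerance = 1e-12)
})
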