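cfg_plain <- function(...) {
  tdaign_config(rank = 2, rank_prime = 3, inner_max_iter = 20, seed = 1, ...)
}

test_that("factor updates solve their row-wise weighted normal equations", {
  set.seed(21)
  f <- rand_factors(c(5, 4, 3), 2)
  x <- cp_reconstruct(f)
  dimnames(x) <- list(paste0("m", 1:5), paste0("d", 1:4), paste0("t", 1:3))

  # exact least-squares recovery: all-ones weights, no ridge, D and T at truth
  cfg <- tdaign_config(rank = 2, rank_prime = 3, lambda = 0, seed = 1)
  st <- tdaign_init_state(x, list(), list(), cfg)
  st$D <- f$D; st$T <- f$T
  st <- update_factor_m(st, x, cfg)
  expect_lt(max(abs(st$M - f$M)), 1e-8)

  # ridge limit: huge lambda shrinks rows to zero
  cfg_big <- tdaign_config(rank = 2, rank_prime = 3, lambda = 1e10, seed = 1)
  stb <- tdaign_init_state(x, list(), list(), cfg_big)
  stb <- update_factor_m(stb, x, cfg_big)
  expect_lt(max(abs(stb$M)), 1e-6)

  # scalar closed form at |m| = 1, r = 1
  x1 <- array(c(0.4, 1, 0, 0.7), c(1, 2, 2))
  dimnames(x1) <- list("m1", c("d1", "d2"), c("t1", "t2"))
  cfg1 <- tdaign_config(rank = 1, rank_prime = 1, lambda = 0.2, seed = 3)
  st1 <- tdaign_init_state(x1, list(), list(), cfg1)
  st1 <- update_factor_m(st1, x1, cfg1)
  z <- khatri_rao(st1$D, st1$T)
  expect_equal(drop(st1$M),
               sum(unfold(x1, 1) * t(z)) / (sum(z^2) + 0.2), tolerance = 1e-12)
})

test_that("weighted factor updates satisfy the exact normal equations", {
  inst <- tiny_instance()
  cfg <- tdaign_config(rank = 2, rank_prime = 3, weight = 1.5, seed = 2)
  st <- tdaign_init_state(inst$x, list(inst$sm), list(inst$sd), cfg)
  set.seed(31)
  w <- array(1, dim(inst$x))
  w[inst$x == 1 & runif(length(inst$x)) < 0.5] <- cfg$weight
  st$W <- w
  check_mode <- function(fac, mode, views) {
    z <- switch(mode,
                `1` = khatri_rao(st$D, st$T),
                `2` = khatri_rao(st$M, st$T),
                `3` = khatri_rao(st$M, st$D))
    xm <- unfold(inst$x, mode); wm <- unfold(st$W, mode)
    asum <- sum(vapply(views, `[[`, numeric(1), "a"))
    aux <- 0
    for (v in views) aux <- aux + v$a * (v$A %*% v$Q)
    for (i in seq_len(nrow(fac))) {
      g <- t(z) %*% diag(wm[i, ]) %*% z + (asum + cfg$lambda) * diag(ncol(z))
      rhs <- drop((wm[i, ] * xm[i, ]) %*% z)
      if (!identical(aux, 0)) rhs <- rhs + aux[i, ]
      expect_lt(max(abs(fac[i, ] %*% g - rhs)), 1e-8)
    }
  }
  # check each factor against its system immediately, before the next update
  # changes the Khatri-Rao basis
  st <- update_factor_m(st, inst$x, cfg)
  check_mode(st$M, 1, st$mviews)
  st <- update_factor_d(st, inst$x, cfg)
  check_mode(st$D, 2, st$dviews)
  st <- update_factor_t(st, inst$x, cfg)
  check_mode(st$T, 3, list())
})

test_that("latent and projection updates satisfy their stated linear systems", {
  inst <- tiny_instance()
  cfg <- tdaign_config(rank = 2, rank_prime = 3, alpha = 0.7, beta = 0.4, seed = 4)
  st <- tdaign_init_state(inst$x, list(inst$sm), list(inst$sd), cfg)
  # desynchronize the splits and multipliers so the systems are non-trivial
  st <- update_factor_m(st, inst$x, cfg)
  st <- update_factor_d(st, inst$x, cfg)
  st <- update_latents(st, cfg)
  st <- update_projections(st, cfg)
  st <- update_multipliers(st, cfg)
  before <- st
  st <- update_latents(st, cfg)
  v0 <- before$mviews[[1]]; v1 <- st$mviews[[1]]
  a <- v0$a; mu <- cfg$mu; ga <- cfg$gamma
  lhs_a <- v1$A %*% (2 * a * crossprod(v0$C) + 2 * a * tcrossprod(v0$Q) +
                       (mu + ga) * diag(3))
  rhs_a <- 2 * a * inst$sm %*% v0$C + 2 * a * st$M %*% t(v0$Q) +
    mu * v0$C + v0$Y + v0$H + ga * v0$F
  expect_lt(max(abs(lhs_a - rhs_a)), 1e-8)
  lhs_c <- v1$C %*% (2 * a * crossprod(v1$A) + mu * diag(3))
  rhs_c <- 2 * a * inst$sm %*% v1$A + mu * v1$A - v0$Y
  expect_lt(max(abs(lhs_c - rhs_c)), 1e-8)
  lhs_f <- (2 * a * v1$L + ga * diag(nrow(v1$L))) %*% v1$F
  expect_lt(max(abs(lhs_f - (ga * v1$A - v0$H))), 1e-8)

  before_q <- st
  st <- update_projections(st, cfg)
  q0 <- before_q$mviews[[1]]$Q; v <- st$mviews[[1]]
  lam <- 1 / pmax(sqrt(rowSums(q0^2)), 1e-8)
  lhs_q <- (crossprod(v$A) + diag(lam / 2)) %*% v$Q
  expect_lt(max(abs(lhs_q - crossprod(v$A, st$M))), 1e-8)
})

test_that("degenerate latent updates collapse to identity maps", {
  inst <- tiny_instance()
  cfg <- tdaign_config(rank = 2, rank_prime = 3, alpha = 0, beta = 0, seed = 5)
  st <- tdaign_init_state(inst$x, list(inst$sm), list(inst$sd), cfg)
  a0 <- st$mviews[[1]]$A
  st <- update_latents(st, cfg)
  # alpha = 0 with zero multipliers: A, C and F all stay equal
  expect_equal(st$mviews[[1]]$A, a0, tolerance = 1e-10)
  expect_equal(st$mviews[[1]]$C, st$mviews[[1]]$A, tolerance = 1e-10)
  expect_equal(st$mviews[[1]]$F, st$mviews[[1]]$A, tolerance = 1e-10)

  # Laplacian disabled (L = 0), zero multiplier: F = A
  cfg_nl <- tdaign_config(rank = 2, rank_prime = 3, alpha = 0.5, beta = 0.5,
                          use_laplacian = FALSE, seed = 5)
  st2 <- tdaign_init_state(inst$x, list(inst$sm), list(inst$sd), cfg_nl)
  st2 <- update_latents(st2, cfg_nl)
  expect_equal(st2$mviews[[1]]$F, st2$mviews[[1]]$A, tolerance = 1e-10)
})

test_that("projection updates induce L2,1 row sparsity pressure", {
  inst <- tiny_instance()
  cfg <- tdaign_config(rank = 2, rank_prime = 3, alpha = 0.7, beta = 0.7, seed = 6)
  st <- tdaign_init_state(inst$x, list(inst$sm), list(inst$sd), cfg)
  # make one projection row small; repeated reweighted updates with fixed A
  # must keep shrinking it
  st$mviews[[1]]$Q[2, ] <- st$mviews[[1]]$Q[2, ] * 1e-3
  norms <- numeric(6)
  for (it in 1:6) {
    norms[it] <- sqrt(sum(st$mviews[[1]]$Q[2, ]^2))
    st <- update_projections(st, cfg)
  }
  expect_true(all(diff(norms[2:6]) <= 1e-10))
  # the L2,1 norm is the sum of row Euclidean norms
  q <- matrix(rnorm(12), 4)
  expect_equal(tdaign:::norm_l21(q), sum(apply(q, 1, function(r) sqrt(sum(r^2)))))

  # orthonormal A without the L2,1 term gives the plain projection
  cfg_no <- tdaign_config(rank = 2, rank_prime = 3, alpha = 0.7, beta = 0.7,
                          use_l21 = FALSE, seed = 6)
  st3 <- tdaign_init_state(inst$x, list(inst$sm), list(inst$sd), cfg_no)
  st3$mviews[[1]]$A <- qr.Q(qr(st3$mviews[[1]]$A))
  st3 <- update_projections(st3, cfg_no)
  expect_equal(st3$mviews[[1]]$Q,
               crossprod(st3$mviews[[1]]$A, st3$M), tolerance = 1e-10)
})

test_that("multiplier ascent steps equal penalty times residual", {
  inst <- tiny_instance()
  cfg <- tdaign_config(rank = 2, rank_prime = 3, alpha = 0.7, beta = 0.4,
                       mu = 2, gamma = 3, eta = 1.5, epsilon = 2.5, seed = 7)
  st <- tdaign_init_state(inst$x, list(inst$sm), list(inst$sd), cfg)
  # splits equal their partners at init: multipliers must not move
  st1 <- update_multipliers(st, cfg)
  expect_equal(st1$mviews[[1]]$Y, st$mviews[[1]]$Y)
  # desynchronize, then one step from zero equals penalty * residual
  st$mviews[[1]]$C <- st$mviews[[1]]$C + 1
  st$dviews[[1]]$F <- st$dviews[[1]]$F - 2
  st2 <- update_multipliers(st, cfg)
  expect_equal(st2$mviews[[1]]$Y,
               cfg$mu * (st$mviews[[1]]$C - st$mviews[[1]]$A))
  expect_equal(st2$dviews[[1]]$H,
               cfg$epsilon * (st$dviews[[1]]$F - st$dviews[[1]]$A))
})

test_that("ADMM split residuals shrink over sweeps", {
  inst <- tiny_instance()
  cfg <- tdaign_config(rank = 2, rank_prime = 3, seed = 8)
  st <- tdaign_init_state(inst$x, list(inst$sm), list(inst$sd), cfg)
  resid <- numeric(50)
  for (sw in 1:50) {
    st <- update_factor_m(st, inst$x, cfg)
    st <- update_factor_d(st, inst$x, cfg)
    st <- update_factor_t(st, inst$x, cfg)
    st <- update_latents(st, cfg)
    st <- update_projections(st, cfg)
    st <- update_multipliers(st, cfg)
    resid[sw] <- sqrt(sum((st$mviews[[1]]$C - st$mviews[[1]]$A)^2))
  }
  expect_lt(resid[50], resid[5])
  expect_lt(resid[50], 1e-3)
})

test_that("weight tensor takes values in {1, w} by the residual threshold rule", {
  # perfect reconstruction keeps all weights at 1
  x <- array(1, c(2, 2, 1))
  cfg <- tdaign_config(rank = 1, rank_prime = 1, seed = 9)
  st <- tdaign_init_state(x, list(), list(), cfg)
  st$M <- matrix(1, 2, 1); st$D <- matrix(1, 2, 1); st$T <- matrix(1, 1, 1)
  st <- update_weight_tensor(st, x, cfg)
  expect_true(all(st$W == 1))

  # a positive predicted at 0.1 with k = 0.3: residual^2 = 0.81 > 0.49 -> w
  x2 <- array(c(1, 0), c(1, 1, 2))
  st2 <- tdaign_init_state(x2, list(), list(), cfg)
  st2$M <- matrix(0.1); st2$D <- matrix(1); st2$T <- matrix(c(1, 1), 2, 1)
  st2 <- update_weight_tensor(st2, x2, cfg)
  expect_equal(as.numeric(st2$W), c(1.5, 1))

  # k near 1 up-weights every imperfect positive
  cfg_k <- tdaign_config(rank = 1, rank_prime = 1, k = 0.999, seed = 9)
  st3 <- tdaign_init_state(x2, list(), list(), cfg_k)
  st3$M <- matrix(0.9); st3$D <- matrix(1); st3$T <- matrix(c(1, 1), 2, 1)
  st3 <- update_weight_tensor(st3, x2, cfg_k)
  expect_equal(as.numeric(st3$W), c(1.5, 1))
})

test_that("weights stay in {1, w} throughout a fit and the toggle disables them", {
  inst <- tiny_instance(dims = c(6, 5, 3), seed = 44)
  cfg <- cfg_plain(episodes = 3, k = 0.6)
  fit <- tdaign(inst$x, list(inst$sm), list(inst$sd), cfg)
  expect_true(all(fit$state$W %in% c(1, cfg$weight)))

  fit_off <- tdaign(inst$x, list(inst$sm), list(inst$sd),
                    cfg_plain(episodes = 3, use_weighting = FALSE))
  expect_true(all(fit_off$state$W == 1))
  expect_true(all(fit_off$trace$n_weighted == 0))
})

test_that("scores are equivariant under consistent miRNA relabeling", {
  sim <- simulate_mda(dims = c(8, 6, 3), true_rank = 2, n_mirna_views = 1,
                      n_disease_views = 1, seed = 17)
  cfg <- tdaign_config(rank = 2, rank_prime = 3, episodes = 2,
                       inner_max_iter = 25, seed = 3)
  fit1 <- tdaign(sim$tensor, sim$mirna_sims, sim$disease_sims, cfg)
  set.seed(99)
  perm <- sample(8)
  xp <- unclass(sim$tensor)[perm, , ]
  msp <- lapply(sim$mirna_sims, function(s) s[perm, perm])
  fit2 <- tdaign(xp, msp, sim$disease_sims, cfg)
  joined <- dplyr::inner_join(tidy(fit1), tidy(fit2),
                              by = c("mirna", "disease", "type"))
  expect_equal(nrow(joined), length(sim$tensor))
  expect_lt(max(abs(joined$score.x - joined$score.y)), 1e-8)
})

test_that("with no auxiliary terms the model reduces to CP-ALS", {
  inst <- tiny_instance(dims = c(7, 5, 3), seed = 55)
  cfg <- tdaign_config(rank = 3, rank_prime = 2, lambda = 0, episodes = 1,
                       use_weighting = FALSE, inner_tol = 1e-10,
                       inner_max_iter = 300, seed = 5)
  fit <- tdaign(inst$x, list(), list(), cfg)
  als <- cp_als(inst$x, rank = 3, max_iter = 300, tol = 1e-10, seed = 5)
  obj_fit <- fit$trace$objective[nrow(fit$trace)]
  obj_als <- als$trace$objective[nrow(als$trace)]
  expect_lt(abs(obj_fit - obj_als) / obj_als, 1e-3)
  expect_lt(max(abs(fit$scores - als$scores)), 1e-4)
})

test_that("stationary point of the reduced model has a small gradient", {
  inst <- tiny_instance(dims = c(4, 3, 2), seed = 66)
  lam <- 0.001
  cfg <- tdaign_config(rank = 2, rank_prime = 2, lambda = lam, episodes = 1,
                       use_weighting = FALSE, inner_tol = 1e-15,
                       inner_max_iter = 5000, seed = 6)
  fit <- tdaign(inst$x, list(), list(), cfg)
  st <- fit$state
  z <- khatri_rao(st$D, st$T)
  grad_m <- 2 * (st$M %*% crossprod(z) - unfold(inst$x, 1) %*% z + lam * st$M)
  expect_lt(sqrt(sum(grad_m^2)), 1e-4)
})

test_that("predict_topk ranks types with deterministic tie-breaking", {
  s <- array(c(0.1, 0.9, 0.5, 0.2), c(1, 1, 4),
             dimnames = list("m1", "d1", paste0("t", 1:4)))
  top <- predict_topk(s, tibble::tibble(mirna = "m1", disease = "d1"), k = 1)
  expect_equal(top$type, "t2")

  tie <- array(0.5, c(1, 1, 4),
               dimnames = list("m1", "d1", paste0("t", 1:4)))
  expect_equal(predict_topk(tie, tibble::tibble(mirna = "m1", disease = "d1"),
                            k = 1)$type, "t1")

  all4 <- predict_topk(s, tibble::tibble(mirna = "m1", disease = "d1"))
  expect_setequal(all4$type, paste0("t", 1:4))
  expect_error(predict_topk(s, tibble::tibble(mirna = "mX", disease = "d1")),
               class = "tdaign_identifier_error")
})
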