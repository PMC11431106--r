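test_that("correlation coordinate matches its closed form and diverges at the boundary", {
  expect_equal(theta_of(joint_law(0.25, 0.25, 0.25, 0.25)), 0)
  expect_equal(theta_of(joint_law(0.4, 0.1, 0.1, 0.4)), log(16))
  # factorized laws are exactly uncorrelated
  for (e1 in c(0.2, 0.5, 0.77)) {
    for (e2 in c(0.1, 0.5, 0.9)) {
      q11 <- e1 * e2
      q <- joint_law(1 - e1 - e2 + q11, e1 - q11, e2 - q11, q11)
      expect_equal(theta_of(q), 0, tolerance = 1e-12)
    }
  }
  expect_error(theta_of(joint_law(0.5, 0.3, 0.2, 0)), "-Inf")
  expect_error(theta_of(joint_law(0.5, 0, 0.3, 0.2)), "\\+Inf")
})

test_that("marginals are the row/column sums of the joint law", {
  expect_equal(etas_of(joint_law(0.25, 0.25, 0.25, 0.25)),
               c(eta1 = 0.5, eta2 = 0.5))
  expect_equal(etas_of(joint_law(0.72, 0.10, 0.16, 0.02)),
               c(eta1 = 0.12, eta2 = 0.18))
  expect_equal(etas_of(joint_law(1, 0, 0, 0)), c(eta1 = 0, eta2 = 0))
})

test_that("coordinates invert to the joint law and back", {
  expect_equal(law_of(0.5, 0.1, 0)[["q11"]], 0.05) # independence: q11 = eta1 eta2
  # strong correlation limit, checked against bisection on theta(q11)
  l <- law_of(0.5, 0.5, 20)
  f <- function(q11) log(q11) + log(q11) - log(0.5 - q11) - log(0.5 - q11) - 20
  q11_bis <- uniroot(f, c(0.25, 0.5 - 1e-12), tol = 1e-15)$root
  expect_equal(l[["q11"]], q11_bis, tolerance = 1e-9)
  expect_lt(l[["q10"]], 1e-4)
  # round trip over 1000 random interior laws
  set.seed(42)
  worst <- 0
  for (i in 1:1000) {
    q <- random_interior_law(min_q = 0.005)
    e <- etas_of(q)
    q2 <- law_of(coords(e[["eta1"]], e[["eta2"]], theta_of(q)))
    worst <- max(worst, max(abs(as.numeric(q2) - as.numeric(q))))
  }
  expect_lt(worst, 1e-10)
})

test_that("theta is strictly increasing in q11 at fixed marginals", {
  for (es in list(c(0.5, 0.5), c(0.3, 0.6), c(0.8, 0.7))) {
    lo <- max(0, sum(es) - 1); hi <- min(es)
    q11 <- seq(lo + 1e-3, hi - 1e-3, length.out = 50)
    th <- vapply(q11, function(v) {
      theta_of(joint_law(1 - es[1] - es[2] + v, es[1] - v, es[2] - v, v))
    }, numeric(1))
    expect_true(all(diff(th) > 0))
  }
})

test_that("log-probability expansion agrees with direct lookup and normalizes", {
  set.seed(7)
  outcomes <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  for (i in 1:20) {
    q <- random_interior_law()
    e <- etas_of(q)
    xi <- coords(e[["eta1"]], e[["eta2"]], theta_of(q))
    lp <- apply(outcomes, 1, log_prob, xi = xi)
    expect_equal(lp, log(as.numeric(law_of(xi))), tolerance = 1e-12)
    expect_equal(sum(exp(lp)), 1, tolerance = 1e-12)
  }
  expect_equal(log_prob(c(1, 1), coords(0.5, 0.5, 0)), log(0.25))
})

test_that("Fisher matrix is orthogonal in the mixed coordinates and PSD", {
  # closed form at independence: g(eta, eta) = 1 / (eta (1 - eta))
  G <- fisher_information(coords(0.5, 0.5, 0))
  expect_equal(G[["eta1", "eta1"]], 4, tolerance = 1e-5)
  expect_equal(G[["eta1", "eta2"]], 0, tolerance = 1e-6)
  grid <- expand.grid(e1 = seq(0.15, 0.85, length.out = 5),
                      e2 = seq(0.15, 0.85, length.out = 5),
                      th = seq(-1.5, 1.5, length.out = 4))
  worst_ortho <- 0; worst_eig <- Inf; worst_asym <- 0
  for (i in seq_len(nrow(grid))) {
    G <- fisher_information(coords(grid$e1[i], grid$e2[i], grid$th[i]))
    worst_ortho <- max(worst_ortho, abs(G[1, 3]), abs(G[2, 3]))
    worst_eig <- min(worst_eig, eigen(unclass(G), symmetric = TRUE)$values)
    worst_asym <- max(worst_asym, max(abs(G - t(G))))
  }
  expect_lt(worst_ortho, 1e-6)
  expect_gt(worst_eig, -1e-9)
  expect_lt(worst_asym, 1e-9)
  expect_error(fisher_information(coords(0.99995, 0.5, 0)), "boundary")
})

test_that("symmetric laws give equal marginal metric components", {
  for (th in c(-1, 0.5, 2)) {
    G <- fisher_information(coords(0.4, 0.4, th)) # q10 = q01 by symmetry
    expect_equal(G[["eta1", "eta1"]], G[["eta2", "eta2"]], tolerance = 1e-6)
  }
})

test_that("squared distance specializes along orthogonal directions", {
  xi <- coords(0.5, 0.3, 0.7)
  G <- fisher_information(xi)
  expect_identical(squared_distance(xi, tangent_step()), 0)
  d_th <- tangent_step(d_theta = 0.2)
  expect_equal(squared_distance(xi, d_th), G[["theta", "theta"]] * 0.04,
               tolerance = 1e-10)
  d_e2 <- tangent_step(d_eta2 = 0.05)
  expect_equal(squared_distance(xi, d_e2), G[["eta2", "eta2"]] * 0.0025,
               tolerance = 1e-10)
  d_rates <- tangent_step(d_eta1 = 0.03, d_eta2 = -0.02)
  expect_equal(squared_distance(xi, d_rates),
               G[1, 1] * 0.03^2 + 2 * G[1, 2] * 0.03 * (-0.02) + G[2, 2] * 0.02^2,
               tolerance = 1e-10)
  expect_error(squared_distance(xi, tangent_step(d_eta1 = 0.6)), "leaves manifold")
})

test_that("squared distance approximates twice the KL divergence to first order", {
  set.seed(11)
  dirs <- list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.5, -0.3, 0.8))
  for (d in dirs) {
    xi <- coords(0.45, 0.35, 0.4)
    ratio <- vapply(c(1e-2, 1e-3), function(eps) {
      step <- d * eps
      p <- law_of(xi)
      p2 <- law_of(coords(0.45 + step[1], 0.35 + step[2], 0.4 + step[3]))
      squared_distance(xi, step) / (2 * kl_div(p, p2))
    }, numeric(1))
    expect_equal(ratio[2], 1, tolerance = 0.01)
    # first-order convergence: the deviation shrinks with eps
    expect_lt(abs(ratio[2] - 1), abs(ratio[1] - 1))
  }
})

test_that("laws and coordinates round-trip through flat JSON", {
  q <- joint_law(0.72, 0.10, 0.16, 0.02)
  expect_equal(as.numeric(law_from_json(as_json(q))), as.numeric(q))
  xi <- coords(0.3, 0.6, -1.2)
  expect_equal(as.numeric(coords_from_json(as_json(xi))), as.numeric(xi))
})
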