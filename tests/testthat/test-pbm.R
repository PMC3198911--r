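# Brute-force oracle for the activation recursion, evaluated term by term.
oracle_recursion <- function(e, alpha, b1, b2, d) {
  n <- length(e)
  u <- numeric(n)
  for (t in seq_len(n)) {
    et <- if (t - d >= 1) e[t - d] else 0
    u1 <- if (t >= 2) u[t - 1] else 0
    u2 <- if (t >= 3) u[t - 2] else 0
    u[t] <- alpha * et - b1 * u1 - b2 * u2
  }
  u
}

test_that("recursive filter matches the direct recursion and passes through
           when recursion is disabled", {
  e <- with_test_seed(1, runif(400))
  p0 <- activation_params(A = 0, C1 = 0, C2 = 0, d_ms = 20)
  u <- recursive_filter(e, p0, 1000)
  expect_equal(u, c(numeric(20), e[1:380]))   # pure delay, alpha = 1
  p <- activation_params(A = -1, C1 = 0.5, C2 = -0.3, d_ms = 15)
  imp <- c(1, numeric(99))
  expect_equal(recursive_filter(imp, p, 1000),
               oracle_recursion(imp, p$alpha, p$beta1, p$beta2, 15),
               tolerance = 1e-12)
  u2 <- recursive_filter(e, p, 1000)
  expect_equal(u2, oracle_recursion(e, p$alpha, p$beta1, p$beta2, 15),
               tolerance = 1e-10)
})

test_that("stable coefficients give unit DC gain and bounded output", {
  # sustained full excitation converges to 1 for any stable (C1, C2)
  for (i in 1:20) {
    cs <- with_test_seed(i, runif(2, -0.9, 0.9))
    p <- activation_params(A = -1, C1 = cs[1], C2 = cs[2], d_ms = 10)
    u <- recursive_filter(rep(1, 3000), p, 1000)
    expect_equal(tail(u, 1), 1, tolerance = 1e-6)
    expect_true(all(is.finite(u)))
    expect_lt(max(abs(u)), 50)
  }
  expect_error(activation_params(C1 = 1.2, C2 = 0), "nstable")
  expect_error(activation_params(d_ms = 5), "d_ms")
})

test_that("activation nonlinearity has forced endpoints and analytic limit", {
  for (A in c(-3, -1.5, -0.01)) {
    expect_equal(activation_nonlinearity(0, A), 0)
    expect_equal(activation_nonlinearity(1, A), 1)
  }
  expect_equal(activation_nonlinearity(0.5, -3),
               (exp(-1.5) - 1) / (exp(-3) - 1), tolerance = 1e-12)
  u <- seq(0, 1, by = 0.01)
  # near the linear limit the deviation is bounded by |A| u(1-u)/2 <= |A|/8
  expect_lt(max(abs(activation_nonlinearity(u, -1e-8) - u)), 1e-8 / 8 + 1e-12)
  expect_equal(activation_nonlinearity(u, 0), u)
  # bijection [0,1] -> [0,1]: strictly increasing for every A in the box
  for (A in seq(-3, -0.1, by = 0.29)) {
    a <- activation_nonlinearity(u, A)
    expect_true(all(diff(a) > 0))
    expect_true(all(a >= 0 & a <= 1))
  }
  expect_error(activation_nonlinearity(1.5, -1), "0, 1")
  expect_error(activation_nonlinearity(0.5, 1), "-3, 0")
})

test_that("joint torque is the PCSA-weighted linear combination", {
  act <- activation_params()
  m1 <- muscle_physiology("F", fmax_N = 100, ma_m = 0.02, pcsa_cm2 = 2)
  m2 <- muscle_physiology("E", fmax_N = 50, ma_m = -0.01, pcsa_cm2 = 3,
                          sigma_pcsa_cm2 = 6)
  p <- pbm_parameters(act, list(m1, m2))
  a <- matrix(0, 5, 2)
  expect_equal(joint_torque(a, p), numeric(5))
  p1 <- pbm_parameters(act, list(m1))
  expect_equal(joint_torque(matrix(0.5, 3, 1), p1), rep(100 * 0.5 * 0.02, 3))
  # hand arithmetic: w1 = 1*100*0.02 = 2; w2 = 2*50*(-0.01) = -1
  a2 <- matrix(c(0.5, 1, 0.2, 0.4), 2, 2)
  expect_equal(joint_torque(a2, p), c(2 * 0.5 - 1 * 0.2, 2 * 1 - 1 * 0.4))
  expect_error(joint_torque(matrix(0, 2, 3), p), "match")
  # superposition: linear in each channel
  x <- matrix(with_test_seed(2, runif(8)), 4, 2)
  y <- matrix(with_test_seed(3, runif(8)), 4, 2)
  expect_equal(joint_torque(x + y, p),
               joint_torque(x, p) + joint_torque(y, p))
})

test_that("two-channel torque pools role-wise PCSA", {
  act <- activation_params()
  # single flexor + single extensor table: weights must both be 1
  tab1 <- data.frame(muscle = c("FCU", "ECU"), role = c("flexor", "extensor"),
                     fmax_mean_N = c(100, 80), fmax_sd_N = c(10, 10),
                     ma_mean_m = c(0.02, -0.01), ma_sd_m = c(0.002, 0.002),
                     pcsa_cm2 = c(3, 4), represented_pcsa_cm2 = c(0, 0))
  tab1$sigma_pcsa_cm2 <- tab1$pcsa_cm2
  p <- pbm_parameters(act, list(
    muscle_physiology("FCU", 100, 0.02, 3),
    muscle_physiology("ECU", 80, -0.01, 4)))
  af <- rep(0.5, 4)
  ae <- rep(0.25, 4)
  expect_equal(two_channel_torque(af, ae, p, tab1),
               rep(100 * 0.5 * 0.02 + 80 * 0.25 * -0.01, 4))
  # full table: hand-computed pooled weights
  tab <- muscle_table()
  sf <- sum(tab$sigma_pcsa_cm2[tab$role == "flexor"])
  se <- sum(tab$sigma_pcsa_cm2[tab$role == "extensor"])
  pf <- 3  # the PCSA of the muscle objects used in the reduced model
  pe <- 4
  expect_equal(two_channel_torque(af, ae, p, tab),
               rep(sf / pf * 100 * 0.5 * 0.02 + se / pe * 80 * 0.25 * -0.01,
                   4))
  p_two_flex <- pbm_parameters(act, list(
    muscle_physiology("FCU", 100, 0.02, 3),
    muscle_physiology("FCR", 80, 0.01, 2)))
  expect_error(two_channel_torque(af, ae, p_two_flex, tab), "extensor")
})

test_that("five-channel redistribution gives each primary flexor half the
           non-primary flexor pool", {
  tab <- muscle_table()
  ch5 <- primary_channels()
  sigma <- redistribute_sigma_pcsa(tab, ch5)
  names(sigma) <- ch5
  pool_flex <- sum(tab$sigma_pcsa_cm2[tab$role == "flexor" &
                                        !(tab$muscle %in% ch5)])
  pool_ext <- sum(tab$sigma_pcsa_cm2[tab$role == "extensor" &
                                       !(tab$muscle %in% ch5)])
  own <- function(mu) tab$sigma_pcsa_cm2[tab$muscle == mu]
  expect_equal(sigma[["FCR"]], own("FCR") + pool_flex / 2)
  expect_equal(sigma[["FCU"]], own("FCU") + pool_flex / 2)
  expect_equal(sigma[["ECRL"]], own("ECRL") + pool_ext / 3)
  # with all channels present the table values are returned unchanged
  expect_equal(redistribute_sigma_pcsa(tab, tab$muscle),
               tab$sigma_pcsa_cm2)
  expect_error(redistribute_sigma_pcsa(tab, c("FCR", "FCU")), "extensor")
})

test_that("forward model equals the composed R-level stages", {
  tab <- muscle_table()
  params <- semgtorque:::pbm_parameters_from_table(
    tab, activation_params(A = -2, C1 = 0.4, C2 = -0.2, d_ms = 35))
  env <- with_test_seed(4, matrix(runif(800 * 8), 800, 8))
  colnames(env) <- semg_channels
  pr <- make_processed(env, numeric(800))
  tau_cpp <- forward_pbm(pr, params)
  a <- sapply(seq_len(8), function(j) {
    u <- recursive_filter(env[, j], params$activation, 1000)
    activation_nonlinearity(u, params$activation$A, clamp = TRUE)
  })
  tau_r <- joint_torque(a, params)
  expect_equal(tau_cpp, tau_r, tolerance = 1e-10)
  expect_equal(forward_pbm(pr, params, idx = seq(100, 800, 100)),
               tau_r[seq(100, 800, 100)], tolerance = 1e-10)
  expect_equal(forward_pbm(make_processed(env * 0, numeric(800)), params),
               numeric(800))
})
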