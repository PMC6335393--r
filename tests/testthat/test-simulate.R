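test_that("the NMDA magnesium block follows the stated voltage dependence", {
  expect_equal(nmda_mg_factor(0), 1 / (1 + 1 / 3.57), tolerance = 1e-12)
  expect_equal(nmda_mg_factor(5, receptor_kinetics(mg = 0)), 1)
  expect_lt(nmda_mg_factor(-300), 1e-6)       # V -> -inf limit
  expect_true(all(nmda_mg_factor(seq(-100, 50, 10)) > 0))
  expect_error(nmda_mg_factor(NaN), "finite")
})

test_that("short-term depression recovers, jumps, and matches closed forms", {
  # recovery towards 1
  D <- 0.5
  for (i in 1:20000) D <- std_update(D, 0.5, 600, 1, FALSE)
  expect_equal(D, 1, tolerance = 1e-10)
  # p_v = 1: jump vanishes
  D <- 1
  for (i in 1:100) D <- std_update(D, 1, 600, 0.1, TRUE)
  expect_equal(D, 1)
  # tau_d = 0 disables STD
  expect_equal(std_update(0.4, 0.5, 0, 0.1, TRUE), 1)

  # periodic 50 Hz drive, p_v 0.5, tau_D 600: exact renewal closed form
  p_v <- 0.5; tau_d <- 600; T_isi <- 20; dt <- 0.1
  e <- exp(-T_isi / tau_d)
  D_star <- (1 - e) / (1 - p_v * e)          # fixed point sampled pre-spike
  avg_exact <- 1 - (1 - p_v * D_star) * (tau_d / T_isi) * (1 - e)
  n <- 400000
  D <- 1; acc <- 0; at_spike <- numeric(0); nacc <- 0
  for (step in seq_len(n)) {
    spiked <- step %% 200 == 0
    if (spiked && step > 100000) at_spike <- c(at_spike, D)
    D <- std_update(D, p_v, tau_d, dt, spiked)
    if (step > 100000) { acc <- acc + D; nacc <- nacc + 1 }
  }
  expect_equal(acc / nacc, avg_exact, tolerance = 0.01)
  # the mean-field ratio 1/(1+(1-p_v) r tau_D) matches D sampled at
  # spike arrival (within 10%); the continuous average dips below it
  mf <- 1 / (1 + (1 - p_v) * 50 * 0.6)
  expect_lt(abs(mean(at_spike) - mf) / mf, 0.1)
  expect_lt(acc / nacc, mf)

  # under Poisson drive the mean-field value holds for the time average
  set.seed(4)
  D <- 1; acc <- 0; nacc <- 0
  for (step in seq_len(n)) {
    D <- std_update(D, p_v, tau_d, dt, runif(1) < 50 * dt / 1000)
    if (step > 100000) { acc <- acc + D; nacc <- nacc + 1 }
  }
  expect_lt(abs(acc / nacc - mf) / mf, 0.1)
})

test_that("reduced gating equals per-synapse aggregation exactly", {
  set.seed(11)
  spk <- lapply(1:20, function(j) sort(sample(10000, 40)))
  g <- runif(20, 0.1, 5)
  for (tau in c(2, 20)) {
    a <- gating_per_synapse_trace(spk, g, tau, dt = 0.1, n_steps = 10000)
    b <- gating_reduced_trace(spk, g, tau, dt = 0.1, n_steps = 10000)
    expect_lt(max(abs(a - b) / pmax(abs(b), 1e-300)), 1e-10)
  }
  # no input: pure exponential decay
  tr <- gating_reduced_trace(list(c(1)), 2, tau = 5, dt = 0.1, n_steps = 500)
  expect_equal(tr[500] / tr[100], exp(-(400) * 0.1 / 5), tolerance = 1e-12)
})

test_that("a presynaptic spike increments the target gate by g and decays", {
  neurons <- data.frame(id = c("pre", "post"),
                        name = c("Cha-F-1", "Cha-F-2"),
                        transmitter = "Cha", length = 1000)
  m <- toy_model(neurons, data.frame(pre = "pre", post = "post", n = 100))
  cfg <- simulation_config(50, dt = 0.1, seed = 1,
                           record_vm = c("pre", "post"),
                           record_gates = TRUE)
  r <- run_simulation(m, cfg, noise = "off", i_ext = c(300, 0))
  g_expect <- 2.2 * 100 / 3000        # B_exc * k_ACh * N, D = 1
  s <- r$gates$S_ach[, 2]
  first <- which(s > 0)[1]
  expect_equal(s[first], g_expect, tolerance = 1e-9)
  # decays by exp(-dt/tau_ACh) until the next spike
  expect_equal(s[first + 1] / s[first], exp(-0.1 / 20), tolerance = 1e-9)
  # post depolarizes (EPSP)
  expect_gt(max(r$vm$post), -70 + 0.5)
})

test_that("leak-only dynamics follow the closed-form exponential", {
  m <- disconnected_model(1)
  cfg <- simulation_config(100, dt = 0.1, seed = 1, record_vm = m$neurons$id,
                           threshold_on = FALSE)
  r <- run_simulation(m, cfg, noise = "off", V0 = -50)
  vexp <- -70 + 20 * exp(-r$vm$time / 16)
  expect_lt(max(abs(r$vm[, 2] - vexp)), 1e-9)
})

test_that("constant suprathreshold drive fires at the LIF closed-form period", {
  m <- disconnected_model(1)
  gL <- m$neurons$g_L
  I <- gL * 30                          # V_inf = -40 mV
  cfg <- simulation_config(2000, dt = 0.01, seed = 1)
  r <- run_simulation(m, cfg, noise = "off", i_ext = I)
  period <- mean(diff(r$spikes$time))
  pred <- 2 + 16 * log((-40 + 55) / (-40 + 45))
  expect_lt(abs(period - pred) / pred, 0.01)
  # no inter-spike interval violates the refractory period
  expect_true(all(diff(r$spikes$time) >= 2))
})

test_that("the per-step |dV| cap blocks the GABAergic rebound artifact", {
  neurons <- data.frame(id = c("pre", "post"),
                        name = c("Gad-F-1", "Cha-F-2"),
                        transmitter = c("Gad", "Cha"), length = 1000)
  m <- toy_model(neurons, data.frame(pre = "pre", post = "post", n = 60000))
  gL <- m$neurons$g_L[1]
  run <- function(dv_max) {
    cfg <- simulation_config(200, dt = 0.1, seed = 1, dv_max = dv_max,
                             record_vm = "post")
    run_simulation(m, cfg, noise = "off", i_ext = c(gL * 40, 0),
                   V0 = c(-70, -80))
  }
  capped <- run(25)
  expect_equal(sum(capped$spikes$neuron_id == "post"), 0)
  expect_lte(max(abs(diff(capped$vm$post))), 25 + 1e-9)
  # without the cap the huge depolarizing swing fires the post neuron
  uncapped <- run(1e9)
  expect_gt(sum(uncapped$spikes$neuron_id == "post"), 0)
})

test_that("runs are deterministic given a seed and empty for zero duration", {
  m <- disconnected_model(20)
  r0 <- run_simulation(m, simulation_config(0, seed = 3))
  expect_equal(nrow(r0$spikes), 0L)
  expect_equal(nrow(r0$rate), 0L)
  # lower the threshold so spikes are plentiful in a short window
  m$neurons$V_threshold <- -53
  m$neurons$V_reset <- -55
  a <- run_simulation(m, simulation_config(2000, seed = 42))
  b <- run_simulation(m, simulation_config(2000, seed = 42))
  c <- run_simulation(m, simulation_config(2000, seed = 43))
  expect_gt(nrow(a$spikes), 50)
  expect_identical(a$spikes, b$spikes)
  expect_false(identical(a$spikes, c$spikes))
})

test_that("population rate implements count / (neurons x bin)", {
  expect_equal(nrow(population_rate(data.frame(time = numeric(0)), 10, 100,
                                    0)), 0L)
  sp <- data.frame(time = runif(100, 0, 1000))
  tr <- population_rate(sp, 100, bin = 1000, duration = 1000)
  expect_equal(tr$rate, 1)                       # 100 spikes, 100 neurons, 1 s
  # Poisson fixture at 5 Hz
  set.seed(9)
  n <- 50; dur <- 20000
  sp2 <- data.frame(time = runif(rpois(1, n * 5 * dur / 1000), 0, dur))
  tr2 <- population_rate(sp2, n, bin = 100, duration = dur)
  se <- sqrt(5 / (n * dur / 1000))
  expect_lt(abs(mean(tr2$rate) - 5), 3 * se)
})

test_that("exponential-Euler spike times converge as dt shrinks", {
  m <- disconnected_model(3)
  I <- m$neurons$g_L * c(28, 32, 36)
  t1 <- run_simulation(m, simulation_config(500, dt = 0.1, seed = 1),
                       noise = "off", i_ext = I)$spikes
  t2 <- run_simulation(m, simulation_config(500, dt = 0.05, seed = 1),
                       noise = "off", i_ext = I)$spikes
  t3 <- run_simulation(m, simulation_config(500, dt = 0.01, seed = 1),
                       noise = "off", i_ext = I)$spikes
  expect_equal(nrow(t1), nrow(t3))
  # error vs the dt/10 reference shrinks with dt; the per-spike error
  # is O(dt) and accumulates linearly over successive spikes
  e1 <- max(abs(sort(t1$time) - sort(t3$time)))
  e2 <- max(abs(sort(t2$time) - sort(t3$time)))
  expect_lt(e2, e1)
  n_spk <- nrow(t3) / 3
  expect_lt(e1, 2 * n_spk * 0.1)
  expect_lt(e2, 2 * n_spk * 0.05)
})
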