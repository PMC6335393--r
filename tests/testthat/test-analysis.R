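ei_fixture <- function(pre_tx, n_contacts) {
  pre_ids <- sprintf("%s-F-%03d", pre_tx, seq_along(pre_tx))
  neurons <- data.frame(id = c(pre_ids, "Cha-F-900"),
                        name = c(pre_ids, "Cha-F-900"),
                        transmitter = c(pre_tx, "Cha"), length = 1000)
  toy_model(neurons, data.frame(pre = pre_ids, post = "Cha-F-900",
                                n = n_contacts))
}

test_that("the E-I index covers its bounds and simple ratios", {
  m <- ei_fixture(c("Cha", "Cha", "Cha"), c(1, 1, 1))
  expect_equal(ei_index(m, "Cha-F-900")$index, 1)
  m2 <- ei_fixture(c("Cha", "Cha", "Gad", "Gad"), rep(1, 4))
  expect_equal(ei_index(m2, "Cha-F-900")$index, 0)
  m3 <- ei_fixture(c("Cha", "VGlut", "Cha", "Gad"), rep(1, 4))
  expect_equal(ei_index(m3, "Cha-F-900")$index, 0.5)
  # weighted variant sums contact counts
  m4 <- ei_fixture(c("Cha", "Gad"), c(30, 10))
  expect_equal(ei_index(m4, "Cha-F-900", weighted = TRUE)$index, 0.5)
  expect_equal(ei_index(m4, "Cha-F-900", weighted = FALSE)$index, 0)
  # neurons with no typed input are NA
  expect_true(is.na(ei_index(m4, m4$neurons$id[1])$index))
})

test_that("swapping excitatory and inhibitory labels negates every index", {
  cn <- synth_connectome(200, connectivity = 0.05, seed = 6)
  m <- suppressWarnings(assemble_model(cn$neurons, cn$contacts))
  idx <- ei_index(m, weighted = TRUE)$index
  swapped <- m
  swapped$neurons$transmitter <- c(Cha = "Gad", VGlut = "Gad", Gad = "Cha",
                                   other = "other")[m$neurons$transmitter]
  idx2 <- ei_index(swapped, weighted = TRUE)$index
  ok <- !is.na(idx) & !is.na(idx2)
  expect_true(any(ok))
  expect_equal(idx2[ok], -idx[ok])
})

test_that("degree statistics handle complete and empty graphs", {
  ids <- sprintf("Cha-F-%03d", 1:5)
  neurons <- data.frame(id = ids, name = ids, transmitter = "Cha",
                        length = 1000)
  edges <- expand.grid(pre = ids, post = ids, stringsAsFactors = FALSE)
  edges <- edges[edges$pre != edges$post, ]
  edges$n <- 1
  m <- toy_model(neurons, edges)
  d <- degree_stats(m)
  expect_equal(d$density, 1)
  expect_true(all(d$per_neuron$in_degree == 4))
  expect_true(all(d$per_neuron$out_degree == 4))
  m0 <- toy_model(neurons, edges[0, ])
  expect_equal(degree_stats(m0)$density, 0)
})

test_that("hyperactivity episodes, onset and prevalence are measured", {
  mk <- function(rates, bin = 100)
    data.frame(time = seq_along(rates) * bin - bin / 2, rate = rates)
  h0 <- detect_hyperactivity(mk(rep(0, 50)))
  expect_equal(h0$prevalence, 0)
  expect_true(is.na(h0$onset))
  h1 <- detect_hyperactivity(mk(rep(2, 100)))
  expect_equal(h1$prevalence, 1)
  expect_equal(h1$onset, 0)
  # square wave, 50% duty cycle
  h2 <- detect_hyperactivity(mk(rep(c(0, 2), 50)))
  expect_equal(h2$prevalence, 0.5)
  expect_equal(nrow(h2$intervals), 50L)
  # prevalence + below-threshold fraction = 1 exactly
  set.seed(1)
  h3 <- detect_hyperactivity(mk(runif(200, 0, 2)))
  below <- 1 - h3$prevalence
  expect_equal(h3$prevalence + below, 1)
})

test_that("Fano factors separate regular, Poisson and bursty firing", {
  trials <- data.frame(start = seq(0, 9000, 1000), end = seq(1000, 10000, 1000))
  # identical counts: fano 0
  reg <- data.frame(neuron_id = "a",
                    time = as.vector(outer(seq(50, 950, 100),
                                           seq(0, 9000, 1000), "+")))
  f <- fano_factor(reg, trials)
  expect_equal(f$per_neuron$fano, 0)
  # bursty counts {0,0,0,40,0,0,0,40,0,0}: var/mean >> 1
  bursty <- data.frame(neuron_id = "b",
                       time = c(runif(40, 3000, 4000), runif(40, 7000, 8000)))
  fb <- fano_factor(bursty, trials)
  counts <- c(0, 0, 0, 40, 0, 0, 0, 40, 0, 0)
  expect_equal(fb$per_neuron$fano, var(counts) / mean(counts))
  expect_gt(fb$per_neuron$fano, 10)
  # silent neuron excluded
  fs <- fano_factor(bursty, trials, neuron_ids = c("b", "ghost"))
  expect_equal(fs$n_excluded, 1L)
  expect_true(is.na(fs$per_neuron$fano[fs$per_neuron$neuron_id == "ghost"]))
  expect_error(fano_factor(bursty, trials[1, , drop = FALSE]), "2")
})

test_that("Poisson spike counts give Fano factors near 1", {
  set.seed(12)
  n_tr <- 500
  trials <- data.frame(start = seq(0, by = 1000, length.out = n_tr))
  trials$end <- trials$start + 1000
  lam <- 5
  sp <- data.frame(neuron_id = "p",
                   time = sort(runif(rpois(1, lam * n_tr), 0, n_tr * 1000)))
  f <- fano_factor(sp, trials)$per_neuron$fano
  # chi-square CI for the variance ratio with n_tr - 1 df
  ci <- qchisq(c(0.0005, 0.9995), n_tr - 1) / (n_tr - 1)
  expect_gt(f, ci[1] * 0.9)
  expect_lt(f, ci[2] * 1.1)
})

test_that("size histograms integrate to one and resolve planted modes", {
  u <- runif(5000)
  h <- size_distribution(u, breaks = seq(0, 1, 0.1))$all
  expect_equal(sum(h$density * h$width), 1)
  expect_true(all(abs(h$density - 1) < 0.15))
  # two planted log-normal modes are both visible
  set.seed(3)
  x <- c(rlnorm(4000, log(300), 0.25), rlnorm(4000, log(3000), 0.25))
  hb <- size_distribution(x, breaks = 25)$all
  d <- hb$density
  peaks <- which(diff(sign(diff(d))) == -2) + 1
  peaks <- peaks[d[peaks] > 0.1 * max(d)]
  expect_gte(length(peaks), 2L)
  # per-class lists, empty class tolerated
  hc <- size_distribution(c(1, 2, 3), factor(c("a", "a", "a"),
                                             levels = c("a", "b")))
  expect_equal(nrow(hc$b), 0L)
  expect_equal(sum(hc$a$density * hc$a$width), 1)
})

test_that("rate-distribution fitting recovers planted laws", {
  set.seed(21)
  # planted exponential: the exponential fit wins and alpha ~ 0
  xe <- rexp(10000, rate = 1 / 5)
  fe <- fit_rate_distribution(xe)
  # a pure power law misfits exponential data; the truncated model only
  # wins through its exponential factor, with a negligible exponent
  expect_lt(fe$fits$exponential$chi2, fe$fits$power_law$chi2)
  expect_lt(fe$fits$truncated_power_law$params$alpha, 0.3)
  expect_equal(1 / fe$fits$exponential$params$lambda, 5, tolerance = 0.5)
  # planted truncated power law x^-1.2 e^(-x/20)
  xt <- rtrunc_powerlaw(10000, alpha = 1.2, beta = 1 / 20, xmin = 0.1)
  ft <- fit_rate_distribution(xt)
  expect_equal(ft$best, "truncated_power_law")
  expect_equal(ft$fits$truncated_power_law$params$alpha, 1.2,
               tolerance = 0.2 / 1.2)
  # degenerate and undersized inputs are rejected
  expect_error(fit_rate_distribution(rep(2, 100)), "degenerate")
  expect_error(fit_rate_distribution(rexp(30)), "at least 50")
})
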