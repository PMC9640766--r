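test_that("category index matches hand cases and the brute-force oracle", {
  # perfect category coding
  r <- category_index(c(1, 1, 1, 0, 0, 0))
  expect_equal(r$WCD, 0)
  expect_equal(r$BCD, 1)
  expect_equal(r$CI, 1)
  # graded case evaluated by hand: WCD = 4/3, BCD = 3, CI = 5/13
  r <- category_index(c(1, 2, 3, 4, 5, 6))
  expect_equal(r$FD_A1, 4)
  expect_equal(r$FD_A2, 4)
  expect_equal(r$WCD, 4 / 3)
  expect_equal(r$BCD, 3)
  expect_equal(r$CI, 5 / 13)
  # swapping the two groups leaves CI unchanged
  x <- c(0.3, 1.2, 0.8, 2.0, 2.4, 1.9)
  expect_equal(category_index(x)$CI,
               category_index(x[c(4:6, 1:3)])$CI)
  # undefined when all means equal
  expect_true(is.na(category_index(rep(2, 6))$CI))
  # agreement with an independent loop-based oracle on random tables
  set.seed(20)
  M <- matrix(stats::runif(1000 * 6, 0, 10), ncol = 6)
  ci_pipe <- category_index(M)
  ci_oracle <- apply(M, 1, brute_ci)
  expect_equal(ci_pipe, ci_oracle, tolerance = 1e-12)
  expect_true(all(ci_pipe >= -1 - 1e-12 & ci_pipe <= 1 + 1e-12))
})

test_that("stimulus index matches hand cases and the brute-force oracle", {
  expect_equal(stimulus_index(c(1, 1, 1, 2, 2, 2))$SI, 0)
  r <- stimulus_index(c(1, 2, 3, 2, 2, 2))
  expect_equal(r$SI_A1, 0.5)
  expect_equal(r$SI_A2, 0)
  expect_equal(r$SI, 0.25)
  # scale invariance
  x <- c(0.5, 1.5, 2.5, 1, 2, 4)
  expect_equal(stimulus_index(x)$SI, stimulus_index(10 * x)$SI)
  # zero-sum group component undefined
  expect_true(is.na(stimulus_index(c(0, 0, 0, 1, 2, 3))$SI))
  set.seed(21)
  M <- matrix(stats::runif(1000 * 6, 0, 10), ncol = 6)
  si_pipe <- stimulus_index(M)
  si_oracle <- apply(M, 1, brute_si)
  expect_equal(si_pipe, si_oracle, tolerance = 1e-12)
  expect_true(all(si_pipe >= 0 & si_pipe <= 1 + 1e-12))
})

test_that("rate tables recover the generator's condition means", {
  set.seed(22)
  syn <- synthetic_rate_tensor(n_neurons = 20, trials_per_condition = 40,
                               wcd = 0.6, bcd = 2, noise_sd = 0.05)
  rec <- synthetic_record(syn)
  rt <- mean_rates(rec)
  expect_equal(dim(rt$means), c(20L, 6L))
  expect_equal(rt$counts, rep(40, 6))
  expect_equal(rt$means, syn$true_means, tolerance = 0.05,
               ignore_attr = TRUE)
  # constant-rate tensor -> all six means equal that constant
  syn0 <- synthetic_rate_tensor(n_neurons = 3, trials_per_condition = 5,
                                wcd = 0, bcd = 0, noise_sd = 0, baseline = 3)
  rt0 <- mean_rates(synthetic_record(syn0))
  expect_true(all(abs(rt0$means - 3) < 1e-12))
})

test_that("index recovery on populations with prescribed structure", {
  set.seed(23)
  syn <- synthetic_rate_tensor(n_neurons = 60, trials_per_condition = 30,
                               wcd = 0.5, bcd = 2.5, noise_sd = 0.3)
  rec <- synthetic_record(syn)
  rt <- mean_rates(rec)
  ci <- category_index(rt$means)
  expect_equal(mean(ci), mean((2.5 - 0.5) / (2.5 + 0.5)), tolerance = 0.05)
  expect_equal(mean(syn$true_ci), (2.5 - 0.5) / (2.5 + 0.5), tolerance = 1e-10)
})

test_that("bootstrap flags strong category structure, not exchangeable data", {
  set.seed(24)
  # between-group gap 10x the noise sd -> significant
  strong <- synthetic_rate_tensor(n_neurons = 10, trials_per_condition = 20,
                                  wcd = 0, bcd = 2, noise_sd = 0.2)
  rec <- synthetic_record(strong)
  rt <- mean_rates(rec)
  boot <- bootstrap_significance(rt$trial_rates, rt$labels, n_shuffles = 200)
  expect_true(all(boot$significant))
  # identical trials across conditions are never significant
  flat <- matrix(3, nrow = 30, ncol = 4)
  labs <- factor(rep(c("A1", "B1", "C1", "A2", "B2", "C2"), each = 5),
                 levels = c("A1", "B1", "C1", "A2", "B2", "C2"))
  boot0 <- bootstrap_significance(flat, labs, n_shuffles = 100)
  expect_true(all(!boot0$significant))
  expect_error(bootstrap_significance(flat[1:6, ], labs[1:6]), ">= 2 trials")
})

test_that("bootstrap false-positive rate is calibrated on exchangeable data", {
  set.seed(25)
  n_neurons <- 1000
  trials_per <- 8
  rates <- matrix(stats::rnorm(6 * trials_per * n_neurons, 5, 1),
                  nrow = 6 * trials_per)
  labs <- factor(rep(c("A1", "B1", "C1", "A2", "B2", "C2"),
                     each = trials_per),
                 levels = c("A1", "B1", "C1", "A2", "B2", "C2"))
  boot <- bootstrap_significance(rates, labs, n_shuffles = 500)
  fp <- mean(boot$significant)
  expect_gte(fp, 0.03)
  expect_lte(fp, 0.07)
})

test_that("neuron taxonomy separates silent, stimulus and category cells", {
  set.seed(26)
  # population: 10 category coders, 10 within-group discriminators, and
  # 5 silent neurons appended by hand
  cat_part <- synthetic_rate_tensor(n_neurons = 10, trials_per_condition = 15,
                                    wcd = 0.1, bcd = 3, noise_sd = 0.3)
  stim_part <- synthetic_rate_tensor(n_neurons = 10, trials_per_condition = 15,
                                     wcd = 2, bcd = 3, noise_sd = 0.3)
  rec <- synthetic_record(cat_part)
  rec2 <- synthetic_record(stim_part)
  win <- array(0, c(dim(rec$win_rates)[1], 25, 1),
               dimnames = list(NULL, NULL, "first_stimulus"))
  win[, 1:10, 1] <- rec$win_rates[, , 1]
  win[, 11:20, 1] <- rec2$win_rates[, , 1]
  rec$win_rates <- win
  rec$max_rate <- c(rec$max_rate, rec2$max_rate, rep(0, 5))
  classes <- classify_neurons(rec, n_shuffles = 200)
  expect_equal(classes$class[21:25], rep("silent", 5))
  expect_true(all(classes$class[1:10] == "category"))
  expect_gt(mean(classes$ci[1:10]), 0.8)
  # strong within-group structure with matching between-group structure
  # should often fail the category test; at minimum its CI is far lower
  expect_lt(mean(classes$ci[11:20]), mean(classes$ci[1:10]))
})

test_that("connectivity split follows the input mask", {
  set.seed(27)
  agent <- init_agent(agent_config(n_policy = 40, n_value = 10, p0 = 0.2))
  classes <- data.frame(neuron = 1:40,
                        class = sample(c("category", "stimulus"), 40, TRUE),
                        ci = stats::runif(40), si = stats::runif(40))
  cs <- connectivity_split(agent, classes)
  expect_equal(cs$direct, rowSums(agent$policy$M_in) > 0)
  expect_equal(cs$n_direct + cs$n_indirect, 40L)
  # degenerate probabilities
  a1 <- init_agent(agent_config(n_policy = 10, n_value = 4, p0 = 1))
  expect_true(all(connectivity_split(a1, classes[1:10, ])$direct))
  a0 <- init_agent(agent_config(n_policy = 10, n_value = 4, p0 = 0))
  expect_true(all(!connectivity_split(a0, classes[1:10, ])$direct))
})

test_that("pairwise similarity analysis recovers a constructed correlation", {
  set.seed(28)
  # two neurons with known trace correlation via direct construction
  base <- stats::rnorm(20)
  noise <- stats::rnorm(20)
  rho <- 0.8
  t1 <- base
  t2 <- rho * scale(base)[, 1] + sqrt(1 - rho^2) * scale(noise)[, 1]
  expect_equal(stats::cor(t1, t2), stats::cor(base, t2))
  # build a minimal fit-like object around the traces
  trace <- rbind(t1, t2)
  fitlike <- list(
    agent = list(policy = list(M_rec = matrix(c(0, 1, 1, 0), 2, 2),
                               W_rec = matrix(c(0, 0.4, -0.2, 0), 2, 2),
                               W_rec_phi = matrix(0, 2, 2),
                               W_rec_psi = matrix(0, 2, 2))),
    init_params = list(p.W_rec = matrix(0, 2, 2),
                       p.W_rec_phi = matrix(0, 2, 2),
                       p.W_rec_psi = matrix(0, 2, 2)),
    final_record = list(trace_first = trace))
  classes <- data.frame(neuron = 1:2, class = c("category", "category"),
                        ci = c(0.9, 0.8), si = c(0.1, 0.2))
  wa <- weight_analyses(fitlike, classes)
  expect_equal(nrow(wa$pairs), 2L)
  expect_equal(wa$pairs$similarity, rep(stats::cor(t1, t2), 2),
               tolerance = 1e-12)
  expect_equal(sort(wa$pairs$dweight), c(-0.2, 0.4))
  # identical initial and final parameters -> all weight changes zero
  fitlike$agent$policy$W_rec <- matrix(0, 2, 2)
  wa0 <- weight_analyses(fitlike, classes)
  expect_true(all(wa0$pairs$dweight == 0))
})

test_that("action-coding classes recover constructed selectivity", {
  set.seed(290)
  n_tr <- 120
  sides <- rep(c("L", "R"), length.out = n_tr)
  stims <- rep(c("A1", "B1", "C1", "A2", "B2", "C2"), length.out = n_tr)
  orders <- c(A = "ABC", B = "BCA", C = "CAB")[substr(stims, 1, 1)]
  trials <- data.frame(order = unname(orders),
                       group = as.integer(substr(stims, 2, 2)),
                       pos1 = sides, pos2 = "L",
                       correct = TRUE, first_choice_side = sides,
                       stringsAsFactors = FALSE)
  # neuron 1: action only (left-choice preference at decision)
  # neuron 2: stimulus only; neuron 3: both; neuron 4: silent
  dec <- cbind(ifelse(sides == "L", 2, 0) + stats::rnorm(n_tr, 0, .1),
               stats::rnorm(n_tr, 1, .1),
               ifelse(sides == "L", 2, 0) + stats::rnorm(n_tr, 0, .1),
               rep(0, n_tr))
  stim_resp <- as.numeric(factor(stims))
  early <- cbind(stats::rnorm(n_tr, 1, .1),
                 stim_resp + stats::rnorm(n_tr, 0, .1),
                 stim_resp + stats::rnorm(n_tr, 0, .1),
                 rep(0, n_tr))
  win <- array(0, c(n_tr, 4, 2),
               dimnames = list(NULL, NULL, c("first_decision", "stim_delay")))
  win[, , "first_decision"] <- dec
  win[, , "stim_delay"] <- early
  rec <- list(trials = trials, win_rates = win,
              max_rate = c(1, 1, 1, 0))
  classes <- data.frame(neuron = 1:4,
                        class = c("stimulus", "stimulus", "category",
                                  "silent"))
  ac <- action_coding_classes(rec, classes)
  expect_equal(ac$action_class,
               c("action-only", "stimulus-only", "stimulus-action",
                 "silent"))
})
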