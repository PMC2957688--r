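test_that("spacing tail probability follows the Erlang-2 survival", {
  expect_equal(p_distance_by_chance(0.1, 0), 1)
  expect_equal(p_distance_by_chance(0.1, 77), 0.0039396, tolerance = 1e-4)
  expect_equal(p_distance_by_chance(0.1, 50), 0.0404277, tolerance = 1e-4)
  expect_error(p_distance_by_chance(0, 1), "> 0")
})

test_that("the Erlang-2 survival matches Monte Carlo of two Exp gaps", {
  set.seed(5)
  n <- 2e5
  d <- rexp(n, 0.1) + rexp(n, 0.1)
  for (dd in c(30, 50, 77)) {
    emp <- mean(d >= dd)
    expect_equal(p_distance_by_chance(0.1, dd), emp,
                 tolerance = 4 * sqrt(emp * (1 - emp) / n) /
                   p_distance_by_chance(0.1, dd))
  }
})

test_that("a lone heterozygote inside a long homozygous run is removed", {
  # heterozygotes every 2 cM outside a 20 cM homozygous run spanning
  # [20, 40], one heterozygote planted at 30; with lambda = 21/60 per cM
  # the planted call's flanking distance (24 cM, P ~ 2e-3) is the only one
  # below the 0.01 threshold (its neighbours see 14 cM, P ~ 0.04)
  left <- seq(0, 19, by = 1)
  run <- seq(20, 40, by = 0.5)
  right <- seq(41, 60, by = 1)
  cm <- c(left, run, right)
  call <- c(rep(c("AB", "AA"), length.out = length(left)),
            ifelse(run == 30, "AB", "AA"),
            rep(c("BB", "AB"), length.out = length(right)))
  calls <- toy_calls(call, cm)
  res <- correct_calls(calls, chrom_lengths_cm = c(`1` = 60))
  expect_equal(nrow(res$report), 1)
  expect_equal(res$report$pos_cm, 30)
  expect_equal(res$calls$call[calls$pos_cm == 30], "NC")
})

test_that("uniformly spaced heterozygotes are left untouched", {
  cm <- seq(0.5, 49.5, by = 1)  # matches lambda = 1 het/cM
  calls <- toy_calls(rep(c("AB", "AA"), length.out = length(cm)), cm)
  res <- correct_calls(calls, chrom_lengths_cm = c(`1` = 50))
  expect_equal(nrow(res$report), 0)
  expect_equal(res$calls$call, calls$call)
})

test_that("correction only ever converts heterozygotes to no-calls", {
  set.seed(6)
  for (i in 1:10) {
    calls <- random_track(300, L = 30)
    res <- correct_calls(calls, chrom_lengths_cm = c(`1` = 30))
    changed <- which(res$calls$call != calls$call)
    expect_true(all(calls$call[changed] == "AB"))
    expect_true(all(res$calls$call[changed] == "NC"))
    expect_true(all(res$report$p_chance < 0.01))
  }
})

test_that("a track without heterozygotes passes through unchanged", {
  calls <- toy_calls(c("AA", "BB", "NC", "AA"), pos_cm = 1:4)
  res <- correct_calls(calls)
  expect_equal(res$calls$call, calls$call)
  expect_equal(nrow(res$report), 0)
})

test_that("false removals on error-free outbred genomes stay near the
          threshold tail mass", {
  set.seed(8)
  cfg <- small_config(no_call_rate = 0)
  removed <- hets <- 0
  for (i in 1:5) {
    s <- generate_outbred_sample(cfg)
    res <- correct_calls(s$calls, chrom_lengths_cm = cfg$chrom_lengths_cm)
    removed <- removed + nrow(res$report)
    hets <- hets + zygosity_counts(s$calls)$n_het
  }
  expect_lt(removed / hets, 0.02)  # ~1% by construction of the threshold
})

test_that("error injection hits the floor(n * rate) contract", {
  calls <- toy_calls(rep(c("AA", "AB", "NC"), length.out = 1000),
                     pos_cm = seq(0.01, 10, by = 0.01))
  n_called <- sum(calls$call != "NC")
  r <- inject_errors(calls, 0.003, seed = 1)
  expect_equal(r$n_injected, floor(n_called * 0.003))
  changed <- which(r$calls$call != calls$call)
  expect_length(changed, r$n_injected)
  expect_true(all(calls$call[changed] != "NC"))
  r0 <- inject_errors(calls, 0, seed = 1)
  expect_equal(r0$n_injected, 0)
  expect_identical(r0$calls$call, calls$call)
})

test_that("error injection is reproducible under a seed", {
  calls <- random_track(500, L = 50)
  a <- inject_errors(calls, 0.05, seed = 9)
  b <- inject_errors(calls, 0.05, seed = 9)
  c <- inject_errors(calls, 0.05, seed = 10)
  expect_identical(a$calls$call, b$calls$call)
  expect_equal(a$n_injected, c$n_injected)
  expect_false(identical(a$calls$call, c$calls$call))
})
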