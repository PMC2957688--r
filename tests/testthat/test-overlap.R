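# random disjoint segment set on one chromosome of length L
random_segset <- function(L = 10, kmax = 4, chrom = 1) {
  k <- sample(0:kmax, 1)
  if (k == 0) {
    return(as_segments(data.frame(chrom = integer(), start_bp = numeric(),
                                  end_bp = numeric(), start_cm = numeric(),
                                  end_cm = numeric(), n_snps = integer(),
                                  kind = character())))
  }
  cuts <- sort(runif(2 * k, 0, L))
  st <- cuts[seq(1, 2 * k, by = 2)]
  en <- cuts[seq(2, 2 * k, by = 2)]
  as_segments(data.frame(chrom = chrom, start_bp = round(st * 1e6) + 1,
                         end_bp = round(en * 1e6) + 2, start_cm = st,
                         end_cm = en, n_snps = 1L, kind = "RHS"))
}

# brute-force coverage on a fine grid: a point is in the intersection iff
# every set covers it
grid_intersection_mass <- function(sets, L, step = 0.01) {
  x <- seq(step / 2, L - step / 2, by = step)
  cov <- rep(TRUE, length(x))
  for (s in sets) {
    inside <- rep(FALSE, length(x))
    for (i in seq_len(nrow(s))) {
      inside <- inside | (x >= s$start_cm[i] & x < s$end_cm[i])
    }
    cov <- cov & inside
  }
  sum(cov) * step
}

test_that("pairwise intersection follows interval algebra", {
  a <- as_segments(data.frame(chrom = 1, start_bp = 10e6, end_bp = 20e6,
                              start_cm = 10, end_cm = 20, n_snps = 5L,
                              kind = "RHS"))
  b <- as_segments(data.frame(chrom = 1, start_bp = 15e6, end_bp = 30e6,
                              start_cm = 15, end_cm = 30, n_snps = 7L,
                              kind = "RHS"))
  ab <- intersect_regions(list(a, b))
  expect_equal(nrow(ab), 1)
  expect_equal(ab$start_cm, 15)
  expect_equal(ab$end_cm, 20)
  expect_equal(ab$kind, "OVERLAP")
  # a single set passes through unchanged
  expect_equal(intersect_regions(list(a)), a)
  # disjoint sets have an empty intersection
  c <- as_segments(data.frame(chrom = 1, start_bp = 40e6, end_bp = 50e6,
                              start_cm = 40, end_cm = 50, n_snps = 2L,
                              kind = "RHS"))
  expect_equal(nrow(intersect_regions(list(a, c))), 0)
})

test_that("intersection matches a discretized coverage oracle and is
          commutative and shrinking", {
  set.seed(31)
  for (i in 1:40) {
    sets <- lapply(1:3, function(j) random_segset())
    inter <- intersect_regions(sets)
    mass <- if (nrow(inter) == 0) 0 else sum(genetic_length_cm(inter))
    expect_lt(abs(mass - grid_intersection_mass(sets, 10)), 0.06)
    perm <- intersect_regions(rev(sets))
    expect_lt(abs(sum(genetic_length_cm(perm)) - mass), 1e-9)
    # adding a set never lengthens the overlap
    more <- intersect_regions(c(sets, list(random_segset())))
    expect_lte(sum(genetic_length_cm(more)), mass + 1e-9)
  }
})

test_that("sharing counts match per-sample brute-force membership", {
  set.seed(32)
  snps <- data.frame(snp_id = sprintf("s%02d", 1:50), chrom = 1,
                     pos_cm = sort(runif(50, 0, 10)))
  pats <- lapply(1:4, function(i) random_segset())
  ctls <- lapply(1:6, function(i) random_segset())
  got <- sharing_counts(snps, pats, ctls)
  expect_equal(got$n1, rep(4, 50))
  expect_equal(got$n2, rep(6, 50))
  brute <- function(sets, cm) {
    sum(vapply(sets, function(s) {
      any(s$start_cm <= cm & cm < s$end_cm)
    }, logical(1)))
  }
  for (k in c(1, 17, 50)) {
    expect_equal(got$x1[k], brute(pats, snps$pos_cm[k]))
    expect_equal(got$x2[k], brute(ctls, snps$pos_cm[k]))
  }
  expect_true(all(got$x1 <= 4 & got$x2 <= 6))
})

test_that("fully shared and unshared SNPs hit the count extremes", {
  snps <- data.frame(snp_id = c("in", "out"), chrom = 1,
                     pos_cm = c(5, 9.5))
  cover <- as_segments(data.frame(chrom = 1, start_bp = 4e6, end_bp = 6e6,
                                  start_cm = 4, end_cm = 6, n_snps = 1L,
                                  kind = "RHS"))
  none <- cover[0, ]
  got <- sharing_counts(snps, list(cover, cover, cover), list(none))
  expect_equal(got$x1, c(3, 0))
  expect_equal(got$x2, c(0, 0))
})

test_that("the u statistic reproduces hand-computed cases", {
  sym <- u_statistic(3, 5, 3, 5)
  expect_equal(sym$u, 0)
  expect_equal(sym$p_value, 0.5)
  r <- u_statistic(5, 5, 4, 86)
  expect_equal(r$u, 6.1788, tolerance = 1e-4)
  expect_equal(r$neg_log10_p, 9.49, tolerance = 1e-2)
  # swapping case and control labels negates u
  expect_equal(u_statistic(4, 86, 5, 5)$u, -r$u)
})

test_that("u statistic P values match the quadrature tail oracle", {
  grid <- expand.grid(x1 = 0:5, x2 = c(0, 3, 40), n2 = c(5, 86))
  grid <- grid[grid$x2 <= grid$n2, ]
  res <- u_statistic(grid$x1, 5, grid$x2, grid$n2)
  expect_equal(res$p_value, oracle_normal_tail(res$u), tolerance = 1e-10)
  # monotone in x1 at fixed other counts
  inc <- u_statistic(0:5, 5, 2, 40)
  expect_true(all(diff(inc$neg_log10_p) > 0))
})

test_that("the printed variance form is available behind a flag", {
  r1 <- u_statistic(5, 5, 4, 86)
  r2 <- u_statistic(5, 5, 4, 86, n1_only_variance = TRUE)
  expect_false(isTRUE(all.equal(r1$u, r2$u)))
  p1 <- (5 + 0.5) / 6
  p2 <- (4 + 0.5) / 87
  pp <- (5 + 4 + 0.5) / 92
  expect_equal(r2$u, (p1 - p2) / sqrt(pp * (1 - pp) * (1 / 5 + 1 / 5)))
})

test_that("overlap ranking follows score, then length, then position", {
  ov <- as_segments(data.frame(
    chrom = c(1, 1, 2), start_bp = c(1e6, 30e6, 1e6),
    end_bp = c(10e6, 45e6, 4e6), start_cm = c(1, 30, 1),
    end_cm = c(10, 45, 4), n_snps = NA_integer_, kind = "OVERLAP"))
  stats <- data.frame(chrom = c(1, 1, 2), pos_cm = c(5, 35, 2),
                      neg_log10_p = c(3, 8, 8))
  ranked <- rank_overlaps(ov, stats)
  expect_equal(ranked$rank, 1:3)
  # both score-8 overlaps tie; the longer one (15 cM) comes first
  expect_equal(ranked$start_cm[1], 30)
  expect_equal(ranked$max_neg_log10_p[1:2], c(8, 8))
  expect_equal(ranked$max_neg_log10_p[3], 3)
  # an overlap containing no scored SNP ranks last
  ranked2 <- rank_overlaps(ov, stats[-3, ])
  expect_equal(ranked2$max_neg_log10_p[3], -Inf)
})
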