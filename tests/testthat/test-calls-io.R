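test_that("native TSV round-trips losslessly, byte for byte", {
  calls <- toy_calls(c("AA", "AB", "BB", "NC", "AA"),
                     pos_cm = c(0.1, 0.5, 1.2, 2.0, 3.3), chrom = 22)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, f1)
  back <- read_calls(f1, sample_id = "toy")
  expect_s3_class(back, "qhm_calls")
  expect_equal(as.data.frame(back), as.data.frame(calls))
  expect_identical(attr(back, "sample_id"), "toy")
  write_calls(back, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("fuzzed tables survive the round trip", {
  set.seed(41)
  for (i in 1:20) {
    n <- sample(2:40, 1)
    calls <- random_track(n, L = sample(1:20, 1))
    f <- tempfile(fileext = ".tsv")
    write_calls(calls, f)
    expect_equal(as.data.frame(read_calls(f, sample_id = "toy")),
                 as.data.frame(calls))
    unlink(f)
  }
})

test_that("non-autosomal rows are dropped with a count, autosomes kept", {
  df <- data.frame(snp_id = c("a", "b", "c"), chrom = c("1", "X", "22"),
                   pos_bp = c(100, 200, 300), pos_cm = c(0.1, 0.2, 0.3),
                   call = c("AA", "AB", "BB"))
  expect_message(calls <- as_calls(df), "1 non-autosomal")
  expect_equal(nrow(calls), 2)
  expect_setequal(calls$chrom, c(1L, 22L))
})

test_that("malformed input is rejected with informative errors", {
  df <- data.frame(snp_id = c("a", "b"), chrom = 1, pos_bp = c(10, 20),
                   pos_cm = c(0.1, 0.2), call = c("AA", "ZZ"))
  expect_error(as_calls(df), "invalid call 'ZZ' at row 2")
  df2 <- data.frame(snp_id = c("a", "b"), chrom = 1, pos_bp = c(10, 10),
                    pos_cm = c(0.1, 0.2), call = c("AA", "BB"))
  expect_error(as_calls(df2), "duplicate pos_bp on chromosome 1")
  df3 <- data.frame(snp_id = c("a", "b"), chrom = 1, pos_bp = c(20, 10),
                    pos_cm = c(0.2, 0.1), call = c("AA", "BB"))
  expect_warning(calls <- as_calls(df3), "not sorted")
  expect_equal(calls$pos_bp, c(10, 20))
  f <- tempfile(fileext = ".tsv")
  writeLines(c("snp_id\tchrom\tpos_bp\tpos_cm\tcall",
               "a\t1\t100\t0.1\tAA",
               "b\t1\toops\t0.2\tBB"), f)
  expect_error(read_calls(f), "malformed pos_bp at line 3")
  unlink(f)
  expect_error(read_calls("/nonexistent/x.tsv"), "no such file")
})

test_that("plink-like map plus call column reads to the same table", {
  calls <- toy_calls(c("AA", "AB", "BB"), pos_cm = c(1, 2, 3), chrom = 7)
  mp <- tempfile(fileext = ".map")
  cl <- tempfile(fileext = ".txt")
  write.table(data.frame(calls$chrom, calls$snp_id, calls$pos_cm,
                         calls$pos_bp),
              mp, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  writeLines(calls$call, cl)
  back <- read_calls(mp, format = "plink", calls_path = cl,
                     sample_id = "toy")
  expect_equal(as.data.frame(back), as.data.frame(calls))
  writeLines(calls$call[-1], cl)
  expect_error(read_calls(mp, format = "plink", calls_path = cl),
               "does not match|lines but map")
  unlink(c(mp, cl))
})

test_that("zygosity counts skip no-calls", {
  calls <- toy_calls(c("AA", "AB", "NC", "BB", "AB"),
                     pos_cm = c(1, 2, 3, 4, 5))
  z <- zygosity_counts(calls)
  expect_equal(z$n_pt, 4)
  expect_equal(z$n_hom, 2)
  expect_equal(z$n_het, 2)
})

test_that("region BED output uses 0-based half-open coordinates", {
  seg <- as_segments(data.frame(chrom = 1, start_bp = 100, end_bp = 200,
                                start_cm = 0.1, end_cm = 0.25, n_snps = 3L,
                                kind = "RHS"))
  f <- tempfile(fileext = ".bed")
  write_regions(seg, f)
  lines <- readLines(f)
  expect_match(lines[1], "^#chrom\tstart_bp\tend_bp")
  expect_match(lines[2], "^1\t100\t200\t")
  back <- read_regions(f)
  expect_equal(as.data.frame(back), as.data.frame(seg))
  unlink(f)
})

test_that("an empty region set writes a header-only BED that reads back", {
  empty <- as_segments(data.frame(chrom = integer(), start_bp = numeric(),
                                  end_bp = numeric(), start_cm = numeric(),
                                  end_cm = numeric(), n_snps = integer(),
                                  kind = character()))
  f <- tempfile(fileext = ".bed")
  write_regions(empty, f)
  expect_length(readLines(f), 1)
  expect_equal(nrow(read_regions(f)), 0)
  unlink(f)
})

test_that("segment invariants are enforced", {
  base <- data.frame(chrom = 1, start_bp = 10, end_bp = 20, start_cm = 1,
                     end_cm = 2, n_snps = 1L, kind = "RHS")
  expect_error(as_segments(transform(base, end_bp = 10)), "end_bp")
  expect_error(as_segments(transform(base, end_cm = 0.5)), "end_cm")
  expect_error(as_segments(transform(base, kind = "weird")), "kind")
  two <- rbind(base, transform(base, start_bp = 15, end_bp = 30,
                               start_cm = 1.5, end_cm = 3))
  expect_error(as_segments(two), "overlapping")
})
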