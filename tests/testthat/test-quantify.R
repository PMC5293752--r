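test_that("FPKM matches the definitional formula and preserves zeros", {
  m <- matrix(c(10L, 0L, 5L, 7L), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ex <- compute_fpkm(m, lengths = c(g1 = 1000, g2 = 2000),
                     totals = c(1e6, 1e6))
  expect_equal(ex$fpkm["g1", "s1"], 10)            # 1e9 * 10 / (1e6 * 1000)
  expect_equal(ex$fpkm["g2", "s1"], 0)             # zero count -> zero FPKM
  expect_equal(ex$fpkm["g1", "s2"], 5)
  expect_true(all((ex$fpkm == 0) == (ex$counts == 0)))
})

test_that("FPKM is invariant to joint scaling of counts and totals", {
  set.seed(11)
  m <- matrix(rpois(60, 40), 20, 3,
              dimnames = list(paste0("g", 1:20), c("a", "b", "c")))
  L <- sample(500:3000, 20)
  f1 <- compute_fpkm(m, L)
  f2 <- compute_fpkm(2L * m, L, totals = 2 * colSums(m))
  expect_equal(f1$fpkm, f2$fpkm)
})

test_that("FPKM validation names the offending gene and sample", {
  m <- matrix(1L, 2, 2, dimnames = list(c("gA", "gB"), c("s1", "s2")))
  expect_error(compute_fpkm(m, lengths = c(0, 100)), "gA")
  expect_error(compute_fpkm(m, lengths = c(100, 100), totals = c(10, 0)),
               "s2")
})

test_that("fold-change calling includes the 2-fold boundary in both tails", {
  fpkm <- matrix(c(1, 2, 4, 2,
                   2, 1, 2, 2), 4, 2,
                 dimnames = list(paste0("g", 1:4), c("M0", "M10")))
  d <- call_degs(fpkm, "M10", "M0", pseudocount = 0, min_fpkm = 0)
  expect_equal(as.character(d$direction), c("up", "down", "down", "none"))
  expect_equal(d$log2fc, c(1, -1, -1, 0))  # FC exactly 2 (or 1/2) is called
  expect_true(all(table(d$direction) == c(up = 1, down = 2, none = 1)))
})

test_that("DEG calls are antisymmetric under condition swap", {
  set.seed(3)
  fpkm <- matrix(rexp(100, 1 / 20), 50, 2,
                 dimnames = list(paste0("g", 1:50), c("M0", "M10")))
  a <- call_degs(fpkm, "M10", "M0")
  b <- call_degs(fpkm, "M0", "M10")
  expect_equal(a$log2fc, -b$log2fc)
  expect_equal(a$direction == "up", b$direction == "down")
  ## up/down/none always partition the universe
  expect_equal(sum(table(a$direction)), nrow(fpkm))
})

test_that("zero-pseudocount division by zero is called up and flagged", {
  fpkm <- matrix(c(0, 5), 1, 2, dimnames = list("g1", c("M0", "M10")))
  d <- call_degs(fpkm, "M10", "M0", pseudocount = 0)
  expect_equal(as.character(d$direction), "up")
  expect_true(is.infinite(d$log2fc))
  expect_true(d$unstable)
})

test_that("the expressed-gene prefilter suppresses calls at trace FPKM", {
  fpkm <- matrix(c(0.01, 0.9), 1, 2, dimnames = list("g1", c("M0", "M10")))
  expect_equal(as.character(
    call_degs(fpkm, "M10", "M0", pseudocount = 0)$direction), "none")
  expect_equal(as.character(
    call_degs(fpkm, "M10", "M0", pseudocount = 0,
              min_fpkm = 0)$direction), "up")
})

test_that("DEG intersection returns shared and exclusive sets", {
  fa <- matrix(c(1, 1, 1, 4, 4, 1), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), c("M0", "M10")))
  fb <- matrix(c(1, 1, 1, 1, 4, 4), 3, 2,
               dimnames = list(c("g1", "g2", "g3"), c("M0", "M20")))
  a <- call_degs(fa, "M10", "M0")
  b <- call_degs(fb, "M20", "M0")
  ov <- intersect_degs(a, b)
  expect_equal(ov$co_up, "g2")
  expect_equal(ov$only_a_up, "g1")
  expect_equal(ov$only_b_up, "g3")
  expect_length(ov$co_down, 0)
  expect_error(intersect_degs(a, call_degs(fb[1:2, ], "M20", "M0")),
               "universe")
})

test_that("fraction_report rounds half-up to one decimal", {
  expect_equal(fraction_report(46, 51), 90.2)
  expect_equal(fraction_report(9, 51), 17.6)
  expect_equal(fraction_report(30, 120), 25.0)
  expect_equal(fraction_report(14, 120), 11.7)   # half-up: 11.666 -> 11.7
  expect_equal(fraction_report(0, 51), 0.0)
  expect_equal(fraction_report(1, 16), 6.3)      # 6.25 rounds up, not to even
  expect_equal(fraction_report(c(46, 9), c(51, 51)), c(90.2, 17.6))
  expect_error(fraction_report(1, 0), "positive")
  expect_error(fraction_report(5, 4))
})
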