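test_that("gap classes respect the 4 h and 72 h boundaries", {
  mk_mask <- function(len, total = 200L) {
    m <- matrix(FALSE, total, 1, dimnames = list(NULL, "PM2.5"))
    m[50:(50 + len - 1), 1] <- TRUE
    m
  }
  expect_equal(classify_gaps(mk_mask(4L))$class, "short")
  expect_equal(classify_gaps(mk_mask(5L))$class, "medium")
  expect_equal(classify_gaps(mk_mask(72L))$class, "medium")
  expect_equal(classify_gaps(mk_mask(73L))$class, "long")
  expect_equal(nrow(classify_gaps(matrix(FALSE, 50, 2))), 0L)
  g <- classify_gaps(mk_mask(10L))
  expect_equal(g$start, 50L)
  expect_equal(g$length, 10L)
})

test_that("short gaps forward fill; leading gap backward fills", {
  v <- cbind(PM2.5 = c(5, NA, NA, 8), X = c(1, 2, 3, 4))
  p <- fill_gaps(make_panel(v))
  expect_equal(p$values[, "PM2.5"], c(5, 5, 5, 8), ignore_attr = TRUE)
  v2 <- cbind(PM2.5 = c(NA, NA, 7, 8), X = 1:4)
  expect_message(p2 <- fill_gaps(make_panel(v2)), "backward")
  expect_equal(p2$values[, "PM2.5"], c(7, 7, 7, 8), ignore_attr = TRUE)
})

test_that("medium gaps: seeded imputation is deterministic and plausible", {
  set.seed(20)
  T_ <- 300L
  x <- 10 + 5 * sin(2 * pi * seq_len(T_) / 24)
  v <- cbind(PM2.5 = x + rnorm(T_, 0, 0.1), PM10 = 2 * x + rnorm(T_, 0, 0.1))
  v[100:130, "PM2.5"] <- NA  # 31 h: medium
  a <- fill_gaps(make_panel(v), seed = 3)
  b <- fill_gaps(make_panel(v), seed = 3)
  expect_identical(a$values, b$values)
  expect_false(anyNA(a$values))
  # regression on PM10 should land near the truth
  expect_lt(max(abs(a$values[100:130, "PM2.5"] - x[100:130])), 2)
  lin <- fill_gaps(make_panel(v), method = "linear")
  expect_false(anyNA(lin$values))
})

test_that("long gaps delete rows and record one segment boundary", {
  set.seed(21)
  v <- cbind(PM2.5 = runif(1000, 5, 50), X = runif(1000, 0, 1))
  v[301:400, "PM2.5"] <- NA  # 100 h: long
  p <- fill_gaps(make_panel(v))
  expect_equal(nrow(p$values), 900L)
  expect_equal(nrow(p$segments), 2L)
  expect_equal(p$segments$end[1] + 1L, p$segments$start[2])
  expect_equal(p$segments$end[2], 900L)
})

test_that("min-max scaler: example, round trip, degenerate feature, excursions", {
  v <- cbind(A = c(0, 25, 50, 100), B = c(1, 2, 3, 4))
  sc <- fit_scaler(v)
  expect_equal(apply_scaler(v, sc)[3, "A"], 0.5, ignore_attr = TRUE)
  set.seed(22)
  r <- matrix(runif(40, -5, 5), 10, 4, dimnames = list(NULL, letters[1:4]))
  sc2 <- fit_scaler(r)
  expect_equal(invert_scaler(apply_scaler(r, sc2), sc2), r)
  expect_error(fit_scaler(cbind(A = rep(3, 4), B = 1:4)), "A")
  # value outside the training range scales outside (0, 1) without error
  out <- apply_scaler(cbind(A = 200, B = 2), sc)
  expect_gt(out[1, "A"], 1)
  # scaled training rows attain both endpoints
  str_ <- apply_scaler(v, sc)
  expect_equal(range(str_[, "A"]), c(0, 1))
})

test_that("windowing: counts, 7:1:2 split, segment boundaries", {
  set.seed(23)
  v <- cbind(PM2.5 = runif(100, 1, 9), X = runif(100))
  wd <- split_and_window(make_panel(v), D = 10, tau = 5)
  expect_equal(nrow(wd$index), 86L)   # 100 - D - tau + 1

  v2 <- cbind(PM2.5 = runif(1000, 1, 9), X = runif(1000))
  wd2 <- split_and_window(make_panel(v2), D = 10, tau = 5)
  expect_equal(as.integer(table(wd2$row_split)[c("train", "val", "test")]),
               c(700L, 100L, 200L))
  # windows are labelled by their input end t
  expect_true(all(wd2$index$split == wd2$row_split[wd2$index$t]))

  # a deleted-segment boundary removes every window spanning it
  v3 <- cbind(PM2.5 = runif(1000, 1, 9), X = runif(1000))
  v3[501:600, "PM2.5"] <- NA
  p3 <- fill_gaps(make_panel(v3))
  wd3 <- split_and_window(p3, D = 10, tau = 5)
  seg_of <- integer(nrow(p3$values))
  for (s in seq_len(nrow(p3$segments))) {
    seg_of[p3$segments$start[s]:p3$segments$end[s]] <- s
  }
  for (i in seq_len(nrow(wd3$index))) {
    t <- wd3$index$t[i]
    expect_equal(length(unique(seg_of[(t - 9):(t + 5)])), 1L)
  }
})

test_that("window count equals the enumeration oracle on random gap layouts", {
  set.seed(24)
  for (rep in 1:100) {
    T_ <- sample(150:400, 1)
    D <- sample(5:15, 1); tau <- sample(2:8, 1)
    v <- cbind(PM2.5 = runif(T_, 1, 9), X = runif(T_))
    n_gaps <- sample(0:2, 1)
    for (g in seq_len(n_gaps)) {
      len <- sample(73:90, 1)
      if (len < T_ - 1) {
        s <- sample(T_ - len, 1)
        v[s:(s + len - 1), "PM2.5"] <- NA
      }
    }
    p <- fill_gaps(make_panel(v))
    got <- tryCatch(nrow(split_and_window(p, D = D, tau = tau)$index),
                    error = function(e) NA_integer_)
    if (is.na(got)) next  # degenerate scaler on a tiny retained split
    # oracle: enumerate every retained row and test window validity directly
    seg_of <- integer(nrow(p$values))
    for (s in seq_len(nrow(p$segments))) {
      seg_of[p$segments$start[s]:p$segments$end[s]] <- s
    }
    Tn <- nrow(p$values)
    want <- 0L
    for (t in seq_len(Tn)) {
      lo <- t - D + 1L; hi <- t + tau
      if (lo >= 1L && hi <= Tn &&
          length(unique(seg_of[lo:hi])) == 1L) want <- want + 1L
    }
    expect_equal(got, want)
  }
})
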