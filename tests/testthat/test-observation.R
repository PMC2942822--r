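make_full_dataset <- function(times = c(0.5, 2, 28), value = 6.25,
                              sd = 1, diet = "adequate") {
  comp <- compartment_names()
  tracer_dataset(
    expand.grid(organ = comp, time = times, stringsAsFactors = FALSE) |>
      transform(mean = value, sd = sd, n = 5),
    diet = diet)
}

test_that("scale_to_body propagates the product-rule SD", {
  expect_equal(scale_to_body(10, 0, 2, 0), list(mean = 20, sd = 0))
  r <- scale_to_body(10, 1, 2, 0.2)
  expect_equal(r$mean, 20)
  expect_equal(r$sd, sqrt(100 * 0.04 + 4 * 1 + 1 * 0.04))
  expect_equal(scale_to_body(0, 0, 5, 1), list(mean = 0, sd = 0))
  expect_error(scale_to_body(-1, 0, 2, 0), "non-negative")
})

test_that("product-rule SD matches brute-force Monte-Carlo", {
  set.seed(42)
  for (i in 1:20) {
    f <- runif(1, 1, 50); h <- runif(1, 0, 0.2 * f)
    w <- runif(1, 0.1, 10); s <- runif(1, 0, 0.2 * w)
    draws_f <- rnorm(2e5, f, h)
    draws_w <- rnorm(2e5, w, s)
    mc_sd <- sd(draws_f * draws_w)
    expect_equal(scale_to_body(f, h, w, s)$sd, mc_sd, tolerance = 0.02)
  }
})

test_that("intestinal segments combine by unweighted mean", {
  one <- data.frame(organ = "ileum", time = 3, mean = 4, sd = 1, n = 5)
  expect_equal(combine_intestinal_segments(one)$mean, 4)
  expect_equal(combine_intestinal_segments(one)$sd, 1)
  two <- data.frame(organ = c("ileum", "colon"), time = 3,
                    mean = c(4, 6), sd = c(1, 1), n = 5)
  r <- combine_intestinal_segments(two)
  expect_identical(r$organ, "intestine")
  expect_equal(r$mean, 5)
  expect_equal(r$sd, sqrt(2) / 2)
  three <- data.frame(organ = c("a", "b", "c"), time = 3, mean = 5,
                      sd = 0, n = 4)
  expect_equal(combine_intestinal_segments(three)$mean, 5)
  expect_equal(combine_intestinal_segments(three)$sd, 0)
  mixed <- data.frame(organ = c("a", "b"), time = c(3, 7), mean = 5,
                      sd = 0, n = 4)
  expect_error(combine_intestinal_segments(mixed), "one timepoint")
})

test_that("normalization rescales to the decaying whole-body total", {
  ds <- make_full_dataset(times = c(0.5, 28, 200))
  nd <- normalize_to_decaying_total(ds)
  for (t in unique(nd$time)) {
    expect_equal(sum(nd$mean[nd$time == t]), 100 * exp(-0.005 * t),
                 tolerance = 1e-9)
  }
  # one month of loss is about 13%; 200 days leaves 100/e
  expect_equal(sum(nd$mean[nd$time == 28]), 86.94, tolerance = 0.005)
  expect_equal(sum(nd$mean[nd$time == 200]), 100 * exp(-1),
               tolerance = 1e-9)
  expect_true(attr(nd, "normalized"))
})

test_that("normalization is idempotent and validates coverage", {
  ds <- make_full_dataset()
  nd <- normalize_to_decaying_total(ds)
  nd2 <- normalize_to_decaying_total(nd)
  expect_equal(nd$mean, nd2$mean, tolerance = 1e-12)
  expect_equal(nd$sd, nd2$sd, tolerance = 1e-12)
  # missing organ at a timepoint
  short <- tracer_dataset(ds[-1, ])
  expect_error(normalize_to_decaying_total(short), "cover")
  zero <- make_full_dataset(value = 0)
  expect_error(normalize_to_decaying_total(zero), "zero total")
})

test_that("clip_negative zeroes negative means only, and records them", {
  df <- data.frame(organ = c("spleen", "liver", "rbc"),
                   time = 1, mean = c(-0.3, 5, 0), sd = c(1, 1, 1),
                   n = 3)
  ds <- tracer_dataset(df, diet = "deficient")
  cl <- clip_negative(ds)
  expect_equal(cl$mean[cl$organ == "spleen"], 0)
  expect_equal(cl$sd, ds$sd)
  clipped <- attr(cl, "clipped")
  expect_identical(clipped$organ, "spleen")
  expect_equal(clipped$original, -0.3)
  # all-positive and exact-zero cells are untouched and unflagged
  pos <- clip_negative(tracer_dataset(transform(df, mean = abs(mean))))
  expect_identical(nrow(attr(pos, "clipped")), 0L)
})

test_that("dataset constructor validates structure", {
  df <- data.frame(organ = "liver", time = 1, mean = 5, sd = 1, n = 3)
  expect_s3_class(tracer_dataset(df), "fk_dataset")
  expect_error(tracer_dataset(rbind(df, df)), "one observation")
  expect_error(tracer_dataset(transform(df, sd = -1)), "sd")
  expect_error(tracer_dataset(transform(df, time = -1)), "time")
  expect_error(tracer_dataset(df[, -3]), "columns")
})

test_that("tracer CSV round-trips through the documented format", {
  ds <- make_full_dataset(times = c(1, 7))
  path <- withr::local_tempfile(fileext = ".csv")
  write_tracer_csv(ds, path)
  back <- read_tracer_csv(path)
  expect_equal(back$mean, ds$mean)
  expect_equal(back$time, ds$time)
  expect_identical(attr(back, "diet"), "adequate")
  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("diet,organ,time_days,mean_pct_dose,sd_pct_dose,n\nx,gizzard,1,1,1,3", bad)
  expect_error(read_tracer_csv(bad), "unknown organs")
})
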