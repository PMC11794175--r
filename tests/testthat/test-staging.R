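test_that("guideline worked examples stage as printed in the table", {
  s <- stage_from_measurements(as_measurements(vmax = 4.5, mpg = 50,
                                               ava = 0.8, calcified = TRUE))
  expect_equal(s$stage, "severe"); expect_true(s$concordant)

  s <- stage_from_measurements(as_measurements(vmax = 1.2, calcified = FALSE))
  expect_equal(s$stage, "normal"); expect_true(s$concordant)

  s <- stage_from_measurements(as_measurements(vmax = 1.8, calcified = TRUE))
  expect_equal(s$stage, "sclerosis"); expect_true(s$concordant)

  s <- stage_from_measurements(as_measurements(vmax = 2.5, mpg = 15,
                                               ava = 1.8))
  expect_equal(s$stage, "mild"); expect_true(s$concordant)

  # low mPG/high AVA are compatible with normal, not forced to mild
  s <- stage_from_measurements(as_measurements(vmax = 1.4, mpg = 6,
                                               ava = 3.2, calcified = FALSE))
  expect_equal(s$stage, "normal"); expect_true(s$concordant)
})

test_that("missing data degrades gracefully", {
  s <- stage_from_measurements(as_measurements())
  expect_equal(s$stage, "indeterminate")
  expect_true("insufficient_data" %in% s$flags)
  expect_false(s$concordant)

  # Vmax < 2 without a calcification flag: normal band, flagged
  s <- stage_from_measurements(as_measurements(vmax = 1.5))
  expect_equal(s$stage, "normal")
  expect_false(s$concordant)
  expect_true("insufficient_data" %in% s$flags)
})

test_that("discordance patterns raise the expected flags", {
  expect_equal(detect_discordance(as_measurements(vmax = 2.8, mpg = 25)),
               "mild_to_moderate")
  expect_equal(detect_discordance(as_measurements(vmax = 3.5, mpg = 30,
                                                  ava = 0.9)),
               "lflg_severe_pattern")
  expect_equal(detect_discordance(as_measurements(vmax = 4.2, mpg = 45,
                                                  ava = 0.9)),
               character())
  expect_equal(detect_discordance(as_measurements(vmax = 3.5, mpg = 45)),
               "moderate_to_severe")
  # fewer than two parameters: nothing to compare
  expect_equal(detect_discordance(as_measurements(vmax = 2.8)), character())
})

test_that("continuity equation and Bernoulli closed forms", {
  expect_equal(compute_ava_continuity(2.0, 20, 80), pi * 1^2 * 20 / 80)
  expect_equal(round(compute_ava_continuity(2.0, 20, 80), 4), 0.7854)
  expect_equal(round(compute_ava_continuity(2.2, 22, 110), 4), 0.7603)
  # vti_lvot == vti_av collapses to the LVOT area
  expect_equal(compute_ava_continuity(2.4, 31, 31), pi * 1.2^2)
  expect_error(compute_ava_continuity(0, 20, 80), "positive")

  expect_equal(bernoulli_pressure(4), 64)
  expect_equal(bernoulli_pressure(0), 0)
  expect_equal(bernoulli_pressure(5), 100)
  expect_error(bernoulli_pressure(-1), ">= 0")
})

test_that("severity bands tile their domains without gaps or overlaps", {
  v <- seq(0, 6, by = 0.001)
  bands <- vapply(v, function(x) severity_band(x, "vmax"), character(1))
  expect_true(all(bands[v < 2] == "sclerosis"))
  expect_true(all(bands[v >= 2 & v < 3] == "mild"))
  expect_true(all(bands[v >= 3 & v < 4] == "moderate"))
  expect_true(all(bands[v >= 4] == "severe"))

  g <- seq(0, 60, by = 0.001)
  gb <- vapply(g, function(x) severity_band(x, "mpg"), character(1))
  expect_true(all(gb[g < 20] == "mild"))
  expect_true(all(gb[g >= 20 & g < 40] == "moderate"))
  expect_true(all(gb[g >= 40] == "severe"))
})

test_that("staging matches the independent brute-force oracle on 10,000 tuples", {
  set.seed(99)
  n <- 10000
  vmax <- round(runif(n, 0, 6), 2); vmax[runif(n) < 0.25] <- NA
  mpg <- round(runif(n, 0, 70), 1); mpg[runif(n) < 0.25] <- NA
  ava <- round(runif(n, 0.2, 4), 2); ava[runif(n) < 0.25] <- NA
  calc <- sample(c(TRUE, FALSE, NA), n, replace = TRUE)
  got <- want <- vector("list", n)
  for (i in seq_len(n)) {
    s <- stage_from_measurements(as_measurements(
      vmax = vmax[i], mpg = mpg[i], ava = ava[i], calcified = calc[i]))
    o <- oracle_stage(vmax[i], mpg[i], ava[i], calc[i])
    got[[i]] <- c(s$stage, s$concordant, paste(s$flags, collapse = ";"))
    want[[i]] <- c(o$stage, o$concordant, paste(o$flags, collapse = ";"))
  }
  mismatch <- which(!vapply(seq_len(n),
                            function(i) identical(got[[i]], want[[i]]),
                            logical(1)))
  if (length(mismatch)) {
    i <- mismatch[1]
    fail(sprintf("%d/%d mismatches; first at i=%d (v=%s g=%s a=%s c=%s): got %s want %s",
                 length(mismatch), n, i, vmax[i], mpg[i], ava[i], calc[i],
                 paste(got[[i]], collapse = "/"),
                 paste(want[[i]], collapse = "/")))
  } else succeed()
})

test_that("raising a single parameter's band never lowers a concordant stage", {
  set.seed(7)
  bump <- list(vmax = 1.1, mpg = 21, ava = -0.55)
  for (rep in 1:400) {
    m <- list(vmax = round(runif(1, 0.5, 5.5), 2),
              mpg = round(runif(1, 1, 60), 1),
              ava = round(runif(1, 0.3, 3.5), 2),
              calcified = sample(c(TRUE, FALSE), 1))
    keep <- sample(c("vmax", "mpg", "ava"), sample(1:3, 1))
    args <- m
    for (p in setdiff(c("vmax", "mpg", "ava"), keep)) args[[p]] <- NA
    s0 <- stage_from_measurements(do.call(as_measurements, args))
    if (!s0$concordant) next
    for (p in keep) {
      args2 <- args
      args2[[p]] <- max(args[[p]] + bump[[p]], 0.1)
      s1 <- stage_from_measurements(do.call(as_measurements, args2))
      if (s1$concordant) {
        expect_gte(stage_ordinal(s1$stage), stage_ordinal(s0$stage))
      }
    }
  }
})

test_that("every input with any available parameter yields exactly one stage", {
  grid <- expand.grid(vmax = c(NA, 1, 2.5, 3.5, 4.5),
                      mpg = c(NA, 10, 30, 50),
                      ava = c(NA, 0.8, 1.2, 2),
                      calc = c(TRUE, FALSE, NA))
  for (i in seq_len(nrow(grid))) {
    s <- stage_from_measurements(as_measurements(
      vmax = grid$vmax[i], mpg = grid$mpg[i], ava = grid$ava[i],
      calcified = grid$calc[i]))
    expect_length(s$stage, 1)
    expect_true(s$stage %in% c(asckit:::AS_STAGES, "indeterminate"))
  }
})

test_that("batch staging mirrors row-wise staging", {
  df <- data.frame(vmax = c(4.5, 1.2, NA), mpg = c(50, NA, 25),
                   ava = c(0.8, NA, NA), calcified = c(TRUE, FALSE, NA))
  out <- stage_table(df)
  expect_equal(out$stage, c("severe", "normal", "moderate"))
  expect_equal(out$concordant, c(TRUE, TRUE, TRUE))
})
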