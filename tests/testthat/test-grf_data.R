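test_that("trial CSV round trip is the identity, including side tokens", {
  trials <- force_trials(
    subject_id = c("s1", "s1", "s2"),
    side = c("L", "right", "r"),
    trial_id = c("t1", "t1", "t1"),
    samples = list(c(0, 700, 0, 1), c(1, 2, 3, 4), c(10, 20, 30, 40)),
    bodyweight_n = c(700, 700, 650)
  )
  expect_equal(as.character(trials$side), c("left", "right", "right"))

  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(back$samples, trials$samples)
  expect_equal(as.character(back$side), as.character(trials$side))
  expect_equal(back$bodyweight_n, trials$bodyweight_n)

  # minimal one-trial file parses to the exact sample vector
  one <- read_trials(path)[1, ]
  expect_equal(one$samples[[1]], c(0, 700, 0, 1))
})

test_that("trial reader rejects malformed files with specific errors", {
  path <- withr::local_tempfile(fileext = ".csv")

  writeLines(c("subject_id,side,trial_id,sample_index,force_n,bodyweight_n",
               "s1,left,t1,0,1,700"), path)
  expect_error(read_trials(path), "sampling_rate_hz",
               class = "gaitsym_format_error")

  writeLines(c(paste("subject_id,side,trial_id,sample_index,force_n",
                     "bodyweight_n,sampling_rate_hz", sep = ","),
               "s1,left,t1,0,abc,700,400"), path)
  expect_error(read_trials(path), "non-numeric",
               class = "gaitsym_parse_error")

  writeLines(c(paste("subject_id,side,trial_id,sample_index,force_n",
                     "bodyweight_n,sampling_rate_hz", sep = ","),
               "s1,left,t1,0,1,700,400",
               "s1,left,t1,0,2,700,400"), path)
  expect_error(read_trials(path), "duplicate",
               class = "gaitsym_integrity_error")

  expect_error(read_trials(file.path(tempdir(), "nope.csv")),
               class = "gaitsym_io_error")
})

test_that("bodyweight normalization is exact and scale-equivariant", {
  tr <- force_trials("s", "left", "t", list(c(350, 700, 875, 0)),
                     bodyweight_n = 700)
  norm <- normalize_bodyweight(tr)
  expect_equal(norm$samples[[1]], c(50, 100, 125, 0))
  expect_equal(norm$units, "pct_bw")

  # doubling forces and bodyweight leaves the %BW curve unchanged
  tr2 <- force_trials("s", "left", "t", list(2 * c(350, 700, 875, 0)),
                      bodyweight_n = 1400)
  expect_equal(normalize_bodyweight(tr2)$samples[[1]], norm$samples[[1]])

  # negative sensor noise is clipped unless disabled
  tr3 <- force_trials("s", "left", "t", list(c(-5, 700, -3, 10)),
                      bodyweight_n = 700)
  expect_equal(normalize_bodyweight(tr3)$samples[[1]][c(1, 3)], c(0, 0))
  expect_lt(normalize_bodyweight(tr3, clip_negative = FALSE)$samples[[1]][1], 0)

  expect_error(normalize_bodyweight(norm), class = "gaitsym_domain_error")
})

test_that("stance segmentation keeps the longest run with one-sample margins", {
  as_pct <- function(samples) {
    tr <- force_trials("s", "left", "t", list(samples), bodyweight_n = 100)
    tr$units <- "pct_bw"
    tr
  }
  seg <- segment_stance(as_pct(c(0, 0, 50, 100, 60, 0)), 5)
  expect_equal(seg$samples[[1]], c(0, 50, 100, 60, 0))

  # brute-force oracle: scan all contiguous above-threshold runs
  brute <- function(s, thr) {
    runs <- rle(s >= thr)
    ends <- cumsum(runs$lengths); starts <- ends - runs$lengths + 1
    ok <- which(runs$values)
    best <- ok[which.max(runs$lengths[ok])]
    s[max(starts[best] - 1, 1):min(ends[best] + 1, length(s))]
  }
  withr::with_seed(11, {
    for (rep in 1:20) {
      s <- pmax(rnorm(30, 20, 30), 0)
      if (!any(s >= 5)) next
      got <- segment_stance(as_pct(s), 5)$samples[[1]]
      expect_equal(got, brute(s, 5))
    }
  })

  # padding amount does not change the cropped stance
  core <- c(10, 80, 110, 70, 9)
  a <- segment_stance(as_pct(c(0, core, 0)), 5)$samples[[1]]
  b <- segment_stance(as_pct(c(rep(0, 17), core, rep(0, 4))), 5)$samples[[1]]
  expect_equal(a, b)

  # entirely above threshold: nothing cropped
  expect_equal(segment_stance(as_pct(core), 5)$samples[[1]], core)

  expect_error(segment_stance(as_pct(rep(0, 10)), 5),
               class = "gaitsym_empty_stance_error")
})

test_that("time normalization yields 101 points matching closed forms", {
  mk <- function(samples) {
    tr <- force_trials("s", "right", "t", list(samples), bodyweight_n = 100)
    tr$units <- "pct_bw"
    tr
  }
  m <- pattern_matrix(time_normalize(mk(rep(7, 55))))
  expect_equal(unname(m[1, ]), rep(7, 101))

  ramp <- seq(0, 100, length.out = 41)
  m <- pattern_matrix(time_normalize(mk(ramp)))
  expect_equal(unname(m[1, ]), as.numeric(0:100))

  # 280-sample sine segment (0.7 s at 400 Hz) against direct evaluation;
  # the linear-interpolation error bound is max|f''| h^2 / 8 ~ 8e-4 here
  t_in <- seq(0, 1, length.out = 280)
  sine <- 60 + 50 * sin(pi * t_in)
  m <- pattern_matrix(time_normalize(mk(sine)))
  expect_lt(max(abs(m[1, ] - (60 + 50 * sin(pi * (0:100) / 100)))), 8e-4)

  # when the input grid contains the output grid (401 samples), the
  # interpolation is exact at the 101 query points
  t_al <- seq(0, 1, length.out = 401)
  m <- pattern_matrix(time_normalize(mk(60 + 50 * sin(pi * t_al))))
  expect_equal(unname(m[1, ]), 60 + 50 * sin(pi * (0:100) / 100),
               tolerance = 1e-9)

  # endpoints always equal the stance endpoints
  withr::with_seed(5, {
    s <- pmax(rnorm(73, 50, 20), 0)
    pat <- time_normalize(mk(s))
    expect_equal(ncol(pattern_matrix(pat)), 101)
    expect_equal(pattern_matrix(pat)[1, c(1, 101)],
                 c(v000 = s[1], v100 = s[73]))
    expect_equal(pat$label, 1L)
  })
})

test_that("pattern CSV round trip preserves values and enforces shape", {
  pat <- toy_pattern_cohort(5, seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_patterns(pat, path)
  back <- read_patterns(path)
  expect_equal(pattern_matrix(back), pattern_matrix(pat))
  expect_equal(back$label, pat$label)

  # truncated pattern table is refused
  broken <- pat[, -ncol(pat)]
  expect_error(write_patterns(broken, path), class = "gaitsym_format_error")

  # header-only file for an empty table round-trips to zero patterns
  write_patterns(pat[0, ], path)
  expect_equal(nrow(read_patterns(path)), 0)
})
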