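test_that("CSV dialect reads a single record and validates intervals", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("session_id,actor,onset_s,offset_s,code",
               "s1,child,2.0,5.0,engage"), f)
  s <- read_annotations(f)
  expect_s3_class(s, "coded_session")
  expect_equal(nrow(s$events), 1)
  expect_equal(s$events$onset, 2)
  expect_equal(s$duration, 5)

  writeLines(c("session_id,actor,onset_s,offset_s,code",
               "s1,child,5.0,2.0,engage"), f)
  expect_error(read_annotations(f), "inverted")

  writeLines(c("session_id,actor,onset_s,offset_s,code",
               "s1,child,1.0,2.0,frolic"), f)
  expect_error(read_annotations(f), "unknown code 'frolic' at data row 1")
})

test_that("write_annotations is lossless for fuzzed random sessions", {
  f <- withr::local_tempfile(fileext = ".csv")
  for (seed in 1:30) {
    set.seed(seed)
    n <- sample(0:12, 1)
    if (n > 0) {
      # non-overlapping even within actor/code: onsets spaced beyond max length
      onset <- cumsum(runif(n, 3.6, 8))
      len <- runif(n, 0.25, 3)
      ev <- data.frame(
        actor = sample(c("child", "caregiver"), n, replace = TRUE),
        code = sample(c("bid", "respond", "engage"), n, replace = TRUE),
        onset = onset, offset = onset + len
      )
    } else {
      ev <- data.frame(actor = character(), code = character(),
                       onset = numeric(), offset = numeric())
    }
    s <- coded_session(ev, duration = 200, session_id = paste0("fz", seed))
    write_annotations(s, f)
    s2 <- read_annotations(f, duration = 200)
    expect_equal(s2$events, s$events)
    # a header-only CSV carries no rows, hence no session id to recover
    if (nrow(ev) > 0) expect_equal(s2$session_id, s$session_id)
  }
})

test_that("empty session writes a header-only CSV", {
  f <- withr::local_tempfile(fileext = ".csv")
  s <- coded_session(data.frame(), duration = 5, session_id = "empty")
  write_annotations(s, f)
  expect_length(readLines(f), 1)
})

test_that("ELAN EAF tiers are mapped to actors via tier_map", {
  f <- withr::local_tempfile(fileext = ".eaf")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<ANNOTATION_DOCUMENT>',
    '<TIME_ORDER>',
    '<TIME_SLOT TIME_SLOT_ID="ts1" TIME_VALUE="1000"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts2" TIME_VALUE="3500"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts3" TIME_VALUE="4000"/>',
    '<TIME_SLOT TIME_SLOT_ID="ts4" TIME_VALUE="9000"/>',
    '</TIME_ORDER>',
    '<TIER TIER_ID="Kind">',
    '<ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a1" TIME_SLOT_REF1="ts1" TIME_SLOT_REF2="ts2">',
    '<ANNOTATION_VALUE>bid</ANNOTATION_VALUE></ALIGNABLE_ANNOTATION></ANNOTATION>',
    '</TIER>',
    '<TIER TIER_ID="Mutter">',
    '<ANNOTATION><ALIGNABLE_ANNOTATION ANNOTATION_ID="a2" TIME_SLOT_REF1="ts3" TIME_SLOT_REF2="ts4">',
    '<ANNOTATION_VALUE>engage</ANNOTATION_VALUE></ALIGNABLE_ANNOTATION></ANNOTATION>',
    '</TIER>',
    '</ANNOTATION_DOCUMENT>'
  ), f)
  s <- read_annotations(f, format = "eaf",
                        tier_map = c(Kind = "child", Mutter = "caregiver"))
  expect_equal(nrow(s$events), 2)
  expect_equal(s$events$actor, c("child", "caregiver"))
  expect_equal(s$events$onset, c(1, 4))
  expect_equal(s$events$offset, c(3.5, 9))
  expect_error(read_annotations(f, format = "eaf"), "tier_map")
})

test_that("validate_session returns violations as data", {
  ok <- coded_session(data.frame(actor = "child", code = "bid",
                                 onset = 0, offset = 2), duration = 10)
  expect_equal(nrow(validate_session(ok)), 0)

  bad <- coded_session(
    data.frame(actor = c("child", "child"), code = c("engage", "engage"),
               onset = c(0, 3), offset = c(5, 8)),
    duration = 10, validate = FALSE)
  v <- validate_session(bad)
  expect_true("same-actor overlap" %in% v$rule)

  oob <- coded_session(data.frame(actor = "child", code = "bid",
                                  onset = 8, offset = 12),
                       duration = 10, validate = FALSE)
  expect_true("out of bounds" %in% validate_session(oob)$rule)
})

test_that("rasterize applies the 50% coverage rule and code precedence", {
  s <- coded_session(data.frame(actor = "child", code = "engage",
                                onset = 0, offset = 10), duration = 10)
  fr <- rasterize(s)
  expect_equal(nrow(fr), 10)
  expect_true(all(fr$child == "engage"))
  expect_true(all(fr$caregiver == "idle"))

  # caregiver bid [2,4), caregiver engage [3,8): frame 3 takes engage
  s2 <- coded_session(
    data.frame(actor = "caregiver", code = c("bid", "engage"),
               onset = c(2, 3), offset = c(4, 8)), duration = 10)
  fr2 <- rasterize(s2)
  expect_equal(fr2$caregiver[fr2$frame == 2], "bid")
  expect_equal(fr2$caregiver[fr2$frame == 3], "engage")
  expect_equal(fr2$caregiver[fr2$frame == 7], "engage")
  expect_equal(fr2$caregiver[fr2$frame == 8], "idle")

  # sub-50% coverage does not label the frame; exactly 50% does
  s3 <- coded_session(data.frame(actor = "child", code = "bid",
                                 onset = c(0.6, 2.5), offset = c(1, 3.1)),
                      duration = 4)
  fr3 <- rasterize(s3)
  expect_equal(fr3$child, c("idle", "idle", "bid", "idle"))

  empty <- coded_session(data.frame(), duration = 5)
  fre <- rasterize(empty)
  expect_equal(nrow(fre), 5)
  expect_true(all(fre$child == "idle" & fre$caregiver == "idle"))
})

test_that("rasterize is length-exact and translation-equivariant on whole frames", {
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(1:8, 1)
    onset <- cumsum(runif(n, 4.2, 9))
    ev <- data.frame(actor = sample(c("child", "caregiver"), n, TRUE),
                     code = sample(c("bid", "respond", "engage"), n, TRUE),
                     onset = onset, offset = onset + runif(n, 0.3, 4))
    dur <- ceiling(max(ev$offset)) + sample(0:5, 1)
    s <- coded_session(ev, duration = dur)
    fr <- rasterize(s)
    expect_equal(nrow(fr), ceiling(dur / 1))

    k <- sample(1:5, 1)
    ev2 <- ev
    ev2$onset <- ev$onset + k
    ev2$offset <- ev$offset + k
    fr2 <- rasterize(coded_session(ev2, duration = dur + k))
    expect_equal(fr2$child[(k + 1):(k + nrow(fr))], fr$child)
    expect_equal(fr2$caregiver[(k + 1):(k + nrow(fr))], fr$caregiver)
    expect_true(all(fr2$child[seq_len(k)] == "idle"))
  }
})
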