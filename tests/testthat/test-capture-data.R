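test_that("collapse_history reduces secondary occasions to session detections", {
  des <- mini_design()
  ind <- make_ind("x", "A", cbind(c(2, 2, 4), c(1, 3, 5)), des)
  cl <- collapse_history(ind$enc)
  expect_equal(cl$detected, c(0L, 1L, 0L, 1L, 0L))
  expect_equal(cl$first, 2L)
  expect_equal(cl$last, 4L)

  one <- make_ind("y", "A", cbind(1, 1), des)
  cl1 <- collapse_history(one$enc)
  expect_equal(cl1$detected, c(1L, 0L, 0L, 0L, 0L))
  expect_equal(cl1$first, 1L)
  expect_equal(cl1$last, 1L)

  expect_equal(collapse_history(matrix(1L, 5, 5))$detected, rep(1L, 5))
  expect_error(collapse_history(matrix(0L, 5, 5)), "all-zero")
})

test_that("collapse is idempotent and invariant to within-session permutation", {
  des <- mini_design()
  set.seed(11)
  for (i in 1:20) {
    enc <- matrix(rbinom(25, 1, 0.3), 5, 5)
    if (sum(enc) == 0) enc[3, 2] <- 1L
    cl <- collapse_history(enc)
    # permute secondary occasions within each session
    perm <- enc[, sample(5), drop = FALSE]
    expect_identical(collapse_history(perm)$detected, cl$detected)
    # re-collapsing the session-level vector changes nothing
    expect_identical(collapse_history(matrix(cl$detected, ncol = 1))$detected,
                     cl$detected)
  }
})

test_that("rd_data validates encounter matrices and age classes", {
  des <- mini_design()
  ok <- make_ind("a", "A", cbind(1, 1), des)
  expect_s3_class(rd_data(des, list(ok)), "rd_data")
  bad_patch <- make_ind("b", "Z", cbind(1, 1), des)
  expect_error(rd_data(des, list(bad_patch)), "unknown patch")
  # adult before young is inconsistent with tooth-eruption ageing
  rev_age <- make_ind("c", "A", cbind(c(1, 3), c(1, 1)), des,
                      age = c("adult", "young"))
  expect_error(rd_data(des, list(rev_age)), "revert")
})

test_that("reduce_to_adults removes young encounters and never-adult animals", {
  des <- mini_design()
  mixed <- make_ind("m", "A", cbind(c(1, 3, 4, 5), c(1, 2, 2, 2)), des,
                    age = c("young", "adult", "adult", "adult"))
  only_young <- make_ind("y", "A", cbind(2, 2), des, age = "young")
  adult <- make_ind("a", "B", cbind(c(1, 2), c(1, 1)), des)
  d <- rd_data(des, list(mixed, only_young, adult))

  red <- reduce_to_adults(d)
  expect_setequal(names(red$individuals), c("m", "a"))
  expect_equal(collapse_history(red$individuals$m$enc)$detected,
               c(0L, 0L, 1L, 1L, 1L))

  # strict rule drops the ever-young animal entirely
  strict <- reduce_to_adults(d, drop_ever_young = TRUE)
  expect_setequal(names(strict$individuals), "a")

  # identity on a dataset without young
  d2 <- rd_data(des, list(adult))
  expect_equal(reduce_to_adults(d2)$individuals, d2$individuals)
})

test_that("reduce_to_adults never increases per-session counts", {
  tr <- rd_truth()
  d <- simulate_rd(tr, seed = 301)
  m_full <- mt1_per_session(d)
  m_adult <- mt1_per_session(reduce_to_adults(d))
  expect_true(all(m_adult <= m_full))
})

test_that("mt1_per_session counts distinct individuals per patch-session", {
  des <- mini_design()
  inds <- list(
    make_ind("i1", "A", cbind(c(1, 1), c(1, 2)), des),
    make_ind("i2", "A", cbind(1, 4), des),
    make_ind("i3", "A", cbind(1, 5), des))
  m <- mt1_per_session(rd_data(des, inds))
  expect_equal(unname(m["A", 1]), 3L)
  expect_equal(unname(m["A", 2:5]), rep(0L, 4))
  expect_equal(unname(m["B", ]), rep(0L, 5))
})

test_that("perfect detection makes M(t+1) equal the true alive count", {
  tr <- uniform_truth(n_patches = 2, N1 = 50, phi = 0.7, imm_rate = 3,
                      young_rate = 0, p = 1, c = 1)
  set.seed(99)
  roster <- simulate_population(tr)
  d <- simulate_detection(roster, tr)
  m <- mt1_per_session(d)
  for (g in 1:2) {
    pid <- tr$design$patches$patch_id[g]
    r <- roster[roster$patch_id == pid, ]
    alive <- vapply(1:5, function(t) sum(r$entry <= t & r$exit >= t),
                    numeric(1))
    expect_equal(unname(m[pid, ]), as.integer(alive))
  }
})

test_that("inp writing matches the format definition", {
  des <- rd_design(2, 2, data.frame(patch_id = "A", landscape = 50))
  ind <- make_ind("solo", "A", cbind(c(1, 2), c(1, 2)), des)
  path <- withr::local_tempfile(fileext = ".inp")
  write_inp(rd_data(des, list(ind)), path)
  line <- readLines(path)
  expect_length(line, 1)
  expect_match(line, "1001 1;$")
  expect_match(line, "id=solo")
})

test_that("inp and csv round trips are identities on the data model", {
  tr <- rd_truth()
  d <- simulate_rd(tr, seed = 77)
  expect_gt(n_individuals(d), 40)

  inp <- withr::local_tempfile(fileext = ".inp")
  write_inp(d, inp)
  d2 <- read_inp(inp, d$design)
  expect_equal(lapply(d2$individuals, `[[`, "enc"),
               lapply(d$individuals, `[[`, "enc"))
  expect_equal(lapply(d2$individuals, `[[`, "age"),
               lapply(d$individuals, `[[`, "age"))
  # write(read(x)) is byte-identical to write(x)
  inp2 <- withr::local_tempfile(fileext = ".inp")
  write_inp(d2, inp2)
  expect_identical(readLines(inp), readLines(inp2))

  csv <- withr::local_tempfile(fileext = ".csv")
  write_capture_csv(d, csv)
  d3 <- read_capture_csv(csv, d$design)
  expect_equal(lapply(d3$individuals, `[[`, "enc"),
               lapply(d$individuals, `[[`, "enc"))
})

test_that("inp parse errors name the offending line", {
  des <- rd_design(2, 2, data.frame(patch_id = "A", landscape = 50))
  path <- withr::local_tempfile(fileext = ".inp")
  writeLines(c("1001 1;", "10012 1;"), path)
  expect_error(read_inp(path, des), "line 2")
  writeLines("1021 1;", path)
  expect_error(read_inp(path, des), "non-binary")
  writeLines("1001 1", path)
  expect_error(read_inp(path, des), "semicolon")
  writeLines(character(0), path)
  expect_equal(n_individuals(read_inp(path, des)), 0)
})
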