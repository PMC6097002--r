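test_that("shift library templates follow the 1-based registry convention", {
  lib <- build_shift_library(4, 1)
  get <- function(orient, k)
    Filter(function(e) e$orientation == orient && e$k == k,
           lib$templates)[[1]]$template
  expect_equal(get("parallel", 0), diag(4), ignore_attr = TRUE)
  # parallel k = +1: ones one step above the diagonal
  tpl <- matrix(0L, 4, 4); tpl[cbind(1:3, 2:4)] <- 1L
  expect_equal(get("parallel", 1), tpl)
  # antiparallel k = 0: the exact reversal map (anti-diagonal)
  tpl <- matrix(0L, 4, 4); tpl[cbind(1:4, 4:1)] <- 1L
  expect_equal(get("antiparallel", 0), tpl)
})

test_that("shift library covers all alignments with SL - |k| entries each", {
  SL <- 9
  lib <- build_shift_library(SL)
  expect_equal(lib$k_max, SL - 3)
  keys <- vapply(lib$templates, function(e)
    paste(e$orientation, e$k), character(1))
  expect_equal(length(keys), length(unique(keys)))
  expect_equal(length(keys), 2 * (2 * (SL - 3) + 1))
  for (e in lib$templates)
    expect_equal(sum(e$template), SL - abs(e$k))
  expect_error(build_shift_library(9, 7), "k_max")
})

test_that("ncc matches the binary-matrix formula and its edge cases", {
  id4 <- diag(4)
  anti <- matrix(0, 4, 4); anti[cbind(1:4, 4:1)] <- 1
  expect_equal(ncc(id4, id4), 1.0)
  expect_equal(ncc(id4, anti), 0.0)      # disjoint supports
  # identity plus one stray: overlap 4, sums 5 and 4
  sub <- id4; sub[1, 3] <- 1
  expect_equal(ncc(sub, id4), 4 / sqrt(5 * 4))
  expect_null(ncc(matrix(0, 4, 4), id4)) # undefined for all-zero input
  expect_error(ncc(id4, diag(5)), "shape")
  # symmetry and invariance under simultaneous row/column permutation
  set.seed(1)
  for (rep in 1:20) {
    a <- matrix(rbinom(36, 1, 0.3), 6, 6)
    b <- matrix(rbinom(36, 1, 0.3), 6, 6)
    if (sum(a) == 0 || sum(b) == 0) next
    expect_equal(ncc(a, b), ncc(b, a))
    perm <- sample(6)
    expect_equal(ncc(a[perm, perm], b[perm, perm]), ncc(a, b))
  }
})

test_that("every library template matches itself with score 1", {
  for (SL in c(4, 7, 10)) {
    lib <- build_shift_library(SL)
    for (e in lib$templates) {
      m <- match_alignment(e$template, lib, min_contacts = 3)
      expect_equal(m$orientation, e$orientation)
      expect_equal(m$k, e$k)
      expect_equal(m$score, 1.0)
      expect_equal(m$contacts, SL - abs(e$k))
    }
  }
})

test_that("match_alignment equals the brute-force argmax on random matrices", {
  SL <- 7
  lib <- build_shift_library(SL)
  set.seed(123)
  for (rep in 1:200) {
    sub <- matrix(rbinom(SL * SL, 1, runif(1, 0.05, 0.4)), SL, SL)
    got <- match_alignment(sub, lib)
    want <- oracle_match(sub, lib)
    expect_equal(got, want)
  }
})

test_that("match_alignment applies the minimum-contact rule and tie-breaks", {
  lib <- build_shift_library(6)
  # 3 on-diagonal ones plus a stray: still parallel in-register
  sub <- matrix(0L, 6, 6); sub[cbind(1:3, 1:3)] <- 1L; sub[2, 5] <- 1L
  m <- match_alignment(sub, lib)
  expect_equal(m$orientation, "parallel")
  expect_equal(m$k, 0L)
  expect_equal(m$contacts, 3L)
  # only 2 contacts on the anti-diagonal: below the H-bond minimum
  sub <- matrix(0L, 6, 6); sub[cbind(1:2, 6:5)] <- 1L
  expect_null(match_alignment(sub, lib))
  expect_null(match_alignment(matrix(0L, 6, 6), lib))
  # symmetric ambiguity between +k and -k resolves to positive shift
  sub <- matrix(0L, 6, 6)
  sub[cbind(1:5, 2:6)] <- 1L; sub[cbind(2:6, 1:5)] <- 1L
  m <- match_alignment(sub, lib)
  expect_equal(m$orientation, "parallel")
  expect_equal(m$k, 1L)
})

test_that("ideal parallel sheet yields S-1 in-register interactions", {
  fx <- make_ideal_sheet(12, 32)
  bb <- build_bb_matrix(fx$frame, fx$topology)
  p <- build_p_matrix(bb)
  expect_equal(n_beta_interactions(p), 11)
  expect_true(all(p$entries$orientation == "parallel"))
  expect_true(all(p$entries$k == 0))
  expect_true(all(p$entries$contacts == 32))
  # zero BB -> all-null P
  gas <- make_random_gas(5, 6, box = 100, min_separation = 30, seed = 2)
  bb0 <- build_bb_matrix(gas$frame, gas$topology)
  expect_equal(n_beta_interactions(build_p_matrix(bb0)), 0)
})

test_that("alternating antiparallel shifts are recovered per pair", {
  fx <- make_ideal_sheet(3, 10, orientation = "antiparallel",
                         shift = c(1L, -1L))
  bb <- build_bb_matrix(fx$frame, fx$topology)
  p <- build_p_matrix(bb)
  expect_equal(n_beta_interactions(p), 2)
  expect_equal(p$entries$orientation, rep("antiparallel", 2))
  expect_equal(p$entries$k, c(1L, -1L))
})

test_that("p_entry transposition negates parallel shifts only", {
  fx <- make_ideal_sheet(3, 10, orientation = "parallel", shift = 2L)
  bb <- build_bb_matrix(fx$frame, fx$topology)
  p <- build_p_matrix(bb)
  e12 <- p_entry(p, 1, 2); e21 <- p_entry(p, 2, 1)
  expect_equal(e12$k, 2L)
  expect_equal(e21$k, -2L)
  fxa <- make_ideal_sheet(3, 10, orientation = "antiparallel", shift = 2L)
  pa <- build_p_matrix(build_bb_matrix(fxa$frame, fxa$topology))
  expect_equal(p_entry(pa, 1, 2)$k, p_entry(pa, 2, 1)$k)
  expect_null(p_entry(p, 1, 1))
})

test_that("beta-interaction count is invariant under strand relabeling", {
  set.seed(77)
  fx <- make_ideal_sheet(5, 8, orientation = "antiparallel", shift = 1L)
  bb <- build_bb_matrix(fx$frame, fx$topology)
  n0 <- n_beta_interactions(build_p_matrix(bb))
  for (rep in 1:3) {
    perm <- sample(5)
    # rebuild the frame with strands permuted
    coords <- fx$frame$coords
    newcoords <- coords
    for (s in 1:5)
      newcoords[((perm[s] - 1) * 8 + 1):(perm[s] * 8), ] <-
        coords[((s - 1) * 8 + 1):(s * 8), ]
    bbp <- build_bb_matrix(backbone_frame(newcoords), fx$topology)
    expect_equal(n_beta_interactions(build_p_matrix(bbp)), n0)
  }
})

test_that("shift profiles bin alignments with fractions summing to one", {
  fx <- make_ideal_sheet(12, 32)
  p <- build_p_matrix(build_bb_matrix(fx$frame, fx$topology))
  prof <- shift_profile(p)
  expect_equal(nrow(prof), 1)
  expect_equal(prof$count, 11L)
  expect_equal(prof$fraction, 1.0)
  expect_equal(dominant_orientation(prof), "parallel")
  # mixed registries
  fx2 <- make_ideal_sheet(4, 10, orientation = c("antiparallel",
                                                 "antiparallel",
                                                 "antiparallel"),
                          shift = c(1L, -1L, 1L))
  prof2 <- shift_profile(build_p_matrix(build_bb_matrix(fx2$frame,
                                                        fx2$topology)))
  expect_equal(sum(prof2$fraction), 1.0)
  expect_equal(sum(prof2$count), 3L)
  expect_equal(dominant_orientation(prof2), "antiparallel")
  # empty profile
  gas <- make_random_gas(4, 6, box = 100, min_separation = 30, seed = 4)
  prof0 <- shift_profile(build_p_matrix(build_bb_matrix(gas$frame,
                                                        gas$topology)))
  expect_equal(nrow(prof0), 0)
  expect_true(is.na(dominant_orientation(prof0)))
})
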