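test_that("degenerate single-point frames give all-zero distances", {
  f <- constant_frame(0, 0)
  expect_equal(unname(compute_deformation(f)), rep(0, 11))
  expect_equal(unname(compute_pose(f)), rep(0, 8))
})

test_that("distances are translation invariant and scale linearly", {
  f <- toy_frame()
  shifted <- landmark_frame(f$points + matrix(c(10, -3), 68, 2, byrow = TRUE))
  expect_equal(compute_deformation(shifted), compute_deformation(f))
  expect_equal(compute_pose(shifted), compute_pose(f))
  scaled <- landmark_frame(f$points * 2.5)
  expect_equal(compute_deformation(scaled), 2.5 * compute_deformation(f))
  expect_equal(compute_pose(scaled), 2.5 * compute_pose(f))
  expect_true(all(compute_deformation(f) >= 0))
})

test_that("mouth width equals the hand-computed corner distance", {
  f <- toy_frame(list(`61` = c(10, 50), `65` = c(40, 50)))
  expect_equal(unname(compute_deformation(f)["d_mw"]), 30)
  # outer-lip configuration uses the outer corners instead
  f2 <- toy_frame(list(`49` = c(0, 0), `55` = c(3, 4)))
  d2 <- compute_deformation(f2, default_mapping(lip = "outer"))
  expect_equal(unname(d2["d_mw"]), 5)
})

test_that("a bilaterally symmetric frame has equal left/right pose distances", {
  d <- compute_pose(toy_frame())  # the template is symmetric about x = 128
  expect_equal(unname(d["d_bbl"]), unname(d["d_bbr"]))
  expect_equal(unname(d["d_bel"]), unname(d["d_ber"]))
  expect_equal(unname(d["d_bnl"]), unname(d["d_bnr"]))
  expect_equal(unname(d["d_bml"]), unname(d["d_bmr"]))
})

test_that("a lateral boundary shift leaves the head-shake signature", {
  f <- toy_frame()
  pts <- f$points
  pts[1:17, 1] <- pts[1:17, 1] + 5  # head swings toward the subject's left
  g <- landmark_frame(pts)
  d0 <- compute_pose(f); d1 <- compute_pose(g)
  # boundary approaches the left-side components and recedes from the right
  expect_true(all(d1[c("d_bbl", "d_bel", "d_bnl", "d_bml")] <
                  d0[c("d_bbl", "d_bel", "d_bnl", "d_bml")]))
  expect_true(all(d1[c("d_bbr", "d_ber", "d_bnr", "d_bmr")] >
                  d0[c("d_bbr", "d_ber", "d_bnr", "d_bmr")]))
})

test_that("pose asymmetry changes sign under horizontal mirroring", {
  seq <- toy_sequence(4, seed = 9)
  f <- seq$frames[[1]]
  mir_pts <- f$points
  mir_pts[, 1] <- 256 - mir_pts[, 1]
  # mirroring swaps anatomical sides; re-index so groups keep their meaning
  rap <- default_rap_config()
  perm <- integer(68)
  perm[c(1:17)] <- 17:1
  perm[18:27] <- 27:18
  perm[28:31] <- 28:31
  perm[32:36] <- 36:32
  perm[37:42] <- c(46, 45, 44, 43, 48, 47)
  perm[43:48] <- c(40, 39, 38, 37, 42, 41)
  perm[49:60] <- c(55, 54, 53, 52, 51, 50, 49, 60, 59, 58, 57, 56)
  perm[61:68] <- c(65, 64, 63, 62, 61, 68, 67, 66)
  g <- landmark_frame(mir_pts[perm, ])
  d0 <- compute_pose(f); d1 <- compute_pose(g)
  asym0 <- d0[c("d_bbl", "d_bel", "d_bnl", "d_bml")] -
           d0[c("d_bbr", "d_ber", "d_bnr", "d_bmr")]
  asym1 <- d1[c("d_bbl", "d_bel", "d_bnl", "d_bml")] -
           d1[c("d_bbr", "d_ber", "d_bnr", "d_bmr")]
  expect_equal(unname(asym1), -unname(asym0), tolerance = 1e-10)
})

test_that("geometry_signals yields 19 aligned signals and propagates errors", {
  seq <- toy_sequence(5, fs = 25)
  sig <- geometry_signals(seq)
  expect_length(sig, 19)
  expect_true(all(lengths(sig) == 5))
  expect_equal(attr(sig, "fs"), 25)
  # constant sequence -> constant signals
  cseq <- landmark_sequence(list(template_face(), template_face()), fs = 30)
  csig <- geometry_signals(cseq)
  expect_true(all(vapply(csig, function(x) diff(range(x)) == 0, logical(1))))
  # synthetic pain mode closes the eyes relative to its matched neutral epoch
  p <- geometry_signals(synthetic_sequence(30, pain = TRUE, seed = 11))
  q <- geometry_signals(synthetic_sequence(30, pain = FALSE, seed = 11))
  expect_lt(mean(p$d_el), mean(q$d_el))
  # a missing group surfaces as a configuration error with the frame index
  bad <- default_mapping()
  bad$groups$mouth <- NULL
  expect_error(geometry_signals(seq, bad), "frame 0.*mouth")
})

test_that("hemiface selection partitions lateral features and keeps midline in both", {
  for (stream in c("dface", "dpose", "gradient", "lbptop")) {
    n_block <- if (stream == "lbptop") 177L else 48L
    n_units <- switch(stream, dface = 11L, dpose = 8L, gradient = 31L,
                      lbptop = 31L)
    whole <- hemiface_select(stream, "whole")
    left <- hemiface_select(stream, "left")
    right <- hemiface_select(stream, "right")
    expect_equal(whole, seq_len(n_block * n_units))
    expect_setequal(union(left, right), whole)
    both <- intersect(left, right)
    # the intersection is exactly the midline blocks
    mid_units <- if (stream %in% c("dface", "dpose")) {
      which(painface:::distance_side(
        if (stream == "dface") deformation_names() else pose_names()) == "mid")
    } else {
      which(default_rap_config()$side == "mid")
    }
    expect_equal(both, as.integer(unlist(lapply(mid_units, function(b)
      ((b - 1L) * n_block + 1L):(b * n_block)))))
  }
  expect_error(hemiface_select("dface", "top"))
})

test_that("mappings round-trip through YAML and gate missing groups", {
  m <- default_mapping()
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(groups = m$groups, distances = m$distances), path)
  m2 <- read_mapping(path)
  f <- toy_frame()
  expect_equal(compute_deformation(f, m2), compute_deformation(f))
  expect_equal(compute_pose(f, m2), compute_pose(f))
  bad <- list(groups = m$groups["brow_left"], distances = m$distances)
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(bad, path2)
  expect_error(compute_deformation(f, read_mapping(path2)), "missing")
  expect_error(read_mapping(withr::local_tempfile(fileext = ".yaml")), "not found")
})
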