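test_that("make_restraints applies the distance and separation rules", {
  # 5-residue toy with exactly 2 eligible pairs (sep >= 3, d <= 15)
  D <- matrix(20, 5, 5); diag(D) <- 0
  D[1, 4] <- D[4, 1] <- 9
  D[2, 5] <- D[5, 2] <- 14.5
  D[1, 2] <- D[2, 1] <- 5          # too close in sequence
  rs <- make_restraints(D)
  expect_equal(nrow(rs), 2L)
  expect_equal(rs$i, c(1L, 2L))
  expect_equal(rs$j, c(4L, 5L))
  # bound width 0.2 A (= +/- 0.1)
  expect_equal(rs$upper - rs$lower, rep(0.2, 2))
  expect_equal(rs$target - rs$lower, rep(0.1, 2))
  expect_true(all(rs$j - rs$i >= 3))
  expect_true(all(rs$target <= 15))
  # all distances > 15 -> empty set
  expect_equal(nrow(make_restraints(matrix(16, 4, 4))), 0L)
  # NA predictions skipped
  D2 <- D; D2[1, 4] <- D2[4, 1] <- NA
  expect_equal(nrow(make_restraints(D2)), 1L)
})

test_that("restraint generation only reads the upper triangle", {
  set.seed(81)
  D <- generate_structure(12, seed = 81)$distmap
  D2 <- D
  D2[lower.tri(D2)] <- 999
  expect_equal(as.data.frame(make_restraints(D)),
               as.data.frame(make_restraints(D2)))
})

test_that("make_subsets yields five nested subsets at the printed cutoffs", {
  set.seed(82)
  D <- generate_structure(20, seed = 82)$distmap
  subs <- make_subsets(D)
  expect_equal(names(subs), c("11", "12", "13", "14", "15"))
  expect_length(subs, 5L)
  sizes <- vapply(subs, nrow, 1L)
  expect_true(all(diff(sizes) >= 0))
  for (k in 1:4) {
    a <- paste(subs[[k]]$i, subs[[k]]$j)
    b <- paste(subs[[k + 1]]$i, subs[[k + 1]]$j)
    expect_true(all(a %in% b))
  }
  # scripted sizes: distances 10.5 / 11.5 / 14.5 at eligible pairs
  D3 <- matrix(20, 8, 8); diag(D3) <- 0
  D3[1, 4] <- D3[4, 1] <- 10.5
  D3[2, 6] <- D3[6, 2] <- 11.5
  D3[3, 8] <- D3[8, 3] <- 14.5
  s3 <- make_subsets(D3)
  expect_equal(nrow(s3[["11"]]), 1L)
  expect_equal(nrow(s3[["12"]]), 2L)
  expect_equal(nrow(s3[["15"]]), 3L)
})

test_that("violation_score sums bound violations", {
  coords <- matrix(c(0, 0, 0,
                     10, 0, 0,
                     10, 10, 0,
                     0, 10, 0), 4, 3, byrow = TRUE)
  D <- coords_to_distmap(coords)
  rs <- make_restraints(D, min_sep = 1, max_dist = 20)
  expect_equal(as.numeric(violation_score(coords, rs)), 0)
  # one restraint violated by exactly 0.5 A above upper
  rs2 <- rs[1, , drop = FALSE]
  rs2$lower <- rs2$lower - 10   # keep lower slack
  rs2$upper <- D[rs2$i, rs2$j] - 0.5
  expect_equal(as.numeric(violation_score(coords, rs2)), 0.5)
  # random model vs per-restraint loop oracle
  set.seed(83)
  st <- generate_structure(15, seed = 83)
  pred <- st$distmap + matrix(rnorm(225, sd = 0.3), 15, 15)
  pred <- (pred + t(pred)) / 2
  rs3 <- make_restraints(pmax(pred, 0))
  got <- as.numeric(violation_score(st$coords, rs3))
  oracle <- 0
  for (r in seq_len(nrow(rs3))) {
    d <- sqrt(sum((st$coords[rs3$i[r], ] - st$coords[rs3$j[r], ])^2))
    oracle <- oracle + max(0, rs3$lower[r] - d) + max(0, d - rs3$upper[r])
  }
  expect_equal(got, oracle, tolerance = 1e-12)
  # missing coordinates: skipped with warning
  cm <- st$coords; cm[3, ] <- NA
  expect_warning(v <- violation_score(cm, rs3), "skipped")
  expect_gte(as.numeric(v), 0)
})

test_that("violation_score is piecewise linear in a single coordinate", {
  coords <- matrix(c(0, 0, 0, 8, 0, 0), 2, 3, byrow = TRUE)
  rs <- make_restraints(matrix(c(0, 8, 8, 0), 2, 2), min_sep = 1)
  xs <- seq(7, 9, by = 0.01)
  vs <- vapply(xs, function(x) {
    co <- coords; co[2, 1] <- x
    as.numeric(violation_score(co, rs))
  }, numeric(1))
  # zero inside the bound window, linear slope 1 outside
  expect_equal(vs[xs >= 7.91 & xs <= 8.09], rep(0, sum(xs >= 7.91 & xs <= 8.09)),
               tolerance = 1e-9)
  out <- xs < 7.9 | xs > 8.1
  expect_equal(vs[out], pmax(0, 7.9 - xs[out]) + pmax(0, xs[out] - 8.1),
               tolerance = 1e-9)
})

test_that("cns tbl writer emits the golden dialect", {
  D <- matrix(99, 5, 5); diag(D) <- 0
  D[1, 4] <- D[4, 1] <- 8.25
  D[2, 5] <- D[5, 2] <- 12.5
  rs <- make_restraints(D)
  p <- tempfile(fileext = ".tbl")
  write_restraints(rs, p)
  expect_identical(readLines(p), c(
    "! distance restraints (CNS dialect: target dminus dplus)",
    "assign (resid 1 and name CB) (resid 4 and name CB) 8.25 0.10 0.10",
    "assign (resid 2 and name CB) (resid 5 and name CB) 12.50 0.10 0.10"))
  # empty set -> header only
  p2 <- tempfile(fileext = ".tbl")
  write_restraints(make_restraints(matrix(99, 5, 5)), p2)
  expect_length(readLines(p2), 1L)
  # tabular round trip
  p3 <- tempfile(fileext = ".tsv")
  write_restraints(rs, p3, format = "tabular")
  back <- utils::read.table(p3, header = TRUE)
  expect_equal(back$target, rs$target)
})

test_that("rr files round-trip through the bundled reader", {
  set.seed(84)
  sc <- matrix(runif(64), 8, 8); sc <- (sc + t(sc)) / 2
  p <- tempfile(fileext = ".rr")
  write_contacts_rr(sc, p, target = "T0999")
  back <- read_contacts_rr(p)
  expect_true(all(diff(back$score) <= 0))          # sorted descending
  expect_equal(back$lower, rep(0, nrow(back)))
  expect_equal(back$upper, rep(8, nrow(back)))
  for (r in sample(nrow(back), 5))   # scores serialized at 6 decimals
    expect_equal(back$score[r], sc[back$i[r], back$j[r]], tolerance = 1e-5)
  # empty scores -> header-only file parses to empty table
  p2 <- tempfile(fileext = ".rr")
  write_contacts_rr(matrix(0, 1, 1), p2)
  expect_equal(nrow(read_contacts_rr(p2)), 0L)
})

test_that("pdb writer/reader round-trip coordinates with glycine handling", {
  set.seed(85)
  st <- generate_structure(10, seed = 85)
  resn <- rep("ALA", 10); resn[4] <- "GLY"
  p <- tempfile(fileext = ".pdb")
  write_pdb_cb(st$coords, p, resnames = resn)
  back <- read_pdb_cb(p)
  expect_equal(back$coords, st$coords, tolerance = 1e-3)
  expect_equal(back$resname[4], "GLY")
  expect_equal(nrow(back$coords), 10L)
})
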