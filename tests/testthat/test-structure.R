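test_that("PDB fixtures round-trip through the parser with exact coordinates", {
  atoms <- tibble::tibble(
    chain = "A", resno = c(1L, 1L), resid = "CYS",
    atom = c("CB", "SG"), element = c("C", "S"),
    x = c(1.5, 0), y = c(-2.25, 0), z = c(3.125, 0), occupancy = 1)
  f <- tempfile(fileext = ".pdb")
  write_pdb(atoms, f)
  back <- read_structure(f)
  expect_equal(nrow(back), 2L)
  expect_equal(back$x[back$atom == "CB"], 1.5)
  expect_equal(back$y[back$atom == "CB"], -2.25)
  expect_equal(back$z[back$atom == "CB"], 3.125)
})

test_that("only the first MODEL is read", {
  f <- write_tmp(c(
    "MODEL        1",
    "ATOM      1  SG  CYS A   1       0.000   0.000   0.000  1.00  0.00           S",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  SG  CYS A   1       9.000   9.000   9.000  1.00  0.00           S",
    "ENDMDL"), ".pdb")
  m <- read_structure(f)
  expect_equal(nrow(m), 1L)
  expect_equal(m$x, 0)
})

test_that("alternate locations resolve to the highest occupancy", {
  f <- write_tmp(c(
    "ATOM      1  SG ACYS A   1       0.000   0.000   0.000  0.30  0.00           S",
    "ATOM      2  SG BCYS A   1       5.000   0.000   0.000  0.70  0.00           S"),
    ".pdb")
  m <- read_structure(f)
  expect_equal(nrow(m), 1L)
  expect_equal(m$x, 5)
})

test_that("malformed coordinates and ATOM-free files raise named errors", {
  bad <- write_tmp(c(
    "ATOM      1  SG  CYS A   1       0.000   0.000   0.000  1.00  0.00           S",
    "ATOM      2  NZ  LYS A   2      bad.00   0.000   0.000  1.00  0.00           N"),
    ".pdb")
  expect_error(read_structure(bad), "line 2.*x coordinate")
  empty <- write_tmp(c("HEADER    TEST", "END"), ".pdb")
  expect_error(read_structure(empty), "no ATOM records")
})

test_that("the parser agrees with bio3d on a fixture", {
  skip_if_not_installed("bio3d")
  f <- tempfile(fileext = ".pdb")
  write_pdb(btb_site_model(), f)
  ours <- read_structure(f)
  ref <- bio3d::read.pdb(f, verbose = FALSE)$atom
  expect_equal(nrow(ours), nrow(ref))
  ord <- order(ref$resno, ref$elety)
  ours2 <- ours[order(ours$resno, ours$atom), ]
  expect_equal(ours2$x, ref$x[ord])
  expect_equal(ours2$resno, ref$resno[ord])
})

test_that("a thiol-nitrogen pair at 3.6 A reports that distance", {
  atoms <- tibble::tibble(
    chain = "A", resno = c(151L, 135L), resid = c("CYS", "ARG"),
    atom = c("SG", "NH1"), element = c("S", "N"),
    x = 0, y = 0, z = c(0, 3.6), occupancy = 1)
  prox <- cys_basic_proximity(atoms, cutoff = 8)
  expect_equal(prox$distance, 3.6, tolerance = 1e-12)
  expect_equal(prox$basic_resno, 135L)
})

test_that("the synthetic BTB site reproduces the planted contact geometry", {
  m <- btb_site_model()
  prox12 <- cys_basic_proximity(m, chain = "A", cutoff = 12)
  c151 <- prox12[prox12$cys_resno == 151L, ]
  # nearest basic residue is the arginine at 3.6 A (guanidinium N to SG)
  expect_equal(c151$basic_resno[1], 135L)
  expect_equal(round(c151$distance[1], 1), 3.6)
  # all five planted basics inside 12 A; the distant control excluded
  expect_setequal(c151$basic_resno, c(129L, 131L, 135L, 150L, 154L))
  expect_true(all(diff(c151$distance) >= 0))
})

test_that("enlarging the cutoff never removes neighbors", {
  m <- btb_site_model()
  prev <- cys_basic_proximity(m, cutoff = 4)
  for (cutoff in c(6, 8, 10, 12)) {
    cur <- cys_basic_proximity(m, cutoff = cutoff)
    expect_true(all(paste(prev$basic_resno) %in% paste(cur$basic_resno)))
    prev <- cur
  }
})

test_that("distances are invariant under rigid rotation and translation", {
  m <- btb_site_model()
  set.seed(77)
  rot <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
  if (det(rot) < 0) rot[, 1] <- -rot[, 1]
  shift <- c(10, -5, 3)
  xyz <- as.matrix(m[, c("x", "y", "z")]) %*% t(rot)
  m2 <- m
  m2$x <- xyz[, 1] + shift[1]
  m2$y <- xyz[, 2] + shift[2]
  m2$z <- xyz[, 3] + shift[3]
  p1 <- cys_basic_proximity(m, cutoff = 12)
  p2 <- cys_basic_proximity(m2, cutoff = 12)
  expect_equal(p1$basic_resno, p2$basic_resno)
  expect_equal(p1$distance, p2$distance, tolerance = 1e-9)
})

test_that("cysteines without SG are skipped with a warning", {
  atoms <- tibble::tibble(
    chain = "A", resno = c(1L, 2L), resid = c("CYS", "LYS"),
    atom = c("CB", "NZ"), element = c("C", "N"),
    x = c(0, 1), y = 0, z = 0, occupancy = 1)
  expect_warning(res <- cys_basic_proximity(atoms, cutoff = 8), "lacks an SG")
  expect_equal(nrow(res), 0L)
  # but the all-atom metric still measures it
  res2 <- cys_basic_proximity(atoms, cutoff = 8, metric = "all-atom")
  expect_equal(res2$distance, 1)
  expect_error(cys_basic_proximity(atoms, chain = "Z"), "not in structure")
})
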