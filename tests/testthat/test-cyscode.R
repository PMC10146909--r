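test_that("reference positions map to their alignment columns and back", {
  aln <- suppressWarnings(aln_from(ref = "A-CD", other = "ABCD"))
  map <- map_reference_positions(aln, "ref")
  expect_equal(map$position, 1:3)
  expect_equal(map$column, c(1L, 3L, 4L))
  expect_equal(col_to_pos(map, pos_to_col(map, 1:3)), 1:3)
  # gap-free reference: identity
  map2 <- map_reference_positions(aln, "other")
  expect_equal(map2$column, 1:4)
  expect_error(map_reference_positions(aln, "nope"), "unknown reference")
})

test_that("group conservation calls follow the presence thresholds", {
  rows <- c(rep("C", 10))
  aln <- cbind(matrix(rows, ncol = 1))
  rownames(aln) <- paste0("g", 1:10)
  res <- classify_group_conservation(aln, 1, rownames(aln))
  expect_equal(res$call, "Yes")
  expect_equal(res$presence, 1.0)
  # monotone in p: No <= Partially <= Yes as presence grows
  calls <- vapply(c(0, 4, 6, 8, 9, 10), function(k) {
    a <- matrix(c(rep("C", k), rep("A", 10 - k)), ncol = 1)
    rownames(a) <- paste0("g", 1:10)
    classify_group_conservation(a, 1, rownames(a))$call
  }, "")
  expect_equal(calls, c("No", "No", "Partially", "Partially", "Yes", "Yes"))
})

test_that("poorly aligned groups are NotAlignable", {
  a <- matrix(c(rep("-", 6), rep("C", 4)), ncol = 1)
  rownames(a) <- paste0("g", 1:10)
  res <- classify_group_conservation(a, 1, rownames(a), alignable = 0.5)
  expect_equal(res$call, "NotAlignable")
  expect_true(is.na(res$presence))
})

test_that("the reference-specific and family-wide cysteine patterns separate", {
  # 40 rows: reference group (2 rows) carries C only at column 1; the other
  # 38 rows carry C only at column 2
  ref_grp <- paste0("r", 1:2)
  fam <- paste0("f", 1:38)
  aln <- rbind(matrix(rep(c("C", "A"), 2), nrow = 2, byrow = TRUE),
               matrix(rep(c("A", "C"), 38), nrow = 38, byrow = TRUE))
  rownames(aln) <- c(ref_grp, fam)
  # column 1: reference group Yes, family No
  c1_ref <- classify_group_conservation(aln, 1, ref_grp)
  c1_fam <- classify_group_conservation(aln, 1, rownames(aln))
  expect_equal(c(c1_ref$call, c1_fam$call), c("Yes", "No"))
  # column 2: reference group No, family Yes (38/40 = 0.95)
  c2_ref <- classify_group_conservation(aln, 2, ref_grp)
  c2_fam <- classify_group_conservation(aln, 2, rownames(aln))
  expect_equal(c(c2_ref$call, c2_fam$call), c("No", "Yes"))
})

test_that("basic flank scan flags cysteines with H/K/R in the window", {
  expect_true(basic_flank_scan("ACK")$has_basic)
  expect_false(basic_flank_scan("ACA")$has_basic)
  # boundary truncation: C at position 1
  edge <- basic_flank_scan("CK")
  expect_equal(edge$position, 1L)
  expect_true(edge$has_basic)
  # sorted by position, one row per cysteine
  multi <- basic_flank_scan("CACRCAAC")
  expect_equal(multi$position, c(1L, 3L, 5L, 8L))
  expect_equal(multi$has_basic, c(FALSE, TRUE, TRUE, FALSE))
})

test_that("widening the flank window never unflags a cysteine", {
  set.seed(33)
  for (k in 1:5) {
    s <- paste(sample(c("A", "C", "K", "R", "H", "S", "T", "G"), 60,
                      replace = TRUE), collapse = "")
    flagged_prev <- integer(0)
    for (w in 1:4) {
      scan <- basic_flank_scan(s, window = w)
      flagged <- scan$position[scan$has_basic]
      expect_true(all(flagged_prev %in% flagged))
      flagged_prev <- flagged
    }
  }
})

test_that("motif scans report all matches including overlaps", {
  krr <- motif_scan("AKRRA", motif_pattern("KRR", "KRR"))
  expect_equal(krr$start, 2L)
  expect_equal(krr$end, 4L)
  # overlapping matches
  aa <- motif_scan("AAAA", motif_pattern("AA", "AA"))
  expect_equal(aa$start, 1:3)
  # class tokens: large hydrophobic, wildcard, exact
  phixe <- motif_scan("GGMSEGG", motif_pattern("phi-xE", "hxE"))
  expect_equal(phixe$start, 3L)
  expect_equal(phixe$match, "MSE")
  # basic class and bracket sets
  expect_equal(motif_scan("AHA", motif_pattern("bA", "bA"))$start, 2L)
  expect_equal(motif_scan("AHA", motif_pattern("set", "[HKR]A"))$start, 2L)
  expect_equal(nrow(motif_scan("AAAA", motif_pattern("KRR", "KRR"))), 0L)
  expect_error(motif_pattern("bad", "K"), "at least 2")
  expect_error(motif_pattern("bad", "K1R"), "invalid pattern token")
})

test_that("the cysteine report reproduces the planted code exactly", {
  fam <- generate_family(family_config(seed = 11, cys_plan = standard_cys_plan()))
  rep <- build_cysteine_report(fam$alignment, fam$truth$reference,
                               fam$truth$clades)
  truth <- fam$truth$cysteines
  planted_ref <- truth[truth$reference_has_c, ]
  # every reference cysteine appears exactly once
  expect_equal(sort(rep$cysteines$position), sort(planted_ref$column))
  expect_equal(anyDuplicated(rep$cysteines$position), 0L)
  got <- rep$cysteines[match(planted_ref$column, rep$cysteines$position), ]
  expect_equal(got$in_reference_group, planted_ref$expected_reference_group)
  expect_equal(got$in_family, planted_ref$expected_family)
  expect_equal(got$basic_flank, planted_ref$basic_flank)
  # family cysteine columns absent from the reference land in the extra
  # section with the clades that carry them
  absent <- truth[!truth$reference_has_c, ]
  expect_true(all(absent$column %in% rep$extra_columns$column))
})

test_that("the report is invariant to alignment row order", {
  fam <- generate_family(family_config(n_clades = 3, taxa_per_clade = 4,
                                       length = 120, seed = 12,
                                       cys_plan = tibble::tibble(
                                         column = 40L, scope = "clade:1",
                                         fraction = 1.0, reference = TRUE,
                                         basic_flank = FALSE)))
  r1 <- build_cysteine_report(fam$alignment, fam$truth$reference,
                              fam$truth$clades)
  set.seed(5)
  perm <- sample(nrow(fam$alignment))
  r2 <- build_cysteine_report(fam$alignment[perm, ], fam$truth$reference,
                              fam$truth$clades)
  expect_equal(r1$cysteines, r2$cysteines)
  expect_equal(r1$extra_columns, r2$extra_columns)
})

test_that("degenerate partitions collapse clade and family calls", {
  fam <- generate_family(family_config(n_clades = 2, taxa_per_clade = 4,
                                       length = 100, seed = 14,
                                       cys_plan = tibble::tibble(
                                         column = 30L, scope = "family",
                                         fraction = 1.0, reference = TRUE,
                                         basic_flank = FALSE)))
  one_clade <- tibble::tibble(id = rownames(fam$alignment), clade = "all")
  rep <- build_cysteine_report(fam$alignment, fam$truth$reference, one_clade)
  expect_equal(rep$cysteines$in_clade, rep$cysteines$in_family)
  expect_equal(rep$cysteines$presence_clade, rep$cysteines$presence_family)
})

test_that("a cysteine-free reference gives an empty main section", {
  aln <- aln_from(ref = "ADEF", x = "ACEF", y = "ACEF")
  clades <- tibble::tibble(id = rownames(aln), clade = "1")
  rep <- build_cysteine_report(aln, "ref", clades)
  expect_equal(nrow(rep$cysteines), 0L)
  expect_equal(glance(rep)$n_cysteines, 0L)
})

test_that("domain labels and annotations join onto the report", {
  aln <- aln_from(ref = "ACDEFC", x = "ACDEFC", y = "ACDEFC")
  clades <- tibble::tibble(id = rownames(aln), clade = "1")
  domains <- tibble::tibble(domain = c("BTB", "Kelch1"),
                            start = c(1L, 5L), end = c(3L, 6L))
  ann <- tibble::tibble(position = 2L, studied = "+")
  rep <- build_cysteine_report(aln, "ref", clades, domains = domains,
                               annotations = ann)
  expect_equal(rep$cysteines$domain, c("BTB", "Kelch1"))
  expect_equal(rep$cysteines$studied, c("+", NA))
})

test_that("cysteine spacing is the successive difference of positions", {
  sp <- cysteine_spacing(c(14, 38, 151))
  expect_equal(sp$spacing, c(24L, 113L))
  expect_equal(nrow(cysteine_spacing(7)), 0L)
})
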