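test_that("zero branch lengths copy the root into every taxon", {
  fam <- generate_family(family_config(n_clades = 3, taxa_per_clade = 3,
                                       length = 50, inter_clade = 0,
                                       intra_clade = 0, p_ultra = 0,
                                       p_conservative = 0, p_weak = 0,
                                       seed = 1))
  seqs <- unique(fam$records$seq)
  expect_equal(length(seqs), 1L)
})

test_that("generation is deterministic given the seed", {
  cfg <- family_config(n_clades = 2, taxa_per_clade = 3, length = 200,
                       seed = 42, cys_plan = standard_cys_plan()[3, ])
  f1 <- generate_family(cfg)
  f2 <- generate_family(cfg)
  expect_identical(f1$alignment, f2$alignment)
  expect_identical(f1$truth$cysteines, f2$truth$cysteines)
  f3 <- generate_family(family_config(n_clades = 2, taxa_per_clade = 3,
                                      length = 80, seed = 43))
  expect_false(identical(f1$alignment, f3$alignment))
})

test_that("planted conservation classes are recovered by column profiling", {
  fam <- generate_family(family_config(seed = 21))
  planted <- fam$truth$columns[fam$truth$columns$class != "free", ]
  prof <- column_profile(fam$alignment, planted$column)
  expect_equal(prof$class, planted$class)
  expect_equal(prof$top_residue, planted$top_residue)
  expect_equal(prof$rank, planted$rank, tolerance = 1e-12)
})

test_that("planted cysteine classifications at {1.0, 0.7, 0.0} recover exactly", {
  plan <- tibble::tibble(
    column = c(40L, 70L, 100L),
    scope = c("family", "family", "clade:2"),
    fraction = c(1.0, 0.7, 0.0),
    reference = c(TRUE, TRUE, TRUE),
    basic_flank = FALSE)
  fam <- generate_family(family_config(seed = 31, cys_plan = plan))
  rep <- build_cysteine_report(fam$alignment, fam$truth$reference,
                               fam$truth$clades, yes = 0.9, partial = 0.5)
  got <- rep$cysteines[match(plan$column, rep$cysteines$position), ]
  expect_equal(got$in_family, c("Yes", "Partially", "No"))
  expect_equal(got$presence_family,
               fam$truth$cysteines$presence_family, tolerance = 1e-12)
})

test_that("planted motifs are always found; false positives stay at chance", {
  fam <- generate_family(family_config(seed = 51,
                                       motif_plan = standard_motif_plan()))
  truth <- fam$truth$motifs
  pi <- jtt_model()$pi
  class_prob <- function(tk) {
    if (tk == "x") 1
    else if (tk == "b") sum(pi[c("H", "K", "R")])
    else if (tk == "h") sum(pi[c("L", "I", "V", "M", "F")])
    else pi[[tk]]
  }
  n_extra <- 0
  expected_extra <- 0
  for (nm in unique(truth$name)) {
    rows <- truth[truth$name == nm, ]
    pat <- motif_pattern(nm, rows$pattern[1])
    p_match <- prod(vapply(pat$tokens, class_prob, 0))
    for (k in seq_len(nrow(rows))) {
      hits <- motif_scan(fam$alignment[rows$id[k], ], pat)
      expect_true(rows$start[k] %in% hits$start)  # zero false negatives
      n_extra <- n_extra + sum(hits$start != rows$start[k])
      expected_extra <- expected_extra +
        (ncol(fam$alignment) - pat$length) * p_match
    }
  }
  # false positives stay at the chance level implied by the equilibrium
  # residue frequencies (generous 2x + slack bound for one fixed seed)
  expect_lt(n_extra, 2 * expected_extra + 10)
})

test_that("corruption with zero gap fraction is the identity", {
  fam <- generate_family(family_config(n_clades = 2, taxa_per_clade = 3,
                                       length = 60, seed = 3))
  out <- corrupt_alignment(fam$alignment, 0, seed = 1)
  expect_identical(out$alignment, fam$alignment)
  expect_equal(nrow(out$mask), 0L)
})

test_that("different seeds give different gap masks", {
  fam <- generate_family(family_config(n_clades = 2, taxa_per_clade = 3,
                                       length = 60, seed = 3))
  m1 <- corrupt_alignment(fam$alignment, 0.3, seed = 1)$mask
  m2 <- corrupt_alignment(fam$alignment, 0.3, seed = 2)$mask
  expect_false(identical(m1, m2))
})

test_that("gapping one clade's region makes it NotAlignable there", {
  plan <- tibble::tibble(column = 30L, scope = "family", fraction = 1.0,
                         reference = TRUE, basic_flank = FALSE)
  fam <- generate_family(family_config(n_clades = 2, taxa_per_clade = 5,
                                       length = 60, seed = 9,
                                       cys_plan = plan))
  clade2 <- fam$truth$clades$id[fam$truth$clades$clade == "2"]
  out <- corrupt_alignment(fam$alignment, 0.9, seed = 4, rows = clade2,
                           columns = 25:35)
  res <- classify_group_conservation(out$alignment, 30L, clade2)
  expect_equal(res$call, "NotAlignable")
  # the other clade still calls Yes
  clade1 <- setdiff(rownames(fam$alignment), clade2)
  expect_equal(classify_group_conservation(out$alignment, 30L, clade1)$call,
               "Yes")
})

test_that("infeasible plans are rejected", {
  dup <- tibble::tibble(column = c(10L, 10L), scope = "family",
                        fraction = 1.0, reference = TRUE, basic_flank = FALSE)
  expect_error(generate_family(family_config(cys_plan = dup)), "infeasible")
  clash <- tibble::tibble(column = c(10L, 11L), scope = "family",
                          fraction = 1.0, reference = TRUE,
                          basic_flank = c(TRUE, FALSE))
  expect_error(generate_family(family_config(cys_plan = clash)), "infeasible")
  motif_clash <- tibble::tibble(name = "KRR", pattern = "KRR",
                                scope = "family", start = 9L)
  expect_error(generate_family(family_config(
    cys_plan = dup[1, ], motif_plan = motif_clash)), "infeasible")
})

test_that("NJ on the emitted alignment recovers the planted clades", {
  ok <- 0L
  for (s in 1:5) {
    fam <- generate_family(family_config(seed = 100 + s))
    tr <- neighbor_joining(jtt_distance_matrix(fam$alignment))
    mono <- all(vapply(unique(fam$truth$clades$clade), function(cl) {
      ape::is.monophyletic(tr, fam$truth$clades$id[fam$truth$clades$clade == cl])
    }, TRUE))
    ok <- ok + mono
  }
  expect_gte(ok, 4L)
})
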