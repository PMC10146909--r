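# Tree building: maximum-likelihood JTT pairwise distances, neighbor-joining
# with deterministic tie-breaking, bootstrap support, conserved-block
# selection, Newick I/O.

# coerce a row spec (string or character vector) to single characters
as_residue_chars <- function(x) {
  if (length(x) == 1L && nchar(x) > 1L) strsplit(x, "")[[1]] else as.character(x)
}

# counts of aligned residue pairs over comparable sites, indexed to match
# as.vector(P): idx = code_a + (code_b - 1) * 20
pair_pattern_counts <- function(code_a, code_b) {
  ok <- !is.na(code_a) & !is.na(code_b)
  if (!any(ok)) return(NULL)
  tabulate(code_a[ok] + (code_b[ok] - 1L) * 20L, nbins = 400L)
}

jtt_distance_from_counts <- function(counts, t_max = 10, tol = 1e-6) {
  nz <- which(counts > 0L)
  # no off-diagonal pattern -> identical over comparable sites
  if (all(((nz - 1L) %% 20L) + 1L == ((nz - 1L) %/% 20L) + 1L)) return(0)
  cnz <- counts[nz]
  nll <- function(t) {
    p <- as.vector(jtt_prob(t))[nz]
    -sum(cnz * log(pmax(p, 1e-300)))
  }
  opt <- optimize(nll, interval = c(0, t_max), tol = tol)
  d <- opt$minimum
  if (t_max - d < 1e-3) {
    warn(sprintf("JTT distance saturated; reporting t_max = %g", t_max))
    return(t_max)
  }
  d
}

#' Maximum-likelihood JTT distance between two aligned rows
#'
#' Finds the evolutionary time t (expected substitutions per site) that
#' maximizes the likelihood of the aligned residue pairs under the JTT
#' model, `sum(log(pi_a * P_ab(t)))`, by derivative-free optimization on
#' `[0, t_max]`. Sites where either row carries a gap or `X` are removed
#' (pairwise deletion); rates are uniform across sites. Saturated pairs are
#' reported as `t_max` with a warning.
#'
#' @param row_a,row_b Aligned sequences (strings or character vectors of
#'   equal length).
#' @param columns Optional increasing column indices restricting the
#'   comparison (e.g. a conserved-block selection).
#' @param t_max Upper bound of the time search.
#' @param tol Optimization tolerance on t.
#' @return The distance in expected substitutions per site.
#' @export
jtt_distance <- function(row_a, row_b, columns = NULL, t_max = 10, tol = 1e-6) {
  a <- as_residue_chars(row_a)
  b <- as_residue_chars(row_b)
  if (length(a) != length(b)) abort("rows differ in length")
  if (!is.null(columns)) {
    stopifnot(all(columns >= 1L), all(columns <= length(a)))
    a <- a[columns]; b <- b[columns]
  }
  counts <- pair_pattern_counts(aa_code(a), aa_code(b))
  if (is.null(counts)) abort("no shared sites")
  jtt_distance_from_counts(counts, t_max = t_max, tol = tol)
}

#' Pairwise JTT distance matrix for an alignment
#'
#' @param aln Alignment matrix (see [as_alignment()]).
#' @inheritParams jtt_distance
#' @return A symmetric numeric matrix with taxa ids as dimnames.
#' @export
jtt_distance_matrix <- function(aln, columns = NULL, t_max = 10, tol = 1e-6) {
  if (is.null(columns)) columns <- seq_len(ncol(aln))
  codes <- matrix(aa_code(aln[, columns, drop = FALSE]), nrow = nrow(aln))
  n <- nrow(aln)
  d <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      counts <- pair_pattern_counts(codes[i, ], codes[j, ])
      if (is.null(counts)) {
        abort(sprintf("no shared sites between %s and %s",
                      rownames(aln)[i], rownames(aln)[j]))
      }
      d[i, j] <- d[j, i] <- jtt_distance_from_counts(counts, t_max, tol)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration on the Q-criterion. Negative
#' branch-length estimates are clamped to zero; ties in Q are broken by the
#' lexicographically smallest pair of cluster representatives (each
#' cluster's smallest taxon label), making the result independent of input
#' ordering. Two taxa yield a two-edge tree whose path length equals their
#' distance; three taxa the closed-form star.
#'
#' @param dm Symmetric non-negative matrix with zero diagonal and taxa ids
#'   as dimnames (or a [stats::dist] object).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  if (is.null(rownames(dm))) abort("distance matrix needs taxa dimnames")
  if (max(abs(dm - t(dm))) > 1e-8) abort("distance matrix is not symmetric")
  n <- nrow(dm)
  if (n < 2L) abort("need at least 2 taxa")
  lab <- rownames(dm)
  bl <- function(x) sprintf("%.15g", max(0, x))
  if (n == 2L) {
    return(ape::read.tree(text = sprintf("(%s:%s,%s:%s);",
      lab[1], bl(dm[1, 2] / 2), lab[2], bl(dm[1, 2] / 2))))
  }
  node <- lab          # growing newick fragment per active cluster
  rep_lab <- lab       # smallest leaf label per cluster, for tie-breaking
  d <- dm
  m <- n
  while (m > 3L) {
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    qmin <- min(q)
    cand <- which(q - qmin < 1e-12, arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pr <- sort(c(rep_lab[cand[k, 1]], rep_lab[cand[k, 2]]))
      paste(pr, collapse = "\r")
    }, "")
    pick <- cand[order(key)[1L], ]
    u <- pick[[1]]; v <- pick[[2]]
    bu <- d[u, v] / 2 + (r[u] - r[v]) / (2 * (m - 2))
    bv <- d[u, v] - bu
    merged <- sprintf("(%s:%s,%s:%s)", node[u], bl(bu), node[v], bl(bv))
    keep <- setdiff(seq_len(m), c(u, v))
    dk <- (d[u, keep] + d[v, keep] - d[u, v]) / 2
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dk), c(dk, 0))
    node <- c(node[keep], merged)
    rep_lab <- c(rep_lab[keep], min(rep_lab[c(u, v)]))
    m <- m - 1L
  }
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);",
                 node[1], bl(b1), node[2], bl(b2), node[3], bl(b3))
  ape::read.tree(text = txt)
}

#' Select conserved alignment blocks
#'
#' Automated stand-in for manual block curation: keeps columns whose gap
#' fraction is at most `max_gap_fraction` and whose top-residue rank (the
#' frequency of the most common residue among non-gap rows) is at least
#' `min_rank`, then drops runs of qualifying columns shorter than
#' `min_block_len`.
#'
#' @param aln Alignment matrix.
#' @param min_rank Minimum top-residue rank, in `[0, 1]`.
#' @param max_gap_fraction Maximum fraction of gap rows per column.
#' @param min_block_len Minimum run length of qualifying columns.
#' @return Strictly increasing integer vector of selected columns (possibly
#'   empty).
#' @export
select_conserved_blocks <- function(aln, min_rank = 0.5,
                                    max_gap_fraction = 0.2,
                                    min_block_len = 3L) {
  n <- nrow(aln)
  rank <- apply(aln, 2L, function(col) {
    res <- col[col != "-"]
    if (!length(res)) return(0)
    max(tabulate(factor(res, levels = c(AA_STANDARD, "X")))) / length(res)
  })
  gapfrac <- colMeans(aln == "-")
  ok <- rank >= min_rank & gapfrac <= max_gap_fraction
  runs <- rle(ok)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  sel <- integer(0)
  for (k in seq_along(runs$values)) {
    if (runs$values[k] && runs$lengths[k] >= min_block_len) {
      sel <- c(sel, seq.int(starts[k], ends[k]))
    }
  }
  sel
}

#' Neighbor-joining tree with bootstrap support
#'
#' Builds the point-estimate tree from the selected columns, then resamples
#' those columns with replacement `n_reps` times, recomputing JTT distances
#' and the NJ tree each time. Support for each internal edge of the point
#' tree is the percentage of effective replicates whose tree contains the
#' same bipartition. Replicates in which some pair has no comparable sites
#' are skipped and excluded from the denominator.
#'
#' @inheritParams jtt_distance_matrix
#' @param n_reps Number of bootstrap replicates (>= 1).
#' @param seed Optional integer seed; identical seeds give identical output.
#' @return An object of class `klhl_boot_tree`: a list with `tree` (the
#'   point-estimate `phylo`, support percentages in `node.label`),
#'   `support` (tibble of internal nodes), `n_reps`, `n_effective`,
#'   `skipped`.
#' @export
bootstrap_support <- function(aln, columns = NULL, n_reps = 100L,
                              seed = NULL, t_max = 10) {
  stopifnot(n_reps >= 1L)
  if (is.null(columns)) columns <- seq_len(ncol(aln))
  point <- neighbor_joining(jtt_distance_matrix(aln, columns, t_max = t_max))
  if (!is.null(seed)) set.seed(seed)
  reps <- vector("list", n_reps)
  skipped <- 0L
  for (r in seq_len(n_reps)) {
    cols_b <- sample(columns, length(columns), replace = TRUE)
    rep_tree <- tryCatch(
      neighbor_joining(jtt_distance_matrix(aln, cols_b, t_max = t_max)),
      error = function(e) {
        if (grepl("no shared sites", conditionMessage(e))) NULL else stop(e)
      })
    if (is.null(rep_tree)) skipped <- skipped + 1L else reps[r] <- list(rep_tree)
  }
  reps <- reps[!vapply(reps, is.null, TRUE)]
  n_eff <- length(reps)
  if (!n_eff) abort("all bootstrap replicates failed (no shared sites)")
  counts <- ape::prop.clades(point, reps, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  support <- as.integer(round(100 * counts / n_eff))
  point$node.label <- as.character(support)
  ntip <- length(point$tip.label)
  structure(list(
    tree = point,
    support = tibble(node = ntip + seq_len(point$Nnode), support = support),
    n_reps = as.integer(n_reps), n_effective = n_eff,
    skipped = skipped
  ), class = "klhl_boot_tree")
}

#' @export
print.klhl_boot_tree <- function(x, ...) {
  cat(sprintf(
    "<klhl_boot_tree> %d taxa, %d/%d effective bootstrap replicates\n",
    length(x$tree$tip.label), x$n_effective, x$n_reps))
  cat(sprintf("  internal-edge support: min %s, median %s\n",
              min(x$support$support[-1]), stats::median(x$support$support[-1])))
  invisible(x)
}

#' @describeIn bootstrap_support Tidy the per-node support table: one row
#'   per internal node with its support and the tips it subtends.
#' @param x A `klhl_boot_tree`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.klhl_boot_tree <- function(x, ...) {
  tr <- x$tree
  ntip <- length(tr$tip.label)
  tips <- vapply(x$support$node, function(nd) {
    paste(sort(ape::extract.clade(tr, nd)$tip.label), collapse = ",")
  }, "")
  mutate(x$support, n_tips = stringr::str_count(tips, ",") + 1L, tips = tips)
}

#' @describeIn bootstrap_support One-row summary of the bootstrap run.
#' @exportS3Method generics::glance
glance.klhl_boot_tree <- function(x, ...) {
  s <- x$support$support[-1]   # drop the trivial root "bipartition"
  tibble(n_taxa = length(x$tree$tip.label), n_reps = x$n_reps,
         n_effective = x$n_effective, skipped = x$skipped,
         min_support = min(s), median_support = stats::median(s))
}

#' Write a tree (optionally with supports) as Newick
#' @param tree A `phylo` or `klhl_boot_tree`; supports become internal node
#'   labels.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "klhl_boot_tree")) tree <- tree$tree
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An `ape::phylo`; internal node labels (bootstrap supports) are
#'   preserved.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
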